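# Delimited-text and JSON input/output.
#
# Traces and tables travel as plain delimited text with unit-bearing column
# names; models, configs and run manifests as JSON.

#' Write / read an arrival-time trace as delimited text
#'
#' Traces are written with columns `time_ms, intensity`; acquisition
#' metadata is carried in a single `#`-prefixed JSON header line.
#' `read_trace()` sniffs the delimiter (comma or tab) and restores the
#' metadata when present.
#'
#' @param trace An `im_trace`.
#' @param path File path.
#' @param sep Field separator for writing (default comma).
#' @return `write_trace()`: `path`, invisibly. `read_trace()`: an
#'   `im_trace`.
#' @export
write_trace <- function(trace, path, sep = ",") {
  stopifnot(inherits(trace, "im_trace"))
  meta <- trace$meta
  meta$warnings <- NULL
  header <- paste0("#", jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  writeLines(paste("time_ms", "intensity", sep = sep), con)
  writeLines(paste(formatC(trace$time_ms, digits = 15, format = "g"),
                   formatC(trace$intensity, digits = 15, format = "g"),
                   sep = sep), con)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  first <- readLines(path, n = 1)
  meta <- list()
  if (startsWith(first, "#")) {
    meta <- tryCatch(jsonlite::fromJSON(sub("^#", "", first)),
                     error = function(e) list())
  }
  dt <- data.table::fread(path, skip = if (startsWith(first, "#")) 1L else 0L,
                          header = TRUE)
  cols <- names(dt)
  tcol <- grep("^time", cols, value = TRUE)[1]
  icol <- grep("^intens", cols, value = TRUE)[1]
  if (is.na(tcol) || is.na(icol)) {
    stop("trace file must have time and intensity columns; found: ",
         paste(cols, collapse = ", "))
  }
  im_trace(dt[[tcol]], dt[[icol]], meta = as.list(meta))
}

#' Read a calibrant reference table
#'
#' Expects delimited text (delimiter sniffed) with columns `label`, `mz`,
#' `z`, `ccs_ref_a2` (or `ccs_ref`), and optionally `arrival_time_ms`.
#'
#' @param path File path.
#' @return A tibble; if arrival times are present, a full reference table
#'   via [reference_points()].
#' @export
read_calibrant_table <- function(path) {
  dt <- tibble::as_tibble(data.table::fread(path, header = TRUE))
  names(dt)[names(dt) == "ccs_ref"] <- "ccs_ref_a2"
  need <- c("label", "mz", "z", "ccs_ref_a2")
  miss <- setdiff(need, names(dt))
  if (length(miss)) {
    stop("calibrant table missing column(s): ", paste(miss, collapse = ", "))
  }
  if ("arrival_time_ms" %in% names(dt)) {
    reference_points(dt$label, dt$mz, dt$z, dt$arrival_time_ms, dt$ccs_ref_a2)
  } else {
    dt
  }
}

#' Write / read a calibration model as JSON
#'
#' @param model A `ccs_calibration`.
#' @param path File path.
#' @return `write_calibration()`: `path`, invisibly. `read_calibration()`:
#'   a `ccs_calibration`.
#' @export
write_calibration <- function(model, path) {
  stopifnot(inherits(model, "ccs_calibration"))
  payload <- list(kind = model$kind,
                  coefficients = as.list(model$coefficients),
                  valid_time_range = model$valid_time_range,
                  r2 = model$r2, monotone = model$monotone,
                  provenance = model$provenance,
                  points = as.data.frame(model$points))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  p <- jsonlite::fromJSON(path)
  structure(
    list(kind = p$kind, coefficients = unlist(p$coefficients),
         valid_time_range = as.numeric(p$valid_time_range),
         r2 = p$r2, monotone = isTRUE(p$monotone),
         points = tibble::as_tibble(p$points),
         provenance = as.list(p$provenance)),
    class = "ccs_calibration"
  )
}

#' Read a simulation/benchmark configuration file
#'
#' YAML (`.yml`/`.yaml`) or JSON. Recognized top-level blocks: `geometry`
#' (fields of [track_geometry()]), `wave` ([wave_config()]), `transport`
#' ([transport_params()]), `sim` (remaining [sim_config()] fields), `grid`
#' ([benchmark_grid()]). Any block may be omitted; defaults apply.
#'
#' @param path File path.
#' @return A list with elements `config` (a [sim_config()]) and `grid`
#'   (a [benchmark_grid()] or `NULL`).
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  geometry <- do.call(track_geometry, as.list(raw$geometry))
  wave <- do.call(wave_config, c(as.list(raw$wave), list(geometry = geometry)))
  transport <- do.call(transport_params, as.list(raw$transport))
  config <- do.call(sim_config, c(list(wave = wave, transport = transport),
                                  as.list(raw$sim)))
  grid <- if (!is.null(raw$grid)) do.call(benchmark_grid, as.list(raw$grid))
  list(config = config, grid = grid)
}
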