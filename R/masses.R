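#' Monoisotopic m/z of a peptide or elemental composition
#'
#' Computes the monoisotopic mass-to-charge ratio of the given analyte under
#' a chosen adduct. Peptide masses are the sum of residue masses plus one
#' water; elemental compositions are parsed from Hill-style formulas
#' (e.g. `"C18H32O16"`). Cation adducts account for the lost electron(s).
#'
#' @param x A peptide sequence in one-letter code (e.g. `"SDGRG"`) or an
#'   elemental composition (e.g. `"C57H92O6"`).
#' @param adduct One of `"+H"`, `"+2H"`, `"+Na"`, `"-2H"`.
#' @param z Charge count; defaults to the charge implied by the adduct and
#'   must match it when supplied.
#' @param type `"auto"` (default: a formula if the string contains a digit,
#'   else a peptide), `"peptide"`, or `"formula"`.
#' @return m/z in Th.
#' @examples
#' round(ion_mz("SDGRG", "+H"))       # 491
#' round(ion_mz("SDGRG", "+2H"))      # 246
#' round(ion_mz("C18H32O16", "+Na"))  # 527
#' @export
ion_mz <- function(x, adduct = "+H", z = NULL,
                   type = c("auto", "peptide", "formula")) {
  type <- match.arg(type)
  if (!adduct %in% names(.adducts)) {
    stop("unknown adduct '", adduct, "'; supported: ",
         paste(names(.adducts), collapse = ", "))
  }
  ad <- .adducts[[adduct]]
  if (is.null(z)) z <- ad$z
  if (z == 0) stop("`z` must be non-zero")
  if (z != ad$z) stop("adduct '", adduct, "' implies z = ", ad$z)
  m <- neutral_monoisotopic_mass(x, type)
  (m + ad$dm) / z
}

#' Monoisotopic neutral mass
#'
#' @inheritParams ion_mz
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' neutral_monoisotopic_mass("SDGRG")
#' @export
neutral_monoisotopic_mass <- function(x, type = c("auto", "peptide", "formula")) {
  type <- match.arg(type)
  stopifnot(is.character(x), length(x) == 1, nzchar(x))
  if (type == "auto") type <- if (grepl("[0-9]", x)) "formula" else "peptide"
  if (type == "peptide") {
    res <- strsplit(x, "")[[1]]
    unknown <- setdiff(res, names(.residue_mass))
    if (length(unknown)) {
      stop("unknown residue(s): ", paste(unique(unknown), collapse = ", "))
    }
    sum(.residue_mass[res]) + .water_Da
  } else {
    comp <- parse_formula(x)
    sum(.element_mass[names(comp)] * comp)
  }
}

#' @keywords internal
#' @noRd
parse_formula <- function(x) {
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", x)[[1]]
  parts <- regmatches(x, list(m))[[1]]
  parts <- parts[nzchar(parts)]
  if (!nzchar(gsub("([A-Z][a-z]?)([0-9]*)", "", x))) {
    els <- sub("^([A-Z][a-z]?).*", "\\1", parts)
    cnt <- sub("^[A-Z][a-z]?", "", parts)
    cnt <- ifelse(nzchar(cnt), as.numeric(cnt), 1)
    unknown <- setdiff(els, names(.element_mass))
    if (length(unknown)) {
      stop("unknown element(s): ", paste(unique(unknown), collapse = ", "))
    }
    counts <- tapply(cnt, els, sum)
    stats::setNames(as.numeric(counts), names(counts))
  } else {
    stop("cannot parse elemental composition: '", x, "'")
  }
}
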