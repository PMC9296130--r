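# Example simulation / benchmark configuration.
geometry:
  pad_pitch_mm: 1.125
  pads_per_cycle: 8
  path_length_m: 13
  board_gap_mm: 3
wave:
  waveform: sine
  amplitude_vpp: 40
  wave_speed_m_s: 180
transport:
  gas: N2
  gas_mass_da: 28.0134
  pressure_torr: 2.5
  temperature_k: 300
  t0_ms: 5
sim:
  sampling_interval_ms: 0.05
  noise: gaussian
  noise_scale: 0.01
  seed: 1
grid:
  wave_speeds_m_s: [45, 90, 135, 180, 225]
  amplitudes_vpp: [30, 35, 40]
  waveforms: [square, sine]
  replicates: 3
  seed: 1
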