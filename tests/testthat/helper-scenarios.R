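# shared fixtures: small, fast scenarios used across test files

fig1_scenario <- function(...) {
  scenario(omega1 = 0.1, s = 0.01, T = 1000, two_ne = 20000, ...)
}

# reduced grid resolution for tests that only need qualitative accuracy
fast_controls <- list(n_points = 200L)

table1_values <- function() {
  data.frame(
    omega1 = c(rep(0.01, 8), rep(0.05, 8)),
    s = rep(c(rep(0.001, 4), rep(0.01, 4)), 2),
    T = rep(c(50, 100, 500, 1000), 4),
    deterministic = c(
      0.0401907, 0.0200985, 0.00402525, 0.00201644,
      0.0402287, 0.02014, 0.00411598, 0.00227902,
      0.0419025, 0.0209646, 0.00421551, 0.00212356,
      0.0420981, 0.0211766, 0.00462923, 0.00286404),
    simulated = c(
      0.0417436, 0.0197123, 0.00407317, 0.00206252,
      0.0415686, 0.0202129, 0.00423004, 0.00237283,
      0.0427474, 0.0210069, 0.00428813, 0.00217073,
      0.0428456, 0.021438, 0.00470731, 0.00290033))
}

table4_sd_values <- function() {
  data.frame(
    omega1 = c(rep(0.01, 8), rep(0.05, 8)),
    s = rep(c(rep(0.001, 4), rep(0.01, 4)), 2),
    T = rep(c(50, 100, 500, 1000), 4),
    deterministic = c(
      0.028513, 0.014260, 0.002858, 0.001433,
      0.028534, 0.014283, 0.002904, 0.001548,
      0.029728, 0.014875, 0.002993, 0.001509,
      0.029834, 0.014989, 0.003196, 0.001835))
}
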