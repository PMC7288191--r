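# Independent oracles used across tests -- deliberately written as direct
# arithmetic, not via the package's own code paths.

# Hertz sphere modulus in MPa, evaluated entirely in SI units
hertz_E_si <- function(Zdefl_nm, h_nm, V = 0.5, k = 0.08, R_nm = 30) {
  F_N <- k * Zdefl_nm * 1e-9
  E_Pa <- 3 * (1 - V^2) * F_N / (4 * sqrt(R_nm * 1e-9) * (h_nm * 1e-9)^1.5)
  E_Pa / 1e6
}

# Hertz forward deflection in nm, evaluated entirely in SI units
hertz_zdefl_si <- function(E_MPa, h_nm, V = 0.5, k = 0.08, R_nm = 30) {
  4 * (E_MPa * 1e6) * sqrt(R_nm * 1e-9) * (h_nm * 1e-9)^1.5 /
    (3 * (1 - V^2) * k) / 1e-9
}

# a small leveled random map for property tests
random_map <- function(n = 32, seed = 1, pixel_size = 10) {
  set.seed(seed)
  level_height_map(height_map(matrix(rnorm(n * n), n, n), pixel_size))
}
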