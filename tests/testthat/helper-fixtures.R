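# Shared fixture builders for the suite.

# Deterministic alternating stripes: column 1 green.
stripes_pattern <- function(n = 6, m = 8) {
  retina_pattern(matrix(rep(rep(c(1L, 0L), length.out = m), each = n), n, m))
}

# Checkerboard (alternating in both directions).
checkerboard_pattern <- function(n = 6, m = 8) {
  retina_pattern(outer(seq_len(n), seq_len(m), function(i, j)
    as.integer((i + j) %% 2L)))
}

# Enumerate all 2^(n*m) binary patterns of a small lattice as a list.
all_patterns <- function(n, m) {
  lapply(0:(2^(n * m) - 1L), function(code) {
    matrix(as.integer(intToBits(code))[seq_len(n * m)], n, m)
  })
}

# The worked striped-eye constants (beta = 8, gamma = 10, X0 = 5, P0 = 1e-4).
worked_params <- function(...) retina_params(...)

# A small custom grid that keeps unit tests fast.
small_grid <- function() {
  parameter_grid(alpha_values = seq(0, 1, by = 0.1),
                 epsilon_values = c(0, 0.2, 0.4),
                 P0_values = c(0, 0.1), k_values = 1, fixed_mode_P0 = 0)
}
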