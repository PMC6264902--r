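test_that("threshold switch returns the correct branch, boundary inclusive", {
  p <- worked_params()
  expect_equal(default_probability(2.0008, p), 1e-4)
  expect_equal(default_probability(6, p), 0.9999)
  # boundary X == X0 belongs to the lower branch
  p2 <- retina_params(P0_structured = 0.3)
  expect_equal(default_probability(p2$X0, p2), 0.3)
  # vectorized
  expect_equal(default_probability(c(0, 10), p), c(1e-4, 0.9999))
})

test_that("X relay update is exact and the worked trajectory alternates", {
  p <- worked_params()
  expect_equal(update_X(0.9999, p), 2.0008)
  expect_equal(update_X(0, p), 10)
  expect_equal(update_X(1, p), 2)
  # full worked trajectory: above-threshold start, then period-2
  cd <- column_defaults(p, 5)
  expect_equal(cd$structured, c(0.9999, 1e-4, 0.9999, 1e-4, 0.9999))
  expect_equal(cd$x_trace[2:3], c(2.0008, 9.9992))
  # mode-parameterized params refuse X dynamics
  expect_error(update_X(0.5, mode_params("ar", 0.5)), "mode-parameterized")
})

test_that("regime classification follows fixed-point self-consistency", {
  expect_equal(as.character(classify_regime(worked_params())), "alternating")
  # both fixed points self-consistent: outcome depends on the initial X
  expect_equal(as.character(
    classify_regime(beta = 8, gamma = 10, X0 = 5, P0 = 0.7)), "bistable")
  # negative coupling, small P0: the uniform retina (initial color persists)
  expect_equal(as.character(
    classify_regime(beta = -8, gamma = 2, X0 = 5, P0 = 1e-4)), "bistable")
  # monostable cases
  expect_equal(as.character(
    classify_regime(beta = 8, gamma = 10, X0 = 12, P0 = 1e-4)), "fixed_low")
  expect_equal(as.character(
    classify_regime(beta = 8, gamma = 10, X0 = 1, P0 = 1e-4)), "fixed_high")
  # inadmissible threshold
  expect_equal(classify_regime(beta = 8, gamma = 10, X0 = -1, P0 = 0.1),
               "invalid")
  # mode parameterization implies its regime
  expect_equal(classify_regime(mode_params("fr", 0.5)), "fixed_low")
  expect_equal(classify_regime(mode_params("ag", 0.5)), "alternating")
})

test_that("mode defaults match their definition and the relay oracle", {
  p <- retina_params(P0_structured = 0.1)
  expect_equal(mode_column_default("fg", 1:8, p), rep(0.9, 8))
  expect_equal(mode_column_default("fr", 1:8, p), rep(0.1, 8))
  expect_equal(mode_column_default("ag", 1:4, p), c(0.9, 0.1, 0.9, 0.1))
  expect_equal(mode_column_default("ar", 1:4, p), c(0.1, 0.9, 0.1, 0.9))
  # inference constraint pins fixed-point modes to P0 = 0
  expect_equal(mode_column_default("fr", 1:3, p, inference_constraint = TRUE),
               rep(0, 3))
  # oracle: iterating the threshold switch + relay in an alternating regime
  # (beta = 8, gamma = 10, X0 = 5, P0 = 0.3 maps each default to the other)
  po <- retina_params(P0_structured = 0.3)
  m <- 12L
  X <- po$X_init
  traj <- numeric(m)
  for (j in seq_len(m)) {
    traj[j] <- default_probability(X, po)
    X <- update_X(traj[j], po)
  }
  expect_equal(mode_column_default("ag", seq_len(m), po), traj)
})

test_that("mistake correction has the stated kernel form and symmetries", {
  p <- retina_params(epsilon = 0.95, k = 1)
  # no mistakes -> default maintained
  expect_equal(mistake_correction(rep(0L, 10), 0.9999, p), rep(0, 10))
  # epsilon = 0 -> no correction even with mistakes
  p0 <- retina_params(epsilon = 0, k = 1)
  expect_equal(mistake_correction(c(1L, rep(0L, 9)), 0.9999, p0), rep(0, 10))
  # single green mistake in a red-majority column, green target column
  expect_equal(mistake_correction(c(1L, rep(0L, 9)), 0.9999, p, rows = 1),
               -0.949905)
  # independent loop-summation oracle for a multi-mistake column
  prev <- c(1L, 0L, 0L, 1L, 0L, 0L, 0L, 1L, 0L, 0L)
  pj <- 0.8
  maj <- 0L  # red majority
  oracle <- vapply(1:10, function(i) {
    s <- 0
    for (ip in which(prev != maj)) {
      s <- s + exp(-(i - ip)^2 / p$k) * ((1 - prev[ip]) - pj)
    }
    p$epsilon * s
  }, numeric(1))
  expect_equal(mistake_correction(prev, pj, p), oracle)
  # row-translation invariance and symmetry in |i - i'|
  n <- 15L
  base <- rep(0L, n)
  for (shift in 0:4) {
    col <- base; col[6 + shift] <- 1L
    l <- mistake_correction(col, 0.9, p)
    expect_equal(l, mistake_correction(base_shifted <- col, 0.9, p))
    expect_equal(l[6 + shift - 3], l[6 + shift + 3])  # symmetric in distance
  }
})

test_that("full probability clips into [0, 1]", {
  expect_equal(full_probability(0.9999, 0), 0.9999)
  expect_equal(full_probability(0.9999, -0.949905), 0.049995)
  expect_equal(full_probability(0.9, 0.5), 1)
  expect_equal(full_probability(0.1, -0.5), 0)
})

test_that("mixture interpolates between components", {
  expect_equal(mixture_probability(0.42, retina_params(alpha = 1)), 0.42)
  p0 <- retina_params(alpha = 0, P0_droso = 0.35)
  expect_equal(mixture_probability(0.42, p0), 0.65)
  expect_equal(
    mixture_probability(0.9999, retina_params(alpha = 0.5, P0_droso = 0.35)),
    0.82495)
})

test_that("all model probabilities stay in [0, 1] over random parameters", {
  set.seed(101)
  for (rep in 1:50) {
    p <- retina_params(alpha = runif(1), beta = runif(1, -10, 10),
                       gamma = runif(1, 0.1, 12), X0 = runif(1, 0, 10),
                       P0_structured = runif(1), P0_droso = runif(1),
                       epsilon = runif(1), k = runif(1, 0.5, 25))
    cd <- column_defaults(p, 10)
    expect_true(all(cd$structured >= 0 & cd$structured <= 1))
    pm <- mixture_probability(cd$structured, p)
    expect_true(all(pm >= 0 & pm <= 1))
    prev <- sample(0:1, 12, replace = TRUE)
    pf <- full_probability(pm[2], mistake_correction(prev, pm[2], p))
    expect_true(all(pf >= 0 & pf <= 1))
  }
})

test_that("parameter validation rejects out-of-range values", {
  expect_error(retina_params(alpha = 1.2), "alpha")
  expect_error(retina_params(gamma = -1), "gamma")
  expect_error(retina_params(X0 = -0.5), "X0")
  expect_error(retina_params(k = 0), "k")
  expect_error(retina_params(mode = "ar", beta = 8), "not both")
  expect_error(retina_params(mode = "xx"))
})
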