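test_that("grid presets carry the reference discretizations", {
  g <- parameter_grid("simulated")
  expect_equal(g$alpha_values, seq(0, 1, by = 0.01))
  expect_equal(g$epsilon_values, seq(0, 0.5, by = 0.1))
  expect_equal(g$P0_values, c(0, 0.1))
  expect_equal(g$k_values, 1)
  co <- grid_combos(g)
  # fixed-point modes are pinned to P0 = 0
  expect_true(all(co$P0[co$mode %in% c("fr", "fg")] == 0))
  expect_equal(nrow(co), 2 * 101 * 6 * 1 + 2 * 101 * 6 * 2)

  gr <- parameter_grid("real_data")
  expect_equal(gr$P0_values, c(0.01, 0.02, 0.04, 0.08, 0.16))
  expect_equal(gr$k_values, (1:25)^2)
  expect_equal(max(gr$k_values), 625)
  expect_null(gr$fixed_mode_P0)
})

test_that("grid combinations are enumerated in lexicographic order", {
  g <- small_grid()
  co <- grid_combos(g)
  key <- order(match(co$mode, c("fr", "fg", "ar", "ag")), co$alpha,
               co$epsilon, co$P0, co$k)
  expect_equal(key, seq_len(nrow(co)))
})

test_that("inference recovers a pure striped pattern with matching phase", {
  pat <- simulate_retina(retina_params(alpha = 1, P0_structured = 0),
                         20, 30, seed = 6)$pattern
  fit <- infer_pattern(pat, small_grid())
  expect_equal(fit$best_params$mode, "ag")  # column 1 is green
  expect_equal(fit$best_params$alpha, 1)
  expect_equal(fit$log_likelihood, 0)
  # a deterministic fit ties across epsilon (no mistakes to calibrate on);
  # the tie-break keeps the first grid point and reports the rest
  expect_true(nrow(fit$ties) >= 2)
  expect_equal(fit$best_params$epsilon, 0)
})

test_that("a red-dominated pattern is assigned the red fixed point", {
  set.seed(13)
  pat <- matrix(rbinom(30 * 50, 1, 0.06), 30, 50)
  fit <- infer_pattern(pat, small_grid())
  expect_equal(fit$best_params$mode, "fr")
  expect_gt(fit$best_params$alpha, 0.8)
})

test_that("self-consistency: inference concentrates near the truth", {
  truth <- mode_params("ar", alpha = 0.7, epsilon = 0.4, P0 = 0.1)
  pat <- simulate_retina(truth, 30, 50, seed = 14)$pattern
  fit <- infer_pattern(pat, small_grid())
  expect_equal(fit$best_params$mode, "ar")
  expect_lt(abs(fit$best_params$alpha - 0.7), 0.15)
  expect_lt(abs(fit$best_params$epsilon - 0.4), 0.25)
})

test_that("the fast surface equals the general likelihood on every point", {
  set.seed(9)
  pat <- simulate_retina(mode_params("ag", 0.6, 0.4, 0.1), 8, 11)$pattern
  g <- parameter_grid(alpha_values = c(0, 0.33, 0.8),
                      epsilon_values = c(0, 0.2, 0.5),
                      P0_values = c(0, 0.1), k_values = c(1, 4),
                      fixed_mode_P0 = 0)
  surf <- infer_pattern(pat, g)$surface
  direct <- mapply(function(md, al, ep, P0, kv)
    log_likelihood(pat, mode_params(md, al, ep, P0, kv)),
    surf$mode, surf$alpha, surf$epsilon, surf$P0, surf$k)
  expect_equal(unname(surf$log_likelihood), unname(direct))
})

test_that("tied-majority columns are handled identically in both paths", {
  # an even-row pattern engineered to contain exact 50/50 columns
  a <- cbind(rep(1L, 4), c(1L, 1L, 0L, 0L), rep(0L, 4), c(0L, 1L, 0L, 1L))
  for (p in list(mode_params("ag", 0.6, 0.3, 0.1),
                 mode_params("fr", 0.4, 0.5, 0))) {
    g <- parameter_grid(alpha_values = p$alpha, epsilon_values = p$epsilon,
                        P0_values = p$P0_structured, k_values = p$k,
                        mode_values = p$mode, fixed_mode_P0 = NULL)
    expect_equal(infer_pattern(pat <- retina_pattern(a), g)$log_likelihood,
                 log_likelihood(pat, p))
  }
})

test_that("recovery experiment aggregates truth vs estimate", {
  g <- parameter_grid(alpha_values = seq(0, 1, 0.25),
                      epsilon_values = c(0, 0.3), P0_values = c(0, 0.1),
                      k_values = 1, fixed_mode_P0 = 0)
  rep1 <- recovery_experiment(1, n_rows = 10, n_cols = 12, grid = g,
                              seed = 3)
  expect_equal(nrow(rep1$realizations), 1L)
  rep20 <- recovery_experiment(20, n_rows = 15, n_cols = 20, grid = g,
                               seed = 5)
  expect_equal(sum(rep20$by_alpha$n), 20L)
  expect_true(all(rep20$by_alpha$err_alpha >= 0, na.rm = TRUE))
  expect_equal(sum(rep20$epsilon_curve$n), 20L)
  # identical seed reproduces the report exactly
  rep20b <- recovery_experiment(20, n_rows = 15, n_cols = 20, grid = g,
                                seed = 5)
  expect_identical(rep20$realizations, rep20b$realizations)
})

test_that("spearman permutation matches exhaustive enumeration", {
  x <- c(3, 1, 4, 1.5, 9)
  y <- c(2, 7, 1, 8, 2.8)
  res <- spearman_permutation(x, y, exact = TRUE)
  expect_equal(res$rho, cor(x, y, method = "spearman"))
  # independent oracle: enumerate all 120 permutations by recursion over
  # insertion positions (distinct from the implementation's generator)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (q in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], q)
    }
    out
  }
  rhos <- vapply(perms(y), function(yy) cor(x, yy, method = "spearman"),
                 numeric(1))
  expect_equal(res$p_value, mean(abs(rhos) >= abs(res$rho) - 1e-12))
  expect_equal(res$n_permutations, 120L)
  # the Monte Carlo estimate agrees within sampling error and is positive
  mc <- spearman_permutation(x, y, n_permutations = 2000, seed = 1)
  expect_gt(mc$p_value, 0)
  expect_lt(abs(mc$p_value - res$p_value), 0.05)
})

test_that("spearman handles monotone, constant and mismatched input", {
  expect_equal(spearman_permutation(1:6, (1:6)^2, n_permutations = 10,
                                    seed = 1)$rho, 1)
  expect_equal(spearman_permutation(1:6, -(1:6)^3, n_permutations = 10,
                                    seed = 1)$rho, -1)
  expect_warning(res <- spearman_permutation(1:5, rep(2, 5)), "constant")
  expect_true(is.na(res$rho))
  expect_error(spearman_permutation(1:4, 1:5), "equal length")
  expect_error(spearman_permutation(1:2, 2:1), "at least 3")
})
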