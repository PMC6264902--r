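#' Discrete parameter grid for maximum-likelihood inference
#'
#' Defines the finite parameter space searched by [infer_pattern()]:
#' modes, mixing weights, speckle correlation coefficients, the shared
#' default-probability constant and the spatial range. Two presets mirror
#' two reference discretizations:
#' \itemize{
#'   \item `"simulated"` — the recovery-study grid: all four modes,
#'     `alpha` in steps of 0.01, `epsilon` in `{0, 0.1, ..., 0.5}`,
#'     `P0` in `{0, 0.1}`, `k = 1`; fixed-point modes are constrained to
#'     `P0 = 0` (`alpha` and `P0` are interdependent there).
#'   \item `"real_data"` — the image-analysis grid: `alpha` in
#'     `{0.01, ..., 0.99}`, `P0` in `{0.01, 0.02, 0.04, 0.08, 0.16}`,
#'     `epsilon` in `{0, 0.001, ..., 0.010}`, `k` over perfect squares
#'     `1, 4, 9, ..., 625`; no fixed-mode constraint.
#' }
#'
#' @param preset `"simulated"`, `"real_data"`, or `NULL` to specify every
#'   component explicitly.
#' @param mode_values Subset of `c("fr", "fg", "ar", "ag")`, in search
#'   order.
#' @param alpha_values,epsilon_values,P0_values,k_values Ordered numeric
#'   grids within the legal parameter ranges.
#' @param fixed_mode_P0 Either a single `P0` value to which fixed-point
#'   modes are pinned, or `NULL` to let them range over `P0_values`.
#' @return An object of class `parameter_grid`.
#' @examples
#' parameter_grid("simulated")
#' parameter_grid(alpha_values = seq(0, 1, 0.1), epsilon_values = c(0, 0.3),
#'                P0_values = 0, k_values = 1)
#' @export
parameter_grid <- function(preset = NULL,
                           mode_values = c("fr", "fg", "ar", "ag"),
                           alpha_values = seq(0, 1, by = 0.01),
                           epsilon_values = seq(0, 0.5, by = 0.1),
                           P0_values = c(0, 0.1),
                           k_values = 1,
                           fixed_mode_P0 = 0) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("simulated", "real_data"))
    if (preset == "real_data") {
      alpha_values <- seq(0.01, 0.99, by = 0.01)
      epsilon_values <- seq(0, 0.010, by = 0.001)
      P0_values <- c(0.01, 0.02, 0.04, 0.08, 0.16)
      k_values <- (1:25)^2
      fixed_mode_P0 <- NULL
    }
  }
  stopifnot(length(mode_values) >= 1, all(mode_values %in% MODES),
            !anyDuplicated(mode_values),
            length(alpha_values) >= 1,
            all(alpha_values >= 0 & alpha_values <= 1),
            length(epsilon_values) >= 1,
            all(epsilon_values >= 0 & epsilon_values <= 1),
            length(P0_values) >= 1,
            all(P0_values >= 0 & P0_values <= 1),
            length(k_values) >= 1, all(k_values > 0))
  if (!is.null(fixed_mode_P0))
    stopifnot(length(fixed_mode_P0) == 1L,
              fixed_mode_P0 >= 0, fixed_mode_P0 <= 1)
  structure(
    list(mode_values = mode_values, alpha_values = alpha_values,
         epsilon_values = epsilon_values, P0_values = P0_values,
         k_values = k_values, fixed_mode_P0 = fixed_mode_P0),
    class = "parameter_grid"
  )
}

#' @export
print.parameter_grid <- function(x, ...) {
  cat("<parameter_grid>\n")
  cat(sprintf("  modes: %s\n", paste(x$mode_values, collapse = ", ")))
  cat(sprintf("  alpha: %d values in [%g, %g]\n", length(x$alpha_values),
              min(x$alpha_values), max(x$alpha_values)))
  cat(sprintf("  epsilon: {%s}\n", paste(x$epsilon_values, collapse = ", ")))
  cat(sprintf("  P0: {%s}%s\n", paste(x$P0_values, collapse = ", "),
              if (is.null(x$fixed_mode_P0)) ""
              else sprintf(" (fixed-point modes pinned to P0 = %g)",
                           x$fixed_mode_P0)))
  cat(sprintf("  k: {%s}\n", paste(x$k_values, collapse = ", ")))
  cat(sprintf("  %d eligible combinations\n", nrow(grid_combos(x))))
  invisible(x)
}

#' Enumerate the eligible parameter combinations of a grid
#'
#' Combinations are listed in the deterministic lexicographic search
#' order (mode, alpha, epsilon, P0, k) used for tie-breaking.
#'
#' @param grid A [parameter_grid()].
#' @return A data frame with columns `mode`, `alpha`, `epsilon`, `P0`,
#'   `k`.
#' @export
grid_combos <- function(grid) {
  stopifnot(inherits(grid, "parameter_grid"))
  blocks <- lapply(grid$mode_values, function(md) {
    P0v <- if (is_fixed_mode(md) && !is.null(grid$fixed_mode_P0))
      grid$fixed_mode_P0 else grid$P0_values
    g <- expand.grid(k = grid$k_values, P0 = P0v,
                     epsilon = grid$epsilon_values,
                     alpha = grid$alpha_values,
                     KEEP.OUT.ATTRS = FALSE)
    data.frame(mode = md, alpha = g$alpha, epsilon = g$epsilon,
               P0 = g$P0, k = g$k, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}

## Fast evaluation of the log-likelihood over every grid combination.
## Shares the model definition with site_probabilities() (verified against
## it in the test suite) but precomputes, per spatial range k, the kernel
## row-sums over each column's mistakes so that the per-combination cost is
## a handful of dense matrix operations.
likelihood_surface <- function(pattern, grid, floor_prob = 0) {
  a <- as_retina_pattern(pattern)
  combos <- grid_combos(grid)
  n <- nrow(a); m <- ncol(a)
  n1 <- colSums(a)
  maj_data <- ifelse(2 * n1 > n, 1L, ifelse(2 * n1 < n, 0L, NA_integer_))
  tied <- is.na(maj_data)
  green <- a == 1L

  ## kernel sums feeding column j from the mistakes of column j - 1;
  ## tied predecessors get both majority variants
  pre <- lapply(unique(combos$k), function(kv) {
    s0 <- matrix(0, n, m)
    s0g <- s0r <- matrix(0, n, m)
    for (j in seq_len(m - 1L) + 1L) {
      jp <- j - 1L
      if (!tied[jp]) {
        s0[, j] <- kernel_sums(n, which(a[, jp] != maj_data[jp]), kv)
      } else {
        s0g[, j] <- kernel_sums(n, which(a[, jp] != 1L), kv)
        s0r[, j] <- kernel_sums(n, which(a[, jp] != 0L), kv)
      }
    }
    list(s0 = s0, s0g = s0g, s0r = s0r)
  })
  names(pre) <- as.character(unique(combos$k))
  tie_fed <- which(tied[seq_len(max(m - 1L, 0L))]) + 1L  # columns after a tie

  mode_prev <- ""; P0_prev <- -1; s <- NULL
  ll <- numeric(nrow(combos))
  for (i in seq_len(nrow(combos))) {
    md <- combos$mode[i]; al <- combos$alpha[i]; ep <- combos$epsilon[i]
    P0 <- combos$P0[i]; kv <- combos$k[i]
    if (md != mode_prev || P0 != P0_prev) {
      s <- switch(md,
                  fr = rep(P0, m), fg = rep(1 - P0, m),
                  ag = ifelse(seq_len(m) %% 2 == 1, 1 - P0, P0),
                  ar = ifelse(seq_len(m) %% 2 == 1, P0, 1 - P0))
      mode_prev <- md; P0_prev <- P0
    }
    p_mix <- al * s + (1 - al) * (1 - DROSO_P0_REF)
    if (ep > 0 && m > 1L) {
      maj <- maj_data
      if (length(tie_fed))
        maj[tie_fed - 1L] <- as.integer(p_mix[tie_fed - 1L] >= 0.5)
      s0 <- pre[[as.character(kv)]]$s0
      for (j in tie_fed) {
        s0[, j] <- if (maj[j - 1L] == 1L) pre[[as.character(kv)]]$s0g[, j]
                   else pre[[as.character(kv)]]$s0r[, j]
      }
      # corrected structured component, then the mixture
      d <- matrix(s, n, m, byrow = TRUE)
      scale <- ep * (maj[seq_len(m - 1L)] - s[-1L])
      d[, -1L] <- d[, -1L] + s0[, -1L, drop = FALSE] * rep(scale, each = n)
      d <- pmin(1, pmax(0, d))
      prob <- al * d + (1 - al) * (1 - DROSO_P0_REF)
    } else {
      prob <- matrix(p_mix, n, m, byrow = TRUE)
    }
    if (floor_prob > 0)
      prob <- pmin(pmax(prob, floor_prob), 1 - floor_prob)
    lik <- prob
    lik[!green] <- 1 - prob[!green]
    ll[i] <- sum(log(lik))
  }
  cbind(combos, log_likelihood = ll)
}

#' Grid-search maximum-likelihood inference of model parameters
#'
#' Evaluates the exact log-likelihood of the pattern at every eligible
#' parameter combination of the grid and returns the maximizer. Ties
#' (within `tie_tol`) are broken deterministically in favor of the first
#' combination in lexicographic grid order (mode, alpha, epsilon, P0, k)
#' and reported.
#'
#' @param pattern A [retina_pattern()] or plain binary matrix.
#' @param grid A [parameter_grid()].
#' @param floor_prob Probability floor passed to the likelihood (see
#'   [log_likelihood()]); default 0.
#' @param tie_tol Log-likelihood slack within which combinations count as
#'   tied with the maximum.
#' @return An object of class `inference_result`: `best_params` (a
#'   mode-parameterized [retina_params()]), `log_likelihood`, `surface`
#'   (data frame of every combination with its log-likelihood), `ties`
#'   (co-maximal combinations, in grid order) and `best_index`.
#' @examples
#' pat <- simulate_retina(mode_params("ag", alpha = 1), 10, 12, seed = 1)$pattern
#' g <- parameter_grid(alpha_values = seq(0, 1, 0.25), epsilon_values = 0,
#'                     P0_values = c(0, 0.1), k_values = 1)
#' infer_pattern(pat, g)$best_params$alpha  # 1
#' @export
infer_pattern <- function(pattern, grid, floor_prob = 0, tie_tol = 1e-8) {
  stopifnot(inherits(grid, "parameter_grid"))
  surface <- likelihood_surface(pattern, grid, floor_prob)
  ll <- surface$log_likelihood
  if (!any(is.finite(ll)))
    stop("every grid combination has zero likelihood; consider `floor_prob`",
         call. = FALSE)
  best <- which.max(ll)  # first maximum = lexicographic tie-break
  ties <- which(is.finite(ll) & ll >= ll[best] - tie_tol)
  structure(
    list(best_params = mode_params(surface$mode[best], surface$alpha[best],
                                   surface$epsilon[best], surface$P0[best],
                                   surface$k[best]),
         log_likelihood = ll[best],
         best_index = best,
         ties = surface[ties, , drop = FALSE],
         surface = surface),
    class = "inference_result"
  )
}

#' @export
print.inference_result <- function(x, ...) {
  b <- x$surface[x$best_index, ]
  cat("<inference_result>\n")
  cat(sprintf(
    "  ML estimate: mode = %s, alpha = %g, epsilon = %g, P0 = %g, k = %g\n",
    b$mode, b$alpha, b$epsilon, b$P0, b$k))
  cat(sprintf("  log-likelihood: %.4f  (%d grid points, %d tied)\n",
              x$log_likelihood, nrow(x$surface), nrow(x$ties)))
  invisible(x)
}

#' Parameter-recovery experiment on simulated patterns
#'
#' For each realization: draw a true parameter combination uniformly at
#' random from the grid's eligible combinations, simulate a pattern,
#' re-infer the parameters by grid-search maximum likelihood, and record
#' truth and estimate. Errors are aggregated in bins of the true mixing
#' weight; the inferred-vs-true curves for `alpha` and `epsilon`
#' summarize estimator calibration.
#'
#' @param n_realizations Number of independent realizations (>= 1).
#' @param n_rows,n_cols Lattice dimensions of each simulated pattern.
#' @param grid A [parameter_grid()]; defaults to the `"simulated"` preset.
#' @param seed Optional integer seed for the whole experiment.
#' @param alpha_bins Breakpoints for binning the true mixing weight.
#' @return An object of class `recovery_report`: `realizations` (one row
#'   per realization with true and inferred values), `by_alpha` (per-bin
#'   mean absolute errors of `alpha`, `epsilon`, `P0`, the mode mismatch
#'   rate, and mean true/inferred `alpha`), and `epsilon_curve` (mean
#'   inferred `epsilon` per true value).
#' @examples
#' g <- parameter_grid(alpha_values = c(0, 0.5, 1), epsilon_values = c(0, 0.3),
#'                     P0_values = c(0, 0.1), k_values = 1)
#' recovery_experiment(3, n_rows = 10, n_cols = 12, grid = g, seed = 1)
#' @export
recovery_experiment <- function(n_realizations, n_rows = 30, n_cols = 50,
                                grid = parameter_grid("simulated"),
                                seed = NULL,
                                alpha_bins = seq(0, 1, by = 0.1)) {
  stopifnot(is.numeric(n_realizations), n_realizations >= 1,
            inherits(grid, "parameter_grid"))
  n_realizations <- as.integer(n_realizations)
  if (!is.null(seed)) set.seed(seed)
  combos <- grid_combos(grid)

  rows <- vector("list", n_realizations)
  for (r in seq_len(n_realizations)) {
    tr <- combos[sample.int(nrow(combos), 1L), ]
    th <- mode_params(tr$mode, tr$alpha, tr$epsilon, tr$P0, tr$k)
    pat <- simulate_retina(th, n_rows, n_cols)$pattern
    fit <- infer_pattern(pat, grid)
    est <- fit$surface[fit$best_index, ]
    rows[[r]] <- data.frame(
      true_mode = tr$mode, true_alpha = tr$alpha, true_epsilon = tr$epsilon,
      true_P0 = tr$P0, true_k = tr$k,
      inf_mode = est$mode, inf_alpha = est$alpha, inf_epsilon = est$epsilon,
      inf_P0 = est$P0, inf_k = est$k,
      log_likelihood = fit$log_likelihood, n_ties = nrow(fit$ties),
      stringsAsFactors = FALSE)
  }
  real <- do.call(rbind, rows)

  bin <- cut(real$true_alpha, breaks = alpha_bins, include.lowest = TRUE)
  agg <- function(v) as.vector(tapply(v, bin, mean))
  by_alpha <- data.frame(
    alpha_bin = levels(bin),
    n = as.vector(table(bin)),
    mean_true_alpha = agg(real$true_alpha),
    mean_inf_alpha = agg(real$inf_alpha),
    err_alpha = agg(abs(real$inf_alpha - real$true_alpha)),
    err_mode = agg(as.numeric(real$inf_mode != real$true_mode)),
    err_epsilon = agg(abs(real$inf_epsilon - real$true_epsilon)),
    err_P0 = agg(abs(real$inf_P0 - real$true_P0)),
    stringsAsFactors = FALSE)

  eb <- factor(real$true_epsilon)
  epsilon_curve <- data.frame(
    true_epsilon = as.numeric(levels(eb)),
    n = as.vector(table(eb)),
    mean_inf_epsilon = as.vector(tapply(real$inf_epsilon, eb, mean)))

  structure(
    list(realizations = real, by_alpha = by_alpha,
         epsilon_curve = epsilon_curve,
         n_realizations = n_realizations, seed = seed,
         size = c(n_rows = n_rows, n_cols = n_cols)),
    class = "recovery_report"
  )
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report> %d realizations at %d x %d\n",
              x$n_realizations, x$size["n_rows"], x$size["n_cols"]))
  print(x$by_alpha, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Spearman rank correlation with a permutation p-value
#'
#' Computes Spearman's rho (average ranks for ties) and a two-sided
#' permutation p-value: the fraction of permutations of `y` whose
#' absolute rank correlation with `x` is at least the observed one. The
#' identity permutation is always included in the count, so the p-value
#' is strictly positive.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @param n_permutations Number of random permutations (ignored when
#'   `exact = TRUE`).
#' @param seed Optional integer seed for the permutation draws.
#' @param exact If `TRUE`, enumerate all `length(x)!` permutations
#'   (allowed up to length 8).
#' @return An object of class `rank_correlation`: `rho`, `p_value`,
#'   `n_permutations`, `exact`. A constant input yields `rho = NA` with a
#'   warning.
#' @examples
#' spearman_permutation(1:6, c(2, 1, 4, 3, 6, 5), exact = TRUE)
#' @export
spearman_permutation <- function(x, y, n_permutations = 10000, seed = NULL,
                                 exact = FALSE) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) stop("`x` and `y` must have equal length",
                                   call. = FALSE)
  n <- length(x)
  if (n < 3) stop("need at least 3 observations", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    warning("constant input: rank correlation undefined")
    return(structure(list(rho = NA_real_, p_value = NA_real_,
                          n_permutations = 0L, exact = exact),
                     class = "rank_correlation"))
  }
  rho <- stats::cor(x, y, method = "spearman")
  tol <- 1e-12
  if (exact) {
    if (n > 8) stop("exact enumeration limited to length <= 8",
                    call. = FALSE)
    perms <- all_permutations(n)
    rhos <- apply(perms, 1L, function(p)
      stats::cor(x, y[p], method = "spearman"))
    p_value <- mean(abs(rhos) >= abs(rho) - tol)
    n_used <- nrow(perms)
  } else {
    stopifnot(n_permutations >= 1)
    if (!is.null(seed)) set.seed(seed)
    hits <- 0L
    for (b in seq_len(n_permutations)) {
      if (abs(stats::cor(x, sample(y), method = "spearman")) >=
          abs(rho) - tol) hits <- hits + 1L
    }
    p_value <- (hits + 1L) / (n_permutations + 1L)  # identity included
    n_used <- as.integer(n_permutations)
  }
  structure(list(rho = rho, p_value = p_value, n_permutations = n_used,
                 exact = exact),
            class = "rank_correlation")
}

#' @export
print.rank_correlation <- function(x, ...) {
  cat(sprintf("Spearman rho = %.3f, permutation P = %.4g (%s%d permutations)\n",
              x$rho, x$p_value, if (x$exact) "all " else "", x$n_permutations))
  invisible(x)
}

## All permutations of 1:n as an n! x n matrix, in lexicographic order.
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(first) {
    rest <- seq_len(n)[-first]
    cbind(first, matrix(rest[sub], nrow(sub)))
  }))
}
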