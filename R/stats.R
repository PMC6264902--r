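#' Column color labels and mistake mask
#'
#' Labels every column by its majority color — a G column is one where
#' most ommatidia are green (1), an R column where most are red (0) — and
#' marks minority elements as mistakes. Exact 50/50 ties are labeled by
#' continuing the alternation phase implied by the nearest unambiguous
#' column (preferring the posterior side) and flagged as ambiguous; a
#' pattern in which every column is tied falls back to alternation
#' starting green at column 1.
#'
#' @param pattern A [retina_pattern()] or plain binary matrix.
#' @return A list with `labels` (`"G"`/`"R"` per column), `majority`
#'   (0/1 per column), `ambiguous` (logical per column), `mistakes`
#'   (logical matrix) and `mistakes_per_column` (integer).
#' @examples
#' pat <- retina_pattern(cbind(rep(1L, 4), c(0L, 0L, 0L, 1L)))
#' column_labels_and_mistakes(pat)$mistakes_per_column  # 0 1
#' @export
column_labels_and_mistakes <- function(pattern) {
  a <- as_retina_pattern(pattern)
  n <- nrow(a); m <- ncol(a)
  n1 <- unname(colSums(a))
  maj <- ifelse(2 * n1 > n, 1L, ifelse(2 * n1 < n, 0L, NA_integer_))
  amb <- is.na(maj)
  if (any(amb)) {
    resolved <- which(!amb)
    if (length(resolved) == 0L) {
      maj <- as.integer(seq_len(m) %% 2L)  # alternate, green at column 1
    } else {
      for (j in which(amb)) {
        anchor <- resolved[which.min(abs(resolved - j))]
        d <- abs(j - anchor)
        maj[j] <- if (d %% 2L == 1L) 1L - maj[anchor] else maj[anchor]
      }
    }
  }
  mist <- a != matrix(maj, n, m, byrow = TRUE)
  list(labels = c("R", "G")[maj + 1L], majority = maj, ambiguous = amb,
       mistakes = mist, mistakes_per_column = colSums(mist))
}

corr_or_na <- function(x, y) {
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Horizontal (inter-column) correlation coefficient
#'
#' Lag-1 Pearson correlation between horizontally adjacent site pairs,
#' pooled over all rows and column pairs: `cor({a_ij}, {a_i,j+1})`. It is
#' -1 for perfect alternating stripes, ~0 for an iid mosaic, and undefined
#' (`NA`) when either pooled vector is constant — which distinguishes the
#' uniform retina from the random one.
#'
#' @param pattern A [retina_pattern()] or plain binary matrix with at
#'   least two columns.
#' @return A single correlation value in `[-1, 1]`, or `NA` if undefined.
#' @examples
#' stripes <- retina_pattern(matrix(rep(c(1L, 0L), each = 4, times = 3), 4))
#' horizontal_correlation(stripes)  # -1
#' @export
horizontal_correlation <- function(pattern) {
  a <- as_retina_pattern(pattern)
  if (ncol(a) < 2L)
    stop("horizontal correlation needs at least 2 columns", call. = FALSE)
  corr_or_na(as.vector(a[, -ncol(a)]), as.vector(a[, -1L]))
}

#' Vertical (intra-column) correlation coefficient
#'
#' Lag-1 Pearson correlation between vertically adjacent site pairs,
#' `cor({a_ij}, {a_i+1,j})`, pooled over all valid pairs. `NA` when
#' undefined (constant input).
#'
#' @param pattern A [retina_pattern()] or plain binary matrix with at
#'   least two rows.
#' @return A single correlation value in `[-1, 1]`, or `NA` if undefined.
#' @export
vertical_correlation <- function(pattern) {
  a <- as_retina_pattern(pattern)
  if (nrow(a) < 2L)
    stop("vertical correlation needs at least 2 rows", call. = FALSE)
  corr_or_na(as.vector(a[-nrow(a), ]), as.vector(a[-1L, ]))
}

#' Summary statistics of a retina pattern
#'
#' @param pattern A [retina_pattern()] or plain binary matrix.
#' @return A list of class `correlation_stats`: `R_h`, `R_v` (lag-1
#'   correlations, `NA` when undefined), `green_fraction`,
#'   `mistakes_per_column`, `labels` and `ambiguous` from
#'   [column_labels_and_mistakes()].
#' @examples
#' pattern_stats(simulate_retina(retina_params(), 10, 12, seed = 1)$pattern)
#' @export
pattern_stats <- function(pattern) {
  a <- as_retina_pattern(pattern)
  cl <- column_labels_and_mistakes(a)
  structure(
    list(R_h = if (ncol(a) >= 2L) horizontal_correlation(a) else NA_real_,
         R_v = if (nrow(a) >= 2L) vertical_correlation(a) else NA_real_,
         green_fraction = mean(a),
         mistakes_per_column = cl$mistakes_per_column,
         labels = cl$labels, ambiguous = cl$ambiguous),
    class = "correlation_stats"
  )
}

#' @export
print.correlation_stats <- function(x, ...) {
  cat("<correlation_stats>\n")
  cat(sprintf("  R_h: %s   R_v: %s   green fraction: %.4f\n",
              format(x$R_h, digits = 4), format(x$R_v, digits = 4),
              x$green_fraction))
  cat(sprintf("  total mistakes: %d (%d ambiguous columns)\n",
              sum(x$mistakes_per_column), sum(x$ambiguous)))
  invisible(x)
}

#' Phase-diagram scan of the mean horizontal correlation
#'
#' Scans the two mixture branches (`beta > 0`: alternating/Doli structured
#' component; `beta < 0`: uniform fly) over grids of the mixing weight and
#' the stochastic-component constant, simulating `n_reps` retinas per cell
#' and averaging the horizontal correlation coefficient. Cells whose
#' pattern is constant (the uniform-fly extreme) yield undefined
#' correlations and are reported through `n_defined`.
#'
#' @param alpha_values Grid of mixing weights in `[0, 1]`.
#' @param P0_droso_values Grid of stochastic-component constants.
#' @param base_params A [retina_params()] supplying all other parameters
#'   (must use the `beta`/`gamma` parameterization).
#' @param n_reps Replicates per grid cell.
#' @param n_rows,n_cols Lattice dimensions per replicate.
#' @param seed Optional integer seed for the whole scan.
#' @param branches Subset of `c("doli", "uniform")` to scan (`beta > 0`
#'   resp. `beta < 0`).
#' @return A data frame of class `phase_diagram` with columns `branch`,
#'   `alpha`, `P0_droso`, `mean_R_h`, `n_defined`, `n_reps`.
#' @examples
#' pd <- phase_diagram(c(0, 1), 0.5, n_reps = 2, n_rows = 10, n_cols = 12,
#'                     seed = 1, branches = "doli")
#' pd
#' @export
phase_diagram <- function(alpha_values = seq(0, 1, by = 0.1),
                          P0_droso_values = seq(0.1, 0.9, by = 0.2),
                          base_params = retina_params(),
                          n_reps = 5, n_rows = 30, n_cols = 50,
                          seed = NULL,
                          branches = c("doli", "uniform")) {
  base_params <- as_retina_params(base_params)
  if (is.null(base_params$beta))
    stop("`base_params` must use the beta/gamma parameterization",
         call. = FALSE)
  branches <- match.arg(branches, several.ok = TRUE)
  stopifnot(length(alpha_values) >= 1, length(P0_droso_values) >= 1,
            all(alpha_values >= 0 & alpha_values <= 1),
            all(P0_droso_values >= 0 & P0_droso_values <= 1))
  if (!is.null(seed)) set.seed(seed)

  cells <- expand.grid(P0_droso = P0_droso_values, alpha = alpha_values,
                       branch = branches, stringsAsFactors = FALSE)
  cells <- cells[, c("branch", "alpha", "P0_droso")]
  out <- lapply(seq_len(nrow(cells)), function(i) {
    p <- base_params
    p$beta <- if (cells$branch[i] == "doli") abs(p$beta) else -abs(p$beta)
    p$alpha <- cells$alpha[i]
    p$P0_droso <- cells$P0_droso[i]
    rh <- vapply(seq_len(n_reps), function(r) {
      horizontal_correlation(simulate_retina(p, n_rows, n_cols)$pattern)
    }, numeric(1))
    c(mean_R_h = mean(rh, na.rm = TRUE), n_defined = sum(!is.na(rh)))
  })
  out <- do.call(rbind, out)
  res <- cbind(cells, as.data.frame(out), n_reps = n_reps)
  res$mean_R_h[res$n_defined == 0] <- NA_real_
  class(res) <- c("phase_diagram", class(res))
  res
}
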