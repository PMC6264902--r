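#' Binary retina pattern
#'
#' Wraps an `n_rows x n_cols` binary matrix of ommatidial color states
#' (`1` = green/yellow, `0` = red/pale). Column 1 is the posterior-most
#' column; column generation follows the morphogenetic furrow toward
#' increasing column index. The lattice is stored rectangularly; the
#' hexagonal packing of a real eye only affects rendering.
#'
#' @param x A matrix (or vector coercible to one) whose entries are all
#'   0 or 1 (logical allowed).
#' @return An integer matrix of class `retina_pattern`.
#' @examples
#' retina_pattern(matrix(c(1, 0, 1, 0), 2, 2))
#' @export
retina_pattern <- function(x) {
  if (!is.matrix(x)) stop("`x` must be a matrix", call. = FALSE)
  if (length(x) == 0L) stop("pattern must have at least one cell",
                            call. = FALSE)
  if (is.logical(x)) storage.mode(x) <- "integer"
  if (!is.numeric(x) || anyNA(x) || !all(x %in% c(0, 1)))
    stop("pattern entries must all be 0 or 1", call. = FALSE)
  storage.mode(x) <- "integer"
  class(x) <- c("retina_pattern", class(matrix()))
  x
}

as_retina_pattern <- function(x) {
  if (inherits(x, "retina_pattern")) return(x)
  retina_pattern(x)
}

#' @export
print.retina_pattern <- function(x, ...) {
  cat(sprintf("<retina_pattern> %d rows x %d columns, %.1f%% green\n",
              nrow(x), ncol(x), 100 * mean(x)))
  if (ncol(x) <= 60 && nrow(x) <= 40) {
    glyph <- matrix(c(".", "#")[x + 1L], nrow(x))
    apply(glyph, 1, function(r) cat(paste(r, collapse = ""), "\n"))
  }
  invisible(x)
}

#' Perturbed-column specification
#'
#' Describes a developmental perturbation: during simulation, column
#' `column` takes the override green probability `P_per` in place of its
#' structured default (corrections and mixing are applied as usual).
#'
#' @param column 1-based column index. The classic experiment perturbs
#'   the ninth column (index 8 in zero-based conventions).
#' @param P_per Override green probability in `[0, 1]`.
#' @return An object of class `perturbation`.
#' @examples
#' perturbation(column = 9, P_per = 0.5)
#' @export
perturbation <- function(column, P_per = 0.5) {
  stopifnot(is.numeric(column), length(column) == 1L, column >= 1,
            column == as.integer(column),
            is.numeric(P_per), length(P_per) == 1L,
            P_per >= 0, P_per <= 1)
  structure(list(column = as.integer(column), P_per = P_per),
            class = "perturbation")
}

as_perturbation <- function(x) {
  if (!inherits(x, "perturbation"))
    stop("`perturbation` must be created with perturbation()", call. = FALSE)
  x
}

#' Simulate a retinal color mosaic column by column
#'
#' Generates an `n_rows x n_cols` binary pattern in furrow order. For each
#' column `j` the structured default is computed (threshold-switch
#' dynamics, mode closed form, or uniform-fly constant; see
#' [column_defaults()]) and corrected site-by-site for mistakes in the
#' realized previous column ([mistake_correction()], clipped via
#' [full_probability()]); the corrected structured component is then mixed
#' with the stochastic component ([mixture_probability()]), so that
#' mistake propagation is carried entirely by the structured mechanism and
#' vanishes in the fully random `alpha = 0` limit. Cell states are drawn
#' as independent Bernoulli variables in fixed column-major order, so a
#' given seed reproduces the pattern exactly.
#'
#' @param params A [retina_params()] object.
#' @param n_rows,n_cols Lattice dimensions (>= 1). The defaults, 30 rows
#'   by 50 columns, are the standard model-eye size.
#' @param seed Optional integer seed (`set.seed()` is called when given;
#'   when `NULL` the current RNG stream is consumed).
#' @param perturbation Optional [perturbation()].
#' @return An object of class `retina_sim`: a list with `pattern`
#'   (a [retina_pattern()]), `x_trace` (per-column X levels; `NA` where no
#'   X dynamics apply), `p_column` (per-column mixture defaults),
#'   `probability_trace` (the realized per-site probabilities `P_ij`),
#'   `seed`, `params` and `perturbation`.
#' @examples
#' sim <- simulate_retina(retina_params(), n_rows = 10, n_cols = 12, seed = 1)
#' sim$pattern
#' @export
simulate_retina <- function(params, n_rows = 30, n_cols = 50, seed = NULL,
                            perturbation = NULL) {
  params <- as_retina_params(params)
  stopifnot(is.numeric(n_rows), n_rows >= 1, is.numeric(n_cols), n_cols >= 1)
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (!is.null(seed)) set.seed(seed)

  cd <- column_defaults(params, n_cols, perturbation)
  p_mix <- mixture_probability(cd$structured, params)

  a <- matrix(0L, n_rows, n_cols)
  prob <- matrix(0, n_rows, n_cols)
  for (j in seq_len(n_cols)) {
    p_struct <- rep(cd$structured[j], n_rows)
    if (j > 1L && params$epsilon > 0) {
      l <- mistake_correction(a[, j - 1L], cd$structured[j], params,
                              prev_p = p_mix[j - 1L])
      p_struct <- full_probability(p_struct, l)
    }
    p <- mixture_probability(p_struct, params)
    prob[, j] <- p
    a[, j] <- stats::rbinom(n_rows, 1L, p)
  }

  structure(
    list(pattern = retina_pattern(a), x_trace = cd$x_trace,
         p_column = p_mix, probability_trace = prob, seed = seed,
         params = params, perturbation = perturbation),
    class = "retina_sim"
  )
}

#' @export
print.retina_sim <- function(x, ...) {
  cat(sprintf("<retina_sim> %d x %d pattern (seed: %s)\n",
              nrow(x$pattern), ncol(x$pattern),
              if (is.null(x$seed)) "none" else x$seed))
  print(x$pattern)
  invisible(x)
}

#' Error-propagation experiment with a perturbed column
#'
#' Repeatedly simulates a perturbed retina and an unperturbed control with
#' the same parameters, and profiles the mean number of mistakes per
#' column (elements disagreeing with their column's majority color) across
#' replicates. In a striped regime with a high speckle correlation
#' coefficient, mistakes seeded in the perturbed column propagate
#' anteriorly over several columns; with `epsilon = 0` the default is
#' restored in the very next column.
#'
#' @param params A [retina_params()] object.
#' @param perturbation A [perturbation()].
#' @param n_reps Number of replicate pairs (>= 1).
#' @param n_rows,n_cols Lattice dimensions.
#' @param seed Optional integer seed for the whole experiment.
#' @return A list of class `perturbation_experiment` with `profile` (a
#'   data frame: `column`, `mean_mistakes_perturbed`,
#'   `mean_mistakes_control`), and the full replicate-by-column mistake
#'   count matrices `perturbed` and `control`.
#' @examples
#' pr <- run_perturbation_experiment(retina_params(epsilon = 0.95),
#'                                   perturbation(9, 0.5),
#'                                   n_reps = 5, n_rows = 10, n_cols = 20,
#'                                   seed = 1)
#' head(pr$profile)
#' @export
run_perturbation_experiment <- function(params, perturbation, n_reps = 100,
                                        n_rows = 30, n_cols = 50,
                                        seed = NULL) {
  params <- as_retina_params(params)
  perturbation <- as_perturbation(perturbation)
  stopifnot(is.numeric(n_reps), n_reps >= 1)
  n_reps <- as.integer(n_reps)
  if (!is.null(seed)) set.seed(seed)

  pert <- matrix(0L, n_reps, n_cols)
  ctrl <- matrix(0L, n_reps, n_cols)
  for (r in seq_len(n_reps)) {
    sp <- simulate_retina(params, n_rows, n_cols,
                          perturbation = perturbation)
    sc <- simulate_retina(params, n_rows, n_cols)
    pert[r, ] <- column_labels_and_mistakes(sp$pattern)$mistakes_per_column
    ctrl[r, ] <- column_labels_and_mistakes(sc$pattern)$mistakes_per_column
  }
  structure(
    list(profile = data.frame(column = seq_len(n_cols),
                              mean_mistakes_perturbed = colMeans(pert),
                              mean_mistakes_control = colMeans(ctrl)),
         perturbed = pert, control = ctrl,
         perturbation = perturbation, n_reps = n_reps, seed = seed),
    class = "perturbation_experiment"
  )
}
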