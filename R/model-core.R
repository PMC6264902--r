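#' Default green probability of a column from the threshold switch
#'
#' The furrow-borne factor X gates the color decision of a whole column:
#' at or below the threshold `X0` the column's default green probability is
#' `P0_structured`, above it `1 - P0_structured`. The boundary `X == X0`
#' belongs to the lower branch.
#'
#' @param X Numeric vector of X levels (finite).
#' @param params A [retina_params()] object.
#' @return Numeric vector of default green probabilities.
#' @examples
#' p <- retina_params()  # P0_structured = 1e-4, X0 = 5
#' default_probability(2.0008, p)  # 1e-4: below threshold
#' default_probability(6, p)      # 0.9999: above threshold
#' @export
default_probability <- function(X, params) {
  params <- as_retina_params(params)
  stopifnot(is.numeric(X), all(is.finite(X)))
  ifelse(X <= params$X0, params$P0_structured, 1 - params$P0_structured)
}

#' Update the signaling factor X for the next column
#'
#' Linear relay dynamics: `X_{j+1} = gamma - beta * p_j`, where `p_j` is the
#' realized default green probability of the current column. Only defined
#' for the `beta`/`gamma` parameterization.
#'
#' @param p_j Numeric vector of column default probabilities in `[0, 1]`.
#' @param params A [retina_params()] object with `beta` and `gamma` set.
#' @return `gamma - beta * p_j`, exactly.
#' @examples
#' update_X(0.9999, retina_params(beta = 8, gamma = 10))  # 2.0008
#' @export
update_X <- function(p_j, params) {
  params <- as_retina_params(params)
  if (is.null(params$beta))
    stop("`params` is mode-parameterized; X dynamics need `beta` and `gamma`",
         call. = FALSE)
  stopifnot(is.numeric(p_j), all(p_j >= 0 & p_j <= 1))
  params$gamma - params$beta * p_j
}

#' Classify the dynamical regime of the column relay
#'
#' The column default probability evolves under the map
#' `p -> P0 if gamma - beta * p <= X0 else 1 - P0` (restricted to the two
#' attainable values `P0` and `1 - P0`). The regime follows from which of
#' the two candidate levels is self-consistent:
#' \itemize{
#'   \item `p = P0` is a fixed point iff `gamma - beta * P0 <= X0`;
#'   \item `p = 1 - P0` is a fixed point iff `gamma - beta * (1 - P0) > X0`;
#'   \item both: `"bistable"` — X settles at `gamma - beta * (1 - P0)` or
#'     `gamma - beta * P0` depending on its initial value (a uniform
#'     retina whose color is set by the first column);
#'   \item neither: `"alternating"` — X oscillates between the two levels
#'     and columns alternate color (the striped Doli retina);
#'   \item exactly one: `"fixed_low"` / `"fixed_high"` (fixed at the
#'     low-green default `P0`, resp. the high-green default `1 - P0`).
#' }
#' A negative threshold is physically inadmissible and returns `"invalid"`.
#'
#' @param params A [retina_params()] object; for mode-parameterized params
#'   the regime is implied by the mode itself. Alternatively pass the raw
#'   constants via `beta`, `gamma`, `X0`, `P0`.
#' @param beta,gamma,X0,P0 Raw constants, used when `params` is `NULL`.
#' @return A single string: one of `"fixed_high"`, `"fixed_low"`,
#'   `"alternating"`, `"bistable"`, `"invalid"`, with the two candidate
#'   fixed X levels attached as attribute `"X_levels"` (where applicable).
#' @examples
#' classify_regime(retina_params(beta = 8, gamma = 10))       # alternating
#' classify_regime(beta = 8, gamma = 10, X0 = 5, P0 = 0.7)    # bistable
#' @export
classify_regime <- function(params = NULL, beta = NULL, gamma = NULL,
                            X0 = NULL, P0 = NULL) {
  if (!is.null(params)) {
    params <- as_retina_params(params)
    if (!is.null(params$mode)) {
      lab <- switch(params$mode,
                    fr = "fixed_low", fg = "fixed_high",
                    ar = "alternating", ag = "alternating")
      return(lab)
    }
    beta <- params$beta; gamma <- params$gamma
    X0 <- params$X0; P0 <- params$P0_structured
  }
  stopifnot(is.numeric(beta), is.numeric(gamma), is.numeric(X0),
            is.numeric(P0), P0 >= 0, P0 <= 1)
  if (X0 < 0) return("invalid")
  x_low <- gamma - beta * P0        # X level while p stays at P0
  x_high <- gamma - beta * (1 - P0) # X level while p stays at 1 - P0
  stable_low <- x_low <= X0
  stable_high <- x_high > X0
  lab <- if (stable_low && stable_high) "bistable"
         else if (stable_low) "fixed_low"
         else if (stable_high) "fixed_high"
         else "alternating"
  structure(lab, X_levels = c(low = x_low, high = x_high))
}

#' Column default probability under the discrete mode parameterization
#'
#' Replays the relay dynamics as a closed form: fixed-point modes give a
#' constant default (`fr` low green, `fg` high green); alternating modes
#' give a strict period-2 sequence whose phase is set by the initial
#' condition (`ag` starts green at column 1, `ar` starts red).
#'
#' @param mode One of `"fr"`, `"fg"`, `"ar"`, `"ag"`.
#' @param j Column indices (1-based), vectorized.
#' @param params A [retina_params()] object (only `P0_structured` is used).
#' @param inference_constraint If `TRUE`, apply the fixed-point constraint
#'   used by the simulated-data inference grid: fixed-point modes force
#'   `P0 = 0` (the mixing weight and `P0` are otherwise interdependent
#'   there).
#' @return Numeric vector of default green probabilities, one per `j`.
#' @examples
#' mode_column_default("ag", 1:4, retina_params(P0_structured = 0.1))
#' @export
mode_column_default <- function(mode, j, params,
                                inference_constraint = FALSE) {
  mode <- match.arg(mode, MODES)
  params <- as_retina_params(params)
  stopifnot(is.numeric(j), all(j >= 1))
  P0 <- params$P0_structured
  if (inference_constraint && is_fixed_mode(mode)) P0 <- 0
  switch(mode,
         fr = rep(P0, length(j)),
         fg = rep(1 - P0, length(j)),
         ag = ifelse(j %% 2 == 1, 1 - P0, P0),
         ar = ifelse(j %% 2 == 1, P0, 1 - P0))
}

## Majority color of a realized column; exact ties resolved by the
## reference probability (>= 0.5 -> green), or green when no reference.
column_majority <- function(col, ref = NULL) {
  n1 <- sum(col)
  n0 <- length(col) - n1
  if (n1 > n0) 1L
  else if (n1 < n0) 0L
  else if (!is.null(ref)) as.integer(ref >= 0.5)
  else 1L
}

## Row-profile of Gaussian kernel weights summed over mistake rows:
## S0[i] = sum_{i'} exp(-(i - i')^2 / k).
kernel_sums <- function(n_rows, mistake_rows, k) {
  if (length(mistake_rows) == 0L) return(numeric(n_rows))
  rowSums(exp(-outer(seq_len(n_rows), mistake_rows, "-")^2 / k))
}

#' Mistake-propagation correction to a site's green probability
#'
#' Mistakes in the previously specified column (elements disagreeing with
#' that column's majority color) perturb the default probability of nearby
#' sites in the current column. The correction is a Gaussian kernel in row
#' distance, signed toward local anticorrelation with the mistaken
#' neighbors' color:
#' \deqn{l_{ij} = \epsilon \sum_{i' \in \mathrm{mistakes}}
#'   e^{-(i-i')^2/k}\,\big((1 - a_{i',j-1}) - p_j\big).}
#' If the previous column is unanimous the default is maintained
#' (`l = 0`), as it is for `epsilon = 0`.
#'
#' @param prev_column Realized binary vector of the previous column.
#' @param p_j Pre-correction green probability of the current column
#'   within the structured component (its column default).
#' @param params A [retina_params()] object (`epsilon` and `k` are used).
#' @param rows Row indices at which to evaluate the correction; defaults
#'   to every row.
#' @param prev_p Optional reference probability of the previous column,
#'   used only to break an exact 50/50 majority tie.
#' @return Numeric vector of signed corrections, one per entry of `rows`.
#' @examples
#' p <- retina_params(epsilon = 0.95, k = 1)
#' # single green mistake in a red-majority column, feeding a green column:
#' prev <- c(1L, rep(0L, 9))
#' mistake_correction(prev, p_j = 0.9999, p, rows = 1)  # -0.949905
#' @export
mistake_correction <- function(prev_column, p_j, params, rows = NULL,
                               prev_p = NULL) {
  params <- as_retina_params(params)
  stopifnot(length(prev_column) >= 1L, all(prev_column %in% c(0L, 1L)),
            is.numeric(p_j), length(p_j) == 1L, p_j >= 0, p_j <= 1)
  n <- length(prev_column)
  if (is.null(rows)) rows <- seq_len(n)
  stopifnot(all(rows >= 1L & rows <= n))
  if (params$epsilon == 0) return(numeric(length(rows)))
  maj <- column_majority(prev_column, ref = prev_p)
  mist <- which(prev_column != maj)
  if (length(mist) == 0L) return(numeric(length(rows)))
  ## every mistake has color 1 - maj, so (1 - a') - p_j == maj - p_j
  s0 <- kernel_sums(n, mist, params$k)[rows]
  params$epsilon * (maj - p_j) * s0
}

#' Full site probability: default plus correction, clipped to [0, 1]
#'
#' @param p_j Pre-correction green probability (or vector thereof).
#' @param l_ij Signed correction(s) from [mistake_correction()].
#' @return `p_j + l_ij`, clipped into `[0, 1]`.
#' @examples
#' full_probability(0.9999, -0.949905)  # 0.049995
#' full_probability(0.9, 0.5)           # clipped to 1
#' @export
full_probability <- function(p_j, l_ij) {
  stopifnot(is.numeric(p_j), is.numeric(l_ij),
            all(p_j >= 0 & p_j <= 1))
  pmin(1, pmax(0, p_j + l_ij))
}

#' Mix the structured and stochastic decision components
#'
#' Linear mixture of the structured (Doli or uniform-fly) column default
#' with the stochastic Drosophila-like component:
#' `alpha * p_structured + (1 - alpha) * (1 - P0_droso)`.
#'
#' @param p_structured Structured-component green probability (vectorized).
#' @param params A [retina_params()] object (`alpha`, `P0_droso`).
#' @return Mixed green probability, in `[0, 1]`.
#' @examples
#' p <- retina_params(alpha = 0.5, P0_droso = 0.35)
#' mixture_probability(0.9999, p)  # 0.82495
#' @export
mixture_probability <- function(p_structured, params) {
  params <- as_retina_params(params)
  stopifnot(all(p_structured >= 0 & p_structured <= 1))
  params$alpha * p_structured + (1 - params$alpha) * (1 - params$P0_droso)
}

#' Structured column defaults and the X trace
#'
#' Computes the per-column structured default probabilities for `n_cols`
#' columns in furrow order, before mixing and mistake corrections:
#' \itemize{
#'   \item mode parameterization: closed-form [mode_column_default()];
#'   \item `beta > 0` (alternating/Doli branch): iterate the threshold
#'     switch and the X relay from `X_init`;
#'   \item `beta < 0` (uniform-fly branch): the constant `P_ordered`.
#' }
#' A perturbation overrides the default of its column; in the dynamic
#' branch the overridden value feeds the X update of the next column.
#'
#' @param params A [retina_params()] object.
#' @param n_cols Number of columns (>= 1).
#' @param perturbation Optional [perturbation()].
#' @return A list with `structured` (numeric, length `n_cols`) and
#'   `x_trace` (numeric, length `n_cols`; `NA` outside the dynamic branch,
#'   where no X level is defined).
#' @export
column_defaults <- function(params, n_cols, perturbation = NULL) {
  params <- as_retina_params(params)
  stopifnot(is.numeric(n_cols), length(n_cols) == 1L, n_cols >= 1)
  n_cols <- as.integer(n_cols)
  if (!is.null(perturbation)) {
    perturbation <- as_perturbation(perturbation)
    if (perturbation$column > n_cols)
      stop("perturbation column out of range", call. = FALSE)
  }
  x_trace <- rep(NA_real_, n_cols)
  if (is.null(params$mode) && params$beta >= 0) {
    p <- numeric(n_cols)
    x_trace[1] <- params$X_init
    for (j in seq_len(n_cols)) {
      p[j] <- default_probability(x_trace[j], params)
      if (!is.null(perturbation) && j == perturbation$column)
        p[j] <- perturbation$P_per
      if (j < n_cols) x_trace[j + 1] <- update_X(p[j], params)
    }
  } else {
    p <- if (is.null(params$mode)) rep(params$P_ordered, n_cols)
         else mode_column_default(params$mode, seq_len(n_cols), params)
    if (!is.null(perturbation)) p[perturbation$column] <- perturbation$P_per
  }
  list(structured = p, x_trace = x_trace)
}
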