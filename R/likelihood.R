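#' Per-site generative probabilities of an observed pattern
#'
#' Reconstructs the probability `P_ij` with which the generative process
#' would have drawn each observed cell, conditioning on the realized
#' previous column exactly as [simulate_retina()] does: structured column
#' default, mixture, mistake correction, clipping. Because the X relay is
#' a deterministic function of the column defaults, no latent variables
#' need to be marginalized and the likelihood factorizes over cells given
#' the preceding column.
#'
#' @param pattern A [retina_pattern()] or plain binary matrix.
#' @param params A [retina_params()] object.
#' @param perturbation Optional [perturbation()] assumed during generation.
#' @return A numeric matrix of green probabilities, same shape as
#'   `pattern`.
#' @export
site_probabilities <- function(pattern, params, perturbation = NULL) {
  a <- as_retina_pattern(pattern)
  params <- as_retina_params(params)
  n <- nrow(a); m <- ncol(a)
  cd <- column_defaults(params, m, perturbation)
  p_mix <- mixture_probability(cd$structured, params)
  prob <- matrix(rep(p_mix, each = n), n, m)
  if (params$epsilon > 0 && m > 1L) {
    for (j in 2:m) {
      l <- mistake_correction(a[, j - 1L], cd$structured[j], params,
                              prev_p = p_mix[j - 1L])
      prob[, j] <- mixture_probability(
        full_probability(rep(cd$structured[j], n), l), params)
    }
  }
  prob
}

#' Exact log-likelihood of a pattern under the model
#'
#' Column-factorized Bernoulli log-likelihood
#' \deqn{\ell = \sum_{ij} a_{ij}\log P_{ij} + (1-a_{ij})\log(1-P_{ij}),}
#' with `P_ij` from [site_probabilities()]. A cell observed against a
#' deterministic probability (0 or 1) makes the result `-Inf`; set
#' `floor_prob` to a small positive value to bound probabilities away from
#' the boundary when fitting deterministic-regime models to imperfect
#' data.
#'
#' @param pattern A [retina_pattern()] or plain binary matrix.
#' @param params A [retina_params()] object (typically mode-parameterized
#'   for inference, but the dynamic parameterization is accepted).
#' @param perturbation Optional [perturbation()] assumed during generation.
#' @param floor_prob Probability floor in `[0, 0.5)`; 0 disables it.
#' @return A single log-likelihood value (possibly `-Inf`).
#' @examples
#' pat <- simulate_retina(retina_params(alpha = 0, P0_droso = 0.5),
#'                        4, 5, seed = 1)$pattern
#' log_likelihood(pat, retina_params(alpha = 0, P0_droso = 0.5))
#' # = 20 * log(0.5)
#' @export
log_likelihood <- function(pattern, params, perturbation = NULL,
                           floor_prob = 0) {
  a <- as_retina_pattern(pattern)
  stopifnot(is.numeric(floor_prob), floor_prob >= 0, floor_prob < 0.5)
  prob <- site_probabilities(a, params, perturbation)
  if (floor_prob > 0) prob <- pmin(pmax(prob, floor_prob), 1 - floor_prob)
  lik <- prob
  red <- a == 0L
  lik[red] <- 1 - prob[red]
  sum(log(lik))
}
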