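#' Conjugate posterior for the effect given a known sampling variance
#'
#' With prior `mu_Delta ~ N(mu0, S)` and the realised difference in sample
#' means `xbar_delta ~ N(mu_Delta, (1/nA + 1/nB) sigma0^2)`, the posterior
#' is normal with precision-additive variance
#' `sigmaN2 = (1/S + 1/((1/nA + 1/nB) sigma0^2))^(-1)` and precision-weighted
#' mean `eta` lying between the prior mean and `xbar_delta`.
#'
#' In the unknown-variance model the same update applies conditionally on
#' `sigma0^2`; the variance prior is integrated out at the criterion level.
#'
#' @param prior a [collective_prior()].
#' @param xbar_delta realised difference in sample means.
#' @param nA,nB group sizes (> 0).
#' @param sigma02 sampling variance (> 0).
#' @return An object of class `"posterior_state"`: list with `eta` (posterior
#'   mean) and `sigmaN2` (posterior variance).
#' @export
posterior_known_var <- function(prior, xbar_delta, nA, nB, sigma02) {
  stopifnot(inherits(prior, "collective_prior"))
  if (any(c(nA, nB, sigma02) <= 0))
    stop("`nA`, `nB`, `sigma02` must be positive", call. = FALSE)
  v_dat <- (1 / nA + 1 / nB) * sigma02
  sigmaN2 <- 1 / (1 / prior$variance + 1 / v_dat)
  eta <- (v_dat * prior$mean + prior$variance * xbar_delta) /
    (prior$variance + v_dat)
  structure(list(eta = eta, sigmaN2 = sigmaN2), class = "posterior_state")
}

#' @export
print.posterior_state <- function(x, digits = 4, ...) {
  cat(sprintf("Posterior: mu_Delta ~ N(%.*g, %.*g)\n",
              digits, x$eta, digits, x$sigmaN2))
  invisible(x)
}

#' Marginal predictive distribution of the difference in sample means
#'
#' Unconditional on the effect, the difference in sample means is normal
#' with the prior mean and variance `(1/nA + 1/nB) sigma0^2 + S` — the SSD
#' criteria average posterior properties over this law.
#'
#' @inheritParams posterior_known_var
#' @return A list with `mean` and `variance`.
#' @export
marginal_predictive <- function(prior, nA, nB, sigma02) {
  stopifnot(inherits(prior, "collective_prior"))
  if (any(c(nA, nB, sigma02) <= 0))
    stop("`nA`, `nB`, `sigma02` must be positive", call. = FALSE)
  list(mean = prior$mean,
       variance = (1 / nA + 1 / nB) * sigma02 + prior$variance)
}

#' Coverage of the fixed-length HPD interval
#'
#' For the normal posterior the highest-posterior-density interval of length
#' `l0` is centred at the posterior mean, and its coverage is
#' `2 * Phi(l0 / (2 * sigma_N)) - 1`.
#'
#' @param post a [posterior_known_var()] state.
#' @param l0 interval length (> 0).
#' @return The posterior probability that the effect lies in the interval.
#' @export
hpd_coverage <- function(post, l0) {
  stopifnot(inherits(post, "posterior_state"))
  if (any(l0 <= 0)) stop("`l0` must be positive", call. = FALSE)
  2 * stats::pnorm(l0 / (2 * sqrt(post$sigmaN2))) - 1
}
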