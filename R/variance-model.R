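#' Sampling-variance models
#'
#' The SSD formulas need the common sampling variance `sigma0^2` of the new
#' experiment. It is either known, or unknown with an inverse-gamma prior
#' induced by the chi-square link `c * S / sigma0^2 ~ chi^2(c)`, where `S`
#' is the collective prior variance and `c` acts as a prior degrees of
#' freedom: the larger `c`, the more tightly `sigma0^2` concentrates at `S`.
#'
#' The inverse-gamma is parameterised **shape-scale** (density proportional
#' to `x^(-shape-1) exp(-scale/x)`), so the link is
#' `sigma0^2 ~ Inv-Gamma(c/2, c*S/2)` with mean `c*S/(c-2)` for `c > 2`.
#' Equivalently the precision `1/sigma0^2 ~ Gamma(c/2, rate = c*S/2)`, with
#' mean `1/S` and variance `2/(c*S^2)`.
#'
#' @param sigma02 known sampling variance (> 0).
#' @return An object of class `"variance_model"`.
#' @seealso [invgamma_variance()], [expected_sigma02()], [expected_sigma_n()]
#' @export
known_variance <- function(sigma02) {
  if (!is.finite(sigma02) || sigma02 <= 0)
    stop("`sigma02` must be positive", call. = FALSE)
  structure(list(kind = "known", sigma02 = sigma02), class = "variance_model")
}

#' @rdname known_variance
#' @param S collective prior variance the chi-square link ties `sigma0^2` to (> 0).
#' @param c prior degrees of freedom of the chi-square link (> 0).
#' @export
invgamma_variance <- function(S, c) {
  if (!is.finite(S) || S <= 0) stop("`S` must be positive", call. = FALSE)
  if (!is.finite(c) || c <= 0) stop("`c` must be positive", call. = FALSE)
  structure(list(kind = "invgamma", c = c, S = S,
                 shape = c / 2, scale = c * S / 2),
            class = "variance_model")
}

#' @rdname known_variance
#' @param prior a [collective_prior()] whose variance supplies `S`.
#' @export
invgamma_from_collective <- function(prior, c) {
  stopifnot(inherits(prior, "collective_prior"))
  invgamma_variance(prior$variance, c)
}

#' @export
print.variance_model <- function(x, ...) {
  if (x$kind == "known") {
    cat(sprintf("Known sampling variance: sigma0^2 = %g\n", x$sigma02))
  } else {
    cat(sprintf("sigma0^2 ~ Inv-Gamma(%.3f, %.3f)  [c = %g, S = %g]\n",
                x$shape, x$scale, x$c, x$S))
  }
  invisible(x)
}

#' Prior expectation of the sampling variance
#'
#' Returns `sigma0^2` itself for a known-variance model, and the
#' inverse-gamma mean `c*S/(c-2)` otherwise. The mean does not exist for
#' `c <= 2`, in which case the closed-form ACC and APVC solutions are
#' unavailable and an error is raised.
#'
#' @param model a [known_variance()] or [invgamma_variance()] model.
#' @return The expected sampling variance.
#' @export
expected_sigma02 <- function(model) {
  stopifnot(inherits(model, "variance_model"))
  if (model$kind == "known") return(model$sigma02)
  if (model$c <= 2)
    stop("E[sigma0^2] does not exist for c <= 2; ",
         "the closed-form ACC/APVC solutions are unavailable", call. = FALSE)
  model$c * model$S / (model$c - 2)
}

#' Draw sampling variances from the model
#'
#' @param model a variance model.
#' @param n number of draws.
#' @return `n` draws of `sigma0^2` (a constant vector for the known case).
#' @export
rsigma02 <- function(model, n) {
  stopifnot(inherits(model, "variance_model"))
  if (model$kind == "known") return(rep(model$sigma02, n))
  1 / stats::rgamma(n, shape = model$shape, rate = model$scale)
}

#' Expected posterior standard deviation
#'
#' The posterior standard deviation of the effect after observing groups of
#' sizes `nA`, `nB` is
#' `sigma_N = (1/S + 1/((1/nA + 1/nB) sigma0^2))^(-1/2)`.
#' For a known-variance model this is returned in closed form; for the
#' inverse-gamma model its expectation over the variance prior is computed
#' by adaptive quadrature on the precision scale: with
#' `tau = 1/sigma0^2 ~ Gamma(c/2, rate = c*S/2)` the integrand
#' `(1/S + Q_n * tau)^(-1/2)` (where `Q_n = nA*nB/(nA+nB)`) is bounded by
#' `sqrt(S)`, so the expectation exists for every `c > 0` even when
#' `E[sigma0^2]` does not.
#'
#' @param model a variance model.
#' @param S prior variance of the effect (> 0).
#' @param nA,nB group sizes (> 0, not necessarily integer).
#' @return The (expected) posterior standard deviation; always < `sqrt(S)`.
#' @export
expected_sigma_n <- function(model, S, nA, nB) {
  stopifnot(inherits(model, "variance_model"))
  if (any(c(S, nA, nB) <= 0) || any(!is.finite(c(S, nA, nB))))
    stop("`S`, `nA`, `nB` must be positive and finite", call. = FALSE)
  q_n <- nA * nB / (nA + nB)
  if (model$kind == "known")
    return(1 / sqrt(1 / S + q_n / model$sigma02))
  integrand <- function(tau)
    stats::dgamma(tau, shape = model$shape, rate = model$scale) /
      sqrt(1 / S + q_n * tau)
  # integrate between extreme gamma quantiles: the integrand is bounded by
  # sqrt(S), so the truncated tail mass (2e-13) is negligible, and finite
  # limits keep the quadrature reliable when the density is sharply peaked
  # (large c)
  lo <- stats::qgamma(1e-13, shape = model$shape, rate = model$scale)
  hi <- stats::qgamma(1e-13, shape = model$shape, rate = model$scale,
                      lower.tail = FALSE)
  res <- stats::integrate(integrand, lo, hi, rel.tol = 1e-8, abs.tol = 0)
  if (res$message != "OK")
    stop("quadrature for E[sigma_N] failed: ", res$message, call. = FALSE)
  res$value
}
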