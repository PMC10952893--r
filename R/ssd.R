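#' Standard normal quantile helper
#'
#' `z_quantile(q)` is the upper q-th quantile of the standard normal
#' distribution, `Phi^{-1}(1 - q)`.
#'
#' @param q probability in (0, 1).
#' @export
z_quantile <- function(q) {
  if (any(q <= 0 | q >= 1)) stop("`q` must lie in (0, 1)", call. = FALSE)
  stats::qnorm(1 - q)
}

#' SSD criteria
#'
#' Three criteria control an average property of the posterior over the
#' predictive distribution of the new data:
#' \describe{
#'   \item{ACC}{the fixed-length-`l0` HPD interval has average coverage at
#'     least `1 - alpha`.}
#'   \item{ALC}{the `(1 - alpha0)`-coverage HPD interval has average length
#'     at most `l`.}
#'   \item{APVC}{the average posterior variance is at most `eps0`.}
#' }
#' The target levels have no conventional defaults in the way significance
#' levels do; `l0`/`l` and `eps0` should come from what constitutes a
#' decision-relevant precision on the effect scale.
#'
#' @param l0,l HPD interval length targets (> 0).
#' @param alpha,alpha0 one minus the coverage target, in (0, 1).
#' @param eps0 posterior-variance target (> 0).
#' @return An object of class `"criterion"`.
#' @export
acc_criterion <- function(l0, alpha = 0.05) {
  if (l0 <= 0) stop("`l0` must be positive", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must lie in (0, 1)", call. = FALSE)
  structure(list(kind = "acc", l0 = l0, alpha = alpha), class = "criterion")
}

#' @rdname acc_criterion
#' @export
alc_criterion <- function(l, alpha0 = 0.05) {
  if (l <= 0) stop("`l` must be positive", call. = FALSE)
  if (alpha0 <= 0 || alpha0 >= 1) stop("`alpha0` must lie in (0, 1)", call. = FALSE)
  structure(list(kind = "alc", l = l, alpha0 = alpha0), class = "criterion")
}

#' @rdname acc_criterion
#' @export
apvc_criterion <- function(eps0) {
  if (eps0 <= 0) stop("`eps0` must be positive", call. = FALSE)
  structure(list(kind = "apvc", eps0 = eps0), class = "criterion")
}

#' @export
print.criterion <- function(x, ...) {
  switch(x$kind,
    acc = cat(sprintf("ACC: average coverage of the length-%g HPD interval >= %g\n",
                      x$l0, 1 - x$alpha)),
    alc = cat(sprintf("ALC: average length of the %g%% HPD interval <= %g\n",
                      100 * (1 - x$alpha0), x$l)),
    apvc = cat(sprintf("APVC: average posterior variance <= %g\n", x$eps0)))
  invisible(x)
}

#' Required information level under the ACC
#'
#' The harmonic-mean information level `Q = nA*nB/(nA+nB)` must satisfy
#' `Q >= (4 z_{alpha/2}^2 / l0^2 - 1/S) * E[sigma0^2]`,
#' with the expectation degenerate at `sigma0^2` for a known-variance model.
#' A negative right-hand side means the prior alone already meets the
#' target, so `Q` is clamped at zero (little or no new information needed).
#'
#' @param S collective prior variance (> 0).
#' @param l0 HPD interval length (> 0).
#' @param alpha one minus the average-coverage target.
#' @param model a variance model ([known_variance()] / [invgamma_variance()];
#'   the inverse-gamma case requires `c > 2`).
#' @return Required `Q >= 0`.
#' @export
required_q_acc <- function(S, l0, alpha = 0.05, model) {
  if (S <= 0) stop("`S` must be positive", call. = FALSE)
  z <- z_quantile(alpha / 2)
  max(0, (4 * z^2 / l0^2 - 1 / S) * expected_sigma02(model))
}

#' Required information level under the APVC
#'
#' `Q >= (1/eps0 - 1/S) * E[sigma0^2]`, clamped at zero when the prior
#' variance is already at or below the target.
#'
#' @inheritParams required_q_acc
#' @param eps0 average-posterior-variance target (> 0).
#' @export
required_q_apvc <- function(S, eps0, model) {
  if (S <= 0) stop("`S` must be positive", call. = FALSE)
  if (eps0 <= 0) stop("`eps0` must be positive", call. = FALSE)
  max(0, (1 / eps0 - 1 / S) * expected_sigma02(model))
}

#' Expected HPD interval length under the ALC
#'
#' The `(1 - alpha0)`-coverage HPD interval has length
#' `2 z_{alpha0/2} sigma_N`; its average over the variance prior is
#' `2 z_{alpha0/2} E[sigma_N]` (see [expected_sigma_n()]). For a known
#' variance the length is deterministic, which is why ACC and ALC coincide
#' there.
#'
#' @inheritParams required_q_acc
#' @param nA,nB group sizes (> 0).
#' @param alpha0 one minus the interval coverage.
#' @export
alc_expected_length <- function(S, nA, nB, alpha0 = 0.05, model) {
  2 * z_quantile(alpha0 / 2) * expected_sigma_n(model, S, nA, nB)
}

#' Smallest total sample size meeting the ALC
#'
#' The expected length has no closed-form inverse when the variance is
#' unknown, so the smallest integer total `n` with
#' `alc_expected_length <= l` is found by exponential bracketing from
#' `n = 1`, integer bisection on the monotone expected-length function, and
#' a final downward scan to guarantee minimality. Per-arm sizes follow the
#' allocation ratio `r = nA/nB` and may be fractional (an equal split of an
#' odd total is allowed); set `policy = "even_total"` to restrict the search
#' to even totals.
#'
#' @inheritParams required_q_acc
#' @param l average-length target (> 0).
#' @param alpha0 one minus the interval coverage.
#' @param ratio allocation ratio `nA/nB` (> 0).
#' @param policy `"integer_total"` (default) or `"even_total"`.
#' @return A list with `total`, `nA`, `nB`, `Q`, and `attained` (the
#'   expected length at the returned total); `total = 0` when the prior
#'   alone meets the target.
#' @export
solve_alc <- function(S, l, alpha0 = 0.05, model, ratio = 1,
                      policy = c("integer_total", "even_total")) {
  policy <- match.arg(policy)
  if (l <= 0) stop("`l` must be positive", call. = FALSE)
  z <- z_quantile(alpha0 / 2)
  if (2 * z * sqrt(S) <= l)
    return(list(total = 0, nA = 0, nB = 0, Q = 0, attained = 2 * z * sqrt(S)))
  step <- if (policy == "even_total") 2L else 1L
  split_arms <- function(n) {
    nB <- n / (1 + ratio)
    list(nA = ratio * nB, nB = nB)
  }
  len_at <- function(n) {
    arms <- split_arms(n)
    alc_expected_length(S, arms$nA, arms$nB, alpha0, model)
  }
  hi <- step
  while (len_at(hi) > l) {
    hi <- hi * 2L
    if (hi > 1e9) stop("ALC search failed to bracket a solution", call. = FALSE)
  }
  lo <- hi %/% 2L  # len_at(lo) > l (or lo == 0)
  while (hi - lo > step) {
    mid <- lo + step * ((hi - lo) %/% (2L * step))
    if (len_at(mid) <= l) hi <- mid else lo <- mid
  }
  while (hi - step >= step && len_at(hi - step) <= l) hi <- hi - step
  arms <- split_arms(hi)
  list(total = hi, nA = arms$nA, nB = arms$nB,
       Q = arms$nA * arms$nB / (arms$nA + arms$nB), attained = len_at(hi))
}

#' Allocate a required information level to two arms
#'
#' Solves `nA = r * nB` and `nA*nB/(nA+nB) = Q`:
#' `nB = Q (1 + r) / r`, `nA = Q (1 + r)`, total `Q (1 + r)^2 / r`
#' (equal allocation gives total `4 Q`). The continuous policy keeps real
#' sizes (the convention for closed-form criteria); `integer_total` rounds
#' the total up and re-splits.
#'
#' @param Q required information level (>= 0).
#' @param ratio allocation ratio `nA/nB` (> 0).
#' @param policy `"continuous"` (default) or `"integer_total"`.
#' @return A list with `nA`, `nB`, `total`.
#' @export
allocate <- function(Q, ratio = 1, policy = c("continuous", "integer_total")) {
  policy <- match.arg(policy)
  if (Q < 0) stop("`Q` must be nonnegative", call. = FALSE)
  if (ratio <= 0) stop("`ratio` must be positive", call. = FALSE)
  total <- Q * (1 + ratio)^2 / ratio
  if (policy == "integer_total") total <- ceiling(total)
  nB <- total / (1 + ratio)
  list(nA = ratio * nB, nB = nB, total = total)
}

#' Design a two-group experiment from a scenario
#'
#' Applies a borrowing strategy to the scenario, synthesises the prior,
#' resolves the variance model, and solves the chosen criterion for the
#' sample size.
#'
#' Strategies:
#' \describe{
#'   \item{robust}{use the scenario's elicited `w_k` (the proposed method).}
#'   \item{no_robustification}{force all `w_k = 0` (historical data fully
#'     trusted).}
#'   \item{no_borrowing}{force all `w_k = 1` (maximal down-weighting of the
#'     prior for the effect; the collective variance so obtained may still
#'     inform an unknown `sigma0^2`).}
#'   \item{single_source}{use only the most informative (smallest-variance)
#'     `N(m_k, s_k^2)` directly as the prior; ties broken by lowest index.}
#'   \item{optimal}{benchmark of perfect commensurability: the robust prior
#'     with the sampling variance known and equated to the collective prior
#'     variance `S`.}
#' }
#'
#' @param scenario a [scenario()] (sources, mixture, s0).
#' @param criterion an [acc_criterion()], [alc_criterion()], or
#'   [apvc_criterion()].
#' @param variance either a fitted variance model, or a spec list
#'   `list(kind = "known", sigma02 = ...)` /
#'   `list(kind = "invgamma", c = ..., S = optional)` — when `S` is omitted
#'   it is filled in from the strategy's collective prior variance. Ignored
#'   (forced known at `S`) by the `optimal` strategy.
#' @param strategy borrowing strategy, see Details.
#' @param ratio allocation ratio `nA/nB` (default 1, equal allocation).
#' @param alc_policy integer-total policy passed to [solve_alc()].
#' @return An object of class `"ssd_design"`: list with `Q`, `nA`, `nB`,
#'   `total`, `attained`, `strategy`, `criterion`, `prior`, `model`.
#' @examples
#' sc <- scenario(
#'   historical_summary(
#'     mean     = c(-0.26, -0.24, -0.37, -0.34, -0.32),
#'     variance = c(0.25, 0.23, 0.22, 0.36, 0.26),
#'     w        = c(0.15, 0.20, 0.17, 0.13, 0.20)
#'   ),
#'   name = "application"
#' )
#' ssd_design(sc, acc_criterion(l0 = 0.65, alpha = 0.05),
#'            variance = list(kind = "known", sigma02 = 0.35))
#' @export
ssd_design <- function(scenario, criterion,
                       variance = list(kind = "invgamma", c = 5),
                       strategy = c("robust", "no_robustification",
                                    "no_borrowing", "single_source", "optimal"),
                       ratio = 1,
                       alc_policy = c("integer_total", "even_total")) {
  strategy <- match.arg(strategy)
  alc_policy <- match.arg(alc_policy)
  stopifnot(inherits(criterion, "criterion"))
  scenario <- as_scenario(scenario)

  prior <- strategy_prior(scenario, strategy)
  S <- prior$variance
  model <- if (strategy == "optimal") {
    known_variance(S)
  } else {
    resolve_variance(variance, S)
  }

  if (criterion$kind == "alc") {
    sol <- solve_alc(S, criterion$l, criterion$alpha0, model,
                     ratio = ratio, policy = alc_policy)
    out <- list(Q = sol$Q, nA = sol$nA, nB = sol$nB, total = sol$total,
                attained = sol$attained)
  } else {
    Q <- if (criterion$kind == "acc") {
      required_q_acc(S, criterion$l0, criterion$alpha, model)
    } else {
      required_q_apvc(S, criterion$eps0, model)
    }
    arms <- allocate(Q, ratio = ratio, policy = "continuous")
    e_s2 <- expected_sigma02(model)
    avg_prec <- 1 / S + Q / e_s2   # average posterior precision delivered
    attained <- if (criterion$kind == "acc") {
      2 * stats::pnorm(criterion$l0 / 2 * sqrt(avg_prec)) - 1
    } else {
      1 / avg_prec
    }
    out <- list(Q = Q, nA = arms$nA, nB = arms$nB, total = arms$total,
                attained = attained)
  }
  structure(c(out,
              list(strategy = strategy, criterion = criterion,
                   prior = prior, model = model, ratio = ratio,
                   scenario_name = scenario$name)),
            class = "ssd_design")
}

#' @export
print.ssd_design <- function(x, ...) {
  crit <- switch(x$criterion$kind,
                 acc = sprintf("ACC (l0 = %g, alpha = %g)",
                               x$criterion$l0, x$criterion$alpha),
                 alc = sprintf("ALC (l = %g, alpha0 = %g)",
                               x$criterion$l, x$criterion$alpha0),
                 apvc = sprintf("APVC (eps0 = %g)", x$criterion$eps0))
  cat(sprintf("Bayesian SSD [%s, strategy = %s]\n", crit, x$strategy))
  if (!is.null(x$scenario_name) && nzchar(x$scenario_name))
    cat(sprintf("  scenario: %s\n", x$scenario_name))
  print(x$model)
  cat(sprintf("  required Q = %.3f;  nA = %.1f, nB = %.1f;  total = %.1f\n",
              x$Q, x$nA, x$nB, round(x$total, 1)))
  lab <- switch(x$criterion$kind, acc = "average coverage",
                alc = "expected length", apvc = "average posterior variance")
  cat(sprintf("  attained %s = %.4f\n", lab, x$attained))
  invisible(x)
}

# -- internal helpers ---------------------------------------------------------

# Transform the scenario prior according to the comparator strategy.
strategy_prior <- function(scenario, strategy) {
  src <- scenario$sources
  if (strategy == "no_robustification") src$w[] <- 0
  if (strategy == "no_borrowing") src$w[] <- 1
  if (strategy == "single_source") {
    k <- which.min(src$variance)
    return(normal_prior(src$mean[k], src$variance[k]))
  }
  collective_prior(src, mix = scenario$mixture, s0 = scenario$s0)
}

# Turn a variance spec (or an already-built model) into a variance_model,
# auto-filling S from the collective prior variance where needed.
resolve_variance <- function(variance, S) {
  if (inherits(variance, "variance_model")) return(variance)
  if (!is.list(variance) || is.null(variance$kind))
    stop("`variance` must be a variance model or a spec list with `kind`",
         call. = FALSE)
  switch(variance$kind,
    known = {
      if (is.null(variance$sigma02))
        stop("known-variance spec needs `sigma02`", call. = FALSE)
      known_variance(variance$sigma02)
    },
    invgamma = {
      if (is.null(variance$c))
        stop("inverse-gamma variance spec needs `c`", call. = FALSE)
      invgamma_variance(S = if (is.null(variance$S)) S else variance$S,
                        c = variance$c)
    },
    stop("unknown variance kind: ", variance$kind, call. = FALSE)
  )
}
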