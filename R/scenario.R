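#' Design scenarios
#'
#' A scenario bundles everything needed to synthesise a collective prior:
#' the historical summaries (with their incommensurability weights), the
#' Gamma mixture prior on the predictive precisions, and the concentration
#' parameter of the synthesis weights.
#'
#' @param sources a [historical_summary()] data frame.
#' @param mixture a [precision_mixture()]; default Gamma(2,2)/Gamma(18,3).
#' @param s0 synthesis-weight concentration parameter (default 0.05).
#' @param name optional label.
#' @return An object of class `"ssd_scenario"`.
#' @export
scenario <- function(sources, mixture = precision_mixture(), s0 = 0.05,
                     name = "") {
  if (!inherits(sources, "historical_summary"))
    sources <- historical_summary(sources$mean, sources$variance, sources$w)
  stopifnot(inherits(mixture, "precision_mixture"))
  if (!is.finite(s0) || s0 <= 0) stop("`s0` must be positive", call. = FALSE)
  structure(list(name = name, sources = sources, mixture = mixture, s0 = s0),
            class = "ssd_scenario")
}

#' @export
print.ssd_scenario <- function(x, ...) {
  cat(sprintf("Scenario%s: %d sources, s0 = %g\n",
              if (nzchar(x$name)) paste0(" '", x$name, "'") else "",
              nrow(x$sources), x$s0))
  print(x$sources)
  print(x$mixture)
  invisible(x)
}

as_scenario <- function(x) {
  if (inherits(x, "ssd_scenario")) return(x)
  if (inherits(x, "historical_summary")) return(scenario(x))
  stop("expected an `ssd_scenario` or `historical_summary`", call. = FALSE)
}

# Hypothetical historical-data configurations used throughout the
# performance evaluation: four base configurations of five N(m_k, s_k^2)
# summaries, each paired with two alternative sets of robust weights.
# Only m_k, s_k^2, w_k are stored; synthesis weights and collective-prior
# moments are always recomputed.
.table1 <- list(
  config1 = list(
    m = c(-0.260, -0.240, -0.370, -0.340, -0.320),
    s2 = c(0.250, 0.230, 0.220, 0.360, 0.260),
    w = list(I = c(0.103, 0.175, 0.081, 0.143, 0.077),
             II = c(0.252, 0.319, 0.140, 0.306, 0.149))
  ),
  config2 = list(
    m = c(-0.260, -0.240, -0.370, -0.340, -0.320),
    s2 = rep(0.100, 5),
    w = list(I = c(0.103, 0.175, 0.081, 0.143, 0.077),
             II = c(0.252, 0.319, 0.140, 0.306, 0.149))
  ),
  config3 = list(
    m = c(-0.260, -0.170, -0.440, -0.150, 0.120),
    s2 = c(0.250, 0.640, 0.970, 1.540, 0.590),
    w = list(I = c(0.101, 0.219, 0.385, 0.385, 0.304),
             II = c(0.325, 0.203, 0.171, 0.180, 0.272))
  ),
  config4 = list(
    m = c(-0.260, -0.170, -0.440, -0.150, 0.120),
    s2 = c(0.250, 0.150, 0.400, 0.890, 0.220),
    w = list(I = c(0.066, 0.303, 0.459, 0.355, 0.115),
             II = c(0.537, 0.306, 0.054, 0.220, 0.350))
  )
)

#' Benchmark scenario fixtures
#'
#' The four hypothetical historical-data configurations used in the
#' performance evaluation, each available with robust-weight sets I and II
#' (eight scenarios in total, named `config1_I`, ..., `config4_II`). All use
#' the default Gamma(2,2)/Gamma(18,3) mixture and `s0 = 0.05`; synthesis
#' weights and collective-prior moments are recomputed on demand, never
#' stored.
#'
#' @param configs which configurations to include (subset of 1:4).
#' @param weights which weight sets to include (subset of `c("I", "II")`).
#' @return A named list of [scenario()] objects.
#' @examples
#' collective_prior(load_scenarios()$config1_I$sources)
#' @export
load_scenarios <- function(configs = 1:4, weights = c("I", "II")) {
  stopifnot(all(configs %in% 1:4), all(weights %in% c("I", "II")))
  out <- list()
  for (i in configs) {
    cfg <- .table1[[paste0("config", i)]]
    for (ws in weights) {
      nm <- sprintf("config%d_%s", i, ws)
      out[[nm]] <- scenario(
        historical_summary(cfg$m, cfg$s2, cfg$w[[ws]]),
        name = nm
      )
    }
  }
  out
}

#' The worked rare-disease application scenario
#'
#' Five expert-opinion summaries of a log-odds ratio of remission,
#' N(-0.26, 0.25), N(-0.24, 0.23), N(-0.37, 0.22), N(-0.34, 0.36),
#' N(-0.32, 0.26), with incommensurability weights
#' (0.15, 0.20, 0.17, 0.13, 0.20), the default mixture, and s0 = 0.05.
#'
#' @return A [scenario()].
#' @export
application_scenario <- function() {
  scenario(
    historical_summary(
      mean     = c(-0.26, -0.24, -0.37, -0.34, -0.32),
      variance = c(0.25, 0.23, 0.22, 0.36, 0.26),
      w        = c(0.15, 0.20, 0.17, 0.13, 0.20)
    ),
    name = "application"
  )
}
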