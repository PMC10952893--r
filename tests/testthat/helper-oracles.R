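# Shared fixtures and independent numerical oracles.

app_prior <- function() collective_prior(application_scenario()$sources)

# Second central moment of the t-mixture predictive density by quadrature,
# independent of the closed-form moment match.
quadrature_mixture_variance <- function(mix, w, theta = 0) {
  stats::integrate(function(x) (x - theta)^2 * t_mixture_pdf(x, theta, mix, w),
                   -Inf, Inf, rel.tol = 1e-9)$value
}

# Inverse-gamma density on the variance scale, via the Gamma density of the
# precision and the change-of-variables Jacobian 1/v^2.
invgamma_density <- function(v, shape, scale) {
  stats::dgamma(1 / v, shape = shape, rate = scale) / v^2
}

# Grid-based posterior moments from an explicit Bayes update (independent of
# the conjugate algebra in posterior_known_var).
grid_posterior_moments <- function(prior_mean, prior_var, xbar, v_dat,
                                   half_width = 12, n = 20001) {
  sd0 <- sqrt(prior_var + v_dat)
  mu <- seq(prior_mean - half_width * sd0, prior_mean + half_width * sd0,
            length.out = n)
  dens <- stats::dnorm(mu, prior_mean, sqrt(prior_var)) *
    stats::dnorm(xbar, mu, sqrt(v_dat))
  dens <- dens / sum(dens)
  m <- sum(mu * dens)
  list(mean = m, var = sum((mu - m)^2 * dens))
}
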