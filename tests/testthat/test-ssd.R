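test_that("z_quantile is the upper-tail standard normal quantile", {
  expect_equal(round(z_quantile(0.025), 5), 1.95996)
  expect_equal(z_quantile(0.5), 0)
  for (q in seq(0.01, 0.99, by = 0.07))
    expect_equal(pnorm(z_quantile(q)), 1 - q)
  expect_error(z_quantile(1.2), "\\(0, 1\\)")
})

test_that("required information level clamps at zero when the prior suffices", {
  model <- known_variance(0.35)
  # ACC: prior variance small enough that 4z^2/l0^2 <= 1/S
  S_small <- 0.9 * (0.65^2 / (4 * z_quantile(0.025)^2))
  expect_equal(required_q_acc(S_small, l0 = 0.65, alpha = 0.05, model), 0)
  # APVC: target at or above the prior variance
  expect_equal(required_q_apvc(0.03, eps0 = 0.03, model), 0)
  expect_equal(required_q_apvc(0.02, eps0 = 0.03, model), 0)
  expect_gt(required_q_apvc(0.2, eps0 = 0.03, model), 0)
})

test_that("allocation solves the harmonic-mean constraint", {
  a <- allocate(10.456, ratio = 1)
  expect_equal(a$total, 4 * 10.456)
  expect_equal(a$nA, a$nB)
  a2 <- allocate(7, ratio = 2)
  expect_equal(a2$nB, 1.5 * 7)
  expect_equal(a2$nA, 3 * 7)
  expect_equal(a2$nA * a2$nB / (a2$nA + a2$nB), 7)
  a3 <- allocate(10.456, ratio = 1, policy = "integer_total")
  expect_equal(a3$total, 42)
})

test_that("ACC and ALC coincide when the variance is known", {
  sc <- application_scenario()
  acc <- ssd_design(sc, acc_criterion(0.65, 0.05),
                    list(kind = "known", sigma02 = 0.35))
  # at the continuous ACC arms the deterministic interval length is exactly l0
  expect_equal(alc_expected_length(acc$prior$variance, acc$nA, acc$nB, 0.05,
                                   known_variance(0.35)), 0.65)
  alc <- ssd_design(sc, alc_criterion(0.65, 0.05),
                    list(kind = "known", sigma02 = 0.35))
  expect_equal(alc$total, ceiling(acc$total))
  expect_equal(round(acc$total, 1), 41.8)
})

test_that("ALC search returns the smallest feasible integer total", {
  S <- app_prior()$variance
  vm <- invgamma_variance(S, c = 5)
  sol <- solve_alc(S, l = 0.65, alpha0 = 0.05, model = vm)
  expect_equal(sol$total, 24)
  # minimality and feasibility, re-checked directly
  expect_lte(alc_expected_length(S, 12, 12, 0.05, vm), 0.65)
  expect_gt(alc_expected_length(S, 11.5, 11.5, 0.05, vm), 0.65)
  # huge target: the prior alone suffices
  sol0 <- solve_alc(S, l = 10 * sqrt(S), alpha0 = 0.05, model = vm)
  expect_equal(sol0$total, 0)
  expect_equal(sol0$attained, 2 * z_quantile(0.025) * sqrt(S))
  # even-total policy never returns an odd total and is never smaller
  sol_even <- solve_alc(S, l = 0.65, alpha0 = 0.05, model = vm,
                        policy = "even_total")
  expect_equal(sol_even$total %% 2, 0)
  expect_gte(sol_even$total, sol$total)
})

test_that("attained criterion values satisfy their bounds", {
  sc <- application_scenario()
  for (variance in list(list(kind = "known", sigma02 = 0.35),
                        list(kind = "invgamma", c = 5))) {
    acc <- ssd_design(sc, acc_criterion(0.65, 0.05), variance)
    expect_equal(acc$attained, 0.95, tolerance = 1e-9)
    expect_equal(acc$nA * acc$nB / (acc$nA + acc$nB), acc$Q)
    apvc <- ssd_design(sc, apvc_criterion(0.03), variance)
    expect_equal(apvc$attained, 0.03, tolerance = 1e-9)
    alc <- ssd_design(sc, alc_criterion(0.65, 0.05), variance)
    expect_lte(alc$attained, 0.65)
  }
})

test_that("robust totals are bracketed by no-robustification and no-borrowing", {
  criteria <- list(acc = acc_criterion(0.65, 0.05),
                   alc = alc_criterion(0.65, 0.05),
                   apvc = apvc_criterion(0.03))
  for (sc in load_scenarios()) {
    for (crit in criteria) {
      totals <- sapply(c("no_robustification", "robust", "no_borrowing"),
                       function(st) ssd_design(sc, crit,
                                               list(kind = "invgamma", c = 3),
                                               strategy = st)$total)
      expect_true(totals[1] <= totals[2] && totals[2] <= totals[3],
                  label = sprintf("%s / %s: %s", sc$name, crit$kind,
                                  paste(round(totals, 1), collapse = " <= ")))
    }
  }
})

test_that("totals shrink with laxer targets and grow with coverage demands", {
  sc <- application_scenario()
  vm <- list(kind = "invgamma", c = 3)
  tot_l0 <- sapply(c(0.5, 0.65, 0.8),
                   function(l0) ssd_design(sc, acc_criterion(l0, 0.05), vm)$total)
  expect_true(all(diff(tot_l0) < 0))
  tot_alpha <- sapply(c(0.10, 0.05, 0.025),
                      function(a) ssd_design(sc, acc_criterion(0.65, a), vm)$total)
  expect_true(all(diff(tot_alpha) > 0))
  tot_eps <- sapply(c(0.02, 0.03, 0.05),
                    function(e) ssd_design(sc, apvc_criterion(e), vm)$total)
  expect_true(all(diff(tot_eps) < 0))
  tot_l <- sapply(c(0.55, 0.65, 0.8),
                  function(l) ssd_design(sc, alc_criterion(l, 0.05), vm)$total)
  expect_true(all(diff(tot_l) <= 0))
})

test_that("totals decrease in c and converge to the optimal benchmark", {
  sc <- application_scenario()
  cs <- c(3, 5, 10, 20, 30, 40)
  acc <- sapply(cs, function(c) ssd_design(sc, acc_criterion(0.65, 0.05),
                                           list(kind = "invgamma", c = c))$total)
  alc <- sapply(cs, function(c) ssd_design(sc, alc_criterion(0.65, 0.05),
                                           list(kind = "invgamma", c = c))$total)
  expect_true(all(diff(acc) < 0))
  expect_true(all(diff(alc) <= 0))
  # ALC below ACC for weakly informative variance priors
  expect_lt(alc[1], acc[1])
  # near-identical for c >= 20
  expect_true(all(abs(acc[cs >= 20] - alc[cs >= 20]) <= 1))
  # c -> infinity approaches the known-variance design at sigma0^2 = S
  opt <- ssd_design(sc, acc_criterion(0.65, 0.05), strategy = "optimal")
  huge <- ssd_design(sc, acc_criterion(0.65, 0.05),
                     list(kind = "invgamma", c = 1e7))
  expect_equal(huge$total, opt$total, tolerance = 1e-5)
})

test_that("comparator strategies transform the prior as documented", {
  sc <- load_scenarios(1, "I")$config1_I
  nb <- ssd_design(sc, acc_criterion(0.65), list(kind = "invgamma", c = 3),
                   strategy = "no_borrowing")
  expect_equal(nb$prior$components$p, rep(0.2, 5))
  expect_equal(nb$prior$components$xi2, sc$sources$variance + 2)
  nr <- ssd_design(sc, acc_criterion(0.65), list(kind = "invgamma", c = 3),
                   strategy = "no_robustification")
  expect_equal(nr$prior$components$xi2, sc$sources$variance + 3 / 17)
  ss <- ssd_design(sc, acc_criterion(0.65), list(kind = "invgamma", c = 3),
                   strategy = "single_source")
  k <- which.min(sc$sources$variance)
  expect_equal(ss$prior$mean, sc$sources$mean[k])
  expect_equal(ss$prior$variance, sc$sources$variance[k])
  opt <- ssd_design(sc, acc_criterion(0.65), strategy = "optimal")
  expect_equal(opt$model$kind, "known")
  expect_equal(opt$model$sigma02, opt$prior$variance)
})

test_that("infeasible or invalid specifications error out", {
  expect_error(acc_criterion(-0.1), "positive")
  expect_error(alc_criterion(0.65, alpha0 = 1.2), "\\(0, 1\\)")
  expect_error(apvc_criterion(0), "positive")
  sc <- application_scenario()
  expect_error(ssd_design(sc, acc_criterion(0.65),
                          list(kind = "invgamma", c = 2)), "c <= 2")
  # ALC remains solvable at c = 2 (the expectation of sigma_N always exists)
  expect_gt(ssd_design(sc, alc_criterion(0.65),
                       list(kind = "invgamma", c = 2))$total, 0)
})
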