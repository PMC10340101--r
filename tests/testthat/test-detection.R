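test_that("removal MLE matches the grid-search oracle and handles boundaries", {
  # perfect first-observer detection
  fit <- fit_removal_fi(make_removal_events(40, 0))
  expect_equal(fit$params[["p"]], 1)
  expect_equal(fit$P_hat, 1)
  expect_equal(fit$se_P, 0)

  # the closed form 1 - n2/n1 is verified against the oracle, not assumed
  cases <- list(c(40, 10), c(17, 5), c(120, 80), c(3, 1), c(55, 27))
  for (cs in cases) {
    n1 <- cs[1]; n2 <- cs[2]
    p_grid <- grid_removal_mle(n1, n2)
    fit <- fit_removal_fi(make_removal_events(n1, n2))
    # grid resolution is 1e-6, so agreement is asserted absolutely
    expect_lt(abs(fit$params[["p"]] - p_grid), 2e-6)
    expect_lt(abs(p_grid - (1 - n2 / n1)), 2e-6)
    expect_equal(fit$P_hat, 1 - (1 - fit$params[["p"]])^2, tolerance = 1e-12)
    # union of two observers cannot detect less than one
    expect_gte(fit$P_hat, fit$params[["p"]])
  }

  expect_error(fit_removal_fi(make_removal_events(0, 5)), "first-observer")
  expect_error(fit_removal_fi(make_removal_events(10, 10)), "p <= 0")
  expect_error(fit_removal_fi(make_removal_events(10, 12)), "undefined")
})

test_that("removal P_hat increases in p and its SE matches the observed information", {
  p_seq <- seq(0.1, 0.99, by = 0.05)
  P <- 1 - (1 - p_seq)^2
  expect_true(all(diff(P) > 0))

  fit <- fit_removal_fi(make_removal_events(40, 10))
  # analytic observed information at p = 0.75
  info <- 10 / 0.25^2 - 50 / 1.25^2
  expect_equal(unname(fit$vcov[1, 1]), 1 / info, tolerance = 1e-8)
  expect_equal(fit$se_P, 2 * 0.25 * sqrt(1 / info), tolerance = 1e-8)
})

test_that("half-normal detection function evaluates correctly", {
  expect_equal(halfnormal_g(0, 0.73, 0.4), 0.73)
  expect_equal(halfnormal_g(1, 1, 1e9), 1, tolerance = 1e-9)
  expect_equal(halfnormal_g(0.5, 1, 0.5), exp(-1 / 2), tolerance = 1e-12)
  expect_equal(halfnormal_g(c(0, 0.3), 0.8, 0.4),
               0.8 * exp(-c(0, 0.09) / 0.32), tolerance = 1e-12)
  expect_error(halfnormal_g(-1, 0.5, 1), "y must")
  expect_error(halfnormal_g(1, 0, 1), "p0")
  expect_error(halfnormal_g(1, 0.5, 0), "sigma")
})

test_that("strip-average detection matches limits and the trapezoid oracle", {
  expect_equal(average_detection(1, 1e9, 1), 1, tolerance = 1e-8)
  expect_equal(average_detection(0.5, 1e9, 2.5), 0.75, tolerance = 1e-8)
  for (pars in list(c(0.8, 0.4, 1), c(0.3, 0.2, 1), c(0.95, 1.5, 2))) {
    expect_equal(average_detection(pars[1], pars[2], pars[3]),
                 trapezoid_average_detection(pars[1], pars[2], pars[3]),
                 tolerance = 1e-6)
  }
})

test_that("distance-removal fit recovers truth and maximises the likelihood", {
  set.seed(2024)
  ev <- simulate_dr_events(800, p0 = 0.8, sigma = 0.4, w = 1)
  fit <- fit_distance_removal(ev, w = 1)
  se <- sqrt(diag(fit$vcov))
  expect_lt(abs(fit$params[["p0"]] - 0.8), 3 * se[["p0"]])
  expect_lt(abs(fit$params[["sigma"]] - 0.4), 3 * se[["sigma"]])
  expect_equal(fit$P_hat,
               average_detection(fit$params[["p0"]], fit$params[["sigma"]], 1),
               tolerance = 1e-8)

  # likelihood at the optimum is at least the likelihood at truth
  ll_truth <- stripdens:::dr_loglik(c(qlogis(0.8), log(0.4)),
                                    ev$distance_m,
                                    as.integer(ev$history == "second_observer_only"),
                                    1, 0, 0)
  expect_gte(fit$loglik + 1e-6, ll_truth)
})

test_that("distance-removal log-likelihood is order invariant and doubles under duplication", {
  set.seed(5)
  ev <- simulate_dr_events(120, 0.7, 0.5, 1)
  fit <- fit_distance_removal(ev, w = 1)
  shuffled <- ev[sample(nrow(ev)), ]
  fit_s <- fit_distance_removal(shuffled, w = 1)
  expect_equal(fit_s$loglik, fit$loglik, tolerance = 1e-6)
  expect_equal(fit_s$params, fit$params, tolerance = 1e-4)
  doubled <- rbind(ev, ev)
  th <- c(qlogis(fit$params[["p0"]]), log(fit$params[["sigma"]]))
  ll1 <- stripdens:::dr_loglik(th, ev$distance_m,
                               as.integer(ev$history == "second_observer_only"),
                               1, 0, 0)
  ll2 <- stripdens:::dr_loglik(th, doubled$distance_m,
                               as.integer(doubled$history == "second_observer_only"),
                               1, 0, 0)
  expect_equal(ll2, 2 * ll1, tolerance = 1e-9)
})

test_that("distance-removal fit handles the p0 -> 1 boundary and missing distances", {
  # all first-observer histories with distances near zero push p0 to 1;
  # the logit internal scale must not overflow
  set.seed(9)
  ev <- data.frame(transect_id = "t01", history = "first_observer",
                   distance_m = abs(rnorm(60, 0, 0.05)),
                   cluster_size = 1L)
  ev$distance_m <- pmin(ev$distance_m, 1)
  fit <- suppressWarnings(fit_distance_removal(ev, w = 1))
  expect_true(is.finite(fit$loglik))
  expect_gt(fit$params[["p0"]], 0.9)

  # events without recorded distances still contribute their history
  set.seed(10)
  ev2 <- simulate_dr_events(300, 0.8, 0.4, 1)
  ev2$distance_m[1:80] <- NA_real_
  fit2 <- fit_distance_removal(ev2, w = 1)
  expect_true(is.finite(fit2$loglik))
  expect_lt(abs(fit2$params[["p0"]] - 0.8), 4 * sqrt(fit2$vcov["p0", "p0"]))

  # degenerate distances: rank-deficiency warning, se_P unavailable not 0
  ev3 <- data.frame(transect_id = "t01",
                    history = rep(c("first_observer", "second_observer_only"),
                                  c(30, 8)),
                    distance_m = 0.3, cluster_size = 1L)
  expect_warning(fit3 <- fit_distance_removal(ev3, w = 1), "rank deficient")
  expect_true(is.na(fit3$se_P))

  expect_error(fit_distance_removal(ev[1:2, ], w = 1), "at least 3")
})

test_that("P_hat increases in p0 and in sigma", {
  base <- average_detection(0.6, 0.5, 1)
  for (p0 in c(0.7, 0.8, 0.9)) {
    expect_gt(average_detection(p0, 0.5, 1), base)
  }
  sig_vals <- c(0.3, 0.5, 0.8, 1.5)
  P_sig <- vapply(sig_vals, function(s) average_detection(0.6, s, 1),
                  numeric(1))
  expect_true(all(diff(P_sig) > 0))
})

test_that("delta-method se_P shrinks with event count in simulation", {
  set.seed(77)
  mean_se <- vapply(c(50, 200, 800), function(n) {
    mean(vapply(1:100, function(i) {
      ev <- simulate_dr_events(n, 0.8, 0.4, 1)
      fit <- tryCatch(suppressWarnings(fit_distance_removal(ev, w = 1)),
                      error = function(e) NULL)
      if (is.null(fit)) NA_real_ else fit$se_P
    }, numeric(1)), na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(mean_se) < 0))
})

test_that("goodness-of-fit binning, df conventions, and calibration behave", {
  set.seed(42)
  ev <- simulate_dr_events(400, 0.8, 0.4, 1)
  fit <- fit_distance_removal(ev, w = 1)

  g <- gof_chisq(fit, ev, k = 5)
  expect_identical(g$df, 2L)          # k - 1 - 2 fitted parameters
  expect_equal(sum(g$expected), length(ev$distance_m), tolerance = 1e-8)
  g7 <- gof_chisq(fit, ev, k = 5, df = 4)
  expect_identical(g7$df, 4L)
  expect_equal(g7$chi2, g$chi2, tolerance = 1e-12)

  # observed exactly equal to expected -> chi2 = 0, p = 1
  fake <- g$expected
  chi2 <- sum((fake - g$expected)^2 / g$expected)
  expect_equal(chi2, 0)
  expect_equal(chisq_gof_pvalue(chi2, g$df), 1)

  expect_error(gof_chisq(fit, ev, k = 3), "degrees of freedom")
  small <- ev[1:6, ]
  expect_warning(gof_chisq(fit, small, k = 5, df = 4), "below 1")

  # simulation-based calibration: data generated from the evaluated model
  # give approximately uniform p-values (params held fixed, df = k - 1)
  set.seed(4242)
  pvals <- vapply(1:400, function(i) {
    e <- simulate_dr_events(150, 0.8, 0.4, 1)
    fixed_fit <- stripdens:::new_detection_fit(
      "distance_removal_hn", c(p0 = 0.8, sigma = 0.4), NA, NA, NA, NULL,
      150L, 1)
    gof_chisq(fixed_fit, e, k = 5, df = 4)$p_value
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(pvals, "punif"))$p.value, 0.01)
})
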