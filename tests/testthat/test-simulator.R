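test_that("population simulation is reproducible and respects intensities", {
  sc <- scenario_burgan_like(seed = 123, n_transects = 5L)
  l1 <- simulate_population(sc)
  l2 <- simulate_population(sc)
  expect_identical(l1$x, l2$x)
  expect_identical(l1$size, l2$size)

  # zero intensity gives an empty lake
  empty <- simulate_population(scenario_florida_like(druse_intensity = 0,
                                                     seed = 1))
  expect_identical(empty$n_druses, 0L)

  # law of large numbers on the Poisson mode
  sc_p <- scenario_florida_like(druse_intensity = 0.2, n_transects = 5L,
                                seed = NULL)
  A <- sc_p$strip_length_m * sc_p$strip_width_m
  set.seed(99)
  counts <- vapply(1:200, function(i)
    simulate_population(sc_p, seed = NULL)$n_druses, numeric(1))
  mc_se <- sqrt(0.2 * A / 200)
  expect_lt(abs(mean(counts) - 0.2 * A), 3 * mc_se)

  expect_error(simulate_population(
    scenario_florida_like(druse_intensity = 1e5)), "1e7")
})

test_that("Thomas clustering produces overdispersed quadrat counts; Poisson does not", {
  set.seed(11)
  sc_t <- scenario_little_birch_like(seed = NULL, n_transects = 5L)
  lake_t <- simulate_population(sc_t, seed = NULL)
  q_t <- simulate_quadrat_survey(lake_t)
  disp_t <- stats::var(q_t$quadrats$count) / mean(q_t$quadrats$count)
  expect_gt(disp_t, 2)

  sc_p <- scenario_florida_like(druse_intensity = 2, seed = NULL,
                                n_transects = 5L)
  lake_p <- simulate_population(sc_p, seed = NULL)
  q_p <- simulate_quadrat_survey(lake_p)
  disp_p <- stats::var(q_p$quadrats$count) / mean(q_p$quadrats$count)
  expect_lt(abs(disp_p - 1), 0.35)
})

test_that("quadrat survey geometry yields 30 counts per full transect", {
  sc <- scenario_burgan_like(seed = 21, n_transects = 3L)
  lake <- simulate_population(sc)
  q <- simulate_quadrat_survey(lake)
  expect_identical(nrow(q$quadrats), 3L * 30L)
  expect_true(all(table(q$quadrats$transect_id) == 30))
  expect_identical(unique(q$transects$n_quadrats), 30L)
  expect_equal(unique(q$transects$quadrat_area_m2), 0.25)
  # subset property: sampled individuals cannot exceed the lake total
  expect_lte(sum(q$quadrats$count), lake$n_individuals)

  # empty lake -> all counts zero
  q0 <- simulate_quadrat_survey(
    simulate_population(scenario_florida_like(druse_intensity = 0, seed = 2)))
  expect_true(all(q0$quadrats$count == 0L))
})

test_that("removal survey detection follows the two-observer binomial model", {
  # p = 1: everything is detected by the first observer
  sc1 <- scenario_burgan_like(removal_p = 1, seed = 31, n_transects = 4L)
  s1 <- simulate_removal_survey(simulate_population(sc1))
  expect_true(all(s1$events$history == "first_observer"))

  # detected fraction approximates 1 - (1-p)^2
  sc <- scenario_little_birch_like(removal_p = 0.75, seed = 32,
                                   n_transects = 10L)
  lake <- simulate_population(sc)
  s <- simulate_removal_survey(lake)
  in_strip <- sum(vapply(stripdens:::transect_centres(sc), function(cx)
    sum(abs(lake$x - cx) <= 0.5 & lake$y >= 0 &
          lake$y <= sc$transect_length_m), numeric(1)))
  P <- 1 - 0.25^2
  expect_lt(abs(nrow(s$events) / in_strip - P),
            3 * sqrt(P * (1 - P) / in_strip))

  # end-to-end recovery of p from the fitted removal model
  fit <- fit_removal_fi(s$events)
  expect_lt(abs(fit$params[["p"]] - 0.75), 3 * sqrt(fit$vcov[1, 1]))
})

test_that("distance survey records distances whose histogram decays with distance", {
  sc <- scenario_little_birch_like(distance_p0 = 0.9, distance_sigma = 0.35,
                                   seed = 41, n_transects = 10L)
  s <- simulate_distance_survey(simulate_population(sc))
  expect_true(all(!is.na(s$events$distance_m)))
  expect_true(all(s$events$distance_m >= 0 & s$events$distance_m <= 1))
  bins <- table(cut(s$events$distance_m, seq(0, 1, by = 0.2)))
  expect_true(all(diff(as.vector(bins)) < 0))

  # p0 = 1 with a flat curve: every in-strip druse detected by observer 1
  sc1 <- scenario_burgan_like(distance_p0 = 1, distance_sigma = 1e9,
                              seed = 42, n_transects = 4L)
  lake1 <- simulate_population(sc1)
  s1 <- simulate_distance_survey(lake1)
  in_strip <- sum(vapply(stripdens:::transect_centres(sc1), function(cx)
    sum(abs(lake1$x - cx) <= 1 & lake1$y >= 0 &
          lake1$y <= sc1$transect_length_m), numeric(1)))
  expect_identical(nrow(s1$events), as.integer(in_strip))
  expect_true(all(s1$events$history == "first_observer"))
})

test_that("generated collections pass survey_io validation and round-trip", {
  sc <- scenario_burgan_like(seed = 51, n_transects = 4L)
  lake <- simulate_population(sc)
  for (s in list(simulate_removal_survey(lake), simulate_distance_survey(lake))) {
    expect_s3_class(as_detection_table(s$events, s$transects),
                    "detection_table")
  }
  q <- simulate_quadrat_survey(lake)
  expect_s3_class(as_quadrat_table(q$quadrats, q$transects), "quadrat_table")
})

test_that("recovery experiments are deterministic under a fixed seed", {
  sc <- scenario_burgan_like(seed = NULL, n_transects = 5L)
  r1 <- recovery_experiment(sc, replicates = 2, seed = 7,
                            designs = c("quadrat", "removal"))
  r2 <- recovery_experiment(sc, replicates = 2, seed = 7,
                            designs = c("quadrat", "removal"))
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  expect_identical(attr(r1, "replicates")$D_hat, attr(r2, "replicates")$D_hat)
  # failures are recorded, not fatal: a scenario that often yields n2 >= n1
  sc_bad <- scenario_florida_like(druse_intensity = 0.002, removal_p = 0.3,
                                  n_transects = 2L, seed = NULL)
  r3 <- recovery_experiment(sc_bad, replicates = 3, seed = 8,
                            designs = "removal")
  reps <- attr(r3, "replicates")
  expect_true(all(is.na(reps$D_hat) == !is.na(reps$failure)))
})

test_that("scenario YAML files load with validation", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("label: demo",
               "druse_intensity: 0.3",
               "cluster_size_law:",
               "  law: ztpois",
               "  mean: 1.5",
               "n_transects: 4",
               "seed: 5"), path)
  sc <- scenario_from_yaml(path)
  expect_s3_class(sc, "sim_scenario")
  expect_equal(true_density(sc), 0.45)

  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("druse_intensity: 0.3", "not_a_field: 2"), bad)
  expect_error(scenario_from_yaml(bad), "unknown scenario field")
})

test_that("true density matches the closed-form law means", {
  expect_equal(true_density(scenario_florida_like()), 0.05)
  expect_equal(true_density(scenario_burgan_like()), 0.5 * 1.2)
  expect_equal(true_density(scenario_little_birch_like()), 4 * 6)
  # sampled sizes match the requested truncated means
  set.seed(6)
  s_p <- stripdens:::sample_sizes(20000, list(law = "ztpois", mean = 1.2))
  expect_lt(abs(mean(s_p) - 1.2), 3 * stats::sd(s_p) / sqrt(20000))
  s_nb <- stripdens:::sample_sizes(20000,
                                   list(law = "ztnb", mean = 6, dispersion = 0.8))
  expect_lt(abs(mean(s_nb) - 6), 3 * stats::sd(s_nb) / sqrt(20000))
  expect_true(all(s_nb >= 1))
})
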