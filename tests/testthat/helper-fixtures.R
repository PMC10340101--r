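# Builders for small in-memory survey tables and independent oracles used
# across the test files.

make_transects <- function(designs = c("removal", "distance"),
                           length_m = 30, lake = "testlake") {
  hw <- ifelse(designs == "removal", 0.5,
               ifelse(designs == "distance", 1, NA_real_))
  as_transect_table(data.frame(
    transect_id = sprintf("t%02d", seq_along(designs)),
    lake = lake, design = designs, length_m = length_m, half_width_m = hw,
    n_quadrats = ifelse(designs == "quadrat", 30L, NA_integer_),
    quadrat_area_m2 = ifelse(designs == "quadrat", 0.25, NA_real_),
    stringsAsFactors = FALSE))
}

make_removal_events <- function(n1, n2, transect_id = "t01", sizes = 1L) {
  data.frame(
    transect_id = transect_id,
    history = c(rep("first_observer", n1), rep("second_observer_only", n2)),
    distance_m = NA_real_,
    cluster_size = sizes,
    stringsAsFactors = FALSE)
}

random_transect_df <- function(n) {
  design <- sample(c("quadrat", "removal", "distance"), n, replace = TRUE)
  data.frame(
    transect_id = sprintf("r%03d", seq_len(n)),
    lake = sample(LETTERS[1:3], n, replace = TRUE),
    design = design,
    length_m = round(stats::runif(n, 5, 50), 6),
    half_width_m = ifelse(design == "quadrat", NA_real_,
                          round(stats::runif(n, 0.3, 2), 6)),
    n_quadrats = ifelse(design == "quadrat",
                        sample(10:40, n, replace = TRUE), NA_integer_),
    quadrat_area_m2 = ifelse(design == "quadrat", 0.25, NA_real_),
    stringsAsFactors = FALSE)
}

# Independent removal-model oracle: two-stage grid search over p (coarse
# 1e-3 grid, then a 1e-6 grid on the bracketing window), maximising the
# conditional likelihood directly.
grid_removal_mle <- function(n1, n2) {
  ll <- function(p) (n1 + n2) * log(p) + n2 * log(1 - p) -
    (n1 + n2) * log(p * (2 - p))
  coarse <- seq(1e-3, 1 - 1e-3, by = 1e-3)
  p0 <- coarse[which.max(ll(coarse))]
  fine <- seq(max(1e-6, p0 - 2e-3), min(1 - 1e-6, p0 + 2e-3), by = 1e-6)
  fine[which.max(ll(fine))]
}

# Brute-force trapezoid quadrature of the strip-average combined detection.
trapezoid_average_detection <- function(p0, sigma, w, n_points = 1e6) {
  y <- seq(0, w, length.out = n_points + 1)
  g <- p0 * exp(-y^2 / (2 * sigma^2))
  f <- 1 - (1 - g)^2
  sum((f[-1] + f[-length(f)]) / 2 * diff(y)) / w
}

# Sample perpendicular distances/histories from the distance-removal model
# itself (rejection from the uniform strip), used for calibration tests.
simulate_dr_events <- function(n, p0, sigma, w) {
  y <- numeric(0); h <- character(0)
  while (length(y) < n) {
    m <- max(2 * n, 100)
    yy <- stats::runif(m, 0, w)
    g <- p0 * exp(-yy^2 / (2 * sigma^2))
    d1 <- stats::runif(m) < g
    d2 <- !d1 & stats::runif(m) < g
    det <- d1 | d2
    y <- c(y, yy[det])
    h <- c(h, ifelse(d1[det], "first_observer", "second_observer_only"))
  }
  data.frame(transect_id = "t01", history = h[seq_len(n)],
             distance_m = y[seq_len(n)], cluster_size = 1L,
             stringsAsFactors = FALSE)
}
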