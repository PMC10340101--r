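#' Define a synthetic survey scenario
#'
#' A scenario describes a shoreline strip populated by druses (mussel
#' clusters, each a point with an integer size), the cluster-size law, the
#' observer detection parameters for each survey design, and the transect
#' layout. Druse locations follow either a homogeneous Poisson process
#' (\code{druse_intensity}) or a Thomas cluster process
#' (\code{parent_intensity}, \code{mean_offspring}, \code{dispersal_sd}):
#' parent points model patches of hard substrate, each spawning a
#' Poisson-distributed number of druses scattered around it with an
#' isotropic Gaussian of the given standard deviation.
#'
#' The true individual density is available in closed form:
#' \code{D_true = (expected druse intensity) x (mean cluster size)}.
#'
#' @param label Scenario name.
#' @param strip_length_m,strip_width_m Dimensions of the simulated shoreline
#'   strip (metres); the strip runs along shore in \code{x}, transects run
#'   perpendicular to shore in \code{y}. Defaults are derived from the
#'   transect layout.
#' @param druse_intensity Druses per m² for the Poisson mode; \code{NULL}
#'   when using the Thomas mode.
#' @param parent_intensity,mean_offspring,dispersal_sd Thomas-process
#'   parameters: parent patches per m², mean druses per patch, Gaussian
#'   scatter standard deviation (m).
#' @param cluster_size_law One of \code{list(law = "fixed_one")},
#'   \code{list(law = "ztpois", mean = m)} (zero-truncated Poisson with mean
#'   \code{m} of the truncated law), or
#'   \code{list(law = "ztnb", mean = m, dispersion = k)} (zero-truncated
#'   negative binomial; \code{dispersion} is the NB size parameter, smaller
#'   values give heavier tails).
#' @param removal_p Per-observer detection probability in the 1-m removal
#'   strip.
#' @param distance_p0,distance_sigma Half-normal detection parameters for
#'   the distance design (detection at the line; scale in metres).
#' @param quadrat_miscount_sd Optional per-quadrat Gaussian miscount SD for
#'   sensitivity runs (default 0 = perfect counts).
#' @param size_effect Optional exponent making per-observer detection scale
#'   as \code{size^size_effect} (capped at 1); default 0 = detection does
#'   not depend on cluster size, matching the fitted models.
#' @param n_transects,transect_length_m,transect_spacing_m Transect layout:
#'   \code{n_transects} transects of the given length, placed
#'   perpendicular to shore at fixed spacing along the strip.
#' @param removal_half_width_m,distance_half_width_m Half-widths of the
#'   removal strip (default 0.5: a 1-m strip between two lines) and the
#'   distance strip (default 1: up to 1 m either side of a single line).
#' @param quadrat_side_m,quadrat_spacing_m,line_spacing_m Quadrat geometry:
#'   square quadrats of the given side placed every
#'   \code{quadrat_spacing_m} starting at 0 m along each of two parallel
#'   lines \code{line_spacing_m} apart.
#' @param seed Default seed used by [simulate_population()] when no seed is
#'   passed explicitly.
#' @return An object of class \code{"sim_scenario"}.
#' @seealso [scenario_florida_like()], [scenario_burgan_like()],
#'   [scenario_little_birch_like()], [simulate_population()]
#' @export
sim_scenario <- function(label = "scenario",
                         strip_length_m = NULL,
                         strip_width_m = NULL,
                         druse_intensity = NULL,
                         parent_intensity = NULL,
                         mean_offspring = NULL,
                         dispersal_sd = NULL,
                         cluster_size_law = list(law = "fixed_one"),
                         removal_p = 0.75,
                         distance_p0 = 0.8,
                         distance_sigma = 0.4,
                         quadrat_miscount_sd = 0,
                         size_effect = 0,
                         n_transects = 15L,
                         transect_length_m = 30,
                         transect_spacing_m = 20,
                         removal_half_width_m = 0.5,
                         distance_half_width_m = 1,
                         quadrat_side_m = 0.5,
                         quadrat_spacing_m = 2,
                         line_spacing_m = 1,
                         seed = 1L) {
  thomas <- !is.null(parent_intensity)
  if (thomas) {
    if (is.null(mean_offspring) || is.null(dispersal_sd)) {
      stop("Thomas mode needs parent_intensity, mean_offspring and ",
           "dispersal_sd", call. = FALSE)
    }
    stopifnot(parent_intensity >= 0, mean_offspring > 0, dispersal_sd > 0)
    intensity <- parent_intensity * mean_offspring
  } else {
    if (is.null(druse_intensity)) {
      stop("supply either druse_intensity (Poisson) or parent_intensity + ",
           "mean_offspring + dispersal_sd (Thomas)", call. = FALSE)
    }
    stopifnot(druse_intensity >= 0)
    intensity <- druse_intensity
  }
  check_size_law(cluster_size_law)
  stopifnot(removal_p > 0, removal_p <= 1,
            distance_p0 > 0, distance_p0 <= 1, distance_sigma > 0,
            quadrat_miscount_sd >= 0, size_effect >= 0,
            n_transects >= 1, transect_length_m > 0, transect_spacing_m > 0,
            removal_half_width_m > 0, distance_half_width_m > 0,
            quadrat_side_m > 0, quadrat_spacing_m > 0, line_spacing_m > 0)
  if (is.null(strip_length_m)) strip_length_m <- n_transects * transect_spacing_m
  if (is.null(strip_width_m)) strip_width_m <- transect_length_m
  if (strip_width_m < transect_length_m) {
    stop("strip_width_m must be at least transect_length_m", call. = FALSE)
  }
  max_hw <- max(distance_half_width_m,
                line_spacing_m / 2 + quadrat_side_m / 2,
                removal_half_width_m)
  if (transect_spacing_m < 2 * max_hw) {
    stop("transect spacing too small: surveyed strips would overlap",
         call. = FALSE)
  }
  if (strip_length_m < n_transects * transect_spacing_m) {
    stop("strip_length_m too short for the transect layout", call. = FALSE)
  }
  structure(list(
    label = label, strip_length_m = strip_length_m,
    strip_width_m = strip_width_m,
    thomas = thomas, druse_intensity = intensity,
    parent_intensity = parent_intensity, mean_offspring = mean_offspring,
    dispersal_sd = dispersal_sd,
    cluster_size_law = cluster_size_law,
    removal_p = removal_p, distance_p0 = distance_p0,
    distance_sigma = distance_sigma,
    quadrat_miscount_sd = quadrat_miscount_sd, size_effect = size_effect,
    n_transects = as.integer(n_transects),
    transect_length_m = transect_length_m,
    transect_spacing_m = transect_spacing_m,
    removal_half_width_m = removal_half_width_m,
    distance_half_width_m = distance_half_width_m,
    quadrat_side_m = quadrat_side_m, quadrat_spacing_m = quadrat_spacing_m,
    line_spacing_m = line_spacing_m, seed = as.integer(seed)
  ), class = "sim_scenario")
}

check_size_law <- function(law) {
  if (!is.list(law) || is.null(law$law)) {
    stop("cluster_size_law must be a list with a 'law' element", call. = FALSE)
  }
  switch(law$law,
         fixed_one = invisible(TRUE),
         ztpois = {
           if (is.null(law$mean) || law$mean < 1) {
             stop("ztpois law needs mean >= 1", call. = FALSE)
           }
         },
         ztnb = {
           if (is.null(law$mean) || law$mean < 1 || is.null(law$dispersion) ||
               law$dispersion <= 0) {
             stop("ztnb law needs mean >= 1 and dispersion > 0", call. = FALSE)
           }
         },
         stop("unknown cluster_size_law: ", law$law, call. = FALSE))
  invisible(TRUE)
}

#' Mean of a cluster-size law (closed form)
#'
#' @param law A cluster-size law as in [sim_scenario()].
#' @return The mean cluster size implied by the law.
#' @export
size_law_mean <- function(law) {
  check_size_law(law)
  switch(law$law, fixed_one = 1, ztpois = law$mean, ztnb = law$mean)
}

#' True individual density of a scenario
#'
#' @param scenario A \code{sim_scenario}.
#' @return Individuals per m²: expected druse intensity times the mean of
#'   the cluster-size law.
#' @export
true_density <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  scenario$druse_intensity * size_law_mean(scenario$cluster_size_law)
}

# Solve for the untruncated parameter giving a zero-truncated mean of m,
# then sample by inverse CDF restricted to {1, 2, ...}.
sample_sizes <- function(n, law) {
  if (n == 0) return(integer(0))
  switch(law$law,
    fixed_one = rep(1L, n),
    ztpois = {
      m <- law$mean
      if (m <= 1 + 1e-9) return(rep(1L, n))
      lam <- stats::uniroot(function(l) l / (1 - exp(-l)) - m,
                            c(1e-9, m), tol = 1e-12)$root
      u <- stats::runif(n, stats::ppois(0, lam), 1)
      as.integer(stats::qpois(u, lam))
    },
    ztnb = {
      m <- law$mean; k <- law$dispersion
      if (m <= 1 + 1e-9) return(rep(1L, n))
      f <- function(mu) mu / (1 - (k / (k + mu))^k) - m
      mu <- stats::uniroot(f, c(1e-9, m), tol = 1e-12)$root
      u <- stats::runif(n, stats::pnbinom(0, size = k, mu = mu), 1)
      as.integer(stats::qnbinom(u, size = k, mu = mu))
    })
}

#' Simulate a synthetic druse population in a shoreline strip
#'
#' Generates druse locations (Poisson or Thomas process; Thomas parents are
#' simulated in a buffered region four dispersal standard deviations wide so
#' edge patches contribute correctly) and independent cluster sizes from the
#' scenario's size law. Fully reproducible from the seed.
#'
#' @param scenario A \code{sim_scenario}.
#' @param seed Integer seed; \code{NULL} continues the current RNG stream,
#'   the default uses \code{scenario$seed}.
#' @return An object of class \code{"synthetic_lake"}: a list with vectors
#'   \code{x}, \code{y}, \code{size}, counts \code{n_druses} and
#'   \code{n_individuals}, and the \code{scenario}.
#' @export
simulate_population <- function(scenario, seed = scenario$seed) {
  stopifnot(inherits(scenario, "sim_scenario"))
  if (!is.null(seed)) set.seed(seed)
  A <- scenario$strip_length_m * scenario$strip_width_m
  expected <- scenario$druse_intensity * A
  if (expected > 1e7) {
    stop("expected druse count ", format(expected, big.mark = ","),
         " exceeds 1e7; reduce intensity or strip size", call. = FALSE)
  }
  if (scenario$thomas) {
    b <- 4 * scenario$dispersal_sd
    Lb <- scenario$strip_length_m + 2 * b
    Wb <- scenario$strip_width_m + 2 * b
    n_par <- stats::rpois(1, scenario$parent_intensity * Lb * Wb)
    if (n_par > 0) {
      px <- stats::runif(n_par, -b, scenario$strip_length_m + b)
      py <- stats::runif(n_par, -b, scenario$strip_width_m + b)
      n_off <- stats::rpois(n_par, scenario$mean_offspring)
      x <- rep(px, n_off) + stats::rnorm(sum(n_off), 0, scenario$dispersal_sd)
      y <- rep(py, n_off) + stats::rnorm(sum(n_off), 0, scenario$dispersal_sd)
      keep <- x >= 0 & x <= scenario$strip_length_m &
        y >= 0 & y <= scenario$strip_width_m
      x <- x[keep]; y <- y[keep]
    } else {
      x <- y <- numeric(0)
    }
  } else {
    n <- stats::rpois(1, expected)
    x <- stats::runif(n, 0, scenario$strip_length_m)
    y <- stats::runif(n, 0, scenario$strip_width_m)
  }
  size <- sample_sizes(length(x), scenario$cluster_size_law)
  structure(list(x = x, y = y, size = size, scenario = scenario,
                 n_druses = length(x), n_individuals = sum(size)),
            class = "synthetic_lake")
}

#' @export
print.synthetic_lake <- function(x, ...) {
  cat(sprintf("Synthetic lake '%s': %d druses, %d individuals over %.0f m2\n",
              x$scenario$label, x$n_druses, x$n_individuals,
              x$scenario$strip_length_m * x$scenario$strip_width_m))
  cat(sprintf("  true density: %.4f individuals/m2\n",
              true_density(x$scenario)))
  invisible(x)
}

transect_centres <- function(scenario) {
  scenario$transect_spacing_m * (seq_len(scenario$n_transects) - 0.5)
}

# per-observer detection probability, optionally size-dependent
obs_detect_prob <- function(base_p, size, size_effect) {
  if (size_effect == 0) return(rep(base_p, length(size)))
  pmin(1, base_p * size^size_effect)
}

#' Simulate a quadrat survey of a synthetic lake
#'
#' Places square quadrats every \code{quadrat_spacing_m} starting at 0 m
#' along each of two parallel lines per transect (the default geometry gives
#' 15 quadrats per line on a 30-m transect, 30 counts per site) and counts
#' the individuals (summed druse sizes) inside each quadrat. Detection is
#' perfect unless \code{quadrat_miscount_sd > 0}.
#'
#' @param lake A \code{synthetic_lake}.
#' @param scenario The scenario to survey under; defaults to the lake's own.
#' @return A list with \code{transects} (a \code{transect_table}) and
#'   \code{quadrats} (a \code{quadrat_table}).
#' @export
simulate_quadrat_survey <- function(lake, scenario = lake$scenario) {
  stopifnot(inherits(lake, "synthetic_lake"))
  centres <- transect_centres(scenario)
  n_per_line <- floor(scenario$transect_length_m / scenario$quadrat_spacing_m)
  side <- scenario$quadrat_side_m
  half_line <- scenario$line_spacing_m / 2
  ids <- sprintf("%s_q%02d", scenario$label, seq_along(centres))
  tr <- as_transect_table(data.frame(
    transect_id = ids, lake = scenario$label, design = "quadrat",
    length_m = scenario$transect_length_m, half_width_m = NA_real_,
    n_quadrats = 2L * n_per_line, quadrat_area_m2 = side^2,
    stringsAsFactors = FALSE))
  rows <- vector("list", length(centres))
  for (j in seq_along(centres)) {
    cj <- centres[j]
    counts <- integer(2L * n_per_line)
    for (line in 1:2) {
      lx <- cj + c(-1, 1)[line] * half_line
      in_x <- lake$x >= lx - side / 2 & lake$x <= lx + side / 2
      yy <- lake$y[in_x]; ss <- lake$size[in_x]
      k <- floor(yy / scenario$quadrat_spacing_m)
      inq <- k < n_per_line & (yy - k * scenario$quadrat_spacing_m) <= side &
        yy >= 0
      if (any(inq)) {
        tot <- tapply(ss[inq], factor(k[inq] + 1, levels = seq_len(n_per_line)),
                      sum)
        tot[is.na(tot)] <- 0
      } else {
        tot <- rep(0, n_per_line)
      }
      counts[(line - 1) * n_per_line + seq_len(n_per_line)] <- as.integer(tot)
    }
    if (scenario$quadrat_miscount_sd > 0) {
      counts <- pmax(0L, counts + as.integer(round(
        stats::rnorm(length(counts), 0, scenario$quadrat_miscount_sd))))
    }
    rows[[j]] <- data.frame(transect_id = ids[j],
                            quadrat_index = seq_along(counts),
                            count = counts, stringsAsFactors = FALSE)
  }
  qt <- as_quadrat_table(do.call(rbind, rows), tr)
  list(transects = tr, quadrats = qt)
}

#' Simulate a two-observer removal survey of a synthetic lake
#'
#' Each druse inside the removal strip (a 1-m-wide band between two parallel
#' lines, by default) is detected by the lead observer with probability
#' \code{removal_p}; misses are detected by the trailing observer with the
#' same probability. Each detected druse yields one event with its capture
#' history and cluster size.
#'
#' @inheritParams simulate_quadrat_survey
#' @return A list with \code{transects} and \code{events} (a
#'   \code{detection_table}; \code{distance_m} is not recorded).
#' @export
simulate_removal_survey <- function(lake, scenario = lake$scenario) {
  stopifnot(inherits(lake, "synthetic_lake"))
  centres <- transect_centres(scenario)
  hw <- scenario$removal_half_width_m
  ids <- sprintf("%s_r%02d", scenario$label, seq_along(centres))
  tr <- as_transect_table(data.frame(
    transect_id = ids, lake = scenario$label, design = "removal",
    length_m = scenario$transect_length_m, half_width_m = hw,
    n_quadrats = NA_integer_, quadrat_area_m2 = NA_real_,
    stringsAsFactors = FALSE))
  rows <- vector("list", length(centres))
  for (j in seq_along(centres)) {
    inb <- abs(lake$x - centres[j]) <= hw & lake$y >= 0 &
      lake$y <= scenario$transect_length_m
    ss <- lake$size[inb]
    m <- length(ss)
    if (m == 0) next
    p <- obs_detect_prob(scenario$removal_p, ss, scenario$size_effect)
    d1 <- stats::runif(m) < p
    d2 <- !d1 & stats::runif(m) < p
    det <- d1 | d2
    if (!any(det)) next
    rows[[j]] <- data.frame(
      transect_id = ids[j],
      history = ifelse(d1[det], "first_observer", "second_observer_only"),
      distance_m = NA_real_, cluster_size = ss[det],
      stringsAsFactors = FALSE)
  }
  ev <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(ev)) {
    ev <- data.frame(transect_id = character(0), history = character(0),
                     distance_m = numeric(0), cluster_size = integer(0))
  }
  list(transects = tr, events = as_detection_table(ev, tr))
}

#' Simulate a distance-removal survey of a synthetic lake
#'
#' Each druse within the distance strip (up to \code{distance_half_width_m}
#' either side of a single line) is detected by each observer independently
#' with half-normal probability \code{halfnormal_g(y; p0, sigma)} of its
#' perpendicular distance; the trailing observer only searches where the
#' lead observer missed. Perpendicular distance is recorded for every event.
#'
#' @inheritParams simulate_quadrat_survey
#' @return A list with \code{transects} and \code{events} (a
#'   \code{detection_table} with \code{distance_m} filled).
#' @export
simulate_distance_survey <- function(lake, scenario = lake$scenario) {
  stopifnot(inherits(lake, "synthetic_lake"))
  centres <- transect_centres(scenario)
  hw <- scenario$distance_half_width_m
  ids <- sprintf("%s_d%02d", scenario$label, seq_along(centres))
  tr <- as_transect_table(data.frame(
    transect_id = ids, lake = scenario$label, design = "distance",
    length_m = scenario$transect_length_m, half_width_m = hw,
    n_quadrats = NA_integer_, quadrat_area_m2 = NA_real_,
    stringsAsFactors = FALSE))
  rows <- vector("list", length(centres))
  for (j in seq_along(centres)) {
    inb <- abs(lake$x - centres[j]) <= hw & lake$y >= 0 &
      lake$y <= scenario$transect_length_m
    dist <- abs(lake$x[inb] - centres[j])
    ss <- lake$size[inb]
    m <- length(ss)
    if (m == 0) next
    g <- halfnormal_g(dist, scenario$distance_p0, scenario$distance_sigma)
    if (scenario$size_effect > 0) {
      g <- pmin(1, g * ss^scenario$size_effect)
    }
    d1 <- stats::runif(m) < g
    d2 <- !d1 & stats::runif(m) < g
    det <- d1 | d2
    if (!any(det)) next
    rows[[j]] <- data.frame(
      transect_id = ids[j],
      history = ifelse(d1[det], "first_observer", "second_observer_only"),
      distance_m = dist[det], cluster_size = ss[det],
      stringsAsFactors = FALSE)
  }
  ev <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(ev)) {
    ev <- data.frame(transect_id = character(0), history = character(0),
                     distance_m = numeric(0), cluster_size = integer(0))
  }
  list(transects = tr, events = as_detection_table(ev, tr))
}

estimate_one_design <- function(lake, scenario, design) {
  if (design == "quadrat") {
    s <- simulate_quadrat_survey(lake, scenario)
    estimate_density(s$transects, quadrats = s$quadrats)
  } else if (design == "removal") {
    s <- simulate_removal_survey(lake, scenario)
    fit <- fit_removal_fi(s$events, half_width_m = scenario$removal_half_width_m)
    estimate_density(s$transects, events = s$events, fit = fit)
  } else {
    s <- simulate_distance_survey(lake, scenario)
    fit <- fit_distance_removal(s$events, w = scenario$distance_half_width_m)
    estimate_density(s$transects, events = s$events, fit = fit)
  }
}

#' Replicated survey simulation and estimator-recovery summary
#'
#' Repeatedly simulates a population under the scenario, runs the requested
#' survey designs on each replicate, estimates density for each, and
#' summarises recovery: mean estimate, relative bias, empirical CV across
#' replicates, mean estimated CV, and coverage of the ±2 SE interval.
#' Per-replicate child seeds are drawn once under the root seed and stored
#' in the replicate table, so any replicate can be reproduced in isolation.
#' Replicates whose fit fails are recorded as \code{NA} with the failure
#' message, not dropped silently.
#'
#' @param scenario A \code{sim_scenario}.
#' @param replicates Number of replicate surveys, >= 2.
#' @param seed Root seed.
#' @param designs Character subset of
#'   \code{c("quadrat", "removal", "distance")}.
#' @return A data frame with one row per design (class
#'   \code{"recovery_summary"}): \code{design}, \code{replicates},
#'   \code{n_ok}, \code{D_true}, \code{mean_D}, \code{rel_bias},
#'   \code{empirical_cv}, \code{mean_cv_hat}, \code{coverage},
#'   \code{mean_detection_share}. The per-replicate table (with child seeds
#'   and failure reasons) is attached as attribute \code{"replicates"}.
#' @export
recovery_experiment <- function(scenario, replicates, seed = 1L,
                                designs = c("quadrat", "removal", "distance")) {
  stopifnot(inherits(scenario, "sim_scenario"), replicates >= 2)
  designs <- match.arg(designs, several.ok = TRUE)
  set.seed(seed)
  child_seeds <- sample.int(.Machine$integer.max, replicates)
  D_true <- true_density(scenario)
  rows <- vector("list", replicates * length(designs))
  k <- 0L
  for (r in seq_len(replicates)) {
    set.seed(child_seeds[r])
    lake <- simulate_population(scenario, seed = NULL)
    for (d in designs) {
      k <- k + 1L
      est <- tryCatch(estimate_one_design(lake, scenario, d),
                      error = function(e) e)
      if (inherits(est, "error")) {
        rows[[k]] <- data.frame(
          replicate = r, seed = child_seeds[r], design = d,
          D_hat = NA_real_, se_D = NA_real_, cv = NA_real_,
          covered = NA, detection_share = NA_real_,
          failure = conditionMessage(est), stringsAsFactors = FALSE)
      } else {
        rows[[k]] <- data.frame(
          replicate = r, seed = child_seeds[r], design = d,
          D_hat = est$D_hat, se_D = est$se_D, cv = est$cv,
          covered = is.finite(est$se_D) && est$se_D > 0 &&
            abs(est$D_hat - D_true) <= 2 * est$se_D,
          detection_share = est$components[["detection"]],
          failure = NA_character_, stringsAsFactors = FALSE)
      }
    }
  }
  reps <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(designs, function(d) {
    rd <- reps[reps$design == d & !is.na(reps$D_hat), ]
    data.frame(
      design = d, replicates = replicates, n_ok = nrow(rd), D_true = D_true,
      mean_D = mean(rd$D_hat),
      rel_bias = (mean(rd$D_hat) - D_true) / D_true,
      empirical_cv = stats::sd(rd$D_hat) / mean(rd$D_hat),
      mean_cv_hat = mean(rd$cv, na.rm = TRUE),
      coverage = mean(rd$covered, na.rm = TRUE),
      mean_detection_share = mean(rd$detection_share, na.rm = TRUE),
      stringsAsFactors = FALSE)
  }))
  attr(summ, "replicates") <- reps
  attr(summ, "scenario") <- scenario$label
  attr(summ, "seed") <- seed
  class(summ) <- c("recovery_summary", "data.frame")
  summ
}

#' @export
print.recovery_summary <- function(x, ...) {
  cat(sprintf("Recovery experiment: scenario '%s', %d replicates (seed %s)\n",
              attr(x, "scenario"), x$replicates[1],
              format(attr(x, "seed"))))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Scenario preset: low-density lake, all detections singletons
#'
#' Sparse, spatially unstructured druses (homogeneous Poisson at 0.05
#' druses/m²) with every cluster a single individual, emulating a recently
#' invaded low-density lake.
#'
#' @param ... Overrides passed to [sim_scenario()].
#' @return A \code{sim_scenario}.
#' @export
scenario_florida_like <- function(...) {
  args <- list(label = "florida_like", druse_intensity = 0.05,
               cluster_size_law = list(law = "fixed_one"))
  do.call(sim_scenario, utils::modifyList(args, list(...)))
}

#' Scenario preset: intermediate density with mild patchiness
#'
#' A Thomas process with moderate patches (0.125 patches/m², 4 druses per
#' patch, 1 m scatter; 0.5 druses/m² overall) and small clusters
#' (zero-truncated Poisson, mean 1.2), emulating an established but not
#' saturated population.
#'
#' @inheritParams scenario_florida_like
#' @return A \code{sim_scenario}.
#' @export
scenario_burgan_like <- function(...) {
  args <- list(label = "burgan_like", parent_intensity = 0.125,
               mean_offspring = 4, dispersal_sd = 1,
               cluster_size_law = list(law = "ztpois", mean = 1.2))
  do.call(sim_scenario, utils::modifyList(args, list(...)))
}

#' Scenario preset: high density, strongly clustered, large druses
#'
#' A Thomas process with few dense patches (0.08 patches/m², 50 druses per
#' patch, 1.5 m scatter; 4 druses/m² overall) and a heavy-tailed cluster-size
#' law (zero-truncated negative binomial, mean 6, dispersion 0.8), emulating
#' dense mussel beds on patchy hard substrate.
#'
#' @inheritParams scenario_florida_like
#' @return A \code{sim_scenario}.
#' @export
scenario_little_birch_like <- function(...) {
  args <- list(label = "little_birch_like", parent_intensity = 0.08,
               mean_offspring = 50, dispersal_sd = 1.5,
               cluster_size_law = list(law = "ztnb", mean = 6,
                                       dispersion = 0.8))
  do.call(sim_scenario, utils::modifyList(args, list(...)))
}

#' Read a scenario from a YAML file
#'
#' The file holds [sim_scenario()] arguments at the top level;
#' \code{cluster_size_law} is a mapping with \code{law} and its parameters.
#'
#' @param path Path to a YAML file.
#' @return A \code{sim_scenario}.
#' @examples
#' path <- system.file("extdata", "example-scenario.yaml",
#'                     package = "stripdens")
#' sc <- scenario_from_yaml(path)
#' true_density(sc)
#' @export
scenario_from_yaml <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("scenario file must be a YAML mapping", call. = FALSE)
  known <- names(formals(sim_scenario))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0) {
    stop("unknown scenario field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(sim_scenario, cfg)
}
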