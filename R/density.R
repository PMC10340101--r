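#' Mean cluster size and its standard error
#'
#' @param sizes Positive integer cluster sizes, one per detection event.
#' @return A list with \code{Es_hat} (arithmetic mean) and \code{se_Es}
#'   (sample standard deviation over \eqn{\sqrt{n}}, with the \eqn{n-1}
#'   denominator; 0 when \eqn{n = 1} or all sizes are equal).
#' @export
mean_cluster_size <- function(sizes) {
  if (length(sizes) == 0) stop("no cluster sizes supplied", call. = FALSE)
  if (any(is.na(sizes)) || any(sizes < 1)) {
    stop("cluster sizes must be positive", call. = FALSE)
  }
  n <- length(sizes)
  Es <- mean(sizes)
  se <- if (n == 1) 0 else stats::sd(sizes) / sqrt(n)
  list(Es_hat = Es, se_Es = se)
}

#' Design-based encounter-rate variance of the total count
#'
#' Between-transect variance of the total count \eqn{n = \sum n_i}, with
#' each transect's contribution weighted by its length:
#' \deqn{\mathrm{Var}(n) = \frac{L}{T-1} \sum_{i=1}^{T} l_i
#'   \left(\frac{n_i}{l_i} - \frac{n}{L}\right)^2, \qquad L = \sum l_i.}
#'
#' @param counts Per-transect counts \eqn{n_i} (length \eqn{T \ge 2}).
#' @param lengths Per-transect efforts \eqn{l_i} (> 0; metres for strip
#'   transects, summed quadrat area for quadrat sites).
#' @return The estimated variance of the total count.
#' @export
encounter_variance <- function(counts, lengths) {
  if (length(counts) != length(lengths)) {
    stop("counts and lengths must have equal length", call. = FALSE)
  }
  T_n <- length(counts)
  if (T_n < 2) {
    stop("encounter-rate variance is inestimable from a single transect",
         call. = FALSE)
  }
  if (any(!is.finite(lengths)) || any(lengths <= 0)) {
    stop("transect lengths must be positive", call. = FALSE)
  }
  L <- sum(lengths)
  n <- sum(counts)
  L / (T_n - 1) * sum(lengths * (counts / lengths - n / L)^2)
}

perfect_detection_fit <- function() {
  new_detection_fit("perfect", c(p = 1), P_hat = 1, se_P = 0, loglik = 0,
                    vcov = matrix(0, 1, 1, dimnames = list("p", "p")),
                    n_events = 0L, half_width_m = NA_real_)
}

#' Estimate density with a delta-method variance decomposition
#'
#' The strip-design estimator of individual density (individuals per m²) is
#' \deqn{\hat D = \frac{n \, \widehat{E(s)}}{2 w \hat P L},}
#' where \eqn{n} is the number of detected clusters over all transects,
#' \eqn{\widehat{E(s)}} the mean cluster size, \eqn{\hat P} the average
#' detection probability from the fitted detection model, \eqn{w} the strip
#' half-width and \eqn{L} the summed transect length. Its variance is
#' approximated by the delta method,
#' \deqn{\mathrm{Var}(\hat D) \approx \hat D^2 \left(
#'   \frac{\mathrm{Var}(n)}{n^2} +
#'   \frac{\mathrm{Var}(\widehat{E(s)})}{\widehat{E(s)}^2} +
#'   \frac{\mathrm{Var}(\hat P)}{\hat P^2}\right),}
#' with \eqn{\mathrm{Var}(n)} the design-based encounter-rate variance
#' ([encounter_variance()]).
#'
#' Quadrat surveys assume perfect detection (\eqn{\hat P = 1},
#' \eqn{\mathrm{Var}(\hat P) = 0}), count individuals rather than clusters
#' (\eqn{\widehat{E(s)} = 1}), and use total count over total quadrat area;
#' their encounter-rate variance takes the site (transect) as the sampling
#' unit with effort \eqn{l_i} equal to the site's summed quadrat area.
#'
#' A survey with zero detections returns a flagged zero estimate
#' (\code{flagged = TRUE}, \code{cv = NA}) rather than an error, so
#' simulation sweeps at very low density do not abort.
#'
#' @param transects A \code{transect_table}; all rows must share one design
#'   (and, for strip designs, one half-width).
#' @param events A \code{detection_table} for removal/distance designs.
#' @param quadrats A \code{quadrat_table} for the quadrat design.
#' @param fit A \code{detection_fit} for removal/distance designs; ignored
#'   (perfect detection imposed) for quadrat surveys.
#' @return An object of class \code{"density_estimate"}: a list with
#'   \code{D_hat}, \code{se_D}, \code{cv}, \code{n}, \code{Es_hat},
#'   \code{se_Es}, \code{P_hat}, \code{se_P}, \code{var_n}, \code{area_m2},
#'   \code{T}, \code{design}, \code{components} (count / cluster-size /
#'   detection proportions of the relative variance), \code{flagged}, and
#'   the \code{fit} used.
#' @export
estimate_density <- function(transects, events = NULL, quadrats = NULL,
                             fit = NULL) {
  transects <- as_transect_table(transects)
  design <- unique(transects$design)
  if (length(design) != 1) {
    stop("all transects must share a single design; got: ",
         paste(design, collapse = ", "), call. = FALSE)
  }

  if (design == "quadrat") {
    if (is.null(quadrats)) stop("quadrat design needs quadrat counts",
                                call. = FALSE)
    quadrats <- as_quadrat_table(quadrats, transects)
    site_area <- transects$n_quadrats * transects$quadrat_area_m2
    counts <- vapply(transects$transect_id, function(id)
      sum(quadrats$count[quadrats$transect_id == id]), numeric(1))
    n <- sum(counts)
    area <- sum(site_area)
    var_n <- if (nrow(transects) >= 2) {
      encounter_variance(counts, site_area)
    } else NA_real_
    fit_used <- perfect_detection_fit()
    Es <- 1; se_Es <- 0; P <- 1; se_P <- 0
    D <- n / area
  } else {
    if (is.null(events)) stop(design, " design needs detection events",
                              call. = FALSE)
    events <- as_detection_table(events, transects)
    if (is.null(fit)) stop(design, " design needs a detection fit",
                           call. = FALSE)
    if (!inherits(fit, "detection_fit")) {
      stop("fit must be a detection_fit", call. = FALSE)
    }
    w <- unique(transects$half_width_m)
    if (length(w) != 1) {
      stop("strip estimator assumes a common half-width across transects",
           call. = FALSE)
    }
    L <- sum(transects$length_m)
    counts <- vapply(transects$transect_id, function(id)
      sum(events$transect_id == id), numeric(1))
    n <- nrow(events)
    area <- 2 * w * L
    var_n <- if (nrow(transects) >= 2) {
      encounter_variance(counts, transects$length_m)
    } else NA_real_
    fit_used <- fit
    P <- fit$P_hat
    se_P <- fit$se_P
    if (n > 0) {
      cs <- mean_cluster_size(events$cluster_size)
      Es <- cs$Es_hat; se_Es <- cs$se_Es
    } else {
      Es <- 1; se_Es <- 0
    }
    D <- n * Es / (2 * w * P * L)
  }

  if (n == 0) {
    est <- list(D_hat = 0, se_D = 0, cv = NA_real_, n = 0L,
                Es_hat = Es, se_Es = se_Es, P_hat = P, se_P = se_P,
                var_n = var_n, area_m2 = area, T = nrow(transects),
                design = design,
                components = c(count = NA_real_, cluster_size = NA_real_,
                               detection = NA_real_),
                flagged = TRUE, counts = counts, fit = fit_used)
    class(est) <- "density_estimate"
    return(est)
  }

  rel_count <- if (is.na(var_n)) NA_real_ else var_n / n^2
  rel_size <- se_Es^2 / Es^2
  rel_det <- if (is.na(se_P)) NA_real_ else se_P^2 / P^2
  rel_total <- rel_count + rel_size + rel_det
  se_D <- sqrt(D^2 * rel_total)
  cv <- se_D / D
  components <- if (!is.na(rel_total) && rel_total > 0) {
    c(count = rel_count, cluster_size = rel_size, detection = rel_det) /
      rel_total
  } else {
    c(count = NA_real_, cluster_size = NA_real_, detection = NA_real_)
  }
  est <- list(D_hat = D, se_D = se_D, cv = cv, n = as.integer(n),
              Es_hat = Es, se_Es = se_Es, P_hat = P, se_P = se_P,
              var_n = var_n, area_m2 = area, T = nrow(transects),
              design = design, components = components,
              flagged = FALSE, counts = counts, fit = fit_used)
  class(est) <- "density_estimate"
  est
}

#' @export
print.density_estimate <- function(x, ...) {
  cat(sprintf("Density estimate (%s design, %d transects, %.1f m2)\n",
              x$design, x$T, x$area_m2))
  cat(sprintf("  D-hat: %.5f individuals/m2  (SE %.5f, CV %s)\n",
              x$D_hat, x$se_D,
              if (is.na(x$cv)) "undefined" else sprintf("%.3f", x$cv)))
  cat(sprintf("  n = %d events, E(s)-hat = %.3f (SE %.3f), P-hat = %.3f (SE %s)\n",
              x$n, x$Es_hat, x$se_Es, x$P_hat,
              if (is.na(x$se_P)) "unavailable" else sprintf("%.3f", x$se_P)))
  if (!any(is.na(x$components))) {
    cat(sprintf("  variance shares: count %.1f%%, cluster size %.1f%%, detection %.1f%%\n",
                100 * x$components[["count"]],
                100 * x$components[["cluster_size"]],
                100 * x$components[["detection"]]))
  }
  if (isTRUE(x$flagged)) cat("  [flagged: zero detections]\n")
  invisible(x)
}

#' Variance-component proportions of a density estimate
#'
#' Splits the relative variance of \eqn{\hat D} into its three delta-method
#' terms — counts, cluster size, and detection — each expressed as a
#' proportion of their sum. Under the delta approximation the detection
#' share equals \eqn{[\mathrm{Var}(\hat P)/\hat P^2] / [\mathrm{Var}(\hat D)/\hat D^2]},
#' i.e. the share of \eqn{\mathrm{Var}(\hat D)} attributable to uncertainty
#' in detection.
#'
#' @param estimate A \code{density_estimate}.
#' @return Named numeric vector \code{c(count, cluster_size, detection)}
#'   summing to 1, or all-\code{NA} when the total variance is zero or the
#'   estimate is a flagged zero.
#' @export
variance_components <- function(estimate) {
  if (!inherits(estimate, "density_estimate")) {
    stop("estimate must be a density_estimate", call. = FALSE)
  }
  if (estimate$D_hat <= 0) {
    stop("variance components require a positive density estimate",
         call. = FALSE)
  }
  estimate$components
}
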