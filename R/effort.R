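#' Transects required to reach a target coefficient of variation
#'
#' Computes the number of transects needed to bring the CV of a density
#' estimate down to a target (default 0.1), from the CV observed on a
#' completed survey. The default rule solves the linear relation
#' \deqn{\mathrm{cv\_target} = \mathrm{CV}(\hat D) \cdot
#'       T_\mathrm{completed} / T_\mathrm{estimated},}
#' so \eqn{T_\mathrm{estimated} = \mathrm{CV} \cdot T_\mathrm{completed} /
#' \mathrm{cv\_target}}. A conventional inverse-square-root alternative,
#' \eqn{T_\mathrm{estimated} = T_\mathrm{completed} \cdot
#' (\mathrm{CV}/\mathrm{cv\_target})^2}, reflecting the usual
#' \eqn{1/\sqrt{T}} scaling of a design-based mean, is available as
#' \code{rule = "sqrt_scaling"} for comparison.
#'
#' The raw value is rounded to the nearest integer with ties away from zero
#' (minimum 1); exact halves are flagged in the result.
#'
#' @param cv_observed Observed CV of the density estimate, > 0.
#' @param T_completed Number of transects the observed CV was based on, >= 1.
#' @param cv_target Target CV, > 0 (default 0.1).
#' @param rule \code{"linear"} (default, the linear relation above) or
#'   \code{"sqrt_scaling"}.
#' @return An object of class \code{"effort_result"}: a list with
#'   \code{T_estimated} (integer), \code{T_estimated_raw},
#'   \code{cv_observed}, \code{T_completed}, \code{cv_target}, \code{rule},
#'   and \code{tie} (TRUE when the raw value was an exact half).
#' @examples
#' transects_for_cv(0.38, 15)   # 57 transects
#' transects_for_cv(0.25, 4)    # 10 transects
#' @export
transects_for_cv <- function(cv_observed, T_completed, cv_target = 0.1,
                             rule = c("linear", "sqrt_scaling")) {
  rule <- match.arg(rule)
  if (!is.numeric(cv_observed) || length(cv_observed) != 1 ||
      !is.finite(cv_observed) || cv_observed <= 0) {
    stop("cv_observed must be a single positive value", call. = FALSE)
  }
  if (!is.numeric(T_completed) || length(T_completed) != 1 ||
      T_completed < 1 || T_completed != round(T_completed)) {
    stop("T_completed must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(cv_target) || length(cv_target) != 1 ||
      !is.finite(cv_target) || cv_target <= 0) {
    stop("cv_target must be a single positive value", call. = FALSE)
  }
  raw <- switch(rule,
                linear = cv_observed * T_completed / cv_target,
                sqrt_scaling = T_completed * (cv_observed / cv_target)^2)
  raw_snapped <- round(raw, 9)          # absorb binary floating-point noise
  tie <- raw_snapped %% 1 == 0.5
  T_est <- max(1L, as.integer(floor(raw_snapped + 0.5)))  # ties away from zero
  structure(list(T_estimated = T_est, T_estimated_raw = raw,
                 cv_observed = cv_observed, T_completed = as.integer(T_completed),
                 cv_target = cv_target, rule = rule, tie = tie),
            class = "effort_result")
}

#' @export
print.effort_result <- function(x, ...) {
  cat(sprintf("Effort to reach CV = %g (%s rule)\n", x$cv_target,
              if (x$rule == "linear") "linear" else "1/sqrt(T)"))
  cat(sprintf("  observed CV %g over %d transects -> %.2f transects, rounded to %d\n",
              x$cv_observed, x$T_completed, x$T_estimated_raw, x$T_estimated))
  if (isTRUE(x$tie)) cat("  [exact half: rounded away from zero]\n")
  invisible(x)
}
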