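#' Read a transect table
#'
#' Reads a comma-separated transect file into a validated data frame of
#' surveyed transects. Each row describes one transect: its survey design
#' (\code{"quadrat"}, \code{"removal"} or \code{"distance"}), length in
#' metres, and for the strip designs the half-width \code{w} such that the
#' surveyed area is \eqn{2wL}. Quadrat transects instead carry the number of
#' quadrats and the per-quadrat area.
#'
#' The half-width convention follows the strip-density estimator
#' \eqn{\hat D = n \hat E(s) / (2 w \hat P L)}: a distance transect searched
#' up to 1 m on either side of a single line has \code{half_width_m = 1}
#' (area \eqn{2 \times 1 \times L}); a removal strip 1 m wide between two
#' lines has \code{half_width_m = 0.5}.
#'
#' @param path Path to a CSV file with header columns
#'   \code{transect_id,lake,design,length_m,half_width_m,n_quadrats,quadrat_area_m2}.
#' @return A data frame of class \code{"transect_table"} with one validated
#'   row per transect.
#' @seealso [write_transects()], [read_detections()], [read_quadrats()]
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' tr <- data.frame(transect_id = c("t1", "t2"), lake = "A",
#'                  design = c("removal", "distance"),
#'                  length_m = 30, half_width_m = c(0.5, 1),
#'                  n_quadrats = NA, quadrat_area_m2 = NA)
#' write_transects(as_transect_table(tr), tf)
#' read_transects(tf)
#' @export
read_transects <- function(path) {
  df <- read_survey_csv(path, c("transect_id", "lake", "design", "length_m",
                                "half_width_m", "n_quadrats", "quadrat_area_m2"))
  as_transect_table(df)
}

#' Construct a validated transect table from a data frame
#'
#' @param df A data frame with the columns documented in [read_transects()];
#'   \code{n_quadrats} and \code{quadrat_area_m2} may be omitted when no
#'   quadrat transects are present.
#' @return The validated data frame with class \code{"transect_table"}.
#' @export
as_transect_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  required <- c("transect_id", "lake", "design", "length_m")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("transect table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in c("half_width_m", "n_quadrats", "quadrat_area_m2")) {
    if (!col %in% names(df)) df[[col]] <- NA_real_
  }
  df$transect_id <- as.character(df$transect_id)
  df$lake <- as.character(df$lake)
  df$design <- as.character(df$design)
  df$length_m <- as.numeric(df$length_m)
  df$half_width_m <- as.numeric(df$half_width_m)
  df$n_quadrats <- as.integer(df$n_quadrats)
  df$quadrat_area_m2 <- as.numeric(df$quadrat_area_m2)

  bad_design <- !df$design %in% c("quadrat", "removal", "distance")
  if (any(bad_design)) {
    stop("unknown design label(s) in row(s) ",
         paste(which(bad_design), collapse = ", "), ": ",
         paste(unique(df$design[bad_design]), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(df$transect_id)) {
    stop("duplicated transect_id: ",
         paste(unique(df$transect_id[duplicated(df$transect_id)]), collapse = ", "),
         call. = FALSE)
  }
  bad_len <- !is.finite(df$length_m) | df$length_m <= 0
  if (any(bad_len)) {
    stop("nonpositive or missing length_m in row(s) ",
         paste(which(bad_len), collapse = ", "), call. = FALSE)
  }
  strip <- df$design %in% c("removal", "distance")
  bad_w <- strip & (!is.finite(df$half_width_m) | df$half_width_m <= 0)
  if (any(bad_w)) {
    stop("removal/distance transects need half_width_m > 0; bad row(s) ",
         paste(which(bad_w), collapse = ", "), call. = FALSE)
  }
  quad <- df$design == "quadrat"
  bad_q <- quad & (is.na(df$n_quadrats) | df$n_quadrats < 1L |
                     !is.finite(df$quadrat_area_m2) | df$quadrat_area_m2 <= 0)
  if (any(bad_q)) {
    stop("quadrat transects need n_quadrats >= 1 and quadrat_area_m2 > 0; bad row(s) ",
         paste(which(bad_q), collapse = ", "), call. = FALSE)
  }
  rownames(df) <- NULL
  class(df) <- c("transect_table", "data.frame")
  df
}

#' Write a transect table to CSV
#'
#' @param transects A \code{transect_table} (see [as_transect_table()]).
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_transects <- function(transects, path) {
  transects <- as_transect_table(transects)
  write_survey_csv(transects, path)
}

#' Read a detection-event table
#'
#' Reads detection events (one row per detected cluster) and cross-validates
#' them against the transect table: every event must reference a known
#' transect, perpendicular distances may only appear on distance transects,
#' and a recorded distance must lie within the transect half-width.
#' Clusters are the detection unit; the number of individuals in the cluster
#' is carried in \code{cluster_size}.
#'
#' @param path Path to a CSV with header
#'   \code{transect_id,history,distance_m,cluster_size}. \code{history} is
#'   \code{"first_observer"} (seen by the lead diver) or
#'   \code{"second_observer_only"} (missed by the lead diver, found by the
#'   trailing diver). \code{distance_m} may be empty for events without a
#'   recorded perpendicular distance.
#' @param transects The \code{transect_table} the events belong to.
#' @return A data frame of class \code{"detection_table"}; zero rows is legal.
#' @export
read_detections <- function(path, transects) {
  df <- read_survey_csv(path, c("transect_id", "history", "distance_m",
                                "cluster_size"))
  as_detection_table(df, transects)
}

#' Construct a validated detection-event table
#'
#' @param df Data frame with columns \code{transect_id}, \code{history},
#'   \code{distance_m} (may be \code{NA}), \code{cluster_size}.
#' @param transects The \code{transect_table} to validate against.
#' @return The validated data frame with class \code{"detection_table"}.
#' @export
as_detection_table <- function(df, transects) {
  transects <- as_transect_table(transects)
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  required <- c("transect_id", "history", "cluster_size")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("detection table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"distance_m" %in% names(df)) df$distance_m <- NA_real_
  df$transect_id <- as.character(df$transect_id)
  df$history <- as.character(df$history)
  df$distance_m <- as.numeric(df$distance_m)
  df$cluster_size <- as.integer(df$cluster_size)

  if (nrow(df) == 0) {
    rownames(df) <- NULL
    class(df) <- c("detection_table", "data.frame")
    return(df)
  }

  bad_hist <- !df$history %in% c("first_observer", "second_observer_only")
  if (any(bad_hist)) {
    stop("unknown capture history in row(s) ",
         paste(which(bad_hist), collapse = ", "), call. = FALSE)
  }
  idx <- match(df$transect_id, transects$transect_id)
  if (anyNA(idx)) {
    stop("detection references unknown transect_id: ",
         paste(unique(df$transect_id[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  design <- transects$design[idx]
  has_dist <- !is.na(df$distance_m)
  if (any(has_dist & design != "distance")) {
    stop("distance_m recorded on non-distance transect(s), row(s) ",
         paste(which(has_dist & design != "distance"), collapse = ", "),
         call. = FALSE)
  }
  w <- transects$half_width_m[idx]
  bad_d <- has_dist & (df$distance_m < 0 | df$distance_m > w)
  if (any(bad_d)) {
    stop("distance_m outside [0, half_width_m] in row(s) ",
         paste(which(bad_d), collapse = ", "), call. = FALSE)
  }
  bad_s <- is.na(df$cluster_size) | df$cluster_size < 1L
  if (any(bad_s)) {
    stop("cluster_size must be a positive integer; bad row(s) ",
         paste(which(bad_s), collapse = ", "), call. = FALSE)
  }
  rownames(df) <- NULL
  class(df) <- c("detection_table", "data.frame")
  df
}

#' Write a detection-event table to CSV
#'
#' @param detections A \code{detection_table}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_detections <- function(detections, path) {
  write_survey_csv(as.data.frame(detections), path)
}

#' Read a quadrat-count table
#'
#' @param path Path to a CSV with header \code{transect_id,quadrat_index,count}.
#' @param transects The \code{transect_table} (quadrat design rows) the counts
#'   belong to.
#' @return A data frame of class \code{"quadrat_table"}.
#' @export
read_quadrats <- function(path, transects) {
  df <- read_survey_csv(path, c("transect_id", "quadrat_index", "count"))
  as_quadrat_table(df, transects)
}

#' Construct a validated quadrat-count table
#'
#' @param df Data frame with columns \code{transect_id}, \code{quadrat_index},
#'   \code{count}.
#' @param transects The \code{transect_table} to validate against.
#' @return The validated data frame with class \code{"quadrat_table"}.
#' @export
as_quadrat_table <- function(df, transects) {
  transects <- as_transect_table(transects)
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  required <- c("transect_id", "quadrat_index", "count")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("quadrat table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df$transect_id <- as.character(df$transect_id)
  df$quadrat_index <- as.integer(df$quadrat_index)
  df$count <- as.integer(df$count)
  if (nrow(df) > 0) {
    idx <- match(df$transect_id, transects$transect_id)
    if (anyNA(idx)) {
      stop("quadrat count references unknown transect_id: ",
           paste(unique(df$transect_id[is.na(idx)]), collapse = ", "),
           call. = FALSE)
    }
    if (any(transects$design[idx] != "quadrat")) {
      stop("quadrat counts recorded on non-quadrat transect(s)", call. = FALSE)
    }
    bad <- is.na(df$count) | df$count < 0L
    if (any(bad)) {
      stop("count must be a nonnegative integer; bad row(s) ",
           paste(which(bad), collapse = ", "), call. = FALSE)
    }
  }
  rownames(df) <- NULL
  class(df) <- c("quadrat_table", "data.frame")
  df
}

#' Write a quadrat-count table to CSV
#'
#' @param quadrats A \code{quadrat_table}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_quadrats <- function(quadrats, path) {
  write_survey_csv(as.data.frame(quadrats), path)
}

#' Write density estimates to CSV with a JSON metadata sidecar
#'
#' Writes one row per density estimate (point estimate, standard error, CV,
#' variance-component proportions, sample sizes, surveyed area) to
#' \code{path}, plus a \code{<path stem>.meta.json} sidecar with full
#' metadata: package version, write time, optional seed, and a content hash
#' of the configuration/estimates.
#'
#' @param estimates A single \code{density_estimate} (see
#'   [estimate_density()]) or a list of them; an empty list writes a
#'   header-only file.
#' @param path Output CSV path; the sidecar replaces the extension with
#'   \code{.meta.json}.
#' @param seed Optional integer recorded in the sidecar for provenance.
#' @param config Optional list echoed (and hashed) into the sidecar.
#' @return \code{path}, invisibly.
#' @export
write_results <- function(estimates, path, seed = NULL, config = NULL) {
  if (inherits(estimates, "density_estimate")) estimates <- list(estimates)
  stopifnot(is.list(estimates))
  rows <- lapply(estimates, as.data.frame.density_estimate)
  if (length(rows) > 0) {
    out <- do.call(rbind, rows)
  } else {
    out <- as.data.frame.density_estimate(NULL)[0, , drop = FALSE]
  }
  write_survey_csv(out, path)
  meta_path <- sub("\\.[^.]*$", "", path)
  meta_path <- paste0(meta_path, ".meta.json")
  meta <- list(
    package = "stripdens",
    version = as.character(utils::packageVersion("stripdens")),
    written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = config,
    config_hash = fnv1a_hash(list(config = config, estimates = out)),
    n_estimates = length(estimates),
    fits = lapply(estimates, function(e) {
      if (is.null(e$fit)) NULL else unclass(e$fit)[c("model", "params", "P_hat",
                                                     "se_P", "loglik", "n_events")]
    })
  )
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a results CSV written by [write_results()]
#'
#' @param path Path to the results CSV.
#' @return A data frame with one row per stored estimate.
#' @export
read_results <- function(path) {
  read_survey_csv(path, c("design", "D_hat", "se_D", "cv"))
}

#' @export
as.data.frame.density_estimate <- function(x, ...) {
  if (is.null(x)) {
    x <- list(design = character(0))
  }
  data.frame(
    design = if (length(x$design)) x$design else NA_character_,
    D_hat = null_na(x$D_hat), se_D = null_na(x$se_D), cv = null_na(x$cv),
    n = null_na(x$n), Es_hat = null_na(x$Es_hat), se_Es = null_na(x$se_Es),
    P_hat = null_na(x$P_hat), se_P = null_na(x$se_P),
    var_n = null_na(x$var_n), area_m2 = null_na(x$area_m2),
    T_transects = null_na(x$T),
    prop_count = null_na(x$components[["count"]]),
    prop_cluster_size = null_na(x$components[["cluster_size"]]),
    prop_detection = null_na(x$components[["detection"]]),
    flagged = isTRUE(x$flagged),
    stringsAsFactors = FALSE
  )
}

null_na <- function(x) if (is.null(x) || length(x) == 0) NA_real_ else x

# Shared CSV plumbing: UTF-8, header row, '.' decimal separator, full
# precision on write (15 significant digits covers the 12-digit round-trip
# contract).
read_survey_csv <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = NA, na.strings = c("NA", ""))
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("file ", path, " is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df
}

write_survey_csv <- function(df, path) {
  df <- as.data.frame(df)
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) {
    ifelse(is.na(x), NA, sprintf("%.15g", x))
  })
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write ", path, ": ", conditionMessage(ok),
                        call. = FALSE)
  invisible(path)
}

# Tiny 32-bit FNV-1a over a deparsed object; provenance fingerprint only.
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}
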