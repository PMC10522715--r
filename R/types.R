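## Domain containers. All are light S3 wrappers with strict validators;
## region_id is the join key everywhere.

#' Parcel geometry
#'
#' Per-region coordinates on the unit sphere plus a hemisphere label. The
#' spherical layout is the substrate for spin permutations and for
#' distance-dependent cross-validation splits.
#'
#' @param region_id character vector of unique region identifiers.
#' @param xyz numeric matrix, regions x 3, each row on the unit sphere.
#' @param hemisphere character vector of "L"/"R" labels per region.
#'
#' @return A `parcel_geometry` object: a data.frame with columns
#'   `region_id`, `x`, `y`, `z`, `hemisphere`.
#' @export
parcel_geometry <- function(region_id, xyz, hemisphere) {
  xyz <- as.matrix(xyz)
  obj <- data.frame(region_id = as.character(region_id),
                    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                    hemisphere = as.character(hemisphere),
                    stringsAsFactors = FALSE)
  class(obj) <- c("parcel_geometry", "data.frame")
  validate_geometry(obj)
  obj
}

validate_geometry <- function(g) {
  if (anyDuplicated(g$region_id))
    stop("region_id values must be unique")
  if (!all(g$hemisphere %in% c("L", "R")))
    stop("hemisphere labels must be 'L' or 'R'")
  nrm <- sqrt(g$x^2 + g$y^2 + g$z^2)
  if (any(abs(nrm - 1) > 1e-9))
    stop("coordinates must lie on the unit sphere (|norm - 1| <= 1e-9)")
  if (nrow(g) >= 2 && length(unique(g$hemisphere)) < 2)
    stop("both hemispheres must be represented")
  invisible(g)
}

geometry_xyz <- function(g) {
  m <- cbind(g$x, g$y, g$z)
  rownames(m) <- g$region_id
  m
}

#' Great-circle angular distances between regions
#'
#' @param g a `parcel_geometry`.
#' @return regions x regions matrix of central angles in radians.
#' @export
great_circle_angles <- function(g) {
  xyz <- geometry_xyz(g)
  cosang <- tcrossprod(xyz)
  cosang[cosang > 1] <- 1
  cosang[cosang < -1] <- -1
  acos(cosang)
}

#' Regional time-series set
#'
#' A regions x samples signal matrix with its sampling rate and a subject
#' label. Signal units are arbitrary.
#'
#' @param values numeric matrix, regions x samples, no missing values.
#' @param fs sampling rate in Hz.
#' @param region_id character vector of region identifiers (rownames).
#' @param subject subject label.
#'
#' @return A `regional_ts` object.
#' @export
regional_ts <- function(values, fs, region_id = rownames(values),
                        subject = "synthetic") {
  values <- as.matrix(values)
  if (is.null(region_id))
    region_id <- sprintf("region_%03d", seq_len(nrow(values)))
  if (anyNA(values) || !all(is.finite(values)))
    stop("time-series values must be finite with no missing entries")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a positive sampling rate in Hz")
  rownames(values) <- as.character(region_id)
  structure(list(values = values, fs = fs, subject = as.character(subject)),
            class = "regional_ts")
}

#' @export
print.regional_ts <- function(x, ...) {
  cat(sprintf("Regional time-series set: %d regions x %d samples, fs = %g Hz (%.1f s), subject '%s'\n",
              nrow(x$values), ncol(x$values), x$fs,
              ncol(x$values) / x$fs, x$subject))
  invisible(x)
}

#' Brain map set
#'
#' A regions x maps matrix of regional brain maps with unique map names.
#' Row order matches a `parcel_geometry`.
#'
#' @param values numeric matrix, regions x maps.
#' @param map_name character vector of unique column names.
#' @param region_id character vector of region identifiers.
#'
#' @return A `brain_maps` object (a named numeric matrix).
#' @export
brain_maps <- function(values, map_name = colnames(values),
                       region_id = rownames(values)) {
  values <- as.matrix(values)
  if (is.null(map_name)) map_name <- sprintf("map_%02d", seq_len(ncol(values)))
  if (anyDuplicated(map_name)) stop("map names must be unique")
  if (is.null(region_id))
    region_id <- sprintf("region_%03d", seq_len(nrow(values)))
  dimnames(values) <- list(as.character(region_id), as.character(map_name))
  structure(values, class = c("brain_maps", "matrix", "array"))
}

#' Feature matrix
#'
#' A regions x features matrix with per-column validity flags and a
#' normalization state. Invalid columns (features that errored, were
#' non-finite for any region, or constant across regions) carry no
#' finiteness requirement; valid columns are finite, and normalized valid
#' columns lie in [0, 1].
#'
#' @param values numeric matrix, regions x features.
#' @param valid logical vector per feature column.
#' @param normalized logical flag; TRUE once sigmoid-normalized.
#' @param region_id,feature_name dimension names.
#'
#' @return A `feature_matrix` object.
#' @export
feature_matrix <- function(values, valid = NULL, normalized = FALSE,
                           region_id = rownames(values),
                           feature_name = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(feature_name))
    feature_name <- sprintf("feature_%03d", seq_len(ncol(values)))
  if (anyDuplicated(feature_name)) stop("feature names must be unique")
  if (is.null(region_id))
    region_id <- sprintf("region_%03d", seq_len(nrow(values)))
  dimnames(values) <- list(as.character(region_id),
                           as.character(feature_name))
  if (is.null(valid)) valid <- apply(values, 2, function(v) all(is.finite(v)))
  valid <- as.logical(valid)
  if (length(valid) != ncol(values))
    stop("`valid` must have one flag per feature column")
  if (any(valid) && !all(is.finite(values[, valid, drop = FALSE])))
    stop("valid feature columns must be finite")
  if (normalized && any(valid)) {
    v <- values[, valid, drop = FALSE]
    if (min(v) < -1e-9 || max(v) > 1 + 1e-9)
      stop("normalized valid columns must lie in [0, 1]")
  }
  structure(list(values = values, valid = setNames(valid, feature_name),
                 normalized = isTRUE(normalized)),
            class = "feature_matrix")
}

#' Valid columns of a feature matrix
#' @param fm a `feature_matrix`.
#' @return numeric matrix restricted to valid feature columns.
#' @export
valid_features <- function(fm) {
  fm$values[, fm$valid, drop = FALSE]
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("Feature matrix: %d regions x %d features (%d valid)%s\n",
              nrow(x$values), ncol(x$values), sum(x$valid),
              if (x$normalized) ", normalized" else ""))
  invisible(x)
}

check_shared_regions <- function(a_ids, b_ids, what = "inputs") {
  if (length(a_ids) != length(b_ids) || !all(a_ids == b_ids))
    stop(sprintf("%s must share the same regions in the same order", what))
  invisible(TRUE)
}
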