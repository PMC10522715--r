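## Tab-delimited readers/writers. region_id is the join key; floats are
## written at 15 significant digits so round-trips agree to <= 1e-10.

#' Read a typed table
#'
#' Reads one of the pipeline's tab-delimited tables into its typed
#' container. Geometry files carry `region_id, x, y, z, hemisphere`;
#' map/feature tables carry `region_id` plus one numeric column per
#' map/feature; time-series tables carry `region_id` plus one column per
#' sample (the sampling rate is supplied separately, it is not stored in
#' the table).
#'
#' @param path file path.
#' @param kind one of "geometry", "maps", "features", "timeseries".
#' @param fs sampling rate in Hz, required for `kind = "timeseries"`.
#' @param subject subject label for time-series tables.
#'
#' @return A `parcel_geometry`, `brain_maps`, `feature_matrix` or
#'   `regional_ts` object.
#' @export
read_table <- function(path, kind = c("geometry", "maps", "features",
                                      "timeseries"),
                       fs = NULL, subject = "unknown") {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!"region_id" %in% names(df))
    stop("format error: missing required column 'region_id' in ", path)
  num_cols <- setdiff(names(df), c("region_id", "hemisphere"))
  for (cn in num_cols) {
    v <- df[[cn]]
    if (is.character(v)) {
      parsed <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(parsed) & !(toupper(v) %in% c("NA", "NAN")))
      if (length(bad))
        stop(sprintf("parse error: non-numeric cell at row %d, column '%s'",
                     bad[1], cn))
      df[[cn]] <- parsed
    }
  }
  switch(kind,
    geometry = {
      need <- c("x", "y", "z", "hemisphere")
      miss <- setdiff(need, names(df))
      if (length(miss))
        stop("format error: geometry table missing column(s) ",
             paste(miss, collapse = ", "))
      parcel_geometry(df$region_id, cbind(df$x, df$y, df$z), df$hemisphere)
    },
    maps = {
      m <- as.matrix(df[num_cols])
      rownames(m) <- df$region_id
      brain_maps(m)
    },
    features = {
      m <- as.matrix(df[num_cols])
      rownames(m) <- df$region_id
      valid <- apply(m, 2, function(v) all(is.finite(v)))
      normalized <- all(valid) && nrow(m) > 0 &&
        min(m[, valid, drop = FALSE]) >= -1e-9 &&
        max(m[, valid, drop = FALSE]) <= 1 + 1e-9
      feature_matrix(m, valid = valid, normalized = normalized)
    },
    timeseries = {
      if (is.null(fs)) stop("`fs` is required when reading a time-series table")
      m <- as.matrix(df[num_cols])
      rownames(m) <- df$region_id
      colnames(m) <- NULL
      regional_ts(m, fs = fs, subject = subject)
    })
}

#' Write a typed table
#'
#' Serializes a typed object as tab-delimited UTF-8 text with a header row.
#' Floating values are written at 15 significant digits; non-finite values
#' are written as literal `NaN`.
#'
#' @param obj a `parcel_geometry`, `brain_maps`, `feature_matrix` or
#'   `regional_ts` object.
#' @param path output file path.
#'
#' @return The path, invisibly.
#' @export
write_table <- function(obj, path) {
  df <- if (inherits(obj, "parcel_geometry")) {
    validate_geometry(obj)
    as.data.frame(unclass(obj), stringsAsFactors = FALSE)
  } else if (inherits(obj, "brain_maps")) {
    m <- unclass(obj)
    if (nrow(m) == 0) stop("cannot serialize an empty-region object")
    data.frame(region_id = rownames(m), as.data.frame(m, check.names = FALSE),
               check.names = FALSE, stringsAsFactors = FALSE)
  } else if (inherits(obj, "feature_matrix")) {
    if (nrow(obj$values) == 0) stop("cannot serialize an empty-region object")
    data.frame(region_id = rownames(obj$values),
               as.data.frame(obj$values, check.names = FALSE),
               check.names = FALSE, stringsAsFactors = FALSE)
  } else if (inherits(obj, "regional_ts")) {
    if (nrow(obj$values) == 0) stop("cannot serialize an empty-region object")
    m <- obj$values
    colnames(m) <- sprintf("s%d", seq_len(ncol(m)))
    data.frame(region_id = rownames(m), as.data.frame(m, check.names = FALSE),
               check.names = FALSE, stringsAsFactors = FALSE)
  } else stop("unsupported object class: ", paste(class(obj), collapse = "/"))
  if (nrow(df) == 0) stop("cannot serialize an empty-region object")
  num <- vapply(df, is.numeric, TRUE)
  for (cn in names(df)[num]) {
    v <- df[[cn]]
    out <- sprintf("%.15g", v)
    out[is.nan(v)] <- "NaN"
    out[is.na(v) & !is.nan(v)] <- "NA"
    df[[cn]] <- out
  }
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' Records the configuration, seed, package version and timestamp of a
#' pipeline run, plus the stages executed, as a flat key/value text file.
#'
#' @param path output file path.
#' @param cfg an `analysis_config`.
#' @param stages character vector of stage names executed.
#'
#' @return The path, invisibly.
#' @export
write_manifest <- function(path, cfg, stages = character()) {
  stopifnot(inherits(cfg, "analysis_config"))
  lines <- c(
    sprintf("package\tmapdyn %s", as.character(utils::packageVersion("mapdyn"))),
    sprintf("timestamp\t%s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    sprintf("seed\t%d", cfg$seed),
    sprintf("n_spins\t%d", cfg$n_spins),
    sprintf("n_boot\t%d", cfg$n_boot),
    sprintf("welch_window_s\t%g", cfg$welch_window_s),
    sprintf("welch_overlap\t%g", cfg$welch_overlap),
    sprintf("fit_range_hz\t%g-%g", cfg$fit_range_hz[1], cfg$fit_range_hz[2]),
    sprintf("segment_drop_s\t%g", cfg$segment_drop_s),
    sprintf("segment_use_s\t%g", cfg$segment_use_s),
    vapply(names(cfg$bands), function(b)
      sprintf("band_%s\t%g-%g", b, cfg$bands[[b]][1], cfg$bands[[b]][2]), ""),
    if (length(stages)) sprintf("stage\t%s", stages)
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
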