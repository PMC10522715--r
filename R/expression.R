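## Toy-scale expression-map construction: probe filtering, differential
## stability, normalization, sample-to-region aggregation, cell-class maps.

#' Intensity-based probe filter
#'
#' Discards probes whose intensity is below background in at least 50% of
#' samples pooled across donors (a probe below background in exactly half
#' of the samples is discarded).
#'
#' @param b an `expression_bundle`.
#' @return The bundle restricted to retained probes.
#' @export
filter_probes_intensity <- function(b) {
  stopifnot(inherits(b, "expression_bundle"))
  frac_below <- rowMeans(!b$above_background)
  keep <- frac_below < 0.5
  if (!any(keep)) stop("all probes fall below background; nothing retained")
  b$intensity <- b$intensity[keep, , drop = FALSE]
  b$above_background <- b$above_background[keep, , drop = FALSE]
  b$probe_id <- b$probe_id[keep]
  b$probe_gene <- b$probe_gene[keep]
  b
}

## Per-donor regional profile of one probe: mean intensity of the donor's
## samples assigned to each region.
donor_profiles <- function(intensity_row, assignment, donors, region_ids) {
  sapply(donors, function(d) {
    rows <- assignment[assignment$donor == d, ]
    v <- tapply(intensity_row[rows$sample], rows$region_id, mean)
    out <- setNames(rep(NA_real_, length(region_ids)), region_ids)
    out[names(v)] <- v
    out
  })
}

#' Differential stability of probes
#'
#' For every probe, computes the mean over all donor pairs of the
#' Spearman correlation between the probe's regional expression profiles
#' (restricted to regions sampled by both donors of a pair). Per gene the
#' probe with maximal differential stability is kept, ties broken by
#' probe_id order; genes with no valid probe are dropped and reported.
#'
#' @param b an `expression_bundle` (typically intensity-filtered).
#' @param assignment a sample-to-region assignment from
#'   [assign_samples()].
#' @return A `probe_stats` data.frame: `probe_id`, `gene`, `ds`, `keep`.
#' @export
differential_stability <- function(b, assignment) {
  stopifnot(inherits(b, "expression_bundle"))
  donors <- unique(assignment$donor)
  if (length(donors) < 2) stop("need at least 2 donors")
  region_ids <- sort(unique(assignment$region_id))
  ds <- vapply(seq_along(b$probe_id), function(p) {
    prof <- donor_profiles(b$intensity[p, ], assignment, donors, region_ids)
    vals <- c()
    for (i in seq_len(length(donors) - 1)) {
      for (j in (i + 1):length(donors)) {
        ok <- is.finite(prof[, i]) & is.finite(prof[, j])
        if (sum(ok) < 3) next
        vals <- c(vals, cor(prof[ok, i], prof[ok, j], method = "spearman"))
      }
    }
    if (!length(vals)) NA_real_ else mean(vals)
  }, 0)
  if (all(is.na(ds)))
    stop("no donor pair shares >= 3 regions; differential stability undefined")
  out <- data.frame(probe_id = b$probe_id, gene = b$probe_gene, ds = ds,
                    keep = FALSE, stringsAsFactors = FALSE)
  for (g in unique(out$gene)) {
    rows <- which(out$gene == g & is.finite(out$ds))
    if (!length(rows)) next                    # gene dropped
    out$keep[rows[which.max(out$ds[rows])]] <- TRUE
  }
  dropped <- setdiff(unique(out$gene), out$gene[out$keep])
  if (length(dropped))
    message("genes dropped (no valid probe): ", paste(dropped, collapse = ", "))
  class(out) <- c("probe_stats", "data.frame")
  out
}

#' Assign tissue samples to regions
#'
#' Mirrors every sample bilaterally (duplicating it with negated x and
#' swapped hemisphere label to increase spatial coverage), then assigns
#' each original or mirrored sample to the nearest region center if the
#' Euclidean distance is at most `radius` (inclusive); ties go to the
#' lower region index. Unassigned samples are discarded.
#'
#' @param b an `expression_bundle`.
#' @param geom a `parcel_geometry` in the same coordinate frame (unit
#'   sphere; `radius` is in the same dimensionless units).
#' @param radius assignment radius (default 0.1 in unit-sphere units).
#' @return data.frame with one row per assigned (possibly mirrored)
#'   sample: `sample` (column index into the bundle), `donor`,
#'   `region_id`, `distance`, `mirrored`.
#' @export
assign_samples <- function(b, geom, radius = 0.1) {
  stopifnot(inherits(b, "expression_bundle"),
            inherits(geom, "parcel_geometry"))
  ns <- ncol(b$intensity)
  xyz <- rbind(b$sample_xyz,
               cbind(-b$sample_xyz[, 1], b$sample_xyz[, 2], b$sample_xyz[, 3]))
  sample_idx <- rep(seq_len(ns), 2)
  donor <- rep(b$sample_donor, 2)
  mirrored <- rep(c(FALSE, TRUE), each = ns)
  centers <- geometry_xyz(geom)
  d2 <- outer(rowSums(xyz^2), rowSums(centers^2), "+") -
    2 * xyz %*% t(centers)
  d2[d2 < 0] <- 0
  nearest <- max.col(-d2, ties.method = "first")  # lower index wins ties
  dist <- sqrt(d2[cbind(seq_along(nearest), nearest)])
  ok <- dist <= radius
  if (!any(ok)) stop("no sample lies within the assignment radius of any region")
  data.frame(sample = sample_idx[ok], donor = donor[ok],
             region_id = geom$region_id[nearest[ok]],
             distance = dist[ok], mirrored = mirrored[ok],
             stringsAsFactors = FALSE)
}

#' Build the regional expression matrix
#'
#' Restricts to the kept probe per gene, then per donor: sigmoid-
#' normalizes each sample across genes, then each gene across the donor's
#' samples; averages samples assigned to the same region per donor, and
#' finally averages across donors. Regions without any assigned sample
#' are filled per donor by inverse-distance weighting of the donor's
#' nearest assigned samples and flagged as interpolated.
#'
#' @param b an `expression_bundle` (intensity-filtered).
#' @param stats a `probe_stats` from [differential_stability()].
#' @param assignment the assignment from [assign_samples()].
#' @param geom the `parcel_geometry` used for the assignment.
#' @param fill_k number of nearest samples used to fill empty regions.
#' @return A `regional_expression`: list with `values` (regions x genes),
#'   `gene`, `interpolated` (logical per region).
#' @export
build_expression_matrix <- function(b, stats, assignment, geom,
                                    fill_k = 3L) {
  stopifnot(inherits(b, "expression_bundle"), inherits(stats, "probe_stats"))
  keep <- match(stats$probe_id[stats$keep], b$probe_id)
  if (anyNA(keep)) stop("probe_stats does not match the bundle")
  genes <- stats$gene[stats$keep]
  expr <- b$intensity[keep, , drop = FALSE]   # genes x samples
  rownames(expr) <- genes
  donors <- unique(b$sample_donor)
  region_ids <- geom$region_id
  centers <- geometry_xyz(geom)
  per_donor <- array(NA_real_, c(length(region_ids), length(genes),
                                 length(donors)),
                     dimnames = list(region_ids, genes, donors))
  for (d in donors) {
    cols <- which(b$sample_donor == d)
    E <- expr[, cols, drop = FALSE]
    E <- sigmoid_normalize(E, axis = "across_genes")    # per sample
    E <- sigmoid_normalize(E, axis = "across_samples")  # per gene
    rows <- assignment[assignment$donor == d, ]
    local_col <- match(rows$sample, cols)
    ok <- !is.na(local_col)
    rows <- rows[ok, ]; local_col <- local_col[ok]
    for (rid in unique(rows$region_id)) {
      cc <- local_col[rows$region_id == rid]
      per_donor[rid, , d] <- rowMeans(E[, cc, drop = FALSE])
    }
    ## inverse-distance fill of uncovered regions from nearest samples
    empty <- which(is.na(per_donor[, 1, d]))
    if (length(empty) && nrow(rows)) {
      ## positions of this donor's assigned samples (original or mirrored)
      sxyz <- rbind(b$sample_xyz, cbind(-b$sample_xyz[, 1],
                                        b$sample_xyz[, 2], b$sample_xyz[, 3]))
      pos <- sxyz[ifelse(rows$mirrored, ncol(b$intensity), 0) + rows$sample, ,
                  drop = FALSE]
      for (ri in empty) {
        d2 <- colSums((t(pos) - centers[ri, ])^2)
        kn <- order(d2)[seq_len(min(fill_k, length(d2)))]
        w <- 1 / pmax(sqrt(d2[kn]), 1e-9)
        vals <- E[, local_col[kn], drop = FALSE]
        per_donor[ri, , d] <- as.vector(vals %*% (w / sum(w)))
      }
    }
  }
  values <- apply(per_donor, c(1, 2), mean, na.rm = TRUE)
  values[is.nan(values)] <- NA_real_
  interpolated <- !(region_ids %in% assignment$region_id)
  structure(list(values = values, gene = genes,
                 interpolated = setNames(interpolated, region_ids)),
            class = "regional_expression")
}

#' @export
print.regional_expression <- function(x, ...) {
  cat(sprintf("Regional expression: %d regions x %d genes (%d interpolated regions)\n",
              nrow(x$values), ncol(x$values), sum(x$interpolated)))
  invisible(x)
}

#' Cell-class expression maps
#'
#' Averages the regional expression columns of each class's gene set
#' (unweighted mean). Genes missing from the matrix are reported and
#' skipped; a class with no matched gene is an error.
#'
#' @param E a `regional_expression`.
#' @param gene_sets named list of gene character vectors, one per class.
#' @return A `brain_maps` with one map per class.
#' @export
cell_type_maps <- function(E, gene_sets) {
  stopifnot(inherits(E, "regional_expression"))
  m <- vapply(names(gene_sets), function(cls) {
    genes <- gene_sets[[cls]]
    hit <- genes %in% colnames(E$values)
    if (!any(hit))
      stop(sprintf("cell class '%s' matches no gene in the expression matrix",
                   cls))
    if (any(!hit))
      message(sprintf("class '%s': %d gene(s) not found, skipped", cls,
                      sum(!hit)))
    rowMeans(E$values[, genes[hit], drop = FALSE])
  }, numeric(nrow(E$values)))
  brain_maps(m, map_name = names(gene_sets),
             region_id = rownames(E$values))
}
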