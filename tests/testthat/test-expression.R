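make_bundle <- function(intensity, above, genes, donors, xyz, hemi,
                        probes = NULL) {
  if (is.null(probes))
    probes <- sprintf("%s_p%d", genes, ave(seq_along(genes), genes,
                                           FUN = seq_along))
  structure(list(intensity = intensity, probe_id = probes,
                 probe_gene = genes, above_background = above,
                 sample_donor = donors, sample_xyz = xyz,
                 sample_hemisphere = hemi),
            class = "expression_bundle")
}

test_that("intensity filter applies the >= 50% below-background rule", {
  ns <- 100
  intensity <- matrix(1, 3, ns)
  above <- rbind(c(rep(FALSE, 50), rep(TRUE, 50)),   # exactly 50% below
                 c(rep(FALSE, 49), rep(TRUE, 51)),   # 49% below
                 rep(TRUE, ns))                      # all above
  b <- make_bundle(intensity, above, c("g1", "g2", "g3"),
                   rep(c("d1", "d2"), each = 50),
                   matrix(rnorm(3 * ns), ns, 3), rep("L", ns))
  fb <- filter_probes_intensity(b)
  expect_equal(fb$probe_gene, c("g2", "g3"))
  ball <- make_bundle(intensity[1, , drop = FALSE],
                      matrix(FALSE, 1, ns), "g1",
                      rep(c("d1", "d2"), each = 50),
                      matrix(rnorm(3 * ns), ns, 3), rep("L", ns))
  expect_error(filter_probes_intensity(ball), "below background")
})

test_that("differential stability equals the brute-force all-pairs oracle", {
  geom <- generate_parcellation(30, seed = 71)
  tr <- planted_truth(geom, n_maps = 2, seed = 71)
  b <- generate_expression_bundle(geom, n_donors = 5, n_genes = 10,
                                  probes_per_gene = 2, truth = tr, seed = 71)
  asn <- assign_samples(b, geom, radius = 0.15)
  ds <- differential_stability(b, asn)
  donors <- unique(asn$donor)
  region_ids <- sort(unique(asn$region_id))
  for (p in seq_along(b$probe_id)) {
    prof <- sapply(donors, function(d) {
      rows <- asn[asn$donor == d, ]
      v <- tapply(b$intensity[p, rows$sample], rows$region_id, mean)
      out <- setNames(rep(NA_real_, length(region_ids)), region_ids)
      out[names(v)] <- v
      out
    })
    expect_equal(ds$ds[p], oracle_ds(prof), tolerance = 1e-12)
  }
  # two donors: single pairwise correlation
  b2 <- generate_expression_bundle(geom, n_donors = 2, n_genes = 4,
                                   probes_per_gene = 1, truth = tr, seed = 72)
  asn2 <- assign_samples(b2, geom, radius = 0.15)
  ds2 <- differential_stability(b2, asn2)
  prof <- sapply(unique(asn2$donor), function(d) {
    rows <- asn2[asn2$donor == d, ]
    v <- tapply(b2$intensity[1, rows$sample], rows$region_id, mean)
    out <- setNames(rep(NA_real_, length(region_ids)), region_ids)
    out[names(v)] <- v
    out
  })
  ok <- complete.cases(prof)
  expect_equal(ds2$ds[1], cor(prof[ok, 1], prof[ok, 2], method = "spearman"),
               tolerance = 1e-12)
  # identical profiles across donors: DS = 1 for the zero-noise probe
  b0 <- generate_expression_bundle(geom, n_donors = 4, n_genes = 4,
                                   probes_per_gene = 1, truth = tr,
                                   seed = 73, donor_noise_sd = 0)
  asn0 <- assign_samples(b0, geom, radius = 0.15)
  ds0 <- differential_stability(b0, asn0)
  expect_true(all(abs(ds0$ds - 1) < 1e-12))
  # exactly one kept probe per gene
  expect_true(all(table(ds$gene[ds$keep]) == 1))
})

test_that("sample assignment mirrors, respects the radius and breaks ties low", {
  xyz <- rbind(c(1, 0, 0), c(0, 1, 0), c(-1, 0, 0), c(0, -1, 0))
  geom <- parcel_geometry(c("L_1", "L_2", "R_1", "R_2"), xyz,
                          c("L", "L", "R", "R"))
  s_xyz <- rbind(c(0.99, 0.05, 0), # near L_1
                 c(0, 1.1, 0))     # distance 0.1 from L_2
  b <- make_bundle(matrix(1, 1, 2), matrix(TRUE, 1, 2), "g1",
                   c("d1", "d2"), s_xyz, c("L", "L"))
  asn <- assign_samples(b, geom, radius = 0.1)
  # the second sample sits exactly at the radius: inclusive boundary
  expect_true(any(asn$sample == 2 & asn$region_id == "L_2"))
  # mirrored copies cover the right hemisphere
  expect_true(any(asn$mirrored & grepl("^R_", asn$region_id)))
  # equidistant sample: lower region index wins
  geom_eq <- parcel_geometry(c("L_1", "L_2", "R_1"),
                             rbind(c(0, 1, 0), c(0, 0, 1), c(-1, 0, 0)),
                             c("L", "L", "R"))
  mid <- c(0, 1, 1) / sqrt(2)
  b_eq <- make_bundle(matrix(1, 1, 1), matrix(TRUE, 1, 1), "g1", "d1",
                      matrix(mid, 1), "L")
  asn_eq <- assign_samples(b_eq, geom_eq, radius = 2)
  expect_equal(asn_eq$region_id[!asn_eq$mirrored], "L_1")
  expect_error(assign_samples(b, geom, radius = 1e-6), "radius")
})

test_that("expression matrix aggregation handles degenerate donor layouts", {
  geom <- generate_parcellation(20, seed = 74)
  tr <- planted_truth(geom, n_maps = 2, seed = 74)
  b <- generate_expression_bundle(geom, n_donors = 2, n_genes = 12,
                                  probes_per_gene = 1, truth = tr,
                                  seed = 74, donor_noise_sd = 0,
                                  samples_per_donor = 20)
  # two donors with identical data equal the single-donor result
  asn <- assign_samples(b, geom, radius = 0.15)
  ds <- differential_stability(b, asn)
  E2 <- build_expression_matrix(b, ds, asn, geom)
  one <- asn$donor == "donor1"
  b1 <- b
  keep_cols <- which(b$sample_donor == "donor1")
  b1$intensity <- b$intensity[, keep_cols, drop = FALSE]
  b1$above_background <- b$above_background[, keep_cols, drop = FALSE]
  b1$sample_donor <- b$sample_donor[keep_cols]
  b1$sample_xyz <- b$sample_xyz[keep_cols, , drop = FALSE]
  b1$sample_hemisphere <- b$sample_hemisphere[keep_cols]
  asn1 <- assign_samples(b1, geom, radius = 0.15)
  E1 <- build_expression_matrix(b1, ds, asn1, geom)
  # donor sampling differs (jitter/selection), so compare the shared regions
  shared <- intersect(rownames(E1$values)[rowSums(is.na(E1$values)) == 0],
                      rownames(E2$values)[rowSums(is.na(E2$values)) == 0])
  expect_gt(length(shared), 5)
  expect_gt(cor(as.vector(E1$values[shared, ]),
                as.vector(E2$values[shared, ])), 0.9)
  # normalized values in [0, 1] before aggregation implies bounded output
  expect_true(all(E2$values >= -1e-9 & E2$values <= 1 + 1e-9, na.rm = TRUE))
})

test_that("planted gene profiles are recovered in the regional matrix", {
  rs <- vapply(1:10, function(s) {
    geom <- generate_parcellation(50, seed = s)
    tr <- planted_truth(geom, n_maps = 2, seed = s)
    b <- generate_expression_bundle(geom, n_donors = 4, n_genes = 30,
                                    probes_per_gene = 2, truth = tr,
                                    seed = s, donor_noise_sd = 0.3)
    fb <- filter_probes_intensity(b)
    asn <- assign_samples(fb, geom, radius = 0.1)
    ds <- differential_stability(fb, asn)
    E <- build_expression_matrix(fb, ds, asn, geom)
    median(abs(vapply(seq_len(ncol(E$values)), function(j)
      suppressWarnings(cor(E$values[, j],
                           b$gene_profile[, colnames(E$values)[j]],
                           use = "complete.obs")), 0)), na.rm = TRUE)
  }, 0)
  expect_gt(median(rs), 0.8)
})

test_that("cell-class maps average their gene sets", {
  geom <- generate_parcellation(20, seed = 75)
  tr <- planted_truth(geom, n_maps = 2, seed = 75)
  b <- generate_expression_bundle(geom, n_donors = 3, n_genes = 9,
                                  probes_per_gene = 1, truth = tr, seed = 75)
  asn <- assign_samples(b, geom, radius = 0.15)
  ds <- differential_stability(b, asn)
  E <- build_expression_matrix(b, ds, asn, geom)
  genes <- colnames(E$values)
  m <- cell_type_maps(E, list(solo = genes[1], pair = genes[2:3]))
  expect_equal(m[, "solo"], E$values[, 1], ignore_attr = TRUE)
  expect_equal(m[, "pair"], rowMeans(E$values[, 2:3]), ignore_attr = TRUE)
  # duplicated column in a set: same as either column
  m2 <- cell_type_maps(E, list(dup = c(genes[4], genes[4])))
  expect_equal(m2[, "dup"], E$values[, 4], ignore_attr = TRUE)
  expect_error(cell_type_maps(E, list(ghost = "NOPE")), "ghost")
  expect_message(cell_type_maps(E, list(mix = c(genes[1], "NOPE"))),
                 "not found")
})
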