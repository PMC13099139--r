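test_that("well aggregation averages only QC-passing cells", {
  layout <- tibble::tibble(plate = 1L, well = c("A01", "A02"),
                           role = "library", gene = c("G1", "G2"))
  cells <- tibble::tibble(
    replicate = 1L, plate = 1L,
    well = c("A01", "A01", "A01", "A01", "A02"),
    gene = c("G1", "G1", "G1", "G1", "G2"),
    cell_id = 1:5,
    spot_count = c(10, 20, 30, 999, 5),
    clustering_score = c(1, 2, 3, 999, 1),
    mean_radial_distance = 0.6, nuclear_area = 100,
    qc_pass = c(TRUE, TRUE, TRUE, FALSE, FALSE)
  )
  w <- aggregate_wells(cells, layout, min_cells = 2)
  a01 <- w[w$well == "A01", ]
  expect_equal(a01$mean_clustering_score, 2)   # the QC-fail 999 is ignored
  expect_equal(a01$mean_spot_count, 20)
  expect_identical(a01$n_cells_pass_qc, 3L)
  expect_true(a01$usable)
  a02 <- w[w$well == "A02", ]
  expect_false(a02$usable)                     # zero usable cells
  expect_true(is.nan(a02$mean_clustering_score))
  # deleting the QC-fail cells changes nothing
  w2 <- aggregate_wells(cells[cells$qc_pass | cells$well == "A02", ],
                        layout, min_cells = 2)
  expect_equal(w2[w2$well == "A01", ]$mean_clustering_score, 2)
  # unknown wells are an error
  bad <- dplyr::mutate(cells, well = "Z99")
  expect_error(aggregate_wells(bad, layout), "missing from the layout")
})

test_that("plate normalization matches the hand-computed robust Z", {
  w <- make_wells(1:9)
  z <- normalize_plate(w)
  # (9 - 5) / (1.4826 * 2) = 1.34899...
  expect_equal(z$z_mean_clustering_score[9], 4 / (1.4826 * 2),
               tolerance = 1e-10)
  expect_equal(median(z$z_mean_clustering_score), 0)
  # adding extreme-valued control wells never moves library Z
  w2 <- make_wells(1:9, ctrl_values = c(1e4, -1e4))
  z2 <- normalize_plate(w2)
  expect_equal(z2$z_mean_clustering_score[1:9], z$z_mean_clustering_score[1:9])
  # controls are scored against the library center
  expect_gt(z2$z_mean_clustering_score[10], 1000)
})

test_that("degenerate library spread falls back to SD and then to zero", {
  w <- make_wells(c(rep(5, 8), 6)) # MAD 0, SD > 0
  z <- normalize_plate(w)
  expect_false(any(is.na(z$z_mean_clustering_score)))
  expect_true(all(is.finite(z$z_mean_clustering_score)))
  w0 <- make_wells(rep(5, 9)) # no spread at all
  expect_warning(centroscreen:::robust_z(5, rep(5, 9)), "zero spread")
  z0 <- suppressWarnings(normalize_plate(w0))
  expect_true(all(z0$z_mean_clustering_score == 0))
  # fewer than 8 usable library wells is an error
  expect_error(normalize_plate(make_wells(1:5)), "fewer than 8")
})

test_that("replicate standardisation is idempotent and centers the library", {
  w <- make_wells(c(2, 7, 1, 9, 4, 6, 3, 8, 5))
  z1 <- normalize_plate(w)
  z2 <- standardize_replicate(z1)
  expect_equal(z2$z_mean_clustering_score, z1$z_mean_clustering_score,
               tolerance = 1e-12)
  # two plates with shifted Z distributions pool to library median zero
  wa <- make_wells(c(2, 7, 1, 9, 4, 6, 3, 8, 5), plate = 1L)
  wb <- make_wells(c(2, 7, 1, 9, 4, 6, 3, 8, 5) + 10, plate = 2L)
  zz <- standardize_replicate(normalize_plate(dplyr::bind_rows(wa, wb)))
  expect_equal(median(zz$z_mean_clustering_score[zz$role == "library"]), 0)
})

test_that("replicate combination averages Z and records the SD", {
  w1 <- make_wells(c(2, 7, 1, 9, 4, 6, 3, 8, 5), replicate = 1L)
  w2 <- make_wells(c(3, 6, 2, 8, 5, 7, 2, 9, 4), replicate = 2L)
  rz <- standardize_replicate(normalize_plate(dplyr::bind_rows(w1, w2)))
  comb <- combine_replicates(rz)
  # brute force per gene
  for (g in comb$gene) {
    zs <- rz$z_mean_clustering_score[rz$gene == g]
    expect_equal(comb$mean_z_mean_clustering_score[comb$gene == g], mean(zs),
                 tolerance = 1e-12)
    expect_equal(comb$sd_z_mean_clustering_score[comb$gene == g], sd(zs),
                 tolerance = 1e-12)
  }
  expect_true(all(comb$n_replicates == 2L))
  # plain arithmetic check: Z = (2, 4) -> mean 3, SD sqrt(2)
  expect_equal(mean(c(2, 4)), 3)
  expect_equal(sd(c(2, 4)), sqrt(2), tolerance = 1e-12)
})

test_that("hit calling applies thresholds and exclusion precedence", {
  calls <- call_hits(dplyr::bind_rows(
    make_gene_z("hit_up", z_clust = 3, sd_clust = 0.5),
    make_gene_z("cyto", z_clust = -3, z_cells = -2.6),
    make_gene_z("inconsistent", z_count = 2.6, sd_count = 3),
    make_gene_z("boundary", z_clust = 2.5),          # strict >: not a hit
    make_gene_z("cyto_boundary", z_clust = 3, z_cells = -2.5), # strict <
    make_gene_z("dysmorphic", z_clust = 4, frac_qc_fail = 0.6),
    make_gene_z("dys_and_cyto", z_clust = 4, z_cells = -3,
                frac_qc_fail = 0.7), # dysmorphic wins the precedence
    make_gene_z("null", z_clust = 0.3)
  ))
  get <- function(g) calls[calls$gene == g, ]
  expect_true(get("hit_up")$hit)
  expect_identical(get("hit_up")$clustering_direction, "clustered")
  expect_identical(get("cyto")$excluded_reason, "cytotoxic")
  expect_false(get("cyto")$hit)
  expect_identical(get("inconsistent")$excluded_reason, "inconsistent")
  expect_false(get("boundary")$hit)
  expect_true(get("cyto_boundary")$hit) # Z = -2.5 does not trigger exclusion
  expect_identical(get("dysmorphic")$excluded_reason, "dysmorphic")
  expect_identical(get("dys_and_cyto")$excluded_reason, "dysmorphic")
  expect_false(get("null")$hit)
  expect_identical(get("null")$excluded_reason, "none")
  # every gene has exactly one reason or none, and hits are never excluded
  expect_false(any(calls$hit & calls$excluded_reason != "none"))
})

test_that("phenotype classification maps sign combinations to categories", {
  calls <- call_hits(dplyr::bind_rows(
    make_gene_z("A", z_clust = 3, z_count = -3),
    make_gene_z("B", z_clust = -3, z_count = 1),
    make_gene_z("C", z_clust = -3, z_count = -3),
    make_gene_z("D", z_clust = 3, z_count = 3),
    make_gene_z("E", z_count = 4)
  ))
  ph <- classify_phenotype(calls)
  lab <- function(g) ph$phenotype[ph$gene == g]
  expect_identical(lab("A"), "higher clustering")
  expect_identical(lab("B"), "clustering-only (unclustered)")
  expect_identical(lab("C"), "fewer larger clusters")
  expect_identical(lab("D"), "more smaller clusters")
  expect_identical(lab("E"), "count-only (higher)")
  expect_error(classify_phenotype(call_hits(make_gene_z("x", z_clust = 0.2))),
               "no hits")
})

test_that("two-screen comparison reproduces hand-computed concordance", {
  calls <- call_hits(dplyr::bind_rows(
    make_gene_z("A", z_clust = 3, z_count = -3),
    make_gene_z("B", z_clust = -4),
    make_gene_z("C", z_clust = 1),
    make_gene_z("D", z_clust = -1),
    make_gene_z("E", z_clust = 0.5),
    make_gene_z("F", z_clust = 2)
  ))
  conc <- compare_cell_lines(calls, calls)
  expect_equal(conc$pearson_r, 1)
  expect_identical(sort(conc$common_hits$gene), c("A", "B"))
  expect_true(all(conc$common_hits$clustering_concordance == "same"))
  # hand-set second screen
  calls_b <- call_hits(dplyr::bind_rows(
    make_gene_z("A", z_clust = 2.8, z_count = -2.6),
    make_gene_z("B", z_clust = 1),
    make_gene_z("C", z_clust = -0.5),
    make_gene_z("D", z_clust = 2),
    make_gene_z("E", z_clust = -1),
    make_gene_z("F", z_clust = 0)
  ))
  conc2 <- compare_cell_lines(calls, calls_b)
  r_hand <- cor(c(3, -4, 1, -1, 0.5, 2), c(2.8, 1, -0.5, 2, -1, 0))
  expect_equal(conc2$pearson_r, r_hand, tolerance = 1e-12)
  expect_identical(conc2$common_hits$gene, "A")
  # disjoint gene sets are an error
  calls_c <- call_hits(make_gene_z("ZZZ"))
  expect_error(compare_cell_lines(calls, calls_c), "share no genes")
  expect_identical(nrow(tidy(conc2)), 1L)
  expect_identical(glance(conc2)$n_compared, 6L)
})

test_that("the pipeline equals a straight-line oracle recomputation", {
  design <- screen_design(n_genes = 40, cells_per_well_mean = 60, seed = 31)
  sim <- generate_screen_dataset(design)
  calls <- analyze_screen(sim$cells, sim$layout)
  for (feature in c("clustering_score", "spot_count")) {
    col <- paste0("mean_z_mean_", feature)
    oracle <- screen_oracle_mean_z(sim$cells, sim$layout, feature)
    lib <- calls$role == "library"
    expect_equal(unname(oracle[calls$gene[lib]]),
                 calls[[col]][lib], tolerance = 1e-12)
  }
})

test_that("permuting well order changes no Z-score or call", {
  design <- screen_design(n_genes = 24, cells_per_well_mean = 50, seed = 5)
  sim <- generate_screen_dataset(design)
  calls1 <- analyze_screen(sim$cells, sim$layout)
  set.seed(99)
  perm_cells <- sim$cells[sample.int(nrow(sim$cells)), ]
  perm_layout <- sim$layout[sample.int(nrow(sim$layout)), ]
  calls2 <- analyze_screen(perm_cells, perm_layout)
  o1 <- dplyr::arrange(tibble::as_tibble(calls1), gene)
  o2 <- dplyr::arrange(tibble::as_tibble(calls2), gene)
  expect_equal(o1$mean_z_mean_clustering_score, o2$mean_z_mean_clustering_score,
               tolerance = 1e-12)
  expect_identical(o1$hit, o2$hit)
})

test_that("screen generation honors the design contract", {
  design <- screen_design(n_genes = 24, cells_per_well_mean = 50, seed = 8)
  layout <- plate_layout(design)
  # 7 wells of each control role per plate
  counts <- dplyr::count(dplyr::filter(layout, role != "library"),
                         plate, role)
  expect_true(all(counts$n == 7L))
  sim <- generate_screen_dataset(design)
  # identical seeds give identical datasets
  sim2 <- generate_screen_dataset(screen_design(n_genes = 24,
                                                cells_per_well_mean = 50,
                                                seed = 8))
  expect_identical(sim$cells, sim2$cells)
  # ground-truth labels describe the generative parameters exactly
  expect_identical(sim$truth$gene, design$genes)
  expect_true(all(!sim$truth$is_hit))
  spiked <- spike_effects(design, n_spike = 5, effect = 4, seed = 2)
  truth2 <- generate_screen_dataset(spiked)$truth
  expect_identical(sum(truth2$is_hit), 5L)
  expect_identical(truth2$clustering_direction[truth2$is_hit],
                   ifelse(truth2$clustering_shift[truth2$is_hit] > 0,
                          "clustered", "unclustered"))
  # missing genes in the effect table are rejected
  bad <- design; bad$effect_table <- design$effect_table[-1, ]
  expect_error(generate_screen_dataset(bad), "missing")
  # PLK1-like cytotoxic controls have strongly reduced cell numbers
  plk1 <- dplyr::count(dplyr::filter(sim$cells, role == "PLK1"),
                       replicate, well)
  scr <- dplyr::count(dplyr::filter(sim$cells, role == "scrambled"),
                      replicate, well)
  expect_lt(mean(plk1$n), 0.3 * mean(scr$n))
})
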