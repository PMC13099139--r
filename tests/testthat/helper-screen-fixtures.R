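# Small hand-built screen fixtures.

# A one-plate wells table with the given library values (recycled across the
# four normalized features) plus optional control wells.
make_wells <- function(lib_values, ctrl_values = numeric(0),
                       ctrl_role = "scrambled", replicate = 1L, plate = 1L) {
  n_lib <- length(lib_values)
  n_ctl <- length(ctrl_values)
  vals <- c(lib_values, ctrl_values)
  tibble::tibble(
    replicate = replicate, plate = plate,
    well = well_names_384()[seq_len(n_lib + n_ctl)],
    role = c(rep("library", n_lib), rep(ctrl_role, n_ctl)),
    gene = c(sprintf("G%02d", seq_len(n_lib)),
             if (n_ctl) sprintf("ctrl%02d", seq_len(n_ctl))),
    n_cells_total = 100L + seq_len(n_lib + n_ctl),
    n_cells_pass_qc = 90L + seq_len(n_lib + n_ctl),
    mean_spot_count = vals, mean_clustering_score = vals,
    mean_radial_distance = 0.66, mean_nuclear_area = vals,
    usable = TRUE
  )
}

# A per-gene Z summary row in the shape produced by combine_replicates().
make_gene_z <- function(gene = "G1", z_clust = 0, z_count = 0, z_cells = 0,
                        sd_clust = 0.1, sd_count = 0.1, frac_qc_fail = 0.05,
                        n_replicates = 2L, missing_replicate = FALSE) {
  tibble::tibble(
    gene = gene, role = "library", plate = 1L, well = "A01",
    n_replicates = n_replicates,
    mean_z_mean_clustering_score = z_clust, sd_z_mean_clustering_score = sd_clust,
    mean_z_mean_spot_count = z_count, sd_z_mean_spot_count = sd_count,
    mean_z_n_cells_pass_qc = z_cells, sd_z_n_cells_pass_qc = 0.1,
    mean_z_mean_nuclear_area = 0, sd_z_mean_nuclear_area = 0.1,
    frac_qc_fail = frac_qc_fail, missing_replicate = missing_replicate
  )
}
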