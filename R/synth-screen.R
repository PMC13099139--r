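# Feature-level simulation of an arrayed 384-well imaging CRISPR screen with
# known ground truth: per-gene effects on the clustering score, spot count and
# cell number, control wells on every plate, and two biological replicates.

#' Arrayed screen design
#'
#' Describes the layout and generative parameters of a synthetic screen. Each
#' gene occupies one well per plate (arrayed format, pooled sgRNAs per well);
#' every plate additionally carries 7 wells each of scrambled, PLK1, OR10A5
#' and NCAPH2 control sgRNAs. Effect sizes for clustering score and spot
#' count are expressed in units of the null SD of a well mean (the scale on
#' which screen Z-scores are measured), so an effect of 4 corresponds to an
#' expected mean Z-score of about 4.
#'
#' @param n_genes Number of library genes (default 1064).
#' @param wells_per_plate Plate format (default 384).
#' @param n_replicates Biological replicates (default 2).
#' @param control_wells_per_plate Named counts of control wells per plate.
#' @param effect_table Tibble with columns `gene`, `clustering_shift`,
#'   `count_shift`, `cellnum_multiplier`; defaults to all-null effects. Must
#'   cover every gene.
#' @param cells_per_well_mean Mean cells imaged per well (negative-binomially
#'   overdispersed; default 300, matching a few hundred cells per gene per
#'   replicate).
#' @param spot_count_mean Baseline mean centromere spots per cell
#'   (default 46, a near-diploid human karyotype).
#' @param qc_fail_rate Baseline fraction of nuclei failing morphology QC.
#' @param cellcycle A [cellcycle_sim_params()] object for DAPI/EdU totals.
#' @param seed Integer seed; identical seeds give identical datasets.
#' @return A `screen_design` list.
#' @export
screen_design <- function(n_genes = 1064L, wells_per_plate = 384L,
                          n_replicates = 2L,
                          control_wells_per_plate = c(scrambled = 7L, PLK1 = 7L,
                                                      OR10A5 = 7L, NCAPH2 = 7L),
                          effect_table = NULL,
                          cells_per_well_mean = 300,
                          spot_count_mean = 46,
                          qc_fail_rate = 0.05,
                          cellcycle = cellcycle_sim_params(),
                          seed = 1L) {
  genes <- sprintf("GENE%04d", seq_len(n_genes))
  if (is.null(effect_table)) {
    effect_table <- tibble::tibble(gene = genes, clustering_shift = 0,
                                   count_shift = 0, cellnum_multiplier = 1)
  }
  missing <- setdiff(genes, effect_table$gene)
  if (length(missing) > 0L) {
    rlang::abort(sprintf("effect_table is missing %d genes (e.g. %s)",
                         length(missing), missing[1]))
  }
  n_controls <- sum(control_wells_per_plate)
  lib_per_plate <- wells_per_plate - n_controls
  if (lib_per_plate <= 0) rlang::abort("controls exceed the plate capacity")
  structure(
    list(n_genes = as.integer(n_genes), genes = genes,
         wells_per_plate = as.integer(wells_per_plate),
         n_plates = as.integer(ceiling(n_genes / lib_per_plate)),
         n_replicates = as.integer(n_replicates),
         control_wells_per_plate = control_wells_per_plate,
         effect_table = effect_table,
         cells_per_well_mean = cells_per_well_mean,
         spot_count_mean = spot_count_mean,
         qc_fail_rate = qc_fail_rate,
         cellcycle = cellcycle,
         seed = as.integer(seed)),
    class = "screen_design"
  )
}

#' Add spike-in effects to a screen design
#'
#' Marks `n_spike` randomly chosen genes with a clustering-score shift of
#' `effect` null well-SD units, with alternating sign.
#'
#' @param design A [screen_design()] object.
#' @param n_spike Number of spiked genes.
#' @param effect Magnitude of the clustering-score shift (well-SD units).
#' @param feature Which feature to spike: `"clustering"` or `"count"`.
#' @param seed Seed for choosing the spiked genes.
#' @return The design with an updated effect table.
#' @export
spike_effects <- function(design, n_spike = 50L, effect = 4,
                          feature = c("clustering", "count"), seed = 1L) {
  stopifnot(inherits(design, "screen_design"))
  feature <- match.arg(feature)
  spiked <- with_seed(seed, sample(design$genes, n_spike))
  signs <- rep_len(c(1, -1), n_spike)
  et <- design$effect_table
  col <- if (feature == "clustering") "clustering_shift" else "count_shift"
  et[[col]][match(spiked, et$gene)] <- effect * signs
  design$effect_table <- et
  design
}

#' Plate layout for a screen design
#'
#' Assigns library genes plate by plate in well order, reserving the final
#' wells of each plate for the control roles (7 wells per role by default).
#' The layout is identical across replicates.
#'
#' @param design A [screen_design()] object.
#' @return Tibble with `plate`, `well`, `role`, `gene` (NA for controls).
#' @export
plate_layout <- function(design) {
  stopifnot(inherits(design, "screen_design"))
  wells <- well_names_384()[seq_len(design$wells_per_plate)]
  ctrl <- design$control_wells_per_plate
  n_ctrl <- sum(ctrl)
  lib_per_plate <- design$wells_per_plate - n_ctrl
  ctrl_roles <- rep(names(ctrl), times = ctrl)
  remaining <- design$genes
  out <- vector("list", design$n_plates)
  for (p in seq_len(design$n_plates)) {
    g <- head(remaining, lib_per_plate)
    remaining <- setdiff(remaining, g)
    roles <- c(rep("library", length(g)), ctrl_roles)
    out[[p]] <- tibble::tibble(
      plate = p,
      well = wells[seq_along(roles)],
      role = roles,
      gene = c(g, paste0("ctrl_", ctrl_roles, "_",
                         unlist(lapply(ctrl, seq_len))))
    )
  }
  purrr::list_rbind(out)
}

# Pool of clustering scores for CSR patterns on a reference circular nucleus,
# used as the empirical null distribution of per-cell scores. Memoised.
pool_cache <- new.env(parent = emptyenv())

#' Empirical null pool of clustering scores
#'
#' Scores `n_scores` CSR spot patterns on a reference circular nucleus with
#' the production scorer, yielding the empirical per-cell null distribution
#' from which feature-level simulations draw. Keeping the generator and the
#' scorer self-consistent this way means the simulated screen inherits
#' whatever small biases the score itself has under CSR.
#'
#' @param n_scores Number of CSR patterns to score.
#' @param n_spots Spots per pattern.
#' @param r_eq_um Equivalent nucleus radius in micron.
#' @param pixel_size Pixel size in micron/pixel.
#' @param n_mc Monte-Carlo replicates for the shared CSR baseline.
#' @param seed Integer seed.
#' @return Numeric vector of null scores.
#' @export
csr_score_pool <- function(n_scores = 2000L, n_spots = 46L, r_eq_um = 6.5,
                           pixel_size = 0.108, n_mc = 100L, seed = 99L) {
  key <- rlang::hash(list(n_scores, n_spots, r_eq_um, pixel_size, n_mc, seed))
  if (!is.null(pool_cache[[key]])) return(pool_cache[[key]])
  mask <- circular_mask(r_eq_um, pixel_size)
  scores <- vapply(seq_len(n_scores), function(i) {
    sp <- sample_spots(mask, spot_process_params(n_spots, "csr"),
                       pixel_size = pixel_size,
                       seed = derive_seed(seed, paste0("pool", i)))
    clustering_score(sp, mask, pixel_size = pixel_size, n_mc = n_mc,
                     seed = derive_seed(seed, "pool-baseline"))
  }, numeric(1))
  pool_cache[[key]] <- scores
  scores
}

# Circular mask with the requested equivalent radius, centered in a snug field.
circular_mask <- function(r_eq_um, pixel_size = 0.108) {
  r_px <- r_eq_um / pixel_size
  n <- 2L * ceiling(r_px + 2)
  ctr <- (n - 1) / 2
  rows <- matrix(0:(n - 1), n, n)
  cols <- t(rows)
  (rows - ctr)^2 + (cols - ctr)^2 <= r_px^2
}

#' Generate a feature-level synthetic screen
#'
#' Simulates per-cell feature tables for every well, plate and replicate of
#' the design. Null cells draw clustering scores from the empirical CSR score
#' pool; effect genes are shifted as specified in the design's effect table
#' (well-SD units for clustering score and spot count, a multiplicative
#' factor for cell number). Per-well cell counts are negative-binomial around
#' `cells_per_well_mean`. Control wells behave as their role dictates:
#' scrambled and OR10A5 are null, PLK1 is cytotoxic (cell-number multiplier
#' 0.1), NCAPH2 increases the clustering score.
#'
#' @param design A [screen_design()] object.
#' @return List with `cells` (per-cell tibble), `layout` (plate layout) and
#'   `truth` (per-gene ground-truth effects and hit labels).
#' @export
generate_screen_dataset <- function(design) {
  stopifnot(inherits(design, "screen_design"))
  missing <- setdiff(design$genes, design$effect_table$gene)
  if (length(missing) > 0L) {
    rlang::abort(sprintf("effect_table is missing %d genes (e.g. %s)",
                         length(missing), missing[1]))
  }
  layout <- plate_layout(design)
  pool <- csr_score_pool(n_spots = round(design$spot_count_mean))
  pool_sd <- sd(pool)
  se_well <- pool_sd / sqrt(design$cells_per_well_mean)
  mu_count <- design$spot_count_mean
  size_count <- 50
  sd_count_cell <- sqrt(mu_count + mu_count^2 / size_count)
  se_count <- sd_count_cell / sqrt(design$cells_per_well_mean)

  control_effects <- tibble::tibble(
    role = c("scrambled", "PLK1", "OR10A5", "NCAPH2"),
    clustering_shift = c(0, 0, 0, 6),
    count_shift = c(0, 0, 0, 0),
    cellnum_multiplier = c(1, 0.1, 1, 1)
  )
  eff <- dplyr::bind_rows(
    dplyr::mutate(design$effect_table, role = "library"),
    dplyr::left_join(
      dplyr::select(dplyr::filter(layout, .data$role != "library"),
                    "gene", "role"),
      control_effects, by = "role"
    ) |> dplyr::distinct()
  )

  wells <- dplyr::left_join(
    layout,
    dplyr::select(eff, "gene", "clustering_shift", "count_shift",
                  "cellnum_multiplier"),
    by = "gene"
  )

  cells <- purrr::map(seq_len(design$n_replicates), function(rep_i) {
    with_seed(derive_seed(design$seed, paste0("rep", rep_i)), {
      n_cells <- pmax(rnbinom(nrow(wells),
                              mu = design$cells_per_well_mean *
                                wells$cellnum_multiplier,
                              size = 10), 1L)
      idx <- rep(seq_len(nrow(wells)), n_cells)
      n_tot <- length(idx)
      score <- sample(pool, n_tot, replace = TRUE) +
        wells$clustering_shift[idx] * se_well
      count_mu <- pmax(mu_count + wells$count_shift[idx] * se_count, 0.1)
      spot_count <- rnbinom(n_tot, mu = count_mu, size = size_count)
      qc_fail <- runif(n_tot) < design$qc_fail_rate
      area <- stats::rlnorm(n_tot, log(140), 0.2)
      solidity <- runif(n_tot, 0.90, 0.99)
      # QC failures are micronucleus-sized or dysmorphic in equal measure
      fail_kind <- runif(n_tot) < 0.5
      area[qc_fail & fail_kind] <- runif(sum(qc_fail & fail_kind), 5, 29)
      solidity[qc_fail & !fail_kind] <- runif(sum(qc_fail & !fail_kind), 0.6, 0.84)
      cc <- simulate_cellcycle_intensities(
        n_tot, design$cellcycle,
        seed = derive_seed(design$seed, paste0("cc", rep_i))
      )
      tibble::tibble(
        replicate = rep_i,
        plate = wells$plate[idx],
        well = wells$well[idx],
        role = wells$role[idx],
        gene = wells$gene[idx],
        cell_id = sequence(n_cells),
        spot_count = spot_count,
        clustering_score = score,
        mean_radial_distance = pmin(pmax(rnorm(n_tot, 0.66, 0.05), 0), 1),
        nuclear_area = area,
        solidity = solidity,
        border_touching = FALSE,
        qc_pass = nucleus_qc(area, solidity, FALSE),
        dapi_total = cc$dapi_total,
        edu_total = cc$edu_total,
        true_phase = cc$true_phase
      )
    })
  }) |> purrr::list_rbind()

  truth <- dplyr::mutate(
    design$effect_table,
    is_hit = abs(.data$clustering_shift) > 0 | abs(.data$count_shift) > 0,
    clustering_direction = dplyr::case_when(
      .data$clustering_shift > 0 ~ "clustered",
      .data$clustering_shift < 0 ~ "unclustered",
      TRUE ~ "none"
    ),
    count_direction = dplyr::case_when(
      .data$count_shift > 0 ~ "higher",
      .data$count_shift < 0 ~ "lower",
      TRUE ~ "none"
    )
  )
  list(cells = cells, layout = layout, truth = truth)
}

#' Render image fields for a handful of wells
#'
#' Image-level smoke path: for each requested well, renders one field holding
#' a few non-touching nuclei with CSR spot patterns, returning the channel
#' images together with the ground-truth nuclei and spot positions. Intended
#' for end-to-end validation of the imaging stages on a desk-scale subset
#' (a few wells), not for full-screen simulation.
#'
#' @param n_wells Number of wells to render (<= 4 recommended).
#' @param nuclei_per_field Nuclei per rendered field.
#' @param n_spots Spots per nucleus.
#' @param pixel_size Pixel size in micron/pixel.
#' @param field_shape Field size in pixels.
#' @param seed Integer seed.
#' @return A list of per-well lists, each with `field` (channel matrices),
#'   `truth_nuclei` and `truth_spots`.
#' @export
simulate_well_images <- function(n_wells = 2L, nuclei_per_field = 6L,
                                 n_spots = 46L, pixel_size = 0.108,
                                 field_shape = c(512L, 512L), seed = 1L) {
  purrr::map(seq_len(n_wells), function(w) {
    wseed <- derive_seed(seed, paste0("well", w))
    ncol_grid <- ceiling(sqrt(nuclei_per_field))
    nrow_grid <- ceiling(nuclei_per_field / ncol_grid)
    pitch_r <- field_shape[1] / nrow_grid
    pitch_c <- field_shape[2] / ncol_grid
    nuclei <- list(); spotsets <- list()
    for (i in seq_len(nuclei_per_field)) {
      gr <- (i - 1) %/% ncol_grid
      gc <- (i - 1) %% ncol_grid
      ctr <- c(pitch_r * (gr + 0.5), pitch_c * (gc + 0.5))
      params <- nucleus_shape_params(
        semi_axis_a = 0.33 * min(pitch_r, pitch_c) * pixel_size,
        semi_axis_b = 0.27 * min(pitch_r, pitch_c) * pixel_size,
        orientation = (i * 0.7) %% pi, centroid = ctr,
        boundary_noise_amplitude = 0.05
      )
      nuc <- generate_nucleus_mask(params, pixel_size, field_shape,
                                   seed = derive_seed(wseed, paste0("nuc", i)))
      sp <- sample_spots(nuc$mask, spot_process_params(n_spots, "csr"),
                         pixel_size,
                         seed = derive_seed(wseed, paste0("spots", i)))
      nuclei[[i]] <- nuc$mask
      spotsets[[i]] <- dplyr::mutate(sp, nucleus = i)
    }
    field <- render_field(nuclei, spotsets, field_shape = field_shape,
                          psf_sigma = 1.5, spot_amplitude = 2000,
                          dapi_level = 800, background = 100,
                          gaussian_sd = 20, seed = derive_seed(wseed, "noise"))
    list(field = field,
         truth_nuclei = nuclei,
         truth_spots = purrr::list_rbind(spotsets))
  })
}
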