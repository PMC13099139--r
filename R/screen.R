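# Hit calling for arrayed imaging screens: per-well aggregation of QC-passing
# cells, per-plate robust Z against the library median, replicate-level
# re-standardisation, replicate averaging, exclusion filters and hit
# definition at |mean Z| > 2.5.

screen_features <- c("mean_clustering_score", "mean_spot_count",
                     "n_cells_pass_qc", "mean_nuclear_area")

#' Aggregate per-cell features to well summaries
#'
#' Arithmetic means per feature over QC-passing cells only; wells with fewer
#' than `min_cells` usable cells are flagged unusable and excluded from
#' normalization. Cells with missing clustering scores (fewer than 2 spots)
#' are excluded from the clustering-score mean but kept for spot-count
#' aggregation.
#'
#' @param cells Per-cell tibble with `replicate`, `plate`, `well`, feature
#'   columns and `qc_pass`.
#' @param layout Plate layout tibble (`plate`, `well`, `role`, `gene`); every
#'   cell's well must appear in it.
#' @param min_cells Minimum QC-passing cells per usable well (default 20).
#' @return Tibble of well summaries with `n_cells_total`, `n_cells_pass_qc`,
#'   per-feature means and `usable`.
#' @export
aggregate_wells <- function(cells, layout, min_cells = 20L) {
  key_cells <- dplyr::distinct(cells, .data$plate, .data$well)
  unknown <- dplyr::anti_join(key_cells, layout, by = c("plate", "well"))
  if (nrow(unknown) > 0L) {
    rlang::abort(sprintf("cells reference wells missing from the layout (e.g. plate %s well %s)",
                         unknown$plate[1], unknown$well[1]))
  }
  sums <- cells |>
    dplyr::group_by(.data$replicate, .data$plate, .data$well) |>
    dplyr::summarise(
      n_cells_total = dplyr::n(),
      n_cells_pass_qc = sum(.data$qc_pass),
      mean_spot_count = mean(.data$spot_count[.data$qc_pass]),
      mean_clustering_score = mean(.data$clustering_score[.data$qc_pass],
                                   na.rm = TRUE),
      mean_radial_distance = mean(.data$mean_radial_distance[.data$qc_pass]),
      mean_nuclear_area = mean(.data$nuclear_area[.data$qc_pass]),
      .groups = "drop"
    )
  sums |>
    dplyr::left_join(layout, by = c("plate", "well")) |>
    dplyr::mutate(usable = .data$n_cells_pass_qc >= min_cells)
}

#' Per-plate robust Z normalization
#'
#' For each plate and feature, centers on the median of the *library* wells
#' and scales by 1.4826 x their MAD (control wells are scored against the
#' library center but never contribute to it). A zero MAD falls back to the
#' SD; zero SD yields all-zero Z with a warning.
#'
#' @param wells Well summaries from [aggregate_wells()] (one replicate or
#'   several; normalization is per replicate x plate).
#' @param features Feature columns to normalize.
#' @param robust Use median/MAD (default) or mean/SD when `FALSE`.
#' @return The input with `z_<feature>` columns added (unusable wells get NA).
#' @export
normalize_plate <- function(wells, features = screen_features, robust = TRUE) {
  wells |>
    dplyr::group_by(.data$replicate, .data$plate) |>
    dplyr::group_modify(function(df, key) {
      lib <- df$role == "library" & df$usable
      if (sum(lib) < 8L) {
        rlang::abort(sprintf("plate %s has fewer than 8 usable library wells",
                             key$plate))
      }
      for (f in features) {
        z <- rep(NA_real_, nrow(df))
        z[df$usable] <- robust_z(df[[f]][df$usable], ref = df[[f]][lib],
                                 robust = robust)
        df[[paste0("z_", f)]] <- z
      }
      df
    }) |>
    dplyr::ungroup()
}

#' Replicate-level robust standardisation
#'
#' Pools the per-plate Z values of all plates belonging to one replicate and
#' re-standardises each feature with a robust Z against the pooled library
#' wells, removing residual between-plate scale differences.
#'
#' @param plate_z Output of [normalize_plate()].
#' @param features Feature columns (the `z_` prefixed versions are used).
#' @param robust Median/MAD (default) or mean/SD.
#' @return The input with the `z_` columns replaced by replicate-standardised
#'   values.
#' @export
standardize_replicate <- function(plate_z, features = screen_features,
                                  robust = TRUE) {
  plate_z |>
    dplyr::group_by(.data$replicate) |>
    dplyr::group_modify(function(df, key) {
      lib <- df$role == "library" & df$usable
      for (f in paste0("z_", features)) {
        ref <- df[[f]][lib]
        df[[f]] <- ifelse(df$usable, robust_z(df[[f]], ref = ref,
                                              robust = robust), NA_real_)
      }
      df
    }) |>
    dplyr::ungroup()
}

#' Combine replicates into per-gene summaries
#'
#' Averages the replicate-standardised Z-scores of the same well/plate
#' combination across biological replicates, gene by gene, and records the
#' across-replicate SD used by the consistency filter. Genes missing from any
#' replicate (e.g. wells unusable in one replicate) are flagged.
#'
#' @param rep_z Output of [standardize_replicate()] covering all replicates.
#' @param features Feature columns.
#' @return Per-gene tibble with `mean_z_*`, `sd_z_*`, `n_replicates` and the
#'   dysmorphic-fraction summary `frac_qc_fail`.
#' @export
combine_replicates <- function(rep_z, features = screen_features) {
  zcols <- paste0("z_", features)
  out <- rep_z |>
    dplyr::filter(!is.na(.data$gene)) |>
    dplyr::group_by(.data$gene, .data$role, .data$plate, .data$well) |>
    dplyr::summarise(
      n_replicates = sum(!is.na(.data[[zcols[1]]])),
      dplyr::across(dplyr::all_of(zcols),
                    list(mean = ~mean(.x, na.rm = TRUE),
                         sd = ~sd(.x[!is.na(.x)]))),
      frac_qc_fail = 1 - sum(.data$n_cells_pass_qc) / sum(.data$n_cells_total),
      .groups = "drop"
    )
  nm <- names(out)
  nm <- sub("^z_(.*)_mean$", "mean_z_\\1", nm)
  nm <- sub("^z_(.*)_sd$", "sd_z_\\1", nm)
  names(out) <- nm
  dplyr::mutate(out, missing_replicate = .data$n_replicates < max(.data$n_replicates))
}

#' Call screen hits
#'
#' Applies the exclusion filters in order of precedence and then the hit
#' threshold. Exclusions: (1) *dysmorphic* -- more than `max_qc_fail_frac` of
#' the gene's nuclei fail morphology QC; (2) *cytotoxic* -- cell-number mean
#' Z below `z_cytotoxic`; (3) *inconsistent* -- for the feature(s) whose
#' |mean Z| would qualify the gene as a hit, the |mean Z| is smaller than the
#' across-replicate SD. Remaining genes are hits iff |mean Z| > `z_hit`
#' (strict) on the clustering score or the spot count.
#'
#' @param gene_z Output of [combine_replicates()].
#' @param z_hit Hit threshold (default 2.5).
#' @param z_cytotoxic Cytotoxicity threshold on the cell-number Z
#'   (default -2.5, strict `<`).
#' @param max_qc_fail_frac Dysmorphic-exclusion threshold on the fraction of
#'   QC-failing nuclei (default 0.5).
#' @return A `gene_calls` tibble with `excluded_reason`, `hit`,
#'   `clustering_direction` and `count_direction`.
#' @export
call_hits <- function(gene_z, z_hit = 2.5, z_cytotoxic = -2.5,
                      max_qc_fail_frac = 0.5) {
  single_rep <- max(gene_z$n_replicates) < 2
  if (single_rep) {
    rlang::warn("single replicate: replicate-consistency filter skipped")
  }
  out <- gene_z |>
    dplyr::mutate(
      qualifies_clustering = abs(.data$mean_z_mean_clustering_score) > z_hit,
      qualifies_count = abs(.data$mean_z_mean_spot_count) > z_hit,
      inconsistent_clustering = !single_rep & .data$qualifies_clustering &
        abs(.data$mean_z_mean_clustering_score) < .data$sd_z_mean_clustering_score,
      inconsistent_count = !single_rep & .data$qualifies_count &
        abs(.data$mean_z_mean_spot_count) < .data$sd_z_mean_spot_count,
      excluded_reason = dplyr::case_when(
        .data$missing_replicate ~ "missing_replicate",
        .data$frac_qc_fail > max_qc_fail_frac ~ "dysmorphic",
        .data$mean_z_n_cells_pass_qc < z_cytotoxic ~ "cytotoxic",
        (.data$qualifies_clustering | .data$qualifies_count) &
          (!.data$qualifies_clustering | .data$inconsistent_clustering) &
          (!.data$qualifies_count | .data$inconsistent_count) ~ "inconsistent",
        TRUE ~ "none"
      ),
      hit = .data$excluded_reason == "none" &
        ((.data$qualifies_clustering & !.data$inconsistent_clustering) |
           (.data$qualifies_count & !.data$inconsistent_count)),
      clustering_direction = dplyr::case_when(
        .data$hit & .data$qualifies_clustering & !.data$inconsistent_clustering &
          .data$mean_z_mean_clustering_score > 0 ~ "clustered",
        .data$hit & .data$qualifies_clustering & !.data$inconsistent_clustering &
          .data$mean_z_mean_clustering_score < 0 ~ "unclustered",
        TRUE ~ "none"
      ),
      count_direction = dplyr::case_when(
        .data$hit & .data$qualifies_count & !.data$inconsistent_count &
          .data$mean_z_mean_spot_count > 0 ~ "higher",
        .data$hit & .data$qualifies_count & !.data$inconsistent_count &
          .data$mean_z_mean_spot_count < 0 ~ "lower",
        TRUE ~ "none"
      )
    ) |>
    dplyr::select(-dplyr::starts_with("qualifies_"),
                  -dplyr::starts_with("inconsistent_"))
  class(out) <- c("gene_calls", class(out))
  out
}

#' Classify hit phenotypes
#'
#' Labels each hit by which read-outs changed and in which direction:
#' clustering-only, count-only, or combined categories such as "higher
#' clustering" (clustering up, count down) and "fewer larger clusters"
#' (both down).
#'
#' @param calls A `gene_calls` tibble restricted to, or containing, hits.
#' @return The hit rows with a `phenotype` column.
#' @export
classify_phenotype <- function(calls) {
  hits <- dplyr::filter(calls, .data$hit)
  if (nrow(hits) == 0L && nrow(calls) > 0L && !any(calls$hit)) {
    rlang::abort("no hits to classify")
  }
  dplyr::mutate(
    hits,
    phenotype = dplyr::case_when(
      .data$clustering_direction == "clustered" & .data$count_direction == "lower" ~
        "higher clustering",
      .data$clustering_direction == "unclustered" & .data$count_direction == "higher" ~
        "dispersion",
      .data$clustering_direction == "unclustered" & .data$count_direction == "lower" ~
        "fewer larger clusters",
      .data$clustering_direction == "clustered" & .data$count_direction == "higher" ~
        "more smaller clusters",
      .data$clustering_direction != "none" ~
        paste0("clustering-only (", .data$clustering_direction, ")"),
      .data$count_direction != "none" ~
        paste0("count-only (", .data$count_direction, ")"),
      TRUE ~ "unclassified"
    )
  )
}

#' Run the full screen analysis
#'
#' Convenience wrapper: aggregate wells, per-plate robust Z, replicate
#' standardisation, replicate combination and hit calling.
#'
#' @inheritParams aggregate_wells
#' @inheritParams call_hits
#' @param robust Use robust (median/MAD) normalization throughout.
#' @return A `gene_calls` tibble.
#' @export
analyze_screen <- function(cells, layout, min_cells = 20L, z_hit = 2.5,
                           z_cytotoxic = -2.5, max_qc_fail_frac = 0.5,
                           robust = TRUE) {
  aggregate_wells(cells, layout, min_cells = min_cells) |>
    normalize_plate(robust = robust) |>
    standardize_replicate(robust = robust) |>
    combine_replicates() |>
    call_hits(z_hit = z_hit, z_cytotoxic = z_cytotoxic,
              max_qc_fail_frac = max_qc_fail_frac)
}

#' Compare screens from two cell lines
#'
#' Pearson correlation of the mean clustering Z across all genes scored and
#' not excluded in both screens, the intersection of the hit sets, and the
#' per-common-hit direction concordance for clustering and spot count.
#'
#' @param calls_a,calls_b `gene_calls` tibbles from [call_hits()] for the two
#'   screens (library genes are compared).
#' @return A `screen_concordance` object.
#' @export
compare_cell_lines <- function(calls_a, calls_b) {
  a <- dplyr::filter(calls_a, .data$role == "library")
  b <- dplyr::filter(calls_b, .data$role == "library")
  shared <- intersect(a$gene, b$gene)
  if (length(shared) == 0L) rlang::abort("the two screens share no genes")
  a <- a[match(shared, a$gene), ]
  b <- b[match(shared, b$gene), ]
  ok <- a$excluded_reason == "none" & b$excluded_reason == "none"
  ct <- stats::cor.test(a$mean_z_mean_clustering_score[ok],
                        b$mean_z_mean_clustering_score[ok])
  common_hits <- shared[a$hit & b$hit]
  ah <- a[match(common_hits, a$gene), ]
  bh <- b[match(common_hits, b$gene), ]
  direction_same <- function(da, db) {
    both <- da != "none" & db != "none"
    ifelse(both, ifelse(da == db, "same", "opposite"), "one-sided")
  }
  structure(
    list(
      n_shared = length(shared),
      n_compared = sum(ok),
      pearson_r = unname(ct$estimate),
      p_value = ct$p.value,
      hits_a = sum(a$hit), hits_b = sum(b$hit),
      common_hits = tibble::tibble(
        gene = common_hits,
        clustering_concordance = direction_same(ah$clustering_direction,
                                                bh$clustering_direction),
        count_concordance = direction_same(ah$count_direction,
                                           bh$count_direction)
      )
    ),
    class = "screen_concordance"
  )
}

#' @export
print.screen_concordance <- function(x, ...) {
  cat("Two-screen concordance over", x$n_compared, "genes\n")
  cat(sprintf("  Pearson R (clustering Z) = %.3f (p = %.3g)\n",
              x$pearson_r, x$p_value))
  cat(sprintf("  hits: %d vs %d, %d in common\n", x$hits_a, x$hits_b,
              nrow(x$common_hits)))
  invisible(x)
}

#' @export
tidy.screen_concordance <- function(x, ...) x$common_hits

#' @export
glance.screen_concordance <- function(x, ...) {
  tibble::tibble(
    n_shared = x$n_shared, n_compared = x$n_compared,
    pearson_r = x$pearson_r, p_value = x$p_value,
    hits_a = x$hits_a, hits_b = x$hits_b,
    n_common_hits = nrow(x$common_hits)
  )
}
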