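# Per-field feature extraction: segmentation + spot detection + spatial
# scoring, producing one row per nucleus (the per-cell analysis record).

#' Extract per-cell features from one field
#'
#' Segments nuclei in the DAPI channel, detects spots in the spot channel,
#' assigns spots to nuclei by mask membership, and computes spot count,
#' clustering score, mean normalized radial distance and morphology per
#' nucleus. Spots falling outside every nucleus are dropped (and counted in
#' the `n_orphan_spots` attribute). Cells with fewer than 2 spots get a
#' missing clustering score.
#'
#' @param field List with `dapi`, `spots` and optionally `edu` matrices.
#' @param pixel_size Pixel size in micron/pixel.
#' @param sigma_range,threshold_k Spot-detection settings
#'   (see [detect_spots()]).
#' @param n_mc,score_seed Clustering-score baseline settings
#'   (see [clustering_score()]).
#' @return Tibble with one row per segmented nucleus; attribute `spots`
#'   carries the per-spot table.
#' @export
extract_features <- function(field, pixel_size = 0.108, sigma_range = c(1, 3),
                             threshold_k = 8, n_mc = 100L, score_seed = 1L) {
  seg <- segment_nuclei(field$dapi, pixel_size = pixel_size,
                        edu_image = field$edu)
  if (nrow(seg$nuclei) == 0L) {
    out <- dplyr::mutate(seg$nuclei, spot_count = integer(0),
                         clustering_score = numeric(0),
                         mean_radial_distance = numeric(0))
    attr(out, "spots") <- NULL
    return(out)
  }
  spots <- detect_spots(field$spots, seg$labels, sigma_range = sigma_range,
                        threshold_k = threshold_k)
  per_nuc <- purrr::map(seg$nuclei$nucleus_id, function(id) {
    mask <- seg$labels == id
    sp <- dplyr::filter(spots, .data$nucleus_id == id)
    score <- clustering_score(sp, mask, pixel_size = pixel_size, n_mc = n_mc,
                              seed = score_seed)
    mrd <- if (nrow(sp) >= 1L) mean(radial_distances(sp, mask)$r_norm) else NA_real_
    tibble::tibble(nucleus_id = id, spot_count = nrow(sp),
                   clustering_score = score, mean_radial_distance = mrd)
  }) |> purrr::list_rbind()
  out <- dplyr::left_join(seg$nuclei, per_nuc, by = "nucleus_id")
  attr(out, "spots") <- spots
  out
}
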