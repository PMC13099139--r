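# Normalized radial position of spots within the nucleus.

# Distance from `ctr` (named row/col, 0-based) to the mask boundary along each
# unit direction in `dirs` (n x 2, rows are (drow, dcol)). March outward in
# fixed sub-pixel steps and take the midpoint of the last-inside /
# first-outside pair.
ray_boundary_distance <- function(mask, ctr, dirs, step = 0.1) {
  dmax <- sqrt(nrow(mask)^2 + ncol(mask)^2)
  ts <- seq(0, dmax, by = step)
  n <- nrow(dirs)
  out <- numeric(n)
  for (i in seq_len(n)) {
    rr <- ctr[["row"]] + ts * dirs[i, 1]
    cc <- ctr[["col"]] + ts * dirs[i, 2]
    inside <- points_in_mask(mask, rr, cc)
    first_out <- which(!inside)[1]
    out[i] <- if (is.na(first_out)) dmax else ts[first_out] - step / 2
  }
  out
}

#' Normalized radial distance of spots
#'
#' For each spot, the distance from the nucleus centroid divided by the
#' distance from the centroid to the mask boundary along the ray through the
#' spot, giving a value in `[0, 1]` (0 = at the center, 1 = on the boundary).
#' The per-cell mean of this quantity summarises how peripheral the
#' centromeres sit.
#'
#' @param spots Tibble with `row`, `col` sub-pixel spot positions (0-based).
#' @param mask Logical matrix, the owning nucleus mask.
#' @return The input tibble with an `r_norm` column; the per-cell mean is
#'   `mean(r_norm)`. With zero spots a zero-row tibble is returned.
#' @export
radial_distances <- function(spots, mask) {
  if (nrow(spots) == 0L) {
    return(dplyr::mutate(spots, r_norm = numeric(0)))
  }
  ctr <- mask_centroid(mask)
  dr <- spots$row - ctr[["row"]]
  dc <- spots$col - ctr[["col"]]
  d <- sqrt(dr^2 + dc^2)
  dirs <- cbind(dr, dc) / pmax(d, 1e-9)
  # a spot exactly at the centroid has no direction; any ray gives r_norm 0
  zero <- d < 1e-9
  if (any(zero)) dirs[zero, ] <- matrix(c(1, 0), sum(zero), 2, byrow = TRUE)
  db <- ray_boundary_distance(mask, ctr, dirs)
  dplyr::mutate(spots, r_norm = pmin(d / pmax(db, 1e-9), 1))
}
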