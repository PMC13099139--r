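# Mask geometry. Masks are logical (or 0/1) matrices indexed [row, col].
# Coordinates are (row, col), 0-based, with pixel centers at integer positions;
# physical quantities are obtained via pixel_size (micron / pixel).

# 0-based pixel-center coordinates of all TRUE pixels, as a 2-column matrix
# (row, col).
mask_coords <- function(mask) {
  idx <- which(mask != 0, arr.ind = TRUE)
  cbind(row = idx[, 1] - 1, col = idx[, 2] - 1)
}

mask_area_px <- function(mask) sum(mask != 0)

#' Mask area in square micron
#' @param mask Logical matrix.
#' @param pixel_size Pixel size in micron/pixel.
#' @return Scalar area in square micron.
#' @export
mask_area <- function(mask, pixel_size) {
  mask_area_px(mask) * pixel_size^2
}

#' Equivalent radius of a mask
#'
#' The radius of the circle with the same area, `sqrt(A / pi)`; used to scale
#' the clustering-score radii grid to nuclear size.
#'
#' @inheritParams mask_area
#' @return Scalar radius in micron.
#' @export
equivalent_radius <- function(mask, pixel_size) {
  sqrt(mask_area(mask, pixel_size) / pi)
}

mask_centroid <- function(mask) {
  xy <- mask_coords(mask)
  c(row = mean(xy[, "row"]), col = mean(xy[, "col"]))
}

# Area (in pixels) of the rasterised convex hull of the mask's pixel centers:
# for each pixel row crossed by the hull polygon, count pixels whose centers
# fall inside the row's [min, max] hull interval. Convexity guarantees a single
# interval per row.
convex_hull_area_px <- function(mask) {
  xy <- mask_coords(mask)
  if (nrow(xy) == 0L) return(0)
  if (nrow(xy) <= 2L) return(nrow(xy))
  hull_idx <- grDevices::chull(xy[, "col"], xy[, "row"])
  hull <- xy[hull_idx, , drop = FALSE]
  nh <- nrow(hull)
  if (nh <= 2L) {
    # collinear points: hull degenerates to a segment
    return(nrow(unique(xy)))
  }
  rows <- seq(min(hull[, "row"]), max(hull[, "row"]))
  total <- 0L
  v1 <- hull
  v2 <- hull[c(2:nh, 1L), , drop = FALSE]
  for (r in rows) {
    xs <- numeric(0)
    for (e in seq_len(nh)) {
      r1 <- v1[e, "row"]; r2 <- v2[e, "row"]
      c1 <- v1[e, "col"]; c2 <- v2[e, "col"]
      if ((r1 <= r && r2 >= r) || (r2 <= r && r1 >= r)) {
        if (r1 == r2) {
          xs <- c(xs, c1, c2)
        } else {
          xs <- c(xs, c1 + (r - r1) * (c2 - c1) / (r2 - r1))
        }
      }
    }
    if (length(xs) > 0) {
      total <- total + max(0L, floor(max(xs) + 1e-9) - ceiling(min(xs) - 1e-9) + 1L)
    }
  }
  total
}

#' Mask solidity
#'
#' Region area divided by the area of its convex hull; values well below 1
#' indicate dysmorphic (non-convex) nuclei.
#'
#' @param mask Logical matrix.
#' @return Scalar in (0, 1].
#' @export
mask_solidity <- function(mask) {
  a <- mask_area_px(mask)
  if (a == 0L) rlang::abort("empty mask has no solidity")
  h <- convex_hull_area_px(mask)
  min(1, a / max(a, h))
}

mask_touches_border <- function(mask) {
  any(mask[1, ] != 0) || any(mask[nrow(mask), ] != 0) ||
    any(mask[, 1] != 0) || any(mask[, ncol(mask)] != 0)
}

# TRUE where (row0, col0) -- 0-based, possibly fractional -- falls on a TRUE
# pixel of the mask (nearest-pixel lookup).
points_in_mask <- function(mask, row0, col0) {
  r <- round(row0) + 1
  c <- round(col0) + 1
  ok <- r >= 1 & r <= nrow(mask) & c >= 1 & c <= ncol(mask)
  inside <- rep(FALSE, length(row0))
  inside[ok] <- mask[cbind(r[ok], c[ok])] != 0
  inside
}
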