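# Point-process simulation of centromere spots inside a nucleus mask.

#' Spot point-process parameters
#'
#' @param n_spots Number of spots to place (exact).
#' @param process_kind One of `"csr"` (uniform over the mask),
#'   `"thomas"` (parent points uniform in the mask, offspring Gaussian around
#'   parents) or `"radial_biased"` (CSR radial coordinate warped by a power).
#' @param thomas_n_parents Number of Thomas parents.
#' @param thomas_sigma Offspring dispersion (micron); required for
#'   `"thomas"`.
#' @param radial_bias_exponent Exponent applied to the normalized radial
#'   coordinate; > 1 pushes spots outward, < 1 pulls them inward.
#' @param min_separation Hard-core distance (micron): points closer than this
#'   are resampled (CSR only). Use for rendering fields whose spots must be
#'   optically resolvable; 0 disables.
#' @return A `spot_process_params` list.
#' @export
spot_process_params <- function(n_spots = 46L, process_kind = c("csr", "thomas", "radial_biased"),
                                thomas_n_parents = 6L, thomas_sigma = NULL,
                                radial_bias_exponent = 1, min_separation = 0) {
  process_kind <- match.arg(process_kind)
  assert_scalar_number(n_spots, "n_spots", lower = 0)
  if (process_kind == "thomas") {
    if (is.null(thomas_sigma)) rlang::abort("`thomas_sigma` is required for the thomas process")
    assert_scalar_number(thomas_sigma, "thomas_sigma", lower = 1e-9)
    assert_scalar_number(thomas_n_parents, "thomas_n_parents", lower = 1)
  }
  structure(
    list(n_spots = as.integer(n_spots), process_kind = process_kind,
         thomas_n_parents = as.integer(thomas_n_parents),
         thomas_sigma = thomas_sigma,
         radial_bias_exponent = radial_bias_exponent,
         min_separation = min_separation),
    class = "spot_process_params"
  )
}

# Uniform positions over mask pixels with sub-pixel jitter; returns an n x 2
# matrix of 0-based (row, col) positions. `xy` may be passed precomputed when
# sampling repeatedly from one mask.
sample_uniform_in_mask <- function(mask, n, xy = mask_coords(mask)) {
  if (nrow(xy) == 0L && n > 0L) rlang::abort("cannot sample spots in an empty mask")
  if (n == 0L) return(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("row", "col"))))
  i <- sample.int(nrow(xy), n, replace = TRUE)
  pts <- xy[i, , drop = FALSE] + matrix(runif(2 * n, -0.5, 0.5), n, 2)
  # jitter may step off the mask at the boundary: nudge those back to centers
  bad <- !points_in_mask(mask, pts[, 1], pts[, 2])
  pts[bad, ] <- xy[i[bad], , drop = FALSE]
  colnames(pts) <- c("row", "col")
  pts
}

#' Sample spot positions inside a mask
#'
#' Places exactly `n_spots` points inside the mask according to the requested
#' point process. Offspring of Thomas parents (and radially warped points)
#' falling outside the mask are redrawn, keeping the spot count exact.
#'
#' @param mask Logical matrix (the nucleus mask).
#' @param params A [spot_process_params()] object.
#' @param pixel_size Pixel size in micron/pixel, used to convert
#'   `thomas_sigma` to pixels.
#' @param seed Integer seed.
#' @return A tibble with columns `spot_id`, `row`, `col` (0-based sub-pixel
#'   positions).
#' @export
sample_spots <- function(mask, params, pixel_size = 0.108, seed = 1L) {
  stopifnot(inherits(params, "spot_process_params"))
  n <- params$n_spots
  if (n > 0L && mask_area_px(mask) == 0L) {
    rlang::abort("cannot sample spots in an empty mask")
  }
  pts <- with_seed(seed, {
    switch(params$process_kind,
      csr = if ((params$min_separation %||% 0) > 0) {
        sample_hardcore(mask, n, params$min_separation / pixel_size)
      } else {
        sample_uniform_in_mask(mask, n)
      },
      thomas = sample_thomas(mask, n, params$thomas_n_parents,
                             params$thomas_sigma / pixel_size),
      radial_biased = sample_radial_biased(mask, n, params$radial_bias_exponent)
    )
  })
  tibble::tibble(spot_id = seq_len(nrow(pts)),
                 row = pts[, "row"], col = pts[, "col"])
}

# Sequential hard-core sampling: uniform proposals, rejected within
# `hc_px` of an accepted point. Gives up on the constraint (keeping the
# count exact) if the mask cannot fit n points at that spacing.
sample_hardcore <- function(mask, n, hc_px) {
  acc <- matrix(numeric(0), 0, 2, dimnames = list(NULL, c("row", "col")))
  attempts <- 0L
  while (nrow(acc) < n && attempts < 200L * n) {
    prop <- sample_uniform_in_mask(mask, 1L)
    ok <- nrow(acc) == 0L ||
      all((acc[, 1] - prop[1, 1])^2 + (acc[, 2] - prop[1, 2])^2 >= hc_px^2)
    if (ok) acc <- rbind(acc, prop)
    attempts <- attempts + 1L
  }
  if (nrow(acc) < n) {
    acc <- rbind(acc, sample_uniform_in_mask(mask, n - nrow(acc)))
  }
  acc
}

sample_thomas <- function(mask, n, n_parents, sigma_px) {
  if (n == 0L) return(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("row", "col"))))
  parents <- sample_uniform_in_mask(mask, n_parents)
  assign <- sample.int(n_parents, n, replace = TRUE)
  out <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("row", "col")))
  # offspring ~ N(parent, sigma^2) conditioned on the mask. For dispersions
  # comparable to the nucleus, rejection against the Gaussian proposal is
  # efficient; for sigma much larger than the mask almost every Gaussian draw
  # misses, so instead sample uniform mask positions and thin them by the
  # (nearly flat) Gaussian density ratio -- the same conditional law.
  wide <- 2 * pi * sigma_px^2 > 4 * mask_area_px(mask)
  todo <- seq_len(n)
  tries <- 0L
  while (length(todo) > 0L && tries < 1000L) {
    k <- length(todo)
    if (wide) {
      prop <- sample_uniform_in_mask(mask, k)
      par <- parents[assign[todo], , drop = FALSE]
      d2 <- (prop[, 1] - par[, 1])^2 + (prop[, 2] - par[, 2])^2
      ok <- runif(k) < exp(-d2 / (2 * sigma_px^2))
    } else {
      prop <- parents[assign[todo], , drop = FALSE] +
        matrix(rnorm(2 * k, 0, sigma_px), k, 2)
      ok <- points_in_mask(mask, prop[, 1], prop[, 2])
    }
    out[todo[ok], ] <- prop[ok, , drop = FALSE]
    todo <- todo[!ok]
    tries <- tries + 1L
  }
  if (length(todo) > 0L) {
    # pathological sigma vs mask: fall back to the parent positions
    out[todo, ] <- parents[assign[todo], , drop = FALSE]
  }
  out
}

# CSR sample expressed in polar coordinates about the mask centroid, with the
# normalized radial coordinate raised to `exponent`; rejection keeps points in
# the mask.
sample_radial_biased <- function(mask, n, exponent) {
  if (n == 0L) return(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("row", "col"))))
  ctr <- mask_centroid(mask)
  out <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("row", "col")))
  todo <- seq_len(n)
  tries <- 0L
  while (length(todo) > 0L && tries < 1000L) {
    k <- length(todo)
    base <- sample_uniform_in_mask(mask, k)
    dr <- base[, 1] - ctr[["row"]]
    dc <- base[, 2] - ctr[["col"]]
    d <- sqrt(dr^2 + dc^2)
    dmax <- ray_boundary_distance(mask, ctr, cbind(dr, dc) / pmax(d, 1e-9))
    rn <- pmin(d / pmax(dmax, 1e-9), 1)
    rn2 <- rn^exponent
    prop <- cbind(ctr[["row"]] + dr / pmax(d, 1e-9) * rn2 * dmax,
                  ctr[["col"]] + dc / pmax(d, 1e-9) * rn2 * dmax)
    ok <- points_in_mask(mask, prop[, 1], prop[, 2])
    out[todo[ok], ] <- prop[ok, , drop = FALSE]
    todo <- todo[!ok]
    tries <- tries + 1L
  }
  if (length(todo) > 0L) out[todo, ] <- sample_uniform_in_mask(mask, length(todo))
  out
}
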