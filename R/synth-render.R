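# Rendering of synthetic multi-channel fluorescence fields: filled nuclei in
# the DAPI channel, diffraction-limited spots (2D Gaussians) in the spot
# channel, phase-dependent EdU signal, Poisson + Gaussian sensor noise,
# clipped to a 16-bit range.

add_gaussian_spot <- function(image, row, col, sigma, amplitude) {
  w <- ceiling(4 * sigma)
  rr <- max(0, floor(row) - w):min(nrow(image) - 1, ceiling(row) + w)
  cc <- max(0, floor(col) - w):min(ncol(image) - 1, ceiling(col) + w)
  g <- outer(exp(-(rr - row)^2 / (2 * sigma^2)),
             exp(-(cc - col)^2 / (2 * sigma^2)))
  image[rr + 1, cc + 1] <- image[rr + 1, cc + 1] + amplitude * g
  image
}

#' Render a synthetic multi-channel field
#'
#' @param nuclei List of nucleus masks (logical matrices on a common field),
#'   or a single mask.
#' @param spot_sets List of spot tibbles (`row`, `col`), one per nucleus.
#' @param field_shape Integer length-2 field size (rows, cols); defaults to
#'   the dimensions of the first mask.
#' @param psf_sigma Point-spread sigma of rendered spots in pixels (> 0).
#' @param spot_amplitude Peak amplitude of each spot (counts).
#' @param dapi_level Mean DAPI fill level inside nuclei (counts); recycled
#'   over nuclei so DNA content can differ between cells.
#' @param edu_level Per-nucleus EdU fill level (counts); recycled. Use 0 for
#'   non-S-phase cells.
#' @param background Background offset (counts) added to every channel.
#' @param gaussian_sd Read-noise SD (counts); 0 disables.
#' @param poisson_noise Apply Poisson (shot) noise to the noiseless signal.
#' @param bit_depth Detector bit depth; output clipped to `[0, 2^bit_depth - 1]`.
#' @param seed Integer seed for the noise draws.
#' @return List of numeric matrices `dapi`, `spots`, `edu`.
#' @export
render_field <- function(nuclei, spot_sets, field_shape = NULL,
                         psf_sigma = 1.5, spot_amplitude = 1000,
                         dapi_level = 500, edu_level = 0, background = 100,
                         gaussian_sd = 10, poisson_noise = TRUE,
                         bit_depth = 16L, seed = 1L) {
  if (is.matrix(nuclei)) nuclei <- list(nuclei)
  if (is.data.frame(spot_sets)) spot_sets <- list(spot_sets)
  if (psf_sigma <= 0) rlang::abort("`psf_sigma` must be > 0")
  field_shape <- field_shape %||% dim(nuclei[[1]])
  dapi_level <- rep_len(dapi_level, length(nuclei))
  edu_level <- rep_len(edu_level, length(nuclei))

  dapi <- matrix(0, field_shape[1], field_shape[2])
  edu <- matrix(0, field_shape[1], field_shape[2])
  spots <- matrix(0, field_shape[1], field_shape[2])
  for (i in seq_along(nuclei)) {
    dapi[nuclei[[i]]] <- dapi[nuclei[[i]]] + dapi_level[i]
    if (edu_level[i] > 0) edu[nuclei[[i]]] <- edu[nuclei[[i]]] + edu_level[i]
  }
  for (ss in spot_sets) {
    if (is.null(ss) || nrow(ss) == 0L) next
    for (j in seq_len(nrow(ss))) {
      if (ss$row[j] < 0 || ss$row[j] > field_shape[1] - 1 ||
          ss$col[j] < 0 || ss$col[j] > field_shape[2] - 1) {
        rlang::abort("spot coordinates fall outside the field")
      }
      spots <- add_gaussian_spot(spots, ss$row[j], ss$col[j], psf_sigma,
                                 spot_amplitude)
    }
  }

  apply_noise <- function(signal) {
    out <- signal + background
    if (poisson_noise) out <- matrix(rpois(length(out), pmax(out, 0)),
                                     nrow(out), ncol(out))
    if (gaussian_sd > 0) out <- out + rnorm(length(out), 0, gaussian_sd)
    pmin(pmax(out, 0), 2^bit_depth - 1)
  }
  with_seed(seed, {
    list(dapi = apply_noise(dapi), spots = apply_noise(spots),
         edu = apply_noise(edu))
  })
}
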