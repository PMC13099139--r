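# Synthetic nuclei: elliptical masks with optional low-frequency boundary
# perturbation, emulating segmented interphase nuclei.

#' Nucleus shape parameters
#'
#' @param semi_axis_a,semi_axis_b Ellipse semi-axes in micron
#'   (`semi_axis_a >= semi_axis_b > 0`).
#' @param orientation Major-axis orientation in radians.
#' @param centroid Numeric length-2 (row, col) center in pixels (0-based).
#' @param boundary_noise_amplitude Fractional radial perturbation amplitude in
#'   `[0, 0.3]`; 0 gives a clean ellipse, larger values produce lobed,
#'   low-solidity shapes useful as QC-fail fixtures.
#' @return A `nucleus_shape_params` list.
#' @export
nucleus_shape_params <- function(semi_axis_a = 6, semi_axis_b = 5,
                                 orientation = 0, centroid = NULL,
                                 boundary_noise_amplitude = 0) {
  assert_scalar_number(semi_axis_a, "semi_axis_a", lower = 1e-6)
  assert_scalar_number(semi_axis_b, "semi_axis_b", lower = 1e-6)
  if (semi_axis_b > semi_axis_a) {
    rlang::abort("`semi_axis_a` must be >= `semi_axis_b`")
  }
  assert_scalar_number(boundary_noise_amplitude, "boundary_noise_amplitude",
                       lower = 0, upper = 0.3)
  structure(
    list(semi_axis_a = semi_axis_a, semi_axis_b = semi_axis_b,
         orientation = orientation, centroid = centroid,
         boundary_noise_amplitude = boundary_noise_amplitude),
    class = "nucleus_shape_params"
  )
}

#' Generate a synthetic nucleus mask
#'
#' Rasterises a (possibly boundary-perturbed) ellipse into a binary mask and
#' measures its morphology. The boundary perturbation is a random low-order
#' Fourier series on the polar radius, so the shape stays a single connected
#' component.
#'
#' @param params A [nucleus_shape_params()] object.
#' @param pixel_size Pixel size in micron/pixel (default 0.108).
#' @param field_shape Integer length-2, (rows, cols) of the field in pixels.
#' @param seed Integer seed controlling the boundary perturbation.
#' @return A list with `mask` (logical matrix) and `record`, a one-row tibble
#'   with `centroid_row`, `centroid_col`, `area` (square micron), `solidity`,
#'   `border_touching` and `qc_pass`.
#' @export
generate_nucleus_mask <- function(params, pixel_size = 0.108,
                                  field_shape = c(256L, 256L), seed = 1L) {
  stopifnot(inherits(params, "nucleus_shape_params"))
  assert_scalar_number(pixel_size, "pixel_size", lower = 1e-9)
  ctr <- params$centroid %||% ((field_shape - 1) / 2)
  a_px <- params$semi_axis_a / pixel_size
  b_px <- params$semi_axis_b / pixel_size
  max_r <- max(a_px, b_px) * (1 + params$boundary_noise_amplitude)
  if (ctr[1] - max_r < 0 || ctr[1] + max_r > field_shape[1] - 1 ||
      ctr[2] - max_r < 0 || ctr[2] + max_r > field_shape[2] - 1) {
    rlang::abort("nucleus ellipse exceeds field bounds")
  }

  n_harmonics <- 4L
  amp <- params$boundary_noise_amplitude
  coefs <- with_seed(seed, {
    if (amp > 0) {
      list(a = rnorm(n_harmonics, 0, amp / sqrt(n_harmonics)),
           b = rnorm(n_harmonics, 0, amp / sqrt(n_harmonics)))
    } else {
      list(a = numeric(n_harmonics), b = numeric(n_harmonics))
    }
  })

  rows <- matrix(0:(field_shape[1] - 1), field_shape[1], field_shape[2])
  cols <- matrix(0:(field_shape[2] - 1), field_shape[1], field_shape[2],
                 byrow = TRUE)
  dr <- rows - ctr[1]
  dc <- cols - ctr[2]
  # rotate into the ellipse frame (orientation measured from the col axis)
  co <- cos(params$orientation); si <- sin(params$orientation)
  u <- dc * co + dr * si
  v <- -dc * si + dr * co
  rho <- sqrt((u / a_px)^2 + (v / b_px)^2) # 1 on the unperturbed boundary
  theta <- atan2(v, u)
  pert <- rep(1, length(theta))
  for (k in seq_len(n_harmonics)) {
    pert <- pert + coefs$a[k] * cos(k * theta) + coefs$b[k] * sin(k * theta)
  }
  mask <- matrix(rho <= pmax(pert, 0.05), field_shape[1], field_shape[2])

  # keep the component containing the center (perturbation cannot detach it,
  # but rasterisation of extreme shapes could leave stray pixels)
  lab <- EBImage::bwlabel(mask * 1)
  center_lab <- lab[round(ctr[1]) + 1, round(ctr[2]) + 1]
  if (center_lab == 0) {
    keep <- which.max(tabulate(lab[lab > 0]))
    mask <- lab == keep
  } else {
    mask <- lab == center_lab
  }

  record <- measure_nucleus(mask, pixel_size, nucleus_id = 1L)
  list(mask = mask, record = record)
}

# Morphology + QC for one mask; shared by the generator and the segmenter.
measure_nucleus <- function(mask, pixel_size, nucleus_id = 1L,
                            dapi_image = NULL, edu_image = NULL) {
  ctr <- mask_centroid(mask)
  area <- mask_area(mask, pixel_size)
  solidity <- mask_solidity(mask)
  border <- mask_touches_border(mask)
  tibble::tibble(
    nucleus_id = nucleus_id,
    centroid_row = ctr[["row"]],
    centroid_col = ctr[["col"]],
    area = area,
    solidity = solidity,
    dapi_total = if (is.null(dapi_image)) NA_real_ else sum(dapi_image[mask]),
    edu_total = if (is.null(edu_image)) NA_real_ else sum(edu_image[mask]),
    border_touching = border,
    qc_pass = nucleus_qc(area, solidity, border)
  )
}
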