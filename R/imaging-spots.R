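# Laplacian-of-Gaussian spot detection with sub-pixel centroid localisation.

log_kernel <- function(sigma) {
  h <- ceiling(3 * sigma)
  x <- -h:h
  g <- exp(-x^2 / (2 * sigma^2))
  gxx <- (x^2 - sigma^2) / sigma^4 * g
  # separable LoG: G''(x)G(y) + G(x)G''(y); normalise the Gaussian factors
  k <- outer(gxx, g) + outer(g, gxx)
  -k / (2 * pi * sigma^2)
}

log_response <- function(image, sigma) {
  # scale-normalised (by sigma^2) negative LoG: positive at bright blobs
  sigma^2 * EBImage::imageData(
    EBImage::filter2(EBImage::Image(image), log_kernel(sigma), boundary = "replicate")
  )
}

local_maxima <- function(resp) {
  nr <- nrow(resp); nc <- ncol(resp)
  pad <- matrix(-Inf, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- resp
  is_max <- matrix(TRUE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- pad[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
    is_max <- is_max & (resp >= nb)
  }
  is_max & is.finite(resp)
}

#' Detect spots with a multi-scale Laplacian-of-Gaussian filter
#'
#' Computes scale-normalised LoG responses over a grid of scales, finds
#' scale-space local maxima above a robust noise threshold inside the mask,
#' merges duplicate maxima closer than one scale unit, segments each focus as
#' the above-half-threshold response region nearest its peak, and reports the
#' response-weighted centroid of each focus as the final sub-pixel coordinate.
#'
#' @param spot_image Numeric matrix (spot channel).
#' @param mask Logical matrix (one nucleus) or integer label matrix from
#'   [segment_nuclei()]; detections outside every nucleus are dropped.
#' @param sigma_range Length-2 numeric, min and max LoG scale in pixels
#'   (default `c(1, 3)`).
#' @param n_scales Number of scales spanning `sigma_range` (default 5).
#' @param threshold_k Detection threshold in robust noise units: a maximum
#'   must exceed `threshold_k * 1.4826 * MAD` of the response image
#'   (default 8).
#' @return Tibble with `nucleus_id`, `row`, `col` (0-based sub-pixel),
#'   `sigma` and `response`; zero rows when nothing is detected.
#' @export
detect_spots <- function(spot_image, mask, sigma_range = c(1, 3),
                         n_scales = 5L, threshold_k = 8) {
  stopifnot(is.matrix(spot_image))
  labels <- if (is.logical(mask)) {
    matrix(as.integer(mask), nrow(mask), ncol(mask))
  } else {
    mask
  }
  if (!any(labels > 0)) rlang::abort("mask is empty")
  sigmas <- seq(sigma_range[1], sigma_range[2], length.out = n_scales)
  resp <- lapply(sigmas, function(s) log_response(spot_image, s))

  # robust noise scale from the finest response (dominated by noise); on a
  # noise-free image the MAD vanishes, so floor the threshold at a small
  # fraction of the strongest response to suppress numerical ripple
  noise <- mad(resp[[1]])
  peak_resp <- max(vapply(resp, max, numeric(1)))
  thr <- max(threshold_k * noise, 1e-3 * peak_resp)

  cand <- purrr::imap(resp, function(r, si) {
    lm <- local_maxima(r) & (r > thr) & (labels > 0)
    # require a maximum across adjacent scales at the same pixel
    if (si > 1L) lm <- lm & (r >= resp[[si - 1L]])
    if (si < length(resp)) lm <- lm & (r >= resp[[si + 1L]])
    idx <- which(lm, arr.ind = TRUE)
    if (nrow(idx) == 0L) return(NULL)
    tibble::tibble(row = idx[, 1] - 1, col = idx[, 2] - 1,
                   sigma = sigmas[si], response = r[idx])
  })
  cand <- purrr::list_rbind(purrr::compact(cand))
  if (is.null(cand) || nrow(cand) == 0L) {
    return(tibble::tibble(nucleus_id = integer(0), row = numeric(0),
                          col = numeric(0), sigma = numeric(0),
                          response = numeric(0)))
  }

  # greedy non-maximum suppression: keep the strongest, drop maxima within
  # 1 * sigma of an accepted peak
  cand <- dplyr::arrange(cand, dplyr::desc(.data$response))
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (i == 1L) { keep[1L] <- TRUE; next }
    acc <- which(keep)
    d <- sqrt((cand$row[acc] - cand$row[i])^2 + (cand$col[acc] - cand$col[i])^2)
    keep[i] <- all(d > pmax(cand$sigma[acc], cand$sigma[i]))
  }
  peaks <- cand[keep, ]

  # focus segmentation + response-weighted centroid around each peak; pixels
  # are assigned to their nearest peak so adjacent foci split at the ridge
  out <- purrr::pmap(peaks, function(row, col, sigma, response) {
    si <- which.min(abs(sigmas - sigma))
    r <- resp[[si]]
    w <- ceiling(2.5 * sigma)
    rr <- max(0, round(row) - w):min(nrow(r) - 1, round(row) + w)
    cc <- max(0, round(col) - w):min(ncol(r) - 1, round(col) + w)
    sub <- r[rr + 1, cc + 1, drop = FALSE]
    wt <- pmax(sub - 0.3 * response, 0)
    grid_r <- matrix(rr, length(rr), length(cc))
    grid_c <- matrix(cc, length(rr), length(cc), byrow = TRUE)
    # suppress pixels nearer another accepted peak than this one
    if (nrow(peaks) > 1L) {
      d_self <- (grid_r - row)^2 + (grid_c - col)^2
      others <- peaks[!(peaks$row == row & peaks$col == col), ]
      for (j in seq_len(nrow(others))) {
        d_o <- (grid_r - others$row[j])^2 + (grid_c - others$col[j])^2
        wt[d_o < d_self] <- 0
      }
    }
    sw <- sum(wt)
    if (sw <= 0) {
      ctr <- c(row, col)
    } else {
      ctr <- c(sum(wt * grid_r), sum(wt * grid_c)) / sw
    }
    tibble::tibble(row = ctr[1], col = ctr[2], sigma = sigma,
                   response = response)
  })
  out <- purrr::list_rbind(out)
  lab_at <- function(r0, c0) {
    labels[cbind(pmin(pmax(round(r0), 0), nrow(labels) - 1) + 1,
                 pmin(pmax(round(c0), 0), ncol(labels) - 1) + 1)]
  }
  out$nucleus_id <- as.integer(lab_at(out$row, out$col))
  out <- dplyr::filter(out, .data$nucleus_id > 0)
  dplyr::select(out, "nucleus_id", "row", "col", "sigma", "response")
}
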