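# Cell-cycle gating from integrated DAPI and EdU intensities: a two-component
# Gaussian mixture on log2 DAPI locates the 2N (G1) and 4N (G2/M) modes;
# S-phase is called from detectable EdU; subG1 and >4N cells are excluded.

# Deterministic 1D two-component Gaussian EM, initialised at the 25th/75th
# percentiles (or explicit means) with equal weights.
fit_gaussian_mixture2 <- function(x, max_iter = 200L, tol = 1e-8,
                                  mu_init = NULL) {
  mu <- mu_init %||% as.numeric(quantile(x, c(0.25, 0.75)))
  sg <- rep(max(sd(x) / 2, 1e-4), 2)
  pi1 <- 0.5
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    d1 <- pi1 * dnorm(x, mu[1], sg[1])
    d2 <- (1 - pi1) * dnorm(x, mu[2], sg[2])
    tot <- pmax(d1 + d2, .Machine$double.xmin)
    g1 <- d1 / tot
    pi1 <- mean(g1)
    mu[1] <- sum(g1 * x) / sum(g1)
    mu[2] <- sum((1 - g1) * x) / sum(1 - g1)
    sg[1] <- sqrt(sum(g1 * (x - mu[1])^2) / sum(g1))
    sg[2] <- sqrt(sum((1 - g1) * (x - mu[2])^2) / sum(1 - g1))
    sg <- pmax(sg, 1e-6)
    ll <- sum(log(tot))
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  ord <- order(mu)
  list(mean = mu[ord], sd = sg[ord], weight = c(pi1, 1 - pi1)[ord])
}

# Initial 2N/4N mode locations from the kernel density of log2 DAPI: prefer
# the pair of local maxima separated by roughly one doubling (0.6-1.4 log2
# units) with the highest combined density; fall back to quantile
# initialisation when no such pair exists.
dapi_mode_anchors <- function(x) {
  d <- density(x, n = 512)
  y <- d$y
  is_peak <- c(FALSE, y[2:(length(y) - 1)] > y[1:(length(y) - 2)] &
                 y[2:(length(y) - 1)] >= y[3:length(y)], FALSE)
  peaks <- which(is_peak)
  peaks <- peaks[y[peaks] > 0.05 * max(y)]
  if (length(peaks) < 2L) return(NULL)
  best <- NULL; best_dens <- -Inf
  for (i in seq_along(peaks)) for (j in seq_along(peaks)) {
    if (i >= j) next
    sep <- d$x[peaks[j]] - d$x[peaks[i]]
    if (sep >= 0.6 && sep <= 1.4 && y[peaks[i]] + y[peaks[j]] > best_dens) {
      best <- c(d$x[peaks[i]], d$x[peaks[j]])
      best_dens <- y[peaks[i]] + y[peaks[j]]
    }
  }
  best
}

# Valley between the two dominant modes of a (log2) intensity distribution,
# via a kernel density estimate. Returns NA when no resolvable valley exists.
find_valley <- function(x, min_separation = 0.5) {
  d <- density(x, n = 512)
  y <- d$y
  is_peak <- c(FALSE, y[2:(length(y) - 1)] > y[1:(length(y) - 2)] &
                 y[2:(length(y) - 1)] >= y[3:length(y)], FALSE)
  peaks <- which(is_peak)
  peaks <- peaks[y[peaks] > 0.05 * max(y)]
  if (length(peaks) < 2L) return(NA_real_)
  top2 <- peaks[order(y[peaks], decreasing = TRUE)][1:2]
  top2 <- sort(top2)
  if (d$x[top2[2]] - d$x[top2[1]] < min_separation) return(NA_real_)
  between <- top2[1]:top2[2]
  d$x[between[which.min(y[between])]]
}

#' Fit a cell-cycle phase gate
#'
#' Fits a deterministic two-component Gaussian mixture to log2 DAPI totals to
#' locate the G1 (2N) and G2/M (4N) modes; the G1/G2 cut is the midpoint of
#' the modes and cells beyond 3 component SD below the G1 mode (subG1) or
#' above the G2 mode (>4N) are excluded from analysis. The EdU-positive cut
#' is the valley of the bimodal log2 EdU distribution; when no valley is
#' resolvable (e.g. no S-phase cells) a conservative upper-tail fallback cut
#' is used so that background-only populations yield no S-phase calls.
#'
#' @param dapi_totals,edu_totals Positive per-cell integrated intensities
#'   (linear scale), at least 200 cells.
#' @return A `phase_gate` object with fields `log2_dapi_g1_mode`,
#'   `log2_dapi_g2_mode`, `g1_g2_cut`, `subg1_cut`, `over4n_cut`,
#'   `edu_positive_cut`, `edu_fallback` and the mixture fit.
#' @export
fit_phase_gate <- function(dapi_totals, edu_totals) {
  if (length(dapi_totals) < 200L) {
    rlang::abort("gate fitting requires at least 200 cells")
  }
  if (any(dapi_totals <= 0) || any(edu_totals <= 0)) {
    rlang::abort("intensity totals must be positive")
  }
  e <- log2(edu_totals)
  valley <- find_valley(e)
  fallback <- !is.finite(valley)
  if (fallback) {
    valley <- quantile(e, 0.995) + 2 * 1.4826 * mad(e)
  }
  # S-phase cells sit between the 2N and 4N modes and would bias the mixture;
  # fit it on EdU-negative cells (G1 + G2/M dominated)
  x <- log2(dapi_totals)
  x_fit <- x[e < valley]
  if (length(x_fit) < 200L) x_fit <- x
  # anchor the fit on the 2N/4N density peaks: the G2/M mode sits about one
  # log2 unit (one genome doubling) above the G1 mode, which keeps subG1
  # debris and 8N doublets from hijacking a mixture component
  anchors <- dapi_mode_anchors(x_fit)
  x_em <- x_fit
  if (!is.null(anchors)) {
    x_em <- x_fit[x_fit >= anchors[1] - 0.45 & x_fit <= anchors[2] + 0.45]
    if (length(x_em) < 200L) x_em <- x_fit
  }
  fit <- fit_gaussian_mixture2(x_em, mu_init = anchors)
  # trimmed refits: contaminants beyond 3 component SD would still drag the
  # component means and inflate the exclusion cuts
  for (i in 1:3) {
    keep <- x_em >= fit$mean[1] - 3 * fit$sd[1] &
      x_em <= fit$mean[2] + 3 * fit$sd[2]
    if (all(keep) || sum(keep) < 200L) break
    fit <- fit_gaussian_mixture2(x_em[keep], mu_init = fit$mean)
  }
  sep <- fit$mean[2] - fit$mean[1]
  if (sep < 0.5) {
    rlang::abort("cannot resolve 2N/4N: DAPI mode separation < 0.5 log2 units")
  }
  structure(
    list(
      log2_dapi_g1_mode = fit$mean[1],
      log2_dapi_g2_mode = fit$mean[2],
      g1_g2_cut = mean(fit$mean),
      subg1_cut = fit$mean[1] - 3 * fit$sd[1],
      over4n_cut = fit$mean[2] + 3 * fit$sd[2],
      edu_positive_cut = unname(valley),
      edu_fallback = fallback,
      mixture = fit,
      n_cells = length(dapi_totals)
    ),
    class = "phase_gate"
  )
}

#' @export
print.phase_gate <- function(x, ...) {
  cat("Cell-cycle phase gate (", x$n_cells, " cells)\n", sep = "")
  cat(sprintf("  log2 DAPI G1 mode: %.3f   G2/M mode: %.3f\n",
              x$log2_dapi_g1_mode, x$log2_dapi_g2_mode))
  cat(sprintf("  cuts: subG1 < %.3f | G1/G2 %.3f | >4N > %.3f\n",
              x$subg1_cut, x$g1_g2_cut, x$over4n_cut))
  cat(sprintf("  EdU-positive cut (log2): %.3f%s\n", x$edu_positive_cut,
              if (x$edu_fallback) " [fallback]" else ""))
  invisible(x)
}

#' Assign cell-cycle phases
#'
#' Applies a fitted [fit_phase_gate()] gate: cells outside the
#' `[subg1_cut, over4n_cut]` DAPI window are `excluded`; otherwise any cell
#' with log2 EdU at or above the EdU-positive cut is `S` (EdU takes
#' precedence over DNA content), and the remainder split into `G1`/`G2M` at
#' the DAPI midpoint cut.
#'
#' @param cells Tibble with `dapi_total` and `edu_total` columns.
#' @param gate A `phase_gate` object.
#' @return The input tibble with a `phase` factor column
#'   (`G1`, `S`, `G2M`, `excluded`).
#' @export
assign_phase <- function(cells, gate) {
  stopifnot(inherits(gate, "phase_gate"))
  ld <- log2(cells$dapi_total)
  le <- log2(cells$edu_total)
  phase <- dplyr::case_when(
    ld < gate$subg1_cut | ld > gate$over4n_cut ~ "excluded",
    le >= gate$edu_positive_cut ~ "S",
    ld < gate$g1_g2_cut ~ "G1",
    TRUE ~ "G2M"
  )
  dplyr::mutate(cells, phase = factor(phase, levels = c("G1", "S", "G2M", "excluded")))
}

#' Phase fractions among analyzable cells
#'
#' @param cells Tibble with a `phase` column from [assign_phase()].
#' @return Tibble with `phase` and `fraction` over non-excluded cells, plus
#'   the excluded fraction of all cells.
#' @export
phase_fractions <- function(cells) {
  analyzable <- cells$phase != "excluded"
  frac <- table(factor(cells$phase[analyzable], levels = c("G1", "S", "G2M")))
  tibble::tibble(
    phase = c(names(frac), "excluded"),
    fraction = c(as.numeric(frac) / max(sum(analyzable), 1L),
                 mean(!analyzable))
  )
}

#' @export
tidy.phase_gate <- function(x, ...) {
  tibble::tibble(
    parameter = c("log2_dapi_g1_mode", "log2_dapi_g2_mode", "g1_g2_cut",
                  "subg1_cut", "over4n_cut", "edu_positive_cut"),
    value = c(x$log2_dapi_g1_mode, x$log2_dapi_g2_mode, x$g1_g2_cut,
              x$subg1_cut, x$over4n_cut, x$edu_positive_cut)
  )
}

#' @export
glance.phase_gate <- function(x, ...) {
  tibble::tibble(
    n_cells = x$n_cells,
    mode_separation = x$log2_dapi_g2_mode - x$log2_dapi_g1_mode,
    edu_fallback = x$edu_fallback
  )
}
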