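# Simulation of per-cell integrated DAPI / EdU intensities with known phase
# labels, for validating the cell-cycle gate.

#' Cell-cycle simulation parameters
#'
#' @param g1_fraction,s_fraction,g2m_fraction Phase fractions of the clean
#'   population (must sum to 1).
#' @param dapi_2n_log2_mean Log2 integrated DAPI intensity of the G1 (2N)
#'   mode; the G2/M (4N) mode sits exactly one log2 unit higher (one genome
#'   doubling).
#' @param dapi_log2_sd Within-mode SD of log2 DAPI.
#' @param edu_background_log2_mean,edu_log2_sd Log2 EdU background location
#'   and spread.
#' @param edu_positive_log2_shift Log2 shift of EdU signal in S-phase cells
#'   above background.
#' @param subg1_fraction,over4n_fraction Contaminant fractions: subG1 debris
#'   centered one log2 unit below the G1 mode, >4N doublets (8N) one unit
#'   above the G2 mode -- both well outside the 3 SD exclusion window.
#' @return A `cellcycle_sim_params` list.
#' @export
cellcycle_sim_params <- function(g1_fraction = 0.5, s_fraction = 0.3,
                                 g2m_fraction = 0.2,
                                 dapi_2n_log2_mean = 10, dapi_log2_sd = 0.12,
                                 edu_background_log2_mean = 6, edu_log2_sd = 0.3,
                                 edu_positive_log2_shift = 2.5,
                                 subg1_fraction = 0.02, over4n_fraction = 0.02) {
  fr <- c(g1_fraction, s_fraction, g2m_fraction, subg1_fraction, over4n_fraction)
  if (any(fr < 0) || any(fr > 1)) rlang::abort("fractions must lie in [0, 1]")
  if (abs(g1_fraction + s_fraction + g2m_fraction - 1) > 1e-8) {
    rlang::abort("phase fractions must sum to 1")
  }
  structure(
    list(g1_fraction = g1_fraction, s_fraction = s_fraction,
         g2m_fraction = g2m_fraction,
         dapi_2n_log2_mean = dapi_2n_log2_mean, dapi_log2_sd = dapi_log2_sd,
         edu_background_log2_mean = edu_background_log2_mean,
         edu_log2_sd = edu_log2_sd,
         edu_positive_log2_shift = edu_positive_log2_shift,
         subg1_fraction = subg1_fraction, over4n_fraction = over4n_fraction),
    class = "cellcycle_sim_params"
  )
}

#' Simulate DAPI/EdU intensities with ground-truth phases
#'
#' Log2 DAPI is a two-Gaussian mixture with modes one unit apart (G1 at the
#' 2N mode, G2/M at the 4N mode) and S-phase cells spread between them; S
#' cells carry EdU signal above background. SubG1 and >4N contaminants are
#' placed beyond 3 SD outside the two modes.
#'
#' @param n_cells Number of cells (> 0).
#' @param params A [cellcycle_sim_params()] object.
#' @param seed Integer seed.
#' @return Tibble with `cell_id`, `dapi_total`, `edu_total` (linear scale) and
#'   `true_phase` in `{G1, S, G2M, subG1, over4N}`.
#' @export
simulate_cellcycle_intensities <- function(n_cells, params = cellcycle_sim_params(),
                                           seed = 1L) {
  stopifnot(inherits(params, "cellcycle_sim_params"))
  if (n_cells <= 0) rlang::abort("`n_cells` must be > 0")
  p <- params
  with_seed(seed, {
    clean <- 1 - p$subg1_fraction - p$over4n_fraction
    probs <- c(G1 = p$g1_fraction * clean, S = p$s_fraction * clean,
               G2M = p$g2m_fraction * clean,
               subG1 = p$subg1_fraction, over4N = p$over4n_fraction)
    phase <- sample(names(probs), n_cells, replace = TRUE, prob = probs)
    m1 <- p$dapi_2n_log2_mean
    m2 <- m1 + 1
    sdd <- p$dapi_log2_sd
    log2_dapi <- numeric(n_cells)
    log2_dapi[phase == "G1"] <- rnorm(sum(phase == "G1"), m1, sdd)
    log2_dapi[phase == "G2M"] <- rnorm(sum(phase == "G2M"), m2, sdd)
    # S-phase DNA content spans 2N..4N as replication proceeds
    log2_dapi[phase == "S"] <- runif(sum(phase == "S"), m1 + 0.15, m2 - 0.15)
    # subG1 = fragmented/apoptotic DNA well below 2N; >4N = doublets around 8N
    log2_dapi[phase == "subG1"] <- rnorm(sum(phase == "subG1"), m1 - 1, sdd)
    log2_dapi[phase == "over4N"] <- rnorm(sum(phase == "over4N"), m2 + 1, sdd)
    log2_edu <- rnorm(n_cells, p$edu_background_log2_mean, p$edu_log2_sd)
    s_like <- phase == "S"
    log2_edu[s_like] <- log2_edu[s_like] + p$edu_positive_log2_shift
    tibble::tibble(
      cell_id = seq_len(n_cells),
      dapi_total = 2^log2_dapi,
      edu_total = 2^log2_edu,
      true_phase = phase
    )
  })
}
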