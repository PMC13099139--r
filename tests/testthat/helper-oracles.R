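# Shared fixtures and independent oracles. Oracles are deliberately written
# as plain straight-line base R so they share no code path with the package.

circle_mask <- function(r_eq_um, pixel_size = 0.108) {
  r_px <- r_eq_um / pixel_size
  n <- 2L * ceiling(r_px + 2)
  ctr <- (n - 1) / 2
  rows <- matrix(0:(n - 1), n, n)
  (rows - ctr)^2 + (t(rows) - ctr)^2 <= r_px^2
}

# Brute-force Ripley K: explicit all-pairs double loop.
k_brute <- function(spots, mask, radii, pixel_size = 0.108) {
  n <- nrow(spots)
  a <- sum(mask) * pixel_size^2
  k <- numeric(length(radii))
  for (ri in seq_along(radii)) {
    count <- 0
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      d <- pixel_size * sqrt((spots$row[i] - spots$row[j])^2 +
                               (spots$col[i] - spots$col[j])^2)
      if (d <= radii[ri]) count <- count + 1
    }
    k[ri] <- a / (n * (n - 1)) * count
  }
  k
}

# CSR-null clustering scores over R_eq x N strata (200 nuclei each),
# memoised so the calibration and count-robustness checks share one run.
compute_null_strata <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    r_eqs <- c(3, 6, 10); ns <- c(23, 46, 92)
    means <- matrix(NA_real_, length(r_eqs), length(ns),
                    dimnames = list(paste0("R", r_eqs), paste0("N", ns)))
    sds <- means
    for (ri in seq_along(r_eqs)) {
      mask <- circle_mask(r_eqs[ri])
      for (ni in seq_along(ns)) {
        # the nuclei share one cached baseline; a large n_mc keeps the
        # baseline's own Monte-Carlo error from dominating the stratum mean,
        # and 500 nuclei per stratum keep the mean's own sampling noise well
        # inside the calibration band (the invariant asks for >= 200)
        s <- vapply(1:500, function(i) {
          clustering_score(
            sample_spots(mask, spot_process_params(ns[ni], "csr"),
                         seed = 7e5 + 1e4 * ri + 1e3 * ni + i),
            mask, n_mc = 4000, seed = 51
          )
        }, numeric(1))
        means[ri, ni] <- mean(s)
        sds[ri, ni] <- sd(s)
      }
    }
    cache <<- list(means = means, sds = sds)
    cache
  }
})

# Greedy one-to-one matching of detections to ground truth within a radius.
match_spots <- function(truth, det, radius = 2) {
  if (nrow(det) == 0L) {
    return(list(tp = 0L, fp = 0L, fn = nrow(truth), errors = numeric(0)))
  }
  D <- sqrt(outer(truth$row, det$row, "-")^2 + outer(truth$col, det$col, "-")^2)
  used <- rep(FALSE, nrow(det))
  tp <- 0L; errors <- numeric(0)
  for (i in order(apply(D, 1, min))) {
    j <- which.min(ifelse(used, Inf, D[i, ]))
    if (length(j) == 1L && is.finite(D[i, j]) && D[i, j] <= radius) {
      used[j] <- TRUE
      tp <- tp + 1L
      errors <- c(errors, D[i, j])
    }
  }
  list(tp = tp, fp = nrow(det) - tp, fn = nrow(truth) - tp, errors = errors)
}

# Straight-line recomputation of per-gene mean Z from a cells table: per-well
# means over QC-passing cells, per-plate robust Z against usable library
# wells, replicate-pooled robust Z, replicate averaging. Plain loops only.
screen_oracle_mean_z <- function(cells, layout, feature, min_cells = 20) {
  rz <- function(x, ref) (x - median(ref)) / (1.4826 * median(abs(ref - median(ref))))
  reps <- sort(unique(cells$replicate))
  per_rep <- list()
  for (r in reps) {
    cr <- cells[cells$replicate == r, ]
    wells <- unique(cr[, c("plate", "well")])
    wells$value <- NA_real_; wells$n_qc <- 0L; wells$role <- NA_character_
    wells$gene <- NA_character_
    for (i in seq_len(nrow(wells))) {
      sel <- cr$plate == wells$plate[i] & cr$well == wells$well[i] & cr$qc_pass
      wells$value[i] <- mean(cr[[feature]][sel])
      wells$n_qc[i] <- sum(sel)
      li <- which(layout$plate == wells$plate[i] & layout$well == wells$well[i])
      wells$role[i] <- layout$role[li]
      wells$gene[i] <- layout$gene[li]
    }
    wells$usable <- wells$n_qc >= min_cells
    wells$z <- NA_real_
    for (p in unique(wells$plate)) {
      lib <- wells$usable & wells$plate == p & wells$role == "library"
      sel <- wells$usable & wells$plate == p
      wells$z[sel] <- rz(wells$value[sel], wells$value[lib])
    }
    lib <- wells$usable & wells$role == "library"
    wells$z[wells$usable] <- rz(wells$z[wells$usable], wells$z[lib])
    per_rep[[as.character(r)]] <- wells
  }
  genes <- unique(unlist(lapply(per_rep, function(w) w$gene)))
  out <- setNames(rep(NA_real_, length(genes)), genes)
  for (g in genes) {
    zs <- unlist(lapply(per_rep, function(w) w$z[w$gene == g]))
    out[g] <- mean(zs[!is.na(zs)])
  }
  out
}

# Tail oracle for the all-null screen: simulate replicate-level Z as standard
# normal draws and apply the downstream combine / exclusion / threshold logic
# directly. Returns false-hit counts per simulated screen.
null_hit_oracle <- function(n_genes, n_sims, z_hit = 2.5, z_cyto = -2.5,
                            seed = 1) {
  set.seed(seed)
  counts <- integer(n_sims)
  for (s in seq_len(n_sims)) {
    hits <- 0L
    z1c <- rnorm(n_genes); z2c <- rnorm(n_genes)
    z1n <- rnorm(n_genes); z2n <- rnorm(n_genes)
    z1v <- rnorm(n_genes); z2v <- rnorm(n_genes)
    mc <- (z1c + z2c) / 2; sc <- abs(z1c - z2c) / sqrt(2)
    mn <- (z1n + z2n) / 2; sn <- abs(z1n - z2n) / sqrt(2)
    mv <- (z1v + z2v) / 2
    for (g in seq_len(n_genes)) {
      if (mv[g] < z_cyto) next
      qc <- abs(mc[g]) > z_hit && abs(mc[g]) >= sc[g]
      qn <- abs(mn[g]) > z_hit && abs(mn[g]) >= sn[g]
      if (qc || qn) hits <- hits + 1L
    }
    counts[s] <- hits
  }
  counts
}
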