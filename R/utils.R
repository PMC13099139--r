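# Internal helpers shared across modules.

# Run code with a temporary RNG state seeded from `seed`, restoring the caller's
# stream afterwards. All stochastic operations in the package go through this so
# results are pure functions of their (inputs, seed).
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Derive a child seed (< 2^31) from a parent seed and a label, so independent
# stages of a pipeline consume independent, reproducible streams.
derive_seed <- function(seed, label) {
  h <- rlang::hash(list(as.integer(seed), as.character(label)))
  # take 7 hex digits -> < 2^28, safely inside integer range
  as.integer(strtoi(substr(h, 1L, 7L), base = 16L))
}

# Robust Z-score: (x - median(ref)) / (1.4826 * MAD(ref)). Falls back to the
# plain SD when the MAD is zero, and to all-zero scores (with a warning) when
# the reference has no spread at all.
robust_z <- function(x, ref = x, robust = TRUE) {
  center <- if (robust) median(ref, na.rm = TRUE) else mean(ref, na.rm = TRUE)
  scale <- if (robust) mad(ref, na.rm = TRUE) else sd(ref, na.rm = TRUE)
  if (robust && (!is.finite(scale) || scale == 0)) {
    scale <- sd(ref, na.rm = TRUE)
  }
  if (!is.finite(scale) || scale == 0) {
    rlang::warn("reference values have zero spread; returning Z = 0")
    return(rep(0, length(x)))
  }
  (x - center) / scale
}

#' Significance stars
#'
#' Encode p-values using the convention * p <= 0.05, ** p <= 0.01,
#' *** p <= 0.001, **** p < 0.0001.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of star codes ("ns" when not significant).
#' @export
significance_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ NA_character_,
    p < 1e-4 ~ "****",
    p <= 1e-3 ~ "***",
    p <= 1e-2 ~ "**",
    p <= 5e-2 ~ "*",
    TRUE ~ "ns"
  )
}

# 384-well plate well names: A01..P24, row-major.
well_names_384 <- function() {
  rows <- LETTERS[1:16]
  cols <- sprintf("%02d", 1:24)
  as.vector(t(outer(rows, cols, paste0)))
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    rlang::abort(sprintf("`%s` must be a finite number in [%s, %s]", name, lower, upper))
  }
  invisible(x)
}
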