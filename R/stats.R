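# Group-comparison reporting: ANOVA + Tukey HSD, or pairwise t-tests with
# Bonferroni correction, with the star convention used throughout the
# package's figures (* p<=0.05, ** p<=0.01, *** p<=0.001, **** p<0.0001).

#' Compare feature values between groups
#'
#' @param data Tibble with the value and group columns.
#' @param value Name of the numeric column.
#' @param group Name of the grouping column.
#' @param method `"anova_tukey"` (one-way ANOVA followed by Tukey's HSD on
#'   all pairs) or `"pairwise_t_bonferroni"` (pairwise t-tests, Bonferroni
#'   adjusted: raw p multiplied by the number of comparisons, capped at 1).
#' @return Tibble with one row per group pair: `group1`, `group2`,
#'   `estimate` (difference in means), `p_adj` and `stars`; carries the
#'   overall ANOVA p-value as attribute `anova_p` for the Tukey method.
#' @export
compare_groups <- function(data, value, group,
                           method = c("anova_tukey", "pairwise_t_bonferroni")) {
  method <- match.arg(method)
  x <- data[[value]]
  g <- factor(data[[group]])
  keep <- is.finite(x) & !is.na(g)
  x <- x[keep]; g <- droplevels(g[keep])
  if (nlevels(g) < 2L) rlang::abort("need at least 2 groups")
  if (any(table(g) < 2L)) rlang::abort("every group needs at least 2 values")

  if (method == "anova_tukey") {
    fit <- aov(x ~ g)
    anova_p <- summary(fit)[[1]][["Pr(>F)"]][1]
    tk <- TukeyHSD(fit)$g
    pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
    out <- tibble::tibble(
      group1 = vapply(pairs, `[`, "", 2),
      group2 = vapply(pairs, `[`, "", 1),
      estimate = -tk[, "diff"],
      p_adj = tk[, "p adj"],
      stars = significance_stars(tk[, "p adj"])
    )
    attr(out, "anova_p") <- anova_p
  } else {
    pt <- pairwise.t.test(x, g, p.adjust.method = "bonferroni",
                          pool.sd = FALSE)
    m <- pt$p.value
    means <- tapply(x, g, mean)
    rows <- list()
    for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
      if (!is.na(m[i, j])) {
        g1 <- colnames(m)[j]; g2 <- rownames(m)[i]
        rows[[length(rows) + 1L]] <- tibble::tibble(
          group1 = g1, group2 = g2,
          estimate = unname(means[g1] - means[g2]),
          p_adj = m[i, j],
          stars = significance_stars(m[i, j])
        )
      }
    }
    out <- purrr::list_rbind(rows)
  }
  out
}
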