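test_that("the clustering score is calibrated around zero under CSR", {
  mask <- circle_mask(6)
  # one shared baseline for all 200 nuclei: use a large n_mc so its own
  # Monte-Carlo error does not masquerade as miscalibration
  s <- vapply(1:200, function(i) {
    clustering_score(sample_spots(mask, spot_process_params(46, "csr"),
                                  seed = 300 + i), mask, n_mc = 2000,
                     seed = 21)
  }, numeric(1))
  expect_lt(abs(mean(s)), 0.1)
  expect_gt(sd(s), 0.5)
  expect_lt(sd(s), 1.4)
})

test_that("coincident spots score beyond the entire CSR score distribution", {
  mask <- circle_mask(5)
  null_scores <- vapply(1:100, function(i) {
    clustering_score(sample_spots(mask, spot_process_params(20, "csr"),
                                  seed = 500 + i), mask, seed = 22)
  }, numeric(1))
  sp <- tibble::tibble(row = rep(46, 20) + rnorm(20, 0, 0.3),
                       col = rep(46, 20) + rnorm(20, 0, 0.3))
  s_max <- clustering_score(sp, mask, seed = 22)
  expect_gt(s_max, max(null_scores)) # above the 99th percentile and then some
})

test_that("fewer than two spots yields a missing score", {
  mask <- circle_mask(4)
  expect_true(is.na(clustering_score(tibble::tibble(row = 30, col = 30), mask)))
  expect_true(is.na(clustering_score(tibble::tibble(row = numeric(0),
                                                    col = numeric(0)), mask)))
})

test_that("the score is scale-free: doubling mask and pattern preserves it", {
  mask1 <- circle_mask(3)
  sp1 <- sample_spots(mask1, spot_process_params(
    30, "thomas", thomas_n_parents = 4, thomas_sigma = 0.3
  ), seed = 6)
  # double the window and the pattern physically; map coordinates through
  # the two mask centers (57.5 px and 113.5 px): x2 = 2 * (x1 - 57.5) + 113.5
  mask2 <- circle_mask(6)
  sp2 <- dplyr::mutate(sp1, row = 2 * row - 1.5, col = 2 * col - 1.5)
  s1 <- clustering_score(sp1, mask1, n_mc = 2000, seed = 13)
  s2 <- clustering_score(sp2, mask2, n_mc = 2000, seed = 13)
  expect_lt(abs(s1 - s2) / abs(s1), 0.05)
})

test_that("the score responds monotonically to true clustering strength", {
  mask <- circle_mask(6)
  means <- vapply(c(2, 1, 0.5, 0.25), function(sg) {
    mean(vapply(1:60, function(i) {
      clustering_score(sample_spots(mask, spot_process_params(
        46, "thomas", thomas_n_parents = 6, thomas_sigma = sg
      ), seed = round(sg * 1e4) + i), mask, seed = 23)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) > 0)) # tighter dispersion, higher score
})

test_that("fixed seeds make the score a pure function of its inputs", {
  mask <- circle_mask(4)
  sp <- sample_spots(mask, spot_process_params(25, "csr"), seed = 2)
  expect_identical(clustering_score(sp, mask, seed = 5),
                   clustering_score(sp, mask, seed = 5))
})
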