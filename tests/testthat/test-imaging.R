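test_that("segmentation recovers non-touching nuclei and their centroids", {
  w <- simulate_well_images(n_wells = 1, nuclei_per_field = 12, n_spots = 20,
                            field_shape = c(600L, 800L), seed = 9)[[1]]
  seg <- segment_nuclei(w$field$dapi)
  expect_identical(nrow(seg$nuclei), 12L)
  truth_ctr <- t(vapply(w$truth_nuclei, function(m) {
    xy <- which(m, arr.ind = TRUE)
    c(mean(xy[, 1]) - 1, mean(xy[, 2]) - 1)
  }, numeric(2)))
  for (i in seq_len(nrow(seg$nuclei))) {
    d <- sqrt((truth_ctr[, 1] - seg$nuclei$centroid_row[i])^2 +
                (truth_ctr[, 2] - seg$nuclei$centroid_col[i])^2)
    expect_lt(min(d), 2)
  }
})

test_that("a blank image yields an empty nucleus list, not an error", {
  seg <- segment_nuclei(matrix(0, 64, 64))
  expect_identical(nrow(seg$nuclei), 0L)
  seg2 <- segment_nuclei(matrix(100, 64, 64)) # flat non-zero is also blank
  expect_identical(nrow(seg2$nuclei), 0L)
})

test_that("nuclei on the field border are flagged and fail QC", {
  img <- matrix(0, 220, 220)
  rows <- matrix(0:219, 220, 220); cols <- t(rows)
  img[(rows - 0)^2 + (cols - 110)^2 <= 45^2] <- 1000    # cut by the top border
  img[(rows - 150)^2 + (cols - 110)^2 <= 50^2] <- 1000  # interior, ~74 um^2
  set.seed(7)
  img <- img + matrix(rnorm(220 * 220, 50, 2), 220, 220)
  seg <- segment_nuclei(img)
  expect_identical(nrow(seg$nuclei), 2L)
  border <- seg$nuclei[seg$nuclei$border_touching, ]
  expect_identical(nrow(border), 1L)
  expect_false(border$qc_pass)
  interior <- seg$nuclei[!seg$nuclei$border_touching, ]
  expect_true(interior$qc_pass)
})

test_that("QC thresholds are strict inequalities exactly as specified", {
  expect_false(nucleus_qc(area = 29, solidity = 0.95))   # too small
  expect_false(nucleus_qc(area = 120, solidity = 0.84))  # dysmorphic
  expect_true(nucleus_qc(area = 120, solidity = 0.97))
  expect_true(nucleus_qc(area = 30, solidity = 0.85))    # boundaries pass
  expect_false(nucleus_qc(area = 120, solidity = 0.97, border_touching = TRUE))
  # pure predicate: same record, same verdict
  expect_identical(nucleus_qc(45, 0.9), nucleus_qc(45, 0.9))
})

test_that("detection is equivariant under whole-pixel translation", {
  mask <- matrix(TRUE, 96, 96)
  img <- matrix(0, 96, 96)
  for (pos in list(c(30.3, 40.8), c(60.1, 25.5), c(70.7, 70.2))) {
    img <- centroscreen:::add_gaussian_spot(img, pos[1], pos[2], 1.5, 1000)
  }
  img2 <- matrix(0, 96, 96)
  img2[11:96, 6:96] <- img[1:86, 1:91] # shift by (+10, +5)
  d1 <- detect_spots(img, mask)
  d2 <- detect_spots(img2, mask)
  expect_identical(nrow(d1), 3L)
  expect_identical(nrow(d2), 3L)
  o1 <- dplyr::arrange(d1, row); o2 <- dplyr::arrange(d2, row)
  expect_equal(o2$row - o1$row, rep(10, 3), tolerance = 1e-6)
  expect_equal(o2$col - o1$col, rep(5, 3), tolerance = 1e-6)
})

test_that("noiseless localization error is far below a quarter pixel", {
  mask <- matrix(TRUE, 64, 64)
  errs <- vapply(1:15, function(i) {
    set.seed(i)
    tr <- c(28 + runif(1, 0, 8), 28 + runif(1, 0, 8))
    img <- centroscreen:::add_gaussian_spot(matrix(0, 64, 64),
                                            tr[1], tr[2], 1.5, 1000)
    d <- detect_spots(img, mask)
    expect_identical(nrow(d), 1L)
    sqrt(sum((c(d$row, d$col) - tr)^2))
  }, numeric(1))
  expect_lt(sqrt(mean(errs^2)), 0.25)
})

test_that("an empty spot image yields an empty SpotSet, empty mask errors", {
  mask <- circle_mask(3)
  set.seed(12)
  d <- detect_spots(matrix(rnorm(prod(dim(mask)), 100, 5), nrow(mask)), mask)
  expect_identical(nrow(d), 0L)
  expect_error(detect_spots(matrix(0, 10, 10), matrix(FALSE, 10, 10)),
               "mask is empty")
})

test_that("normalized radial distance has the right limits and CSR mean", {
  mask <- circle_mask(5.4) # 50 px radius
  ctr <- (nrow(mask) - 1) / 2
  at_center <- radial_distances(tibble::tibble(row = ctr, col = ctr), mask)
  expect_equal(at_center$r_norm, 0, tolerance = 1e-9)
  on_boundary <- radial_distances(
    tibble::tibble(row = ctr, col = ctr + 49.5), mask
  )
  expect_gt(on_boundary$r_norm, 0.97)
  # uniform points in a disk have E[r/R] = 2/3; pool >= 1e4 spots
  pooled <- purrr::map(1:5, function(i) {
    sp <- sample_spots(mask, spot_process_params(2000, "csr"), seed = i)
    radial_distances(sp, mask)
  }) |> purrr::list_rbind()
  expect_equal(mean(pooled$r_norm), 2 / 3, tolerance = 0.01)
})
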