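test_that("blank frames segment to zero labels and identical inputs give identical output", {
  blank <- matrix(0, 64, 64)
  lab <- segment_frame(blank, pixel_size_um = 25)
  expect_true(all(lab == 0L))
  expect_equal(max(lab), 0)

  img <- matrix(0, 64, 64); img[20:30, 20:30] <- 100
  a <- segment_frame(img, pixel_size_um = 25)
  b <- segment_frame(img, pixel_size_um = 25)
  expect_identical(a, b)
  expect_error(
    segment_frame(image_series(array(0, c(1, 1, 8, 8)), c(tcell = 1L), 25, 1), 1),
    "missing channel role")
})

test_that("noise-free renders segment into the right number of blobs with accurate areas", {
  traj <- constant_trajectories(c(2L, 3L, 1L, 2L), n_days = 1, area = 0.6)
  ser <- render_timelapse(traj, array_layout(2, 2, pitch_um = 2200), seed = 1)
  lab <- segment_frame(ser, 1)
  expect_equal(max(lab), 4)
  px_area <- (ser$pixel_size_um / 1000)^2
  for (j in 1:4) {
    got <- sum(lab == j) * px_area
    expect_lt(abs(got - 0.6) / 0.6, 0.10)
  }
})

test_that("mask geometry: area arithmetic and brute-force Feret agreement", {
  ## 100x100 px solid square at 10 um/px
  mask <- matrix(FALSE, 120, 120); mask[11:110, 11:110] <- TRUE
  m <- measure_mask(mask, 10)
  expect_equal(m$area_mm2, 1.0)
  ## oracle: brute force over all boundary pixel-centre pairs
  idx <- which(mask, arr.ind = TRUE)
  on_edge <- idx[, 1] %in% c(11, 110) | idx[, 2] %in% c(11, 110)
  b <- idx[on_edge, ]
  oracle <- 0
  for (i in seq_len(nrow(b)))
    oracle <- max(oracle, sqrt((b[i, 1] - b[, 1])^2 + (b[i, 2] - b[, 2])^2))
  expect_equal(m$feret_um, oracle * 10, tolerance = 1e-10)
  expect_equal(m$feret_um, 99 * sqrt(2) * 10, tolerance = 1e-10)

  single <- matrix(FALSE, 5, 5); single[3, 3] <- TRUE
  s <- measure_mask(single, 10)
  expect_equal(s$area_mm2, 1e-4)
  expect_equal(s$feret_um, 0)

  empty <- measure_mask(matrix(FALSE, 5, 5), 10)
  expect_equal(empty$area_mm2, 0)
  expect_true(is.na(empty$feret_um))
})

test_that("static blobs yield one full-length track each; vanishing ends detection", {
  mk <- function(ids) {
    l <- matrix(0L, 60, 60)
    if (1 %in% ids) l[disc_mask(60, 5, 15, 15)] <- 1L
    if (2 %in% ids) l[disc_mask(60, 5, 45, 45)] <- max(l) + 1L
    l
  }
  frames <- replicate(5, mk(1:2), simplify = FALSE)
  tr <- link_tracks(frames, pixel_size_um = 25)
  expect_equal(nrow(tr$assign), 2)
  expect_true(all(tr$table$detected))

  frames2 <- list(mk(1:2), mk(1:2), mk(1), mk(1), mk(1))
  tr2 <- link_tracks(frames2, days = 1:5, pixel_size_um = 25)
  expect_equal(nrow(tr2$assign), 2)
  tab2 <- tr2$table[tr2$table$tumour_id == 2, ]
  expect_identical(tab2$detected, c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(max(tab2$day[tab2$detected]), 2)
})

test_that("mutual-nearest linking matches exhaustive matching on a crossing fixture", {
  ## two blobs approach each other; mutual-nearest must pick the assignment
  ## that minimizes total displacement (no identity swap)
  f1 <- matrix(0L, 60, 80)
  f1[20:26, 17:23] <- 1L; f1[34:40, 57:63] <- 2L
  f2 <- matrix(0L, 60, 80)
  f2[20:26, 29:35] <- 1L; f2[34:40, 45:51] <- 2L
  tr <- link_tracks(list(f1, f2), pixel_size_um = 25,
                    max_displacement_um = 500)
  props1 <- list(c(23, 20), c(37, 60)); props2 <- list(c(23, 32), c(37, 48))
  cost <- function(perm) sum(vapply(1:2, function(i)
    sqrt(sum((props1[[i]] - props2[[perm[i]]])^2)), 0))
  best <- if (cost(c(1, 2)) <= cost(c(2, 1))) c(1, 2) else c(2, 1)
  expect_equal(unname(tr$assign[, 2]), best)
  expect_equal(nrow(tr$assign), 2)
})

test_that("linking is invariant to label renumbering within a frame", {
  f1 <- matrix(0L, 60, 60); f1[10:16, 10:16] <- 1L; f1[40:46, 40:46] <- 2L
  f2 <- matrix(0L, 60, 60); f2[11:17, 11:17] <- 1L; f2[41:47, 41:47] <- 2L
  f2_swapped <- matrix(0L, 60, 60)
  f2_swapped[11:17, 11:17] <- 2L; f2_swapped[41:47, 41:47] <- 1L
  a <- link_tracks(list(f1, f2), pixel_size_um = 25)
  b <- link_tracks(list(f1, f2_swapped), pixel_size_um = 25)
  expect_equal(a$table$area_mm2, b$table$area_mm2)
  expect_equal(a$table$centroid_y, b$table$centroid_y)
})

test_that("response classification follows the shrinkage rules", {
  expect_equal(classify_response(c(1, 2, 3)), "PD")
  expect_equal(classify_response(c(1, 4, 3)), "PR")   # (4-3)/4 = 25% >= 20%
  expect_equal(classify_response(c(1, 1, 1, 1), c(TRUE, TRUE, FALSE, FALSE)), "CR")
  ## single-frame dropout is not a CR
  expect_equal(classify_response(c(1, 1, 1, 1), c(TRUE, TRUE, TRUE, FALSE)), "SD")
  expect_equal(classify_response(c(1, 1.1, 1.05)), "SD")
  expect_equal(classify_response(c(1, 2, 3), merge_sd_pd = TRUE), "SD/PD")
  expect_error(classify_response(c(1, 1), c(FALSE, FALSE)), "never detected")
})
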