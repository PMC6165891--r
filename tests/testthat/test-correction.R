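# A hand-sized correction fixture: a 10-voxel lesion with known intensities
# on a grid whose WM mask yields a known mean.
make_correction_fixture <- function() {
  dims <- c(6, 6, 6)
  t1 <- array(0, dims)
  wm <- array(0, dims)
  les <- array(0, dims)
  wm[1:3, 1, 1] <- 1
  t1[1:3, 1, 1] <- c(180, 190, 200)           # wm mean = 190
  les_idx <- cbind(1:5, 3, rep(2:3, length.out = 10)[1:5])
  les_idx <- rbind(les_idx, cbind(1:5, 4, 4))
  lesion_intensities <- c(120, 185, 190, 195, 240, 60, 186.5, 193.4, 80, 250)
  for (i in seq_len(10)) {
    les[les_idx[i, 1], les_idx[i, 2], les_idx[i, 3]] <- 1
    t1[les_idx[i, 1], les_idx[i, 2], les_idx[i, 3]] <- lesion_intensities[i]
  }
  list(t1 = volume(t1, diag(4)), wm = volume(wm, diag(4), role = "mask"),
       lesion = volume(les, diag(4), role = "mask"),
       lesion_intensities = lesion_intensities)
}

test_that("the removal window is wm_mean +/- 255*(p/100)/2, unclamped", {
  expect_equal(unname(removal_window(128, 5)), c(121.625, 134.375))
  expect_equal(unname(removal_window(128, 0)), c(128, 128))
  expect_equal(unname(removal_window(200, 100)), c(72.5, 327.5))
  expect_error(removal_window(128, -1), "\\[0, 100\\]")
  expect_error(removal_window(128, 101), "\\[0, 100\\]")
})

test_that("WM mean is the arithmetic mean, optionally excluding lesion voxels", {
  fx <- make_correction_fixture()
  expect_equal(wm_mean_intensity(fx$t1, fx$wm), 190)
  # lesion covering the 200-intensity WM voxel
  les <- array(0, dim(fx$t1$data)); les[3, 1, 1] <- 1
  lesv <- volume(les, diag(4), role = "mask")
  expect_equal(wm_mean_intensity(fx$t1, fx$wm, lesv, exclude_lesion = TRUE),
               185)
  empty <- volume(array(0, dim(fx$t1$data)), diag(4), role = "mask")
  expect_error(wm_mean_intensity(fx$t1, empty), "empty")
})

test_that("correction removes exactly the voxels a brute-force window scan finds", {
  fx <- make_correction_fixture()
  for (p in c(0, 2, 5, 10, 40, 100)) {
    res <- correct_lesion(fx$t1, fx$wm, fx$lesion, p = p)
    h <- 255 * (p / 100) / 2
    brute_removed <- sum(fx$lesion_intensities >= 190 - h &
                           fx$lesion_intensities <= 190 + h)
    expect_identical(res$removed_voxels, as.integer(brute_removed))
    expect_identical(res$original_voxels, 10L)
    expect_identical(res$surviving_voxels,
                     as.integer(10L - brute_removed))
    # corrected is a subset of the original lesion
    expect_true(all(res$corrected_mask$data <= fx$lesion$data))
  }
})

test_that("removal is monotone in the percentage parameter", {
  fx <- make_correction_fixture()
  ps <- c(0, 1, 3, 5, 8, 15, 30, 60, 100)
  prev <- NULL
  for (p in ps) {
    cur <- correct_lesion(fx$t1, fx$wm, fx$lesion, p = p)$corrected_mask$data
    if (!is.null(prev)) expect_true(all(cur <= prev))  # survivors shrink
    prev <- cur
  }
})

test_that("p = 0 with no voxel exactly at the mean leaves the mask unchanged", {
  fx <- make_correction_fixture()
  # nudge the 190-voxel off the mean
  t1 <- fx$t1
  t1$data[fx$lesion$data > 0 & t1$data == 190] <- 190.01
  res <- correct_lesion(t1, fx$wm, fx$lesion, p = 0)
  expect_identical(res$corrected_mask$data, fx$lesion$data)
  expect_identical(res$removed_voxels, 0L)
})

test_that("a lesion entirely inside the window empties with a warning", {
  dims <- c(4, 4, 4)
  t1 <- array(100, dims)
  wm <- array(0, dims); wm[1:4, 1, 1] <- 1
  les <- array(0, dims); les[1:4, 4, 4] <- 1
  expect_warning(
    res <- correct_lesion(volume(t1, diag(4)),
                          volume(wm, diag(4), role = "mask"),
                          volume(les, diag(4), role = "mask"), p = 10),
    "entirely within")
  expect_identical(res$surviving_voxels, 0L)
  expect_equal(sum(res$corrected_mask$data), 0)
})

test_that("empty lesions and grid mismatches are handled per contract", {
  fx <- make_correction_fixture()
  empty <- volume(array(0, dim(fx$t1$data)), diag(4), role = "mask")
  expect_warning(res <- correct_lesion(fx$t1, fx$wm, empty), "empty lesion")
  expect_identical(res$original_voxels, 0L)
  other <- volume(array(1, c(3, 3, 3)), diag(4), role = "mask")
  expect_error(correct_lesion(fx$t1, fx$wm, other), "grid")
})

test_that("the correction report has one row per (subject, lesion) with percents", {
  fx <- make_correction_fixture()
  r1 <- correct_lesion(fx$t1, fx$wm, fx$lesion, p = 5,
                       subject_id = "s1", lesion_file = "s1_Lesion1.nii.gz")
  r2 <- correct_lesion(fx$t1, fx$wm, fx$lesion, p = 40,
                       subject_id = "s1", lesion_file = "s1_Lesion2.nii.gz")
  r3 <- correct_lesion(fx$t1, fx$wm, fx$lesion, p = 5,
                       subject_id = "s2", lesion_file = "s2_Lesion.nii.gz")
  csv <- withr::local_tempfile(fileext = ".csv")
  df <- write_correction_report(list(r1, r2, r3), csv)
  expect_equal(nrow(df), 3)
  expect_equal(sum(df$subject_id == "s1"), 2)
  expect_equal(df$percent_removed,
               100 * df$removed_voxels / df$original_voxels)
  ondisk <- utils::read.csv(csv)
  expect_identical(names(ondisk),
                   c("subject_id", "lesion_file", "original_voxels",
                     "removed_voxels", "surviving_voxels", "percent_removed",
                     "wm_mean", "window_lo", "window_hi"))
  # 3 of 10 removed reports 30.0 (window [186.175, 193.825] at p = 3)
  r <- correct_lesion(fx$t1, fx$wm, fx$lesion, p = 3)
  expect_identical(r$removed_voxels, 3L)
  expect_equal(100 * r$removed_voxels / r$original_voxels, 30)
})
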