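world_sample <- function(v, idx0) {
  # intensity at the world coordinate of 0-based voxel idx0 of volume v
  v$data[idx0[1] + 1, idx0[2] + 1, idx0[3] + 1]
}

test_that("to_radiological flips a neurological volume and preserves anatomy in world space", {
  ph <- small_phantom()
  expect_identical(storage_convention(ph$t1), "neurological")
  r <- to_radiological(ph$t1)
  expect_identical(storage_convention(r), "radiological")
  # every sampled world coordinate keeps its intensity
  set.seed(42)
  for (i in 1:25) {
    idx0 <- sapply(dim(ph$t1$data), function(n) sample.int(n, 1)) - 1
    w <- ph$t1$affine %*% c(idx0, 1)
    iv <- round(solve(r$affine) %*% w)[1:3]
    expect_equal(r$data[iv[1] + 1, iv[2] + 1, iv[3] + 1],
                 world_sample(ph$t1, idx0))
  }
})

test_that("to_radiological conserves an already-radiological volume and is idempotent", {
  ph <- small_phantom()
  r <- to_radiological(ph$t1)
  expect_identical(to_radiological(r), r)
  r2 <- to_radiological(to_radiological(ph$t1))
  expect_identical(r2$data, r$data)
  expect_identical(r2$affine, r$affine)
})

test_that("to_canonical restores a permuted grid and preserves anatomy and convention", {
  ph <- small_phantom()
  perm <- c(3, 1, 2)
  A <- ph$t1$affine
  A[, 1:3] <- A[, perm]
  p <- volume(aperm(ph$t1$data, order(perm)), A)
  expect_identical(storage_convention(p), storage_convention(ph$t1))
  canon <- to_canonical(p)
  expect_identical(canon$data, ph$t1$data)
  expect_identical(unname(canon$affine), unname(ph$t1$affine))
})

test_that("to_canonical leaves an already-canonical volume unchanged", {
  ph <- small_phantom()
  expect_identical(to_canonical(ph$t1), ph$t1)
  r <- to_radiological(ph$t1)
  canon <- to_canonical(r)
  expect_identical(canon$data, r$data)
  expect_identical(storage_convention(canon), "radiological")
})

test_that("canonicalizing a permuted grid recovers the original up to convention", {
  # even permutations keep the storage convention: the original grid returns
  # exactly; odd permutations flip it, and since to_canonical preserves the
  # convention the result is the x-flipped (world-equivalent) grid
  ph <- small_phantom()
  for (perm in list(c(2, 3, 1), c(3, 1, 2))) {
    A <- ph$t1$affine
    A[, 1:3] <- A[, perm]
    p <- volume(aperm(ph$t1$data, order(perm)), A)
    expect_identical(to_canonical(p)$data, ph$t1$data)
  }
  flipped <- flip_axis(ph$t1, 1)
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(1, 3, 2))) {
    A <- ph$t1$affine
    A[, 1:3] <- A[, perm]
    p <- volume(aperm(ph$t1$data, order(perm)), A)
    canon <- to_canonical(p)
    expect_identical(canon$data, flipped$data)
    expect_equal(unname(canon$affine), unname(flipped$affine))
  }
})

test_that("harmonization preserves mask voxel counts and yields radiological outputs", {
  root <- withr::local_tempdir()
  make_orientation_case(1, root, spec = small_spec())
  cfg <- run_config(input_dir = root, output_dir = tempfile(),
                    modules = "reorient")
  s <- discover_subjects(cfg)[[1]]
  before <- sum(read_volume(s$lesion_paths[1], role = "mask")$data)
  rep <- harmonize_subject(s)
  expect_false(rep$flagged)
  for (v in rep$volumes)
    expect_identical(storage_convention(v), "radiological")
  expect_equal(sum(rep$volumes$lesion1$data), before)
})

test_that("a flagged subject's files are not modified", {
  root <- withr::local_tempdir()
  sdir <- make_orientation_case(3, root, spec = small_spec())
  sizes <- file.size(list.files(sdir, full.names = TRUE))
  cfg <- run_config(input_dir = root, output_dir = tempfile("o"),
                    modules = "reorient")
  s <- discover_subjects(cfg)[[1]]
  out <- withr::local_tempdir()
  rep <- harmonize_subject(s, out_dir = out)
  expect_true(rep$flagged)
  expect_length(rep$actions, 0)
  expect_identical(file.size(list.files(sdir, full.names = TRUE)), sizes)
  expect_length(list.files(out, recursive = TRUE), 0)
})

test_that("a T1/lesion grid-shape mismatch flags the subject instead of aborting", {
  root <- withr::local_tempdir()
  sdir <- file.path(root, "subjX")
  ph <- small_phantom()
  write_volume(ph$t1, file.path(sdir, "subjX_T1.nii.gz"))
  shrunk <- volume(ph$lesion$data[1:20, 1:20, 1:20], ph$lesion$affine,
                   role = "mask")
  write_volume(shrunk, file.path(sdir, "subjX_Lesion.nii.gz"))
  cfg <- run_config(input_dir = root, output_dir = tempfile(),
                    modules = "reorient")
  rep <- harmonize_subject(discover_subjects(cfg)[[1]])
  expect_true(rep$flagged)
  expect_identical(rep$flag_reason, "shape-mismatch")
})

test_that("flagged-subjects report lists per-file conventions with a reason", {
  root <- withr::local_tempdir()
  make_orientation_case(5, root, spec = small_spec())
  cfg <- run_config(input_dir = root, output_dir = tempfile(),
                    modules = "reorient")
  rep <- harmonize_subject(discover_subjects(cfg)[[1]])
  csv <- withr::local_tempfile(fileext = ".csv")
  df <- write_flagged_report(list(rep), csv)
  expect_equal(nrow(df), 4)
  expect_setequal(df$convention, c("radiological", "neurological"))
  expect_true(all(df$reason == "orientation-mismatch"))
  expect_identical(names(utils::read.csv(csv)),
                   c("subject_id", "file", "convention", "reason"))
})
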