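write_subject_files <- function(root, id, files) {
  # files: named list suffix -> volume
  sdir <- file.path(root, id)
  dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
  for (suf in names(files))
    write_volume(files[[suf]], file.path(sdir, paste0(id, suf)))
  sdir
}

test_that("subject discovery matches identifiers and orders indexed lesions", {
  root <- withr::local_tempdir()
  ph <- small_phantom()
  write_subject_files(root, "subj1",
                      list("_T1.nii.gz" = ph$t1, "_Lesion.nii.gz" = ph$lesion))
  write_subject_files(root, "subj2",
                      list("_T1.nii.gz" = ph$t1,
                           "_Lesion2.nii.gz" = ph$lesion,
                           "_Lesion1.nii.gz" = ph$lesion,
                           "_Lesion10.nii.gz" = ph$lesion))
  cfg <- run_config(input_dir = root, output_dir = tempfile(),
                    modules = "reorient")
  subs <- discover_subjects(cfg)
  names(subs) <- vapply(subs, `[[`, character(1), "subject_id")
  expect_length(subs$subj1$lesion_paths, 1)
  expect_false(subs$subj1$flagged)
  expect_identical(basename(subs$subj2$lesion_paths),
                   c("subj2_Lesion1.nii.gz", "subj2_Lesion2.nii.gz",
                     "subj2_Lesion10.nii.gz"))
})

test_that("missing or ambiguous files flag the subject with a reason", {
  root <- withr::local_tempdir()
  ph <- small_phantom()
  write_subject_files(root, "noLesion", list("_T1.nii.gz" = ph$t1))
  write_subject_files(root, "noT1", list("_Lesion.nii.gz" = ph$lesion))
  write_subject_files(root, "mixed",
                      list("_T1.nii.gz" = ph$t1,
                           "_Lesion.nii.gz" = ph$lesion,
                           "_Lesion1.nii.gz" = ph$lesion))
  cfg <- run_config(input_dir = root, output_dir = tempfile(),
                    modules = "reorient")
  subs <- discover_subjects(cfg)
  names(subs) <- vapply(subs, `[[`, character(1), "subject_id")
  expect_match(subs$noLesion$flag_reason, "missing-lesion")
  expect_match(subs$noT1$flag_reason, "missing-t1")
  expect_match(subs$mixed$flag_reason, "ambiguous-files")
})

test_that("configuration validation rejects bad inputs", {
  expect_error(run_config("a", "b", modules = "load"), "roi_config")
  expect_error(run_config("a", "b", modules = character(0)))
  expect_error(run_config("a", "b", wm_removal_percent = 120), "\\[0, 100\\]")
  cfg <- run_config("a", "b")
  expect_s3_class(cfg, "run_config")
})

test_that("JSON configurations round-trip through read_config", {
  j <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(input_dir = "in", output_dir = "out",
                            modules = c("reorient", "correct"),
                            wm_removal_percent = 10, seed = 42),
                       j, auto_unbox = TRUE)
  cfg <- read_config(j)
  expect_identical(cfg$modules, c("reorient", "correct"))
  expect_equal(cfg$wm_removal_percent, 10)
  expect_identical(cfg$seed, 42L)
  jsonlite::write_json(list(input_dir = "in", output_dir = "out",
                            bogus_field = 1), j, auto_unbox = TRUE)
  expect_error(read_config(j), "bogus_field")
})

test_that("a reorient-only run produces only orientation outputs", {
  root <- withr::local_tempdir()
  indir <- file.path(root, "in")
  make_phantom_dataset(indir, n_subjects = 1, seed = 4, spec = small_spec())
  out <- file.path(root, "out")
  summ <- run_pipeline(run_config(input_dir = indir, output_dir = out,
                                  modules = "reorient"))
  expect_equal(summ$processed, 1)
  files <- list.files(out, recursive = TRUE)
  expect_true("subj1/Intermediate_Files/subj1_T1.nii.gz" %in% files)
  expect_false(any(grepl("corrected|lesion_load|QC_", files)))
  # harmonized output is radiological
  h <- read_volume(file.path(out, "subj1", "Intermediate_Files",
                             "subj1_T1.nii.gz"))
  expect_identical(storage_convention(h), "radiological")
})

test_that("an orientation-flagged subject is excluded from correction", {
  root <- withr::local_tempdir()
  indir <- file.path(root, "in")
  make_phantom_dataset(indir, n_subjects = 1, seed = 5, spec = small_spec())
  make_orientation_case(3, indir, subject_id = "subjBad",
                        spec = small_spec())
  out <- file.path(root, "out")
  summ <- suppressWarnings(
    run_pipeline(run_config(input_dir = indir, output_dir = out,
                            modules = c("reorient", "correct"))))
  expect_equal(summ$flagged, 1)
  expect_equal(summ$processed, 1)
  flagged <- utils::read.csv(file.path(out, "flagged_subjects.csv"))
  expect_true(all(flagged$subject_id == "subjBad"))
  rep <- utils::read.csv(file.path(out, "lesion_correction_report.csv"))
  expect_identical(unique(rep$subject_id), "subj1")
  expect_false(file.exists(file.path(out, "subjBad",
                                     "subjBad_Lesion_corrected.nii.gz")))
})

test_that("one subject without a brain mask overrides skip for all subjects", {
  root <- withr::local_tempdir()
  indir <- file.path(root, "in")
  spec <- small_spec()
  make_phantom_dataset(indir, n_subjects = 2, seed = 6, spec = spec,
                       with_masks = TRUE)
  file.remove(file.path(indir, "subj2", "subj2_Brain.nii.gz"))
  file.remove(file.path(indir, "subj2", "subj2_WM.nii.gz"))
  out <- file.path(root, "out")
  summ <- suppressWarnings(run_pipeline(
    run_config(input_dir = indir, output_dir = out,
               modules = c("reorient", "correct"),
               skip_brain_extraction = TRUE, skip_wm_segmentation = TRUE)))
  expect_equal(summ$processed, 2)
  logf <- list.files(file.path(out, "logs"), full.names = TRUE)
  log <- readLines(logf[1])
  expect_true(any(grepl("brain extraction set to run on all subjects", log)))
  expect_true(any(grepl("computed", log[grepl("tissue prep subj1", log)])))
})

test_that("a nonempty output directory aborts the run unless forced", {
  root <- withr::local_tempdir()
  indir <- file.path(root, "in")
  make_phantom_dataset(indir, n_subjects = 1, seed = 7, spec = small_spec())
  out <- file.path(root, "out")
  dir.create(out)
  writeLines("x", file.path(out, "leftover.txt"))
  cfg <- run_config(input_dir = indir, output_dir = out,
                    modules = "reorient")
  expect_error(run_pipeline(cfg), "not empty")
  cfg$force <- TRUE
  expect_no_error(run_pipeline(cfg))
})

test_that("re-running with identical config yields byte-identical reports and masks", {
  root <- withr::local_tempdir()
  indir <- file.path(root, "in")
  spec <- small_spec()
  make_phantom_dataset(indir, n_subjects = 2, seed = 8, spec = spec)
  tr <- write_template_rois(root, spec)
  mkcfg <- function(out)
    run_config(input_dir = indir, output_dir = out,
               modules = c("reorient", "correct", "load", "qc"),
               roi_config = list(mode = "template", roi_dir = tr$roi_dir,
                                 template_path = tr$template_path))
  suppressWarnings(run_pipeline(mkcfg(file.path(root, "out1"))))
  suppressWarnings(run_pipeline(mkcfg(file.path(root, "out2"))))
  files <- list.files(file.path(root, "out1"), recursive = TRUE)
  files <- files[grepl("\\.(csv|nii\\.gz|mat|png)$", files)]
  expect_gt(length(files), 20)
  for (f in files)
    expect_same_bytes(file.path(root, "out1", f), file.path(root, "out2", f))
})

test_that("the output tree matches the documented layout", {
  root <- withr::local_tempdir()
  indir <- file.path(root, "in")
  spec <- small_spec()
  make_phantom_dataset(indir, n_subjects = 1, seed = 9, spec = spec)
  tr <- write_template_rois(root, spec)
  out <- file.path(root, "out")
  suppressWarnings(run_pipeline(
    run_config(input_dir = indir, output_dir = out,
               modules = c("reorient", "correct", "load", "qc"),
               roi_config = list(mode = "template", roi_dir = tr$roi_dir,
                                 template_path = tr$template_path))))
  files <- list.files(out, recursive = TRUE)
  expect_true("subj1/Intermediate_Files/Original_Files/subj1_T1.nii.gz"
              %in% files)
  expect_true("subj1/Intermediate_Files/subj1_brain_mask.nii.gz" %in% files)
  expect_true("subj1/subj1_Lesion_corrected.nii.gz" %in% files)
  expect_true("lesion_correction_report.csv" %in% files)
  expect_true("lesion_load_report.csv" %in% files)
  expect_true("flagged_subjects.csv" %in% files)
  for (q in c("QC_BrainExtractions", "QC_WMSegmentations",
              "QC_Registrations", "QC_LesionCorrections", "QC_LesionLoads"))
    expect_true(file.exists(file.path(out, q, "index.html")), label = q)
  expect_length(list.files(file.path(out, "logs")), 1)
  # the log replays stage decisions in order
  log <- readLines(list.files(file.path(out, "logs"), full.names = TRUE))
  expect_lt(grep("harmonized", log)[1], grep("corrected", log)[1])
})

test_that("subject-space label ROIs compute loads without registration", {
  root <- withr::local_tempdir()
  indir <- file.path(root, "in")
  spec <- small_spec()
  make_phantom_dataset(indir, n_subjects = 1, seed = 10, spec = spec)
  ph <- make_head_phantom(phantom_spec(shape = spec$shape,
                                       seed = 10))   # matches subj1's grid
  labels <- volume(ph$wm$data * 7 + ph$csf$data * 3, ph$t1$affine)
  write_volume(labels, file.path(indir, "subj1", "subj1_Labels.nii.gz"))
  out <- file.path(root, "out")
  summ <- suppressWarnings(run_pipeline(
    run_config(input_dir = indir, output_dir = out,
               modules = c("reorient", "load"),
               roi_config = list(mode = "subject_labels",
                                 label_table = c(wm = 7, ventricles = 3)))))
  rep <- utils::read.csv(file.path(out, "lesion_load_report.csv"))
  expect_equal(nrow(rep), 2)
  expect_setequal(rep$roi_name, c("wm", "ventricles"))
  expect_true(all(rep$percent_overlap >= 0 & rep$percent_overlap <= 100))
})
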