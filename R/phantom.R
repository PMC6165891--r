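# Deterministic synthetic head phantoms: nested-ellipsoid brain (GM cortex
# shell outermost, WM beneath it, a CSF ventricle core at the center) inside
# a bright skull shell, with an intensity-lowered lesion and exact
# ground-truth tissue masks. Stands in for patient MRI so every pipeline
# stage is testable offline.

ellipsoid_mask <- function(shape, center, radii) {
  i <- seq_len(shape[1]); j <- seq_len(shape[2]); k <- seq_len(shape[3])
  di <- ((i - center[1]) / radii[1])^2
  dj <- ((j - center[2]) / radii[2])^2
  dk <- ((k - center[3]) / radii[3])^2
  outer(outer(di, dj, "+"), dk, "+") <= 1
}

#' Head-phantom specification
#'
#' Geometry and intensity parameters of the synthetic head. Defaults: a
#' 64 x 80 x 64 grid at 2 mm isotropic spacing in neurological convention
#' (positive-determinant affine, so convention harmonization is exercised by
#' default); tissue mean intensities CSF 40 < GM 110 < WM 180 on an arbitrary
#' scanner-like scale (skull shell 240, background 5), arranged as a GM
#' cortex shell over a WM interior with a CSF ventricle core; additive
#' Gaussian noise with SD 5; an ellipsoidal lesion in the left-hemisphere
#' white matter whose intensity is lowered to `wm * (1 - lesion_drop)`.
#'
#' @param shape grid dimensions `(nx, ny, nz)`.
#' @param tissue_means `c(csf, gm, wm)` mean intensities, strictly
#'   increasing.
#' @param noise_sd Gaussian noise SD (0 = noiseless).
#' @param lesion_center lesion ellipsoid center, 1-based voxel coordinates
#'   (default: offset into the left-hemisphere WM).
#' @param lesion_radii lesion ellipsoid semi-axes in voxels.
#' @param lesion_drop fractional intensity drop of lesion voxels relative to
#'   the WM mean (0.5 = half WM intensity, between CSF and GM — typical of a
#'   chronic stroke cavity rim).
#' @param voxel_mm isotropic voxel size in mm.
#' @param seed RNG seed for the noise.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(64L, 80L, 64L),
                         tissue_means = c(csf = 40, gm = 110, wm = 180),
                         noise_sd = 5,
                         lesion_center = NULL,
                         lesion_radii = NULL,
                         lesion_drop = 0.5,
                         voxel_mm = 2,
                         seed = 1L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 16L))
  tm <- unname(tissue_means)
  if (!(tm[1] < tm[2] && tm[2] < tm[3]))
    stop("tissue means must satisfy csf < gm < wm", call. = FALSE)
  c0 <- (shape + 1) / 2
  brain_radii <- round(c(22, 28, 22) * shape / c(64, 80, 64))
  if (is.null(lesion_center))
    lesion_center <- c0 + round(c(0.40, 0.07, 0.07) * brain_radii)
  if (is.null(lesion_radii))
    lesion_radii <- pmax(round(0.28 * brain_radii), 3)
  # lesion ellipsoid must sit fully inside the brain ellipsoid
  corners <- t(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1))) * lesion_radii
  ext <- sweep(corners, 1, lesion_center, "+")
  if (any(colSums(((ext - c0) / brain_radii)^2) > 1))
    stop("lesion ellipsoid extends outside the brain ellipsoid",
         call. = FALSE)
  structure(list(shape = shape, tissue_means = tm, noise_sd = noise_sd,
                 brain_radii = brain_radii, center = c0,
                 lesion_center = lesion_center, lesion_radii = lesion_radii,
                 lesion_drop = lesion_drop, voxel_mm = voxel_mm,
                 seed = as.integer(seed),
                 background = 5, skull_intensity = 240),
            class = "phantom_spec")
}

phantom_affine <- function(spec) {
  A <- diag(c(rep(spec$voxel_mm, 3), 1))
  A[1:3, 4] <- -(spec$shape - 1) / 2 * spec$voxel_mm
  A
}

#' Generate a synthetic head phantom
#'
#' Builds the T1 volume plus exact ground-truth masks. The CSF, GM and WM
#' truth masks partition the brain ellipsoid (pairwise disjoint, covering
#' it exactly); the lesion truth is the lesion ellipsoid, whose voxels are
#' re-assigned the lowered intensity. A skull shell, separated from the
#' brain surface by a dark gap, surrounds the head. Pure function of the
#' spec (including its seed): the same spec yields bit-identical volumes.
#'
#' @param spec a [phantom_spec()].
#' @return list of [volume()]s: `t1`, `brain`, `csf`, `gm`, `wm`, `lesion`,
#'   plus the `spec`.
#' @export
make_head_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  sh <- spec$shape
  c0 <- spec$center
  brain <- ellipsoid_mask(sh, c0, spec$brain_radii)
  wm_outer <- ellipsoid_mask(sh, c0, spec$brain_radii * 0.85)
  csf_core <- ellipsoid_mask(sh, c0, spec$brain_radii * 0.35)
  gm <- brain & !wm_outer            # cortex shell
  wm <- wm_outer & !csf_core         # white matter beneath it
  csf <- csf_core                    # ventricle-like core
  lesion <- ellipsoid_mask(sh, spec$lesion_center, spec$lesion_radii)
  skull <- ellipsoid_mask(sh, c0, spec$brain_radii + 4) &
    !ellipsoid_mask(sh, c0, spec$brain_radii + 2)

  tm <- spec$tissue_means
  t1 <- array(spec$background, sh)
  t1[csf] <- tm[1]
  t1[gm] <- tm[2]
  t1[wm] <- tm[3]
  t1[lesion] <- tm[3] * (1 - spec$lesion_drop)
  t1[skull] <- spec$skull_intensity
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    t1 <- t1 + array(stats::rnorm(prod(sh), 0, spec$noise_sd), sh)
    t1[t1 < 0] <- 0
  }
  A <- phantom_affine(spec)
  list(t1 = volume(t1, A, role = "intensity"),
       brain = volume(brain + 0, A, role = "mask"),
       csf = volume(csf + 0, A, role = "mask"),
       gm = volume(gm + 0, A, role = "mask"),
       wm = volume(wm + 0, A, role = "mask"),
       lesion = volume(lesion + 0, A, role = "mask"),
       spec = spec)
}

#' Simulate tracer variants of a lesion mask
#'
#' Emulates `n` human raters segmenting the same lesion: each variant
#' perturbs the truth mask's boundary by seeded random erosions/dilations
#' (depth and probability growing with `boundary_sd`), then sprinkles in a
#' seeded fraction of peri-lesional voxels — drawn from `wm_mask` when given,
#' so the sprinkled voxels carry healthy-WM intensity and the correction
#' stage has something to remove.
#'
#' @param lesion_truth binary lesion [volume()].
#' @param n number of variants (>= 2).
#' @param boundary_sd boundary perturbation scale in voxels; 0 = no boundary
#'   change.
#' @param seed RNG seed.
#' @param wm_mask optional WM mask [volume()] restricting sprinkle
#'   candidates.
#' @param sprinkle_frac fraction of the lesion size added as peri-lesional
#'   sprinkle voxels (default 0.1).
#' @return list of `n` binary mask [volume()]s.
#' @export
make_tracer_variants <- function(lesion_truth, n = 10L, boundary_sd = 1,
                                 seed = 1L, wm_mask = NULL,
                                 sprinkle_frac = 0.1) {
  stopifnot(is_volume(lesion_truth), n >= 2L, boundary_sd >= 0)
  truth <- lesion_truth$data > 0
  set.seed(seed)
  depth <- max(1L, ceiling(boundary_sd))
  pflip <- 1 - exp(-boundary_sd)
  shell_out <- binary_dilate(truth, 2L) & !truth
  cand <- shell_out
  if (!is.null(wm_mask)) {
    cand <- cand & (wm_mask$data > 0)
    if (!any(cand)) cand <- shell_out
  }
  cand_idx <- which(cand)
  n_sprinkle <- round(sum(truth) * sprinkle_frac)
  out <- vector("list", n)
  for (v in seq_len(n)) {
    m <- truth
    if (boundary_sd > 0) {
      for (d in seq_len(depth)) {
        b_out <- binary_dilate(m) & !m
        b_in <- m & !binary_erode(m)
        add <- which(b_out)[stats::runif(sum(b_out)) < pflip / 2]
        rem <- which(b_in)[stats::runif(sum(b_in)) < pflip / 2]
        m[add] <- TRUE
        m[rem] <- FALSE
      }
    }
    if (n_sprinkle > 0 && length(cand_idx) > 0) {
      take <- sample(cand_idx, min(n_sprinkle, length(cand_idx)))
      m[take] <- TRUE
    }
    if (!any(m))
      stop("boundary_sd too large: tracer variant ", v, " is empty",
           call. = FALSE)
    out[[v]] <- volume(m + 0, lesion_truth$affine, role = "mask")
  }
  out
}

#' Write a phantom subject for one orientation validation case
#'
#' Builds the six input-orientation cases used to validate convention
#' harmonization: per-file neurological/radiological storage, or missing
#' optional files.
#'
#' | case | lesion | T1 | brain | WM | expected outcome |
#' |------|--------|----|-------|----|------------------|
#' | 1 | neuro | neuro | neuro | neuro | all radiological |
#' | 2 | radio | radio | radio | radio | conserved radiological |
#' | 3 | neuro | neuro | radio | neuro | flagged |
#' | 4 | neuro | neuro | radio | radio | flagged |
#' | 5 | neuro | radio | radio | radio | flagged |
#' | 6 | neuro | neuro | missing | missing | radiological + skip overrides |
#'
#' @param case integer 1..6.
#' @param dir directory in which the subject subdirectory is created.
#' @param subject_id subject directory / file prefix (default `case<k>`).
#' @param spec [phantom_spec()] for the underlying head phantom.
#' @return the subject directory path, invisibly.
#' @export
make_orientation_case <- function(case, dir, subject_id = NULL,
                                  spec = phantom_spec()) {
  stopifnot(case %in% 1:6)
  if (is.null(subject_id)) subject_id <- paste0("case", case)
  ph <- make_head_phantom(spec)
  conv <- switch(case,
    `1` = c(t1 = "n", lesion = "n", brain = "n", wm = "n"),
    `2` = c(t1 = "r", lesion = "r", brain = "r", wm = "r"),
    `3` = c(t1 = "n", lesion = "n", brain = "r", wm = "n"),
    `4` = c(t1 = "n", lesion = "n", brain = "r", wm = "r"),
    `5` = c(t1 = "r", lesion = "n", brain = "r", wm = "r"),
    `6` = c(t1 = "n", lesion = "n"))
  vols <- list(t1 = ph$t1, lesion = ph$lesion, brain = ph$brain, wm = ph$wm)
  fname <- c(t1 = "_T1.nii.gz", lesion = "_Lesion.nii.gz",
             brain = "_Brain.nii.gz", wm = "_WM.nii.gz")
  sdir <- file.path(dir, subject_id)
  dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
  for (f in names(conv)) {
    v <- vols[[f]]
    if (conv[f] == "r") v <- to_radiological(v)
    write_volume(v, file.path(sdir, paste0(subject_id, fname[f])))
  }
  invisible(sdir)
}

#' Generate a template volume plus ROI masks
#'
#' A lesion-free head phantom serves as the registration template
#' (radiological convention, as standard templates are usually stored), with
#' binary ellipsoidal ROI masks on its grid. One-hemisphere ROIs (e.g. a
#' corticospinal-tract-like column confined to the left hemisphere) support
#' the contralateral-lesion zero-load check.
#'
#' @param spec [phantom_spec()] for the template head (its lesion is not
#'   painted).
#' @param rois named list; each element `list(center =, radii =)` in 1-based
#'   voxel coordinates of the template grid, or one of the string presets
#'   `"cst_left"` / `"cst_right"` (tall columns in the left/right hemisphere
#'   white matter).
#' @return list with `template` ([volume()]) and `rois` (named list of
#'   binary mask [volume()]s).
#' @export
make_template_with_rois <- function(spec = phantom_spec(),
                                    rois = list("cst_left", "cst_right")) {
  tpl_spec <- spec
  tpl_spec$lesion_drop <- 0   # paint no lesion: template is healthy anatomy
  ph <- make_head_phantom(tpl_spec)
  tpl <- to_radiological(ph$t1)
  c0 <- spec$center
  br <- spec$brain_radii
  preset <- function(side) {
    sgn <- if (side == "left") 1 else -1
    list(center = c(c0[1] + sgn * round(0.45 * br[1]), c0[2],
                    c0[3]),
         radii = round(c(0.16, 0.16, 0.55) * br))
  }
  out <- list()
  nm <- names(rois)
  for (i in seq_along(rois)) {
    r <- rois[[i]]
    if (is.character(r)) {
      side <- sub("^cst_", "", r)
      name <- r
      r <- preset(side)
    } else {
      name <- if (!is.null(nm) && nzchar(nm[i])) nm[i] else paste0("roi", i)
    }
    corners <- t(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1))) * r$radii
    ext <- sweep(corners, 1, r$center, "+")
    if (any(colSums(((ext - c0) / br)^2) > 1))
      stop("ROI '", name, "' extends outside the template brain",
           call. = FALSE)
    mask <- ellipsoid_mask(spec$shape, r$center, r$radii)
    mv <- volume(mask + 0, phantom_affine(spec), role = "mask")
    out[[name]] <- to_radiological(mv)
  }
  list(template = tpl, rois = out)
}

#' Write a ready-to-run phantom input directory
#'
#' Creates `n_subjects` subject subdirectories, each with a T1 and lesion
#' mask (and optional brain/WM truth masks), laid out the way
#' [discover_subjects()] expects. Subjects differ by noise seed and lesion
#' size jitter.
#'
#' @param dir input directory to create.
#' @param n_subjects number of subjects.
#' @param seed base RNG seed.
#' @param spec base [phantom_spec()].
#' @param with_masks also write brain and WM truth masks?
#' @return `dir`, invisibly.
#' @export
make_phantom_dataset <- function(dir, n_subjects = 2L, seed = 1L,
                                 spec = phantom_spec(), with_masks = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in seq_len(n_subjects)) {
    sp <- spec
    sp$seed <- as.integer(seed + s - 1L)
    sp$lesion_radii <- pmax(sp$lesion_radii - (s - 1L) %% 2L, 3L)
    ph <- make_head_phantom(sp)
    id <- sprintf("subj%d", s)
    sdir <- file.path(dir, id)
    dir.create(sdir, showWarnings = FALSE)
    write_volume(ph$t1, file.path(sdir, paste0(id, "_T1.nii.gz")))
    write_volume(ph$lesion, file.path(sdir, paste0(id, "_Lesion.nii.gz")))
    if (with_masks) {
      write_volume(ph$brain, file.path(sdir, paste0(id, "_Brain.nii.gz")))
      write_volume(ph$wm, file.path(sdir, paste0(id, "_WM.nii.gz")))
    }
  }
  invisible(dir)
}
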