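# Shared fixtures, generated in code. Small grids keep the suite fast;
# default-size phantoms are reserved for the registration checks.

small_spec <- function(seed = 1L, noise_sd = 5, ...) {
  phantom_spec(shape = c(32L, 40L, 32L), seed = seed, noise_sd = noise_sd,
               ...)
}

# cache expensive fixtures across test files (phantom + tissue prep)
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

small_phantom <- function(noise_sd = 5) {
  key <- paste0("ph_", noise_sd)
  cached(key, make_head_phantom(small_spec(noise_sd = noise_sd)))
}

small_tissue <- function(noise_sd = 5) {
  key <- paste0("ts_", noise_sd)
  cached(key, {
    ph <- small_phantom(noise_sd)
    t1n <- normalize_intensity(ph$t1)
    bm <- extract_brain(t1n)
    wm <- segment_white_matter(t1n, bm)
    list(t1n = t1n, brain = bm, wm = wm)
  })
}

# a mask volume on a trivial grid from 1-based voxel index rows
mask_from_idx <- function(dims, idx, affine = diag(4)) {
  a <- array(0, dims)
  a[idx] <- 1
  volume(a, affine, role = "mask")
}

# random binary mask on a tiny grid (for property loops)
random_mask <- function(dims, p = 0.3) {
  volume((array(stats::runif(prod(dims)), dims) < p) + 0, diag(4),
         role = "mask")
}

# ground-truth WM at phantom construction, minus the lesion re-assignment
wm_minus_lesion <- function(ph) {
  volume((ph$wm$data > 0 & !(ph$lesion$data > 0)) + 0, ph$wm$affine,
         role = "mask")
}

expect_same_bytes <- function(a, b) {
  expect_identical(readBin(a, "raw", file.size(a) + 10),
                   readBin(b, "raw", file.size(b) + 10))
}

write_template_rois <- function(root, spec) {
  tset <- make_template_with_rois(spec)
  roidir <- file.path(root, "rois")
  dir.create(roidir, recursive = TRUE, showWarnings = FALSE)
  tpl <- file.path(root, "template.nii.gz")
  write_volume(tset$template, tpl)
  for (nm in names(tset$rois))
    write_volume(tset$rois[[nm]], file.path(roidir, paste0(nm, ".nii.gz")))
  list(template_path = tpl, roi_dir = roidir, tset = tset)
}
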