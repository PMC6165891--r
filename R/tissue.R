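#' Normalize T1 intensities to the 0-255 scale
#'
#' Linear map of the volume's full intensity range onto `[0, 255]` (the scale
#' the white-matter removal window is defined on). Values stay continuous;
#' no quantization. The whole volume is normalized, not just the brain,
#' because normalization precedes skull stripping in the pipeline.
#'
#' @param t1 an intensity [volume()].
#' @return a [volume()] with min 0 and max 255; a constant input yields an
#'   all-zero volume with a warning (degenerate normalization).
#' @export
normalize_intensity <- function(t1) {
  stopifnot(is_volume(t1))
  r <- range(t1$data)
  if (diff(r) == 0) {
    warning("constant input volume: degenerate normalization, returning ",
            "all zeros", call. = FALSE)
    return(volume(array(0, dim(t1$data)), t1$affine, role = t1$role,
                  path = t1$path))
  }
  volume((t1$data - r[1]) / diff(r) * 255, t1$affine, role = "intensity",
         path = t1$path)
}

#' Extract a brain mask from a T1 volume
#'
#' A parameter-free skull-stripping stand-in: global Otsu threshold
#' (256-bin between-class-variance maximization), largest 6-connected
#' component, morphological closing and hole filling. Works on the phantom's
#' head geometry, where the skull shell is separated from the brain surface
#' by a dark gap; it is not a general-purpose brain extractor.
#'
#' @param t1 raw or normalized T1 [volume()].
#' @param close_iter closing radius in voxels (default 2).
#' @return binary brain-mask [volume()] with attribute
#'   `provenance = "computed"`.
#' @export
extract_brain <- function(t1, close_iter = 2L) {
  stopifnot(is_volume(t1))
  thr <- otsu_threshold(as.vector(t1$data))
  fg <- t1$data > thr
  if (!any(fg))
    stop("brain extraction failed: empty mask after thresholding",
         call. = FALSE)
  comp <- largest_component(fg)
  mask <- fill_holes(binary_close(comp, close_iter))
  if (!any(mask))
    stop("brain extraction failed: empty mask", call. = FALSE)
  out <- volume(mask + 0, t1$affine, role = "mask", path = "")
  attr(out, "provenance") <- "computed"
  out
}

#' Segment white matter by 3-class intensity clustering
#'
#' Stand-in for an automated tissue segmentation: a deterministic 1-D
#' three-class clustering (CSF/GM/WM) of within-brain intensities. Class
#' means are initialized at the 25/50/75% points of the within-brain
#' intensity range (percentile initialization degenerates when one tissue
#' dominates the volume) and refined by fixed-point (Lloyd) iteration to
#' tolerance `tol` or `max_iter` iterations; white matter is the nonempty
#' class with the highest mean.
#'
#' @param t1_norm normalized T1 [volume()] (see [normalize_intensity()]).
#' @param brain_mask binary brain-mask [volume()] on the same grid.
#' @param max_iter,tol iteration cap and convergence tolerance on the class
#'   means.
#' @return binary WM-mask [volume()] (a subset of `brain_mask`) with
#'   attributes `provenance = "computed"` and `class_means` (sorted CSF, GM,
#'   WM means).
#' @export
segment_white_matter <- function(t1_norm, brain_mask, max_iter = 100L,
                                 tol = 1e-6) {
  stopifnot(is_volume(t1_norm), is_volume(brain_mask))
  stop_grid_mismatch(t1_norm, brain_mask, "T1 and brain mask")
  inb <- brain_mask$data > 0
  if (!any(inb))
    stop("white-matter segmentation failed: empty brain mask", call. = FALSE)
  x <- t1_norm$data[inb]
  if (length(unique(x)) < 3L)
    stop("white-matter segmentation failed: fewer than 3 distinct ",
         "within-brain intensities", call. = FALSE)
  r <- range(x)
  mu <- r[1] + diff(r) * c(0.25, 0.5, 0.75)
  for (it in seq_len(max_iter)) {
    d <- abs(outer(x, mu, "-"))
    cl <- max.col(-d, ties.method = "first")
    mu_new <- vapply(1:3, function(k)
      if (any(cl == k)) mean(x[cl == k]) else mu[k], numeric(1))
    if (max(abs(mu_new - mu)) < tol) { mu <- mu_new; break }
    mu <- mu_new
  }
  d <- abs(outer(x, mu, "-"))
  cl <- max.col(-d, ties.method = "first")
  occupied <- vapply(1:3, function(k) any(cl == k), logical(1))
  wm_class <- which(occupied)[which.max(mu[occupied])]
  mask <- array(0, dim(t1_norm$data))
  mask[inb][cl == wm_class] <- 1
  out <- volume(mask, t1_norm$affine, role = "mask", path = "")
  attr(out, "provenance") <- "computed"
  attr(out, "class_means") <- sort(mu)
  out
}

#' Prepare a subject's tissue set
#'
#' Normalizes the T1 and produces brain and white-matter masks, honoring
#' user-supplied masks: a provided mask is returned unchanged with
#' `provenance = "provided"`; otherwise it is computed with
#' [extract_brain()] / [segment_white_matter()].
#'
#' @param t1 raw T1 [volume()].
#' @param brain_mask optional user-supplied brain mask [volume()].
#' @param wm_mask optional user-supplied WM mask [volume()].
#' @return list with `normalized_t1`, `brain_mask`, `wm_mask`, `provenance`
#'   (named character, `"computed"`/`"provided"` per mask).
#' @export
prepare_tissue <- function(t1, brain_mask = NULL, wm_mask = NULL) {
  t1n <- normalize_intensity(t1)
  prov <- c(brain_mask = "computed", wm_mask = "computed")
  if (is.null(brain_mask)) {
    brain_mask <- extract_brain(t1n)
  } else {
    prov["brain_mask"] <- "provided"
    attr(brain_mask, "provenance") <- "provided"
  }
  if (is.null(wm_mask)) {
    wm_mask <- segment_white_matter(t1n, brain_mask)
  } else {
    prov["wm_mask"] <- "provided"
    attr(wm_mask, "provenance") <- "provided"
    if (any(wm_mask$data > brain_mask$data))
      warning("provided WM mask extends outside the brain mask",
              call. = FALSE)
  }
  list(normalized_t1 = t1n, brain_mask = brain_mask, wm_mask = wm_mask,
       provenance = prov)
}
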