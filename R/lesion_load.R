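#' Lesion-ROI overlap mask
#'
#' The binarized lesion and ROI masks are summed voxelwise (overlapping
#' voxels get the value 2), everything below 2 is zeroed, and the result is
#' rebinarized — equivalently, the voxelwise AND of the two masks.
#'
#' @param lesion,roi binary mask [volume()]s on the same grid.
#' @return binary overlap-mask [volume()].
#' @export
overlap_mask <- function(lesion, roi) {
  stopifnot(is_volume(lesion), is_volume(roi))
  stop_grid_mismatch(lesion, roi, "lesion and ROI masks")
  s <- (lesion$data > 0) + (roi$data > 0)
  s[s < 2] <- 0
  volume((s >= 2) + 0, lesion$affine, role = "mask")
}

#' Percent lesion load within an ROI
#'
#' Counts overlap voxels between the lesion and the ROI and reports
#' `percent_overlap = 100 * overlap / roi_voxels` — the denominator is the
#' ROI volume, so 100% means the ROI is fully covered by the lesion.
#'
#' @param lesion,roi binary mask [volume()]s on the same grid; `roi` must be
#'   nonempty.
#' @param subject_id,lesion_file,roi_name labels carried into the result.
#' @return A `load_result`: list with `subject_id`, `lesion_file`,
#'   `roi_name`, `roi_voxels`, `overlap_voxels`, `percent_overlap`.
#' @export
lesion_load <- function(lesion, roi, subject_id = "", lesion_file = "",
                        roi_name = "") {
  nroi <- sum(roi$data > 0)
  if (nroi == 0L)
    stop("empty ROI", if (nzchar(roi_name)) paste0(": ", roi_name),
         call. = FALSE)
  ov <- sum(overlap_mask(lesion, roi)$data)
  res <- list(subject_id = subject_id, lesion_file = lesion_file,
              roi_name = roi_name, roi_voxels = as.integer(nroi),
              overlap_voxels = as.integer(ov),
              percent_overlap = 100 * ov / nroi)
  class(res) <- "load_result"
  res
}

#' @export
print.load_result <- function(x, ...) {
  cat(sprintf("<load_result> %s %s vs %s: %d/%d voxels = %.2f%%\n",
              x$subject_id, x$lesion_file, x$roi_name, x$overlap_voxels,
              x$roi_voxels, x$percent_overlap))
  invisible(x)
}

#' Extract ROI masks from an integer label volume
#'
#' For subject-space parcellations: each requested label code becomes one
#' binary ROI mask (`label volume == code`).
#'
#' @param labels integer-valued [volume()].
#' @param codes named integer vector: ROI name -> label code.
#' @return named list of binary mask [volume()]s.
#' @export
rois_from_labels <- function(labels, codes) {
  stopifnot(is_volume(labels))
  out <- lapply(codes, function(code)
    volume((labels$data == code) + 0, labels$affine, role = "mask"))
  names(out) <- names(codes)
  out
}

#' Compute lesion loads for one subject against a set of ROIs
#'
#' Registers the subject's T1 to the template (unless the grids already
#' coincide, in which case the identity shortcut is taken, or a precomputed
#' transform is supplied), applies the transform to each lesion mask with
#' nearest-neighbour interpolation, binarizes each ROI, and emits one
#' result per (lesion, ROI) pair.
#'
#' @param t1 subject T1 [volume()] (used to estimate the registration).
#' @param lesions named list of binary lesion-mask [volume()]s in subject
#'   space.
#' @param rois named list of ROI mask [volume()]s on the template grid.
#' @param template template [volume()] defining the ROI space.
#' @param transform optional precomputed `affine_transform` (subject world to
#'   template world); bypasses estimation.
#' @param subject_id label carried into results.
#' @return list with `transform`, `lesions_in_roi_space` (named list of
#'   resampled masks) and `results` (list of `load_result`s).
#' @export
subject_lesion_load <- function(t1, lesions, rois, template,
                                transform = NULL, subject_id = "") {
  if (is.null(transform)) {
    if (same_grid(t1, template)) {
      transform <- identity_transform()
    } else {
      transform <- register_affine(t1, template)
    }
  }
  rois <- lapply(rois, function(r)
    volume((r$data > 0) + 0, r$affine, role = "mask"))
  results <- list()
  lesions_t <- list()
  for (lf in names(lesions)) {
    les_t <- resample_to(lesions[[lf]], transform, template,
                         interp = "nearest")
    lesions_t[[lf]] <- les_t
    for (rn in names(rois)) {
      results[[length(results) + 1L]] <-
        lesion_load(les_t, rois[[rn]], subject_id = subject_id,
                    lesion_file = lf, roi_name = rn)
    }
  }
  list(transform = transform, lesions_in_roi_space = lesions_t,
       results = results)
}

#' Write the lesion-load report CSV
#'
#' @param results list of `load_result`s.
#' @param path output CSV path.
#' @return the data frame written, invisibly.
#' @export
write_load_report <- function(results, path) {
  rows <- do.call(rbind, lapply(results, function(r) {
    data.frame(subject_id = r$subject_id, lesion_file = r$lesion_file,
               roi_name = r$roi_name, roi_voxels = r$roi_voxels,
               overlap_voxels = r$overlap_voxels,
               percent_overlap = r$percent_overlap,
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows))
    rows <- data.frame(subject_id = character(0), lesion_file = character(0),
                       roi_name = character(0), roi_voxels = integer(0),
                       overlap_voxels = integer(0),
                       percent_overlap = numeric(0))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(rows)
}
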