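#' White-matter intensity removal window
#'
#' The removal half-width is the user's percentage converted to the 0-255
#' intensity scale and divided by two: `h = 255 * (p/100) / 2`. The window is
#' `wm_mean - h` to `wm_mean + h`, inclusive and unclamped (values outside
#' `[0, 255]` cannot match any normalized intensity anyway).
#'
#' @param wm_mean mean white-matter intensity on the 0-255 scale.
#' @param p removal percentage in `[0, 100]` (default 5).
#' @return numeric `c(lo, hi)`.
#' @examples
#' removal_window(128, 5)   # c(121.625, 134.375)
#' @export
removal_window <- function(wm_mean, p = 5) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 100)
    stop("removal percentage must be a single value in [0, 100]",
         call. = FALSE)
  h <- 255 * (p / 100) / 2
  c(lo = wm_mean - h, hi = wm_mean + h)
}

#' Mean white-matter intensity
#'
#' Arithmetic mean of the normalized T1 over the white-matter mask. With
#' `exclude_lesion = TRUE` lesion voxels are excluded from the mask first —
#' an opt-in deviation from the default, which averages over the full WM
#' segmentation (lesion voxels that fell into the WM class included).
#'
#' @param t1_norm normalized T1 [volume()].
#' @param wm_mask binary WM mask [volume()].
#' @param lesion_mask binary lesion mask [volume()] (required when
#'   `exclude_lesion = TRUE`).
#' @param exclude_lesion drop lesion voxels from the averaging mask?
#' @return scalar mean intensity on the 0-255 scale.
#' @export
wm_mean_intensity <- function(t1_norm, wm_mask, lesion_mask = NULL,
                              exclude_lesion = FALSE) {
  stopifnot(is_volume(t1_norm), is_volume(wm_mask))
  stop_grid_mismatch(t1_norm, wm_mask, "T1 and WM mask")
  sel <- wm_mask$data > 0
  if (exclude_lesion) {
    if (is.null(lesion_mask))
      stop("exclude_lesion = TRUE requires a lesion mask", call. = FALSE)
    stop_grid_mismatch(t1_norm, lesion_mask, "T1 and lesion mask")
    sel <- sel & !(lesion_mask$data > 0)
  }
  if (!any(sel))
    stop("empty effective white-matter mask", call. = FALSE)
  mean(t1_norm$data[sel])
}

#' Correct a lesion mask for healthy white-matter voxels
#'
#' Removes from the lesion mask every voxel whose normalized T1 intensity
#' lies within the removal window around the subject's mean white-matter
#' intensity (see [removal_window()]), then binarizes the survivors as the
#' final lesion mask. Intended for manually traced lesions; voxels at
#' healthy-WM intensity inside a manual tracing are likely tracing spillover.
#'
#' @param t1_norm normalized T1 [volume()].
#' @param wm_mask binary WM mask [volume()] on the same grid.
#' @param lesion_mask binary lesion mask [volume()] on the same grid.
#' @param p removal percentage (default 5).
#' @param exclude_lesion see [wm_mean_intensity()].
#' @param subject_id,lesion_file labels carried into the report row.
#' @return A `correction_result`: list with `corrected_mask` ([volume()]),
#'   `original_voxels`, `removed_voxels`, `surviving_voxels`, `wm_mean`,
#'   `window` (`c(lo, hi)`), `percent_param`, `subject_id`, `lesion_file`.
#' @export
correct_lesion <- function(t1_norm, wm_mask, lesion_mask, p = 5,
                           exclude_lesion = FALSE,
                           subject_id = "", lesion_file = "") {
  stopifnot(is_volume(t1_norm), is_volume(wm_mask), is_volume(lesion_mask))
  stop_grid_mismatch(t1_norm, wm_mask, "T1 and WM mask")
  stop_grid_mismatch(t1_norm, lesion_mask, "T1 and lesion mask")
  les <- lesion_mask$data > 0
  n0 <- sum(les)
  if (n0 == 0L) {
    warning("empty lesion mask: nothing to correct", call. = FALSE)
    res <- list(corrected_mask = lesion_mask, original_voxels = 0L,
                removed_voxels = 0L, surviving_voxels = 0L,
                wm_mean = NA_real_, window = c(lo = NA_real_, hi = NA_real_),
                percent_param = p, subject_id = subject_id,
                lesion_file = lesion_file)
    class(res) <- "correction_result"
    return(res)
  }
  wm_mean <- wm_mean_intensity(t1_norm, wm_mask, lesion_mask, exclude_lesion)
  win <- removal_window(wm_mean, p)
  inwin <- les & t1_norm$data >= win["lo"] & t1_norm$data <= win["hi"]
  surv <- les & !inwin
  if (!any(surv))
    warning("lesion mask entirely within the removal window: corrected ",
            "mask is empty", call. = FALSE)
  res <- list(
    corrected_mask = volume(surv + 0, lesion_mask$affine, role = "mask",
                            path = lesion_mask$path),
    original_voxels = as.integer(n0),
    removed_voxels = as.integer(sum(inwin)),
    surviving_voxels = as.integer(sum(surv)),
    wm_mean = wm_mean, window = win, percent_param = p,
    subject_id = subject_id, lesion_file = lesion_file)
  class(res) <- "correction_result"
  res
}

#' @export
print.correction_result <- function(x, ...) {
  cat(sprintf(
    "<correction_result> %s %s: %d voxels, %d removed (%.1f%%), window [%.2f, %.2f] around WM mean %.2f\n",
    x$subject_id, x$lesion_file, x$original_voxels, x$removed_voxels,
    if (x$original_voxels > 0) 100 * x$removed_voxels / x$original_voxels else 0,
    x$window[1], x$window[2], x$wm_mean))
  invisible(x)
}

#' Write the lesion-correction report CSV
#'
#' One row per (subject, lesion mask) with the removal accounting.
#'
#' @param results list of `correction_result`s from [correct_lesion()].
#' @param path output CSV path.
#' @return the data frame written, invisibly.
#' @export
write_correction_report <- function(results, path) {
  if (length(results) < 1L)
    stop("no correction results to report", call. = FALSE)
  rows <- do.call(rbind, lapply(results, function(r) {
    data.frame(subject_id = r$subject_id, lesion_file = r$lesion_file,
               original_voxels = r$original_voxels,
               removed_voxels = r$removed_voxels,
               surviving_voxels = r$surviving_voxels,
               percent_removed = if (r$original_voxels > 0)
                 100 * r$removed_voxels / r$original_voxels else 0,
               wm_mean = unname(r$wm_mean),
               window_lo = unname(r$window[1]),
               window_hi = unname(r$window[2]),
               stringsAsFactors = FALSE)
  }))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(rows)
}
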