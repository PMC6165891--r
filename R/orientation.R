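#' Flip a volume along one voxel axis, preserving world-space anatomy
#'
#' Reverses the data grid along `axis` and updates the affine (column
#' negation plus translation shift) so every voxel center keeps its world
#' coordinate and intensity. Toggles the storage convention.
#'
#' @param v a [volume()].
#' @param axis voxel axis to flip, 1..3.
#' @return flipped [volume()].
#' @export
flip_axis <- function(v, axis) {
  stopifnot(is_volume(v), axis %in% 1:3)
  n <- dim(v$data)[axis]
  A <- v$affine
  A[1:3, 4] <- A[1:3, 4] + A[1:3, axis] * (n - 1)
  A[1:3, axis] <- -A[1:3, axis]
  idx <- rep(list(quote(expr = )), 3)
  idx[[axis]] <- n:1
  data <- do.call(`[`, c(list(v$data), idx, list(drop = FALSE)))
  out <- volume(data, A, role = v$role, path = v$path)
  out
}

# voxel axis whose affine column is dominant along world axis `world`
dominant_axis <- function(affine, world = 1L) {
  which.max(abs(affine[world, 1:3]))
}

#' Convert a volume to radiological storage convention
#'
#' If the volume is already radiological (negative spatial determinant) it is
#' returned unchanged — the convention is conserved. Otherwise the voxel axis
#' dominant along world left-right is flipped with the matching affine
#' update, so the intensity sampled at any world coordinate is unchanged.
#'
#' @param v a [volume()].
#' @return a radiological-convention [volume()].
#' @export
to_radiological <- function(v) {
  if (storage_convention(v) == "radiological") return(v)
  out <- flip_axis(v, dominant_axis(v$affine, 1L))
  out
}

#' Reorient a volume to canonical axis ordering
#'
#' Permutes and flips the voxel axes so the affine's spatial block is closest
#' to a diagonal matrix (per-column dominant world axis), with the second and
#' third diagonal entries positive and the first diagonal's sign chosen so
#' the storage convention is preserved. World-space anatomy is unchanged.
#' Ambiguous dominant axes (two equal-magnitude entries in a column) are
#' broken toward the lower world-axis index, with a warning.
#'
#' @param v a [volume()].
#' @return a canonical-axes [volume()] in the same convention.
#' @export
to_canonical <- function(v) {
  stopifnot(is_volume(v))
  conv <- storage_convention(v)
  S <- v$affine[1:3, 1:3]
  dom <- integer(3)
  for (j in 1:3) {
    a <- abs(S[, j])
    top <- which(a == max(a))
    if (length(top) > 1L)
      warning("ambiguous dominant axis for voxel axis ", j,
              "; tie broken toward the lower world-axis index",
              call. = FALSE)
    dom[j] <- top[1L]
  }
  if (anyDuplicated(dom))
    stop("invalid header: affine columns do not define a unique axis ",
         "permutation", call. = FALSE)
  perm <- order(dom)          # new voxel axis i <- old voxel axis perm[i]
  out <- v
  if (!identical(perm, 1:3)) {
    A <- out$affine
    A[, 1:3] <- A[, perm]
    # aperm takes the inverse permutation: order(perm) == dom
    out <- volume(aperm(out$data, order(perm)), A, role = v$role,
                  path = v$path)
  }
  for (ax in 2:3)
    if (out$affine[ax, ax] < 0) out <- flip_axis(out, ax)
  if (storage_convention(out) != conv) out <- flip_axis(out, 1L)
  out
}

#' Harmonize one subject's files to radiological convention
#'
#' Reads the subject's T1, lesion mask(s) and any optional brain/WM masks,
#' inspects each file's storage convention, and either (a) converts every
#' file to radiological convention and canonical axis ordering when all
#' files agree, or (b) flags the subject without touching any file when
#' conventions differ (or grids mismatch). Flagged subjects are excluded
#' from all later stages. If an optional input is missing while the run
#' requested skipping its producing stage, a skip override naming that stage
#' is recorded (the stage must then run for all subjects).
#'
#' @param subject a subject record from [discover_subjects()], or a list with
#'   `subject_id`, `t1_path`, `lesion_paths` and optional `brain_mask_path`,
#'   `wm_mask_path`.
#' @param out_dir if non-`NULL`, harmonized files are written under
#'   `out_dir/<subject>/Intermediate_Files/` with their original basenames.
#' @param skip_brain_extraction,skip_wm_segmentation whether the run asked to
#'   skip these stages (a missing optional file then forces an override).
#' @return An orientation report: list with `subject_id`,
#'   `per_file_convention` (named character), `flagged`, `flag_reason`,
#'   `actions` (named character, `"flipped"`/`"conserved"` plus
#'   `"reoriented-to-canonical"`), `skip_overrides` (character vector of
#'   stage names), and `volumes` (named list of harmonized [volume()]s,
#'   empty when flagged).
#' @export
harmonize_subject <- function(subject, out_dir = NULL,
                              skip_brain_extraction = FALSE,
                              skip_wm_segmentation = FALSE) {
  paths <- c(t1 = subject$t1_path,
             stats::setNames(subject$lesion_paths,
                             paste0("lesion", seq_along(subject$lesion_paths))))
  if (!is.null(subject$brain_mask_path) && length(subject$brain_mask_path) &&
      !is.na(subject$brain_mask_path) && nzchar(subject$brain_mask_path))
    paths <- c(paths, brain = subject$brain_mask_path)
  if (!is.null(subject$wm_mask_path) && length(subject$wm_mask_path) &&
      !is.na(subject$wm_mask_path) && nzchar(subject$wm_mask_path))
    paths <- c(paths, wm = subject$wm_mask_path)

  roles <- ifelse(names(paths) == "t1", "intensity", "mask")
  vols <- mapply(function(p, r) read_volume(p, role = r), paths, roles,
                 SIMPLIFY = FALSE)
  conv <- vapply(vols, storage_convention, character(1))
  names(conv) <- basename(paths)

  skip_overrides <- character(0)
  if (skip_brain_extraction && !("brain" %in% names(vols)))
    skip_overrides <- c(skip_overrides, "brain_extraction")
  if (skip_wm_segmentation && !("wm" %in% names(vols)))
    skip_overrides <- c(skip_overrides, "wm_segmentation")

  t1dim <- dim(vols[["t1"]]$data)
  shapes_ok <- vapply(vols, function(v) identical(dim(v$data), t1dim),
                      logical(1))

  report <- list(subject_id = subject$subject_id,
                 per_file_convention = conv,
                 flagged = FALSE, flag_reason = "",
                 actions = character(0),
                 skip_overrides = skip_overrides,
                 volumes = list())

  if (!all(shapes_ok)) {
    report$flagged <- TRUE
    report$flag_reason <- "shape-mismatch"
    return(report)
  }
  if (length(unique(conv)) > 1L) {
    report$flagged <- TRUE
    report$flag_reason <- "orientation-mismatch"
    return(report)
  }

  actions <- character(length(vols))
  names(actions) <- basename(paths)
  out_vols <- vols
  for (i in seq_along(vols)) {
    conserved <- storage_convention(vols[[i]]) == "radiological"
    h <- to_canonical(to_radiological(vols[[i]]))
    actions[i] <- paste0(if (conserved) "conserved" else "flipped",
                         "+reoriented-to-canonical")
    out_vols[[i]] <- h
  }
  report$actions <- actions
  report$volumes <- out_vols

  if (!is.null(out_dir)) {
    dest <- file.path(out_dir, subject$subject_id, "Intermediate_Files")
    dir.create(dest, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(out_vols))
      write_volume(out_vols[[i]], file.path(dest, basename(paths[i])))
  }
  report
}

#' Write the flagged-subjects table
#'
#' One row per (subject, file) for every flagged subject, recording the
#' per-file storage conventions and the flag reason, so flagged data can be
#' checked by hand as recommended.
#'
#' @param reports list of reports from [harmonize_subject()].
#' @param path output CSV path.
#' @return the data frame written, invisibly.
#' @export
write_flagged_report <- function(reports, path) {
  rows <- do.call(rbind, lapply(reports, function(r) {
    if (!isTRUE(r$flagged)) return(NULL)
    if (length(r$per_file_convention) == 0L)
      return(data.frame(subject_id = r$subject_id, file = "",
                        convention = "", reason = r$flag_reason,
                        stringsAsFactors = FALSE))
    data.frame(subject_id = r$subject_id,
               file = names(r$per_file_convention),
               convention = unname(r$per_file_convention),
               reason = r$flag_reason, stringsAsFactors = FALSE)
  }))
  if (is.null(rows))
    rows <- data.frame(subject_id = character(0), file = character(0),
                       convention = character(0), reason = character(0))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(rows)
}
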