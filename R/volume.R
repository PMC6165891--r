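#' In-memory 3-D volume
#'
#' The unit every module consumes and produces: a 3-D scalar grid plus the
#' 4x4 voxel-index-to-world (mm) affine that places it in space. Voxel
#' indices are 0-based in the affine convention (world = affine %*%
#' c(i, j, k, 1) with i, j, k starting at 0), matching the NIfTI standard.
#' Mask-role volumes hold only 0/1.
#'
#' @param data numeric 3-D array.
#' @param affine numeric 4x4 matrix; the upper-left 3x3 spatial block must be
#'   nonsingular and the last row `c(0, 0, 0, 1)`.
#' @param role `"intensity"` or `"mask"`. Masks are binarized (values > 0
#'   map to 1).
#' @param path provenance string (source file), or `""`.
#' @return An object of class `volume`: a list with elements `data`,
#'   `affine`, `role`, `path`.
#' @examples
#' v <- volume(array(rnorm(8), c(2, 2, 2)), diag(4))
#' dim(v$data)
#' @export
volume <- function(data, affine = diag(4), role = c("intensity", "mask"),
                   path = "") {
  role <- match.arg(role)
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop("volume data must be a 3-D array, got ", length(dim(data)),
         " dimensions", call. = FALSE)
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)))
    stop("affine must be a 4x4 matrix", call. = FALSE)
  if (!isTRUE(all.equal(affine[4, ], c(0, 0, 0, 1))))
    stop("last affine row must be (0, 0, 0, 1)", call. = FALSE)
  if (abs(det(affine[1:3, 1:3])) < .Machine$double.eps * 16)
    stop("invalid header: singular spatial affine block", call. = FALSE)
  storage.mode(data) <- "double"
  if (role == "mask") {
    data <- (data > 0) + 0
  }
  structure(list(data = data, affine = affine, role = role, path = path),
            class = "volume")
}

#' @export
print.volume <- function(x, ...) {
  cat(sprintf("<volume> %s  %s  %s\n",
              paste(dim(x$data), collapse = "x"), x$role,
              as.character(storage_convention(x))))
  if (nzchar(x$path)) cat("  path:", x$path, "\n")
  cat("  affine:\n")
  print(unname(x$affine))
  invisible(x)
}

is_volume <- function(x) inherits(x, "volume")

#' Volume grid shape
#' @param v a [volume()].
#' @return integer vector `(nx, ny, nz)`.
#' @export
vol_shape <- function(v) dim(v$data)

same_grid <- function(a, b, tol = 1e-4) {
  identical(dim(a$data), dim(b$data)) &&
    max(abs(a$affine - b$affine)) <= tol
}

stop_grid_mismatch <- function(a, b, what = "volumes") {
  if (!same_grid(a, b))
    stop(what, " are not on the same voxel grid (shape/affine mismatch)",
         call. = FALSE)
  invisible(TRUE)
}

#' Read a NIfTI-1 volume
#'
#' Reads a `.nii` or `.nii.gz` file into a [volume()]. The affine is taken
#' from the header's preferred spatial transform: the sform when its code is
#' nonzero, else the qform, else a pixdim-scaled identity. When both forms
#' are present but disagree, a warning is emitted and the sform is used;
#' no repair is attempted.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param role `"intensity"` or `"mask"`; masks are binarized on read
#'   (values > 0 map to 1).
#' @return A [volume()]; the attribute `"xform_used"` records which header
#'   transform supplied the affine (`"sform"`, `"qform"` or `"fallback"`).
#' @export
read_volume <- function(path, role = c("intensity", "mask")) {
  role <- match.arg(role)
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e)
                    stop("not a readable NIfTI-1 file: ", path, " (",
                         conditionMessage(e), ")", call. = FALSE))
  arr <- array(as.double(img), dim = dim(img))
  nd <- length(dim(arr))
  if (nd == 4L && dim(arr)[4] == 1L) {
    arr <- arr[, , , 1L, drop = TRUE]
  } else if (nd != 3L) {
    stop("expected a 3-D volume, got ", nd, " dimensions in ", path,
         call. = FALSE)
  }
  hdr <- RNifti::niftiHeader(img)
  sform <- rbind(hdr$srow_x, hdr$srow_y, hdr$srow_z, c(0, 0, 0, 1))
  qform <- unclass(RNifti::xform(img, useQuaternionFirst = TRUE))
  qform <- rbind(qform[1:3, , drop = FALSE], c(0, 0, 0, 1))
  if (hdr$sform_code > 0L) {
    affine <- sform
    used <- "sform"
    if (hdr$qform_code > 0L && max(abs(sform - qform)) > 1e-3)
      warning("inconsistent qform/sform in ", path,
              "; using the sform (no repair attempted)", call. = FALSE)
  } else if (hdr$qform_code > 0L) {
    affine <- qform
    used <- "qform"
  } else {
    affine <- diag(c(abs(hdr$pixdim[2:4]), 1))
    used <- "fallback"
  }
  if (abs(det(affine[1:3, 1:3])) < .Machine$double.eps * 16)
    stop("invalid header: singular spatial affine in ", path, call. = FALSE)
  v <- volume(arr, affine, role = role, path = path)
  attr(v, "xform_used") <- used
  v
}

#' Write a volume to NIfTI-1
#'
#' Masks are stored as uint8, intensity volumes as float64, so a write/read
#' round trip reproduces `data` exactly. Both the sform and qform are set to
#' the volume's affine (codes 2), preserving the storage convention. `.gz`
#' suffix selects gzip compression.
#'
#' @param v a [volume()].
#' @param path destination `.nii` or `.nii.gz` path; the parent directory is
#'   created if needed.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  stopifnot(is_volume(v))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dirname(path)))
    stop("cannot create directory for ", path, call. = FALSE)
  sp <- v$affine[1:3, 1:3]
  pd <- sqrt(colSums(sp^2))
  img <- RNifti::asNifti(v$data, list(pixdim = c(1, pd, 0, 0, 0, 0)))
  img <- RNifti::`sform<-`(img, structure(v$affine, code = 2L))
  img <- RNifti::`qform<-`(img, structure(v$affine, code = 2L))
  dtype <- if (v$role == "mask") "uint8" else "double"
  RNifti::writeNifti(img, path, datatype = dtype)
  invisible(path)
}

#' Storage convention of a volume
#'
#' Radiological storage puts the patient's left on the right of the displayed
#' image; neurological storage puts left on the left. At the header level the
#' criterion is the sign of the determinant of the affine's 3x3 spatial
#' block: negative = radiological, positive = neurological.
#'
#' @param v a [volume()].
#' @return `"radiological"` or `"neurological"`.
#' @export
storage_convention <- function(v) {
  stopifnot(is_volume(v))
  d <- det(v$affine[1:3, 1:3])
  if (abs(d) < .Machine$double.eps * 16)
    stop("invalid header: singular spatial affine block", call. = FALSE)
  if (d < 0) "radiological" else "neurological"
}

#' World coordinates of voxel centers
#'
#' @param v a [volume()].
#' @param idx0 n x 3 matrix of 0-based voxel indices.
#' @return n x 3 matrix of world (mm) coordinates.
#' @keywords internal
voxel_to_world <- function(v, idx0) {
  idx0 <- matrix(idx0, ncol = 3)
  t(v$affine %*% rbind(t(idx0), 1))[, 1:3, drop = FALSE]
}
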