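# Affine registration stand-in for the pipeline's normalization step:
# 12-parameter (translation, rotation, log-scale, shear) transform maximizing
# normalized cross-correlation, multi-resolution coarse-to-fine, derivative-
# free coordinate descent with fixed parameter ordering (deterministic, no
# RNG). Not numerically equivalent to any external registration tool.

rot3 <- function(rx, ry, rz) {
  Rx <- matrix(c(1, 0, 0, 0, cos(rx), sin(rx), 0, -sin(rx), cos(rx)), 3, 3)
  Ry <- matrix(c(cos(ry), 0, -sin(ry), 0, 1, 0, sin(ry), 0, cos(ry)), 3, 3)
  Rz <- matrix(c(cos(rz), sin(rz), 0, -sin(rz), cos(rz), 0, 0, 0, 1), 3, 3)
  Rx %*% Ry %*% Rz
}

# params: t(1:3) mm, rot(4:6) rad, log-scale(7:9), shear(10:12)
# returns moving-world -> fixed-world 4x4, rotating/scaling about `center`
params_to_affine <- function(p, center = c(0, 0, 0)) {
  R <- rot3(p[4], p[5], p[6])
  S <- diag(exp(p[7:9]))
  H <- diag(3)
  H[1, 2] <- p[10]; H[1, 3] <- p[11]; H[2, 3] <- p[12]
  L <- R %*% S %*% H
  M <- diag(4)
  M[1:3, 1:3] <- L
  M[1:3, 4] <- center + p[1:3] - L %*% center
  M
}

# 0-based voxel coords (3 x n) of all grid points of a volume
grid_points0 <- function(dims) {
  i <- seq_len(dims[1]) - 1
  j <- seq_len(dims[2]) - 1
  k <- seq_len(dims[3]) - 1
  rbind(rep(i, times = dims[2] * dims[3]),
        rep(rep(j, each = dims[1]), times = dims[3]),
        rep(k, each = dims[1] * dims[2]))
}

# sample volume at 0-based voxel coords (3 x n); outside -> 0
sample_at <- function(data, pts, interp = c("linear", "nearest")) {
  interp <- match.arg(interp)
  d <- dim(data)
  n <- ncol(pts)
  out <- numeric(n)
  if (interp == "nearest") {
    x <- round(pts[1, ]); y <- round(pts[2, ]); z <- round(pts[3, ])
    ok <- x >= 0 & x <= d[1] - 1 & y >= 0 & y <= d[2] - 1 &
      z >= 0 & z <= d[3] - 1
    li <- 1 + x[ok] + y[ok] * d[1] + z[ok] * d[1] * d[2]
    out[ok] <- data[li]
    return(out)
  }
  x0 <- floor(pts[1, ]); y0 <- floor(pts[2, ]); z0 <- floor(pts[3, ])
  fx <- pts[1, ] - x0; fy <- pts[2, ] - y0; fz <- pts[3, ] - z0
  ok <- x0 >= 0 & x0 <= d[1] - 2 & y0 >= 0 & y0 <= d[2] - 2 &
    z0 >= 0 & z0 <= d[3] - 2
  # boundary voxels that land exactly on the last plane
  edge <- !ok & pts[1, ] >= 0 & pts[1, ] <= d[1] - 1 &
    pts[2, ] >= 0 & pts[2, ] <= d[2] - 1 & pts[3, ] >= 0 & pts[3, ] <= d[3] - 1
  if (any(edge)) {
    xe <- pmin(x0[edge], d[1] - 2); ye <- pmin(y0[edge], d[2] - 2)
    ze <- pmin(z0[edge], d[3] - 2)
    x0[edge] <- xe; y0[edge] <- ye; z0[edge] <- ze
    fx[edge] <- pts[1, edge] - xe; fy[edge] <- pts[2, edge] - ye
    fz[edge] <- pts[3, edge] - ze
    ok <- ok | edge
  }
  if (!any(ok)) return(out)
  x0 <- x0[ok]; y0 <- y0[ok]; z0 <- z0[ok]
  fx <- fx[ok]; fy <- fy[ok]; fz <- fz[ok]
  nx <- d[1]; nxy <- d[1] * d[2]
  l000 <- 1 + x0 + y0 * nx + z0 * nxy
  v <- data[l000] * (1 - fx) * (1 - fy) * (1 - fz) +
    data[l000 + 1] * fx * (1 - fy) * (1 - fz) +
    data[l000 + nx] * (1 - fx) * fy * (1 - fz) +
    data[l000 + nx + 1] * fx * fy * (1 - fz) +
    data[l000 + nxy] * (1 - fx) * (1 - fy) * fz +
    data[l000 + nxy + 1] * fx * (1 - fy) * fz +
    data[l000 + nxy + nx] * (1 - fx) * fy * fz +
    data[l000 + nxy + nx + 1] * fx * fy * fz
  out[ok] <- v
  out
}

# intensity-weighted center of mass and per-axis spread, world coordinates
world_moments <- function(v) {
  w <- v$data - min(v$data)
  thr <- max(w) * 0.1
  sel <- which(w > thr)
  if (length(sel) == 0L) sel <- seq_along(w)
  d <- dim(v$data)
  idx <- arrayInd(sel, d) - 1
  wts <- w[sel] / sum(w[sel])
  wpts <- voxel_to_world(v, idx)
  com <- colSums(wpts * wts)
  spread <- sqrt(colSums((wpts - rep(com, each = nrow(wpts)))^2 * wts))
  list(com = com, spread = pmax(spread, 1e-6))
}

# block-mean downsample by integer factor (anti-aliased; affine kept in sync:
# the new voxel center is the mean of the f^3 merged centers)
downsample <- function(v, f) {
  if (f == 1L) return(v)
  d <- dim(v$data)
  nd <- pmax(d %/% f, 1L)
  a <- v$data[seq_len(nd[1] * f), seq_len(nd[2] * f), seq_len(nd[3] * f),
              drop = FALSE]
  dim(a) <- c(f, nd[1], f, nd[2], f, nd[3])
  a <- apply(a, c(2, 4, 6), mean)
  A <- v$affine
  A[1:3, 4] <- A[1:3, 4] + A[1:3, 1:3] %*% rep((f - 1) / 2, 3)
  A[1:3, 1:3] <- A[1:3, 1:3] * f
  volume(a, A, role = "intensity", path = v$path)
}

# bounding box (0-based index ranges) of nonzero fixed voxels, padded
nonzero_bbox <- function(v, pad = 2L) {
  w <- v$data - min(v$data)
  sel <- which(w > max(w) * 0.05)
  if (length(sel) == 0L) sel <- seq_along(w)
  idx <- arrayInd(sel, dim(v$data))
  lo <- pmax(apply(idx, 2, min) - pad, 1L)
  hi <- pmin(apply(idx, 2, max) + pad, dim(v$data))
  list(lo = lo, hi = hi)
}

ncc <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(-1)
  stats::cor(a, b)
}

#' Estimate an affine transform between two volumes
#'
#' Fits a 12-parameter affine (translation, rotation, anisotropic scale,
#' shear) taking `moving`'s world space onto `fixed`'s world space by
#' maximizing normalized cross-correlation over the fixed image's nonzero
#' bounding box. Three-level multiresolution (subsampling x4, x2, x1),
#' initialized by center-of-mass alignment and spread-ratio scale, optimized
#' by derivative-free coordinate descent with a fixed parameter ordering —
#' fully deterministic.
#'
#' @param moving,fixed intensity [volume()]s with nondegenerate intensities.
#' @param levels integer subsampling factors, coarse to fine.
#' @param max_iter per-level sweep caps.
#' @param init_scale initialize per-axis log-scale from intensity-spread
#'   ratios?
#' @return An `affine_transform`: list with `matrix` (4x4 moving-world to
#'   fixed-world), `dof = 12`, `similarity_score` (final full-resolution
#'   NCC), `converged`, `params`.
#' @export
register_affine <- function(moving, fixed, levels = c(4L, 2L, 1L),
                            max_iter = c(100L, 50L, 25L),
                            init_scale = TRUE) {
  stopifnot(is_volume(moving), is_volume(fixed))
  if (stats::sd(moving$data) == 0 || stats::sd(fixed$data) == 0)
    stop("registration metric undefined for a constant image", call. = FALSE)
  mm <- world_moments(moving)
  mf <- world_moments(fixed)
  p <- numeric(12)
  p[1:3] <- mf$com - mm$com
  if (init_scale)
    p[7:9] <- pmin(pmax(log(mf$spread / mm$spread), -0.3), 0.3)
  center <- mf$com
  converged <- FALSE

  for (li in seq_along(levels)) {
    f <- levels[li]
    fx <- downsample(fixed, f)
    mv <- downsample(moving, f)
    bb <- nonzero_bbox(fx)
    ii <- (bb$lo[1]:bb$hi[1]) - 1; jj <- (bb$lo[2]:bb$hi[2]) - 1
    kk <- (bb$lo[3]:bb$hi[3]) - 1
    pts_vox <- rbind(rep(ii, times = length(jj) * length(kk)),
                     rep(rep(jj, each = length(ii)), times = length(kk)),
                     rep(kk, each = length(ii) * length(jj)))
    fvals <- fx$data[bb$lo[1]:bb$hi[1], bb$lo[2]:bb$hi[2], bb$lo[3]:bb$hi[3]]
    fvals <- as.vector(fvals)
    pts_world <- fx$affine %*% rbind(pts_vox, 1)
    Ainv <- solve(mv$affine)
    cost <- function(par) {
      M <- params_to_affine(par, center)          # moving -> fixed world
      ptm <- Ainv %*% solve(M) %*% pts_world      # fixed grid -> moving vox
      ncc(fvals, sample_at(mv$data, ptm[1:3, , drop = FALSE], "linear"))
    }
    vox <- min(sqrt(colSums(fx$affine[1:3, 1:3]^2)))
    steps <- c(rep(vox, 3), rep(0.04, 3), rep(0.04, 3), rep(0.02, 3))
    tolv <- c(rep(vox / 8, 3), rep(0.002, 3), rep(0.002, 3), rep(0.001, 3))
    best <- cost(p)
    converged <- FALSE
    for (it in seq_len(max_iter[li])) {
      improved <- FALSE
      for (k in 1:12) {
        for (sgn in c(1, -1)) {
          cand <- p
          cand[k] <- cand[k] + sgn * steps[k]
          val <- cost(cand)
          if (val > best + 1e-9) {
            best <- val
            p <- cand
            improved <- TRUE
          }
        }
      }
      if (!improved) {
        steps <- steps / 2
        if (all(steps < tolv)) { converged <- TRUE; break }
      }
    }
    score <- best
  }
  res <- list(matrix = params_to_affine(p, center), dof = 12L,
              similarity_score = score, converged = converged, params = p)
  class(res) <- "affine_transform"
  res
}

#' Identity affine transform
#' @param score optional similarity score to record.
#' @return an `affine_transform` with an identity matrix.
#' @export
identity_transform <- function(score = NA_real_) {
  res <- list(matrix = diag(4), dof = 12L, similarity_score = score,
              converged = TRUE, params = numeric(12))
  class(res) <- "affine_transform"
  res
}

#' @export
print.affine_transform <- function(x, ...) {
  cat(sprintf("<affine_transform> dof=%d NCC=%.4f converged=%s\n",
              x$dof, x$similarity_score, x$converged))
  print(unname(x$matrix))
  invisible(x)
}

as_transform_matrix <- function(t) {
  m <- if (inherits(t, "affine_transform")) t$matrix else as.matrix(t)
  if (!all(dim(m) == c(4, 4)))
    stop("transform must be a 4x4 matrix or affine_transform", call. = FALSE)
  if (abs(det(m[1:3, 1:3])) < .Machine$double.eps * 16)
    stop("singular transform", call. = FALSE)
  m
}

#' Resample a volume onto another volume's grid through a transform
#'
#' Samples `v` on `grid_of`'s voxel grid through the world-to-world transform
#' `t` (mapping `v`'s world space to `grid_of`'s world space). Mask-role
#' volumes must use nearest-neighbour interpolation so they remain binary.
#' When `t` is the identity and the grids already coincide, `v` is returned
#' unchanged (identity shortcut).
#'
#' @param v [volume()] to resample.
#' @param t an `affine_transform` or 4x4 matrix (v-world to grid_of-world).
#' @param grid_of [volume()] supplying the target grid (shape + affine).
#' @param interp `"linear"` or `"nearest"`.
#' @return [volume()] on `grid_of`'s grid.
#' @export
resample_to <- function(v, t, grid_of, interp = c("linear", "nearest")) {
  interp <- match.arg(interp)
  stopifnot(is_volume(v), is_volume(grid_of))
  if (v$role == "mask" && interp == "linear")
    stop("linear interpolation requested for a mask-role volume; use ",
         "interp = \"nearest\"", call. = FALSE)
  m <- as_transform_matrix(t)
  if (max(abs(m - diag(4))) < 1e-10 && same_grid(v, grid_of, tol = 0))
    return(v)
  pts <- grid_points0(dim(grid_of$data))
  ptm <- solve(v$affine) %*% solve(m) %*% grid_of$affine %*% rbind(pts, 1)
  vals <- sample_at(v$data, ptm[1:3, , drop = FALSE], interp)
  volume(array(vals, dim(grid_of$data)), grid_of$affine, role = v$role,
         path = v$path)
}

#' Write / read a 4x4 transform as a whitespace-separated text file
#'
#' The on-disk convention for `<subject>_to_template.mat` files: four lines
#' of four numbers, world (mm) to world (mm).
#'
#' @param t an `affine_transform` or 4x4 matrix.
#' @param path destination path.
#' @return `path` (write) / an `affine_transform` (read).
#' @export
write_transform <- function(t, path) {
  m <- as_transform_matrix(t)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  writeLines(apply(m, 1, function(r)
    paste(formatC(r, digits = 17, format = "g"), collapse = " ")), path)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  m <- as.matrix(utils::read.table(path))
  if (!all(dim(m) == c(4, 4)))
    stop("transform file must contain a 4x4 matrix: ", path, call. = FALSE)
  res <- list(matrix = unname(m), dof = 12L, similarity_score = NA_real_,
              converged = NA, params = NULL)
  class(res) <- "affine_transform"
  res
}
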