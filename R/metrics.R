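#' Dice similarity coefficient
#'
#' `DC = 2|X n Y| / (|X| + |Y|)`, ranging from 0 (no overlap) to 1 (complete
#' overlap), where X and Y are the voxel sets of two binary masks on a common
#' grid.
#'
#' @param x,y binary mask [volume()]s on the same grid.
#' @return scalar in `[0, 1]`; an error if both masks are empty (the metric
#'   is undefined).
#' @export
dice <- function(x, y) {
  stopifnot(is_volume(x), is_volume(y))
  stop_grid_mismatch(x, y, "masks")
  nx <- sum(x$data > 0)
  ny <- sum(y$data > 0)
  if (nx + ny == 0L)
    stop("Dice coefficient undefined: both masks are empty", call. = FALSE)
  2 * sum(x$data > 0 & y$data > 0) / (nx + ny)
}

#' Pairwise inter-rater Dice matrix
#'
#' Dice coefficients for all unordered pairs among `n` tracers' masks of the
#' same lesion, with the mean and its standard error over the `n(n-1)/2`
#' pairs (the granularity at which inter-rater agreement is usually
#' reported; note the pairs are not independent, so the SEM is descriptive).
#'
#' @param masks list of >= 2 binary mask [volume()]s on a common grid.
#' @param ids optional tracer identifiers (default `tracer1..n`).
#' @return A `pairwise_dice`: list with `tracer_ids`, `matrix` (symmetric,
#'   unit diagonal), `pairs` (long-format data frame), `mean_dc`, `sem`.
#' @export
pairwise_dice <- function(masks, ids = NULL) {
  n <- length(masks)
  if (n < 2L) stop("need at least 2 masks", call. = FALSE)
  if (is.null(ids)) ids <- paste0("tracer", seq_len(n))
  for (i in seq_len(n)) {
    if (!same_grid(masks[[1]], masks[[i]]))
      stop("mask ", ids[i], " is not on the common grid", call. = FALSE)
  }
  m <- diag(1, n)
  rows <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- dice(masks[[i]], masks[[j]])
      m[i, j] <- m[j, i] <- d
      rows[[length(rows) + 1L]] <- data.frame(
        tracer_a = ids[i], tracer_b = ids[j], dc = d,
        stringsAsFactors = FALSE)
    }
  }
  pairs <- do.call(rbind, rows)
  dimnames(m) <- list(ids, ids)
  res <- list(tracer_ids = ids, matrix = m, pairs = pairs,
              mean_dc = mean(pairs$dc),
              sem = stats::sd(pairs$dc) / sqrt(nrow(pairs)))
  class(res) <- "pairwise_dice"
  res
}

#' @export
print.pairwise_dice <- function(x, ...) {
  cat(sprintf("<pairwise_dice> %d tracers, %d pairs: mean DC %.4f (SEM %.4f)\n",
              length(x$tracer_ids), nrow(x$pairs), x$mean_dc, x$sem))
  invisible(x)
}

#' Inter-tracer overlap heat map
#'
#' Voxelwise count of how many masks include each voxel (range `[0, n]`),
#' the volume behind inter-tracer agreement heat maps.
#'
#' @param masks list of >= 2 binary mask [volume()]s on a common grid.
#' @return integer-valued [volume()] (role `"intensity"`).
#' @export
overlap_heatmap <- function(masks) {
  n <- length(masks)
  if (n < 2L) stop("need at least 2 masks", call. = FALSE)
  acc <- array(0, dim(masks[[1]]$data))
  for (i in seq_len(n)) {
    if (!same_grid(masks[[1]], masks[[i]]))
      stop("mask ", i, " is not on the common grid", call. = FALSE)
    acc <- acc + (masks[[i]]$data > 0)
  }
  volume(acc, masks[[1]]$affine, role = "intensity")
}

#' Write the inter-rater report CSV
#'
#' @param results named list: lesion id -> `pairwise_dice`.
#' @param path output CSV path.
#' @param long also append one row per tracer pair?
#' @return the data frame written, invisibly.
#' @export
write_interrater_report <- function(results, path, long = FALSE) {
  rows <- do.call(rbind, lapply(names(results), function(id) {
    r <- results[[id]]
    data.frame(lesion_id = id, n_tracers = length(r$tracer_ids),
               tracer_a = NA_character_, tracer_b = NA_character_,
               mean_dc = r$mean_dc, sem = r$sem, dc = NA_real_,
               stringsAsFactors = FALSE)
  }))
  if (long) {
    rows <- rbind(rows, do.call(rbind, lapply(names(results), function(id) {
      p <- results[[id]]$pairs
      data.frame(lesion_id = id, n_tracers = length(results[[id]]$tracer_ids),
                 tracer_a = p$tracer_a, tracer_b = p$tracer_b,
                 mean_dc = NA_real_, sem = NA_real_, dc = p$dc,
                 stringsAsFactors = FALSE)
    })))
  }
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(rows)
}
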