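# Visual QC: tri-planar overlay screenshots, per-stage HTML review galleries,
# and the pass/fail review records that gate downstream stages. The
# authoritative review state is the review CSV, not the HTML checkboxes (the
# page is a display aid; there is no server behind it).

# one 2-D slice of a 3-D array, oriented for display (first axis -> columns,
# second/third -> rows bottom-up)
slice2d <- function(a, plane, idx) {
  s <- switch(plane,
              axial = a[, , idx],
              coronal = a[, idx, ],
              sagittal = a[idx, , ])
  t(s)[rev(seq_len(ncol(s))), , drop = FALSE]
}

mask_centroid <- function(mask) {
  sel <- which(mask$data > 0)
  if (length(sel) == 0L) return(NULL)
  idx <- arrayInd(sel, dim(mask$data))
  round(colMeans(idx))
}

#' Render a tri-planar overlay screenshot
#'
#' One raster image with axial, coronal and sagittal slices through the
#' focus point, the base volume in grayscale and each overlay mask
#' alpha-blended in its stated color.
#'
#' @param base intensity [volume()] (nonempty).
#' @param overlays list of `list(mask = <volume>, color = <R color>)`;
#'   may be empty for a plain anatomical tri-planar.
#' @param path output PNG path.
#' @param focus `"mask_centroid"` (slices through the first overlay's
#'   centroid; the default when an overlay exists) or `"center"`.
#' @param alpha overlay opacity in `[0, 1]`.
#' @return `path`, invisibly; the attribute `"focus_voxel"` records the
#'   1-based slice indices used.
#' @export
render_triplanar <- function(base, overlays = list(), path,
                             focus = c("mask_centroid", "center"),
                             alpha = 0.5) {
  stopifnot(is_volume(base))
  focus <- match.arg(focus)
  if (all(base$data == 0) && length(base$data) == 0)
    stop("empty base volume", call. = FALSE)
  for (ov in overlays)
    stop_grid_mismatch(base, ov$mask, "base and overlay")
  d <- dim(base$data)
  fv <- NULL
  if (focus == "mask_centroid" && length(overlays) > 0)
    fv <- mask_centroid(overlays[[1]]$mask)
  if (is.null(fv)) fv <- round((d + 1) / 2)

  r <- range(base$data)
  g <- if (diff(r) == 0) array(0, d) else (base$data - r[1]) / diff(r)

  panels <- lapply(list(c("sagittal", 1), c("coronal", 2), c("axial", 3)),
                   function(pl) {
    plane <- pl[[1]]; ax <- as.integer(pl[[2]])
    gs <- slice2d(g, plane, fv[ax])
    img <- array(rep(gs, 3), c(dim(gs), 3))
    for (ov in overlays) {
      ms <- slice2d(ov$mask$data, plane, fv[ax]) > 0
      if (!any(ms)) next
      rgb <- grDevices::col2rgb(ov$color)[, 1] / 255
      for (ch in 1:3) {
        chan <- img[, , ch]
        chan[ms] <- (1 - alpha) * chan[ms] + alpha * rgb[ch]
        img[, , ch] <- chan
      }
    }
    img
  })
  h <- max(vapply(panels, function(p) dim(p)[1], integer(1)))
  w <- sum(vapply(panels, function(p) dim(p)[2], integer(1))) +
    2L * (length(panels) - 1L)
  canvas <- array(0, c(h, w, 3))
  x <- 1L
  for (p in panels) {
    dp <- dim(p)
    y0 <- floor((h - dp[1]) / 2)
    canvas[y0 + seq_len(dp[1]), x + seq_len(dp[2]) - 1L, ] <- p
    x <- x + dp[2] + 2L
  }
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  png::writePNG(canvas, path)
  out <- invisible(path)
  attr(out, "focus_voxel") <- fv
  out
}

review_csv_path <- function(out_dir, stage) {
  file.path(out_dir, paste0(stage, "_review.csv"))
}

#' Build an HTML review gallery for one pipeline stage
#'
#' Concatenates per-subject screenshots into a single HTML page with a
#' checkbox and note field under each, and writes a blank review CSV
#' (`subject_id, passed, note`) beside it for the user to fill. An existing
#' review CSV with any filled `passed` entries is never clobbered: the
#' gallery refuses to overwrite it and says so.
#'
#' @param stage stage name (used in the page title and CSV name).
#' @param entries data frame with columns `subject_id`, `image` (paths to
#'   PNGs; copied/referenced relative to `out_dir` when inside it).
#' @param out_dir gallery directory (created if needed).
#' @return path of the `index.html` written, invisibly.
#' @export
build_gallery <- function(stage, entries, out_dir) {
  if (NROW(entries) < 1L) stop("no gallery entries", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir))
    stop("cannot create gallery directory ", out_dir, call. = FALSE)
  rel <- vapply(entries$image, function(p) {
    if (startsWith(normalizePath(p, mustWork = FALSE),
                   normalizePath(out_dir, mustWork = FALSE)))
      basename(p) else p
  }, character(1))
  html <- c(
    "<!DOCTYPE html>",
    "<html><head><meta charset=\"utf-8\">",
    sprintf("<title>QC review: %s</title>", stage),
    "<style>body{font-family:sans-serif;background:#111;color:#eee}",
    "img{max-width:95%;border:1px solid #444}",
    "section{margin-bottom:2em;border-bottom:1px solid #333}</style>",
    "</head><body>",
    sprintf("<h1>QC review: %s</h1>", stage),
    sprintf("<p>%d subjects. Record pass/fail in <code>%s_review.csv</code>;",
            NROW(entries), stage),
    "the CSV, not these checkboxes, gates downstream stages.</p>")
  for (i in seq_len(NROW(entries))) {
    sid <- entries$subject_id[i]
    html <- c(html,
      "<section>",
      sprintf("<h2>%s</h2>", sid),
      sprintf("<img src=\"%s\" alt=\"%s\">", rel[i], sid),
      sprintf(paste0("<p><label><input type=\"checkbox\" name=\"pass_%s\"> ",
                     "passes visual inspection</label> "), sid),
      sprintf("<input type=\"text\" name=\"note_%s\" placeholder=\"note\"></p>",
              sid),
      "</section>")
  }
  html <- c(html, "</body></html>")
  index <- file.path(out_dir, "index.html")
  writeLines(html, index)

  csv <- review_csv_path(out_dir, stage)
  write_blank <- TRUE
  if (file.exists(csv)) {
    old <- utils::read.csv(csv, colClasses = "character")
    if (any(nzchar(trimws(old$passed)))) {
      message("review CSV ", csv, " already contains decisions; not ",
              "overwriting it")
      write_blank <- FALSE
    }
  }
  if (write_blank)
    utils::write.csv(data.frame(subject_id = entries$subject_id,
                                passed = "", note = "",
                                stringsAsFactors = FALSE),
                     csv, row.names = FALSE)
  invisible(index)
}

parse_pass <- function(x) {
  x <- tolower(trimws(x))
  ifelse(x %in% c("true", "t", "1", "pass", "yes", "y"), TRUE,
         ifelse(x %in% c("false", "f", "0", "fail", "no", "n"), FALSE, NA))
}

#' Apply a filled review CSV as a stage gate
#'
#' Parses the stage's review CSV into pass/fail decisions. In interactive
#' mode (an R session at a terminal) the call blocks, re-prompting until
#' every row is filled; in non-interactive / no-pause runs, blank rows
#' default to passed with a logged warning — users are still encouraged to
#' inspect every stage after completion.
#'
#' @param stage stage name.
#' @param review_csv path to the review CSV.
#' @param subjects optional character vector of subject ids expected at this
#'   stage; rows for unknown subjects raise a validation error.
#' @param interactive block until all rows are filled? (Only honored when
#'   the session itself is interactive.)
#' @return A `review_record`: list with `stage` and `decisions` (data frame
#'   `subject_id`, `passed`, `note`).
#' @export
apply_review <- function(stage, review_csv, subjects = NULL,
                         interactive = FALSE) {
  if (!file.exists(review_csv))
    stop("review CSV not found: ", review_csv, call. = FALSE)
  read_it <- function() {
    df <- utils::read.csv(review_csv, colClasses = "character")
    df$passed_parsed <- parse_pass(df$passed)
    df
  }
  df <- read_it()
  if (!is.null(subjects)) {
    unknown <- setdiff(df$subject_id, subjects)
    if (length(unknown))
      stop("review CSV ", review_csv, " names unknown subject(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }
  while (interactive && base::interactive() && anyNA(df$passed_parsed)) {
    readline(sprintf(
      "Stage '%s': fill the 'passed' column of %s, then press Enter... ",
      stage, review_csv))
    df <- read_it()
  }
  if (anyNA(df$passed_parsed)) {
    warning(sum(is.na(df$passed_parsed)), " unreviewed subject(s) at stage '",
            stage, "' default to passed; visual inspection after completion ",
            "is highly encouraged", call. = FALSE)
    df$passed_parsed[is.na(df$passed_parsed)] <- TRUE
  }
  res <- list(stage = stage,
              decisions = data.frame(subject_id = df$subject_id,
                                     passed = df$passed_parsed,
                                     note = df$note,
                                     stringsAsFactors = FALSE))
  class(res) <- "review_record"
  res
}

#' Subjects passing a review
#' @param record a `review_record` from [apply_review()].
#' @return character vector of passing subject ids.
#' @export
passing_subjects <- function(record) {
  record$decisions$subject_id[record$decisions$passed]
}

#' Stand-alone lesion visualization
#'
#' Renders a lesion-over-T1 gallery for every subject in an input directory
#' with no other processing — the QC feature as a stand-alone tool.
#'
#' @param input_dir input directory (see [discover_subjects()]).
#' @param out_dir output directory for the gallery.
#' @param t1_id,lesion_id filename identifiers.
#' @return path of the gallery `index.html`, invisibly.
#' @export
visualize_lesions <- function(input_dir, out_dir, t1_id = "T1",
                              lesion_id = "Lesion") {
  cfg <- run_config(input_dir = input_dir, output_dir = out_dir,
                    t1_identifier = t1_id, lesion_identifier = lesion_id,
                    modules = "qc", force = TRUE)
  subs <- discover_subjects(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  gdir <- file.path(out_dir, "QC_Lesions")
  entries <- list()
  for (s in subs) {
    if (s$flagged) next
    t1 <- read_volume(s$t1_path, role = "intensity")
    les <- read_volume(s$lesion_paths[1], role = "mask")
    img <- file.path(gdir, paste0(s$subject_id, ".png"))
    render_triplanar(t1, list(list(mask = les, color = "red")), img)
    entries[[length(entries) + 1L]] <-
      data.frame(subject_id = s$subject_id, image = img,
                 stringsAsFactors = FALSE)
  }
  if (!length(entries)) stop("no usable subjects found", call. = FALSE)
  build_gallery("lesions", do.call(rbind, entries), gdir)
}
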