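#' Run configuration
#'
#' Collects every pipeline option. Mirrors the JSON configuration file
#' accepted by [read_config()] and the CLI flags.
#'
#' @param input_dir directory of per-subject subdirectories.
#' @param output_dir output directory; must be empty at run start unless
#'   `force`.
#' @param t1_identifier,lesion_identifier case-sensitive substrings matched
#'   against file basenames to locate each subject's T1 / lesion mask(s).
#'   Multiple lesions use the identifier plus an index starting at 1
#'   (`subj1_Lesion1.nii.gz`, ...).
#' @param brain_identifier,wm_identifier,label_identifier identifiers for the
#'   optional brain mask, WM mask, and label-volume files.
#' @param modules subset of `c("reorient", "correct", "load", "qc")`.
#' @param wm_removal_percent white-matter removal percentage (default 5).
#' @param skip_brain_extraction,skip_wm_segmentation use user-supplied masks
#'   instead of computing them? (All-or-none: one subject missing the mask
#'   forces the stage to run for all subjects.)
#' @param roi_config `NULL`, or a list: `list(mode = "template", roi_dir =,
#'   template_path =)` for template-space ROI files, or
#'   `list(mode = "subject_labels", label_table =)` for subject-space label
#'   volumes (`label_table`: named integer vector or CSV path with columns
#'   `roi_name`, `code`).
#' @param wm_mean_exclude_lesion exclude lesion voxels when averaging WM
#'   intensity (opt-in; the default averages over the full segmentation)?
#' @param lesion_provenance `"manual"` or `"automated"`; correction of
#'   automated segmentations is supported but warned against.
#' @param interactive pause at each QC gate until the review CSV is filled?
#' @param seed integer seed recorded in the log (all pipeline stages are
#'   deterministic; the seed is forwarded to any phantom generation done on
#'   top of a run).
#' @param force allow a nonempty output directory?
#' @param verbose echo log lines to the console?
#' @return a `run_config` list.
#' @export
run_config <- function(input_dir, output_dir,
                       t1_identifier = "T1", lesion_identifier = "Lesion",
                       brain_identifier = "Brain", wm_identifier = "WM",
                       label_identifier = "Labels",
                       modules = c("reorient", "correct", "qc"),
                       wm_removal_percent = 5,
                       skip_brain_extraction = FALSE,
                       skip_wm_segmentation = FALSE,
                       roi_config = NULL,
                       wm_mean_exclude_lesion = FALSE,
                       lesion_provenance = c("manual", "automated"),
                       interactive = FALSE, seed = 1L, force = FALSE,
                       verbose = FALSE) {
  modules <- match.arg(modules, c("reorient", "correct", "load", "qc"),
                       several.ok = TRUE)
  if (length(modules) < 1L) stop("modules must be nonempty", call. = FALSE)
  lesion_provenance <- match.arg(lesion_provenance)
  if ("load" %in% modules && is.null(roi_config))
    stop("the load module requires roi_config", call. = FALSE)
  removal_window(128, wm_removal_percent)  # validates the percentage
  structure(list(
    input_dir = input_dir, output_dir = output_dir,
    t1_identifier = t1_identifier, lesion_identifier = lesion_identifier,
    brain_identifier = brain_identifier, wm_identifier = wm_identifier,
    label_identifier = label_identifier,
    modules = modules, wm_removal_percent = wm_removal_percent,
    skip_brain_extraction = isTRUE(skip_brain_extraction),
    skip_wm_segmentation = isTRUE(skip_wm_segmentation),
    roi_config = roi_config,
    wm_mean_exclude_lesion = isTRUE(wm_mean_exclude_lesion),
    lesion_provenance = lesion_provenance,
    interactive = isTRUE(interactive), seed = as.integer(seed),
    force = isTRUE(force), verbose = isTRUE(verbose)),
    class = "run_config")
}

#' Read a JSON run configuration
#'
#' @param path JSON file whose fields mirror the arguments of [run_config()].
#' @return a `run_config`.
#' @export
read_config <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  known <- names(formals(run_config))
  extra <- setdiff(names(cfg), known)
  if (length(extra))
    stop("unknown config field(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  do.call(run_config, cfg)
}

nifti_files <- function(dir) {
  list.files(dir, pattern = "\\.nii(\\.gz)?$", full.names = TRUE)
}

strip_nii <- function(x) sub("\\.nii(\\.gz)?$", "", x)

match_one <- function(files, id) {
  hits <- files[grepl(id, basename(files), fixed = TRUE)]
  if (length(hits) > 1L) return(structure(NA_character_, ambiguous = TRUE))
  if (length(hits) == 1L) hits else NULL
}

#' Discover subjects in an input directory
#'
#' One subject record per subdirectory. Files are matched by case-sensitive
#' substring identifiers on the basename; multiple lesions must follow the
#' `<identifier><k>` convention with k starting at 1 and are ordered
#' numerically. Subjects missing a T1 or any lesion mask, or with ambiguous
#' identifier matches (including an unindexed lesion file coexisting with
#' indexed ones), are flagged with a reason rather than aborting the run.
#'
#' @param cfg a [run_config()].
#' @return list of subject records: `subject_id`, `t1_path`, `lesion_paths`,
#'   `brain_mask_path`, `wm_mask_path`, `label_volume_path`, `flagged`,
#'   `flag_reason`.
#' @export
discover_subjects <- function(cfg) {
  if (!dir.exists(cfg$input_dir))
    stop("input directory does not exist: ", cfg$input_dir, call. = FALSE)
  sdirs <- list.dirs(cfg$input_dir, recursive = FALSE)
  if (length(sdirs) == 0L)
    stop("input directory contains no subject subdirectories: ",
         cfg$input_dir, call. = FALSE)
  lapply(sdirs, function(sd) {
    id <- basename(sd)
    files <- nifti_files(sd)
    rec <- list(subject_id = id, t1_path = NA_character_,
                lesion_paths = character(0),
                brain_mask_path = NULL, wm_mask_path = NULL,
                label_volume_path = NULL,
                flagged = FALSE, flag_reason = "")
    flag <- function(reason) {
      rec$flagged <<- TRUE
      rec$flag_reason <<- if (nzchar(rec$flag_reason))
        paste(rec$flag_reason, reason, sep = ";") else reason
    }
    # lesions first so the T1 match can exclude them
    les <- files[grepl(cfg$lesion_identifier, basename(files), fixed = TRUE)]
    suffix <- sub(paste0("^.*", cfg$lesion_identifier), "",
                  strip_nii(basename(les)))
    valid <- grepl("^[0-9]*$", suffix)
    les <- les[valid]; suffix <- suffix[valid]
    if (length(les) == 0L) {
      flag("missing-lesion")
    } else if (length(les) > 1L && any(suffix == "")) {
      flag("ambiguous-files")   # unindexed lesion coexisting with indexed
    } else if (anyDuplicated(suffix)) {
      flag("ambiguous-files")
    } else {
      rec$lesion_paths <- les[order(as.integer(ifelse(suffix == "", "0",
                                                      suffix)))]
    }
    rest <- setdiff(files, les)
    t1 <- match_one(rest, cfg$t1_identifier)
    if (is.null(t1)) flag("missing-t1")
    else if (isTRUE(attr(t1, "ambiguous"))) flag("ambiguous-files")
    else rec$t1_path <- t1
    optional <- c(brain_mask_path = cfg$brain_identifier,
                  wm_mask_path = cfg$wm_identifier,
                  label_volume_path = cfg$label_identifier)
    for (fname in names(optional)) {
      m <- match_one(setdiff(rest, t1), optional[[fname]])
      if (isTRUE(attr(m, "ambiguous"))) flag("ambiguous-files")
      else if (!is.null(m)) rec[[fname]] <- m
    }
    rec
  })
}

log_open <- function(output_dir, verbose = FALSE) {
  ldir <- file.path(output_dir, "logs")
  dir.create(ldir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(ldir, format(Sys.time(), "run_%Y%m%d-%H%M%S.log"))
  # avoid clobbering a same-second log from a previous run
  while (file.exists(path)) path <- sub("\\.log$", "x.log", path)
  file.create(path)
  function(...) {
    line <- paste0(format(Sys.time(), "[%H:%M:%S] "), paste0(...))
    cat(line, "\n", file = path, append = TRUE, sep = "")
    if (verbose) message(line)
    invisible(line)
  }
}

copy_originals <- function(subject, output_dir) {
  dest <- file.path(output_dir, subject$subject_id, "Intermediate_Files",
                    "Original_Files")
  dir.create(dest, recursive = TRUE, showWarnings = FALSE)
  src <- c(subject$t1_path, subject$lesion_paths, subject$brain_mask_path,
           subject$wm_mask_path, subject$label_volume_path)
  src <- src[!is.na(src)]
  file.copy(src, file.path(dest, basename(src)), overwrite = TRUE)
}

load_roi_set <- function(roi_config) {
  if (identical(roi_config$mode, "template")) {
    template <- read_volume(roi_config$template_path, role = "intensity")
    rfiles <- nifti_files(roi_config$roi_dir)
    if (length(rfiles) == 0L)
      stop("no ROI NIfTI files in ", roi_config$roi_dir, call. = FALSE)
    rois <- lapply(rfiles, read_volume, role = "mask")
    names(rois) <- strip_nii(basename(rfiles))
    list(mode = "template", template = template, rois = rois)
  } else if (identical(roi_config$mode, "subject_labels")) {
    lt <- roi_config$label_table
    if (is.character(lt) && length(lt) == 1L && file.exists(lt)) {
      df <- utils::read.csv(lt, stringsAsFactors = FALSE)
      codes <- stats::setNames(as.integer(df$code), df$roi_name)
    } else {
      codes <- stats::setNames(as.integer(lt), names(lt))
    }
    if (is.null(names(codes)) || any(!nzchar(names(codes))))
      stop("label_table must name every ROI code", call. = FALSE)
    list(mode = "subject_labels", codes = codes)
  } else {
    stop("roi_config$mode must be 'template' or 'subject_labels'",
         call. = FALSE)
  }
}

# gallery + review gate for one stage; returns passing subject ids
qc_gate <- function(stage, entries, output_dir, cfg, log, active_ids) {
  if (NROW(entries) == 0L) return(active_ids)
  gdir <- file.path(output_dir, paste0("QC_", stage))
  build_gallery(stage, entries, gdir)
  log("QC gallery for stage '", stage, "' at ", gdir)
  rec <- withCallingHandlers(
    apply_review(stage, review_csv_path(gdir, stage),
                 subjects = entries$subject_id,
                 interactive = cfg$interactive),
    warning = function(w) {
      log("review warning [", stage, "]: ", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  pass <- passing_subjects(rec)
  failed <- setdiff(entries$subject_id, pass)
  for (f in failed) log("subject ", f, " failed review at stage '", stage, "'")
  setdiff(active_ids, failed)
}

#' Run the lesion-analysis pipeline
#'
#' Executes the selected modules in pipeline order — (1) reorientation to
#' radiological convention, (2) lesion correction for healthy white matter,
#' (3) lesion load calculation, with visual QC galleries gating each
#' producing stage — on every unflagged, review-passing subject. Originals
#' are copied to `Intermediate_Files/Original_Files`, per-stage outputs and
#' root-level CSVs are written under the output directory, and a timestamped
#' log records every option, input and stage decision. Per-subject errors
#' are recorded and skipped; they never abort the run.
#'
#' @param cfg a [run_config()].
#' @return summary list: `processed`, `flagged`, `failed_review`, `errors`,
#'   plus `orientation_reports`, `correction_results`, `load_results` and
#'   the discovered `subjects`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if (dir.exists(cfg$output_dir) &&
      length(list.files(cfg$output_dir, all.files = TRUE, no.. = TRUE)) > 0 &&
      !cfg$force)
    stop("output directory is not empty: ", cfg$output_dir,
         " (use force = TRUE to override)", call. = FALSE)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  log <- log_open(cfg$output_dir, cfg$verbose)
  log("run started; modules: ", paste(cfg$modules, collapse = ","),
      "; seed: ", cfg$seed)
  log("config: wm_removal_percent=", cfg$wm_removal_percent,
      " skip_brain_extraction=", cfg$skip_brain_extraction,
      " skip_wm_segmentation=", cfg$skip_wm_segmentation,
      " interactive=", cfg$interactive)

  subjects <- discover_subjects(cfg)
  names(subjects) <- vapply(subjects, `[[`, character(1), "subject_id")
  for (s in subjects)
    log("discovered ", s$subject_id, ": ",
        if (s$flagged) paste0("FLAGGED (", s$flag_reason, ")")
        else paste0(length(s$lesion_paths), " lesion(s)"))

  errors <- character(0)
  note_error <- function(id, stage, e) {
    msg <- paste0(id, " [", stage, "]: ", conditionMessage(e))
    log("ERROR ", msg)
    errors <<- c(errors, msg)
  }

  active <- names(subjects)[!vapply(subjects, `[[`, logical(1), "flagged")]
  for (id in active) copy_originals(subjects[[id]], cfg$output_dir)

  skip_be <- cfg$skip_brain_extraction
  skip_wm <- cfg$skip_wm_segmentation
  orientation_reports <- list()
  vols <- list()   # per subject: t1, lesions (named), brain, wm

  read_subject <- function(s) {
    les <- lapply(s$lesion_paths, read_volume, role = "mask")
    names(les) <- basename(s$lesion_paths)
    list(t1 = read_volume(s$t1_path, role = "intensity"), lesions = les,
         brain = if (!is.null(s$brain_mask_path))
           read_volume(s$brain_mask_path, role = "mask"),
         wm = if (!is.null(s$wm_mask_path))
           read_volume(s$wm_mask_path, role = "mask"))
  }

  if ("reorient" %in% cfg$modules) {
    for (id in active) {
      rep <- tryCatch(
        harmonize_subject(subjects[[id]], out_dir = cfg$output_dir,
                          skip_brain_extraction = skip_be,
                          skip_wm_segmentation = skip_wm),
        error = function(e) { note_error(id, "reorient", e); NULL })
      if (is.null(rep)) next
      orientation_reports[[id]] <- rep
      if (rep$flagged) {
        subjects[[id]]$flagged <- TRUE
        subjects[[id]]$flag_reason <- rep$flag_reason
        log("subject ", id, " flagged: ", rep$flag_reason)
      } else {
        nles <- grep("^lesion", names(rep$volumes))
        vols[[id]] <- list(
          t1 = rep$volumes[["t1"]],
          lesions = stats::setNames(rep$volumes[nles],
                                    basename(subjects[[id]]$lesion_paths)),
          brain = rep$volumes[["brain"]], wm = rep$volumes[["wm"]])
        log("subject ", id, " harmonized: ",
            paste(names(rep$actions), unname(rep$actions), sep = "=",
                  collapse = " "))
      }
      for (ov in rep$skip_overrides) {
        if (ov == "brain_extraction" && skip_be) {
          skip_be <- FALSE
          log("SKIP OVERRIDE: ", id, " has no brain mask; brain extraction ",
              "set to run on all subjects")
        }
        if (ov == "wm_segmentation" && skip_wm) {
          skip_wm <- FALSE
          log("SKIP OVERRIDE: ", id, " has no WM mask; WM segmentation set ",
              "to run for all subjects")
        }
      }
    }
    active <- names(subjects)[!vapply(subjects, `[[`, logical(1), "flagged")]
  }
  write_flagged_report(
    c(orientation_reports[vapply(orientation_reports, `[[`, logical(1),
                                 "flagged")],
      lapply(Filter(function(s) s$flagged &&
                      !(s$subject_id %in% names(orientation_reports)),
                    subjects),
             function(s) list(subject_id = s$subject_id,
                              per_file_convention = character(0),
                              flagged = TRUE, flag_reason = s$flag_reason))),
    file.path(cfg$output_dir, "flagged_subjects.csv"))

  qc_on <- "qc" %in% cfg$modules
  need_tissue <- "correct" %in% cfg$modules
  tissue <- list()
  correction_results <- list()

  if (need_tissue) {
    if (cfg$lesion_provenance == "automated")
      warning("lesion correction is recommended only for manually segmented ",
              "lesions, not automated segmentations", call. = FALSE)
    be_entries <- wm_entries <- list()
    for (id in active) {
      ok <- tryCatch({
        if (is.null(vols[[id]])) vols[[id]] <- read_subject(subjects[[id]])
        v <- vols[[id]]
        ts <- prepare_tissue(v$t1,
                             brain_mask = if (skip_be) v$brain,
                             wm_mask = if (skip_wm) v$wm)
        tissue[[id]] <- ts
        idir <- file.path(cfg$output_dir, id, "Intermediate_Files")
        write_volume(ts$brain_mask,
                     file.path(idir, paste0(id, "_brain_mask.nii.gz")))
        write_volume(ts$wm_mask,
                     file.path(idir, paste0(id, "_wm_mask.nii.gz")))
        log("tissue prep ", id, ": brain mask ", ts$provenance["brain_mask"],
            " (", sum(ts$brain_mask$data), " voxels), WM mask ",
            ts$provenance["wm_mask"], " (", sum(ts$wm_mask$data), " voxels)")
        if (qc_on) {
          qdir <- file.path(cfg$output_dir, "QC_BrainExtractions")
          img <- file.path(qdir, paste0(id, ".png"))
          render_triplanar(ts$normalized_t1,
                           list(list(mask = ts$brain_mask, color = "green")),
                           img, focus = "center")
          be_entries[[id]] <- data.frame(subject_id = id, image = img,
                                         stringsAsFactors = FALSE)
          qdir <- file.path(cfg$output_dir, "QC_WMSegmentations")
          img <- file.path(qdir, paste0(id, ".png"))
          render_triplanar(ts$normalized_t1,
                           list(list(mask = ts$wm_mask, color = "yellow")),
                           img, focus = "center")
          wm_entries[[id]] <- data.frame(subject_id = id, image = img,
                                         stringsAsFactors = FALSE)
        }
        TRUE
      }, error = function(e) { note_error(id, "tissue_prep", e); FALSE })
      if (!ok) active <- setdiff(active, id)
    }
    if (qc_on && length(be_entries)) {
      active <- qc_gate("BrainExtractions", do.call(rbind, be_entries),
                        cfg$output_dir, cfg, log, active)
      active <- qc_gate("WMSegmentations", do.call(rbind, wm_entries),
                        cfg$output_dir, cfg, log, active)
    }

    lc_entries <- list()
    for (id in active) {
      ok <- tryCatch({
        v <- vols[[id]]
        ts <- tissue[[id]]
        overlays <- list()
        for (lf in names(v$lesions)) {
          res <- correct_lesion(ts$normalized_t1, ts$wm_mask, v$lesions[[lf]],
                                p = cfg$wm_removal_percent,
                                exclude_lesion = cfg$wm_mean_exclude_lesion,
                                subject_id = id, lesion_file = lf)
          correction_results[[paste(id, lf)]] <- res
          out <- file.path(cfg$output_dir, id,
                           paste0(strip_nii(lf), "_corrected.nii.gz"))
          write_volume(res$corrected_mask, out)
          log("corrected ", id, "/", lf, ": removed ", res$removed_voxels,
              " of ", res$original_voxels, " voxels (window [",
              round(res$window[1], 3), ", ", round(res$window[2], 3), "])")
          overlays <- c(overlays,
                        list(list(mask = v$lesions[[lf]], color = "red"),
                             list(mask = res$corrected_mask,
                                  color = "deepskyblue")))
        }
        if (qc_on) {
          qdir <- file.path(cfg$output_dir, "QC_LesionCorrections")
          img <- file.path(qdir, paste0(id, ".png"))
          render_triplanar(ts$normalized_t1, overlays, img)
          lc_entries[[id]] <- data.frame(subject_id = id, image = img,
                                         stringsAsFactors = FALSE)
        }
        TRUE
      }, error = function(e) { note_error(id, "lesion_correction", e); FALSE })
      if (!ok) active <- setdiff(active, id)
    }
    if (length(correction_results))
      write_correction_report(correction_results,
                              file.path(cfg$output_dir,
                                        "lesion_correction_report.csv"))
    if (qc_on && length(lc_entries))
      active <- qc_gate("LesionCorrections", do.call(rbind, lc_entries),
                        cfg$output_dir, cfg, log, active)
  }

  load_results <- list()
  if ("load" %in% cfg$modules) {
    roiset <- load_roi_set(cfg$roi_config)
    reg_entries <- ll_entries <- list()
    transforms <- list()
    lesions_t <- list()
    if (roiset$mode == "template") {
      for (id in active) {
        ok <- tryCatch({
          if (is.null(vols[[id]])) vols[[id]] <- read_subject(subjects[[id]])
          v <- vols[[id]]
          sll <- subject_lesion_load(v$t1, v$lesions, roiset$rois,
                                     roiset$template, subject_id = id)
          transforms[[id]] <- sll$transform
          lesions_t[[id]] <- sll$lesions_in_roi_space
          write_transform(sll$transform,
                          file.path(cfg$output_dir, id, "Intermediate_Files",
                                    paste0(id, "_to_template.mat")))
          load_results <- c(load_results, sll$results)
          log("registered ", id, " to template: NCC ",
              round(sll$transform$similarity_score, 4), ", converged ",
              sll$transform$converged)
          if (qc_on) {
            t1t <- resample_to(v$t1, sll$transform, roiset$template,
                               interp = "linear")
            qdir <- file.path(cfg$output_dir, "QC_Registrations")
            img <- file.path(qdir, paste0(id, ".png"))
            tplmask <- volume((roiset$template$data >
                                 stats::median(roiset$template$data)) + 0,
                              roiset$template$affine, role = "mask")
            render_triplanar(t1t, list(list(mask = tplmask,
                                            color = "orange")),
                             img, focus = "center", alpha = 0.25)
            reg_entries[[id]] <- data.frame(subject_id = id, image = img,
                                            stringsAsFactors = FALSE)
          }
          TRUE
        }, error = function(e) { note_error(id, "registration", e); FALSE })
        if (!ok) active <- setdiff(active, id)
      }
      if (qc_on && length(reg_entries))
        active <- qc_gate("Registrations", do.call(rbind, reg_entries),
                          cfg$output_dir, cfg, log, active)
      load_results <- Filter(function(r) r$subject_id %in% active,
                             load_results)
      if (qc_on) {
        for (id in active) {
          if (is.null(lesions_t[[id]])) next
          first_roi <- roiset$rois[[1]]
          overlays <- c(list(list(mask = first_roi, color = "tan")),
                        lapply(lesions_t[[id]],
                               function(m) list(mask = m, color = "blue")))
          qdir <- file.path(cfg$output_dir, "QC_LesionLoads")
          img <- file.path(qdir, paste0(id, ".png"))
          render_triplanar(roiset$template, overlays, img)
          ll_entries[[id]] <- data.frame(subject_id = id, image = img,
                                         stringsAsFactors = FALSE)
        }
        if (length(ll_entries))
          active <- qc_gate("LesionLoads", do.call(rbind, ll_entries),
                            cfg$output_dir, cfg, log, active)
      }
    } else {  # subject-space label volumes: no registration
      for (id in active) {
        ok <- tryCatch({
          if (is.null(vols[[id]])) vols[[id]] <- read_subject(subjects[[id]])
          v <- vols[[id]]
          lp <- subjects[[id]]$label_volume_path
          if (is.null(lp))
            stop("no label volume for subject ", id, call. = FALSE)
          labels <- read_volume(lp, role = "intensity")
          if ("reorient" %in% cfg$modules)
            labels <- to_canonical(to_radiological(labels))
          rois <- rois_from_labels(labels, roiset$codes)
          for (lf in names(v$lesions)) {
            for (rn in names(rois)) {
              load_results[[length(load_results) + 1L]] <-
                lesion_load(v$lesions[[lf]], rois[[rn]], subject_id = id,
                            lesion_file = lf, roi_name = rn)
            }
          }
          log("lesion load (subject labels) done for ", id)
          TRUE
        }, error = function(e) { note_error(id, "lesion_load", e); FALSE })
        if (!ok) active <- setdiff(active, id)
      }
    }
    write_load_report(load_results,
                      file.path(cfg$output_dir, "lesion_load_report.csv"))
  }

  flagged_n <- sum(vapply(subjects, `[[`, logical(1), "flagged"))
  failed_review <- length(setdiff(
    names(subjects)[!vapply(subjects, `[[`, logical(1), "flagged")], active)) -
    length(unique(sub(" .*", "", errors)))
  log("run finished: ", length(active), " processed, ", flagged_n,
      " flagged, ", length(errors), " errors")
  list(processed = length(active), flagged = flagged_n,
       failed_review = max(failed_review, 0), errors = errors,
       orientation_reports = orientation_reports,
       correction_results = correction_results,
       load_results = load_results, subjects = subjects,
       active_subjects = active)
}
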