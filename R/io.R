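# Readers/writers and the end-to-end run: PNG frame sequences are the
# canonical video medium (codec-free), landmarks travel as long-format CSV
# (frame, point_index, x, y), and run_pipeline() ties generation,
# cross-validated classification and evaluation together.

#' Write a face video as a PNG frame sequence plus landmark CSV
#'
#' Frames are written as `frame_0001.png`, ... and landmarks as
#' `landmarks.csv` with columns `frame`, `point_index`, `x`, `y`.
#'
#' @param video an `fw_face_video`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_video_png <- function(video, dir) {
  stopifnot(inherits(video, "fw_face_video"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(video$frames)) {
    png::writePNG(video$frames[[i]],
                  file.path(dir, sprintf("frame_%04d.png", i)))
  }
  lm_rows <- list()
  for (i in seq_along(video$landmarks)) {
    L <- video$landmarks[[i]]
    if (is.null(L)) next
    lm_rows[[length(lm_rows) + 1L]] <- data.frame(
      frame = i, point_index = seq_len(nrow(L)), x = L[, 1], y = L[, 2])
  }
  if (length(lm_rows))
    utils::write.csv(do.call(rbind, lm_rows),
                     file.path(dir, "landmarks.csv"), row.names = FALSE)
  meta <- data.frame(subject_id = video$subject_id,
                     video_id = video$video_id, fps = video$fps,
                     true_label = video$true_label,
                     image_size = video$image_size)
  utils::write.csv(meta, file.path(dir, "meta.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a PNG-sequence video directory
#'
#' Reads sequentially numbered PNG frames (sorted by filename), converting
#' to grayscale by channel averaging if needed, and resamples to
#' `target_fps` by nearest-frame selection. Landmarks and metadata written
#' by [write_video_png()] are picked up when present.
#'
#' @param path directory containing `frame_*.png`.
#' @param fps source frame rate; defaults to the stored metadata, else 30.
#' @param target_fps output frame rate.
#' @return an `fw_face_video` (with `true_label = "unknown"` when no
#'   metadata is stored).
#' @export
read_video_png <- function(path, fps = NULL, target_fps = 30) {
  if (!dir.exists(path)) stop("no such video directory: ", path)
  files <- sort(list.files(path, pattern = "^frame_.*\\.png$",
                           full.names = TRUE))
  if (!length(files)) stop("no PNG frames found in ", path)
  meta_file <- file.path(path, "meta.csv")
  meta <- if (file.exists(meta_file)) utils::read.csv(meta_file) else NULL
  if (is.null(fps)) fps <- if (!is.null(meta)) meta$fps else 30

  frames <- lapply(files, function(f) {
    a <- png::readPNG(f)
    if (length(dim(a)) == 3) a <- apply(a[, , 1:min(3, dim(a)[3])], c(1, 2),
                                        mean)
    a
  })
  n <- length(frames)
  keep <- if (fps > target_fps) {
    unique(round(seq(1, n, by = fps / target_fps)))
  } else seq_len(n)
  frames <- frames[keep]

  lms <- vector("list", length(keep))
  lm_file <- file.path(path, "landmarks.csv")
  if (file.exists(lm_file)) {
    lt <- utils::read.csv(lm_file)
    for (j in seq_along(keep)) {
      d <- lt[lt$frame == keep[j], , drop = FALSE]
      if (nrow(d)) lms[[j]] <- cbind(d$x, d$y)[order(d$point_index), ,
                                               drop = FALSE]
    }
  }
  structure(list(
    frames = frames, landmarks = lms,
    subject_id = if (!is.null(meta)) meta$subject_id else basename(path),
    video_id = if (!is.null(meta)) meta$video_id else basename(path),
    fps = target_fps,
    true_label = if (!is.null(meta)) meta$true_label else "unknown",
    image_size = nrow(frames[[1]])), class = "fw_face_video")
}

#' Write a cohort to disk (one PNG-sequence directory per video)
#'
#' @param cohort output of [generate_cohort()].
#' @param dir output directory; the manifest goes to `manifest.csv`.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (v in cohort$videos) write_video_png(v, file.path(dir, v$video_id))
  utils::write.csv(cohort$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Run configuration for the end-to-end pipeline
#'
#' @param seed master seed for cohort generation, fold assignment and the
#'   penalty selection.
#' @param n_normal,n_left,n_right cohort composition (subjects per class).
#' @param severity_range droop severity interval.
#' @param n_frames_range per-video frame-count range.
#' @param image_size frame side, pixels.
#' @param jitter an [jitter_params()].
#' @param folds cross-validation folds.
#' @param hog an [hog_config()].
#' @param variance_target PCA retained-variance fraction.
#' @param lambda pLDA penalty (number or `"auto"`).
#' @param n_boot bootstrap replicates for the metric confidence intervals.
#' @param target_fps frame-rate videos are standardized to.
#' @return an object of class `fw_run_config`.
#' @export
run_config <- function(seed = 1, n_normal = 30, n_left = 15, n_right = 15,
                       severity_range = c(0.6, 0.9),
                       n_frames_range = c(12, 40), image_size = 128,
                       jitter = default_jitter(), folds = 5,
                       hog = hog_config(), variance_target = 0.95,
                       lambda = "auto", n_boot = 2000, target_fps = 30) {
  structure(as.list(environment()), class = "fw_run_config")
}

#' Run the full pipeline on a synthetic cohort
#'
#' Generates the cohort, runs subject-grouped cross-validated
#' classification, evaluates the pooled calls (metrics with bootstrap CIs,
#' ROC) and optionally writes all artifacts (manifest, calls table,
#' metrics, provenance log) to `out_dir`. Deterministic given the seed.
#'
#' @param config an [run_config()].
#' @param out_dir optional output directory.
#' @return list with `manifest`, `calls`, `metrics` (point estimates and
#'   CIs), `roc`, `cv`, and `log` (configuration echo and timings).
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "fw_run_config"))
  t0 <- Sys.time()
  cohort <- generate_cohort(
    config$n_normal, config$n_left, config$n_right,
    severity_range = config$severity_range, seed = config$seed,
    n_frames_range = config$n_frames_range, image_size = config$image_size,
    jitter = config$jitter, fps = config$target_fps)
  t1 <- Sys.time()
  cv <- cross_validate(cohort$videos, cohort$manifest, k = config$folds,
                       seed = config$seed, hog = config$hog,
                       variance_target = config$variance_target,
                       lambda = config$lambda)
  t2 <- Sys.time()
  ok <- cv$calls[!cv$calls$excluded, , drop = FALSE]
  calls_tab <- labels_to_calls(ok$predicted, ok$video_id)
  truth <- cv$truth
  mets <- lapply(c(accuracy = "accuracy", sensitivity = "sensitivity",
                   specificity = "specificity"), function(m)
                     bootstrap_ci(calls_tab, truth, metric = m,
                                  n_boot = config$n_boot, seed = config$seed))
  roc <- roc_points(ok$fraction_abnormal,
                    truth$truth[match(ok$video_id, truth$video_id)] ==
                      "present")
  t3 <- Sys.time()
  log <- list(
    config = config[setdiff(names(config), c("hog", "jitter"))],
    hog = unclass(config$hog), jitter = unclass(config$jitter),
    r_version = as.character(getRversion()),
    timing_s = c(generate = as.numeric(t1 - t0, units = "secs"),
                 crossval = as.numeric(t2 - t1, units = "secs"),
                 evaluate = as.numeric(t3 - t2, units = "secs")))
  res <- list(manifest = cohort$manifest, calls = cv$calls, metrics = mets,
              roc = roc, cv = cv, log = log)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(cohort$manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
    utils::write.csv(cv$calls, file.path(out_dir, "calls.csv"),
                     row.names = FALSE)
    utils::write.csv(roc$points, file.path(out_dir, "roc.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(metrics = mets, auc = roc$auc, log = log),
                         file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  res
}
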