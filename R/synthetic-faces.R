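#' Jitter settings for the synthetic face generator
#'
#' Amplitudes of the nuisance variation added to each generated video:
#' a per-video similarity transform (rotation, scale, translation of the
#' whole head), a linear illumination gradient, and i.i.d. pixel noise.
#' Jitter changes the rendering only; it never changes the true label.
#'
#' @param rotation maximum head rotation, degrees (drawn uniformly in
#'   `[-rotation, rotation]`).
#' @param scale maximum relative scale jitter (scale drawn in
#'   `[1 - scale, 1 + scale]`).
#' @param translation maximum head translation, pixels, per axis.
#' @param illumination amplitude of the linear illumination gradient
#'   (intensity units across the frame; direction drawn uniformly).
#' @param noise_sd standard deviation of additive Gaussian pixel noise.
#' @return an object of class `fw_jitter`.
#' @export
jitter_params <- function(rotation = 0, scale = 0, translation = 0,
                          illumination = 0, noise_sd = 0) {
  stopifnot(rotation >= 0, scale >= 0, scale < 1, translation >= 0,
            illumination >= 0, noise_sd >= 0)
  structure(list(rotation = rotation, scale = scale, translation = translation,
                 illumination = illumination, noise_sd = noise_sd),
            class = "fw_jitter")
}

#' Default study-like jitter
#'
#' Moderate pose/scale/illumination variation emulating hand-held consumer
#' video: up to 8 degrees of head roll, 8\% scale change, 4 px translation,
#' a 0.15-amplitude illumination gradient and 0.02-sd pixel noise.
#' @return an `fw_jitter` object.
#' @export
default_jitter <- function() {
  jitter_params(rotation = 8, scale = 0.08, translation = 4,
                illumination = 0.15, noise_sd = 0.02)
}

# Severity below this is labelled "normal"; severities in
# [PATHOLOGY_THRESHOLD, MIN_CLEAR_SEVERITY) are refused by default as
# clinically ambiguous fixtures.
PATHOLOGY_THRESHOLD <- 0.05
MIN_CLEAR_SEVERITY <- 0.30

#' Parameters of one synthetic smiling-face video
#'
#' @param droop_side patient side of the simulated weakness: `"none"`,
#'   `"left"` or `"right"`. Patient left appears on the viewer's right.
#' @param droop_severity droop severity in `[0, 1]`; 0 is a symmetric
#'   smile. The affected mouth corner's smile excursion is scaled by
#'   `1 - droop_severity`. Severities below 0.05 are labelled normal;
#'   severities in `[0.05, 0.3)` are refused unless `allow_ambiguous`.
#' @param n_frames number of frames (>= 2).
#' @param fps nominal frame rate, frames per second.
#' @param image_size side length of the square frames, pixels (>= 64).
#' @param jitter an [jitter_params()] object.
#' @param seed integer seed; identical parameters and seed give
#'   bit-identical videos.
#' @param allow_ambiguous allow severities in `[0.05, 0.3)`.
#' @return an object of class `fw_face_params`.
#' @export
face_params <- function(droop_side = "none", droop_severity = 0,
                        n_frames = 24, fps = 30, image_size = 128,
                        jitter = jitter_params(), seed = 1,
                        allow_ambiguous = FALSE) {
  droop_side <- match.arg(droop_side, c("none", "left", "right"))
  if (!is.numeric(droop_severity) || length(droop_severity) != 1 ||
      is.na(droop_severity) || droop_severity < 0 || droop_severity > 1)
    stop("droop_severity must be a number in [0, 1]")
  if (droop_severity >= PATHOLOGY_THRESHOLD && droop_side == "none")
    stop("droop_severity >= ", PATHOLOGY_THRESHOLD,
         " requires droop_side 'left' or 'right'")
  if (!allow_ambiguous && droop_severity >= PATHOLOGY_THRESHOLD &&
      droop_severity < MIN_CLEAR_SEVERITY)
    stop("severities in [", PATHOLOGY_THRESHOLD, ", ", MIN_CLEAR_SEVERITY,
         ") are ambiguous fixtures; set allow_ambiguous = TRUE to force")
  if (n_frames < 2) stop("n_frames must be >= 2")
  if (fps <= 0) stop("fps must be positive")
  if (image_size < 64) stop("image_size must be >= 64")
  stopifnot(inherits(jitter, "fw_jitter"))
  structure(list(droop_side = droop_side, droop_severity = droop_severity,
                 n_frames = as.integer(n_frames), fps = fps,
                 image_size = as.integer(image_size), jitter = jitter,
                 seed = as.integer(seed)),
            class = "fw_face_params")
}

# Smile trajectory: smooth rise over the first 40% of the video, then a
# held full smile (subjects smile and hold), giving voting a clear majority
# of informative frames.
smile_trajectory <- function(n_frames) {
  tt <- seq(0, 1, length.out = n_frames)
  ifelse(tt >= 0.4, 1, 0.5 * (1 - cos(pi * tt / 0.4)))
}

#' Generate one synthetic smiling-face video
#'
#' Animates the parametric face from neutral to full smile. Landmarks are
#' the exact analytic curve points (before rasterization), transformed by
#' the same per-video jitter transform as the pixels.
#'
#' @param params an [face_params()] object.
#' @param subject_id,video_id identifiers stored in the result.
#' @return an object of class `fw_face_video`: list with `frames` (list of
#'   `image_size` x `image_size` matrices in `[0, 1]`), `landmarks` (list of
#'   68 x 2 matrices, image coordinates, x rightward / y downward, 1-based
#'   pixel centres), `subject_id`, `video_id`, `fps`, `true_label`
#'   (`"normal"`, `"left"` or `"right"`) and `image_size`.
#' @export
#' @examples
#' v <- generate_face_video(face_params("left", 0.8, n_frames = 4, seed = 7))
#' v$true_label
generate_face_video <- function(params, subject_id = "s1", video_id = "v1") {
  stopifnot(inherits(params, "fw_face_params"))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(params$seed)

  j <- params$jitter
  rot <- if (j$rotation > 0) stats::runif(1, -j$rotation, j$rotation) else 0
  scl <- if (j$scale > 0) stats::runif(1, 1 - j$scale, 1 + j$scale) else 1
  shift <- if (j$translation > 0)
    stats::runif(2, -j$translation, j$translation) else c(0, 0)
  ill_angle <- if (j$illumination > 0) stats::runif(1, 0, 2 * pi) else 0

  n <- params$image_size
  u <- n / 128
  c0 <- (n + 1) / 2
  rot_rad <- rot * pi / 180
  R <- matrix(c(cos(rot_rad), sin(rot_rad), -sin(rot_rad), cos(rot_rad)), 2, 2)
  side <- params$droop_side
  sev <- params$droop_severity
  label <- if (sev < PATHOLOGY_THRESHOLD) "normal" else side

  s <- smile_trajectory(params$n_frames)
  frames <- vector("list", params$n_frames)
  lms <- vector("list", params$n_frames)
  for (i in seq_len(params$n_frames)) {
    g <- face_landmarks_canonical(s[i], sev, side)
    q <- u * scl * (g %*% t(R))
    lms[[i]] <- cbind(q[, 1] + c0 + shift[1], q[, 2] + c0 + shift[2])
    frames[[i]] <- render_face_frame(
      s[i], sev, side, n, rot_rad = rot_rad, scale = scl, shift = shift,
      illum_amp = j$illumination, illum_angle = ill_angle,
      noise_sd = j$noise_sd)
  }
  structure(list(frames = frames, landmarks = lms,
                 subject_id = subject_id, video_id = video_id,
                 fps = params$fps, true_label = label,
                 image_size = n, params = params),
            class = "fw_face_video")
}

#' @export
print.fw_face_video <- function(x, ...) {
  cat(sprintf("<fw_face_video %s: subject %s, %d frames @ %g fps, %dpx, label %s>\n",
              x$video_id, x$subject_id, length(x$frames), x$fps,
              x$image_size, x$true_label))
  invisible(x)
}

#' Generate a labelled cohort of synthetic face videos
#'
#' Emulates a study cohort: a mix of normal-smile and unilateral-droop
#' subjects. With `paired = TRUE` every droop subject also contributes a
#' normal-smile video of the same face (repeated measures per patient).
#'
#' @param n_normal,n_left,n_right subject counts per class (>= 0, not all 0).
#' @param severity_range interval the droop severities are drawn from;
#'   must lie within `[0.3, 1]`.
#' @param seed master seed; per-video seeds are derived from it.
#' @param n_frames_range range the per-video frame counts are drawn from
#'   (uniform integers), default 12-260 frames at 30 fps.
#' @param image_size frame side length, pixels.
#' @param jitter an [jitter_params()] object (use [default_jitter()] for
#'   study-like nuisance variation).
#' @param paired give each droop subject a paired normal video.
#' @param fps nominal frame rate.
#' @return list with `videos` (list of `fw_face_video`) and `manifest`
#'   (data.frame: `video_id`, `subject_id`, `true_label`, `severity`,
#'   `n_frames`).
#' @export
generate_cohort <- function(n_normal, n_left, n_right,
                            severity_range = c(0.6, 0.9), seed = 1,
                            n_frames_range = c(12, 260), image_size = 128,
                            jitter = jitter_params(), paired = FALSE,
                            fps = 30) {
  stopifnot(n_normal >= 0, n_left >= 0, n_right >= 0)
  if (n_normal + n_left + n_right == 0) stop("empty cohort requested")
  if (severity_range[1] < MIN_CLEAR_SEVERITY || severity_range[2] > 1 ||
      severity_range[1] > severity_range[2])
    stop("severity_range must lie within [", MIN_CLEAR_SEVERITY, ", 1]")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)

  sides <- c(rep("none", n_normal), rep("left", n_left), rep("right", n_right))
  n_subj <- length(sides)
  videos <- list()
  rows <- list()
  for (i in seq_len(n_subj)) {
    sid <- sprintf("subj%03d", i)
    side <- sides[i]
    sev <- if (side == "none") 0 else
      stats::runif(1, severity_range[1], severity_range[2])
    nf_rng <- seq(n_frames_range[1], n_frames_range[2])
    nf <- nf_rng[sample.int(length(nf_rng), 1)]
    vseed <- sample.int(.Machine$integer.max, 1)
    p <- face_params(droop_side = side, droop_severity = sev, n_frames = nf,
                     fps = fps, image_size = image_size, jitter = jitter,
                     seed = vseed)
    vid <- sprintf("vid%03d", length(videos) + 1L)
    videos[[vid]] <- generate_face_video(p, subject_id = sid, video_id = vid)
    rows[[length(rows) + 1L]] <- data.frame(
      video_id = vid, subject_id = sid, true_label = videos[[vid]]$true_label,
      severity = sev, n_frames = nf, stringsAsFactors = FALSE)
    if (paired && side != "none") {
      nf2 <- nf_rng[sample.int(length(nf_rng), 1)]
      vseed2 <- sample.int(.Machine$integer.max, 1)
      p2 <- face_params(droop_side = "none", droop_severity = 0,
                        n_frames = nf2, fps = fps, image_size = image_size,
                        jitter = jitter, seed = vseed2)
      vid2 <- sprintf("vid%03d", length(videos) + 1L)
      videos[[vid2]] <- generate_face_video(p2, subject_id = sid,
                                            video_id = vid2)
      rows[[length(rows) + 1L]] <- data.frame(
        video_id = vid2, subject_id = sid, true_label = "normal",
        severity = 0, n_frames = nf2, stringsAsFactors = FALSE)
    }
  }
  list(videos = videos, manifest = do.call(rbind, rows))
}

#' Horizontally mirror a face video
#'
#' Flips every frame about the vertical midline, mirrors the landmark x
#' coordinates and applies the standard 68-point left/right index swap, and
#' swaps the true label's laterality (normal stays normal).
#'
#' @param video an `fw_face_video`.
#' @return the mirrored `fw_face_video`.
#' @export
mirror_video <- function(video) {
  stopifnot(inherits(video, "fw_face_video"))
  n <- video$image_size
  video$frames <- lapply(video$frames, function(f) f[, n:1, drop = FALSE])
  video$landmarks <- lapply(video$landmarks, function(L) {
    if (is.null(L)) return(NULL)
    cbind(n + 1 - L[LANDMARK_MIRROR_PERM, 1], L[LANDMARK_MIRROR_PERM, 2])
  })
  video$true_label <- switch(video$true_label,
                             left = "right", right = "left", "normal")
  video$video_id <- paste0(video$video_id, "_mir")
  video
}

#' Blank a video's frames (simulated landmark-detection failure)
#'
#' Replaces all frames with a constant image and removes the attached
#' landmarks, so landmark extraction reports a detection failure and the
#' video is excluded from classification.
#'
#' @param video an `fw_face_video`.
#' @return the blanked video.
#' @export
blank_video <- function(video) {
  stopifnot(inherits(video, "fw_face_video"))
  n <- video$image_size
  video$frames <- lapply(video$frames, function(f) matrix(0.5, n, n))
  video$landmarks <- vector("list", length(video$landmarks))
  video
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
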