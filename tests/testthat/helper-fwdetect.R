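# Shared fixtures built in code. Heavier objects are memoised per test run.

.fw_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fw_cache)) assign(key, force(expr), envir = .fw_cache)
  get(key, envir = .fw_cache)
}

# quick, small video for unit tests (no jitter, clear droop)
tiny_video <- function(side = "left", severity = 0.8, n_frames = 4,
                       seed = 7, image_size = 128, jitter = jitter_params()) {
  generate_face_video(face_params(side, severity, n_frames = n_frames,
                                  seed = seed, image_size = image_size,
                                  jitter = jitter))
}

# synthetic rater table: n_weak weak + n_normal normal subjects, one video
# each; the rater detects weakness with the given sensitivity/specificity
# and mislateralizes detected weakness with probability p_lat_err.
simulate_rater_calls <- function(n_weak, n_normal, sens = 0.9, spec = 0.95,
                                 p_lat_err = 0, rater_id = "r1") {
  vid <- sprintf("v%03d", seq_len(n_weak + n_normal))
  truth <- data.frame(
    video_id = vid,
    truth = rep(c("present", "absent"), c(n_weak, n_normal)),
    laterality = c(sample(c("left", "right"), n_weak, TRUE),
                   rep(NA_character_, n_normal)),
    subject_id = paste0("s", seq_along(vid)),
    stringsAsFactors = FALSE)
  detected <- c(stats::runif(n_weak) < sens, stats::runif(n_normal) > spec)
  lat <- ifelse(detected & truth$truth == "present",
                ifelse(stats::runif(length(vid)) < p_lat_err,
                       ifelse(truth$laterality == "left", "right", "left"),
                       truth$laterality),
                ifelse(detected, sample(c("left", "right"), length(vid),
                                        TRUE), NA))
  calls <- data.frame(
    rater_id = rater_id, video_id = vid,
    call = ifelse(detected, "present", "absent"),
    laterality = ifelse(detected, lat, NA_character_),
    stringsAsFactors = FALSE)
  list(calls = calls, truth = truth)
}

# truth/calls fixture reproducing a 2x2 presence cross-tabulation:
# tp correct-present calls, fn_absent absent calls on present truth,
# fp present calls on absent truth, tn correct absent calls, plus
# fn_lat wrong-laterality present calls (scored as FN).
counts_fixture <- function(tp, fp, fn_absent, tn, fn_lat = 0,
                           n_right = NULL) {
  n_pres <- tp + fn_absent + fn_lat
  n_abs <- tn + fp
  vid <- sprintf("v%03d", seq_len(n_pres + n_abs))
  lat_true <- rep(c("right", "left"), length.out = n_pres)
  truth <- data.frame(
    video_id = vid,
    truth = rep(c("present", "absent"), c(n_pres, n_abs)),
    laterality = c(lat_true, rep(NA_character_, n_abs)),
    subject_id = paste0("s", seq_along(vid)), stringsAsFactors = FALSE)
  call <- c(rep("present", tp), rep("present", fn_lat),
            rep("absent", fn_absent),
            rep("present", fp), rep("absent", tn))
  lat_call <- c(lat_true[seq_len(tp)],
                ifelse(lat_true[tp + seq_len(fn_lat)] == "left", "right",
                       "left")[seq_len(fn_lat)],
                rep(NA_character_, fn_absent),
                rep("left", fp), rep(NA_character_, tn))
  calls <- data.frame(rater_id = "r", video_id = vid, call = call,
                      laterality = lat_call, stringsAsFactors = FALSE)
  list(calls = calls, truth = truth)
}
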