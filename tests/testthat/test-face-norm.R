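test_that("procrustes alignment recovers a known similarity transform", {
  set.seed(3)
  src <- matrix(rnorm(136, sd = 10), 68, 2)
  tf0 <- similarity_transform(1.5, 30 * pi / 180, c(10, -4))
  dst <- transform_points(tf0, src)
  rec <- procrustes_align(src, dst)
  expect_lt(abs(rec$scale - 1.5), 1e-7)
  expect_lt(abs(rec$rotation - 30 * pi / 180), 1e-7)
  expect_lt(max(abs(rec$translation - c(10, -4))), 1e-7)
  # identity case
  id <- procrustes_align(src, src)
  expect_lt(abs(id$scale - 1), 1e-9)
  expect_lt(abs(id$rotation), 1e-9)
  expect_lt(max(abs(id$translation)), 1e-9)
})

test_that("alignment residual never exceeds the identity residual", {
  set.seed(4)
  for (i in 1:20) {
    src <- matrix(rnorm(136, sd = 5), 68, 2)
    dst <- matrix(rnorm(136, sd = 5), 68, 2) + 3
    tf <- procrustes_align(src, dst)
    res_fit <- sum((transform_points(tf, src) - dst)^2)
    res_id <- sum((src - dst)^2)
    expect_lte(res_fit, res_id + 1e-9)
  }
})

test_that("reflection is never returned even when it would fit better", {
  set.seed(5)
  src <- matrix(rnorm(136, sd = 10), 68, 2)
  dst <- cbind(-src[, 1], src[, 2])   # a pure reflection of the source
  tf <- procrustes_align(src, dst)
  R <- fwdetect:::.rot_mat(tf$rotation)
  expect_gt(det(R), 0)
})

test_that("a transform composed with its inverse is the identity", {
  tf <- similarity_transform(2.3, 0.7, c(-5, 12))
  inv <- invert_transform(tf)
  pts <- matrix(rnorm(20), 10, 2)
  expect_lt(max(abs(transform_points(inv, transform_points(tf, pts)) - pts)),
            1e-9)
})

test_that("the template of a single landmark set is that set, centred and scaled", {
  v <- tiny_video("none", 0, n_frames = 2)
  tpl <- fit_template(v$landmarks[1], out_size = 128)
  expect_equal(colMeans(tpl$points), c(64.5, 64.5), tolerance = 1e-9)
  # congruent to the input (similarity-aligned residual ~ 0)
  tf <- procrustes_align(v$landmarks[[1]], tpl)
  expect_lt(max(abs(transform_points(tf, v$landmarks[[1]]) - tpl$points)),
            1e-6)
})

test_that("the template of similarity-transformed copies is congruent to the shape", {
  v <- tiny_video("none", 0, n_frames = 2)
  base <- v$landmarks[[1]]
  moved <- transform_points(similarity_transform(1.4, 0.5, c(20, -8)), base)
  tpl <- fit_template(list(base, moved), out_size = 128)
  tf <- procrustes_align(base, tpl)
  expect_lt(max(abs(transform_points(tf, base) - tpl$points)), 1e-6)
})

test_that("the GPA mean of noisy copies approaches the true shape", {
  set.seed(11)
  base <- fwdetect:::face_landmarks_canonical(1, 0, "none")
  n_rep <- 10; noise_sd <- 1
  copies <- lapply(1:n_rep, function(i) base + matrix(rnorm(136, 0, noise_sd),
                                                      68, 2))
  tpl <- fit_template(copies, out_size = 128)
  # compare in the template frame: align truth to template, residual RMS
  tf <- procrustes_align(base, tpl)
  resid <- transform_points(tf, base) - tpl$points
  rms <- sqrt(mean(rowSums(resid^2)))
  # Monte-Carlo averaging: error ~ noise_sd / sqrt(n_rep), scaled to the
  # template frame (~0.33 px per canonical px); allow 4x slack
  expect_lt(rms, 4 * tf$scale * noise_sd / sqrt(n_rep) * sqrt(2))
})

test_that("warping with the identity transform reproduces the input", {
  set.seed(6)
  f <- matrix(runif(128 * 128), 128, 128)
  w <- normalize_frame(f, similarity_transform(), 128)
  expect_lt(max(abs(w - f)), 1e-6)
})

test_that("normalization undoes an in-plane rotation up to interpolation error", {
  v0 <- tiny_video("left", 0.8, n_frames = 3, seed = 5)
  vr <- generate_face_video(face_params("left", 0.8, n_frames = 3, seed = 5,
                                        jitter = jitter_params(rotation = 15)))
  # force the drawn rotation to be nonzero by construction of the seed:
  tpl <- fit_template(v0$landmarks, 128)
  n0 <- normalize_frame(v0$frames[[3]],
                        procrustes_align(v0$landmarks[[3]], tpl), 128)
  nr <- normalize_frame(vr$frames[[3]],
                        procrustes_align(vr$landmarks[[3]], tpl), 128)
  expect_lt(mean(abs(n0 - nr)), 0.02)
})

test_that("source pixels outside the frame are filled with zero", {
  f <- matrix(1, 64, 64)
  # shift far to the right: left part of output samples outside the frame
  tf <- similarity_transform(1, 0, c(40, 0))
  w <- normalize_frame(f, tf, 64)
  expect_true(all(w[, 1:30] == 0))
  expect_true(all(w[, 45:64] == 1))
})

test_that("normalizing an already-normalized frame is idempotent", {
  v <- tiny_video("left", 0.8, n_frames = 3, seed = 5,
                  jitter = jitter_params(rotation = 10, scale = 0.05,
                                         translation = 3))
  tpl <- fit_template(v$landmarks, 128)
  tf <- procrustes_align(v$landmarks[[3]], tpl)
  lm1 <- transform_points(tf, v$landmarks[[3]])
  tf2 <- procrustes_align(lm1, tpl)
  expect_lt(abs(tf2$scale - 1), 1e-6)
  expect_lt(abs(tf2$rotation), 1e-6)
  expect_lt(max(abs(tf2$translation)), 1e-4)
})

test_that("landmark extraction passes through analytic landmarks and flags failures", {
  v <- tiny_video("left", 0.8, n_frames = 3)
  L <- extract_landmarks(v$frames[[2]], "synthetic", video = v,
                         frame_index = 2)
  expect_identical(L, v$landmarks[[2]])
  # blank frame -> failure signal, not an error
  vb <- blank_video(v)
  expect_null(extract_landmarks(vb$frames[[1]], "synthetic", video = vb,
                                frame_index = 1))
  # external backend without a detector is a configuration error
  expect_error(extract_landmarks(v$frames[[1]], "external"), "detector")
  # external detector contract
  det <- function(frame) matrix(1, 68, 2)
  expect_equal(dim(extract_landmarks(v$frames[[1]], "external",
                                     detector = det)), c(68, 2))
})

test_that("planted landmark failures are excluded and accounted for", {
  co <- generate_cohort(4, 2, 2, seed = 8, n_frames_range = c(3, 4),
                        image_size = 64)
  blanked <- c("vid002", "vid005")
  for (b in blanked) co$videos[[b]] <- blank_video(co$videos[[b]])
  status <- vapply(co$videos, function(v)
    extract_video_landmarks(v)$excluded, logical(1))
  expect_identical(sort(names(status)[status]), blanked)
  # videos in = classified + excluded
  expect_equal(sum(status) + sum(!status), nrow(co$manifest))
})
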