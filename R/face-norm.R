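# Landmark acquisition and similarity-transform face normalization.
#
# Every frame is aligned to a common landmark template with a 4-dof
# similarity transform (scale, rotation, translation) estimated from its 68
# landmarks by closed-form least squares; the identical transform is then
# applied to the pixel data by inverse-mapped bilinear warping. Reflections
# are explicitly disallowed: laterality is an output class and must never be
# flipped by preprocessing.

#' Create a similarity transform
#'
#' Maps a point x to `scale * R(rotation) %*% x + translation`, with
#' coordinates x rightward and y downward (so positive rotation is
#' clockwise on screen).
#'
#' @param scale positive scale factor.
#' @param rotation rotation angle, radians.
#' @param translation length-2 numeric (tx, ty), pixels.
#' @return an object of class `fw_similarity`.
#' @export
similarity_transform <- function(scale = 1, rotation = 0,
                                 translation = c(0, 0)) {
  if (!is.numeric(scale) || scale <= 0) stop("scale must be positive")
  structure(list(scale = scale, rotation = rotation,
                 translation = as.numeric(translation)),
            class = "fw_similarity")
}

#' @export
print.fw_similarity <- function(x, ...) {
  cat(sprintf("<similarity: scale %.4f, rotation %.4f rad, shift (%.2f, %.2f)>\n",
              x$scale, x$rotation, x$translation[1], x$translation[2]))
  invisible(x)
}

.rot_mat <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}

#' Apply a similarity transform to points
#' @param tf an `fw_similarity`.
#' @param pts n x 2 matrix of (x, y) coordinates.
#' @return transformed n x 2 matrix.
#' @export
transform_points <- function(tf, pts) {
  stopifnot(inherits(tf, "fw_similarity"))
  pts <- rbind(pts)
  q <- tf$scale * (pts %*% t(.rot_mat(tf$rotation)))
  cbind(q[, 1] + tf$translation[1], q[, 2] + tf$translation[2])
}

#' Invert a similarity transform
#' @param tf an `fw_similarity`.
#' @return the inverse `fw_similarity`.
#' @export
invert_transform <- function(tf) {
  stopifnot(inherits(tf, "fw_similarity"))
  Rinv <- .rot_mat(-tf$rotation)
  t_inv <- -(Rinv %*% tf$translation) / tf$scale
  similarity_transform(1 / tf$scale, -tf$rotation, as.numeric(t_inv))
}

#' Least-squares similarity alignment of landmarks to a template
#'
#' Closed-form (SVD of the centred cross-covariance) estimate of the
#' similarity transform minimizing the sum of squared distances from the
#' transformed source points to the target. The rotation determinant is
#' constrained positive: a reflection is never returned.
#'
#' @param source n x 2 matrix of source landmarks.
#' @param template n x 2 matrix, or an `fw_template`.
#' @return an `fw_similarity` mapping source onto the template.
#' @export
procrustes_align <- function(source, template) {
  if (inherits(template, "fw_template")) template <- template$points
  X <- as.matrix(source); Y <- as.matrix(template)
  stopifnot(nrow(X) == nrow(Y), ncol(X) == 2, ncol(Y) == 2,
            all(is.finite(X)), all(is.finite(Y)))
  mx <- colMeans(X); my <- colMeans(Y)
  Xc <- sweep(X, 2, mx); Yc <- sweep(Y, 2, my)
  vx <- sum(Xc^2) / nrow(X)
  if (vx < 1e-12) stop("degenerate source: zero landmark variance")
  C <- crossprod(Xc, Yc) / nrow(X)
  sv <- svd(C)
  s_sign <- c(1, sign(det(sv$u %*% t(sv$v))))
  R <- sv$v %*% diag(s_sign) %*% t(sv$u)    # rotation only, det = +1
  scale <- sum(sv$d * s_sign) / vx
  theta <- atan2(R[2, 1], R[1, 1])
  trans <- my - scale * as.numeric(.rot_mat(theta) %*% mx)
  similarity_transform(scale, theta, trans)
}

#' Fit a landmark template by generalized Procrustes analysis
#'
#' Iteratively aligns all training landmark sets to the running mean shape
#' and re-averages until convergence, then centres the mean at the middle
#' of an `out_size` frame and scales it to a fixed fraction of the frame
#' (RMS landmark distance from the centroid = 0.26 * out_size, matching the
#' generator's face framing).
#'
#' @param landmark_list list of n x 2 landmark matrices (>= 1).
#' @param out_size side length of the normalized frame, pixels.
#' @param max_iter,tol GPA iteration controls.
#' @return an object of class `fw_template` with `points` and `out_size`.
#' @export
fit_template <- function(landmark_list, out_size = 128, max_iter = 20,
                         tol = 1e-10) {
  stopifnot(length(landmark_list) >= 1, out_size > 0)
  norm_shape <- function(P) {
    P <- sweep(P, 2, colMeans(P))
    rms <- sqrt(sum(P^2) / nrow(P))
    if (rms < 1e-12) stop("degenerate landmark set: all points coincident")
    P / rms
  }
  mean_shape <- norm_shape(as.matrix(landmark_list[[1]]))
  if (length(landmark_list) > 1) {
    for (it in seq_len(max_iter)) {
      aligned <- lapply(landmark_list, function(P) {
        tf <- procrustes_align(as.matrix(P), mean_shape)
        transform_points(tf, as.matrix(P))
      })
      new_mean <- norm_shape(Reduce(`+`, aligned) / length(aligned))
      if (max(abs(new_mean - mean_shape)) < tol) { mean_shape <- new_mean; break }
      mean_shape <- new_mean
    }
  }
  pts <- mean_shape * (0.26 * out_size)
  pts <- sweep(pts, 2, colMeans(pts))
  pts <- sweep(pts, 2, c(out_size + 1, out_size + 1) / 2, `+`)
  structure(list(points = pts, out_size = as.integer(out_size)),
            class = "fw_template")
}

#' @export
print.fw_template <- function(x, ...) {
  cat(sprintf("<fw_template: %d points, %d px frame>\n",
              nrow(x$points), x$out_size))
  invisible(x)
}

#' Warp a frame by a similarity transform
#'
#' Produces the normalized `out_size` x `out_size` frame by inverse mapping:
#' each output pixel is bilinearly sampled at the source position
#' `tf^{-1}(x, y)`. Source positions falling outside the input frame are
#' filled with 0.
#'
#' @param frame numeric matrix (rows = y, cols = x), intensities in `[0, 1]`.
#' @param tf `fw_similarity` mapping source coordinates to output
#'   (template) coordinates.
#' @param out_size output side length, pixels.
#' @return `out_size` x `out_size` numeric matrix.
#' @export
normalize_frame <- function(frame, tf, out_size = 128) {
  if (out_size <= 0) stop("out_size must be positive")
  stopifnot(inherits(tf, "fw_similarity"), is.matrix(frame))
  n <- as.integer(out_size)
  ox <- rep(seq_len(n), each = n)
  oy <- rep(seq_len(n), times = n)
  inv <- invert_transform(tf)
  src <- transform_points(inv, cbind(ox, oy))
  sx <- src[, 1]; sy <- src[, 2]

  h <- nrow(frame); w <- ncol(frame)
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  out <- numeric(n * n)
  ok <- sx >= 1 & sx <= w & sy >= 1 & sy <= h
  if (any(ok)) {
    x0k <- x0[ok]; y0k <- y0[ok]; fxk <- fx[ok]; fyk <- fy[ok]
    x1k <- pmin(x0k + 1, w); y1k <- pmin(y0k + 1, h)  # clamp at the border
    v00 <- frame[(x0k - 1) * h + y0k]; v10 <- frame[(x1k - 1) * h + y0k]
    v01 <- frame[(x0k - 1) * h + y1k]; v11 <- frame[(x1k - 1) * h + y1k]
    out[ok] <- v00 * (1 - fxk) * (1 - fyk) + v10 * fxk * (1 - fyk) +
      v01 * (1 - fxk) * fyk + v11 * fxk * fyk
  }
  matrix(out, nrow = n, ncol = n)
}

#' Extract the facial landmarks of one frame
#'
#' The `"synthetic"` backend passes through the generator's analytic
#' landmarks attached to the video; it reports a detection failure when the
#' landmarks are missing or the frame carries no face signal (constant
#' image). The `"external"` backend is a mount point for a real detector
#' (e.g. an ensemble-of-regression-trees landmark model) supplied by the
#' user as a function `frame -> 68 x 2 matrix or NULL`.
#'
#' @param frame numeric matrix.
#' @param backend `"synthetic"` or `"external"`.
#' @param video the `fw_face_video` the frame belongs to (synthetic backend).
#' @param frame_index index of `frame` within `video`.
#' @param detector function implementing the external backend.
#' @return a 68 x 2 landmark matrix, or `NULL` to signal detection failure.
#' @export
extract_landmarks <- function(frame, backend = c("synthetic", "external"),
                              video = NULL, frame_index = 1L,
                              detector = NULL) {
  backend <- match.arg(backend)
  stopifnot(is.matrix(frame), length(frame) > 0)
  if (backend == "synthetic") {
    if (is.null(video)) stop("synthetic backend requires the source video")
    L <- video$landmarks[[frame_index]]
    if (is.null(L) || diff(range(frame)) < 1e-12) return(NULL)
    stopifnot(nrow(L) == 68, all(is.finite(L)))
    return(L)
  }
  if (is.null(detector))
    stop("external backend selected but no detector function supplied")
  res <- detector(frame)
  if (is.null(res)) return(NULL)
  res <- as.matrix(res)
  if (nrow(res) != 68 || ncol(res) != 2 || !all(is.finite(res)))
    stop("external detector must return a finite 68 x 2 matrix or NULL")
  res
}

#' Extract landmarks for a whole video, with exclusion accounting
#'
#' @param video an `fw_face_video`.
#' @inheritParams extract_landmarks
#' @return list with `landmarks` (per-frame list; `NULL` where detection
#'   failed), `n_failed`, and `excluded` (TRUE when every frame failed).
#' @export
extract_video_landmarks <- function(video, backend = "synthetic",
                                    detector = NULL) {
  lms <- lapply(seq_along(video$frames), function(i)
    extract_landmarks(video$frames[[i]], backend, video = video,
                      frame_index = i, detector = detector))
  n_failed <- sum(vapply(lms, is.null, logical(1)))
  list(landmarks = lms, n_failed = n_failed,
       excluded = n_failed == length(lms))
}
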