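# Parametric sketch of a midline-symmetric face, used by the synthetic video
# generator. All geometry lives in canonical coordinates: origin at the face
# centre, x to the viewer's right, y downward, units of pixels on a 128-px
# reference frame. Patient laterality is mirrored relative to the camera:
# the patient's LEFT side is the viewer's RIGHT (+x).

# Full-smile vertical excursion of a mouth corner (px, 128-px reference).
# The drooped corner's excursion is scaled by (1 - severity), so the final
# frame corner height gap is severity * MOUTH_EXCURSION (analytic oracle).
MOUTH_EXCURSION <- 7
MOUTH_HALF_WIDTH <- 16
MOUTH_WIDEN <- 4
MOUTH_Y <- 30

#' @keywords internal
viewer_sign <- function(side) {
  # patient's left appears on the viewer's right (+x)
  switch(side, left = 1, right = -1, none = 0)
}

quad_bezier <- function(p0, p1, p2, t) {
  cbind(
    (1 - t)^2 * p0[1] + 2 * t * (1 - t) * p1[1] + t^2 * p2[1],
    (1 - t)^2 * p0[2] + 2 * t * (1 - t) * p1[2] + t^2 * p2[2]
  )
}

# Amplitude of the smile on each viewer side given the droop parameters.
# `smile` in [0, 1]; the corner on the affected side is attenuated.
smile_amplitudes <- function(smile, severity, side) {
  vd <- viewer_sign(side)
  c(
    left  = smile * (1 - severity * (vd == -1)),
    right = smile * (1 - severity * (vd == 1))
  )
}

# Mouth corner positions (outer lip) for a given smile state.
mouth_corners <- function(smile, severity, side) {
  s <- smile_amplitudes(smile, severity, side)
  rbind(
    left  = c(-(MOUTH_HALF_WIDTH + MOUTH_WIDEN * s[["left"]]),
              MOUTH_Y - MOUTH_EXCURSION * s[["left"]]),
    right = c(MOUTH_HALF_WIDTH + MOUTH_WIDEN * s[["right"]],
              MOUTH_Y - MOUTH_EXCURSION * s[["right"]])
  )
}

mouth_inner_corners <- function(smile, severity, side) {
  s <- smile_amplitudes(smile, severity, side)
  rbind(
    left  = c(-(MOUTH_HALF_WIDTH - 2.5 + MOUTH_WIDEN * s[["left"]]),
              MOUTH_Y + 1 - 0.9 * MOUTH_EXCURSION * s[["left"]]),
    right = c(MOUTH_HALF_WIDTH - 2.5 + MOUTH_WIDEN * s[["right"]],
              MOUTH_Y + 1 - 0.9 * MOUTH_EXCURSION * s[["right"]])
  )
}

# Left-side (viewer) feature primitives; right-side features are exact
# mirrors, which guarantees midline symmetry at severity 0.
.brow_left <- function(n = 5) {
  t <- seq(0, 1, length.out = n)
  cbind(-30 + 22 * t, -26 - 4 * sin(pi * t))
}

.eye_left <- function(theta) {
  cbind(-18 + 7 * cos(theta), -14 + 3.5 * sin(theta))
}

.mirror_x <- function(p) cbind(-p[, 1], p[, 2])

#' Analytic 68-point landmark set of the parametric face
#'
#' Standard 68-point ordering: 1-17 jaw, 18-27 brows, 28-36 nose, 37-48 eyes,
#' 49-68 mouth (outer then inner lip).
#'
#' @param smile smile amplitude in `[0, 1]` (0 = neutral, 1 = full smile).
#' @param severity droop severity in `[0, 1]`.
#' @param side patient side of the droop: `"none"`, `"left"` or `"right"`.
#' @return a 68 x 2 matrix of (x, y) canonical coordinates.
#' @keywords internal
face_landmarks_canonical <- function(smile, severity = 0, side = "none") {
  th <- seq(pi, 0, length.out = 17)
  jaw <- cbind(42 * cos(th), 54 * sin(th))

  browL <- .brow_left()
  browR <- .mirror_x(browL)[5:1, , drop = FALSE]

  bridge <- cbind(0, c(-16, -9, -2, 5))
  base <- cbind(c(-8, -4, 0, 4, 8), c(8, 9.5, 10.5, 9.5, 8))

  eyeL <- .eye_left(c(pi, 4 * pi / 3, 5 * pi / 3, 0, pi / 3, 2 * pi / 3))
  # right eye: 43 inner, 46 outer (mirror of 40, 39, 38, 37, 42, 41)
  eyeR <- .mirror_x(eyeL)[c(4, 3, 2, 1, 6, 5), , drop = FALSE]

  oc <- mouth_corners(smile, severity, side)
  CL <- oc["left", ]; CR <- oc["right", ]
  upper <- quad_bezier(CL, c(0, MOUTH_Y - 7), CR, c(0.18, 0.35, 0.5, 0.65, 0.82))
  lower <- quad_bezier(CL, c(0, MOUTH_Y + 9), CR, c(0.82, 0.65, 0.5, 0.35, 0.18))
  ic <- mouth_inner_corners(smile, severity, side)
  ICL <- ic["left", ]; ICR <- ic["right", ]
  iu <- quad_bezier(ICL, c(0, MOUTH_Y - 1.5), ICR, c(0.3, 0.5, 0.7))
  il <- quad_bezier(ICL, c(0, MOUTH_Y + 4.5), ICR, c(0.7, 0.5, 0.3))

  rbind(
    jaw, browL, browR, bridge, base, eyeL, eyeR,
    rbind(CL), upper, rbind(CR), lower,
    rbind(ICL), iu, rbind(ICR), il
  )
}

# Index permutation p such that mirroring a face maps landmark p[i] onto
# landmark i (after negating x). Standard 68-point left/right swap.
LANDMARK_MIRROR_PERM <- c(
  17:1,                 # jaw
  27:23, 22:18,         # brows
  28:31, 36:32,         # nose
  46, 45, 44, 43, 48, 47,   # left eye <- right eye
  40, 39, 38, 37, 42, 41,   # right eye <- left eye
  55, 54, 53, 52, 51, 50, 49, 60, 59, 58, 57, 56,  # outer lip
  65, 64, 63, 62, 61, 68, 67, 66                   # inner lip
)

# Dense stroke polylines for rasterization. Returns a list of strokes, each
# list(pts, width, col, point) in canonical coordinates.
face_strokes <- function(smile, severity = 0, side = "none") {
  th <- seq(0, 2 * pi, length.out = 49)
  ellipse <- cbind(42 * cos(th), 54 * sin(th))

  tb <- seq(0, 1, length.out = 13)
  browL <- cbind(-30 + 22 * tb, -26 - 4 * sin(pi * tb))
  browR <- .mirror_x(browL)

  te <- seq(0, 2 * pi, length.out = 21)
  eyeL <- .eye_left(te)
  eyeR <- .mirror_x(eyeL)

  oc <- mouth_corners(smile, severity, side)
  tm <- seq(0, 1, length.out = 21)
  upper <- quad_bezier(oc["left", ], c(0, MOUTH_Y - 7), oc["right", ], tm)
  lower <- quad_bezier(oc["left", ], c(0, MOUTH_Y + 9), oc["right", ], rev(tm))
  outer_lip <- rbind(upper, lower)
  ic <- mouth_inner_corners(smile, severity, side)
  inner_lip <- rbind(
    quad_bezier(ic["left", ], c(0, MOUTH_Y - 1.5), ic["right", ], tm),
    quad_bezier(ic["left", ], c(0, MOUTH_Y + 4.5), ic["right", ], rev(tm))
  )

  list(
    list(pts = ellipse, width = 1.6, col = 0.35),
    list(pts = browL, width = 2.0, col = 0.15),
    list(pts = browR, width = 2.0, col = 0.15),
    list(pts = eyeL, width = 1.2, col = 0.20),
    list(pts = eyeR, width = 1.2, col = 0.20),
    list(pts = cbind(-18, -14), width = 2.2, col = 0.10),  # iris dots
    list(pts = cbind(18, -14), width = 2.2, col = 0.10),
    list(pts = cbind(0, c(-16, 5)), width = 1.3, col = 0.40),
    list(pts = cbind(c(-8, -4, 0, 4, 8), c(8, 9.5, 10.5, 9.5, 8)),
         width = 1.3, col = 0.40),
    list(pts = outer_lip, width = 1.8, col = 0.12),
    list(pts = inner_lip, width = 1.0, col = 0.25)
  )
}

# Minimum distance from each query point to a polyline (vectorized over
# query points, looped over segments).
.dist_to_polyline <- function(px, py, pts) {
  n <- nrow(pts)
  if (n == 1L) {
    return(sqrt((px - pts[1, 1])^2 + (py - pts[1, 2])^2))
  }
  d2 <- rep(Inf, length(px))
  for (k in seq_len(n - 1L)) {
    x1 <- pts[k, 1]; y1 <- pts[k, 2]
    x2 <- pts[k + 1L, 1]; y2 <- pts[k + 1L, 2]
    dx <- x2 - x1; dy <- y2 - y1
    len2 <- dx * dx + dy * dy
    if (len2 < 1e-12) {
      dd <- (px - x1)^2 + (py - y1)^2
    } else {
      t <- ((px - x1) * dx + (py - y1) * dy) / len2
      t <- pmin(pmax(t, 0), 1)
      dd <- (px - x1 - t * dx)^2 + (py - y1 - t * dy)^2
    }
    d2 <- pmin(d2, dd)
  }
  sqrt(d2)
}

# Rasterize one frame. `transform` maps canonical geometry into image
# coordinates: q = centre + translation + scale * R %*% (u * g), where
# u = image_size / 128. Illumination gradient is added before pixel noise.
render_face_frame <- function(smile, severity, side, image_size,
                              rot_rad = 0, scale = 1, shift = c(0, 0),
                              illum_amp = 0, illum_angle = 0, noise_sd = 0) {
  n <- image_size
  u <- n / 128
  c0 <- (n + 1) / 2
  R <- matrix(c(cos(rot_rad), sin(rot_rad), -sin(rot_rad), cos(rot_rad)), 2, 2)

  px <- rep(seq_len(n), each = n)   # x = column
  py <- rep(seq_len(n), times = n)  # y = row
  # canonical coordinates of each pixel (inverse transform)
  qx <- px - c0 - shift[1]
  qy <- py - c0 - shift[2]
  gx <- (R[1, 1] * qx + R[2, 1] * qy) / (scale * u)
  gy <- (R[1, 2] * qx + R[2, 2] * qy) / (scale * u)

  # skin fill with a soft ellipse edge
  e <- (gx / 42)^2 + (gy / 54)^2
  img <- 0.25 + (0.82 - 0.25) / (1 + exp((e - 1) * 30))

  fwd <- function(pts) {
    g <- u * scale * (pts %*% t(R))
    cbind(g[, 1] + c0 + shift[1], g[, 2] + c0 + shift[2])
  }
  for (st in face_strokes(smile, severity, side)) {
    pts <- fwd(st$pts)
    w <- st$width * scale * u
    # restrict to the stroke's bounding box (4 sd of the stroke profile)
    m <- 4 * w
    sel <- which(px >= min(pts[, 1]) - m & px <= max(pts[, 1]) + m &
                   py >= min(pts[, 2]) - m & py <= max(pts[, 2]) + m)
    if (!length(sel)) next
    d <- .dist_to_polyline(px[sel], py[sel], pts)
    f <- exp(-0.5 * (d / w)^2)
    img[sel] <- img[sel] * (1 - f) + st$col * f
  }

  if (illum_amp != 0) {
    img <- img + illum_amp * (((px - 1) / (n - 1) - 0.5) * cos(illum_angle) +
                                ((py - 1) / (n - 1) - 0.5) * sin(illum_angle))
  }
  if (noise_sd > 0) img <- img + stats::rnorm(n * n, 0, noise_sd)

  # vector order: y fastest within each x block -> column-major [row = y, col = x]
  matrix(pmin(pmax(img, 0), 1), nrow = n, ncol = n)
}
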