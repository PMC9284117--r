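# Penalized linear discriminant analysis of individual frames and the
# plurality vote that reduces frame calls to one per-video call.
#
# The discriminant directions solve the generalized eigenproblem of the
# between-class scatter against the ridge-penalized within-class scatter
# (Sw + lambda I); the penalty stabilizes the directions when the reduced
# feature dimension approaches the number of training frames. Classification
# is nearest class centroid in discriminant space.

FW_CLASSES <- c("normal", "left", "right")

.class_factor <- function(y) {
  f <- factor(as.character(y), levels = FW_CLASSES)
  if (anyNA(f)) stop("labels must be in {normal, left, right}")
  droplevels(f)
}

#' Fit a penalized linear discriminant model
#'
#' @param X numeric matrix of reduced feature vectors (rows = frames).
#' @param y frame class labels (subset of `normal`, `left`, `right`).
#' @param lambda ridge penalty added to the within-class scatter; a
#'   nonnegative number, or `"auto"` to select by inner cross-validation
#'   over the grid `c(1e-4, 1e-2, 1, 10) * mean(diag(Sw))`.
#' @param inner_folds folds for the `"auto"` selection.
#' @param groups optional grouping vector (e.g. source video of each frame)
#'   for the `"auto"` selection; inner folds never split a group, so frames
#'   of one video cannot appear on both sides of the inner split.
#' @param seed seed for the inner-CV fold assignment.
#' @return an object of class `fw_plda`: `directions` (columns = up to
#'   n_classes - 1 unit-norm discriminant directions in the reduced space),
#'   `centroids` (class centroids projected to discriminant space),
#'   `classes`, `lambda`, `eigenvalues`.
#' @export
fit_plda <- function(X, y, lambda = "auto", inner_folds = 3, groups = NULL,
                     seed = 1) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("non-finite values in training features")
  f <- .class_factor(y)
  classes <- levels(f)
  if (length(classes) < 2) stop("need at least 2 classes to fit a discriminant")
  if (any(table(f) < 2)) stop("each class needs at least 2 samples")
  if (identical(lambda, "auto")) {
    lambda <- select_plda_lambda(X, f, inner_folds = inner_folds,
                                 groups = groups, seed = seed)
  }
  stopifnot(is.numeric(lambda), lambda >= 0)

  d <- ncol(X)
  mu <- colMeans(X)
  Sw <- matrix(0, d, d)
  Sb <- matrix(0, d, d)
  cent_x <- matrix(0, length(classes), d)
  for (i in seq_along(classes)) {
    Xi <- X[f == classes[i], , drop = FALSE]
    mi <- colMeans(Xi)
    cent_x[i, ] <- mi
    Xic <- sweep(Xi, 2, mi)
    Sw <- Sw + crossprod(Xic)
    Sb <- Sb + nrow(Xi) * tcrossprod(mi - mu)
  }
  # MLE-style divisor: scatters are invariant under sample duplication,
  # so a fixed penalty keeps its meaning when the data are replicated
  Sw <- Sw / nrow(X)
  Sb <- Sb / nrow(X)

  U <- chol(Sw + (lambda + 1e-12) * diag(d))
  # M = U^-T Sb U^-1 is symmetric; its eigenvectors v give w = U^-1 v
  Y <- forwardsolve(t(U), Sb)
  M <- forwardsolve(t(U), t(Y))
  M <- (M + t(M)) / 2
  eg <- eigen(M, symmetric = TRUE)
  k <- min(length(classes) - 1L, d)
  W <- backsolve(U, eg$vectors[, seq_len(k), drop = FALSE])
  W <- apply(W, 2, function(w) w / sqrt(sum(w^2)))
  W <- matrix(W, nrow = d)
  for (j in seq_len(ncol(W))) {      # sign convention: largest |entry| > 0
    i <- which.max(abs(W[, j]))
    if (W[i, j] < 0) W[, j] <- -W[, j]
  }
  structure(list(directions = W, centroids = cent_x %*% W,
                 classes = classes, lambda = lambda,
                 eigenvalues = eg$values[seq_len(k)]),
            class = "fw_plda")
}

#' @export
print.fw_plda <- function(x, ...) {
  cat(sprintf("<fw_plda: %d classes (%s), %d direction(s), lambda %.4g>\n",
              length(x$classes), paste(x$classes, collapse = "/"),
              ncol(x$directions), x$lambda))
  invisible(x)
}

#' Select the pLDA ridge penalty by inner cross-validation
#'
#' @param X,y training frames and labels.
#' @param grid candidate penalties as multiples of `mean(diag(Sw))`.
#' @param inner_folds number of folds.
#' @param groups optional grouping vector; frames sharing a group value are
#'   kept in the same inner fold (prevents within-video leakage).
#' @param seed fold-assignment seed.
#' @return the selected numeric penalty.
#' @export
select_plda_lambda <- function(X, y, grid = c(1e-4, 1e-2, 1, 10),
                               inner_folds = 3, groups = NULL, seed = 1) {
  X <- as.matrix(X)
  f <- .class_factor(y)
  d <- ncol(X)
  Sw_diag <- 0
  for (cl in levels(f)) {
    Xi <- X[f == cl, , drop = FALSE]
    Sw_diag <- Sw_diag + sum(sweep(Xi, 2, colMeans(Xi))^2)
  }
  scale0 <- Sw_diag / (nrow(X) * d)
  cand <- grid * max(scale0, 1e-12)

  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  fold <- integer(nrow(X))
  if (is.null(groups)) {
    for (cl in levels(f)) {    # stratified fold assignment
      idx <- sample(which(f == cl))
      fold[idx] <- rep_len(seq_len(inner_folds), length(idx))
    }
  } else {
    groups <- as.character(groups)
    gclass <- tapply(as.character(f), groups, function(z) z[1])
    gfold <- integer(length(gclass)); names(gfold) <- names(gclass)
    for (cl in unique(gclass)) {   # stratified at the group (video) level
      g <- sample(names(gclass)[gclass == cl])
      gfold[g] <- rep_len(seq_len(inner_folds), length(g))
    }
    fold <- gfold[groups]
  }
  acc <- numeric(length(cand))
  for (g in seq_along(cand)) {
    correct <- 0
    for (k in seq_len(inner_folds)) {
      tr <- fold != k
      if (nlevels(droplevels(f[tr])) < 2 || any(table(f[tr]) < 2)) next
      m <- fit_plda(X[tr, , drop = FALSE], f[tr], lambda = cand[g])
      pred <- predict_frames(m, X[!tr, , drop = FALSE])$class
      correct <- correct + sum(pred == as.character(f[!tr]))
    }
    acc[g] <- correct
  }
  cand[which.max(acc)]          # ties resolved toward the smallest penalty
}

#' Classify reduced feature vectors frame-by-frame
#'
#' Nearest-centroid calls in discriminant space; per-class scores are
#' negative Euclidean distances. Ties are broken by class order
#' (normal before left before right).
#'
#' @param model an `fw_plda`.
#' @param X numeric vector or matrix of reduced features.
#' @return list with `class` (character vector), `scores` (matrix, one
#'   column per class) and `coords` (discriminant coordinates).
#' @export
predict_frames <- function(model, X) {
  stopifnot(inherits(model, "fw_plda"))
  X <- rbind(X)
  if (ncol(X) != nrow(model$directions))
    stop("feature dimension does not match the model")
  Z <- X %*% model$directions
  d2 <- outer(rowSums(Z^2), rowSums(model$centroids^2), `+`) -
    2 * Z %*% t(model$centroids)
  d2 <- pmax(d2, 0)
  colnames(d2) <- model$classes
  # ties: max.col with ties.method = "first" keeps the class-order rule
  cls <- model$classes[max.col(-d2, ties.method = "first")]
  list(class = cls, scores = -sqrt(d2), coords = Z)
}

#' Plurality vote over frame calls
#'
#' @param frame_classes character vector of per-frame calls.
#' @return list with `class` (winning label), `fractions` (named vote
#'   fractions over normal/left/right, summing to 1) and `n_frames`. Ties
#'   are broken in the order normal, left, right.
#' @export
vote <- function(frame_classes) {
  if (length(frame_classes) == 0) stop("no frame calls to vote over")
  f <- factor(as.character(frame_classes), levels = FW_CLASSES)
  if (anyNA(f)) stop("frame calls must be in {normal, left, right}")
  counts <- table(f)
  frac <- as.numeric(counts) / length(frame_classes)
  names(frac) <- FW_CLASSES
  list(class = FW_CLASSES[which.max(counts)], fractions = frac,
       n_frames = length(frame_classes))
}

#' Bundle a fitted frame-classification pipeline
#'
#' @param template an `fw_template`.
#' @param hog an [hog_config()].
#' @param pca an `fw_pca`.
#' @param plda an `fw_plda`.
#' @return an object of class `fw_pipeline`.
#' @export
fw_pipeline <- function(template, hog, pca, plda) {
  stopifnot(inherits(template, "fw_template"), inherits(hog, "fw_hog_config"),
            inherits(pca, "fw_pca"), inherits(plda, "fw_plda"))
  structure(list(template = template, hog = hog, pca = pca, plda = plda),
            class = "fw_pipeline")
}

#' Train the frame-classification pipeline on a set of videos
#'
#' Fits the landmark template (generalized Procrustes mean of the training
#' landmarks), computes normalized-frame HoG features, fits the PCA
#' retaining `variance_target` of training variance, and fits the pLDA
#' frame classifier with video labels assigned to every frame.
#'
#' @param videos list of `fw_face_video` training videos.
#' @param labels per-video labels; defaults to each video's `true_label`.
#' @param hog an [hog_config()].
#' @param variance_target PCA retained-variance fraction.
#' @param lambda pLDA penalty (number or `"auto"`).
#' @param out_size normalized frame side, pixels.
#' @param backend,detector landmark backend (see [extract_landmarks()]).
#' @param template_max_sets cap on the number of landmark sets entering the
#'   generalized Procrustes template fit (evenly subsampled).
#' @param seed seed for the inner lambda-selection CV.
#' @return an `fw_pipeline`.
#' @export
train_pipeline <- function(videos, labels = NULL, hog = hog_config(),
                           variance_target = 0.95, lambda = "auto",
                           out_size = 128, backend = "synthetic",
                           detector = NULL, template_max_sets = 300,
                           seed = 1) {
  if (is.null(labels))
    labels <- vapply(videos, function(v) v$true_label, character(1))
  stopifnot(length(labels) == length(videos))

  all_lms <- list(); frame_video <- integer(0)
  kept_frames <- list()
  for (i in seq_along(videos)) {
    ex <- extract_video_landmarks(videos[[i]], backend, detector)
    okf <- which(!vapply(ex$landmarks, is.null, logical(1)))
    for (k in okf) {
      all_lms[[length(all_lms) + 1L]] <- ex$landmarks[[k]]
      kept_frames[[length(kept_frames) + 1L]] <- videos[[i]]$frames[[k]]
      frame_video <- c(frame_video, i)
    }
  }
  if (!length(all_lms)) stop("no usable training frames (all landmarks failed)")

  tpl_idx <- if (length(all_lms) > template_max_sets)
    unique(round(seq(1, length(all_lms), length.out = template_max_sets)))
  else seq_along(all_lms)
  template <- fit_template(all_lms[tpl_idx], out_size = out_size)

  feats <- matrix(0, length(all_lms), hog_length(out_size, hog))
  for (k in seq_along(all_lms)) {
    tf <- procrustes_align(all_lms[[k]], template)
    nf <- normalize_frame(kept_frames[[k]], tf, out_size)
    feats[k, ] <- compute_hog(nf, hog)
  }
  pca <- fit_pca(feats, variance_target)
  Z <- pca_project(feats, pca)
  plda <- fit_plda(Z, labels[frame_video], lambda = lambda,
                   groups = frame_video, seed = seed)
  fw_pipeline(template, hog, pca, plda)
}

#' Classify one video with a fitted pipeline
#'
#' Runs the full chain per frame (landmark alignment to the template,
#' pixel warp, HoG, PCA projection, pLDA call) and reduces the frame calls
#' to a per-video call by plurality vote. Frames whose landmark extraction
#' failed are skipped and counted; if every frame fails the video is
#' excluded (`excluded = TRUE`).
#'
#' @param video an `fw_face_video`.
#' @param pipeline an `fw_pipeline`.
#' @param backend,detector landmark backend (see [extract_landmarks()]).
#' @return list with `video_id`, `class`, `fractions`, `n_frames_used`,
#'   `n_frames_failed`, `excluded`, and `frame_classes`.
#' @export
classify_video <- function(video, pipeline, backend = "synthetic",
                           detector = NULL) {
  stopifnot(inherits(pipeline, "fw_pipeline"))
  ex <- extract_video_landmarks(video, backend, detector)
  okf <- which(!vapply(ex$landmarks, is.null, logical(1)))
  if (!length(okf)) {
    return(list(video_id = video$video_id, class = NA_character_,
                fractions = c(normal = NA, left = NA, right = NA),
                n_frames_used = 0L, n_frames_failed = ex$n_failed,
                excluded = TRUE, frame_classes = character(0)))
  }
  out_size <- pipeline$template$out_size
  feats <- matrix(0, length(okf), hog_length(out_size, pipeline$hog))
  for (j in seq_along(okf)) {
    k <- okf[j]
    tf <- procrustes_align(ex$landmarks[[k]], pipeline$template)
    nf <- normalize_frame(video$frames[[k]], tf, out_size)
    feats[j, ] <- compute_hog(nf, pipeline$hog)
  }
  Z <- pca_project(feats, pipeline$pca)
  pred <- predict_frames(pipeline$plda, Z)
  v <- vote(pred$class)
  list(video_id = video$video_id, class = v$class, fractions = v$fractions,
       n_frames_used = length(okf), n_frames_failed = ex$n_failed,
       excluded = FALSE, frame_classes = pred$class)
}
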