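# Frame descriptors: histograms of oriented gradients (HoG) over the
# normalized face, followed by a PCA retaining 95% of training variance.
# The HoG configuration follows the method's stated settings: 9 unsigned
# orientation bins per cell, 8x8-pixel cells, 2x2 cells per block; blocks
# overlap with stride one cell and are L2-Hys normalized.

#' HoG configuration
#'
#' @param n_orientations number of orientation bins over `[0, 180)` degrees
#'   (unsigned gradients) or `[0, 360)` (signed).
#' @param cell_size cell side, pixels; must divide the image side.
#' @param block_size block side, cells.
#' @param block_stride block stride, cells.
#' @param normalization block normalization: `"l2hys"` (L2-normalize, clip
#'   at 0.2, renormalize), `"l2"`, or `"none"`.
#' @param norm_eps block-normalization regularizer, on the scale of block
#'   gradient energy for intensities in `[0, 1]`: norms are computed as
#'   `sqrt(sum(v^2) + norm_eps^2)`, so blocks with little gradient energy
#'   (flat background) stay near zero instead of being amplified into
#'   resampling noise.
#' @param signed_gradients use signed gradient directions.
#' @return an object of class `fw_hog_config`.
#' @export
hog_config <- function(n_orientations = 9, cell_size = 8, block_size = 2,
                       block_stride = 1, normalization = "l2hys",
                       norm_eps = 0.5, signed_gradients = FALSE) {
  normalization <- match.arg(normalization, c("l2hys", "l2", "none"))
  stopifnot(n_orientations >= 2, cell_size >= 2, block_size >= 1,
            block_stride >= 1, block_stride <= block_size, norm_eps >= 0)
  structure(list(n_orientations = as.integer(n_orientations),
                 cell_size = as.integer(cell_size),
                 block_size = as.integer(block_size),
                 block_stride = as.integer(block_stride),
                 normalization = normalization, norm_eps = norm_eps,
                 signed_gradients = signed_gradients),
            class = "fw_hog_config")
}

#' Length of the HoG descriptor for a given image size
#' @param image_size square image side, pixels.
#' @param config an [hog_config()].
#' @return integer descriptor length.
#' @export
hog_length <- function(image_size, config = hog_config()) {
  nc <- image_size %/% config$cell_size
  nb <- (nc - config$block_size) %/% config$block_stride + 1L
  nb * nb * config$block_size^2 * config$n_orientations
}

#' Histogram-of-oriented-gradients descriptor of one frame
#'
#' Gradients are computed with `[-1, 0, 1]` central differences (edge rows
#' and columns use the one-sided difference). Each pixel votes its gradient
#' magnitude into the two orientation bins adjacent to its gradient
#' direction, split linearly; votes are pooled per cell (hard spatial
#' assignment, so total histogram mass equals total gradient magnitude),
#' grouped into overlapping blocks and block-normalized, then concatenated
#' in row-major block order (within a block: cells row-major, then bins).
#'
#' @param image numeric matrix (rows = y, cols = x); side lengths must be
#'   multiples of the cell size and equal.
#' @param config an [hog_config()].
#' @return numeric descriptor vector (all entries >= 0).
#' @export
compute_hog <- function(image, config = hog_config()) {
  stopifnot(is.matrix(image), nrow(image) == ncol(image))
  n <- nrow(image)
  cs <- config$cell_size
  if (n %% cs != 0) stop("image side must be a multiple of the cell size")
  nbin <- config$n_orientations

  # central differences; replicate-padded borders -> one-sided at edges
  xr <- image[, c(2:n, n), drop = FALSE] - image[, c(1, 1:(n - 1)), drop = FALSE]
  yr <- image[c(2:n, n), , drop = FALSE] - image[c(1, 1:(n - 1)), , drop = FALSE]
  gx <- as.numeric(xr); gy <- as.numeric(yr)
  mag <- sqrt(gx^2 + gy^2)
  ang <- atan2(gy, gx)
  period <- if (config$signed_gradients) 2 * pi else pi
  ang <- ang %% period
  # linear interpolation between the two adjacent orientation bins
  b <- ang / (period / nbin) - 0.5
  b0 <- floor(b)
  w1 <- b - b0
  bin0 <- (b0 %% nbin) + 1L
  bin1 <- (bin0 %% nbin) + 1L

  ncell <- n %/% cs
  col_ix <- rep(seq_len(n), each = n)  # column-major: row fastest
  row_ix <- rep(seq_len(n), times = n)
  cell_id <- ((col_ix - 1L) %/% cs) * ncell + ((row_ix - 1L) %/% cs) + 1L
  K <- ncell * ncell * nbin
  acc <- numeric(K)
  id0 <- (cell_id - 1L) * nbin + bin0
  id1 <- (cell_id - 1L) * nbin + bin1
  s0 <- rowsum(mag * (1 - w1), id0)
  s1 <- rowsum(mag * w1, id1)
  acc[as.integer(rownames(s0))] <- acc[as.integer(rownames(s0))] + s0[, 1]
  acc[as.integer(rownames(s1))] <- acc[as.integer(rownames(s1))] + s1[, 1]
  # hist[bin, cell_row, cell_col]
  hist <- array(acc, dim = c(nbin, ncell, ncell))

  bs <- config$block_size; stv <- config$block_stride
  nb <- (ncell - bs) %/% stv + 1L
  out <- vector("list", nb * nb)
  k <- 0L
  for (br in seq_len(nb)) {
    for (bc in seq_len(nb)) {
      r0 <- (br - 1L) * stv; c0 <- (bc - 1L) * stv
      v <- numeric(bs * bs * nbin)
      m <- 0L
      for (cr in seq_len(bs)) {          # cells row-major within the block
        for (cc in seq_len(bs)) {
          v[m + seq_len(nbin)] <- hist[, r0 + cr, c0 + cc]
          m <- m + nbin
        }
      }
      if (config$normalization != "none") {
        eps2 <- config$norm_eps^2 + 1e-20
        v <- v / sqrt(sum(v^2) + eps2)
        if (config$normalization == "l2hys") {
          v <- pmin(v, 0.2)
          v <- v / sqrt(sum(v^2) + eps2)
        }
      }
      k <- k + 1L
      out[[k]] <- v
    }
  }
  unlist(out, use.names = FALSE)
}

#' Raw (unnormalized) per-cell HoG histograms
#'
#' Cell histograms before block grouping/normalization; their total mass
#' equals the total gradient magnitude of the image.
#'
#' @inheritParams compute_hog
#' @return array `[bin, cell_row, cell_col]`.
#' @export
hog_cell_histograms <- function(image, config = hog_config()) {
  cfg <- config; cfg$normalization <- "none"
  n <- nrow(image); cs <- cfg$cell_size; nbin <- cfg$n_orientations
  ncell <- n %/% cs
  # recompute via compute_hog internals would double-normalize; simplest is
  # a one-block-per-cell pass with no normalization
  cfg$block_size <- 1L; cfg$block_stride <- 1L
  v <- compute_hog(image, cfg)
  # blocks are single cells in row-major (cell_row, cell_col) order
  arr <- array(0, dim = c(nbin, ncell, ncell))
  k <- 0L
  for (br in seq_len(ncell)) for (bc in seq_len(ncell)) {
    arr[, br, bc] <- v[k + seq_len(nbin)]; k <- k + nbin
  }
  arr
}

#' Fit a PCA projection on training feature vectors
#'
#' Components are computed from the training set only (SVD of the centred
#' matrix); the number of components kept is the smallest k whose
#' cumulative explained variance reaches `variance_target`. Component signs
#' are fixed by convention: the largest-magnitude loading of each component
#' is positive.
#'
#' @param X numeric matrix, rows = training feature vectors (>= 2 rows).
#' @param variance_target fraction of variance to retain, in (0, 1].
#' @return an object of class `fw_pca`: `mean`, `rotation` (columns =
#'   components, orthonormal), `n_components`, `explained` (per-component
#'   variance fractions), `variance_target`.
#' @export
fit_pca <- function(X, variance_target = 0.95) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need at least 2 training vectors")
  if (!is.numeric(variance_target) || variance_target <= 0 ||
      variance_target > 1) stop("variance_target must be in (0, 1]")
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc, nu = 0)
  var_all <- sv$d^2
  tot <- sum(var_all)
  if (tot < 1e-24) stop("training features have zero variance")
  frac <- var_all / tot
  keep <- frac > 1e-12            # drop numerically null directions
  cum <- cumsum(frac)
  k <- which(cum >= variance_target - 1e-12)[1]
  k <- min(k, sum(keep))
  rot <- sv$v[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) rot[, j] <- -rot[, j]
  }
  structure(list(mean = mu, rotation = rot, n_components = k,
                 explained = frac[seq_len(k)],
                 variance_target = variance_target),
            class = "fw_pca")
}

#' @export
print.fw_pca <- function(x, ...) {
  cat(sprintf("<fw_pca: %d components, %.1f%% variance retained>\n",
              x$n_components, 100 * sum(x$explained)))
  invisible(x)
}

#' Project feature vectors onto a fitted PCA basis
#' @param x numeric vector or matrix (rows = observations).
#' @param projection an `fw_pca`.
#' @return matrix of scores (rows = observations, cols = components).
#' @export
pca_project <- function(x, projection) {
  stopifnot(inherits(projection, "fw_pca"))
  x <- rbind(x)
  if (ncol(x) != length(projection$mean))
    stop("feature dimension does not match the projection")
  sweep(x, 2, projection$mean) %*% projection$rotation
}
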