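# Independent oracles used to cross-check the implementation. These are
# deliberately written as naive loops / direct formulas, sharing no code
# with the package internals.

# brute-force HoG: per-pixel gradients, orientation binning and block
# normalization computed with explicit loops.
hog_oracle <- function(img, cfg = hog_config()) {
  n <- nrow(img); cs <- cfg$cell_size; nbin <- cfg$n_orientations
  ncell <- n %/% cs
  hist <- array(0, c(nbin, ncell, ncell))
  for (y in 1:n) for (x in 1:n) {
    xm <- max(x - 1, 1); xp <- min(x + 1, n)
    ym <- max(y - 1, 1); yp <- min(y + 1, n)
    gx <- img[y, xp] - img[y, xm]
    gy <- img[yp, x] - img[ym, x]
    mag <- sqrt(gx^2 + gy^2)
    if (mag == 0) next
    ang <- atan2(gy, gx) %% pi
    b <- ang / (pi / nbin) - 0.5
    b0 <- floor(b); w1 <- b - b0
    i0 <- (b0 %% nbin) + 1; i1 <- (i0 %% nbin) + 1
    cr <- (y - 1) %/% cs + 1; cc <- (x - 1) %/% cs + 1
    hist[i0, cr, cc] <- hist[i0, cr, cc] + mag * (1 - w1)
    hist[i1, cr, cc] <- hist[i1, cr, cc] + mag * w1
  }
  bs <- cfg$block_size; stv <- cfg$block_stride
  nb <- (ncell - bs) %/% stv + 1
  out <- c()
  for (br in 1:nb) for (bc in 1:nb) {
    v <- c()
    for (cr in 1:bs) for (cc in 1:bs)
      v <- c(v, hist[, (br - 1) * stv + cr, (bc - 1) * stv + cc])
    eps2 <- cfg$norm_eps^2 + 1e-20
    v <- v / sqrt(sum(v^2) + eps2)
    v <- pmin(v, 0.2)
    v <- v / sqrt(sum(v^2) + eps2)
    out <- c(out, v)
  }
  out
}

# dense generalized-eigenvalue oracle for Fisher/penalized LDA directions
lda_direction_oracle <- function(X, y, lambda = 0) {
  f <- factor(y)
  d <- ncol(X); mu <- colMeans(X)
  Sw <- matrix(0, d, d); Sb <- matrix(0, d, d)
  for (cl in levels(f)) {
    Xi <- X[f == cl, , drop = FALSE]
    mi <- colMeans(Xi)
    Sw <- Sw + crossprod(sweep(Xi, 2, mi))
    Sb <- Sb + nrow(Xi) * tcrossprod(mi - mu)
  }
  Sw <- Sw / (nrow(X) - nlevels(f))
  Sb <- Sb / (nlevels(f) - 1)
  eg <- eigen(solve(Sw + lambda * diag(d)) %*% Sb)
  Re(eg$vectors[, seq_len(nlevels(f) - 1), drop = FALSE])
}

angle_between <- function(a, b) {
  acos(min(1, abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))))
}

make_gaussians <- function(n = 100, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(2 * n), n, 2),
             sweep(matrix(rnorm(2 * n), n, 2), 2, c(4, 1), `+`))
  list(X = X, y = rep(c("normal", "left"), each = n))
}

# exhaustive hypergeometric enumeration for the two-sided Fisher p
fisher_oracle <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
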