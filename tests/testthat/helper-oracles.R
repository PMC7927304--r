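# Independent brute-force oracles and small fixtures used across the suite.
# These deliberately avoid the package's own code paths.

# --- statistics oracles -----------------------------------------------------

oracle_welch_t <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  v1 <- var(a); v2 <- var(b)
  se2 <- v1 / n1 + v2 / n2
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

oracle_welch_anova <- function(groups) {
  k <- length(groups)
  n <- vapply(groups, length, 0L)
  m <- vapply(groups, mean, 0)
  v <- vapply(groups, var, 0)
  w <- n / v
  mw <- sum(w * m) / sum(w)
  A <- sum(w * (m - mw)^2) / (k - 1)
  B <- 1 + 2 * (k - 2) / (k^2 - 1) * sum((1 - w / sum(w))^2 / (n - 1))
  Fst <- A / B
  df2 <- (k^2 - 1) / (3 * sum((1 - w / sum(w))^2 / (n - 1)))
  list(F = Fst, df1 = k - 1, df2 = df2, p = pf(Fst, k - 1, df2, lower.tail = FALSE))
}

# Step-up BH from the definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# Group F in outcome ~ bmi + group via explicit projection matrices.
oracle_ancova_F <- function(outcome, group, bmi) {
  G <- model.matrix(~ factor(group))[, -1, drop = FALSE]
  X0 <- cbind(1, bmi)
  X1 <- cbind(X0, G)
  H <- function(X) X %*% solve(crossprod(X)) %*% t(X)
  r0 <- sum((outcome - H(X0) %*% outcome)^2)
  r1 <- sum((outcome - H(X1) %*% outcome)^2)
  q <- ncol(G)
  dfres <- length(outcome) - ncol(X1)
  ((r0 - r1) / q) / (r1 / dfres)
}

# Per-voxel OLS t by explicit normal equations, one voxel at a time.
oracle_glm_t <- function(Y, X, contrast) {
  apply(Y, 2, function(y) {
    XtXi <- solve(t(X) %*% X)
    b <- XtXi %*% t(X) %*% y
    r <- y - X %*% b
    s2 <- sum(r^2) / (nrow(X) - ncol(X))
    drop(t(contrast) %*% b) / sqrt(drop(t(contrast) %*% XtXi %*% contrast) * s2)
  })
}

# --- geometry oracles -------------------------------------------------------

# Voxels visited by a polyline, by dense sampling of each segment.
oracle_voxels <- function(points, affine, dims, nsamp = 6000) {
  inv <- solve(affine)
  v <- t(inv %*% rbind(t(points), 1))[, 1:3, drop = FALSE]
  out <- integer(0)
  for (s in seq_len(nrow(v) - 1)) {
    t <- seq(0, 1, length.out = nsamp)
    P <- outer(t, v[s + 1, ] - v[s, ]) + rep(v[s, ], each = nsamp)
    idx <- floor(P + 0.5)
    ok <- idx[, 1] >= 0 & idx[, 1] < dims[1] & idx[, 2] >= 0 & idx[, 2] < dims[2] &
      idx[, 3] >= 0 & idx[, 3] < dims[3]
    out <- c(out, 1 + idx[ok, 1] + dims[1] * (idx[ok, 2] + dims[2] * idx[ok, 3]))
  }
  sort(unique(out))
}

# Max inter-segment angle by direct dot products.
oracle_max_turn <- function(p) {
  d <- diff(p)
  d <- d / sqrt(rowSums(d^2))
  if (nrow(d) < 2) return(0)
  ang <- acos(pmin(pmax(rowSums(d[-nrow(d), , drop = FALSE] * d[-1, , drop = FALSE]), -1), 1))
  max(ang) * 180 / pi
}

# Direct discrete Gaussian convolution with an explicit 3-D kernel.
oracle_convolve <- function(arr, sigma_vox) {
  r <- max(1L, ceiling(3.5 * max(sigma_vox)))
  off <- expand.grid(i = -r:r, j = -r:r, k = -r:r)
  k1 <- function(s) { x <- exp(-(-r:r)^2 / (2 * s^2)); x / sum(x) }
  w <- k1(sigma_vox[1])[off$i + r + 1] * k1(sigma_vox[2])[off$j + r + 1] *
    k1(sigma_vox[3])[off$k + r + 1]
  d <- dim(arr)
  out <- array(0, d)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    xi <- x + off$i; yi <- y + off$j; zi <- z + off$k
    ok <- xi >= 1 & xi <= d[1] & yi >= 1 & yi <= d[2] & zi >= 1 & zi <= d[3]
    out[x, y, z] <- sum(w[ok] * arr[cbind(xi[ok], yi[ok], zi[ok])])
  }
  out
}

# --- fixtures ---------------------------------------------------------------

# A straight polyline along +x at (y0, z0), world mm.
straight_line <- function(x0, x1, y0, z0, step = 0.5) {
  xs <- seq(x0, x1, by = step)
  cbind(xs, y0, z0)
}

# Polyline turning `turn_deg` at every vertex in the xy plane.
turning_line <- function(n_seg, turn_deg, step = 1, start = c(5, 5, 5)) {
  ang <- cumsum(c(0, rep(turn_deg * pi / 180, n_seg - 1)))
  d <- cbind(cos(ang), sin(ang), 0) * step
  rbind(start, start + apply(d, 2, cumsum))
}

# Single-bundle straight-tube phantom used by tracking tests.
tube_phantom <- function(len = 30, radius = 2.2) {
  phantom_spec(grid_shape = c(len + 6, 12, 12), voxel_size = c(1, 1, 1),
               bundles = list(bundle_geometry(
                 "tube", rbind(c(3, 6, 6), c(len + 3, 6, 6)),
                 radius_mm = radius, start_label = 1L, end_label = 2L)),
               blob_region = list(bundle = "tube", lo = c(8, 0, 0),
                                  hi = c(14, 12, 12)),
               correlate_region = list(bundle = "tube", lo = c(20, 0, 0),
                                       hi = c(26, 12, 12)))
}

small_cohort <- function(seed = 1, ...) {
  generate_cohort(cohort_spec(seed = seed, ...))
}
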