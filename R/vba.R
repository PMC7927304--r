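gaussian_kernel_1d <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, ceiling(3.5 * sigma_vox))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma_vox^2))
  k / sum(k)
}

# Convolve a 3-D array along one axis with a 1-D kernel (zero padding),
# via a banded convolution matrix so each axis is a single matrix product.
conv_axis <- function(arr, kernel, axis) {
  if (length(kernel) == 1L) return(arr)
  d <- dim(arr)
  perm <- switch(axis, `1` = 1:3, `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  a <- aperm(arr, perm)
  n <- dim(a)[1]
  r <- (length(kernel) - 1L) / 2L
  K <- matrix(0, n, n)
  for (j in seq_len(n)) {
    i <- (j - r):(j + r)
    ok <- i >= 1 & i <= n
    K[cbind(i[ok], j)] <- kernel[ok]
  }
  out <- K %*% matrix(a, n)
  dim(out) <- dim(a)
  aperm(out, order(perm))
}

smooth_array <- function(arr, sigma_vox) {
  for (ax in 1:3) arr <- conv_axis(arr, gaussian_kernel_1d(sigma_vox[ax]), ax)
  arr
}

#' Masked isotropic Gaussian smoothing
#'
#' Gaussian convolution restricted to a mask, with kernel renormalization at
#' the mask boundary: the smoothed field is `conv(vol * mask) / conv(mask)`
#' inside the mask, so constant fields are preserved exactly and no signal
#' bleeds in from outside.
#'
#' @param vol a [volume3d].
#' @param sigma_mm kernel standard deviation, mm (isotropic in world units).
#' @param mask optional [volume3d] binary mask (default: whole grid).
#' @return Smoothed [volume3d]; zero outside the mask.
#' @export
smooth_volume <- function(vol, sigma_mm = 1, mask = NULL) {
  check_number(sigma_mm, "sigma_mm", 0, Inf, closed_lower = FALSE)
  m <- if (is.null(mask)) array(1, dim(vol$grid)) else {
    check_same_space(vol, mask, "volume and mask")
    (mask$grid > 0) + 0
  }
  sig <- sigma_mm / voxel_sizes(vol)
  num <- smooth_array(vol$grid * m, sig)
  den <- smooth_array(m, sig)
  out <- array(0, dim(vol$grid))
  inside <- m > 0 & den > 0
  out[inside] <- num[inside] / den[inside]
  volume3d(out, vol$affine, vol$space)
}

#' Smooth every subject volume of an FA stack
#'
#' @param stack an `fa_stack`.
#' @param sigma_mm kernel SD in mm.
#' @param mask optional mask [volume3d].
#' @return A smoothed `fa_stack`.
#' @export
smooth_stack <- function(stack, sigma_mm = 1, mask = NULL) {
  n <- dim(stack$data)[4]
  for (i in seq_len(n)) {
    v <- smooth_volume(volume3d(stack$data[, , , i], stack$affine, stack$space),
                       sigma_mm, mask)
    stack$data[, , , i] <- v$grid
  }
  stack
}

#' Build a voxel-wise GLM design from a cohort table
#'
#' Constructs the design matrix (intercept, effect of interest, covariates)
#' and contrast for the standard analyses: the two-class group contrasts
#' and the one-class (within-group) accuracy/trait-prediction-error
#' regressions. Sex is coded 0/1 and all covariates are mean-centered
#' (this leaves contrast t values unchanged and improves conditioning).
#'
#' @param cohort cohort table.
#' @param contrast one of `"group-2class"` (all patients vs controls),
#'   `"seiz-vs-hc"`, `"movt-vs-hc"`, `"seiz-vs-movt"`, `"htt"`, `"itpe"`.
#' @param scores data frame from [score_cohort()] (required for the
#'   one-class analyses, which are restricted to patients with usable ECG).
#' @param covariates character vector of covariate column names; defaults to
#'   age, sex, head motion, depression and trait anxiety for between-group
#'   contrasts, plus BMI for within-group analyses.
#' @return List of class `vba_design`: `X`, `contrast` weights, `type`
#'   (`"two-sample"` or `"continuous"`), subject `rows` of the cohort used,
#'   and group sizes for two-sample contrasts.
#' @export
vba_design <- function(cohort,
                       contrast = c("group-2class", "seiz-vs-hc", "movt-vs-hc",
                                    "seiz-vs-movt", "htt", "itpe"),
                       scores = NULL, covariates = NULL) {
  contrast <- match.arg(contrast)
  two_sample <- contrast %in% c("group-2class", "seiz-vs-hc", "movt-vs-hc",
                                "seiz-vs-movt")
  if (two_sample) {
    keep <- switch(contrast,
                   "group-2class" = rep(TRUE, nrow(cohort)),
                   "seiz-vs-hc" = cohort$group %in% c("FND-seiz", "HC"),
                   "movt-vs-hc" = cohort$group %in% c("FND-movt", "HC"),
                   "seiz-vs-movt" = cohort$group %in% c("FND-seiz", "FND-movt"))
    sub <- cohort[keep, , drop = FALSE]
    g1 <- switch(contrast, "group-2class" = sub$group != "HC",
                 "seiz-vs-hc" = sub$group == "FND-seiz",
                 "movt-vs-hc" = sub$group == "FND-movt",
                 "seiz-vs-movt" = sub$group == "FND-seiz")
    effect <- as.numeric(g1)
    covariates <- covariates %||% c("age", "sex", "head_motion", "bdi", "stai_trait")
    n1 <- sum(g1); n2 <- sum(!g1)
  } else {
    if (is.null(scores)) stop_input("one-class analyses need 'scores'")
    keep <- cohort$id %in% scores$id & cohort$group != "HC"
    sub <- cohort[keep, , drop = FALSE]
    effect <- scores[[if (contrast == "htt") "htt" else "itpe"]][
      match(sub$id, scores$id)]
    covariates <- covariates %||% c("age", "sex", "bmi", "head_motion", "bdi",
                                    "stai_trait")
    n1 <- n2 <- NULL
  }
  X <- cbind(intercept = 1, effect = effect)
  for (cv in covariates) {
    x <- sub[[cv]]
    if (is.null(x)) stop_input("covariate '", cv, "' not found in cohort")
    if (cv == "sex") x <- as.numeric(x == "M")
    X <- cbind(X, scale(x, center = TRUE, scale = FALSE)[, 1])
    colnames(X)[ncol(X)] <- cv
  }
  if (qr(X)$rank < ncol(X)) stop_input("design matrix is rank deficient")
  structure(list(X = X, contrast = c(0, 1, rep(0, length(covariates))),
                 type = if (two_sample) "two-sample" else "continuous",
                 rows = which(keep), n1 = n1, n2 = n2),
            class = "vba_design")
}

#' Voxel-wise general linear model
#'
#' Ordinary least squares per voxel inside the mask; returns the t statistic
#' for the supplied contrast with `df = n - p` residual degrees of freedom.
#'
#' @param stack an `fa_stack` (use [vba_design()]'s `rows` subset
#'   automatically when `design` carries one).
#' @param design a `vba_design`, or a plain numeric design matrix.
#' @param mask [volume3d] analysis mask.
#' @param contrast contrast weight vector (ignored when `design` is a
#'   `vba_design`).
#' @return Object of class `stat_map`: `t` (3-D array, `NA` outside the
#'   mask), `df`, `mask`, design metadata, and the residual matrix used for
#'   smoothness estimation.
#' @export
fit_voxelwise_glm <- function(stack, design, mask, contrast = NULL) {
  if (inherits(design, "vba_design")) {
    X <- design$X
    contrast <- design$contrast
    rows <- design$rows
    meta <- design
  } else {
    X <- as.matrix(design)
    if (is.null(contrast)) stop_input("a contrast vector is required")
    rows <- seq_len(dim(stack$data)[4])
    meta <- list(type = "custom", n1 = NULL, n2 = NULL)
  }
  if (length(contrast) != ncol(X)) stop_input("contrast length != design columns")
  n <- nrow(X); p <- ncol(X)
  if (length(rows) != n) stop_input("stack length != design rows")
  if (n <= p) stop_input("no residual degrees of freedom (n <= p)")
  if (qr(X)$rank < p) stop_input("design matrix is rank deficient")
  dims <- dim(stack$data)[1:3]
  if (!identical(dims, dim(mask$grid))) stop_input("mask does not match the stack grid")
  mvox <- which(mask$grid > 0)
  Y <- matrix(stack$data[, , , rows, drop = FALSE], prod(dims), n)[mvox, , drop = FALSE]
  Y <- t(Y)                                    # n x V
  XtXinv <- solve(crossprod(X))
  beta <- XtXinv %*% crossprod(X, Y)
  res <- Y - X %*% beta
  df <- n - p
  sigma2 <- colSums(res^2) / df
  cvar <- drop(t(contrast) %*% XtXinv %*% contrast)
  tval <- drop(crossprod(contrast, beta)) / sqrt(pmax(cvar * sigma2, .Machine$double.xmin))
  tval[sigma2 == 0] <- 0
  tarr <- array(NA_real_, dims)
  tarr[mvox] <- tval
  structure(list(t = tarr, df = df, mask = mask, affine = stack$affine,
                 space = stack$space, n = n, p = p,
                 type = meta$type, n1 = meta$n1, n2 = meta$n2,
                 residuals = res, mask_voxels = mvox),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("<stat_map> %s contrast, n = %d, df = %d\n", x$type, x$n, x$df))
  cat(sprintf("  t in [%.2f, %.2f] over %d mask voxels\n",
              min(x$t, na.rm = TRUE), max(x$t, na.rm = TRUE),
              length(x$mask_voxels)))
  invisible(x)
}

#' @export
plot.stat_map <- function(x, z = NULL, ...) {
  v <- volume3d(ifelse(is.na(x$t), 0, x$t), x$affine, x$space)
  plot(v, z = z, ...)
}

#' Cohen's d from a t statistic
#'
#' Two-sample contrasts use `d = |t| * sqrt(1/n1 + 1/n2)`; continuous
#' (correlation-style) contrasts use `d = |t| / sqrt(n)`, the convention
#' that reproduces the published within-group effect sizes.
#'
#' @param t t statistic.
#' @param n1,n2 group sizes (two-sample form).
#' @param n sample size (correlation form).
#' @param type `"two-sample"` or `"correlation"`.
#' @return Effect-size magnitude.
#' @export
cohens_d <- function(t, n1 = NULL, n2 = NULL, n = NULL,
                     type = c("two-sample", "correlation")) {
  type <- match.arg(type)
  if (!is.finite(t)) stop_input("'t' must be finite")
  if (type == "two-sample") {
    if (is.null(n1) || is.null(n2)) stop_input("two-sample form needs n1 and n2")
    abs(t) * sqrt(1 / n1 + 1 / n2)
  } else {
    if (is.null(n)) stop_input("correlation form needs n")
    abs(t) / sqrt(n)
  }
}

#' Estimate residual spatial smoothness (FWHM per axis)
#'
#' Classic random-field estimator from the variance of spatial first
#' differences of the standardized GLM residuals: per axis,
#' `FWHM = sqrt(8 log 2) * dx / sqrt(2 * var(diff) / var)`, pooled over
#' residual volumes and mask voxels. For spatially white noise this returns
#' a voxel-size-scale FWHM (about 1.18 voxels); for noise smoothed with a
#' Gaussian kernel it recovers the kernel FWHM.
#'
#' @param stat a `stat_map` (its residuals are used), or an n x V residual
#'   matrix with `mask` and `voxel_size` supplied.
#' @param mask [volume3d] mask (taken from the stat map when omitted).
#' @param voxel_size mm per axis.
#' @return Named vector of per-axis FWHM (mm) with attribute `mean`
#'   (geometric mean).
#' @export
estimate_smoothness <- function(stat, mask = NULL, voxel_size = NULL) {
  if (inherits(stat, "stat_map")) {
    res <- stat$residuals
    mask <- mask %||% stat$mask
    voxel_size <- voxel_size %||% voxel_sizes(mask)
    mvox <- stat$mask_voxels
  } else {
    res <- as.matrix(stat)
    if (is.null(mask)) stop_input("a mask is required")
    voxel_size <- voxel_size %||% voxel_sizes(mask)
    mvox <- which(mask$grid > 0)
  }
  if (nrow(res) < 2L) stop_input("need at least 2 residual volumes")
  dims <- dim(mask$grid)
  marr <- array(FALSE, dims); marr[mvox] <- TRUE
  v_tot <- 0; v_diff <- c(0, 0, 0); n_diff <- c(0, 0, 0); n_tot <- 0
  for (i in seq_len(nrow(res))) {
    e <- array(NA_real_, dims)
    e[mvox] <- res[i, ]
    v_tot <- v_tot + sum(res[i, ]^2); n_tot <- n_tot + length(mvox)
    for (ax in 1:3) {
      d <- switch(ax,
                  e[-1, , , drop = FALSE] - e[-dims[1], , , drop = FALSE],
                  e[, -1, , drop = FALSE] - e[, -dims[2], , drop = FALSE],
                  e[, , -1, drop = FALSE] - e[, , -dims[3], drop = FALSE])
      ok <- !is.na(d)
      v_diff[ax] <- v_diff[ax] + sum(d[ok]^2)
      n_diff[ax] <- n_diff[ax] + sum(ok)
    }
  }
  vart <- v_tot / n_tot
  if (vart < .Machine$double.eps * 100 || all(v_diff == 0))
    stop_input("residuals are spatially constant")
  if (any(n_diff == 0)) stop_input("mask too thin to estimate smoothness")
  ratio <- (v_diff / n_diff) / vart
  fwhm <- sqrt(8 * log(2)) * voxel_size / sqrt(2 * ratio)
  names(fwhm) <- c("x", "y", "z")
  attr(fwhm, "mean") <- exp(mean(log(fwhm)))
  fwhm
}

# ---- connected components --------------------------------------------------

neighbor_offsets <- function(connectivity = 26) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  keep <- switch(as.character(connectivity),
                 "6" = rowSums(abs(g)) == 1,
                 "18" = rowSums(abs(g)) <= 2,
                 "26" = rep(TRUE, nrow(g)),
                 stop_input("connectivity must be 6, 18 or 26"))
  g[keep, , drop = FALSE]
}

# Label connected components of a logical 3-D array. Returns an integer
# array (0 = background) and a vector of component sizes.
label_components <- function(mask_arr, connectivity = 26) {
  dims <- dim(mask_arr)
  vox <- which(mask_arr)
  labels <- array(0L, dims)
  if (!length(vox)) return(list(labels = labels, sizes = integer(0)))
  offs <- neighbor_offsets(connectivity)
  coord <- arrayInd(vox, dims)
  # linear offsets are position-dependent only through boundary effects, so
  # neighbor candidates are computed from coordinates
  vmap <- array(0L, dims); vmap[vox] <- seq_along(vox)
  lab <- integer(length(vox))
  cur <- 0L
  for (s in seq_along(vox)) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    queue <- s; lab[s] <- cur
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      cc <- coord[v, ]
      nb <- sweep(offs, 2L, cc, `+`)
      ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
        nb[, 2] >= 1 & nb[, 2] <= dims[2] &
        nb[, 3] >= 1 & nb[, 3] <= dims[3]
      nb <- nb[ok, , drop = FALSE]
      ids <- vmap[nb]
      ids <- ids[ids > 0L]
      new <- ids[lab[ids] == 0L]
      if (length(new)) {
        lab[new] <- cur
        queue <- c(queue, new)
      }
    }
  }
  labels[vox] <- lab
  list(labels = labels, sizes = tabulate(lab))
}

# Kernel sigma (voxels) whose smoothed-white-noise field yields the given
# estimated FWHM (voxels) under the first-difference estimator used by
# estimate_smoothness(). Inverting the same discrete measurement keeps the
# null fields' measured smoothness equal to the residuals' instead of
# inheriting the continuous-formula discretization bias. A Gaussian ACF for
# the smoothed field gives diff-variance ratio 2*(1 - exp(-1/(4 sigma^2))).
fwhm_to_sigma_vox <- function(fwhm_vox) {
  ratio <- (sqrt(8 * log(2)) / fwhm_vox)^2 / 2
  ifelse(ratio >= 2, 0, sqrt(-1 / (4 * log(1 - ratio / 2))))
}

#' Null distribution of maximum cluster extent by Monte-Carlo simulation
#'
#' Each iteration draws Gaussian white noise on the grid, smooths it to the
#' supplied FWHM, standardizes it within the mask, applies the two-sided
#' cluster-forming threshold at the voxel probability `cft_p`, and records
#' the maximum connected-component extent (0 when nothing survives).
#'
#' @param mask [volume3d] analysis mask.
#' @param fwhm smoothness (mm); scalar or per-axis.
#' @param cft_p two-sided voxel-level cluster-forming probability.
#' @param n_iter number of iterations.
#' @param connectivity 6, 18 or 26.
#' @param seed integer seed.
#' @return Integer vector of `n_iter` maximum extents (voxels).
#' @export
mc_null_extents <- function(mask, fwhm, cft_p = 0.001, n_iter = 1000,
                            connectivity = 26, seed = 1L) {
  n_iter <- check_count(n_iter, "n_iter", min = 1L)
  check_number(cft_p, "cft_p", 0, 1, closed_lower = FALSE, closed_upper = FALSE)
  dims <- dim(mask$grid)
  mvox <- which(mask$grid > 0)
  if (!length(mvox)) stop_input("empty mask")
  sig <- fwhm_to_sigma_vox(rep_len(fwhm, 3L) / voxel_sizes(mask))
  zcrit <- stats::qnorm(1 - cft_p / 2)
  with_seed(seed, {
    vapply(seq_len(n_iter), function(i) {
      e <- smooth_array(array(stats::rnorm(prod(dims)), dims), sig)
      z <- e[mvox]
      z <- (z - mean(z)) / stats::sd(z)
      supra <- array(FALSE, dims)
      supra[mvox[abs(z) >= zcrit]] <- TRUE
      sz <- label_components(supra, connectivity)$sizes
      if (length(sz)) max(sz) else 0L
    }, 0L)
  })
}

#' Monte-Carlo cluster-wise correction
#'
#' Thresholds the observed t map two-sided at the t quantile of `cft_p`,
#' labels connected components, and assigns each component a corrected p
#' value by comparison with the Monte-Carlo null distribution of maximum
#' cluster extent under smoothness-matched Gaussian noise:
#' `p = (1 + #(null max extent >= observed extent)) / (n_iter + 1)`.
#' Clusters with corrected `p < alpha` are flagged as retained.
#'
#' @param stat a `stat_map`.
#' @param fwhm smoothness (mm) for the null fields; `NULL` estimates it from
#'   the GLM residuals via [estimate_smoothness()].
#' @param n_iter Monte-Carlo iterations (10,000 for the reference analysis).
#' @param cft_p two-sided voxel-level cluster-forming probability.
#' @param alpha cluster-level significance threshold.
#' @param connectivity 6, 18 or 26.
#' @param seed integer seed.
#' @param null_extents optional precomputed [mc_null_extents()] vector
#'   (reused across maps that share mask, smoothness and threshold).
#' @return Object of class `cluster_table`: data frame with one row per
#'   cluster (size, peak t, peak world coordinates, corrected p, sign,
#'   Cohen's d at peak, retained flag), with the label volume and call
#'   configuration as attributes.
#' @export
cluster_correct_mc <- function(stat, fwhm = NULL, n_iter = 1000, cft_p = 0.001,
                               alpha = 0.05, connectivity = 26, seed = 1L,
                               null_extents = NULL) {
  stopifnot(inherits(stat, "stat_map"))
  if (is.null(stat$df)) stop_input("stat map lacks degrees of freedom")
  check_number(alpha, "alpha", 0, 1, closed_lower = FALSE)
  fwhm <- fwhm %||% as.numeric(estimate_smoothness(stat))
  tcrit <- stats::qt(1 - cft_p / 2, stat$df)
  supra <- !is.na(stat$t) & abs(stat$t) >= tcrit
  comp <- label_components(supra, connectivity)
  if (is.null(null_extents))
    null_extents <- mc_null_extents(stat$mask, fwhm, cft_p = cft_p,
                                    n_iter = n_iter, connectivity = connectivity,
                                    seed = seed)
  n_iter <- length(null_extents)
  nclust <- length(comp$sizes)
  rows <- vector("list", nclust)
  for (k in seq_len(nclust)) {
    vox <- which(comp$labels == k)
    tv <- stat$t[vox]
    pk <- vox[which.max(abs(tv))]
    peak_t <- stat$t[pk]
    pc <- voxel_to_world(stat$affine, arrayInd(pk, dim(stat$t)) - 1)
    pcorr <- (1 + sum(null_extents >= length(vox))) / (n_iter + 1)
    d <- if (identical(stat$type, "two-sample"))
      cohens_d(peak_t, n1 = stat$n1, n2 = stat$n2)
    else cohens_d(peak_t, n = stat$n, type = "correlation")
    rows[[k]] <- data.frame(cluster = k, size = length(vox), peak_t = peak_t,
                            peak_x = pc[1], peak_y = pc[2], peak_z = pc[3],
                            p_corrected = pcorr, sign = sign(peak_t),
                            d_peak = d, retained = pcorr < alpha)
  }
  out <- if (nclust) do.call(rbind, rows) else
    data.frame(cluster = integer(0), size = integer(0), peak_t = numeric(0),
               peak_x = numeric(0), peak_y = numeric(0), peak_z = numeric(0),
               p_corrected = numeric(0), sign = numeric(0), d_peak = numeric(0),
               retained = logical(0))
  out <- out[order(-out$size), , drop = FALSE]
  structure(out, class = c("cluster_table", "data.frame"),
            labels = comp$labels, affine = stat$affine,
            config = list(fwhm = fwhm, n_iter = n_iter, cft_p = cft_p,
                          alpha = alpha, connectivity = connectivity,
                          df = stat$df, t_critical = tcrit))
}

#' @export
print.cluster_table <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("<cluster_table> %d clusters (%d retained at alpha = %g), cft p = %g, %d iterations\n",
              nrow(x), sum(x$retained), cfg$alpha, cfg$cft_p, cfg$n_iter))
  if (nrow(x)) print.data.frame(utils::head(x, 10), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Binary volume of retained clusters ("blob")
#'
#' @param clusters a `cluster_table`.
#' @param mask a [volume3d] giving grid and affine.
#' @return Binary [volume3d].
#' @export
cluster_mask <- function(clusters, mask) {
  labels <- attr(clusters, "labels")
  keep <- clusters$cluster[clusters$retained]
  volume3d(array(as.numeric(labels %in% keep), dim(labels)), mask$affine, mask$space)
}
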