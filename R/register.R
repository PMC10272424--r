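# Intensity-based registration of a skull-stripped, min-max-normalized CT
# (moving) to the atlas intensity volume (fixed): a similarity transform
# (translation + rotation + isotropic scale) optimized by Nelder-Mead under
# a multi-resolution pyramid, followed by a cubic B-spline free-form
# deformation refined by greedy per-control-point coordinate ascent. Both
# stages maximize binned mutual information and only ever accept parameter
# updates that do not decrease it.

#' Registration settings
#'
#' @param bins number of histogram bins for mutual information.
#' @param levels pyramid downsampling factors for the similarity stage,
#'   coarse to fine.
#' @param iterations Nelder-Mead iteration cap per pyramid level.
#' @param bspline_spacing control-point spacing in finest-level voxels.
#' @param bspline_levels pyramid factors for the B-spline stage.
#' @param bspline_sweeps greedy optimization sweeps over all control points
#'   per B-spline level; 0 disables the B-spline stage in pipelines.
#' @param bspline_step trial displacement step (voxels) per control point.
#' @param bspline_min_gain minimum MI gain (bits) required to accept a
#'   control-point move; guards against chasing histogram noise.
#' @param smooth_sigma Gaussian prefilter width (voxels) applied to both
#'   images before the metric is evaluated; 0 disables.
#' @param rotation_starts half-width (degrees) of the coarsest-level
#'   rotation multi-start grid (`{-g, 0, g}` per axis, 27 starts); 0
#'   disables restarts.
#' @return A list of class `register_control`.
#' @export
register_control <- function(bins = 48, levels = c(4, 2, 1),
                             iterations = 100, bspline_spacing = 8,
                             bspline_levels = c(2), bspline_sweeps = 2,
                             bspline_step = 1, bspline_min_gain = 2e-4,
                             rotation_starts = 7,
                             smooth_sigma = 1.0) {
  if (bins < 2) hm_stop("bins must be >= 2", "hemomap_bad_config")
  structure(list(bins = as.integer(bins), levels = as.integer(levels),
                 iterations = as.integer(iterations),
                 rotation_starts = as.numeric(rotation_starts),
                 smooth_sigma = as.numeric(smooth_sigma),
                 bspline_spacing = as.numeric(bspline_spacing),
                 bspline_levels = as.integer(bspline_levels),
                 bspline_sweeps = as.integer(bspline_sweeps),
                 bspline_step = as.numeric(bspline_step),
                 bspline_min_gain = as.numeric(bspline_min_gain)),
            class = "register_control")
}

smooth_for_metric <- function(a, sigma) {
  if (is.null(sigma) || sigma <= 0) return(a)
  gauss_smooth3(a, sigma)
}

mi_vec <- function(x, y, bins) {
  rx <- range(x); ry <- range(y)
  if (rx[2] <= rx[1]) rx[2] <- rx[1] + 1
  if (ry[2] <= ry[1]) ry[2] <- ry[1] + 1
  h <- cpp_joint_hist(x, y, as.integer(bins), rx[1], rx[2], ry[1], ry[2])
  p <- h / sum(h)
  px <- rowSums(p)
  py <- colSums(p)
  nz <- which(p > 0)
  denom <- outer(px, py)
  sum(p[nz] * log2(p[nz] / denom[nz]))
}

#' Mutual information and binned entropy of volumes
#'
#' `mutual_information()` computes the binned mutual information (bits)
#' between two volumes on identical geometry: the joint histogram is taken
#' over `bins` equal-width bins spanning each volume's own intensity range,
#' normalized to joint frequencies `p(i, j)`, and
#' `MI = sum p(i,j) log2(p(i,j) / (p_x(i) p_y(j)))` with zero-probability
#' cells contributing 0. `binned_entropy()` is the matching marginal Shannon
#' entropy, so `mutual_information(x, x) == binned_entropy(x)`.
#'
#' @param a,b `scalar_volume`s (or plain numeric arrays of equal length).
#' @param bins number of equal-width bins (>= 2).
#' @return Mutual information (respectively entropy) in bits.
#' @export
mutual_information <- function(a, b, bins = 32) {
  if (bins < 2) hm_stop("bins must be >= 2", "hemomap_bad_config")
  if (inherits(a, "hemomap_volume") && inherits(b, "hemomap_volume"))
    require_same_geometry(a, b)
  da <- if (inherits(a, "hemomap_volume")) a$data else a
  db <- if (inherits(b, "hemomap_volume")) b$data else b
  if (length(da) != length(db))
    hm_stop("volumes must have the same number of voxels",
            "hemomap_geometry_mismatch")
  mi_vec(as.numeric(da), as.numeric(db), bins)
}

#' @rdname mutual_information
#' @param x a `scalar_volume` or numeric array.
#' @export
binned_entropy <- function(x, bins = 32) {
  dx <- as.numeric(if (inherits(x, "hemomap_volume")) x$data else x)
  rx <- range(dx)
  if (rx[2] <= rx[1]) return(0)
  w <- (rx[2] - rx[1]) / bins
  idx <- pmin(floor((dx - rx[1]) / w), bins - 1)  # same binning as the joint histogram
  h <- tabulate(idx + 1L, nbins = bins)
  p <- h / sum(h)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Block-mean downsampling by integer factor f (trailing remainder cropped).
downsample_mean <- function(a, f) {
  if (f == 1) return(a)
  d <- dim(a)
  dn <- d %/% f
  a <- a[seq_len(dn[1] * f), seq_len(dn[2] * f), seq_len(dn[3] * f),
         drop = FALSE]
  for (ax in 1:3) {
    d <- dim(a)
    m <- matrix(a, nrow = f)
    a <- array(colMeans(m), c(d[1] %/% f, d[2], d[3]))
    a <- aperm(a, c(2, 3, 1))
  }
  a
}

# Full-resolution affine for parameters th = (t1..t3, r1..r3, s):
# y = s R (x - c_f) + c_m + t
param_affine <- function(th, c_f, c_m) {
  L <- th[7] * rot_matrix(th[4:6])
  cbind(L, c_m + th[1:3] - L %*% c_f)
}

# MI of fixed level volume vs moving level volume warped by th (+ optional
# dense field in full-resolution voxel units, sampled on the level grid).
mi_warped <- function(th, fixed_l, moving_l, f, c_f, c_m, bins,
                      field = NULL) {
  A <- param_affine(th, c_f, c_m)
  off1 <- (f - 1) / 2
  Ap <- cbind(f * A[, 1:3], A[, 4] - A[, 1:3] %*% rep(off1, 3))
  w <- cpp_warp(moving_l$vec, moving_l$dim, dim(fixed_l), Ap, field,
                rep(f, 3), rep(-off1, 3), FALSE, 0)
  mi_vec(as.numeric(fixed_l), w, bins)
}

#' Register a CT to the atlas with a similarity transform
#'
#' Optimizes translation, rotation and isotropic scale to maximize the
#' binned mutual information between the fixed (atlas) volume and the warped
#' moving (CT) volume, coarse-to-fine over a multi-resolution pyramid. A
#' level's result is only accepted if it does not decrease the
#' full-resolution MI, so the reported per-level MI is non-decreasing and
#' the final MI is at least the MI of the identity alignment. Both inputs
#' are expected skull-stripped and min-max normalized.
#'
#' @param moving,fixed `scalar_volume`s (CT and atlas intensity).
#' @param control a [register_control()].
#' @return List with `transform` (a `spatial_transform`, atlas grid to
#'   subject grid, dense part empty) and `report` (final MI in bits,
#'   per-level MI, iteration counts, convergence flag).
#' @export
register_similarity <- function(moving, fixed, control = register_control()) {
  stopifnot(inherits(moving, "scalar_volume"), inherits(fixed, "scalar_volume"))
  dim_f <- dim(fixed$data)
  dim_m <- dim(moving$data)
  c_f <- (dim_f + 1) / 2
  c_m <- (dim_m + 1) / 2
  # light Gaussian prefilter: regularizes the MI surface (voxel noise makes
  # it multimodal and biases the scale estimate)
  fdat <- smooth_for_metric(fixed$data, control$smooth_sigma)
  mdat <- smooth_for_metric(moving$data, control$smooth_sigma)
  lv <- function(a, f) {
    d <- downsample_mean(a, f)
    list(vec = as.numeric(d), dim = dim(d))
  }
  th <- c(0, 0, 0, 0, 0, 0, 1)
  fixed_full <- lv(fdat, 1)
  moving_full <- lv(mdat, 1)
  mi_full <- function(p) mi_warped(p, array(fixed_full$vec, dim_f),
                                   moving_full, 1, c_f, c_m, control$bins)
  best_mi <- mi_full(th)
  mi_per_level <- numeric(0)
  iters <- integer(0)
  conv <- TRUE
  first <- TRUE
  for (f in control$levels) {
    if (min(dim_f %/% f, dim_m %/% f) < 8) next
    fx <- downsample_mean(fdat, f)
    mv <- lv(mdat, f)
    obj <- function(p) mi_warped(p, fx, mv, f, c_f, c_m, control$bins)
    # the MI surface is multimodal in the rotations: at the coarsest level,
    # restart Nelder-Mead from a grid of rotation offsets and keep the best
    starts <- list(th)
    if (first && control$rotation_starts > 0) {
      g <- control$rotation_starts
      for (rx in c(-g, 0, g)) for (ry in c(-g, 0, g)) for (rz in c(-g, 0, g))
        if (rx || ry || rz)
          starts <- c(starts, list(th + c(0, 0, 0, rx, ry, rz, 0)))
      first <- FALSE
    }
    lvl_best <- NULL
    lvl_mi <- -Inf
    it <- 0L
    for (s0 in starts) {
      fit <- tryCatch(
        stats::optim(s0, obj, method = "Nelder-Mead",
                     control = list(maxit = control$iterations,
                                    fnscale = -1,
                                    parscale = c(rep(2, 3), rep(2, 3),
                                                 0.02))),
        error = function(e) NULL)
      if (is.null(fit)) { conv <- FALSE; next }
      it <- it + fit$counts[1]
      if (fit$value > lvl_mi) { lvl_mi <- fit$value; lvl_best <- fit$par }
    }
    # restarting resets the simplex around the incumbent, which lets
    # Nelder-Mead escape the collapsed simplexes it is prone to in 7D
    for (rs in seq_len(3)) {
      if (is.null(lvl_best)) break
      fit <- tryCatch(
        stats::optim(lvl_best, obj, method = "Nelder-Mead",
                     control = list(maxit = control$iterations,
                                    fnscale = -1,
                                    parscale = c(rep(2, 3), rep(2, 3),
                                                 0.02))),
        error = function(e) NULL)
      if (is.null(fit)) break
      it <- it + fit$counts[1]
      gain <- fit$value - lvl_mi
      if (fit$value > lvl_mi) { lvl_mi <- fit$value; lvl_best <- fit$par }
      if (gain < 1e-4) break
    }
    iters <- c(iters, it)
    if (!is.null(lvl_best)) {
      cand <- mi_full(lvl_best)
      if (cand >= best_mi) { th <- lvl_best; best_mi <- cand }
    }
    mi_per_level <- c(mi_per_level, best_mi)
  }
  st <- similarity_transform(translation = th[1:3] + (c_m - c_f),
                             rotation = th[4:6], scale = th[7],
                             center = c_f)
  tf <- spatial_transform(st, NULL, domain = geometry(fixed),
                          codomain = geometry(moving))
  report <- structure(list(final_mi = best_mi, mi_per_level = mi_per_level,
                           iterations_per_level = iters, converged = conv),
                      class = "registration_report")
  list(transform = tf, report = report)
}

#' @exportS3Method base::print
print.registration_report <- function(x, ...) {
  cat(sprintf("<registration_report> final MI %.4f bits over %d level(s)%s\n",
              x$final_mi, length(x$mi_per_level),
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

# 1D cubic B-spline weights of control point m (0-based) at positions x
# (full-res voxel coordinates), given spacing h; nonzero only where
# floor((x-1)/h) is in {m-3, ..., m}.
bspline_w1 <- function(x, m, h) {
  u <- (x - 1) / h
  i <- floor(u)
  t <- u - i
  k <- m - i  # which of the 4 weights applies
  w <- numeric(length(x))
  s0 <- k == 0; s1 <- k == 1; s2 <- k == 2; s3 <- k == 3
  t0 <- t[s0]; t1 <- t[s1]; t2 <- t[s2]; t3 <- t[s3]
  w[s0] <- (1 - t0)^3 / 6
  w[s1] <- (3 * t1^3 - 6 * t1^2 + 4) / 6
  w[s2] <- (-3 * t2^3 + 3 * t2^2 + 3 * t2 + 1) / 6
  w[s3] <- t3^3 / 6
  w
}

#' Refine a similarity registration with a B-spline deformation
#'
#' Starting from the similarity transform in `init`, optimizes a cubic
#' B-spline free-form deformation (control-point spacing
#' `control$bspline_spacing` voxels) to further increase the mutual
#' information, by greedy coordinate ascent: each control-point component in
#' turn is perturbed by +/- `bspline_step` voxels and the move is kept only
#' if MI strictly increases. The returned transform composes the similarity
#' part with the sampled displacement field.
#'
#' @inheritParams register_similarity
#' @param init result transform of [register_similarity()].
#' @return As [register_similarity()], with the dense displacement filled in.
#' @export
register_bspline <- function(moving, fixed, init,
                             control = register_control()) {
  stopifnot(inherits(init, "spatial_transform"))
  dim_f <- dim(fixed$data)
  dim_m <- dim(moving$data)
  c_f <- (dim_f + 1) / 2
  c_m <- (dim_m + 1) / 2
  st <- init$similarity
  # recover the pyramid parameterization: t = translation - (c_m - c_f)
  th <- c(st$translation - (c_m - c_f), st$rotation, st$scale)
  h <- control$bspline_spacing
  cdim <- as.integer(floor((dim_f - 1) / h) + 4)
  coef <- array(0, c(cdim, 3))
  nc <- prod(cdim)
  fdat <- smooth_for_metric(fixed$data, control$smooth_sigma)
  mdat <- smooth_for_metric(moving$data, control$smooth_sigma)
  moving_full <- list(vec = as.numeric(mdat), dim = dim_m)
  full_field <- function(cf) {
    cpp_bspline_field(as.numeric(cf), cdim, h, as.integer(dim_f),
                      rep(1, 3), rep(0, 3))
  }
  mi_full <- function(cf) {
    fld <- if (all(cf == 0)) NULL else full_field(cf)
    mi_warped(th, fdat, moving_full, 1, c_f, c_m, control$bins, fld)
  }
  init_mi <- mi_full(coef)
  best_mi <- init_mi
  best_coef <- coef
  mi_per_level <- numeric(0)
  # foreground bounding box (full-res): only optimize control points whose
  # support touches it
  fg <- which(fixed$data > 1e-3, arr.ind = TRUE)
  bb <- if (nrow(fg) == 0) cbind(rep(1, 3), dim_f) else
    cbind(apply(fg, 2, min), apply(fg, 2, max))
  for (f in control$bspline_levels) {
    if (control$bspline_sweeps < 1) break
    fx <- downsample_mean(fdat, f)
    mvd <- downsample_mean(mdat, f)
    mv <- list(vec = as.numeric(mvd), dim = dim(mvd))
    odim <- dim(fx)
    off1 <- (f - 1) / 2
    nvox <- prod(odim)
    field <- cpp_bspline_field(as.numeric(coef), cdim, h,
                               as.integer(odim), rep(f, 3), rep(-off1, 3))
    cur <- mi_warped(th, fx, mv, f, c_f, c_m, control$bins, field)
    # per-axis level voxel ranges and weights for each control index
    ax_support <- lapply(1:3, function(ax) {
      lapply(seq_len(cdim[ax]), function(m0) {
        m <- m0 - 1
        xr <- c((m - 3) * h + 1, (m + 1) * h + 1)  # full-res support
        vr <- c(ceiling((xr[1] + off1) / f), floor((xr[2] + off1) / f))
        vr <- c(max(1, vr[1]), min(odim[ax], vr[2]))
        if (vr[1] > vr[2]) return(NULL)
        v <- vr[1]:vr[2]
        list(v = v, w = bspline_w1(f * v - off1, m, h))
      })
    })
    for (sweep in seq_len(control$bspline_sweeps)) {
      step <- control$bspline_step / 2^(sweep - 1)  # coarse-to-fine bumps
      improved <- FALSE
      for (kz in seq_len(cdim[3])) {
        sz <- ax_support[[3]][[kz]]
        if (is.null(sz)) next
        zr <- range(f * sz$v - off1)
        if (zr[2] < bb[3, 1] - h || zr[1] > bb[3, 2] + h) next
        for (ky in seq_len(cdim[2])) {
          sy <- ax_support[[2]][[ky]]
          if (is.null(sy)) next
          yr <- range(f * sy$v - off1)
          if (yr[2] < bb[2, 1] - h || yr[1] > bb[2, 2] + h) next
          for (kx in seq_len(cdim[1])) {
            sx <- ax_support[[1]][[kx]]
            if (is.null(sx)) next
            xr <- range(f * sx$v - off1)
            if (xr[2] < bb[1, 1] - h || xr[1] > bb[1, 2] + h) next
            # linear indices and tensor weights of the support block
            li <- as.vector(outer(outer(sx$v, (sy$v - 1) * odim[1], "+"),
                                  (sz$v - 1) * odim[1] * odim[2], "+"))
            w3 <- as.vector(outer(outer(sx$w, sy$w), sz$w))
            ci <- kx + (ky - 1) * cdim[1] + (kz - 1) * cdim[1] * cdim[2]
            for (a in 1:3) {
              fi <- li + (a - 1) * nvox
              for (dlt in c(step, -step)) {
                field[fi] <- field[fi] + dlt * w3
                cand <- mi_warped(th, fx, mv, f, c_f, c_m, control$bins,
                                  field)
                if (cand > cur + control$bspline_min_gain) {
                  cur <- cand
                  coef[ci + (a - 1) * nc] <- coef[ci + (a - 1) * nc] + dlt
                  improved <- TRUE
                  break
                } else {
                  field[fi] <- field[fi] - dlt * w3
                }
              }
            }
          }
        }
      }
      if (!improved) break
    }
    cand_full <- mi_full(coef)
    if (cand_full >= best_mi) { best_mi <- cand_full; best_coef <- coef }
    else coef <- best_coef
    mi_per_level <- c(mi_per_level, best_mi)
  }
  disp <- array(full_field(best_coef), c(dim_f, 3))
  tf <- spatial_transform(st, disp, domain = geometry(fixed),
                          codomain = geometry(moving))
  tf$bspline <- list(coef = best_coef, spacing = h)
  report <- structure(list(final_mi = best_mi, mi_per_level = mi_per_level,
                           iterations_per_level =
                             rep(control$bspline_sweeps,
                                 length(mi_per_level)),
                           converged = TRUE, initial_mi = init_mi),
                      class = "registration_report")
  list(transform = tf, report = report)
}
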