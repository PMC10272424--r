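# Spatial transforms. A transform maps 1-based voxel coordinates of its
# domain grid (the fixed/atlas grid for registration outputs) to voxel
# coordinates of its codomain grid (the moving/subject grid):
#   y = similarity(x) + displacement(x)
# with the similarity applied first and the dense displacement (in voxel
# units, defined over the domain grid) added in the codomain space.

rot_matrix <- function(angles_deg) {
  a <- angles_deg * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

rot_angles <- function(R) {
  # Euler angles (degrees) for R = Rz %*% Ry %*% Rx
  beta <- -asin(max(-1, min(1, R[3, 1])))
  alpha <- atan2(R[3, 2], R[3, 3])
  gamma <- atan2(R[2, 1], R[1, 1])
  c(alpha, beta, gamma) * 180 / pi
}

#' Similarity and composite spatial transforms
#'
#' A `similarity_transform` maps voxel coordinates as
#' `y = scale * R * (x - center) + center + translation`, with `R` the
#' rotation matrix for intrinsic Z-Y-X Euler angles in degrees. A
#' `spatial_transform` composes a similarity part with an optional dense
#' displacement field (voxel units, one 3-component field over the domain
#' grid), applied additively after the similarity — the registration model
#' used throughout: a rigid-plus-scale alignment refined by a free-form
#' deformation.
#'
#' @param translation numeric length 3, voxels.
#' @param rotation numeric length 3, degrees about the x, y, z axes.
#' @param scale single positive number (isotropic).
#' @param center rotation/scaling center in voxel coordinates.
#' @return `similarity_transform()` / `spatial_transform()` return objects of
#'   the corresponding class.
#' @export
similarity_transform <- function(translation = c(0, 0, 0),
                                 rotation = c(0, 0, 0), scale = 1,
                                 center = c(0, 0, 0)) {
  if (length(scale) != 1L || !is.finite(scale) || scale <= 0)
    hm_stop("similarity scale must be a single positive number",
            "hemomap_bad_transform")
  structure(list(translation = as.numeric(translation),
                 rotation = as.numeric(rotation),
                 scale = as.numeric(scale),
                 center = as.numeric(center),
                 matrix = rot_matrix(as.numeric(rotation))),
            class = "similarity_transform")
}

#' @rdname similarity_transform
#' @param similarity a `similarity_transform`.
#' @param displacement `NULL`, or a 4D array `dim = c(domain dim, 3)` of
#'   per-voxel displacements (voxel units) over the domain grid.
#' @param domain,codomain geometry lists (`dim`, `spacing`, `origin`) of the
#'   grids the transform maps from and to.
#' @export
spatial_transform <- function(similarity, displacement = NULL,
                              domain = NULL, codomain = NULL) {
  stopifnot(inherits(similarity, "similarity_transform"))
  if (!is.null(displacement)) {
    if (length(dim(displacement)) != 4L || dim(displacement)[4] != 3L)
      hm_stop("displacement must be a 4D array with 3 components",
              "hemomap_bad_transform")
    if (!is.null(domain) && !all(dim(displacement)[1:3] == domain$dim))
      hm_stop("displacement field geometry must equal the domain geometry",
              "hemomap_bad_transform")
  }
  structure(list(similarity = similarity, displacement = displacement,
                 domain = domain, codomain = codomain),
            class = "spatial_transform")
}

#' @exportS3Method base::print
print.similarity_transform <- function(x, ...) {
  cat(sprintf(
    "<similarity_transform> t = (%s) vox, rot = (%s) deg, scale = %.4f\n",
    paste(sprintf("%.2f", x$translation), collapse = ", "),
    paste(sprintf("%.2f", x$rotation), collapse = ", "), x$scale))
  invisible(x)
}

#' @exportS3Method base::print
print.spatial_transform <- function(x, ...) {
  print(x$similarity)
  if (is.null(x$displacement)) {
    cat("  dense part: none\n")
  } else {
    mx <- max_displacement(x)
    cat(sprintf("  dense part: %s field, max |d| = %.3f vox\n",
                paste(dim(x$displacement)[1:3], collapse = "x"), mx))
  }
  invisible(x)
}

similarity_affine <- function(st) {
  # 3x4 matrix A with y = A %*% c(x, 1)
  L <- st$scale * st$matrix
  cbind(L, st$center + st$translation - L %*% st$center)
}

#' Invert a similarity transform
#'
#' @param st a `similarity_transform`.
#' @return The `similarity_transform` mapping y back to x.
#' @export
invert_similarity <- function(st) {
  Rt <- t(st$matrix)
  s <- 1 / st$scale
  tr <- -s * as.vector(Rt %*% st$translation)
  out <- similarity_transform(tr, rot_angles(Rt), s, st$center)
  out$matrix <- Rt
  out
}

#' Maximum dense displacement magnitude
#' @param tf a `spatial_transform`.
#' @return Max Euclidean norm (voxels) of the dense part; 0 if none.
#' @export
max_displacement <- function(tf) {
  if (is.null(tf$displacement)) return(0)
  d <- tf$displacement
  sqrt(max(d[, , , 1]^2 + d[, , , 2]^2 + d[, , , 3]^2))
}

# Trilinear interpolation of a 3D array at arbitrary 1-based voxel
# coordinates (n x 3 matrix); coordinates are clamped to the grid.
interp3 <- function(arr, pts) {
  d <- dim(arr)
  x <- pmin(pmax(pts[, 1], 1), d[1])
  y <- pmin(pmax(pts[, 2], 1), d[2])
  z <- pmin(pmax(pts[, 3], 1), d[3])
  x0 <- pmin(floor(x), d[1] - 1); y0 <- pmin(floor(y), d[2] - 1)
  z0 <- pmin(floor(z), d[3] - 1)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  idx <- function(i, j, k) (k - 1) * d[1] * d[2] + (j - 1) * d[1] + i
  v000 <- arr[idx(x0, y0, z0)];     v100 <- arr[idx(x0 + 1, y0, z0)]
  v010 <- arr[idx(x0, y0 + 1, z0)]; v110 <- arr[idx(x0 + 1, y0 + 1, z0)]
  v001 <- arr[idx(x0, y0, z0 + 1)]; v101 <- arr[idx(x0 + 1, y0, z0 + 1)]
  v011 <- arr[idx(x0, y0 + 1, z0 + 1)]
  v111 <- arr[idx(x0 + 1, y0 + 1, z0 + 1)]
  c00 <- v000 * (1 - fx) + v100 * fx
  c10 <- v010 * (1 - fx) + v110 * fx
  c01 <- v001 * (1 - fx) + v101 * fx
  c11 <- v011 * (1 - fx) + v111 * fx
  (c00 * (1 - fy) + c10 * fy) * (1 - fz) + (c01 * (1 - fy) + c11 * fy) * fz
}

#' Apply a transform to voxel coordinates
#'
#' Maps points from the transform's domain grid to its codomain grid; the
#' dense displacement (if any) is interpolated trilinearly at the input
#' points.
#'
#' @param tf a `spatial_transform` or `similarity_transform`.
#' @param pts n x 3 matrix of 1-based voxel coordinates.
#' @return n x 3 matrix of transformed coordinates.
#' @export
transform_points <- function(tf, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  st <- if (inherits(tf, "similarity_transform")) tf else tf$similarity
  A <- similarity_affine(st)
  out <- t(A %*% rbind(t(pts), 1))
  if (inherits(tf, "spatial_transform") && !is.null(tf$displacement)) {
    for (a in 1:3)
      out[, a] <- out[, a] + interp3(tf$displacement[, , , a], pts)
  }
  out
}

# Flatten a 4D displacement array into the layout cpp_warp expects
# (three stacked component blocks), or NULL.
field_vector <- function(tf) {
  if (is.null(tf$displacement)) NULL else as.numeric(tf$displacement)
}

#' Warp a volume through a spatial transform
#'
#' Resamples `moving` onto the transform's domain grid (pull-back: the output
#' value at domain voxel v is `moving` sampled at the transformed coordinate).
#' Scalar volumes use trilinear interpolation; labels and masks use nearest
#' neighbor.
#'
#' @param moving a volume object in the codomain grid.
#' @param tf a `spatial_transform` whose `domain` is set.
#' @param fill value for coordinates falling outside `moving`.
#' @return A volume of the same class as `moving` on the domain grid.
#' @export
warp_volume <- function(moving, tf, fill = 0) {
  stopifnot(inherits(tf, "spatial_transform"), !is.null(tf$domain))
  nearest <- !inherits(moving, "scalar_volume")
  odim <- tf$domain$dim
  A <- similarity_affine(tf$similarity)
  out <- cpp_warp(as.numeric(moving$data), dim(moving$data),
                  as.integer(odim), A, field_vector(tf),
                  c(1, 1, 1), c(0, 0, 0), nearest, fill)
  out <- array(out, dim = odim)
  make <- if (inherits(moving, "label_volume")) label_volume
          else if (inherits(moving, "binary_mask")) binary_mask
          else scalar_volume
  make(out, tf$domain$spacing, tf$domain$origin)
}

#' Transfer a hemorrhage mask into atlas space
#'
#' Applies the composite transform estimated for a subject's CT to the
#' subject's binary hemorrhage mask, resampling into the atlas grid with
#' nearest-neighbor interpolation so the output stays binary. This mirrors
#' the CT's spatial processing; no skull-stripping or intensity step applies
#' to a mask.
#'
#' @param mask a `binary_mask` in the subject grid.
#' @param transform the `spatial_transform` from registering that subject's
#'   CT to the atlas.
#' @param atlas_geometry optional geometry to resample into; defaults to the
#'   transform's domain.
#' @return A `binary_mask` in atlas space.
#' @export
apply_to_mask <- function(mask, transform, atlas_geometry = NULL) {
  stopifnot(inherits(mask, "binary_mask"),
            inherits(transform, "spatial_transform"))
  if (!is.null(transform$codomain) &&
      !same_geometry(geometry(mask), transform$codomain))
    hm_stop("mask geometry does not match the transform's moving-image grid",
            "hemomap_geometry_mismatch")
  if (is.null(atlas_geometry)) atlas_geometry <- transform$domain
  if (!same_geometry(atlas_geometry, transform$domain))
    hm_stop("requested output geometry does not match the transform domain",
            "hemomap_geometry_mismatch")
  warp_volume(mask, transform, fill = 0)
}

#' Registration error against a ground-truth transform
#'
#' The phantom generator builds each subject by pulling the atlas through a
#' known transform `truth` (subject grid to atlas grid); registration
#' estimates `estimate` (atlas grid to subject grid). If the estimate were
#' exact, `truth(estimate(v)) = v` for every atlas voxel v, so the residual
#' `|truth(estimate(v)) - v|` measures displacement error in voxels.
#'
#' @param estimate estimated `spatial_transform` (atlas to subject).
#' @param truth generator `spatial_transform` (subject to atlas).
#' @param region optional `binary_mask` on the atlas grid restricting the
#'   evaluation (typically the brain).
#' @return List with `mean`, `max` residual (voxels) and `n` voxels used.
#' @export
registration_error <- function(estimate, truth, region = NULL) {
  odim <- estimate$domain$dim
  if (is.null(region)) {
    keep <- rep(TRUE, prod(odim))
  } else {
    require_same_geometry(geometry(region), estimate$domain,
                          "region mask and transform domain")
    keep <- region$data > 0
  }
  g <- expand.grid(x = seq_len(odim[1]), y = seq_len(odim[2]),
                   z = seq_len(odim[3]))
  pts <- as.matrix(g)[keep, , drop = FALSE]
  fwd <- transform_points(estimate, pts)
  back <- transform_points(truth, fwd)
  res <- sqrt(rowSums((back - pts)^2))
  list(mean = mean(res), max = max(res), n = nrow(pts))
}

#' Serialize a spatial transform
#'
#' Writes the similarity parameters as JSON and, when present, the dense
#' displacement field as a 4D NIfTI volume next to it.
#'
#' @param tf a `spatial_transform`.
#' @param path output path for the JSON file (a `_field.nii.gz` sibling is
#'   written if the transform has a dense part).
#' @return `path`, invisibly.
#' @export
save_transform <- function(tf, path) {
  st <- tf$similarity
  obj <- list(translation = st$translation, rotation = st$rotation,
              scale = st$scale, center = st$center,
              domain = tf$domain, codomain = tf$codomain,
              has_field = !is.null(tf$displacement))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  if (!is.null(tf$displacement)) {
    img <- RNifti::asNifti(tf$displacement)
    RNifti::writeNifti(img, sub("\\.json$", "_field.nii.gz", path),
                       datatype = "double")
  }
  invisible(path)
}

#' @rdname save_transform
#' @export
load_transform <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  st <- similarity_transform(obj$translation, obj$rotation, obj$scale,
                             obj$center)
  disp <- NULL
  if (isTRUE(obj$has_field)) {
    f <- sub("\\.json$", "_field.nii.gz", path)
    disp <- as.array(RNifti::readNifti(f))
  }
  fixg <- function(g) if (is.null(g)) NULL else
    list(dim = as.integer(g$dim), spacing = as.numeric(g$spacing),
         origin = as.numeric(g$origin))
  spatial_transform(st, disp, domain = fixg(obj$domain),
                    codomain = fixg(obj$codomain))
}
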