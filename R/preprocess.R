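# CT preprocessing: automatic skull-stripping (threshold + morphology +
# connected components), min-max intensity normalization, resampling onto a
# reference geometry, and Hu-window tissue quantification.

# 6-neighborhood binary dilation/erosion via array shifts.
dilate6 <- function(m) {
  d <- dim(m)
  out <- m
  sh <- function(a, axis, by) {
    idx <- rep(list(quote(expr = )), 3)
    n <- d[axis]
    src <- if (by > 0) c(1, seq_len(n - 1)) else c(seq_len(n - 1) + 1, n)
    idx[[axis]] <- src
    do.call(`[`, c(list(a), idx))
  }
  for (axis in 1:3) {
    out <- out | sh(m, axis, 1) | sh(m, axis, -1)
  }
  out
}

erode6 <- function(m) !dilate6(!m)

largest_component <- function(m) {
  lab <- cpp_label_components(as.logical(m), dim(m))
  k <- attr(lab, "n_components")
  if (k == 0) return(array(FALSE, dim(m)))
  best <- which.max(tabulate(lab, nbins = k))
  array(lab == best, dim(m))
}

fill_holes <- function(m) {
  d <- dim(m)
  lab <- cpp_label_components(as.logical(!m), d)
  k <- attr(lab, "n_components")
  if (k == 0) return(m)
  lab <- array(lab, d)
  border <- unique(c(lab[c(1, d[1]), , ], lab[, c(1, d[2]), ],
                     lab[, , c(1, d[3])]))
  border <- border[border > 0]
  m | !(lab %in% c(0L, border))
}

#' Default Hounsfield windows for tissue quantification
#'
#' Half-open intensity windows (Hu) used to count cerebrospinal fluid,
#' brain parenchyma and hemorrhage voxels inside the brain mask, plus the
#' bone threshold used by skull-stripping. These are declared conventions in
#' standard neuroradiology ranges, overridable wherever they are consumed.
#'
#' @return Named list with elements `csf`, `parenchyma`, `hemorrhage`
#'   (2-vectors, lower inclusive / upper exclusive) and `bone` (scalar
#'   threshold).
#' @export
hu_windows <- function() {
  list(csf = c(0, 15), parenchyma = c(20, 45), hemorrhage = c(45, 90),
       bone = 300)
}

#' Automatic skull-stripping of a CT volume
#'
#' Thresholds bone at `bone_hu`, takes the largest 6-connected component of
#' the sub-bone, above-air interior, then applies one morphological closing
#' and fills internal holes to recover the intracranial cavity. If no bone
#' voxel is found a warning (`hemomap_no_bone`) is signalled and the mask
#' falls back to the largest above-air component.
#'
#' @param ct a `scalar_volume` in native Hounsfield units.
#' @param bone_hu bone threshold (default 300 Hu).
#' @param air_hu lower cut separating head from background air.
#' @param fill value written outside the brain mask (default -1000).
#' @return List with `volume` (the masked CT, `fill` outside the brain) and
#'   `mask` (a `binary_mask`).
#' @export
strip_skull <- function(ct, bone_hu = hu_windows()$bone, air_hu = -500,
                        fill = -1000) {
  stopifnot(inherits(ct, "scalar_volume"))
  x <- ct$data
  bone <- x >= bone_hu
  if (!any(bone)) {
    hm_warn("no bone voxels found; falling back to above-air component",
            "hemomap_no_bone")
    cand <- x > air_hu
  } else {
    cand <- x > air_hu & x < bone_hu
  }
  if (!any(cand))
    hm_stop("no brain voxels found (volume is all air?)",
            "hemomap_empty_brain")
  mask <- largest_component(cand)
  mask <- erode6(dilate6(mask))  # closing
  mask <- fill_holes(mask)
  mask <- mask & !bone
  if (!any(mask))
    hm_stop("skull-stripping produced an empty brain mask",
            "hemomap_empty_brain")
  out <- array(fill, dim(x))
  out[mask] <- x[mask]
  list(volume = scalar_volume(out, ct$spacing, ct$origin),
       mask = binary_mask(mask * 1L, ct$spacing, ct$origin))
}

#' Min-max intensity normalization
#'
#' Rescales a volume linearly so its minimum maps to 0 and its maximum to 1:
#' `v' = (v - min) / (max - min)`. Order-preserving and idempotent after the
#' first application; invariant to affine rescaling `a * v + b` (a > 0) of
#' the input.
#'
#' @param volume a `scalar_volume`.
#' @return The normalized `scalar_volume`, values in `[0, 1]`.
#' @export
minmax_normalize <- function(volume) {
  stopifnot(inherits(volume, "scalar_volume"))
  rng <- range(volume$data)
  if (rng[2] <= rng[1])
    hm_stop("cannot normalize a constant volume (max == min)",
            "hemomap_constant_volume")
  scalar_volume((volume$data - rng[1]) / (rng[2] - rng[1]),
                volume$spacing, volume$origin)
}

#' Resample a volume onto a reference geometry
#'
#' Maps the output grid to the source grid through world coordinates
#' (origin + spacing) and interpolates: trilinear for scalar volumes,
#' nearest-neighbor for label volumes and masks (so labels and masks stay
#' integral/binary).
#'
#' @param volume a `scalar_volume`, `label_volume` or `binary_mask`.
#' @param reference a volume object or a geometry list (`dim`, `spacing`,
#'   `origin`).
#' @param fill value outside the source grid; defaults to the source minimum.
#' @return A volume of the same class on the reference geometry.
#' @export
resample_to <- function(volume, reference, fill = NULL) {
  stopifnot(inherits(volume, "hemomap_volume"))
  ref <- if (inherits(reference, "hemomap_volume")) geometry(reference)
         else reference
  if (is.null(ref$dim) || length(ref$dim) != 3L || any(ref$dim < 2) ||
      is.null(ref$spacing) || any(!is.finite(ref$spacing)) ||
      any(ref$spacing <= 0))
    hm_stop("degenerate reference geometry", "hemomap_bad_geometry")
  if (same_geometry(geometry(volume), ref)) {
    volume$spacing <- as.numeric(ref$spacing)
    volume$origin <- as.numeric(ref$origin)
    return(volume)
  }
  # world coord of output voxel v: o_r + (v - 1) * sp_r; source voxel:
  # (world - o_s) / sp_s + 1  -> affine in voxel coordinates
  A <- cbind(diag(ref$spacing / volume$spacing),
             (ref$origin - volume$origin - ref$spacing +
                volume$spacing) / volume$spacing)
  nearest <- !inherits(volume, "scalar_volume")
  if (is.null(fill)) fill <- if (nearest) 0 else min(volume$data)
  out <- cpp_warp(as.numeric(volume$data), dim(volume$data),
                  as.integer(ref$dim), A, NULL, c(1, 1, 1), c(0, 0, 0),
                  nearest, fill)
  out <- array(out, dim = ref$dim)
  make <- if (inherits(volume, "label_volume")) label_volume
          else if (inherits(volume, "binary_mask")) binary_mask
          else scalar_volume
  make(out, ref$spacing, ref$origin)
}

#' Prepare a skull-stripped CT for registration
#'
#' Replaces everything outside the brain mask with the minimum intensity
#' found inside it and then min-max normalizes. Without the clamping step
#' the air fill value (-1000 Hu) would dominate the normalized range and
#' compress all soft-tissue contrast into a sliver of `[0, 1]`, starving
#' the binned mutual-information metric of the internal structure it needs.
#'
#' @param stripped result of [strip_skull()] (list with `volume`, `mask`),
#'   or a `scalar_volume` together with `mask`.
#' @param mask brain `binary_mask` (ignored when `stripped` is the
#'   [strip_skull()] result list).
#' @return A normalized `scalar_volume` in `[0, 1]`.
#' @export
registration_input <- function(stripped, mask = NULL) {
  if (is.list(stripped) && !inherits(stripped, "hemomap_volume") &&
      !is.null(stripped$volume)) {
    mask <- stripped$mask
    stripped <- stripped$volume
  }
  stopifnot(inherits(stripped, "scalar_volume"),
            inherits(mask, "binary_mask"))
  require_same_geometry(stripped, mask, "volume and mask")
  x <- stripped$data
  inside <- mask$data == 1L
  if (!any(inside))
    hm_stop("empty brain mask", "hemomap_empty_brain")
  x[!inside] <- min(x[inside])
  minmax_normalize(scalar_volume(x, stripped$spacing, stripped$origin))
}

#' Quantify tissue volumes from native-Hu CT
#'
#' Counts voxels within the brain mask falling into the CSF, parenchyma and
#' hemorrhage Hounsfield windows. Must be run on the native-Hu CT, before
#' min-max normalization (normalization destroys the Hu scale); an input
#' whose values all lie in `[0, 1]` is rejected.
#'
#' @param ct a `scalar_volume` in Hounsfield units.
#' @param brain_mask a `binary_mask` from [strip_skull()] (or ground truth).
#' @param windows Hu windows, see [hu_windows()].
#' @return A list of class `tissue_volumes`: `csf_voxels`,
#'   `parenchyma_voxels`, `hemorrhage_voxels`, `voxel_volume` (mm^3).
#' @export
segment_tissues <- function(ct, brain_mask, windows = hu_windows()) {
  stopifnot(inherits(ct, "scalar_volume"), inherits(brain_mask, "binary_mask"))
  require_same_geometry(ct, brain_mask, "CT and brain mask")
  rng <- range(ct$data)
  if (rng[1] >= 0 && rng[2] <= 1)
    hm_stop("CT appears min-max normalized; tissue windows need native Hu",
            "hemomap_normalized_input")
  x <- ct$data[brain_mask$data == 1L]
  in_win <- function(w) sum(x >= w[1] & x < w[2])
  structure(list(csf_voxels = in_win(windows$csf),
                 parenchyma_voxels = in_win(windows$parenchyma),
                 hemorrhage_voxels = in_win(windows$hemorrhage),
                 voxel_volume = prod(ct$spacing)),
            class = "tissue_volumes")
}

#' @exportS3Method base::print
print.tissue_volumes <- function(x, ...) {
  cat(sprintf("<tissue_volumes> CSF %d, parenchyma %d, hemorrhage %d voxels (%.2f mm^3 each)\n",
              x$csf_voxels, x$parenchyma_voxels, x$hemorrhage_voxels,
              x$voxel_volume))
  invisible(x)
}

#' Dice overlap coefficient
#'
#' `2|A intersect B| / (|A| + |B|)` between two binary masks on the same
#' grid; 1 for identical non-empty masks, defined as 1 when both are empty.
#'
#' @param a,b `binary_mask` objects (or plain logical/0-1 arrays).
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(a, b) {
  da <- if (inherits(a, "hemomap_volume")) a$data else a
  db <- if (inherits(b, "hemomap_volume")) b$data else b
  sa <- sum(da == 1)
  sb <- sum(db == 1)
  if (sa + sb == 0) return(1)
  2 * sum(da == 1 & db == 1) / (sa + sb)
}
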