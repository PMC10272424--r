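#' @useDynLib hemomap, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Volumetric containers
#'
#' Light S3 containers for 3D volumes on a regular grid: a real-valued
#' `scalar_volume` (atlas intensity, CT in Hounsfield units), an integer
#' `label_volume` (atlas parcellation, values 0 = background and 1-35 per the
#' structure table), and a `binary_mask` (hemorrhage segmentation, brain
#' mask). All three carry the same geometry metadata: voxel spacing (mm) and
#' the world coordinates of voxel (1,1,1). Voxel indices are 1-based;
#' cross-volume operations require identical geometry or explicit resampling
#' (see [resample_to()]).
#'
#' @param data 3D numeric array, each dimension at least 8.
#' @param spacing positive numeric vector of length 3, mm per voxel.
#' @param origin numeric vector of length 3, world coordinates of voxel
#'   (1,1,1).
#' @return An object of class `scalar_volume`, `label_volume` or
#'   `binary_mask` (all also `hemomap_volume`): a list with elements `data`,
#'   `spacing`, `origin`.
#' @examples
#' v <- scalar_volume(array(rnorm(16^3), dim = c(16, 16, 16)))
#' dim(v$data)
#' @export
scalar_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  check_grid(data, spacing, origin)
  if (anyNA(data) || any(!is.finite(data)))
    hm_stop("scalar_volume data contains non-finite values", "hemomap_nonfinite")
  structure(list(data = data, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = c("scalar_volume", "hemomap_volume"))
}

#' @rdname scalar_volume
#' @export
label_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  check_grid(data, spacing, origin)
  if (anyNA(data) || any(data != as.integer(data)) ||
      any(data < 0) || any(data > 35))
    hm_stop("label_volume values must be integers in 0..35",
            "hemomap_bad_labels")
  storage.mode(data) <- "integer"
  structure(list(data = data, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = c("label_volume", "hemomap_volume"))
}

#' @rdname scalar_volume
#' @export
binary_mask <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  check_grid(data, spacing, origin)
  if (anyNA(data) || !all(data %in% c(0, 1)))
    hm_stop("binary_mask values must be 0 or 1", "hemomap_bad_mask")
  storage.mode(data) <- "integer"
  structure(list(data = data, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = c("binary_mask", "hemomap_volume"))
}

check_grid <- function(data, spacing, origin) {
  if (!is.array(data) || length(dim(data)) != 3L)
    hm_stop("volume data must be a 3D array", "hemomap_bad_dims")
  if (any(dim(data) < 8L))
    hm_stop("all three volume dimensions must be >= 8", "hemomap_bad_dims")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    hm_stop("spacing must be 3 strictly positive values", "hemomap_bad_geometry")
  if (length(origin) != 3L || any(!is.finite(origin)))
    hm_stop("origin must be 3 finite values", "hemomap_bad_geometry")
  invisible(TRUE)
}

#' @exportS3Method base::print
print.hemomap_volume <- function(x, ...) {
  cat(sprintf("<%s> %s voxels, spacing %s mm, origin (%s)\n",
              class(x)[1], paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              paste(format(x$origin), collapse = ", ")))
  rng <- range(x$data)
  cat(sprintf("  values in [%g, %g]\n", rng[1], rng[2]))
  invisible(x)
}

geometry <- function(v) list(dim = dim(v$data), spacing = v$spacing,
                             origin = v$origin)

same_geometry <- function(a, b, tol = 1e-6) {
  ga <- if (is.list(a) && !is.null(a$data)) geometry(a) else a
  gb <- if (is.list(b) && !is.null(b$data)) geometry(b) else b
  all(ga$dim == gb$dim) &&
    all(abs(ga$spacing - gb$spacing) < tol) &&
    all(abs(ga$origin - gb$origin) < tol)
}

require_same_geometry <- function(a, b, what = "volumes") {
  if (!same_geometry(a, b))
    hm_stop(paste(what, "must share geometry (dim/spacing/origin)"),
            "hemomap_geometry_mismatch")
  invisible(TRUE)
}

#' Read and write volumes in NIfTI-1 format
#'
#' `read_volume()` reads a 3D NIfTI-1 file (`.nii` or `.nii.gz`) into one of
#' the package's volume containers; `write_volume()` is its inverse.
#' Round-tripping is bit-exact for label volumes and masks (stored as int32)
#' and exact to double precision for scalar volumes.
#'
#' @param path file path to a NIfTI-1 image.
#' @param kind one of `"scalar"`, `"label"`, `"mask"`; selects the returned
#'   container class and storage datatype on write.
#' @return `read_volume()` returns a volume object; `write_volume()` returns
#'   `path` invisibly.
#' @export
read_volume <- function(path, kind = c("scalar", "label", "mask")) {
  kind <- match.arg(kind)
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    hm_stop(sprintf("file not found: %s", path), "hemomap_missing_file")
  img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e)
                    hm_stop(sprintf("unreadable NIfTI header in %s: %s",
                                    path, conditionMessage(e)),
                            "hemomap_bad_header"))
  a <- as.array(img)
  if (length(dim(a)) != 3L)
    hm_stop(sprintf("%s is %dD; a 3D volume is required",
                    path, length(dim(a))), "hemomap_bad_dims")
  hdr <- RNifti::niftiHeader(img)
  spacing <- RNifti::pixdim(img)[1:3]
  origin <- c(hdr$qoffset_x, hdr$qoffset_y, hdr$qoffset_z)
  a <- array(as.numeric(a), dim = dim(a))
  switch(kind,
         scalar = scalar_volume(a, spacing, origin),
         label = label_volume(a, spacing, origin),
         mask = binary_mask(a, spacing, origin))
}

#' @rdname read_volume
#' @param volume a `scalar_volume`, `label_volume` or `binary_mask`.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "hemomap_volume"))
  img <- RNifti::asNifti(volume$data)
  RNifti::pixdim(img) <- volume$spacing
  m <- diag(c(volume$spacing, 1))
  m[1:3, 4] <- volume$origin
  RNifti::qform(img) <- structure(m, code = 2L)
  dt <- if (inherits(volume, "scalar_volume")) "double" else "int32"
  RNifti::writeNifti(img, path, datatype = dt)
  invisible(path)
}

#' Brain structure lookup (35-region parcellation)
#'
#' The atlas parcellation assigns each voxel an integer gray value 1-35; this
#' table maps the gray values to anatomical structure names
#' (Left-/Right- pairs plus the midline 3rd-Ventricle, 4th-Ventricle and
#' Brain-Stem). The table ships as a TSV under `inst/extdata`.
#'
#' @return `structure_table()` returns a 35-row data.frame with columns
#'   `label` and `name`; `structure_name()` returns the name(s) for given
#'   label(s).
#' @examples
#' structure_name(14)  # "Left-Hippocampus"
#' @export
structure_table <- function() {
  if (is.null(.hemomap_env$structures)) {
    f <- system.file("extdata", "brain_structures.tsv", package = "hemomap",
                     mustWork = TRUE)
    .hemomap_env$structures <- utils::read.delim(f, stringsAsFactors = FALSE)
  }
  .hemomap_env$structures
}

.hemomap_env <- new.env(parent = emptyenv())

#' @rdname structure_table
#' @param label integer vector of gray values in 1..35.
#' @export
structure_name <- function(label) {
  if (any(is.na(label)) || any(label != as.integer(label)) ||
      any(label < 1) || any(label > 35))
    hm_stop("structure labels must be integers in 1..35",
            "hemomap_bad_label_lookup")
  structure_table()$name[as.integer(label)]
}

# Labels whose structures are fluid spaces (ventricles, choroid plexus);
# used by the phantom generator to assign CSF-range Hounsfield values.
csf_labels <- function() c(3L, 4L, 11L, 12L, 19L, 22L, 23L, 35L)

left_labels <- function() {
  tb <- structure_table()
  tb$label[startsWith(tb$name, "Left-")]
}

right_labels <- function() {
  tb <- structure_table()
  tb$label[startsWith(tb$name, "Right-")]
}

#' Per-structure voxel counts
#'
#' Counts the voxels assigned to each of the 35 parcellation labels; these
#' counts are the denominators of the bleeding-distribution features (the
#' total number of voxels in each structure).
#'
#' @param parcellation a `label_volume`.
#' @return Named integer vector of length 35 (names are the labels
#'   `"1"`..`"35"`); labels absent from the volume count 0.
#' @export
label_voxel_counts <- function(parcellation) {
  stopifnot(inherits(parcellation, "label_volume"))
  counts <- tabulate(parcellation$data[parcellation$data > 0L], nbins = 35L)
  names(counts) <- as.character(1:35)
  counts
}
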