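# Feature extraction: 35 bleeding-distribution features (per-structure
# occupancy fractions of the atlas-space hemorrhage mask) and 8
# bleeding-extrusion features (tissue volumes and their mutual ratios),
# assembled into the per-cohort feature table the classifiers consume.

#' Bleeding-distribution features
#'
#' For an atlas-space hemorrhage mask, counts the bleeding voxels falling on
#' each of the 35 parcellation structures (`bnum`) and divides by the
#' structure's total voxel count to obtain the occupancy fraction
#' `bd_i = bnum_i / allnum_i`. Mask voxels on background (label 0) are
#' excluded; a structure absent from the parcellation gets `bd = 0`.
#'
#' @param transformed_mask a `binary_mask` in atlas space.
#' @param parcellation the atlas `label_volume` (same geometry).
#' @return List with `bd` (35 fractions in `[0, 1]`) and `bnum` (35 integer
#'   counts), both named by label.
#' @export
distribution_features <- function(transformed_mask, parcellation) {
  stopifnot(inherits(transformed_mask, "binary_mask"),
            inherits(parcellation, "label_volume"))
  require_same_geometry(transformed_mask, parcellation,
                        "mask and parcellation")
  labs <- parcellation$data[transformed_mask$data == 1L]
  bnum <- tabulate(labs[labs > 0L], nbins = 35L)
  allnum <- label_voxel_counts(parcellation)
  bd <- ifelse(allnum > 0, bnum / allnum, 0)
  names(bnum) <- names(allnum)
  names(bd) <- names(allnum)
  list(bd = bd, bnum = bnum)
}

#' Bleeding-extrusion features
#'
#' The 8-vector of volumetric mass-effect descriptors: the CSF, parenchyma
#' and hemorrhage voxel counts plus five ratios (CSF/parenchyma,
#' CSF/(parenchyma+CSF), hemorrhage/CSF, hemorrhage/parenchyma,
#' hemorrhage/(CSF+parenchyma)). `hemorrhage/CSF` is defined as 0 when both
#' are 0 and is an error when CSF is 0 with hemorrhage present.
#'
#' @param tissues a `tissue_volumes` from [segment_tissues()].
#' @return Named numeric vector of length 8.
#' @export
extrusion_features <- function(tissues) {
  stopifnot(inherits(tissues, "tissue_volumes"))
  csf <- tissues$csf_voxels
  par <- tissues$parenchyma_voxels
  hem <- tissues$hemorrhage_voxels
  if (par <= 0)
    hm_stop("no parenchyma voxels: not a valid brain", "hemomap_no_parenchyma")
  hem_csf <- if (csf == 0) {
    if (hem == 0) 0
    else hm_stop("hemorrhage present but no CSF voxels: hemorrhage/CSF undefined",
                 "hemomap_zero_csf")
  } else hem / csf
  c(csf_vol = csf, parenchyma_vol = par, hemorrhage_vol = hem,
    ratio_csf_parenchyma = csf / par,
    ratio_csf_brain = csf / (par + csf),
    ratio_hem_csf = hem_csf,
    ratio_hem_parenchyma = hem / par,
    ratio_hem_brain = hem / (csf + par))
}

bd_colnames <- function() {
  sprintf("bd_%d_%s", 1:35, structure_table()$name)
}

extrusion_colnames <- function() {
  c("csf_vol", "parenchyma_vol", "hemorrhage_vol", "ratio_csf_parenchyma",
    "ratio_csf_brain", "ratio_hem_csf", "ratio_hem_parenchyma",
    "ratio_hem_brain")
}

feature_colnames <- function() c(bd_colnames(), extrusion_colnames())

# Full per-subject pipeline: skull-strip, normalize, resample, register,
# transfer the mask, extract both feature blocks.
subject_features <- function(subject, atlas_norm, parcellation, control,
                             windows = hu_windows()) {
  stripped <- strip_skull(subject$ct, bone_hu = windows$bone)
  norm <- registration_input(stripped)
  if (!same_geometry(norm, atlas_norm))
    norm <- resample_to(norm, atlas_norm)
  reg <- register_similarity(norm, atlas_norm, control)
  if (control$bspline_sweeps > 0)
    reg <- register_bspline(norm, atlas_norm, reg$transform, control)
  mask <- subject$hemorrhage
  if (!same_geometry(mask, reg$transform$codomain))
    mask <- resample_to(mask, reg$transform$codomain)
  tmask <- apply_to_mask(mask, reg$transform)
  df <- distribution_features(tmask, parcellation)
  tissues <- segment_tissues(subject$ct, stripped$mask, windows)
  ext <- extrusion_features(tissues)
  list(bd = df$bd, bnum = df$bnum, extrusion = ext,
       transform = reg$transform, report = reg$report,
       transformed_mask = tmask, brain_mask = stripped$mask)
}

#' Build the cohort feature table
#'
#' Runs the per-subject pipeline (skull-strip, normalize, register to the
#' atlas, transfer the hemorrhage mask, extract distribution and extrusion
#' features) over a phantom cohort or a manifest of NIfTI paths, and
#' assembles one row per subject: `id`, the 35 `bd_*` columns (named after
#' the structure table), the 8 extrusion columns, and `sap_category`.
#' Subjects whose registration fails are excluded and recorded in the
#' `failures` attribute with the failure reason.
#'
#' @param cohort a `phantom_cohort`, or a manifest data.frame with columns
#'   `id`, `category`, `ct_path`, `mask_path`.
#' @param atlas,parcellation atlas intensity (`scalar_volume`) and
#'   parcellation (`label_volume`); taken from `cohort` when it is a
#'   `phantom_cohort` and these are `NULL`.
#' @param control a [register_control()].
#' @param keep_masks if `TRUE`, atlas-space hemorrhage masks are returned in
#'   the `masks` attribute (needed for probability maps).
#' @param verbose print one progress line per subject.
#' @return A data.frame (`1 + 35 + 8 + 1` columns) of class
#'   `sap_feature_table`, with attributes `masks` (optional) and `failures`.
#' @export
build_feature_table <- function(cohort, atlas = NULL, parcellation = NULL,
                                control = register_control(),
                                keep_masks = FALSE, verbose = FALSE) {
  if (inherits(cohort, "phantom_cohort")) {
    if (is.null(atlas)) atlas <- cohort$atlas
    if (is.null(parcellation)) parcellation <- cohort$parcellation
    subjects <- cohort$subjects
    ids <- cohort$manifest$id
    cats <- cohort$manifest$category
  } else {
    man <- as.data.frame(cohort)
    stopifnot(all(c("id", "category", "ct_path", "mask_path") %in%
                    names(man)))
    subjects <- lapply(seq_len(nrow(man)), function(i) {
      list(ct = read_volume(man$ct_path[i], "scalar"),
           hemorrhage = read_volume(man$mask_path[i], "mask"))
    })
    ids <- man$id
    cats <- man$category
  }
  stopifnot(inherits(atlas, "scalar_volume"),
            inherits(parcellation, "label_volume"))
  atlas_norm <- minmax_normalize(atlas)
  rows <- vector("list", length(subjects))
  masks <- if (keep_masks) vector("list", length(subjects)) else NULL
  fail <- data.frame(id = character(0), reason = character(0))
  for (i in seq_along(subjects)) {
    res <- tryCatch(
      subject_features(subjects[[i]], atlas_norm, parcellation, control),
      error = function(e) e)
    if (inherits(res, "error")) {
      fail <- rbind(fail, data.frame(id = ids[i],
                                     reason = conditionMessage(res)))
      message(sprintf("subject %s excluded: %s", ids[i],
                      conditionMessage(res)))
      next
    }
    row <- c(res$bd, res$extrusion)
    names(row) <- feature_colnames()
    rows[[i]] <- row
    if (keep_masks) masks[[i]] <- res$transformed_mask
    if (verbose)
      message(sprintf("%s (%s): MI %.3f, %d bleeding voxels in atlas space",
                      ids[i], cats[i], res$report$final_mi,
                      sum(res$transformed_mask$data)))
  }
  ok <- !vapply(rows, is.null, logical(1))
  tab <- as.data.frame(do.call(rbind, rows[ok]), check.names = FALSE)
  tab <- cbind(data.frame(id = ids[ok], stringsAsFactors = FALSE), tab)
  tab$sap_category <- cats[ok]
  class(tab) <- c("sap_feature_table", "data.frame")
  if (keep_masks) {
    names(masks) <- ids
    attr(tab, "masks") <- masks[ok]
  }
  attr(tab, "failures") <- fail
  tab
}

#' Read and write feature tables as TSV
#'
#' @param table an `sap_feature_table`.
#' @param path TSV file path.
#' @return `write_feature_table()` returns `path` invisibly;
#'   `read_feature_table()` returns the table.
#' @export
write_feature_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  class(tab) <- c("sap_feature_table", "data.frame")
  tab
}

# Numeric feature matrix (the 43 classifier inputs) from a feature table.
feature_matrix <- function(table) {
  cols <- feature_colnames()
  missing <- setdiff(cols, names(table))
  if (length(missing) > 0)
    hm_stop(sprintf("feature table lacks %d expected columns (e.g. %s)",
                    length(missing), missing[1]),
            "hemomap_bad_feature_table")
  as.matrix(table[, cols])
}
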