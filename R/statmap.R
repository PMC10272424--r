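# Statistical model: per-category hemorrhage probability maps built by
# superimposing atlas-space binary masks, hemisphere mass comparison, and
# the box-plot summaries of the bleeding-volume-to-brain-tissue ratio.

#' Hemorrhage probability map for one SAP category
#'
#' Superimposes atlas-space binary hemorrhage masks of all subjects in a
#' category and divides by their number, giving at each voxel the fraction
#' of subjects whose hemorrhage covers it. Values therefore lie on the grid
#' `{0, 1/n, ..., 1}`.
#'
#' @param masks non-empty list of `binary_mask` objects in atlas space.
#' @param category optional SAP category tag carried on the result.
#' @return A `probability_map` (also a `scalar_volume`) with fields
#'   `category` and `n_subjects`.
#' @export
probability_map <- function(masks, category = NA_character_) {
  if (length(masks) == 0)
    hm_stop("probability_map needs at least one mask", "hemomap_empty_list")
  if (!all(vapply(masks, inherits, logical(1), "binary_mask")))
    hm_stop("all inputs must be binary masks", "hemomap_bad_mask")
  for (m in masks[-1]) require_same_geometry(masks[[1]], m, "masks")
  acc <- Reduce(`+`, lapply(masks, function(m) m$data))
  out <- scalar_volume(acc / length(masks), masks[[1]]$spacing,
                       masks[[1]]$origin)
  out$category <- category
  out$n_subjects <- length(masks)
  class(out) <- c("probability_map", class(out))
  out
}

#' @exportS3Method base::print
print.probability_map <- function(x, ...) {
  cat(sprintf("<probability_map> category %s, n = %d, max probability %.3f\n",
              x$category, x$n_subjects, max(x$data)))
  invisible(x)
}

#' Plot an axial slice of a probability map
#' @param x a `probability_map`.
#' @param slice axial slice index (defaults to the middle slice).
#' @param ... passed to [graphics::image()].
#' @importFrom graphics image
#' @importFrom grDevices grey.colors
#' @exportS3Method graphics::plot
plot.probability_map <- function(x, slice = NULL, ...) {
  if (is.null(slice)) slice <- ceiling(dim(x$data)[3] / 2)
  image(x$data[, , slice], zlim = c(0, 1), col = grey.colors(64, 0, 1),
        main = sprintf("probability map (%s), slice %d", x$category, slice),
        ...)
  invisible(x)
}

#' Hemispheric hemorrhage mass
#'
#' Sums a probability map over the voxels belonging to `Left-` versus
#' `Right-` structures of the parcellation; midline structures
#' (3rd-Ventricle, 4th-Ventricle, Brain-Stem) and background are excluded.
#' A left/right imbalance of the severe-category map reflects the
#' laterality of hemorrhage in severe pneumonia.
#'
#' @param map a `probability_map` (or any `scalar_volume`) in atlas space.
#' @param parcellation the atlas `label_volume`.
#' @return Named numeric vector `c(left = , right = )`.
#' @export
hemisphere_mass <- function(map, parcellation) {
  stopifnot(inherits(map, "scalar_volume"),
            inherits(parcellation, "label_volume"))
  require_same_geometry(map, parcellation, "map and parcellation")
  lab <- parcellation$data
  c(left = sum(map$data[lab %in% left_labels()]),
    right = sum(map$data[lab %in% right_labels()]))
}

#' Per-category bleeding-volume ratio summaries
#'
#' For each SAP category present in the feature table, summarizes the ratio
#' of hemorrhage volume to brain tissue volume (parenchyma + CSF voxels):
#' min, Tukey whiskers (1.5 IQR beyond the quartiles, clipped to the data
#' range), quartiles by linear interpolation, mean, median, max. These are
#' the statistics behind the severity box plot.
#'
#' @param features an `sap_feature_table`.
#' @return Data.frame of class `ratio_summary`, one row per category with
#'   columns `category`, `n`, `min`, `lower_whisker`, `q1`, `median`,
#'   `mean`, `q3`, `upper_whisker`, `max`.
#' @export
ratio_summary <- function(features) {
  stopifnot(all(c("hemorrhage_vol", "csf_vol", "parenchyma_vol",
                  "sap_category") %in% names(features)))
  ratio <- features$hemorrhage_vol /
    (features$csf_vol + features$parenchyma_vol)
  rows <- list()
  for (cat in sap_levels()) {
    x <- ratio[features$sap_category == cat]
    if (length(x) == 0) {
      hm_warn(sprintf("no subjects in category '%s'; skipped", cat),
              "hemomap_empty_category")
      next
    }
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    iqr <- q[3] - q[1]
    lw <- min(x[x >= q[1] - 1.5 * iqr])
    uw <- max(x[x <= q[3] + 1.5 * iqr])
    rows[[cat]] <- data.frame(category = cat, n = length(x), min = min(x),
                              lower_whisker = lw, q1 = q[1], median = q[2],
                              mean = mean(x), q3 = q[3], upper_whisker = uw,
                              max = max(x))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("ratio_summary", "data.frame")
  out
}

#' Draw the per-category bleeding-ratio box plot
#' @param x a `ratio_summary`.
#' @param ... passed to [graphics::bxp()].
#' @importFrom graphics bxp
#' @exportS3Method graphics::plot
plot.ratio_summary <- function(x, ...) {
  stats <- sapply(seq_len(nrow(x)), function(i)
    c(x$lower_whisker[i], x$q1[i], x$median[i], x$q3[i], x$upper_whisker[i]))
  bxp(list(stats = stats, n = x$n, names = x$category),
      ylab = "hemorrhage / brain tissue volume", ...)
  invisible(x)
}
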