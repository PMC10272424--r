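# Synthetic phantom cohort. The generator builds a labeled ellipsoidal
# "brain" atlas with all 35 structures, then derives each subject's CT by
# pulling the atlas through a random similarity transform plus a smooth
# random deformation, remapping intensities into clinically typical
# Hounsfield windows, adding a skull shell, and implanting one ellipsoidal
# hemorrhage whose location and volume depend on the pneumonia category.
# Ground-truth transforms, lesion footprints and tissue tallies are stored
# so every downstream stage has a known correct answer.

# Generator Hu windows; strictly inside the segmentation windows of
# hu_windows() so tissue counts on phantoms are exact.
phantom_hu <- list(csf = c(4, 12), parenchyma = c(25, 40),
                   blood = c(50, 80), skull = c(700, 1200), air = -1000)

#' Phantom cohort configuration
#'
#' Collects the knobs of the synthetic cohort generator. Defaults mirror the
#' study conditions the pipeline is meant to handle: a 244-subject cohort
#' split 101/77/47/19 over none/mild/moderate/severe pneumonia, lesion volume
#' medians increasing with severity, and a left-hemisphere bias for severe
#' disease.
#'
#' @param grid_size voxels per axis (even, >= 32).
#' @param n_subjects cohort size (>= 8).
#' @param category_proportions probabilities over
#'   (none, mild, moderate, severe); must sum to 1.
#' @param volume_medians median lesion volume as a fraction of brain volume,
#'   per category, strictly increasing.
#' @param laterality_bias probability that a severe-category lesion sits in
#'   the left hemisphere (0.5-1).
#' @param deformation_amplitude maximum magnitude (voxels) of the smooth
#'   random deformation; 0 gives pure-similarity subjects.
#' @param translation_range,rotation_range,scale_range similarity sampling
#'   ranges: translations uniform within +/- `translation_range` voxels per
#'   axis (default 5 at grid 64, scaled with the grid), rotations uniform
#'   within +/- `rotation_range` degrees per axis, isotropic scale uniform in
#'   `scale_range`.
#' @param seed integer master seed; all per-subject seeds derive from it.
#' @return A list of class `phantom_config`.
#' @export
phantom_config <- function(grid_size = 64, n_subjects = 244,
                           category_proportions = c(none = 101, mild = 77,
                                                    moderate = 47,
                                                    severe = 19) / 244,
                           volume_medians = c(none = 0.012, mild = 0.03,
                                              moderate = 0.055,
                                              severe = 0.09),
                           laterality_bias = 0.9,
                           deformation_amplitude = 2,
                           translation_range = 5 * grid_size / 64,
                           rotation_range = 10,
                           scale_range = c(0.9, 1.1),
                           seed = 1) {
  if (grid_size < 32 || grid_size %% 2 != 0)
    hm_stop("grid_size must be an even integer >= 32", "hemomap_grid_too_small")
  if (length(category_proportions) != 4 ||
      abs(sum(category_proportions) - 1) > 1e-8)
    hm_stop("category_proportions must be 4 probabilities summing to 1",
            "hemomap_bad_config")
  if (length(volume_medians) != 4 || any(diff(volume_medians) <= 0))
    hm_stop("volume_medians must be strictly increasing none -> severe",
            "hemomap_bad_config")
  if (laterality_bias < 0.5 || laterality_bias > 1)
    hm_stop("laterality_bias must lie in [0.5, 1]", "hemomap_bad_config")
  structure(list(grid_size = as.integer(grid_size),
                 n_subjects = as.integer(n_subjects),
                 category_proportions = stats::setNames(
                   as.numeric(category_proportions), sap_levels()),
                 volume_medians = stats::setNames(
                   as.numeric(volume_medians), sap_levels()),
                 laterality_bias = laterality_bias,
                 deformation_amplitude = deformation_amplitude,
                 translation_range = translation_range,
                 rotation_range = rotation_range,
                 scale_range = as.numeric(scale_range),
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# Separable Gaussian smoothing of a 3D array (sigma in voxels).
gauss_smooth3 <- function(a, sigma) {
  smooth_axis <- function(a, axis) {
    n <- dim(a)[axis]
    K <- exp(-(outer(seq_len(n), seq_len(n), "-"))^2 / (2 * sigma^2))
    K <- K / rowSums(K)
    perm <- switch(axis, `1` = 1:3, `2` = c(2, 1, 3), `3` = c(3, 2, 1))
    ap <- aperm(a, perm)
    d <- dim(ap)
    out <- array(K %*% matrix(ap, d[1]), d)
    aperm(out, order(perm))
  }
  for (ax in 1:3) a <- smooth_axis(a, ax)
  a
}

# Axis-aligned structure boxes in unit ellipsoid coordinates
# (x: left < 0 < right; y: anterior < 0 < posterior; z: inferior < 0 <
# superior). Paired structures list the left box; the right partner is its
# x-mirror. Chosen disjoint by construction (distinct x/y/z band triples).
phantom_boxes <- function() {
  mid <- list(
    list(11L, c(-0.07, 0.07), c(-0.10, 0.12), c(-0.05, 0.18)),  # 3rd-Vent
    list(12L, c(-0.09, 0.09), c(0.25, 0.42), c(-0.40, -0.22)),  # 4th-Vent
    list(13L, c(-0.11, 0.11), c(-0.05, 0.18), c(-0.88, -0.45))) # Brain-Stem
  X1 <- c(-0.48, -0.30); X2 <- c(-0.28, -0.10)
  Y1 <- c(-0.42, -0.24); Y2 <- c(-0.22, -0.04)
  Y3 <- c(-0.02, 0.16); Y4 <- c(0.18, 0.36)
  Z1 <- c(-0.40, -0.22); Z2 <- c(-0.20, -0.02)
  Z3 <- c(0.00, 0.18); Z4 <- c(0.20, 0.38)
  paired <- list(
    list(3L, X2, Y3, Z4),   # Lateral-Ventricle
    list(4L, X2, Y3, Z1),   # Inf-Lat-Ventricle
    list(19L, X2, Y4, Z4),  # Choroid-Plexus
    list(7L, X2, Y3, Z3),   # Thalamus
    list(8L, X2, Y2, Z3),   # Caudate
    list(9L, X1, Y2, Z3),   # Putamen
    list(10L, X2, Y2, Z2),  # Pallidum
    list(14L, X1, Y4, Z2),  # Hippocampus
    list(15L, X1, Y2, Z2),  # Amygdala
    list(16L, X2, Y1, Z2),  # Accumbens
    list(17L, X2, Y3, Z2),  # Ventral-DC
    list(18L, X1, Y3, Z2))  # Vessel
  list(mid = mid, paired = paired)
}

# Right-hemisphere partner of a left label: 1..10 -> 20..29, 14..19 -> 30..35.
mirror_label <- function(label) ifelse(label <= 10L, label + 19L, label + 16L)

#' Generate the phantom atlas and parcellation
#'
#' Builds a deterministic geometric brain: an ellipsoid spanning roughly half
#' of each grid axis, parcellated into the 35 structures of
#' [structure_table()]. `Left-` structures lie strictly in the x < midline
#' half-space and `Right-` structures strictly in x > midline (the grid is
#' even, so no voxel sits on the midline); 3rd-Ventricle, 4th-Ventricle and
#' Brain-Stem straddle it. Atlas intensity is a per-structure mean plus
#' Gaussian noise with sigma equal to 2 percent of the intensity range.
#'
#' @param grid_size even integer >= 32, voxels per axis.
#' @param seed integer seed for the intensity noise (geometry is
#'   deterministic).
#' @return List with `intensity` (a `scalar_volume`) and `parcellation`
#'   (a `label_volume`).
#' @export
make_atlas <- function(grid_size = 64, seed = 1) {
  if (grid_size < 32 || grid_size %% 2 != 0)
    hm_stop("grid_size must be an even integer >= 32 to fit 35 regions",
            "hemomap_grid_too_small")
  N <- as.integer(grid_size)
  ctr <- (N + 1) / 2
  semi <- c(0.30, 0.26, 0.28) * N
  ux <- (seq_len(N) - ctr) / semi[1]
  uy <- (seq_len(N) - ctr) / semi[2]
  uz <- (seq_len(N) - ctr) / semi[3]
  UX <- array(rep(ux, times = N * N), c(N, N, N))
  UY <- array(rep(rep(uy, each = N), times = N), c(N, N, N))
  UZ <- array(rep(uz, each = N * N), c(N, N, N))
  rho <- sqrt(UX^2 + UY^2 + UZ^2)
  brain <- rho <= 1
  lab <- array(0L, c(N, N, N))

  in_box <- function(xr, yr, zr) {
    UX >= xr[1] & UX <= xr[2] & UY >= yr[1] & UY <= yr[2] &
      UZ >= zr[1] & UZ <= zr[2] & brain
  }
  boxes <- phantom_boxes()
  for (b in boxes$mid) {
    sel <- in_box(b[[2]], b[[3]], b[[4]]) & lab == 0L
    lab[sel] <- b[[1]]
  }
  for (b in boxes$paired) {
    sel <- in_box(b[[2]], b[[3]], b[[4]]) & lab == 0L
    lab[sel] <- b[[1]]
    selR <- in_box(-rev(b[[2]]), b[[3]], b[[4]]) & lab == 0L
    lab[selR] <- mirror_label(b[[1]])
  }
  # remaining brain voxels: cerebellum (posterior-inferior), cortex shell,
  # white-matter bulk; all split by hemisphere
  rest <- brain & lab == 0L
  left <- UX < 0
  cereb <- rest & UY > 0.30 & UZ < -0.25
  shell <- rho > 0.80
  lab[cereb & shell & left] <- 6L    # Left-Cerebellum-Cortex
  lab[cereb & shell & !left] <- 25L
  lab[cereb & !shell & left] <- 5L   # Left-Cerebellum-White-Matter
  lab[cereb & !shell & !left] <- 24L
  rest <- brain & lab == 0L
  lab[rest & shell & left] <- 2L     # Left-Cerebral-Cortex
  lab[rest & shell & !left] <- 21L
  rest <- brain & lab == 0L
  lab[rest & left] <- 1L             # Left-Cerebral-White-Matter
  lab[rest & !left] <- 20L

  counts <- tabulate(lab[lab > 0L], nbins = 35L)
  if (any(counts == 0L))
    hm_stop(sprintf("grid %d too small: structures %s received no voxels",
                    N, paste(which(counts == 0L), collapse = ", ")),
            "hemomap_grid_too_small")

  set.seed(seed)
  means <- seq(30, 250, length.out = 35)
  intens <- array(0, c(N, N, N))
  nb <- sum(brain)
  intens[brain] <- means[lab[brain]] +
    stats::rnorm(nb, sd = 0.02 * (max(means) - 0))
  list(intensity = scalar_volume(intens),
       parcellation = label_volume(lab))
}

# Sample the generator's ground-truth transform for one subject:
# subject-grid voxel -> atlas-grid voxel (similarity + smooth deformation).
sample_true_transform <- function(config, dim3) {
  ctr <- (dim3 + 1) / 2
  st <- similarity_transform(
    translation = stats::runif(3, -config$translation_range,
                               config$translation_range),
    rotation = stats::runif(3, -config$rotation_range,
                            config$rotation_range),
    scale = stats::runif(1, config$scale_range[1], config$scale_range[2]),
    center = ctr)
  disp <- NULL
  if (config$deformation_amplitude > 0) {
    sg <- 4 * config$grid_size / 64
    disp <- array(0, c(dim3, 3))
    for (a in 1:3)
      disp[, , , a] <- gauss_smooth3(array(stats::rnorm(prod(dim3)), dim3), sg)
    mx <- sqrt(max(disp[, , , 1]^2 + disp[, , , 2]^2 + disp[, , , 3]^2))
    disp <- disp * (config$deformation_amplitude / mx)
  }
  g <- list(dim = dim3, spacing = c(1, 1, 1), origin = c(0, 0, 0))
  spatial_transform(st, disp, domain = g, codomain = g)
}

runif_window <- function(n, w) stats::runif(n, w[1], w[2])

#' Generate one phantom subject
#'
#' Derives a subject CT from the atlas: the atlas is pulled through a random
#' similarity transform composed with a smooth random deformation, tissue
#' intensities are remapped into Hounsfield windows (CSF-role structures 4-12
#' Hu, other brain 25-40 Hu, blood 50-80 Hu, a 2-voxel skull shell 700-1200
#' Hu, air background -1000 Hu), and a single ellipsoidal hemorrhage is
#' implanted. The lesion is drawn in atlas space -- uniformly over the brain
#' for none/mild, in the left hemisphere with probability `laterality_bias`
#' for severe, in the right hemisphere or ventricular structures for
#' moderate -- and warped into the subject grid, so its atlas-space footprint
#' is known exactly.
#'
#' @param atlas,parcellation the pair from [make_atlas()].
#' @param category one of `"none"`, `"mild"`, `"moderate"`, `"severe"`.
#' @param config a [phantom_config()].
#' @param seed integer seed for this subject.
#' @return A list of class `phantom_subject`: `ct` (`scalar_volume`, Hu),
#'   `hemorrhage` (`binary_mask`, subject grid), `sap_category`,
#'   `true_transform` (subject-to-atlas `spatial_transform`), `brain_mask`,
#'   `lesion_atlas` (ground-truth atlas-space footprint), `tissue_counts`,
#'   and `lesion_fraction`.
#' @export
make_subject <- function(atlas, parcellation, category, config, seed) {
  stopifnot(inherits(atlas, "scalar_volume"),
            inherits(parcellation, "label_volume"))
  require_same_geometry(atlas, parcellation, "atlas and parcellation")
  category <- match.arg(category, sap_levels())
  set.seed(as.integer(seed))
  dim3 <- dim(atlas$data)
  N <- dim3[1]
  ctr <- (N + 1) / 2

  P <- sample_true_transform(config, dim3)

  # atlas-space lesion: ellipsoid with category-dependent center
  abrain <- parcellation$data > 0L
  n_brain <- sum(abrain)
  frac <- exp(stats::rnorm(1, log(config$volume_medians[[category]]),
                           0.4))
  n_target <- max(8, round(frac * n_brain))
  r0 <- (3 * n_target / (4 * pi))^(1 / 3)
  aniso <- stats::runif(3, 0.8, 1.25)
  radii <- r0 * aniso / prod(aniso)^(1 / 3)

  semi <- c(0.30, 0.26, 0.28) * N
  ui <- lapply(1:3, function(a) (seq_len(N) - ctr) / semi[a])
  rho2 <- outer(outer(ui[[1]]^2, ui[[2]]^2, "+"), ui[[3]]^2, "+")
  interior <- abrain & rho2 <= 0.75^2
  lab <- parcellation$data
  allowed <- switch(category,
    none = ,
    mild = interior,
    severe = {
      side <- if (stats::runif(1) < config$laterality_bias)
        left_labels() else right_labels()
      interior & array(lab %in% side, dim3)
    },
    moderate = interior &
      array(lab %in% c(right_labels(), csf_labels()), dim3))
  if (!any(allowed)) allowed <- interior
  cand <- which(allowed)
  pick <- cand[sample.int(length(cand), 1)]
  cidx <- arrayInd(pick, dim3)
  cx <- as.numeric(cidx)
  if (category == "severe") {
    # keep the lesion center (centroid) strictly on the drawn side; the
    # ellipsoid may spill over the midline, as real hematomas do
    if (lab[pick] %in% left_labels())
      cx[1] <- min(cx[1], ctr - 1)
    else
      cx[1] <- max(cx[1], ctr + 1)
  }
  gx <- seq_len(N)
  le2 <- outer(outer(((gx - cx[1]) / radii[1])^2,
                     ((gx - cx[2]) / radii[2])^2, "+"),
               ((gx - cx[3]) / radii[3])^2, "+")
  lesion_atlas <- (le2 <= 1) & abrain

  # draw per-voxel Hounsfield values in atlas space, then pull them into the
  # subject grid with trilinear interpolation: the realized image then
  # encodes the ground-truth transform with sub-voxel fidelity, which a
  # nearest-neighbor remap of the labels would quantize away
  src <- array(phantom_hu$air + 0, dim3)
  a_csf <- abrain & array(lab %in% csf_labels(), dim3) & !lesion_atlas
  a_par <- abrain & !a_csf & !lesion_atlas
  src[a_csf] <- runif_window(sum(a_csf), phantom_hu$csf)
  src[a_par] <- runif_window(sum(a_par), phantom_hu$parenchyma)
  src[lesion_atlas] <- runif_window(sum(lesion_atlas), phantom_hu$blood)
  ct <- warp_volume(scalar_volume(src), P, fill = phantom_hu$air)$data
  bsoft <- warp_volume(scalar_volume(abrain * 1), P, fill = 0)$data
  brain_s <- bsoft >= 0.5
  les_s <- warp_volume(binary_mask(lesion_atlas * 1L), P, fill = 0)$data
  shell <- dilate6(dilate6(brain_s)) & !brain_s
  ct[shell] <- runif_window(sum(shell), phantom_hu$skull)
  les_in <- les_s == 1L & brain_s

  # tissue tallies of the realized CT inside the true brain, in the
  # segmentation windows (interior voxels sit in the generator windows,
  # which lie strictly inside; boundary blends may fall between windows)
  win <- hu_windows()
  xb <- ct[brain_s]
  tissue_counts <- c(csf = sum(xb >= win$csf[1] & xb < win$csf[2]),
                     parenchyma = sum(xb >= win$parenchyma[1] &
                                        xb < win$parenchyma[2]),
                     hemorrhage = sum(xb >= win$hemorrhage[1] &
                                        xb < win$hemorrhage[2]))

  structure(list(
    ct = scalar_volume(ct),
    hemorrhage = binary_mask(les_in * 1L),
    sap_category = category,
    true_transform = P,
    brain_mask = binary_mask(brain_s * 1L),
    lesion_atlas = binary_mask(lesion_atlas * 1L),
    tissue_counts = tissue_counts,
    lesion_fraction = frac,
    seed = as.integer(seed)), class = "phantom_subject")
}

#' @exportS3Method base::print
print.phantom_subject <- function(x, ...) {
  cat(sprintf("<phantom_subject> category %s, lesion %d voxels (%.1f%% of brain)\n",
              x$sap_category, sum(x$hemorrhage$data),
              100 * x$lesion_fraction))
  invisible(x)
}

#' Generate a phantom cohort
#'
#' Draws each subject's pneumonia category from `category_proportions`,
#' derives per-subject seeds deterministically from the master seed, and
#' generates all subjects against a shared atlas. When `out_dir` is given,
#' CT and hemorrhage volumes are written as NIfTI and a manifest TSV
#' (columns id, category, ct_path, mask_path) is written alongside.
#'
#' @param config a [phantom_config()].
#' @param out_dir optional directory for NIfTI volumes and `manifest.tsv`.
#' @return A list of class `phantom_cohort` with `atlas`, `parcellation`,
#'   `subjects` (list of `phantom_subject`), `manifest` (data.frame) and
#'   `config`.
#' @export
make_cohort <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "phantom_config"))
  if (config$n_subjects < 8)
    hm_stop("a cohort needs at least 8 subjects", "hemomap_cohort_too_small")
  at <- make_atlas(config$grid_size, config$seed)
  set.seed(config$seed)
  cats <- sample(sap_levels(), config$n_subjects, replace = TRUE,
                 prob = config$category_proportions)
  seeds <- sample.int(.Machine$integer.max - 1L, config$n_subjects)
  ids <- sprintf("S%03d", seq_len(config$n_subjects))
  subjects <- mapply(function(cat, sd) {
    make_subject(at$intensity, at$parcellation, cat, config, sd)
  }, cats, seeds, SIMPLIFY = FALSE)
  names(subjects) <- ids
  manifest <- data.frame(id = ids, category = cats,
                         ct_path = NA_character_, mask_path = NA_character_,
                         stringsAsFactors = FALSE)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(subjects)) {
      ctp <- file.path(out_dir, paste0(ids[i], "_ct.nii.gz"))
      mkp <- file.path(out_dir, paste0(ids[i], "_hem.nii.gz"))
      write_volume(subjects[[i]]$ct, ctp)
      write_volume(subjects[[i]]$hemorrhage, mkp)
      manifest$ct_path[i] <- ctp
      manifest$mask_path[i] <- mkp
    }
    write_volume(at$intensity, file.path(out_dir, "atlas.nii.gz"))
    write_volume(at$parcellation, file.path(out_dir, "parcellation.nii.gz"))
    utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  structure(list(atlas = at$intensity, parcellation = at$parcellation,
                 subjects = subjects, manifest = manifest, config = config),
            class = "phantom_cohort")
}

#' @exportS3Method base::print
print.phantom_cohort <- function(x, ...) {
  cat(sprintf("<phantom_cohort> %d subjects at grid %d\n",
              length(x$subjects), x$config$grid_size))
  print(table(x$manifest$category))
  invisible(x)
}
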