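test_that("the generated atlas contains all 35 structures, lateralized", {
  at <- fx_atlas64()
  cnt <- label_voxel_counts(at$parcellation)
  expect_true(all(cnt > 0))
  expect_equal(sum(cnt > 0), 35)
  expect_true(all(cnt >= 27))

  lab <- at$parcellation$data
  mid <- (dim(lab)[1] + 1) / 2
  xcoord <- slice.index(lab, 1)
  for (l in hemomap:::left_labels())
    expect_true(all(xcoord[lab == l] < mid), label = paste("left", l))
  for (l in hemomap:::right_labels())
    expect_true(all(xcoord[lab == l] > mid), label = paste("right", l))
  for (l in c(11L, 12L, 13L)) {
    expect_true(any(xcoord[lab == l] < mid) && any(xcoord[lab == l] > mid),
                label = paste("midline", l))
  }
  # Left-Hippocampus centroid strictly left of the midline
  expect_lt(mean(xcoord[lab == 14L]), mid)

  # brain spans roughly half of each axis
  brain <- lab > 0L
  for (ax in 1:3) {
    ext <- range(which(apply(brain, ax, any)))
    frac <- diff(ext) / dim(lab)[ax]
    expect_gt(frac, 0.4); expect_lt(frac, 0.7)
  }
})

test_that("atlas generation is deterministic and guards the grid", {
  a1 <- make_atlas(32, seed = 9)
  a2 <- make_atlas(32, seed = 9)
  expect_identical(a1$intensity$data, a2$intensity$data)
  expect_identical(a1$parcellation$data, a2$parcellation$data)
  expect_error(make_atlas(16), class = "hemomap_grid_too_small")
  expect_error(make_atlas(33), class = "hemomap_grid_too_small")
})

test_that("phantom_config validates its invariants", {
  expect_error(phantom_config(category_proportions = c(0.5, 0.5, 0.2, 0.2)),
               class = "hemomap_bad_config")
  expect_error(phantom_config(volume_medians = c(0.05, 0.03, 0.02, 0.01)),
               class = "hemomap_bad_config")
  expect_error(phantom_config(laterality_bias = 0.3),
               class = "hemomap_bad_config")
  expect_error(phantom_config(laterality_bias = 1.2),
               class = "hemomap_bad_config")
  cfg <- phantom_config()
  expect_equal(sum(cfg$category_proportions), 1)
  expect_equal(unname(cfg$category_proportions),
               c(101, 77, 47, 19) / 244, tolerance = 1e-12)
})

test_that("subjects are deterministic with tissue in the generator windows", {
  at <- fx_atlas32()
  cfg <- phantom_config(grid_size = 32, seed = 2)
  s1 <- make_subject(at$intensity, at$parcellation, "moderate", cfg, seed = 5)
  s2 <- make_subject(at$intensity, at$parcellation, "moderate", cfg, seed = 5)
  expect_identical(s1$ct$data, s2$ct$data)
  expect_identical(s1$hemorrhage$data, s2$hemorrhage$data)

  # hemorrhage lies inside the subject brain
  expect_true(all(s1$brain_mask$data[s1$hemorrhage$data == 1L] == 1L))
  # background is air, skull shell is high-Hu
  expect_equal(min(s1$ct$data), -1000)
  expect_gt(max(s1$ct$data), 600)
  # no Hu above the skull window, none between blood and skull inside brain
  inside <- s1$ct$data[s1$brain_mask$data == 1L]
  expect_lt(max(inside), 90)
})

test_that("severe lesions with full laterality bias sit left of midline", {
  at <- fx_atlas32()
  cfg <- phantom_config(grid_size = 32, laterality_bias = 1, seed = 2)
  mid <- (32 + 1) / 2
  for (sd in 1:5) {
    s <- make_subject(at$intensity, at$parcellation, "severe", cfg, seed = sd)
    xcoord <- slice.index(s$lesion_atlas$data, 1)
    centroid <- mean(xcoord[s$lesion_atlas$data == 1L])
    expect_lt(centroid, mid)
  }
})

test_that("lesion volume fractions increase with severity", {
  at <- fx_atlas32()
  cfg <- phantom_config(grid_size = 32, seed = 2)
  med <- sapply(hemomap:::sap_levels(), function(cc) {
    fr <- sapply(1:60, function(sd) {
      s <- make_subject(at$intensity, at$parcellation, cc, cfg,
                        seed = 1000 + sd)
      sum(s$hemorrhage$data) / sum(s$brain_mask$data)
    })
    median(fr)
  })
  expect_true(all(diff(med) > 0))
})

test_that("cohorts are reproducible with category draws near expectation", {
  cfg <- phantom_config(grid_size = 32, n_subjects = 120, seed = 6)
  co1 <- make_cohort(cfg)
  co2 <- make_cohort(cfg)
  expect_identical(co1$manifest, co2$manifest)
  expect_identical(co1$subjects[[7]]$ct$data, co2$subjects[[7]]$ct$data)

  # category counts within the 99% binomial band of their expectation
  n <- cfg$n_subjects
  tab <- table(factor(co1$manifest$category,
                      levels = hemomap:::sap_levels()))
  for (cc in hemomap:::sap_levels()) {
    p <- cfg$category_proportions[[cc]]
    expect_gte(tab[[cc]], qbinom(0.005, n, p))
    expect_lte(tab[[cc]], qbinom(0.995, n, p))
  }

  expect_error(make_cohort(phantom_config(grid_size = 32, n_subjects = 5)),
               class = "hemomap_cohort_too_small")
})

test_that("degenerate proportions give a single-category cohort", {
  cfg <- phantom_config(grid_size = 32, n_subjects = 10,
                        category_proportions = c(1, 0, 0, 0), seed = 3)
  co <- make_cohort(cfg)
  expect_true(all(co$manifest$category == "none"))
})

test_that("cohort manifests round-trip through disk", {
  d <- file.path(tempdir(), "cohortio")
  cfg <- phantom_config(grid_size = 32, n_subjects = 8, seed = 4)
  co <- make_cohort(cfg, out_dir = d)
  expect_true(file.exists(file.path(d, "manifest.tsv")))
  man <- utils::read.delim(file.path(d, "manifest.tsv"))
  expect_equal(nrow(man), 8)
  ct <- read_volume(man$ct_path[1], "scalar")
  expect_equal(ct$data, co$subjects[[1]]$ct$data, tolerance = 1e-12)
  hm <- read_volume(man$mask_path[1], "mask")
  expect_identical(hm$data, co$subjects[[1]]$hemorrhage$data)
})
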