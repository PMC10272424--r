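test_that("probability maps equal the voxelwise mask average", {
  m1 <- random_mask(16, seed = 1)
  pm <- probability_map(list(m1), "none")
  expect_equal(pm$data, m1$data + 0, ignore_attr = TRUE)
  expect_equal(pm$n_subjects, 1)

  same <- probability_map(list(m1, m1, m1), "none")
  expect_equal(same$data, m1$data + 0, ignore_attr = TRUE)

  m2 <- random_mask(16, seed = 2)
  m3 <- random_mask(16, seed = 3)
  pm3 <- probability_map(list(m1, m2, m3))
  # brute-force voxel loop
  brute <- array(0, c(16, 16, 16))
  for (i in seq_along(brute))
    brute[i] <- (m1$data[i] + m2$data[i] + m3$data[i]) / 3
  expect_equal(pm3$data, brute, tolerance = 1e-15)
  # values on the {0, 1/n, ..., 1} grid
  expect_true(all(abs(pm3$data * 3 - round(pm3$data * 3)) < 1e-12))
  expect_lte(max(pm3$data), 1)
  # permutation invariance
  pm3b <- probability_map(list(m3, m1, m2))
  expect_equal(pm3$data, pm3b$data)
  # conservation under superposition
  expect_equal(sum(pm3$data) * 3,
               sum(m1$data) + sum(m2$data) + sum(m3$data))
})

test_that("probability_map validates its inputs", {
  expect_error(probability_map(list()), class = "hemomap_empty_list")
  expect_error(probability_map(list(random_mask(16), random_mask(8))),
               class = "hemomap_geometry_mismatch")
  expect_error(probability_map(list(scalar_volume(array(0, c(8, 8, 8))))),
               class = "hemomap_bad_mask")
})

test_that("hemisphere mass splits left and right structures", {
  at <- fx_atlas32()
  lab <- at$parcellation
  left_only <- binary_mask((lab$data == 14L) * 1L)  # Left-Hippocampus
  hm <- hemisphere_mass(probability_map(list(left_only)), lab)
  expect_gt(hm[["left"]], 0)
  expect_equal(hm[["right"]], 0)

  # mirror-symmetric map on the mirror-symmetric parcellation
  sym <- binary_mask(((lab$data == 14L) | (lab$data == 30L)) * 1L)
  hms <- hemisphere_mass(probability_map(list(sym)), lab)
  expect_equal(hms[["left"]], hms[["right"]])

  # midline structures contribute to neither side
  mid <- binary_mask((lab$data == 13L) * 1L)
  hmm <- hemisphere_mass(probability_map(list(mid)), lab)
  expect_equal(unname(hmm), c(0, 0))
})

test_that("ratio summaries match a direct sorted-array computation", {
  tab <- synthetic_feature_table(
    12, c(rep("none", 5), rep("mild", 4), rep("moderate", 2), "severe"),
    seed = 13)
  set.seed(13)
  tab$csf_vol <- runif(12, 50, 100)
  tab$parenchyma_vol <- runif(12, 900, 1100)
  tab$hemorrhage_vol <- runif(12, 10, 200)
  rs <- ratio_summary(tab)
  expect_s3_class(rs, "ratio_summary")
  expect_equal(rs$category, c("none", "mild", "moderate", "severe"))

  ratio <- tab$hemorrhage_vol / (tab$csf_vol + tab$parenchyma_vol)
  x <- sort(ratio[tab$sap_category == "none"])
  expect_equal(rs$min[1], x[1])
  expect_equal(rs$max[1], x[length(x)])
  expect_equal(rs$median[1], stats::median(x))
  expect_equal(rs$mean[1], mean(x))
  expect_equal(rs$q1[1], unname(stats::quantile(x, 0.25)))
  expect_equal(rs$q3[1], unname(stats::quantile(x, 0.75)))
  # ordering and whisker invariants, every category
  for (i in seq_len(nrow(rs))) {
    expect_true(rs$min[i] <= rs$q1[i] && rs$q1[i] <= rs$median[i] &&
                  rs$median[i] <= rs$q3[i] && rs$q3[i] <= rs$max[i])
    expect_gte(rs$lower_whisker[i], rs$min[i])
    expect_lte(rs$upper_whisker[i], rs$max[i])
  }

  # single-subject category: all order statistics collapse
  sev <- rs[rs$category == "severe", ]
  rsev <- ratio[tab$sap_category == "severe"]
  expect_true(all(abs(unlist(sev[c("min", "lower_whisker", "q1", "median",
                                   "mean", "q3", "upper_whisker", "max")]) -
                        rsev) < 1e-12))

  # missing category skipped with a warning
  tab2 <- tab[tab$sap_category != "severe", ]
  expect_warning(rs2 <- ratio_summary(tab2),
                 class = "hemomap_empty_category")
  expect_equal(nrow(rs2), 3)
})
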