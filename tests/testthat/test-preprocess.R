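test_that("skull-stripping recovers the phantom brain", {
  at <- fx_atlas32()
  cfg <- phantom_config(grid_size = 32, seed = 2)
  s <- make_subject(at$intensity, at$parcellation, "mild", cfg, seed = 8)
  st <- strip_skull(s$ct)
  # no skull-shell voxel survives inside the mask
  expect_true(all(st$volume$data[st$mask$data == 1L] < 700))
  # close agreement with the generator's brain
  expect_gte(dice(st$mask, s$brain_mask), 0.95)
  # outside the mask the volume is the fill value
  expect_true(all(st$volume$data[st$mask$data == 0L] == -1000))
})

test_that("skull-stripping degenerate inputs raise typed conditions", {
  air <- scalar_volume(array(-1000, c(16, 16, 16)))
  expect_error(suppressWarnings(strip_skull(air)),
               class = "hemomap_empty_brain")

  # soft tissue but no bone: warning-level fallback, still returns a mask
  soft <- array(-1000, c(16, 16, 16))
  soft[5:12, 5:12, 5:12] <- 30
  expect_warning(res <- strip_skull(scalar_volume(soft)),
                 class = "hemomap_no_bone")
  expect_gt(sum(res$mask$data), 0)
})

test_that("min-max normalization follows its defining identities", {
  v <- scalar_volume(array(c(0, 50, 100, rep(50, 8^3 - 3)), c(8, 8, 8)))
  n <- minmax_normalize(v)
  expect_equal(sort(unique(as.vector(n$data))), c(0, 0.5, 1))
  expect_equal(min(n$data), 0)
  expect_equal(max(n$data), 1)
  # idempotent after the first application
  expect_equal(minmax_normalize(n)$data, n$data, tolerance = 1e-15)
  # invariant to affine intensity rescaling a*v + b, a > 0
  w <- scalar_volume(3.7 * v$data - 11, v$spacing, v$origin)
  expect_equal(minmax_normalize(w)$data, n$data, tolerance = 1e-12)
  # order-preserving
  set.seed(1)
  r <- scalar_volume(array(rnorm(8^3), c(8, 8, 8)))
  expect_identical(order(minmax_normalize(r)$data), order(r$data))
  expect_error(minmax_normalize(scalar_volume(array(5, c(8, 8, 8)))),
               class = "hemomap_constant_volume")
})

test_that("resampling respects geometry, interpolation kind and binarity", {
  set.seed(3)
  v <- scalar_volume(array(rnorm(16^3), c(16, 16, 16)))
  same <- resample_to(v, v)
  expect_equal(same$data, v$data)

  m <- random_mask(16, seed = 5)
  ref <- list(dim = c(11L, 13L, 9L), spacing = c(16 / 11, 16 / 13, 16 / 9),
              origin = c(0, 0, 0))
  rm <- resample_to(m, ref)
  expect_true(all(rm$data %in% c(0L, 1L)))
  expect_equal(dim(rm$data), ref$dim)

  const <- scalar_volume(array(2.5, c(64, 64, 64)))
  down <- resample_to(const, list(dim = c(32L, 32L, 32L),
                                  spacing = c(2, 2, 2), origin = c(0, 0, 0)))
  expect_true(all(abs(down$data - 2.5) < 1e-12))

  expect_error(resample_to(v, list(dim = c(1L, 1L, 1L),
                                   spacing = c(1, 1, 1),
                                   origin = c(0, 0, 0))),
               class = "hemomap_bad_geometry")
})

test_that("tissue quantification matches the generator tallies exactly", {
  at <- fx_atlas32()
  cfg <- phantom_config(grid_size = 32, seed = 2)
  for (sd in c(3, 4)) {
    s <- make_subject(at$intensity, at$parcellation, "moderate", cfg,
                      seed = sd)
    tis <- segment_tissues(s$ct, s$brain_mask)
    expect_identical(tis$csf_voxels, unname(s$tissue_counts["csf"]))
    expect_identical(tis$parenchyma_voxels,
                     unname(s$tissue_counts["parenchyma"]))
    expect_identical(tis$hemorrhage_voxels,
                     unname(s$tissue_counts["hemorrhage"]))
    # window gaps mean the three classes never exceed the brain volume
    expect_lte(tis$csf_voxels + tis$parenchyma_voxels + tis$hemorrhage_voxels,
               sum(s$brain_mask$data))
  }
})

test_that("tissue quantification rejects normalized input and empty masks", {
  at <- fx_atlas32()
  cfg <- phantom_config(grid_size = 32, seed = 2)
  s <- make_subject(at$intensity, at$parcellation, "none", cfg, seed = 9)
  norm <- minmax_normalize(s$ct)
  expect_error(segment_tissues(norm, s$brain_mask),
               class = "hemomap_normalized_input")

  empty <- binary_mask(array(0L, dim(s$ct$data)))
  tis <- segment_tissues(s$ct, empty)
  expect_equal(tis$csf_voxels + tis$parenchyma_voxels + tis$hemorrhage_voxels,
               0)
})
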