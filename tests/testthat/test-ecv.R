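test_that("the ECV relation evaluates its closed form and guards its domain", {
  expect_equal(compute_ecv(0.40, 30, 60), 0.30)
  expect_equal(compute_ecv(1.0, 45, 60), 0)
  expect_equal(compute_ecv(0.0, 57, 57), 1)
  expect_error(compute_ecv(0.4, 30, 0), "non-zero")
  expect_error(compute_ecv(1.2, 30, 60), "fraction")
  # out-of-range values are returned, not clipped, and flagged downstream
  big <- compute_ecv(0.1, 90, 60)
  expect_gt(big, 1)
  expect_true(ecv_flagged(big))
  expect_false(ecv_flagged(0.5))
})

test_that("face-adjacent erosion shrinks cubes as expected and is anti-extensive", {
  cube <- array(TRUE, c(5, 5, 5))
  once <- erode_mask(cube, 1)
  expect_equal(sum(once), 27)
  expect_identical(erode_mask(cube, 0), cube)

  single <- array(FALSE, c(3, 3, 3)); single[2, 2, 2] <- TRUE
  expect_error(erode_mask(single, 1), "empty")

  withr::with_seed(5, {
    for (i in 1:3) {
      m <- array(runif(10^3) > 0.25, c(10, 10, 10))
      e1 <- tryCatch(erode_mask(m, 1), error = function(e) NULL)
      if (is.null(e1)) next
      expect_true(all(m[e1]))        # output is a subset of the input
      e2 <- tryCatch(erode_mask(m, 2), error = function(e) NULL)
      if (!is.null(e2)) expect_true(all(e1[e2])) # decreasing in iterations
    }
  })
})

test_that("the pipeline is the exact inverse of the phantom generator", {
  pair <- generate_volume_pair(0.32, hct = 0.40, dhu_blood = 60)
  map <- compute_ecv_map(pair, hct = 0.40)
  expect_equal(map$mean_lv_ecv, 0.32, tolerance = 1e-12)
  expect_equal(map$dhu_blood, 60, tolerance = 1e-12)
  expect_equal(map$n_flagged, 0)

  geom <- phantom_geometry()
  field <- phantom_gradient_field(geom)
  pair2 <- generate_volume_pair(field, hct = 0.40, dhu_blood = 60)
  map2 <- compute_ecv_map(pair2, hct = 0.40)
  lv <- geom$lv_mask
  expect_lt(max(abs(map2$ecv[lv] - field[lv])), 1e-12)
  expect_true(all(is.na(map2$ecv[!lv])))
  expect_equal(map2$mean_lv_ecv, mean(field[lv]), tolerance = 1e-12)
})

test_that("synthetic and conventional maps differ by the plasma-fraction ratio", {
  pair <- generate_volume_pair(0.32, hct = 0.40, dhu_blood = 60,
                               noise_sd = 2, seed = 3)
  con <- compute_ecv_map(pair, hct = 0.40)
  syn_hct <- predict_hct(published_models()$literature, 50) / 100
  syn <- compute_ecv_map(pair, hct = syn_hct, source = "synthetic")
  lv <- pair$lv_mask
  ratio <- syn$ecv[lv] / con$ecv[lv]
  expect_lt(max(abs(ratio - (1 - syn_hct) / (1 - 0.40))), 1e-12)
})

test_that("mean LV ECV is unbiased under voxel noise", {
  means <- vapply(1:40, function(s) {
    pair <- generate_volume_pair(0.32, hct = 0.40, dhu_blood = 60,
                                 noise_sd = 5, seed = s)
    compute_ecv_map(pair, hct = 0.40)$mean_lv_ecv
  }, 0)
  mc_se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - 0.32), 4 * mc_se + 1e-4)
})

test_that("phantom construction rejects impossible inputs", {
  expect_error(generate_volume_pair(0.32, hct = 1.2, dhu_blood = 60), "hct")
  expect_error(generate_volume_pair(0.32, hct = 0.4, dhu_blood = -5),
               "positive")
  expect_error(generate_volume_pair(1.5, hct = 0.4, dhu_blood = 60),
               "ecv_field")
  geom <- phantom_geometry()
  expect_false(any(geom$lv_mask & geom$bp_mask))
  expect_gt(sum(geom$bp_mask), 0)
})

test_that("per-record synthetic ECV routes through stratified models", {
  rec <- list(hu_blood = 50, sex = "male", bmi = 25)
  expect_equal(compute_synecv(rec, published_models()$literature, 30, 60),
               (1 - 0.429) * 0.5)
  combined <- published_models()$combined
  expect_true(is.na(compute_synecv(list(hu_blood = 50, sex = "female",
                                        bmi = 20), combined, 30, 60)))
  # a model predicting the serum value exactly gives synECV == conECV
  oracle_model <- linear_hct_model(0, 40)
  expect_equal(compute_synecv(list(hu_blood = 50), oracle_model, 30, 60),
               compute_ecv(0.40, 30, 60))
})

test_that("volume pairs and ECV maps survive NIfTI round trips", {
  pair <- generate_volume_pair(0.32, hct = 0.40, dhu_blood = 60,
                               geometry = phantom_geometry(dim = 32L))
  dir <- withr::local_tempdir()
  paths <- write_volume_pair(pair, dir)
  expect_true(all(file.exists(paths)))
  back <- read_volume_pair(paths["baseline"], paths["lie"],
                           paths["lv_mask"], paths["bp_mask"])
  expect_identical(back$lv_mask, pair$lv_mask)
  expect_identical(back$bp_mask, pair$bp_mask)
  expect_lt(max(abs(back$lie_hu - pair$lie_hu)), 1e-4) # float32 storage
  expect_equal(back$voxel_spacing, pair$voxel_spacing, tolerance = 1e-6)

  map <- compute_ecv_map(back, hct = 0.40)
  out <- file.path(dir, "map.nii.gz")
  files <- write_ecv_map(map, out, voxel_spacing = back$voxel_spacing)
  sidecar <- jsonlite::read_json(files[["sidecar"]])
  expect_equal(sidecar$mean_lv_ecv, map$mean_lv_ecv, tolerance = 1e-12)
  expect_equal(sidecar$hct_used, 0.40)
  expect_identical(sidecar$source, "conventional")
  img <- RNifti::readNifti(out)
  expect_equal(sum(!is.na(img[])), sum(back$lv_mask))
})
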