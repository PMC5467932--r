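test_that("lung partition yields exactly 24 nonempty disjoint regions covering the mask", {
  ph <- thorax_default()
  regions <- partition_lung_regions(ph$truth$rois$lung)
  expect_length(regions, 24)
  expect_true(all(vapply(regions, mask_count, numeric(1)) > 0))
  total <- Reduce(`+`, lapply(regions, function(m) m$values))
  ## disjoint (no voxel in two regions) and exhaustive (union == input)
  expect_true(all(total %in% c(0, 1)))
  expect_identical(total, ph$truth$rois$lung$values)
})

test_that("a symmetric two-lung phantom partitions into mirror-equal region sizes", {
  ph <- thorax_lungs_only()
  regions <- partition_lung_regions(ph$truth$rois$lung)
  counts <- vapply(regions, mask_count, numeric(1))
  left <- counts[grep("^L_", names(counts))]
  right <- counts[sub("^L_", "R_", names(left))]
  expect_equal(unname(left), unname(right))
})

test_that("partition fails when one side of the split is empty", {
  ph <- thorax_lungs_only()
  mid_plane <- dim(ph$ct$values)[1] / 2  # 0-based mid-sagittal grid plane
  expect_error(partition_lung_regions(ph$truth$rois$lung_left,
                                      side_split = mid_plane),
               "one side")
})

test_that("blood-pool SUV is the pooled mean over the mask union", {
  vals <- array(0, c(10, 10, 10))
  la <- array(0, c(10, 10, 10)); aorta <- array(0, c(10, 10, 10))
  la[1:4, 1:5, 1:5] <- 1          # 100 voxels
  aorta[6:10, 1:10, 1:6] <- 1     # 300 voxels
  vals[la == 1] <- 1.0
  vals[aorta == 1] <- 2.0
  g <- voxel_grid(vals); mla <- voxel_grid(la); mao <- voxel_grid(aorta)
  expect_equal(blood_pool_suv(g, mla, mao), 1.75)  # (100*1 + 300*2)/400
  ## constant field
  g2 <- voxel_grid(array(1.2, c(10, 10, 10)))
  expect_equal(blood_pool_suv(g2, mla, mao), 1.2)
  expect_error(blood_pool_suv(g, voxel_grid(array(0, c(10, 10, 10))), mao),
               "empty")
})

test_that("blood-pool SUV on the phantom equals the configured blood uptake", {
  ph <- thorax_default()
  suv <- to_suv(average_frames(ph$series), ph$series$injected_dose,
                ph$series$body_weight)
  expect_equal(blood_pool_suv(suv, ph$truth$rois$la, ph$truth$rois$aorta),
               ph$truth$uptake$blood, tolerance = 1e-12)
})

test_that("air-fraction correction follows SUV_M / (1 + HU/1000)", {
  expect_equal(suv_air_corrected(0.44, -700), 0.44 / 0.3)
  expect_equal(suv_air_corrected(0.5, 0), 0.5)     # no air, no change
  expect_equal(suv_air_corrected(0, -500), 0)
  expect_error(suv_air_corrected(0.5, -1000), "air")
})

test_that("tissue-fraction correction follows (SUV_M - f SUV_B)/(1 + HU/1000 - f)", {
  expect_equal(suv_tissue_corrected(0.44, -700, 1.0, 0.16),
               (0.44 - 0.16) / (0.30 - 0.16))  # = 2.0, the phantom tissue SUV
  ## f = 0 reduces to the air-only correction
  hu <- c(-800, -700, -300, 0); sm <- c(0.3, 0.44, 0.8, 1.1)
  expect_equal(suv_tissue_corrected(sm, hu, 1.0, 0),
               suv_air_corrected(sm, hu))
  ## zero tissue uptake: measured SUV entirely explained by blood
  expect_equal(suv_tissue_corrected(0.16 * 1.2, -700, 1.2, 0.16), 0)
  expect_error(suv_tissue_corrected(0.4, -900, 1.0, 0.16), "positive")
  expect_error(suv_tissue_corrected(0.4, -700, 1.0, 1.2), "blood_fraction")
})

test_that("corrected SUVs increase strictly as HU falls toward -1000", {
  hu <- seq(-100, -950, by = -50)
  sl <- suv_air_corrected(0.44, hu)
  expect_true(all(diff(sl) > 0))
  st <- suv_tissue_corrected(0.44, hu[hu > -840], 1.0, 0.16)
  expect_true(all(diff(st) > 0))
})

test_that("noise-free phantom region means invert the mixing model exactly", {
  ph <- thorax_default()
  suv <- to_suv(average_frames(ph$series), ph$series$injected_dose,
                ph$series$body_weight)
  regions <- partition_lung_regions(ph$truth$rois$lung)
  meas <- region_measures(suv, ph$ct, regions)
  suv_b <- blood_pool_suv(suv, ph$truth$rois$la, ph$truth$rois$aorta)
  st <- suv_tissue_corrected(meas$suv_m, meas$mean_hu, suv_b, 0.16)
  expect_equal(st, rep(ph$truth$uptake$lung_tissue, 24), tolerance = 1e-6)
})

test_that("lung summary averages the included regions and excludes lower lobes on request", {
  ph <- thorax_default()
  suv <- to_suv(average_frames(ph$series), ph$series$injected_dose,
                ph$series$body_weight)
  regions <- partition_lung_regions(ph$truth$rois$lung)
  meas <- region_measures(suv, ph$ct, regions)
  s_all <- lung_summary(meas, suv_b = 1.0)
  expect_length(s_all$included_regions, 24)
  ## homogeneous lungs: average equals any single region's value
  expect_equal(s_all$avg_suv_m, meas$suv_m[1], tolerance = 1e-12)
  expect_equal(s_all$avg_suv_m, mean(meas$suv_m))
  s_up <- lung_summary(meas, suv_b = 1.0, exclude_lower = TRUE)
  expect_length(s_up$included_regions, 16)
  expect_false(any(grepl("lower", s_up$included_regions)))
})

test_that("negative SUV_T is flagged, not clipped", {
  df <- data.frame(region = "R_upper_anterior_medial", side = "R",
                   level = "upper", zone = "anterior", half = "medial",
                   n_voxels = 10, mean_hu = -700, suv_m = 0.05)
  expect_warning(s <- lung_summary(df, suv_b = 1.0), "negative SUV_T")
  expect_lt(s$avg_suv_t, 0)
  expect_true(s$negative_suv_t)
})

test_that("masked mean and max agree exactly with a brute-force voxel loop", {
  for (seed in 1:4) {
    g <- random_grid(seed = seed)
    m <- random_mask(g, seed = seed + 10)
    acc <- c(); d <- dim(g$values)
    for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3])
      if (m$values[i, j, k] == 1) acc <- c(acc, g$values[i, j, k])
    expect_identical(masked_mean(g, m), mean(acc))
    expect_identical(masked_max(g, m), max(acc))
  }
})
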