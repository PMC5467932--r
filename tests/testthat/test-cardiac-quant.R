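make_frames <- function(vals) {
  lapply(vals, function(v) voxel_grid(array(v, c(4, 4, 4))))
}

test_that("ED/ES extraction averages the gating-convention frame pairs", {
  ## constant series: both phases equal the constant
  ph <- extract_ed_es(make_frames(rep(3.5, 8)))
  expect_equal(unique(as.vector(ph$ed$values)), 3.5)
  expect_equal(unique(as.vector(ph$es$values)), 3.5)
  ## frame 1 = 2, frame 8 = 4, rest 0: ED mean 3, ES 0
  ph <- extract_ed_es(make_frames(c(2, 0, 0, 0, 0, 0, 0, 4)))
  expect_equal(unique(as.vector(ph$ed$values)), 3)
  expect_equal(unique(as.vector(ph$es$values)), 0)
  ## raw sum kept for count-space data
  ph <- extract_ed_es(make_frames(c(2, 0, 0, 0, 0, 0, 0, 4)), combine = "sum")
  expect_equal(unique(as.vector(ph$ed$values)), 6)
  expect_error(extract_ed_es(make_frames(rep(1, 7))), "8")
})

test_that("ED/ES is invariant to gate relabeling within {1,8} and {4,5}", {
  set.seed(31)
  frames <- lapply(1:8, function(k)
    voxel_grid(array(rnorm(64, mean = k), c(4, 4, 4))))
  swapped <- frames[c(8, 2, 3, 5, 4, 6, 7, 1)]
  a <- extract_ed_es(frames)
  b <- extract_ed_es(swapped)
  expect_identical(a$ed$values, b$ed$values)
  expect_identical(a$es$values, b$es$values)
})

test_that("cavity volume is voxel count times voxel volume", {
  m <- voxel_grid(array(0, c(10, 10, 10)))
  m$values[1:10, 1:10, 1:10] <- 1
  expect_equal(cavity_volume(m), 1.0)  # 1000 voxels at 1 mm^3
  expect_equal(cavity_volume(voxel_grid(array(0, c(5, 5, 5)))), 0)
  ## analytic ellipsoid
  g <- voxel_grid(array(0, c(41, 41, 41)), origin = c(-20, -20, -20))
  co <- lapply(1:3, function(k) -20:20)
  semi <- c(14, 10, 16)
  q <- outer(outer((co[[1]] / semi[1])^2, (co[[2]] / semi[2])^2, "+"),
             (co[[3]] / semi[3])^2, "+")
  g$values[q <= 1] <- 1
  expect_lt(abs(cavity_volume(g) - 4 / 3 * pi * prod(semi) / 1000),
            0.02 * 4 / 3 * pi * prod(semi) / 1000)
})

test_that("ejection metrics follow the EF and SV definitions", {
  em <- ejection_metrics(200, 120)
  expect_equal(em$ef, 40)
  expect_equal(em$sv, 80)
  expect_equal(ejection_metrics(150, 150)$ef, 0)
  expect_error(ejection_metrics(0, 0), "EDV")
  expect_error(ejection_metrics(100, 120), "ESV")
})

test_that("wall max SUV agrees exactly with a brute-force scan", {
  g <- voxel_grid(array(2, c(5, 5, 5)))
  m <- voxel_grid(array(1, c(5, 5, 5)))
  expect_equal(wall_max_suv(g, m), 2)
  g$values[3, 4, 2] <- 7.3
  expect_equal(wall_max_suv(g, m), 7.3)
  for (seed in 1:4) {
    gg <- random_grid(seed = seed)
    mm <- random_mask(gg, seed = seed + 20)
    best <- -Inf; d <- dim(gg$values)
    for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3])
      if (mm$values[i, j, k] == 1 && gg$values[i, j, k] > best)
        best <- gg$values[i, j, k]
    expect_identical(wall_max_suv(gg, mm), best)
  }
})

test_that("RV/LV ratio is a guarded division", {
  expect_equal(rv_lv_ratio(2, 2), 1)
  expect_equal(rv_lv_ratio(3, 2), 1.5)
  expect_error(rv_lv_ratio(3, 0), "positive")
})

test_that("cavity segmentation recovers the phantom cavity and is deterministic", {
  ph <- heart_only()
  suv <- series_to_suv(ph$series)
  phase <- extract_ed_es(suv)
  seed <- ph$truth$rv_seed_voxel
  m1 <- segment_rv_cavity(phase$ed, seed)
  m2 <- segment_rv_cavity(phase$ed, seed)
  expect_identical(m1$values, m2$values)
  expect_lt(abs(cavity_volume(m1) - ph$truth$true_edv),
            0.02 * ph$truth$true_edv)
  mes <- segment_rv_cavity(phase$es, seed)
  expect_lt(abs(cavity_volume(mes) - ph$truth$true_esv),
            0.02 * ph$truth$true_esv)
})

test_that("segmentation distinguishes a misplaced seed from a non-contourable image", {
  ph <- heart_only()
  phase <- extract_ed_es(series_to_suv(ph$series))
  ## seed on the bright wall: a cavity exists, seed is just not in it
  wall_idx <- which(ph$truth$rois$rv_wall$values == 1, arr.ind = TRUE)
  on_wall <- wall_idx[which.max(abs(wall_idx[, 1])), ] - 1
  expect_error(segment_rv_cavity(phase$ed, on_wall), "seed")
  ## wall uptake equal to cavity uptake: no boundary exists at all
  spec_flat <- phantom_spec(shape = c(76, 60, 76), spacing = c(2, 2, 2),
                            true_rv_edv = 150, true_rv_esv = 97.5,
                            include_lungs = FALSE,
                            uptake = list(lv_wall = 2.0, rv_wall = 1.0,
                                          septum = 2.0, ra_wall = 1.5,
                                          blood = 1.0, lung_tissue = 2.0,
                                          soft = 1.0),
                            seed = 3L)
  flat <- make_thorax(spec_flat)
  fl_phase <- extract_ed_es(series_to_suv(flat$series))
  expect_error(segment_rv_cavity(fl_phase$ed, flat$truth$rv_seed_voxel),
               "non-contourable")
})

test_that("contourability degrades monotonically as wall uptake approaches cavity uptake", {
  flags <- vapply(c(2.8, 1.6, 1.05), function(wall_suv) {
    spec <- phantom_spec(shape = c(76, 60, 76), spacing = c(2, 2, 2),
                         true_rv_edv = 150, true_rv_esv = 97.5,
                         include_lungs = FALSE, noise_sigma = 0.05,
                         uptake = list(lv_wall = 2.0, rv_wall = wall_suv,
                                       septum = 2.0, ra_wall = 1.5,
                                       blood = 1.0, lung_tissue = 2.0,
                                       soft = 0.8),
                         seed = 5L)
    ph <- make_thorax(spec)
    cm <- cardiac_measures(ph$series, ph$truth$rois, ph$truth$rv_seed_voxel)
    cm$contourable
  }, logical(1))
  ## once contourability is lost it does not come back as contrast falls
  expect_true(all(diff(as.integer(flags)) <= 0))
  expect_true(flags[1])    # clear wall/cavity contrast segments fine
  expect_false(flags[3])   # near-isointense wall cannot be contoured
})

test_that("full cardiac quantification recovers phantom truth on a noise-free study", {
  ph <- heart_only()
  cm <- cardiac_measures(ph$series, ph$truth$rois, ph$truth$rv_seed_voxel)
  expect_true(cm$contourable)
  expect_lt(abs(cm$ef - ph$truth$true_ef), 1)
  expect_equal(cm$rv_lv_ratio,
               ph$truth$uptake$rv_wall / ph$truth$uptake$lv_wall,
               tolerance = 1e-9)
  expect_equal(cm$max_suv$ra_wall, ph$truth$uptake$ra_wall, tolerance = 1e-9)
  expect_equal(cm$max_suv$septum, ph$truth$uptake$septum, tolerance = 1e-9)
  expect_equal(cm$sv, cm$edv - cm$esv)
})
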