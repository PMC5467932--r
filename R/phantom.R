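#' Specification of the digital thorax phantom
#'
#' The phantom is a schematic beating thorax with analytic ground truth:
#' two ellipsoidal lungs of configurable air and blood volume fraction, an
#' ellipsoidal-shell left and right ventricle with an interventricular
#' septum, a right atrium, a left-atrial blood pool, and a descending
#' thoracic aorta, embedded in a soft-tissue body. The RV cavity volume
#' follows a prescribed cycle over the eight gated frames, so true
#' end-diastolic volume (EDV), end-systolic volume (ESV) and ejection
#' fraction are known exactly. Geometry is deliberately schematic, not
#' anatomical: what it exercises is the quantitative formulas downstream
#' (compartment mixing, SUV corrections, voxel-counting volumetry), for
#' which an analytic truth is essential.
#'
#' Lung voxels mix three compartments: air (no activity, -1000 HU), blood
#' (blood-pool SUV), and lung tissue (tissue SUV), with
#' `activity = blood_fraction * suv_blood + tissue_fraction * suv_tissue`
#' and `HU = air_fraction * hu_air + (1 - air_fraction) * hu_soft`, where
#' `tissue_fraction = 1 - air_fraction - blood_fraction`. The default blood
#' fraction of 0.16 is the literature estimate of lung blood volume used by
#' the tissue-fraction SUV correction.
#'
#' @param shape integer length-3 grid shape (voxels); the grid is centred
#'   on the physical origin.
#' @param spacing voxel spacing, mm.
#' @param true_rv_edv,true_rv_esv true RV cavity volumes at end diastole and
#'   end systole, mL; `true_rv_esv < true_rv_edv`.
#' @param cycle_curve 8 values in `[0, 1]`: normalized cavity-volume phase,
#'   `V_f = ESV + (EDV - ESV) * cycle_curve[f]`. Must be maximal at frame
#'   1 or 8 (end diastole begins at the R wave) and minimal at frame 4 or 5.
#' @param uptake named list of SUV-scale uptake per compartment:
#'   `lv_wall`, `rv_wall`, `septum`, `ra_wall`, `blood`, `lung_tissue`,
#'   `soft` (background soft tissue).
#' @param air_fraction,blood_fraction lung air and blood volume fractions;
#'   `air_fraction + blood_fraction <= 1`.
#' @param hu_air,hu_soft Hounsfield units of pure air and soft tissue.
#' @param wall_thickness myocardial wall thickness, mm.
#' @param rv_axis_ratio RV cavity semi-axis ratios (y, z) relative to x.
#' @param lv_semi LV cavity semi-axes, mm (the LV does not beat; only RV
#'   function is measured downstream).
#' @param septum_gap gap between LV and RV cavity surfaces along x, mm;
#'   smaller than `2 * wall_thickness` so the two wall shells overlap and
#'   define the septum.
#' @param include_heart,include_lungs switch structures off for focused
#'   experiments (e.g. a symmetric lungs-only phantom).
#' @param noise_sigma additive Gaussian noise SD on each frame's activity,
#'   in SUV units (applied before conversion to kBq/mL).
#' @param injected_dose,body_weight dose (MBq) and weight (kg) written into
#'   the series metadata.
#' @param seed RNG seed making the phantom bit-reproducible.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(96, 80, 80),
                         spacing = c(2, 2, 2),
                         true_rv_edv = 160,
                         true_rv_esv = 104,
                         cycle_curve = c(1, 0.75, 0.3, 0, 0, 0.3, 0.75, 1),
                         uptake = list(lv_wall = 2.0, rv_wall = 2.8,
                                       septum = 2.0, ra_wall = 1.5,
                                       blood = 1.0, lung_tissue = 2.0,
                                       soft = 0.8),
                         air_fraction = 0.7,
                         blood_fraction = 0.16,
                         hu_air = -1000,
                         hu_soft = 0,
                         wall_thickness = 6,
                         rv_axis_ratio = c(0.9, 1.4),
                         lv_semi = c(22, 25, 32),
                         septum_gap = 6,
                         include_heart = TRUE,
                         include_lungs = TRUE,
                         noise_sigma = 0,
                         injected_dose = 370,
                         body_weight = 70,
                         seed = 1L) {
  spec <- list(shape = as.integer(shape), spacing = as.numeric(spacing),
               true_rv_edv = true_rv_edv, true_rv_esv = true_rv_esv,
               cycle_curve = cycle_curve, uptake = uptake,
               air_fraction = air_fraction, blood_fraction = blood_fraction,
               hu_air = hu_air, hu_soft = hu_soft,
               wall_thickness = wall_thickness,
               rv_axis_ratio = as.numeric(rv_axis_ratio),
               lv_semi = as.numeric(lv_semi), septum_gap = septum_gap,
               include_heart = include_heart, include_lungs = include_lungs,
               noise_sigma = noise_sigma, injected_dose = injected_dose,
               body_weight = body_weight, seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  with(spec, {
    if (length(shape) != 3L || any(shape < 8))
      stop("phantom grid shape must be three dims of at least 8 voxels",
           call. = FALSE)
    if (any(spacing <= 0)) stop("spacing must be positive", call. = FALSE)
    if (!(true_rv_esv < true_rv_edv) || true_rv_esv < 0)
      stop("need 0 <= true_rv_esv < true_rv_edv", call. = FALSE)
    if (length(cycle_curve) != 8L || any(cycle_curve < 0 | cycle_curve > 1))
      stop("cycle_curve must be 8 values in [0, 1]", call. = FALSE)
    if (!(which.max(cycle_curve) %in% c(1L, 8L)))
      stop("cycle_curve must peak at frame 1 or 8 (end diastole)", call. = FALSE)
    if (!(which.min(cycle_curve) %in% c(4L, 5L)))
      stop("cycle_curve must be minimal at frame 4 or 5 (end systole)",
           call. = FALSE)
    if (air_fraction < 0 || blood_fraction < 0 ||
        air_fraction + blood_fraction > 1)
      stop("need 0 <= air_fraction + blood_fraction <= 1", call. = FALSE)
    if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  })
  invisible(spec)
}

## logical ellipsoid on voxel-centre coordinates
ellipsoid_arr <- function(coords, center, semi) {
  x2 <- ((coords[[1]] - center[1]) / semi[1])^2
  y2 <- ((coords[[2]] - center[2]) / semi[2])^2
  z2 <- ((coords[[3]] - center[3]) / semi[3])^2
  outer(outer(x2, y2, "+"), z2, "+") <= 1
}

## z-aligned cylinder, optionally restricted in z (mm)
cylinder_arr <- function(coords, center_xy, radius, zlim = NULL) {
  x2 <- (coords[[1]] - center_xy[1])^2
  y2 <- (coords[[2]] - center_xy[2])^2
  disc <- outer(x2, y2, "+") <= radius^2
  zin <- if (is.null(zlim)) rep(TRUE, length(coords[[3]]))
         else coords[[3]] >= zlim[1] & coords[[3]] <= zlim[2]
  outer(disc, zin, "&")
}

## RV cavity semi-axes (mm) realizing volume V (mL) at the spec's ratios
rv_semi_for_volume <- function(spec, volume_ml) {
  r <- spec$rv_axis_ratio
  a <- (volume_ml * 1000 / (4 / 3 * pi * r[1] * r[2]))^(1 / 3)
  c(a, r[1] * a, r[2] * a)
}

phantom_geometry <- function(spec) {
  half <- (spec$shape - 1) * spec$spacing / 2
  rv_semi_ed <- rv_semi_for_volume(spec, spec$true_rv_edv)
  lv_center <- c(-32, 0, 0)
  rv_center <- lv_center +
    c(spec$lv_semi[1] + rv_semi_ed[1] + spec$septum_gap, 0, 0)
  ## RA sits clear of the RV: chambers are separate structures here (no
  ## valve-plane contact), so cavity segmentation cannot bridge them
  ra_semi <- c(12, 12, 10)
  ra_wall <- 4
  ra_center <- rv_center +
    c(0, 0, -(rv_semi_ed[3] + ra_semi[3] + ra_wall + 2))
  la_center <- lv_center + c(0, -(spec$lv_semi[2] + 14), 0)
  geom <- list(
    half = half,
    body_semi = c(0.95 * half[1], 0.92 * half[2]),
    lung_center = list(L = c(-58, 0, 5), R = c(58, 0, 5)),
    lung_semi = c(26, 36, 52),
    lv_center = lv_center, rv_center = rv_center,
    rv_semi_ed = rv_semi_ed,
    ra_center = ra_center, ra_semi = ra_semi, ra_wall = ra_wall,
    la_center = la_center, la_semi = c(14, 12, 14),
    aorta_center = c(-8, -45), aorta_radius = 8
  )
  ## every structure must fit inside the grid
  t <- spec$wall_thickness
  reach <- list(
    c(abs(lv_center) + spec$lv_semi + t),
    if (spec$include_heart) abs(rv_center) + rv_semi_ed + t,
    if (spec$include_heart) abs(geom$ra_center) + geom$ra_semi + geom$ra_wall,
    if (spec$include_heart) abs(geom$la_center) + geom$la_semi,
    if (spec$include_lungs) abs(geom$lung_center$L) + geom$lung_semi,
    if (spec$include_lungs) abs(geom$lung_center$R) + geom$lung_semi
  )
  for (r in reach)
    if (!is.null(r) && any(r > half))
      stop("phantom geometry exceeds the grid extent; enlarge shape/spacing",
           call. = FALSE)
  geom
}

#' Generate the beating digital thorax
#'
#' Builds the eight-frame gated PET activity series (kBq/mL), the matching
#' CT HU volume, and the ground-truth record: true EDV/ESV/EF/SV, the
#' configured compartment SUVs, the true mean lung HU, and exact masks
#' (lungs, LA cavity and descending-aorta blood pool, RV/LV free walls,
#' septum, RA wall, and the RV cavity at ED and ES). Rerunning with the
#' same spec is bit-identical.
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `series` ([gated_pet_series()]), `ct`
#'   ([voxel_grid()], HU), and `truth` (list; `$rois` holds the masks).
#' @export
make_thorax <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  validate_phantom_spec(spec)
  geom <- phantom_geometry(spec)
  origin <- -(spec$shape - 1) * spec$spacing / 2
  proto <- voxel_grid(array(0, spec$shape), spacing = spec$spacing,
                      origin = origin)
  coords <- axis_coords(proto)
  upt <- spec$uptake
  t <- spec$wall_thickness

  body <- outer(outer((coords[[1]] / geom$body_semi[1])^2,
                      (coords[[2]] / geom$body_semi[2])^2, "+") <= 1,
                rep(TRUE, length(coords[[3]])), "&")

  lungL <- lungR <- array(FALSE, spec$shape)
  if (spec$include_lungs) {
    lungL <- ellipsoid_arr(coords, geom$lung_center$L, geom$lung_semi) & body
    lungR <- ellipsoid_arr(coords, geom$lung_center$R, geom$lung_semi) & body
  }

  lv_shell <- lv_cav <- septum <- ra_shell <- ra_cav <- la_blob <-
    aorta <- array(FALSE, spec$shape)
  rv_shell_ed <- rv_cav_ed <- array(FALSE, spec$shape)
  if (spec$include_heart) {
    lv_cav <- ellipsoid_arr(coords, geom$lv_center, spec$lv_semi)
    lv_shell <- ellipsoid_arr(coords, geom$lv_center, spec$lv_semi + t) & !lv_cav
    rv_cav_ed <- ellipsoid_arr(coords, geom$rv_center, geom$rv_semi_ed)
    rv_shell_ed <- ellipsoid_arr(coords, geom$rv_center, geom$rv_semi_ed + t) &
      !rv_cav_ed
    septum <- lv_shell & rv_shell_ed
    ra_cav <- ellipsoid_arr(coords, geom$ra_center, geom$ra_semi)
    ra_shell <- ellipsoid_arr(coords, geom$ra_center,
                              geom$ra_semi + geom$ra_wall) & !ra_cav
    la_blob <- ellipsoid_arr(coords, geom$la_center, geom$la_semi)
    aorta <- cylinder_arr(coords, geom$aorta_center, geom$aorta_radius) & body
  }

  heart_any <- lv_shell | lv_cav | rv_shell_ed | rv_cav_ed | septum |
    ra_shell | ra_cav | la_blob | aorta
  lungL_mask <- lungL & !heart_any
  lungR_mask <- lungR & !heart_any
  lung_mask <- lungL_mask | lungR_mask

  ## CT: air outside body, lung mixture inside lungs, soft tissue elsewhere
  hu_lung <- spec$air_fraction * spec$hu_air +
    (1 - spec$air_fraction) * spec$hu_soft
  ct <- array(spec$hu_air, spec$shape)
  ct[body] <- spec$hu_soft
  ct[lung_mask] <- hu_lung

  ## activity mixing in lung voxels (air contributes nothing)
  tissue_fraction <- 1 - spec$air_fraction - spec$blood_fraction
  suv_lung <- spec$blood_fraction * upt$blood + tissue_fraction * upt$lung_tissue

  ## per-frame RV geometry; identical curve values share one painted frame
  phis <- spec$cycle_curve
  vols <- spec$true_rv_esv + (spec$true_rv_edv - spec$true_rv_esv) * phis
  uniq <- !duplicated(vols)
  painted <- vector("list", 8L)
  for (f in which(uniq)) {
    act <- array(0, spec$shape)
    act[body] <- upt$soft
    act[lung_mask] <- suv_lung
    if (spec$include_heart) {
      semi_f <- rv_semi_for_volume(spec, vols[f])
      rv_cav_f <- ellipsoid_arr(coords, geom$rv_center, semi_f)
      rv_shell_f <- ellipsoid_arr(coords, geom$rv_center, semi_f + t) & !rv_cav_f
      act[lv_shell] <- upt$lv_wall
      act[rv_shell_f] <- upt$rv_wall
      act[septum] <- upt$septum
      act[ra_shell] <- upt$ra_wall
      act[lv_cav | rv_cav_f | ra_cav | la_blob | aorta] <- upt$blood
    }
    painted[[f]] <- act
  }
  for (f in which(!uniq)) painted[[f]] <- painted[[match(vols[f], vols)]]

  ## noise and SUV -> activity conversion (inverse of to_suv)
  set.seed(spec$seed)
  kbq_per_suv <- spec$injected_dose / spec$body_weight
  frames <- vector("list", 8L)
  for (f in 1:8) {
    suv_f <- painted[[f]]
    if (spec$noise_sigma > 0)
      suv_f <- suv_f + array(stats::rnorm(length(suv_f), 0, spec$noise_sigma),
                             spec$shape)
    frames[[f]] <- grid_like(proto, suv_f * kbq_per_suv)
  }
  series <- gated_pet_series(frames, injected_dose = spec$injected_dose,
                             body_weight = spec$body_weight)

  ## ES cavity at the curve minimum (frames 4/5 by construction)
  es_semi <- rv_semi_for_volume(spec, min(vols))
  rv_cav_es <- if (spec$include_heart)
    ellipsoid_arr(coords, geom$rv_center, es_semi) else rv_cav_ed

  as_mask <- function(a) grid_like(proto, array(as.numeric(a), spec$shape))
  ## blood-pool sampling masks: central portion of each cavity only
  la_central <- if (spec$include_heart)
    ellipsoid_arr(coords, geom$la_center, 0.6 * geom$la_semi) else la_blob
  zc <- range(coords[[3]])
  aorta_central <- if (spec$include_heart)
    cylinder_arr(coords, geom$aorta_center, 0.6 * geom$aorta_radius,
                 zlim = mean(zc) + c(-0.3, 0.3) * diff(zc)) & body
    else aorta

  truth <- list(
    true_edv = spec$true_rv_edv,
    true_esv = spec$true_rv_esv,
    true_ef = 100 * (spec$true_rv_edv - spec$true_rv_esv) / spec$true_rv_edv,
    true_sv = spec$true_rv_edv - spec$true_rv_esv,
    uptake = upt,
    lung_mean_hu = hu_lung,
    lung_suv_m = suv_lung,
    air_fraction = spec$air_fraction,
    blood_fraction = spec$blood_fraction,
    rv_seed_voxel = round((geom$rv_center - origin) / spec$spacing),
    seed = spec$seed,
    rois = list(
      lung = as_mask(lung_mask),
      lung_left = as_mask(lungL_mask),
      lung_right = as_mask(lungR_mask),
      la = as_mask(la_central),
      aorta = as_mask(aorta_central),
      lv_wall = as_mask(lv_shell & !septum),
      rv_wall = as_mask(rv_shell_ed & !septum),
      septum = as_mask(septum),
      ra_wall = as_mask(ra_shell),
      rv_cavity_ed = as_mask(rv_cav_ed),
      rv_cavity_es = as_mask(rv_cav_es)
    )
  )
  list(series = series, ct = grid_like(proto, ct), truth = truth)
}

#' Write a phantom study to disk
#'
#' Writes the gated series (`frame_1..8.nii.gz` + `meta.json`), the CT
#' (`ct.nii.gz`), all truth masks (`mask_<name>.nii.gz`) and a truth JSON
#' (`truth.json`, scalar ground truth only).
#'
#' @param phantom result of [make_thorax()].
#' @param dir output directory.
#' @return `dir` invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_gated_series(phantom$series, dir)
  write_volume(phantom$ct, file.path(dir, "ct.nii.gz"))
  for (nm in names(phantom$truth$rois))
    write_volume(phantom$truth$rois[[nm]],
                 file.path(dir, sprintf("mask_%s.nii.gz", nm)))
  scalars <- phantom$truth[setdiff(names(phantom$truth), "rois")]
  jsonlite::write_json(scalars, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a phantom study back from disk
#'
#' Inverse of [write_phantom()]: loads the gated series, CT, truth masks
#' and scalar truth JSON. Missing files are reported explicitly.
#'
#' @param dir directory written by [write_phantom()].
#' @return list with `series`, `ct`, `truth` as in [make_thorax()].
#' @export
read_phantom <- function(dir) {
  if (!dir.exists(dir))
    stop(sprintf("phantom directory not found: %s", dir), call. = FALSE)
  series <- read_gated_series(dir)
  ct <- read_volume(file.path(dir, "ct.nii.gz"))
  truth_path <- file.path(dir, "truth.json")
  if (!file.exists(truth_path))
    stop(sprintf("truth.json missing in %s", dir), call. = FALSE)
  truth <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
  mask_files <- list.files(dir, pattern = "^mask_.*\\.nii\\.gz$")
  rois <- lapply(mask_files, function(f) read_volume(file.path(dir, f)))
  names(rois) <- sub("^mask_(.*)\\.nii\\.gz$", "\\1", mask_files)
  truth$rois <- rois
  list(series = series, ct = ct, truth = truth)
}
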