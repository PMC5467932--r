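#' Partition a lung mask into the 24 standard sampling regions
#'
#' Each lung contributes 12 regions (24 in total): its z extent is divided
#' into three equal-thickness slabs (upper / mid / lower level; z runs
#' inferior to superior), each slab is split at that lung's own
#' mid-coronal plane (the midpoint of its y extent) into anterior and
#' posterior zones, and each zone is split at the lung's own mid-sagittal
#' plane into medial and lateral halves: 2 sides x 3 levels x 2 zones x 2
#' halves = 24 regions. The regions are pairwise disjoint and their union
#' is the input mask.
#'
#' @param lung_mask binary [voxel_grid()] covering both lungs.
#' @param side_split 0-based x voxel index of the sagittal separating
#'   plane; voxels with x index strictly below it are the left lung.
#'   Defaults to the midpoint of the mask's x extent.
#' @return named list of 24 binary [voxel_grid()] masks with keys
#'   `<side>_<level>_<zone>_<half>`, e.g. `"L_upper_anterior_medial"`.
#' @export
partition_lung_regions <- function(lung_mask, side_split = NULL) {
  assert_mask(lung_mask, allow_empty = FALSE)
  v <- lung_mask$values
  idx <- which(v == 1, arr.ind = TRUE)  # 1-based (x, y, z)
  if (is.null(side_split)) {
    side_split <- mean(range(idx[, 1])) - 1  # 0-based plane
  }
  split1 <- side_split + 1  # back to 1-based
  is_left <- idx[, 1] < split1
  if (!any(is_left) || all(is_left))
    stop("lung mask is empty on one side of the sagittal split", call. = FALSE)

  out <- list()
  for (side in c("L", "R")) {
    pts <- idx[if (side == "L") is_left else !is_left, , drop = FALSE]
    zr <- range(pts[, 3])
    ## three equal-thickness z slabs over this lung's own extent
    zb <- seq(zr[1] - 0.5, zr[2] + 0.5, length.out = 4)
    level <- cut(pts[, 3], breaks = zb,
                 labels = c("lower", "mid", "upper"), include.lowest = TRUE)
    ymid <- mean(range(pts[, 2]))
    zone <- ifelse(pts[, 2] <= ymid, "posterior", "anterior")
    ## medial = towards the mediastinum, i.e. towards the sagittal split
    xmid <- mean(range(pts[, 1]))
    half <- if (side == "L") ifelse(pts[, 1] > xmid, "medial", "lateral")
            else ifelse(pts[, 1] <= xmid, "medial", "lateral")
    for (lev in c("upper", "mid", "lower"))
      for (zn in c("anterior", "posterior"))
        for (hf in c("medial", "lateral")) {
          sel <- pts[level == lev & zone == zn & half == hf, , drop = FALSE]
          if (nrow(sel) == 0)
            stop(sprintf("lung partition produced an empty region (%s %s %s %s)",
                         side, lev, zn, hf), call. = FALSE)
          m <- array(0, dim(v))
          m[sel] <- 1
          out[[paste(side, lev, zn, hf, sep = "_")]] <- grid_like(lung_mask, m)
        }
  }
  out
}

#' Per-region mean HU and mean SUV
#'
#' Records, for each lung region, the mean CT Hounsfield units and the mean
#' PET SUV -- the raw per-region quantities the lung SUV corrections are
#' applied to.
#'
#' @param suv SUV [voxel_grid()].
#' @param ct CT HU [voxel_grid()] on the same lattice.
#' @param regions named list of region masks from [partition_lung_regions()].
#' @return data.frame with columns `region`, `side`, `level`, `zone`,
#'   `half`, `n_voxels`, `mean_hu`, `suv_m`.
#' @export
region_measures <- function(suv, ct, regions) {
  stopifnot(length(regions) == 24L)
  assert_same_lattice(suv, ct)
  rows <- lapply(names(regions), function(nm) {
    parts <- strsplit(nm, "_", fixed = TRUE)[[1]]
    mask <- regions[[nm]]
    data.frame(region = nm, side = parts[1], level = parts[2], zone = parts[3],
               half = parts[4],
               n_voxels = mask_count(mask),
               mean_hu = masked_mean(ct, mask),
               suv_m = masked_mean(suv, mask),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Blood-pool SUV reference
#'
#' Pooled mean SUV over the union of the left-atrial cavity and
#' descending-thoracic-aorta masks (each voxel weighted equally, not the
#' mean of the two structure means). Masks should cover only the central
#' portion of each cavity.
#'
#' @param suv SUV [voxel_grid()].
#' @param la_mask,aorta_mask nonempty binary masks on the same lattice.
#' @return scalar blood-pool SUV.
#' @export
blood_pool_suv <- function(suv, la_mask, aorta_mask) {
  assert_same_lattice(suv, la_mask)
  assert_same_lattice(suv, aorta_mask)
  assert_mask(la_mask, allow_empty = FALSE)
  assert_mask(aorta_mask, allow_empty = FALSE)
  sel <- la_mask$values == 1 | aorta_mask$values == 1
  mean(suv$values[sel])
}

#' Air-fraction-corrected lung SUV (SUV_L)
#'
#' Corrects the measured lung SUV for the air volume fraction inferred from
#' CT density, giving the uptake of bulk lung material:
#' `SUV_L = SUV_M / (1 + HU/1000)` (air = -1000 HU contributes no mass).
#'
#' @param suv_m measured SUV (scalar or vector).
#' @param hu mean Hounsfield units of the same region(s); must be > -1000.
#' @return SUV_L, same length as the inputs.
#' @export
suv_air_corrected <- function(suv_m, hu) {
  if (any(hu <= -1000))
    stop("HU <= -1000 is pure air: no bulk material to correct to",
         call. = FALSE)
  suv_m / (1 + hu / 1000)
}

#' Air- and blood-fraction-corrected lung SUV (SUV_T)
#'
#' Removes both the air fraction (from CT density) and a blood
#' compartment of fraction `f` at blood-pool uptake `suv_b`, giving the
#' uptake of lung tissue proper:
#' `SUV_T = (SUV_M - f * SUV_B) / (1 + HU/1000 - f)`.
#' The default `f = 0.16` is the literature estimate of the lung blood
#' volume fraction. Values may legitimately exceed SUV_M; negative values
#' (measured SUV below the expected blood signal) are returned as computed
#' and flagged by [lung_summary()], never clipped.
#'
#' @param suv_m measured SUV (scalar or vector).
#' @param hu mean Hounsfield units; `1 + hu/1000 - f` must be positive.
#' @param suv_b blood-pool SUV from [blood_pool_suv()].
#' @param blood_fraction lung blood volume fraction `f`, in `[0, 1)`.
#' @return SUV_T, same length as the inputs.
#' @export
suv_tissue_corrected <- function(suv_m, hu, suv_b, blood_fraction = 0.16) {
  if (blood_fraction < 0 || blood_fraction >= 1)
    stop("blood_fraction must be in [0, 1)", call. = FALSE)
  denom <- 1 + hu / 1000 - blood_fraction
  if (any(denom <= 0))
    stop("1 + HU/1000 - blood_fraction must be positive: region is all air and blood",
         call. = FALSE)
  (suv_m - blood_fraction * suv_b) / denom
}

#' Subject-level lung SUV summary
#'
#' Applies the air and air+blood corrections to each region's mean HU/SUV
#' (region-level correction, matching how the per-region quantities are
#' recorded) and averages over the included regions: all 24, or the 16
#' non-lower regions when `exclude_lower = TRUE` (lower lobes may be
#' contaminated by scatter from the liver and heart).
#'
#' @param regions data.frame from [region_measures()].
#' @param suv_b blood-pool SUV.
#' @param blood_fraction lung blood volume fraction (default 0.16).
#' @param exclude_lower drop the 8 lower-level regions before averaging.
#' @return an object of class `lung_summary`: per-region table with
#'   `suv_l`/`suv_t` columns plus `avg_suv_m`, `avg_suv_l`, `avg_suv_t`,
#'   `included_regions`, `suv_b`, `blood_fraction` and a
#'   `negative_suv_t` flag.
#' @export
lung_summary <- function(regions, suv_b, blood_fraction = 0.16,
                         exclude_lower = FALSE) {
  stopifnot(is.data.frame(regions),
            all(c("region", "level", "mean_hu", "suv_m") %in% names(regions)))
  keep <- if (exclude_lower) regions$level != "lower" else rep(TRUE, nrow(regions))
  inc <- regions[keep, , drop = FALSE]
  if (nrow(inc) == 0) stop("no regions left to average", call. = FALSE)
  inc$suv_l <- suv_air_corrected(inc$suv_m, inc$mean_hu)
  inc$suv_t <- suv_tissue_corrected(inc$suv_m, inc$mean_hu, suv_b,
                                    blood_fraction)
  neg <- any(inc$suv_t < 0)
  if (neg)
    warning("negative SUV_T in at least one region (measured SUV below the expected blood signal)",
            call. = FALSE)
  structure(
    list(avg_suv_m = mean(inc$suv_m),
         avg_suv_l = mean(inc$suv_l),
         avg_suv_t = mean(inc$suv_t),
         included_regions = inc$region,
         regions = inc,
         suv_b = suv_b,
         blood_fraction = blood_fraction,
         negative_suv_t = neg),
    class = "lung_summary"
  )
}

#' @export
print.lung_summary <- function(x, ...) {
  cat(sprintf(
    "<lung_summary> %d regions; SUV_M %.3f, SUV_L %.3f, SUV_T %.3f (SUV_B %.3f, f %.2f)%s\n",
    length(x$included_regions), x$avg_suv_m, x$avg_suv_l, x$avg_suv_t,
    x$suv_b, x$blood_fraction,
    if (x$negative_suv_t) " [negative SUV_T flagged]" else ""))
  invisible(x)
}
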