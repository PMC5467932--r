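#' Convert activity concentration to standardized uptake value
#'
#' Body-weight SUV: voxel activity divided by injected dose distributed over
#' body mass, `SUV = C[kBq/mL] * weight[kg] / dose[MBq]`. The unit
#' bookkeeping (dose in MBq = 1000 kBq, body mass in kg at water density =
#' 1000 mL) cancels, so a uniform distribution of the whole dose over the
#' body gives SUV 1 everywhere. No decay correction is applied: input
#' activity is expected to be decay-corrected to a single reference time,
#' which is the standard reconstructed-image convention.
#'
#' @param activity [voxel_grid()] of activity concentration, kBq/mL.
#' @param dose injected dose, MBq (> 0).
#' @param weight body weight, kg (> 0).
#' @return a [voxel_grid()] in SUV units on the same lattice.
#' @examples
#' g <- voxel_grid(array(5, c(4, 4, 4)))
#' range(to_suv(g, dose = 370, weight = 74)$values)  # 1 1
#' @export
to_suv <- function(activity, dose, weight) {
  stopifnot(is_voxel_grid(activity))
  if (!is.numeric(dose) || length(dose) != 1L || !is.finite(dose) || dose <= 0)
    stop("dose must be a single positive number (MBq)", call. = FALSE)
  if (!is.numeric(weight) || length(weight) != 1L || !is.finite(weight) || weight <= 0)
    stop("weight must be a single positive number (kg)", call. = FALSE)
  grid_like(activity, activity$values * (weight / dose))
}

#' SUV image of a gated series frame combination
#'
#' Convenience wrapper: converts each frame of a gated series to SUV using
#' its own dose/weight metadata.
#'
#' @param series a [gated_pet_series()].
#' @return list of 8 SUV [voxel_grid()]s.
#' @export
series_to_suv <- function(series) {
  stopifnot(inherits(series, "gated_pet_series"))
  lapply(series$frames, to_suv,
         dose = series$injected_dose, weight = series$body_weight)
}
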