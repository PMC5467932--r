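#' RV systolic pressure by the simplified Bernoulli equation
#'
#' `RVSP = 4 V^2 + RAP`, with `V` the peak tricuspid-regurgitation jet
#' velocity (m/s) and RAP the estimated right-atrial pressure (mmHg).
#'
#' @param tr_peak_velocity peak TR jet velocity, m/s (>= 0).
#' @param rap estimated right-atrial pressure, mmHg (>= 0).
#' @return RVSP, mmHg.
#' @export
rvsp <- function(tr_peak_velocity, rap) {
  if (any(tr_peak_velocity < 0, na.rm = TRUE) || any(rap < 0, na.rm = TRUE))
    stop("TR velocity and RAP must be nonnegative", call. = FALSE)
  4 * tr_peak_velocity^2 + rap
}

#' RV fractional shortening from end-diastolic and end-systolic areas
#'
#' `(RVED area - RVES area) / RVED area * 100` (percent).
#'
#' @param rved_area RV end-diastolic area, cm^2 (> 0).
#' @param rves_area RV end-systolic area, cm^2.
#' @return fractional shortening, percent.
#' @export
fractional_shortening <- function(rved_area, rves_area) {
  if (any(rved_area <= 0, na.rm = TRUE))
    stop("RVED area must be positive", call. = FALSE)
  (rved_area - rves_area) / rved_area * 100
}

#' RV Tei index (index of myocardial performance)
#'
#' Tricuspid-valve closing-to-opening time minus RV ejection time, divided
#' by the RV ejection time: the fraction of the closed-valve interval spent
#' in isovolumic contraction and relaxation. Invariant under a common
#' rescaling of both times (only the ratio matters).
#'
#' @param tv_closure_opening_time TV closing-to-opening time, ms (> 0).
#' @param rv_ejection_time RV ejection time, ms (> 0).
#' @return dimensionless index.
#' @export
tei_index <- function(tv_closure_opening_time, rv_ejection_time) {
  if (any(tv_closure_opening_time <= 0, na.rm = TRUE) ||
      any(rv_ejection_time <= 0, na.rm = TRUE))
    stop("both times must be positive", call. = FALSE)
  (tv_closure_opening_time - rv_ejection_time) / rv_ejection_time
}

#' Echocardiographic estimate of pulmonary vascular resistance
#'
#' `PVR = TRV / TVI(RVOT) * 10 + 0.16` Wood units, with TRV in m/s and the
#' RV-outflow-tract time-velocity integral in cm. Depends on the two
#' velocities only through their ratio.
#'
#' @param trv peak TR jet velocity, m/s (>= 0).
#' @param rvot_tvi RVOT time-velocity integral, cm (> 0).
#' @return PVR estimate, Wood units.
#' @export
pvr_estimate <- function(trv, rvot_tvi) {
  if (any(rvot_tvi <= 0, na.rm = TRUE))
    stop("RVOT TVI must be positive", call. = FALSE)
  if (any(trv < 0, na.rm = TRUE))
    stop("TR velocity must be nonnegative", call. = FALSE)
  trv / rvot_tvi * 10 + 0.16
}

#' Heart-rate recovery after the six-minute walk test
#'
#' Heart rate at the end of the walk minus heart rate one minute after
#' completion, bpm. A negative value (rate still rising) is clinically
#' meaningful and is preserved with a warning, never clamped.
#'
#' @param hr_end heart rate at 6 min, bpm (> 0).
#' @param hr_1min heart rate 1 min after completion, bpm (> 0).
#' @return recovery, bpm.
#' @export
heart_rate_recovery <- function(hr_end, hr_1min) {
  if (any(hr_end <= 0, na.rm = TRUE) || any(hr_1min <= 0, na.rm = TRUE))
    stop("heart rates must be positive", call. = FALSE)
  out <- hr_end - hr_1min
  if (any(out < 0, na.rm = TRUE))
    warning("negative heart-rate recovery in at least one subject",
            call. = FALSE)
  out
}

#' Append derived echocardiographic quantities to a subject table
#'
#' Computes RVSP, fractional shortening, Tei index, the PVR estimate and
#' heart-rate recovery from the raw echo/exercise input columns
#' (`tr_peak_velocity`, `rap`, `rved_area`, `rves_area`,
#' `tv_closure_opening_time`, `rv_ejection_time`, `rvot_tvi`,
#' `hr_end_6mwt`, `hr_1min_recovery`). Missing inputs propagate to `NA`
#' outputs; pass-through measurements (TAPSE, S', RA volume, strain, RV
#' thickness) are untouched.
#'
#' @param subjects data.frame, one row per subject.
#' @return the data.frame with columns `rvsp`, `fractional_shortening`,
#'   `tei_index`, `pvr_est`, `hrr` appended.
#' @export
derive_echo <- function(subjects) {
  stopifnot(is.data.frame(subjects))
  need <- c("tr_peak_velocity", "rap", "rved_area", "rves_area",
            "tv_closure_opening_time", "rv_ejection_time", "rvot_tvi",
            "hr_end_6mwt", "hr_1min_recovery")
  miss <- setdiff(need, names(subjects))
  if (length(miss) > 0)
    stop("missing echo input columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  subjects$rvsp <- rvsp(subjects$tr_peak_velocity, subjects$rap)
  subjects$fractional_shortening <-
    fractional_shortening(subjects$rved_area, subjects$rves_area)
  subjects$tei_index <- tei_index(subjects$tv_closure_opening_time,
                                  subjects$rv_ejection_time)
  subjects$pvr_est <- pvr_estimate(subjects$tr_peak_velocity,
                                   subjects$rvot_tvi)
  subjects$hrr <- suppressWarnings(
    heart_rate_recovery(subjects$hr_end_6mwt, subjects$hr_1min_recovery))
  subjects
}
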