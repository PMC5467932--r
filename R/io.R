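#' Read a single 3D volume from a NIfTI file
#'
#' Accepts `.nii` or `.nii.gz` files holding exactly one 3D volume (PET
#' frame, CT, SUV image or mask). Spacing and origin are taken from the
#' NIfTI header (diagonal affine assumed; this package writes such files).
#'
#' @param path path to the NIfTI file.
#' @return a [voxel_grid()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path))
    stop(sprintf("volume file not found: %s", path), call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop(sprintf("expected a 3D volume, got %dD payload in %s",
                 length(d), path), call. = FALSE)
  aff <- RNifti::xform(img)
  spacing <- abs(diag(aff)[1:3])
  if (any(spacing <= 0) || any(!is.finite(spacing)))
    stop(sprintf("non-positive voxel spacing in header of %s", path),
         call. = FALSE)
  origin <- as.numeric(aff[1:3, 4])
  voxel_grid(array(as.numeric(img), dim = d), spacing = spacing, origin = origin)
}

#' Write a voxel grid to a NIfTI file
#'
#' Values are stored as 64-bit floats so the read/write round trip is exact.
#'
#' @param grid a [voxel_grid()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path` invisibly.
#' @export
write_volume <- function(grid, path) {
  stopifnot(is_voxel_grid(grid))
  img <- RNifti::asNifti(grid$values)
  RNifti::pixdim(img) <- grid$spacing
  aff <- rbind(cbind(diag(grid$spacing), grid$origin), c(0, 0, 0, 1))
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Construct an eight-frame gated PET series
#'
#' Frame 1 begins at the R wave (end diastole); frames advance through the
#' cardiac cycle in eight equal ECG bins. Activity is in kBq/mL and is
#' assumed to be decay-corrected to a single reference time by the scanner.
#'
#' @param frames list of exactly 8 [voxel_grid()] activity volumes (kBq/mL)
#'   sharing one lattice.
#' @param injected_dose injected FDG dose, MBq (> 0).
#' @param body_weight body weight, kg (> 0).
#' @param uptake_time minutes from injection to acquisition (> 0).
#' @return an object of class `gated_pet_series`.
#' @export
gated_pet_series <- function(frames, injected_dose, body_weight,
                             uptake_time = 90) {
  if (!is.list(frames) || length(frames) != 8L)
    stop("a gated series has exactly 8 frames", call. = FALSE)
  lapply(frames, function(f) stopifnot(is_voxel_grid(f)))
  for (k in 2:8) assert_same_lattice(frames[[1]], frames[[k]])
  if (!is.numeric(injected_dose) || injected_dose <= 0)
    stop("injected_dose must be > 0 MBq", call. = FALSE)
  if (!is.numeric(body_weight) || body_weight <= 0)
    stop("body_weight must be > 0 kg", call. = FALSE)
  if (!is.numeric(uptake_time) || uptake_time <= 0)
    stop("uptake_time must be > 0 min", call. = FALSE)
  structure(
    list(frames = frames, injected_dose = injected_dose,
         body_weight = body_weight, uptake_time = uptake_time),
    class = "gated_pet_series"
  )
}

#' @export
print.gated_pet_series <- function(x, ...) {
  d <- dim(x$frames[[1]]$values)
  cat(sprintf(
    "<gated_pet_series> 8 frames of %d x %d x %d voxels; dose %.1f MBq, weight %.1f kg, uptake %.0f min\n",
    d[1], d[2], d[3], x$injected_dose, x$body_weight, x$uptake_time))
  invisible(x)
}

#' Write a gated PET series to disk
#'
#' Writes `frame_1.nii.gz` ... `frame_8.nii.gz` plus a JSON sidecar
#' `meta.json` carrying dose, weight and uptake time.
#'
#' @param series a [gated_pet_series()].
#' @param dir output directory (created if needed).
#' @return `dir` invisibly.
#' @export
write_gated_series <- function(series, dir) {
  stopifnot(inherits(series, "gated_pet_series"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (k in 1:8)
    write_volume(series$frames[[k]], file.path(dir, sprintf("frame_%d.nii.gz", k)))
  meta <- list(injected_dose_MBq = series$injected_dose,
               body_weight_kg = series$body_weight,
               uptake_time_min = series$uptake_time)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a gated PET series from disk
#'
#' Accepts either a directory of `frame_1..frame_8` single-frame NIfTI files
#' with a `meta.json` sidecar, or a single 4D NIfTI file (8 time points)
#' given alongside explicit metadata.
#'
#' @param path directory of per-frame files, or a 4D NIfTI file.
#' @param injected_dose,body_weight,uptake_time metadata overrides; required
#'   when `path` is a 4D file without a sidecar.
#' @return a [gated_pet_series()].
#' @export
read_gated_series <- function(path, injected_dose = NULL, body_weight = NULL,
                              uptake_time = NULL) {
  if (dir.exists(path)) {
    files <- file.path(path, sprintf("frame_%d.nii.gz", 1:8))
    missing_gz <- !file.exists(files)
    files[missing_gz] <- file.path(path, sprintf("frame_%d.nii", (1:8)[missing_gz]))
    if (!all(file.exists(files)))
      stop(sprintf("gated series directory %s lacks frame_1..frame_8", path),
           call. = FALSE)
    frames <- lapply(files, read_volume)
    meta_path <- file.path(path, "meta.json")
    meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
    dose <- injected_dose %||% meta$injected_dose_MBq
    wt <- body_weight %||% meta$body_weight_kg
    ut <- uptake_time %||% meta$uptake_time_min %||% 90
  } else {
    if (!file.exists(path))
      stop(sprintf("gated series not found: %s", path), call. = FALSE)
    img <- RNifti::readNifti(path)
    d <- dim(img)
    if (length(d) != 4L || d[4] != 8L)
      stop("a 4D gated file must hold exactly 8 frames", call. = FALSE)
    aff <- RNifti::xform(img)
    spacing <- abs(diag(aff)[1:3])
    origin <- as.numeric(aff[1:3, 4])
    arr <- array(as.numeric(img), dim = d)
    frames <- lapply(1:8, function(k)
      voxel_grid(arr[, , , k], spacing = spacing, origin = origin))
    dose <- injected_dose; wt <- body_weight; ut <- uptake_time %||% 90
  }
  if (is.null(dose) || is.null(wt))
    stop("injected_dose and body_weight must come from meta.json or arguments",
         call. = FALSE)
  gated_pet_series(frames, as.numeric(dose), as.numeric(wt), as.numeric(ut))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
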