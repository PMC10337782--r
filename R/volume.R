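#' PET volume container
#'
#' A 3D scalar field on a regular grid, carrying the voxel spacing, the
#' physical origin and the kind of value stored: `"SUV"` (dimensionless
#' standardized uptake value) or `"BQML"` (activity concentration, Bq/ml).
#' Segmentation and index computation require SUV values; [to_suv()]
#' converts a BQML volume given its injection metadata.
#'
#' @param values Numeric 3D array of voxel values.
#' @param spacing Numeric length-3 vector, voxel size per axis in mm
#'   (strictly positive).
#' @param origin Numeric length-3 vector, physical offset of the first
#'   voxel in mm. Defaults to `c(0, 0, 0)`.
#' @param value_kind `"SUV"` or `"BQML"`.
#' @param frame_time Minutes post-injection at which the frame was
#'   acquired, or `NA` if unknown.
#' @return An object of class `pet_volume`.
#' @export
pet_volume <- function(values, spacing, origin = c(0, 0, 0),
                       value_kind = c("SUV", "BQML"), frame_time = NA_real_) {
  value_kind <- match.arg(value_kind)
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three strictly positive voxel sizes (mm)", call. = FALSE)
  if (any(!is.finite(values)))
    stop("voxel values must all be finite", call. = FALSE)
  origin <- as.numeric(origin)
  if (length(origin) != 3L) stop("`origin` must have length 3", call. = FALSE)
  structure(
    list(values = values, spacing = spacing, origin = origin,
         value_kind = value_kind, frame_time = frame_time),
    class = "pet_volume"
  )
}

#' @describeIn pet_volume compact printer.
#' @param x,... Passed to the print method.
#' @export
print.pet_volume <- function(x, ...) {
  cat(sprintf("<pet_volume> %s, %s voxels, spacing %s mm\n",
              x$value_kind, paste(dim(x$values), collapse = "x"),
              paste(format(x$spacing), collapse = "x")))
  invisible(x)
}

#' Injection metadata for SUV computation
#'
#' @param injected_activity_mbq Activity at injection time, MBq (> 0).
#' @param body_weight_kg Patient weight, kg (> 0).
#' @param body_height_cm Patient height, cm (optional).
#' @param injection_to_scan_min Minutes from injection to the renal
#'   acquisition (>= 0).
#' @param half_life_min Isotope half-life in minutes; default 67.71
#'   (gallium-68).
#' @return An object of class `injection_meta`.
#' @export
injection_meta <- function(injected_activity_mbq, body_weight_kg,
                           body_height_cm = NA_real_,
                           injection_to_scan_min = 0,
                           half_life_min = 67.71) {
  if (!is.finite(injected_activity_mbq) || injected_activity_mbq <= 0)
    stop("`injected_activity_mbq` must be positive", call. = FALSE)
  if (!is.finite(body_weight_kg) || body_weight_kg <= 0)
    stop("`body_weight_kg` must be positive", call. = FALSE)
  if (!is.finite(injection_to_scan_min) || injection_to_scan_min < 0)
    stop("`injection_to_scan_min` must be >= 0", call. = FALSE)
  structure(
    list(injected_activity_mbq = injected_activity_mbq,
         body_weight_kg = body_weight_kg,
         body_height_cm = body_height_cm,
         injection_to_scan_min = injection_to_scan_min,
         half_life_min = half_life_min),
    class = "injection_meta"
  )
}

#' Volume-of-interest mask
#'
#' A boolean field on the same grid as its PET volume, tagging one
#' anatomical compartment.
#'
#' @param mask Logical 3D array.
#' @param label One of `"LEFT_KIDNEY"`, `"RIGHT_KIDNEY"`, `"AORTA"`,
#'   `"TUMOR"`, or `"OTHER"`.
#' @return An object of class `voi_mask`.
#' @export
voi_mask <- function(mask, label = c("OTHER", "LEFT_KIDNEY", "RIGHT_KIDNEY",
                                     "AORTA", "TUMOR")) {
  label <- match.arg(label)
  if (!is.array(mask) || length(dim(mask)) != 3L)
    stop("`mask` must be a 3D array", call. = FALSE)
  mask <- array(as.logical(mask), dim = dim(mask))
  if (any(is.na(mask))) stop("mask values must be TRUE/FALSE", call. = FALSE)
  structure(list(mask = mask, label = label), class = "voi_mask")
}

# Grids must match exactly: no resampling in this package.
check_same_grid <- function(volume, voi) {
  if (!identical(dim(volume$values), dim(voi$mask)))
    stop("alignment error: mask grid ", paste(dim(voi$mask), collapse = "x"),
         " does not match volume grid ",
         paste(dim(volume$values), collapse = "x"), call. = FALSE)
  invisible(TRUE)
}

#' Radioactive decay correction
#'
#' Decays an activity over an elapsed time: `activity * 2^(-elapsed / half_life)`.
#'
#' @param activity_mbq Activity in MBq.
#' @param elapsed_min Elapsed time in minutes (>= 0).
#' @param half_life_min Half-life in minutes (> 0); default 67.71 for
#'   gallium-68.
#' @return Decayed activity, MBq.
#' @export
decay_correct <- function(activity_mbq, elapsed_min, half_life_min = 67.71) {
  if (!is.finite(half_life_min) || half_life_min <= 0)
    stop("`half_life_min` must be positive", call. = FALSE)
  if (any(elapsed_min < 0)) stop("`elapsed_min` must be >= 0", call. = FALSE)
  activity_mbq * 2^(-elapsed_min / half_life_min)
}

#' Convert activity concentration to body-weight SUV
#'
#' SUV = concentration (Bq/ml) * body weight (g) / injected activity (Bq),
#' the body-weight convention with tissue density 1 g/ml, under which a
#' uniform whole-body distribution has SUV 1 everywhere. The injected
#' activity may be referenced to injection time (`"INJECTION"`, default)
#' or decay-corrected to the start of the acquisition (`"SCAN"`).
#'
#' @param volume A `pet_volume` with `value_kind == "BQML"`.
#' @param meta An [injection_meta()].
#' @param decay_reference `"INJECTION"` or `"SCAN"`.
#' @return A `pet_volume` with `value_kind == "SUV"`; spacing, origin and
#'   frame time are preserved.
#' @export
to_suv <- function(volume, meta, decay_reference = c("INJECTION", "SCAN")) {
  decay_reference <- match.arg(decay_reference)
  stopifnot(inherits(volume, "pet_volume"), inherits(meta, "injection_meta"))
  if (volume$value_kind != "BQML")
    stop("`to_suv()` expects a BQML volume; got ", volume$value_kind, call. = FALSE)
  activity_mbq <- meta$injected_activity_mbq
  if (decay_reference == "SCAN")
    activity_mbq <- decay_correct(activity_mbq, meta$injection_to_scan_min,
                                  meta$half_life_min)
  suv <- volume$values * (meta$body_weight_kg * 1000) / (activity_mbq * 1e6)
  pet_volume(suv, volume$spacing, volume$origin, value_kind = "SUV",
             frame_time = volume$frame_time)
}

#' Voxel volume in ml
#'
#' @param spacing Length-3 voxel size in mm.
#' @return Volume of one voxel in ml (= cm^3).
#' @export
voxel_volume_ml <- function(spacing) prod(spacing) / 1000

#' Physical volume of a mask in ml
#'
#' @param voi A `voi_mask` (or logical array).
#' @param spacing Length-3 voxel size in mm.
#' @return Voxel count times voxel volume, ml.
#' @export
mask_volume_ml <- function(voi, spacing) {
  m <- if (inherits(voi, "voi_mask")) voi$mask else voi
  sum(m) * voxel_volume_ml(spacing)
}

suv_datatype <- "double"

#' Read and write PET volumes and masks (NIfTI)
#'
#' Volumes and masks are stored as NIfTI with spacing and origin in the
#' sform. `read_volume()` requires the caller to state the value kind —
#' NIfTI carries no unit field, so units are never assumed silently.
#'
#' @param path File path (`.nii` or `.nii.gz`).
#' @param expected_kind `"SUV"` or `"BQML"`; recorded on the returned
#'   volume.
#' @param frame_time Minutes post-injection, if known.
#' @return `read_volume()`: a `pet_volume`; `read_mask()`: a `voi_mask`
#'   (voxels > 0.5 are in the mask).
#' @export
read_volume <- function(path, expected_kind = c("SUV", "BQML"),
                        frame_time = NA_real_) {
  expected_kind <- match.arg(expected_kind)
  img <- RNifti::readNifti(path)
  geo <- nifti_geometry(img)
  pet_volume(array(as.numeric(img), dim = dim(img)), geo$spacing, geo$origin,
             value_kind = expected_kind, frame_time = frame_time)
}

#' @rdname read_volume
#' @param volume A `pet_volume` to write.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "pet_volume"))
  write_nifti_grid(volume$values, volume$spacing, volume$origin, path,
                   datatype = suv_datatype)
  invisible(path)
}

#' @rdname read_volume
#' @param label Compartment label recorded on the mask.
#' @export
read_mask <- function(path, label = "OTHER") {
  img <- RNifti::readNifti(path)
  voi_mask(array(as.numeric(img) > 0.5, dim = dim(img)), label = label)
}

#' @rdname read_volume
#' @param voi A `voi_mask` to write.
#' @param spacing,origin Grid geometry recorded in the mask header.
#' @export
write_mask <- function(voi, path, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  stopifnot(inherits(voi, "voi_mask"))
  write_nifti_grid(array(as.integer(voi$mask), dim = dim(voi$mask)),
                   spacing = spacing, origin = origin, path = path,
                   datatype = "uint8")
  invisible(path)
}

# Spacing and origin are carried in the sform (RNifti's qform setter
# orthonormalizes away voxel scaling).
write_nifti_grid <- function(values, spacing, origin, path,
                             datatype = "double") {
  img <- RNifti::asNifti(values, datatype = datatype, internal = FALSE)
  aff <- diag(c(spacing, 1))
  aff[1:3, 4] <- origin
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
}

nifti_geometry <- function(img) {
  x <- RNifti::xform(img)
  code <- attr(x, "code")
  if (!is.null(code) && code > 0) {
    spacing <- sqrt(colSums(x[1:3, 1:3]^2))
    origin <- x[1:3, 4]
  } else {
    spacing <- RNifti::pixdim(img)[1:3]
    origin <- c(0, 0, 0)
  }
  list(spacing = as.numeric(spacing), origin = as.numeric(origin))
}

#' Read and write injection metadata as a JSON sidecar
#'
#' Keys: `injected_activity_mbq`, `body_weight_kg`, `body_height_cm`,
#' `injection_to_scan_min`, `half_life_min`.
#'
#' @param path JSON file path.
#' @return `read_injection_meta()`: an [injection_meta()].
#' @export
read_injection_meta <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  injection_meta(
    injected_activity_mbq = x$injected_activity_mbq,
    body_weight_kg = x$body_weight_kg,
    body_height_cm = if (is.null(x$body_height_cm)) NA_real_ else x$body_height_cm,
    injection_to_scan_min = if (is.null(x$injection_to_scan_min)) 0 else x$injection_to_scan_min,
    half_life_min = if (is.null(x$half_life_min)) 67.71 else x$half_life_min
  )
}

#' @rdname read_injection_meta
#' @param meta An [injection_meta()] to write.
#' @export
write_injection_meta <- function(meta, path) {
  stopifnot(inherits(meta, "injection_meta"))
  jsonlite::write_json(unclass(meta), path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
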