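#' Total kidney accumulation (TKA)
#'
#' TKA = SUVmean of the segmented parenchyma times the tracer-avid
#' parenchymal volume (ml.SUV). Zero when the segmentation is empty.
#'
#' @param suv_mean Parenchymal SUVmean (>= 0; may be `NA` for an empty
#'   segmentation, in which case the volume must be 0).
#' @param parenchymal_volume_ml Parenchymal volume, ml (>= 0).
#' @return TKA in ml.SUV.
#' @export
compute_tka <- function(suv_mean, parenchymal_volume_ml) {
  if (parenchymal_volume_ml < 0) stop("volume must be >= 0", call. = FALSE)
  if (parenchymal_volume_ml == 0) return(0)
  if (is.na(suv_mean) || suv_mean < 0)
    stop("`suv_mean` must be >= 0 when volume > 0", call. = FALSE)
  suv_mean * parenchymal_volume_ml
}

#' Blood-pool-corrected total kidney accumulation
#'
#' bpcTKA = (parenchymal SUVmean - blood-pool SUVmean) * parenchymal
#' volume. Negative when the blood pool exceeds the parenchymal uptake;
#' that case is flagged via a warning attribute.
#'
#' @inheritParams compute_tka
#' @param blood_suv_mean Blood-pool SUVmean (>= 0).
#' @return bpcTKA in ml.SUV, with attribute `negative_uptake = TRUE` when
#'   blood pool exceeds parenchymal SUVmean.
#' @export
compute_bpc_tka <- function(suv_mean, blood_suv_mean, parenchymal_volume_ml) {
  if (blood_suv_mean < 0) stop("blood SUVmean must be >= 0", call. = FALSE)
  if (parenchymal_volume_ml == 0) return(0)
  out <- (suv_mean - blood_suv_mean) * parenchymal_volume_ml
  if (suv_mean < blood_suv_mean) {
    warning("blood-pool SUVmean exceeds parenchymal SUVmean; bpcTKA is negative")
    attr(out, "negative_uptake") <- TRUE
  }
  out
}

#' Accumulation index (ACI)
#'
#' ACI = tracer-avid parenchymal volume / parenchymal SUVmean (ml).
#' An empty segmentation (volume 0) yields ACI 0 with attribute
#' `empty = TRUE`: a kidney with no avid parenchyma contributes nothing
#' to function, and a finite value keeps split-function arithmetic
#' defined for a non-functional kidney.
#'
#' @param parenchymal_volume_ml Parenchymal volume, ml (>= 0).
#' @param suv_mean Parenchymal SUVmean (> 0 whenever volume > 0).
#' @return ACI in ml.
#' @export
compute_aci <- function(parenchymal_volume_ml, suv_mean) {
  if (parenchymal_volume_ml < 0) stop("volume must be >= 0", call. = FALSE)
  if (parenchymal_volume_ml == 0)
    return(structure(0, empty = TRUE))
  if (is.na(suv_mean) || suv_mean <= 0)
    stop("internal-consistency error: positive volume with non-positive SUVmean",
         call. = FALSE)
  parenchymal_volume_ml / suv_mean
}

#' Split renal function
#'
#' Percentage contribution of the left kidney: 100 * left / (left +
#' right), computed on any non-negative per-kidney quantity (ACI is the
#' primary estimator; SUVmean, TKA and parenchymal volume are the
#' comparison estimators).
#'
#' @param left_value,right_value Non-negative per-kidney values, not both
#'   zero.
#' @return A list with `split_left_pct` (`NA` with `undefined = TRUE`
#'   when both inputs are zero) and `undefined`.
#' @export
split_renal_function <- function(left_value, right_value) {
  if (left_value < 0 || right_value < 0)
    stop("per-kidney values must be >= 0", call. = FALSE)
  if (left_value + right_value == 0)
    return(list(split_left_pct = NA_real_, undefined = TRUE))
  list(split_left_pct = 100 * left_value / (left_value + right_value),
       undefined = FALSE)
}

#' Metabolic tumor volume (MTV)
#'
#' MTV = tumor SUVmean * segmented tumor volume (ml.SUV).
#'
#' @param suv_mean_tumor Tumor SUVmean (>= 0; ignored when the volume is 0).
#' @param tumor_volume_ml Segmented tumor volume, ml (>= 0).
#' @return MTV in ml.SUV.
#' @export
compute_mtv <- function(suv_mean_tumor, tumor_volume_ml) {
  if (tumor_volume_ml < 0) stop("tumor volume must be >= 0", call. = FALSE)
  if (tumor_volume_ml == 0) return(0)
  if (is.na(suv_mean_tumor) || suv_mean_tumor < 0)
    stop("tumor SUVmean must be >= 0", call. = FALSE)
  suv_mean_tumor * tumor_volume_ml
}

#' Percent injected dose of the tumor burden
#'
#' %ID = 100 * MTV / (body weight * SUV 1). With body-weight SUV and a
#' tissue density of 1 g/ml, the whole-body tracer content at uniform
#' SUV 1 corresponds to the body weight in grams, so
#' %ID = 100 * MTV\[ml.SUV\] / (1000 * weight\[kg\]).
#'
#' @param mtv Metabolic tumor volume, ml.SUV (>= 0).
#' @param body_weight_kg Body weight, kg (> 0).
#' @return Percent of the injected dose sequestered by tumor.
#' @export
compute_pct_id <- function(mtv, body_weight_kg) {
  if (!is.finite(body_weight_kg) || body_weight_kg <= 0)
    stop("`body_weight_kg` must be positive", call. = FALSE)
  if (mtv < 0) stop("`mtv` must be >= 0", call. = FALSE)
  100 * mtv / (1000 * body_weight_kg)
}
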