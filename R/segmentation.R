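#' Dual-threshold isocontour parameters
#'
#' The renal parenchyma is defined as the SUV band between a lower
#' threshold (excluding background and non-avid tissue; default 5) and
#' an upper threshold (excluding radioactive urine in the
#' pelvicocaliceal system; default 15). Both bounds are inclusive.
#'
#' @param lower_suv Lower SUV threshold (> 0; default 5).
#' @param upper_suv Upper SUV threshold (> lower; default 15).
#' @param connectivity Neighborhood used when `keep =
#'   "LARGEST_COMPONENT"`: 6, 18 or 26 (default 26).
#' @param keep `"ALL_VOXELS"` (pure thresholding, default — matching a
#'   freehand-VOI isocontour workflow) or `"LARGEST_COMPONENT"`.
#' @return An object of class `isocontour_params`.
#' @export
isocontour_params <- function(lower_suv = 5, upper_suv = 15,
                              connectivity = 26,
                              keep = c("ALL_VOXELS", "LARGEST_COMPONENT")) {
  keep <- match.arg(keep)
  if (!is.finite(lower_suv) || !is.finite(upper_suv) ||
      lower_suv <= 0 || upper_suv <= 0)
    stop("thresholds must be positive", call. = FALSE)
  if (lower_suv >= upper_suv)
    stop("`lower_suv` must be strictly below `upper_suv`", call. = FALSE)
  if (!connectivity %in% c(6, 18, 26))
    stop("`connectivity` must be 6, 18 or 26", call. = FALSE)
  structure(list(lower_suv = lower_suv, upper_suv = upper_suv,
                 connectivity = as.integer(connectivity), keep = keep),
            class = "isocontour_params")
}

require_suv <- function(volume) {
  if (!inherits(volume, "pet_volume") || volume$value_kind != "SUV")
    stop("unit error: segmentation requires an SUV volume", call. = FALSE)
  invisible(TRUE)
}

#' Segment the tracer-avid renal parenchyma
#'
#' Selects, inside the supplied per-kidney VOI, every voxel whose SUV
#' lies in the inclusive band \[lower, upper\]. Voxels above the upper
#' threshold (urine) are excluded from both the volume and the SUVmean.
#' An empty selection is flagged and its SUVmean reported as `NA`, never
#' as zero.
#'
#' @param volume A `pet_volume` in SUV units.
#' @param kidney_voi A non-empty `voi_mask` on the same grid.
#' @param params An [isocontour_params()].
#' @return An object of class `kidney_measurement`: `side`, `suv_mean`,
#'   `parenchymal_volume_ml`, `voxel_count`, `mask` (a `voi_mask`), and
#'   `flags` (character vector; may contain `"EMPTY_SEGMENTATION"`).
#' @export
segment_parenchyma <- function(volume, kidney_voi, params = isocontour_params()) {
  require_suv(volume)
  stopifnot(inherits(kidney_voi, "voi_mask"),
            inherits(params, "isocontour_params"))
  check_same_grid(volume, kidney_voi)
  if (!any(kidney_voi$mask)) stop("kidney VOI is empty", call. = FALSE)

  sel <- kidney_voi$mask &
    volume$values >= params$lower_suv & volume$values <= params$upper_suv
  if (params$keep == "LARGEST_COMPONENT" && any(sel))
    sel <- largest_component(sel, params$connectivity)

  n <- sum(sel)
  flags <- character(0)
  if (n == 0) flags <- "EMPTY_SEGMENTATION"
  side <- switch(kidney_voi$label, LEFT_KIDNEY = "LEFT",
                 RIGHT_KIDNEY = "RIGHT", NA_character_)
  structure(
    list(side = side,
         suv_mean = if (n > 0) mean(volume$values[sel]) else NA_real_,
         parenchymal_volume_ml = n * voxel_volume_ml(volume$spacing),
         voxel_count = n,
         mask = voi_mask(sel, kidney_voi$label),
         flags = flags,
         params = params),
    class = "kidney_measurement"
  )
}

#' Measure the aortic blood pool
#'
#' SUVmean over a cylindric VOI placed in the descending aorta. The
#' acquisition protocol requires a VOI of at least 5 ml; a smaller VOI
#' raises a protocol-violation error unless `allow_small` is set (then
#' it is flagged).
#'
#' @param volume A `pet_volume` in SUV units.
#' @param aorta_mask A non-empty `voi_mask` on the same grid.
#' @param min_volume_ml Minimum admissible VOI volume, ml (default 5).
#' @param allow_small Override the minimum-volume check.
#' @return An object of class `blood_pool_measurement`: `suv_mean`,
#'   `volume_ml`, `mask`, `flags`.
#' @export
measure_blood_pool <- function(volume, aorta_mask, min_volume_ml = 5,
                               allow_small = FALSE) {
  require_suv(volume)
  stopifnot(inherits(aorta_mask, "voi_mask"))
  check_same_grid(volume, aorta_mask)
  if (!any(aorta_mask$mask)) stop("aorta VOI is empty", call. = FALSE)
  vol_ml <- mask_volume_ml(aorta_mask, volume$spacing)
  flags <- character(0)
  if (vol_ml < min_volume_ml) {
    if (!allow_small)
      stop(sprintf(
        "protocol violation: blood-pool VOI is %.2f ml (< %.1f ml required)",
        vol_ml, min_volume_ml), call. = FALSE)
    flags <- "SUB_MINIMAL_VOI"
  }
  structure(
    list(suv_mean = mean(volume$values[aorta_mask$mask]),
         volume_ml = vol_ml, mask = aorta_mask, flags = flags),
    class = "blood_pool_measurement"
  )
}

#' Segment a tumor by background-referenced isocontour
#'
#' Selects, inside the tumor VOI, every voxel strictly above the SUVmax
#' of adjacent healthy tissue (measured by the caller from an
#' adjacent-tissue VOI). Disjoint lesions inside one VOI are all
#' retained. An empty selection yields volume 0 and SUVmean `NA` with
#' the `EMPTY_SEGMENTATION` flag.
#'
#' @param volume A `pet_volume` in SUV units.
#' @param tumor_voi A non-empty `voi_mask`.
#' @param background_suvmax SUVmax of adjacent healthy tissue (> 0).
#' @return A list: `mask` (a `voi_mask`), `suv_mean`, `volume_ml`,
#'   `voxel_count`, `flags`.
#' @export
segment_tumor <- function(volume, tumor_voi, background_suvmax) {
  require_suv(volume)
  stopifnot(inherits(tumor_voi, "voi_mask"))
  check_same_grid(volume, tumor_voi)
  if (!is.finite(background_suvmax) || background_suvmax <= 0)
    stop("`background_suvmax` must be positive", call. = FALSE)
  sel <- tumor_voi$mask & volume$values > background_suvmax
  n <- sum(sel)
  list(mask = voi_mask(sel, "TUMOR"),
       suv_mean = if (n > 0) mean(volume$values[sel]) else NA_real_,
       volume_ml = n * voxel_volume_ml(volume$spacing),
       voxel_count = n,
       flags = if (n == 0) "EMPTY_SEGMENTATION" else character(0))
}

# 3D connected-component labelling (flood fill) under 6/18/26
# connectivity; returns the largest component of a logical mask.
largest_component <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nd <- rowSums(abs(offs))
  offs <- switch(as.character(connectivity),
                 "6"  = offs[nd == 1, , drop = FALSE],
                 "18" = offs[nd >= 1 & nd <= 2, , drop = FALSE],
                 "26" = offs[nd >= 1, , drop = FALSE])
  labels <- array(0L, dim = d)
  current <- 0L
  idx <- which(mask & labels == 0L)
  sizes <- integer(0)
  while (length(idx) > 0) {
    current <- current + 1L
    seed <- idx[1]
    queue <- seed
    labels[seed] <- current
    size <- 1L
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      ijk <- arrayInd(v, d)
      nb <- sweep(offs, 2, as.integer(ijk), `+`)
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
        nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- nb[, 1] + (nb[, 2] - 1L) * d[1] + (nb[, 3] - 1L) * d[1] * d[2]
      lin <- lin[mask[lin] & labels[lin] == 0L]
      if (length(lin) > 0) {
        labels[lin] <- current
        queue <- c(queue, lin)
        size <- size + length(lin)
      }
    }
    sizes[current] <- size
    idx <- which(mask & labels == 0L)
  }
  labels == which.max(sizes)
}
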