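#' Per-patient renal-function workup from a static PET volume
#'
#' Runs the full single-patient chain: dual-threshold parenchyma
#' segmentation of each kidney inside its VOI, aortic blood-pool
#' measurement, ACI / TKA / bpcTKA per kidney, split renal function by
#' all four estimators (ACI, SUVmean, TKA, parenchymal volume), and —
#' when tumor VOIs and a background SUVmax are supplied — MTV and %ID.
#' Deterministic for fixed inputs.
#'
#' @param volume A `pet_volume` in SUV units.
#' @param vois Named list of `voi_mask` objects; recognized names:
#'   `left`, `right`, `aorta`, and any number of `tumor*` entries.
#' @param params [isocontour_params()] for the parenchyma.
#' @param min_blood_volume_ml Minimum aortic VOI volume (default 5 ml).
#' @param background_suvmax Adjacent-tissue SUVmax for tumor
#'   segmentation, or `NULL` to skip the tumor arm.
#' @param meta Optional [injection_meta()]; needed for %ID.
#' @return A list of class `patient_report`: `kidneys` (per-side
#'   measurements), `blood_pool`, `indices` (per-kidney aci/tka/bpc_tka
#'   and `aci_total`), `split` (per-estimator left-kidney %, with
#'   `undefined` flags), `tumor` (`mtv`, `pct_id`, per-lesion detail) or
#'   `NULL`, and `log` (thresholds and voxel counts of every step).
#' @export
run_patient <- function(volume, vois, params = isocontour_params(),
                        min_blood_volume_ml = 5, background_suvmax = NULL,
                        meta = NULL) {
  require_suv(volume)
  log <- list(lower_suv = params$lower_suv, upper_suv = params$upper_suv)

  kidneys <- list()
  for (side in c("left", "right")) {
    if (is.null(vois[[side]])) next
    kidneys[[side]] <- segment_parenchyma(volume, vois[[side]], params)
    log[[paste0(side, "_voxel_count")]] <- kidneys[[side]]$voxel_count
  }
  if (length(kidneys) == 0)
    stop("at least one kidney VOI is required", call. = FALSE)

  blood <- NULL
  if (!is.null(vois$aorta)) {
    blood <- measure_blood_pool(volume, vois$aorta, min_blood_volume_ml)
    log$blood_pool_voxels <- sum(blood$mask$mask)
    log$blood_pool_suv_mean <- blood$suv_mean
  }

  per_kidney <- lapply(kidneys, function(k) {
    vol <- k$parenchymal_volume_ml
    aci <- compute_aci(vol, k$suv_mean)
    tka <- compute_tka(k$suv_mean, vol)
    bpc <- if (!is.null(blood) && vol > 0)
      suppressWarnings(compute_bpc_tka(k$suv_mean, blood$suv_mean, vol))
    else if (vol == 0) 0 else NA_real_
    list(suv_mean = k$suv_mean, parenchymal_volume_ml = vol,
         aci = as.numeric(aci), tka = tka, bpc_tka = as.numeric(bpc),
         flags = k$flags)
  })
  aci_total <- sum(vapply(per_kidney, `[[`, numeric(1), "aci"))

  # estimator value of a missing/empty kidney is 0 (it contributes no
  # function); SUVmean NA from an empty segmentation likewise enters as 0
  est_value <- function(k, what) {
    if (is.null(k)) return(0)
    v <- switch(what, ACI = k$aci, SUVMEAN = k$suv_mean, TKA = k$tka,
                VOLUME = k$parenchymal_volume_ml)
    if (is.na(v)) 0 else v
  }
  split <- lapply(c(ACI = "ACI", SUVMEAN = "SUVMEAN", TKA = "TKA",
                    VOLUME = "VOLUME"), function(w) {
    split_renal_function(est_value(per_kidney$left, w),
                         est_value(per_kidney$right, w))
  })

  tumor <- NULL
  tumor_names <- grep("^tumor", names(vois), value = TRUE)
  if (length(tumor_names) > 0 && !is.null(background_suvmax)) {
    lesions <- lapply(vois[tumor_names], function(v)
      segment_tumor(volume, v, background_suvmax))
    mtv <- sum(vapply(lesions, function(l)
      compute_mtv(if (is.na(l$suv_mean)) 0 else l$suv_mean, l$volume_ml),
      numeric(1)))
    pct_id <- if (!is.null(meta)) compute_pct_id(mtv, meta$body_weight_kg)
              else NA_real_
    tumor <- list(mtv = mtv, pct_id = pct_id,
                  lesions = lapply(lesions, function(l)
                    l[c("suv_mean", "volume_ml", "voxel_count", "flags")]))
    log$background_suvmax <- background_suvmax
  }

  structure(
    list(kidneys = kidneys, blood_pool = blood, indices = per_kidney,
         aci_total = aci_total, split = split, tumor = tumor, log = log),
    class = "patient_report"
  )
}

#' Serialize a patient report
#'
#' Writes the scalar results (indices, splits, blood pool, tumor burden,
#' log) as JSON, omitting the voxel masks.
#'
#' @param report A `patient_report`.
#' @param path Output JSON path.
#' @export
write_patient_report <- function(report, path) {
  x <- list(
    indices = report$indices,
    aci_total = report$aci_total,
    split = report$split,
    blood_pool = if (!is.null(report$blood_pool))
      report$blood_pool[c("suv_mean", "volume_ml", "flags")],
    tumor = report$tumor,
    log = report$log
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(path)
}

#' Cohort-level comparison against the reference standard
#'
#' Takes a per-patient table carrying the four estimator-based splits
#' (`split_aci`, `split_suv`, `split_tka`, `split_vol`; computed from
#' per-kidney columns if absent) and, where available, reference columns
#' `split_ref` (scintigraphic split, %), `ter_ref` and `gfr_ref`
#' (absolute function). Emits the full estimator-by-reference Pearson
#' cross-table with strength labels, a Bland-Altman agreement analysis
#' of the chosen estimator against `split_ref`, and cohort summaries
#' when demographic columns are present. Analyses whose reference
#' columns are missing are skipped with a warning.
#'
#' @param cohort Data frame; see Details above. The output of
#'   [simulate_cohort()] works directly with `split_ref = "split_true"`
#'   etc. via the `ref_cols` mapping.
#' @param estimator Estimator for the agreement analysis: `"ACI"`
#'   (default), `"SUVMEAN"`, `"TKA"` or `"VOLUME"`.
#' @param threshold Clinically relevant split-function deviation,
#'   percentage points (default 10).
#' @param ref_cols Named character vector mapping `split_ref`, `ter_ref`,
#'   `gfr_ref` to columns of `cohort`.
#' @return A list of class `cohort_report`: `correlations` (data frame:
#'   estimator, reference, r, p_value, n, strength), `agreement`
#'   (an `agreement_result` or `NULL`), `summaries` (when age/sex/gfr
#'   columns exist), `estimator`.
#' @export
run_cohort <- function(cohort, estimator = c("ACI", "SUVMEAN", "TKA", "VOLUME"),
                       threshold = 10,
                       ref_cols = c(split_ref = "split_ref",
                                    ter_ref = "ter_ref",
                                    gfr_ref = "gfr_ref")) {
  estimator <- match.arg(estimator)
  est_col <- c(ACI = "split_aci", SUVMEAN = "split_suv", TKA = "split_tka",
               VOLUME = "split_vol")

  # derive estimator splits from per-kidney columns if not supplied
  pairs <- list(split_aci = c("aci_left", "aci_right"),
                split_suv = c("suv_left", "suv_right"),
                split_tka = c("tka_left", "tka_right"),
                split_vol = c("vol_left", "vol_right"))
  for (nm in names(pairs)) {
    if (!nm %in% names(cohort) && all(pairs[[nm]] %in% names(cohort))) {
      l <- cohort[[pairs[[nm]][1]]]; r <- cohort[[pairs[[nm]][2]]]
      cohort[[nm]] <- 100 * l / (l + r)
    }
  }

  ref_present <- vapply(ref_cols, function(cn) cn %in% names(cohort), logical(1))
  rows <- list()
  add_cor <- function(est_name, ref_name, x, y) {
    cr <- pearson_cor(x, y)
    rows[[length(rows) + 1]] <<- data.frame(
      estimator = est_name, reference = ref_name, r = cr$r,
      p_value = cr$p_value, n = cr$n, strength = cr$strength,
      stringsAsFactors = FALSE)
  }

  if (ref_present["split_ref"]) {
    ref <- cohort[[ref_cols[["split_ref"]]]]
    for (e in names(est_col))
      if (est_col[[e]] %in% names(cohort))
        add_cor(e, "split_function", cohort[[est_col[[e]]]], ref)
  } else warning("reference column '", ref_cols[["split_ref"]],
                 "' missing; split-function correlations skipped")

  totals <- list(ACI = c("aci_left", "aci_right"),
                 TKA = c("tka_left", "tka_right"),
                 VOLUME = c("vol_left", "vol_right"))
  for (ref_name in c("ter_ref", "gfr_ref")) {
    if (!ref_present[ref_name]) {
      warning("reference column '", ref_cols[[ref_name]],
              "' missing; its correlations are skipped")
      next
    }
    ref <- cohort[[ref_cols[[ref_name]]]]
    lab <- sub("_ref$", "", ref_name)
    for (e in names(totals))
      if (all(totals[[e]] %in% names(cohort)))
        add_cor(e, lab, cohort[[totals[[e]][1]]] + cohort[[totals[[e]][2]]], ref)
    if (all(c("suv_left", "suv_right") %in% names(cohort)))
      add_cor("SUVMEAN", lab,
              (cohort$suv_left + cohort$suv_right) / 2, ref)
  }

  agreement <- NULL
  if (ref_present["split_ref"] && est_col[[estimator]] %in% names(cohort))
    agreement <- bland_altman(cohort[[est_col[[estimator]]]],
                              cohort[[ref_cols[["split_ref"]]]],
                              threshold = threshold)

  summaries <- if (all(c("age", "sex", "gfr") %in% names(cohort)))
    summarize_cohort(cohort) else NULL

  structure(
    list(correlations = if (length(rows)) do.call(rbind, rows) else
           data.frame(),
         agreement = agreement, summaries = summaries, estimator = estimator),
    class = "cohort_report"
  )
}
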