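#' CKD-EPI 2009 estimated glomerular filtration rate
#'
#' The 2009 CKD-EPI creatinine equation:
#' eGFR = 141 * min(Scr/k, 1)^a * max(Scr/k, 1)^-1.209 * 0.993^age
#'        * 1.018 (if female) \[* 1.159 if the historical race term is
#'        requested\],
#' with k = 0.7 (female) / 0.9 (male) and a = -0.329 (female) / -0.411
#' (male). The race-free form is the default, matching current clinical
#' practice; `race_black = TRUE` restores the original 2009 coefficient
#' for strict historical replication.
#'
#' @param serum_creatinine Serum creatinine, mg/dl (> 0). Vectorized.
#' @param age Age in years (> 0).
#' @param sex `"M"` or `"F"`.
#' @param race_black Apply the 1.159 race coefficient (default `FALSE`).
#' @return eGFR in ml/min/1.73 m2.
#' @export
ckd_epi_gfr <- function(serum_creatinine, age, sex = c("M", "F"),
                        race_black = FALSE) {
  sex <- match.arg(sex)
  if (any(!is.finite(serum_creatinine)) || any(serum_creatinine <= 0))
    stop("serum creatinine must be positive", call. = FALSE)
  if (any(age <= 0)) stop("age must be positive", call. = FALSE)
  kappa <- if (sex == "F") 0.7 else 0.9
  alpha <- if (sex == "F") -0.329 else -0.411
  r <- serum_creatinine / kappa
  gfr <- 141 * pmin(r, 1)^alpha * pmax(r, 1)^-1.209 * 0.993^age
  if (sex == "F") gfr <- gfr * 1.018
  if (race_black) gfr <- gfr * 1.159
  gfr
}

#' CKD G-stage from GFR
#'
#' GFR bands: G1 >= 90, G2 60-89, G3a 45-59, G3b 30-44, G4 15-29,
#' G5 < 15. Band boundaries (90, 60, 45, 30, 15) belong to the
#' higher-function stage.
#'
#' @param gfr GFR in ml/min/1.73 m2 (>= 0). Vectorized.
#' @return Factor with levels G1, G2, G3a, G3b, G4, G5.
#' @export
ckd_stage <- function(gfr) {
  if (any(!is.finite(gfr)) || any(gfr < 0))
    stop("GFR must be >= 0", call. = FALSE)
  stage <- cut(gfr, breaks = c(-Inf, 15, 30, 45, 60, 90, Inf),
               labels = c("G5", "G4", "G3b", "G3a", "G2", "G1"),
               right = FALSE)
  factor(stage, levels = c("G1", "G2", "G3a", "G3b", "G4", "G5"))
}

#' Side-separated tubular extraction rate
#'
#' Splits a total TER between the kidneys by multiplying with the split
#' renal function; the two sides sum to the total exactly.
#'
#' @param ter_total Total TER, ml/min/1.73 m2 (>= 0).
#' @param split_left_pct Left-kidney split function, percent in \[0, 100\].
#' @return A list with `left` and `right` TER, ml/min/1.73 m2.
#' @export
side_separated_ter <- function(ter_total, split_left_pct) {
  if (ter_total < 0) stop("`ter_total` must be >= 0", call. = FALSE)
  if (split_left_pct < 0 || split_left_pct > 100)
    stop("`split_left_pct` must be in [0, 100]", call. = FALSE)
  left <- ter_total * split_left_pct / 100
  list(left = left, right = ter_total - left)
}

#' Load the packaged 25-patient cohort table
#'
#' The study cohort: 25 consecutive patients with metastatic,
#' predominantly neuroendocrine tumors evaluated for peptide receptor
#' radionuclide therapy. Columns: `id`, `sex` ("M"/"F"), `age` (years),
#' `gfr` (CKD-EPI, ml/min/1.73 m2), `mtv` (ml.SUV) and `pct_id`
#' (% injected dose).
#'
#' @return A 25-row data frame.
#' @export
load_table1_fixture <- function() {
  path <- system.file("extdata", "table1_cohort.csv", package = "renalpet",
                      mustWork = TRUE)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("id", "sex", "age", "gfr", "mtv", "pct_id")
  if (!identical(names(x), required))
    stop("fixture columns must be: ", paste(required, collapse = ", "),
         call. = FALSE)
  stopifnot(all(x$sex %in% c("M", "F")), all(x$age > 0), all(x$gfr >= 0),
            all(x$pct_id >= 0), all(x$mtv >= 0))
  x
}

#' Summarize a cohort table
#'
#' Recomputes the cohort characteristics reported for the study
#' population: n, sex counts, mean/SD age, mean/SD GFR (sample SD,
#' n - 1), CKD stage counts, and the tumor-burden summaries (mean/SD
#' MTV, mean/SD/range %ID).
#'
#' @param cohort A data frame as returned by [load_table1_fixture()].
#' @return A named list of summary statistics.
#' @export
summarize_cohort <- function(cohort) {
  st <- ckd_stage(cohort$gfr)
  list(
    n = nrow(cohort),
    n_male = sum(cohort$sex == "M"),
    n_female = sum(cohort$sex == "F"),
    age_mean = mean(cohort$age), age_sd = stats::sd(cohort$age),
    gfr_mean = mean(cohort$gfr), gfr_sd = stats::sd(cohort$gfr),
    ckd_counts = table(st),
    n_ckd2 = sum(st == "G2"),
    n_ckd3 = sum(st %in% c("G3a", "G3b")),
    n_ckd3a = sum(st == "G3a"),
    n_ckd3b = sum(st == "G3b"),
    mtv_mean = mean(cohort$mtv), mtv_sd = stats::sd(cohort$mtv),
    pct_id_mean = mean(cohort$pct_id), pct_id_sd = stats::sd(cohort$pct_id),
    pct_id_min = min(cohort$pct_id), pct_id_max = max(cohort$pct_id)
  )
}
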