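#' CKD-EPI eGFR and incident-CKD phenotyping
#'
#' Estimated glomerular filtration rate from the CKD-EPI (2009) creatinine
#' equation, and incident chronic kidney disease ascertainment from
#' longitudinal serum creatinine: a new CKD case is a decline of eGFR to below
#' 60 mL/min/1.73 m2 at any follow-up visit among subjects whose baseline eGFR
#' is at least 60.
#'
#' @name phenotypes
NULL

#' CKD-EPI creatinine eGFR
#'
#' eGFR = 141 x min(Scr/k, 1)^alpha x max(Scr/k, 1)^-1.209 x 0.993^Age
#' x 1.018 (if female), with k = 0.7 mg/dL, alpha = -0.329 for females and
#' k = 0.9 mg/dL, alpha = -0.411 for males.
#'
#' @param scr serum creatinine, mg/dL (> 0). Vectorized.
#' @param age age in years (> 0).
#' @param sex `"male"` or `"female"` (recycled).
#' @return eGFR in mL/min/1.73 m2.
#' @examples
#' egfr_ckd_epi(0.7, 50, "female")  # Scr/k = 1, so 141 * 0.993^50 * 1.018
#' @export
egfr_ckd_epi <- function(scr, age, sex) {
  sex <- match.arg(tolower(as.character(sex)), c("male", "female"),
                   several.ok = TRUE)
  n <- max(length(scr), length(age), length(sex))
  scr <- rep_len(scr, n); age <- rep_len(age, n); sex <- rep_len(sex, n)
  if (any(!is.finite(scr) | scr <= 0)) stop("scr must be positive")
  if (any(!is.finite(age) | age <= 0)) stop("age must be positive")
  female <- sex == "female"
  k <- ifelse(female, 0.7, 0.9)
  alpha <- ifelse(female, -0.329, -0.411)
  ratio <- scr / k
  141 * pmin(ratio, 1)^alpha * pmax(ratio, 1)^-1.209 *
    0.993^age * ifelse(female, 1.018, 1)
}

#' Serum creatinine giving a target eGFR
#'
#' Inverse of [egfr_ckd_epi()] in `scr` for fixed age and sex; used by the
#' cohort simulator to construct creatinine trajectories with prescribed
#' eGFR crossings.
#'
#' @param egfr target eGFR, mL/min/1.73 m2 (> 0).
#' @inheritParams egfr_ckd_epi
#' @return serum creatinine in mg/dL.
#' @export
scr_for_egfr <- function(egfr, age, sex) {
  sex <- match.arg(tolower(as.character(sex)), c("male", "female"),
                   several.ok = TRUE)
  n <- max(length(egfr), length(age), length(sex))
  egfr <- rep_len(egfr, n); age <- rep_len(age, n); sex <- rep_len(sex, n)
  if (any(!is.finite(egfr) | egfr <= 0)) stop("egfr must be positive")
  female <- sex == "female"
  k <- ifelse(female, 0.7, 0.9)
  alpha <- ifelse(female, -0.329, -0.411)
  base <- 141 * 0.993^age * ifelse(female, 1.018, 1)  # eGFR at Scr = k
  ratio <- ifelse(egfr < base,
                  (egfr / base)^(-1 / 1.209),  # Scr/k > 1 branch
                  (egfr / base)^(1 / alpha))   # Scr/k < 1 branch
  k * ratio
}

#' Classify a subject's incident-CKD status from visit-level creatinine
#'
#' @param visits data.frame with one row per visit: `time` (years from
#'   baseline, strictly increasing, first visit at 0), `age` (years at the
#'   visit), `scr` (serum creatinine, mg/dL).
#' @param sex `"male"` or `"female"`.
#' @return one of `"excluded_baseline"` (baseline eGFR < 60),
#'   `"incident_case"` (baseline >= 60 and any follow-up eGFR < 60), or
#'   `"non_case"`. eGFR is not rounded before the threshold comparison, and
#'   the first qualifying follow-up decides: no confirmatory visit required.
#' @export
classify_incident_ckd <- function(visits, sex) {
  if (is.null(visits) || nrow(visits) == 0L) stop("no visits supplied")
  stopifnot(all(c("time", "age", "scr") %in% names(visits)))
  if (is.unsorted(visits$time, strictly = TRUE)) {
    stop("visit times must be strictly increasing")
  }
  if (visits$time[1] != 0) stop("first visit must be baseline (time 0)")
  egfr <- egfr_ckd_epi(visits$scr, visits$age, sex)
  if (egfr[1] < 60) return("excluded_baseline")
  if (nrow(visits) > 1L && any(egfr[-1] < 60)) return("incident_case")
  "non_case"
}

#' Classify every subject in a visit-level cohort table
#'
#' @param cohort data.frame with columns `subject_id`, `sex`, `time`, `age`,
#'   `scr` (one row per visit).
#' @return data.frame with one row per subject: `subject_id`, `status`.
#' @export
classify_cohort <- function(cohort) {
  stopifnot(all(c("subject_id", "sex", "time", "age", "scr") %in% names(cohort)))
  ids <- unique(cohort$subject_id)
  status <- vapply(ids, function(id) {
    rows <- cohort[cohort$subject_id == id, ]
    rows <- rows[order(rows$time), ]
    classify_incident_ckd(rows[c("time", "age", "scr")], rows$sex[1])
  }, character(1))
  data.frame(subject_id = ids, status = unname(status),
             stringsAsFactors = FALSE)
}
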