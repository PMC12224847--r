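#' Derive the five cardiometabolic disease flags from raw measurements
#'
#' Applies the guideline-based diagnostic rules to a table of raw
#' measurements, one row per subject:
#'
#' * hypertension: mean systolic BP > 140 mmHg, or mean diastolic BP >
#'   90 mmHg, or a physician diagnosis;
#' * dyslipidemia: total cholesterol >= 5.18 mmol/L, or triglycerides >=
#'   1.70 mmol/L, or LDL-C >= 3.37 mmol/L, or HDL-C < 1.04 mmol/L;
#' * diabetes: fasting glucose >= 7.0 mmol/L, or 2-h post-load glucose >=
#'   11.1 mmol/L, or a physician diagnosis;
#' * chronic kidney disease: structural/functional kidney damage persisting
#'   more than 3 months, or ACR >= 30 mg/g, or eGFR < 60 mL/min/1.73m^2
#'   persisting more than 3 months;
#' * hyperuricemia: serum uric acid > 420 umol/L in men, > 357 umol/L in
#'   women.
#'
#' Comparators follow the printed rules exactly (strict `>` for blood
#' pressure and uric acid, `>=` for the lipid/glucose/ACR cutoffs, strict
#' `<` for HDL-C and eGFR). Persistence of kidney findings is carried by
#' boolean flags because single-visit data cannot verify duration; if the
#' `egfr_low_over_3mo` column is absent, a low eGFR is assumed persistent.
#'
#' @param measurements data.frame with columns `sex` ("Male"/"Female"),
#'   `sbp`, `dbp`, `dx_hypertension`, `total_cholesterol`, `triglycerides`,
#'   `ldl_c`, `hdl_c`, `fasting_glucose_mmol`, `ogtt_2h_glucose` (optional,
#'   NA allowed), `dx_diabetes`, `acr`, `egfr`, `kidney_damage_over_3mo`,
#'   `egfr_low_over_3mo` (optional), `serum_uric_acid`.
#' @return data.frame of five logical columns, one row per input row.
#' @export
flag_diseases <- function(measurements) {
  m <- as.data.frame(measurements)
  need <- c("sex", "sbp", "dbp", "dx_hypertension", "total_cholesterol",
            "triglycerides", "ldl_c", "hdl_c", "fasting_glucose_mmol",
            "dx_diabetes", "acr", "egfr", "kidney_damage_over_3mo",
            "serum_uric_acid")
  miss <- setdiff(need, names(m))
  if (length(miss))
    stop("missing measurement columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (is.null(m$ogtt_2h_glucose)) m$ogtt_2h_glucose <- NA_real_
  if (is.null(m$egfr_low_over_3mo)) m$egfr_low_over_3mo <- TRUE

  conc <- c("total_cholesterol", "triglycerides", "ldl_c", "hdl_c",
            "fasting_glucose_mmol", "acr", "egfr", "serum_uric_acid")
  for (v in conc)
    if (any(m[[v]] < 0, na.rm = TRUE))
      stop("negative concentration in '", v, "'", call. = FALSE)
  if (any(m$sbp <= 0 | m$sbp >= 400 | m$dbp <= 0 | m$dbp >= 400))
    stop("blood pressures must lie in (0, 400) mmHg", call. = FALSE)

  sex <- as.character(m$sex)
  bad_sex <- !(sex %in% c("Male", "Female"))
  if (any(bad_sex & !is.na(m$serum_uric_acid)))
    stop("sex must be known (\"Male\"/\"Female\") to apply the sex-specific ",
         "hyperuricemia cutoff", call. = FALSE)

  hypertension <- m$sbp > 140 | m$dbp > 90 | as.logical(m$dx_hypertension)
  dyslipidemia <- m$total_cholesterol >= 5.18 | m$triglycerides >= 1.70 |
    m$ldl_c >= 3.37 | m$hdl_c < 1.04
  diabetes <- m$fasting_glucose_mmol >= 7.0 |
    (!is.na(m$ogtt_2h_glucose) & m$ogtt_2h_glucose >= 11.1) |
    as.logical(m$dx_diabetes)
  ckd <- as.logical(m$kidney_damage_over_3mo) | m$acr >= 30 |
    (m$egfr < 60 & as.logical(m$egfr_low_over_3mo))
  ua_cut <- ifelse(sex == "Male", 420, 357)
  hyperuricemia <- m$serum_uric_acid > ua_cut

  data.frame(hypertension = hypertension, dyslipidemia = dyslipidemia,
             diabetes = diabetes, ckd = ckd, hyperuricemia = hyperuricemia)
}

#' Restrict a cohort to multimorbid subjects
#'
#' Keeps exactly the records carrying at least two of the five disease
#' flags, preserving order. This mirrors the study inclusion rule that
#' excludes subjects with zero or one cardiometabolic disease.
#'
#' @param cohort data.frame with logical (or 0/1) columns `hypertension`,
#'   `dyslipidemia`, `diabetes`, `ckd`, `hyperuricemia`.
#' @return the retained rows of `cohort`.
#' @export
filter_cmm <- function(cohort) {
  cohort <- as.data.frame(cohort)
  miss <- setdiff(.cmm_diseases, names(cohort))
  if (length(miss))
    stop("cohort lacks disease flag columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(cohort) == 0) return(cohort)
  nflag <- Reduce(`+`, lapply(cohort[.cmm_diseases],
                              function(x) as.integer(as.logical(x))))
  out <- cohort[nflag >= 2, , drop = FALSE]
  rownames(out) <- NULL
  out
}
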