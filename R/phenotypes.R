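#' Derive binary hypertension status from blood pressure and medication
#'
#' An individual is a CASE if systolic blood pressure exceeds 140 mmHg, or
#' diastolic blood pressure exceeds 90 mmHg, or they take antihypertensive
#' medication (the rule is a disjunction: one satisfied trigger suffices even
#' when other fields are missing). An individual is a CONTROL when all
#' non-missing blood pressures are at or below threshold, at least one blood
#' pressure is observed, and medication is "no" or missing (a sub-threshold
#' individual whose medication field is missing counts as a control).
#' Everyone else — in particular, both pressures missing without a recorded
#' medication "yes" — is EXCLUDED from analysis.
#'
#' @param sbp Systolic blood pressure in mmHg (`NA` allowed).
#' @param dbp Diastolic blood pressure in mmHg (`NA` allowed).
#' @param med Antihypertensive medication flag: 0/1, `"yes"`/`"no"`, logical,
#'   or `NA`.
#' @return Character vector with values `"CASE"`, `"CONTROL"`, `"EXCLUDED"`.
#' @export
#' @examples
#' derive_status(c(150, 120, 140, NA), c(80, 70, 90, NA), c(0, NA, 0, NA))
derive_status <- function(sbp, dbp, med) {
  n <- max(length(sbp), length(dbp), length(med))
  sbp <- rep_len(as.numeric(sbp), n)
  dbp <- rep_len(as.numeric(dbp), n)
  med <- rep_len(med, n)
  if (is.character(med)) {
    med <- tolower(med)
    med <- ifelse(med %in% c("yes", "y", "1", "true"), 1L,
                  ifelse(med %in% c("no", "n", "0", "false"), 0L, NA_integer_))
  }
  med <- as.integer(med)
  bad <- function(x) !is.na(x) & (x < 0 | x > 400)
  if (any(bad(sbp)) || any(bad(dbp)))
    stop("malformed blood pressure values (negative or > 400 mmHg)")

  case <- (!is.na(sbp) & sbp > 140) | (!is.na(dbp) & dbp > 90) |
    (!is.na(med) & med == 1L)
  sbp_ok <- is.na(sbp) | sbp <= 140
  dbp_ok <- is.na(dbp) | dbp <= 90
  any_bp <- !is.na(sbp) | !is.na(dbp)
  med_ok <- is.na(med) | med == 0L
  control <- !case & sbp_ok & dbp_ok & any_bp & med_ok
  ifelse(case, "CASE", ifelse(control, "CONTROL", "EXCLUDED"))
}

#' Read a phenotype table and derive case-control status
#'
#' Reads a CSV with header `ID,SBP,DBP,MED,AGE` (`MED` in \{0, 1, NA\}) and
#' appends the derived `status` (via [derive_status()]) and the dichotomized
#' age indicator `age_group` (1 if age >= 55 years, 0 otherwise, `NA` when
#' age is missing).
#'
#' @param path Path to the phenotype CSV.
#' @param age_cut Age threshold in years for the binary covariate; default 55.
#' @return A tibble with columns `ID`, `SBP`, `DBP`, `MED`, `AGE`, `status`,
#'   `age_group`.
#' @export
read_phenotypes <- function(path, age_cut = 55) {
  tab <- utils::read.csv(path, na.strings = c("NA", ""))
  need <- c("ID", "SBP", "DBP", "MED", "AGE")
  if (!all(need %in% names(tab)))
    stop("phenotype file must have header ID,SBP,DBP,MED,AGE")
  add_phenotype_status(tibble::as_tibble(tab), age_cut = age_cut)
}

#' Append derived status and age group to a phenotype table
#' @param pheno Data frame with columns `ID`, `SBP`, `DBP`, `MED`, `AGE`.
#' @param age_cut Age threshold in years; default 55.
#' @return The input as a tibble with `status` and `age_group` appended.
#' @export
add_phenotype_status <- function(pheno, age_cut = 55) {
  pheno <- tibble::as_tibble(pheno)
  pheno$status <- derive_status(pheno$SBP, pheno$DBP, pheno$MED)
  pheno$age_group <- ifelse(is.na(pheno$AGE), NA_integer_,
                            as.integer(pheno$AGE >= age_cut))
  pheno
}
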