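#' Phenotype configuration for the composite case definition
#'
#' A subject is a case if they self-reported the condition, carry any ICD-10
#' code whose digits match the configured prefix (dots are stripped on both
#' sides, so `"G431"` and `"G43.1"` both match prefix `"G43"`), or report
#' taking one of the configured condition-specific medications. The
#' medication list shipped with the package is a documented placeholder
#' standing in for a curated list; supply your own via `medication_codes`
#' or [read_phenotype_config()].
#'
#' @param icd10_prefix ICD-10 code prefix (default `"G43"`, the migraine
#'   block).
#' @param medication_codes Character vector of qualifying medication codes;
#'   must be non-empty unless `use_medication = FALSE`.
#' @param use_medication Logical; disable the medication criterion entirely.
#' @return A list of class `phenotype_config`.
#' @export
phenotype_config <- function(icd10_prefix = "G43",
                             medication_codes = default_medication_codes(),
                             use_medication = TRUE) {
  if (use_medication && !length(medication_codes))
    stop("medication_codes must be non-empty when the medication criterion is enabled")
  structure(
    list(icd10_prefix = gsub(".", "", icd10_prefix, fixed = TRUE),
         medication_codes = as.character(medication_codes),
         use_medication = isTRUE(use_medication)),
    class = "phenotype_config"
  )
}

#' Default (placeholder) migraine-specific medication codes
#'
#' Generic names of triptans, ditans, gepants and other migraine-specific
#' agents; a stand-in for a biobank-specific coded medication list.
#' @return Character vector.
#' @export
default_medication_codes <- function() {
  path <- system.file("extdata", "medications.json", package = "burdenscan")
  if (nzchar(path)) {
    unlist(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    c("sumatriptan", "zolmitriptan", "naratriptan", "rizatriptan",
      "almotriptan", "eletriptan", "frovatriptan", "lasmiditan",
      "rimegepant", "ubrogepant", "pizotifen", "ergotamine",
      "dihydroergotamine", "clonidine_migraine")
  }
}

#' Read a phenotype configuration from JSON
#' @param path JSON file with fields `icd10_prefix` and `medication_codes`.
#' @return A `phenotype_config`.
#' @export
read_phenotype_config <- function(path) {
  if (!file.exists(path)) stop("phenotype config not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  phenotype_config(
    icd10_prefix = raw$icd10_prefix %||% "G43",
    medication_codes = unlist(raw$medication_codes),
    use_medication = raw$use_medication %||% TRUE
  )
}

#' Classify a single subject as case or control
#'
#' @param self_report Logical self-report flag.
#' @param icd10_codes Character vector of ICD-10 codes (may be empty).
#' @param medication_codes Character vector of medication codes (may be
#'   empty).
#' @param config A [phenotype_config()].
#' @return TRUE iff any of the three indicators qualifies.
#' @examples
#' classify_case(FALSE, "G43.1", character(0))        # TRUE: ICD-10 G43.*
#' classify_case(FALSE, "G44.2", character(0))        # FALSE: G44 is not G43
#' classify_case(FALSE, character(0), "sumatriptan")  # TRUE: medication
#' @export
classify_case <- function(self_report, icd10_codes, medication_codes,
                          config = phenotype_config()) {
  isTRUE(self_report) ||
    icd_matches(icd10_codes, config$icd10_prefix) ||
    (config$use_medication && any(medication_codes %in% config$medication_codes))
}

icd_matches <- function(codes, prefix_nodot) {
  if (!length(codes)) return(FALSE)
  any(startsWith(gsub(".", "", codes, fixed = TRUE), prefix_nodot))
}

#' Assign case/control status across a cohort
#'
#' Applies [classify_case()] to every subject and stores the result in
#' `is_case`, together with the three per-subject indicator columns so the
#' composite definition stays recomputable.
#'
#' @param cohort Cohort data.frame from [read_cohort()] (or the simulator).
#' @param config A [phenotype_config()].
#' @return The cohort with logical columns `ind_self`, `ind_icd`,
#'   `ind_med` and `is_case` added.
#' @export
classify_cohort <- function(cohort, config = phenotype_config()) {
  cohort$ind_self <- as.logical(cohort$self_report_migraine)
  cohort$ind_icd <- vapply(cohort$icd10_codes, icd_matches,
                           logical(1), prefix_nodot = config$icd10_prefix)
  cohort$ind_med <- if (config$use_medication) {
    vapply(cohort$medication_codes,
           function(m) any(m %in% config$medication_codes), logical(1))
  } else rep(FALSE, nrow(cohort))
  cohort$is_case <- cohort$ind_self | cohort$ind_icd | cohort$ind_med
  cohort
}

#' Summarise the phenotype composition of a classified cohort
#'
#' Reports case/control counts, percent female in each stratum, mean/SD age
#' when an `age` column is present, and the seven-way breakdown of cases by
#' indicator combination (which partitions the cases).
#'
#' @param cohort A cohort with `is_case` (and indicator columns) assigned by
#'   [classify_cohort()].
#' @return A list with `n_cases`, `n_controls`, `pct_female_cases`,
#'   `pct_female_controls`, optional `age_cases`/`age_controls` (mean, sd),
#'   and `breakdown` (named integer vector over indicator combinations).
#' @export
phenotype_summary <- function(cohort) {
  stopifnot("is_case" %in% names(cohort))
  cases <- cohort[cohort$is_case, , drop = FALSE]
  controls <- cohort[!cohort$is_case, , drop = FALSE]
  out <- list(
    n_cases = nrow(cases),
    n_controls = nrow(controls),
    pct_female_cases = 100 * mean(cases$sex == 1),
    pct_female_controls = 100 * mean(controls$sex == 1)
  )
  if ("age" %in% names(cohort)) {
    out$age_cases <- c(mean = mean(cases$age), sd = stats::sd(cases$age))
    out$age_controls <- c(mean = mean(controls$age), sd = stats::sd(controls$age))
  }
  if (all(c("ind_self", "ind_icd", "ind_med") %in% names(cohort))) {
    combo <- paste0(ifelse(cases$ind_self, "self+", ""),
                    ifelse(cases$ind_icd, "icd+", ""),
                    ifelse(cases$ind_med, "med+", ""))
    combo <- sub("\\+$", "", combo)
    levels7 <- c("self", "icd", "med", "self+icd", "self+med", "icd+med",
                 "self+icd+med")
    out$breakdown <- table(factor(combo, levels = levels7))
  }
  out
}
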