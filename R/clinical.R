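#' Timepoint calendar
#'
#' Maps the serial-collection labels to months after treatment. Fixed
#' constants used for relapse labelling: baseline = 0, 2 weeks = 0.5 months,
#' then 3, 6 and 12 months.
#'
#' @return Named numeric vector of months keyed by timepoint label.
#' @export
timepoint_months <- function() {
  c(baseline = 0, "2wk" = 0.5, "3mo" = 3, "6mo" = 6, "12mo" = 12)
}

CNV_STATES <- c("LOH", "ROH", "Gain", "none")
CNV_REGIONS <- c("1p", "3", "6p", "6q", "8p", "8q")

#' Clinical cohort fixture
#'
#' Loads the version-controlled clinical table for the 11-patient uveal
#' melanoma monitoring cohort (treatment, relapse status and timing,
#' follow-up, and clinical copy-number calls on 1p/3/6p/6q/8p/8q) together
#' with the plasma collection schedule across the five serial timepoints.
#' The schedule encodes the cohort's documented exceptions: one patient with
#' no baseline draw, one discontinued after baseline, and four patients
#' without a 12-month sample.
#'
#' @return A list with `records` (one row per patient) and `schedule`
#'   (patient x timepoint collection flags).
#' @export
make_clinical_fixture <- function() {
  rec_path <- system.file("extdata", "clinical_table1.tsv", package = "cfMRD",
                          mustWork = TRUE)
  sch_path <- system.file("extdata", "sample_schedule.tsv", package = "cfMRD",
                          mustWork = TRUE)
  records <- utils::read.delim(rec_path, stringsAsFactors = FALSE,
                               na.strings = "NA")
  schedule <- utils::read.delim(sch_path, stringsAsFactors = FALSE)
  validate_clinical(records, schedule)
  list(records = records, schedule = schedule)
}

validate_clinical <- function(records, schedule) {
  stopifnot(!anyDuplicated(records$patient_id))
  if (!all(records$relapse %in% c("yes", "no", "lost"))) {
    stop_data("relapse must be yes/no/lost")
  }
  if (!all(records$treatment %in% c("brachytherapy", "enucleation"))) {
    stop_data("unknown treatment value")
  }
  has_months <- !is.na(records$relapse_months)
  if (!all(has_months == (records$relapse == "yes"))) {
    stop_data("relapse_months must be present iff relapse = yes")
  }
  if (any(records$relapse_months > records$followup_months, na.rm = TRUE)) {
    stop_data("relapse_months exceeds followup_months")
  }
  for (region in CNV_REGIONS) {
    col <- records[[paste0("cnv_", region)]]
    if (!all(col %in% CNV_STATES)) {
      stop_data("cnv_", region, " has values outside {LOH, ROH, Gain, none}")
    }
  }
  if (!all(schedule$patient_id %in% records$patient_id)) {
    stop_data("schedule references unknown patients")
  }
  if (!all(schedule$timepoint %in% names(timepoint_months()))) {
    stop_data("schedule references unknown timepoints")
  }
  invisible(NULL)
}

#' Cohort summary statistics
#'
#' Computes the headline clinical quantities: median disease-free survival
#' over relapsing patients (explicit `NA` when no patient relapsed),
#' per-region copy-number event counts by state, and the expected number of
#' collected plasma samples (`patients x timepoints - missing`).
#'
#' @param records,schedule As returned by [make_clinical_fixture()].
#' @return A list with `n_patients`, `n_relapsed`, `median_dfs_months`,
#'   `cnv_counts` (region x state matrix), `expected_samples`, and
#'   `collected_samples`.
#' @export
cohort_summary <- function(records, schedule) {
  if (nrow(records) < 1L) stop_data("need at least one clinical record")
  relapse_times <- records$relapse_months[records$relapse == "yes"]
  median_dfs <- if (length(relapse_times)) stats::median(relapse_times) else NA_real_
  cnv_counts <- sapply(CNV_REGIONS, function(region) {
    table(factor(records[[paste0("cnv_", region)]], levels = CNV_STATES))
  })
  cnv_counts <- t(cnv_counts)  # region x state
  n_tp <- length(timepoint_months())
  missing <- sum(schedule$collected == "no")
  list(
    n_patients = nrow(records),
    n_relapsed = sum(records$relapse == "yes"),
    median_dfs_months = median_dfs,
    cnv_counts = cnv_counts,
    expected_samples = nrow(records) * n_tp - missing,
    collected_samples = sum(schedule$collected == "yes")
  )
}
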