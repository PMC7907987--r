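DAYS_PER_MONTH <- 30.4375  # mean Gregorian month

#' Therapy-course duration in months
#'
#' Exact day-count arithmetic: (stop - start) in days divided by 30.4375.
#' Ongoing courses (missing `stop`) are measured to `censor_date`.
#'
#' @param start,stop `Date` vectors (or coercible); `stop` may be `NA` for
#'   ongoing courses.
#' @param censor_date `Date` used for ongoing courses; required if any
#'   `stop` is `NA`.
#' @return numeric months.
#' @export
duration_months <- function(start, stop, censor_date = NULL) {
  start <- as.Date(start)
  stop <- as.Date(stop)
  if (anyNA(stop)) {
    stop_if_not(!is.null(censor_date),
                "ongoing courses require a `censor_date`")
    stop[is.na(stop)] <- as.Date(censor_date)
  }
  stop_if_not(!anyNA(start), "`start` dates must be valid")
  stop_if_not(all(stop >= start), "`stop` must not precede `start`")
  as.numeric(stop - start) / DAYS_PER_MONTH
}

BENEFIT_MONTHS <- 6
EXCEPTIONAL_MONTHS <- 12

#' Classify a sequencing-directed therapy course
#'
#' Clinical benefit means remaining on the sequencing-directed therapy for
#' 6 months or longer; exceptional response means 12 months or longer. Both
#' thresholds are inclusive, so the exceptional set is always a subset of
#' the benefit set. Only SDT courses are classified.
#'
#' @param courses data frame with `sdt`, `start`, `stop` (and optionally
#'   `best_response`); or precomputed durations via `duration` argument.
#' @param censor_date for ongoing courses.
#' @param duration optional numeric months, bypassing date arithmetic.
#' @return the input with `duration_months`, `benefit`, `exceptional`
#'   columns appended.
#' @export
classify_course <- function(courses, censor_date = NULL, duration = NULL) {
  stop_if_not(all(courses$sdt),
              "only SDT courses are classified for clinical benefit")
  d <- if (is.null(duration)) {
    duration_months(courses$start, courses$stop, censor_date)
  } else duration
  courses$duration_months <- d
  courses$benefit <- d >= BENEFIT_MONTHS
  courses$exceptional <- d >= EXCEPTIONAL_MONTHS
  courses
}

#' Clinical benefit rate
#'
#' Proportion of sequencing-directed therapy (SDT) recipients with clinical
#' benefit, as a percent rounded half-up to one decimal. With
#' `unit = "patient"` the rate is patients with >= 1 benefit course over
#' patients with >= 1 SDT course; with `unit = "instance"` it is benefit
#' courses over SDT courses (used for strata where one patient can
#' contribute several serial SDTs).
#'
#' @param courses classified SDT course table (needs `patient_id`,
#'   `benefit`).
#' @param unit `"patient"` or `"instance"`.
#' @return percent (0-100 scale, one decimal).
#' @export
clinical_benefit_rate <- function(courses, unit = c("patient", "instance")) {
  unit <- match.arg(unit)
  stop_if_not(nrow(courses) > 0, "benefit rate is undefined on an empty table")
  if (unit == "patient") {
    benefit_patients <- unique(courses$patient_id[courses$benefit])
    pct(length(benefit_patients), length(unique(courses$patient_id)))
  } else {
    pct(sum(courses$benefit), nrow(courses))
  }
}

#' Cohort headline rates from count inputs
#'
#' Turns the cohort's numerator/denominator counts into the named headline
#' percentages, each computed as round-half-up(100 * num / den, 1). Count
#' invariants (benefit <= SDT patients, exceptional <= benefit, reclassified
#' CUPs <= CUPs) are validated first.
#'
#' @param counts named list or vector with `n_cohort`, `n_actionable`,
#'   `n_tier2_somatic`, `n_sdt_patients`, `n_benefit`, `n_exceptional`,
#'   `n_pgv_patients`, `n_pgv_total`, `n_pgv_unknown_before`,
#'   `n_pgv_penetrant`, `n_second_hit`, `n_therapeutic_pgv`,
#'   `n_therapeutic_second_hit`, `n_cup`, `n_cup_reclassified`,
#'   `n_cup_sdt_instances`, `n_cup_benefit_instances`.
#' @return named list of percentages (0-100 scale, one decimal).
#' @export
cohort_rates <- function(counts) {
  cn <- as.list(counts)
  need <- c("n_cohort", "n_actionable", "n_tier2_somatic", "n_sdt_patients",
            "n_benefit", "n_exceptional", "n_pgv_patients", "n_pgv_total",
            "n_pgv_unknown_before", "n_pgv_penetrant", "n_second_hit",
            "n_therapeutic_pgv", "n_therapeutic_second_hit", "n_cup",
            "n_cup_reclassified", "n_cup_sdt_instances",
            "n_cup_benefit_instances")
  missing <- setdiff(need, names(cn))
  stop_if_not(length(missing) == 0,
              paste("counts lack:", paste(missing, collapse = ", ")))
  stop_if_not(cn$n_benefit <= cn$n_sdt_patients,
              "benefit patients cannot exceed SDT patients")
  stop_if_not(cn$n_exceptional <= cn$n_benefit,
              "exceptional responders cannot exceed benefit patients")
  stop_if_not(cn$n_cup_reclassified <= cn$n_cup,
              "reclassified CUPs cannot exceed CUP cases")
  stop_if_not(cn$n_actionable <= cn$n_cohort,
              "actionable patients cannot exceed the cohort")
  list(
    actionable_pct = pct(cn$n_actionable, cn$n_cohort),
    tier2_somatic_pct = pct(cn$n_tier2_somatic, cn$n_cohort),
    sdt_of_actionable_pct = pct(cn$n_sdt_patients, cn$n_actionable),
    benefit_of_sdt_pct = pct(cn$n_benefit, cn$n_sdt_patients),
    exceptional_of_sdt_pct = pct(cn$n_exceptional, cn$n_sdt_patients),
    pgv_patient_pct = pct(cn$n_pgv_patients, cn$n_cohort),
    pgv_unknown_before_pct = pct(cn$n_pgv_unknown_before, cn$n_pgv_total),
    pgv_penetrant_pct = pct(cn$n_pgv_penetrant, cn$n_pgv_total),
    second_hit_pct = pct(cn$n_second_hit, cn$n_pgv_total),
    therapeutic_second_hit_pct = pct(cn$n_therapeutic_second_hit,
                                     cn$n_therapeutic_pgv),
    cup_reclassified_pct = pct(cn$n_cup_reclassified, cn$n_cup),
    cup_benefit_rate_pct = pct(cn$n_cup_benefit_instances,
                               cn$n_cup_sdt_instances))
}

#' Read therapy courses from TSV
#'
#' Expects columns `patient_id`, `therapy`, `sdt` (logical), `setting`,
#' `start`, `stop` (ISO-8601 dates; empty `stop` = ongoing),
#' `best_response`.
#'
#' @param path TSV file path.
#' @return course data frame with `Date` columns.
#' @export
read_courses <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  d$sdt <- as.logical(d$sdt)
  d$start <- as.Date(d$start)
  d$stop <- as.Date(ifelse(d$stop == "" | is.na(d$stop), NA, d$stop))
  d
}
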