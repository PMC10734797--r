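# Population-level cohort selection: identify prevalent MS cases in a claims
# inclusion period and apply the enrollment, age, exclusion-diagnosis and
# vital-status filters, reporting attrition per filter.

# shift a Date by whole months, clamping to the last day of short months
add_months <- function(date, months) {
  lt <- as.POSIXlt(date)
  day <- lt$mday
  lt$mday <- 1L
  lt$mon <- lt$mon + months
  first <- as.Date(lt)
  last_day <- as.integer(format(seq(first, by = "1 month", length.out = 2)[2] - 1, "%d"))
  first + pmin(day, last_day) - 1L
}

#' Select an MS cohort from claims with attrition reporting
#'
#' Applies, in order: (1) the MS case rule - at least one inpatient or two
#' confirmed outpatient diagnoses (distinct service dates) with an ICD-10-GM
#' code starting `G35` dated inside the inclusion period; (2) index date =
#' date of the first qualifying MS diagnosis in the period; (3) adult at
#' index; (4) continuous insurance from `baseline_months` before index through
#' `study_end`, where a coverage gap explained by death is tolerated here and
#' handled by filter (6); (5) no pregnancy-related or other
#' demyelinating-disease diagnosis in the window from `baseline_months` before
#' index through `study_end`; (6) alive through the `followup_months` after
#' index.
#'
#' @param demographics data.frame `patient_id`, `birth_year`.
#' @param events claims events for all candidate patients.
#' @param coverage data.frame `patient_id`, `start`, `end`.
#' @param inclusion_start,inclusion_end `Date` bounds of the inclusion period.
#' @param study_end `Date` end of the study period.
#' @param deaths optional data.frame `patient_id`, `date`.
#' @param baseline_months,followup_months lengths of the baseline and
#'   follow-up periods (default 12 each).
#' @param min_age minimum age in years at index (default 18), computed from
#'   birth year.
#' @param ms_codes ICD stems defining an MS diagnosis (default `"G35"`).
#' @param pregnancy_codes,demyelinating_codes ICD stems for the exclusion
#'   diagnoses; site-specific lists should be supplied, the defaults are the
#'   pregnancy chapter (O00-O99 via stem `"O"`, plus Z34/Z35 supervision
#'   codes) and other acute/other demyelinating diseases (G36, G37).
#' @return object of class `pedss_cohort`: list with `cohort`
#'   (patient_id, index_date) and `attrition` (filter, n_removed, n_remaining).
#' @export
select_cohort <- function(demographics, events, coverage,
                          inclusion_start, inclusion_end, study_end,
                          deaths = NULL,
                          baseline_months = 12, followup_months = 12,
                          min_age = 18,
                          ms_codes = "G35",
                          pregnancy_codes = c("O", "Z34", "Z35"),
                          demyelinating_codes = c("G36", "G37")) {
  inclusion_start <- as.Date(inclusion_start)
  inclusion_end <- as.Date(inclusion_end)
  study_end <- as.Date(study_end)
  if (inclusion_start > inclusion_end || inclusion_end > study_end)
    stop("inconsistent period parameters: require inclusion_start <= inclusion_end <= study_end")

  demographics <- as.data.frame(demographics)
  events$date <- as.Date(events$date)
  ev_by_patient <- split(events, events$patient_id)
  cov_by_patient <- split(coverage, coverage$patient_id)
  death_date <- if (!is.null(deaths) && nrow(deaths))
    stats::setNames(as.Date(deaths$date), deaths$patient_id) else c()

  attrition <- data.frame(filter = character(0), n_removed = integer(0),
                          n_remaining = integer(0), stringsAsFactors = FALSE)
  note <- function(label, n_before, n_after) {
    rbind(attrition, data.frame(filter = label, n_removed = n_before - n_after,
                                n_remaining = n_after, stringsAsFactors = FALSE))
  }

  pids <- unique(demographics$patient_id)
  n0 <- length(pids)

  # (1) MS case rule + (2) index date
  index_of <- function(pid) {
    ev <- ev_by_patient[[pid]]
    if (is.null(ev)) return(as.Date(NA))
    inper <- ev[ev$date >= inclusion_start & ev$date <= inclusion_end, , drop = FALSE]
    ms <- inper$code_system == "ICD10GM" & match_code_set(inper$code, ms_codes) &
      inper$setting %in% c("inpatient_dx", "outpatient_dx")
    if (!any(ms)) return(as.Date(NA))
    inp <- ms & inper$setting == "inpatient_dx"
    out <- ms & inper$setting == "outpatient_dx" & inper$qualifier == "confirmed"
    ok <- any(inp) || length(unique(inper$date[out])) >= 2L
    if (!ok) return(as.Date(NA))
    min(inper$date[(inp | out)])
  }
  index <- as.Date(vapply(pids, function(p) as.character(index_of(p)), character(1)),
                   format = "%Y-%m-%d")
  keep <- !is.na(index)
  attrition <- note("MS case rule (G35, >=1 inpatient or >=2 confirmed outpatient)",
                    n0, sum(keep))
  pids <- pids[keep]; index <- index[keep]

  # (3) adult at index
  by <- demographics$birth_year[match(pids, demographics$patient_id)]
  age <- as.integer(format(index, "%Y")) - by
  keep <- !is.na(age) & age >= min_age
  attrition <- note(sprintf("adult at index (>=%d years)", min_age),
                    length(pids), sum(keep))
  pids <- pids[keep]; index <- index[keep]

  # (4) continuous insurance from baseline start through study end
  # (coverage ending at death is tolerated; the death itself is filter 6)
  keep <- vapply(seq_along(pids), function(i) {
    pid <- pids[i]
    from <- add_months(index[i], -baseline_months)
    to <- study_end
    if (pid %in% names(death_date)) to <- min(to, death_date[[pid]])
    covers_interval(cov_by_patient[[pid]], from, to)
  }, logical(1))
  attrition <- note(sprintf("continuously insured (%d months baseline through study end)",
                            baseline_months), length(pids), sum(keep))
  pids <- pids[keep]; index <- index[keep]

  # (5) exclusion diagnoses in the exclusion window
  excl_codes <- c(pregnancy_codes, demyelinating_codes)
  keep <- vapply(seq_along(pids), function(i) {
    ev <- ev_by_patient[[pids[i]]]
    from <- add_months(index[i], -baseline_months)
    w <- ev[ev$date >= from & ev$date <= study_end, , drop = FALSE]
    !any(w$code_system == "ICD10GM" & match_code_set(w$code, excl_codes))
  }, logical(1))
  attrition <- note("no pregnancy-related or other demyelinating-disease diagnosis",
                    length(pids), sum(keep))
  pids <- pids[keep]; index <- index[keep]

  # (6) alive through follow-up
  keep <- vapply(seq_along(pids), function(i) {
    pid <- pids[i]
    !(pid %in% names(death_date)) ||
      death_date[[pid] ] > add_months(index[i], followup_months)
  }, logical(1))
  attrition <- note(sprintf("alive through %d-month follow-up", followup_months),
                    length(pids), sum(keep))
  pids <- pids[keep]; index <- index[keep]

  structure(list(
    cohort = data.frame(patient_id = pids, index_date = index,
                        stringsAsFactors = FALSE),
    attrition = attrition
  ), class = "pedss_cohort")
}

#' @export
print.pedss_cohort <- function(x, ...) {
  cat("MS cohort:", nrow(x$cohort), "patient(s) included\n")
  cat("Attrition:\n")
  a <- x$attrition
  for (i in seq_len(nrow(a)))
    cat(sprintf("  %-70s removed=%-5d remaining=%d\n",
                a$filter[i], a$n_removed[i], a$n_remaining[i]))
  invisible(x)
}
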