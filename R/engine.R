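# Claims-to-pEDSS engine. Events observed in an assessment window around an
# index date are aggregated into a symptom profile (qualified symptom sets by
# severity, drug counts by severity, special ambulation/medication flags) and
# the profile is pushed through the rule cascade to a disability step 0-9.

#' Select claims events inside an assessment window
#'
#' Keeps events dated between `index_date - days_before` and
#' `index_date + days_after`, both ends inclusive. Three months is implemented
#' as 90 fixed days for reproducibility.
#'
#' @param events data.frame of claims events for one patient (columns
#'   `patient_id`, `date` (Date), `code_system`, `code`, `setting`,
#'   `qualifier`).
#' @param index_date a `Date` (typically the date of a reference EDSS
#'   measurement).
#' @param days_before,days_after non-negative window half-widths in days
#'   (default 90/90).
#' @return the windowed events, original order preserved.
#' @export
select_window_events <- function(events, index_date,
                                 days_before = 90, days_after = 90) {
  stopifnot(days_before >= 0, days_after >= 0, inherits(index_date, "Date"))
  d <- as.Date(events$date)
  keep <- d >= index_date - days_before & d <= index_date + days_after
  events[keep, , drop = FALSE]
}

#' Does windowed evidence qualify as a diagnosis?
#'
#' A symptom diagnosis is accepted when the windowed events contain at least
#' one inpatient diagnosis matching the code set, or at least two confirmed
#' outpatient diagnoses matching the code set on at least two distinct service
#' dates. Codes match by prefix at the granularity of the code set. The
#' stricter variant requiring the two outpatient diagnoses to fall in distinct
#' calendar quarters is available via `require_distinct_quarters`.
#'
#' @param events windowed, normalized events of one patient.
#' @param codes character vector of ICD-10-GM codes or stems.
#' @param require_distinct_quarters logical; if TRUE the two confirmed
#'   outpatient diagnoses must come from different calendar quarters.
#' @return single logical.
#' @export
qualify_diagnosis <- function(events, codes, require_distinct_quarters = FALSE) {
  if (!nrow(events)) return(FALSE)
  dx <- events$code_system == "ICD10GM" &
    events$setting %in% c("inpatient_dx", "outpatient_dx") &
    match_code_set(events$code, codes)
  if (!any(dx)) return(FALSE)
  if (any(dx & events$setting == "inpatient_dx")) return(TRUE)
  out <- dx & events$setting == "outpatient_dx" & events$qualifier == "confirmed"
  if (!any(out)) return(FALSE)
  dates <- as.Date(events$date[out])
  if (require_distinct_quarters) {
    q <- paste(format(dates, "%Y"), quarters(dates))
    length(unique(q)) >= 2L
  } else {
    length(unique(dates)) >= 2L
  }
}

#' Build a symptom profile from one patient's windowed claims
#'
#' Aggregates the events in the assessment window into the quantities the
#' cascade consumes: per catalog symptom, diagnosis evidence at a severity
#' tier is accepted only if [qualify_diagnosis()] holds for that symptom's
#' diagnosis codes at that tier, and a symptom qualifying at several tiers is
#' counted once at the highest; distinct medication/therapy codes with at
#' least one event are counted per tier (no confirmation rule applies to
#' prescriptions); the special flags (fampridine, ambulation aids) are set by
#' any single matching event, while the gait-disturbance, plegia and
#' bed-confinement flags require a qualified diagnosis.
#'
#' Gait disturbance is tracked as its own flag and never enters the moderate
#' symptom set; the special-role codes are not meant to appear as ordinary
#' catalog entries.
#'
#' @param events data.frame of one patient's claims events.
#' @param catalog a validated `symptom_catalog`.
#' @param index_date `Date`; if `NULL` the events are assumed pre-windowed.
#' @param days_before,days_after window half-widths in days.
#' @param alive_at_period_end logical flag supplied by the caller from vital
#'   status (death date vs. study end), not inferred from claims.
#' @param require_distinct_quarters passed to [qualify_diagnosis()].
#' @return object of class `symptom_profile`.
#' @export
build_profile <- function(events, catalog, index_date = NULL,
                          days_before = 90, days_after = 90,
                          alive_at_period_end = TRUE,
                          require_distinct_quarters = FALSE) {
  if (!inherits(catalog, "symptom_catalog"))
    stop("catalog must be a validated symptom_catalog; see default_catalog()")
  validate_catalog(catalog)
  if (!is.null(index_date))
    events <- select_window_events(events, index_date, days_before, days_after)

  e <- catalog$entries
  dx_sets <- list(mild = character(0), moderate = character(0),
                  severe = character(0))
  drug_counts <- c(mild = 0L, moderate = 0L, severe = 0L)

  if (nrow(e)) {
    dx_entries <- e[e$evidence_kind == "diagnosis", , drop = FALSE]
    if (nrow(dx_entries)) {
      groups <- split(dx_entries,
                      list(dx_entries$symptom_id, dx_entries$severity),
                      drop = TRUE)
      qualified <- lapply(groups, function(g) {
        ok <- qualify_diagnosis(events, g$code, require_distinct_quarters)
        if (ok) c(symptom = g$symptom_id[1], severity = g$severity[1]) else NULL
      })
      qualified <- do.call(rbind, Filter(Negate(is.null), qualified))
      if (!is.null(qualified)) {
        # one count per symptom, at its highest qualified severity
        sev_rank <- match(qualified[, "severity"], SEVERITIES)
        best <- tapply(sev_rank, qualified[, "symptom"], max)
        for (sym in names(best)) {
          tier <- SEVERITIES[best[[sym]]]
          dx_sets[[tier]] <- c(dx_sets[[tier]], sym)
        }
      }
    }

    rx_entries <- e[e$evidence_kind %in% c("medication", "therapy"), , drop = FALSE]
    if (nrow(rx_entries) && nrow(events)) {
      setting_for <- c(medication = "prescription", therapy = "procedure")
      has_event <- vapply(seq_len(nrow(rx_entries)), function(i) {
        r <- rx_entries[i, ]
        cand <- events$code_system == r$code_system &
          events$setting == setting_for[[r$evidence_kind]]
        if (!any(cand)) return(FALSE)
        if (r$match_mode == "exact") any(events$code[cand] == r$code)
        else any(startsWith(events$code[cand], r$code))
      }, logical(1))
      if (any(has_event)) {
        hit <- rx_entries[has_event, , drop = FALSE]
        # distinct drug/therapy codes per tier
        tab <- tapply(hit$code, factor(hit$severity, levels = SEVERITIES),
                      function(z) length(unique(z)))
        tab[is.na(tab)] <- 0L
        drug_counts <- drug_counts + as.integer(tab)
      }
    }
  }

  sp <- catalog$special
  aid_events <- events[events$setting == "aid" & events$code_system == "AID", , drop = FALSE]
  rx_events <- events[events$setting == "prescription" & events$code_system == "ATC", , drop = FALSE]

  structure(list(
    mild_dx_symptoms     = sort(unique(dx_sets$mild)),
    moderate_dx_symptoms = sort(unique(dx_sets$moderate)),
    severe_dx_symptoms   = sort(unique(dx_sets$severe)),
    mild_drug_count      = drug_counts[["mild"]],
    moderate_drug_count  = drug_counts[["moderate"]],
    severe_drug_count    = drug_counts[["severe"]],
    fampridine           = any(match_code_set(rx_events$code, sp$fampridine_atc)),
    gait_disturbance_dx  = qualify_diagnosis(events, sp$gait_disturbance_icd,
                                             require_distinct_quarters),
    walking_stick        = any(match_code_set(aid_events$code, sp$walking_stick_aid)),
    wheelchair           = any(match_code_set(aid_events$code, sp$wheelchair_aid)),
    paraplegia_dx        = qualify_diagnosis(events, sp$paraplegia_icd,
                                             require_distinct_quarters),
    tetraplegia_dx       = qualify_diagnosis(events, sp$tetraplegia_icd,
                                             require_distinct_quarters),
    chair_bed            = any(match_code_set(aid_events$code, sp$chair_bed_aid)),
    bed_confinement_dx   = qualify_diagnosis(events, sp$bed_confinement_icd,
                                             require_distinct_quarters),
    alive_at_period_end  = isTRUE(alive_at_period_end)
  ), class = "symptom_profile")
}

#' @export
print.symptom_profile <- function(x, ...) {
  cat("Symptom profile\n")
  cat(sprintf("  dx symptoms: mild=%d moderate=%d severe=%d\n",
              length(x$mild_dx_symptoms), length(x$moderate_dx_symptoms),
              length(x$severe_dx_symptoms)))
  cat(sprintf("  drug/therapy codes: mild=%d moderate=%d severe=%d\n",
              x$mild_drug_count, x$moderate_drug_count, x$severe_drug_count))
  flags <- c("fampridine", "gait_disturbance_dx", "walking_stick", "wheelchair",
             "paraplegia_dx", "tetraplegia_dx", "chair_bed", "bed_confinement_dx")
  on <- flags[vapply(flags, function(f) isTRUE(x[[f]]), logical(1))]
  cat("  flags:", if (length(on)) paste(on, collapse = ", ") else "none", "\n")
  cat("  alive at period end:", x$alive_at_period_end, "\n")
  invisible(x)
}

# Vectorized cascade kernel: evaluates the step conditions top-down (9 first)
# and returns the first (= highest) step whose condition holds. All arguments
# recycle to a common length; counts are integers, flags logical.
step_cascade <- function(mild, moderate, severe,
                         mild_drugs, moderate_drugs, severe_drugs,
                         fampridine, gait, stick, wheelchair,
                         para, tetra, chair_bed, bed_conf, alive) {
  n <- max(lengths(list(mild, moderate, severe, mild_drugs, moderate_drugs,
                        severe_drugs, fampridine, gait, stick, wheelchair,
                        para, tetra, chair_bed, bed_conf, alive)))
  step <- rep(NA_integer_, n)
  hold <- function(cond) !is.na(cond) & cond & is.na(step)
  step[hold(bed_conf & alive)] <- 9L
  step[hold(chair_bed | tetra)] <- 8L
  step[hold(wheelchair | para)] <- 7L
  step[hold(stick)] <- 6L
  step[hold(severe >= 1 | severe_drugs >= 1 | moderate >= 4 |
              (fampridine & (moderate >= 1 | severe >= 1)))] <- 5L
  step[hold(moderate >= 3 | moderate_drugs >= 3 | gait |
              (fampridine & moderate == 0 & severe == 0))] <- 4L
  step[hold(((moderate >= 1 & moderate <= 2) |
               (moderate_drugs >= 1 & moderate_drugs <= 2)) & !fampridine)] <- 3L
  step[hold(mild >= 2 & !fampridine)] <- 2L
  step[hold((mild == 1 | mild_drugs >= 1) & !fampridine)] <- 1L
  step[is.na(step)] <- 0L
  step
}

#' Compute the pEDSS step for one symptom profile
#'
#' Applies the rule cascade top-down and returns the highest step 0-9 whose
#' condition holds:
#' step 9 bed confinement (and alive at period end); 8 chair/specialty bed or
#' tetraplegia; 7 wheelchair or paraplegia; 6 walking stick; 5 at least one
#' severe symptom or severe-tier drug, or >=4 moderate symptoms, or fampridine
#' together with a moderate/severe symptom; 4 three moderate symptoms, or >=3
#' moderate-tier drugs, or gait disturbance, or fampridine without
#' moderate/severe symptoms; 3 one or two moderate symptoms or moderate-tier
#' drugs (no fampridine); 2 two or more mild symptoms (no fampridine); 1 one
#' mild symptom or any mild-tier drug (no fampridine); otherwise 0.
#'
#' @param profile a `symptom_profile` from [build_profile()].
#' @return object of class `pedss_result`: list with `pedss`, `fired_step`
#'   (equal to `pedss`) and `fired_clause`, a human-readable trace of the
#'   condition that fired.
#' @export
compute_pedss <- function(profile) {
  stopifnot(inherits(profile, "symptom_profile"))
  p <- profile
  step <- step_cascade(length(p$mild_dx_symptoms), length(p$moderate_dx_symptoms),
                       length(p$severe_dx_symptoms),
                       p$mild_drug_count, p$moderate_drug_count, p$severe_drug_count,
                       p$fampridine, p$gait_disturbance_dx, p$walking_stick,
                       p$wheelchair, p$paraplegia_dx, p$tetraplegia_dx,
                       p$chair_bed, p$bed_confinement_dx, p$alive_at_period_end)
  structure(list(pedss = step, fired_step = step,
                 fired_clause = fired_clause(step, p)),
            class = "pedss_result")
}

fired_clause <- function(step, p) {
  nmod <- length(p$moderate_dx_symptoms)
  nsev <- length(p$severe_dx_symptoms)
  nmil <- length(p$mild_dx_symptoms)
  parts <- switch(as.character(step),
    "9" = "bed confinement diagnosis, alive at period end",
    "8" = c(if (p$chair_bed) "chair/specialty bed aid",
            if (p$tetraplegia_dx) "tetraplegia diagnosis"),
    "7" = c(if (p$wheelchair) "wheelchair aid",
            if (p$paraplegia_dx) "paraplegia diagnosis"),
    "6" = "walking stick aid",
    "5" = c(if (nsev >= 1) sprintf("%d severe symptom diagnosis(es)", nsev),
            if (p$severe_drug_count >= 1) sprintf("%d severe-tier drug(s)/therapy(ies)", p$severe_drug_count),
            if (nmod >= 4) sprintf("%d moderate symptom diagnoses", nmod),
            if (p$fampridine && (nmod >= 1 || nsev >= 1)) "fampridine with moderate/severe symptom"),
    "4" = c(if (nmod >= 3) sprintf("%d moderate symptom diagnoses", nmod),
            if (p$moderate_drug_count >= 3) sprintf("%d moderate-tier drugs", p$moderate_drug_count),
            if (p$gait_disturbance_dx) "gait disturbance diagnosis",
            if (p$fampridine && nmod == 0 && nsev == 0) "fampridine without moderate/severe symptoms"),
    "3" = c(if (nmod >= 1) sprintf("%d moderate symptom diagnosis(es)", nmod),
            if (nmod == 0 && p$moderate_drug_count >= 1) sprintf("%d moderate-tier drug(s)", p$moderate_drug_count)),
    "2" = sprintf("%d mild symptom diagnoses", nmil),
    "1" = c(if (nmil == 1) "1 mild symptom diagnosis",
            if (nmil == 0 && p$mild_drug_count >= 1) sprintf("%d mild-tier drug(s)", p$mild_drug_count)),
    "0" = "no symptom diagnosis or symptom-associated medication")
  sprintf("step %d: %s", step, paste(parts, collapse = "; "))
}

#' @export
print.pedss_result <- function(x, ...) {
  cat("pEDSS", x$pedss, "-", x$fired_clause, "\n")
  invisible(x)
}

#' Compute pEDSS for many patients and index dates
#'
#' Produces one pEDSS per (patient, index date) pair; a patient can contribute
#' several index dates (e.g. one per reference EDSS measurement). When
#' coverage intervals are supplied, an index date is only scored if the
#' patient is continuously insured for the full window around it; records
#' lacking coverage are reported in the `excluded` table with a reason, never
#' silently dropped. Vital status at period end is derived from the `deaths`
#' table against `study_end`.
#'
#' @param events data.frame of claims events for all patients.
#' @param index_dates data.frame with columns `patient_id`, `date`.
#' @param catalog a validated `symptom_catalog`.
#' @param days_before,days_after window half-widths in days (default 90/90).
#' @param coverage optional data.frame `patient_id`, `start`, `end`
#'   (insurance coverage intervals; overlapping or adjacent intervals are
#'   merged before the continuity check).
#' @param deaths optional data.frame `patient_id`, `date`.
#' @param study_end optional `Date`; a patient is alive at period end when
#'   they have no death record on or before it. Defaults to the latest index
#'   date plus `days_after`.
#' @param require_distinct_quarters passed to [qualify_diagnosis()].
#' @return object of class `pedss_batch`: list with `results`
#'   (patient_id, index_date, pedss, fired_clause) and `excluded`
#'   (patient_id, index_date, reason).
#' @export
compute_pedss_batch <- function(events, index_dates, catalog,
                                days_before = 90, days_after = 90,
                                coverage = NULL, deaths = NULL,
                                study_end = NULL,
                                require_distinct_quarters = FALSE) {
  validate_catalog(catalog)
  index_dates <- as.data.frame(index_dates)
  res <- list(); exc <- list()
  if (nrow(index_dates)) {
    index_dates$date <- as.Date(index_dates$date)
    if (is.null(study_end)) study_end <- max(index_dates$date) + days_after
    cov_by_patient <- if (!is.null(coverage))
      split(coverage, coverage$patient_id) else NULL
    death_date <- if (!is.null(deaths) && nrow(deaths))
      stats::setNames(as.Date(deaths$date), deaths$patient_id) else c()
    ev_by_patient <- split(events, events$patient_id)
    for (i in seq_len(nrow(index_dates))) {
      pid <- index_dates$patient_id[i]
      idx <- index_dates$date[i]
      if (!is.null(cov_by_patient)) {
        iv <- cov_by_patient[[pid]]
        if (!covers_interval(iv, idx - days_before, idx + days_after)) {
          exc[[length(exc) + 1L]] <- data.frame(
            patient_id = pid, index_date = idx,
            reason = sprintf("not continuously insured %d days before through %d days after index",
                             days_before, days_after),
            stringsAsFactors = FALSE)
          next
        }
      }
      alive <- !(pid %in% names(death_date)) || death_date[[pid]] > study_end
      ev <- ev_by_patient[[pid]]
      if (is.null(ev)) ev <- events[0, , drop = FALSE]
      prof <- build_profile(ev, catalog, index_date = idx,
                            days_before = days_before, days_after = days_after,
                            alive_at_period_end = alive,
                            require_distinct_quarters = require_distinct_quarters)
      r <- compute_pedss(prof)
      res[[length(res) + 1L]] <- data.frame(
        patient_id = pid, index_date = idx, pedss = r$pedss,
        fired_clause = r$fired_clause, stringsAsFactors = FALSE)
    }
  }
  empty_res <- data.frame(patient_id = character(0),
                          index_date = as.Date(character(0)),
                          pedss = integer(0), fired_clause = character(0),
                          stringsAsFactors = FALSE)
  empty_exc <- data.frame(patient_id = character(0),
                          index_date = as.Date(character(0)),
                          reason = character(0), stringsAsFactors = FALSE)
  structure(list(
    results = if (length(res)) do.call(rbind, res) else empty_res,
    excluded = if (length(exc)) do.call(rbind, exc) else empty_exc
  ), class = "pedss_batch")
}

# TRUE when the merged coverage intervals contain [from, to] entirely.
covers_interval <- function(intervals, from, to) {
  if (is.null(intervals) || !nrow(intervals)) return(FALSE)
  s <- as.Date(intervals$start); e <- as.Date(intervals$end)
  o <- order(s)
  s <- s[o]; e <- e[o]
  cur_s <- s[1]; cur_e <- e[1]
  merged <- list()
  for (i in seq_along(s)[-1]) {
    if (s[i] <= cur_e + 1) cur_e <- max(cur_e, e[i])
    else { merged[[length(merged) + 1L]] <- c(cur_s, cur_e); cur_s <- s[i]; cur_e <- e[i] }
  }
  merged[[length(merged) + 1L]] <- c(cur_s, cur_e)
  any(vapply(merged, function(m) m[1] <= from && m[2] >= to, logical(1)))
}

#' @export
print.pedss_batch <- function(x, ...) {
  cat("pEDSS batch:", nrow(x$results), "scored record(s),",
      nrow(x$excluded), "excluded\n")
  if (nrow(x$results)) {
    tab <- table(factor(x$results$pedss, levels = 0:9))
    cat("  step distribution:",
        paste(sprintf("%s:%d", names(tab), tab), collapse = " "), "\n")
  }
  invisible(x)
}

#' @export
summary.pedss_batch <- function(object, ...) {
  r <- object$results
  cat("pEDSS batch summary\n")
  cat(sprintf("  records scored: %d (patients: %d), excluded: %d\n",
              nrow(r), length(unique(r$patient_id)), nrow(object$excluded)))
  if (nrow(r))
    cat(sprintf("  mean pEDSS %.2f (SD %.2f), median %.1f, range %d-%d\n",
                mean(r$pedss), stats::sd(r$pedss), stats::median(r$pedss),
                min(r$pedss), max(r$pedss)))
  if (nrow(object$excluded)) {
    cat("  exclusion reasons:\n")
    tab <- table(object$excluded$reason)
    for (nm in names(tab)) cat(sprintf("    %s: %d\n", nm, tab[[nm]]))
  }
  invisible(object)
}

#' @export
as.data.frame.pedss_batch <- function(x, ...) x$results
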