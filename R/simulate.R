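# Synthetic administrative-claims generator. Each simulated patient carries a
# latent true disability step; for every reference EDSS measurement the
# canonical claims evidence of that step is emitted and then degraded by
# severity-dependent capture probabilities, mirroring how mild and moderate
# symptoms are poorly documented in claims while reimbursement-relevant aids
# (wheelchairs, specialty beds) are captured well.

#' Generator configuration
#'
#' Defaults emulate the validation setting: a bimodal step distribution with
#' modes at 1-3 and 6-7; 1-18 reference measurements per patient with mean
#' about 6; diagnosis capture rising with severity (mild 0.25, moderate 0.45,
#' severe 0.85); aid capture of 0.22 for walking sticks, 0.86 for wheelchairs
#' and 0.85 for chair/specialty beds (walking sticks are accessible outside
#' reimbursement, wheelchairs rarely so); and a 0.9 probability that an
#' outpatient diagnosis carries the "confirmed" qualifier. The drug-emission
#' probabilities (also used for fampridine and, on the diagnosis side, bed
#' confinement at the severe tier) are plausible tunable values, not
#' published facts.
#'
#' @param n_patients number of patients.
#' @param seed integer seed; all randomness in [generate_cohort()] flows from
#'   it.
#' @param edss_distribution probability vector over steps 0-9 (must sum to 1).
#' @param measures_range integer range for measurements per patient.
#' @param measures_mean target mean number of measurements per patient.
#' @param dx_capture named probabilities (mild/moderate/severe) that a
#'   symptom's diagnosis evidence appears in claims.
#' @param drug_emission named probabilities (mild/moderate/severe) that a
#'   symptom-associated prescription appears.
#' @param aid_capture named probabilities (walking_stick/wheelchair/chair_bed)
#'   that an aid is billed.
#' @param outpatient_confirmed_prob probability that an outpatient diagnosis
#'   is coded "confirmed" rather than "suspected".
#' @param window_jitter_days events are jittered uniformly within plus/minus
#'   this many days (kept inside the 90-day window).
#' @return list of class `generator_config`.
#' @export
generator_config <- function(n_patients = 100, seed = 1,
                             edss_distribution = c(0.02, 0.15, 0.18, 0.17, 0.09,
                                                   0.06, 0.13, 0.12, 0.05, 0.03),
                             measures_range = c(1L, 18L),
                             measures_mean = 6.2,
                             dx_capture = c(mild = 0.25, moderate = 0.45, severe = 0.85),
                             drug_emission = c(mild = 0.20, moderate = 0.35, severe = 0.60),
                             aid_capture = c(walking_stick = 0.22, wheelchair = 0.86,
                                             chair_bed = 0.85),
                             outpatient_confirmed_prob = 0.9,
                             window_jitter_days = 30) {
  probs <- c(dx_capture, drug_emission, aid_capture, outpatient_confirmed_prob)
  if (any(probs < 0 | probs > 1)) stop("capture/emission probabilities must be in [0, 1]")
  if (length(edss_distribution) != 10L || abs(sum(edss_distribution) - 1) > 1e-8 ||
      any(edss_distribution < 0))
    stop("edss_distribution must be 10 non-negative probabilities over steps 0-9 summing to 1")
  stopifnot(n_patients >= 0, measures_range[1] >= 1,
            measures_range[2] >= measures_range[1],
            window_jitter_days >= 0, window_jitter_days <= 90)
  structure(list(n_patients = as.integer(n_patients), seed = as.integer(seed),
                 edss_distribution = edss_distribution,
                 measures_range = as.integer(measures_range),
                 measures_mean = measures_mean,
                 dx_capture = dx_capture, drug_emission = drug_emission,
                 aid_capture = aid_capture,
                 outpatient_confirmed_prob = outpatient_confirmed_prob,
                 window_jitter_days = window_jitter_days),
            class = "generator_config")
}

# Canonical evidence for a step, structured as thinnable units. Each unit is
# dropped (or kept) as a whole by the generator: a diagnosis unit is the
# confirmed-outpatient pair that qualifies one symptom, an aid/prescription
# unit is a single event.
canonical_units <- function(step, index_date, catalog, patient_id = "P1") {
  stopifnot(step %in% 0:9)
  e <- catalog$entries
  dx <- e[e$evidence_kind == "diagnosis", , drop = FALSE]
  first_code <- function(sev) {
    sub <- dx[dx$severity == sev, , drop = FALSE]
    codes <- sub$code[!duplicated(sub$symptom_id)]
    if (!length(codes))
      stop("catalog lacks a ", sev, "-tier diagnosis code required for step ", step)
    codes
  }
  ev <- function(code, code_system, setting, qualifier, offset) {
    data.frame(patient_id = patient_id, date = index_date + offset,
               code_system = code_system, code = code, setting = setting,
               qualifier = qualifier, stringsAsFactors = FALSE)
  }
  dx_pair <- function(code, kind, severity) {
    list(kind = kind, severity = severity,
         events = rbind(ev(code, "ICD10GM", "outpatient_dx", "confirmed", -7L),
                        ev(code, "ICD10GM", "outpatient_dx", "confirmed", 7L)))
  }
  sp <- catalog$special
  units <- switch(as.character(step),
    "0" = list(),
    "1" = list(dx_pair(first_code("mild")[1], "dx", "mild")),
    "2" = lapply(first_code("mild")[1:2], dx_pair, kind = "dx", severity = "mild"),
    "3" = list(dx_pair(first_code("moderate")[1], "dx", "moderate")),
    "4" = list(list(kind = "fampridine", severity = "severe",
                    events = ev(sp$fampridine_atc[1], "ATC", "prescription", "none", 0L))),
    "5" = list(dx_pair(first_code("severe")[1], "dx", "severe")),
    "6" = list(list(kind = "walking_stick", severity = NA,
                    events = ev(sp$walking_stick_aid[1], "AID", "aid", "none", 0L))),
    "7" = list(list(kind = "wheelchair", severity = NA,
                    events = ev(paste0(sp$wheelchair_aid[1], ".04"), "AID", "aid",
                                "none", 0L))),
    "8" = list(list(kind = "chair_bed", severity = NA,
                    events = ev(sp$chair_bed_aid[1], "AID", "aid", "none", 0L))),
    "9" = list(dx_pair(sp$bed_confinement_icd[1], "bed_confinement", "severe")))
  if (step == 2 && length(first_code("mild")) < 2L)
    stop("catalog lacks two distinct mild-tier symptoms required for step 2")
  units
}

#' Canonical claims events for a disability step
#'
#' The constructive inverse of the cascade: a minimal event set, placed inside
#' the assessment window around `index_date`, that the engine maps back to
#' exactly `step`. Qualified diagnoses are emitted as a pair of confirmed
#' outpatient events on two distinct dates; aids and fampridine as single
#' events (step 9 assumes the alive-at-period-end flag is handled by the
#' caller).
#'
#' @param step integer 0-9.
#' @param index_date a `Date`.
#' @param catalog a validated `symptom_catalog` with at least one diagnosis
#'   code per severity tier and the full special code set.
#' @param patient_id id to stamp on the events.
#' @return data.frame of claims events (zero rows for step 0).
#' @export
canonical_events <- function(step, index_date, catalog, patient_id = "P1") {
  validate_catalog(catalog)
  units <- canonical_units(step, index_date, catalog, patient_id)
  if (!length(units)) return(empty_events())
  do.call(rbind, lapply(units, `[[`, "events"))
}

empty_events <- function() {
  data.frame(patient_id = character(0), date = as.Date(character(0)),
             code_system = character(0), code = character(0),
             setting = character(0), qualifier = character(0),
             stringsAsFactors = FALSE)
}

#' Generate a linked synthetic cohort
#'
#' For each patient, draws a latent disability step from the configured
#' distribution and a number of reference EDSS measurements; every
#' measurement emits the true score (step plus possibly a half point) and the
#' canonical claims evidence of the step, which is then degraded: diagnosis
#' units are dropped with probability 1 - capture for their severity,
#' outpatient qualifiers are set to "suspected" with probability
#' 1 - `outpatient_confirmed_prob`, aids and fampridine are dropped at their
#' own capture rates, and event dates are jittered inside the window. Full
#' insurance coverage spanning all windows is emitted per patient; the deaths
#' table is empty by default (the generator exercises living patients, as the
#' cascade is designed for them).
#'
#' Fully reproducible: two runs with the same config are identical, and the
#' caller's RNG state is left untouched.
#'
#' @param config a [generator_config()].
#' @param catalog catalog used for code emission (default [default_catalog()]).
#' @return list of class `pedss_simulation` with data.frames `measures`
#'   (patient_id, date, score, true_step), `events`, `coverage`, `deaths`.
#' @export
generate_cohort <- function(config = generator_config(),
                            catalog = default_catalog()) {
  stopifnot(inherits(config, "generator_config"))
  validate_catalog(catalog)
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(config$seed)

  measures <- list(); events <- list(); coverage <- list()
  origin <- as.Date("2016-01-01")
  jit <- config$window_jitter_days
  for (i in seq_len(config$n_patients)) {
    pid <- sprintf("SIM%04d", i)
    step <- sample(0:9, 1, prob = config$edss_distribution)
    n_meas <- min(config$measures_range[2],
                  max(config$measures_range[1],
                      1L + stats::rpois(1, config$measures_mean - 1)))
    dates <- origin + sample(0:365, 1) + cumsum(c(0L, sample(90:240, n_meas - 1,
                                                             replace = TRUE)))
    for (d in seq_along(dates)) {
      idx <- dates[d]
      half <- if (step %in% 1:8) sample(c(0, 0.5), 1) else 0
      measures[[length(measures) + 1L]] <- data.frame(
        patient_id = pid, date = idx, score = step + half, true_step = step,
        stringsAsFactors = FALSE)
      units <- canonical_units(step, idx, catalog, pid)
      for (u in units) {
        p_keep <- switch(u$kind,
                         dx = config$dx_capture[[u$severity]],
                         bed_confinement = config$dx_capture[["severe"]],
                         fampridine = config$drug_emission[["severe"]],
                         walking_stick = config$aid_capture[["walking_stick"]],
                         wheelchair = config$aid_capture[["wheelchair"]],
                         chair_bed = config$aid_capture[["chair_bed"]])
        if (stats::runif(1) > p_keep) next
        uev <- u$events
        out <- uev$setting == "outpatient_dx"
        if (any(out)) {
          flip <- stats::runif(sum(out)) > config$outpatient_confirmed_prob
          uev$qualifier[out][flip] <- "suspected"
        }
        if (jit > 0) {
          shift <- sample(seq(-jit, jit), nrow(uev), replace = TRUE)
          uev$date <- pmin(pmax(uev$date + shift, idx - 90), idx + 90)
        }
        events[[length(events) + 1L]] <- uev
      }
    }
    coverage[[length(coverage) + 1L]] <- data.frame(
      patient_id = pid, start = min(dates) - 120, end = max(dates) + 120,
      stringsAsFactors = FALSE)
  }
  structure(list(
    measures = if (length(measures)) do.call(rbind, measures) else
      data.frame(patient_id = character(0), date = as.Date(character(0)),
                 score = numeric(0), true_step = integer(0)),
    events = if (length(events)) do.call(rbind, events) else empty_events(),
    coverage = if (length(coverage)) do.call(rbind, coverage) else
      data.frame(patient_id = character(0), start = as.Date(character(0)),
                 end = as.Date(character(0))),
    deaths = data.frame(patient_id = character(0), date = as.Date(character(0)),
                        stringsAsFactors = FALSE)
  ), class = "pedss_simulation")
}

#' @export
print.pedss_simulation <- function(x, ...) {
  cat("Synthetic claims cohort:",
      length(unique(x$measures$patient_id)), "patient(s),",
      nrow(x$measures), "reference measurement(s),",
      nrow(x$events), "claims event(s)\n")
  invisible(x)
}
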