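# Shared fixture builders for the test suite. Everything is generated in
# code; no binary fixtures.

IDX <- as.Date("2017-06-01")

make_event <- function(code, code_system = "ICD10GM", setting = "outpatient_dx",
                       qualifier = if (setting == "outpatient_dx") "confirmed" else "none",
                       date = IDX, patient_id = "P1") {
  data.frame(patient_id = patient_id, date = as.Date(date),
             code_system = code_system, code = code, setting = setting,
             qualifier = qualifier, stringsAsFactors = FALSE)
}

# a qualified diagnosis: two confirmed outpatient events on distinct dates
dx_pair <- function(code, patient_id = "P1", dates = IDX + c(-7, 7)) {
  rbind(make_event(code, date = dates[1], patient_id = patient_id),
        make_event(code, date = dates[2], patient_id = patient_id))
}

bind_events <- function(...) do.call(rbind, list(...))

# profile built directly from component values, bypassing claims aggregation,
# for cascade-only tests
raw_profile <- function(mild = 0, moderate = 0, severe = 0,
                        mild_drugs = 0, moderate_drugs = 0, severe_drugs = 0,
                        fampridine = FALSE, gait = FALSE, stick = FALSE,
                        wheelchair = FALSE, para = FALSE, tetra = FALSE,
                        chair_bed = FALSE, bed_conf = FALSE, alive = TRUE) {
  structure(list(
    mild_dx_symptoms = if (mild) paste0("mi", seq_len(mild)) else character(0),
    moderate_dx_symptoms = if (moderate) paste0("mo", seq_len(moderate)) else character(0),
    severe_dx_symptoms = if (severe) paste0("se", seq_len(severe)) else character(0),
    mild_drug_count = as.integer(mild_drugs),
    moderate_drug_count = as.integer(moderate_drugs),
    severe_drug_count = as.integer(severe_drugs),
    fampridine = fampridine, gait_disturbance_dx = gait,
    walking_stick = stick, wheelchair = wheelchair,
    paraplegia_dx = para, tetraplegia_dx = tetra,
    chair_bed = chair_bed, bed_confinement_dx = bed_conf,
    alive_at_period_end = alive), class = "symptom_profile")
}

# Independent cascade oracle: evaluates every step predicate separately and
# returns the maximum satisfied step (vectorized). Written from the step
# definitions, deliberately not sharing code with the engine.
oracle_step <- function(mild, moderate, severe, mild_drugs, moderate_drugs,
                        severe_drugs, fampridine, gait, stick, wheelchair,
                        para, tetra, chair_bed, bed_conf, alive) {
  p1 <- (mild == 1 | mild_drugs >= 1) & !fampridine
  p2 <- mild >= 2 & !fampridine
  p3 <- ((moderate >= 1 & moderate <= 2) |
           (moderate_drugs >= 1 & moderate_drugs <= 2)) & !fampridine
  p4 <- moderate >= 3 | moderate_drugs >= 3 | gait |
    (fampridine & moderate == 0 & severe == 0)
  p5 <- severe >= 1 | severe_drugs >= 1 | moderate >= 4 |
    (fampridine & (moderate >= 1 | severe >= 1))
  p6 <- stick
  p7 <- wheelchair | para
  p8 <- chair_bed | tetra
  p9 <- bed_conf & alive
  pmax(1L * p1, 2L * p2, 3L * p3, 4L * p4, 5L * p5, 6L * p6, 7L * p7,
       8L * p8, 9L * p9)
}

# the full count grid of the exhaustive cascade check (fixed across tests)
cascade_count_grid <- function() {
  expand.grid(mild = 0:5, moderate = 0:5, severe = 0:5,
              mild_drugs = 0:4, moderate_drugs = 0:4, severe_drugs = 0:4,
              KEEP.OUT.ATTRS = FALSE)
}

# published one-vs-rest validation metrics (2-dp), row order matching
# validation_counts()
published_metrics <- function() {
  m <- rbind(
    c(0.72, 0.65, 0.31, 0.91, 0.66, 0.24, 0.43),
    c(0.17, 0.97, 0.67, 0.80, 0.79, 0.20, 0.28),
    c(0.30, 0.86, 0.44, 0.77, 0.71, 0.18, 0.36),
    c(0.09, 0.93, 0.14, 0.89, 0.84, 0.03, 0.11),
    c(0.25, 0.87, 0.07, 0.97, 0.84, 0.05, 0.11),
    c(0.11, 0.99, 0.50, 0.92, 0.91, 0.15, 0.18),
    c(0.57, 0.95, 0.44, 0.97, 0.92, 0.46, 0.50),
    c(0.00, 0.98, 0.00, 0.99, 0.97, -0.01, 0.00),
    c(0.85, 0.75, 0.88, 0.71, 0.82, 0.59, 0.87),
    c(0.53, 0.85, 0.38, 0.91, 0.80, 0.33, 0.44),
    c(0.65, 0.98, 0.85, 0.93, 0.92, 0.69, 0.73),
    c(0.98, 0.65, 0.93, 0.85, 0.92, 0.69, 0.95),
    c(0.65, 0.98, 0.85, 0.93, 0.92, 0.69, 0.73))
  colnames(m) <- c("sensitivity", "specificity", "ppv", "npv", "accuracy",
                   "kappa", "f1")
  m
}

# reconstruct multiclass truth/pred label pairs from one-vs-rest counts for a
# single target class (tp as target/target, fn as target/other, ...)
labels_from_counts <- function(tp, tn, fp, fn, target = "pos", other = "neg") {
  list(truth = c(rep(target, tp + fn), rep(other, fp + tn)),
       pred = c(rep(target, tp), rep(other, fn), rep(target, fp), rep(other, tn)))
}
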