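CAT <- default_catalog()

test_that("assessment window is inclusive on both 90-day boundaries", {
  ev <- bind_events(make_event("H55", date = IDX - 90),
                    make_event("H55", date = IDX + 90),
                    make_event("H55", date = IDX + 91),
                    make_event("H55", date = IDX - 91))
  kept <- select_window_events(ev, IDX)
  expect_identical(kept$date, c(IDX - 90, IDX + 90))
  expect_identical(nrow(select_window_events(ev[0, ], IDX)), 0L)
})

test_that("diagnosis qualification needs one inpatient or two confirmed outpatient dates", {
  expect_true(qualify_diagnosis(make_event("G82.12", setting = "inpatient_dx"),
                                "G82.12"))
  same_day <- rbind(make_event("R26.0"), make_event("R26.0"))
  expect_false(qualify_diagnosis(same_day, "R26.0"))
  expect_true(qualify_diagnosis(dx_pair("R26.0"), "R26.0"))
  mixed <- rbind(make_event("R26.0", date = IDX - 7),
                 make_event("R26.0", date = IDX + 7, qualifier = "suspected"))
  expect_false(qualify_diagnosis(mixed, "R26.0"))
  # optional stricter reading: distinct calendar quarters
  same_quarter <- dx_pair("R26.0", dates = as.Date(c("2017-04-03", "2017-05-10")))
  expect_true(qualify_diagnosis(same_quarter, "R26.0"))
  expect_false(qualify_diagnosis(same_quarter, "R26.0",
                                 require_distinct_quarters = TRUE))
  cross_quarter <- dx_pair("R26.0", dates = as.Date(c("2017-03-20", "2017-04-10")))
  expect_true(qualify_diagnosis(cross_quarter, "R26.0",
                                require_distinct_quarters = TRUE))
})

test_that("profiles set special flags and severity sets from windowed claims", {
  p <- build_profile(make_event("18.51.02", "AID", "aid"), CAT, IDX)
  expect_true(p$wheelchair)
  expect_false(p$walking_stick)

  p <- build_profile(make_event("N07XX07", "ATC", "prescription"), CAT, IDX)
  expect_true(p$fampridine)
  expect_identical(length(p$mild_dx_symptoms) + length(p$moderate_dx_symptoms) +
                     length(p$severe_dx_symptoms), 0L)

  p <- build_profile(make_event("G82.42", setting = "inpatient_dx"), CAT, IDX)
  expect_true(p$tetraplegia_dx)
  expect_false(p$paraplegia_dx)

  # gait disturbance is a flag, never a moderate symptom
  p <- build_profile(dx_pair("R26.1"), CAT, IDX)
  expect_true(p$gait_disturbance_dx)
  expect_identical(length(p$moderate_dx_symptoms), 0L)

  # prescriptions count distinct codes per tier without a confirmation rule
  p <- build_profile(bind_events(make_event("M03BX01", "ATC", "prescription"),
                                 make_event("M03BX01", "ATC", "prescription"),
                                 make_event("G04BD04", "ATC", "prescription")),
                     CAT, IDX)
  expect_identical(p$moderate_drug_count, 2L)
})

test_that("a symptom qualifying at several tiers is counted once, at the highest", {
  two_tier <- rbind(
    catalog_entry("R29.8", "ICD10GM", "prefix", "sym", "pyramidal", "mild", "diagnosis"),
    catalog_entry("G83.9", "ICD10GM", "prefix", "sym", "pyramidal", "moderate", "diagnosis"))
  cat2 <- symptom_catalog(two_tier)
  p <- build_profile(bind_events(dx_pair("R29.8"), dx_pair("G83.9")), cat2, IDX)
  expect_identical(p$mild_dx_symptoms, character(0))
  expect_identical(p$moderate_dx_symptoms, "sym")
})

test_that("cascade returns the published step for the anchor cases", {
  step_of <- function(...) compute_pedss(raw_profile(...))$pedss
  expect_identical(step_of(), 0L)
  expect_identical(step_of(fampridine = TRUE), 4L)
  expect_identical(step_of(wheelchair = TRUE, tetra = TRUE), 8L)
  expect_identical(step_of(moderate = 4), 5L)
  expect_identical(step_of(mild = 2), 2L)
  expect_identical(step_of(mild = 2, fampridine = TRUE), 4L)
  expect_identical(step_of(moderate = 2), 3L)
  expect_identical(step_of(moderate = 3), 4L)
  expect_identical(step_of(gait = TRUE), 4L)
  expect_identical(step_of(stick = TRUE), 6L)
  expect_identical(step_of(para = TRUE), 7L)
  expect_identical(step_of(bed_conf = TRUE), 9L)
  expect_identical(step_of(bed_conf = TRUE, alive = FALSE), 0L)
  expect_identical(step_of(fampridine = TRUE, moderate = 1), 5L)
  expect_identical(step_of(mild_drugs = 2), 1L)
  expect_match(compute_pedss(raw_profile(stick = TRUE))$fired_clause, "walking stick")
})

test_that("cascade equals the independent max-of-predicates oracle on random profiles", {
  set.seed(77)
  for (i in 1:300) {
    args <- list(mild = sample(0:5, 1), moderate = sample(0:5, 1),
                 severe = sample(0:5, 1), mild_drugs = sample(0:4, 1),
                 moderate_drugs = sample(0:4, 1), severe_drugs = sample(0:4, 1),
                 fampridine = sample(c(TRUE, FALSE), 1),
                 gait = sample(c(TRUE, FALSE), 1),
                 stick = sample(c(TRUE, FALSE), 1),
                 wheelchair = sample(c(TRUE, FALSE), 1),
                 para = sample(c(TRUE, FALSE), 1),
                 tetra = sample(c(TRUE, FALSE), 1),
                 chair_bed = sample(c(TRUE, FALSE), 1),
                 bed_conf = sample(c(TRUE, FALSE), 1),
                 alive = sample(c(TRUE, FALSE), 1))
    expect_identical(compute_pedss(do.call(raw_profile, args))$pedss,
                     as.integer(do.call(oracle_step, args)))
  }
})

test_that("adding ambulation aids never lowers the step below the aid's floor", {
  set.seed(78)
  for (i in 1:100) {
    base <- list(mild = sample(0:5, 1), moderate = sample(0:5, 1),
                 severe = sample(0:3, 1), moderate_drugs = sample(0:4, 1),
                 fampridine = sample(c(TRUE, FALSE), 1),
                 gait = sample(c(TRUE, FALSE), 1),
                 stick = sample(c(TRUE, FALSE), 1),
                 bed_conf = FALSE, alive = TRUE)
    with_wc <- compute_pedss(do.call(raw_profile, c(base, wheelchair = TRUE)))$pedss
    expect_gte(with_wc, 7L)
    with_cb <- compute_pedss(do.call(raw_profile, c(base, chair_bed = TRUE)))$pedss
    expect_gte(with_cb, 8L)
  }
})

test_that("events outside the window never influence the profile", {
  inside <- dx_pair("R27.0")
  outside <- bind_events(make_event("18.51.02", "AID", "aid", date = IDX + 120),
                         dx_pair("R13.9", dates = IDX + c(95, 110)),
                         make_event("N07XX07", "ATC", "prescription",
                                    date = IDX - 100))
  p1 <- build_profile(inside, CAT, IDX)
  p2 <- build_profile(bind_events(inside, outside), CAT, IDX)
  expect_identical(p1, p2)
  expect_identical(compute_pedss(p2)$pedss, 3L)
})

test_that("batch computation is deterministic, independent across index dates, and flags missing coverage", {
  ev <- bind_events(dx_pair("R27.0", "A", as.Date(c("2017-05-25", "2017-06-08"))),
                    make_event("18.50.01", "AID", "aid", patient_id = "A",
                               date = as.Date("2018-06-01")))
  idx <- data.frame(patient_id = "A",
                    date = as.Date(c("2017-06-01", "2018-06-01")))
  b1 <- compute_pedss_batch(ev, idx, CAT)
  expect_identical(b1$results$pedss, c(3L, 7L))
  b2 <- compute_pedss_batch(ev, idx, CAT)
  expect_identical(b1, b2)

  cov <- data.frame(patient_id = "A", start = as.Date("2017-05-01"),
                    end = as.Date("2019-01-01"))
  b3 <- compute_pedss_batch(ev, idx, CAT, coverage = cov)
  expect_identical(nrow(b3$results), 1L)  # first index lacks 90 days before
  expect_identical(b3$excluded$index_date, as.Date("2017-06-01"))
  expect_match(b3$excluded$reason, "insured")

  empty <- compute_pedss_batch(ev[0, ], idx[0, ], CAT)
  expect_identical(nrow(empty$results), 0L)
  expect_identical(nrow(empty$excluded), 0L)
})

test_that("death before study end drops the bed-confinement step to 8", {
  ev <- bind_events(dx_pair("R26.3", "D"), make_event("19.40.01", "AID", "aid",
                                                      patient_id = "D"))
  idx <- data.frame(patient_id = "D", date = IDX)
  alive <- compute_pedss_batch(ev, idx, CAT, study_end = as.Date("2018-12-31"))
  expect_identical(alive$results$pedss, 9L)
  dead <- compute_pedss_batch(ev, idx, CAT, study_end = as.Date("2018-12-31"),
                              deaths = data.frame(patient_id = "D",
                                                  date = as.Date("2017-10-01")))
  expect_identical(dead$results$pedss, 8L)
})
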