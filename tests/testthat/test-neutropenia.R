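test_that("daily grid reproduces measured days and carries forward", {
  g <- daily_grid(0:5, c(1, 2, 3, 4, 5, 6), c(0, 5))
  expect_equal(g$value, 1:6)
  expect_true(all(g$provenance == "measured"))

  g2 <- daily_grid(c(0, 5), c(0.3, 0.8), c(0, 5))
  expect_equal(g2$value, c(rep(0.3, 5), 0.8))
  expect_equal(g2$provenance,
               c("measured", rep("carried_forward", 4), "measured"))

  g3 <- daily_grid(c(3, 6), c(1, 2), c(0, 10))
  expect_true(all(is.na(g3$value[1:3])))
  expect_equal(g3$provenance[1:3], rep("unknown", 3))
  expect_error(daily_grid(integer(0), numeric(0), c(0, 5)), "empty")
  expect_error(daily_grid(c(2, 1), c(1, 2), c(0, 5)), "increasing")
})

test_that("severe-neutropenia day counts follow the carried-forward rule", {
  expect_equal(severe_neutropenia_days(c(0, 10, 20), c(1, 2, 0.8)), 0)
  # below threshold on days 2-10 inclusive, at/above elsewhere
  day <- 0:60
  val <- rep(1, 61); val[day >= 2 & val & day <= 10] <- 0.4
  expect_equal(severe_neutropenia_days(day, val), 9)
  # sparse series: day 0 severe, day 5 recovered -> 5 carried severe days
  expect_equal(severe_neutropenia_days(c(0, 5), c(0.4, 0.9)), 5)
  # measured-days-only sensitivity mode
  expect_equal(severe_neutropenia_days(c(0, 5), c(0.4, 0.9),
                                       mode = "measured"), 1)
  expect_error(severe_neutropenia_days(c(70, 80), c(1, 1)), "window")
})

test_that("phenotype classification follows the precedence rules", {
  # continuous severe neutropenia for >= 14 days: aplastic
  ap <- classify_neutrophil_phenotype(0:14, rep(0.2, 15))
  expect_equal(ap$phenotype, "aplastic")

  # always recovered: quick
  q <- classify_neutrophil_phenotype(seq(0, 100, 5), rep(2, 21))
  expect_equal(q$phenotype, "quick")
  expect_false(q$low_confidence)

  # recovery > 1.5 then dip < 1.0 after day 21: intermittent
  im <- classify_neutrophil_phenotype(c(0, 10, 25, 30),
                                      c(2.0, 1.6, 0.8, 1.8))
  expect_equal(im$phenotype, "intermittent")

  # dip before day 22 does not qualify: quick
  early <- classify_neutrophil_phenotype(c(0, 10, 15, 20, 30),
                                         c(2.0, 1.6, 0.8, 1.4, 1.8))
  expect_equal(early$phenotype, "quick")

  # aplastic takes precedence over a later intermittent pattern
  both <- classify_neutrophil_phenotype(c(0:14, 18, 25, 30),
                                        c(rep(0.3, 15), 1.8, 0.7, 1.9))
  expect_equal(both$phenotype, "aplastic")

  # short follow-up: classified but low confidence
  short <- classify_neutrophil_phenotype(c(0, 5, 10), c(2, 2, 2))
  expect_true(short$low_confidence)
})

test_that("run-length metrics match the hand trace", {
  co <- ht_cohort(
    patient_row("A"),
    lab_rows("A", c(0, 3, 9, 10, 40, 41, 60),
             c(0.4, 0.05, 0.09, 1.2, 0.4, 0.9, 2)))
  m <- neutropenia_metrics(co)
  # ANC < 0.1 carried over days 3-9 = 7 consecutive days
  expect_true(m$protracted_profound)
  expect_true(m$profound_d0_100)
  expect_true(m$protracted_severe)     # days 0-9 severe
  expect_true(m$severe_d0_30)
  expect_true(m$severe_d31_100)        # day 40 dip
  expect_true(m$prolonged)             # 0.4 at day 40 (also < 1.0)
  expect_equal(m$severe_days_d0_60, 10 + 1)

  co2 <- ht_cohort(patient_row("B"),
                   lab_rows("B", c(0, 20, 40, 60), c(2, 3, 2, 2)))
  m2 <- neutropenia_metrics(co2)
  expect_equal(m2$severe_days_d0_60, 0)
  expect_equal(m2$phenotype, "quick")
  expect_false(any(unlist(m2[, c("severe_d0_30", "severe_d31_100",
                                 "protracted_severe", "profound_d0_100",
                                 "protracted_profound", "prolonged")])))
})

test_that("windowed severity separates days 0-30 from 31-100", {
  co <- ht_cohort(patient_row("A"),
                  lab_rows("A", c(0, 39, 40, 41), c(2, 2, 0.4, 2)))
  m <- neutropenia_metrics(co)
  expect_false(m$severe_d0_30)
  expect_true(m$severe_d31_100)
})

test_that("run-length and carried-forward logic matches brute force on random grids", {
  set.seed(42)
  for (rep in 1:300) {
    nd <- sample(3:12, 1)
    day <- sort(sample(0:60, nd))
    value <- round(stats::rlnorm(nd, log(0.8), 1), 2)
    win <- c(0, sample(40:80, 1))
    got <- daily_grid(day, value, win)$value
    want <- locf_oracle(day, value, win)
    expect_identical(got, want)
    # severe run lengths against the explicit scan
    sev <- got < 0.5
    expect_identical(hematotox:::.max_run(sev), max_run_oracle(sev))
    if (any(day <= 60))
      expect_equal(severe_neutropenia_days(day, value),
                   sum(locf_oracle(day, value, c(0, 60)) < 0.5,
                       na.rm = TRUE))
  }
})

test_that("metrics are invariant to denser sampling of the same step function", {
  day <- c(0, 4, 9, 21, 30)
  value <- c(0.3, 0.4, 1.8, 0.9, 2.2)
  co1 <- ht_cohort(patient_row("A"), lab_rows("A", day, value))
  # re-sample the implied step function every day
  grid <- daily_grid(day, value, c(0, 100))
  co2 <- ht_cohort(patient_row("A"), lab_rows("A", grid$day, grid$value))
  m1 <- neutropenia_metrics(co1)
  m2 <- neutropenia_metrics(co2)
  for (col in c("severe_days_d0_60", "phenotype", "severe_d0_30",
                "severe_d31_100", "protracted_severe", "profound_d0_100",
                "protracted_profound", "prolonged"))
    expect_identical(m1[[col]], m2[[col]])
})

test_that("severe-day counts never increase when ANC rises pointwise", {
  set.seed(7)
  for (rep in 1:50) {
    nd <- sample(4:10, 1)
    day <- sort(sample(0:60, nd))
    value <- round(stats::rlnorm(nd, log(0.6), 0.8), 2)
    up <- value + stats::runif(nd, 0, 0.5)
    expect_lte(severe_neutropenia_days(day, up),
               severe_neutropenia_days(day, value))
  }
})

test_that("cytopenia flags follow thresholds, transfusions and evaluability", {
  co <- tiny_cohort()
  fl <- cytopenia_flags(co)
  b <- fl[fl$patient_id == "B", ]
  expect_true(b$severe_thrombocytopenia_d0_30)   # platelets 40 at day 0
  expect_true(b$severe_anemia_d0_30)             # pRBC transfusion day 12
  expect_true(b$severe_anemia_d31_100)           # Hb 7.5 carried into day 31+
  a <- fl[fl$patient_id == "A", ]
  expect_false(a$severe_thrombocytopenia_d0_30)
  expect_false(a$severe_anemia_d0_30)

  # no platelet data in a window -> not evaluable, distinct from FALSE
  co2 <- ht_cohort(patient_row("D"),
                   rbind(lab_rows("D", c(0, 10), c(2, 2)),
                         lab_rows("D", c(0, 10), c(120, 130),
                                  analyte = "platelets"),
                         lab_rows("D", c(0, 10), c(11, 11),
                                  analyte = "hemoglobin", unit = "g_dl")))
  fl2 <- cytopenia_flags(co2)
  expect_false(fl2$severe_thrombocytopenia_d0_30)
  expect_true(is.na(fl2$severe_thrombocytopenia_d31_100))
})

test_that("transfusion in window marks severe anemia even with normal Hb", {
  co <- ht_cohort(patient_row("A"),
                  rbind(lab_rows("A", c(0, 50), c(2, 2)),
                        lab_rows("A", c(0, 50), c(11, 12),
                                 analyte = "hemoglobin", unit = "g_dl")),
                  events = data.frame(patient_id = "A", day = 40L,
                                      event_type = "prbc_transfusion"))
  fl <- cytopenia_flags(co)
  expect_false(fl$severe_anemia_d0_30)
  expect_true(fl$severe_anemia_d31_100)
})
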