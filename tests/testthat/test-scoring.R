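test_that("component scores follow the published bins and edge conventions", {
  cases <- list(
    # component, value, expected points
    list("heart_rate", 120, 2), list("heart_rate", 100, 2),
    list("heart_rate", 160, 2), list("heart_rate", 161, 1),
    list("heart_rate", 99, 0), list("heart_rate", 0, 0),
    list("mean_bp", 29.9, 0), list("mean_bp", 30, 1),
    list("mean_bp", 39, 1), list("mean_bp", 39.1, 2),
    list("temp_rectal", 35.9, 0), list("temp_rectal", 36, 1),
    list("temp_rectal", 36.4, 1), list("temp_rectal", 36.5, 2),
    list("temp_rectal", 37.5, 2),
    list("crt_sec", 2.9, 2), list("crt_sec", 3, 1), list("crt_sec", 5, 1),
    list("crt_sec", 5.1, 0),
    list("glucose_first", 39, 0), list("glucose_first", 40, 1),
    list("glucose_first", 50, 1), list("glucose_first", 60, 1),
    list("glucose_first", 61, 2),
    list("spo2", 84, 0), list("spo2", 85, 1), list("spo2", 92, 1),
    list("spo2", 93, 2),
    list("resp_effort", "apnea_or_grunting", 0),
    list("resp_effort", "tachypnea", 1), list("resp_effort", "normal", 2))
  for (cs in cases)
    expect_identical(score_sns_component(cs[[1]], cs[[2]]), as.integer(cs[[3]]),
                     label = paste(cs[[1]], cs[[2]]))
})

test_that("aliases work and the unscored findings are configurable", {
  expect_identical(score_sns_component("blood_glucose", 50), 1L)
  expect_identical(score_sns_component("temperature", 36.5), 2L)
  expect_identical(score_sns_component("capillary_refill", 4), 1L)
  expect_identical(score_sns_component("respiratory_effort", "normal"), 2L)
  # hyperthermia and non-apneic low rate default to 1 point, overridable
  expect_identical(score_sns_component("temp_rectal", 38.5), 1L)
  expect_identical(score_sns_component("resp_effort", "low_rate_other"), 1L)
  cfg <- sns_config(hyperthermia_score = 0, low_rate_score = 0)
  expect_identical(score_sns_component("temp_rectal", 38.5, cfg), 0L)
  expect_identical(score_sns_component("resp_effort", "low_rate_other", cfg), 0L)
})

test_that("component scoring rejects bad input naming the component", {
  expect_error(score_sns_component("ph", 7.3), "unknown")
  expect_error(score_sns_component("heart_rate", NaN), "heart_rate")
  expect_error(score_sns_component("heart_rate", Inf), "heart_rate")
  expect_error(score_sns_component("temp_rectal", 20), "temp_rectal")
  expect_error(score_sns_component("spo2", 105), "sanity range")
  expect_error(score_sns_component("resp_effort", "gasping"), "resp_effort")
})

test_that("SNS totals: extremes and a mixed admission", {
  expect_identical(score_sns(best_vitals()), 14L)
  expect_identical(score_sns(worst_vitals()), 0L)
  mixed <- list(resp_effort = "apnea_or_grunting", heart_rate = 170,
                mean_bp = 35, temp_rectal = 36.2, crt_sec = 4,
                glucose_first = 35, spo2 = 90)
  expect_identical(score_sns(mixed), 5L)  # 0+1+1+1+1+0+1
})

test_that("SNS refuses incomplete records rather than imputing", {
  v <- best_vitals()
  v$spo2 <- NULL
  expect_error(score_sns(v), "spo2")
  v2 <- best_vitals()
  v2$mean_bp <- NA_real_
  expect_error(score_sns(v2), "mean_bp")
})

test_that("GA/BW/AT point tables and their bin edges", {
  expect_equal(unlist(msnsat_points(30, 1200, 20)), c(ga_points = 0,
               bw_points = 0, at_points = 0))
  expect_equal(unlist(msnsat_points(38, 3100, 3)), c(ga_points = 2,
               bw_points = 2, at_points = 3))
  expect_equal(unlist(msnsat_points(33, 1600, 8)), c(ga_points = 1,
               bw_points = 1, at_points = 1))
  # edges: 32 and 37 weeks, 1500 and 2500 g, 6 and 12 h
  expect_equal(msnsat_points(c(31, 32, 36, 37), 2000, 1)$ga_points,
               c(0L, 1L, 1L, 2L))
  expect_equal(msnsat_points(35, c(1499, 1500, 2499, 2500), 1)$bw_points,
               c(0L, 1L, 1L, 2L))
  expect_equal(msnsat_points(35, 2000, c(0, 5.9, 6, 11.9, 12, 30))$at_points,
               c(3L, 3L, 1L, 1L, 0L, 0L))
  expect_error(msnsat_points(35, 2000, -1), "non-negative")
  expect_error(msnsat_points(50, 2000, 1), "ga_weeks")
})

test_that("admission-time category and risk strata", {
  expect_equal(as.character(at_category(c(3, 8, 20))),
               c("early", "intermediate", "late"))
  expect_equal(as.character(at_category(c(5.99, 6, 11.99, 12))),
               c("early", "intermediate", "intermediate", "late"))
  expect_error(at_category(-0.1), "non-negative")
  expect_equal(as.character(risk_stratum(c(0, 7, 8, 10, 15, 16, 21))),
               c("high", "high", "intermediate", "intermediate",
                 "intermediate", "low", "low"))
  expect_error(risk_stratum(22), "\\[0, 21\\]")
  expect_error(risk_stratum(-1), "\\[0, 21\\]")
})

test_that("full MSNS-AT breakdown: extremes and a worked mid-range case", {
  best <- make_record(ga_weeks = 40, bw_grams = 3500, at_hours = 2)
  sb <- score_msnsat(best)
  expect_identical(sb$msnsat_total, 21L)  # 14 + 2 + 2 + 3
  expect_equal(as.character(sb$risk_stratum), "low")
  worst <- make_record(ga_weeks = 28, bw_grams = 900, at_hours = 24,
                       vitals = worst_vitals())
  expect_identical(score_msnsat(worst)$msnsat_total, 0L)
  mid <- make_record(ga_weeks = 33, bw_grams = 1600, at_hours = 8,
                     vitals = list(resp_effort = "apnea_or_grunting",
                                   heart_rate = 170, mean_bp = 35,
                                   temp_rectal = 36.2, crt_sec = 4,
                                   glucose_first = 35, spo2 = 90))
  sbm <- score_msnsat(mid)
  expect_identical(sbm$sns_total, 5L)
  expect_identical(sbm$msnsat_total, 8L)  # 5 + 1 + 1 + 1
  expect_equal(as.character(sbm$risk_stratum), "intermediate")
})

test_that("moving any single vital to a more abnormal bin never raises a score", {
  reps <- bin_representatives()
  base <- make_record(ga_weeks = 34, bw_grams = 2000, at_hours = 8)
  for (comp in names(reps)) {
    vals <- reps[[comp]]
    totals <- sapply(seq_along(vals), function(i) {
      r <- base
      r[[comp]] <- vals[i]
      sb <- score_msnsat(r)
      c(sns = sb$sns_total, msnsat = sb$msnsat_total)
    })
    # representatives are ordered most-abnormal first
    expect_true(all(diff(totals["sns", ]) >= 0), label = comp)
    expect_true(all(diff(totals["msnsat", ]) >= 0), label = comp)
  }
  # and for the GA/BW/AT tables
  expect_true(all(diff(msnsat_points(c(28, 34, 40), 2000, 8)$ga_points) >= 0))
  expect_true(all(diff(msnsat_points(34, c(1000, 2000, 3000), 8)$bw_points) >= 0))
  expect_true(all(diff(msnsat_points(34, 2000, c(20, 8, 2))$at_points) >= 0))
})

test_that("additivity and flag consistency hold across a generated cohort", {
  coh <- generate_cohort(cohort_params(n = 400, seed = 21))
  sb <- score_msnsat(coh$records)
  extra <- sb$msnsat_total - sb$sns_total
  expect_identical(extra, sb$ga_points + sb$bw_points + sb$at_points)
  expect_true(all(extra >= 0 & extra <= 7))
  expect_identical(sb$sns_le8, sb$sns_total <= 8)
  expect_identical(sb$msnsat_le10, sb$msnsat_total <= 10)
  expect_identical(as.character(sb$risk_stratum),
                   as.character(risk_stratum(sb$msnsat_total)))
  expect_true(all(sb$sns_total >= 0 & sb$sns_total <= 14))
  expect_true(all(sb$msnsat_total >= 0 & sb$msnsat_total <= 21))
})

test_that("every valid measurement maps to exactly one score (dense sweep)", {
  grids <- list(heart_rate = seq(0, 350, by = 0.5),
                mean_bp = seq(0, 200, by = 0.25),
                temp_rectal = seq(25, 45, by = 0.01),
                crt_sec = seq(0, 60, by = 0.05),
                glucose_first = seq(0, 1500, by = 1),
                spo2 = seq(0, 100, by = 0.1))
  for (comp in names(grids)) {
    sc <- score_sns_component(comp, grids[[comp]])
    expect_true(all(sc %in% 0:2), label = comp)
    expect_length(sc, length(grids[[comp]]))
  }
})

test_that("dropping the admission-time points collapses the score", {
  coh <- generate_cohort(cohort_params(n = 200, seed = 3))
  with_at <- score_msnsat(coh$records)
  without <- score_msnsat(coh$records, include_at_points = FALSE)
  expect_identical(without$msnsat_total,
                   with_at$sns_total + with_at$ga_points + with_at$bw_points)
  expect_true(all(without$at_points == 0L))
})
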