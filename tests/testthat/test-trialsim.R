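# Synthetic trial generator: structure, reproducibility, censoring behavior,
# and recovery of planted effects.

test_that("cohort has the configured structure and invariants", {
  co <- simulate_cohort(sim_config(n_treated = 60, n_control = 40, seed = 4))
  expect_equal(nrow(co), 100)
  expect_equal(sum(co$arm == "treated"), 60)
  expect_true(all(co$pfs_time <= co$os_time + 1e-12))
  expect_true(all(co$os_event %in% 0:1) && all(co$pfs_event %in% 0:1))
  # T1 counts always present and strictly positive
  t1_cols <- grep("_T1$", names(co), value = TRUE)
  expect_true(all(!is.na(co[t1_cols])))
  cnt <- as.matrix(co[grep("^count_", names(co))])
  expect_true(all(cnt > 0, na.rm = TRUE))
  expect_true(all(co$os_time >= 0))
})

test_that("same seed gives a byte-identical cohort, different seed differs", {
  cfg <- sim_config(n_treated = 30, n_control = 20, seed = 99)
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))
  cfg2 <- sim_config(n_treated = 30, n_control = 20, seed = 100)
  expect_false(identical(simulate_cohort(cfg), simulate_cohort(cfg2)))
})

test_that("patients dying before a timepoint have missing counts there", {
  co <- simulate_cohort(sim_config(n_treated = 300, n_control = 100, seed = 5,
                                   baseline_hazard = 0.5, missing_prob = 0))
  early <- co$os_time < 6 * 12 / 52.1775
  expect_true(any(early))
  expect_true(all(is.na(co$count_neutrophils_T2[early])))
  late <- co$os_time >= 12 * 12 / 52.1775
  expect_true(all(!is.na(co$count_neutrophils_T3[late])))
})

test_that("zero follow-up horizon censors everyone and screening refuses to fit", {
  co <- simulate_cohort(sim_config(n_treated = 20, n_control = 10, seed = 6,
                                   followup_max = 0))
  expect_true(all(co$os_event == 0))
  expect_error(cox_ph(co$os_time, co$os_event, as.numeric(co$arm == "treated")),
               "no events")
})

test_that("censoring summary counts are consistent and match competing exponentials", {
  co <- simulate_cohort(sim_config(n_treated = 10, n_control = 5, seed = 7,
                                   accrual_censor_rate = 0))
  cs <- censoring_summary(co)
  expect_equal(sum(cs$n), 15)
  expect_equal(cs$events + cs$censored, cs$n)
  # all-event / all-censored extremes
  co2 <- co; co2$os_event <- 1L
  expect_equal(censoring_summary(co2)$censor_fraction, c(0, 0))
  co2$os_event <- 0L
  expect_equal(censoring_summary(co2)$censor_fraction, c(1, 1))
  # censor rate == hazard, long horizon: P(censored first) = 1/2
  co3 <- simulate_cohort(sim_config(n_treated = 1500, n_control = 500, seed = 8,
                                    baseline_hazard = 0.05,
                                    accrual_censor_rate = 0.05,
                                    followup_max = 1e6))
  frac <- censoring_summary(co3)$censor_fraction
  expect_true(all(abs(frac - 0.5) < 3 * sqrt(0.25 / 500)))
})

test_that("effects referencing unknown biomarkers or bad shapes are rejected", {
  expect_error(sim_config(prognostic_effects =
                            biomarker_effect("cd8", "T1", 0.5)), "unknown biomarkers")
  expect_error(sim_config(prognostic_effects =
                            biomarker_effect("nlr", "T9", 0.5)), "unknown timepoint")
  expect_error(sim_config(predictive_effects =
                            biomarker_effect("nlr", "T3", 0.5, form = "step")),
               "positive threshold")
  expect_error(sim_config(n_treated = 0), "n_treated")
})

test_that("a planted treated-only effect is recovered in the treated arm only", {
  set.seed(41)
  seeds <- sample.int(1e6, 10)
  hr_tr <- numeric(10); covers_ctrl <- logical(10)
  for (i in 1:10) {
    co <- simulate_cohort(sim_config(
      n_treated = 750, n_control = 350, seed = seeds[i], missing_prob = 0,
      predictive_effects = biomarker_effect("nlr", "T3", 0.6)))
    panel <- derive_ratios(co)
    for (a in c("treated", "control")) {
      sub <- panel[panel$arm == a & !is.na(panel$nlr_T3), ]
      hi <- as.numeric(sub$nlr_T3 >= stats::median(sub$nlr_T3))
      fit <- cox_ph(sub$os_time, sub$os_event, hi)
      if (a == "treated") hr_tr[i] <- fit$hr[1]
      else covers_ctrl[i] <- fit$ci_low[1] <= 1 && 1 <= fit$ci_high[1]
    }
  }
  # median split of a 0.6-per-SD effect: expected log-HR ~ 0.6 * 1.596,
  # i.e. HR ~ 2.6; band allows Monte-Carlo spread at 10 replicates
  expect_true(all(hr_tr > 1.5))
  expect_gte(mean(hr_tr >= 1.8 & hr_tr <= 3.6), 0.8)
  expect_gte(mean(covers_ctrl), 0.9)
})

test_that("doubling a prognostic log-HR increases the median recovered effect", {
  set.seed(51)
  seeds <- sample.int(1e6, 8)
  est <- function(loghr) {
    vapply(seeds, function(s) {
      co <- simulate_cohort(sim_config(
        n_treated = 300, n_control = 100, seed = s, missing_prob = 0,
        prognostic_effects = biomarker_effect("plr", "T1", loghr)))
      panel <- derive_ratios(co)
      z <- scale(log(panel$plr_T1))
      unname(coef(cox_ph(panel$os_time, panel$os_event, z))[1])
    }, 0)
  }
  expect_lt(stats::median(est(0.3)), stats::median(est(0.6)))
})

test_that("null cohorts show no between-arm survival difference", {
  set.seed(61)
  seeds <- sample.int(1e6, 20)
  rej <- vapply(seeds, function(s) {
    co <- simulate_cohort(null_config(150, 150, s))
    logrank_test(co$os_time, co$os_event, co$arm)$p_value <= 0.05
  }, TRUE)
  expect_lte(sum(rej), 4)  # P(>4 | Binom(20, .05)) < 0.003
})
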