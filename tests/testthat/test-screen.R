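# Ratio derivation, dichotomization, cutoff scans, the screening cascade, and
# integer-cutoff narrowing.

make_count_cohort <- function(df) {
  # wrap a minimal hand-built count table into the cohort column layout
  base <- data.frame(patient_id = sprintf("P%02d", seq_len(nrow(df))),
                     cohort = "FIX", arm = "treated",
                     os_time = 10, os_event = 1L, pfs_time = 5, pfs_event = 1L,
                     stringsAsFactors = FALSE)
  cbind(base, df)
}

test_that("ratios follow their definitions and missingness propagates", {
  co <- make_count_cohort(data.frame(
    count_neutrophils_T3 = 4.0, count_lymphocytes_T3 = 0.8,
    count_neutrophils_T2 = 6.0, count_lymphocytes_T2 = NA,
    count_monocytes_T2 = 0.5, count_platelets_T2 = 200))
  p <- derive_ratios(co)
  expect_equal(p$nlr_T3, 5.0)
  expect_true(is.na(p$nlr_T2) && is.na(p$plr_T2) && is.na(p$lmr_T2))
  expect_equal(p$nmr_T2, 12)  # lymphocyte-free ratio survives missing lymphocytes
})

test_that("nmr equals nlr x lmr wherever all three are defined", {
  co <- make_count_cohort(data.frame(
    count_neutrophils_T1 = 6.0, count_lymphocytes_T1 = 1.5,
    count_monocytes_T1 = 0.5))
  p <- derive_ratios(co)
  expect_equal(p$nlr_T1, 4)
  expect_equal(p$lmr_T1, 3)
  expect_equal(p$nmr_T1, p$nlr_T1 * p$lmr_T1)
  # property over a simulated cohort
  sim <- derive_ratios(simulate_cohort(sim_config(50, 20, seed = 14)))
  for (tp in c("T1", "T2", "T3")) {
    ok <- !is.na(sim[[paste0("nmr_", tp)]])
    expect_equal(sim[[paste0("nmr_", tp)]][ok],
                 (sim[[paste0("nlr_", tp)]] * sim[[paste0("lmr_", tp)]])[ok])
  }
  # zero denominator flagged non-evaluable, never infinite
  co0 <- make_count_cohort(data.frame(count_neutrophils_T1 = 4,
                                      count_lymphocytes_T1 = 0))
  expect_true(is.na(derive_ratios(co0)$nlr_T1))
})

test_that("fraction dichotomization splits at the treated-arm quantile", {
  co <- make_count_cohort(data.frame(count_neutrophils_T1 = as.numeric(1:10),
                                     count_lymphocytes_T1 = 1))
  p <- derive_ratios(co)
  d <- dichotomize(p, "nlr_T1", "fraction", 0.5)
  expect_equal(sum(d$labels == "high"), 5)
  expect_equal(sum(d$labels == "low"), 5)
  d2 <- dichotomize(p, "nlr_T1", "absolute", 5)
  expect_equal(as.character(d2$labels[4:6]), c("low", "high", "high"))
  # paper-scale anchor: 4.9 low, 5.0 high under the >= convention
  co3 <- make_count_cohort(data.frame(
    count_neutrophils_T3 = c(4.9, 5.0, 5.1), count_lymphocytes_T3 = 1))
  d3 <- dichotomize(derive_ratios(co3), "nlr_T3", "absolute", 5)
  expect_equal(as.character(d3$labels), c("low", "high", "high"))
  # degenerate: all values equal
  cod <- make_count_cohort(data.frame(count_neutrophils_T1 = rep(3, 5),
                                      count_lymphocytes_T1 = 1))
  expect_true(dichotomize(derive_ratios(cod), "nlr_T1", "fraction", 0.5)$degenerate)
})

test_that("a strong high-fails-early fixture yields HR > 1 and p < 0.05 at the median cut", {
  # high-ratio patients fail mostly before low-ratio patients (one overlap so
  # the likelihood stays bounded); n = 20, no ties
  nlr <- c(seq(6, 8, length.out = 10), seq(1, 3, length.out = 10))
  co <- make_count_cohort(data.frame(count_neutrophils_T1 = nlr,
                                     count_lymphocytes_T1 = 1))
  co$os_time <- c(seq(1, 5, length.out = 9), 7.5, seq(5.5, 10, length.out = 10))
  co$pfs_time <- co$os_time
  sc <- scan_biomarker(derive_ratios(co), "nlr_T1", "os", "treated",
                       fractions = 0.5, min_events = 5)
  expect_true(sc$estimable)
  expect_gt(sc$hr, 1)
  expect_lt(sc$p, 0.05)
})

test_that("scan marks cells with too few events as not estimable", {
  co <- simulate_cohort(sim_config(40, 20, seed = 15))
  sc <- scan_biomarker(derive_ratios(co), "nlr_T1", "os", "treated",
                       fractions = c(0.1, 0.5, 0.9), min_events = 30)
  expect_true(all(!sc$estimable))
  expect_true(all(sc$reason == "too few events"))
})

test_that("cascade rules remove prognostic, absolute-count and inconsistent biomarkers", {
  co <- simulate_cohort(sim_config(
    n_treated = 750, n_control = 350, seed = 16, missing_prob = 0,
    predictive_effects = biomarker_effect("nlr", "T3", 0.6),
    prognostic_effects = rbind(biomarker_effect("plr", "T1", 0.6),
                               biomarker_effect("platelets", "T1", 0.6))))
  panel <- derive_ratios(co)
  bms <- c("nlr_T3", "plr_T1", "platelets_T1")
  scans <- scan_cutoffs(panel, bms)
  casc <- screening_cascade(scans[scans$arm == "treated", ],
                            scans[scans$arm == "control", ])
  expect_true("nlr_T3" %in% casc$retained)
  expect_false("plr_T1" %in% casc$retained)
  aud <- casc$audit
  expect_match(aud$rule_failed[aud$biomarker == "plr_T1"], "^b:")
  # platelets_T1 must not survive: either not treated-significant, control
  # significant, or caught by the absolute-count rule
  expect_false("platelets_T1" %in% casc$retained)
  expect_error(screening_cascade(scans[0, ], scans[0, ]), "empty scan")
})

test_that("cascade output is invariant to row permutation and biomarker order", {
  co <- simulate_cohort(sim_config(300, 150, seed = 17, missing_prob = 0,
                                   predictive_effects = biomarker_effect("nlr", "T3", 0.8)))
  panel <- derive_ratios(co)
  bms <- c("nlr_T3", "nmr_T2")
  scans1 <- scan_cutoffs(panel, bms, fractions = c(0.3, 0.5, 0.7), min_events = 5)
  set.seed(1)
  perm <- sample(nrow(panel))
  scans2 <- scan_cutoffs(panel[perm, ], rev(bms),
                         fractions = c(0.3, 0.5, 0.7), min_events = 5)
  c1 <- screening_cascade(scans1[scans1$arm == "treated", ],
                          scans1[scans1$arm == "control", ])
  c2 <- screening_cascade(scans2[scans2$arm == "treated", ],
                          scans2[scans2$arm == "control", ])
  expect_identical(c1$retained, c2$retained)
  expect_identical(c1$audit, c2$audit)
})

test_that("integer cutoff grid follows the 25-50% quantile window", {
  # uniform values on [2, 10]: q25 = 4, q50 = 6 -> integer candidates {4, 5, 6}
  # (window closed at both quantiles)
  co <- make_count_cohort(data.frame(
    count_neutrophils_T1 = seq(2, 10, length.out = 201),
    count_lymphocytes_T1 = 1))
  g <- narrow_integer_cutoffs(derive_ratios(co), "nlr_T1", rescan = FALSE)
  expect_equal(as.numeric(g), c(4, 5, 6))
  # platelet-ratio scale, uniform on [100, 300]: step 10 inside [150, 200]
  co2 <- make_count_cohort(data.frame(
    count_platelets_T1 = seq(100, 300, length.out = 401),
    count_lymphocytes_T1 = 1))
  g2 <- narrow_integer_cutoffs(derive_ratios(co2), "plr_T1", rescan = FALSE)
  expect_equal(as.numeric(g2), c(150, 160, 170, 180, 190, 200))
  # degenerate window: quantiles closer than the step
  co3 <- make_count_cohort(data.frame(
    count_neutrophils_T1 = seq(5.1, 5.4, length.out = 50),
    count_lymphocytes_T1 = 1))
  expect_length(narrow_integer_cutoffs(derive_ratios(co3), "nlr_T1",
                                       rescan = FALSE), 0)
})

test_that("re-scan keeps cutoffs with genuine effects and drops null biomarker grids", {
  co <- simulate_cohort(sim_config(
    n_treated = 800, n_control = 50, seed = 18, missing_prob = 0,
    predictive_effects = biomarker_effect("nlr", "T3", 0.9, form = "step",
                                          threshold = 5)))
  panel <- derive_ratios(co)
  kept <- narrow_integer_cutoffs(panel, "nlr_T3", rescan = TRUE)
  expect_gt(length(kept), 0)
  expect_true(all(kept %in% attr(kept, "all_candidates")))
})
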