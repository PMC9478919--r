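# Synthetic two-arm trial generator: longitudinal log-normal blood counts with
# within-patient correlation across timepoints, proportional-hazards survival
# with planted prognostic (both-arm) and predictive (treated-only) biomarker
# effects, independent exponential + administrative censoring, and a response
# outcome sharing the survival linear predictor.

.CELLS <- c("neutrophils", "lymphocytes", "monocytes", "platelets", "rbc", "wbc")
.TIMEPOINTS <- c("T1", "T2", "T3")
# measurement months: baseline, ~6 weeks (cycle 3), ~12 weeks (cycle 5)
.TP_MONTHS <- c(T1 = 0, T2 = 6 * 12 / 52.1775, T3 = 12 * 12 / 52.1775)
.RATIOS <- c("nlr", "plr", "lmr", "nmr")
.RATIO_DEF <- list(nlr = c("neutrophils", "lymphocytes"),
                   plr = c("platelets", "lymphocytes"),
                   lmr = c("lymphocytes", "monocytes"),
                   nmr = c("neutrophils", "monocytes"))

#' Configuration for the synthetic trial generator
#'
#' Defaults emulate the cohort structure of a two-arm advanced-NSCLC
#' immunotherapy-vs-chemotherapy setting: 1,479 treated / 707 control
#' patients, blood counts (10^9/L) log-normal with locations typical of
#' advanced disease (median neutrophils ~5.5, lymphocytes ~1.05, monocytes
#' ~0.7, platelets ~250), exchangeable within-patient correlation 0.7 across the
#' three timepoints, constant baseline hazard 0.05/month (median OS ~14
#' months), progression hazard 0.15/month (median PFS ~4.6 months),
#' accrual/dropout censoring 0.02/month and administrative censoring at 30
#' months.
#'
#' @param n_treated,n_control Arm sizes.
#' @param baseline_hazard Constant death hazard per month (> 0).
#' @param progression_hazard Constant progression hazard per month (> 0).
#' @param followup_max Administrative censoring time, months.
#' @param accrual_censor_rate Independent exponential censoring rate per
#'   month (>= 0).
#' @param count_log_means,count_log_sds Named per-cell-type location/scale of
#'   the log-normal counts (names: neutrophils, lymphocytes, monocytes,
#'   platelets, rbc, wbc). Defaults reflect an advanced-NSCLC profile
#'   (neutrophilia with lymphopenia: median NLR ~5, PLR ~240, NMR ~8).
#' @param timepoint_correlation Within-patient correlation of log-counts
#'   across T1/T2/T3, in `[0, 1)`.
#' @param prognostic_effects,predictive_effects Data frames as built by
#'   [biomarker_effect()]: columns `biomarker` (one of nlr/plr/lmr/nmr or a
#'   cell type), `timepoint` (T1/T2/T3), `loghr`, and optionally `form`
#'   (`"linear"`: log-HR per SD of the standardized log-biomarker, the
#'   default; or `"step"`: log-HR applied when the raw biomarker value is
#'   `>= threshold`) and `threshold`. Prognostic effects act in both arms,
#'   predictive effects in the treated arm only.
#' @param treatment_loghr Arm main effect: log hazard ratio of treated vs
#'   control applied to both endpoints (default 0).
#' @param response_base_prob Baseline objective-response (CR/PR) probability
#'   in `[0, 1]`; default 0.22, anchoring the arm-level response rate of
#'   checkpoint-inhibitor NSCLC cohorts.
#' @param sd_base_prob Baseline probability of stable disease among
#'   non-responders (default 0.30), so the baseline clinical-benefit
#'   (CR+PR+SD) rate is ~0.47.
#' @param response_scale Logistic coefficient linking the (negated) survival
#'   linear predictor to both the response and the stable-disease
#'   probability: good-risk patients respond more and progress less.
#' @param missing_prob Independent probability that an on-treatment (T2/T3)
#'   count panel is missing, on top of deterministic missingness for patients
#'   whose follow-up ends before the timepoint.
#' @param cohort Cohort label stamped on every record.
#' @param seed Integer seed; the cohort is byte-identical for a given config.
#' @return List of class `"sim_config"`.
#' @export
sim_config <- function(n_treated = 1479L, n_control = 707L,
                       baseline_hazard = 0.05, progression_hazard = 0.15,
                       followup_max = 30, accrual_censor_rate = 0.02,
                       count_log_means = c(neutrophils = log(5.5),
                                           lymphocytes = log(1.05),
                                           monocytes = log(0.7),
                                           platelets = log(250),
                                           rbc = log(4.4), wbc = log(7.5)),
                       count_log_sds = c(neutrophils = 0.35, lymphocytes = 0.35,
                                         monocytes = 0.35, platelets = 0.25,
                                         rbc = 0.10, wbc = 0.30),
                       timepoint_correlation = 0.7,
                       prognostic_effects = NULL, predictive_effects = NULL,
                       treatment_loghr = 0,
                       response_base_prob = 0.22, sd_base_prob = 0.30,
                       response_scale = 0.8,
                       missing_prob = 0.05, cohort = "SIM", seed = 1L) {
  stopifnot(n_treated >= 1, n_control >= 1,
            baseline_hazard > 0, progression_hazard > 0,
            followup_max >= 0, accrual_censor_rate >= 0,
            timepoint_correlation >= 0, timepoint_correlation < 1,
            response_base_prob >= 0, response_base_prob <= 1,
            sd_base_prob >= 0, sd_base_prob <= 1,
            missing_prob >= 0, missing_prob <= 1)
  if (!all(.CELLS %in% names(count_log_means)) ||
      !all(.CELLS %in% names(count_log_sds)))
    stop("count_log_means/count_log_sds must name all cell types")
  if (any(count_log_sds <= 0)) stop("count_log_sds must be strictly positive")
  chk_eff <- function(e) {
    if (is.null(e)) return(.empty_effects())
    e <- as.data.frame(e)
    stopifnot(all(c("biomarker", "timepoint", "loghr") %in% names(e)))
    if (is.null(e$form)) e$form <- "linear"
    if (is.null(e$threshold)) e$threshold <- NA_real_
    bad <- !(e$biomarker %in% c(.RATIOS, .CELLS))
    if (any(bad)) stop("effects reference unknown biomarkers: ",
                       paste(e$biomarker[bad], collapse = ", "))
    if (!all(e$timepoint %in% .TIMEPOINTS)) stop("unknown timepoint in effects")
    if (!all(e$form %in% c("linear", "step"))) stop("effect form must be linear or step")
    if (any(e$form == "step" & !(is.finite(e$threshold) & e$threshold > 0)))
      stop("step effects need a positive threshold")
    e
  }
  cfg <- list(n_treated = as.integer(n_treated), n_control = as.integer(n_control),
              baseline_hazard = baseline_hazard,
              progression_hazard = progression_hazard,
              followup_max = followup_max,
              accrual_censor_rate = accrual_censor_rate,
              count_log_means = count_log_means[.CELLS],
              count_log_sds = count_log_sds[.CELLS],
              timepoint_correlation = timepoint_correlation,
              prognostic_effects = chk_eff(prognostic_effects),
              predictive_effects = chk_eff(predictive_effects),
              treatment_loghr = treatment_loghr,
              response_base_prob = response_base_prob,
              sd_base_prob = sd_base_prob,
              response_scale = response_scale,
              missing_prob = missing_prob, cohort = cohort,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

.empty_effects <- function() {
  data.frame(biomarker = character(), timepoint = character(),
             loghr = numeric(), form = character(), threshold = numeric(),
             stringsAsFactors = FALSE)
}

#' Convenience constructor for effect tables
#' @param biomarker,timepoint,loghr Vectors defining one effect per element.
#' @param form `"linear"` (per-SD effect on the standardized log-biomarker)
#'   or `"step"` (effect switched on where the raw value `>= threshold`).
#' @param threshold Raw-scale threshold for `form = "step"`.
#' @export
biomarker_effect <- function(biomarker, timepoint, loghr,
                             form = "linear", threshold = NA_real_) {
  data.frame(biomarker = biomarker, timepoint = timepoint, loghr = loghr,
             form = form, threshold = threshold, stringsAsFactors = FALSE)
}

# theoretical mean/sd of the log-biomarker (ratios of independent log-normals)
.biomarker_log_moments <- function(cfg, biomarker) {
  mu <- cfg$count_log_means; sd <- cfg$count_log_sds
  if (biomarker %in% .CELLS) {
    c(mean = unname(mu[biomarker]), sd = unname(sd[biomarker]))
  } else {
    nd <- .RATIO_DEF[[biomarker]]
    c(mean = unname(mu[nd[1]] - mu[nd[2]]),
      sd = sqrt(unname(sd[nd[1]])^2 + unname(sd[nd[2]])^2))
  }
}

#' Simulate a two-arm trial cohort
#'
#' Draws per-patient log-counts multivariate-normal across the three
#' timepoints with exchangeable correlation, computes the latent linear
#' predictor from the configured standardized log-biomarker effects
#' (prognostic in both arms, predictive in the treated arm only), and draws
#' death/progression times by inverse transform from constant baseline
#' hazards under proportional hazards. Independent exponential censoring and
#' administrative censoring at `followup_max` apply to both endpoints, so
#' `pfs_time <= os_time` always. On-treatment counts are missing for patients
#' whose follow-up ends before the timepoint, plus independent missingness.
#'
#' @param config A [sim_config()].
#' @return A `data.frame` of class `"bct_cohort"`, one row per patient, with
#'   columns `patient_id`, `cohort`, `arm`, clinical covariates, the 18
#'   `count_<cell>_<T>` columns, `os_time`, `os_event`, `pfs_time`,
#'   `pfs_event`, `response`.
#' @examples
#' co <- simulate_cohort(sim_config(n_treated = 50, n_control = 30, seed = 7))
#' table(co$arm)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n_treated + cfg$n_control
  arm <- rep(c("treated", "control"), c(cfg$n_treated, cfg$n_control))

  # log-counts: exchangeable correlation rho across timepoints per cell type
  rho <- cfg$timepoint_correlation
  logc <- array(NA_real_, dim = c(n, length(.CELLS), 3),
                dimnames = list(NULL, .CELLS, .TIMEPOINTS))
  for (cell in .CELLS) {
    shared <- stats::rnorm(n)
    for (tp in 1:3) {
      z <- sqrt(rho) * shared + sqrt(1 - rho) * stats::rnorm(n)
      logc[, cell, tp] <- cfg$count_log_means[cell] + cfg$count_log_sds[cell] * z
    }
  }

  log_biomarker <- function(biomarker, timepoint) {
    if (biomarker %in% .CELLS) {
      logc[, biomarker, timepoint]
    } else {
      nd <- .RATIO_DEF[[biomarker]]
      logc[, nd[1], timepoint] - logc[, nd[2], timepoint]
    }
  }
  effect_term <- function(eff, k) {
    lv <- log_biomarker(eff$biomarker[k], eff$timepoint[k])
    if (eff$form[k] == "step") {
      eff$loghr[k] * (exp(lv) >= eff$threshold[k])
    } else {
      mo <- .biomarker_log_moments(cfg, eff$biomarker[k])
      eff$loghr[k] * (lv - mo["mean"]) / mo["sd"]
    }
  }
  tr <- arm == "treated"
  eta <- cfg$treatment_loghr * tr
  pe <- cfg$prognostic_effects
  for (k in seq_len(nrow(pe))) eta <- eta + effect_term(pe, k)
  qe <- cfg$predictive_effects
  for (k in seq_len(nrow(qe))) eta <- eta + tr * effect_term(qe, k)

  # inverse-transform exponential survival under PH
  t_death <- stats::rexp(n, rate = 1) / (cfg$baseline_hazard * exp(eta))
  t_prog <- stats::rexp(n, rate = 1) / (cfg$progression_hazard * exp(eta))
  t_cens <- if (cfg$accrual_censor_rate > 0)
    stats::rexp(n, rate = cfg$accrual_censor_rate) else rep(Inf, n)
  t_admin <- pmin(t_cens, cfg$followup_max)
  os_time <- pmin(t_death, t_admin)
  os_event <- as.integer(t_death <= t_admin)
  t_pfs <- pmin(t_prog, t_death)
  pfs_time <- pmin(t_pfs, t_admin)
  pfs_event <- as.integer(t_pfs <= t_admin)

  # clinical covariates (plausible advanced-NSCLC mix; not fit to any trial)
  sex <- sample(c("male", "female"), n, replace = TRUE, prob = c(0.6, 0.4))
  age <- pmin(pmax(round(stats::rnorm(n, 63, 9)), 25), 89)
  race <- sample(c("white", "asian", "other"), n, replace = TRUE,
                 prob = c(0.6, 0.25, 0.15))
  ecog_ps <- sample(c(0L, 1L, 2L), n, replace = TRUE, prob = c(0.35, 0.55, 0.10))
  metastasis <- sample(c("yes", "no"), n, replace = TRUE, prob = c(0.65, 0.35))
  pdl1_level <- stats::rbeta(n, 0.5, 2)

  # response shares the survival linear predictor with opposite sign;
  # the SD-vs-PD split among non-responders is risk-dependent too
  p_resp <- stats::plogis(stats::qlogis(cfg$response_base_prob) -
                            cfg$response_scale * eta)
  p_sd <- stats::plogis(stats::qlogis(cfg$sd_base_prob) -
                          cfg$response_scale * eta)
  u_resp <- stats::runif(n); u_cr <- stats::runif(n)
  u_ne <- stats::runif(n); u_sd <- stats::runif(n)
  responder <- u_resp < p_resp
  response <- rep("PD", n)
  response[responder] <- ifelse(u_cr[responder] < 0.15, "CR", "PR")
  response[!responder & u_ne < 0.05] <- "NE"
  sd_sel <- !responder & u_ne >= 0.05 & u_sd < p_sd
  response[sd_sel] <- "SD"

  counts <- matrix(NA_real_, n, length(.CELLS) * 3)
  cn <- as.vector(outer(.CELLS, .TIMEPOINTS, function(c, t) paste0("count_", c, "_", t)))
  colnames(counts) <- cn
  miss2 <- os_time < .TP_MONTHS["T2"] | stats::runif(n) < cfg$missing_prob
  miss3 <- os_time < .TP_MONTHS["T3"] | stats::runif(n) < cfg$missing_prob
  for (cell in .CELLS) {
    counts[, paste0("count_", cell, "_T1")] <- exp(logc[, cell, "T1"])
    counts[, paste0("count_", cell, "_T2")] <- ifelse(miss2, NA, exp(logc[, cell, "T2"]))
    counts[, paste0("count_", cell, "_T3")] <- ifelse(miss3, NA, exp(logc[, cell, "T3"]))
  }

  out <- data.frame(
    patient_id = sprintf("%s-%05d", cfg$cohort, seq_len(n)),
    cohort = cfg$cohort, arm = arm, sex = sex, age = age, race = race,
    ecog_ps = ecog_ps, metastasis = metastasis, pdl1_level = pdl1_level,
    counts,
    os_time = os_time, os_event = os_event,
    pfs_time = pfs_time, pfs_event = pfs_event,
    response = response, stringsAsFactors = FALSE)
  class(out) <- c("bct_cohort", "data.frame")
  out
}

#' Per-arm event counts and censoring fractions
#'
#' @param cohort A cohort data frame (as from [simulate_cohort()] or
#'   [read_cohort()]).
#' @param endpoint `"os"` or `"pfs"`.
#' @return Data frame with one row per arm: `n`, `events`, `censored`,
#'   `censor_fraction`.
#' @export
censoring_summary <- function(cohort, endpoint = c("os", "pfs")) {
  endpoint <- match.arg(endpoint)
  if (nrow(cohort) == 0L) stop("empty cohort")
  ev <- cohort[[paste0(endpoint, "_event")]]
  agg <- lapply(split(ev, cohort$arm), function(e)
    data.frame(n = length(e), events = sum(e), censored = sum(1 - e),
               censor_fraction = mean(1 - e)))
  out <- do.call(rbind, agg)
  out <- cbind(arm = rownames(out), out)
  rownames(out) <- NULL
  out
}
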