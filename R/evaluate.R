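# Final evaluation: within-stratum treatment hazard ratios (predictive vs
# prognostic), treatment-by-score interaction, AUC comparison of the score
# against its single components, KM summaries, and report assembly.

#' Predictive-vs-prognostic assessment of a risk classification
#'
#' Fits the treatment indicator (treated vs control) by Cox regression within
#' the high-risk and the low-risk stratum separately, for OS and PFS, and in
#' addition fits an explicit treatment x score interaction model on the whole
#' evaluable cohort. A score is flagged predictive under the informal
#' criterion when exactly one stratum's treatment HR CI excludes 1, and under
#' the formal criterion when the interaction Wald p <= `alpha`. Both are
#' reported: the informal criterion is the field's common practice but is
#' statistically fragile, so the interaction test accompanies it.
#'
#' @param cohort Two-arm cohort data frame.
#' @param classification A `"risk_classification"` for this cohort (or a
#'   factor of low/high labels).
#' @param endpoints Endpoints to assess.
#' @param landmark Landmark months subtracted from survival times (default:
#'   the T3 measurement time when the classification carries a candidate,
#'   else 0).
#' @param alpha Significance threshold.
#' @param min_events Minimum events per stratum.
#' @return List of class `"predictive_assessment"`, one element per endpoint
#'   with `hr_high`, `hr_low` (each HR/CI/p), `interaction_p`,
#'   `predictive_informal`, `predictive_interaction`.
#' @export
predictive_assessment <- function(cohort, classification,
                                  endpoints = c("os", "pfs"),
                                  landmark = NULL, alpha = 0.05,
                                  min_events = 5L) {
  risk <- if (inherits(classification, "risk_classification"))
    classification$risk else factor(classification, levels = c("low", "high"))
  if (length(risk) != nrow(cohort))
    stop("classification length must match cohort")
  if (length(unique(cohort$arm)) < 2L) stop("both arms required")
  if (is.null(landmark)) {
    landmark <- if (inherits(classification, "risk_classification")) {
      tps <- vapply(classification$candidate$rules$biomarker,
                    .biomarker_timepoint, "")
      max(unname(.TP_MONTHS[tps]))
    } else 0
  }
  treated <- as.numeric(cohort$arm == "treated")
  out <- list()
  for (ep in endpoints) {
    tcol <- cohort[[paste0(ep, "_time")]]
    ecol <- cohort[[paste0(ep, "_event")]]
    keep <- !is.na(risk) & tcol > landmark
    tms <- tcol - landmark
    strat <- list()
    for (lev in c("high", "low")) {
      sel <- keep & risk == lev
      if (sum(ecol[sel]) < min_events || length(unique(treated[sel])) < 2L) {
        strat[[lev]] <- list(hr = NA_real_, ci_low = NA_real_,
                             ci_high = NA_real_, p = NA_real_,
                             n = sum(sel), n_events = sum(ecol[sel]))
        next
      }
      fit <- cox_ph(tms[sel], ecol[sel],
                    matrix(treated[sel], ncol = 1,
                           dimnames = list(NULL, "treated")))
      strat[[lev]] <- list(hr = fit$hr[["treated"]],
                           ci_low = fit$ci_low[["treated"]],
                           ci_high = fit$ci_high[["treated"]],
                           p = fit$wald_p[["treated"]],
                           n = sum(sel), n_events = fit$n_events)
    }
    # interaction model: treated + high + treated:high
    xm <- cbind(treated = treated[keep],
                high = as.numeric(risk[keep] == "high"),
                treated_x_high = treated[keep] * (risk[keep] == "high"))
    ifit <- tryCatch(cox_ph(tms[keep], ecol[keep], xm), error = function(e) NULL)
    int_p <- if (is.null(ifit)) NA_real_ else ifit$wald_p[["treated_x_high"]]
    int_coef <- if (is.null(ifit)) NA_real_ else ifit$coef[["treated_x_high"]]
    excl_high <- !is.na(strat$high$ci_low) &&
      (strat$high$ci_low > 1 || strat$high$ci_high < 1)
    excl_low <- !is.na(strat$low$ci_low) &&
      (strat$low$ci_low > 1 || strat$low$ci_high < 1)
    out[[ep]] <- list(
      hr_high = strat$high, hr_low = strat$low,
      interaction_coef = int_coef, interaction_p = int_p,
      predictive_informal = xor(excl_high, excl_low),
      predictive_interaction = !is.na(int_p) && int_p <= alpha,
      landmark = landmark)
  }
  class(out) <- "predictive_assessment"
  out
}

#' @export
print.predictive_assessment <- function(x, ...) {
  for (ep in names(x)) {
    e <- x[[ep]]
    cat(toupper(ep), ": treated-vs-control HR\n", sep = "")
    cat(sprintf("  high risk: HR = %.3f [%.3f, %.3f], p = %.4f (n=%d)\n",
                e$hr_high$hr, e$hr_high$ci_low, e$hr_high$ci_high,
                e$hr_high$p, e$hr_high$n))
    cat(sprintf("  low  risk: HR = %.3f [%.3f, %.3f], p = %.4f (n=%d)\n",
                e$hr_low$hr, e$hr_low$ci_low, e$hr_low$ci_high,
                e$hr_low$p, e$hr_low$n))
    cat(sprintf("  interaction p = %.4f; predictive (informal/interaction): %s/%s\n",
                e$interaction_p, e$predictive_informal, e$predictive_interaction))
  }
  invisible(x)
}

#' Compare the score's AUC against its single component biomarkers
#'
#' Time-dependent AUC (IPCW) at `horizon` of the ordinal score (count of
#' positive rules) and of each continuous single biomarker, treated arm,
#' landmark population of the score's latest timepoint.
#'
#' @param cohort Cohort data frame (treated arm is used).
#' @param classification A `"risk_classification"` for the treated arm, or the
#'   object from `predict.bctscore` on `cohort`.
#' @param single_biomarkers Biomarker names to compare against (default: the
#'   score's own components).
#' @param horizon AUC horizon (months from landmark).
#' @param endpoint `"os"` or `"pfs"`.
#' @param landmark Apply the landmark convention.
#' @return Data frame: marker, auc, score_not_worse flag.
#' @export
auc_comparison <- function(cohort, classification, single_biomarkers = NULL,
                           horizon = 12, endpoint = "os", landmark = TRUE) {
  panel <- if (all(.RATIOS %in% sub("_T[123]$", "", names(cohort))) ||
               any(grepl("^nlr_", names(cohort)))) cohort else derive_ratios(cohort)
  tr <- panel[panel$arm == "treated", , drop = FALSE]
  cl <- if (inherits(classification, "risk_classification")) classification
        else stop("classification must be a risk_classification")
  if (length(cl$risk) != nrow(tr)) {
    cl <- classify_patients(tr, cl$candidate)
  }
  if (is.null(single_biomarkers))
    single_biomarkers <- cl$candidate$rules$biomarker
  tps <- vapply(cl$candidate$rules$biomarker, .biomarker_timepoint, "")
  lm_tp <- .TIMEPOINTS[max(match(tps, .TIMEPOINTS))]
  ls <- .landmark_subset(tr, lm_tp, endpoint, landmark)
  sel <- ls$keep & !is.na(cl$risk)
  score_auc <- td_auc(cl$n_positive[sel], ls$times[sel], ls$events[sel], horizon)$auc
  rows <- data.frame(marker = "score", auc = score_auc,
                     score_not_worse = NA, stringsAsFactors = FALSE)
  for (bm in single_biomarkers) {
    v <- .biomarker_column(tr, bm)
    s2 <- ls$keep & !is.na(v)
    a <- tryCatch(td_auc(v[s2], ls$times[s2], ls$events[s2], horizon)$auc,
                  error = function(e) NA_real_)
    rows <- rbind(rows, data.frame(marker = bm, auc = a,
                                   score_not_worse = !is.na(a) && score_auc >= a,
                                   stringsAsFactors = FALSE))
  }
  rows
}

#' Assemble the full evaluation report
#'
#' Gathers, per cohort: KM summaries by risk group x arm, within-stratum
#' treatment Cox fits, RR for clinical benefit and response by risk, and the
#' AUC table of the score and its single components. The report is a plain
#' list serializable to JSON and is bit-identical for identical inputs.
#'
#' @param model A `"bctscore"` fit with a selected candidate.
#' @param cohorts Named list of two-arm cohort data frames.
#' @param horizon AUC horizon.
#' @param landmark Landmark convention.
#' @return List of class `"bct_report"`.
#' @export
assemble_report <- function(model, cohorts, horizon = 12, landmark = TRUE) {
  if (is.null(model$selected)) stop("model has no selected candidate")
  if (is.null(names(cohorts)) || any(names(cohorts) == ""))
    stop("cohorts must be a named list")
  rep_cohort <- function(co, nm) {
    panel <- derive_ratios(co)
    cl <- classify_patients(panel, model$selected)
    tps <- vapply(model$selected$rules$biomarker, .biomarker_timepoint, "")
    lm <- max(unname(.TP_MONTHS[tps])) * landmark
    km <- list()
    cells <- 0L
    for (lev in c("high", "low")) {
      for (a in unique(panel$arm)) {
        sel <- !is.na(cl$risk) & cl$risk == lev & panel$arm == a &
          panel$os_time > lm
        cells <- cells + sum(sel)
        if (sum(sel) == 0L) next
        kf <- km_fit(panel$os_time[sel] - lm, panel$os_event[sel])
        km[[paste(lev, a, sep = "_")]] <- list(
          n = kf$n, events = kf$n_events, median = kf$median,
          times = kf$times, survival = kf$survival)
      }
    }
    pa <- if (length(unique(panel$arm)) >= 2L)
      tryCatch(unclass(predictive_assessment(panel, cl)), error = function(e) NULL)
    else NULL
    auc <- tryCatch(auc_comparison(panel, cl, horizon = horizon,
                                   landmark = landmark), error = function(e) NULL)
    tr <- panel[panel$arm == "treated", , drop = FALSE]
    cltr <- classify_patients(tr, model$selected)
    rrres <- list()
    known <- tr$response != "NE" & !is.na(cltr$risk)
    for (nm in c("cb", "orr")) {
      y <- if (nm == "cb") tr$response %in% c("CR", "PR", "SD")
           else tr$response %in% c("CR", "PR")
      hi <- cltr$risk == "high"
      tab <- rbind(c(sum(y[known & hi]), sum(!y[known & hi])),
                   c(sum(y[known & !hi]), sum(!y[known & !hi])))
      r <- tryCatch(rr_from_table(tab), error = function(e) NULL)
      rrres[[nm]] <- if (is.null(r)) NULL else
        list(rr = r$rr, ci_low = r$ci_low, ci_high = r$ci_high,
             p = r$p_value, method = r$method)
    }
    list(n = nrow(panel), n_evaluable = sum(!is.na(cl$risk)),
         km_by_risk_arm = km, km_cell_total = cells,
         treatment_effect_by_stratum = pa, rr = rrres,
         auc = if (is.null(auc)) NULL else auc)
  }
  out <- list(
    model = list(candidate_id = model$selected$candidate_id,
                 rules = model$selected$rules,
                 combination_rule = model$selected$combination_rule),
    horizon = horizon, landmark = landmark,
    cohorts = lapply(names(cohorts), function(nm) rep_cohort(cohorts[[nm]], nm)))
  names(out$cohorts) <- names(cohorts)
  class(out) <- "bct_report"
  out
}

#' @export
print.bct_report <- function(x, ...) {
  cat("BCTscore evaluation report:", length(x$cohorts), "cohort(s)\n")
  cat("Model:", x$model$candidate_id, "-",
      paste(sprintf("%s >= %g", x$model$rules$biomarker, x$model$rules$cutoff),
            collapse = ", "), "\n")
  for (nm in names(x$cohorts)) {
    co <- x$cohorts[[nm]]
    cat(sprintf("  %s: n=%d evaluable=%d\n", nm, co$n, co$n_evaluable))
    if (!is.null(co$auc))
      cat("    OS AUC(score) =",
          format(co$auc$auc[co$auc$marker == "score"], digits = 3), "\n")
  }
  invisible(x)
}

#' Serialize a report (or any pipeline artifact) to canonical JSON
#' @param x Report/list to serialize.
#' @param path Output file.
#' @export
write_report_json <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
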