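# Threshold-combination risk scores: candidate enumeration over per-biomarker
# cutoff grids, high/low classification, cross-cohort selection by
# time-dependent AUC, and the top-level bctscore() fitting interface.

#' Enumerate threshold-combination score candidates
#'
#' Cartesian product of per-biomarker cutoff options: one cutoff is chosen per
#' biomarker, so the number of candidates is the product of the list sizes
#' (e.g. 2 x 4 x 2 = 16).
#'
#' @param cutoff_candidates Named list, one numeric vector of cutoff
#'   candidates per biomarker.
#' @param combination_rule How per-rule positives combine into one high/low
#'   call: `"any_high"` (default; high iff >= 1 rule met), `"majority"`,
#'   `"all_high"`, or `"count_threshold"` with `k`.
#' @param k Threshold for `combination_rule = "count_threshold"`.
#' @return List of `"score_candidate"` objects, ids `cand_01`, `cand_02`, ...
#'   in lexicographic grid order.
#' @examples
#' cands <- enumerate_candidates(list(nlr_T3 = c(4, 5), plr_T3 = c(170, 180)))
#' length(cands)  # 4
#' @export
enumerate_candidates <- function(cutoff_candidates,
                                 combination_rule = c("any_high", "majority",
                                                      "all_high", "count_threshold"),
                                 k = NULL) {
  combination_rule <- match.arg(combination_rule)
  if (length(cutoff_candidates) == 0L) stop("no biomarkers given")
  if (any(vapply(cutoff_candidates, length, 0L) == 0L))
    stop("empty cutoff list for at least one biomarker")
  if (any(unlist(cutoff_candidates) <= 0)) stop("cutoffs must be > 0")
  if (combination_rule == "count_threshold") {
    if (is.null(k) || k < 1 || k > length(cutoff_candidates))
      stop("count_threshold requires 1 <= k <= number of rules")
  }
  grid <- expand.grid(cutoff_candidates, KEEP.OUT.ATTRS = FALSE)
  width <- max(2L, nchar(nrow(grid)))
  lapply(seq_len(nrow(grid)), function(i) {
    cand <- list(
      candidate_id = sprintf("cand_%0*d", width, i),
      rules = data.frame(biomarker = names(cutoff_candidates),
                         cutoff = as.numeric(grid[i, ]),
                         stringsAsFactors = FALSE),
      combination_rule = combination_rule,
      k = if (combination_rule == "count_threshold") as.integer(k) else NULL)
    class(cand) <- "score_candidate"
    cand
  })
}

#' @export
print.score_candidate <- function(x, ...) {
  cat(x$candidate_id, " [", x$combination_rule,
      if (!is.null(x$k)) paste0(" k=", x$k), "]: ",
      paste(sprintf("%s >= %g", x$rules$biomarker, x$rules$cutoff),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

# per-patient count of positive rules (NA when any required ratio is missing)
.rule_count <- function(panel, candidate) {
  pos <- sapply(seq_len(nrow(candidate$rules)), function(j) {
    as.numeric(.biomarker_column(panel, candidate$rules$biomarker[j]) >=
                 candidate$rules$cutoff[j])
  })
  if (is.null(dim(pos))) pos <- matrix(pos, nrow = nrow(panel))
  rowSums(pos)  # NA propagates: non-evaluable patients stay NA
}

#' Classify patients as high/low risk under a score candidate
#'
#' A patient is evaluable only when every rule biomarker is present at its
#' timepoint. Classification is boundary-inclusive (`value >= cutoff` makes a
#' rule positive) and monotone: raising any ratio can never move a patient
#' from high to low.
#'
#' @param panel A `ratio_panel`.
#' @param candidate A `"score_candidate"`.
#' @return List of class `"risk_classification"`: `risk` (factor
#'   low/high, NA = non-evaluable), `n_positive` (ordinal rule count, used as
#'   the score's marker for ROC analyses), `candidate`.
#' @export
classify_patients <- function(panel, candidate) {
  stopifnot(inherits(candidate, "score_candidate"))
  have <- candidate$rules$biomarker %in% names(panel) |
    paste0("count_", candidate$rules$biomarker) %in% names(panel)
  if (any(!have))
    stop("candidate references biomarkers absent from panel: ",
         paste(candidate$rules$biomarker[!have], collapse = ", "))
  npos <- .rule_count(panel, candidate)
  nr <- nrow(candidate$rules)
  thr <- switch(candidate$combination_rule,
                any_high = 1L,
                majority = floor(nr / 2) + 1L,
                all_high = nr,
                count_threshold = candidate$k)
  risk <- factor(ifelse(npos >= thr, "high", "low"), levels = c("low", "high"))
  out <- list(risk = risk, n_positive = npos, candidate = candidate)
  class(out) <- "risk_classification"
  out
}

#' @export
print.risk_classification <- function(x, ...) {
  tb <- table(x$risk, useNA = "ifany")
  cat("Risk classification under", x$candidate$candidate_id, ":\n")
  print(tb)
  invisible(x)
}

# per-cohort endpoint panel for a candidate: Cox high-vs-low (uni+multi),
# RR for CB/ORR, td-AUC for OS/PFS, binary AUC for CB/ORR
.evaluate_candidate_cohort <- function(panel, candidate, horizon = 12,
                                       landmark = TRUE, min_events = 5L) {
  tr <- panel[panel$arm == "treated", , drop = FALSE]
  cl <- classify_patients(tr, candidate)
  lm_tp <- .TIMEPOINTS[max(match(vapply(candidate$rules$biomarker,
                                        .biomarker_timepoint, ""), .TIMEPOINTS))]
  res <- list(n_evaluable = sum(!is.na(cl$risk)))
  ok <- !is.na(cl$risk)
  hi <- cl$risk == "high"
  for (ep in c("os", "pfs")) {
    ls <- .landmark_subset(tr, lm_tp, ep, landmark)
    sel <- ok & ls$keep
    fit <- tryCatch(
      cox_ph(ls$times[sel], ls$events[sel],
             matrix(as.numeric(hi[sel]), ncol = 1, dimnames = list(NULL, "high"))),
      error = function(e) NULL)
    res[[paste0(ep, "_hr")]] <- if (is.null(fit)) NA_real_ else fit$hr[["high"]]
    res[[paste0(ep, "_p")]] <- if (is.null(fit)) NA_real_ else fit$wald_p[["high"]]
    auc <- tryCatch(
      td_auc(cl$n_positive[sel], ls$times[sel], ls$events[sel], horizon)$auc,
      error = function(e) NA_real_)
    res[[paste0(ep, "_auc")]] <- auc
  }
  cb <- tr$response %in% c("CR", "PR", "SD")
  orr <- tr$response %in% c("CR", "PR")
  known <- tr$response != "NE"
  for (nm in c("cb", "orr")) {
    y <- if (nm == "cb") cb else orr
    sel <- ok & known
    tab <- rbind(c(sum(y[sel & hi]), sum(!y[sel & hi])),
                 c(sum(y[sel & !hi]), sum(!y[sel & !hi])))
    rr <- tryCatch(rr_from_table(tab), error = function(e) NULL)
    res[[paste0(nm, "_rr")]] <- if (is.null(rr)) NA_real_ else rr$rr
    res[[paste0(nm, "_p")]] <- if (is.null(rr)) NA_real_ else rr$p_value
    res[[paste0(nm, "_auc")]] <- tryCatch(
      binary_auc(cl$n_positive[sel], as.integer(!y[sel])),  # high score ranks non-benefit
      error = function(e) NA_real_)
  }
  res
}

#' Select the best score candidate across cohorts
#'
#' For every candidate and cohort, computes the treated-arm Cox HR and p of
#' high vs low for OS and PFS, the relative risk and p for clinical benefit
#' (CB = CR+PR+SD) and objective response (ORR = CR+PR), and the
#' time-dependent AUC for OS/PFS at `horizon` months from the landmark (plus
#' binary AUC for CB/ORR). A candidate is admissible when significant
#' (p <= `alpha`) for all four endpoints in every cohort; among admissible
#' candidates the one maximizing the minimum-across-cohorts OS AUC is
#' selected, ties broken by lexicographic candidate id.
#'
#' @param candidates List of `"score_candidate"`s.
#' @param cohorts Named list of `ratio_panel`s (e.g. training, validation1,
#'   validation2).
#' @param horizon AUC horizon in months (default 12).
#' @param alpha Significance threshold (default 0.05).
#' @param landmark Landmark convention for survival endpoints.
#' @return List of class `"score_selection"`: `selected` (a candidate or
#'   NULL), `ranking` (data frame, one row per candidate x cohort),
#'   `admissible` ids, `warning` state when nothing is admissible.
#' @export
select_candidate <- function(candidates, cohorts, horizon = 12, alpha = 0.05,
                             landmark = TRUE) {
  stopifnot(length(candidates) >= 1L, length(cohorts) >= 1L)
  if (is.null(names(cohorts)))
    names(cohorts) <- paste0("cohort", seq_along(cohorts))
  rows <- list()
  for (cand in candidates) {
    for (cn in names(cohorts)) {
      r <- .evaluate_candidate_cohort(cohorts[[cn]], cand, horizon, landmark)
      rows[[length(rows) + 1L]] <- data.frame(
        candidate_id = cand$candidate_id, cohort = cn,
        os_hr = r$os_hr, os_p = r$os_p, os_auc = r$os_auc,
        pfs_hr = r$pfs_hr, pfs_p = r$pfs_p, pfs_auc = r$pfs_auc,
        cb_rr = r$cb_rr, cb_p = r$cb_p, cb_auc = r$cb_auc,
        orr_rr = r$orr_rr, orr_p = r$orr_p, orr_auc = r$orr_auc,
        n_evaluable = r$n_evaluable, stringsAsFactors = FALSE)
    }
  }
  ranking <- do.call(rbind, rows)
  by_cand <- split(ranking, ranking$candidate_id)
  admissible <- names(by_cand)[vapply(by_cand, function(d) {
    ps <- c(d$os_p, d$pfs_p, d$cb_p, d$orr_p)
    all(is.finite(ps)) && all(ps <= alpha)
  }, TRUE)]
  sel <- NULL
  warn <- NULL
  if (length(admissible)) {
    min_auc <- vapply(by_cand[admissible], function(d) min(d$os_auc), 0)
    best <- admissible[order(-min_auc, admissible)][1]
    sel <- candidates[[which(vapply(candidates, `[[`, "", "candidate_id") == best)]]
  } else {
    warn <- "no candidate significant for all endpoints in all cohorts"
  }
  out <- list(selected = sel, ranking = ranking, admissible = admissible,
              horizon = horizon, alpha = alpha, warning = warn)
  class(out) <- "score_selection"
  out
}

#' @export
print.score_selection <- function(x, ...) {
  cat("Candidate selection over", length(unique(x$ranking$candidate_id)),
      "candidates,", length(unique(x$ranking$cohort)), "cohorts\n")
  if (!is.null(x$selected)) {
    cat("Selected: "); print(x$selected)
  } else {
    cat("No admissible candidate:", x$warning, "\n")
  }
  invisible(x)
}

#' Fit a blood-cell-count threshold score on trial cohorts
#'
#' End-to-end discovery: derives ratio biomarkers, runs decile-fraction Cox
#' scans in both arms, applies the screening cascade (treated-arm
#' significance for OS and PFS, control-arm exclusion, absolute-count
#' elimination, HR-direction consistency), narrows surviving biomarkers to
#' absolute integer cutoff candidates over the 25-50% quantile window,
#' enumerates threshold-combination candidates, and selects the final score
#' by minimum-across-cohorts OS AUC among candidates significant for OS, PFS,
#' clinical benefit and response everywhere.
#'
#' @param train Training cohort (two-arm; data frame as from
#'   [simulate_cohort()] or [read_cohort()]).
#' @param validation Optional named list of further cohorts used in candidate
#'   selection (treated arm only is used there).
#' @param biomarkers Biomarker universe to screen (default: 4 ratios + 6
#'   absolute counts at each of the 3 timepoints).
#' @param fractions Cutoff fractions for the scans.
#' @param share,alpha Cascade share and significance threshold.
#' @param max_biomarkers Cap on score biomarkers, ranked by treated-arm scan
#'   strength (default 3).
#' @param combination_rule,k Combination rule for [enumerate_candidates()].
#' @param horizon AUC horizon (months from landmark, default 12).
#' @param landmark Landmark convention (default TRUE).
#' @param min_events Minimum events per group in scan cells.
#' @return Object of class `"bctscore"`: `selected`, `selection` (ranking),
#'   `screen` (cascade audit), `cutoff_candidates`, `scans`, and call
#'   parameters. `predict()` classifies new patients with the selected score.
#' @export
bctscore <- function(train, validation = NULL,
                     biomarkers = screen_biomarkers(),
                     fractions = sort(unique(c(seq(0.1, 0.9, 0.1), 0.25, 0.75))),
                     share = 0.8, alpha = 0.05, max_biomarkers = 3L,
                     combination_rule = "any_high", k = NULL,
                     horizon = 12, landmark = TRUE, min_events = 10L) {
  panel <- derive_ratios(train)
  scans <- scan_cutoffs(panel, biomarkers, endpoints = c("os", "pfs"),
                        arms = c("treated", "control"),
                        analyses = "univariate", fractions = fractions,
                        landmark = landmark, min_events = min_events)
  sc_tr <- scans[scans$arm == "treated", ]
  sc_ct <- scans[scans$arm == "control", ]
  casc <- screening_cascade(sc_tr, sc_ct, share = share, alpha = alpha)
  retained <- casc$retained
  empty_fit <- function(msg, cuts = list()) {
    sel <- structure(list(selected = NULL, ranking = NULL,
                          admissible = character(0), horizon = horizon,
                          alpha = alpha, warning = msg),
                     class = "score_selection")
    out <- list(selected = NULL, selection = sel, screen = casc,
                cutoff_candidates = cuts, scans = scans,
                biomarkers = biomarkers, share = share, alpha = alpha,
                horizon = horizon, landmark = landmark,
                combination_rule = combination_rule)
    class(out) <- "bctscore"
    out
  }
  if (length(retained) == 0L)
    return(empty_fit("screening cascade retained no biomarkers"))
  # rank retained biomarkers by treated-arm scan strength (mean -log10 p),
  # keeping at most one timepoint per ratio family: different timepoints of
  # the same ratio are strongly correlated and would make the score redundant
  strength <- vapply(retained, function(bm) {
    s <- sc_tr[sc_tr$biomarker == bm & sc_tr$estimable, ]
    mean(-log10(pmax(s$p, 1e-300)))
  }, 0)
  ranked <- retained[order(-strength, retained)]
  fam <- sub("_T[123]$", "", ranked)
  ranked <- ranked[!duplicated(fam)]
  chosen <- ranked[seq_len(min(max_biomarkers, length(ranked)))]
  cuts <- lapply(chosen, function(bm)
    narrow_integer_cutoffs(panel, bm, rescan = TRUE, alpha = alpha,
                           min_events = min_events, landmark = landmark))
  names(cuts) <- chosen
  # drop biomarkers whose narrowed grid is empty
  cuts <- cuts[vapply(cuts, length, 0L) > 0L]
  if (length(cuts) == 0L)
    return(empty_fit("no biomarker has a significant integer cutoff candidate"))
  candidates <- enumerate_candidates(lapply(cuts, as.numeric),
                                     combination_rule = combination_rule, k = k)
  cohorts <- c(list(training = panel),
               lapply(validation, derive_ratios))
  selection <- select_candidate(candidates, cohorts, horizon = horizon,
                                alpha = alpha, landmark = landmark)
  out <- list(selected = selection$selected, selection = selection,
              screen = casc, cutoff_candidates = cuts, scans = scans,
              biomarkers = biomarkers, share = share, alpha = alpha,
              horizon = horizon, landmark = landmark,
              combination_rule = combination_rule)
  class(out) <- "bctscore"
  out
}

#' @export
print.bctscore <- function(x, ...) {
  cat("BCTscore model\n")
  print(x$screen)
  if (!is.null(x$selected)) {
    cat("Selected score: "); print(x$selected)
  } else {
    cat("No score selected:", x$selection$warning, "\n")
  }
  invisible(x)
}

#' @export
summary.bctscore <- function(object, ...) {
  out <- list(audit = object$screen$audit,
              cutoff_candidates = object$cutoff_candidates,
              ranking = object$selection$ranking,
              selected = object$selected)
  class(out) <- "summary.bctscore"
  out
}

#' @export
print.summary.bctscore <- function(x, ...) {
  cat("Screening audit:\n"); print(x$audit)
  cat("\nCutoff candidates:\n"); utils::str(x$cutoff_candidates)
  cat("\nSelection ranking (per candidate x cohort):\n")
  print(x$ranking, digits = 3)
  if (!is.null(x$selected)) { cat("\nSelected: "); print(x$selected) }
  invisible(x)
}

#' Classify new patients with a fitted score
#' @param object A `"bctscore"` fit with a selected candidate.
#' @param newdata Cohort data frame (ratios derived automatically if absent).
#' @param ... Unused.
#' @return A `"risk_classification"`.
#' @export
predict.bctscore <- function(object, newdata, ...) {
  if (is.null(object$selected)) stop("no selected score candidate")
  if (!all(object$selected$rules$biomarker %in% names(newdata)))
    newdata <- derive_ratios(newdata)
  classify_patients(newdata, object$selected)
}

#' Forest-style plot of scan HRs for the retained biomarkers
#' @param x A `"bctscore"` fit.
#' @param endpoint Endpoint to plot.
#' @param ... Passed to `plot()`.
#' @export
plot.bctscore <- function(x, endpoint = "os", ...) {
  s <- x$scans[x$scans$endpoint == endpoint & x$scans$arm == "treated" &
                 x$scans$estimable & x$scans$biomarker %in% x$screen$retained, ]
  if (nrow(s) == 0L) stop("nothing to plot")
  s$idx <- seq_len(nrow(s))
  plot(s$hr, s$idx, xlim = range(c(s$ci_low, s$ci_high), finite = TRUE),
       pch = 16, xlab = "Hazard ratio (high vs low)", ylab = "",
       yaxt = "n", log = "x", ...)
  segments(s$ci_low, s$idx, s$ci_high, s$idx)
  abline(v = 1, lty = 2)
  axis(2, at = s$idx, labels = paste0(s$biomarker, "@", s$cutoff_value),
       las = 1, cex.axis = 0.6)
  invisible(x)
}
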