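# Biomarker screening: ratio derivation, quantile/absolute dichotomization,
# per-arm Cox scans over cutoff fractions, the screening cascade
# (treated-arm significance -> control-arm exclusion -> absolute-count
# elimination -> HR-direction consistency), and integer cutoff narrowing.

#' Derive blood-count ratio biomarkers
#'
#' Adds NLR (neutrophil/lymphocyte), PLR (platelet/lymphocyte),
#' LMR (lymphocyte/monocyte) and NMR (neutrophil/monocyte) columns per
#' timepoint to a cohort. Missingness in any component propagates; zero
#' denominators are flagged non-evaluable (NA), never infinite.
#'
#' @param cohort Cohort data frame with `count_<cell>_<T>` columns.
#' @return The cohort with added `nlr_T1 ... nmr_T3` columns, class
#'   `"ratio_panel"`.
#' @examples
#' co <- simulate_cohort(sim_config(n_treated = 20, n_control = 10, seed = 2))
#' panel <- derive_ratios(co)
#' head(panel$nlr_T1)
#' @export
derive_ratios <- function(cohort) {
  out <- as.data.frame(cohort)
  for (tp in .TIMEPOINTS) {
    for (r in .RATIOS) {
      nd <- .RATIO_DEF[[r]]
      num <- out[[paste0("count_", nd[1], "_", tp)]]
      den <- out[[paste0("count_", nd[2], "_", tp)]]
      if (is.null(num) || is.null(den)) {
        out[[paste0(r, "_", tp)]] <- NA_real_
      } else {
        val <- num / den
        val[!is.finite(val)] <- NA_real_
        out[[paste0(r, "_", tp)]] <- val
      }
    }
  }
  class(out) <- c("ratio_panel", "bct_cohort", "data.frame")
  out
}

#' All screened biomarker names
#' @param include_counts Include the absolute-count biomarkers.
#' @return Character vector like `"nlr_T3"`, `"neutrophils_T1"`.
#' @export
screen_biomarkers <- function(include_counts = TRUE) {
  b <- as.vector(outer(.RATIOS, .TIMEPOINTS, paste, sep = "_"))
  if (include_counts)
    b <- c(b, as.vector(outer(.CELLS, .TIMEPOINTS, paste, sep = "_")))
  b
}

# biomarker name -> per-patient values; accepts ratio and count biomarkers
.biomarker_column <- function(panel, biomarker) {
  if (biomarker %in% names(panel)) return(panel[[biomarker]])
  cn <- paste0("count_", biomarker)
  if (cn %in% names(panel)) return(panel[[cn]])
  stop("unknown biomarker: ", biomarker)
}

.biomarker_timepoint <- function(biomarker) {
  tp <- sub(".*_(T[123])$", "\\1", biomarker)
  if (!tp %in% .TIMEPOINTS) stop("biomarker name must end in _T1/_T2/_T3: ", biomarker)
  tp
}

.is_ratio_biomarker <- function(biomarker) {
  sub("_(T[123])$", "", biomarker) %in% .RATIOS
}

#' Dichotomize a biomarker at a fraction or absolute cutoff
#'
#' Fraction cutoffs are the type-7 empirical quantile of the biomarker in the
#' reference set (by default the treated arm of the panel, the convention for
#' cutoffs derived on a combined treated cohort). Values `>= cutoff` are
#' labelled `high`.
#'
#' @param panel A `ratio_panel`.
#' @param biomarker Name like `"nlr_T3"`.
#' @param cutoff_kind `"fraction"` or `"absolute"`.
#' @param cutoff_value Fraction in (0,1) or absolute threshold > 0.
#' @param reference Optional data frame whose treated-arm values define the
#'   quantile (default: `panel` itself).
#' @return List: `labels` (factor low/high, NA when non-evaluable),
#'   `cutoff` (absolute threshold used), `degenerate` flag.
#' @export
dichotomize <- function(panel, biomarker,
                        cutoff_kind = c("fraction", "absolute"),
                        cutoff_value, reference = NULL) {
  cutoff_kind <- match.arg(cutoff_kind)
  vals <- .biomarker_column(panel, biomarker)
  if (cutoff_kind == "fraction") {
    if (cutoff_value <= 0 || cutoff_value >= 1) stop("fraction cutoff must be in (0,1)")
    ref <- if (is.null(reference)) panel else reference
    rv <- .biomarker_column(ref, biomarker)
    if ("arm" %in% names(ref)) rv <- rv[ref$arm == "treated"]
    rv <- rv[!is.na(rv)]
    if (length(rv) == 0L) stop("no reference values for ", biomarker)
    if (diff(range(rv)) == 0)
      return(list(labels = factor(rep(NA, nrow(panel)), levels = c("low", "high")),
                  cutoff = rv[1], degenerate = TRUE))
    cutoff <- unname(stats::quantile(rv, cutoff_value, type = 7))
  } else {
    if (cutoff_value <= 0) stop("absolute cutoff must be > 0")
    cutoff <- cutoff_value
  }
  labels <- factor(ifelse(vals >= cutoff, "high", "low"), levels = c("low", "high"))
  list(labels = labels, cutoff = cutoff, degenerate = FALSE)
}

# landmark subset: event-free and under follow-up at the biomarker timepoint,
# with survival measured from the landmark (guards immortal-time bias)
.landmark_subset <- function(panel, timepoint, endpoint, landmark = TRUE) {
  tcol <- paste0(endpoint, "_time"); ecol <- paste0(endpoint, "_event")
  lm <- if (landmark) unname(.TP_MONTHS[timepoint]) else 0
  keep <- panel[[tcol]] > lm
  times <- panel[[tcol]] - lm
  list(keep = keep, times = times, events = panel[[ecol]], landmark = lm)
}

# dummy-coded clinical adjustment covariates; PD-L1 high/low at 1%
# (5% when the cohort label is BIRCH); complete-case
.clinical_covariates <- function(panel) {
  thr <- ifelse(!is.null(panel$cohort) & panel$cohort == "BIRCH", 0.05, 0.01)
  data.frame(
    sex_male = as.numeric(panel$sex == "male"),
    age = as.numeric(panel$age),
    race_asian = as.numeric(panel$race == "asian"),
    race_other = as.numeric(panel$race == "other"),
    ecog_ps = as.numeric(panel$ecog_ps),
    metastasis = as.numeric(panel$metastasis == "yes"),
    pdl1_high = as.numeric(panel$pdl1_level >= thr))
}

#' Cox scan of one biomarker over cutoff fractions or absolute cutoffs
#'
#' For each cutoff, dichotomizes the biomarker (fraction quantiles computed on
#' the treated arm of the full panel), restricts to the landmark population of
#' the biomarker's timepoint, and fits a Cox model of high vs low (univariate,
#' or adjusted for sex, age, race, ECOG PS, metastasis and PD-L1 high/low when
#' `analysis = "multivariate"`).
#'
#' @param panel A `ratio_panel` (both arms; the scanned arm is selected here).
#' @param biomarker Biomarker name, e.g. `"nlr_T3"`.
#' @param endpoint `"os"` or `"pfs"`.
#' @param arm `"treated"` or `"control"`.
#' @param analysis `"univariate"` or `"multivariate"`.
#' @param fractions Cutoff fractions (default deciles 0.1-0.9 plus 0.25, 0.75).
#' @param absolute_cutoffs Optional absolute cutoffs scanned instead.
#' @param landmark Apply the landmark convention (default TRUE).
#' @param min_events Minimum events required in each of the high/low groups
#'   for the cell to be estimable (default 10).
#' @return Data frame, one row per cutoff: HR, CI, p, group sizes, flags.
#' @export
scan_biomarker <- function(panel, biomarker, endpoint = c("os", "pfs"),
                           arm = c("treated", "control"),
                           analysis = c("univariate", "multivariate"),
                           fractions = sort(unique(c(seq(0.1, 0.9, 0.1), 0.25, 0.75))),
                           absolute_cutoffs = NULL,
                           landmark = TRUE, min_events = 10L) {
  endpoint <- match.arg(endpoint)
  arm <- match.arg(arm)
  analysis <- match.arg(analysis)
  tp <- .biomarker_timepoint(biomarker)
  cuts <- if (is.null(absolute_cutoffs)) {
    data.frame(kind = "fraction", value = fractions)
  } else {
    data.frame(kind = "absolute", value = absolute_cutoffs)
  }
  rows <- vector("list", nrow(cuts))
  for (i in seq_len(nrow(cuts))) {
    di <- dichotomize(panel, biomarker, cuts$kind[i], cuts$value[i], reference = panel)
    base <- data.frame(biomarker = biomarker, timepoint = tp,
                       cutoff_kind = cuts$kind[i], cutoff_value = cuts$value[i],
                       cutoff_abs = di$cutoff, endpoint = endpoint, arm = arm,
                       analysis = analysis, hr = NA_real_, ci_low = NA_real_,
                       ci_high = NA_real_, p = NA_real_, n_high = NA_integer_,
                       n_low = NA_integer_, n_events = NA_integer_,
                       estimable = FALSE, reason = "", stringsAsFactors = FALSE)
    if (di$degenerate) {
      base$reason <- "degenerate cutoff"
      rows[[i]] <- base
      next
    }
    sel <- panel$arm == arm & !is.na(di$labels)
    ls <- .landmark_subset(panel, tp, endpoint, landmark)
    sel <- sel & ls$keep
    hi <- di$labels[sel] == "high"
    times <- ls$times[sel]; events <- ls$events[sel]
    base$n_high <- sum(hi); base$n_low <- sum(!hi)
    base$n_events <- sum(events)
    ev_hi <- sum(events[hi]); ev_lo <- sum(events[!hi])
    if (base$n_high == 0L || base$n_low == 0L || ev_hi < min_events || ev_lo < min_events) {
      base$reason <- "too few events"
      rows[[i]] <- base
      next
    }
    xm <- matrix(as.numeric(hi), ncol = 1, dimnames = list(NULL, "high"))
    if (analysis == "multivariate") {
      cc <- .clinical_covariates(panel)[sel, , drop = FALSE]
      xm <- cbind(xm, as.matrix(cc))
      ok <- stats::complete.cases(xm)
      xm <- xm[ok, , drop = FALSE]; times <- times[ok]; events <- events[ok]
      xm <- xm[, apply(xm, 2, function(v) diff(range(v)) > 0), drop = FALSE]
    }
    fit <- tryCatch(cox_ph(times, events, xm), error = function(e) NULL)
    if (is.null(fit) || !fit$converged) {
      base$reason <- if (is.null(fit)) "fit error" else "non-convergence"
      rows[[i]] <- base
      next
    }
    base$hr <- fit$hr[["high"]]
    base$ci_low <- fit$ci_low[["high"]]
    base$ci_high <- fit$ci_high[["high"]]
    base$p <- fit$wald_p[["high"]]
    base$estimable <- TRUE
    rows[[i]] <- base
  }
  do.call(rbind, rows)
}

#' Run Cox scans for many biomarkers/endpoints/arms
#'
#' @inheritParams scan_biomarker
#' @param biomarkers Character vector of biomarker names.
#' @param endpoints,arms,analyses Vectors of levels to scan.
#' @return Long data frame of scan cells.
#' @export
scan_cutoffs <- function(panel, biomarkers = screen_biomarkers(),
                         endpoints = c("os", "pfs"),
                         arms = c("treated", "control"),
                         analyses = "univariate",
                         fractions = sort(unique(c(seq(0.1, 0.9, 0.1), 0.25, 0.75))),
                         landmark = TRUE, min_events = 10L) {
  grid <- expand.grid(biomarker = biomarkers, endpoint = endpoints, arm = arms,
                      analysis = analyses, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(grid)), function(i)
    scan_biomarker(panel, grid$biomarker[i], grid$endpoint[i], grid$arm[i],
                   grid$analysis[i], fractions = fractions,
                   landmark = landmark, min_events = min_events))
  do.call(rbind, out)
}

#' Screening cascade
#'
#' Retains a biomarker iff (a) it is significant in the treated arm for BOTH
#' OS and PFS in at least `share` of estimable fractions; (b) it is NOT
#' control-arm significant under the same rule for either endpoint; (c) it is
#' a ratio, not an absolute count; (d) its HR direction is consistent (same
#' side of 1) across all significant treated-arm fractions. The audit trail
#' records the first rule that removed each biomarker.
#'
#' @param scan_treated,scan_control Long scan tables (from [scan_cutoffs()])
#'   for the treated and control arms, covering both endpoints.
#' @param share Minimum share of estimable fractions that must be significant
#'   (default 0.8).
#' @param alpha Significance threshold (default 0.05).
#' @return List of class `"screen_result"`: `retained` (character vector) and
#'   `audit` (data frame biomarker/retained/rule_failed/detail).
#' @export
screening_cascade <- function(scan_treated, scan_control,
                              share = 0.8, alpha = 0.05) {
  if (nrow(scan_treated) == 0L) stop("empty scan input")
  bms <- sort(unique(scan_treated$biomarker))
  sig_share <- function(scans, bm, ep) {
    s <- scans[scans$biomarker == bm & scans$endpoint == ep & scans$estimable, ]
    if (nrow(s) == 0L) return(0)
    mean(s$p <= alpha)
  }
  audit <- lapply(bms, function(bm) {
    res <- data.frame(biomarker = bm, retained = FALSE, rule_failed = "",
                      detail = "", stringsAsFactors = FALSE)
    sh_os <- sig_share(scan_treated, bm, "os")
    sh_pfs <- sig_share(scan_treated, bm, "pfs")
    if (sh_os < share || sh_pfs < share) {
      res$rule_failed <- "a:treated-arm significance"
      res$detail <- sprintf("treated sig share OS=%.2f PFS=%.2f < %.2f",
                            sh_os, sh_pfs, share)
      return(res)
    }
    # control-arm exclusion applies the same rule as (a): share reached for
    # BOTH endpoints
    csh_os <- sig_share(scan_control, bm, "os")
    csh_pfs <- sig_share(scan_control, bm, "pfs")
    if (csh_os >= share && csh_pfs >= share) {
      res$rule_failed <- "b:control-arm prognostic"
      res$detail <- sprintf("control sig share OS=%.2f PFS=%.2f", csh_os, csh_pfs)
      return(res)
    }
    if (!.is_ratio_biomarker(bm)) {
      res$rule_failed <- "c:absolute count"
      return(res)
    }
    s <- scan_treated[scan_treated$biomarker == bm & scan_treated$estimable &
                        scan_treated$p <= alpha, ]
    if (nrow(s) > 0 && length(unique(sign(log(s$hr)))) > 1L) {
      res$rule_failed <- "d:inconsistent HR direction"
      return(res)
    }
    res$retained <- TRUE
    res
  })
  audit <- do.call(rbind, audit)
  out <- list(retained = audit$biomarker[audit$retained], audit = audit,
              share = share, alpha = alpha)
  class(out) <- "screen_result"
  out
}

#' @export
print.screen_result <- function(x, ...) {
  cat("Screening cascade:", nrow(x$audit), "biomarkers,",
      length(x$retained), "retained\n")
  if (length(x$retained)) cat("  retained:", paste(x$retained, collapse = ", "), "\n")
  invisible(x)
}

#' Narrow a retained biomarker to absolute integer cutoff candidates
#'
#' Candidate cutoffs are the step-multiples `c` with
#' `q(lo) <= c <= q(hi)` where `q` is the type-7 empirical quantile of the
#' biomarker in the treated arm and `(lo, hi)` is `fraction_range`
#' (default 25-50%, both ends included, so a cutoff sitting exactly at the
#' median stays in the window). Step defaults to 1, or 10 for platelet-ratio-scale
#' markers (median value > 50). Each candidate is then re-scanned (OS and
#' PFS, optionally per cohort and with multivariate adjustment) and dropped
#' unless significant everywhere required.
#'
#' @param panel A `ratio_panel`.
#' @param biomarker Biomarker name.
#' @param fraction_range Quantile window, default `c(0.25, 0.50)`.
#' @param step Integer grid step; `NULL` = auto (1 or 10 by marker scale).
#' @param rescan Filter candidates by significance re-scan (default TRUE).
#' @param analyses Analyses required in the re-scan.
#' @param by_cohort Require significance in every cohort label separately.
#' @param alpha,min_events,landmark Passed to the re-scan.
#' @return Integer-valued numeric vector of surviving cutoff candidates, with
#'   attribute `"all_candidates"` holding the pre-filter grid.
#' @export
narrow_integer_cutoffs <- function(panel, biomarker,
                                   fraction_range = c(0.25, 0.50), step = NULL,
                                   rescan = TRUE, analyses = "univariate",
                                   by_cohort = FALSE, alpha = 0.05,
                                   min_events = 10L, landmark = TRUE) {
  vals <- .biomarker_column(panel, biomarker)
  if ("arm" %in% names(panel)) vals <- vals[panel$arm == "treated"]
  vals <- vals[!is.na(vals)]
  if (is.null(step)) step <- if (stats::median(vals) > 50) 10 else 1
  q <- stats::quantile(vals, fraction_range, type = 7)
  lo <- ceiling(q[[1]] / step) * step
  grid <- seq(lo, by = step,
              length.out = max(0, floor((q[[2]] - lo) / step) + 1))
  grid <- grid[grid >= q[[1]] & grid <= q[[2]]]
  if (length(grid) == 0L) {
    out <- numeric(0)
    attr(out, "all_candidates") <- numeric(0)
    return(out)
  }
  keep <- grid
  if (rescan) {
    cohorts <- if (by_cohort && "cohort" %in% names(panel))
      unique(panel$cohort) else NA
    ok <- rep(TRUE, length(grid))
    for (co in cohorts) {
      sub <- if (is.na(co)[1]) panel else panel[panel$cohort == co, ]
      for (an in analyses) {
        for (ep in c("os", "pfs")) {
          sc <- scan_biomarker(sub, biomarker, endpoint = ep, arm = "treated",
                               analysis = an, absolute_cutoffs = grid,
                               landmark = landmark, min_events = min_events)
          ok <- ok & sc$estimable & !is.na(sc$p) & sc$p <= alpha
        }
      }
    }
    keep <- grid[ok]
  }
  attr(keep, "all_candidates") <- grid
  keep
}
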