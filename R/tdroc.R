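# Time-dependent ROC at a fixed horizon: cumulative cases / dynamic controls
# with inverse-probability-of-censoring weights (IPCW) from the Kaplan-Meier
# estimate of the censoring distribution.

#' Time-dependent AUC (cumulative/dynamic, IPCW)
#'
#' Cases at horizon tau are subjects with an observed event at or before tau;
#' controls are subjects still under observation beyond tau. Each case i is
#' weighted 1/G(T_i-), each control 1/G(tau), where G is the Kaplan-Meier
#' estimate of the censoring survival function (events and censorings swapped).
#' Ties in the marker contribute 1/2. With no censoring all weights are 1 and
#' the estimate reduces to the Mann-Whitney AUC between cases and controls.
#'
#' @param marker Numeric risk marker (higher = higher risk).
#' @param times Follow-up times.
#' @param events 0/1 event indicators.
#' @param horizon Evaluation time tau (> 0, within follow-up).
#' @param weight_floor Lower truncation for IPCW weights' denominator
#'   (default 1e-6) to avoid blow-up near the end of follow-up.
#' @return List of class `"td_auc"`: `auc`, `horizon`, `n_cases`, `n_controls`,
#'   `sensitivity`, `specificity`, `thresholds`.
#' @export
td_auc <- function(marker, times, events, horizon, weight_floor = 1e-6) {
  marker <- as.numeric(marker)
  times <- as.numeric(times)
  events <- as.integer(events)
  keep <- is.finite(marker) & !is.na(times)
  marker <- marker[keep]; times <- times[keep]; events <- events[keep]
  if (!is.finite(horizon) || horizon <= 0) stop("horizon must be > 0")
  if (horizon >= max(times)) stop("horizon must lie inside observed follow-up")
  if (any(!is.finite(marker))) stop("marker must be finite")

  case <- times <= horizon & events == 1L
  ctrl <- times > horizon
  if (!any(case)) stop("no cases at horizon")
  if (!any(ctrl)) stop("no controls at horizon")

  # censoring-distribution KM: flip the event indicator
  Gfit <- km_fit(times, 1L - events)
  Gleft <- function(t) {
    # left limit G(t-)
    if (length(Gfit$times) == 0L) return(rep(1, length(t)))
    idx <- findInterval(t, Gfit$times, left.open = TRUE)
    c(1, Gfit$survival)[idx + 1L]
  }
  w <- numeric(length(times))
  w[case] <- 1 / pmax(Gleft(times[case]), weight_floor)
  w[ctrl] <- 1 / pmax(Gleft(horizon + .Machine$double.eps * horizon), weight_floor)

  mc <- marker[case]; wc <- w[case]
  mk <- marker[ctrl]; wk <- w[ctrl]
  num <- 0
  for (i in seq_along(mc)) {
    num <- num + wc[i] * sum(wk * (ifelse(mc[i] > mk, 1, 0) + 0.5 * (mc[i] == mk)))
  }
  auc <- num / (sum(wc) * sum(wk))

  thr <- sort(unique(marker))
  sens <- vapply(thr, function(c) sum(wc[mc >= c]) / sum(wc), 0)
  spec <- vapply(thr, function(c) sum(wk[mk < c]) / sum(wk), 0)
  out <- list(auc = auc, horizon = horizon,
              n_cases = sum(case), n_controls = sum(ctrl),
              sensitivity = sens, specificity = spec, thresholds = thr)
  class(out) <- "td_auc"
  out
}

#' @export
print.td_auc <- function(x, ...) {
  cat("Time-dependent AUC at t =", x$horizon, ":",
      format(x$auc, digits = 4),
      sprintf("(%d cases / %d controls)\n", x$n_cases, x$n_controls))
  invisible(x)
}

#' Binary-outcome ROC AUC (Mann-Whitney)
#'
#' Pairwise-count AUC of a (possibly ordinal) marker against a binary outcome;
#' ties contribute 1/2. Used for clinical-benefit and response endpoints.
#'
#' @param marker Numeric/ordinal marker.
#' @param outcome 0/1 outcome (1 = the "case" class the marker should rank high).
#' @return AUC in `[0, 1]`.
#' @export
binary_auc <- function(marker, outcome) {
  outcome <- as.integer(outcome)
  keep <- is.finite(marker) & !is.na(outcome)
  marker <- marker[keep]; outcome <- outcome[keep]
  m1 <- marker[outcome == 1L]
  m0 <- marker[outcome == 0L]
  if (length(m1) == 0L || length(m0) == 0L) stop("need both outcome classes")
  r <- rank(c(m1, m0))
  (sum(r[seq_along(m1)]) - length(m1) * (length(m1) + 1) / 2) /
    (length(m1) * length(m0))
}
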