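# Product-limit estimator with Greenwood variance, and the (stratified)
# log-rank test. Censorings tied with an event time are counted as at risk
# for that event time (censored "just after" the events).

#' Kaplan-Meier product-limit estimate
#'
#' @param times Follow-up times (>= 0).
#' @param events 0/1 event indicators.
#' @return Object of class `"km_fit"`: `times` (distinct event times),
#'   `survival`, `greenwood_var`, `n_risk`, `n_event`, `median`
#'   (`NA` when the curve never reaches 0.5), `n`.
#' @examples
#' km <- km_fit(c(1, 2, 3), c(1, 0, 1))
#' km$survival  # 2/3 at t=1, 0 at t=3
#' @export
km_fit <- function(times, events) {
  times <- as.numeric(times)
  events <- as.integer(events)
  if (length(times) == 0L) stop("empty input")
  if (any(times < 0) || any(!is.finite(times))) stop("negative or non-finite times")
  if (!all(events %in% c(0L, 1L))) stop("events must be 0/1")
  et <- sort(unique(times[events == 1L]))
  n_risk <- vapply(et, function(t) sum(times >= t), 0L)
  n_event <- vapply(et, function(t) sum(times == t & events == 1L), 0L)
  surv <- cumprod(1 - n_event / n_risk)
  # Greenwood: var(S) = S^2 * cumsum(d / (r (r - d)));  0/0 at S = 0 -> 0
  gsum <- cumsum(ifelse(n_risk > n_event, n_event / (n_risk * (n_risk - n_event)), 0))
  gvar <- surv^2 * gsum
  med <- if (any(surv <= 0.5)) et[which(surv <= 0.5)[1]] else NA_real_
  out <- list(times = et, survival = surv, greenwood_var = gvar,
              n_risk = n_risk, n_event = n_event, median = med,
              n = length(times), n_events = sum(events))
  class(out) <- "km_fit"
  out
}

#' Survival probability at given times (right-continuous step function)
#' @param object A `"km_fit"`.
#' @param t Times at which to evaluate S(t).
#' @param ... Unused.
#' @export
predict.km_fit <- function(object, t, ...) {
  if (length(object$times) == 0L) return(rep(1, length(t)))
  idx <- findInterval(t, object$times)
  c(1, object$survival)[idx + 1L]
}

#' @export
print.km_fit <- function(x, ...) {
  cat("Kaplan-Meier estimate: n =", x$n, " events =", x$n_events,
      " median =", ifelse(is.na(x$median), "not reached", format(x$median)), "\n")
  invisible(x)
}

#' @export
summary.km_fit <- function(object, ...) {
  data.frame(time = object$times, n_risk = object$n_risk,
             n_event = object$n_event, survival = object$survival,
             std_err = sqrt(object$greenwood_var))
}

#' @export
plot.km_fit <- function(x, xlab = "Time", ylab = "Survival probability", ...) {
  tt <- c(0, rep(x$times, each = 2))
  ss <- c(1, 1, rep(x$survival, each = 2))[seq_along(tt)]
  plot(tt, ss, type = "l", ylim = c(0, 1), xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Log-rank test, optionally stratified
#'
#' Observed-minus-expected chi-square with hypergeometric variance, summed
#' over strata when given; df = number of groups - 1. With two groups and no
#' tied event times this equals the squared Cox score test at beta = 0.
#'
#' @param times Follow-up times.
#' @param events 0/1 event indicators.
#' @param group Group labels (>= 2 levels).
#' @param strata Optional stratum labels.
#' @return A list of class `"bct_test"`: `statistic`, `df`, `p_value`, `method`.
#' @export
logrank_test <- function(times, events, group, strata = NULL) {
  times <- as.numeric(times)
  events <- as.integer(events)
  group <- factor(group)
  if (nlevels(group) < 2L) stop("need at least two groups")
  if (sum(events) == 0L) stop("no events")
  if (is.null(strata)) strata <- rep(1L, length(times))
  strata <- factor(strata)
  g <- nlevels(group)
  U <- rep(0, g - 1L)
  V <- matrix(0, g - 1L, g - 1L)
  for (s in levels(strata)) {
    sel <- strata == s
    ts <- times[sel]; es <- events[sel]; gs <- group[sel]
    if (sum(es) == 0L) next
    for (t in sort(unique(ts[es == 1L]))) {
      at <- ts >= t
      r <- sum(at)
      d <- sum(ts == t & es == 1L)
      rk <- vapply(levels(group)[-g], function(l) sum(at & gs == l), 0L)
      dk <- vapply(levels(group)[-g], function(l) sum(ts == t & es == 1L & gs == l), 0L)
      U <- U + dk - d * rk / r
      if (r > 1L) {
        cv <- d * (r - d) / (r - 1) *
          (diag(rk / r, nrow = g - 1L) - tcrossprod(rk / r))
        V <- V + cv
      }
    }
  }
  stat <- tryCatch(drop(t(U) %*% solve(V, U)), error = function(e) 0)
  if (!is.finite(stat)) stat <- 0
  out <- list(statistic = stat, df = g - 1L,
              p_value = stats::pchisq(stat, df = g - 1L, lower.tail = FALSE),
              method = if (nlevels(strata) > 1L) "stratified log-rank" else "log-rank")
  class(out) <- "bct_test"
  out
}

#' @export
print.bct_test <- function(x, ...) {
  cat(x$method, ": statistic = ", format(x$statistic, digits = 5),
      ", df = ", x$df, ", p = ", format(x$p_value, digits = 4), "\n", sep = "")
  invisible(x)
}
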