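# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths: the partial likelihood is evaluated by
# naive O(n^2) risk-set sums and maximized by golden-section search; AUC is a
# direct pairwise count.

# Naive Cox partial log-likelihood for a single covariate, Efron or Breslow.
oracle_coxpl_1d <- function(beta, times, events, x, ties = "efron") {
  ll <- 0
  for (t in sort(unique(times[events == 1]))) {
    D <- which(times == t & events == 1)
    R <- which(times >= t)
    d <- length(D)
    wR <- exp(beta * x[R])
    wD <- exp(beta * x[D])
    for (j in seq_len(d) - 1) {
      f <- if (ties == "efron") j / d else 0
      ll <- ll - log(sum(wR) - f * sum(wD))
    }
    ll <- ll + beta * sum(x[D])
  }
  ll
}

# Golden-section maximizer over [-10, 10] to 1e-6.
oracle_cox_coef_1d <- function(times, events, x, ties = "efron") {
  gr <- (sqrt(5) - 1) / 2
  a <- -10; b <- 10
  c1 <- b - gr * (b - a); c2 <- a + gr * (b - a)
  f1 <- oracle_coxpl_1d(c1, times, events, x, ties)
  f2 <- oracle_coxpl_1d(c2, times, events, x, ties)
  while (b - a > 1e-6) {
    if (f1 < f2) {
      a <- c1; c1 <- c2; f1 <- f2
      c2 <- a + gr * (b - a)
      f2 <- oracle_coxpl_1d(c2, times, events, x, ties)
    } else {
      b <- c2; c2 <- c1; f2 <- f1
      c1 <- b - gr * (b - a)
      f1 <- oracle_coxpl_1d(c1, times, events, x, ties)
    }
  }
  (a + b) / 2
}

# Direct pairwise Mann-Whitney AUC (ties count 1/2).
oracle_pairwise_auc <- function(marker_cases, marker_controls) {
  s <- 0
  for (mc in marker_cases)
    for (mk in marker_controls)
      s <- s + (mc > mk) + 0.5 * (mc == mk)
  s / (length(marker_cases) * length(marker_controls))
}

# Small random survival fixture; ties introduced by rounding when asked.
make_fixture <- function(n, with_ties = FALSE, binary_x = TRUE) {
  tm <- rexp(n)
  if (with_ties) tm <- ceiling(tm * 4) / 4
  ev <- rbinom(n, 1, 0.8)
  if (sum(ev) == 0) ev[1] <- 1L
  x <- if (binary_x) rep_len(c(0, 1), n) else rnorm(n)
  if (diff(range(x)) == 0) x[1] <- x[1] + 1
  list(times = tm, events = ev, x = x)
}

# Null two-arm config at a given size (no planted effects).
null_config <- function(n_treated, n_control, seed, ...) {
  sim_config(n_treated = n_treated, n_control = n_control, seed = seed,
             missing_prob = 0, ...)
}
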