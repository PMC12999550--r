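# Shared fixtures and brute-force oracles used across the test files.

# Brute-force product-limit estimator: risk sets counted record by record
# straight from the definition Y(t) = #{L_j < t <= T_j}.
brute_km <- function(rec) {
  tt <- sort(unique(rec$followup_time[rec$event == 1]))
  surv <- 1
  rows <- lapply(tt, function(t) {
    Y <- sum(rec$truncation_time < t & rec$followup_time >= t)
    d <- sum(rec$followup_time == t & rec$event == 1)
    surv <<- surv * (1 - d / Y)
    data.frame(time = t, n_risk = Y, n_event = d, surv = surv)
  })
  if (length(rows) == 0) {
    return(data.frame(time = numeric(), n_risk = integer(),
                      n_event = integer(), surv = numeric()))
  }
  do.call(rbind, rows)
}

# Random small record sets, optionally left-truncated, for property tests.
# Times live on a dyadic grid so that ties are exact in floating point.
random_records <- function(n, truncated = FALSE, arm = "C") {
  tt <- sample(1:256, n, replace = TRUE) / 128
  ev <- rbinom(n, 1, 0.7)
  L <- if (truncated) sample(0:96, n, replace = TRUE) / 128 else rep(0, n)
  keep <- tt > L
  observed_records(tt[keep], ev[keep], L[keep], rep(arm, sum(keep)))
}

# Reference two-piece-exponential survival function.
pw_surv <- function(t, t0, lambda0, lambda) {
  ifelse(t <= t0, exp(-lambda0 * t),
         exp(-lambda0 * t0 - lambda * (t - t0)))
}

# A small planning configuration used when a full design_plan would be
# overkill; fields match what recalculate_n2 / conditional_power need.
toy_plan <- function(w1 = 0.664, delta0 = 0.075, n1 = 772, n_max = 1908,
                     beta_cond = 0.2, cp_min = 0.2) {
  list(w1 = w1, w2 = sqrt(1 - w1^2), delta0 = delta0, n1 = n1,
       n_max = n_max, beta_cond = beta_cond, cp_min = cp_min)
}
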