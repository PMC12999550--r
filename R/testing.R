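#' O'Brien-Fleming-type alpha-spending function
#'
#' `alpha_tilde(I) = 2 * (1 - Phi( Phi^-1(1 - alpha/2) / sqrt(I / I_max) ))`,
#' capped at `alpha` once the observed information reaches the planned
#' maximum (over-running spends all remaining alpha at the interim look).
#'
#' @param info observed information level (positive).
#' @param I_max planned maximum information level.
#' @param alpha global one-sided significance level.
#' @return The cumulative alpha spent at information `info`.
#' @export
obf_spending <- function(info, I_max, alpha) {
  if (info <= 0 || I_max <= 0) stop("information levels must be positive")
  frac <- info / I_max
  if (frac >= 1) return(alpha)
  2 * (1 - pnorm(qnorm(1 - alpha / 2) / sqrt(frac)))
}

# P(w1 Z1 + w2 Z2 >= cfinal, Z1 < c1) with Z1 ~ N(m1, 1), Z2 ~ N(m2, 1)
# independent and w2 = sqrt(1 - w1^2). Exact one-dimensional conditioning
# integral; the joint law of (Z1, Zfinal) is bivariate normal with
# correlation w1.
.pr_joint <- function(cfinal, c1, w1, m1 = 0, m2 = 0) {
  w2 <- sqrt(1 - w1^2)
  if (!is.finite(cfinal)) return(0)
  integrate(function(z) {
    dnorm(z, mean = m1) * pnorm((cfinal - w1 * z - w2 * m2) / w2,
                                lower.tail = FALSE)
  }, lower = -Inf, upper = c1, rel.tol = 1e-10, abs.tol = 1e-12)$value
}

# Solve P(Zfinal >= c, Z1 < c1) = target for c by bracketed root search.
.solve_cfinal <- function(c1, w1, target) {
  if (target <= 0) return(Inf)
  f <- function(c) .pr_joint(c, c1, w1) - target
  lo <- qnorm(1 - target) - 2
  hi <- 9
  uniroot(f, lower = lo, upper = hi, tol = 1e-10, extendInt = "downX")$root
}

#' Interim and final critical values under alpha spending
#'
#' The interim boundary is `c1 = Phi^-1(1 - alpha_tilde(I_1))` with
#' `alpha_tilde` the O'Brien-Fleming-type spending at the observed interim
#' information. The final boundary `c_final` solves
#' `P(Z_final >= c, Z1 < c1) = alpha - alpha_tilde(I_1)` under the null
#' bivariate normal law of `(Z1, Z_final)` with correlation `w1`. If all
#' alpha is already spent at interim, `c_final` is `+Inf`.
#'
#' @param info_1 observed interim information level.
#' @param I_max planned maximum information level.
#' @param alpha global one-sided significance level.
#' @param w1 pre-specified first-stage weight, `0 < w1 < 1`.
#' @return An object of class `critical_values` with `c1`, `c_final`,
#'   `alpha_spent_interim` and `alpha`.
#' @export
critical_values <- function(info_1, I_max, alpha, w1) {
  if (w1 <= 0 || w1 >= 1) stop("w1 must lie strictly in (0, 1)")
  a1 <- obf_spending(info_1, I_max, alpha)
  c1 <- qnorm(1 - a1)
  cf <- .solve_cfinal(c1, w1, alpha - a1)
  structure(list(c1 = c1, c_final = cf, alpha_spent_interim = a1,
                 alpha = alpha),
            class = "critical_values")
}

#' @export
print.critical_values <- function(x, ...) {
  cat(sprintf(
    "Boundaries: c1 = %.4f (alpha spent %.5f of %.4f), c_final = %.4f\n",
    x$c1, x$alpha_spent_interim, x$alpha, x$c_final))
  invisible(x)
}

#' Standardized stage statistic
#'
#' For a stage dataset with `n` records, computes the RMST difference, its
#' scaled dispersion `sigma_hat = sqrt(n (se_I^2 + se_C^2))`, the
#' standardized statistic `z = sqrt(n) delta_hat / sigma_hat` and the
#' information level `info = n / sigma_hat^2`.
#'
#' @param data a [stage_data()] (or records data.frame with an `arm`
#'   column).
#' @param tau truncation horizon.
#' @return A list with `z`, `delta_hat`, `sigma_hat`, `info` and `n`.
#' @export
stage_statistic <- function(data, tau) {
  rec <- as_records(data)
  d <- .rmst_diff_records(rec, tau)
  list(z = d$z, delta_hat = d$delta_hat, sigma_hat = d$sigma_hat,
       info = d$n / d$sigma_hat^2, n = d$n)
}

#' Inverse normal combination of stage statistics
#'
#' `z_final = w1 * z1 + w2 * z2` with pre-specified weights satisfying
#' `w1^2 + w2^2 = 1`.
#'
#' @param z1,z2 stage-wise standardized statistics.
#' @param w1,w2 pre-specified weights.
#' @return The combined statistic.
#' @export
combine_stages <- function(z1, z2, w1, w2) {
  # tolerance generous enough for weights quoted to three decimals
  if (abs(w1^2 + w2^2 - 1) > 1e-3) stop("weights must satisfy w1^2 + w2^2 = 1")
  w1 * z1 + w2 * z2
}

#' Second-stage statistic variants
#'
#' Computes the three ways of forming the stage-2 standardized statistic:
#' \describe{
#'   \item{`truncated`}{`z2 = sqrt(n2 + nbar1) * delta_hat(X2) / sigma_hat_2`,
#'     directly from the left-truncated stage-2 data.}
#'   \item{`desseaux_porcher`}{`z2' = (z_all sqrt(I_all) - z1 sqrt(I_1)) /
#'     sqrt(I_all - I_1)`, avoiding truncated-data estimation entirely.}
#'   \item{`combined`}{`z2'' = delta_hat(X2) * sqrt(I_all - I_1)`,
#'     the truncated-data effect estimate with the information increment of
#'     the full data.}
#' }
#' All three are asymptotically equivalent under the independent-increment
#' structure `I_all = I_1 + I_2 + o_p(n)`.
#'
#' @param stat1 interim [stage_statistic()].
#' @param stat2 stage-2 [stage_statistic()] (truncated data).
#' @param stat_all full-data [stage_statistic()].
#' @return Named list with `truncated`, `desseaux_porcher`, `combined`.
#' @export
stage_two_variants <- function(stat1, stat2, stat_all) {
  if (stat_all$info <= stat1$info) stop("non-increasing information")
  dI <- stat_all$info - stat1$info
  list(
    truncated = stat2$z,
    desseaux_porcher = (stat_all$z * sqrt(stat_all$info) -
                          stat1$z * sqrt(stat1$info)) / sqrt(dI),
    combined = stat2$delta_hat * sqrt(dI)
  )
}

# --- comparator tests ------------------------------------------------------

# Risk-set table at the pooled event times, truncation-aware.
.logrank_table <- function(time, status, entry, grp) {
  evt <- sort(unique(time[status == 1L]))
  if (length(evt) == 0L) return(NULL)
  st <- sort(time)
  se <- sort(entry)
  stI <- sort(time[grp])
  seI <- sort(entry[grp])
  n <- length(time)
  nI <- length(stI)
  # #{x < t} via findInterval with left-open intervals
  lt <- function(t, v) findInterval(t, v, left.open = TRUE)
  Y <- as.numeric(lt(evt, se) - lt(evt, st))
  YI <- as.numeric(lt(evt, seI) - lt(evt, stI))
  tab <- function(tt) {
    idx <- match(tt, evt)
    counts <- integer(length(evt))
    tbl <- table(idx)
    counts[as.integer(names(tbl))] <- as.integer(tbl)
    counts
  }
  d <- tab(time[status == 1L])
  dI <- tab(time[status == 1L & grp])
  list(time = evt, Y = Y, YI = YI, d = d, dI = dI)
}

#' One-sided log-rank statistic with delayed-entry risk sets
#'
#' Standardized log-rank score statistic comparing the intervention and
#' control arms, with risk sets `Y(t) = #[L < t <= T]` so that
#' left-truncated records are handled by delayed entry. The sign is
#' oriented so that positive values favour the intervention arm (fewer
#' events than expected), matching the orientation of the RMST statistics.
#'
#' @param data a [stage_data()] or records data.frame with both arms.
#' @return The standardized one-sided z statistic, with the score `score`
#'   and its variance `var` as attributes.
#' @export
logrank_z <- function(data) {
  rec <- as_records(data)
  grp <- rec$arm == "I"
  if (all(grp) || !any(grp)) stop("both arms must be present")
  tb <- .logrank_table(rec$followup_time, rec$event, rec$truncation_time, grp)
  if (is.null(tb)) stop("no events observed")
  keep <- tb$Y > 1
  U <- sum(tb$dI - tb$YI * tb$d / tb$Y)
  V <- sum((tb$d[keep] * (tb$Y[keep] - tb$d[keep]) / (tb$Y[keep] - 1)) *
             (tb$YI[keep] / tb$Y[keep]) * (1 - tb$YI[keep] / tb$Y[keep]))
  z <- -U / sqrt(V)
  attr(z, "score") <- U
  attr(z, "var") <- V
  z
}

#' One-sided tau-year survival statistic
#'
#' Difference in Kaplan-Meier survival at `tau` between the arms over its
#' Greenwood standard error, positive when the intervention arm survives
#' longer.
#'
#' @param data a [stage_data()] or records data.frame with both arms.
#' @param tau evaluation time (years).
#' @return Standardized z statistic, with attributes `surv_I`, `surv_C`.
#' @export
tau_year_z <- function(data, tau) {
  rec <- as_records(data)
  one_arm <- function(a) {
    cv <- km_fit(rec[rec$arm == a, , drop = FALSE])
    keep <- cv$time <= tau & cv$n_risk > cv$n_event
    s <- km_surv_at(cv, tau)
    if (s <= 0) stop(sprintf("S(tau) undefined (zero) in arm %s", a))
    y <- as.numeric(cv$n_risk[keep])
    d <- as.numeric(cv$n_event[keep])
    v <- s^2 * sum(d / (y * (y - d)))
    c(s, v)
  }
  sI <- one_arm("I")
  sC <- one_arm("C")
  z <- (sI[1] - sC[1]) / sqrt(sI[2] + sC[2])
  attr(z, "surv_I") <- sI[1]
  attr(z, "surv_C") <- sC[1]
  z
}
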