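#' Kaplan-Meier estimation for right-censored, left-truncated data
#'
#' Fits the product-limit estimator for the records of one arm. The risk set
#' at time t is `Y(t) = #[j : L_j < t <= T_j]`, so subjects with a positive
#' truncation (delayed entry) time `L` enter the risk set strictly after `L`;
#' with all `L = 0` this is the standard right-censored Kaplan-Meier
#' estimator. Tied events are aggregated into a single multiplicative step,
#' and censored observations tied with an event time stay in the risk set
#' for that event.
#'
#' @param records data.frame of observed records for a single arm
#'   (see [observed_records()]); an `arm` column, if present, must be
#'   constant.
#' @return An object of class `km_curve`: a list with `time` (event times),
#'   `surv` (the estimator at each event time), `n_risk`, `n_event` and
#'   `n` (number of records used).
#' @export
km_fit <- function(records) {
  records <- as_records(records)
  if (is.null(records) || nrow(records) == 0L) stop("no records")
  if (!is.null(records$arm) && length(unique(records$arm)) > 1L)
    stop("km_fit expects records from a single arm")
  validate_records_single <- records[, c("followup_time", "event",
                                         "truncation_time")]
  if (any(validate_records_single$truncation_time > 0 &
          validate_records_single$followup_time <=
          validate_records_single$truncation_time))
    stop("invalid truncation")
  cv <- .km_curve_cpp(as.numeric(records$followup_time),
                      as.integer(records$event),
                      as.numeric(records$truncation_time))
  structure(cv, class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: %d records, %d event times\n",
              x$n, length(x$time)))
  if (length(x$time)) {
    show <- data.frame(time = x$time, n_risk = x$n_risk,
                       n_event = x$n_event, surv = x$surv)
    print(utils::head(show, 10), row.names = FALSE)
    if (length(x$time) > 10) cat("  ...\n")
  }
  invisible(x)
}

# Step-function evaluation S(t) with right-continuous steps at event times.
km_surv_at <- function(curve, t) {
  if (length(curve$time) == 0L) return(rep(1, length(t)))
  idx <- findInterval(t, curve$time)
  c(1, curve$surv)[idx + 1L]
}

#' Restricted mean survival time from a fitted curve
#'
#' Integrates the Kaplan-Meier step function over `[0, tau]`. The standard
#' error is the Greenwood-type estimator for the integrated survival curve:
#' `sum over event times t_i <= tau of A_i^2 d_i / (Y_i (Y_i - d_i))`, with
#' `A_i` the residual area of the curve on `(t_i, tau]`. If the last step is
#' before `tau` the curve is carried forward. With no events before `tau` the
#' point estimate is `tau` and the standard error is 0 (flagged via
#' `se_defined`).
#'
#' @param curve a [km_fit()] result.
#' @param tau positive truncation horizon (years).
#' @return An object of class `rmst_estimate` with `tau`, `mu_hat`, `se`,
#'   `se_defined` and `n_used`.
#' @export
rmst <- function(curve, tau) {
  if (!inherits(curve, "km_curve")) stop("curve must be a km_curve")
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0)
    stop("tau must be a positive scalar")
  keep <- curve$time <= tau
  t_i <- curve$time[keep]
  s_i <- curve$surv[keep]
  y_i <- as.numeric(curve$n_risk[keep])   # avoid integer overflow in Y(Y-d)
  d_i <- as.numeric(curve$n_event[keep])
  k <- length(t_i)
  if (k == 0L) {
    return(structure(list(tau = tau, mu_hat = tau, se = 0,
                          se_defined = FALSE, n_used = curve$n),
                     class = "rmst_estimate"))
  }
  s_prev <- c(1, s_i[-k])
  areas <- s_prev * diff(c(0, t_i))
  mu <- sum(areas) + s_i[k] * (tau - t_i[k])
  cum <- cumsum(areas)
  resid <- mu - cum                       # area on (t_i, tau]
  ok <- y_i > d_i
  v <- sum(resid[ok]^2 * d_i[ok] / (y_i[ok] * (y_i[ok] - d_i[ok])))
  structure(list(tau = tau, mu_hat = mu, se = sqrt(v),
                 se_defined = TRUE, n_used = curve$n),
            class = "rmst_estimate")
}

#' @export
print.rmst_estimate <- function(x, ...) {
  cat(sprintf("RMST(tau = %g): %.4f years (SE %.4f, n = %d)\n",
              x$tau, x$mu_hat, x$se, x$n_used))
  invisible(x)
}

# Fast single-arm (mu, var, n_events) via the compiled kernel.
.rmst_arm <- function(followup, event, truncation, tau) {
  .rmst_arm_cpp(as.numeric(followup), as.integer(event),
                as.numeric(truncation), tau)
}

#' Between-arm RMST difference and its scaled standard deviation
#'
#' Computes `delta_hat = mu_hat(I) - mu_hat(C)` and the standardized-scale
#' dispersion `sigma_hat = sqrt(n * (se_I^2 + se_C^2))`, where `n` is the
#' total number of records supplied, so that
#' `sqrt(n) * delta_hat / sigma_hat = delta_hat / sqrt(se_I^2 + se_C^2)` is
#' the standardized test statistic. If one arm has no events before `tau`,
#' its variance contribution is zero and a warning is issued.
#'
#' @param data_I,data_C records (or `stage_data`) for the intervention and
#'   control arms; either may contain an `arm` column restricted to one arm.
#' @param tau truncation horizon.
#' @return A list with `delta_hat`, `sigma_hat`, `mu_I`, `mu_C`, `se_I`,
#'   `se_C`, `n` and `z` (the standardized statistic).
#' @export
rmst_difference <- function(data_I, data_C, tau) {
  recI <- as_records(data_I)
  recC <- as_records(data_C)
  if (nrow(recI) == 0L || nrow(recC) == 0L) stop("both arms must be non-empty")
  aI <- .rmst_arm(recI$followup_time, recI$event, recI$truncation_time, tau)
  aC <- .rmst_arm(recC$followup_time, recC$event, recC$truncation_time, tau)
  if (aI[3] == 0 || aC[3] == 0)
    warning("an arm has no events before tau; its variance contribution is 0")
  n <- nrow(recI) + nrow(recC)
  delta <- aI[1] - aC[1]
  vsum <- aI[2] + aC[2]
  sigma <- sqrt(n * vsum)
  list(delta_hat = delta, sigma_hat = sigma,
       mu_I = aI[1], mu_C = aC[1],
       se_I = sqrt(aI[2]), se_C = sqrt(aC[2]),
       n = n, z = if (vsum > 0) delta / sqrt(vsum) else NA_real_)
}

# Split records into arms and compute the stage difference in one call.
.rmst_diff_records <- function(records, tau) {
  isI <- records$arm == "I"
  rmst_difference(records[isI, , drop = FALSE],
                  records[!isI, , drop = FALSE], tau)
}
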