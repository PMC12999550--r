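#' Conditional power of the combination test
#'
#' Probability of final rejection given the observed interim statistic
#' `z1`, computed under the design alternative `delta0` and current
#' nuisance values:
#' `CP = 1 - Phi( (c_final - w1 z1)/w2 -
#'   delta0 * sqrt( nbar1/sigma21^2 + n2/sigma1_star^2 ) )`.
#' The square root term is the drift of the stage-2 statistic: pipeline
#' patients contribute information `nbar1/sigma21^2`, newly recruited
#' patients `n2/sigma1_star^2`.
#'
#' @param delta0 assumed RMST difference.
#' @param z1 observed interim statistic.
#' @param c_final final critical value (from the observed interim
#'   information).
#' @param w1,w2 pre-specified combination weights.
#' @param n_pipeline number of pipeline patients (`nbar1`, both arms).
#' @param n2 newly recruited stage-2 patients (both arms).
#' @param sigma21 pipeline-follow-up asymptotic SD.
#' @param sigma1_star full-follow-up asymptotic SD.
#' @return The conditional power.
#' @export
conditional_power <- function(delta0, z1, c_final, w1, w2, n_pipeline, n2,
                              sigma21, sigma1_star) {
  if (sigma1_star <= 0 || sigma21 <= 0) stop("sigmas must be positive")
  if (!is.finite(c_final)) return(0)
  drift <- delta0 * sqrt(n_pipeline / sigma21^2 + n2 / sigma1_star^2)
  1 - pnorm((c_final - w1 * z1) / w2 - drift)
}

# Occurrence/exposure rate with window-restricted events and person-time.
.oe_rate <- function(events, exposure) {
  if (exposure <= 0 || events == 0) return(NA_real_)
  events / exposure
}

# Piecewise-exponential occurrence/exposure MLEs from interim
# right-censored records: pooled early hazard on (0, t0], control-arm late
# hazard on (t0, tau], and the dropout rate from censorings occurring
# strictly before both tau and the administrative horizon t_int - entry.
.interim_rate_mle <- function(rec, t0, tau, t_int) {
  fu <- rec$followup_time
  ev <- rec$event
  expo0 <- sum(pmin(fu, t0))
  d0 <- sum(ev == 1L & fu <= t0)
  ctrl <- rec$arm == "C"
  expoC <- sum(pmax(fu[ctrl] - t0, 0))
  dC <- sum(ev[ctrl] == 1L & fu[ctrl] > t0)
  if (all(is.na(rec$entry_time))) stop("entry_time required for dropout MLE")
  Lj <- t_int - rec$entry_time
  ndrop <- sum(ev == 0L & fu < pmin(Lj, tau) - 1e-9)
  list(lambda0 = .oe_rate(d0, expo0),
       lambdaC = .oe_rate(dC, expoC),
       dropout = ndrop / sum(fu),
       events_early = d0, exposure_early = expo0,
       events_late_control = dC, exposure_late_control = expoC,
       n_dropout = ndrop, exposure_total = sum(fu))
}

#' Constrained interim re-estimation of nuisance parameters
#'
#' Re-estimates the data-generating rates from interim right-censored data
#' by piecewise-exponential maximum likelihood (occurrence/exposure):
#' the shared early hazard `lambda0` from pooled events and person-time on
#' `(0, t0]`, the control late hazard `lambdaC` from control-arm events and
#' person-time on `(t0, tau]`, and the dropout rate from identified dropout
#' censorings over total person-time. The intervention late hazard is not
#' estimated freely: it is fixed by the constraint that the RMST difference
#' equals the design alternative `delta0` (only nuisance rates are
#' updated). The three asymptotic SDs are then re-estimated by simulation
#' at the updated rates via [estimate_sigmas()].
#'
#' Records whose censoring time is strictly before both `tau` and the
#' administrative interim horizon `t_int - entry_time` are counted as
#' dropouts; this requires `entry_time` to be present in the records.
#' A rate whose window carries no events or no exposure falls back to the
#' planning guess, with a warning.
#'
#' @param interim_data interim [stage_data()] (right-censored, both arms).
#' @param t0 change point of the piecewise hazards.
#' @param delta0 design RMST difference imposed as a constraint.
#' @param tau truncation horizon.
#' @param t_int interim analysis time.
#' @param fallback optional guessed [hazard_scenario()] supplying fallback
#'   rates (and `tE`).
#' @param L_sims,sim_n simulation size for the SD re-estimation.
#' @param seed optional seed; `NULL` continues the RNG stream.
#' @return A list with the updated `nuisance` ([estimate_sigmas()] result),
#'   the fitted `scenario`, and the raw `rates`.
#' @export
interim_nuisance_update <- function(interim_data, t0, delta0, tau, t_int,
                                    fallback = NULL, L_sims = 100,
                                    sim_n = 10000, seed = NULL) {
  rec <- as_records(interim_data)
  if (length(unique(rec$arm)) < 2L) stop("both arms required")
  mle <- .interim_rate_mle(rec, t0, tau, t_int)
  lambda0_hat <- mle$lambda0
  lambdaC_hat <- mle$lambdaC
  drop_hat <- mle$dropout

  if (is.na(lambda0_hat)) {
    if (is.null(fallback)) stop("no events/exposure on (0, t0] and no fallback")
    warning("falling back to planning guess for lambda0")
    lambda0_hat <- fallback$lambda0
  }
  if (is.na(lambdaC_hat)) {
    if (is.null(fallback)) stop("no control events/exposure on (t0, tau]")
    warning("falling back to planning guess for lambdaC")
    lambdaC_hat <- fallback$lambdaC
  }

  # constrained step: lambdaI is implied by Delta = delta0 at the updated
  # nuisance rates; clamp to the attainable range if needed
  u <- tau - t0
  bound <- exp(-lambda0_hat * t0) *
    (u - (1 - exp(-lambdaC_hat * u)) / lambdaC_hat)
  lambdaI_hat <- if (delta0 <= 0) lambdaC_hat
  else if (delta0 >= bound * (1 - 1e-9)) {
    warning("delta0 at the boundary of the attainable range; clamping lambdaI")
    lambdaC_hat * 1e-6
  } else solve_lambda_I(t0, lambda0_hat, lambdaC_hat, tau, delta0)

  tE <- if (!is.null(fallback)) fallback$tE else t_int + tau
  scen <- hazard_scenario(t0, lambda0_hat, lambdaC_hat,
                          lambdaI = lambdaI_hat, dropout_rate = drop_hat,
                          tau = tau, tE = tE)
  nuis <- estimate_sigmas(scen, t_int, L_sims = L_sims, sim_n = sim_n,
                          seed = seed)
  list(nuisance = nuis, scenario = scen,
       rates = list(lambda0 = lambda0_hat, lambdaC = lambdaC_hat,
                    lambdaI = lambdaI_hat, dropout = drop_hat))
}

#' Recalculated second-stage sample size
#'
#' Inverts the conditional-power equation in closed form: with
#' `q = (c_final - w1 z1)/w2` and `z_cond = Phi^-1(1 - beta_cond)`, the
#' smallest stage-2 recruitment achieving conditional power
#' `1 - beta_cond` is
#' `n2* = sigma1_star^2 * ( ((q + z_cond)/delta0)^2 - nbar1/sigma21^2 )`,
#' rounded up to an even integer and clamped to `[0, n_max - n1]`. A
#' non-positive `n2*` means the pipeline data alone already deliver the
#' target conditional power; a clamped value means even the maximally
#' feasible sample size falls short, and the trial continues at the cap.
#'
#' @param z1 observed interim statistic.
#' @param c_final final critical value.
#' @param plan a [design_plan()].
#' @param nuisance updated [estimate_sigmas()] values.
#' @param n_pipeline realized number of pipeline patients.
#' @return Even integer `n2` in `[0, n_max - n1]`.
#' @export
recalculate_n2 <- function(z1, c_final, plan, nuisance, n_pipeline) {
  cap <- max(plan$n_max - plan$n1, 0L)
  if (!is.finite(c_final)) return(as.integer(cap))
  q <- (c_final - plan$w1 * z1) / plan$w2
  need <- q + qnorm(1 - plan$beta_cond)
  if (need <= 0) return(0L)
  base <- n_pipeline / nuisance$sigma21^2
  n2_raw <- nuisance$sigma1_star^2 * ((need / plan$delta0)^2 - base)
  if (n2_raw <= 0) return(0L)
  if (n2_raw >= cap) return(as.integer(cap))
  .even_ceiling(n2_raw)
}

#' Interim decision: efficacy, futility, or continue with recalculated n2
#'
#' Applies the full interim logic to observed interim data: computes the
#' interim statistic and critical values from the observed information,
#' stops for efficacy when `z1 >= c1`; otherwise re-estimates the nuisance
#' parameters under the `Delta = delta0` constraint, evaluates the
#' conditional power at the *initially planned* stage-2 size, stops
#' (non-bindingly) for futility when it falls below `cp_min`, and otherwise
#' recalculates the second-stage recruitment to reach conditional power
#' `1 - beta_cond` within the sample-size cap.
#'
#' @param interim_data interim [stage_data()].
#' @param plan a [design_plan()].
#' @param planned_n2 initially planned stage-2 recruitment (defaults to
#'   `n_total - n1`).
#' @param L_sims,sim_n simulation size for the nuisance re-estimation.
#' @param seed optional seed; `NULL` continues the RNG stream.
#' @return An object of class `interim_decision`.
#' @export
interim_decide <- function(interim_data, plan,
                           planned_n2 = plan$n_total - plan$n1,
                           L_sims = 100, sim_n = 10000, seed = NULL) {
  tau <- plan$tau
  stat1 <- stage_statistic(interim_data, tau)
  cv <- critical_values(stat1$info, plan$I_max, plan$alpha, plan$w1)
  nbar1 <- interim_data$n_pipeline
  if (is.na(nbar1)) stop("interim data must carry n_pipeline")
  out <- list(z1 = stat1$z, c1 = cv$c1, c_final = cv$c_final,
              info_1 = stat1$info, stat1 = stat1, boundaries = cv,
              n_pipeline = nbar1, cp_planned_n2 = NA_real_,
              n2_new = NA_integer_, cp_achieved = NA_real_,
              nuisance = NULL, rates = NULL)
  if (stat1$z >= cv$c1) {
    out$action <- "stop_efficacy"
    out$n2_new <- 0L
    return(structure(out, class = "interim_decision"))
  }
  upd <- interim_nuisance_update(interim_data, plan$scenario$t0,
                                 plan$delta0, tau, plan$t_int,
                                 fallback = plan$scenario,
                                 L_sims = L_sims, sim_n = sim_n, seed = seed)
  out$nuisance <- upd$nuisance
  out$rates <- upd$rates
  out$cp_planned_n2 <- conditional_power(
    plan$delta0, stat1$z, cv$c_final, plan$w1, plan$w2,
    nbar1, planned_n2, upd$nuisance$sigma21, upd$nuisance$sigma1_star)
  if (out$cp_planned_n2 < plan$cp_min) {
    out$action <- "stop_futility"
    out$n2_new <- 0L
    return(structure(out, class = "interim_decision"))
  }
  out$action <- "continue"
  out$n2_new <- recalculate_n2(stat1$z, cv$c_final, plan, upd$nuisance, nbar1)
  out$cp_achieved <- conditional_power(
    plan$delta0, stat1$z, cv$c_final, plan$w1, plan$w2,
    nbar1, out$n2_new, upd$nuisance$sigma21, upd$nuisance$sigma1_star)
  structure(out, class = "interim_decision")
}

#' @export
print.interim_decision <- function(x, ...) {
  cat(sprintf("Interim decision: %s\n", x$action))
  cat(sprintf("  z1 = %.3f vs c1 = %.3f (info %.1f); c_final = %.3f\n",
              x$z1, x$c1, x$info_1, x$c_final))
  if (!is.na(x$cp_planned_n2))
    cat(sprintf("  CP at planned n2 = %.3f", x$cp_planned_n2))
  if (!is.na(x$n2_new) && x$action == "continue")
    cat(sprintf("; recalculated n2 = %d (CP %.3f)", x$n2_new, x$cp_achieved))
  cat("\n")
  invisible(x)
}
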