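#' Delayed-treatment-effect hazard scenario
#'
#' Describes the piecewise-constant hazard data model used throughout the
#' package: both arms share the early hazard `lambda0` up to the change
#' point `t0`; afterwards the control arm has hazard `lambdaC` and the
#' intervention arm `lambdaI`. Dropout is exponential with rate
#' `dropout_rate`, accrual is uniform over `[0, tE]`, and every patient is
#' followed for exactly `tau` years (absent dropout). Exactly one of
#' `lambdaI` and `delta` must be given: the other is filled in through the
#' closed-form RMST difference of the two-piece exponential model.
#'
#' @param t0 change point (years), `0 < t0 < tau`.
#' @param lambda0 shared early hazard rate.
#' @param lambdaC control-arm late hazard rate.
#' @param lambdaI intervention-arm late hazard rate (or `NULL`).
#' @param delta target true RMST difference (or `NULL`).
#' @param dropout_rate exponential loss-to-follow-up rate (per year).
#' @param tau RMST truncation horizon (years).
#' @param tE accrual duration (years).
#' @return An object of class `hazard_scenario`.
#' @export
hazard_scenario <- function(t0, lambda0, lambdaC, lambdaI = NULL,
                            delta = NULL, dropout_rate = 0, tau, tE) {
  if (t0 <= 0 || t0 >= tau) stop("t0 must lie strictly inside (0, tau)")
  if (lambda0 <= 0 || lambdaC <= 0) stop("hazard rates must be positive")
  if (dropout_rate < 0) stop("dropout_rate must be non-negative")
  if (is.null(lambdaI) == is.null(delta))
    stop("give exactly one of lambdaI and delta")
  if (is.null(lambdaI)) {
    lambdaI <- if (delta == 0) lambdaC else
      solve_lambda_I(t0, lambda0, lambdaC, tau, delta)
  } else {
    if (lambdaI <= 0) stop("hazard rates must be positive")
    delta <- rmst_diff_closed_form(t0, lambda0, lambdaI, lambdaC, tau)
  }
  structure(list(t0 = t0, lambda0 = lambda0, lambdaC = lambdaC,
                 lambdaI = lambdaI, dropout_rate = dropout_rate,
                 tau = tau, tE = tE, delta = delta),
            class = "hazard_scenario")
}

#' @export
print.hazard_scenario <- function(x, ...) {
  cat(sprintf(
    "Two-piece exponential scenario: t0 = %g, lambda0 = %g, lambdaC = %g, lambdaI = %g\n",
    x$t0, x$lambda0, x$lambdaC, x$lambdaI))
  cat(sprintf("  dropout rate = %g, tau = %g, tE = %g, true RMST difference = %.5f\n",
              x$dropout_rate, x$tau, x$tE, x$delta))
  invisible(x)
}

# Two-piece exponential event times by inversion: with cumulative hazard
# lambda0*t up to t0 and lambda0*t0 + lambda*(t - t0) after.
.sim_event_times <- function(n, t0, lambda0, lambda) {
  e <- rexp(n)
  brk <- lambda0 * t0
  tt <- e / lambda0
  late <- e > brk
  tt[late] <- t0 + (e[late] - brk) / lambda
  tt
}

# Latent times for n subjects with alternating 1:1 block allocation.
.sim_latent <- function(scenario, n) {
  arm <- rep_len(c("I", "C"), n)
  isI <- arm == "I"
  tt <- numeric(n)
  tt[isI] <- .sim_event_times(sum(isI), scenario$t0, scenario$lambda0,
                              scenario$lambdaI)
  tt[!isI] <- .sim_event_times(sum(!isI), scenario$t0, scenario$lambda0,
                               scenario$lambdaC)
  cc <- if (scenario$dropout_rate > 0) rexp(n, scenario$dropout_rate)
        else rep(Inf, n)
  list(event_time = tt, dropout_time = cc, arm = arm, isI = isI)
}

#' Simulate subject-level trial data
#'
#' Draws `n` subjects from a [hazard_scenario()]: entry calendar times
#' uniform over `accrual`, latent event times from the two-piece exponential
#' model by inversion, latent dropout times exponential. Arms are assigned
#' by deterministic 1:1 alternation, so even `n` splits exactly 1:1.
#'
#' @param scenario a [hazard_scenario()].
#' @param n number of subjects.
#' @param accrual length-2 vector, the calendar accrual window.
#' @param seed optional integer seed; `NULL` continues the current RNG
#'   stream.
#' @return A data.frame with `id`, `entry_time`, `event_time`,
#'   `dropout_time` and `arm` (latent subject records).
#' @export
simulate_subjects <- function(scenario, n,
                              accrual = c(0, scenario$tE), seed = NULL) {
  if (n <= 0) stop("n must be positive")
  if (!is.null(seed)) set.seed(seed)
  lat <- .sim_latent(scenario, n)
  data.frame(id = seq_len(n),
             entry_time = runif(n, accrual[1], accrual[2]),
             event_time = lat$event_time,
             dropout_time = lat$dropout_time,
             arm = lat$arm,
             stringsAsFactors = FALSE)
}

# Final-analysis observables: T~ = min(T, C, tau), delta = 1(T <= min(C, tau)).
.observe <- function(subjects, tau) {
  tfull <- pmin(subjects$event_time, subjects$dropout_time, tau)
  list(followup = tfull,
       event = as.integer(subjects$event_time <=
                            pmin(subjects$dropout_time, tau)))
}

#' Full-follow-up records for a set of subjects
#'
#' @param subjects latent subject data from [simulate_subjects()].
#' @param tau truncation horizon.
#' @param stage stage label for the returned [stage_data()].
#' @return A `stage_data` with truncation 0 and follow-up
#'   `min(T, C, tau)` for every subject.
#' @export
observe_full <- function(subjects, tau, stage = "all") {
  ob <- .observe(subjects, tau)
  rec <- observed_records(ob$followup, ob$event, 0, subjects$arm,
                          entry_time = subjects$entry_time,
                          id = subjects$id)
  stage_data(rec, stage = stage, n1 = nrow(rec))
}

#' Interim snapshot of stage-1 subjects
#'
#' Administratively censors every stage-1 subject at calendar time `t_int`:
#' the interim follow-up is `min(T~, L)` with `L = t_int - entry_time`, and
#' the interim event indicator is `1(T <= min(C, tau, L))`. All truncation
#' times are 0 (interim data are only right-censored). The returned object
#' records `n_pipeline`, the number of subjects whose interim follow-up is
#' strictly shorter than their final follow-up, i.e. those still under
#' observation at the interim analysis.
#'
#' @param subjects latent stage-1 subject data (all entries before `t_int`).
#' @param t_int calendar time of the interim analysis.
#' @param tau truncation horizon.
#' @return A `stage_data` with `stage = "interim"`.
#' @export
interim_snapshot <- function(subjects, t_int, tau) {
  if (any(subjects$entry_time >= t_int))
    stop("all stage-1 subjects must enter before t_int")
  L <- t_int - subjects$entry_time
  ob <- .observe(subjects, tau)
  fu1 <- pmin(ob$followup, L)
  ev1 <- as.integer(ob$event == 1L & ob$followup <= L)
  rec <- observed_records(fu1, ev1, 0, subjects$arm,
                          entry_time = subjects$entry_time,
                          id = subjects$id)
  stage_data(rec, stage = "interim", n1 = nrow(rec),
             n_pipeline = sum(fu1 < ob$followup))
}

#' Assemble the second-stage dataset
#'
#' The stage-2 data consist of (a) every stage-1 subject not fully observed
#' at interim (the "pipeline" patients), entered with their *final*
#' follow-up and a left-truncation time `L = t_int - entry_time`, and (b)
#' all newly recruited stage-2 subjects with truncation 0. Pipeline
#' patients are left-truncated because they contribute to stage 2 only
#' conditional on being event-free at the interim analysis.
#'
#' @param subjects latent stage-1 subject data.
#' @param t_int calendar time of the interim analysis.
#' @param tau truncation horizon.
#' @param new_subjects latent data for newly recruited stage-2 subjects
#'   (may have zero rows).
#' @return A `stage_data` with `stage = "stage2"`, `n2 = nrow(new_subjects)`
#'   and `n_pipeline` the size of group (a).
#' @export
stage_two_assemble <- function(subjects, t_int, tau, new_subjects = NULL) {
  L <- t_int - subjects$entry_time
  ob <- .observe(subjects, tau)
  pipe <- ob$followup > L            # interim follow-up < final follow-up
  recs <- list()
  if (any(pipe)) {
    recs$pipeline <- observed_records(
      ob$followup[pipe], ob$event[pipe], L[pipe], subjects$arm[pipe],
      entry_time = subjects$entry_time[pipe], id = subjects$id[pipe])
  }
  n2 <- 0L
  if (!is.null(new_subjects) && nrow(new_subjects) > 0L) {
    ob2 <- .observe(new_subjects, tau)
    recs$new <- observed_records(
      ob2$followup, ob2$event, 0, new_subjects$arm,
      entry_time = new_subjects$entry_time, id = new_subjects$id)
    n2 <- nrow(new_subjects)
  }
  if (length(recs) == 0L) stop("stage-2 data are empty")
  rec <- do.call(rbind, recs)
  rownames(rec) <- NULL
  stage_data(rec, stage = "stage2", n1 = nrow(subjects), n2 = n2,
             n_pipeline = sum(pipe))
}

#' Reconstruct the full-follow-up dataset from the two stage files
#'
#' At the final analysis the complete (untruncated) dataset consists of the
#' stage-1 records that were already fully observed at interim plus every
#' stage-2 record with its truncation removed (pipeline rows in the stage-2
#' data carry the final follow-up of their subjects). Requires subject ids
#' unique across stages.
#'
#' @param stage1 interim [stage_data()] (or records).
#' @param stage2 stage-2 [stage_data()] (or records).
#' @return A `stage_data` with `stage = "all"`.
#' @export
assemble_full_data <- function(stage1, stage2) {
  r1 <- as_records(stage1)
  r2 <- as_records(stage2)
  done <- !(r1$id %in% r2$id)
  r2$truncation_time <- rep(0, nrow(r2))
  rec <- rbind(r1[done, , drop = FALSE], r2)
  rownames(rec) <- NULL
  stage_data(rec, stage = "all", n1 = nrow(r1),
             n2 = if (inherits(stage2, "stage_data")) stage2$n2
                  else NA_integer_)
}

#' Dropout and interim censoring probabilities by numeric integration
#'
#' `P(C < min(T, tau))`, the probability that a subject is censored by
#' dropout within the `tau`-year follow-up, computed by quadrature from the
#' scenario's survival and dropout distributions (averaged over the two
#' arms).
#'
#' @param scenario a [hazard_scenario()].
#' @return Scalar dropout probability.
#' @export
dropout_probability <- function(scenario) {
  c0 <- scenario$dropout_rate
  if (c0 == 0) return(0)
  surv <- function(t, lam) {
    ifelse(t <= scenario$t0, exp(-scenario$lambda0 * t),
           exp(-scenario$lambda0 * scenario$t0 - lam * (t - scenario$t0)))
  }
  one <- function(lam) {
    integrate(function(t) c0 * exp(-c0 * t) * surv(t, lam),
              0, scenario$tau, rel.tol = 1e-10)$value
  }
  (one(scenario$lambdaI) + one(scenario$lambdaC)) / 2
}
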