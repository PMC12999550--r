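#' Closed-form RMST difference of the two-piece exponential model
#'
#' For hazards equal to `lambda0` in both arms up to `t0` and `lambdaI`
#' (intervention) / `lambdaC` (control) afterwards, the RMST difference at
#' horizon `tau` is
#' `exp(-lambda0 t0) * [(1 - exp(-lambdaI (tau - t0)))/lambdaI -
#'  (1 - exp(-lambdaC (tau - t0)))/lambdaC]`,
#' since the survival curves coincide on `[0, t0]`.
#'
#' @param t0 change point, `t0 < tau`.
#' @param lambda0,lambdaI,lambdaC positive hazard rates.
#' @param tau truncation horizon.
#' @return The exact RMST difference (years).
#' @export
rmst_diff_closed_form <- function(t0, lambda0, lambdaI, lambdaC, tau) {
  if (t0 >= tau) stop("t0 must be smaller than tau")
  u <- tau - t0
  exp(-lambda0 * t0) *
    ((1 - exp(-lambdaI * u)) / lambdaI - (1 - exp(-lambdaC * u)) / lambdaC)
}

#' Solve the intervention hazard for a target RMST difference
#'
#' Finds `lambdaI` such that the closed-form RMST difference equals
#' `delta0`, by bracketed root search to an absolute tolerance of 1e-12 in
#' the difference. `delta0` must be attainable: it has to be smaller than
#' the supremum reached as `lambdaI -> 0`
#' (`exp(-lambda0 t0) * [(tau - t0) - (1 - exp(-lambdaC (tau-t0)))/lambdaC]`).
#'
#' @inheritParams rmst_diff_closed_form
#' @param delta0 target RMST difference, `0 <= delta0 <` the attainable
#'   bound.
#' @return The solved `lambdaI`.
#' @export
solve_lambda_I <- function(t0, lambda0, lambdaC, tau, delta0) {
  if (delta0 == 0) return(lambdaC)
  u <- tau - t0
  bound <- exp(-lambda0 * t0) * (u - (1 - exp(-lambdaC * u)) / lambdaC)
  if (delta0 < 0 || delta0 >= bound)
    stop(sprintf("delta0 must lie in [0, %.6f) for these rates", bound))
  f <- function(l) rmst_diff_closed_form(t0, lambda0, l, lambdaC, tau) - delta0
  lo <- 1e-12
  uniroot(f, lower = lo, upper = lambdaC, tol = 1e-14,
          f.lower = bound - delta0 - 1e-15)$root
}

#' Simulation-based asymptotic standard deviations
#'
#' Estimates, for a given data-generating scenario and interim time, the
#' three asymptotic standard deviations needed for planning and sample-size
#' recalculation:
#' `sigma1` (limit of the scaled interim-data estimator dispersion),
#' `sigma1_star` (limit of the full-follow-up dispersion `sigma_hat_all`),
#' and `sigma21` (per-pipeline-patient dispersion of the post-interim
#' follow-up information). Each of `L_sims` replicates simulates `sim_n`
#' stage-1 subjects entering uniformly on `[0, t_int]`, computes the scaled
#' variance `n * (se_I^2 + se_C^2)` of the RMST difference on (a) the
#' interim snapshot and (b) the full `tau`-year follow-up, and records the
#' fraction of pipeline subjects. `sigma1^2` and `sigma1_star^2` are the
#' averages of (a) and (b); `sigma21` is derived from the information
#' additivity of the two stages,
#' `n1/sigma1_star^2 = n1/sigma1^2 + nbar1/sigma21^2`, giving
#' `sigma21^2 = (nbar1/n1) / (1/sigma1_star^2 - 1/sigma1^2)`.
#'
#' @param scenario a [hazard_scenario()].
#' @param t_int interim analysis time (years after accrual start).
#' @param L_sims number of simulation replicates.
#' @param sim_n subjects per replicate.
#' @param seed optional integer seed; `NULL` continues the RNG stream.
#' @return An object of class `nuisance_estimates` with `sigma1`,
#'   `sigma21`, `sigma1_star`, `pipeline_fraction`, `L_sims`, `sim_n`.
#' @export
estimate_sigmas <- function(scenario, t_int, L_sims = 100, sim_n = 10000,
                            seed = NULL) {
  if (L_sims < 1) stop("L_sims must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  tau <- scenario$tau
  s1sq <- numeric(L_sims)
  sallsq <- numeric(L_sims)
  pipe <- numeric(L_sims)
  for (l in seq_len(L_sims)) {
    lat <- .sim_latent(scenario, sim_n)
    entry <- runif(sim_n, 0, t_int)
    Lj <- t_int - entry
    tfull <- pmin(lat$event_time, lat$dropout_time, tau)
    dfull <- as.integer(lat$event_time <= pmin(lat$dropout_time, tau))
    fu1 <- pmin(tfull, Lj)
    ev1 <- as.integer(dfull == 1L & tfull <= Lj)
    isI <- lat$isI
    zI <- numeric(sum(isI))
    zC <- numeric(sim_n - length(zI))
    aI1 <- .rmst_arm_cpp(fu1[isI], ev1[isI], zI, tau)
    aC1 <- .rmst_arm_cpp(fu1[!isI], ev1[!isI], zC, tau)
    aIa <- .rmst_arm_cpp(tfull[isI], dfull[isI], zI, tau)
    aCa <- .rmst_arm_cpp(tfull[!isI], dfull[!isI], zC, tau)
    s1sq[l] <- sim_n * (aI1[2] + aC1[2])
    sallsq[l] <- sim_n * (aIa[2] + aCa[2])
    pipe[l] <- mean(fu1 < tfull)
  }
  sigma1 <- sqrt(mean(s1sq))
  sigma1_star <- sqrt(mean(sallsq))
  pf <- mean(pipe)
  dinfo <- 1 / sigma1_star^2 - 1 / sigma1^2
  sigma21 <- if (dinfo > 0) sqrt(pf / dinfo) else Inf
  structure(list(sigma1 = sigma1, sigma21 = sigma21,
                 sigma1_star = sigma1_star, pipeline_fraction = pf,
                 L_sims = L_sims, sim_n = sim_n),
            class = "nuisance_estimates")
}

#' @export
print.nuisance_estimates <- function(x, ...) {
  cat(sprintf(
    "Nuisance SDs (L = %d x n = %d): sigma1 = %.4f, sigma1* = %.4f, sigma21 = %.4f\n",
    x$L_sims, x$sim_n, x$sigma1, x$sigma1_star, x$sigma21))
  cat(sprintf("  expected pipeline fraction nbar1/n1 = %.3f\n",
              x$pipeline_fraction))
  invisible(x)
}

#' Planned maximum information level
#'
#' `I_max = gamma * (Phi^-1(alpha) + Phi^-1(beta))^2 / delta0^2`, the
#' information a two-look design must accumulate to retain power
#' `1 - beta`, with `gamma` the group-sequential inflation factor.
#'
#' @param alpha one-sided significance level.
#' @param beta type-II error rate.
#' @param delta0 alternative-hypothesis RMST difference.
#' @param gamma inflation factor (1 for a fixed design).
#' @return The maximum information level.
#' @export
max_information <- function(alpha, beta, delta0, gamma = 1.01) {
  if (alpha <= 0 || alpha >= 1 || beta <= 0 || beta >= 1)
    stop("alpha and beta must be in (0, 1)")
  if (delta0 == 0) stop("delta0 must be non-zero")
  gamma * (qnorm(1 - alpha) + qnorm(1 - beta))^2 / delta0^2
}

#' Initial total sample size
#'
#' `n = gamma * (Phi^-1(alpha) + Phi^-1(beta))^2 / (delta0 / sigma1_star)^2`,
#' rounded up to the next even integer (1:1 allocation; per-group size is
#' `n/2`). With `gamma = 1` this is the fixed-design sample size.
#'
#' @inheritParams max_information
#' @param sigma1_star asymptotic SD of the full-follow-up RMST difference
#'   (scaled by the square root of the total sample size).
#' @return Even integer total sample size.
#' @export
fixed_sample_size <- function(alpha, beta, delta0, sigma1_star, gamma = 1) {
  raw <- max_information(alpha, beta, delta0, gamma) * sigma1_star^2
  .even_ceiling(raw)
}

.even_ceiling <- function(x) {
  n <- as.integer(ceiling(x - 1e-9))
  if (n %% 2L == 1L) n + 1L else n
}

#' First-stage sample size under uniform accrual
#'
#' `n1 = n * t_int / tE`, rounded to the nearest even integer (ties up).
#'
#' @param n total planned sample size.
#' @param t_int interim analysis time.
#' @param tE accrual duration, `0 < t_int <= tE`.
#' @return Even integer stage-1 size.
#' @export
stage_one_size <- function(n, t_int, tE) {
  if (t_int <= 0 || t_int > tE) stop("need 0 < t_int <= tE")
  as.integer(2 * floor(n * t_int / tE / 2 + 0.5))
}

#' Pre-specified combination-test weights
#'
#' `w1 = sqrt((n1/sigma1^2) / (n/sigma1_star^2))` -- the square root of the
#' expected fraction of the maximum information available at interim -- and
#' `w2 = sqrt(1 - w1^2)`, so that `w1^2 + w2^2 = 1`.
#'
#' @param n1 stage-1 sample size.
#' @param sigma1 interim-data asymptotic SD.
#' @param n total planned sample size.
#' @param sigma1_star full-follow-up asymptotic SD.
#' @return List with `w1` and `w2`.
#' @export
combination_weights <- function(n1, sigma1, n, sigma1_star) {
  if (min(n1, sigma1, n, sigma1_star) <= 0) stop("arguments must be positive")
  if (n1 > n) stop("n1 must not exceed n")
  w1sq <- (n1 / sigma1^2) / (n / sigma1_star^2)
  if (w1sq > 1)
    stop("inconsistent inputs: interim information exceeds total information")
  list(w1 = sqrt(w1sq), w2 = sqrt(1 - w1sq))
}

#' Group-sequential inflation factor
#'
#' The factor `gamma >= 1` by which the maximum information of a two-look
#' design must exceed the fixed-design information so that the design,
#' spending alpha at the interim look according to `spending`, still
#' attains power `1 - beta`. Computed by solving the two-stage power
#' equation (the bivariate-normal joint law of the interim and final
#' statistics with correlation `sqrt(info_fraction)`) numerically.
#'
#' @param alpha one-sided significance level.
#' @param beta type-II error rate.
#' @param info_fraction planned interim information fraction.
#' @param spending alpha-spending function with the signature of
#'   [obf_spending()]; the default is the O'Brien-Fleming-type spending
#'   used throughout the package.
#' @return The inflation factor `gamma`.
#' @export
inflation_factor <- function(alpha = 0.025, beta = 0.2,
                             info_fraction = 0.6, spending = obf_spending) {
  f <- info_fraction
  atilde <- spending(f, 1, alpha)
  w1 <- sqrt(f)
  w2 <- sqrt(1 - f)
  theta <- qnorm(1 - alpha) + qnorm(1 - beta)
  if (atilde <= 0) return(1)            # no interim spending: fixed design
  c1 <- qnorm(1 - atilde)
  cf <- .solve_cfinal(c1, w1, alpha - atilde)
  power <- function(gamma) {
    m1 <- sqrt(gamma * f) * theta
    m2 <- sqrt(gamma * (1 - f)) * theta
    (1 - pnorm(c1 - m1)) + .pr_joint(cf, c1, w1, m1 = m1, m2 = m2)
  }
  uniroot(function(g) power(g) - (1 - beta), lower = 1, upper = 1.5,
          tol = 1e-9, extendInt = "upX")$root
}

#' Full pre-trial design plan
#'
#' Runs the complete planning pipeline for a guessed data-generating
#' scenario: simulation-based nuisance SDs, fixed-design and inflated total
#' sample sizes, stage-1 size under uniform accrual, maximum information,
#' combination weights and the sample-size cap.
#'
#' @param scenario the guessed [hazard_scenario()] used for planning (its
#'   `delta` is the design effect `delta0` unless overridden).
#' @param t_int interim analysis time.
#' @param alpha,beta one-sided significance level and type-II error rate.
#' @param beta_cond conditional-power shortfall target (recalculation aims
#'   at conditional power `1 - beta_cond`).
#' @param delta0 design RMST difference (defaults to `scenario$delta`).
#' @param gamma inflation factor for the maximum information.
#' @param cp_min futility boundary on the conditional power.
#' @param n_max_factor cap multiplier: `n_max = n_max_factor * n_fix`.
#' @param L_sims,sim_n simulation size for [estimate_sigmas()].
#' @param seed optional seed for the planning simulations.
#' @return An object of class `design_plan`.
#' @export
design_plan <- function(scenario, t_int, alpha = 0.025, beta = 0.2,
                        beta_cond = 0.2, delta0 = scenario$delta,
                        gamma = 1.01, cp_min = 0.2, n_max_factor = 1.5,
                        L_sims = 100, sim_n = 10000, seed = NULL) {
  if (is.null(delta0) || delta0 <= 0)
    stop("delta0 must be positive for planning")
  nuisance <- estimate_sigmas(scenario, t_int, L_sims, sim_n, seed)
  n_fix <- fixed_sample_size(alpha, beta, delta0, nuisance$sigma1_star,
                             gamma = 1)
  n_total <- fixed_sample_size(alpha, beta, delta0, nuisance$sigma1_star,
                               gamma = gamma)
  n1 <- stage_one_size(n_total, t_int, scenario$tE)
  n_max <- .even_ceiling(n_max_factor * n_fix)
  w <- combination_weights(n1, nuisance$sigma1, n_total,
                           nuisance$sigma1_star)
  structure(list(
    alpha = alpha, beta = beta, beta_cond = beta_cond, delta0 = delta0,
    tau = scenario$tau, tE = scenario$tE, t_int = t_int,
    t_final = scenario$tE + scenario$tau, gamma = gamma,
    I_max = max_information(alpha, beta, delta0, gamma),
    n_fix = n_fix, n_total = n_total, n1 = n1, n_max = n_max,
    cp_min = cp_min, w1 = w$w1, w2 = w$w2,
    nuisance = nuisance, scenario = scenario),
    class = "design_plan")
}

#' Serialize a design plan to a flat key-value file
#'
#' Writes (and reads back) every design constant, the nuisance SDs and the
#' guessed scenario as `key = value` text, so a plan fixed at trial start
#' can be archived and reused at the interim and final analyses.
#'
#' @param plan a [design_plan()].
#' @param path file path.
#' @return `read_design_plan()` returns a `design_plan` object.
#' @export
write_design_plan <- function(plan, path) {
  sc <- plan$scenario
  nu <- plan$nuisance
  kv <- list(alpha = plan$alpha, beta = plan$beta,
             beta_cond = plan$beta_cond, delta0 = plan$delta0,
             tau = plan$tau, tE = plan$tE, t_int = plan$t_int,
             t_final = plan$t_final, gamma = plan$gamma,
             I_max = plan$I_max, n_fix = plan$n_fix,
             n_total = plan$n_total, n1 = plan$n1, n_max = plan$n_max,
             cp_min = plan$cp_min, w1 = plan$w1, w2 = plan$w2,
             sigma1 = nu$sigma1, sigma21 = nu$sigma21,
             sigma1_star = nu$sigma1_star,
             pipeline_fraction = nu$pipeline_fraction,
             L_sims = nu$L_sims, sim_n = nu$sim_n,
             scenario_t0 = sc$t0, scenario_lambda0 = sc$lambda0,
             scenario_lambdaC = sc$lambdaC, scenario_lambdaI = sc$lambdaI,
             scenario_dropout_rate = sc$dropout_rate)
  write_keyvalue(kv, path)
}

#' @rdname write_design_plan
#' @export
read_design_plan <- function(path) {
  kv <- read_keyvalue(path)
  sc <- hazard_scenario(kv$scenario_t0, kv$scenario_lambda0,
                        kv$scenario_lambdaC, lambdaI = kv$scenario_lambdaI,
                        dropout_rate = kv$scenario_dropout_rate,
                        tau = kv$tau, tE = kv$tE)
  nu <- structure(list(sigma1 = kv$sigma1, sigma21 = kv$sigma21,
                       sigma1_star = kv$sigma1_star,
                       pipeline_fraction = kv$pipeline_fraction,
                       L_sims = as.integer(kv$L_sims),
                       sim_n = as.integer(kv$sim_n)),
                  class = "nuisance_estimates")
  structure(list(alpha = kv$alpha, beta = kv$beta,
                 beta_cond = kv$beta_cond, delta0 = kv$delta0,
                 tau = kv$tau, tE = kv$tE, t_int = kv$t_int,
                 t_final = kv$t_final, gamma = kv$gamma, I_max = kv$I_max,
                 n_fix = as.integer(kv$n_fix),
                 n_total = as.integer(kv$n_total),
                 n1 = as.integer(kv$n1), n_max = as.integer(kv$n_max),
                 cp_min = kv$cp_min, w1 = kv$w1, w2 = kv$w2,
                 nuisance = nu, scenario = sc),
            class = "design_plan")
}

#' @export
print.design_plan <- function(x, ...) {
  cat("Adaptive two-stage RMST design plan\n")
  cat(sprintf("  alpha = %g (one-sided), power = %g, delta0 = %g, tau = %g\n",
              x$alpha, 1 - x$beta, x$delta0, x$tau))
  cat(sprintf("  n (total, gamma = %g) = %d  [fixed design %d, cap %d]\n",
              x$gamma, x$n_total, x$n_fix, x$n_max))
  cat(sprintf("  n1 = %d at t_int = %g (accrual %g y), I_max = %.1f\n",
              x$n1, x$t_int, x$tE, x$I_max))
  cat(sprintf("  weights: w1 = %.3f, w2 = %.3f\n", x$w1, x$w2))
  print(x$nuisance)
  invisible(x)
}
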