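#' Simulation scenario configuration
#'
#' Bundles everything a full adaptive-trial simulation needs: the true
#' data-generating rates, the (possibly mis-specified) planning guesses
#' expressed as multipliers `g0` and `gC` on the true rates, the design
#' constants and the interim timing. The guessed rates are
#' `lambda0_guess = g0 * lambda0_true` and `lambdaC_guess = gC *
#' lambdaC_true`; the intervention hazards are implied by the RMST
#' differences (`delta_true` for the truth, `delta0` for the guess).
#'
#' @param name scenario label.
#' @param delta_true true RMST difference (0 under the null).
#' @param delta0 design alternative used for planning and recalculation.
#' @param t_int interim analysis time.
#' @param g0,gC mis-specification multipliers for the guessed rates.
#' @param t0 change point.
#' @param lambda0_true,lambdaC_true true rates.
#' @param r_cens_true,r_cens_guess true and guessed dropout rates.
#' @param tau,tE truncation horizon and accrual duration.
#' @param alpha,beta,beta_cond,cp_min,n_max_factor,gamma design constants.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(name, delta_true, delta0, t_int = 1.8,
                            g0 = 1, gC = 1, t0 = 0.8,
                            lambda0_true = 0.4, lambdaC_true = 0.7,
                            r_cens_true = 0.095, r_cens_guess = 0.090,
                            tau = 1.5, tE = 3, alpha = 0.025, beta = 0.2,
                            beta_cond = 0.2, cp_min = 0.2,
                            n_max_factor = 1.5, gamma = 1.01) {
  structure(list(name = name, delta_true = delta_true, delta0 = delta0,
                 t_int = t_int, g0 = g0, gC = gC, t0 = t0,
                 lambda0_true = lambda0_true, lambdaC_true = lambdaC_true,
                 r_cens_true = r_cens_true, r_cens_guess = r_cens_guess,
                 tau = tau, tE = tE, alpha = alpha, beta = beta,
                 beta_cond = beta_cond, cp_min = cp_min,
                 n_max_factor = n_max_factor, gamma = gamma),
            class = "scenario_config")
}

#' True and guessed data-generating scenarios of a configuration
#'
#' @param config a [scenario_config()].
#' @return A [hazard_scenario()].
#' @export
scenario_truth <- function(config) {
  hazard_scenario(config$t0, config$lambda0_true, config$lambdaC_true,
                  delta = config$delta_true,
                  dropout_rate = config$r_cens_true,
                  tau = config$tau, tE = config$tE)
}

#' @rdname scenario_truth
#' @export
scenario_guess <- function(config) {
  hazard_scenario(config$t0, config$g0 * config$lambda0_true,
                  config$gC * config$lambdaC_true,
                  delta = config$delta0,
                  dropout_rate = config$r_cens_guess,
                  tau = config$tau, tE = config$tE)
}

#' The ten benchmark scenarios
#'
#' S1 is the reference (delayed effect `delta = 0.075`, interim at 1.8
#' years, mildly mis-specified guesses `g0 = 0.8`, `gC = 1.1`); S2 and S3
#' are null scenarios; S4 and S5 vary the effect size; S6 and S7 the
#' interim timing; S8-S10 the quality of the planning guesses, with S10
#' interchanging the true and guessed rates of S9 (so the initial sample
#' size is larger than needed).
#'
#' @return Named list of [scenario_config()] objects `S1`-`S10`.
#' @export
scenario_fixtures <- function() {
  list(
    S1 = scenario_config("S1", delta_true = 0.075, delta0 = 0.075,
                         t_int = 1.8, g0 = 0.8, gC = 1.1),
    S2 = scenario_config("S2", delta_true = 0, delta0 = 0.075,
                         t_int = 1.8, g0 = 0.8, gC = 1.1),
    S3 = scenario_config("S3", delta_true = 0, delta0 = 0.075,
                         t_int = 1.8, g0 = 1, gC = 1),
    S4 = scenario_config("S4", delta_true = 0.05, delta0 = 0.05,
                         t_int = 1.8, g0 = 0.8, gC = 1.1),
    S5 = scenario_config("S5", delta_true = 0.1, delta0 = 0.1,
                         t_int = 1.8, g0 = 0.8, gC = 1.1),
    S6 = scenario_config("S6", delta_true = 0.075, delta0 = 0.075,
                         t_int = 2.0, g0 = 0.8, gC = 1.1),
    S7 = scenario_config("S7", delta_true = 0.075, delta0 = 0.075,
                         t_int = 2.2, g0 = 0.8, gC = 1.1),
    S8 = scenario_config("S8", delta_true = 0.075, delta0 = 0.075,
                         t_int = 1.8, g0 = 1, gC = 1),
    S9 = scenario_config("S9", delta_true = 0.075, delta0 = 0.075,
                         t_int = 1.8, g0 = 0.5, gC = 0.8),
    S10 = scenario_config("S10", delta_true = 0.075, delta0 = 0.075,
                          t_int = 1.8, g0 = 2.0, gC = 1.25,
                          lambda0_true = 0.2, lambdaC_true = 0.56)
  )
}

# Comparator stage statistics: z, an effect estimate and an information
# level, so the same three combination variants can be formed.
.comparator_stats <- function(records, tau) {
  lr <- tryCatch(logrank_z(records), error = function(e) NULL)
  ty <- tryCatch(tau_year_z(records, tau), error = function(e) NULL)
  list(
    lr = if (is.null(lr)) NULL else {
      V <- attr(lr, "var")
      list(z = as.numeric(lr), info = V, effect = -attr(lr, "score") / V)
    },
    ty = if (is.null(ty)) NULL else {
      eff <- attr(ty, "surv_I") - attr(ty, "surv_C")
      zz <- as.numeric(ty)
      info <- if (eff != 0) (zz / eff)^2 else NA_real_
      list(z = zz, info = info, effect = eff)
    }
  )
}

.variants_generic <- function(s1, s2, sall) {
  if (is.null(s1) || is.null(s2) || is.null(sall) ||
      !is.finite(sall$info) || !is.finite(s1$info) || sall$info <= s1$info)
    return(list(v1 = NA_real_, v2 = NA_real_, v3 = NA_real_))
  dI <- sall$info - s1$info
  list(v1 = s2$z,
       v2 = (sall$z * sqrt(sall$info) - s1$z * sqrt(s1$info)) / sqrt(dI),
       v3 = s2$effect * sqrt(dI))
}

#' Run one adaptive trial replicate
#'
#' Generates stage-1 data at the true rates, applies the full interim
#' decision logic (efficacy / futility / continue with recalculated `n2`),
#' generates second-stage data if the trial continues, and evaluates the
#' three RMST combination-test variants plus the log-rank and tau-year
#' comparators at the spending-based boundaries.
#'
#' @param config a [scenario_config()].
#' @param seed integer replicate seed (`NULL` continues the RNG stream).
#' @param plan a precomputed [design_plan()]; computed from the guessed
#'   rates if `NULL`.
#' @param truth a precomputed true [hazard_scenario()]; derived from
#'   `config` if `NULL`.
#' @param L_sims,sim_n simulation size of the interim nuisance
#'   re-estimation.
#' @return One-row data.frame with the decision path, sample sizes,
#'   conditional power and the rejection indicator of every test/variant.
#' @export
run_trial_once <- function(config, seed = NULL, plan = NULL, truth = NULL,
                           L_sims = 100, sim_n = 10000) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(truth)) truth <- scenario_truth(config)
  if (is.null(plan))
    plan <- design_plan(scenario_guess(config), config$t_int,
                        alpha = config$alpha, beta = config$beta,
                        beta_cond = config$beta_cond, delta0 = config$delta0,
                        gamma = config$gamma, cp_min = config$cp_min,
                        n_max_factor = config$n_max_factor,
                        L_sims = L_sims, sim_n = sim_n)
  tau <- config$tau
  t_int <- config$t_int
  subjects <- simulate_subjects(truth, plan$n1, accrual = c(0, t_int))
  x1 <- interim_snapshot(subjects, t_int, tau)
  # rare boundary conditions (clamped constraint, event-free arms) raise
  # warnings that are expected noise inside a Monte-Carlo run
  dec <- suppressWarnings(interim_decide(x1, plan, L_sims = L_sims,
                                         sim_n = sim_n))
  cmp1 <- .comparator_stats(x1$records, tau)

  rej <- matrix(FALSE, nrow = 3, ncol = 3,
                dimnames = list(c("rmst", "lr", "ty"), c("v1", "v2", "v3")))
  n2 <- 0L
  cp <- NA_real_
  if (dec$action == "stop_efficacy") {
    rej["rmst", ] <- TRUE
    if (!is.null(cmp1$lr)) rej["lr", ] <- cmp1$lr$z >= dec$c1
    if (!is.null(cmp1$ty)) rej["ty", ] <- cmp1$ty$z >= dec$c1
  } else if (dec$action == "continue") {
    n2 <- dec$n2_new
    cp <- dec$cp_achieved
    new_subj <- if (n2 > 0)
      simulate_subjects(truth, n2, accrual = c(t_int, max(config$tE, t_int + 1e-6)))
    else NULL
    x2 <- stage_two_assemble(subjects, t_int, tau, new_subj)
    all_subjects <- if (is.null(new_subj)) subjects else
      rbind(subjects, new_subj)
    xall <- observe_full(all_subjects, tau)
    stat2 <- stage_statistic(x2, tau)
    statall <- stage_statistic(xall, tau)
    v_rmst <- stage_two_variants(dec$stat1, stat2, statall)
    zf <- plan$w1 * dec$z1 + plan$w2 * unlist(v_rmst)
    rej["rmst", ] <- zf >= dec$c_final
    cmp2 <- .comparator_stats(x2$records, tau)
    cmpall <- .comparator_stats(xall$records, tau)
    for (tst in c("lr", "ty")) {
      s1c <- cmp1[[tst]]
      vv <- .variants_generic(s1c, cmp2[[tst]], cmpall[[tst]])
      if (!is.null(s1c)) {
        zfc <- plan$w1 * s1c$z + plan$w2 * unlist(vv)
        rej[tst, ] <- !is.na(zfc) & zfc >= dec$c_final
      }
    }
  }
  data.frame(
    action = dec$action, z1 = dec$z1, c1 = dec$c1, c_final = dec$c_final,
    n1 = plan$n1, n_pipeline = dec$n_pipeline, n2 = n2,
    n_total = plan$n1 + n2,
    cp_planned = dec$cp_planned_n2, cp = cp,
    rej_rmst_1 = rej["rmst", 1], rej_rmst_2 = rej["rmst", 2],
    rej_rmst_3 = rej["rmst", 3],
    rej_lr_1 = rej["lr", 1], rej_lr_2 = rej["lr", 2],
    rej_lr_3 = rej["lr", 3],
    rej_ty_1 = rej["ty", 1], rej_ty_2 = rej["ty", 2],
    rej_ty_3 = rej["ty", 3],
    stringsAsFactors = FALSE
  )
}

#' Monte-Carlo operating characteristics of a scenario
#'
#' Plans the trial once from the guessed rates, then runs `n_mc`
#' independent seeded replicates of the full adaptive design at the true
#' rates and aggregates rejection rates (power or type-I error for the
#' three RMST variants and both comparators), early-stopping
#' probabilities, sample-size summaries with quartiles, conditional-power
#' summaries and the total-sample-size histogram with its point masses at
#' `n1` and `n_max`. Replicates receive sub-seeds drawn once from the
#' master seed, so results do not depend on execution order.
#'
#' @param config a [scenario_config()].
#' @param n_mc number of Monte-Carlo replicates.
#' @param L_sims,sim_n simulation size used for planning and for the
#'   interim nuisance re-estimation.
#' @param seed master seed.
#' @param keep_replicates keep the per-replicate log in the result?
#' @return An object of class `oc_result`.
#' @export
run_scenario <- function(config, n_mc = 1000, L_sims = 100, sim_n = 10000,
                         seed = 1, keep_replicates = FALSE) {
  if (n_mc < 1) stop("n_mc must be at least 1")
  set.seed(seed)
  subseeds <- sample.int(.Machine$integer.max - 1L, n_mc + 2L)
  truth <- scenario_truth(config)

  set.seed(subseeds[1])
  plan <- design_plan(scenario_guess(config), config$t_int,
                      alpha = config$alpha, beta = config$beta,
                      beta_cond = config$beta_cond, delta0 = config$delta0,
                      gamma = config$gamma, cp_min = config$cp_min,
                      n_max_factor = config$n_max_factor,
                      L_sims = L_sims, sim_n = sim_n)
  # fixed-design benchmark at the true rates (lambdaI implied by delta0)
  set.seed(subseeds[2])
  truth_d0 <- hazard_scenario(config$t0, config$lambda0_true,
                              config$lambdaC_true, delta = config$delta0,
                              dropout_rate = config$r_cens_true,
                              tau = config$tau, tE = config$tE)
  sig_true <- estimate_sigmas(truth_d0, config$t_int, L_sims, sim_n)
  n_fix_true <- fixed_sample_size(config$alpha, config$beta, config$delta0,
                                  sig_true$sigma1_star, gamma = 1)

  reps <- vector("list", n_mc)
  for (i in seq_len(n_mc)) {
    reps[[i]] <- run_trial_once(config, seed = subseeds[i + 2L],
                                plan = plan, truth = truth,
                                L_sims = L_sims, sim_n = sim_n)
  }
  log <- do.call(rbind, reps)
  log$seed <- subseeds[seq_len(n_mc) + 2L]   # replicate replay seeds

  q13 <- function(x) {
    if (!length(x) || all(is.na(x))) return(c(NA_real_, NA_real_))
    unname(quantile(x, c(0.25, 0.75), na.rm = TRUE))
  }
  cont <- log$action == "continue"
  rej_cols <- grep("^rej_", names(log), value = TRUE)
  power <- vapply(rej_cols, function(cn) mean(log[[cn]]), numeric(1))
  names(power) <- sub("^rej_", "", rej_cols)
  hist_tab <- table(log$n_total)
  res <- structure(list(
    config = config, plan = plan, n_mc = n_mc,
    n_fix_true = n_fix_true, n_fix_guess = plan$n_fix,
    n1 = plan$n1, n_max = plan$n_max,
    power = power,
    p_eff = mean(log$action == "stop_efficacy"),
    p_fut = mean(log$action == "stop_futility"),
    e_n_pipeline = mean(log$n_pipeline),
    e_n2_cont = mean(log$n2[cont]), q_n2_cont = q13(log$n2[cont]),
    e_ntotal_cont = mean(log$n_total[cont]),
    q_ntotal_cont = q13(log$n_total[cont]),
    e_ntotal = mean(log$n_total), q_ntotal = q13(log$n_total),
    e_cp_cont = mean(log$cp[cont]), q_cp_cont = q13(log$cp[cont]),
    e_cp_all = mean(pmin(pmax(log$cp_planned, 0), 1), na.rm = TRUE),
    histogram = data.frame(n_total = as.numeric(names(hist_tab)),
                           proportion = as.numeric(hist_tab) / n_mc),
    mass_n1 = mean(log$n_total == plan$n1),
    mass_n_max = mean(log$n_total == plan$n_max),
    replicates = if (keep_replicates) log else NULL),
    class = "oc_result")
  res
}

#' @export
print.oc_result <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Operating characteristics: %s (delta = %g, delta0 = %g, t_int = %g), n_mc = %d\n",
              cfg$name, cfg$delta_true, cfg$delta0, cfg$t_int, x$n_mc))
  cat(sprintf("  n_fix,true = %d  n_fix,guess = %d  n1 = %d  n_max = %d\n",
              x$n_fix_true, x$n_fix_guess, x$n1, x$n_max))
  cat(sprintf("  RMST power/TOER: (1) %.1f%%  (2) %.1f%%  (3) %.1f%%\n",
              100 * x$power["rmst_1"], 100 * x$power["rmst_2"],
              100 * x$power["rmst_3"]))
  cat(sprintf("  log-rank: %.1f / %.1f / %.1f %%   tau-year: %.1f / %.1f / %.1f %%\n",
              100 * x$power["lr_1"], 100 * x$power["lr_2"],
              100 * x$power["lr_3"], 100 * x$power["ty_1"],
              100 * x$power["ty_2"], 100 * x$power["ty_3"]))
  cat(sprintf("  P(eff stop) = %.1f%%  P(fut stop) = %.1f%%\n",
              100 * x$p_eff, 100 * x$p_fut))
  cat(sprintf("  E[nbar1] = %.0f  E[n2|cont] = %.0f (%.0f; %.0f)  E[ntotal] = %.0f (%.0f; %.0f)\n",
              x$e_n_pipeline, x$e_n2_cont, x$q_n2_cont[1], x$q_n2_cont[2],
              x$e_ntotal, x$q_ntotal[1], x$q_ntotal[2]))
  cat(sprintf("  E[CP|cont] = %.1f%% (%.1f; %.1f)  mass at n1 = %.1f%%, at n_max = %.1f%%\n",
              100 * x$e_cp_cont, 100 * x$q_cp_cont[1], 100 * x$q_cp_cont[2],
              100 * x$mass_n1, 100 * x$mass_n_max))
  invisible(x)
}

#' Tabulate an `oc_result` as a one-row summary
#'
#' @param x an `oc_result`.
#' @return One-row data.frame mirroring the headline simulation metrics.
#' @export
oc_summary_row <- function(x) {
  data.frame(scenario = x$config$name,
             n_fix_true = x$n_fix_true, n_fix_guess = x$n_fix_guess,
             n1 = x$n1,
             e_nbar1 = x$e_n_pipeline, e_n2_cont = x$e_n2_cont,
             e_ntotal_cont = x$e_ntotal_cont, e_ntotal = x$e_ntotal,
             pow_rmst_1 = 100 * x$power[["rmst_1"]],
             pow_rmst_2 = 100 * x$power[["rmst_2"]],
             pow_rmst_3 = 100 * x$power[["rmst_3"]],
             pow_lr_1 = 100 * x$power[["lr_1"]],
             pow_ty_1 = 100 * x$power[["ty_1"]],
             e_cp_cont = 100 * x$e_cp_cont,
             p_eff = 100 * x$p_eff, p_fut = 100 * x$p_fut,
             stringsAsFactors = FALSE)
}
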