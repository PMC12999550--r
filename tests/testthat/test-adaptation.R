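test_that("conditional power limits and monotonicity", {
  # no drift: reduces to the plain tail probability, independent of n2
  cp0 <- conditional_power(0, 1.2, 1.96, 0.664, 0.748, 450, 500, 1.5, 1.0)
  expect_equal(cp0, 1 - pnorm((1.96 - 0.664 * 1.2) / 0.748))
  expect_equal(cp0,
               conditional_power(0, 1.2, 1.96, 0.664, 0.748, 450, 5000,
                                 1.5, 1.0))
  # monotone in n2 and z1
  cps_n <- vapply(seq(0, 2000, by = 250), function(n2) {
    conditional_power(0.075, 0.5, 1.96, 0.664, 0.748, 450, n2, 1.5, 1.0)
  }, numeric(1))
  expect_true(all(diff(cps_n) > 0))
  cps_z <- vapply(seq(-2, 3, by = 0.5), function(z) {
    conditional_power(0.075, z, 1.96, 0.664, 0.748, 450, 500, 1.5, 1.0)
  }, numeric(1))
  expect_true(all(diff(cps_z) > 0))
  # exhausted alpha: no final rejection possible
  expect_equal(conditional_power(0.075, 0.5, Inf, 0.664, 0.748, 450, 500,
                                 1.5, 1.0), 0)
})

test_that("conditional power approximates a data-level rejection rate", {
  # generate genuine stage-2 datasets at the design alternative and compare
  # the rejection fraction of the combined test with Eq-style CP; the
  # agreement is asymptotic, so the tolerance is looser than MC error
  scen <- hazard_scenario(0.8, 0.4, 0.7, delta = 0.075,
                          dropout_rate = 0.095, tau = 1.5, tE = 3)
  t_int <- 1.8
  set.seed(701)
  sig <- estimate_sigmas(scen, t_int, L_sims = 100, sim_n = 10000)
  z1 <- 0.8
  w1 <- 0.664; w2 <- sqrt(1 - w1^2)
  cfin <- 1.98
  n1 <- 772
  n2 <- 600
  nrep <- 4000
  rej <- nbar <- numeric(nrep)
  cp_pred <- numeric(nrep)
  for (i in seq_len(nrep)) {
    s1 <- simulate_subjects(scen, n1, accrual = c(0, t_int))
    new <- simulate_subjects(scen, n2, accrual = c(t_int, 3))
    x2 <- stage_two_assemble(s1, t_int, 1.5, new)
    st2 <- suppressWarnings(stage_statistic(x2, 1.5))
    rej[i] <- (w1 * z1 + w2 * st2$z) >= cfin
    cp_pred[i] <- conditional_power(0.075, z1, cfin, w1, w2,
                                    x2$n_pipeline, n2,
                                    sig$sigma21, sig$sigma1_star)
  }
  expect_equal(mean(rej), mean(cp_pred), tolerance = 0.025)
})

test_that("interim rate MLE counts events and exposure correctly", {
  # 10-subject fixture, hand-counted occurrence/exposure
  rec <- observed_records(
    followup_time  = c(0.5, 0.8, 1.0, 1.2, 0.3, 1.5, 0.9, 0.6, 1.4, 0.2),
    event          = c(1,   0,   1,   1,   0,   0,   1,   1,   0,   1),
    truncation_time = 0,
    arm            = c("C", "C", "C", "C", "C", "I", "I", "I", "I", "I"),
    entry_time     = c(0.5, 1.0, 0.8, 0.6, 1.5, 0.3, 0.9, 1.2, 0.4, 1.6))
  t0 <- 0.8; tau <- 1.5; t_int <- 1.8
  mle <- adaptRMST:::.interim_rate_mle(rec, t0, tau, t_int)
  # events in (0, t0]: subjects with event = 1 at 0.5, 0.6, 0.2
  expect_equal(mle$events_early, 3)
  expect_equal(mle$exposure_early,
               sum(pmin(c(0.5, 0.8, 1.0, 1.2, 0.3, 1.5, 0.9, 0.6, 1.4, 0.2),
                        0.8)))
  # control events after t0: 1.0 and 1.2
  expect_equal(mle$events_late_control, 2)
  expect_equal(mle$exposure_late_control, (1.0 - 0.8) + (1.2 - 0.8))
  expect_equal(mle$lambda0, mle$events_early / mle$exposure_early)
  # dropouts: censored strictly before min(L, tau):
  #  subj2 (fu 0.8 < L 0.8? no, equal) -> not dropout
  #  subj5 (fu 0.3 == L 0.3) -> administrative, not dropout
  #  subj6 (fu 1.5 = tau) -> completed, not dropout
  #  subj9 (fu 1.4 = L 1.4) -> administrative
  expect_equal(mle$n_dropout, 0)
})

test_that("interim MLE recovers the true rates at trial scale", {
  scen <- hazard_scenario(0.8, 0.4, 0.7, delta = 0.075,
                          dropout_rate = 0.095, tau = 1.5, tE = 3)
  set.seed(702)
  l0 <- lC <- numeric(500)
  for (i in 1:500) {
    s1 <- simulate_subjects(scen, 772, accrual = c(0, 1.8))
    x1 <- interim_snapshot(s1, 1.8, 1.5)
    mle <- adaptRMST:::.interim_rate_mle(x1$records, 0.8, 1.5, 1.8)
    l0[i] <- mle$lambda0
    lC[i] <- mle$lambdaC
  }
  expect_lt(abs(mean(l0) - 0.4) / 0.4, 0.05)
  expect_lt(abs(mean(lC) - 0.7) / 0.7, 0.05)
})

test_that("constrained update reproduces delta0 exactly", {
  scen <- hazard_scenario(0.8, 0.4, 0.7, delta = 0.075,
                          dropout_rate = 0.095, tau = 1.5, tE = 3)
  set.seed(703)
  s1 <- simulate_subjects(scen, 772, accrual = c(0, 1.8))
  x1 <- interim_snapshot(s1, 1.8, 1.5)
  upd <- interim_nuisance_update(x1, 0.8, 0.075, 1.5, 1.8,
                                 fallback = scen, L_sims = 5, sim_n = 1000)
  expect_equal(rmst_diff_closed_form(0.8, upd$rates$lambda0,
                                     upd$rates$lambdaI, upd$rates$lambdaC,
                                     1.5), 0.075, tolerance = 1e-9)
})

test_that("n2 recalculation is minimal and respects the cap", {
  plan <- toy_plan()
  nuis <- list(sigma21 = 1.5, sigma1_star = 1.02)
  for (z1 in c(-0.5, 0.3, 1.0)) {
    for (cfin in c(1.9, 2.1)) {
      n2 <- recalculate_n2(z1, cfin, plan, nuis, n_pipeline = 450)
      cap <- plan$n_max - plan$n1
      expect_true(n2 >= 0 && n2 <= cap)
      cp_at <- function(n) conditional_power(plan$delta0, z1, cfin, plan$w1,
                                             plan$w2, 450, n, nuis$sigma21,
                                             nuis$sigma1_star)
      if (n2 > 0 && n2 < cap) {
        expect_gte(cp_at(n2), 1 - plan$beta_cond - 1e-12)
        expect_lt(cp_at(n2 - 2), 1 - plan$beta_cond)
      }
    }
  }
  # very favourable interim data: pipeline alone suffices
  expect_identical(recalculate_n2(8, 1.96, plan, nuis, 450), 0L)
  # vanishing effect: unreachable power, spend the cap
  plan0 <- toy_plan(delta0 = 1e-6)
  expect_identical(recalculate_n2(0, 1.96, plan0, nuis, 450),
                   as.integer(plan0$n_max - plan0$n1))
})

test_that("interim decision takes the three paths correctly", {
  cfg <- scenario_fixtures()$S1
  guess <- scenario_guess(cfg)
  set.seed(704)
  plan <- design_plan(guess, cfg$t_int, delta0 = cfg$delta0,
                      L_sims = 10, sim_n = 2000)

  # overwhelming effect (far beyond the design alternative): the interim
  # statistic has to clear the conservative early O'Brien-Fleming boundary
  strong <- hazard_scenario(0.1, 0.1, 3, lambdaI = 0.01,
                            dropout_rate = 0.095, tau = 1.5, tE = 3)
  set.seed(705)
  s1 <- simulate_subjects(strong, plan$n1, accrual = c(0, cfg$t_int))
  x1 <- interim_snapshot(s1, cfg$t_int, 1.5)
  dec <- interim_decide(x1, plan, L_sims = 5, sim_n = 1000)
  expect_identical(dec$action, "stop_efficacy")
  expect_gte(dec$z1, dec$c1)

  # strongly unfavourable data: futility stop
  harm <- hazard_scenario(0.8, 0.4, 0.7, lambdaI = 2.5,
                          dropout_rate = 0.095, tau = 1.5, tE = 3)
  set.seed(706)
  s1h <- simulate_subjects(harm, plan$n1, accrual = c(0, cfg$t_int))
  x1h <- interim_snapshot(s1h, cfg$t_int, 1.5)
  dech <- suppressWarnings(interim_decide(x1h, plan, L_sims = 5,
                                          sim_n = 1000))
  expect_identical(dech$action, "stop_futility")
  expect_lt(dech$cp_planned_n2, plan$cp_min)

  # data at the design alternative: typically continue, with a coherent n2
  set.seed(707)
  truth <- scenario_truth(cfg)
  s1c <- simulate_subjects(truth, plan$n1, accrual = c(0, cfg$t_int))
  x1c <- interim_snapshot(s1c, cfg$t_int, 1.5)
  decc <- suppressWarnings(interim_decide(x1c, plan, L_sims = 20,
                                          sim_n = 5000))
  if (decc$action == "continue") {
    expect_true(decc$n2_new >= 0 &&
                  decc$n2_new <= plan$n_max - plan$n1)
    expect_gte(decc$cp_achieved, 0)
  }
})
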