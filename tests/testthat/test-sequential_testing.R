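test_that("O'Brien-Fleming spending has the right shape and values", {
  expect_equal(obf_spending(7, 7, 0.025), 0.025)
  expect_equal(obf_spending(10, 7, 0.025), 0.025)   # over-running cap
  expect_equal(obf_spending(0.5, 1, 0.025),
               2 * (1 - pnorm(qnorm(1 - 0.0125) / sqrt(0.5))),
               tolerance = 1e-12)
  expect_equal(obf_spending(0.5, 1, 0.025), 0.001525, tolerance = 1e-3)
  fracs <- seq(0.1, 1, by = 0.1)
  sp <- vapply(fracs, function(f) obf_spending(f, 1, 0.025), numeric(1))
  expect_true(all(diff(sp) > 0))
  expect_error(obf_spending(-1, 1, 0.025), "positive")
})

test_that("critical values conserve alpha analytically", {
  for (frac in c(0.3, 0.5, 0.7)) {
    cv <- critical_values(frac * 100, 100, 0.025, w1 = 0.664)
    # interim mass
    expect_equal(pnorm(cv$c1, lower.tail = FALSE), cv$alpha_spent_interim,
                 tolerance = 1e-12)
    # final mass recovers the remainder through the joint law
    got <- adaptRMST:::.pr_joint(cv$c_final, cv$c1, 0.664)
    expect_equal(got, 0.025 - cv$alpha_spent_interim, tolerance = 1e-8)
  }
})

test_that("critical values reach the classic limits", {
  # almost no interim spending: final boundary is the fixed-design quantile
  cv <- critical_values(5, 100, 0.025, w1 = 0.664)
  expect_gt(cv$c1, 6)
  expect_equal(cv$c_final, qnorm(0.975), tolerance = 1e-3)
  # full correlation: boundary of the classic two-look design with the same
  # spending, P(c_final <= Z < c1) = alpha - alpha_tilde => c = z_{1-alpha}
  cv2 <- critical_values(60, 100, 0.025, w1 = 0.9999)
  expect_equal(cv2$c_final, qnorm(0.975), tolerance = 2e-3)
  # over-running: all alpha spent at interim, no final rejection possible
  cv3 <- critical_values(120, 100, 0.025, w1 = 0.664)
  expect_identical(cv3$c_final, Inf)
  expect_equal(cv3$c1, qnorm(0.975))
})

test_that("combination statistic is linear with valid weights", {
  expect_equal(combine_stages(0, 0, 0.664, sqrt(1 - 0.664^2)), 0)
  expect_equal(combine_stages(1, 1, 0.664, 0.748), 1.412, tolerance = 1e-3)
  expect_error(combine_stages(1, 1, 0.9, 0.9), "w1\\^2")
  z1 <- rnorm(5); z2 <- rnorm(5)
  w1 <- sqrt(0.44); w2 <- sqrt(0.56)
  expect_equal(combine_stages(2 * z1, z2, w1, w2) -
                 combine_stages(z1, z2, w1, w2), w1 * z1)
})

test_that("the three stage-2 variants converge on large trials", {
  scen <- hazard_scenario(0.8, 0.4, 0.7, delta = 0.075,
                          dropout_rate = 0.095, tau = 1.5, tE = 3)
  set.seed(601)
  rel_gap <- vapply(c(2000, 20000), function(n) {
    subj <- simulate_subjects(scen, n, accrual = c(0, 3))
    s1 <- subj[subj$entry_time < 1.8, ]
    x1 <- interim_snapshot(s1, 1.8, 1.5)
    x2 <- stage_two_assemble(s1, 1.8, 1.5, subj[subj$entry_time >= 1.8, ])
    xall <- observe_full(subj, 1.5)
    v <- stage_two_variants(stage_statistic(x1, 1.5),
                            stage_statistic(x2, 1.5),
                            stage_statistic(xall, 1.5))
    max(abs(v$desseaux_porcher - v$truncated),
        abs(v$combined - v$truncated)) / abs(v$truncated)
  }, numeric(1))
  expect_lt(rel_gap[2], rel_gap[1])
  expect_lt(rel_gap[2], 0.15)
})

test_that("degenerate information ordering is rejected", {
  s <- list(z = 1, info = 10, delta_hat = 0.1, sigma_hat = 1, n = 10)
  s_small <- list(z = 1, info = 5, delta_hat = 0.1, sigma_hat = 1, n = 10)
  expect_error(stage_two_variants(s, s_small, s_small),
               "non-increasing information")
})

test_that("log-rank statistic matches survival-package oracles", {
  skip_if_not_installed("survival")
  set.seed(602)
  n <- 400
  tt <- rexp(n, 0.5) * rep(c(1.4, 1), n / 2)  # PH benefit for I
  cc <- runif(n, 0.5, 3)
  fu <- pmin(tt, cc)
  ev <- as.integer(tt <= cc)
  arm <- rep(c("I", "C"), n / 2)
  rec <- observed_records(fu, ev, 0, arm)
  z <- logrank_z(rec)
  sd_or <- survival::survdiff(survival::Surv(fu, ev) ~ arm)
  expect_equal(as.numeric(z)^2, sd_or$chisq, tolerance = 1e-10)
  expect_gt(as.numeric(z), 0)   # intervention benefit => positive

  # delayed entry: agree with the Cox score test on truncated data
  L <- runif(n, 0, 0.3)
  keep <- fu > L
  recT <- observed_records(fu[keep], ev[keep], L[keep], arm[keep])
  zT <- logrank_z(recT)
  cox <- survival::coxph(
    survival::Surv(L[keep], fu[keep], ev[keep]) ~ I(arm[keep] == "I"),
    ties = "breslow")
  expect_equal(as.numeric(zT)^2, as.numeric(cox$score), tolerance = 1e-6)
})

test_that("log-rank magnitude follows the Schoenfeld approximation", {
  set.seed(603)
  n <- 20000
  hr <- 0.75
  tt <- rexp(n)
  isI <- rep(c(TRUE, FALSE), n / 2)
  tt[isI] <- rexp(n / 2, hr)
  fu <- pmin(tt, 2)
  ev <- as.integer(tt <= 2)
  rec <- observed_records(fu, ev, 0, ifelse(isI, "I", "C"))
  z <- as.numeric(logrank_z(rec))
  z_approx <- sqrt(sum(ev) / 4) * (-log(hr))
  expect_equal(z, z_approx, tolerance = 0.1)
})

test_that("log-rank and tau-year tests are calibrated under the null", {
  set.seed(604)
  rej_lr <- rej_ty <- logical(2000)
  for (i in 1:2000) {
    tt <- rexp(120, 0.7)
    fu <- pmin(tt, 1.5)
    ev <- as.integer(tt <= 1.5)
    rec <- observed_records(fu, ev, 0, rep(c("I", "C"), 60))
    rej_lr[i] <- as.numeric(logrank_z(rec)) > qnorm(0.975)
    rej_ty[i] <- as.numeric(tau_year_z(rec, 1.49)) > qnorm(0.975)
  }
  se <- sqrt(0.025 * 0.975 / 2000)
  expect_lt(abs(mean(rej_lr) - 0.025), 3 * se + 0.003)
  expect_lt(abs(mean(rej_ty) - 0.025), 3 * se + 0.006)
})

test_that("tau-year statistic reduces to a two-proportion z without censoring", {
  set.seed(605)
  n <- 4000
  tt <- rexp(n, 0.6)
  arm <- rep(c("I", "C"), n / 2)
  tt[arm == "I"] <- rexp(n / 2, 0.45)
  rec <- observed_records(tt, rep(1, n), 0, arm)
  tau <- 1.2
  z <- tau_year_z(rec, tau)
  pI <- mean(tt[arm == "I"] > tau)
  pC <- mean(tt[arm == "C"] > tau)
  z_bin <- (pI - pC) / sqrt(pI * (1 - pI) / (n / 2) + pC * (1 - pC) / (n / 2))
  expect_equal(as.numeric(z), z_bin, tolerance = 0.02 * abs(z_bin))
  expect_equal(attr(z, "surv_I"), pI, tolerance = 1e-12)
})
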