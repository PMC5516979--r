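control <- condition_preset("control")

test_that("parameter constructors enforce their invariants", {
  expect_error(model_params(1.2, 0, 0, 0, 0), "gamma")
  expect_error(model_params(0.5, Inf, 0, 0, 0), "finite")
  expect_error(kappa_params(0, 1, 1, 1, 1), "alpha")
  expect_error(to_delta(kappa_params(1e-9, 1, 1, 1, 1)), NA)
})

test_that("learning-rate form maps onto the decay form", {
  # full learning rate: gamma 0, increments equal the kappas
  p <- to_delta(kappa_params(1, 2, -1, 0.5, 0))
  expect_equal(p$gamma, 0)
  expect_equal(p$d_plus_mf, 2)
  expect_equal(p$d_plus_mb, -1)
  # alpha = 0.5, all kappa = 1 -> gamma 0.5, all increments 0.5
  p <- to_delta(kappa_params(0.5, 1, 1, 1, 1))
  expect_equal(unlist(p, use.names = FALSE), c(0.5, 0.5, 0.5, 0.5, 0.5))
})

test_that("value updates attribute increments by transition and valence", {
  # identity update: gamma 1, all increments 0
  ident <- model_params(1, 0, 0, 0, 0)
  expect_equal(update_values(c(0.3, -0.7), "a1", "common", TRUE, ident),
               c(0.3, -0.7))
  # common & rewarded: chosen gets mf + mb
  expect_equal(update_values(c(0, 0), "a1", "common", TRUE, control),
               c(1.42, 0))
  # rare & rewarded: chosen gets mf, unchosen gets mb
  expect_equal(update_values(c(0, 0), "a1", "rare", TRUE, control),
               c(1.09, 0.33))
  # unrewarded attributions mirror the rewarded ones
  expect_equal(update_values(c(0, 0), "a2", "common", FALSE, control),
               c(0, 0.48 - 0.14))
  expect_equal(update_values(c(0, 0), "a2", "rare", FALSE, control),
               c(-0.14, 0.48))
  # decay applies to both options before the increments land
  expect_equal(update_values(c(1, 1), "a1", "rare", TRUE, control),
               c(0.47 + 1.09, 0.47 + 0.33))
  expect_error(update_values(c(0, 0), "a3", "common", TRUE, control),
               "invalid")
})

test_that("choice rule is the logistic of the value difference", {
  for (c0 in c(-3, 0, 10)) expect_equal(choice_prob(c(c0, c0)), 0.5)
  expect_equal(choice_prob(c(1, 0)), 0.7310585786300049)
  expect_equal(choice_prob(c(-5, 5)), 4.5397868702434395e-05)
  # complement and translation invariance
  set.seed(11)
  for (i in 1:20) {
    v <- stats::rnorm(2, sd = 3)
    expect_equal(choice_prob(v) + choice_prob(rev(v)), 1)
    expect_equal(choice_prob(v + 17.3), choice_prob(v))
  }
})

test_that("the two parameterizations generate identical trajectories", {
  set.seed(21)
  for (rep in 1:25) {
    kp <- kappa_params(stats::runif(1, 0.01, 1), stats::rnorm(1, 0, 2),
                       stats::rnorm(1, 0, 2), stats::rnorm(1, 0, 2),
                       stats::rnorm(1, 0, 2))
    dp <- to_delta(kp)
    v_k <- v_d <- c(0, 0)
    for (t in 1:60) {
      ch <- sample(c("a1", "a2"), 1)
      tr <- sample(c("common", "rare"), 1)
      rw <- stats::runif(1) < 0.5
      v_k <- kappa_update(v_k, ch, tr, rw, kp)
      v_d <- update_values(v_d, ch, tr, rw, dp)
      expect_lt(max(abs(v_k - v_d)), 1e-12)
    }
  }
})

test_that("session log-likelihood matches the step-by-step value trace", {
  # 5-trial hand-built session at the control preset; expected values frozen
  # from an independent spreadsheet-style trace of the update and choice rules
  trials <- make_trials(
    choice1 = c("a1", "a1", "a2", "a1", "a2"),
    transition = c("common", "rare", "common", "rare", "common"),
    rewarded = c(TRUE, FALSE, FALSE, TRUE, TRUE)
  )
  expect_equal(session_loglik(control, trials), -4.2403463118715035)
  # and the compiled kernel agrees with the pure-R composition of the
  # exported update and choice operations
  expect_equal(session_loglik(control, trials), reference_loglik(control, trials))

  set.seed(31)
  sess <- simulate_session(agent_spec("hybrid", control), seed = 99)
  expect_equal(session_loglik(control, sess), reference_loglik(control, sess),
               tolerance = 1e-12)
})

test_that("session log-likelihood degenerate and invariance properties hold", {
  set.seed(41)
  sess <- simulate_session(agent_spec("random"), seed = 3)
  # frozen values force uniform choice: n * log(0.5)
  frozen <- model_params(0.5, 0, 0, 0, 0)
  expect_equal(session_loglik(frozen, sess), nrow(sess) * log(0.5))
  # log-likelihoods never exceed 0
  for (i in 1:5) {
    p <- model_params(stats::runif(1), stats::rnorm(1), stats::rnorm(1),
                      stats::rnorm(1), stats::rnorm(1))
    expect_lte(session_loglik(p, sess), 0)
  }
  # empty sequence: 0 with a warning
  expect_warning(ll0 <- session_loglik(frozen, sess[0, ]), "empty")
  expect_equal(ll0, 0)
  # relabeling actions consistently leaves the likelihood unchanged
  relabeled <- dplyr::mutate(
    sess,
    choice1 = ifelse(choice1 == "a1", "a2", "a1")
  )
  p <- condition_preset("stress")
  expect_equal(session_loglik(p, relabeled), session_loglik(p, sess))
})
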