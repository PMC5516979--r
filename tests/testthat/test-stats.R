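test_that("perseverator exclusion applies the strict 95% rule", {
  persev <- simulate_session(agent_spec("perseverator"), seed = 1) |>
    dplyr::mutate(subject_id = "p1", condition = "control", .before = 1L)
  rand <- simulate_session(agent_spec("random"), seed = 2) |>
    dplyr::mutate(subject_id = "r1", condition = "control", .before = 1L)
  kept <- exclude_perseverators(dplyr::bind_rows(persev, rand))
  expect_equal(excluded_subjects(kept)$subject_id, "p1")
  expect_equal(unique(kept$subject_id), "r1")

  # exactly at the threshold: retained (strictly "more than 95%")
  n <- 240L
  n_same <- as.integer(0.95 * n)  # 228 of 240
  at <- tibble::tibble(
    subject_id = "edge", condition = "control", trial = seq_len(n),
    block = ceiling(seq_len(n) / 40),
    choice1 = c(rep("a1", n_same), rep("a2", n - n_same)),
    transition = "common", state2 = "s2", choice2 = "o1", outcome = 0
  )
  kept <- exclude_perseverators(at)
  expect_equal(nrow(excluded_subjects(kept)), 0L)
  # one more repeat tips it over
  over <- dplyr::mutate(at, choice1 = c(rep("a1", n_same + 1L),
                                        rep("a2", n - n_same - 1L)))
  expect_equal(excluded_subjects(exclude_perseverators(over))$subject_id,
               "edge")
})

test_that("stay probabilities match manual enumeration", {
  trials <- make_trials(
    choice1 = c("a1", "a1", "a2", "a2", "a1", "a1"),
    transition = c("common", "rare", "common", "rare", "common", "common"),
    rewarded = c(TRUE, FALSE, FALSE, TRUE, TRUE, FALSE)
  )
  # by-hand classification of trials 2..6 by the previous trial:
  # t2 <- (R, common) stay; t3 <- (U, rare) shift; t4 <- (U, common) stay;
  # t5 <- (R, rare) shift; t6 <- (R, common) stay
  st <- stay_probabilities(trials)
  get <- function(o, tr) st$stay_prob[st$prev_outcome == o & st$prev_transition == tr]
  getn <- function(o, tr) st$n[st$prev_outcome == o & st$prev_transition == tr]
  expect_equal(get("rewarded", "common"), 1.0)
  expect_equal(getn("rewarded", "common"), 2L)
  expect_equal(get("rewarded", "rare"), 0.0)
  expect_equal(get("unrewarded", "common"), 1.0)
  expect_equal(get("unrewarded", "rare"), 0.0)
  expect_equal(sum(st$n), nrow(trials) - 1L)
})

test_that("stay probabilities classify every lagged cell correctly", {
  # enumerate all four cells with one observation each
  trials <- make_trials(
    choice1 = c("a1", "a1", "a1", "a2", "a2"),
    transition = c("common", "rare", "common", "rare", "common"),
    rewarded = c(TRUE, TRUE, FALSE, FALSE, TRUE)
  )
  # t2: prev (R, common), stay; t3: prev (R, rare), stay;
  # t4: prev (U, common), shift; t5: prev (U, rare), stay
  st <- stay_probabilities(trials)
  expect_equal(st$n, rep(1L, 4))
  lookup <- function(o, tr) st$stay_prob[st$prev_outcome == o & st$prev_transition == tr]
  expect_equal(lookup("rewarded", "common"), 1)
  expect_equal(lookup("rewarded", "rare"), 1)
  expect_equal(lookup("unrewarded", "common"), 0)
  expect_equal(lookup("unrewarded", "rare"), 1)

  # perseverator: every cell (when occupied) is a stay
  persev <- simulate_session(agent_spec("perseverator"), seed = 3)
  stp <- stay_probabilities(persev)
  expect_true(all(stp$stay_prob[stp$n > 0] == 1))
  expect_equal(sum(stp$n), 239L)

  # strict win-stay/lose-shift: rewarded cells 1, unrewarded cells 0
  n <- 100L
  set.seed(5)
  rewarded <- stats::runif(n) < 0.5
  ch <- character(n); ch[1] <- "a1"
  for (t in 2:n) {
    ch[t] <- if (rewarded[t - 1]) ch[t - 1] else setdiff(c("a1", "a2"), ch[t - 1])
  }
  wsls <- make_trials(ch, sample(c("common", "rare"), n, TRUE), rewarded)
  stw <- stay_probabilities(wsls)
  expect_true(all(stw$stay_prob[stw$prev_outcome == "rewarded" & stw$n > 0] == 1))
  expect_true(all(stw$stay_prob[stw$prev_outcome == "unrewarded" & stw$n > 0] == 0))
})

test_that("the mixed ANOVA separates generative regimes", {
  # two identical pure-model-free groups: reward effect huge, no three-way
  mf <- dplyr::bind_rows(
    simulate_kind("pure_model_free", 40, 300) |>
      dplyr::mutate(condition = "control"),
    simulate_kind("pure_model_free", 40, 400) |>
      dplyr::mutate(subject_id = paste0("x", subject_id), condition = "stress")
  )
  res <- stay_anova(stay_probabilities(mf))
  expect_lt(res$p.value[res$effect == "outcome"], 1e-6)
  expect_gt(res$p.value[res$effect == "condition:outcome:transition"], 0.05)
  expect_equal(res$df1, rep(1, 7))

  # control vs stress presets: the three-way interaction appears
  co <- cohort_spec(n_per_condition = 100, master_seed = 55)
  trials <- exclude_perseverators(simulate_cohort(co))
  res2 <- stay_anova(stay_probabilities(trials))
  expect_lt(res2$p.value[res2$effect == "condition:outcome:transition"], 0.05)

  # degenerate input: all stay values equal
  flat <- stay_probabilities(mf) |> dplyr::mutate(stay_prob = 0.5)
  expect_error(stay_anova(flat), "identical")
})

test_that("empty stay cells drop the subject with a warning", {
  ok <- simulate_session(agent_spec("random"), seed = 6) |>
    dplyr::mutate(subject_id = "ok1", condition = "control", .before = 1L)
  ok2 <- dplyr::mutate(ok, subject_id = "ok2", condition = "stress")
  ok3 <- simulate_session(agent_spec("random"), seed = 8) |>
    dplyr::mutate(subject_id = "ok3", condition = "stress", .before = 1L)
  ok4 <- dplyr::mutate(ok3, subject_id = "ok4", condition = "control")
  # a three-trial subject cannot fill all four cells
  short <- make_trials(c("a1", "a1", "a2"), c("common", "rare", "common"),
                       c(TRUE, TRUE, FALSE)) |>
    dplyr::mutate(subject_id = "short", condition = "control", .before = 1L)
  stays <- stay_probabilities(dplyr::bind_rows(ok, ok2, ok3, ok4, short))
  expect_warning(res <- stay_anova(stays), "empty stay cells")
  expect_s3_class(res, "tbl_df")
})

test_that("performance summaries count points and advantageous choices", {
  cfg <- default_task_config()
  s <- simulate_session(agent_spec("hybrid"), cfg, seed = 7)
  perf <- performance_summary(s, cfg)
  expect_equal(perf$total_points, 100 * sum(s$outcome > 0))
  expect_true(perf$p_advantageous >= 0 && perf$p_advantageous <= 1)

  # an agent always choosing the advantageous action scores exactly 1
  adv <- favored_states(cfg)
  forced <- s |>
    dplyr::left_join(adv, by = "block") |>
    dplyr::mutate(choice1 = dplyr::coalesce(advantageous_action, "a1")) |>
    dplyr::select(-favored_state, -advantageous_action)
  expect_equal(performance_summary(forced, cfg)$p_advantageous, 1)

  # all-zero outcomes
  zero <- dplyr::mutate(s, outcome = 0)
  expect_equal(performance_summary(zero, cfg)$total_points, 0)

  # block 1 choices do not enter p_advantageous: changing them is a no-op
  flipped1 <- dplyr::mutate(forced, choice1 = ifelse(
    block == 1, ifelse(choice1 == "a1", "a2", "a1"), choice1))
  expect_equal(performance_summary(flipped1, cfg)$p_advantageous, 1)
})

test_that("condition comparisons use the pooled-variance t convention", {
  d <- tibble::tibble(
    condition = rep(c("control", "stress"), each = 26),
    val = c(stats::rnorm(26, 1, 1), stats::rnorm(26, 0, 1))
  )
  res <- compare_conditions(d, "val", ref = "control")
  expect_equal(res$df, 50)
  tt <- stats::t.test(val ~ condition, data = d, var.equal = TRUE)
  expect_equal(res$statistic, unname(tt$statistic))

  # identical groups: t = 0, p = 1
  same <- tibble::tibble(condition = rep(c("a", "b"), each = 5),
                         val = rep(c(1, 2, 3, 4, 5), 2))
  res0 <- compare_conditions(same, "val")
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p.value, 1)

  # zero pooled variance is an explicit error
  degen <- tibble::tibble(condition = rep(c("a", "b"), each = 3),
                          val = rep(c(0, 1), each = 3))
  expect_error(compare_conditions(degen, "val"), "zero pooled variance")
})

test_that("the decay/treatment regression behaves under null and degenerate inputs", {
  set.seed(123)
  # treatment unrelated to the outcome: coefficient near zero
  n <- 2000
  d <- tibble::tibble(
    condition = rep(c("control", "stress"), each = n / 2),
    gamma = stats::runif(n),
    d_minus_mf = 0.5 * gamma + stats::rnorm(n, 0, 0.3)
  )
  res <- delta_regression(d)
  b_treat <- res$estimate[res$term == "treatment"]
  expect_lt(abs(b_treat), 0.05)
  expect_gt(res$p.value[res$term == "treatment"], 0.01)
  expect_lt(res$p.value[res$term == "gamma"], 1e-6)

  # zero-variance predictor
  flat <- dplyr::mutate(d, gamma = 0.5)
  expect_error(delta_regression(flat), "zero variance")
})

test_that("the ANCOVA adjusts the condition effect for performance", {
  set.seed(321)
  n <- 60
  base <- tibble::tibble(
    subject_id = sprintf("s%02d", 1:n),
    condition = rep(c("control", "stress"), each = n / 2),
    d_minus_mf = stats::rnorm(n, ifelse(condition == "control", 0.5, 0), 0.3)
  )
  # pure-noise covariate: condition F close to the unadjusted t^2
  perf_noise <- tibble::tibble(subject_id = base$subject_id,
                               p_advantageous = stats::runif(n))
  res <- delta_ancova(base, perf_noise)
  f_cond <- res$statistic[res$effect == "condition"]
  t_un <- compare_conditions(base, "d_minus_mf")$statistic
  expect_lt(abs(f_cond - t_un^2) / t_un^2, 0.25)
  expect_lt(res$p.value[res$effect == "condition"], 0.01)

  # outcome driven entirely through the covariate: the strong raw condition
  # difference disappears once the covariate is adjusted for
  x <- stats::rnorm(n, ifelse(base$condition == "control", 0.5, 0), 0.3)
  confound <- dplyr::mutate(base, d_minus_mf = 2 * x + stats::rnorm(n, 0, 0.05))
  perf_conf <- tibble::tibble(subject_id = base$subject_id, p_advantageous = x)
  expect_lt(compare_conditions(confound, "d_minus_mf")$p.value, 0.001)
  res2 <- delta_ancova(confound, perf_conf)
  expect_gt(res2$p.value[res2$effect == "condition"], 0.1)
  expect_error(
    delta_ancova(base, dplyr::mutate(perf_noise, p_advantageous = 0.5)),
    "zero variance"
  )
})

test_that("permuted condition labels give a calibrated three-way null", {
  co <- cohort_spec(n_per_condition = 8, master_seed = 99)
  trials <- exclude_perseverators(simulate_cohort(co))
  stays <- stay_probabilities(trials)
  subjects <- dplyr::distinct(stays, subject_id)
  set.seed(17)
  pvals <- purrr::map_dbl(1:200, function(i) {
    perm <- dplyr::mutate(subjects,
                          condition = sample(rep(c("a", "b"), length.out = nrow(subjects))))
    st <- stays |>
      dplyr::select(-condition) |>
      dplyr::inner_join(perm, by = "subject_id")
    res <- stay_anova(st)
    res$p.value[res$effect == "condition:outcome:transition"]
  })
  # uniform null: mean 0.5 and calibrated tail masses (permutations can
  # repeat, so moment checks rather than a tie-sensitive KS test)
  expect_lt(abs(mean(pvals) - 0.5), 3 * sqrt(1 / 12 / length(pvals)))
  expect_lt(abs(mean(pvals < 0.25) - 0.25), 0.1)
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.06)
})
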