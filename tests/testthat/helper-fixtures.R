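# Shared fixtures and independent reference implementations used as oracles.

# A trial-log tibble from explicit vectors; outcome given as rewarded logical.
make_trials <- function(choice1, transition, rewarded, magnitude = 100) {
  tibble::tibble(
    trial = seq_along(choice1),
    block = 1L,
    choice1 = choice1,
    transition = transition,
    state2 = "s2",
    choice2 = "o1",
    outcome = ifelse(rewarded, magnitude, 0)
  )
}

# Pure-R reference log-likelihood: composes the exported update_values() and
# choice_prob() step by step, independently of the compiled session kernel.
reference_loglik <- function(params, trials, v0 = c(0, 0)) {
  v <- v0
  ll <- 0
  for (t in seq_len(nrow(trials))) {
    p1 <- choice_prob(v)
    ll <- ll + log(if (trials$choice1[t] == "a1") p1 else 1 - p1)
    v <- update_values(v, trials$choice1[t], trials$transition[t],
                       trials$outcome[t] > 0, params)
  }
  ll
}

# Explicit learning-rate-form update (the alpha/kappa recursion written out
# directly), for the equivalence property against to_delta().
kappa_update <- function(v, choice1, transition, rewarded, kp) {
  ch <- match(choice1, c("a1", "a2"))
  un <- 3L - ch
  kmf <- if (rewarded) kp$k_plus_mf else kp$k_minus_mf
  kmb <- if (rewarded) kp$k_plus_mb else kp$k_minus_mb
  v <- (1 - kp$alpha) * v
  if (transition == "common") {
    v[ch] <- v[ch] + kp$alpha * (kmf + kmb)
  } else {
    v[ch] <- v[ch] + kp$alpha * kmf
    v[un] <- v[un] + kp$alpha * kmb
  }
  v
}

# Simulate n sessions of one agent kind and return stacked trial logs.
simulate_kind <- function(kind, n, seed0, config = default_task_config(), ...) {
  purrr::map_dfr(seq_len(n), function(i) {
    simulate_session(agent_spec(kind, ...), config, seed = seed0 + i) |>
      dplyr::mutate(subject_id = sprintf("%s_%03d", kind, i), .before = 1L)
  })
}

# Per-session stay-table contrasts: the reward main effect and the
# reward-by-transition interaction, one row per subject.
stay_contrasts <- function(stays) {
  stays |>
    dplyr::select("subject_id", "prev_outcome", "prev_transition", "stay_prob") |>
    tidyr::unite("cell", "prev_outcome", "prev_transition") |>
    tidyr::pivot_wider(names_from = "cell", values_from = "stay_prob") |>
    dplyr::mutate(
      reward_effect = (rewarded_common + rewarded_rare) / 2 -
        (unrewarded_common + unrewarded_rare) / 2,
      interaction = (rewarded_common - rewarded_rare) -
        (unrewarded_common - unrewarded_rare)
    )
}
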