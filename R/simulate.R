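#' Specify a generative agent
#'
#' Agents play the two-stage reversal task and produce trial logs with known
#' ground truth. Five kinds are available:
#' \describe{
#'   \item{hybrid}{chooses stage-1 actions by the softmax over the hybrid
#'     model's values and updates them with [update_values()] after every
#'     trial; the workhorse for synthetic cohorts.}
#'   \item{pure_model_free}{a hybrid agent with both model-based increments
#'     fixed at zero; shows the win-stay pattern regardless of transition.}
#'   \item{pure_model_based}{a hybrid agent with both model-free increments
#'     fixed at zero; shows the reward-by-transition crossover.}
#'   \item{random}{chooses uniformly at both stages.}
#'   \item{perseverator}{repeats its first stage-1 choice on every trial;
#'     used to exercise the exclusion rule.}
#' }
#'
#' Because the first-stage likelihood never sees stage-2 choices, the
#' stage-2 policy is a modeling choice of the generator: value-driven agents
#' keep a per-state action value updated by a Rescorla-Wagner rule at rate
#' `stage2_alpha` on the rewarded/unrewarded (0/1) outcome, and choose by a
#' softmax with inverse temperature `stage2_beta`.
#'
#' @param kind Agent kind, see above.
#' @param params A [model_params()] object (hybrid family). For the pure
#'   kinds the corresponding increments are forced to zero; defaults provide
#'   canonical textbook agents.
#' @param stage2_alpha Stage-2 learning rate in \[0, 1\].
#' @param stage2_beta Stage-2 softmax inverse temperature (>= 0).
#' @return An object of class `agent_spec`.
#' @export
agent_spec <- function(kind = c("hybrid", "pure_model_free", "pure_model_based",
                                "random", "perseverator"),
                       params = NULL,
                       stage2_alpha = 0.5,
                       stage2_beta = 5) {
  kind <- match.arg(kind)
  stopifnot(stage2_alpha >= 0, stage2_alpha <= 1, stage2_beta >= 0)
  if (kind %in% c("hybrid", "pure_model_free", "pure_model_based")) {
    if (is.null(params)) {
      params <- switch(kind,
        hybrid = condition_preset("control"),
        pure_model_free = model_params(0.5, 1, 0, -1, 0),
        pure_model_based = model_params(0.5, 0, 1, 0, -1)
      )
    }
    stopifnot(inherits(params, "model_params"))
    if (kind == "pure_model_free") {
      params$d_plus_mb <- 0
      params$d_minus_mb <- 0
    }
    if (kind == "pure_model_based") {
      params$d_plus_mf <- 0
      params$d_minus_mf <- 0
    }
  } else {
    params <- NULL
  }
  structure(
    list(kind = kind, params = params,
         stage2_alpha = stage2_alpha, stage2_beta = stage2_beta),
    class = "agent_spec"
  )
}

#' Simulate one session of the two-stage reversal task
#'
#' Plays a full session with the given agent: stage-1 choice, probabilistic
#' transition, stage-2 choice, scheduled outcome, then value updates. Block
#' transitions are uncued and values carry over across them; all values
#' start at zero, so the first stage-1 choice is uniform for value-driven
#' agents.
#'
#' @param agent An [agent_spec()].
#' @param config A [task_config()].
#' @param seed Integer seed for the session's random stream.
#' @return A tibble with one row per trial and columns `trial`, `block`,
#'   `choice1`, `transition`, `state2`, `choice2`, `outcome`.
#' @export
simulate_session <- function(agent, config = default_task_config(), seed = NULL) {
  stopifnot(inherits(agent, "agent_spec"))
  validate_task_config(config)
  if (!is.null(seed)) set.seed(seed)

  nt <- n_trials(config)
  tpb <- config$trials_per_block
  p_common <- config$common_transition_prob
  mag <- config$reward_magnitude
  states <- c("s2", "s3")
  mapped_state <- unname(config$action_state_map[c("a1", "a2")])

  # reward schedule as [block, state, option] array for O(1) lookup
  sch <- array(NA_real_, dim = c(config$n_blocks, 2L, 2L))
  rs <- config$reward_schedule
  sch[cbind(rs$block, match(rs$state, states), match(rs$option, c("o1", "o2")))] <-
    rs$p_reward

  v <- c(0, 0)                      # stage-1 values
  q <- matrix(0, 2L, 2L)            # stage-2 values [state, option]
  value_driven <- agent$kind %in% c("hybrid", "pure_model_free", "pure_model_based")
  persev_choice <- NA_integer_

  choice1 <- transition <- state2 <- choice2 <- integer(nt)
  outcome <- numeric(nt)
  block <- rep(seq_len(config$n_blocks), each = tpb)

  for (t in seq_len(nt)) {
    ch1 <- if (value_driven) {
      if (stats::runif(1) < stats::plogis(v[1] - v[2])) 1L else 2L
    } else if (agent$kind == "random") {
      if (stats::runif(1) < 0.5) 1L else 2L
    } else {  # perseverator
      if (is.na(persev_choice)) {
        persev_choice <- if (stats::runif(1) < 0.5) 1L else 2L
      }
      persev_choice
    }

    common <- stats::runif(1) < p_common
    st <- match(mapped_state[ch1], states)
    if (!common) st <- 3L - st

    ch2 <- if (value_driven) {
      p_o1 <- stats::plogis(agent$stage2_beta * (q[st, 1] - q[st, 2]))
      if (stats::runif(1) < p_o1) 1L else 2L
    } else {
      if (stats::runif(1) < 0.5) 1L else 2L
    }

    rew <- stats::runif(1) < sch[block[t], st, ch2]
    out <- if (rew) mag else 0

    if (value_driven) {
      v <- update_values(v, c("a1", "a2")[ch1],
                         if (common) "common" else "rare", rew, agent$params)
      q[st, ch2] <- q[st, ch2] + agent$stage2_alpha * (as.numeric(rew) - q[st, ch2])
    }

    choice1[t] <- ch1
    transition[t] <- if (common) 1L else 2L
    state2[t] <- st
    choice2[t] <- ch2
    outcome[t] <- out
  }

  tibble::tibble(
    trial = seq_len(nt),
    block = block,
    choice1 = c("a1", "a2")[choice1],
    transition = c("common", "rare")[transition],
    state2 = states[state2],
    choice2 = c("o1", "o2")[choice2],
    outcome = outcome
  )
}

#' Specify a synthetic cohort
#'
#' A cohort is a set of synthetic subjects split across conditions, each
#' playing one session with hybrid-model parameters drawn around the
#' condition's preset. Between-subject heterogeneity is normal jitter with
#' per-parameter standard deviations (default: IQR-derived scales from
#' [condition_jitter_sd()], multiplied by `jitter_scale`); jittered `gamma`
#' is clamped to \[0, 1\]. All randomness derives deterministically from
#' `master_seed`.
#'
#' @param n_per_condition Subjects per condition. Default 26.
#' @param conditions Character vector of condition labels with presets
#'   available from [condition_preset()].
#' @param presets Named list of [model_params()] per condition; defaults to
#'   the condition presets.
#' @param jitter_sd Named list of per-parameter sd vectors per condition;
#'   defaults to [condition_jitter_sd()].
#' @param jitter_scale Multiplier on all jitter sds (0 = every subject at
#'   the preset). Default 1.
#' @param stage2_alpha,stage2_beta Stage-2 policy shared by all subjects.
#' @param master_seed Integer master seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_condition = 26L,
                        conditions = c("control", "stress"),
                        presets = NULL,
                        jitter_sd = NULL,
                        jitter_scale = 1,
                        stage2_alpha = 0.5,
                        stage2_beta = 5,
                        master_seed = 1L) {
  if (is.null(presets)) {
    presets <- purrr::map(rlang::set_names(conditions), condition_preset)
  }
  if (is.null(jitter_sd)) {
    jitter_sd <- purrr::map(rlang::set_names(conditions), condition_jitter_sd)
  }
  stopifnot(all(conditions %in% names(presets)),
            all(conditions %in% names(jitter_sd)),
            jitter_scale >= 0, n_per_condition >= 1L)
  structure(
    list(n_per_condition = as.integer(n_per_condition),
         conditions = conditions, presets = presets, jitter_sd = jitter_sd,
         jitter_scale = jitter_scale, stage2_alpha = stage2_alpha,
         stage2_beta = stage2_beta, master_seed = as.integer(master_seed)),
    class = "cohort_spec"
  )
}

#' Draw per-subject ground-truth parameters for a cohort
#'
#' @param cohort A [cohort_spec()].
#' @return A tibble with one row per subject: `subject_id`, `condition`,
#'   `seed` (the session seed), and the five true parameters.
#' @export
cohort_truth_table <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_spec"))
  set.seed(cohort$master_seed)
  n_total <- cohort$n_per_condition * length(cohort$conditions)
  seeds <- sample.int(.Machine$integer.max - 1L, n_total)
  purrr::imap_dfr(rlang::set_names(cohort$conditions), function(cond, nm) {
    preset <- as_param_vector(cohort$presets[[cond]])
    sds <- cohort$jitter_sd[[cond]][param_names] * cohort$jitter_scale
    purrr::map_dfr(seq_len(cohort$n_per_condition), function(i) {
      th <- preset + stats::rnorm(5L, 0, sds)
      th[["gamma"]] <- min(max(th[["gamma"]], 0), 1)
      tibble::tibble(
        subject_id = sprintf("%s_%02d", cond, i),
        condition = cond,
        !!!rlang::set_names(as.list(th), param_names)
      )
    })
  }) |>
    dplyr::mutate(seed = seeds[dplyr::row_number()], .after = "condition")
}

#' Simulate a full synthetic cohort
#'
#' Draws each subject's true parameters ([cohort_truth_table()]) and plays
#' one session per subject. The per-subject truth (including session seeds)
#' is attached as the `"truth"` attribute, retrievable with
#' [cohort_truth()].
#'
#' @param cohort A [cohort_spec()].
#' @param config A [task_config()].
#' @return A trial-log tibble with columns `subject_id`, `condition`,
#'   `trial`, `block`, `choice1`, `transition`, `state2`, `choice2`,
#'   `outcome`.
#' @export
simulate_cohort <- function(cohort, config = default_task_config()) {
  truth <- cohort_truth_table(cohort)
  logs <- purrr::pmap_dfr(truth, function(subject_id, condition, seed, ...) {
    params <- model_params(...)
    agent <- agent_spec("hybrid", params,
                        stage2_alpha = cohort$stage2_alpha,
                        stage2_beta = cohort$stage2_beta)
    simulate_session(agent, config, seed = seed) |>
      dplyr::mutate(subject_id = subject_id, condition = condition,
                    .before = 1L)
  })
  attr(logs, "truth") <- truth
  logs
}

#' Ground-truth parameters attached to a simulated cohort
#' @param trials A trial log produced by [simulate_cohort()].
#' @return The truth tibble, or `NULL` if none is attached.
#' @export
cohort_truth <- function(trials) {
  attr(trials, "truth")
}

#' Read and write trial logs as CSV
#'
#' The delimited-text interchange format for trial logs: one row per trial,
#' fixed header `subject_id, condition, trial, block, choice1, transition,
#' state2, choice2, outcome`.
#'
#' @param trials A trial-log tibble.
#' @param path File path.
#' @return `write_trial_log()` returns `path` invisibly; `read_trial_log()`
#'   returns the trial-log tibble.
#' @export
write_trial_log <- function(trials, path) {
  cols <- c("subject_id", "condition", "trial", "block", "choice1",
            "transition", "state2", "choice2", "outcome")
  missing <- setdiff(cols, names(trials))
  if (length(missing)) {
    stop("trial log lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  readr::write_csv(trials[cols], path)
  invisible(path)
}

#' @rdname write_trial_log
#' @export
read_trial_log <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    subject_id = readr::col_character(),
    condition = readr::col_character(),
    trial = readr::col_integer(),
    block = readr::col_integer(),
    choice1 = readr::col_character(),
    transition = readr::col_character(),
    state2 = readr::col_character(),
    choice2 = readr::col_character(),
    outcome = readr::col_double()
  ))
}
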