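#' Task configuration for the two-stage reversal task
#'
#' A `task_config` bundles everything that defines a session of the two-stage
#' Markov decision task with uncued reversals: the block structure, the
#' first-stage-to-second-stage transition probability, the per-block reward
#' probability schedule for the four second-stage options, the reward
#' magnitude, and the (fixed) mapping from first-stage actions to their
#' strongly associated second-stage states.
#'
#' @param n_blocks Number of blocks. Default 6.
#' @param trials_per_block Trials per block. Default 40.
#' @param common_transition_prob Probability that a first-stage choice leads
#'   to its strongly associated second-stage state. Must lie in (0.5, 1].
#'   Default 0.7.
#' @param reward_schedule Tibble with columns `block`, `state`, `option`,
#'   `p_reward` giving the reward probability of each second-stage option in
#'   each block. Must cover every (block, state, option) cell exactly once.
#'   Defaults to the standard reversal schedule, see [default_task_config()].
#' @param reward_magnitude Points delivered on a rewarded trial. Default 100.
#' @param action_state_map Named character vector mapping the two first-stage
#'   actions to their strongly associated second-stage states; must be a
#'   bijection. Default `c(a1 = "s2", a2 = "s3")`.
#'
#' @return An object of class `task_config`.
#' @seealso [default_task_config()], [practice_task_config()]
#' @export
task_config <- function(n_blocks = 6L,
                        trials_per_block = 40L,
                        common_transition_prob = 0.7,
                        reward_schedule = default_reward_schedule(n_blocks),
                        reward_magnitude = 100,
                        action_state_map = c(a1 = "s2", a2 = "s3")) {
  cfg <- structure(
    list(
      n_blocks = as.integer(n_blocks),
      trials_per_block = as.integer(trials_per_block),
      common_transition_prob = common_transition_prob,
      reward_schedule = tibble::as_tibble(reward_schedule),
      reward_magnitude = reward_magnitude,
      action_state_map = action_state_map
    ),
    class = "task_config"
  )
  validate_task_config(cfg)
}

validate_task_config <- function(cfg) {
  stopifnot(inherits(cfg, "task_config"))
  if (!(cfg$n_blocks >= 1L && cfg$trials_per_block >= 1L)) {
    stop("n_blocks and trials_per_block must be positive integers", call. = FALSE)
  }
  p <- cfg$common_transition_prob
  if (!(is.numeric(p) && length(p) == 1L && p > 0.5 && p <= 1)) {
    stop("common_transition_prob must lie in (0.5, 1]", call. = FALSE)
  }
  sch <- cfg$reward_schedule
  req <- c("block", "state", "option", "p_reward")
  if (!all(req %in% names(sch))) {
    stop("reward_schedule needs columns block, state, option, p_reward", call. = FALSE)
  }
  if (any(sch$p_reward < 0 | sch$p_reward > 1)) {
    stop("every reward probability must lie in [0, 1]", call. = FALSE)
  }
  cells <- tidyr::expand_grid(
    block = seq_len(cfg$n_blocks), state = c("s2", "s3"), option = c("o1", "o2")
  )
  have <- dplyr::distinct(sch[, c("block", "state", "option")])
  if (nrow(sch) != nrow(cells) || nrow(dplyr::inner_join(cells, have,
      by = c("block", "state", "option"))) != nrow(cells)) {
    stop("reward_schedule must cover each (block, state, option) cell exactly once",
         call. = FALSE)
  }
  m <- cfg$action_state_map
  if (!identical(sort(names(m)), c("a1", "a2")) ||
      !identical(sort(unname(m)), c("s2", "s3"))) {
    stop("action_state_map must be a bijection between {a1, a2} and {s2, s3}",
         call. = FALSE)
  }
  cfg
}

#' The standard block-wise reversal reward schedule
#'
#' Block 1 offers a 0.6 vs 0.2 option in both second-stage states, so neither
#' first-stage action dominates. From block 2 onward one state is "favored"
#' (its better option pays with probability 0.8, the other with 0.2) while
#' both options of the unfavored state pay with probability 0.2; the favored
#' state alternates at every uncued block transition (s2 favored in blocks
#' 2, 4, 6; s3 in blocks 3 and 5).
#'
#' @param n_blocks Number of blocks; schedules longer than 6 blocks continue
#'   the alternation.
#' @return A tibble with columns `block`, `state`, `option`, `p_reward`.
#' @export
default_reward_schedule <- function(n_blocks = 6L) {
  n_blocks <- as.integer(n_blocks)
  purrr::map_dfr(seq_len(n_blocks), function(b) {
    if (b == 1L) {
      tibble::tibble(
        block = b,
        state = c("s2", "s2", "s3", "s3"),
        option = c("o1", "o2", "o1", "o2"),
        p_reward = c(0.6, 0.2, 0.6, 0.2)
      )
    } else {
      favored <- if (b %% 2L == 0L) "s2" else "s3"
      st <- c("s2", "s2", "s3", "s3")
      tibble::tibble(
        block = b,
        state = st,
        option = c("o1", "o2", "o1", "o2"),
        p_reward = ifelse(st == favored, c(0.8, 0.2, 0.8, 0.2), 0.2)
      )
    }
  })
}

#' Default task configuration (6 blocks of 40 trials)
#'
#' The standard session: 240 trials in 6 uncued blocks of 40, a 70% common
#' transition probability, 100-point rewards, and the block-wise reversal
#' schedule of [default_reward_schedule()].
#'
#' @return A `task_config`.
#' @export
default_task_config <- function() {
  task_config()
}

#' Practice-session task configuration (6 blocks of 5 trials)
#'
#' The short familiarization session: 30 trials, five per block, with the
#' same transition structure and reversal schedule as the main task.
#'
#' @return A `task_config`.
#' @export
practice_task_config <- function() {
  task_config(trials_per_block = 5L)
}

#' Total number of trials in a session
#' @param config A `task_config`.
#' @return Integer trial count.
#' @export
n_trials <- function(config) {
  config$n_blocks * config$trials_per_block
}

#' @export
print.task_config <- function(x, ...) {
  cat("<task_config>\n")
  cat(sprintf("  %d blocks x %d trials = %d trials\n",
              x$n_blocks, x$trials_per_block, n_trials(x)))
  cat(sprintf("  common transition prob: %.2f; reward magnitude: %g\n",
              x$common_transition_prob, x$reward_magnitude))
  cat(sprintf("  action -> state: %s\n",
              paste(names(x$action_state_map), x$action_state_map,
                    sep = " -> ", collapse = ", ")))
  invisible(x)
}

#' Read or write a task configuration as YAML
#'
#' Round-trips a `task_config` through a plain-text YAML file with keys
#' `n_blocks`, `trials_per_block`, `common_transition_prob`,
#' `reward_schedule`, `reward_magnitude`, `action_state_map`.
#'
#' @param config A `task_config`.
#' @param path File path.
#' @return `write_task_config()` returns `path` invisibly;
#'   `read_task_config()` returns a `task_config`.
#' @export
write_task_config <- function(config, path) {
  validate_task_config(config)
  obj <- list(
    n_blocks = config$n_blocks,
    trials_per_block = config$trials_per_block,
    common_transition_prob = config$common_transition_prob,
    reward_magnitude = config$reward_magnitude,
    action_state_map = as.list(config$action_state_map),
    reward_schedule = purrr::pmap(config$reward_schedule, function(block, state, option, p_reward) {
      list(block = block, state = state, option = option, p_reward = p_reward)
    })
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_task_config
#' @export
read_task_config <- function(path) {
  obj <- yaml::read_yaml(path)
  sched <- purrr::map_dfr(obj$reward_schedule, tibble::as_tibble)
  sched$block <- as.integer(sched$block)
  task_config(
    n_blocks = obj$n_blocks,
    trials_per_block = obj$trials_per_block,
    common_transition_prob = obj$common_transition_prob,
    reward_schedule = sched,
    reward_magnitude = obj$reward_magnitude,
    action_state_map = unlist(obj$action_state_map)
  )
}

#' Sample a second-stage state for a first-stage choice
#'
#' Draws the strongly associated state of `choice1` with probability
#' `common_transition_prob` and the other state otherwise.
#'
#' @param choice1 `"a1"` or `"a2"`.
#' @param config A `task_config`.
#' @return A list with elements `state2` and `transition`
#'   (`"common"`/`"rare"`).
#' @export
sample_transition <- function(choice1, config) {
  if (!choice1 %in% names(config$action_state_map)) {
    stop("invalid first-stage action: ", choice1, call. = FALSE)
  }
  mapped <- unname(config$action_state_map[[choice1]])
  other <- setdiff(c("s2", "s3"), mapped)
  common <- stats::runif(1) < config$common_transition_prob
  list(
    state2 = if (common) mapped else other,
    transition = if (common) "common" else "rare"
  )
}

#' Sample a trial outcome for a second-stage choice
#'
#' Pays `reward_magnitude` points with the probability the block's schedule
#' assigns to `(state2, choice2)`, else 0.
#'
#' @param state2 `"s2"` or `"s3"`.
#' @param choice2 `"o1"` or `"o2"`.
#' @param block Block index (1-based, within the schedule).
#' @param config A `task_config`.
#' @return Outcome in points (`0` or `reward_magnitude`).
#' @export
sample_outcome <- function(state2, choice2, block, config) {
  if (!(block >= 1L && block <= config$n_blocks)) {
    stop("block out of range: ", block, call. = FALSE)
  }
  p <- reward_prob(config, block, state2, choice2)
  if (stats::runif(1) < p) config$reward_magnitude else 0
}

reward_prob <- function(config, block, state2, choice2) {
  sch <- config$reward_schedule
  p <- sch$p_reward[sch$block == block & sch$state == state2 & sch$option == choice2]
  if (length(p) != 1L) {
    stop(sprintf("no schedule entry for block %s, state %s, option %s",
                 block, state2, choice2), call. = FALSE)
  }
  p
}

#' Favored second-stage state per block
#'
#' For blocks with an asymmetric schedule, the state holding the
#' high-probability option; `NA` for blocks (like block 1) where the two
#' first-stage actions are equally favorable.
#'
#' @param config A `task_config`.
#' @return A tibble with columns `block`, `favored_state`,
#'   `advantageous_action`.
#' @export
favored_states <- function(config) {
  best <- config$reward_schedule |>
    dplyr::group_by(.data$block, .data$state) |>
    dplyr::summarise(best = max(.data$p_reward), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "state", values_from = "best")
  inv_map <- stats::setNames(names(config$action_state_map),
                             config$action_state_map)
  best |>
    dplyr::mutate(
      favored_state = dplyr::case_when(
        .data$s2 > .data$s3 ~ "s2",
        .data$s3 > .data$s2 ~ "s3",
        TRUE ~ NA_character_
      ),
      advantageous_action = unname(inv_map[.data$favored_state])
    ) |>
    dplyr::select("block", "favored_state", "advantageous_action")
}
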