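#' Hybrid model parameters (decay parameterization)
#'
#' The five quantities governing first-stage value dynamics: a decay
#' (discount) factor `gamma` weighting the previous value estimate, and four
#' unbounded value-change increments, one per (outcome valence, learning
#' system) combination: `d_plus_mf` and `d_plus_mb` after reward,
#' `d_minus_mf` and `d_minus_mb` after no reward. `gamma = 1 - alpha`
#' relates the decay factor to the learning rate, and each increment equals
#' `alpha * kappa` in the learning-rate parameterization (see
#' [kappa_params()]). A negative `d_minus_*` expresses a tendency to switch
#' away from an unrewarded action; a positive one, to stay despite it.
#'
#' @param gamma Decay factor in \[0, 1\].
#' @param d_plus_mf,d_plus_mb,d_minus_mf,d_minus_mb Finite value-change
#'   increments.
#' @return An object of class `model_params` (a named list).
#' @export
model_params <- function(gamma, d_plus_mf, d_plus_mb, d_minus_mf, d_minus_mb) {
  p <- list(gamma = gamma, d_plus_mf = d_plus_mf, d_plus_mb = d_plus_mb,
            d_minus_mf = d_minus_mf, d_minus_mb = d_minus_mb)
  vals <- unlist(p)
  if (!all(is.finite(vals))) stop("all parameters must be finite", call. = FALSE)
  if (gamma < 0 || gamma > 1) stop("gamma must lie in [0, 1]", call. = FALSE)
  structure(p, class = "model_params")
}

#' Hybrid model parameters (learning-rate parameterization)
#'
#' The equivalent parameterization with an explicit learning rate `alpha`
#' and reinforcement-strength parameters `kappa`: the chosen option's value
#' moves toward `kappa` at rate `alpha`. Undefined at `alpha = 0`, where any
#' `kappa` is unidentifiable — the reason fitting uses the decay form.
#'
#' @param alpha Learning rate in (0, 1\].
#' @param k_plus_mf,k_plus_mb,k_minus_mf,k_minus_mb Finite reinforcement
#'   strengths.
#' @return An object of class `kappa_params`.
#' @export
kappa_params <- function(alpha, k_plus_mf, k_plus_mb, k_minus_mf, k_minus_mb) {
  p <- list(alpha = alpha, k_plus_mf = k_plus_mf, k_plus_mb = k_plus_mb,
            k_minus_mf = k_minus_mf, k_minus_mb = k_minus_mb)
  if (!all(is.finite(unlist(p)))) stop("all parameters must be finite", call. = FALSE)
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]", call. = FALSE)
  structure(p, class = "kappa_params")
}

#' Convert learning-rate parameters to the decay parameterization
#'
#' `gamma = 1 - alpha` and each increment `d = alpha * kappa`. The two forms
#' generate identical value trajectories; the decay form stays identifiable
#' as `alpha` approaches 0.
#'
#' @param kp A [kappa_params()] object.
#' @return A [model_params()] object.
#' @export
to_delta <- function(kp) {
  stopifnot(inherits(kp, "kappa_params"))
  model_params(
    gamma = 1 - kp$alpha,
    d_plus_mf = kp$alpha * kp$k_plus_mf,
    d_plus_mb = kp$alpha * kp$k_plus_mb,
    d_minus_mf = kp$alpha * kp$k_minus_mf,
    d_minus_mb = kp$alpha * kp$k_minus_mb
  )
}

delta_names <- c("d_plus_mf", "d_plus_mb", "d_minus_mf", "d_minus_mb")
param_names <- c("gamma", delta_names)

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params> ",
      paste(sprintf("%s = %.3g", param_names, unlist(x[param_names])),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' One value-update step for the first-stage actions
#'
#' Both first-stage values are first decayed by `gamma`; the increments are
#' then attributed according to the trial's transition and outcome:
#' \describe{
#'   \item{common, rewarded}{chosen `+= d_plus_mf + d_plus_mb` — both
#'     systems credit the chosen action.}
#'   \item{rare, rewarded}{chosen `+= d_plus_mf`, unchosen `+= d_plus_mb` —
#'     a model-based learner credits the action that usually reaches the
#'     rewarded state.}
#'   \item{common, unrewarded}{chosen `+= d_minus_mf + d_minus_mb`.}
#'   \item{rare, unrewarded}{chosen `+= d_minus_mf`, unchosen
#'     `+= d_minus_mb`.}
#' }
#' The unchosen action decays too (its update is `gamma * v` plus any
#' model-based increment).
#'
#' @param v Numeric length-2 vector of values for actions `a1`, `a2`.
#' @param choice1 `"a1"` or `"a2"` (the chosen first-stage action).
#' @param transition `"common"` or `"rare"`.
#' @param rewarded Logical.
#' @param params A [model_params()] object.
#' @return The updated length-2 value vector.
#' @export
update_values <- function(v, choice1, transition, rewarded, params) {
  stopifnot(length(v) == 2L, all(is.finite(v)))
  ch <- match(choice1, c("a1", "a2"))
  if (is.na(ch)) stop("invalid first-stage action: ", choice1, call. = FALSE)
  if (!transition %in% c("common", "rare")) {
    stop("transition must be 'common' or 'rare'", call. = FALSE)
  }
  un <- 3L - ch
  d_mf <- if (rewarded) params$d_plus_mf else params$d_minus_mf
  d_mb <- if (rewarded) params$d_plus_mb else params$d_minus_mb
  v <- params$gamma * v
  if (transition == "common") {
    v[ch] <- v[ch] + d_mf + d_mb
  } else {
    v[ch] <- v[ch] + d_mf
    v[un] <- v[un] + d_mb
  }
  v
}

#' Softmax probability of choosing action a1
#'
#' The logistic of the value difference,
#' `P(a1) = 1 / (1 + exp(-(v[1] - v[2])))`. No inverse temperature is
#' needed: choice stochasticity is absorbed by the magnitude of the
#' increments.
#'
#' @param v Numeric length-2 value vector.
#' @return Probability of choosing `a1`.
#' @export
choice_prob <- function(v) {
  stopifnot(length(v) == 2L, all(is.finite(v)))
  stats::plogis(v[1] - v[2])
}

#' Session log-likelihood of first-stage choices
#'
#' Starting from `v0`, accumulates the log of the softmax probability of
#' each observed first-stage choice, updating the values with
#' [update_values()] after every trial. Second-stage choices do not enter
#' the likelihood. Trials must be in session order.
#'
#' @param params A [model_params()] object (or a named list/vector with the
#'   same five elements).
#' @param trials A trial-log tibble for one subject with columns `choice1`,
#'   `transition`, and `outcome` (points; rewarded iff positive), ordered by
#'   trial.
#' @param v0 Initial values; default `c(0, 0)` makes the first choice
#'   uniform.
#' @return The log-likelihood (a non-positive number). For an empty trial
#'   sequence, 0 with a warning.
#' @export
session_loglik <- function(params, trials, v0 = c(0, 0)) {
  if (nrow(trials) == 0L) {
    warning("empty trial sequence: log-likelihood 0 by convention")
    return(0)
  }
  th <- as_param_vector(params)
  loglik_session_cpp(
    choice = match(trials$choice1, c("a1", "a2")),
    common = as.integer(trials$transition == "common"),
    rewarded = as.integer(trials$outcome > 0),
    gamma = th[["gamma"]],
    d = th[delta_names],
    v0 = as.numeric(v0)
  )
}

as_param_vector <- function(params) {
  v <- unlist(params[param_names])
  if (length(v) != 5L || any(is.na(v))) {
    stop("params must provide gamma, d_plus_mf, d_plus_mb, d_minus_mf, d_minus_mb",
         call. = FALSE)
  }
  v
}

#' Condition parameter presets
#'
#' Median best-fitting parameter values by condition, used as simulation
#' presets: control (gamma 0.47, d_plus_mf 1.09, d_plus_mb 0.33, d_minus_mf
#' 0.48, d_minus_mb -0.14) and stress (gamma 0.73, d_plus_mf 0.50, d_plus_mb
#' -0.04, d_minus_mf 0.02, d_minus_mb -0.01). The accompanying jitter scales
#' are per-parameter normal-equivalent standard deviations derived from the
#' reported interquartile ranges (IQR / 1.349).
#'
#' @param condition `"control"` or `"stress"`.
#' @return For `condition_preset()`, a [model_params()]; for
#'   `condition_jitter_sd()`, a named numeric vector of jitter standard
#'   deviations.
#' @export
condition_preset <- function(condition = c("control", "stress")) {
  condition <- match.arg(condition)
  if (condition == "control") {
    model_params(0.47, 1.09, 0.33, 0.48, -0.14)
  } else {
    model_params(0.73, 0.50, -0.04, 0.02, -0.01)
  }
}

#' @rdname condition_preset
#' @export
condition_jitter_sd <- function(condition = c("control", "stress")) {
  condition <- match.arg(condition)
  iqr <- if (condition == "control") {
    c(gamma = 0.60 - 0.23, d_plus_mf = 1.67 - 0.70, d_plus_mb = 0.80 - 0.10,
      d_minus_mf = 0.78 - 0.12, d_minus_mb = 0.04 - (-0.41))
  } else {
    c(gamma = 0.95 - 0.56, d_plus_mf = 1.06 - 0.04, d_plus_mb = 0.18 - (-0.23),
      d_minus_mf = 0.14 - (-0.10), d_minus_mb = 0.11 - (-0.13))
  }
  iqr / 1.349
}
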