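#' Fit the hybrid model to one subject's session by maximum likelihood
#'
#' Maximizes the first-stage choice log-likelihood ([session_loglik()]) with
#' the Nelder-Mead simplex from `n_restarts` random initial points and
#' returns the best optimum. The decay factor is constrained to \[0, 1\] by
#' optimizing an unconstrained surrogate through a logistic map (avoiding
#' boundary-clipping artifacts in the simplex); the four increments float
#' freely. Initial points draw `gamma` uniformly on (0.05, 0.95) and each
#' increment uniformly on (-2, 2).
#'
#' @param trials Trial-log tibble for a single subject (>= 2 trials),
#'   ordered by trial.
#' @param n_restarts Number of random restarts. Default 500.
#' @param seed Integer seed making the restart stream reproducible.
#' @param reltol Relative convergence tolerance on the function value passed
#'   to [stats::optim()]. Default 1e-6.
#' @param maxit Maximum simplex iterations per restart. Default 2000.
#' @return An object of class `rl_fit` with elements `params`
#'   ([model_params()]), `loglik`, `n_restarts`, `n_converged`,
#'   `best_restart_index`, `seed`, `n_trials`, and `degenerate` (TRUE when
#'   the session holds a single unique first-stage choice, where the MLE
#'   diverges).
#' @export
fit_subject <- function(trials, n_restarts = 500L, seed = 1L,
                        reltol = 1e-6, maxit = 2000L) {
  if (nrow(trials) < 2L) stop("need at least 2 trials to fit", call. = FALSE)
  if ("subject_id" %in% names(trials) &&
      dplyr::n_distinct(trials$subject_id) > 1L) {
    stop("fit_subject() expects trials from a single subject", call. = FALSE)
  }
  choice <- match(trials$choice1, c("a1", "a2"))
  common <- as.integer(trials$transition == "common")
  rewarded <- as.integer(trials$outcome > 0)
  degenerate <- dplyr::n_distinct(choice) == 1L

  negll <- function(theta) {
    g <- stats::plogis(theta[1])
    -loglik_session_cpp(choice, common, rewarded, g, theta[2:5], c(0, 0))
  }

  # each restart consumes five consecutive uniforms, so for a fixed seed the
  # first k restarts are a prefix of the first k + m (restart monotonicity)
  set.seed(seed)
  u <- matrix(stats::runif(n_restarts * 5L), ncol = 5L, byrow = TRUE)
  inits <- cbind(stats::qlogis(0.05 + 0.90 * u[, 1, drop = FALSE]),
                 -2 + 4 * u[, 2:5, drop = FALSE])

  best <- NULL
  n_converged <- 0L
  best_idx <- NA_integer_
  failures <- character(0)
  for (r in seq_len(n_restarts)) {
    fit <- tryCatch(
      stats::optim(inits[r, ], negll, method = "Nelder-Mead",
                   control = list(reltol = reltol, maxit = maxit)),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      failures <- c(failures, conditionMessage(fit))
      next
    }
    if (fit$convergence == 0L) n_converged <- n_converged + 1L
    if (is.null(best) || fit$value < best$value) {
      best <- fit
      best_idx <- r
    }
  }
  if (is.null(best)) {
    stop("all ", n_restarts, " restarts failed to evaluate; first error: ",
         failures[1], call. = FALSE)
  }

  params <- model_params(
    gamma = stats::plogis(best$par[1]),
    d_plus_mf = best$par[2], d_plus_mb = best$par[3],
    d_minus_mf = best$par[4], d_minus_mb = best$par[5]
  )
  structure(
    list(params = params, loglik = -best$value,
         n_restarts = as.integer(n_restarts), n_converged = n_converged,
         best_restart_index = best_idx, seed = as.integer(seed),
         n_trials = nrow(trials), degenerate = degenerate),
    class = "rl_fit"
  )
}

#' @export
print.rl_fit <- function(x, ...) {
  cat(sprintf("<rl_fit> loglik %.3f over %d trials (%d/%d restarts converged)%s\n",
              x$loglik, x$n_trials, x$n_converged, x$n_restarts,
              if (x$degenerate) " [degenerate session]" else ""))
  print(x$params)
  invisible(x)
}

#' Fit every subject in a trial-log dataset
#'
#' Runs [fit_subject()] independently per subject. Each subject's restart
#' seed is derived deterministically from `seed` and the subject identifier
#' (not from subject order), so shuffling rows leaves every fit unchanged.
#'
#' @param trials Trial-log tibble with `subject_id` (and optionally
#'   `condition`) columns.
#' @param n_restarts Restarts per subject.
#' @param seed Master seed for the fit stage.
#' @param ... Passed to [fit_subject()].
#' @return A tibble with one row per subject: `subject_id`, `condition` (if
#'   present), the five fitted parameters, `loglik`, `n_restarts`,
#'   `n_converged`, `degenerate`, `seed`.
#' @export
fit_cohort <- function(trials, n_restarts = 500L, seed = 1L, ...) {
  stopifnot("subject_id" %in% names(trials))
  trials |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::group_map(function(df, key) {
      df <- dplyr::arrange(df, .data$trial)
      sseed <- subject_seed(seed, key$subject_id)
      fit <- fit_subject(df, n_restarts = n_restarts, seed = sseed, ...)
      out <- tibble::tibble(subject_id = key$subject_id)
      if ("condition" %in% names(df)) out$condition <- df$condition[1]
      dplyr::bind_cols(out, tidy_params(fit$params),
                       tibble::tibble(loglik = fit$loglik,
                                      n_restarts = fit$n_restarts,
                                      n_converged = fit$n_converged,
                                      degenerate = fit$degenerate,
                                      seed = fit$seed))
    }) |>
    purrr::list_rbind()
}

# deterministic 31-bit seed from a master seed and a subject id,
# independent of subject order
subject_seed <- function(seed, subject_id) {
  h <- 0
  for (k in utf8ToInt(as.character(subject_id))) {
    h <- (h * 31 + k) %% 2147480009  # large prime < 2^31
  }
  as.integer((h + as.numeric(seed) * 7919) %% 2147480009) + 1L
}

tidy_params <- function(params) {
  tibble::as_tibble(params[param_names])
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted hybrid model
#'
#' @param x An `rl_fit` object.
#' @param ... Unused.
#' @return One row per parameter with columns `term` and `estimate`.
#' @export
tidy.rl_fit <- function(x, ...) {
  tibble::tibble(term = param_names,
                 estimate = unlist(x$params[param_names], use.names = FALSE))
}

#' Fit-level summary of a fitted hybrid model
#'
#' @param x An `rl_fit` object.
#' @param ... Unused.
#' @return A one-row tibble with `loglik`, `n_trials`, `n_restarts`,
#'   `n_converged`, `best_restart_index`, `degenerate`, `seed`.
#' @export
glance.rl_fit <- function(x, ...) {
  tibble::tibble(loglik = x$loglik, n_trials = x$n_trials,
                 n_restarts = x$n_restarts, n_converged = x$n_converged,
                 best_restart_index = x$best_restart_index,
                 degenerate = x$degenerate, seed = x$seed)
}

#' Parameter-recovery summary
#'
#' Joins a ground-truth table to a fitted-parameter table and reports, per
#' parameter, the Spearman rank correlation between true and recovered
#' values — the core validation when no raw study data exists.
#'
#' @param truth Tibble of true parameters (as from [cohort_truth()]).
#' @param fits Tibble of fitted parameters (as from [fit_cohort()]).
#' @return A tibble with columns `term`, `rank_correlation`, `n`.
#' @export
recovery_summary <- function(truth, fits) {
  joined <- dplyr::inner_join(
    truth |> dplyr::select("subject_id", dplyr::all_of(param_names)),
    fits |> dplyr::select("subject_id", dplyr::all_of(param_names)),
    by = "subject_id", suffix = c("_true", "_fit")
  )
  purrr::map_dfr(param_names, function(p) {
    tibble::tibble(
      term = p,
      rank_correlation = stats::cor(joined[[paste0(p, "_true")]],
                                    joined[[paste0(p, "_fit")]],
                                    method = "spearman"),
      n = nrow(joined)
    )
  })
}
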