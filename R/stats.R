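#' Exclude perseverating subjects
#'
#' Removes subjects whose modal first-stage action frequency strictly
#' exceeds `threshold` (default 0.95), indicating absence of learning.
#'
#' @param trials Trial-log tibble with `subject_id` and `choice1`.
#' @param threshold Exclusion threshold on the modal-action proportion.
#' @return The retained trial log, with the excluded subjects (tibble of
#'   `subject_id`, `p_same_action`) attached as attribute `"excluded"` and
#'   retrievable via [excluded_subjects()].
#' @export
exclude_perseverators <- function(trials, threshold = 0.95) {
  props <- trials |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(
      p_same_action = max(table(.data$choice1)) / dplyr::n(),
      .groups = "drop"
    )
  excluded <- dplyr::filter(props, .data$p_same_action > threshold)
  kept <- dplyr::filter(trials, !.data$subject_id %in% excluded$subject_id)
  attr(kept, "excluded") <- excluded
  attr(kept, "truth") <- attr(trials, "truth")
  kept
}

#' @rdname exclude_perseverators
#' @param trials_after A trial log returned by [exclude_perseverators()].
#' @export
excluded_subjects <- function(trials_after) {
  attr(trials_after, "excluded")
}

#' Per-subject stay probabilities by previous outcome and transition
#'
#' For every trial after the first, classifies the trial by the *previous*
#' trial's outcome (rewarded/unrewarded) and transition (common/rare), and
#' records whether the subject repeated ("stayed with") the previous
#' first-stage choice. Block boundaries are not breaks: transitions between
#' blocks were uncued, so trial t = 41 is classified by trial 40.
#'
#' @param trials Trial-log tibble for one or more subjects (columns
#'   `subject_id`, `condition` optional for a single unnamed session).
#' @return A tibble with one row per subject x previous-outcome x
#'   previous-transition cell: `prev_outcome` (`"rewarded"`/`"unrewarded"`),
#'   `prev_transition`, `n` (cell count), `stay_prob` (`NaN` for empty
#'   cells).
#' @export
stay_probabilities <- function(trials) {
  if (!"subject_id" %in% names(trials)) {
    trials <- dplyr::mutate(trials, subject_id = "session")
  }
  grp_cols <- intersect(c("subject_id", "condition"), names(trials))
  cells <- tidyr::expand_grid(
    prev_outcome = c("rewarded", "unrewarded"),
    prev_transition = c("common", "rare")
  )
  trials |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp_cols))) |>
    dplyr::arrange(.data$trial, .by_group = TRUE) |>
    dplyr::mutate(
      stay = .data$choice1 == dplyr::lag(.data$choice1),
      prev_outcome = ifelse(dplyr::lag(.data$outcome) > 0,
                            "rewarded", "unrewarded"),
      prev_transition = dplyr::lag(.data$transition)
    ) |>
    dplyr::filter(!is.na(.data$stay)) |>
    dplyr::group_by(.data$prev_outcome, .data$prev_transition, .add = TRUE) |>
    dplyr::summarise(n = dplyr::n(), stay_prob = mean(.data$stay),
                     .groups = "drop") |>
    # make empty cells explicit (n = 0, stay_prob NaN)
    dplyr::right_join(
      tidyr::expand_grid(
        dplyr::distinct(trials, dplyr::across(dplyr::all_of(grp_cols))), cells
      ),
      by = c(grp_cols, "prev_outcome", "prev_transition")
    ) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L),
                  stay_prob = ifelse(.data$n == 0L, NaN, .data$stay_prob)) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(
      c(grp_cols, "prev_outcome", "prev_transition"))))
}

#' Mixed-design ANOVA on stay probabilities
#'
#' The 2 x 2 x 2 mixed ANOVA on per-subject stay probabilities: previous
#' outcome (rewarded/unrewarded) and previous transition (common/rare) as
#' within-subject factors, condition as the between-subject factor.
#' Computed by the conventional sum-of-squares partitioning for one
#' between- and two within-subject factors (two-level factors need no
#' sphericity correction). Subjects with any empty cell are dropped with a
#' warning.
#'
#' @param stays A stay table from [stay_probabilities()] including a
#'   `condition` column.
#' @return A tibble with columns `effect`, `df1`, `df2`, `statistic`
#'   (F value), `p.value`.
#' @export
stay_anova <- function(stays) {
  stopifnot(all(c("subject_id", "condition", "prev_outcome",
                  "prev_transition", "stay_prob") %in% names(stays)))
  bad <- stays |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::filter(any(!is.finite(.data$stay_prob))) |>
    dplyr::pull(.data$subject_id) |>
    unique()
  if (length(bad)) {
    warning("dropping ", length(bad),
            " subject(s) with empty stay cells: ",
            paste(utils::head(bad, 5L), collapse = ", "))
    stays <- dplyr::filter(stays, !.data$subject_id %in% bad)
  }
  n_per <- stays |>
    dplyr::distinct(.data$subject_id, .data$condition) |>
    dplyr::count(.data$condition)
  if (nrow(n_per) != 2L || any(n_per$n < 2L)) {
    stop("need two conditions with at least 2 subjects each", call. = FALSE)
  }
  if (stats::var(stays$stay_prob) == 0) {
    stop("all stay probabilities are identical; ANOVA is degenerate",
         call. = FALSE)
  }
  d <- stays |>
    dplyr::mutate(
      subject_id = factor(.data$subject_id),
      condition = factor(.data$condition),
      prev_outcome = factor(.data$prev_outcome),
      prev_transition = factor(.data$prev_transition)
    )
  fit <- stats::aov(
    stay_prob ~ condition * prev_outcome * prev_transition +
      Error(subject_id / (prev_outcome * prev_transition)),
    data = d
  )
  s <- summary(fit)
  rows <- purrr::map_dfr(s, function(stratum) {
    tab <- stratum[[1]]
    terms <- trimws(rownames(tab))
    keep <- terms != "Residuals"
    resid_df <- tab[terms == "Residuals", "Df"]
    tibble::tibble(
      effect = terms[keep],
      df1 = tab[keep, "Df"],
      df2 = resid_df,
      statistic = tab[keep, "F value"],
      p.value = tab[keep, "Pr(>F)"]
    )
  })
  dplyr::mutate(rows, effect = gsub("prev_", "", .data$effect))
}

#' Per-subject performance summary
#'
#' Total points, the probability of choosing the advantageous first-stage
#' action, and the modal first-stage action proportion. The advantageous
#' action is the one more strongly linked to the currently favored
#' second-stage state; block 1, where neither action dominates, is excluded
#' from `p_advantageous`.
#'
#' @param trials Trial-log tibble (one or more subjects).
#' @param config The [task_config()] the sessions were played under.
#' @return A tibble with one row per subject: `subject_id`, `condition` (if
#'   present), `total_points`, `p_advantageous`, `p_same_action`.
#' @export
performance_summary <- function(trials, config = default_task_config()) {
  if (!"subject_id" %in% names(trials)) {
    trials <- dplyr::mutate(trials, subject_id = "session")
  }
  grp_cols <- intersect(c("subject_id", "condition"), names(trials))
  adv <- favored_states(config)
  trials |>
    dplyr::left_join(adv, by = "block") |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp_cols))) |>
    dplyr::summarise(
      total_points = sum(.data$outcome),
      p_advantageous = mean(
        (.data$choice1 == .data$advantageous_action)[!is.na(.data$advantageous_action)]
      ),
      p_same_action = max(table(.data$choice1)) / dplyr::n(),
      .groups = "drop"
    )
}

#' Two-sample comparisons between conditions
#'
#' Two-tailed pooled-variance t tests (the df convention matching n1 + n2 -
#' 2) on each requested column of a per-subject table.
#'
#' @param data Per-subject tibble with a `condition` column.
#' @param vars Character vector of numeric columns to compare; defaults to
#'   every numeric column.
#' @param ref The condition treated as the reference (first) group; the
#'   reported `estimate` is `mean(ref) - mean(other)`. Defaults to the
#'   first condition level in the data.
#' @return A tibble with one row per variable: `variable`, `estimate`,
#'   `statistic` (t), `df`, `p.value`.
#' @export
compare_conditions <- function(data, vars = NULL, ref = NULL) {
  stopifnot("condition" %in% names(data))
  conds <- unique(data$condition)
  if (length(conds) != 2L) stop("need exactly two conditions", call. = FALSE)
  if (is.null(ref)) ref <- conds[1]
  other <- setdiff(conds, ref)
  if (is.null(vars)) {
    vars <- names(data)[vapply(data, is.numeric, logical(1))]
    vars <- setdiff(vars, c("seed", "n_restarts", "n_converged"))
  }
  counts <- table(data$condition)
  if (any(counts < 2L)) stop("each condition needs n >= 2", call. = FALSE)
  purrr::map_dfr(vars, function(v) {
    x <- data[[v]][data$condition == ref]
    y <- data[[v]][data$condition == other]
    if (stats::var(x) + stats::var(y) == 0) {
      stop("zero pooled variance for '", v, "'", call. = FALSE)
    }
    tt <- stats::t.test(x, y, var.equal = TRUE)
    tibble::tibble(variable = v,
                   estimate = unname(tt$estimate[1] - tt$estimate[2]),
                   statistic = unname(tt$statistic),
                   df = unname(tt$parameter),
                   p.value = tt$p.value)
  })
}

#' Regression of the model-free loss increment on decay and treatment
#'
#' Ordinary least squares of `d_minus_mf` on `gamma` and a treatment
#' indicator, testing whether the treatment effect on the model-free
#' response to negative outcomes survives controlling for the decay factor.
#' Standardized coefficients are from the same model refit on z-scored
#' outcome and predictors.
#'
#' @param fits Per-subject fitted-parameter tibble (from [fit_cohort()])
#'   with `condition`, `gamma`, `d_minus_mf`.
#' @param treatment The condition coded 1 in the treatment indicator.
#'   Default `"stress"`.
#' @param outcome Column to regress; default `"d_minus_mf"`.
#' @return A tibble with one row per predictor: `term`, `estimate` (B),
#'   `std.error`, `beta` (standardized), `statistic`, `p.value`.
#' @export
delta_regression <- function(fits, treatment = "stress",
                             outcome = "d_minus_mf") {
  stopifnot(all(c("condition", "gamma", outcome) %in% names(fits)))
  d <- fits |>
    dplyr::mutate(treatment = as.numeric(.data$condition == treatment)) |>
    dplyr::select(y = dplyr::all_of(outcome), "gamma", "treatment")
  if (nrow(d) < 5L) stop("need at least 3 more subjects than predictors",
                         call. = FALSE)
  if (stats::var(d$gamma) == 0 || stats::var(d$treatment) == 0) {
    stop("a predictor has zero variance; regression is degenerate",
         call. = FALSE)
  }
  fit <- stats::lm(y ~ gamma + treatment, data = d)
  if (any(!is.finite(stats::coef(fit)))) {
    stop("collinear predictors", call. = FALSE)
  }
  zs <- dplyr::mutate(d, dplyr::across(dplyr::everything(),
                                       ~ as.numeric(scale(.x))))
  zfit <- stats::lm(y ~ gamma + treatment, data = zs)
  ct <- summary(fit)$coefficients
  zb <- stats::coef(zfit)
  tibble::tibble(
    term = rownames(ct),
    estimate = ct[, "Estimate"],
    std.error = ct[, "Std. Error"],
    beta = dplyr::if_else(rownames(ct) == "(Intercept)", NA_real_,
                          unname(zb[rownames(ct)])),
    statistic = ct[, "t value"],
    p.value = ct[, "Pr(>|t|)"]
  )
}

#' ANCOVA of the model-free loss increment with a performance covariate
#'
#' Tests the condition effect on `d_minus_mf` adjusting for the probability
#' of choosing the advantageous action (which proxies latent-state
#' inference): an F test of the condition term in
#' `outcome ~ covariate + condition`.
#'
#' @param fits Fitted-parameter tibble with `subject_id`, `condition`, and
#'   the outcome column.
#' @param performance Per-subject performance tibble with `subject_id` and
#'   the covariate column.
#' @param covariate Covariate column name. Default `"p_advantageous"`.
#' @param outcome Outcome column. Default `"d_minus_mf"`.
#' @return A tibble with one row per model term: `effect`, `df1`, `df2`,
#'   `statistic` (F), `p.value`.
#' @export
delta_ancova <- function(fits, performance, covariate = "p_advantageous",
                         outcome = "d_minus_mf") {
  d <- dplyr::inner_join(
    fits |> dplyr::select("subject_id", "condition", dplyr::all_of(outcome)),
    performance |> dplyr::select("subject_id", dplyr::all_of(covariate)),
    by = "subject_id"
  ) |>
    dplyr::rename(y = dplyr::all_of(outcome), x = dplyr::all_of(covariate)) |>
    dplyr::mutate(condition = factor(.data$condition))
  if (nrow(d) < 5L) stop("need at least 3 more subjects than predictors",
                         call. = FALSE)
  if (stats::var(d$x) == 0) {
    stop("covariate has zero variance", call. = FALSE)
  }
  fit <- stats::lm(y ~ x + condition, data = d)
  # F tests of each term adjusted for the other (type II; equal to type III
  # here since no interaction is modeled)
  dr <- stats::drop1(fit, scope = ~ x + condition, test = "F")
  resid_df <- fit$df.residual
  tibble::tibble(
    effect = c(covariate, "condition"),
    df1 = dr$Df[-1],
    df2 = resid_df,
    statistic = dr$`F value`[-1],
    p.value = dr$`Pr(>F)`[-1]
  )
}
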