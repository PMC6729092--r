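#' Two-way group-by-trial ANOVA with Type II sums of squares
#'
#' Compares groups (PD vs control) and the three TUG trials on one response.
#' Type II sums of squares are used instead of Type III to minimise the bias
#' of the strongly unbalanced groups: each main effect is adjusted for the
#' other main effect ignoring the interaction, and the interaction is
#' adjusted for both mains. Post-hoc pairwise cell contrasts carry
#' Sidak-adjusted p-values; the number of contrasts adjusted for (`m`) is
#' the number of contrasts performed.
#'
#' @param data a data frame.
#' @param response unquoted column holding the response.
#' @param group,trial unquoted factor columns (coerced to factor).
#' @param posthoc compute Sidak-adjusted pairwise cell contrasts (default
#'   TRUE).
#' @return a `tug_anova` object; `tidy()` returns the effect table
#'   (`term`, `sumsq`, `df`, `statistic`, `p.value`), `glance()` a one-row
#'   model summary, and `$posthoc` the adjusted contrasts.
#' @examples
#' cohort <- tidyr::crossing(subject = 1:8, trial_index = 1:3) |>
#'   dplyr::mutate(group = ifelse(subject <= 4, "PD", "control"),
#'                 sparc = -4 - (group == "PD") * 2 + rnorm(24, 0, 0.5))
#' fit <- anova_group_trial(cohort, sparc, group, trial_index)
#' tidy(fit)
#' @export
anova_group_trial <- function(data, response, group, trial, posthoc = TRUE) {
  df <- tibble(
    .y = dplyr::pull(data, {{ response }}),
    .g = factor(dplyr::pull(data, {{ group }})),
    .t = factor(dplyr::pull(data, {{ trial }}))
  )
  if (nlevels(df$.g) < 2 || nlevels(df$.t) < 2) {
    stop_fmt("design_error", "need at least 2 levels of both group and trial")
  }
  cells <- table(df$.g, df$.t)
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)
    stop_fmt("design_error", "empty design cell(s): ",
             paste(rownames(cells)[empty[, 1]], colnames(cells)[empty[, 2]],
                   sep = ":", collapse = ", "))
  }
  fit <- lm(.y ~ .g * .t, data = df)
  a2 <- car::Anova(fit, type = 2)
  tab <- tibble(
    term = c("group", "trial", "group:trial", "residuals"),
    sumsq = a2$`Sum Sq`,
    df = a2$Df,
    statistic = a2$`F value`,
    p.value = a2$`Pr(>F)`
  )
  ph <- NULL
  if (posthoc) {
    emm <- emmeans::emmeans(fit, ~ .g * .t)
    prs <- summary(emmeans::contrast(emm, method = "pairwise", adjust = "sidak"))
    ph <- tibble(contrast = as.character(prs$contrast),
                 estimate = prs$estimate, se = prs$SE, df = prs$df,
                 t.ratio = prs$t.ratio, p.value = prs$p.value,
                 m = nrow(prs))
  }
  structure(list(anova = tab, posthoc = ph, model = fit,
                 n = nrow(df), cells = cells),
            class = "tug_anova")
}

#' @method tidy tug_anova
#' @export
tidy.tug_anova <- function(x, ...) x$anova

#' @method glance tug_anova
#' @export
glance.tug_anova <- function(x, ...) {
  s <- summary(x$model)
  tibble(r.squared = s$r.squared, adj.r.squared = s$adj.r.squared,
         sigma = s$sigma, df.residual = x$model$df.residual, nobs = x$n)
}

#' @export
print.tug_anova <- function(x, ...) {
  cat("Two-way group x trial ANOVA (Type II sums of squares)\n")
  print(x$anova)
  if (!is.null(x$posthoc)) {
    cat("Post-hoc pairwise contrasts (Sidak, m =", x$posthoc$m[[1]], ")\n")
  }
  invisible(x)
}

#' Sidak correction for multiple comparisons
#'
#' `p_adj = 1 - (1 - p)^m`, clipped to `[0, 1]`; `m` defaults to the number
#' of p-values supplied. Monotone in both `p` and `m`, and never smaller
#' than the raw p-value.
#'
#' @param pvals numeric p-values in `[0, 1]`.
#' @param m number of comparisons.
#' @return adjusted p-values, same length.
#' @export
sidak_adjust <- function(pvals, m = length(pvals)) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    stop_fmt("value_error", "p-values must lie in [0, 1]")
  }
  pmin(1, 1 - (1 - pvals)^m)
}

#' Pearson product-moment correlation
#'
#' Correlation between two numeric vectors with the two-sided p-value from
#' the t transform, returned broom-style as a one-row tibble with `r`,
#' `r_squared`, `p_value` and `n`.
#'
#' @param x,y equal-length numeric vectors, n >= 3.
#' @return one-row tibble.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) stop_fmt("shape_error", "x and y differ in length")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop_fmt("length_error", "need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) {
    stop_fmt("degenerate_input", "zero variance: correlation undefined")
  }
  ct <- cor.test(x, y, method = "pearson")
  tibble(r = unname(ct$estimate), r_squared = unname(ct$estimate)^2,
         p_value = ct$p.value, n = length(x))
}

#' Correlation map between smoothness metrics and clinical scores
#'
#' Computes the Pearson correlation of every clinical score against every
#' (TUG phase, SPARC channel) combination across subjects, the layout in
#' which such maps are reported: one row per score x phase x channel with
#' `r`, `r_squared` and the unadjusted `p_value`, flagged significant at
#' p < 0.05. Sidak-adjusted p-values over the whole map are available as an
#' option (off by default, matching how these tables are usually printed).
#' Score columns with zero variance across the joined subjects yield `NA`
#' rows with a warning rather than an error.
#'
#' @param smoothness a `smoothness_result` table (typically trial-averaged,
#'   one row per subject x channel x phase).
#' @param scores tibble with `subject_id` and numeric score columns.
#' @param score_cols character vector of score columns to use; defaults to
#'   every numeric column except `subject_id`/`degradation`.
#' @param sidak also report Sidak-adjusted p-values over the map.
#' @return tibble with columns `score`, `phase`, `channel`, `r`,
#'   `r_squared`, `p_value`, `significant` (and `p_sidak` if requested),
#'   ordered by score then p-value.
#' @export
correlation_map <- function(smoothness, scores, score_cols = NULL, sidak = FALSE) {
  if (!all(unique(smoothness$subject_id) %in% scores$subject_id)) {
    missing_subj <- setdiff(unique(smoothness$subject_id), scores$subject_id)
    stop_fmt("join_error", "subjects missing from the score table: ",
             paste(missing_subj, collapse = ", "))
  }
  if (is.null(score_cols)) {
    score_cols <- setdiff(names(scores)[vapply(scores, is.numeric, logical(1))],
                          c("degradation", "trial_index"))
  }
  wide <- dplyr::left_join(
    dplyr::select(as_tibble(smoothness), "subject_id", "channel", "phase", "sparc"),
    dplyr::select(scores, "subject_id", dplyr::all_of(score_cols)),
    by = "subject_id"
  )
  combos <- tidyr::crossing(
    score = score_cols,
    dplyr::distinct(wide, .data$phase, .data$channel)
  )
  rows <- purrr::pmap(combos, function(score, phase, channel) {
    sub <- wide[wide$phase == phase & wide$channel == channel, ]
    ct <- tryCatch(pearson_cor(sub[[score]], sub$sparc), error = function(e) {
      warn(paste0("correlation undefined for ", score, " x ", phase, " x ",
                  channel, ": ", conditionMessage(e)))
      tibble(r = NA_real_, r_squared = NA_real_, p_value = NA_real_,
             n = sum(stats::complete.cases(sub[[score]], sub$sparc)))
    })
    dplyr::bind_cols(tibble(score = score, phase = phase, channel = channel), ct)
  })
  out <- dplyr::bind_rows(rows)
  out$significant <- !is.na(out$p_value) & out$p_value < 0.05
  if (sidak) out$p_sidak <- sidak_adjust(out$p_value, m = sum(!is.na(out$p_value)))
  dplyr::arrange(out, .data$score, .data$p_value)
}

#' Cohen's d effect size
#'
#' Absolute standardised mean difference with the pooled SD, classified by
#' the conventional thresholds — small (0.2), moderate (0.5), large (0.8) —
#' and flagged clinically relevant when d > 0.4.
#'
#' @param group_a,group_b numeric vectors, each of length >= 2.
#' @return one-row tibble with `d`, `class` and `clinically_relevant`.
#' @export
cohen_d <- function(group_a, group_b) {
  n1 <- length(group_a); n2 <- length(group_b)
  if (n1 < 2 || n2 < 2) stop_fmt("length_error", "need at least 2 values per group")
  sp <- sqrt(((n1 - 1) * stats::var(group_a) + (n2 - 1) * stats::var(group_b)) /
               (n1 + n2 - 2))
  if (sp == 0) stop_fmt("degenerate_input", "zero pooled SD: effect size undefined")
  d <- abs(mean(group_a) - mean(group_b)) / sp
  cls <- if (d >= 0.8) "large" else if (d >= 0.5) "moderate"
         else if (d >= 0.2) "small" else "negligible"
  tibble(d = d, class = cls, clinically_relevant = d > 0.4)
}

#' Power and sample size for the two-sample t-test
#'
#' Noncentral-t power computations for a two-sample t-test on standardised
#' effect size d. `required_n_ttest()` returns the smallest equal per-group
#' n (at least 2) whose power reaches the target; `achieved_power_ttest()`
#' gives the (possibly retrospective) power of given, possibly unequal,
#' group sizes. The noncentrality parameter is `d * sqrt(n1*n2/(n1+n2))`
#' with `n1 + n2 - 2` degrees of freedom. With d = 0 the two-sided power
#' equals alpha, the probability of rejecting a true null.
#'
#' @param d standardised effect size (mean difference / SD), positive.
#' @param alpha significance level (default 0.05).
#' @param power target power for the sample-size search (default 0.90).
#' @param tails `"one"` or `"two"`.
#' @param n_max search bound.
#' @return `required_n_ttest()`: integer n per group.
#'   `achieved_power_ttest()`: power in `(0, 1)`.
#' @examples
#' required_n_ttest(1.57 / 0.79, alpha = 0.05, power = 0.90, tails = "one")
#' @export
required_n_ttest <- function(d, alpha = 0.05, power = 0.90,
                             tails = c("one", "two"), n_max = 1e5) {
  tails <- match.arg(tails)
  if (!is.numeric(d) || d <= 0) stop_fmt("value_error", "effect size d must be positive")
  for (n in 2:n_max) {
    if (achieved_power_ttest(d, n, n, alpha = alpha, tails = tails) >= power) {
      return(n)
    }
  }
  stop_fmt("value_error", "no n <= ", n_max, " reaches the target power")
}

#' @rdname required_n_ttest
#' @param n1,n2 group sizes, each >= 2.
#' @export
achieved_power_ttest <- function(d, n1, n2, alpha = 0.05,
                                 tails = c("two", "one")) {
  tails <- match.arg(tails)
  if (n1 < 2 || n2 < 2) stop_fmt("value_error", "group sizes must be at least 2")
  if (alpha <= 0 || alpha >= 1) stop_fmt("value_error", "alpha must be in (0, 1)")
  df <- n1 + n2 - 2
  ncp <- d * sqrt(n1 * n2 / (n1 + n2))
  if (tails == "one") {
    1 - pt(qt(1 - alpha, df), df, ncp = ncp)
  } else {
    crit <- qt(1 - alpha / 2, df)
    (1 - pt(crit, df, ncp = ncp)) + pt(-crit, df, ncp = ncp)
  }
}

#' Sample size for detecting a correlation
#'
#' Fisher-z approximation: the number of pairs needed for a test of
#' H0: rho = 0 against a true correlation `r` to reach the target power.
#'
#' @param r true correlation magnitude, 0 < r < 1.
#' @param alpha significance level.
#' @param power target power.
#' @param tails `"one"` or `"two"`.
#' @return integer sample size.
#' @export
required_n_correlation <- function(r, alpha = 0.05, power = 0.95,
                                   tails = c("one", "two")) {
  tails <- match.arg(tails)
  if (r <= 0 || r >= 1) stop_fmt("value_error", "r must be in (0, 1)")
  za <- stats::qnorm(1 - if (tails == "one") alpha else alpha / 2)
  zb <- stats::qnorm(power)
  ceiling(((za + zb) / atanh(r))^2 + 3)
}

#' Table-2-style group summary with effect sizes
#'
#' For each channel of the full-test SPARC values (plus, if supplied, the
#' total TUG duration), reports group means with 95% confidence intervals,
#' Cohen's d and the two-sample Welch p-value — the layout of a smoothness
#' summary table.
#'
#' @param smoothness a trial-averaged `smoothness_result`.
#' @param durations optional tibble with `subject_id`, `group`, `total_s`.
#' @return tibble with one row per variable.
#' @export
group_effects_table <- function(smoothness, durations = NULL) {
  full <- dplyr::filter(as_tibble(smoothness), .data$phase == "full")
  vars <- dplyr::transmute(full, variable = paste0("sparc_", .data$channel),
                           group = .data$group, value = .data$sparc)
  if (!is.null(durations)) {
    vars <- dplyr::bind_rows(vars, dplyr::transmute(
      durations, variable = "tug_time_s", group = .data$group,
      value = .data$total_s))
  }
  ci <- function(v) stats::qt(0.975, length(v) - 1) * sd(v) / sqrt(length(v))
  vars |>
    dplyr::group_by(.data$variable) |>
    dplyr::group_modify(function(g, key) {
      pd <- g$value[g$group == "PD"]
      hc <- g$value[g$group == "control"]
      es <- cohen_d(pd, hc)
      wt <- stats::t.test(pd, hc)
      tibble(mean_pd = mean(pd), ci_pd = ci(pd),
             mean_control = mean(hc), ci_control = ci(hc),
             d = es$d, class = es$class, p_value = wt$p.value)
    }) |>
    dplyr::ungroup()
}
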