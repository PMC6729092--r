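# explicit model-comparison oracle for Type II sums of squares
type2_oracle <- function(df) {
  rss <- function(form) sum(stats::residuals(lm(form, data = df))^2)
  full <- rss(.y ~ .g * .t)
  list(
    group = rss(.y ~ .t) - rss(.y ~ .g + .t),
    trial = rss(.y ~ .g) - rss(.y ~ .g + .t),
    interaction = rss(.y ~ .g + .t) - full,
    residual = full
  )
}

test_that("Type II sums of squares match an explicit regression oracle", {
  set.seed(14)
  # small unbalanced two-by-two design, hand-checkable
  df <- data.frame(
    .y = c(2.1, 1.9, 3.2, 4.0, 4.4, 2.8, 3.1, 5.0),
    .g = c("a", "a", "a", "b", "b", "b", "a", "b"),
    .t = c(1, 2, 2, 1, 2, 2, 1, 1)
  )
  fit <- anova_group_trial(df, .y, .g, .t, posthoc = FALSE)
  tab <- tidy(fit)
  oracle <- type2_oracle(df)
  expect_equal(tab$sumsq[tab$term == "group"], oracle$group, tolerance = 1e-8)
  expect_equal(tab$sumsq[tab$term == "trial"], oracle$trial, tolerance = 1e-8)
  expect_equal(tab$sumsq[tab$term == "group:trial"], oracle$interaction,
               tolerance = 1e-8)
  expect_equal(tab$sumsq[tab$term == "residuals"], oracle$residual,
               tolerance = 1e-8)
  # F follows from the oracle SS
  ms_res <- oracle$residual / tab$df[tab$term == "residuals"]
  expect_equal(tab$statistic[tab$term == "group"],
               (oracle$group / 1) / ms_res, tolerance = 1e-8)
  g <- glance(fit)
  expect_equal(g$nobs, 8)
})

test_that("Type II equals Type III on balanced designs", {
  for (seed in 1:3) {
    set.seed(seed)
    df <- expand.grid(.g = c("pd", "hc"), .t = 1:3, rep = 1:4)
    df$.y <- rnorm(nrow(df)) + 2 * (df$.g == "pd")
    t2 <- tidy(anova_group_trial(df, .y, .g, .t, posthoc = FALSE))
    fit3 <- lm(.y ~ .g * .t,
               data = transform(df, .g = factor(.g), .t = factor(.t)),
               contrasts = list(.g = "contr.sum", .t = "contr.sum"))
    t3 <- car::Anova(fit3, type = 3)
    expect_equal(t2$sumsq[t2$term == "group"], t3[".g", "Sum Sq"],
                 tolerance = 1e-10)
    expect_equal(t2$sumsq[t2$term == "trial"], t3[".t", "Sum Sq"],
                 tolerance = 1e-10)
  }
})

test_that("degenerate ANOVA designs fail loudly", {
  df <- data.frame(.y = rnorm(6), .g = c("a", "a", "a", "b", "b", "b"),
                   .t = c(1, 2, 1, 1, 1, 1))
  expect_error(anova_group_trial(df, .y, .g, .t), "empty design cell",
               class = "sparctug_design_error")
  df2 <- data.frame(.y = rnorm(6), .g = "a", .t = rep(1:2, 3))
  expect_error(anova_group_trial(df2, .y, .g, .t),
               class = "sparctug_design_error")
})

test_that("post-hoc contrasts carry Sidak-adjusted p-values", {
  set.seed(20)
  df <- expand.grid(.g = c("pd", "hc"), .t = 1:2, rep = 1:6)
  df$.y <- rnorm(nrow(df)) + 1.5 * (df$.g == "pd")
  fit <- anova_group_trial(df, .y, .g, .t)
  expect_false(is.null(fit$posthoc))
  expect_equal(fit$posthoc$m[[1]], nrow(fit$posthoc))
  expect_true(all(fit$posthoc$p.value >= 0 & fit$posthoc$p.value <= 1))
})

test_that("Sidak adjustment follows its closed form", {
  expect_equal(sidak_adjust(0.04, m = 1), 0.04)
  expect_equal(sidak_adjust(0.05, m = 3), 1 - 0.95^3)   # 0.142625
  expect_equal(sidak_adjust(0.05, m = 3), 0.142625)
  expect_equal(sidak_adjust(0, m = 10), 0)
  expect_equal(sidak_adjust(1, m = 5), 1)
  p <- c(0.001, 0.01, 0.05, 0.2, 0.9)
  adj <- sidak_adjust(p)
  expect_true(all(adj >= p))                            # never smaller
  expect_true(all(diff(adj) > 0))                       # monotone in p
  expect_true(all(sidak_adjust(0.05, 5) > sidak_adjust(0.05, 2)))  # and in m
  expect_error(sidak_adjust(c(0.5, 1.2)), class = "sparctug_value_error")
})

test_that("Pearson correlation matches the direct formula and t transform", {
  x <- 1:10
  perfect <- pearson_cor(x, x)
  expect_equal(perfect$r, 1)
  expect_equal(perfect$r_squared, 1)
  for (seed in 1:5) {
    set.seed(seed)
    a <- rnorm(20); b <- rnorm(20)
    got <- pearson_cor(a, b)
    r_oracle <- sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    expect_equal(got$r, r_oracle, tolerance = 1e-12)
    expect_equal(got$r_squared, r_oracle^2, tolerance = 1e-12)
    tstat <- r_oracle * sqrt(18 / (1 - r_oracle^2))
    expect_equal(got$p_value, 2 * pt(-abs(tstat), 18), tolerance = 1e-12)
  }
  # slope sign determines r exactly for affine relations
  set.seed(6)
  z <- rnorm(15)
  expect_equal(pearson_cor(z, 3 - 2 * z)$r, -1, tolerance = 1e-12)
  expect_error(pearson_cor(rep(1, 5), rnorm(5)),
               class = "sparctug_degenerate_input")
  expect_error(pearson_cor(1:4, 1:5), class = "sparctug_shape_error")
})

test_that("correlation map recovers a built-in monotone association", {
  set.seed(33)
  subjects <- sprintf("P%02d", 1:20)
  smooth <- tidyr::crossing(
    subject_id = subjects,
    channel = c("acc_l_total", "acc_a_total"),
    phase = c("turn", "full")
  )
  severity <- stats::setNames(runif(20, 0, 1), subjects)
  smooth$sparc <- -2 - 3 * severity[smooth$subject_id] + rnorm(nrow(smooth), 0, 0.3)
  smooth$group <- "PD"
  scores <- tibble::tibble(subject_id = subjects,
                           fogq = round(20 * severity + rnorm(20, 0, 1)),
                           flat = 5)
  w <- capture_warnings(
    cm <- correlation_map(smooth, scores, score_cols = c("fogq", "flat"))
  )
  expect_length(w, 4)                   # one per phase x channel combination
  expect_true(all(grepl("correlation undefined", w)))
  expect_identical(names(cm)[1:3], c("score", "phase", "channel"))
  fog <- cm[cm$score == "fogq", ]
  expect_true(all(fog$r < 0))           # higher FOG-Q, lower smoothness
  expect_true(all(is.na(cm$r[cm$score == "flat"])))
  expect_true(all(fog$significant == (fog$p_value < 0.05)))
  expect_equal(fog$r_squared, fog$r^2, tolerance = 1e-12)

  cm2 <- suppressWarnings(correlation_map(smooth, scores,
                                          score_cols = c("fogq", "flat"),
                                          sidak = TRUE))
  expect_true(all(cm2$p_sidak >= cm2$p_value, na.rm = TRUE))

  expect_error(correlation_map(smooth, scores[1:3, ]),
               class = "sparctug_join_error")
})

test_that("Cohen's d uses the pooled SD and the stated classes", {
  base <- c(-1, 1, -1, 1)
  expect_equal(cohen_d(base, base)$d, 0)
  expect_identical(cohen_d(base, base)$class, "negligible")
  # pooled SD of two copies of {-1, 1} is known, so d is exact
  shift <- cohen_d(base, base + 1.52 * sd(base))
  expect_equal(shift$d, 1.52, tolerance = 1e-12)
  expect_identical(shift$class, "large")
  expect_true(shift$clinically_relevant)
  expect_identical(cohen_d(base, base + 0.6 * sd(base))$class, "moderate")
  expect_identical(cohen_d(base, base + 0.3 * sd(base))$class, "small")
  expect_false(cohen_d(base, base + 0.3 * sd(base))$clinically_relevant)

  for (seed in 1:4) {
    set.seed(seed)
    a <- rnorm(12); b <- rnorm(9, 1)
    sp <- sqrt((11 * var(a) + 8 * var(b)) / 19)
    expect_equal(cohen_d(a, b)$d, abs(mean(a) - mean(b)) / sp, tolerance = 1e-12)
  }
  expect_error(cohen_d(rep(2, 3), rep(2, 4)), class = "sparctug_degenerate_input")
})

test_that("noncentral-t power calculations agree with power.t.test", {
  d <- 1.57 / 0.79
  expect_identical(required_n_ttest(d, tails = "one"), 6L + 0L)
  expect_identical(required_n_ttest(d, tails = "two"), 7L + 0L)
  expect_identical(required_n_ttest(10), 2L + 0L)

  # independent oracle: stats::power.t.test on the same designs
  for (n in c(6, 10, 20)) {
    expect_equal(
      achieved_power_ttest(d, n, n, tails = "two"),
      power.t.test(n = n, delta = d, sd = 1, sig.level = 0.05)$power,
      tolerance = 1e-6
    )
    expect_equal(
      achieved_power_ttest(d, n, n, tails = "one"),
      power.t.test(n = n, delta = d, sd = 1, sig.level = 0.05,
                   alternative = "one.sided")$power,
      tolerance = 1e-6
    )
  }
  expect_equal(achieved_power_ttest(1.9873, 6, 6, tails = "one"), 0.94,
               tolerance = 0.01)
  expect_equal(achieved_power_ttest(0, 10, 10, tails = "two"), 0.05,
               tolerance = 1e-9)
  expect_gt(achieved_power_ttest(2, 50, 50), 0.999)

  # monotonicity of the search
  expect_lte(required_n_ttest(2.5), required_n_ttest(1.5))
  expect_lte(required_n_ttest(1.5, alpha = 0.1), required_n_ttest(1.5, alpha = 0.01))
  expect_lt(achieved_power_ttest(1, 5, 5), achieved_power_ttest(1, 15, 15))
  expect_error(required_n_ttest(-1), class = "sparctug_value_error")
  expect_error(achieved_power_ttest(1, 1, 5), class = "sparctug_value_error")
})

test_that("correlation sample size follows the Fisher-z approximation", {
  # hand-computed Fisher-z values: ((z_a + z_b) / atanh(r))^2 + 3, rounded up
  expect_equal(required_n_correlation(0.65, power = 0.95, tails = "one"), 22)
  expect_equal(required_n_correlation(0.65, power = 0.95, tails = "two"), 25)
  expect_gt(required_n_correlation(0.3), required_n_correlation(0.6))
  expect_error(required_n_correlation(1.2), class = "sparctug_value_error")
})

test_that("group effects table summarises full-test channels", {
  set.seed(44)
  smooth <- tidyr::crossing(
    subject_id = sprintf("S%02d", 1:12),
    channel = c("acc_l_total", "acc_a_total"),
    phase = c("full", "turn")
  )
  smooth$group <- ifelse(as.integer(substr(smooth$subject_id, 2, 3)) <= 8,
                         "PD", "control")
  smooth$sparc <- -3 - 2 * (smooth$group == "PD") + rnorm(nrow(smooth), 0, 0.4)
  tab <- group_effects_table(smooth)
  expect_equal(nrow(tab), 2)          # full-test rows only, one per channel
  expect_true(all(tab$mean_pd < tab$mean_control))
  expect_true(all(tab$d > 0))
  expect_true(all(c("mean_pd", "ci_pd", "mean_control", "ci_control",
                    "d", "class", "p_value") %in% names(tab)))
})
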