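test_that("fragmentation score hits its bounds and the straddle midpoint", {
  all_above <- make_trace("s1", seq(15000, 30000, length.out = 50), 1)
  expect_equal(gqn_surrogate(all_above, threshold = 10000)$gqn, 10)
  none_above <- make_trace("s1", seq(250, 5000, length.out = 50), 1)
  expect_equal(gqn_surrogate(none_above, threshold = 10000)$gqn, 0)
  straddle <- make_trace("s1", seq(5000, 15000, by = 10), 1)
  expect_equal(gqn_surrogate(straddle, threshold = 10000)$gqn, 5)
  expect_warning(z <- gqn_surrogate(make_trace("s1", c(300, 400, 500), 0)),
                 "zero total signal")
  expect_true(is.na(z$gqn))
})

test_that("constant response degenerates to zero SS and missing F", {
  sim <- simulate_experiment(small_config(n_fish = 2, replicates_per_cell = 2,
                                          time_points_days = c(1, 7)))
  scores <- tibble::tibble(sample_id = sim$design$sample_id, gqn = 4.2)
  a <- factorial_anova(scores, sim$design)
  expect_equal(a$table$sumsq, rep(0, 15), tolerance = 1e-20)
  expect_true(all(is.na(a$table$statistic)))
  expect_true(all(is.na(a$table$p_value)))
})

test_that("single two-level factor F equals the squared two-sample t statistic", {
  set.seed(8)
  design <- make_design(sprintf("s%02d", 1:20),
                        solution = rep(c("DESS", "ETOH"), each = 10),
                        fish = "fish1")
  y <- rnorm(20) + rep(c(0, 0.8), each = 10)
  scores <- tibble::tibble(sample_id = design$sample_id, gqn = y)
  a <- factorial_anova(scores, design, terms = "solution",
                       verify_order_invariance = FALSE)
  tt <- t.test(y[1:10], y[11:20], var.equal = TRUE)
  expect_equal(a$table$statistic, unname(tt$statistic)^2, tolerance = 1e-12)
  expect_equal(a$table$p_value, tt$p.value, tolerance = 1e-12)
  expect_equal(a$table$df, 1L)
  expect_equal(a$residual$df, 18L)
})

test_that("balanced 2x2 sums of squares match the direct projection oracle", {
  set.seed(9)
  n_rep <- 4
  design <- make_design(sprintf("s%02d", 1:16),
                        solution = rep(c("DESS", "ETOH"), each = 8),
                        heat = rep(rep(c("treated", "untreated"), each = 4), 2))
  mu <- c(1, 3, 2, 7)[interaction(design$solution, design$heat) |> as.integer()]
  y <- mu + rnorm(16, 0, 0.3)
  scores <- tibble::tibble(sample_id = design$sample_id, gqn = y)
  a <- factorial_anova(scores, design,
                       terms = c("solution", "heat", "solution:heat"))
  cA <- ifelse(design$solution == "DESS", 1, -1)
  cB <- ifelse(design$heat == "treated", 1, -1)
  expected <- c(projection_ss(y, cA), projection_ss(y, cB),
                projection_ss(y, cA * cB))
  expect_equal(a$table$sumsq, expected, tolerance = 1e-8)
  expect_equal(a$table$sumsq |> sum() + a$residual$sumsq, a$total_ss,
               tolerance = 1e-8 * a$total_ss)
})

test_that("sequential SS are order-invariant on the balanced design and match anova(lm)", {
  sim <- simulate_experiment(small_config(seed = 17))
  scores <- gqn_surrogate(sim$traces)
  a <- factorial_anova(scores, sim$design)
  expect_true(a$balanced)

  perm <- c(15, 3, 7, 1, 12, 5, 9, 2, 14, 6, 11, 4, 13, 8, 10)
  a_perm <- factorial_anova(scores, sim$design, terms = a$terms[perm],
                            verify_order_invariance = FALSE)
  reord <- a_perm$table[match(a$table$term, a_perm$table$term), ]
  expect_equal(reord$sumsq, a$table$sumsq, tolerance = 1e-8)

  # independent route: base R model fit
  df <- dplyr::inner_join(scores, sim$design, by = "sample_id")
  df$time <- factor(df$time_days)
  fit <- lm(gqn ~ solution * heat * temperature * time, data = df,
            contrasts = list(solution = "contr.sum", heat = "contr.sum",
                             temperature = "contr.sum", time = "contr.sum"))
  ref <- anova(fit)
  expect_equal(a$table$sumsq, ref$`Sum Sq`[seq_len(15)], tolerance = 1e-10)
  expect_equal(a$table$statistic, ref$`F value`[seq_len(15)], tolerance = 1e-10)
  expect_equal(a$table$p_value, ref$`Pr(>F)`[seq_len(15)], tolerance = 1e-10)
  expect_equal(a$residual$sumsq, ref$`Sum Sq`[16], tolerance = 1e-10)
  expect_equal(a$table$sumsq |> sum() + a$residual$sumsq, a$total_ss,
               tolerance = 1e-8 * a$total_ss)
})

test_that("rank-deficient designs are refused with advice to reduce terms", {
  sim <- simulate_experiment(small_config(n_fish = 2, replicates_per_cell = 2,
                                          time_points_days = c(1, 7)))
  keep <- !(sim$design$solution == "ETOH" & sim$design$heat == "untreated" &
              sim$design$temperature == "room" & sim$design$time_days == 7)
  design <- sim$design[keep, ]
  scores <- tibble::tibble(sample_id = design$sample_id, gqn = rnorm(nrow(design)))
  expect_error(factorial_anova(scores, design), "reduce the term list")
  expect_error(factorial_anova(scores, design, terms = "storage"), "unknown model term")
})

test_that("partial F test matches anova(lm, lm) and the identity case", {
  sim <- simulate_experiment(small_config(seed = 23))
  scores <- gqn_surrogate(sim$traces)
  full <- factorial_anova(scores, sim$design, terms = "full")
  reduced <- factorial_anova(scores, sim$design, terms = "solution")
  cmp <- compare_models(full, reduced)
  expect_equal(cmp$df_num, 38L)
  expect_equal(cmp$df_den, 160L)

  df <- dplyr::inner_join(scores, sim$design, by = "sample_id")
  df$time <- factor(df$time_days)
  fit_full <- lm(gqn ~ solution * heat * temperature * time, data = df)
  fit_red <- lm(gqn ~ solution, data = df)
  ref <- anova(fit_red, fit_full)
  expect_equal(cmp$statistic, ref$F[2], tolerance = 1e-10)
  expect_equal(cmp$p_value, ref$`Pr(>F)`[2], tolerance = 1e-10)

  self <- compare_models(full, full)
  expect_equal(self$statistic, 0)
  expect_equal(self$p_value, 1)
  expect_error(compare_models(reduced, full), "not nested")
  other <- factorial_anova(scores, sim$design, terms = "heat")
  expect_error(compare_models(full,
                              factorial_anova(scores, sim$design,
                                              terms = c("solution", "fish"))),
               "unknown model term")
  expect_silent(compare_models(full, other))
})
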