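rural_g <- function() group_summary("rural", 96, 70.2, 9.8)
municipal_g <- function() group_summary("municipal", 729, 62.6, 11.1)

test_that("Cohen's d from published-style summaries", {
  d_zone <- cohens_d(rural_g(), municipal_g())
  expect_equal(round(d_zone$d, 2), 0.73)
  d_sex <- cohens_d(group_summary("male", 328, 64.6, 10.9),
                    group_summary("female", 497, 62.8, 11.2))
  expect_equal(round(d_sex$d, 2), 0.16)
  # size-weighted pooled SD standardizer gives a smaller zone effect
  d_pooled <- cohens_d(rural_g(), municipal_g(), method = "pooled_sd")
  expect_lt(d_pooled$d, d_zone$d)
  expect_equal(round(d_pooled$d, 2), 0.69)
})

test_that("effect-size intervals behave: antisymmetry, coverage of zero, methods", {
  a <- group_summary("a", 50, 10, 2)
  b <- group_summary("b", 60, 11, 2.5)
  dab <- cohens_d(a, b)
  dba <- cohens_d(b, a)
  expect_equal(dab$d, -dba$d)
  expect_equal(dab$ci_low, -dba$ci_high, tolerance = 1e-6)
  expect_equal(dab$ci_high, -dba$ci_low, tolerance = 1e-6)
  same <- cohens_d(a, group_summary("a2", 40, 10, 2))
  expect_equal(same$d, 0)
  expect_lt(same$ci_low, 0)
  expect_gt(same$ci_high, 0)
  expect_error(cohens_d(a, group_summary("z", 10, 5, 0)), "positive")
  dn <- cohens_d(a, b, ci_method = "normal")
  expect_equal(dn$d - dn$ci_low, dn$ci_high - dn$d, tolerance = 1e-10)
})

test_that("summary-statistic t-tests match expectations", {
  tt <- ttest_from_summary(rural_g(), municipal_g(), variant = "pooled")
  expect_lt(tt$p, 1e-4)
  expect_equal(tt$df, 96 + 729 - 2)
  eq <- ttest_from_summary(group_summary("a", 30, 5, 1),
                           group_summary("b", 40, 5, 2))
  expect_equal(eq$t, 0)
  expect_equal(eq$p, 1)
  a <- group_summary("a", 25, 4, 1.5)
  b <- group_summary("b", 25, 5, 1.5)
  expect_equal(ttest_from_summary(a, b, "pooled"),
               ttest_from_summary(a, b, "welch"))
})

test_that("pooling subgroup summaries reconstructs the published totals", {
  tot <- pool_groups(list(municipal_g(), rural_g()))
  expect_identical(tot$n, 825L)
  expect_equal(round(tot$mean, 1), 63.5)
  expect_equal(round(tot$sd, 1), 11.2)
  expect_equal(round(100 * 497 / 825, 1), 60.2)
})

test_that("pooling is associative and a single group is the identity", {
  gs <- list(group_summary("a", 10, 1, 0.5), group_summary("b", 20, 2, 1),
             group_summary("c", 30, 3, 2))
  p1 <- pool_groups(list(pool_groups(gs[1:2]), gs[[3]]))
  p2 <- pool_groups(list(gs[[1]], pool_groups(gs[2:3])))
  p3 <- pool_groups(gs)
  expect_equal(p1$mean, p3$mean, tolerance = 1e-10)
  expect_equal(p1$sd, p3$sd, tolerance = 1e-10)
  expect_equal(p2$sd, p3$sd, tolerance = 1e-10)
  expect_identical(pool_groups(gs[1]), gs[[1]])
})

test_that("age trend recovers a generating slope and fits exactly when exact", {
  set.seed(61)
  age <- runif(400, 18, 89)
  df <- data.frame(age = age, meq_total = 50 + 0.26 * age + rnorm(400, 0, 8))
  tr <- age_trend(df)
  se <- summary(tr$fit)$coefficients["age", "Std. Error"]
  expect_lt(abs(tr$slope - 0.26), 1.96 * se * 1.5)
  expect_lt(tr$p, 1e-4)
  exact <- data.frame(age = c(20, 30, 40), meq_total = c(50, 55, 60))
  tre <- suppressWarnings(age_trend(exact))  # lm warns on a perfect fit
  expect_equal(tre$slope, 0.5)
  expect_equal(tre$r_squared, 1)
  expect_error(age_trend(data.frame(age = rep(40, 5), meq_total = rnorm(5))),
               "constant")
})

test_that("slope p-values are uniform under the null", {
  set.seed(4242)
  ps <- replicate(500, {
    df <- data.frame(age = runif(40, 18, 89), meq_total = rnorm(40, 60, 10))
    age_trend(df)$p
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("qq coordinates use (i - 0.5)/n plotting positions", {
  q3 <- qq_coordinates(c(5, 1, 3))
  expect_equal(q3$theoretical, qnorm(c(1, 3, 5) / 6))
  expect_equal(q3$observed, c(1, 3, 5))
  set.seed(8)
  z <- rnorm(2000)
  qq <- qq_coordinates(z)
  expect_lt(max(abs(qq$observed - qq$theoretical))[1], 0.5)
})

test_that("ceiling censoring bends the qq upper tail below the central trend", {
  cfg <- sim_config(n_families = 112, seed = 55)  # censored by default
  coh <- simulate_cohort(cfg)
  qq <- qq_coordinates(coh$phenotypes$meq_total)
  n <- nrow(qq)
  central <- qq[qq$theoretical > qnorm(0.1) & qq$theoretical < qnorm(0.9), ]
  line <- stats::lm(observed ~ theoretical, data = central)
  top <- qq[seq.int(ceiling(0.98 * n), n), ]
  pred <- predict(line, newdata = top)
  expect_lt(mean(top$observed - pred), 0)
})

test_that("histogram counts are exact, conserved, and validated", {
  h <- histogram_counts(c(60, 60, 60))
  expect_identical(nrow(h), 1L)
  expect_identical(h$count, 3L)
  vals <- c(20, 20, 45, 86, 86, 86)
  grp <- c("a", "b", "a", "a", "b", "b")
  hg <- histogram_counts(vals, by = grp)
  expect_identical(sum(hg$count), length(vals))
  expect_identical(sum(hg$count[hg$group == "a"]), 3L)
  full <- histogram_counts(vals, complete = TRUE)
  expect_identical(nrow(full), 71L)
  expect_error(histogram_counts(c(15, 60)), "16..86")
  expect_error(histogram_counts(c(60.5)), "16..86")
})
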