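raw_df <- function(...) {
  groups <- list(...)
  tibble::tibble(
    group = rep(names(groups), lengths(groups)),
    value = unlist(groups, use.names = FALSE)
  )
}

test_that("one-way ANOVA matches explicit sum-of-squares arithmetic", {
  d <- raw_df(a = c(6, 8, 4, 5, 3, 4), b = c(8, 12, 9, 11, 6, 8),
              c = c(13, 9, 11, 8, 7, 12))
  fit <- oneway_anova(d)
  # oracle: direct decomposition
  grand <- mean(d$value)
  ssb <- sum(tapply(d$value, d$group, function(v) length(v) * (mean(v) - grand)^2))
  ssw <- sum(tapply(d$value, d$group, function(v) sum((v - mean(v))^2)))
  f_ref <- (ssb / 2) / (ssw / 15)
  expect_equal(fit$f, f_ref)
  expect_equal(fit$df1, 2)
  expect_equal(fit$df2, 15)
  expect_equal(fit$p_value, pf(f_ref, 2, 15, lower.tail = FALSE))
  td <- tidy(fit)
  expect_equal(td$statistic, f_ref)
})

test_that("two-group ANOVA F equals the squared pooled t statistic", {
  set.seed(2)
  d <- raw_df(a = rnorm(8, 1), b = rnorm(12, 0))
  fit <- oneway_anova(d)
  tt <- two_sample_t(d, welch = FALSE)
  expect_equal(fit$f, tt$t^2, tolerance = 1e-12)
  expect_equal(fit$p_value, tt$p_value, tolerance = 1e-12)
})

test_that("equal-valued groups are degenerate with F = 0", {
  d <- raw_df(a = rep(3, 4), b = rep(3, 5))
  fit <- oneway_anova(d)
  expect_true(fit$degenerate)
  expect_equal(fit$f, 0)
})

test_that("summary-statistic and raw inputs agree for every procedure", {
  set.seed(7)
  d <- raw_df(a = rnorm(10, 0, 1), b = rnorm(14, 0.8, 1.6),
              c = rnorm(9, -0.3, 0.7))
  s <- as_group_summary(d)
  expect_equal(tidy(oneway_anova(d)), tidy(oneway_anova(s)))
  expect_equal(tidy(tukey_hsd(d)), tidy(tukey_hsd(s)))
  expect_equal(tidy(dunnett_t3(d)), tidy(dunnett_t3(s)))
  d2 <- dplyr::filter(d, group != "c")
  expect_equal(tidy(two_sample_t(d2)), tidy(two_sample_t(as_group_summary(d2))))
})

test_that("Tukey HSD matches stats::TukeyHSD on a balanced example", {
  set.seed(11)
  d <- raw_df(a = rnorm(10, 0), b = rnorm(10, 1), c = rnorm(10, 1.5))
  mine <- tukey_hsd(d)$comparisons
  ref <- stats::TukeyHSD(stats::aov(value ~ group, data = d))$group
  # align pair order: ref rows are "b-a", "c-a", "c-b"
  expect_equal(mine$p_value, unname(ref[, "p adj"]), tolerance = 1e-3)
  expect_equal(abs(mine$diff), unname(abs(ref[, "diff"])), tolerance = 1e-12)
})

test_that("two identical groups give q = 0 and p = 1", {
  s <- tibble::tibble(group = c("a", "b"), n = c(6, 6), mean = c(5, 5),
                      sd = c(1, 1))
  tk <- tukey_hsd(s)
  expect_equal(tk$comparisons$q, 0)
  expect_equal(tk$comparisons$p_value, 1)
})

test_that("two-group Tukey reduces to the pooled t test", {
  set.seed(3)
  d <- raw_df(a = rnorm(9, 0), b = rnorm(7, 0.7))
  tk <- tukey_hsd(d)$comparisons
  tt <- two_sample_t(d, welch = FALSE)
  expect_equal(tk$p_value, tt$p_value, tolerance = 1e-6)
})

test_that("the SMM distribution reduces to Student t at m = 1", {
  for (q in c(0.5, 1.7, 3.2)) {
    for (df in c(4, 12, 33)) {
      expect_equal(psmm(q, 1, df), pt(q, df) - pt(-q, df), tolerance = 1e-5)
    }
  }
})

test_that("two-group Dunnett T3 reduces to the Welch t test", {
  set.seed(4)
  d <- raw_df(a = rnorm(9, 0, 1), b = rnorm(7, 0.7, 2.5))
  t3 <- dunnett_t3(d)$comparisons
  tt <- two_sample_t(d, welch = TRUE)
  expect_equal(t3$df, tt$df, tolerance = 1e-9)
  expect_equal(t3$p_value, tt$p_value, tolerance = 1e-4)
})

test_that("Dunnett T3 p values match a Monte-Carlo SMM oracle", {
  set.seed(9)
  d <- raw_df(a = rnorm(8, 0, 1), b = rnorm(12, 1, 3), c = rnorm(6, -0.5, 0.5),
              d = rnorm(10, 0.8, 2))
  t3 <- dunnett_t3(d)$comparisons
  m <- 6
  nrep <- 2e5
  for (i in seq_len(nrow(t3))) {
    z <- matrix(rnorm(nrep * m), nrep, m)
    s <- sqrt(stats::rchisq(nrep, t3$df[i]) / t3$df[i])
    p_mc <- mean(apply(abs(z), 1, max) / s > t3$t[i])
    se <- sqrt(p_mc * (1 - p_mc) / nrep)
    expect_lt(abs(t3$p_value[i] - p_mc), 4 * se + 1e-4)
  }
})

test_that("equal groups give T3 p values of 1", {
  s <- tibble::tibble(group = c("a", "b", "c"), n = 10, mean = 2, sd = 1)
  t3 <- dunnett_t3(s)$comparisons
  expect_true(all(t3$p_value == 1))
})

test_that("post hoc p values decrease with the mean difference", {
  base <- tibble::tibble(group = c("a", "b"), n = c(10, 10), sd = c(2, 2))
  deltas <- c(0.5, 1, 2, 4)
  p_tukey <- p_t3 <- numeric(length(deltas))
  for (i in seq_along(deltas)) {
    s <- dplyr::mutate(base, mean = c(0, deltas[i]))
    p_tukey[i] <- tukey_hsd(s)$comparisons$p_value
    p_t3[i] <- dunnett_t3(s)$comparisons$p_value
  }
  expect_true(all(diff(p_tukey) < 0))
  expect_true(all(diff(p_t3) < 0))
})

test_that("percent differences recover simple ratios", {
  expect_equal(percent_difference(3, 2), 50)
  expect_equal(percent_difference(2, 2), 0)
})
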