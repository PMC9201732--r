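test_that("effective and complication rates reproduce the printed group data", {
  experimental <- group_outcome("experimental", 25,
    c(effective = 13, markedly_effective = 10, ineffective = 2))
  control <- group_outcome("control", 25,
    c(effective = 10, markedly_effective = 10, ineffective = 5))
  expect_identical(effective_rate(experimental), 92.0)
  expect_identical(effective_rate(control), 80.0)
  none <- group_outcome("none", 20, c(0, 0, 20))
  expect_identical(effective_rate(none), 0.0)
  comp_exp <- group_outcome("experimental", 25, c(deep_vein_thrombosis = 2))
  comp_ctl <- group_outcome("control", 25,
    c(deep_vein_thrombosis = 2, screw_fell_off = 1, fixation_rupture = 1))
  expect_identical(complication_rate(comp_exp), 8.0)
  expect_identical(complication_rate(comp_ctl), 16.0)
  expect_identical(complication_rate(group_outcome("x", 10, integer(3))), 0.0)
})

test_that("group_outcome validates counts and summaries", {
  expect_error(group_outcome("g", 0), "positive")
  expect_error(group_outcome("g", 10, c(5, 6, 2)), "at most n")
  expect_error(group_outcome("g", 10, c(-1, 2, 3)), "non-negative")
  expect_error(group_outcome("g", 10,
    mean_sd = data.frame(measure = "m", mean = 1, sd = 0)), "positive")
  expect_error(effective_rate(group_outcome("g", 10, c(1, 2))), "three")
})

test_that("2x2 chi-square matches the hand Pearson formula", {
  # identical proportions: statistic 0, p = 1
  same <- chisq_2x2(10, 20, 10, 20)
  expect_identical(same$statistic, 0)
  expect_identical(same$p_value, 1)
  # hand-computed Pearson statistic from expected counts
  pearson <- function(a, an, b, bn) {
    tbl <- rbind(c(a, an - a), c(b, bn - b))
    E <- outer(rowSums(tbl), colSums(tbl)) / sum(tbl)
    sum((tbl - E)^2 / E)
  }
  for (case in list(c(23, 25, 20, 25), c(2, 25, 4, 25), c(15, 30, 9, 27))) {
    got <- chisq_2x2(case[1], case[2], case[3], case[4])
    want <- pearson(case[1], case[2], case[3], case[4])
    expect_equal(got$statistic, want, tolerance = 1e-10)
    expect_equal(got$p_value, stats::pchisq(want, 1, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
  # extreme table
  extreme <- chisq_2x2(25, 25, 0, 25)
  expect_lt(extreme$p_value, 1e-6)
  # Yates correction shrinks the statistic
  expect_lt(chisq_2x2(23, 25, 20, 25, correct = TRUE)$statistic,
            chisq_2x2(23, 25, 20, 25)$statistic)
  expect_error(chisq_2x2(0, 10, 0, 10), "margin")
  expect_error(chisq_2x2(11, 10, 5, 10), "within")
})

test_that("summary t test matches t.test on reconstructed samples", {
  # equal summaries: statistic 0, p = 1
  eq <- t_from_summary(5, 1, 10, 5, 1, 10)
  expect_identical(eq$statistic, 0)
  expect_identical(eq$p_value, 1)
  # build samples with exactly the requested mean and SD, compare to t.test
  make_sample <- function(m, s, n) {
    x <- scale(rnorm(n))[, 1]  # mean 0, sd 1 exactly
    m + s * x
  }
  set.seed(51)
  for (rep in 1:5) {
    m1 <- runif(1, 0, 10); s1 <- runif(1, 0.5, 3); n1 <- sample(5:30, 1)
    m2 <- runif(1, 0, 10); s2 <- runif(1, 0.5, 3); n2 <- sample(5:30, 1)
    x1 <- make_sample(m1, s1, n1); x2 <- make_sample(m2, s2, n2)
    got <- t_from_summary(m1, s1, n1, m2, s2, n2)
    ref <- stats::t.test(x1, x2, var.equal = TRUE)
    expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-8)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-8)
    gotw <- t_from_summary(m1, s1, n1, m2, s2, n2, var_equal = FALSE)
    refw <- stats::t.test(x1, x2)
    expect_equal(gotw$statistic, unname(refw$statistic), tolerance = 1e-8)
    expect_equal(gotw$p_value, refw$p.value, tolerance = 1e-8)
  }
  expect_error(t_from_summary(1, 1, 1, 2, 1, 10), "n >= 2")
  expect_error(t_from_summary(1, 0, 10, 2, 1, 10), "positive")
})

test_that("block-time comparisons are significant at the printed summaries", {
  sens <- t_from_summary(7.53, 1.47, 25, 3.38, 1.26, 25)
  expect_lt(sens$p_value, 0.05)
  mot <- t_from_summary(5.45, 1.36, 25, 3.02, 1.31, 25)
  expect_lt(mot$p_value, 0.05)
  # statistic matches the pooled-variance formula evaluated from scratch
  sp2 <- (24 * 1.47^2 + 24 * 1.26^2) / 48
  tstat <- (7.53 - 3.38) / sqrt(sp2 * (2 / 25))
  expect_equal(sens$statistic, tstat, tolerance = 1e-10)
})

test_that("clinical report assembles rates and tests from the bundled tables", {
  rep <- clinical_report()
  eff <- rep$rates[rep$rates$measure == "effective_rate", ]
  expect_setequal(eff$rate_percent, c(92.0, 80.0))
  comp <- rep$rates[rep$rates$measure == "complication_rate", ]
  expect_setequal(comp$rate_percent, c(8.0, 16.0))
  expect_true(all(rep$rates$p_value > 0 & rep$rates$p_value <= 1))
  expect_true(all(rep$times$p_value < 0.05))
  expect_output(print(rep), "chi-square")
})
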