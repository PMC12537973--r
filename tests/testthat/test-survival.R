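test_that("median split follows the stated tie and boundary rules", {
  co <- stratify_by_median(c(a = 1, b = 2, c = 3, d = 4))
  expect_equal(co$split_value, 2.5)
  expect_equal(as.character(co$stratum), c("low", "low", "high", "high"))

  co2 <- stratify_by_median(c(2, 2, 2, 3))
  expect_equal(co2$split_value, 2)
  expect_equal(sum(co2$stratum == "low"), 3)  # ties go low by default
  co2h <- stratify_by_median(c(2, 2, 2, 3), ties = "high")
  expect_equal(sum(co2h$stratum == "low"), 0)

  co3 <- stratify_by_median(c(5, 1))
  expect_equal(as.character(co3$stratum), c("high", "low"))

  expect_error(stratify_by_median(rep(7, 4)), "identical")
})

test_that("product-limit estimate matches the hand-computed worked example", {
  km <- km_estimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km$time, c(1, 3))
  expect_equal(km$n_risk, c(3, 1))
  expect_equal(km$survival, c(2/3, 0), tolerance = 1e-12)
  expect_equal(km_survival_at(km, c(0.5, 1, 2.9, 3)), c(1, 2/3, 2/3, 0))
})

test_that("KM degenerate cases: no events, simultaneous failures", {
  km0 <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_equal(nrow(km0), 0)
  expect_equal(km_survival_at(km0, c(0, 10)), c(1, 1))

  km1 <- km_estimate(c(1, 1), c(1, 1))
  expect_equal(km1$survival, 0)
  expect_error(km_estimate(numeric(), numeric()), "empty")
})

test_that("without censoring KM equals the empirical survivor fraction", {
  set.seed(12)
  times <- rexp(40)
  km <- km_estimate(times, rep(1, 40))
  emp <- vapply(km$time, function(t) mean(times > t), numeric(1))
  expect_equal(km$survival, emp, tolerance = 1e-12)
})

test_that("KM is invariant to permutation of input order", {
  set.seed(13)
  times <- rexp(30)
  events <- rbinom(30, 1, 0.7)
  perm <- sample(30)
  km1 <- km_estimate(times, events)
  km2 <- km_estimate(times[perm], events[perm])
  expect_equal(as.data.frame(km1), as.data.frame(km2))
})

test_that("log-rank reproduces the hand-computed O/E/V worked example", {
  # group A (low) times 1,2 both events; group B (high) times 3,4 both events
  co <- structure(list(sample = as.character(1:4),
                       stratum = factor(c("low", "low", "high", "high"),
                                        levels = c("low", "high")),
                       split_value = 0),
                  class = "stratified_cohort")
  lr <- logrank_test(co, c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_equal(lr$chi_square, (7/6)^2 / (1/4 + 2/9), tolerance = 1e-9)
  expect_equal(lr$observed[["low"]], 2)
  expect_equal(lr$expected[["low"]], 5/6, tolerance = 1e-9)
  expect_equal(sum(lr$observed), sum(lr$expected), tolerance = 1e-12)
  expect_equal(lr$p_value, pchisq(lr$chi_square, 1, lower.tail = FALSE))
})

test_that("log-rank is symmetric in group labels and null on identical groups", {
  set.seed(14)
  times <- rexp(60, 0.2)
  events <- rbinom(60, 1, 0.8)
  strat <- rep(c("low", "high"), 30)
  co <- structure(list(sample = as.character(1:60),
                       stratum = factor(strat, levels = c("low", "high")),
                       split_value = 0), class = "stratified_cohort")
  co_sw <- co
  co_sw$stratum <- factor(ifelse(strat == "low", "high", "low"),
                          levels = c("low", "high"))
  lr <- logrank_test(co, times, events)
  lr_sw <- logrank_test(co_sw, times, events)
  expect_equal(lr$chi_square, lr_sw$chi_square, tolerance = 1e-12)
  expect_equal(lr$p_value, lr_sw$p_value, tolerance = 1e-12)

  # identical (time,event) multisets in both groups -> chi 0, p 1
  co2 <- structure(list(sample = as.character(1:6),
                        stratum = factor(rep(c("low", "high"), each = 3),
                                         levels = c("low", "high")),
                        split_value = 0), class = "stratified_cohort")
  lr2 <- logrank_test(co2, c(1, 2, 3, 1, 2, 3), c(1, 1, 0, 1, 1, 0))
  expect_equal(lr2$chi_square, 0, tolerance = 1e-12)
  expect_equal(lr2$p_value, 1, tolerance = 1e-12)
})

test_that("log-rank with no events returns the no-information contract", {
  co <- structure(list(sample = as.character(1:4),
                       stratum = factor(c("low", "low", "high", "high"),
                                        levels = c("low", "high")),
                       split_value = 0), class = "stratified_cohort")
  expect_warning(lr <- logrank_test(co, 1:4, rep(0, 4)), "no information")
  expect_equal(lr$chi_square, 0)
  expect_equal(lr$p_value, 1)
})

test_that("between-strata expression comparison is a Welch t test", {
  co <- stratify_by_median(c(s1 = 1, s2 = 2, s3 = 3, s4 = 10, s5 = 11, s6 = 12))
  same <- c(s1 = 5, s2 = 5, s3 = 5, s4 = 5, s5 = 5, s6 = 5)
  r <- compare_expression_between_strata(same, co)
  expect_equal(r$t_stat, 0)
  expect_equal(r$p_value, 1)

  set.seed(15)
  jit <- c(rnorm(3, 0, 1e-3), rnorm(3, 1, 1e-3))
  names(jit) <- co$sample
  r2 <- compare_expression_between_strata(jit, co)
  expect_lt(r2$p_value, 0.001)
  expect_gt(r2$t_stat, 0)  # high stratum has the larger mean

  # correlated covariate: high-X stratum has higher Y mean
  set.seed(16)
  x <- rnorm(60)
  y <- x + rnorm(60, sd = 0.3)
  names(x) <- names(y) <- sprintf("s%02d", 1:60)
  cox <- stratify_by_median(x)
  r3 <- compare_expression_between_strata(y, cox)
  expect_gt(r3$mean_high, r3$mean_low)
  expect_gt(r3$t_stat, 0)

  expect_error(compare_expression_between_strata(same[1:6],
    stratify_by_median(c(s1 = 1, s2 = 2, s3 = 3, s4 = 10, s5 = 11, s6 = 12),
                       ties = "high")), NA)
})

test_that("km_curves_by_stratum exports one step-curve per stratum", {
  cl <- gen_survival(n_patients = 80, beta = 1, seed = 3)
  co <- stratify_by_median(cl$expression, samples = cl$sample)
  curves <- km_curves_by_stratum(co, cl$os_time, cl$os_event)
  expect_setequal(unique(curves$stratum), c("low", "high"))
  for (s in c("low", "high")) {
    surv <- curves$survival[curves$stratum == s]
    expect_true(all(diff(surv) <= 1e-12))  # non-increasing
    expect_true(all(surv >= 0 & surv <= 1))
  }
})
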