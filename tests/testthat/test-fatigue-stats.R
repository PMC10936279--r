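test_that("baseline normalization divides by each subject's own baseline mean", {
  tbl <- tibble::tibble(
    subject = c(rep(1, 6), rep(2, 6)),
    phase = rep(c(rep("baseline", 5), "recovery"), 2),
    torque_nm = c(rep(2, 5), 1.24, rep(4, 5), 1.24)
  )
  out <- normalize_to_baseline(tbl, "torque_nm")
  expect_equal(out$torque_nm[out$subject == 1],
               c(rep(1, 5), 0.62))
  # same raw recovery value, different subject baselines -> different ratios
  expect_equal(out$torque_nm[12], 0.31)

  zero <- tbl
  zero$torque_nm[zero$subject == 2 & zero$phase == "baseline"] <- 0
  err <- tryCatch(normalize_to_baseline(zero, "torque_nm"),
                  error = function(e) e)
  expect_s3_class(err, "twitchtdi_zero_baseline")
  expect_match(conditionMessage(err), "torque_nm")
  expect_match(conditionMessage(err), "2")
})

test_that("Holm adjustment reproduces the hand-computed step-down and edge cases", {
  # engineer three paired comparisons with raw p ~= .01, .03, .04, then
  # verify against the hand step-down of those raw values
  set.seed(1)
  mk <- function(p_target, n = 10) {
    # paired samples whose t-test p equals p_target by construction:
    # fixed differences with the right t statistic
    t_val <- stats::qt(1 - p_target / 2, df = n - 1)
    d <- scale(rnorm(n))[, 1]          # mean 0, sd 1
    d <- d + t_val / sqrt(n)           # mean shifts to t/sqrt(n), sd 1
    list(x = d, y = rep(0, n))
  }
  res <- holm_paired_tests(list(a = mk(0.01), b = mk(0.03), c = mk(0.04)))
  expect_equal(res$p_raw, c(0.01, 0.03, 0.04), tolerance = 1e-8)
  hand <- cummax(c(0.01 * 3, 0.03 * 2, 0.04 * 1))
  expect_equal(res$p_holm, pmin(hand, 1), tolerance = 1e-8)

  # identical samples: t = 0, p = 1, d = 0
  same <- holm_paired_tests(list(s = list(x = c(1, 2, 3, 4), y = c(1, 2, 3, 4))))
  expect_equal(same$t, 0)
  expect_equal(same$p_raw, 1)
  expect_equal(same$cohens_d, 0)

  # single comparison: adjusted equals raw
  one <- holm_paired_tests(list(u = list(x = c(1, 2, 3, 5), y = c(2, 2, 2, 2))))
  expect_equal(one$p_holm, one$p_raw)

  expect_error(holm_paired_tests(list(tiny = list(x = 1:2, y = 2:3))),
               class = "twitchtdi_invalid_argument")
})

test_that("Holm adjusted p-values are monotone and never below raw", {
  set.seed(2)
  for (i in 1:10) {
    m <- sample(2:6, 1)
    pairs <- lapply(seq_len(m), function(j) {
      x <- rnorm(8)
      list(x = x + rnorm(8, sd = 0.5), y = x)
    })
    names(pairs) <- paste0("c", seq_len(m))
    res <- holm_paired_tests(pairs)
    expect_true(all(res$p_holm >= res$p_raw - 1e-12))
    ord <- order(res$p_raw)
    expect_true(all(diff(res$p_holm[ord]) >= -1e-12))
    expect_equal(res$p_holm, p.adjust(res$p_raw, "holm"))
  }
})

test_that("repeated-measures ANOVA matches the paired t-test and aov decompositions", {
  # all cells equal: F = 0, partial eta^2 = 0
  flat <- rm_anova(matrix(5, 4, 3))
  expect_equal(flat$f_statistic, 0)
  expect_equal(flat$partial_eta_squared, 0)

  # two conditions: F equals the squared paired t
  set.seed(3)
  m <- matrix(rnorm(16), 8, 2)
  res <- rm_anova(m)
  tt <- t.test(m[, 1], m[, 2], paired = TRUE)
  expect_equal(res$f_statistic, unname(tt$statistic)^2, tolerance = 1e-8)
  expect_equal(res$p_value, tt$p.value, tolerance = 1e-8)

  # cross-check F, df and p against aov with a subject error stratum
  set.seed(4)
  mm <- matrix(rnorm(40), 8, 5) + outer(rnorm(8), rep(1, 5))
  long <- data.frame(
    value = as.vector(mm),
    subject = factor(rep(1:8, 5)),
    condition = factor(rep(1:5, each = 8)))
  fit <- summary(stats::aov(value ~ condition + Error(subject / condition),
                            data = long))
  ref <- fit[["Error: subject:condition"]][[1]]
  mine <- rm_anova(mm)
  expect_equal(mine$f_statistic, ref["condition", "F value"],
               tolerance = 1e-8)
  expect_equal(mine$p_value, ref["condition", "Pr(>F)"], tolerance = 1e-8)

  # a large condition shift is detected
  set.seed(5)
  shifted <- matrix(rnorm(30), 6, 5) + outer(rep(1, 6), c(0, 2, 4, 6, 8))
  expect_lt(rm_anova(shifted)$p_value, 1e-3)

  # invariant to adding per-subject constants
  base <- rm_anova(mm)
  shifted2 <- rm_anova(mm + outer(rnorm(8, sd = 50), rep(1, 5)))
  expect_equal(shifted2$f_statistic, base$f_statistic, tolerance = 1e-8)
  expect_equal(shifted2$partial_eta_squared, base$partial_eta_squared,
               tolerance = 1e-8)

  holes <- mm
  holes[2, 3] <- NA
  expect_error(rm_anova(holes), class = "twitchtdi_invalid_argument")
  expect_error(rm_anova(matrix(1:4, 1, 4)),
               class = "twitchtdi_invalid_argument")
})

test_that("power trend fit is exact on noiseless power-law data", {
  x <- 1:5
  fit <- suppressWarnings(fit_power_trend(x, 0.614 * x^0.236))  # exact fit
  expect_equal(fit$b0, 0.614, tolerance = 1e-8)
  expect_equal(fit$b1, 0.236, tolerance = 1e-8)
  expect_equal(fit$r_squared, 1, tolerance = 1e-8)

  flat <- suppressWarnings(fit_power_trend(1:6, rep(2.5, 6)))
  expect_equal(flat$b1, 0)
  expect_equal(flat$r_squared, 0)

  lin <- suppressWarnings(fit_power_trend(1:5, 2 * (1:5)))
  expect_equal(lin$b0, 2, tolerance = 1e-12)
  expect_equal(lin$b1, 1, tolerance = 1e-12)

  expect_error(fit_power_trend(0:4, 1:5), class = "twitchtdi_invalid_argument")
  expect_error(fit_power_trend(1:5, c(1, 2, -1, 4, 5)),
               class = "twitchtdi_invalid_argument")
})

test_that("power trend fit is exactly scale equivariant", {
  set.seed(6)
  x <- rep(1:5, 4)
  y <- 0.7 * x^0.3 * exp(rnorm(20, sd = 0.1))
  f1 <- fit_power_trend(x, y)
  f2 <- fit_power_trend(x, 3.5 * y)
  expect_equal(f2$b0, 3.5 * f1$b0, tolerance = 1e-10)
  expect_equal(f2$b1, f1$b1, tolerance = 1e-12)
  expect_equal(f2$r_squared, f1$r_squared, tolerance = 1e-10)
})

test_that("stepwise regression selects planted predictors and nothing else", {
  set.seed(7)
  n <- 50
  x1 <- rnorm(n)
  x2 <- rnorm(n)
  d <- data.frame(x1 = x1, x2 = x2,
                  y = 3 * x1 + rnorm(n, sd = 0.1 * sd(x1)))
  fit <- stepwise_regression(d, "y", c("x1", "x2"))
  expect_identical(fit$selected_features, "x1")
  expect_gt(fit$r_squared, 0.95)

  # exact deterministic predictor
  d2 <- data.frame(x1 = rnorm(20), x2 = rnorm(20))
  d2$y <- d2$x1
  fit2 <- suppressWarnings(stepwise_regression(d2, "y", c("x1", "x2")))
  expect_identical(fit2$selected_features, "x1")
  expect_equal(fit2$r_squared, 1, tolerance = 1e-10)

  # rank-deficient candidate is skipped with a warning
  d3 <- data.frame(x1 = rnorm(20))
  d3$x2 <- 2 * d3$x1
  d3$y <- d3$x1 + rnorm(20, sd = 0.05)
  expect_warning(fit3 <- stepwise_regression(d3, "y", c("x1", "x2")),
                 "rank deficient")
  expect_identical(fit3$selected_features, "x1")

  expect_error(stepwise_regression(data.frame(x1 = 1:3, y = 1:3), "y", "x1"),
               class = "twitchtdi_invalid_argument")
})

test_that("stepwise entry keeps the family-wise null inclusion near its nominal rate", {
  # with 5 independent null candidates at p_enter = .05, the model stays
  # empty with probability 0.95^5 ~ 0.77
  empty <- 0
  for (s in 1:100) {
    set.seed(s + 500)
    d <- as.data.frame(matrix(rnorm(50 * 5), 50, 5))
    names(d) <- paste0("x", 1:5)
    d$y <- rnorm(50)
    fit <- stepwise_regression(d, "y", paste0("x", 1:5))
    if (length(fit$selected_features) == 0) empty <- empty + 1
  }
  expect_gte(empty, 60)
  expect_lte(empty, 90)
})

test_that("stepwise retained-feature p-values respect the entry and removal thresholds", {
  set.seed(8)
  for (i in 1:5) {
    n <- 40
    d <- as.data.frame(matrix(rnorm(n * 4), n, 4))
    names(d) <- paste0("x", 1:4)
    d$y <- 1.5 * d$x1 + 0.8 * d$x3 + rnorm(n)
    fit <- stepwise_regression(d, "y", paste0("x", 1:4))
    if (length(fit$selected_features)) {
      p_final <- summary(fit$fit)$coefficients[fit$selected_features, 4]
      expect_true(all(p_final <= 0.10))
      entries <- fit$steps[fit$steps$action == "add", ]
      expect_true(all(entries$p < 0.05))
    }
  }
})

test_that("tidy and glance methods return the expected one-row summaries", {
  fit <- fit_power_trend(rep(1:5, 3), 0.6 * rep(1:5, 3)^0.25 *
                           exp(rnorm(15, sd = 0.05)))
  td <- tidy(fit)
  expect_equal(td$term, c("b0", "b1"))
  gl <- glance(fit)
  expect_named(gl, c("r.squared", "statistic", "p.value", "nobs"))

  ra <- rm_anova(matrix(rnorm(20), 5, 4))
  expect_equal(nrow(tidy(ra)), 3)
  expect_equal(glance(ra)$df, 3)

  d <- data.frame(x1 = rnorm(30))
  d$y <- d$x1 + rnorm(30, sd = 0.2)
  sw <- stepwise_regression(d, "y", "x1")
  expect_equal(tidy(sw)$term, "x1")
  expect_equal(glance(sw)$n.selected, 1)
})
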