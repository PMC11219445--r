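test_that("Fisher exact matches the printed 2x2 examples and the oracle", {
  expect_equal(round(fisher_exact_2x2(2, 23, 0, 39), 3), 0.149)
  expect_equal(round(fisher_exact_2x2(4, 21, 5, 34), 3), 0.728)
  expect_lt(fisher_exact_2x2(2, 23, 35, 4), 0.001)
  expect_lt(fisher_exact_2x2(7, 18, 0, 39), 0.001)
  # symmetry under swapping groups and outcomes
  expect_equal(fisher_exact_2x2(2, 23, 0, 39), fisher_exact_2x2(0, 39, 2, 23))
  expect_equal(fisher_exact_2x2(2, 23, 0, 39), fisher_exact_2x2(23, 2, 39, 0))
  expect_warning(p0 <- fisher_exact_2x2(0, 0, 0, 0), "all-zero")
  expect_equal(p0, 1)
  expect_error(fisher_exact_2x2(-1, 2, 3, 4), "non-negative")
  # spot-check against the enumeration oracle on random tables
  set.seed(31)
  for (i in 1:60) {
    cells <- as.vector(stats::rmultinom(1, sample(5:60, 1), rep(0.25, 4)))
    expect_equal(do.call(fisher_exact_2x2, as.list(cells)),
                 do.call(fisher_oracle, as.list(cells)), tolerance = 1e-12)
  }
})

test_that("fit_mixed recovers a known fixed effect", {
  # Gaussian, beta_sex = -0.3, 11 group levels: the estimate lands within
  # 2 SE of truth in nearly all replicates
  hits <- 0L
  for (r in 1:40) {
    set.seed(1000 + r)
    id <- sample(letters[1:11], 300, replace = TRUE)
    sex <- sample(c("male", "female"), 300, replace = TRUE)
    re <- stats::setNames(stats::rnorm(11, 0, 0.2), letters[1:11])
    y <- 1 + (sex == "female") * (-0.3) + re[id] + stats::rnorm(300, 0, 0.4)
    f <- fit_mixed(y ~ sex + (1 | id), data.frame(y, sex, id), "gaussian")
    est <- f$coefficients[f$coefficients$term == "sexmale", ]
    # sexmale = +0.3 under treatment coding with female reference
    if (abs(est$estimate - 0.3) < 2 * est$se) hits <- hits + 1L
  }
  expect_gte(hits, 38L)  # >= 95% of 40
})

test_that("a zero random-intercept variance is estimated at the boundary", {
  set.seed(5)
  d <- data.frame(y = stats::rnorm(200), g = gl(10, 20))
  f <- fit_mixed(y ~ 1 + (1 | g), d, "gaussian")
  expect_lt(sum(vapply(lme4::VarCorr(f$fit), function(v) sum(diag(v)),
                       numeric(1))), 0.01)
  expect_true(is.finite(f$logLik))
  expect_equal(f$n, 200)
})

test_that("the LRT matches the closed-form linear-model deviance", {
  # a draw whose random-intercept variance is estimated at the boundary 0,
  # so ordinary least squares is the exact ML oracle
  set.seed(8)
  d <- data.frame(x = stats::rnorm(60), g = gl(6, 10))
  d$y <- 0.5 * d$x + stats::rnorm(60)
  full <- fit_mixed(y ~ x + (1 | g), d, "gaussian")
  red <- fit_mixed(y ~ 1 + (1 | g), d, "gaussian")
  got <- lrt(full, red)
  expect_equal(got$df, 1L)
  # closed form for nested Gaussian ML fits: n * log(RSS0 / RSS1); the
  # random-intercept variance sits at ~0 here so lm() is the oracle
  rss1 <- sum(stats::resid(stats::lm(y ~ x, d))^2)
  rss0 <- sum(stats::resid(stats::lm(y ~ 1, d))^2)
  expect_equal(got$chisq, 60 * log(rss0 / rss1), tolerance = 1e-2)
  # identity comparison
  self <- lrt(full, full)
  expect_error(self, NA)
  expect_equal(self$chisq, 0, tolerance = 1e-6)
  expect_error(lrt(red, full), "not nested")
  # p monotone decreasing in chisq at fixed df
  ps <- stats::pchisq(c(1, 2, 5, 10), 3, lower.tail = FALSE)
  expect_true(all(diff(ps) < 0))
})

test_that("Tukey contrasts agree with the studentized-range oracle", {
  set.seed(21)
  d <- data.frame(g = gl(4, 25), id = gl(20, 5))
  d$y <- c(0, 0.4, 0.1, 0.6)[d$g] + stats::rnorm(100, 0, 0.5)
  f <- fit_mixed(y ~ g + (1 | id), d, "gaussian")
  tk <- tukey_pairwise(f, "g")
  expect_equal(nrow(tk), 6L)  # m(m-1)/2 contrasts for m = 4
  # balanced design, df treated as infinite: single-step adjustment equals
  # the studentized-range tail probability
  for (i in seq_len(6L))
    expect_lt(abs(tk$p_adjusted[i] - tukey_oracle_balanced(tk$z[i], 4L)),
              1e-6)
  # estimates are coefficient differences
  beta <- lme4::fixef(f$fit)
  expect_equal(tk$estimate[tk$contrast == "1 - 2"], -unname(beta["g2"]),
               tolerance = 1e-12)
  # four identical groups: all adjusted p near 1
  set.seed(22)
  d0 <- data.frame(g = gl(4, 30), id = gl(24, 5), y = stats::rnorm(120))
  tk0 <- tukey_pairwise(fit_mixed(y ~ g + (1 | id), d0, "gaussian"), "g")
  expect_true(all(tk0$p_adjusted > 0.2))
  # < 3 levels degrades to a plain z test with a warning
  d2 <- data.frame(g = gl(2, 30), id = gl(12, 5), y = stats::rnorm(60))
  expect_warning(tk2 <- tukey_pairwise(fit_mixed(y ~ g + (1 | id), d2,
                                                 "gaussian"), "g"),
                 "fewer than 3 levels")
  expect_equal(tk2$p_adjusted, 2 * stats::pnorm(-abs(tk2$z)))
})

test_that("VIF diagnostics are reported for multi-term fits", {
  set.seed(9)
  d <- data.frame(x1 = stats::rnorm(120), g = gl(12, 10))
  d$x2 <- 0.5 * d$x1 + stats::rnorm(120, 0, 0.9)
  d$y <- d$x1 + stats::rnorm(120)
  f <- fit_mixed(y ~ x1 + x2 + (1 | g), d, "gaussian")
  expect_true(all(f$vif >= 1))
  expect_named(f$vif, c("x1", "x2"))
})

test_that("fit_stage wires full-vs-control comparisons per stage", {
  ds <- model_datasets(cached_bundle(), seed = 4)
  st <- fit_stage("shift", ds$shift)
  expect_equal(st$lrt$df, 3L)
  expect_s3_class(st$full, "yawn_fit")
  expect_equal(nrow(st$tukey), 6L)
  dur <- fit_stage("duration", ds$duration)
  expect_equal(dur$lrt$df, 4L)
  expect_true(dur$full$converged)
  yh <- fit_stage("yhalf", ds$yhalf)
  expect_equal(yh$lrt$df, 1L)
})
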