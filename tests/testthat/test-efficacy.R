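test_that("tumor volume follows 0.5 L W^2 with the measurement convention enforced", {
  expect_equal(tumor_volume(1, 1), 0.5)
  expect_equal(tumor_volume(6, 5), 75)
  expect_lt(tumor_volume(10, 1e-4), 1e-6)
  expect_error(tumor_volume(5, 6), "W > L")
  # scale law: (sL, sW) scales volume by s^3
  expect_equal(tumor_volume(2 * 6, 2 * 5), 8 * tumor_volume(6, 5))
})

test_that("inhibition rate reproduces the reference group arithmetic and its limits", {
  expect_equal(as.numeric(inhibition_rate(1.73, 1.54)), 10.98)
  expect_equal(as.numeric(inhibition_rate(1.73, 1.63)), 5.78)
  expect_equal(as.numeric(inhibition_rate(1.73, 0.62)), 64.16)
  expect_equal(as.numeric(inhibition_rate(1.5, 1.5)), 0)
  expect_equal(as.numeric(inhibition_rate(1.5, 0)), 100)
  # antitone in the test weight
  w <- seq(0, 1.7, by = 0.1)
  expect_true(all(diff(as.numeric(inhibition_rate(1.73, w))) < 0))
  expect_error(inhibition_rate(0, 1), "positive")
  # full precision retained alongside the 2-decimal report
  expect_equal(attr(inhibition_rate(1.73, 1.54), "exact"),
               (1.73 - 1.54) / 1.73 * 100)
})

test_that("two identical groups compare as indistinguishable; separated groups are detected", {
  set.seed(3)
  g <- rnorm(6)
  res <- compare_groups(list(a = g, b = g))
  expect_gt(res$p_value, 0.99)
  expect_false(res$significant)
  # power: groups 5 SD apart at n = 6 are flagged in >= 95% of simulations
  hits <- mean(vapply(1:200, function(i) {
    x <- rnorm(6)
    y <- rnorm(6, mean = 5)
    compare_groups(list(x = x, y = y))$significant
  }, TRUE))
  expect_gte(hits, 0.95)
  expect_error(compare_groups(list(a = c(1, 1), b = c(1, 1))), "variance")
})

test_that("SNK on three groups matches a direct studentized-range computation", {
  groups <- list(g1 = c(5.1, 4.9, 5.3, 5.0, 4.8, 5.2),
                 g2 = c(6.0, 6.3, 5.8, 6.1, 6.2, 5.9),
                 g3 = c(8.0, 8.4, 7.9, 8.2, 8.1, 7.8))
  res <- compare_groups(groups)
  expect_true(res$significant)
  ph <- res$posthoc
  # independent recomputation on the fixed fixture
  values <- unlist(groups)
  fac <- rep(names(groups), each = 6)
  fit <- aov(values ~ fac)
  mse <- sum(fit$residuals^2) / fit$df.residual
  means <- sort(tapply(values, fac, mean))
  q31 <- (means[3] - means[1]) / sqrt(mse / 6)
  q21 <- (means[2] - means[1]) / sqrt(mse / 6)
  q32 <- (means[3] - means[2]) / sqrt(mse / 6)
  row31 <- ph[ph$span == 3, ]
  expect_equal(row31$q, unname(q31), tolerance = 1e-12)
  expect_equal(row31$p, 1 - ptukey(unname(q31), 3, 15), tolerance = 1e-12)
  rows2 <- ph[ph$span == 2 & ph$tested, ]
  expect_equal(sort(rows2$q), sort(unname(c(q21, q32))), tolerance = 1e-12)
  expect_true(all(ph$significant[ph$tested]))
})

test_that("SNK stepwise logic blocks sub-ranges of a non-significant stretch", {
  # two close groups and one far: the close pair should be testable,
  # and in a fixture where the omnibus range is NOT significant the
  # sub-ranges are declared non-significant without testing
  set.seed(5)
  base <- rnorm(6, sd = 2)
  groups <- list(a = base, b = base + 0.1, c = base + 0.2)
  values <- unlist(groups)
  fac <- rep(names(groups), each = 6)
  fit <- anova(aov(values ~ fac))
  res <- compare_groups(groups)
  if (fit[["Pr(>F)"]][1] >= 0.05) {
    expect_null(res$posthoc)
  } else {
    top <- res$posthoc[res$posthoc$span == 3, ]
    if (!top$significant)
      expect_true(all(!res$posthoc$tested[res$posthoc$span == 2]))
  }
})

test_that("efficacy summary computes per-group statistics and control-relative rates", {
  wts <- list(I = c(1.7, 1.76), II = c(1.5, 1.58), IV = c(0.6, 0.64))
  out <- efficacy_summary(wts, control = "I")
  expect_true(is.na(out$inhibition_rate[out$group == "I"]))
  expect_equal(out$inhibition_rate[out$group == "IV"],
               as.numeric(inhibition_rate(1.73, 0.62)))
  expect_equal(out$mean_weight, c(1.73, 1.54, 0.62))
})
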