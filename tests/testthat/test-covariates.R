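bins2 <- time_bins(older = c(20, 10), younger = c(10, 0))

test_that("bin averaging uses the half-open older-inclusive convention", {
  pts <- data.frame(age = c(5, 6), value = c(1, 3))
  expect_equal(unname(bin_average(pts, bins2)), c(NA, 2))
  expect_equal(unname(bin_average(data.frame(age = c(15, 4), value = 3.1), bins2)),
               c(3.1, 3.1))
  ## a point exactly on the boundary belongs to the older bin only
  expect_equal(unname(bin_average(data.frame(age = 10, value = 7), bins2)),
               c(7, NA))
  expect_warning(bin_average(data.frame(age = 99, value = 1), bins2), "no points")
})

test_that("Spearman correlation matches hand values and the classical test", {
  expect_equal(spearman_test(1:6, (1:6)^3)$estimate, 1)
  expect_equal(spearman_test(1:6, -(1:6))$estimate, -1)
  hand <- spearman_test(c(1, 2, 3, 4, 5), c(1, 3, 2, 5, 4))
  expect_equal(hand$estimate, 0.8, tolerance = 1e-12)   # 1 - 6*4/(5*24)
  ## exact permutation p agrees with cor.test's exact method (no ties)
  set.seed(51)
  x <- rnorm(7)
  y <- rnorm(7)
  ours <- spearman_test(x, y)
  ref <- cor.test(x, y, method = "spearman", exact = TRUE)
  expect_equal(ours$estimate, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(ours$p.value, ref$p.value, tolerance = 1e-9)
  ## t-approximation branch agrees with cor.test for larger n
  x2 <- rnorm(30); y2 <- x2 + rnorm(30)
  ref2 <- cor.test(x2, y2, method = "spearman", exact = FALSE)
  expect_equal(spearman_test(x2, y2)$p.value, ref2$p.value, tolerance = 1e-9)
  ## invariance under strictly monotone transforms
  expect_equal(spearman_test(exp(x), y)$estimate, ours$estimate)
  expect_equal(spearman_test(x, qlogis(plogis(y)))$estimate, ours$estimate)
  ## degenerate all-tied input flagged with r = 0
  tied <- spearman_test(rep(1, 5), 1:5)
  expect_true(tied$all_tied)
  expect_equal(tied$estimate, 0)
  expect_error(spearman_test(1:2, 1:2), "at least 3")
})

test_that("OLS matches the closed-form normal equations", {
  ex <- ols_fit(0:2, c(0, 1, 3))
  expect_equal(ex$slope, 1.5, tolerance = 1e-12)
  expect_equal(ex$r.squared, 27 / 28, tolerance = 1e-12)
  exact <- suppressWarnings(ols_fit(1:10, 2 * (1:10) + 1))  # lm warns on perfect fit
  expect_equal(exact$slope, 2, tolerance = 1e-10)
  expect_equal(exact$intercept, 1, tolerance = 1e-10)
  expect_equal(exact$r.squared, 1)
  flat <- ols_fit(1:5, rep(3, 5))
  expect_equal(flat$slope, 0)
  expect_equal(flat$r.squared, 0)
  expect_error(ols_fit(rep(1, 5), 1:5), "constant")
  ## R^2 equals the squared Pearson correlation
  set.seed(53)
  x <- rnorm(40); y <- 0.3 * x + rnorm(40)
  expect_equal(ols_fit(x, y)$r.squared, cor(x, y)^2, tolerance = 1e-10)
})

test_that("AR(1) GLS reduces to OLS at phi = 0 and fits exact lines", {
  set.seed(55)
  x <- rnorm(20)
  y <- 1 + 0.5 * x + rnorm(20)
  g0 <- gls_ar1_fit(x, y, phi = 0)
  ols <- ols_fit(x, y)
  expect_equal(g0$slope, ols$slope, tolerance = 1e-8)
  expect_equal(g0$intercept, ols$intercept, tolerance = 1e-8)
  g <- gls_ar1_fit(x, y)
  expect_true(g$converged)
  expect_true(abs(g$phi) < 1)
  ## noiseless line: slope recovered regardless of the correlation parameter
  g2 <- gls_ar1_fit(1:12, 2 * (1:12), phi = 0.5)
  if (g2$converged) expect_equal(g2$slope, 2, tolerance = 1e-6)
})

test_that("phi estimates are centred on zero for independent residuals", {
  set.seed(57)
  phis <- replicate(200, {
    x <- rnorm(40)
    gls_ar1_fit(x, 2 + x + rnorm(40))$phi
  })
  phis <- phis[!is.na(phis)]
  expect_lt(abs(mean(phis)), 3 * sd(phis) / sqrt(length(phis)))
})

test_that("first differences compose the Spearman test on successive changes", {
  x <- c(1, 2, 4, 8, 16, 32)
  expect_equal(first_difference_test(x, 2 * x)$estimate, 1)
  set.seed(59)
  a <- rnorm(12); b <- rnorm(12)
  expect_equal(first_difference_test(a, b)$estimate,
               spearman_test(diff(a), diff(b))$estimate, tolerance = 1e-12)
  ## arithmetic progressions: all differences tied -> flagged zero
  ap <- first_difference_test(seq(0, 10, 2), seq(5, 10, 1))
  expect_true(ap$all_tied)
  expect_equal(ap$estimate, 0)
  expect_error(first_difference_test(1:3, 1:3), "at least 4")
})

test_that("order-preserving reshuffles leave the tests unchanged", {
  set.seed(61)
  x <- rnorm(15); y <- rnorm(15)
  per <- sample(15)
  expect_equal(spearman_test(x[per], y[per])$estimate, spearman_test(x, y)$estimate)
  expect_equal(ols_fit(x[per], y[per])$slope, ols_fit(x, y)$slope, tolerance = 1e-12)
})

test_that("the correlation battery assembles one labelled row", {
  set.seed(63)
  disp <- cumsum(abs(rnorm(12)))
  cov <- disp + rnorm(12, 0, 0.5)
  row <- correlate_disparity(disp, cov, label = "all", covariate_label = "d18O")
  expect_equal(row$label, "all")
  expect_true(row$r_s > 0 && row$r_squared > 0 && row$r_squared <= 1)
  expect_true(all(c("p_spearman", "p_ols", "p_gls", "p_first_diff") %in% names(row)))
  ## missing bins are dropped pairwise
  cov[3] <- NA
  expect_equal(correlate_disparity(disp, cov)$n, 11)
})
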