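test_that("Spearman S and rho match the classical examples", {
  r <- spearman_rank(1:3, 1:3)
  expect_equal(r$S, 0); expect_equal(r$rho, 1); expect_equal(r$p, 0)
  r2 <- spearman_rank(1:3, 3:1)
  expect_equal(r2$S, 8); expect_equal(r2$rho, -1)
  expect_error(spearman_rank(1:3, 1:4), "equal length")
  expect_error(spearman_rank(1:2, 1:2), "at least 3")
  expect_error(spearman_rank(rep(1, 5), 1:5), "zero variance")
})

test_that("tied vectors match the explicit rank-vector oracle and cor.test", {
  set.seed(9)
  for (i in 1:25) {
    n <- sample(5:40, 1)
    x <- sample(1:6, n, replace = TRUE)
    y <- sample(1:6, n, replace = TRUE)
    if (var(rank(x)) == 0 || var(rank(y)) == 0) next
    r <- spearman_rank(x, y)
    o <- spearman_oracle(x, y)
    expect_equal(r$S, o$S, tolerance = 1e-10)
    expect_equal(r$rho, o$rho, tolerance = 1e-10)
    expect_equal(r$rho, suppressWarnings(cor.test(x, y, method = "spearman"))$estimate[[1]],
                 tolerance = 1e-10)
  }
})

test_that("t-approximate and exact permutation p-values are sane", {
  set.seed(10)
  x <- c(2, 9, 1, 5, 7); y <- c(1, 8, 3, 5, 9)
  r_t <- spearman_rank(x, y)
  r_e <- spearman_rank(x, y, method = "exact")
  # exact enumeration agrees with cor.test's exact p for untied small samples
  expect_equal(r_e$p, cor.test(x, y, method = "spearman")$p.value, tolerance = 1e-10)
  expect_lt(abs(r_t$p - r_e$p), 0.05)
  expect_error(spearman_rank(1:10, c(2:10, 1), method = "exact"), "n <= 9")
})

test_that("OLS matches exact lines, constants, and the normal-equation oracle", {
  x <- 0:4
  f <- ols_fit(2 * x + 1, x)
  expect_equal(unname(f$coefficients[, "estimate"]), c(1, 2), tolerance = 1e-12)
  expect_equal(f$r_squared, 1)
  fc <- ols_fit(rep(3, 6), 1:6)
  expect_equal(fc$r_squared, 0)
  set.seed(11)
  for (i in 1:20) {
    n <- sample(8:60, 1); p <- sample(1:3, 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- rnorm(n)
    f <- ols_fit(y, X)
    o <- ols_oracle(y, X)
    expect_equal(unname(f$coefficients[, "estimate"]), unname(o$beta), tolerance = 1e-8)
    expect_equal(f$r_squared, o$r_squared, tolerance = 1e-8)
    # overall test agrees with summary.lm
    sm <- summary(lm(y ~ X))
    expect_equal(f$p, unname(pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                                lower.tail = FALSE)), tolerance = 1e-8)
  }
  X <- cbind(a = 1:10, b = 2 * (1:10))
  expect_error(ols_fit(rnorm(10), X), "singular.*b")
})

test_that("R-squared is invariant to affine rescaling of predictors", {
  set.seed(12)
  X <- matrix(rnorm(60), 30, 2); y <- rnorm(30)
  f1 <- ols_fit(y, X)
  f2 <- ols_fit(y, sweep(X * 3.7, 2, c(5, -2), "+"))
  expect_equal(f1$r_squared, f2$r_squared, tolerance = 1e-12)
})

test_that("one-way ANOVA matches hand decomposition and aov", {
  expect_equal(oneway_anova(list(c(1, 2, 3), c(1, 2, 3)))$f, 0)
  r <- oneway_anova(list(c(1, 2), c(3, 4)))
  expect_equal(r$f, 8)            # SSB = 4, SSW = 1, df 1 and 2
  expect_identical(r$df_between, 1L %/% 1L)
  set.seed(13)
  for (i in 1:15) {
    k <- sample(2:5, 1)
    groups <- lapply(seq_len(k), function(j) rnorm(sample(2:10, 1), mean = j / 2))
    r <- oneway_anova(groups)
    o <- anova_oracle(groups)
    expect_equal(r$f, o$f, tolerance = 1e-10)
    expect_equal(r$p, o$p, tolerance = 1e-10)
  }
  deg <- oneway_anova(list(c(1, 1), c(2, 2)))
  expect_true(deg$degenerate)
  expect_identical(deg$p, 0)
  expect_error(oneway_anova(list(1:3)), "at least 2 groups")
})

test_that("ANOVA null p-values are roughly uniform", {
  set.seed(14)
  ps <- vapply(1:400, function(i) {
    oneway_anova(list(rnorm(6), rnorm(6), rnorm(6)))$p
  }, 0)
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.03)
  expect_lt(abs(mean(ps < 0.5) - 0.5), 0.07)
})

test_that("variance decomposition: trivial cases and brute-force equality", {
  v <- load_variance_decomposition(c(1, 1, 5, 5), c("a", "a", "b", "b"))
  expect_equal(v$within_sd, 0)
  expect_gt(v$overall_sd, 0)
  one <- load_variance_decomposition(c(1, 4, 6), rep("a", 3))
  expect_equal(one$within_sd, one$overall_sd)
  set.seed(15)
  vals <- rnorm(60); grp <- sample(letters[1:8], 60, replace = TRUE)
  v2 <- load_variance_decomposition(vals, grp)
  per <- vapply(split(vals, grp), function(g) if (length(g) >= 2) sd(g) else NA_real_, 0)
  expect_equal(v2$within_sd, mean(per, na.rm = TRUE), tolerance = 1e-12)
  expect_equal(v2$overall_sd, sd(vals), tolerance = 1e-12)
  expect_error(load_variance_decomposition(1:3, c("a", "b", "c")), "at least 2 members")
})
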