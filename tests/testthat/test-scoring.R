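test_that("retention_score pools heated nubbins over a control mean", {
  r <- retention_score(c(0.10, 0.12), c(0.08, 0.02, 0.05))
  expect_equal(r$retention, 0.05 / 0.11, tolerance = 1e-12)
  expect_equal(retention_score(0.1, c(0.1, 0.1))$retention, 1.0)
  # not capped above 1
  expect_gt(retention_score(c(0.08), c(0.09, 0.085))$retention, 1)
  # control floor flags unstable colonies instead of dividing
  low <- retention_score(c(0.001, 0.002), 0.01)
  expect_true(is.na(low$retention))
  expect_false(low$ok)
  expect_error(retention_score(numeric(0), 0.1), "at least one")
})

test_that("retention is invariant to rescaling a colony's loads", {
  set.seed(1)
  for (i in 1:10) {
    ctl <- runif(2, 0.05, 0.2); heat <- runif(3, 0, 0.2); c_ <- runif(1, 0.5, 3)
    expect_equal(retention_score(ctl, heat)$retention,
                 retention_score(ctl * c_, heat * c_)$retention, tolerance = 1e-12)
  }
})

test_that("resistance classification uses the interpolated 75th percentile", {
  col <- data.frame(retention = c(0.1, 0.2, 0.3, 0.4))
  cl <- classify_resistant(col)
  expect_equal(attr(cl, "retention_threshold"), 0.325)
  expect_identical(cl$resistant, c(FALSE, FALSE, FALSE, TRUE))
  # all tied -> everyone at the threshold, flagged degenerate
  tied <- classify_resistant(data.frame(retention = rep(0.5, 6)))
  expect_true(all(tied$resistant))
  expect_true(attr(tied, "degenerate"))
  expect_error(classify_resistant(data.frame(retention = c(NA, NA, 1, 2))), "at least 4")
})

test_that("classification is invariant under strictly monotone transforms", {
  set.seed(2)
  ret <- runif(40)
  a <- classify_resistant(data.frame(retention = ret))$resistant
  b <- classify_resistant(data.frame(retention = exp(3 * ret)))$resistant
  expect_identical(a, b)
})

test_that("quartile contrast picks floor(n/4) extremes per group", {
  col <- data.frame(retention = 1:8, depth_m = 1:8)
  qc <- summarize_quartile_contrast(col)
  expect_identical(qc$group_size, 2L)
  expect_equal(qc$means["top25", "depth_m"], mean(c(7, 8)))
  expect_equal(qc$means["bottom25", "depth_m"], mean(c(1, 2)))
  # identical colonies -> identical rows
  same <- data.frame(retention = rep(1, 8), control_load = rep(0.1, 8))
  qs <- summarize_quartile_contrast(same)
  expect_equal(unname(unlist(qs$means["top25", ])), unname(unlist(qs$means["bottom25", ])))
  expect_error(summarize_quartile_contrast(data.frame(retention = 1:3)), "at least 4")
})

test_that("quartile membership counts are balanced", {
  set.seed(3)
  for (n in c(8, 13, 221)) {
    ret <- runif(n)
    top <- reefheat:::quartile_members(ret, "top")
    bot <- reefheat:::quartile_members(ret, "bottom")
    expect_identical(length(top), length(bot))
    expect_lte(length(top) + length(bot), n)
    expect_identical(length(intersect(top, bot)), 0L)
  }
})

test_that("reef and region resistance fractions count correctly", {
  col <- data.frame(reef_id = rep(c("A", "B"), c(10, 4)),
                    region = rep(c("North", "South"), c(10, 4)),
                    resistant = c(rep(TRUE, 3), rep(FALSE, 7), rep(FALSE, 4)))
  fr <- reef_resistance_fraction(col)
  expect_equal(fr$reefs$fraction[fr$reefs$reef_id == "A"], 0.3)
  expect_equal(fr$reefs$fraction[fr$reefs$reef_id == "B"], 0.0)
  expect_equal(fr$regions$n[fr$regions$region == "North"], 10L)
})
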