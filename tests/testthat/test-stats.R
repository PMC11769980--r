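test_that("signed-rank exact branch matches hand enumeration", {
  # 5 pairs, all differences positive: two-sided p = 2 / 2^5
  res <- wilcoxon_signed(c(5, 6, 7, 8, 9), c(1, 2, 3, 4, 5))
  expect_equal(res$p, 0.0625)
  expect_equal(res$method, "exact")
  expect_equal(res$statistic, 15)

  expect_error(wilcoxon_signed(1:6, 1:6), class = "cardioresp_error_input")
  expect_error(wilcoxon_signed(1:3, c(2, 3, 4)),
               class = "cardioresp_error_input")

  # swapping the samples changes nothing two-sided
  x <- c(3.1, 4.5, 2.2, 6.6, 5.0, 4.1, 3.3)
  y <- c(2.0, 4.9, 1.1, 4.2, 5.5, 3.0, 2.8)
  a <- wilcoxon_signed(x, y)
  b <- wilcoxon_signed(y, x)
  expect_equal(a$p, b$p)
  expect_equal(a$z, b$z)
})

test_that("exact signed-rank agrees with brute-force enumeration", {
  for (n in c(6, 8, 10)) {
    for (s in 1:5) {
      d <- withr::with_seed(100 * n + s, {
        round(rnorm(n, 0.4, 1), 1) # some ties in |d| by rounding
      })
      d <- d[d != 0]
      if (length(d) < 5) next
      res <- wilcoxon_signed(d, rep(0, length(d)))
      expect_equal(res$p, brute_signed_rank_p(d), tolerance = 1e-12,
                   info = sprintf("n=%d seed=%d", n, s))
    }
  }
})

test_that("exact and normal branches agree near the switch point", {
  diffs <- withr::with_seed(7, replicate(20, rnorm(20, 0.3), simplify = FALSE))
  for (d in diffs) {
    exact <- wilcoxon_signed(d, rep(0, 20), exact_n = 20)
    approx <- wilcoxon_signed(d, rep(0, 20), exact_n = 0)
    expect_lt(abs(exact$p - approx$p), 0.01)
  }
})

test_that("rank-sum test matches enumeration and rank invariances", {
  expect_equal(mannwhitney(c(1, 2, 3), c(10, 11, 12))$p, 0.1)

  same <- mannwhitney(c(1, 2, 3, 4), c(4, 3, 2, 1))
  expect_gt(same$p, 0.99)

  a <- c(3, 8, 1, 9, 4)
  b <- c(7, 2, 10, 6, 5)
  raw <- mannwhitney(a, b)
  transformed <- mannwhitney(exp(a), exp(b)) # common monotone transform
  expect_equal(raw$p, transformed$p)
  expect_equal(raw$statistic, transformed$statistic)

  expect_error(mannwhitney(1:2, 1:5), class = "cardioresp_error_input")
})

test_that("sequential ANOVA matches the projection oracle to 1e-8", {
  # fixed unbalanced 24-row dataset, 2 x 4 design with cells of 2..5
  cells <- expand.grid(a = c("CR6", "CR15"), b = c("I", "II", "III", "IV"))
  reps <- c(2, 3, 4, 5, 3, 2, 3, 2)
  df <- do.call(rbind, lapply(seq_len(8), function(i) {
    data.frame(a = cells$a[i], b = cells$b[i])[rep(1, reps[i]), ]
  }))
  df$y <- withr::with_seed(99, {
    round(rnorm(24, mean = as.integer(factor(df$b)), sd = 2), 2)
  })

  fit <- anova2(df, "y", "a", "b")
  oracle <- brute_anova2_ss(df$y, df$a, df$b)
  got <- setNames(fit$table$ss[1:4], fit$table$source[1:4])
  expect_equal(got, oracle[c("A", "B", "AB", "error")], tolerance = 1e-8)

  # decomposition sums exactly to the total SS of the data
  expect_equal(fit$table$ss[fit$table$source == "total"],
               sum((df$y - mean(df$y))^2), tolerance = 1e-10)
  expect_equal(fit$table$df[fit$table$source == "total"], 23)

  # scale equivariance: doubling y quadruples SS, leaves F untouched
  df2 <- df
  df2$y <- 2 * df$y
  fit2 <- anova2(df2, "y", "a", "b")
  expect_equal(fit2$table$ss[1:4], 4 * fit$table$ss[1:4])
  expect_equal(fit2$table$f[1:3], fit$table$f[1:3], tolerance = 1e-12)
})

test_that("degenerate ANOVA designs are rejected", {
  cells <- expand.grid(a = c("x", "y"), b = c("p", "q"))
  single <- data.frame(cells, y = 1:4)
  expect_error(anova2(single, "y", "a", "b"),
               class = "cardioresp_error_input")

  missing_cell <- data.frame(a = c("x", "x", "y", "y", "x", "x"),
                             b = c("p", "p", "p", "p", "q", "q"),
                             y = rnorm(6))
  expect_error(anova2(missing_cell, "y", "a", "b"),
               class = "cardioresp_error_input")
})

test_that("table finishing reproduces published F statistics", {
  f_a <- assemble_anova_table(
    ss = c(A = 3253.7438, error = 1322.5479),
    dfs = c(A = 1, error = 358)
  )
  expect_equal(f_a$table$f[1], 880.7547, tolerance = 1e-4)

  f_b <- assemble_anova_table(
    ss = c(B = 3472.8871, error = 45936.9429),
    dfs = c(B = 3, error = 358)
  )
  expect_equal(f_b$table$f[1], 9.0217, tolerance = 1e-4)

  zero <- assemble_anova_table(ss = c(A = 0, error = 10),
                               dfs = c(A = 1, error = 8))
  expect_equal(zero$table$f[1], 0)

  expect_error(assemble_anova_table(ss = c(A = 1), dfs = c(A = 1)),
               class = "cardioresp_error_input")
})

test_that("anova tidiers expose the table and totals", {
  df <- expand.grid(a = c("x", "y"), b = c("p", "q"), r = 1:3)
  df$y <- withr::with_seed(3, rnorm(12))
  fit <- anova2(df, "y", "a", "b")
  td <- tidy(fit)
  expect_equal(td$source, c("A", "B", "AB", "error"))
  g <- glance(fit)
  expect_equal(g$nobs, 12)
  expect_equal(g$df_total, 11)
})
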