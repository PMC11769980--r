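#' Wilcoxon matched-pairs signed-rank test
#'
#' Zero differences are dropped; ties among absolute differences receive
#' average ranks. For `n <= exact_n` pairs the two-sided p-value comes from
#' the exact distribution of the positive-rank sum, computed by a tie-aware
#' generating-function convolution over the (doubled, hence integer) ranks;
#' for larger n the normal approximation with tie-corrected variance and
#' continuity correction is used. The standardized statistic is reported as
#' |z|, the convention of paired-comparison tables.
#'
#' @param x,y Paired numeric vectors.
#' @param exact_n Largest n for which the exact branch is used.
#' @return A tibble (one row) with `n` (non-zero pairs), `statistic`
#'   (positive-rank sum W+), `z` (|z|, tie-corrected, continuity-corrected),
#'   `p` (two-sided), `method` (`"exact"` or `"normal"`).
#' @export
#' @examples
#' wilcoxon_signed(c(5, 6, 7, 8, 9), c(1, 2, 3, 4, 5)) # p = 0.0625
wilcoxon_signed <- function(x, y, exact_n = 20) {
  if (length(x) != length(y)) {
    cr_abort("paired test needs equal-length vectors",
             class = "cardioresp_error_input")
  }
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    cr_abort("all differences are zero: signed-rank test undefined",
             class = "cardioresp_error_input")
  }
  if (n < 5) {
    cr_abort("signed-rank test needs at least 5 non-zero differences",
             class = "cardioresp_error_input")
  }
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- (w_pos - mu - sign(w_pos - mu) * 0.5) / sqrt(sigma2)

  if (n <= exact_n) {
    # distribution of W+ over all 2^n sign assignments via convolution on
    # doubled ranks (integers even with .5 average ranks)
    r2 <- round(2 * r)
    counts <- c(1, numeric(sum(r2)))
    for (rk in r2) {
      shifted <- c(numeric(rk), counts[seq_len(length(counts) - rk)])
      counts <- counts + shifted
    }
    probs <- counts / 2^n
    w2 <- round(2 * w_pos)
    p <- 2 * min(sum(probs[seq_len(w2 + 1)]),
                 sum(probs[seq(w2 + 1, length(probs))]))
    p <- min(p, 1)
    method <- "exact"
  } else {
    p <- 2 * pnorm(-abs(z))
    method <- "normal"
  }
  tibble::tibble(n = n, statistic = w_pos, z = abs(z), p = p,
                 method = method)
}

#' Mann-Whitney rank-sum test for two independent groups
#'
#' Wraps [stats::wilcox.test()]: exact when both groups are small and
#' untied, otherwise the normal approximation with tie correction and
#' continuity correction.
#'
#' @param a,b Numeric vectors (each at least 3 values).
#' @return A tibble (one row) with `statistic` (U), `p` (two-sided),
#'   `n_a`, `n_b`.
#' @export
#' @examples
#' mannwhitney(c(1, 2, 3), c(10, 11, 12)) # exact p = 0.1
mannwhitney <- function(a, b) {
  if (length(a) < 3 || length(b) < 3) {
    cr_abort("rank-sum test needs at least 3 values per group",
             class = "cardioresp_error_input")
  }
  ht <- suppressWarnings(wilcox.test(a, b, correct = TRUE))
  tibble::tibble(statistic = unname(ht$statistic), p = ht$p.value,
                 n_a = length(a), n_b = length(b))
}

#' Unbalanced two-way ANOVA with sequential (Type I) sums of squares
#'
#' Fits `y ~ A + B + A:B` by least squares and decomposes the total sum of
#' squares sequentially (A, then B given A, then the interaction), the
#' decomposition whose components sum exactly to the total even for heavily
#' unbalanced designs. Every factor-level cell must contain at least one
#' observation, and the residual must retain positive degrees of freedom.
#'
#' @param data Data frame.
#' @param value,factor_a,factor_b Column names (strings or bare names via
#'   `{{ }}`-style tidy evaluation is not needed; pass strings) of the
#'   response and the two factors.
#' @return An object of class `cr_anova`: list with `table` (tibble with
#'   `source`, `df`, `ss`, `ms`, `f`, `p`) and `nobs`.
#' @export
#' @examples
#' df <- expand.grid(a = c("x", "y"), b = c("p", "q"), rep = 1:3)
#' df$y <- rnorm(nrow(df))
#' anova2(df, "y", "a", "b")
anova2 <- function(data, value, factor_a, factor_b) {
  y <- data[[value]]
  a <- factor(data[[factor_a]])
  b <- factor(data[[factor_b]])
  if (nlevels(a) < 2 || nlevels(b) < 2) {
    cr_abort("two-way ANOVA needs at least 2 levels of each factor",
             class = "cardioresp_error_input")
  }
  if (any(table(a, b) == 0)) {
    cr_abort("two-way ANOVA needs every A x B cell non-empty",
             class = "cardioresp_error_input")
  }
  df_err <- length(y) - nlevels(a) * nlevels(b)
  if (df_err <= 0) {
    cr_abort("no residual degrees of freedom for the interaction model",
             class = "cardioresp_error_input")
  }
  fit <- lm(y ~ a * b)
  tab <- anova(fit) # sequential Type I by construction
  ss <- tab$`Sum Sq`
  dfs <- tab$Df
  assemble_anova_table(
    ss = c(A = ss[1], B = ss[2], AB = ss[3], error = ss[4]),
    dfs = c(A = dfs[1], B = dfs[2], AB = dfs[3], error = dfs[4]),
    nobs = length(y)
  )
}

#' Finish an ANOVA table from sums of squares and degrees of freedom
#'
#' Computes mean squares (`ms = ss / df`), F statistics for each effect
#' against the error mean square, p-values from the F distribution, and the
#' total row -- the arithmetic that turns a printed SS/df decomposition into
#' the full published table.
#'
#' @param ss Named numeric vector of sums of squares; must include `error`
#'   and may include `A`, `B`, `AB`.
#' @param dfs Named numeric vector of degrees of freedom, same names.
#' @param nobs Optional number of observations (for `glance()`).
#' @return A `cr_anova` object.
#' @export
#' @examples
#' assemble_anova_table(ss = c(A = 3253.7438, error = 1322.5479),
#'                      dfs = c(A = 1, error = 358))
assemble_anova_table <- function(ss, dfs, nobs = NA_integer_) {
  if (!"error" %in% names(ss) || !"error" %in% names(dfs)) {
    cr_abort("ANOVA assembly needs an 'error' source",
             class = "cardioresp_error_input")
  }
  if (any(dfs <= 0)) {
    cr_abort("degrees of freedom must be positive",
             class = "cardioresp_error_input")
  }
  sources <- names(ss)
  ms <- ss / dfs
  effects <- setdiff(sources, "error")
  f <- ms[effects] / ms[["error"]]
  p <- pf(f, dfs[effects], dfs[["error"]], lower.tail = FALSE)
  table <- tibble::tibble(
    source = c(effects, "error", "total"),
    df = unname(c(dfs[effects], dfs[["error"]], sum(dfs))),
    ss = unname(c(ss[effects], ss[["error"]], sum(ss))),
    ms = unname(c(ms[effects], ms[["error"]], sum(ss) / sum(dfs))),
    f = unname(c(f, NA, NA)),
    p = unname(c(p, NA, NA))
  )
  structure(list(table = table, nobs = nobs), class = "cr_anova")
}

#' @export
print.cr_anova <- function(x, ...) {
  cat("Two-way ANOVA (sequential SS)\n")
  print(as.data.frame(x$table), row.names = FALSE, digits = 6)
  invisible(x)
}

#' Reference two-way ANOVA decompositions for the maneuver increments
#'
#' Sums of squares, degrees of freedom and printed F statistics of the
#' breathing-condition x HRR-type ANOVA of the four maneuver increments
#' (delta HI, delta VSI, delta BR_LF, delta BR_HF), as published for a
#' 183-athlete cohort (366 = 183 x 2 increment rows). Shipped so the
#' finishing arithmetic of [assemble_anova_table()] can be checked against
#' a published decomposition.
#'
#' @return A tibble with columns `index`, `source`, `df`, `ss`, `f_printed`.
#' @export
reference_anova_ss <- function() {
  path <- system.file("extdata", "reference_anova_ss.csv",
                      package = "cardioresp", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE)
}
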