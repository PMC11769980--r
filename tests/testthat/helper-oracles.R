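# Independent oracles used across tests. These deliberately avoid the code
# paths they check.

# Exact two-sided signed-rank p-value by full 2^n enumeration of sign
# assignments (usable for n <= ~15).
brute_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  min(1, 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs)))
}

# Sequential (Type I) two-way ANOVA by explicit least-squares projections:
# fit nested models mean -> +A -> +A+B -> +A*B via model matrices and QR,
# take differences of residual sums of squares.
brute_anova2_ss <- function(y, a, b) {
  rss <- function(x) {
    fit <- qr(x)
    sum((y - x %*% qr.coef(fit, y))^2)
  }
  a <- factor(a)
  b <- factor(b)
  m0 <- matrix(1, length(y), 1)
  ma <- model.matrix(~a)
  mab <- model.matrix(~ a + b)
  mfull <- model.matrix(~ a * b)
  c(
    A = rss(m0) - rss(ma),
    B = rss(ma) - rss(mab),
    AB = rss(mab) - rss(mfull),
    error = rss(mfull)
  )
}

# Uniform sinusoid series for spectral tests.
sine_series <- function(freq, amp, duration = 120, fs = 4, phase = 0) {
  t <- seq(0, duration, by = 1 / fs)
  tibble::tibble(t = t, value = amp * sin(2 * pi * freq * t + phase))
}

# A low-variability beat tibble (white-noise RR around a mean) for QC and
# IO tests where physiological oscillations would get in the way.
flat_beats <- function(n = 150, mean_rr = 800, sd = 5, seed = 1) {
  withr::with_seed(seed, {
    rr <- rnorm(n, mean_rr, sd)
    t <- cumsum(rr) / 1000
    tibble::tibble(
      t_s = t, rr_ms = rr,
      sbp_mmhg = rnorm(n, 115, 2), dbp_mmhg = rnorm(n, 75, 2),
      sv_ml = 65
    )
  })
}
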