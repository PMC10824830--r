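# minimal curve builder on an arbitrary grid
mk_curve <- function(r, m, lags = c(0, 100), id = "d") {
  structure(data.frame(lag_ms = lags, lag_frames = round(lags * 0.12),
                       r = r, m = m),
            dyad_id = id, segment = "whole",
            class = c("xcorr_curve", "data.frame"))
}

test_that("Fisher transform pair is exact and mutually inverse", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.8), log(3), tolerance = 1e-15)   # 0.5 ln(1.8/0.2)
  expect_equal(fisher_inv(0.5 * log(3)), 0.5, tolerance = 1e-15)
  expect_equal(fisher_inv(0), 0)
  rs <- seq(-0.9, 0.9, by = 0.1)
  expect_equal(fisher_z(-rs), -fisher_z(rs), tolerance = 1e-15)
  rs <- seq(-0.999, 0.999, length.out = 201)
  expect_equal(fisher_inv(fisher_z(rs)), rs, tolerance = 1e-12)
  expect_error(fisher_z(1), "domain")
})

test_that("pooling averages in Fisher space with the pair-count standard error", {
  # two dyads at r = 0.8 and r = 0 with equal m: X = ln(3)/2, R = 0.5 exactly
  fc <- pool_curves(list(mk_curve(c(0.8, 0.8), c(10, 10)),
                         mk_curve(c(0, 0), c(10, 10))))
  expect_equal(fc$X, rep(log(3) / 2, 2), tolerance = 1e-15)
  expect_equal(fisher_inv(fc$X), rep(0.5, 2), tolerance = 1e-15)
  expect_equal(fc$se, rep(1 / sqrt(20), 2), tolerance = 1e-15)
  expect_equal(fc$m_total, rep(20, 2))
  expect_equal(fc$n_dyads, rep(2L, 2))
  # identity pooling: all dyads share r -> R is that r
  fc2 <- pool_curves(lapply(1:5, function(i) mk_curve(c(0.3, 0.3), c(7, 7))))
  expect_equal(fisher_inv(fc2$X), rep(0.3, 2), tolerance = 1e-12)
  # permutation invariance and the effect of an at-the-mean dyad
  set.seed(31)
  curves <- lapply(1:6, function(i) mk_curve(runif(2, -0.5, 0.5),
                                             sample(50:90, 2)))
  a <- pool_curves(curves)
  b <- pool_curves(rev(curves))
  expect_equal(a$X, b$X, tolerance = 1e-14)
  extra <- mk_curve(fisher_inv(a$X), c(60, 60))
  c_ <- pool_curves(c(curves, list(extra)))
  expect_equal(c_$X, a$X, tolerance = 1e-12)
  expect_true(all(c_$se < a$se))
  # undefined dyad-lags are excluded, not fabricated
  d <- pool_curves(list(mk_curve(c(0.4, NA), c(10, 10)),
                        mk_curve(c(0.4, 0.2), c(10, 10))))
  expect_equal(d$n_dyads, c(2L, 1L))
  expect_equal(d$m_total, c(20, 10))
  expect_error(pool_curves(list()), "no curves")
})

test_that("perfect correlations are clamped before pooling, with a warning", {
  expect_warning(fc <- pool_curves(list(mk_curve(1, 5, lags = 0),
                                        mk_curve(-1, 5, lags = 0))),
                 "clamped")
  expect_true(all(is.finite(fc$X)))
})

test_that("Fisher-space subtraction combines errors in quadrature", {
  set.seed(32)
  a <- pool_curves(lapply(1:4, function(i) mk_curve(runif(2, -0.4, 0.6),
                                                    c(40, 40))))
  b <- pool_curves(lapply(1:4, function(i) mk_curve(runif(2, -0.4, 0.6),
                                                    c(40, 40))))
  self <- subtract_fisher(a, a)
  expect_equal(self$X, c(0, 0))
  d1 <- subtract_fisher(a, b); d2 <- subtract_fisher(b, a)
  expect_equal(d1$X, -d2$X, tolerance = 1e-14)
  a$se <- c(0.03, 0.03); b$se <- c(0.04, 0.04)
  expect_equal(subtract_fisher(a, b)$se, c(0.05, 0.05), tolerance = 1e-15)
  bad <- a; bad$lag_ms <- c(0, 200)
  expect_error(subtract_fisher(a, bad), "different lag grids")
})

test_that("corrected confidence bands use the Bonferroni z cutoff", {
  fc <- structure(data.frame(lag_ms = c(0, 100), X = c(0, 0.3),
                             se = c(0.05, 0.05), m_total = c(400, 400),
                             n_dyads = 2L),
                  label = "g", class = c("fisher_curve", "data.frame"))
  # alpha 0.05 with a single comparison: the familiar 1.96 cutoff
  ac <- confidence_band(fc, alpha = 0.05, n_comparisons = 1)
  expect_equal(attr(ac, "z_crit"), qnorm(0.975), tolerance = 1e-12)
  expect_equal(attr(ac, "z_crit"), 1.96, tolerance = 1e-3)
  # printed defaults: corrected level alpha/41 is about 2e-5
  ac2 <- confidence_band(fc, alpha = 0.001, n_comparisons = 41)
  expect_equal(attr(ac2, "p_corrected"), 0.001 / 41, tolerance = 1e-15)
  expect_lt(abs(attr(ac2, "p_corrected") - 0.00002), 5e-6)
  # interval construction on Pearson scale
  z <- attr(ac2, "z_crit")
  expect_equal(ac2$ci_low, tanh(fc$X - z * fc$se), tolerance = 1e-12)
  expect_equal(ac2$ci_high, tanh(fc$X + z * fc$se), tolerance = 1e-12)
  # X = 0 gives a symmetric, non-significant interval labeled 'none'
  expect_equal(ac2$ci_low[1], -ac2$ci_high[1], tolerance = 1e-12)
  expect_false(ac2$significant[1])
  expect_equal(ac2$morphology[1], "none")
  # X well clear of zero is significant with symmetric morphology
  expect_true(ac2$significant[2])
  expect_equal(ac2$morphology[2], "symmetric")
  neg <- fc; neg$X <- c(-0.4, -0.4)
  expect_equal(confidence_band(neg)$morphology, rep("asymmetric", 2))
  # band width shrinks monotonically as the total pair count grows
  widths <- sapply(c(100, 400, 1600, 6400), function(m) {
    f <- fc; f$se <- 1 / sqrt(m); f$m_total <- m
    a <- confidence_band(f)
    a$ci_high[2] - a$ci_low[2]
  })
  expect_true(all(diff(widths) < 0))
})

test_that("peaks are the grid's local extrema with sign-read morphology", {
  grid <- c(0, seq(100, 1500, 100))
  mk_ac <- function(R) {
    structure(data.frame(lag_ms = grid, R = R, ci_low = R - 0.01,
                         ci_high = R + 0.01, X = atanh(R), se = 0.01,
                         m_total = 1000, n_dyads = 5L, significant = TRUE,
                         morphology = "none", stringsAsFactors = FALSE),
              label = "t", class = c("aggregated_curve", "data.frame"))
  }
  mono <- mk_ac(seq(0.01, 0.16, by = 0.01))
  pk <- find_peaks(mono)
  expect_equal(pk$lag_ms[pk$type == "max" & pk$global], 1500)
  expect_equal(pk$lag_ms[pk$type == "min" & pk$global], 0)
  inj <- rep(0.01, 16); inj[grid == 500] <- 0.2; inj[grid == 1100] <- -0.3
  pk2 <- find_peaks(mk_ac(inj))
  expect_equal(pk2$lag_ms[pk2$type == "max" & pk2$global], 500)
  expect_equal(pk2$morphology[pk2$type == "max" & pk2$global], "symmetric")
  expect_equal(pk2$lag_ms[pk2$type == "min" & pk2$global], 1100)
  expect_equal(pk2$morphology[pk2$type == "min" & pk2$global], "asymmetric")
  # global extremes equal a brute-force scan on random curves
  set.seed(33)
  for (i in 1:10) {
    R <- runif(16, -0.5, 0.5)
    pk3 <- find_peaks(mk_ac(R))
    expect_equal(pk3$lag_ms[pk3$type == "max" & pk3$global],
                 grid[which.max(R)])
    expect_equal(pk3$lag_ms[pk3$type == "min" & pk3$global],
                 grid[which.min(R)])
  }
})
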