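co <- asl_constants()

test_that("closed-form tissue curve matches its piecewise definition", {
  p <- hemo_params(f = 60, att = 1.0)
  # before arrival and with zero perfusion the signal is zero
  expect_equal(tissue_curve_closedform(p, co, 0.5)$value, 0)
  expect_equal(tissue_curve_closedform(hemo_params(f = 0), co,
                                       c(0, 1, 2, 3))$value,
               rep(0, 4))
  expect_error(tissue_curve_closedform(p, co, c(-0.1, 1)), ">= 0")

  # quadrature oracle: during-bolus value is the integral of the decayed
  # inflow against the tissue residue function
  t_eval <- 2.0
  oracle <- integrate(
    function(u) (60 / 6000) * 2 * 0.85 * exp(-1.0 / 1.65) *
      exp(-(t_eval - u) / 1.3),
    lower = 1.0, upper = t_eval, rel.tol = 1e-12
  )$value
  got <- tissue_curve_closedform(p, co, t_eval)$value
  expect_lt(abs(got - oracle) / oracle, 1e-6)
})

test_that("gamma kernel has unit area and its mode sits at p", {
  tg <- seq(0, 5, by = 0.005)
  for (sp in list(c(7.389, 0.1), c(3, 0.4), c(20, 0.05))) {
    k <- gamma_kernel(sp[1], sp[2], tg)
    area <- aslcvr:::trapz(k$time, k$value)
    expect_lt(abs(area - 1), 1e-6)
    expect_lt(abs(k$time[which.max(k$value)] - sp[2]), 0.005 + 1e-9)
  }
  expect_error(gamma_kernel(-1, 0.1, tg), "> 0")
  expect_error(gamma_kernel(7, 0, tg), "> 0")
})

test_that("a very sharp kernel acts as a delta: dispersion vanishes", {
  tg <- seq(0, 4.5, by = 5e-4)  # fine grid so peak sampling is not limiting
  # peak deviation shrinks like 1/s and is below 1e-3 of the peak for a
  # near-delta kernel; pointwise agreement is only meaningful away from
  # the bolus edges, where the undispersed input is discontinuous
  peak_dev <- vapply(c(500, 5000, 50000), function(s) {
    p <- hemo_params(f = 60, att = 1, att_art = 0.5, s = s, p = 1 / s)
    a0 <- aif(p, co, tg, dispersed = FALSE)
    a1 <- aif(p, co, tg, dispersed = TRUE)
    abs(max(a1$value) - max(a0$value)) / max(a0$value)
  }, numeric(1))
  expect_true(all(diff(peak_dev) < 0))
  expect_lt(peak_dev[3], 1e-3)

  p <- hemo_params(f = 60, att = 1, att_art = 0.5, s = 50000, p = 2e-5)
  interior <- tg > 0.6 & tg < 1.8
  a0 <- aif(p, co, tg, dispersed = FALSE)
  a1 <- aif(p, co, tg, dispersed = TRUE)
  expect_lt(max(abs(a1$value - a0$value)[interior]) / max(a0$value), 1e-3)
  # the (continuous) dispersed tissue curve approaches the closed form
  t0 <- tissue_curve_closedform(p, co, tg)
  t1 <- tissue_curve_numeric(p, co, tg, dispersed = TRUE)
  expect_lt(max(abs(t1$value - t0$value)) / max(t0$value), 1e-3)
})

test_that("arterial input follows the decayed rectangular bolus", {
  tg <- seq(0, 4.5, by = 0.005)
  p <- hemo_params(f = 60, att = 1, att_art = 0.5)
  a <- aif(p, co, tg)
  expect_equal(a$value[tg < 0.5], rep(0, sum(tg < 0.5)))
  expect_equal(a$value[which.min(abs(tg - 0.5))],
               2 * 0.85 * exp(-0.5 / 1.65),
               tolerance = 1e-6)
  expect_error(aif(p, co, seq(0, 1, 0.005)), "too short")
})

test_that("dispersion conserves the bolus area (decay before kernel)", {
  tg <- seq(0, 6, by = 0.005)
  p <- hemo_params(f = 60, att = 1, att_art = 0.5, s = exp(2), p = 0.1)
  ad <- aif(p, co, tg, dispersed = TRUE)
  # exact area of the decayed bolus (the sampled undispersed boxcar has
  # first-order edge error, so compare against the analytic integral)
  area_exact <- 2 * 0.85 * 1.65 *
    (exp(-0.5 / 1.65) - exp(-(0.5 + 1.4) / 1.65))
  expect_lt(abs(aslcvr:::trapz(ad$time, ad$value) - area_exact) /
              area_exact, 1e-3)
})

test_that("numeric convolution reproduces the closed form without dispersion", {
  tg <- seq(0, 4.5, by = 0.005)
  set.seed(42)
  for (i in 1:5) {
    p <- hemo_params(f = runif(1, 20, 80), att = runif(1, 0.4, 1.5),
                     att_art = 0.2)
    cf <- tissue_curve_closedform(p, co, tg)
    nm <- tissue_curve_numeric(p, co, tg)
    expect_lt(max(abs(cf$value - nm$value)), 1e-3 * max(cf$value))
  }
  expect_equal(tissue_curve_numeric(hemo_params(f = 0), co, tg)$value,
               rep(0, length(tg)))
})

test_that("dispersion delays and blunts the tissue peak", {
  tg <- seq(0, 4.5, by = 0.005)
  p <- hemo_params(f = 60, att = 1, s = 7.39, p = 0.1)
  nm <- tissue_curve_numeric(p, co, tg, dispersed = FALSE)
  nd <- tissue_curve_numeric(p, co, tg, dispersed = TRUE)
  expect_lt(max(nd$value), max(nm$value))
  expect_gt(tg[which.max(nd$value)], tg[which.max(nm$value)])
})

test_that("macrovascular component scales linearly with aBV", {
  tg <- seq(0, 4.5, by = 0.005)
  p0 <- hemo_params(f = 60, att = 1, abv = 0, att_art = 0.5, check = FALSE)
  p1 <- hemo_params(f = 60, att = 1, abv = 1, att_art = 0.5)
  p2 <- hemo_params(f = 60, att = 1, abv = 2, att_art = 0.5)
  expect_equal(arterial_curve(p0, co, tg)$value, rep(0, length(tg)))
  a1 <- arterial_curve(p1, co, tg)
  expect_equal(a1$value, 0.01 * aif(p1, co, tg)$value)
  expect_equal(arterial_curve(p2, co, tg)$value, 2 * a1$value)
  p1$abv <- -1
  expect_error(arterial_curve(p1, co, tg), ">= 0")
})

test_that("model_signal nests correctly across the four models", {
  pr <- asl_protocol()
  p <- hemo_params(f = 60, att = 1, abv = 0, att_art = 0.5,
                   s = 7.39, p = 0.1, check = FALSE)
  base <- tissue_curve_closedform(p, co, sample_times(pr, 0), tau = pr$tau)
  m1 <- model_signal("noart_nodisp", p, pr, co)
  expect_equal(m1$value, base$value, tolerance = 1e-12)
  m2 <- model_signal("art_nodisp", p, pr, co)
  expect_equal(m2$value, m1$value, tolerance = 1e-12)
  # dispersed pair coincide when abv = 0
  m3 <- model_signal("noart_disp", p, pr, co)
  m4 <- model_signal("art_disp", p, pr, co)
  expect_equal(m4$value, m3$value, tolerance = 1e-12)
  expect_error(model_signal("fancy_model", p, pr, co), "valid codes")
})

test_that("full model matches a brute-force double-convolution oracle", {
  pr <- asl_protocol()
  p <- hemo_params(f = 60, att = 1, abv = 1, att_art = 0.7,
                   s = 7.39, p = 0.1)
  got <- model_signal("art_disp", p, pr, co, slice_index = 0L)

  # independent oracle on a fine grid: rectangle-rule convolutions
  hh <- 5e-4
  tt <- seq(0, 4.6, by = hh)
  kern <- dgamma(tt, shape = 1 + 7.39 * 0.1, rate = 7.39)
  box_t <- as.numeric(tt >= 1 & tt < 2.4)
  disp_t <- stats::convolve(box_t, rev(kern), type = "open")[seq_along(tt)] * hh
  resid <- exp(-tt / 1.3)
  tiss <- (60 / 6000) * 2 * 0.85 * exp(-1 / 1.65) *
    stats::convolve(disp_t, rev(resid), type = "open")[seq_along(tt)] * hh
  box_a <- 2 * 0.85 * exp(-tt / 1.65) * (tt >= 0.7 & tt < 2.1)
  art <- 0.01 * stats::convolve(box_a, rev(kern), type = "open")[seq_along(tt)] * hh
  oracle <- approx(tt, tiss + art, xout = got$time)$y

  expect_lt(max(abs(got$value - oracle)) / max(oracle), 1e-3)
})

test_that("signals are non-negative, vanish at late times, linear in f and aBV", {
  pr <- asl_protocol()
  tg <- seq(0, 16, by = 0.01)
  set.seed(7)
  for (i in 1:8) {
    p <- hemo_params(f = runif(1, 5, 90), att = runif(1, 0.3, 1.6),
                     abv = runif(1, 0, 2), att_art = runif(1, 0.2, 0.3),
                     s = runif(1, 3, 15), p = runif(1, 0.05, 0.4))
    dispersed <- i %% 2 == 0
    tiss <- tissue_curve_numeric(p, co, tg, dispersed = dispersed)$value
    art <- arterial_curve(p, co, tg, dispersed = dispersed)$value
    tot <- tiss + art
    expect_true(all(tot >= -1e-12))
    expect_lt(tot[length(tot)], 1e-3 * max(tot))
    # linearity
    p2 <- p; p2$f <- 2 * p$f; p2$abv <- 2 * p$abv
    tot2 <- tissue_curve_numeric(p2, co, tg, dispersed = dispersed)$value +
      arterial_curve(p2, co, tg, dispersed = dispersed)$value
    expect_equal(tot2, 2 * tot, tolerance = 1e-10)
  }
})
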