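test_that("monoexponential fits recover the generating rate constant exactly", {
  for (k in c(1e-3, 0.01, 0.03, 0.19, 1)) {
    tr <- exp_rise_trace(k, t_max = max(60, 5 / k))
    fit <- fit_exponential_rise(tr, "LSI12")
    expect_lt(abs(fit$k / k - 1), 1e-3)
    expect_equal(fit$i_m, 100, tolerance = 1e-3)
    expect_gt(fit$r2, 0.999999)
    expect_true(fit$ok)
  }
})

test_that("rate recovery is robust to additive noise", {
  k <- 0.19
  tr0 <- exp_rise_trace(k)
  set.seed(7)
  rel_err <- replicate(100, {
    tr <- tr0
    tr$LSI12 <- tr$LSI12 + rnorm(nrow(tr), 0, 2) # sd = 2% of Im
    abs(fit_exponential_rise(tr, "LSI12")$k / k - 1)
  })
  expect_lt(median(rel_err), 0.05)
})

test_that("degenerate and absent channels are rejected", {
  flat <- tibble::tibble(t = seq(0, 30, 0.1), LSI12 = 5)
  expect_error(fit_exponential_rise(flat, "LSI12"), "degenerate")
  expect_error(fit_exponential_rise(flat, "LSI1"), "not present")
  short <- tibble::tibble(t = 0:5, LSI12 = exp(0:5))
  expect_error(fit_exponential_rise(short, "LSI12"), "at least 10")
})

test_that("initial rates match the analytic tangent", {
  ramp <- tibble::tibble(t = seq(0, 30, 0.1), LSI1 = 2 * seq(0, 30, 0.1))
  expect_equal(initial_rate(ramp, "LSI1", t_eval = 5), 2, tolerance = 1e-9)
  expect_equal(initial_rate(ramp, "LSI1", t_eval = 20), 2, tolerance = 1e-9)

  tr <- exp_rise_trace(0.19)
  truth <- 100 * 0.19 * exp(-0.19 * 5)  # derivative of the saturation curve
  expect_equal(initial_rate(tr, "LSI12", t_eval = 5, half_window = 0.5),
               truth, tolerance = 5e-3)
  # the default 2 s window trades a small curvature bias for noise robustness
  expect_equal(initial_rate(tr, "LSI12", t_eval = 5), truth, tolerance = 0.05)

  flat <- tibble::tibble(t = seq(0, 30, 0.1), LSI1 = 4)
  expect_equal(initial_rate(flat, "LSI1", t_eval = 10), 0)
  expect_error(initial_rate(flat, "LSI1", t_eval = 40), "outside")
})

test_that("areas under the curve match closed forms and a Riemann oracle", {
  const <- tibble::tibble(t = seq(0, 120, 0.1), LSI1 = 1)
  expect_equal(trace_auc(const, "LSI1", 120), 120)
  lin <- tibble::tibble(t = seq(0, 20, 0.1), FL527 = 0.5 * seq(0, 20, 0.1))
  expect_equal(trace_auc(lin, "FL527", 20), 100)

  k <- 0.19; im <- 100
  tr <- exp_rise_trace(k, t_max = 120)
  closed <- im * 120 - im * (1 - exp(-k * 120)) / k
  expect_equal(trace_auc(tr, "LSI12", 120), closed, tolerance = 1e-4)

  # trapezoid oracle computed by hand on an arbitrary trace
  set.seed(11)
  y <- cumsum(rnorm(201))
  arb <- tibble::tibble(t = seq(0, 20, 0.1), LSI1 = y)
  oracle <- sum((y[-1] + y[-length(y)]) / 2 * diff(arb$t))
  expect_equal(trace_auc(arb, "LSI1", 20), oracle, tolerance = 1e-9)

  expect_error(trace_auc(const, "LSI1", 200), "overruns")
})

test_that("disaggregation percentage covers the full, partial and absent cases", {
  t <- seq(0, 100, 0.5)
  rise <- tibble::tibble(t = t, LSI1 = 100 * (1 - exp(-0.1 * t)))
  expect_equal(disaggregation_percent(rise, "LSI1"), 0, tolerance = 1e-6)

  up_down <- tibble::tibble(t = t, LSI1 = 100 * exp(-((t - 30) / 12)^2))
  expect_equal(disaggregation_percent(up_down, "LSI1"), 100, tolerance = 1e-3)

  half_back <- tibble::tibble(t = t, LSI1 = pmin(100, 10 * t) - pmax(0, t - 50))
  expect_equal(disaggregation_percent(half_back, "LSI1"), 50)

  # invariant under affine rescaling of the channel
  scaled <- half_back
  scaled$LSI1 <- 3.7 * scaled$LSI1 + 12
  expect_equal(disaggregation_percent(scaled, "LSI1"),
               disaggregation_percent(half_back, "LSI1"))

  flat <- tibble::tibble(t = t, LSI1 = 5)
  expect_error(disaggregation_percent(flat, "LSI1"), "no maximum")
})

test_that("onset detection finds the first departure beyond three noise SDs", {
  t <- seq(0, 60, 0.1)
  set.seed(3)
  y <- rnorm(length(t), 10, 0.2)
  y[t >= 20] <- y[t >= 20] + 50 * (1 - exp(-0.3 * (t[t >= 20] - 20)))
  tr <- tibble::tibble(t = t, LSI12 = y)
  on <- detect_onset(tr, "LSI12", t_event = 15)
  expect_gte(on, 20)
  expect_lt(on, 22)
  expect_error(detect_onset(tibble::tibble(t = t, LSI12 = rnorm(length(t))),
                            "LSI12", t_event = 30), "no onset")
})
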