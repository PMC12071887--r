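test_that("noiseless Hill data are refit to the generating parameters", {
  # steepness range covers the steepest printed coefficient (6.68)
  cases <- list(
    c(k_max = 0.19, half_conc = 46.8, h = 1.27),
    c(k_max = 0.03, half_conc = 589.8, h = 3.92),
    c(k_max = 0.03, half_conc = 2309, h = 6.68),
    c(k_max = 1, half_conc = 10, h = 1),
    c(k_max = 5, half_conc = 1000, h = 7)
  )
  for (mode in c("activation", "inhibition")) {
    for (cs in cases) {
      p <- hill_params(cs[["k_max"]], cs[["half_conc"]], cs[["h"]], mode = mode)
      ds <- generate_dose_response_dataset(p)
      fit <- fit_hill(ds, mode = mode)
      expect_lt(abs(fit$params$k_max / p$k_max - 1), 5e-3)
      expect_lt(abs(fit$params$half_conc / p$half_conc - 1), 5e-3)
      expect_lt(abs(fit$params$h / p$h - 1), 5e-3)
      expect_gt(fit$r2, 1 - 1e-8)
    }
  }
})

test_that("half-effect concentration is recovered under multiplicative noise", {
  p <- hill_params(0.19, 46.8, 1.27)
  errs <- vapply(1:100, function(s) {
    ds <- generate_dose_response_dataset(p, noise_sd = 0.05, seed = s)
    fit_hill(ds, mode = "activation")$params$half_conc
  }, numeric(1))
  expect_lt(median(abs(errs / 46.8 - 1)), 0.10)
})

test_that("the printed k6 points are fit at least as well as a grid-search oracle", {
  ds <- dose_response_dataset(table_k6$adp, table_k6$k)
  fit <- fit_hill(ds, mode = "inhibition")
  pred <- eval_hill(fit$params, table_k6$adp)
  ssr_fit <- sum((table_k6$k - pred)^2)
  grid <- expand.grid(k_max = seq(0.02, 0.12, length.out = 25),
                      ic = 10^seq(2, 3.7, length.out = 25),
                      h = seq(0.5, 5, length.out = 25))
  ssr_grid <- min(apply(grid, 1, function(g) {
    sum((table_k6$k - g[1] * g[2]^g[3] / (g[2]^g[3] + table_k6$adp^g[3]))^2)
  }))
  expect_lte(ssr_fit, ssr_grid + 1e-12)
})

test_that("degenerate and under-determined datasets are handled explicitly", {
  flat <- dose_response_dataset(c(1, 10, 100, 1000), rep(0.05, 4))
  fit <- fit_hill(flat, mode = "activation")
  expect_true("ec50_at_lower_boundary" %in% fit$flags)

  two <- dose_response_dataset(c(10, 100), c(0.01, 0.02))
  expect_error(fit_hill(two, mode = "activation"), "under-determined")
  # fixing k_max frees a parameter, so 2 points become fittable
  expect_s3_class(fit_hill(two, mode = "activation", fix_kmax = 0.03)$params,
                  "hill_params")
})

test_that("responses trending against the stated mode raise a warning, not an error", {
  falling <- dose_response_dataset(c(1, 10, 100, 1000),
                                   c(0.9, 0.6, 0.3, 0.1))
  expect_warning(fit_hill(falling, mode = "activation"), "against")
})

test_that("inverse-variance weighting favours the precise points", {
  p <- hill_params(1, 100, 2)
  d <- 10^seq(0, 4, length.out = 8)
  y <- eval_hill(p, d)
  y[1] <- y[1] * 3 # corrupt one point, give it a huge uncertainty
  ds_w <- dose_response_dataset(d, y, sd = c(10, rep(0.001, 7)))
  fit_w <- fit_hill(ds_w, mode = "activation")
  ds_u <- dose_response_dataset(d, y)
  fit_u <- fit_hill(ds_u, mode = "activation")
  expect_lt(abs(fit_w$params$half_conc - 100), abs(fit_u$params$half_conc - 100))
})

test_that("tidy and glance summarise Hill fits in broom style", {
  p <- hill_params(0.19, 46.8, 1.27)
  fit <- fit_hill(generate_dose_response_dataset(p), mode = "activation")
  td <- tidy(fit)
  expect_equal(td$term, c("k_max", "half_conc", "h"))
  expect_equal(td$estimate[2], 46.8, tolerance = 1e-3)
  expect_equal(glance(fit)$r.squared, 1, tolerance = 1e-8)
})
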