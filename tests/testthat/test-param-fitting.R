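test_that("coefficient of determination behaves at its reference points", {
  obs <- c(1, 3, 2, 5, 4)
  expect_equal(r_squared(obs, obs), 1)
  expect_equal(r_squared(obs, rep(mean(obs), 5)), 0)
  expect_lt(r_squared(obs, rev(obs) * 10), 0)
  expect_error(r_squared(rep(2, 5), obs), "zero-variance")
  expect_error(r_squared(1:3, 1:4), "equal length")
})

make_inh_obs <- function(noise_sd = 0, seed = 1, fitted = default_fitted_constants()) {
  pr <- stimulus_protocol(add_inhibitor(0, "iloprost", 0.3),
                          add_agonist(30, "ADP", 5000), t_end = 300)
  gt <- observables(simulate_phenotypes(pr, fitted = fitted, sample_dt = 2))
  tr <- gt
  if (noise_sd > 0) {
    set.seed(seed)
    for (ch in c("LSI1", "LSI12")) {
      rng <- diff(range(gt[[ch]]))
      tr[[ch]] <- gt[[ch]] + rnorm(nrow(gt), 0, noise_sd * rng)
    }
  }
  list(list(protocol = pr, trace = tr))
}

test_that("a free disaggregation constant is recovered from a noisy trace", {
  obs <- make_inh_obs(noise_sd = 0.02, seed = 5)
  prob <- fit_problem(list(k7 = c(5e-3, 5e-1)), obs, sample_dt = 2)
  fit <- fit_model(prob, global_iters = 1, n_starts = 1, seed = 11)
  expect_lt(abs(fit$estimates[["k7"]] / 0.05 - 1), 0.10)
  expect_gt(fit$r2[1], 0.98)
  expect_gt(fit$identifiability[["k7"]], 0.05)
})

test_that("identical seeds and inputs reproduce the fit exactly", {
  obs <- make_inh_obs(noise_sd = 0.02, seed = 9)
  prob <- fit_problem(list(k7 = c(5e-3, 5e-1)), obs, sample_dt = 2)
  f1 <- fit_model(prob, global_iters = 1, n_starts = 1, seed = 21)
  f2 <- fit_model(prob, global_iters = 1, n_starts = 1, seed = 21)
  expect_identical(f1$estimates, f2$estimates)
  expect_identical(f1$loss, f2$loss)
})

test_that("zero free parameters returns the forward simulation and its fit quality", {
  obs <- make_inh_obs()
  prob <- fit_problem(list(), obs, sample_dt = 2)
  fit <- fit_model(prob, seed = 1)
  expect_equal(fit$estimates, default_fitted_constants())
  expect_equal(fit$r2[1], 1, tolerance = 1e-6) # noiseless self-comparison
  expect_lt(fit$loss, 1e-8)
})

test_that("perturbing a constant away from truth strictly increases the loss", {
  obs <- make_inh_obs()
  loss_at <- function(k7) {
    fitted <- default_fitted_constants()
    fitted["k7"] <- k7
    prob <- fit_problem(list(), obs, sample_dt = 2)
    prob$fixed <- fitted
    fit_model(prob, seed = 1)$loss
  }
  l0 <- loss_at(0.05)
  expect_gt(loss_at(0.075), l0)
  expect_gt(loss_at(0.025), l0)
})

test_that("a constant with no pathway engaged is reported unidentifiable", {
  pr <- stimulus_protocol(add_agonist(0, "ADP", 2000), t_end = 200)
  gt <- observables(simulate_phenotypes(pr, sample_dt = 2))
  # no inhibitor anywhere: the inhibition-reversal constant cannot matter
  prob <- fit_problem(list(k_m4 = c(5e-4, 5e-2)),
                      list(list(protocol = pr, trace = gt)), sample_dt = 2)
  fit <- fit_model(prob, global_iters = 1, n_starts = 1, seed = 2)
  expect_lt(fit$identifiability[["k_m4"]], 1e-6)
})

test_that("malformed fitting problems are rejected", {
  obs <- make_inh_obs()
  expect_error(fit_problem(list(k9 = c(1e-3, 1)), obs), "among")
  expect_error(fit_problem(list(k7 = c(0.1, 0.01)), obs), "lower, upper")
  expect_error(fit_problem(list(k7 = c(-1, 1)), obs), "positive")
})
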