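test_that("zero-noise generation equals the deterministic forward map", {
  pr <- stimulus_protocol(add_agonist(0, "ADP", 5000, unit = "nM"), t_end = 60)
  tr <- generate_trace(pr, noise = noise_model(additive_sd = 0, seed = 3),
                       sample_dt = 0.5)
  ref <- observables(simulate_phenotypes(pr, sample_dt = 0.5))
  expect_equal(tr$LSI1, ref$LSI1)
  expect_equal(tr$LSI12, ref$LSI12)
})

test_that("trace generation is reproducible under a fixed seed", {
  pr <- stimulus_protocol(add_agonist(0, "ADP", 2000), t_end = 60)
  a <- generate_trace(pr, noise = noise_model(seed = 42), sample_dt = 0.5)
  b <- generate_trace(pr, noise = noise_model(seed = 42), sample_dt = 0.5)
  c <- generate_trace(pr, noise = noise_model(seed = 43), sample_dt = 0.5)
  expect_identical(a$LSI1, b$LSI1)
  expect_false(identical(a$LSI1, c$LSI1))
})

test_that("every noisy fixture carries its noiseless twin", {
  pr <- stimulus_protocol(add_agonist(0, "ADP", 5, unit = "uM"), t_end = 120)
  tr <- generate_trace(pr, noise = noise_model(seed = 1), sample_dt = 0.5)
  gt <- attr(tr, "ground_truth")
  expect_s3_class(gt, "platelet_trace")
  # the high-dose fixture aggregates: positive initial aggregation rate at 20 s
  expect_gt(initial_rate(gt, "LSI1", t_eval = 20), 0)
  # default noise is small relative to the signal
  expect_lt(max(abs(tr$LSI1 - gt$LSI1)), 0.1 * diff(range(gt$LSI1)))
})

test_that("default noise leaves exponential rate recovery within 5%", {
  k <- 0.19
  tr0 <- exp_rise_trace(k)
  errs <- vapply(1:20, function(s) {
    set.seed(s)
    tr <- tr0
    tr$LSI12 <- apply_noise_for_test(tr$LSI12, tr$t)
    abs(fit_exponential_rise(tr, "LSI12")$k / k - 1)
  }, numeric(1))
  expect_lt(median(errs), 0.05)
})

test_that("dose-response generation hits the law exactly without noise", {
  p <- hill_params(0.19, 46.8, 1.27)
  ds <- generate_dose_response_dataset(p)
  expect_equal(ds$response, eval_hill(p, ds$dose))
  expect_equal(attr(ds, "ground_truth"), ds$response)
  n1 <- generate_dose_response_dataset(p, noise_sd = 0.05, seed = 2)
  n2 <- generate_dose_response_dataset(p, noise_sd = 0.05, seed = 2)
  expect_identical(n1$response, n2$response)
})

test_that("protocol suites emit the published delay and dose grids", {
  post <- generate_protocol_suite("disaggregation_post")
  offs <- vapply(post, function(pr) {
    pr$events$t[pr$events$kind == "add_inhibitor"]
  }, numeric(1))
  expect_true(all(c(5, 30, 120) %in% offs))
  expect_true(all(vapply(post, function(pr) {
    pr$events$conc[pr$events$kind == "add_inhibitor"] == 5
  }, logical(1))))

  doses <- vapply(generate_protocol_suite("dose_series"), function(pr) {
    pr$events$conc[1]
  }, numeric(1))
  expect_setequal(doses, c(100, 500, 2000, 10000))

  pre <- generate_protocol_suite("inhibition_pre")
  gaps <- vapply(pre, function(pr) {
    pr$events$t[pr$events$kind == "add_agonist"] -
      pr$events$t[pr$events$kind == "add_inhibitor"]
  }, numeric(1))
  expect_equal(unname(range(gaps)), c(2, 180))

  pause <- generate_protocol_suite("stir_pause")[[1]]
  expect_true(all(c("stir_off", "stir_on") %in% pause$events$kind))
  expect_error(generate_protocol_suite("unknown"), "arg")
})
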