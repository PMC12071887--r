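test_that("an unstimulated population stays entirely at rest", {
  pr <- stimulus_protocol(t_end = 120)
  traj <- simulate_phenotypes(pr, fitted = zero_fitted, sample_dt = 1)
  expect_equal(traj$n_rest, rep(100, nrow(traj)))
  expect_equal(rowSums(traj[, c("n_sph", "n_gp", "n_agg", "n_exh", "n_inh")]),
               rep(0, nrow(traj)))
})

test_that("phenotype fractions are conserved and non-negative across protocols", {
  protocols <- list(
    stimulus_protocol(add_agonist(0, "ADP", 100), t_end = 200),
    stimulus_protocol(add_agonist(0, "ADP", 10000), t_end = 200),
    stimulus_protocol(add_agonist(0, "TRAP", 5000), t_end = 200),
    stimulus_protocol(add_agonist(0, "ADP", 5000),
                      add_inhibitor(30, "iloprost", 5), t_end = 250),
    stimulus_protocol(add_inhibitor(0, "iloprost", 0.2),
                      add_agonist(60, "ADP", 2000),
                      stir_off(120), stir_on(150), t_end = 300),
    stimulus_protocol(add_agonist(0, "ADP", 100),
                      add_agonist(120, "ADP", 2000), t_end = 300)
  )
  for (pr in protocols) {
    traj <- simulate_phenotypes(pr, sample_dt = 0.5)
    sums <- rowSums(traj[, c("n_rest", "n_sph", "n_gp", "n_agg", "n_exh", "n_inh")])
    expect_lt(max(abs(sums - 100)) / 100, 1e-6)
    expect_true(all(as.matrix(traj[, -1]) >= -1e-9))
  }
})

test_that("with only shape change active the rise matches the closed form", {
  pt <- isolated_param_table("k1")
  pr <- stimulus_protocol(add_agonist(0, "ADP", 46.8), stir_off(0), t_end = 60)
  traj <- simulate_phenotypes(pr, param_table = pt, fitted = zero_fitted,
                              sample_dt = 0.5)
  k1 <- 0.19 / 2 # half-maximal at the EC50 dose
  expect_equal(traj$n_sph, 100 * (1 - exp(-k1 * traj$t)), tolerance = 1e-6)
})

test_that("splitting a segment at an event-free time leaves the trajectory unchanged", {
  pr1 <- stimulus_protocol(add_agonist(0, "ADP", 2000), t_end = 200)
  # stir_on while already stirring is chemically a no-op but forces a restart
  pr2 <- stimulus_protocol(add_agonist(0, "ADP", 2000), stir_on(77.3), t_end = 200)
  t1 <- simulate_phenotypes(pr1, sample_dt = 1)
  t2 <- simulate_phenotypes(pr2, sample_dt = 1)
  for (col in names(t1)) expect_equal(t1[[col]], t2[[col]], tolerance = 1e-7)
})

test_that("protocol validation rejects malformed inputs", {
  expect_error(stimulus_protocol(add_agonist(400, "ADP", 100), t_end = 300),
               "outside")
  expect_error(stimulus_protocol(add_agonist(-5, "ADP", 100), t_end = 300),
               "outside")
  expect_error(add_agonist(0, "ADP", -10), "non-negative")
  expect_error(stimulus_protocol(t_end = -1), "positive")
  expect_error(simulate_phenotypes(stimulus_protocol(t_end = 10),
                                   init = c(n_rest = 60, n_sph = 20, n_gp = 0,
                                            n_agg = 0, n_exh = 0, n_inh = 0)),
               "sum to 100")
})

test_that("dose ordering: stronger ADP stimulation aggregates no less", {
  peak <- vapply(c(100, 1000, 10000), function(d) {
    max(simulate_phenotypes(stimulus_protocol(add_agonist(0, "ADP", d),
                                              t_end = 150),
                            sample_dt = 1)$n_agg)
  }, numeric(1))
  expect_true(all(diff(peak) >= 0))
})

test_that("observable channels reflect the phenotype composition", {
  # unstimulated: both channels flat at their baselines
  flat <- observables(simulate_phenotypes(stimulus_protocol(t_end = 30),
                                          fitted = zero_fitted, sample_dt = 1),
                      trace_map(baseline_lsi1 = 3, baseline_lsi12 = 7))
  expect_equal(flat$LSI1, rep(3, nrow(flat)))
  expect_equal(flat$LSI12, rep(7, nrow(flat)))

  # pure shape change (low dose, no aggregation): 12-degree rises, 1-degree flat
  low <- observables(simulate_phenotypes(
    stimulus_protocol(add_agonist(0, "ADP", 100), stir_off(0), t_end = 60),
    param_table = isolated_param_table("k1"), fitted = zero_fitted,
    sample_dt = 0.5))
  expect_gt(max(low$LSI12), 50)
  expect_equal(max(low$LSI1), 0)

  # full aggregation: 1-degree monotone rise, 12-degree falls after its peak
  high <- observables(simulate_phenotypes(
    stimulus_protocol(add_agonist(0, "ADP", 10000), t_end = 200),
    fitted = zero_fitted, sample_dt = 0.5))
  expect_true(all(diff(high$LSI1) >= -1e-9))
  i_pk <- which.max(high$LSI12)
  expect_lt(high$LSI12[nrow(high)], high$LSI12[i_pk])
})
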