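#' Measurement noise model for synthetic traces
#'
#' @param additive_sd Additive Gaussian SD in AU. The default used by
#'   [generate_trace()] is 1% of the channel range.
#' @param multiplicative_sd Multiplicative Gaussian SD as a fraction of the
#'   signal.
#' @param drift Linear baseline drift in AU/s.
#' @param seed Integer seed making generation reproducible.
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(additive_sd = NULL, multiplicative_sd = 0,
                        drift = 0, seed = 1) {
  if ((!is.null(additive_sd) && additive_sd < 0) || multiplicative_sd < 0) {
    stop("noise spreads must be non-negative", call. = FALSE)
  }
  structure(list(additive_sd = additive_sd,
                 multiplicative_sd = multiplicative_sd,
                 drift = drift, seed = as.integer(seed)),
            class = "noise_model")
}

apply_noise <- function(values, t, noise, channel_range) {
  add_sd <- noise$additive_sd %||% (0.01 * channel_range)
  values * (1 + stats::rnorm(length(values), 0, noise$multiplicative_sd)) +
    stats::rnorm(length(values), 0, add_sd) + noise$drift * t
}

#' Generate an instrument-like trace from a stimulation protocol
#'
#' Forward-simulates the phenotype model, maps the trajectory to scatter
#' channels and adds seeded measurement noise. The noiseless twin is kept in
#' the `ground_truth` attribute so estimator tests can quantify bias against
#' truth rather than against a noise realization.
#'
#' @inheritParams simulate_phenotypes
#' @param map_spec Channel map ([trace_map()]).
#' @param noise A [noise_model()]; pass `noise_model(additive_sd = 0, seed =
#'   s)` for a noiseless trace.
#' @return A `platelet_trace` tibble (`t`, `LSI1`, `LSI12`) with attributes
#'   `ground_truth` (noiseless trace), `events` and `seed`.
#' @export
generate_trace <- function(protocol,
                           param_table = platelet_params(),
                           fitted = default_fitted_constants(),
                           map_spec = trace_map(),
                           noise = noise_model(),
                           sample_dt = 0.1) {
  traj <- simulate_phenotypes(protocol, param_table = param_table,
                              fitted = fitted, sample_dt = sample_dt)
  clean <- observables(traj, map_spec)
  out <- clean
  set.seed(noise$seed)
  for (ch in c("LSI1", "LSI12")) {
    rng <- diff(range(clean[[ch]]))
    if (rng <= 0) rng <- 1
    out[[ch]] <- apply_noise(clean[[ch]], clean$t, noise, rng)
  }
  attr(out, "ground_truth") <- clean
  attr(out, "seed") <- noise$seed
  out
}

#' Generate a synthetic dose-response dataset from a Hill law
#'
#' @param params Generating [hill_params()].
#' @param doses Concentration grid; default 8 log-spaced points spanning one
#'   decade either side of the half-effect concentration.
#' @param noise_sd Multiplicative Gaussian noise fraction (0 for noiseless).
#' @param seed Integer seed.
#' @param response_kind Passed to [dose_response_dataset()].
#' @return A [dose_response_dataset()] with the noiseless responses in the
#'   `ground_truth` attribute.
#' @examples
#' generate_dose_response_dataset(hill_params(0.19, 46.8, 1.27))
#' @export
generate_dose_response_dataset <- function(params, doses = NULL,
                                           noise_sd = 0, seed = 1,
                                           response_kind = "k") {
  if (is.null(doses)) {
    doses <- 10^seq(log10(params$half_conc / 10), log10(params$half_conc * 10),
                    length.out = 8)
  }
  truth <- eval_hill(params, doses)
  set.seed(seed)
  resp <- truth * (1 + stats::rnorm(length(doses), 0, noise_sd))
  # the noise law is known here, so the per-point spread is recorded and
  # downstream fits can weight by inverse variance
  ds <- dose_response_dataset(
    doses, resp,
    sd = if (noise_sd > 0) noise_sd * truth else NULL,
    response_kind = response_kind, unit = params$unit
  )
  attr(ds, "ground_truth") <- truth
  attr(ds, "seed") <- as.integer(seed)
  ds
}

#' Standard stimulation-protocol suites
#'
#' Emits the protocol families of the laser-diffraction experiments the
#' model emulates, on their published delay and dose grids:
#'
#' * `"shape_change_delay"` — 100 nM ADP prime, then a high ADP dose
#'   (default 1000 nM) after delays of 60-360 s.
#' * `"stir_pause"` — high ADP with stirring halted at 20 s and resumed
#'   after pauses of 30-300 s.
#' * `"inhibition_pre"` — 5 nM iloprost added 180 to 2 s before 5000 nM ADP.
#' * `"disaggregation_post"` — 5 nM iloprost added 5, 30, 60, 120 or 180 s
#'   after 5000 nM ADP.
#' * `"dose_series"` — single additions of ADP at 100, 500, 2000 and
#'   10000 nM.
#'
#' @param kind Suite name, one of the above.
#' @param agonist_conc High ADP dose (nM) for the delay/pause suites.
#' @param t_end Horizon (s) appended after the last event, default 300.
#' @return Named list of [stimulus_protocol()]s.
#' @export
generate_protocol_suite <- function(kind = c("shape_change_delay", "stir_pause",
                                             "inhibition_pre",
                                             "disaggregation_post",
                                             "dose_series"),
                                    agonist_conc = 1000, t_end = 300) {
  kind <- match.arg(kind)
  switch(kind,
    shape_change_delay = {
      delays <- c(60, 120, 180, 240, 360)
      stats::setNames(lapply(delays, function(d) {
        stimulus_protocol(add_agonist(0, "ADP", 100),
                          add_agonist(d, "ADP", agonist_conc),
                          t_end = d + t_end)
      }), paste0("delay_", delays, "s"))
    },
    stir_pause = {
      pauses <- c(30, 60, 120, 180, 300)
      stats::setNames(lapply(pauses, function(p) {
        stimulus_protocol(add_agonist(0, "ADP", agonist_conc),
                          stir_off(20), stir_on(20 + p),
                          t_end = 20 + p + t_end)
      }), paste0("pause_", pauses, "s"))
    },
    inhibition_pre = {
      offsets <- c(180, 120, 60, 30, 10, 5, 2)
      stats::setNames(lapply(offsets, function(o) {
        stimulus_protocol(add_inhibitor(0, "iloprost", 5),
                          add_agonist(o, "ADP", 5000),
                          t_end = o + t_end)
      }), paste0("pre_", offsets, "s"))
    },
    disaggregation_post = {
      offsets <- c(5, 30, 60, 120, 180)
      stats::setNames(lapply(offsets, function(o) {
        stimulus_protocol(add_agonist(0, "ADP", 5000),
                          add_inhibitor(o, "iloprost", 5),
                          t_end = o + t_end)
      }), paste0("post_", offsets, "s"))
    },
    dose_series = {
      doses <- c(100, 500, 2000, 10000)
      stats::setNames(lapply(doses, function(d) {
        stimulus_protocol(add_agonist(0, "ADP", d), t_end = t_end)
      }), paste0("ADP_", doses, "nM"))
    }
  )
}
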