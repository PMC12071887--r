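#' Simulate platelet phenotype dynamics under a stimulation protocol
#'
#' Integrates the six-state phenotype-transition system
#' \deqn{dN_{rest}/dt = k_{-4}N_{inh} + k_{-1}N_{exh} - k_4 N_{rest} - k_1 N_{rest}}
#' \deqn{dN_{sph}/dt  = k_1 N_{rest} - k_2 N_{sph} - k_5 N_{sph}}
#' \deqn{dN_{gp}/dt   = k_2 N_{sph} - k_3 N_{gp}^2 - k_6 N_{gp}}
#' \deqn{dN_{agg}/dt  = k_3 N_{gp}^2 - k_7 N_{agg}}
#' \deqn{dN_{exh}/dt  = k_5 N_{sph} + k_6 N_{gp} + k_7 N_{agg} - k_{-1} N_{exh}}
#' \deqn{dN_{inh}/dt  = k_4 N_{rest} - k_{-4} N_{inh}}
#' where each `N` is a percentage of the platelet population, all transitions
#' are first order except aggregation (`k3`, second order in the
#' integrin-activated fraction). Rate constants are reassembled from the Hill
#' laws of `param_table` at every protocol event (concentrations are step
#' functions; the integrator restarts at each event). An added inhibitor's
#' effect develops gradually: per pathway (shape change, aggregation) an
#' effect level `e(t)` relaxes first order toward the inhibitor's Hill
#' occupancy at its onset rate, and the non-competitive factor on the forward
#' constants is evaluated at the effective concentration `e(t) * I`.
#' Disaggregation (`k7`, scaled by inhibitor occupancy) is active only while
#' inhibitor is present within 180 s of the most recent agonist addition;
#' beyond that window aggregation is irreversible.
#'
#' @param protocol A [stimulus_protocol()].
#' @param param_table Dose-response parameter table ([platelet_params()]).
#' @param fitted Named vector of the trajectory-fitted constants
#'   `k_m1`, `k_m4`, `k7` ([default_fitted_constants()]).
#' @param init Optional initial phenotype fractions (named, percent, summing
#'   to 100); default all platelets resting.
#' @param sample_dt Output sampling interval (s), default 0.1.
#' @param rtol,atol Relative/absolute solver tolerances (stiff-capable
#'   adaptive integrator).
#' @param disagg_window Duration (s) after an agonist addition during which
#'   inhibitor-driven disaggregation can occur; default 180.
#'
#' @return A `platelet_trajectory`: tibble with columns `t`, `n_rest`,
#'   `n_sph`, `n_gp`, `n_agg`, `n_exh`, `n_inh` (percent), carrying the
#'   protocol and parameters as attributes.
#' @examples
#' pr <- stimulus_protocol(add_agonist(0, "ADP", 5000), t_end = 60)
#' traj <- simulate_phenotypes(pr, sample_dt = 1)
#' range(rowSums(traj[, -1])) # conservation: 100 everywhere
#' @export
simulate_phenotypes <- function(protocol,
                                param_table = platelet_params(),
                                fitted = default_fitted_constants(),
                                init = NULL,
                                sample_dt = 0.1,
                                rtol = 1e-8, atol = 1e-10,
                                disagg_window = 180) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  pheno <- c("n_rest", "n_sph", "n_gp", "n_agg", "n_exh", "n_inh")
  if (is.null(init)) {
    y0 <- stats::setNames(c(100, 0, 0, 0, 0, 0), pheno)
  } else {
    if (!all(pheno %in% names(init))) {
      stop("`init` must name all six phenotype fractions", call. = FALSE)
    }
    y0 <- init[pheno]
    if (abs(sum(y0) - 100) > 1e-6 || any(y0 < 0)) {
      stop("`init` fractions must be non-negative and sum to 100", call. = FALSE)
    }
  }
  inh_species <- unique(protocol$events$species[protocol$events$kind == "add_inhibitor"])
  e_names <- if (length(inh_species) > 0L) {
    c(paste0("e_sc.", inh_species), paste0("e_agg.", inh_species))
  } else character()
  y0 <- c(y0, stats::setNames(rep(0, length(e_names)), e_names))

  agonist_times <- protocol$events$t[protocol$events$kind == "add_agonist"]
  breaks <- sort(unique(c(0, protocol$events$t,
                          agonist_times + disagg_window, protocol$t_end)))
  breaks <- breaks[breaks >= 0 & breaks <= protocol$t_end]
  grid <- seq(0, protocol$t_end, by = sample_dt)

  out_t <- numeric(0)
  out_y <- NULL
  y <- y0
  for (i in seq_len(length(breaks) - 1L)) {
    t0 <- breaks[i]; t1 <- breaks[i + 1L]
    if (t1 - t0 < 1e-12) next
    cond <- protocol_condition(protocol, t0)
    seg <- make_segment_rhs(cond, param_table, fitted, inh_species,
                            t0, disagg_window)
    times <- unique(c(t0, grid[grid > t0 + 1e-12 & grid <= t1 + 1e-12], t1))
    sol <- deSolve::lsoda(y = y, times = times, func = seg$rhs, parms = NULL,
                          rtol = rtol, atol = atol)
    if (any(!is.finite(sol[, -1])) || nrow(sol) < length(times)) {
      last_ok <- sol[stats::complete.cases(sol), , drop = FALSE]
      stop("integration error in segment [", t0, ", ", t1, "] s; last valid t = ",
           if (nrow(last_ok)) last_ok[nrow(last_ok), 1] else t0, call. = FALSE)
    }
    y <- sol[nrow(sol), -1]
    keep <- sol[, 1] %in% grid & !(sol[, 1] %in% out_t)
    out_t <- c(out_t, sol[keep, 1])
    out_y <- rbind(out_y, sol[keep, -1, drop = FALSE])
  }

  frac <- out_y[, pheno, drop = FALSE]
  frac[frac < 0 & frac > -1e-6] <- 0 # clip solver-level negatives for reporting
  traj <- tibble::as_tibble(as.data.frame(frac))
  traj <- dplyr::bind_cols(tibble::tibble(t = out_t), traj)
  structure(traj,
            class = c("platelet_trajectory", class(traj)),
            protocol = protocol, param_table = param_table, fitted = fitted)
}

# Build the right-hand side for one event-free segment. The chemical
# condition (concentrations, stirring, disaggregation window) is constant
# within a segment; only the inhibitor effect levels evolve as states.
# All Hill terms are reduced to precomputed scalars so the inner function
# does plain positional arithmetic (it runs thousands of times per fit).
make_segment_rhs <- function(cond, param_table, fitted, inh_species,
                             t0, disagg_window) {
  base <- assemble_rate_constants(
    agonist_concs = cond$agonists,
    inhibitor_concs = cond$inhibitors,
    inhibitor_exposure = lapply(cond$inhibitors, function(x) c(sc = 1, agg = 1)),
    param_table = param_table, stirring = cond$stirring, fitted = fitted
  )
  # agonist-side forward constants without the inhibitor factor (reapplied
  # per time step from the evolving effect levels)
  nofit <- assemble_rate_constants(cond$agonists, numeric(), NULL,
                                   param_table, cond$stirring, fitted)
  k1a <- nofit[["k1"]]; k2a <- nofit[["k2"]]

  nsp <- length(inh_species)
  conc <- ich_sc <- h_sc <- ich_ag <- h_ag <- occ_sc <- occ_ag <-
    on_sc <- on_ag <- numeric(nsp)
  has_sc <- has_ag <- logical(nsp)
  for (j in seq_len(nsp)) {
    sp <- inh_species[j]
    conc[j] <- if (sp %in% names(cond$inhibitors)) cond$inhibitors[[sp]] else 0
    p_sc <- lookup_hill(param_table, "inh_sc", sp)
    p_ag <- lookup_hill(param_table, "inh_agg", sp)
    has_sc[j] <- !is.null(p_sc); has_ag[j] <- !is.null(p_ag)
    if (has_sc[j]) {
      ich_sc[j] <- p_sc$half_conc^p_sc$h; h_sc[j] <- p_sc$h
      occ_sc[j] <- if (conc[j] > 0) hill_occupancy(conc[j], p_sc) else 0
    }
    if (has_ag[j]) {
      ich_ag[j] <- p_ag$half_conc^p_ag$h; h_ag[j] <- p_ag$h
      occ_ag[j] <- if (conc[j] > 0) hill_occupancy(conc[j], p_ag) else 0
    }
    on_sc[j] <- lookup_onset(param_table, "sc", sp)
    on_ag[j] <- lookup_onset(param_table, "agg", sp)
  }
  occ_agg_total <- if (nsp > 0L) min(1, sum(occ_ag)) else 0
  k7_active <- length(cond$inhibitors) > 0L && !is.na(cond$last_agonist) &&
    t0 < cond$last_agonist + disagg_window - 1e-9
  k7_eff <- if (k7_active) fitted[["k7"]] * occ_agg_total else 0
  k_m4 <- base[["k_m4"]]; k_m1 <- base[["k_m1"]]
  k3 <- base[["k3"]]; k4 <- base[["k4"]]; k5 <- base[["k5"]]; k6 <- base[["k6"]]
  i_sc <- 6L + 2L * seq_len(nsp) - 1L
  i_ag <- i_sc + 1L

  rhs <- function(t, y, parms) {
    f_sc <- 1; f_agg <- 1
    d_e <- numeric(2L * nsp)
    for (j in seq_len(nsp)) {
      esc <- y[i_sc[j]]; eag <- y[i_ag[j]]
      if (conc[j] > 0) {
        if (has_sc[j]) f_sc <- f_sc * ich_sc[j] / (ich_sc[j] + (esc * conc[j])^h_sc[j])
        if (has_ag[j]) f_agg <- f_agg * ich_ag[j] / (ich_ag[j] + (eag * conc[j])^h_ag[j])
      }
      d_e[2L * j - 1L] <- on_sc[j] * (occ_sc[j] - esc)
      d_e[2L * j] <- on_ag[j] * (occ_ag[j] - eag)
    }
    k1 <- k1a * f_sc
    k2 <- k2a * f_agg
    gp2 <- k3 * y[3L]^2
    d <- c(
      k_m4 * y[6L] + k_m1 * y[5L] - (k4 + k1) * y[1L],
      k1 * y[1L] - (k2 + k5) * y[2L],
      k2 * y[2L] - gp2 - k6 * y[3L],
      gp2 - k7_eff * y[4L],
      k5 * y[2L] + k6 * y[3L] + k7_eff * y[4L] - k_m1 * y[5L],
      k4 * y[1L] - k_m4 * y[6L]
    )
    list(c(d, d_e))
  }
  list(rhs = rhs)
}

#' Map a phenotype trajectory to instrument-like scatter channels
#'
#' Low-angle laser diffraction reads aggregation as a rise in scatter
#' intensity at 1 degree and shape change as a rise at 12 degrees. The map is
#' affine: `LSI1 = baseline + gain * n_agg`,
#' `LSI12 = baseline + gain * (n_sph + n_gp)` (sphered and integrin-activated
#' platelets are both spherical and scatter alike at 12 degrees).
#'
#' @param traj A `platelet_trajectory` from [simulate_phenotypes()].
#' @param map_spec Channel map from [trace_map()].
#' @return A `platelet_trace` tibble with columns `t`, `LSI1`, `LSI12`,
#'   carrying the protocol's event times in the `events` attribute.
#' @export
observables <- function(traj, map_spec = trace_map()) {
  stopifnot(inherits(traj, "platelet_trajectory"))
  tr <- tibble::tibble(
    t = traj$t,
    LSI1 = map_spec$baseline_lsi1 + map_spec$gain_lsi1 * traj$n_agg,
    LSI12 = map_spec$baseline_lsi12 + map_spec$gain_lsi12 * (traj$n_sph + traj$n_gp)
  )
  protocol <- attr(traj, "protocol")
  structure(tr, class = c("platelet_trace", class(tr)),
            events = if (!is.null(protocol)) protocol$events else NULL)
}

#' Channel map specification for [observables()]
#'
#' @param baseline_lsi1,baseline_lsi12 Channel baselines (AU).
#' @param gain_lsi1,gain_lsi12 Channel gains (AU per percent).
#' @return A list of class `trace_map`.
#' @export
trace_map <- function(baseline_lsi1 = 0, gain_lsi1 = 1,
                      baseline_lsi12 = 0, gain_lsi12 = 1) {
  vals <- c(baseline_lsi1, gain_lsi1, baseline_lsi12, gain_lsi12)
  if (any(!is.finite(vals))) stop("trace_map values must be finite", call. = FALSE)
  structure(list(baseline_lsi1 = baseline_lsi1, gain_lsi1 = gain_lsi1,
                 baseline_lsi12 = baseline_lsi12, gain_lsi12 = gain_lsi12),
            class = "trace_map")
}
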