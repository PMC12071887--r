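#' Build a desensitization decay dataset
#'
#' Records the decline of the restimulation aggregation response with the
#' delay imposed between a priming condition and the aggregating stimulus:
#' either a low-dose shape-change prime followed by high-dose ADP
#' (`"shape_change_delay"`, probing exit from the sphered state) or a
#' stir pause after high-dose ADP (`"stir_pause"`, probing integrin
#' deactivation).
#'
#' @param delays Wait durations (s), strictly increasing, >= 0.
#' @param responses Initial aggregation rate normalized to the zero-delay
#'   control (%); the response at delay 0 is 100 by definition.
#' @param agonist_conc ADP concentration (nM) of the aggregating stimulus.
#' @param protocol_kind `"shape_change_delay"` or `"stir_pause"`.
#' @return A tibble of class `decay_dataset`.
#' @export
decay_dataset <- function(delays, responses, agonist_conc,
                          protocol_kind = c("shape_change_delay", "stir_pause")) {
  protocol_kind <- match.arg(protocol_kind)
  if (any(delays < 0) || is.unsorted(delays, strictly = TRUE)) {
    stop("delays must be non-negative and strictly increasing", call. = FALSE)
  }
  if (length(responses) != length(delays) || any(!is.finite(responses))) {
    stop("responses must be finite and match delays in length", call. = FALSE)
  }
  ds <- tibble::tibble(delay = delays, response = responses)
  structure(ds, class = c("decay_dataset", class(ds)),
            agonist_conc = agonist_conc, protocol_kind = protocol_kind)
}

#' Estimate a desensitization rate constant from delayed responses
#'
#' Assumes first-order decay of responsiveness with delay time,
#' `response(delay) = 100 * exp(-k * delay)` (anchored at the zero-delay
#' control, 100%), and estimates `k` by least squares.
#'
#' @param ds A [decay_dataset()] or data frame with columns `delay`,
#'   `response`.
#' @return List with `k` (1/s) and `r2`. `k = 0` with an `"all_control"`
#'   flag when responses never fall below control.
#' @examples
#' d <- decay_dataset(c(60, 180, 360), 100 * exp(-0.0019 * c(60, 180, 360)), 1000)
#' fit_decay_constant(d)$k
#' @export
fit_decay_constant <- function(ds) {
  if (nrow(ds) < 3L) stop("need at least 3 delays", call. = FALSE)
  delay <- ds$delay
  y <- ds$response
  if (all(abs(y - 100) < 1e-9)) {
    return(list(k = 0, r2 = 1, flags = "all_control"))
  }
  ord <- order(delay)
  if (all(diff(y[ord]) > 0)) {
    stop("model mismatch: responses rise with delay; first-order decay cannot apply",
         call. = FALSE)
  }
  # log-linear start, then bounded nonlinear refinement
  pos <- y > 0
  k0 <- if (sum(pos) >= 2L) {
    max(1e-8, -unname(stats::coef(stats::lm(log(y[pos] / 100) ~ 0 + delay[pos]))[1L]))
  } else 0.01
  df <- data.frame(delay = delay, y = y)
  fit <- minpack.lm::nlsLM(y ~ 100 * exp(-k * delay), data = df,
                           start = list(k = k0), lower = c(k = 0),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  res <- stats::resid(fit)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(res^2) / ss_tot else 1
  list(k = unname(stats::coef(fit)[["k"]]), r2 = r2, flags = character())
}

#' Half-time of a first-order process
#'
#' @param k First-order rate constant (1/s), > 0.
#' @return `ln(2) / k` in seconds.
#' @examples
#' half_time(0.0019) # ~365 s
#' @export
half_time <- function(k) {
  if (any(!is.finite(k)) || any(k <= 0)) {
    stop("`k` must be positive and finite", call. = FALSE)
  }
  log(2) / k
}

#' Agonist dose-dependence of a desensitization constant
#'
#' Chains [fit_decay_constant()] over decay datasets collected at different
#' agonist concentrations, then fits the inhibitory Hill law to the
#' (concentration, k) pairs: higher agonist doses protect against
#' desensitization, so `k` falls with dose from its maximum `k_max`.
#'
#' @param datasets List of [decay_dataset()]s at distinct agonist
#'   concentrations (>= 3 levels).
#' @return A `hill_fit` (inhibition mode) carrying the intermediate
#'   constants in its `data`; if the decay constants are identical across
#'   doses, the Hill coefficient is unidentifiable and the fit is flagged.
#' @export
dose_dependence_of_decay <- function(datasets) {
  if (length(datasets) < 3L) stop("need decay datasets at >= 3 agonist levels",
                                  call. = FALSE)
  concs <- purrr::map_dbl(datasets, ~ attr(.x, "agonist_conc"))
  ks <- purrr::map_dbl(datasets, ~ fit_decay_constant(.x)$k)
  if (stats::sd(ks) < 1e-14 * max(ks, 1e-300)) {
    fit <- fit_hill(dose_response_dataset(concs, ks, response_kind = "k"),
                    mode = "inhibition")
    fit$flags <- unique(c(fit$flags, "h_unidentifiable"))
    fit$ok <- FALSE
    return(fit)
  }
  fit_hill(dose_response_dataset(concs, ks, response_kind = "k"),
           mode = "inhibition")
}
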