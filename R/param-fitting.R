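#' Coefficient of determination between two aligned series
#'
#' `R2 = 1 - SS_res / SS_tot`, with the observed series defining the total
#' sum of squares. Can be negative for predictions worse than the observed
#' mean.
#'
#' @param observed,predicted Equal-length numeric vectors.
#' @return Value in `(-Inf, 1]`.
#' @export
r_squared <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    stop("observed and predicted must have equal length", call. = FALSE)
  }
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) stop("R-squared undefined for a zero-variance observed series",
                        call. = FALSE)
  1 - sum((observed - predicted)^2) / ss_tot
}

#' Define a trajectory-fitting problem
#'
#' Bundles the constants to estimate (with bounds), the fixed dose-response
#' parameter table, and the observed traces with the protocols that produced
#' them. The loss is the sum over traces and channels of squared residuals
#' after per-channel range normalization (so a 100-AU aggregation channel
#' and a 30-AU shape-change channel weigh equally).
#'
#' @param free Named list of `c(lower, upper)` bounds for the free constants
#'   (subset of `k_m1`, `k_m4`, `k7`); may be empty.
#' @param observations List of `list(protocol = , trace = )` pairs; each
#'   trace needs columns `t`, `LSI1`, `LSI12` sampled on the grid the
#'   simulation will use.
#' @param param_table Fixed dose-response table ([platelet_params()]).
#' @param fixed Values for the non-free fitted constants.
#' @param map_spec Channel map used to predict traces ([trace_map()]).
#' @param sample_dt Simulation output grid (s); must match the traces.
#' @return A list of class `fit_problem`.
#' @export
fit_problem <- function(free, observations,
                        param_table = platelet_params(),
                        fixed = default_fitted_constants(),
                        map_spec = trace_map(),
                        sample_dt = 1) {
  if (length(free) > 0L) {
    bad <- purrr::map_lgl(free, ~ length(.x) != 2L || any(!is.finite(.x)) ||
                            any(.x <= 0) || .x[1] >= .x[2])
    if (any(bad)) stop("each free-parameter bound must be a positive finite c(lower, upper)",
                       call. = FALSE)
    if (!all(names(free) %in% c("k_m1", "k_m4", "k7"))) {
      stop("free parameters must be among k_m1, k_m4, k7", call. = FALSE)
    }
  }
  structure(list(free = free, observations = observations,
                 param_table = param_table, fixed = fixed,
                 map_spec = map_spec, sample_dt = sample_dt),
            class = "fit_problem")
}

problem_loss <- function(problem, values) {
  fitted <- problem$fixed
  fitted[names(values)] <- values
  total <- 0
  for (obs in problem$observations) {
    pred <- observables(
      simulate_phenotypes(obs$protocol, param_table = problem$param_table,
                          fitted = fitted, sample_dt = problem$sample_dt,
                          rtol = 1e-5, atol = 1e-7),
      problem$map_spec
    )
    for (ch in c("LSI1", "LSI12")) {
      yo <- obs$trace[[ch]]
      yp <- pred[[ch]][match(round(obs$trace$t, 9), round(pred$t, 9))]
      rng <- diff(range(yo))
      if (rng <= 0) rng <- 1
      total <- total + sum(((yo - yp) / rng)^2)
    }
  }
  total
}

#' Estimate experimentally inaccessible constants by trajectory fitting
#'
#' The recovery constants `k_m1` (exhausted to resting), `k_m4` (inhibited to
#' resting) and the disaggregation constant `k7` cannot be read from
#' light-scatter traces directly, because the scatter signatures of resting,
#' inhibited and exhausted platelets overlap. They are estimated by matching
#' simulated observables to observed traces: a seeded stochastic global stage
#' (multi-start in log-parameter space with basin-hop-style perturbations)
#' followed by a bounded quasi-Newton polish (L-BFGS-B on log10 parameters
#' with numerical gradients).
#'
#' @param problem A [fit_problem()].
#' @param global_iters Number of hop perturbations per start, default 4.
#' @param n_starts Number of independent starts, default 3.
#' @param seed Integer seed; identical seed and inputs reproduce the result.
#' @param step Log10 step size of the hop perturbations, default 0.5.
#' @return A `platelet_fit` object: list with `estimates` (named vector),
#'   `r2` (per observation, on the aggregation channel), `loss`,
#'   `loss_trace` (loss after each accepted hop), `identifiability`
#'   (per-parameter relative loss rise when the parameter is pushed to its
#'   bounds; near-zero values flag unidentifiable parameters) and
#'   `convergence`.
#' @export
fit_model <- function(problem, global_iters = 4, n_starts = 3, seed = 1,
                      step = 0.5) {
  stopifnot(inherits(problem, "fit_problem"))
  free <- problem$free
  if (length(free) == 0L) {
    est <- problem$fixed
    r2 <- obs_r2(problem, numeric())
    return(structure(list(estimates = est, r2 = r2,
                          loss = problem_loss(problem, numeric()),
                          loss_trace = numeric(), identifiability = numeric(),
                          convergence = 0L, seed = seed),
                     class = "platelet_fit"))
  }
  set.seed(seed)
  nm <- names(free)
  lo <- log10(purrr::map_dbl(free, 1))
  hi <- log10(purrr::map_dbl(free, 2))
  obj <- function(lp) problem_loss(problem, stats::setNames(10^lp, nm))

  local_polish <- function(lp0) {
    stats::optim(lp0, obj, method = "L-BFGS-B", lower = lo, upper = hi,
                 control = list(maxit = 25, factr = 1e11))
  }
  best <- NULL
  loss_trace <- numeric()
  for (s in seq_len(n_starts)) {
    lp <- stats::runif(length(nm), lo, hi)
    res <- local_polish(lp)
    if (is.null(best) || res$value < best$value) best <- res
    loss_trace <- c(loss_trace, res$value)
    cur <- res
    for (g in seq_len(global_iters)) {
      lp_new <- pmin(hi, pmax(lo, cur$par + stats::rnorm(length(nm), 0, step)))
      res_new <- local_polish(lp_new)
      # greedy (zero-temperature) acceptance of hops
      if (res_new$value < cur$value) cur <- res_new
      if (cur$value < best$value) best <- cur
      loss_trace <- c(loss_trace, cur$value)
    }
  }
  est_free <- stats::setNames(10^best$par, nm)
  est <- problem$fixed
  est[nm] <- est_free

  # identifiability: relative loss increase when each parameter is pushed to
  # its bound with the others held at the optimum
  ident <- purrr::map_dbl(seq_along(nm), function(j) {
    probe <- function(v) {
      lp <- best$par; lp[j] <- v; obj(lp)
    }
    base <- best$value
    max(probe(lo[j]), probe(hi[j])) / max(base, 1e-12) - 1
  })
  names(ident) <- nm

  structure(list(estimates = est, r2 = obs_r2(problem, est_free),
                 loss = best$value, loss_trace = loss_trace,
                 identifiability = ident,
                 convergence = best$convergence, seed = seed),
            class = "platelet_fit")
}

obs_r2 <- function(problem, values) {
  fitted <- problem$fixed
  fitted[names(values)] <- values
  purrr::map_dbl(problem$observations, function(obs) {
    pred <- observables(
      simulate_phenotypes(obs$protocol, param_table = problem$param_table,
                          fitted = fitted, sample_dt = problem$sample_dt,
                          rtol = 1e-5, atol = 1e-7),
      problem$map_spec
    )
    yp <- pred$LSI1[match(round(obs$trace$t, 9), round(pred$t, 9))]
    if (stats::sd(obs$trace$LSI1) == 0) NA_real_ else r_squared(obs$trace$LSI1, yp)
  })
}

#' @export
print.platelet_fit <- function(x, ...) {
  cat("<platelet_fit>\n  estimates:\n")
  print(round(x$estimates, 6))
  cat(sprintf("  loss = %.5g; per-trace R2 (LSI1): %s\n",
              x$loss, paste(round(x$r2, 4), collapse = ", ")))
  if (length(x$identifiability)) {
    flat <- names(x$identifiability)[x$identifiability < 0.01]
    if (length(flat)) cat("  possibly unidentifiable:", paste(flat, collapse = ", "), "\n")
  }
  invisible(x)
}
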