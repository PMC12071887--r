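#' Build a dose-response dataset
#'
#' @param doses Concentrations (>= 0), any single unit.
#' @param responses Rate constants (1/s) or normalized readouts (%), same
#'   length as `doses`.
#' @param sd Optional per-point spread (same unit as responses).
#' @param n Optional replicate counts.
#' @param response_kind What the responses are: `"k"`, `"Vsh"`, `"Vagg"` or
#'   `"AUCagg"`.
#' @param unit Dose unit label.
#' @return A tibble of class `dose_response_dataset`.
#' @export
dose_response_dataset <- function(doses, responses, sd = NULL, n = NULL,
                                  response_kind = c("k", "Vsh", "Vagg", "AUCagg"),
                                  unit = "nM") {
  response_kind <- match.arg(response_kind)
  check_conc(doses)
  if (length(responses) != length(doses) || any(!is.finite(responses))) {
    stop("responses must be finite and match doses in length", call. = FALSE)
  }
  ds <- tibble::tibble(
    dose = doses, response = responses,
    sd = if (is.null(sd)) NA_real_ else sd,
    n = if (is.null(n)) NA_integer_ else n
  )
  structure(ds, class = c("dose_response_dataset", class(ds)),
            response_kind = response_kind, unit = unit)
}

#' Fit a Hill dose-response law
#'
#' Weighted nonlinear least squares of the activating
#' (`k = k_max A^h / (EC50^h + A^h)`) or inhibitory
#' (`k = k_max IC50^h / (IC50^h + I^h)`) Hill law to a dose-response
#' dataset, over `(k_max, half_conc, h)` or with `k_max` fixed. Hill fits
#' have notoriously flat valleys in `half_conc`, so the optimizer is
#' multi-started from five log-spaced half-effect seeds; `half_conc` is
#' bounded to `[min dose / 100, max dose * 100]` and `h` to `[0.3, 10]`.
#' Weights are inverse-variance when `sd` is supplied, else uniform.
#'
#' @param ds A [dose_response_dataset()], or a data frame with columns
#'   `dose` and `response`.
#' @param mode `"activation"` or `"inhibition"`.
#' @param fix_kmax Optional fixed value for `k_max` (then only two
#'   parameters are free and 3 distinct doses suffice).
#' @return A `hill_fit` object: list with `params` (a [hill_params()]),
#'   `stderr` (named), `r2`, `ok`, `flags` (character, e.g. boundary or
#'   saturation warnings) and `data`.
#' @examples
#' p <- hill_params(0.19, 46.8, 1.27)
#' d <- 10^seq(log10(4.68), log10(468), length.out = 8)
#' fit_hill(dose_response_dataset(d, eval_hill(p, d)), mode = "activation")
#' @export
fit_hill <- function(ds, mode = c("activation", "inhibition"), fix_kmax = NULL) {
  mode <- match.arg(mode)
  doses <- ds$dose
  y <- ds$response
  n_distinct <- length(unique(doses))
  n_free <- if (is.null(fix_kmax)) 3L else 2L
  if (n_distinct < n_free) {
    stop("under-determined fit: need at least ", n_free,
         " distinct doses for ", n_free, " free parameters", call. = FALSE)
  }
  flags <- character()
  pos <- doses[doses > 0]
  lo_hc <- min(pos) / 100
  hi_hc <- max(pos) * 100
  # saturated data: responses flat at the top of the law
  if (stats::sd(y) < 1e-12 * max(abs(y), 1)) {
    flags <- c(flags, if (mode == "activation") "ec50_at_lower_boundary" else "ic50_at_upper_boundary")
    hc <- if (mode == "activation") lo_hc else hi_hc
    p <- hill_params(max(mean(y), 1e-12), hc, 1, mode = mode,
                     unit = attr(ds, "unit") %||% "nM")
    return(structure(list(params = p,
                          stderr = c(k_max = NA, half_conc = NA, h = NA),
                          r2 = 1, ok = TRUE, flags = flags, data = ds),
                     class = "hill_fit"))
  }
  # monotonicity sanity check relative to mode
  ord <- order(doses)
  rough <- stats::cor(doses[ord], y[ord], method = "spearman")
  if (is.finite(rough) &&
      ((mode == "activation" && rough < 0) || (mode == "inhibition" && rough > 0))) {
    warning("responses trend against the requested mode; fit proceeds",
            call. = FALSE)
    flags <- c(flags, "mode_mismatch")
  }
  w <- if (all(is.finite(ds$sd)) && !all(is.na(ds$sd)) && all(ds$sd > 0, na.rm = TRUE)) {
    1 / ds$sd^2
  } else {
    rep(1, length(y))
  }

  model <- function(kmax, hc, h) {
    if (mode == "activation") {
      ah <- doses^h
      r <- kmax * ah / (hc^h + ah)
      r[doses == 0] <- 0
      r
    } else {
      kmax * hc^h / (hc^h + doses^h)
    }
  }
  df <- data.frame(doses = doses, y = y, w = w)
  seeds <- 10^seq(log10(lo_hc * 10), log10(hi_hc / 10), length.out = 5)
  kmax0 <- if (is.null(fix_kmax)) max(abs(y)) else fix_kmax
  best <- NULL
  for (hc0 in seeds) {
    fit <- tryCatch({
      if (is.null(fix_kmax)) {
        minpack.lm::nlsLM(
          y ~ model(kmax, hc, h), data = df, weights = w,
          start = list(kmax = kmax0, hc = hc0, h = 1.5),
          lower = c(kmax = 1e-12, hc = lo_hc, h = 0.3),
          upper = c(kmax = Inf, hc = hi_hc, h = 10),
          control = minpack.lm::nls.lm.control(maxiter = 300)
        )
      } else {
        kmax <- fix_kmax
        minpack.lm::nlsLM(
          y ~ model(kmax, hc, h), data = df, weights = w,
          start = list(hc = hc0, h = 1.5),
          lower = c(hc = lo_hc, h = 0.3), upper = c(hc = hi_hc, h = 10),
          control = minpack.lm::nls.lm.control(maxiter = 300)
        )
      }
    }, error = function(e) NULL)
    if (!is.null(fit)) {
      ssr <- sum(w * stats::resid(fit)^2)
      if (is.null(best) || ssr < best$ssr) best <- list(fit = fit, ssr = ssr)
    }
  }
  if (is.null(best)) stop("Hill fit failed from all starting points", call. = FALSE)
  est <- stats::coef(best$fit)
  kmax_hat <- if (is.null(fix_kmax)) unname(est[["kmax"]]) else fix_kmax
  hc_hat <- unname(est[["hc"]])
  h_hat <- unname(est[["h"]])
  if (hc_hat <= lo_hc * 1.0001) flags <- c(flags, "half_conc_at_lower_boundary")
  if (hc_hat >= hi_hc * 0.9999) flags <- c(flags, "half_conc_at_upper_boundary")
  se <- tryCatch({
    s <- summary(best$fit)$coefficients[, "Std. Error"]
    c(k_max = if (is.null(fix_kmax)) unname(s["kmax"]) else NA_real_,
      half_conc = unname(s["hc"]), h = unname(s["h"]))
  }, error = function(e) c(k_max = NA_real_, half_conc = NA_real_, h = NA_real_))
  res <- stats::resid(best$fit)
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  structure(
    list(params = hill_params(kmax_hat, hc_hat, h_hat, mode = mode,
                              unit = attr(ds, "unit") %||% "nM"),
         stderr = se, r2 = r2, ok = length(flags) == 0L, flags = flags,
         data = ds),
    class = "hill_fit"
  )
}

#' @export
print.hill_fit <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "<hill_fit> mode=%s: k_max = %.5g, %s = %.5g %s, h = %.3g, R2 = %.5f\n",
    p$mode, p$k_max, if (p$mode == "activation") "EC50" else "IC50",
    p$half_conc, p$unit, p$h, x$r2))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
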