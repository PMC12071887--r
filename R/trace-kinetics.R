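#' Fit a monoexponential saturation to a trace channel
#'
#' The rise of a light-scatter channel at a saturating agonist dose follows
#' `I(t) = Im - (Im - Io) * exp(-k * (t - t0))`, whose rate constant `k` is
#' the transition constant of the underlying reaction (shape change on the
#' 12-degree channel, integrin activation/aggregation on the 1-degree
#' channel). Fitted by nonlinear least squares with analytic gradients,
#' initialized at `Im = max(I)`, `Io = I(t0)` and `k = ln 2 /` time to
#' half-range.
#'
#' @param trace A trace tibble with column `t` and the named channel
#'   (e.g. from [observables()] or [read_trace()]).
#' @param channel Channel column name, e.g. `"LSI12"`.
#' @param window Optional `c(t0, t1)` fit window (s); default the whole
#'   trace. The onset is taken at `t0`.
#' @param r2_floor Fits with a coefficient of determination below this are
#'   flagged (`ok = FALSE`), default 0.5.
#' @param noise_floor Signal ranges below this (AU) are rejected as
#'   degenerate; default `1e-9 * max(|I|, 1)`.
#'
#' @return An `exp_fit` object: list with `k`, `i_m`, `i_o` (estimates),
#'   `stderr_k`, `r2`, `ok`, `window`, `channel`. [tidy()][tidy.exp_fit] and
#'   [glance()][glance.exp_fit] methods are provided.
#' @examples
#' t <- seq(0, 60, 0.1)
#' tr <- tibble::tibble(t = t, LSI12 = 100 * (1 - exp(-0.19 * t)))
#' fit_exponential_rise(tr, "LSI12")$k
#' @export
fit_exponential_rise <- function(trace, channel, window = NULL,
                                 r2_floor = 0.5, noise_floor = NULL) {
  y_all <- get_channel(trace, channel)
  t_all <- trace$t
  if (is.null(window)) window <- range(t_all)
  sel <- t_all >= window[1] & t_all <= window[2]
  if (sum(sel) < 10L) stop("fit window must contain at least 10 samples", call. = FALSE)
  tt <- t_all[sel] - window[1]
  y <- y_all[sel]
  if (is.null(noise_floor)) noise_floor <- 1e-9 * max(abs(y), 1)
  if (diff(range(y)) < noise_floor) {
    stop("degenerate fit: channel '", channel, "' is flat within the noise floor",
         call. = FALSE)
  }
  io0 <- y[1L]
  im0 <- max(y)
  half <- io0 + (im0 - io0) / 2
  t_half <- tt[which(y >= half)[1L]]
  k0 <- if (is.finite(t_half) && t_half > 0) log(2) / t_half else 0.1
  # residuals and analytic Jacobian of I(t) = Im - (Im - Io) exp(-k t)
  fn <- function(p) y - (p[1L] - (p[1L] - p[2L]) * exp(-p[3L] * tt))
  jac <- function(p) {
    ek <- exp(-p[3L] * tt)
    -cbind(1 - ek, ek, (p[1L] - p[2L]) * tt * ek)
  }
  res <- minpack.lm::nls.lm(
    par = c(im0, io0, k0), fn = fn, jac = jac,
    lower = c(-Inf, -Inf, 1e-10),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  if (!res$info %in% 1:4) {
    stop("exponential fit failed to converge: ", res$message, call. = FALSE)
  }
  est <- res$par
  ssr <- sum(res$fvec^2)
  r2 <- 1 - ssr / sum((y - mean(y))^2)
  se <- tryCatch({
    cov_k <- solve(res$hessian)[3L, 3L] * ssr / max(length(y) - 3L, 1L)
    sqrt(max(cov_k, 0))
  }, error = function(e) NA_real_)
  structure(
    list(k = est[3L], i_m = est[1L], i_o = est[2L], stderr_k = se, r2 = r2,
         ok = r2 >= r2_floor, window = window, channel = channel),
    class = "exp_fit"
  )
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("<exp_fit> %s: k = %.5g 1/s (se %.3g), Im = %.4g, Io = %.4g, R2 = %.4f%s\n",
              x$channel, x$k, x$stderr_k, x$i_m, x$i_o, x$r2,
              if (x$ok) "" else "  [flagged: low R2]"))
  invisible(x)
}

get_channel <- function(trace, channel) {
  if (!channel %in% names(trace)) {
    stop("channel '", channel, "' not present in trace", call. = FALSE)
  }
  trace[[channel]]
}

#' Instantaneous signal rate at a fixed time from onset
#'
#' The initial-rate readouts of aggregometry traces: the tangent slope of a
#' channel at a stated time after process onset, estimated by local linear
#' regression for noise robustness. `Vsh` is the 12-degree slope at 5 s from
#' onset; `Vagg` the 1-degree slope at 20 s.
#'
#' @inheritParams fit_exponential_rise
#' @param t_eval Evaluation time in seconds from onset.
#' @param t_onset Process onset time (s); default 0. Use
#'   [detect_onset()] when the event time is unknown.
#' @param half_window Half-width (s) of the regression window, default 2.
#' @return Slope in AU/s.
#' @examples
#' tr <- tibble::tibble(t = seq(0, 30, 0.1), LSI1 = 2 * seq(0, 30, 0.1))
#' initial_rate(tr, "LSI1", t_eval = 20) # 2 AU/s
#' @export
initial_rate <- function(trace, channel, t_eval, t_onset = 0, half_window = 2) {
  y <- get_channel(trace, channel)
  t_star <- t_onset + t_eval
  if (t_star < min(trace$t) || t_star > max(trace$t)) {
    stop("evaluation point ", t_star, " s outside trace range", call. = FALSE)
  }
  sel <- trace$t >= t_star - half_window & trace$t <= t_star + half_window
  if (sum(sel) < 3L) stop("too few samples in the regression window", call. = FALSE)
  unname(stats::coef(stats::lm(y[sel] ~ trace$t[sel]))[2L])
}

#' Area under a trace channel
#'
#' Trapezoidal area of the baseline-subtracted channel over
#' `[t_onset, t_onset + window_len]`. The aggregation readout `AUCagg` uses
#' the 1-degree channel over 120 s; the calcium readout `AUCCa` uses the
#' fluorescence channel over 20 s.
#'
#' @inheritParams initial_rate
#' @param window_len Integration window length (s).
#' @param baseline Baseline (AU) subtracted before integration; default the
#'   channel value at `t_onset` is *not* used — pass the pre-event baseline
#'   explicitly or 0 for already baseline-corrected signals.
#' @return Area in AU s.
#' @export
trace_auc <- function(trace, channel, window_len, t_onset = 0, baseline = 0) {
  y <- get_channel(trace, channel)
  t1 <- t_onset + window_len
  if (t_onset < min(trace$t) - 1e-9 || t1 > max(trace$t) + 1e-9) {
    stop("integration window [", t_onset, ", ", t1, "] overruns the trace",
         call. = FALSE)
  }
  sel <- trace$t >= t_onset - 1e-9 & trace$t <= t1 + 1e-9
  pracma::trapz(trace$t[sel], y[sel] - baseline)
}

#' Disaggregation percentage of a trace channel
#'
#' Reversal of aggregation is quantified as the percentage decrease of the
#' 1-degree scatter signal from its maximum:
#' `100 * (max - final) / (max - baseline)`, clipped to `[0, 100]`. A
#' monotone-rising trace returns 0 (no disaggregation).
#'
#' @inheritParams initial_rate
#' @param baseline Baseline (AU); default the first sample of the channel.
#' @return Percentage in `[0, 100]`.
#' @export
disaggregation_percent <- function(trace, channel, baseline = NULL) {
  y <- get_channel(trace, channel)
  if (is.null(baseline)) baseline <- y[1L]
  y_max <- max(y)
  if (y_max - baseline <= 0) {
    stop("channel has no maximum above baseline", call. = FALSE)
  }
  y_final <- y[length(y)]
  min(100, max(0, 100 * (y_max - y_final) / (y_max - baseline)))
}

#' Detect process onset in a trace channel
#'
#' Onset is the first time the channel exceeds its pre-event baseline by
#' three pre-event noise standard deviations. The baseline and noise are
#' taken from the `baseline_window` seconds preceding `t_event` (or the
#' start of the trace).
#'
#' @inheritParams initial_rate
#' @param t_event Known event time (s); if supplied the search starts there.
#' @param baseline_window Length (s) of the pre-event span used for the
#'   baseline median and noise SD, default 5.
#' @return Onset time (s), or `t_event` itself when the pre-event noise is
#'   zero and the signal departs immediately.
#' @export
detect_onset <- function(trace, channel, t_event = NULL, baseline_window = 5) {
  y <- get_channel(trace, channel)
  t <- trace$t
  if (is.null(t_event)) t_event <- t[1L]
  pre <- t < t_event & t >= t_event - baseline_window
  if (!any(pre)) pre <- seq_along(t) == 1L
  base <- stats::median(y[pre])
  noise <- stats::sd(y[pre])
  if (!is.finite(noise) || noise == 0) noise <- 0
  idx <- which(t >= t_event & y > base + 3 * noise)
  if (length(idx) == 0L) {
    stop("no onset detected: channel never exceeds baseline + 3 SD", call. = FALSE)
  }
  t[idx[1L]]
}
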