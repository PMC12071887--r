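#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a monoexponential trace fit
#'
#' @param x An `exp_fit` from [fit_exponential_rise()].
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`, `std.error`.
#' @export
tidy.exp_fit <- function(x, ...) {
  tibble::tibble(
    term = c("k", "i_m", "i_o"),
    estimate = c(x$k, x$i_m, x$i_o),
    std.error = c(x$stderr_k, NA_real_, NA_real_)
  )
}

#' @rdname tidy.exp_fit
#' @export
glance.exp_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r2, ok = x$ok, channel = x$channel)
}

#' Tidy a Hill dose-response fit
#'
#' @param x A `hill_fit` from [fit_hill()] or [dose_dependence_of_decay()].
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`, `std.error`.
#' @export
tidy.hill_fit <- function(x, ...) {
  p <- x$params
  tibble::tibble(
    term = c("k_max", "half_conc", "h"),
    estimate = c(p$k_max, p$half_conc, p$h),
    std.error = unname(x$stderr[c("k_max", "half_conc", "h")])
  )
}

#' @rdname tidy.hill_fit
#' @export
glance.hill_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r2, mode = x$params$mode,
                 ok = x$ok, flags = paste(x$flags, collapse = ";"))
}

#' Tidy a trajectory-fitting result
#'
#' @param x A `platelet_fit` from [fit_model()].
#' @param ... Unused.
#' @return One row per constant: `term`, `estimate`, `identifiability`
#'   (relative loss rise at the bounds; `NA` for fixed constants).
#' @export
tidy.platelet_fit <- function(x, ...) {
  nm <- names(x$estimates)
  tibble::tibble(
    term = nm,
    estimate = unname(x$estimates),
    identifiability = unname(x$identifiability[nm])
  )
}

#' @rdname tidy.platelet_fit
#' @export
glance.platelet_fit <- function(x, ...) {
  tibble::tibble(loss = x$loss, mean.r.squared = mean(x$r2),
                 convergence = x$convergence, seed = x$seed)
}
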