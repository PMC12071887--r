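#' Hill dose-response parameter set
#'
#' Bundles the three parameters of a sigmoidal dose-response law governing one
#' transition rate constant: the maximal rate constant attained at a saturating
#' stimulus, the half-effect concentration (EC50 for an activating stimulus,
#' IC50 for an inhibitory one) and the Hill coefficient controlling steepness.
#'
#' @param k_max Maximal rate constant (1/s), or maximal response for normalized
#'   readouts. Must be positive and finite.
#' @param half_conc Half-effect concentration (EC50 or IC50) in the unit given
#'   by `unit`. Must be positive and finite.
#' @param h Dimensionless Hill coefficient, positive.
#' @param mode `"activation"` (rate rises from 0 to `k_max` with concentration)
#'   or `"inhibition"` (rate falls from `k_max` to 0).
#' @param unit Concentration unit label, recorded for bookkeeping (default
#'   `"nM"`). Not used in arithmetic: callers must supply concentrations in
#'   this unit.
#'
#' @return An object of class `hill_params`: a named list with elements
#'   `k_max`, `half_conc`, `h`, `mode`, `unit`.
#' @examples
#' hp <- hill_params(k_max = 0.19, half_conc = 46.8, h = 1.27)
#' hill_rate(46.8, hp) # half-maximal by construction: 0.095
#' @export
hill_params <- function(k_max, half_conc, h,
                        mode = c("activation", "inhibition"),
                        unit = "nM") {
  mode <- match.arg(mode)
  for (nm in c("k_max", "half_conc", "h")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("`", nm, "` must be a single positive finite number", call. = FALSE)
    }
  }
  structure(
    list(k_max = k_max, half_conc = half_conc, h = h, mode = mode, unit = unit),
    class = "hill_params"
  )
}

#' @export
print.hill_params <- function(x, ...) {
  cat(sprintf(
    "<hill_params> mode=%s  k_max=%g 1/s  %s=%g %s  h=%g\n",
    x$mode, x$k_max,
    if (x$mode == "activation") "EC50" else "IC50",
    x$half_conc, x$unit, x$h
  ))
  invisible(x)
}

check_conc <- function(conc) {
  if (!is.numeric(conc) || any(!is.finite(conc)) || any(conc < 0)) {
    stop("concentrations must be finite and non-negative", call. = FALSE)
  }
  conc
}

#' Activating Hill law for a rate constant
#'
#' Evaluates `k = k_max * A^h / (EC50^h + A^h)`: the transition rate constant
#' as a function of agonist concentration `A`. Zero at zero agonist, exactly
#' half-maximal at `A = EC50`, saturating at `k_max`.
#'
#' @param conc Agonist concentration(s), same unit as `p$half_conc`.
#' @param p A [hill_params()] object with `mode = "activation"`.
#' @return Rate constant(s) in 1/s, same length as `conc`.
#' @seealso [hill_inhibition()], [eval_hill()]
#' @export
hill_activation <- function(conc, p) {
  stopifnot(inherits(p, "hill_params"))
  if (p$mode != "activation") {
    stop("`p` must have mode = 'activation'", call. = FALSE)
  }
  check_conc(conc)
  ah <- conc^p$h
  out <- p$k_max * ah / (p$half_conc^p$h + ah)
  out[conc == 0] <- 0 # exact zero-stimulus limit (avoids 0^h edge cases)
  out
}

#' Inhibitory Hill law for a rate constant
#'
#' Evaluates `k = k_max * IC50^h / (IC50^h + I^h)`: the rate constant as a
#' function of inhibitor concentration `I`. Equals `k_max` with no inhibitor
#' and falls to half-maximum at `I = IC50`.
#'
#' @inheritParams hill_activation
#' @param p A [hill_params()] object with `mode = "inhibition"`.
#' @return Rate constant(s) in 1/s.
#' @export
hill_inhibition <- function(conc, p) {
  stopifnot(inherits(p, "hill_params"))
  if (p$mode != "inhibition") {
    stop("`p` must have mode = 'inhibition'", call. = FALSE)
  }
  check_conc(conc)
  ich <- p$half_conc^p$h
  ich / (ich + conc^p$h) * p$k_max
}

#' Evaluate a Hill law at a vector of doses
#'
#' Dispatches on `p$mode` to [hill_activation()] or [hill_inhibition()].
#'
#' @inheritParams hill_activation
#' @param doses Concentration vector (>= 0).
#' @return Responses, same length as `doses`.
#' @export
eval_hill <- function(p, doses) {
  if (p$mode == "activation") hill_activation(doses, p) else hill_inhibition(doses, p)
}

#' Fractional receptor-style Hill occupancy
#'
#' The dimensionless saturation term `I^h / (half^h + I^h)` in `[0, 1]`, used
#' when a maximal rate constant is scaled by how strongly a species engages its
#' pathway (e.g. the resting-to-inhibited transition driven by iloprost).
#'
#' @inheritParams hill_activation
#' @param p A [hill_params()] object; only `half_conc` and `h` are used.
#' @return Occupancy in `[0, 1]`.
#' @export
hill_occupancy <- function(conc, p) {
  check_conc(conc)
  ch <- conc^p$h
  out <- ch / (p$half_conc^p$h + ch)
  out[conc == 0] <- 0
  out
}
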