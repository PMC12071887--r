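#' Assemble the transition rate constants for one chemical condition
#'
#' Combines the Hill dose-response laws of a parameter table with the current
#' agonist and inhibitor concentrations, the per-pathway inhibitor effect
#' levels and the stirring state into the nine transition constants of the
#' phenotype model:
#'
#' * `k1`, `k2` — agonist-activated forward constants (shape change, integrin
#'   activation), each multiplied non-competitively by the inhibitor factor
#'   `IC50^h / (IC50^h + (e * I)^h)` where `e` is the current effect level of
#'   that inhibitor on the relevant pathway (shape-change factor for `k1`,
#'   aggregation factor for `k2`).
#' * `k3` — second-order aggregation constant, `2 * k_max2 / 100` per (% s)
#'   while stirring so that at 100% integrin-activated platelets the
#'   pseudo-first-order rate is twice the integrin-activation maximum (never
#'   rate-limiting); `0` with stirring off.
#' * `k4` — resting-to-inhibited constant: the aggregation-pathway onset rate
#'   scaled by the inhibitor's Hill occupancy.
#' * `k5`, `k6` — desensitization constants, inhibitory Hill laws of the
#'   agonist concentration (zero with no agonist present).
#' * `k_m1`, `k_m4`, `k7` — passed through from `fitted`.
#'
#' @param agonist_concs Named numeric vector of agonist concentrations (nM),
#'   names are species (e.g. `c(ADP = 5000)`). May be empty.
#' @param inhibitor_concs Named numeric vector of inhibitor concentrations
#'   (nM). May be empty.
#' @param inhibitor_exposure Named list per inhibitor species of effect levels
#'   in `[0, 1]`, each a vector `c(sc = , agg = )`; defaults to full exposure
#'   (steady state) for every species present.
#' @param param_table Parameter table as from [platelet_params()]; must
#'   provide `k1`, `k2`, `k5` and `k6` rows.
#' @param stirring Logical; stirring drives platelet collisions, so `FALSE`
#'   forces `k3 = 0`.
#' @param fitted Named numeric vector supplying `k_m1`, `k_m4`, `k7`
#'   (see [default_fitted_constants()]).
#'
#' @return An object of class `rate_constants`: named numeric vector
#'   `k1, k2, k3, k4, k_m4, k5, k6, k7, k_m1` (all 1/s except `k3`,
#'   1/(% s)).
#' @examples
#' assemble_rate_constants(c(ADP = 5000), stirring = TRUE)
#' @export
assemble_rate_constants <- function(agonist_concs = numeric(),
                                    inhibitor_concs = numeric(),
                                    inhibitor_exposure = NULL,
                                    param_table = platelet_params(),
                                    stirring = TRUE,
                                    fitted = default_fitted_constants()) {
  check_conc(unname(agonist_concs))
  check_conc(unname(inhibitor_concs))
  need <- c("k1", "k2", "k5", "k6")
  missing <- setdiff(need, unique(param_table$constant))
  if (length(missing) > 0L) {
    stop("param_table is missing required constants: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  agonist_concs <- agonist_concs[agonist_concs > 0]
  inhibitor_concs <- inhibitor_concs[inhibitor_concs > 0]
  if (is.null(inhibitor_exposure)) {
    inhibitor_exposure <- lapply(inhibitor_concs, function(x) c(sc = 1, agg = 1))
  }

  sum_activation <- function(constant) {
    if (length(agonist_concs) == 0L) return(0)
    sum(purrr::imap_dbl(agonist_concs, function(conc, sp) {
      p <- lookup_hill(param_table, constant, sp)
      if (is.null(p)) 0 else hill_activation(conc, p)
    }))
  }
  sum_desens <- function(constant) {
    if (length(agonist_concs) == 0L) return(0)
    sum(purrr::imap_dbl(agonist_concs, function(conc, sp) {
      p <- lookup_hill(param_table, constant, sp)
      if (is.null(p)) 0 else hill_inhibition(conc, p)
    }))
  }
  # Non-competitive factor on a forward pathway ("sc" or "agg"):
  # product over inhibitor species of the Eq-style term at effective conc e*I.
  inhibition_factor <- function(pathway) {
    if (length(inhibitor_concs) == 0L) return(1)
    prod(purrr::imap_dbl(inhibitor_concs, function(conc, sp) {
      p <- lookup_hill(param_table, paste0("inh_", pathway), sp)
      if (is.null(p)) return(1)
      e <- inhibitor_exposure[[sp]][[pathway]]
      hill_inhibition(e * conc, p) / p$k_max
    }))
  }
  occupancy_agg <- function() {
    if (length(inhibitor_concs) == 0L) return(0)
    min(1, sum(purrr::imap_dbl(inhibitor_concs, function(conc, sp) {
      p <- lookup_hill(param_table, "inh_agg", sp)
      if (is.null(p)) 0 else hill_occupancy(conc, p)
    })))
  }

  k1 <- sum_activation("k1") * inhibition_factor("sc")
  k2 <- sum_activation("k2") * inhibition_factor("agg")
  kmax2 <- max(param_table$k_max[param_table$constant == "k2"])
  k3 <- if (isTRUE(stirring)) 2 * kmax2 / 100 else 0
  k4_onset <- if (length(inhibitor_concs) > 0L) {
    max(purrr::map_dbl(names(inhibitor_concs),
                       function(sp) lookup_onset(param_table, "agg", sp)))
  } else 0.31
  k4 <- k4_onset * occupancy_agg()
  k5 <- sum_desens("k5")
  k6 <- sum_desens("k6")

  out <- c(
    k1 = k1, k2 = k2, k3 = k3, k4 = k4,
    k_m4 = unname(fitted[["k_m4"]]),
    k5 = k5, k6 = k6,
    k7 = unname(fitted[["k7"]]),
    k_m1 = unname(fitted[["k_m1"]])
  )
  if (any(!is.finite(out)) || any(out < 0)) {
    stop("assembled rate constants must be finite and non-negative", call. = FALSE)
  }
  structure(out, class = c("rate_constants", "numeric"))
}

#' @export
print.rate_constants <- function(x, ...) {
  cat("<rate_constants> (1/s; k3 in 1/(% s))\n")
  print(round(unclass(x), 6))
  invisible(x)
}
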