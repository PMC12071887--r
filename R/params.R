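#' Default kinetic parameter table
#'
#' The dose-response laws governing each concentration-dependent transition
#' constant of the six-state phenotype model, one row per (constant, species)
#' pair. Activation rows give the Hill law of an agonist-driven forward
#' constant (shape change `k1`, integrin activation `k2`); inhibition rows give
#' the agonist-dependence of the desensitization constants (`k5` from the
#' sphered state, `k6` from the integrin-activated state) and the inhibitor
#' dose-dependence factors applied non-competitively to the forward reactions
#' (`inh_sc` on shape change, `inh_agg` on integrin activation/aggregation).
#' `onset` rows carry the first-order onset rate constants with which an added
#' inhibitor's effect develops (shape-change and aggregation pathways share
#' 0.31 1/s; the calcium-linked pathway, 0.085 1/s, is recorded for
#' completeness but does not enter the light-scatter model).
#'
#' Values are the package defaults for ADP/TRAP agonism and iloprost
#' inhibition; any table with the same columns can be passed wherever a
#' `param_table` is accepted.
#'
#' @return A tibble with columns `constant`, `species`, `k_max` (1/s),
#'   `half_conc`, `unit`, `h`, `mode`.
#' @examples
#' platelet_params()
#' @export
platelet_params <- function() {
  tibble::tribble(
    ~constant,   ~species,   ~k_max, ~half_conc, ~unit,   ~h, ~mode,
    "k1",        "ADP",        0.19,       46.8, "nM",  1.27, "activation",
    "k1",        "TRAP",       0.19,      204.0, "nM",  1.24, "activation",
    "k2",        "ADP",        0.03,      589.8, "nM",  3.92, "activation",
    "k2",        "TRAP",       0.03,     2309.0, "nM",  6.68, "activation",
    "k5",        "ADP",      0.0028,     1840.0, "nM",  1.40, "inhibition",
    "k6",        "ADP",       0.055,      990.0, "nM",  1.90, "inhibition",
    "inh_sc",    "iloprost",    1.0,      0.048, "nM",  1.52, "inhibition",
    "inh_agg",   "iloprost",    1.0,       0.21, "nM",  2.14, "inhibition",
    "onset_sc",  "iloprost",   0.31,         NA, NA,      NA, "onset",
    "onset_agg", "iloprost",   0.31,         NA, NA,      NA, "onset",
    "onset_ca",  "iloprost",  0.085,         NA, NA,      NA, "onset"
  )
}

#' Default values of the constants not set by dose-response laws
#'
#' `k_m1` (exhausted -> resting recovery), `k_m4` (inhibited -> resting
#' reversal) and `k7` (aggregated -> exhausted disaggregation) are not
#' observable directly in light-scatter traces and must be estimated by
#' trajectory fitting ([fit_model()]). These defaults are plausible
#' magnitudes for forward simulation: recovery from exhaustion on a
#' ten-minute scale, reversal of inhibition on a few-minute scale, and
#' disaggregation fast enough to empty an aggregate within the
#' three-minute reversibility window.
#'
#' @return Named numeric vector with elements `k_m1`, `k_m4`, `k7` (1/s).
#' @export
default_fitted_constants <- function() {
  c(k_m1 = 0.001, k_m4 = 0.005, k7 = 0.05)
}

# Look up the hill_params for one (constant, species) row; NULL if absent.
lookup_hill <- function(param_table, constant, species = NULL) {
  rows <- param_table[param_table$constant == constant, , drop = FALSE]
  if (!is.null(species)) rows <- rows[rows$species == species, , drop = FALSE]
  if (nrow(rows) == 0L) return(NULL)
  r <- rows[1L, ]
  hill_params(r$k_max, r$half_conc, r$h,
              mode = r$mode, unit = if (is.na(r$unit)) "nM" else r$unit)
}

# Onset rate for an inhibitor species on one pathway ("sc" or "agg").
lookup_onset <- function(param_table, pathway, species) {
  rows <- param_table[param_table$constant == paste0("onset_", pathway) &
                        param_table$species == species, , drop = FALSE]
  if (nrow(rows) == 0L) return(0.31) # pathway default when a species lacks a row
  rows$k_max[1L]
}
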