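# Shared fixture builders: everything is generated in code at test time.

# Eq-style monoexponential saturation trace on a uniform grid.
exp_rise_trace <- function(k, i_m = 100, i_o = 0, t_max = 60, dt = 0.1,
                           channel = "LSI12") {
  t <- seq(0, t_max, by = dt)
  out <- tibble::tibble(t = t)
  out[[channel]] <- i_m - (i_m - i_o) * exp(-k * t)
  out
}

# Parameter table whose forward/desensitization constants are numerically
# negligible except those listed in `keep` (used to isolate single reactions).
isolated_param_table <- function(keep = "k1") {
  pt <- platelet_params()
  off <- !(pt$constant %in% keep) & pt$mode %in% c("activation", "inhibition")
  pt$k_max[off] <- 1e-12
  pt
}

zero_fitted <- c(k_m1 = 0, k_m4 = 0, k7 = 0)

# Printed desensitization table used across modules: ADP dose (nM) -> k5 (1/s).
table_k5 <- tibble::tibble(adp = c(1000, 2000, 5000),
                           k = c(0.0019, 0.0013, 0.0005))
table_k6 <- tibble::tibble(adp = c(1000, 2000, 5000),
                           k = c(0.0279, 0.0092, 0.0026))

# Default-noise emulation: additive Gaussian, sd = 1% of the channel range.
apply_noise_for_test <- function(y, t) {
  y + rnorm(length(y), 0, 0.01 * diff(range(y)))
}

# Decay datasets consistent with a stated first-order constant.
decay_from_k <- function(k, adp, delays = c(60, 180, 360),
                         kind = "shape_change_delay") {
  decay_dataset(delays, 100 * exp(-k * delays), agonist_conc = adp,
                protocol_kind = kind)
}
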