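#' Timed stimulation events
#'
#' Helpers building the event rows of a [stimulus_protocol()]: agonist or
#' inhibitor additions and stirring toggles at stated times. Concentrations
#' are converted to nM at construction (`unit` may be `"nM"`, `"uM"`/`"µM"`
#' or `"mM"`); additions are cumulative (a second addition of the same
#' species raises its concentration).
#'
#' @param t Event time in seconds (>= 0), absolute from recording start.
#' @param species Species name, e.g. `"ADP"`, `"TRAP"`, `"iloprost"`.
#' @param conc Added concentration (>= 0).
#' @param unit Concentration unit.
#' @return One-row tibble with columns `t`, `kind`, `species`, `conc` (nM).
#' @name protocol_events
#' @examples
#' add_agonist(0, "ADP", 5, unit = "uM")
NULL

conc_to_nM <- function(conc, unit) {
  fac <- switch(unit,
    "nM" = 1, "uM" = 1e3, "µM" = 1e3, "mM" = 1e6,
    stop("unknown concentration unit: ", unit, call. = FALSE)
  )
  conc * fac
}

event_row <- function(t, kind, species, conc) {
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t)) {
    stop("event time must be a single finite number", call. = FALSE)
  }
  if (conc < 0) stop("event concentration must be non-negative", call. = FALSE)
  tibble::tibble(t = t, kind = kind, species = species, conc = conc)
}

#' @rdname protocol_events
#' @export
add_agonist <- function(t, species, conc, unit = "nM") {
  event_row(t, "add_agonist", species, conc_to_nM(conc, unit))
}

#' @rdname protocol_events
#' @export
add_inhibitor <- function(t, species, conc, unit = "nM") {
  event_row(t, "add_inhibitor", species, conc_to_nM(conc, unit))
}

#' @rdname protocol_events
#' @export
stir_on <- function(t) event_row(t, "stir_on", NA_character_, 0)

#' @rdname protocol_events
#' @export
stir_off <- function(t) event_row(t, "stir_off", NA_character_, 0)

#' Scripted stimulation protocol
#'
#' An ordered list of timed events (agonist/inhibitor additions, stir
#' toggles) plus a simulation horizon. Stirring defaults to on at `t = 0`.
#'
#' @param ... Event rows from [add_agonist()], [add_inhibitor()],
#'   [stir_on()], [stir_off()], or tibbles of such rows.
#' @param t_end Simulation horizon in seconds (> 0).
#' @return An object of class `stimulus_protocol`: list with `events`
#'   (tibble sorted by time) and `t_end`.
#' @examples
#' stimulus_protocol(add_agonist(0, "ADP", 5000), t_end = 300)
#' @export
stimulus_protocol <- function(..., t_end) {
  events <- dplyr::bind_rows(...)
  if (!is.numeric(t_end) || length(t_end) != 1L || !is.finite(t_end) || t_end <= 0) {
    stop("`t_end` must be a single positive number", call. = FALSE)
  }
  if (nrow(events) > 0L) {
    if (any(events$t < 0) || any(events$t > t_end)) {
      stop("protocol error: event outside [0, t_end]", call. = FALSE)
    }
    events <- dplyr::arrange(events, .data$t)
  } else {
    events <- tibble::tibble(t = numeric(), kind = character(),
                             species = character(), conc = numeric())
  }
  structure(list(events = events, t_end = t_end), class = "stimulus_protocol")
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat(sprintf("<stimulus_protocol> t_end = %g s, %d event(s)\n",
              x$t_end, nrow(x$events)))
  if (nrow(x$events) > 0L) print(as.data.frame(x$events))
  invisible(x)
}

# Chemical condition at time t (just after any event at t):
# cumulative concentrations per species and the stirring flag.
protocol_condition <- function(protocol, t) {
  ev <- protocol$events[protocol$events$t <= t, , drop = FALSE]
  agonists <- inhibitors <- numeric()
  stirring <- TRUE
  if (nrow(ev) > 0L) {
    for (i in seq_len(nrow(ev))) {
      k <- ev$kind[i]
      if (k == "add_agonist") {
        sp <- ev$species[i]
        agonists[sp] <- (if (sp %in% names(agonists)) agonists[[sp]] else 0) + ev$conc[i]
      } else if (k == "add_inhibitor") {
        sp <- ev$species[i]
        inhibitors[sp] <- (if (sp %in% names(inhibitors)) inhibitors[[sp]] else 0) + ev$conc[i]
      } else if (k == "stir_on") {
        stirring <- TRUE
      } else if (k == "stir_off") {
        stirring <- FALSE
      }
    }
  }
  last_agonist <- if (any(ev$kind == "add_agonist")) max(ev$t[ev$kind == "add_agonist"]) else NA_real_
  list(agonists = agonists, inhibitors = inhibitors,
       stirring = stirring, last_agonist = last_agonist)
}
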