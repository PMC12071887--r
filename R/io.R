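#' Read and write trace, trajectory, protocol and parameter files
#'
#' Plain-text round-tripping for the package's tabular objects. Traces and
#' trajectories are CSV with a header row and `.` decimal separator;
#' protocols are JSON; parameter tables and dose-response datasets are CSV.
#' Concentrations are stored in nM. Numeric round trips are lossless to at
#' least 12 significant digits.
#'
#' @param trace,traj,protocol,param_table,ds Object to write.
#' @param path File path.
#' @param response_kind,unit Metadata restored onto a read dose-response
#'   dataset (CSV does not carry attributes).
#' @param sidecar Optional path of a JSON annotation sidecar holding the
#'   protocol event times; defaults to `<path>.json` when the trace carries
#'   events (write) or when such a file exists (read).
#' @return The written path (write), or the reconstructed object (read).
#' @name platelet_io
NULL

#' @rdname platelet_io
#' @export
write_trace <- function(trace, path, sidecar = NULL) {
  readr::write_csv(tibble::as_tibble(trace), path)
  events <- attr(trace, "events")
  if (!is.null(events) && nrow(events) > 0L) {
    if (is.null(sidecar)) sidecar <- paste0(path, ".json")
    jsonlite::write_json(events, sidecar, digits = NA)
  }
  invisible(path)
}

#' @rdname platelet_io
#' @export
read_trace <- function(path, sidecar = NULL) {
  tr <- read_checked_csv(path, required = "t")
  if (is.null(sidecar)) sidecar <- paste0(path, ".json")
  events <- if (file.exists(sidecar)) {
    tibble::as_tibble(jsonlite::read_json(sidecar, simplifyVector = TRUE))
  } else NULL
  structure(tr, class = c("platelet_trace", class(tr)), events = events)
}

#' @rdname platelet_io
#' @export
write_trajectory <- function(traj, path) {
  readr::write_csv(tibble::as_tibble(traj), path)
  invisible(path)
}

#' @rdname platelet_io
#' @export
read_trajectory <- function(path) {
  tr <- read_checked_csv(path, required = c("t", "n_rest", "n_sph", "n_gp",
                                            "n_agg", "n_exh", "n_inh"))
  structure(tr, class = c("platelet_trajectory", class(tr)))
}

#' @rdname platelet_io
#' @export
write_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  jsonlite::write_json(
    list(events = protocol$events, t_end = protocol$t_end),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname platelet_io
#' @export
read_protocol <- function(path) {
  obj <- parse_json_file(path)
  ev <- tibble::as_tibble(obj$events)
  rows <- if (nrow(ev) > 0L) {
    lapply(seq_len(nrow(ev)), function(i) {
      switch(ev$kind[i],
        add_agonist = add_agonist(ev$t[i], ev$species[i], ev$conc[i]),
        add_inhibitor = add_inhibitor(ev$t[i], ev$species[i], ev$conc[i]),
        stir_on = stir_on(ev$t[i]),
        stir_off = stir_off(ev$t[i]),
        stop("parse error in ", path, ": unknown event kind '", ev$kind[i], "'",
             call. = FALSE)
      )
    })
  } else list()
  do.call(stimulus_protocol, c(rows, list(t_end = obj$t_end)))
}

#' @rdname platelet_io
#' @export
write_param_table <- function(param_table, path) {
  readr::write_csv(param_table, path)
  invisible(path)
}

#' @rdname platelet_io
#' @export
read_param_table <- function(path) {
  read_checked_csv(path, required = c("constant", "species", "k_max",
                                      "half_conc", "unit", "h", "mode"))
}

#' @rdname platelet_io
#' @export
write_dose_response <- function(ds, path) {
  readr::write_csv(tibble::as_tibble(ds), path)
  invisible(path)
}

#' @rdname platelet_io
#' @export
read_dose_response <- function(path, response_kind = "k", unit = "nM") {
  d <- read_checked_csv(path, required = c("dose", "response"))
  dose_response_dataset(d$dose, d$response,
                        sd = if ("sd" %in% names(d)) d$sd else NULL,
                        n = if ("n" %in% names(d)) d$n else NULL,
                        response_kind = response_kind, unit = unit)
}

read_checked_csv <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) stop("parse error in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  missing <- setdiff(required, names(d))
  if (length(missing) > 0L) {
    stop("parse error in ", path, ": missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  d
}

parse_json_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
           error = function(e) stop("parse error in ", path, ": ",
                                    conditionMessage(e), call. = FALSE))
}

#' Run a configured analysis job
#'
#' Dispatches one of the pipeline's commands on file inputs and writes its
#' outputs together with a JSON manifest (`<out>.manifest.json`) recording
#' the command, input paths, seed and package version, so every artifact is
#' regenerable from its manifest.
#'
#' @param config Named list with elements:
#'   * `command` — one of `"simulate"`, `"fit-trace"`, `"fit-dose-response"`,
#'     `"fit-decay"`, `"fit-model"`, `"synthesize"`;
#'   * `paths` — named list of input/output paths (`protocol`, `trace`,
#'     `dataset`, `out` as the command requires);
#'   * `params_path` — optional parameter-table CSV (default table used
#'     when absent);
#'   * `seed` — integer, default 1;
#'   * plus per-command fields (`channel`, `mode`, `window`,
#'     `agonist_conc`, `free`, `observations`).
#' @param verbose Print progress messages.
#' @return Invisibly, the primary result object; artifacts are written to
#'   `config$paths$out`.
#' @export
run_job <- function(config, verbose = FALSE) {
  cmd <- config$command
  if (is.null(cmd) || !cmd %in% c("simulate", "fit-trace", "fit-dose-response",
                                  "fit-decay", "fit-model", "synthesize")) {
    stop("unknown command: ", cmd %||% "<missing>", call. = FALSE)
  }
  paths <- config$paths %||% list()
  out <- paths$out
  if (is.null(out)) stop("config$paths$out is required", call. = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  param_table <- if (!is.null(config$params_path)) {
    read_param_table(config$params_path)
  } else {
    platelet_params()
  }
  say <- function(...) if (isTRUE(verbose)) message(...)

  result <- switch(cmd,
    simulate = {
      pr <- read_protocol(paths$protocol)
      say("simulating ", pr$t_end, " s")
      traj <- simulate_phenotypes(pr, param_table = param_table,
                                  sample_dt = config$sample_dt %||% 0.1)
      write_trajectory(traj, out)
      traj
    },
    synthesize = {
      pr <- read_protocol(paths$protocol)
      tr <- generate_trace(pr, param_table = param_table,
                           noise = noise_model(seed = seed),
                           sample_dt = config$sample_dt %||% 0.1)
      write_trace(tr, out)
      tr
    },
    `fit-trace` = {
      tr <- read_trace(paths$trace)
      fit <- fit_exponential_rise(tr, config$channel %||% "LSI12",
                                  window = config$window)
      jsonlite::write_json(list(k = fit$k, i_m = fit$i_m, i_o = fit$i_o,
                                r2 = fit$r2, ok = fit$ok),
                           out, auto_unbox = TRUE, digits = NA)
      fit
    },
    `fit-dose-response` = {
      ds <- read_dose_response(paths$dataset)
      fit <- fit_hill(ds, mode = config$mode %||% "activation")
      jsonlite::write_json(list(k_max = fit$params$k_max,
                                half_conc = fit$params$half_conc,
                                h = fit$params$h, r2 = fit$r2,
                                flags = fit$flags),
                           out, auto_unbox = TRUE, digits = NA)
      fit
    },
    `fit-decay` = {
      d <- read_checked_csv(paths$dataset, required = c("delay", "response"))
      ds <- decay_dataset(d$delay, d$response,
                          agonist_conc = config$agonist_conc %||% NA_real_)
      fit <- fit_decay_constant(ds)
      jsonlite::write_json(fit, out, auto_unbox = TRUE, digits = NA)
      fit
    },
    `fit-model` = {
      obs <- lapply(config$observations, function(o) {
        list(protocol = read_protocol(o$protocol), trace = read_trace(o$trace))
      })
      prob <- fit_problem(free = config$free, observations = obs,
                          param_table = param_table,
                          sample_dt = config$sample_dt %||% 1)
      fit <- fit_model(prob, seed = seed)
      jsonlite::write_json(list(estimates = as.list(fit$estimates),
                                r2 = fit$r2, loss = fit$loss, seed = seed),
                           out, auto_unbox = TRUE, digits = NA)
      fit
    }
  )
  manifest <- list(
    command = cmd,
    inputs = paths[setdiff(names(paths), "out")],
    params_path = config$params_path,
    seed = seed,
    package = "plateletkin",
    version = as.character(utils::packageVersion("plateletkin"))
  )
  jsonlite::write_json(manifest, paste0(out, ".manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  say("wrote ", out)
  invisible(result)
}
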