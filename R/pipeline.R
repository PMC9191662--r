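# Multi-stage pipeline runner: a YAML (or list) config names an ordered
# set of stages; each stage consumes the running state, writes its
# artifacts into the run directory, and every written file is hashed into
# a manifest so reruns with the same config and seed can be verified
# byte-for-byte for the deterministic stages.

pipeline_stages <- function() {
  list(
    simulate_kymograph = function(state, p, dir) {
      # YAML cannot carry an R function; build the velocity law from
      # scalar keys: v(t) = velocity_mean * (1 + modulation * sin(2 pi f0 t))
      v0 <- p$velocity_mean %||% 2
      m <- p$modulation %||% 0
      f0 <- p$f0 %||% 10
      p <- p[setdiff(names(p), c("velocity_mean", "modulation", "f0"))]
      vfun <- function(t) v0 * (1 + m * sin(2 * pi * f0 * t))
      spec <- do.call(sim_kymograph_spec,
                      c(p, list(velocity_fn = vfun, seed = state$seed)))
      sim <- simulate_kymograph(spec)
      state$kymograph <- sim$kymograph
      state$truth <- sim$truth
      write_kymograph(sim$kymograph, file.path(dir, "kymograph.tif"))
      utils::write.csv(data.frame(time_s = sim$truth$time,
                                  velocity_mm_s = sim$truth$velocity_mm_s),
                       file.path(dir, "truth_velocity.csv"), row.names = FALSE)
      state
    },
    simulate_penetrating = function(state, p, dir) {
      spec <- do.call(sim_penetrating_spec, c(p, list(seed = state$seed)))
      sim <- simulate_penetrating_trace(spec)
      state$trace <- sim$trace
      state$trace_rate <- spec$frame_rate
      utils::write.csv(data.frame(time_s = sim$time, intensity = sim$trace),
                       file.path(dir, "penetrating_trace.csv"),
                       row.names = FALSE)
      jsonlite::write_json(list(event_times_s = sim$truth$event_times),
                           file.path(dir, "truth_events.json"),
                           auto_unbox = TRUE, digits = NA)
      state
    },
    normalize_kymograph = function(state, p, dir) {
      res <- do.call(normalize_kymograph,
                     c(list(k = state$kymograph), p))
      state$kymograph <- res$kymograph
      write_gain_csv(res$gain, file.path(dir, "gain_profile.csv"))
      state
    },
    bin_time = function(state, p, dir) {
      state$kymograph <- bin_time(state$kymograph, p$factor)
      state
    },
    piv = function(state, p, dir) {
      cfg <- do.call(piv_config, p)
      state$velocity <- piv_velocity(state$kymograph, cfg)
      write_velocity_csv(state$velocity, file.path(dir, "velocity_piv.csv"))
      state
    },
    spectrum = function(state, p, dir) {
      sp <- do.call(velocity_spectrum, c(list(trace = state$velocity), p))
      state$spectrum <- sp
      utils::write.csv(data.frame(frequency_hz = sp$frequency,
                                  amplitude = sp$amplitude),
                       file.path(dir, "spectrum.csv"), row.names = FALSE)
      jsonlite::write_json(list(f0_hz = sp$f0, harmonics = sp$harmonics),
                           file.path(dir, "spectrum_summary.json"),
                           auto_unbox = TRUE, digits = NA)
      state
    },
    pulsatility = function(state, p, dir) {
      f0 <- p$f0 %||% state$spectrum$f0
      res <- pulsatility_index(state$velocity, f0)
      state$pulsatility <- res
      utils::write.csv(res$cycles, file.path(dir, "cycles.csv"),
                       row.names = FALSE)
      jsonlite::write_json(list(pulsatility_index = res$pi, f0_hz = f0),
                           file.path(dir, "pulsatility.json"),
                           auto_unbox = TRUE, digits = NA)
      state
    },
    count_events = function(state, p, dir) {
      res <- do.call(count_rbc_events,
                     c(list(trace = state$trace,
                            frame_rate = state$trace_rate), p))
      state$flux <- res
      utils::write.csv(data.frame(event_time_s = res$event_times),
                       file.path(dir, "events.csv"), row.names = FALSE)
      jsonlite::write_json(list(flux_cells_per_s = res$flux,
                                n_events = length(res$event_times)),
                           file.path(dir, "flux.json"),
                           auto_unbox = TRUE, digits = NA)
      state
    }
  )
}

validate_keys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad)) {
    stop("unknown key(s) in ", where, ": ", paste(bad, collapse = ", "))
  }
}

#' Run a multi-stage analysis pipeline
#'
#' The config (YAML path or list) has top-level keys `seed`, `out_dir`
#' (optional if `out_dir` argument is given), and `stages`: an ordered
#' list of `list(stage = <name>, params = <list>)` entries. Unknown keys
#' anywhere are rejected by name. Every file a stage writes is md5-hashed
#' into `manifest.json`; rerunning with the same config and seed
#' reproduces the hashes of all deterministic stages.
#'
#' Available stages: `simulate_kymograph`, `simulate_penetrating`,
#' `normalize_kymograph`, `bin_time`, `piv`, `spectrum`, `pulsatility`,
#' `count_events`.
#'
#' @param config YAML file path or config list.
#' @param out_dir run directory (created if needed); overrides the config.
#' @return invisibly, a list with the final `state`, the `manifest`
#'   data.frame (`file`, `md5`), and `out_dir`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  validate_keys(config, c("seed", "out_dir", "stages", "log_level"),
                "pipeline config")
  if (is.null(config$stages) || !length(config$stages)) {
    stop("config has no stages")
  }
  out_dir <- out_dir %||% config$out_dir
  if (is.null(out_dir)) stop("no output directory given")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  registry <- pipeline_stages()
  state <- new.env(parent = emptyenv())
  state$seed <- config$seed %||% 1L
  for (i in seq_along(config$stages)) {
    entry <- config$stages[[i]]
    validate_keys(entry, c("stage", "params"),
                  sprintf("stage entry %d", i))
    nm <- entry$stage
    if (is.null(nm) || !nm %in% names(registry)) {
      stop("unknown stage: ", nm %||% "<missing>")
    }
    state <- tryCatch(
      registry[[nm]](state, entry$params %||% list(), out_dir),
      error = function(e) {
        stop("stage '", nm, "' failed: ", conditionMessage(e), call. = FALSE)
      })
  }
  files <- setdiff(list.files(out_dir, full.names = TRUE), character(0))
  files <- files[!grepl("manifest\\.json$", files)]
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$file), ]
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       digits = NA)
  invisible(list(state = state, manifest = manifest, out_dir = out_dir))
}
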