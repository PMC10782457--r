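# Run configuration, orchestration and diagnostics summaries.
#
# A run is fully described by a serializable configuration (YAML on disk);
# identical configurations give byte-identical numerical outputs, since all
# solvers are deterministic.

.RUN_TASKS <- c("uvvis", "cd", "states")

#' Create a run configuration
#'
#' @param xyz path to an XYZ geometry file.
#' @param basis basis-set name.
#' @param task `"uvvis"` (CPP absorption), `"cd"` (CPP circular dichroism)
#'   or `"states"` (eigensolver + stick table).
#' @param freq_start,freq_stop,freq_count frequency window for CPP tasks.
#' @param freq_unit unit of the window (`"hartree"`, `"ev"`, `"cm-1"`).
#' @param gamma damping value; `gamma_unit` as for frequencies.
#' @param gamma_unit unit of `gamma`.
#' @param strategy subspace strategy for CPP tasks.
#' @param threshold relative-residual threshold.
#' @param n_states number of states for the `"states"` task.
#' @param moment_order perturbative order of transition moments.
#' @param output_dir directory for result files.
#' @return a `run_config`.
#' @export
run_config <- function(xyz, basis, task = "uvvis",
                       freq_start = 4, freq_stop = 11, freq_count = 101L,
                       freq_unit = "ev", gamma = 1000, gamma_unit = "cm-1",
                       strategy = "separate", threshold = 1e-4,
                       n_states = 10L, moment_order = 2L,
                       output_dir = ".") {
  task <- match.arg(task, .RUN_TASKS)
  cfg <- list(xyz = xyz, basis = basis, task = task,
              freq_start = freq_start, freq_stop = freq_stop,
              freq_count = as.integer(freq_count), freq_unit = freq_unit,
              gamma = gamma, gamma_unit = gamma_unit, strategy = strategy,
              threshold = threshold, n_states = as.integer(n_states),
              moment_order = as.integer(moment_order),
              output_dir = output_dir)
  class(cfg) <- "run_config"
  cfg
}

#' Serialize / parse a run configuration
#'
#' YAML round trip: `read_run_config(write_run_config(cfg, path))` equals
#' `cfg`.
#' @param cfg a `run_config`.
#' @param path file path.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

#' Execute a configured run
#'
#' Builds the SCF reference and ADC(2) workspace, executes the configured
#' task and writes spectra / state tables / diagnostics to
#' `cfg$output_dir`. The returned status is 0 only if every equation or
#' root converged.
#'
#' @param cfg a `run_config`.
#' @param quiet suppress progress messages.
#' @return (invisibly) list with `status`, result objects and output paths.
#' @export
run <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  if (!file.exists(cfg$xyz)) stop("XYZ file not found: ", cfg$xyz)
  say <- function(...) if (!quiet) message(sprintf(...))
  mol <- read_xyz(cfg$xyz)
  say("SCF reference: %s / %s", basename(cfg$xyz), cfg$basis)
  ref <- build_reference(mol, cfg$basis)
  ws <- adc_workspace(mo_integral_set(ref))
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  outfile <- function(name) file.path(cfg$output_dir, name)
  paths <- character(0)
  status <- 0L
  gamma_au <- convert_units(cfg$gamma, cfg$gamma_unit, "hartree")
  result <- NULL
  if (cfg$task %in% c("uvvis", "cd")) {
    grid <- convert_units(
      freq_grid(cfg$freq_start, cfg$freq_stop, count = cfg$freq_count),
      cfg$freq_unit, "hartree")
    say("CPP task %s: %d frequencies, gamma = %.6f hartree, %s subspaces",
        cfg$task, length(grid), gamma_au, cfg$strategy)
    result <- if (cfg$task == "uvvis")
      compute_uvvis_cpp(ws, grid, gamma_au, strategy = cfg$strategy,
                        threshold = cfg$threshold,
                        moment_order = cfg$moment_order)
    else
      compute_cd_cpp(ws, grid, gamma_au, strategy = cfg$strategy,
                     threshold = cfg$threshold,
                     moment_order = cfg$moment_order)
    conv <- vapply(result$solutions, function(s) isTRUE(s$converged), TRUE)
    if (!all(conv)) status <- 1L
    p <- outfile(paste0(cfg$task, "_spectrum.csv"))
    write_spectrum_csv(result, p); paths <- c(paths, p)
    p <- outfile("cpp_diagnostics.csv")
    utils::write.csv(result$diagnostics$records, p, row.names = FALSE)
    paths <- c(paths, p)
    say("systems: %d, converged: %d", result$diagnostics$n_systems, sum(conv))
  } else {
    states <- withCallingHandlers(
      solve_states(ws, cfg$n_states),
      warning = function(w) { status <<- 1L; invokeRestart("muffleWarning") })
    tb <- stick_table(ws, states, moment_order = cfg$moment_order)
    conv <- vapply(states, function(s) isTRUE(s$converged), TRUE)
    if (!all(conv)) status <- 1L
    p <- outfile("states.csv")
    utils::write.csv(tb, p, row.names = FALSE); paths <- c(paths, p)
    p <- outfile("states.json")
    jsonlite::write_json(tb, p, dataframe = "rows", digits = NA)
    paths <- c(paths, p)
    result <- list(states = states, table = tb)
    say("states converged: %d / %d", sum(conv), length(conv))
  }
  p <- outfile("run_config.yaml")
  write_run_config(cfg, p); paths <- c(paths, p)
  invisible(list(status = status, result = result, paths = paths))
}

#' Convergence summary of CPP diagnostics
#'
#' Per-frequency iterations-to-convergence (the iteration at which the last
#' component system converged) and cumulative trial-vector / sigma-pair
#' curves.
#'
#' @param diagnostics the `diagnostics` element returned by [cpp_solve()]
#'   (or attached to a CPP `spectrum_result`).
#' @return list with `per_frequency` and `cumulative` data frames; the
#'   summary carries attribute `partial = TRUE` if any system did not
#'   converge.
#' @export
replot_diagnostics <- function(diagnostics) {
  rec <- diagnostics$records
  if (is.null(rec) || nrow(rec) == 0L) {
    warning("empty diagnostics record stream; summary flagged partial")
    out <- list(per_frequency = data.frame(), cumulative = data.frame())
    attr(out, "partial") <- TRUE
    return(out)
  }
  per_freq <- do.call(rbind, lapply(split(rec, abs(rec$omega)), function(df) {
    data.frame(omega = abs(df$omega[1]),
               iterations = max(df$iteration),
               systems = length(unique(df$system)),
               final_residual = max(df$residual[df$iteration == max(df$iteration)]))
  }))
  per_freq <- per_freq[order(per_freq$omega), ]
  rownames(per_freq) <- NULL
  cum <- NULL
  for (g in names(diagnostics$groups)) {
    pit <- diagnostics$groups[[g]]$per_iteration
    if (is.null(pit)) next
    pit$group <- g
    pit$cumulative_trial_vectors <- cumsum(pit$new_vectors)
    pit$cumulative_sigma_pairs <- cumsum(pit$sigma_built)
    cum <- rbind(cum, pit)
  }
  out <- list(per_frequency = per_freq, cumulative = cum)
  attr(out, "partial") <- FALSE
  out
}
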