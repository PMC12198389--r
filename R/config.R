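#' Run configuration files
#'
#' A run config is a YAML file that fully specifies a scan so the run is
#' reproducible from its echo.  Recognized keys:
#'
#' ```yaml
#' backend: bead_spring_flex         # or muller_brown, quartic_double_well
#' scan: k                           # "k" or "force"
#' grid: [0, 2.5, 5, 10, 15, 20, 30, 40, 50]
#' alignment: attachment_in_plane    # k scans only
#' attachment_pair: [1, 3]           # 1-based atom indices
#' reactant_xyz: reactant.xyz        # optional; default: built-in fixture
#' ts_xyz: ts.xyz                    # optional
#' settings:
#'   gradient_convergence: 1.0e-4
#'   max_steps: 500
#'   seed: 1
#' out: scan.csv
#' ```
#'
#' @param path YAML file path.
#' @return validated config list of class `fmpes_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$backend <- cfg$backend %||% "bead_spring_flex"
  cfg$scan <- cfg$scan %||% "k"
  if (!cfg$scan %in% c("k", "force")) {
    stop("config 'scan' must be \"k\" or \"force\"", call. = FALSE)
  }
  st <- cfg$settings %||% list()
  cfg$settings <- do.call(opt_settings, st)
  structure(cfg, class = "fmpes_config")
}

#' Execute a scan described by a run config
#'
#' Loads (or generates) the starting structures, builds the requested
#' backend, runs the scan and — when `out` is set — writes the CSV table
#' plus a YAML echo of the resolved configuration next to it.
#'
#' @param config an `fmpes_config` from [read_run_config()], or a path.
#' @return the `fmpes_scan` table, invisibly when written to file.
#' @export
run_from_config <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  backend <- switch(config$backend,
                    bead_spring_flex = bead_spring_flex_backend(),
                    muller_brown = muller_brown_backend(),
                    quartic_double_well = quartic_double_well_backend(),
                    stop("unknown backend '", config$backend, "'",
                         call. = FALSE))
  reactant <- if (!is.null(config$reactant_xyz)) {
    read_xyz(config$reactant_xyz)
  } else if (config$backend == "bead_spring_flex") {
    bead_spring_flex_geometry("reactant")
  } else stop("config needs reactant_xyz for backend '", config$backend,
              "'", call. = FALSE)
  ts_guess <- if (!is.null(config$ts_xyz)) {
    read_xyz(config$ts_xyz)
  } else if (config$backend == "bead_spring_flex") {
    bead_spring_flex_geometry("ts")
  } else NULL
  if (!is.null(config$attachment_pair)) {
    reactant$attachment_pair <- as.integer(config$attachment_pair)
  }
  scan <- if (config$scan == "k") {
    scan_uniaxial_k(reactant, ts_guess, backend,
                    ks = config$grid %||% c(0, 2.5, 5, 10, 15, 20, 30, 40, 50),
                    settings = config$settings,
                    alignment = config$alignment)
  } else {
    scan_pulling_force(reactant, ts_guess, backend,
                       forces = config$grid %||% seq(0, 4, by = 0.5),
                       settings = config$settings)
  }
  if (!is.null(config$out)) {
    write_scan_csv(scan, config$out)
    echo <- unclass(config)
    echo$settings <- unclass(config$settings)
    yaml::write_yaml(echo, paste0(config$out, ".config.yaml"))
    return(invisible(scan))
  }
  scan
}

`%||%` <- function(a, b) if (is.null(a)) b else a
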