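#' Activation energy between two stationary points
#'
#' V_A = E(TS) - E(reactant), reported in kcal/mol.  Both points must be
#' converged and must live on the same (identically perturbed) surface:
#' comparing energies across different external perturbations is invalid
#' and raises an error.
#'
#' @param reactant,ts `stationary_point` objects from [minimize()] /
#'   [dimer_ts_search()] on the same surface.
#' @return scalar activation energy in kcal/mol.
#' @export
activation_energy <- function(reactant, ts) {
  stopifnot(inherits(reactant, "stationary_point"),
            inherits(ts, "stationary_point"))
  if (!identical(reactant$pes_signature, ts$pes_signature)) {
    stop("reactant and TS were obtained on different surfaces (",
         reactant$pes_signature, " vs ", ts$pes_signature,
         "); activation energies across different perturbations are invalid",
         call. = FALSE)
  }
  if (!isTRUE(reactant$converged) || !isTRUE(ts$converged)) {
    stop("both stationary points must be converged", call. = FALSE)
  }
  (ts$energy - reactant$energy) * .HARTREE_KCAL
}

## shared scan engine: loops over perturbation values, builds the modified
## surface, re-optimizes reactant (minimize) and TS (dimer), with optional
## warm-start continuation from the previous step's converged structures.
.run_scan <- function(reactant, ts_guess, pes_base, values, term_factory,
                      settings, warm_start, value_name, value_unit) {
  ord <- order(values)
  values <- values[ord]
  rows <- vector("list", length(values))
  cur_reactant <- reactant
  cur_ts <- ts_guess
  for (i in seq_along(values)) {
    val <- values[i]
    pes <- compose_modified_pes(pes_base, term_factory(val))
    r_sp <- minimize(cur_reactant, pes, settings)
    row <- data.frame(value = val,
                      e_reactant = r_sp$energy,
                      e_ts = NA_real_,
                      activation_kcal = NA_real_,
                      reactant_converged = r_sp$converged,
                      ts_converged = NA,
                      ts_is_saddle = NA,
                      reactant_sum_z2 = sum_z_squared(r_sp$geometry))
    ts_sp <- NULL
    if (!is.null(cur_ts)) {
      ts_sp <- suppressWarnings(dimer_ts_search(cur_ts, pes, settings))
      row$e_ts <- ts_sp$energy
      row$ts_converged <- ts_sp$converged
      row$ts_is_saddle <- ts_sp$classification == "first_order_saddle"
      if (isTRUE(ts_sp$converged) && isTRUE(row$ts_is_saddle) &&
          isTRUE(r_sp$converged)) {
        ## saddle collapse or non-convergence leaves the row's V_A as NA
        ## rather than reporting an invalid number
        row$activation_kcal <- (ts_sp$energy - r_sp$energy) * .HARTREE_KCAL
      }
    }
    rows[[i]] <- row
    if (warm_start) {
      if (r_sp$converged) cur_reactant <- r_sp$geometry
      if (!is.null(ts_sp) && ts_sp$converged) cur_ts <- ts_sp$geometry
    }
  }
  out <- do.call(rbind, rows)
  names(out)[1] <- value_name
  structure(out,
            class = c("fmpes_scan", "data.frame"),
            metadata = list(backend = pes_base$name,
                            value_name = value_name,
                            value_unit = value_unit,
                            warm_start = warm_start,
                            settings = unclass(settings),
                            seed = settings$seed))
}

#' Activation energy versus pulling force
#'
#' Scans a constant collinear pulling force over a grid (default 0 to
#' 4.0 nN in 0.5 nN increments): at each force the reactant is minimized
#' and the transition state dimer-optimized on the force-modified surface,
#' warm-started from the previous step's converged structures
#' (continuation), and the activation energy V_A is tabulated.  The zero-
#' force row reproduces the unperturbed barrier.
#'
#' @param reactant starting reactant [geometry()].
#' @param ts_guess starting transition-state guess [geometry()], or NULL
#'   for a reactant-only scan.
#' @param pes_base the unperturbed [potential_backend()].
#' @param forces force grid in nN (default `seq(0, 4, by = 0.5)`).
#' @param settings an [opt_settings()] list.
#' @param attachment_pair the two pulled atoms; defaults to the reactant
#'   geometry's own attachment pair.
#' @param warm_start continuation between steps (default TRUE); FALSE
#'   re-optimizes every step from the original inputs (cold start, for
#'   auditing).
#' @param term_factory optional function(force_nN) returning the external
#'   term; overrides the default [pulling_term()] (used e.g. to apply a
#'   one-dimensional [linear_tilt_term()] on benchmark surfaces).
#' @return an `fmpes_scan` data frame: one row per force with reactant/TS
#'   energies (hartree), `activation_kcal`, convergence and saddle-validity
#'   flags, and the reactant's flatness measure `reactant_sum_z2`
#'   (Angstrom^2).  Failed rows carry NA activation energies; the scan
#'   continues past them.
#' @export
scan_pulling_force <- function(reactant, ts_guess, pes_base,
                               forces = seq(0, 4, by = 0.5),
                               settings = opt_settings(),
                               attachment_pair = reactant$attachment_pair,
                               warm_start = TRUE,
                               term_factory = NULL) {
  if (is.null(term_factory)) {
    if (is.null(attachment_pair)) {
      stop("scan_pulling_force needs an attachment_pair (or a term_factory)",
           call. = FALSE)
    }
    term_factory <- function(f) {
      if (f == 0) list() else list(pulling_term(f, attachment_pair))
    }
  } else {
    tf <- term_factory
    term_factory <- function(f) {
      tm <- tf(f)
      if (inherits(tm, "fmpes_external_term")) list(tm) else tm
    }
  }
  .run_scan(reactant, ts_guess, pes_base, forces, term_factory, settings,
            warm_start, value_name = "force_nN", value_unit = "nN")
}

#' Activation energy versus uniaxial compression force constant
#'
#' Scans the harmonic uniaxial-compression strength k over a grid (default
#' `{0, 2.5, 5, 10, 15, 20, 30, 40, 50}` N/m: 10 N/m increments, finer
#' below 20 N/m to resolve the onset).  The working frame is established
#' once at the start — the reactant is aligned with [align_to_frame()] and
#' the identical rigid transformation is applied to the TS guess — and held
#' fixed across the scan.  At each k the reactant is minimized and the TS
#' dimer-optimized on the compressed surface with warm-start continuation,
#' and V_A is tabulated; structures flatten (non-increasing sum of squared
#' z) as k grows.
#'
#' @inheritParams scan_pulling_force
#' @param ks force-constant grid in N/m.
#' @param alignment `"attachment_in_plane"` when the reactant has an
#'   attachment pair (the default), else `"principal_axes"`; `"none"` keeps
#'   the input frame.
#' @return an `fmpes_scan` data frame, as in [scan_pulling_force()].
#' @export
scan_uniaxial_k <- function(reactant, ts_guess, pes_base,
                            ks = c(0, 2.5, 5, 10, 15, 20, 30, 40, 50),
                            settings = opt_settings(),
                            alignment = NULL,
                            warm_start = TRUE) {
  if (any(ks < 0)) stop("compression force constants must be >= 0",
                        call. = FALSE)
  if (is.null(alignment)) {
    alignment <- if (!is.null(reactant$attachment_pair)) {
      "attachment_in_plane"
    } else "principal_axes"
  }
  if (pes_base$coord_unit == "angstrom" && alignment != "none") {
    reactant <- align_to_frame(reactant, alignment)
    if (!is.null(ts_guess)) {
      ts_guess <- apply_frame(ts_guess, attr(reactant, "transform"))
    }
  }
  out <- .run_scan(reactant, ts_guess, pes_base, ks,
                   function(k) if (k == 0) list() else list(uniaxial_term(k)),
                   settings, warm_start,
                   value_name = "k_N_m", value_unit = "N/m")
  md <- attr(out, "metadata")
  md$alignment <- alignment
  attr(out, "metadata") <- md
  out
}

#' @export
print.fmpes_scan <- function(x, ...) {
  md <- attr(x, "metadata")
  cat(sprintf("<fmpes_scan on '%s': %s in %s, %d rows%s>\n", md$backend,
              md$value_name, md$value_unit, nrow(x),
              if (isTRUE(md$warm_start)) ", warm-start" else ", cold-start"))
  print.data.frame(x, row.names = FALSE, digits = 6)
  invisible(x)
}

#' Write / read a scan table as CSV with metadata header
#'
#' The metadata (backend, grid unit, settings, seed, alignment) is stored
#' as `# key: value` lines above the CSV header, so the file is both
#' machine-parsable and self-describing; [read_scan_csv()] restores an
#' equivalent in-memory table.
#'
#' @param scan an `fmpes_scan` object.
#' @param path output file.
#' @return `path` invisibly (writer); an `fmpes_scan` (reader).
#' @export
write_scan_csv <- function(scan, path) {
  md <- attr(scan, "metadata")
  flat <- function(x) {
    if (is.list(x)) paste(sprintf("%s=%s", names(x), unlist(x)),
                          collapse = "; ")
    else paste(x, collapse = ",")
  }
  hdr <- sprintf("# %s: %s", names(md), vapply(md, flat, character(1)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(as.data.frame(scan), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scan_csv
#' @export
read_scan_csv <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines)
  md <- list()
  for (ln in lines[meta_lines]) {
    kv <- sub("^#\\s*", "", ln)
    key <- sub(":.*$", "", kv)
    md[[key]] <- trimws(sub("^[^:]*:", "", kv))
  }
  df <- utils::read.csv(text = paste(lines[-meta_lines], collapse = "\n"))
  structure(df, class = c("fmpes_scan", "data.frame"), metadata = md)
}
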