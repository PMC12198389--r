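#' Read a geometry from an XYZ file
#'
#' Standard XYZ layout: an atom-count line, a comment line, then one
#' `element x y z` record per atom (coordinates in Angstrom).  Metadata may
#' be stored on the comment line as whitespace-separated `key=value` pairs;
#' the keys `attachment_pair` (two comma-separated 1-based indices) and
#' `frozen` (comma-separated 1-based indices) are mapped onto the geometry
#' fields and round-trip through [write_xyz()].
#'
#' @param path file path.
#' @return an [geometry()] object.
#' @examples
#' f <- tempfile(fileext = ".xyz")
#' writeLines(c("1", "", "H 0 0 0"), f)
#' read_xyz(f)
#' @export
read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2) stop("XYZ file too short: ", path, call. = FALSE)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1) {
    stop("line 1: malformed atom count '", trimws(lines[1]), "'",
         call. = FALSE)
  }
  if (length(lines) < n + 2) {
    stop(sprintf("count line declares %d atoms but file body has only %d lines",
                 n, length(lines) - 2), call. = FALSE)
  }
  comment <- lines[2]
  elements <- character(n)
  coords <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    ln <- i + 2
    tok <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(tok) < 4) {
      stop(sprintf("line %d: expected 'element x y z', got '%s'",
                   ln, lines[ln]), call. = FALSE)
    }
    xyz <- suppressWarnings(as.numeric(tok[2:4]))
    if (anyNA(xyz)) {
      stop(sprintf("line %d: could not parse coordinates", ln), call. = FALSE)
    }
    elements[i] <- tok[1]
    coords[i, ] <- xyz
  }
  meta <- .parse_xyz_meta(comment)
  geometry(elements, coords,
           attachment_pair = meta$attachment_pair,
           frozen_mask = if (!is.null(meta$frozen)) {
             seq_len(n) %in% meta$frozen
           },
           comment = meta$comment)
}

#' Write a geometry (or trajectory) to an XYZ file
#'
#' @param geom an [geometry()] object, or a list of geometries (written as a
#'   multi-frame XYZ trajectory).
#' @param path file path.
#' @param digits number of decimal places for coordinates (default 8, which
#'   round-trips well below any optimizer tolerance used here).
#' @return `path`, invisibly.
#' @export
write_xyz <- function(geom, path, digits = 8) {
  frames <- if (inherits(geom, "fmpes_geometry")) list(geom) else geom
  out <- unlist(lapply(frames, function(g) {
    meta <- character(0)
    if (nzchar(g$comment)) meta <- g$comment
    if (!is.null(g$attachment_pair)) {
      meta <- c(meta, sprintf("attachment_pair=%d,%d",
                              g$attachment_pair[1], g$attachment_pair[2]))
    }
    if (!is.null(g$frozen_mask) && any(g$frozen_mask)) {
      meta <- c(meta, paste0("frozen=",
                             paste(which(g$frozen_mask), collapse = ",")))
    }
    body <- sprintf(paste0("%-2s %", digits + 6, ".", digits, "f %",
                           digits + 6, ".", digits, "f %",
                           digits + 6, ".", digits, "f"),
                    g$elements, g$coords[, 1], g$coords[, 2], g$coords[, 3])
    c(as.character(n_atoms(g)), paste(meta, collapse = " "), body)
  }))
  writeLines(out, path)
  invisible(path)
}

## comment line: free text plus key=value pairs (keys we know are consumed,
## the rest stays part of the comment text)
.parse_xyz_meta <- function(comment) {
  tok <- strsplit(trimws(comment), "\\s+")[[1]]
  tok <- tok[nzchar(tok)]
  is_kv <- grepl("^[A-Za-z_][A-Za-z0-9_]*=", tok)
  kv <- tok[is_kv]
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  pick <- function(key) {
    i <- match(key, keys)
    if (is.na(i)) NULL else as.integer(strsplit(vals[i], ",")[[1]])
  }
  list(attachment_pair = pick("attachment_pair"),
       frozen = pick("frozen"),
       comment = paste(tok[!is_kv], collapse = " "))
}
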