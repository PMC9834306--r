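# PDB snapshot I/O and trajectory assembly. The PDB dialect is deliberately
# minimal: only ATOM/HETATM/TER/END records are honoured (the files are used
# purely as coordinate containers), coordinates are Angstrom with no periodic
# boundary handling.

#' Validate a snapshot atom table
#'
#' A snapshot is a data frame with one row per atom and columns `element`,
#' `residue_name`, `residue_id`, `x`, `y`, `z`. It must contain at least two
#' atoms, finite coordinates, positive residue ids, and only vocabulary
#' elements. A single timestep is required: if `timestep` is present it must
#' be constant.
#'
#' @param snapshot Data frame to validate.
#' @param vocabulary Allowed element symbols.
#' @param min_atoms Minimum atom count (2 for descriptor work; single-atom
#'   tables are meaningful for SASA).
#' @return The input, invisibly, if valid; otherwise an error.
#' @export
validate_snapshot <- function(snapshot, vocabulary = mbtr_vocabulary(),
                              min_atoms = 2) {
  need <- c("element", "residue_name", "residue_id", "x", "y", "z")
  missing_cols <- setdiff(need, names(snapshot))
  if (length(missing_cols) > 0) {
    abort(paste0("snapshot lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(snapshot) < min_atoms) {
    abort(paste0("snapshot needs at least ", min_atoms, " atom(s)"))
  }
  if ("timestep" %in% names(snapshot) &&
      length(unique(snapshot$timestep)) != 1) {
    abort("snapshot spans multiple timesteps")
  }
  bad <- setdiff(unique(snapshot$element), vocabulary)
  if (length(bad) > 0) {
    abort(paste0("element(s) outside vocabulary: ", paste(bad, collapse = ", ")))
  }
  xyz <- as.matrix(snapshot[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) abort("non-finite coordinates in snapshot")
  if (any(nchar(trimws(snapshot$residue_name)) == 0)) {
    abort("empty residue name")
  }
  if (any(snapshot$residue_id < 1)) abort("residue ids must be positive")
  invisible(snapshot)
}

# normalize an element symbol to vocabulary case ("AU" -> "Au"); NA if unknown
.normalize_element <- function(sym, vocabulary) {
  vocabulary[match(toupper(sym), toupper(vocabulary))]
}

# fall back to the atom-name field: leading alphabetic characters, two-letter
# vocabulary symbols (Au, Cl) tried before one-letter ones
.element_from_name <- function(name, vocabulary) {
  alpha <- gsub("[^A-Za-z].*$", "", trimws(name))
  two <- .normalize_element(substr(alpha, 1, 2), vocabulary)
  one <- .normalize_element(substr(alpha, 1, 1), vocabulary)
  ifelse(!is.na(two), two, one)
}

#' Read one PDB snapshot
#'
#' Parses ATOM/HETATM records from PDB text: residue name from columns 18-20,
#' residue sequence number from 23-26, coordinates from 31-54 (Angstrom), and
#' the element from columns 77-78 when present, otherwise inferred from the
#' atom-name field (two-letter vocabulary symbols tried first). All other
#' record types are ignored.
#'
#' @param stream A file path, or a character vector of PDB lines (a single
#'   string may contain newlines).
#' @param vocabulary Allowed element symbols.
#' @param design_id,timestep Optional identifiers attached as columns.
#' @return Snapshot tibble: `element`, `residue_name`, `residue_id`, `x`,
#'   `y`, `z` (plus `design_id`/`timestep` when given).
#' @export
read_pdb_snapshot <- function(stream, vocabulary = mbtr_vocabulary(),
                              design_id = NULL, timestep = NULL) {
  lines <- if (length(stream) == 1 && !grepl("\n", stream) &&
               file.exists(stream)) {
    readLines(stream, warn = FALSE)
  } else {
    unlist(strsplit(stream, "\n", fixed = TRUE))
  }
  is_atom <- startsWith(lines, "ATOM") | startsWith(lines, "HETATM")
  idx <- which(is_atom)
  if (length(idx) == 0) abort("no ATOM/HETATM records in stream")
  al <- lines[idx]

  parse_num <- function(txt, what) {
    out <- suppressWarnings(as.numeric(txt))
    bad <- which(is.na(out) | nchar(trimws(txt)) == 0)
    if (length(bad) > 0) {
      abort(paste0("malformed ", what, " field at line ", idx[bad[1]]))
    }
    out
  }
  x <- parse_num(substr(al, 31, 38), "x coordinate")
  y <- parse_num(substr(al, 39, 46), "y coordinate")
  z <- parse_num(substr(al, 47, 54), "z coordinate")
  res_name <- trimws(substr(al, 18, 20))
  res_id <- parse_num(substr(al, 23, 26), "residue id")

  el_col <- trimws(substr(al, 77, 78))
  element <- .normalize_element(el_col, vocabulary)
  from_name <- .element_from_name(substr(al, 13, 16), vocabulary)
  element[el_col == ""] <- from_name[el_col == ""]
  unknown <- which(is.na(element))
  if (length(unknown) > 0) {
    raw <- ifelse(el_col[unknown] == "",
                  trimws(substr(al[unknown], 13, 16)), el_col[unknown])
    abort(paste0("element(s) outside vocabulary: ",
                 paste(unique(raw), collapse = ", ")))
  }

  snap <- tibble::tibble(
    element = element, residue_name = res_name,
    residue_id = as.integer(res_id), x = x, y = y, z = z)
  if (!is.null(design_id)) snap <- dplyr::mutate(snap, design_id = design_id,
                                                 .before = 1)
  if (!is.null(timestep)) {
    snap <- dplyr::mutate(snap, timestep = as.integer(timestep),
                          .after = if (is.null(design_id)) 0L else 1L)
  }
  validate_snapshot(snap, vocabulary)
  snap
}

#' Write one snapshot as PDB text
#'
#' Emits fixed-width ATOM records (element right-justified in columns 77-78,
#' coordinates at 0.001 Angstrom precision) terminated by END, so that
#' [read_pdb_snapshot()] recovers the snapshot to within 1e-3 Angstrom.
#'
#' @param snapshot Valid snapshot table.
#' @param path Optional file path; when given, lines are written there.
#' @return Character vector of PDB lines (invisibly when `path` is given).
#' @export
write_pdb_snapshot <- function(snapshot, path = NULL) {
  validate_snapshot(snapshot)
  xyz <- as.matrix(snapshot[, c("x", "y", "z")])
  if (any(abs(xyz) > 9999.999)) {
    abort("coordinate magnitude exceeds 9999.999 Angstrom: PDB field overflow")
  }
  n <- nrow(snapshot)
  name <- substr(paste0(snapshot$element, seq_len(n)), 1, 4)
  lines <- sprintf(
    "ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    seq_len(n), name, substr(snapshot$residue_name, 1, 3),
    snapshot$residue_id %% 10000L, snapshot$x, snapshot$y, snapshot$z,
    snapshot$element)
  lines <- c(lines, "END")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Assemble a trajectory from ordered PDB snapshot files
#'
#' Reads one snapshot per file (files must be ordered by timestep) and stacks
#' them into a long atom table with consecutive timesteps `0 .. T-1`. Atom
#' count, element and residue identity must be constant across snapshots.
#'
#' @param paths Character vector of PDB file paths, sorted by timestep.
#' @param design_id Design identifier attached to every row.
#' @param timesteps Optional integer timesteps, one per file; must then be
#'   consecutive from 0.
#' @param vocabulary Allowed element symbols.
#' @return Long tibble: `design_id`, `timestep`, `element`, `residue_name`,
#'   `residue_id`, `x`, `y`, `z`.
#' @export
load_trajectory <- function(paths, design_id, timesteps = NULL,
                            vocabulary = mbtr_vocabulary()) {
  stopifnot(length(paths) >= 1)
  if (is.null(timesteps)) {
    timesteps <- seq_along(paths) - 1L
  } else {
    timesteps <- as.integer(timesteps)
    if (!identical(timesteps, seq_along(paths) - 1L)) {
      abort("gap or disorder in timesteps: expected consecutive 0..T-1")
    }
  }
  snaps <- purrr::map2(paths, timesteps, function(p, t) {
    read_pdb_snapshot(p, vocabulary, design_id = design_id, timestep = t)
  })
  counts <- purrr::map_int(snaps, nrow)
  if (length(unique(counts)) != 1) {
    abort(paste0("atom count differs between snapshot files: ",
                 paste(unique(counts), collapse = " vs ")))
  }
  ident <- purrr::map(snaps, function(s) {
    paste(s$element, s$residue_name, s$residue_id)
  })
  if (!all(purrr::map_lgl(ident, identical, ident[[1]]))) {
    abort("atom identity differs between snapshot files")
  }
  dplyr::bind_rows(snaps)
}

#' Write / read a descriptor table as CSV
#'
#' One row per snapshot with columns `design_id`, `timestep`, `f0` ...
#' `f(n-1)`. Reading a written table reproduces the values to full double
#' precision.
#'
#' @param mbtr_table Descriptor tibble (possibly zero rows with columns
#'   present).
#' @param path CSV path.
#' @return `write_mbtr_table()` returns the input invisibly;
#'   `read_mbtr_table()` returns the tibble.
#' @export
write_mbtr_table <- function(mbtr_table, path) {
  cols <- names(mbtr_table)
  if (!all(c("design_id", "timestep") %in% cols) ||
      !any(grepl("^f[0-9]+$", cols))) {
    abort("descriptor table needs design_id, timestep and f* columns")
  }
  readr::write_csv(mbtr_table, path)
  invisible(mbtr_table)
}

#' @rdname write_mbtr_table
#' @export
read_mbtr_table <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(design_id = "c",
                                                 timestep = "i",
                                                 .default = "d"))
  probs <- readr::problems(out)
  if (nrow(probs) > 0) {
    abort(paste0("malformed descriptor table: ragged or non-numeric row at line ",
                 probs$row[1]))
  }
  out
}

#' Write / read a SASA series as CSV
#'
#' Columns `design_id`, `timestep`, `sasa` (Angstrom^2).
#'
#' @param sasa_table SASA tibble.
#' @param path CSV path.
#' @return As [write_mbtr_table()]/[read_mbtr_table()].
#' @export
write_sasa_table <- function(sasa_table, path) {
  stopifnot(all(c("design_id", "timestep", "sasa") %in% names(sasa_table)))
  readr::write_csv(sasa_table, path)
  invisible(sasa_table)
}

#' @rdname write_sasa_table
#' @export
read_sasa_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(design_id = "c", timestep = "i",
                                          sasa = "d"))
}
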