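## Molecule file I/O: SMILES files (one record per line, optional
## whitespace-separated name) and SDF V2000 connection tables. Invalid records
## are reported with their 1-based record index and excluded, never silently
## dropped.

#' Read molecules from a SMILES or SDF file
#'
#' @param path file path.
#' @param format `"smi"` or `"sdf"`; default guessed from the extension.
#' @return list of `molecule` objects with attributes `n_failed` (integer) and
#'   `failures` (data.frame with columns `record`, `message`).
#' @export
parse_molecules <- function(path, format = c("smi", "sdf")) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (length(format) > 1L) {
    format <- if (grepl("\\.sdf$", path, ignore.case = TRUE)) "sdf" else "smi"
  }
  format <- match.arg(format, c("smi", "sdf"))
  if (format == "smi") parse_smi_file(path) else parse_sdf_file(path)
}

collect_records <- function(records, parser) {
  mols <- list()
  failures <- list()
  for (i in seq_along(records)) {
    res <- tryCatch(parser(records[[i]], i), error = function(e) e)
    if (inherits(res, "error")) {
      warning(sprintf("record %d: %s", i, conditionMessage(res)), call. = FALSE)
      failures[[length(failures) + 1L]] <-
        data.frame(record = i, message = conditionMessage(res))
    } else {
      mols[[length(mols) + 1L]] <- res
    }
  }
  attr(mols, "n_failed") <- length(failures)
  attr(mols, "failures") <- if (length(failures)) do.call(rbind, failures) else
    data.frame(record = integer(), message = character())
  mols
}

parse_smi_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  collect_records(as.list(lines), function(line, i) {
    parts <- strsplit(trimws(line), "[ \t]+")[[1]]
    parse_smiles(parts[1L], name = if (length(parts) > 1L) parts[2L] else NULL)
  })
}

parse_sdf_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  ends <- which(trimws(lines) == "$$$$")
  if (!length(ends)) stop("no SDF records found (missing $$$$ terminators)")
  starts <- c(1L, head(ends, -1L) + 1L)
  recs <- Map(function(s, e) lines[s:(e - 1L)], starts, ends)
  collect_records(recs, function(rec, i) parse_sdf_record(rec))
}

parse_sdf_record <- function(rec) {
  rec <- rec[cumsum(nzchar(rec) | seq_along(rec) <= 4L) > 0L]
  if (length(rec) < 4L) stop("truncated SDF record")
  name <- trimws(rec[1L])
  counts <- rec[4L]
  na <- as.integer(substr(counts, 1L, 3L))
  nb <- as.integer(substr(counts, 4L, 6L))
  if (is.na(na) || is.na(nb)) stop("bad counts line")
  if (length(rec) < 4L + na + nb) stop("truncated atom/bond block")
  atom_lines <- rec[5L:(4L + na)]
  element <- trimws(substr(atom_lines, 32L, 34L))
  old_chg <- suppressWarnings(as.integer(substr(atom_lines, 37L, 39L)))
  charge <- vapply(old_chg, function(cc) {
    if (is.na(cc) || cc == 0L) 0L else c(3L, 2L, 1L, 0L, -1L, -2L, -3L)[cc]
  }, integer(1))
  bond_a <- integer(nb); bond_b <- integer(nb); bond_order <- integer(nb)
  if (nb > 0L) {
    bond_lines <- rec[(5L + na):(4L + na + nb)]
    bond_a <- as.integer(substr(bond_lines, 1L, 3L))
    bond_b <- as.integer(substr(bond_lines, 4L, 6L))
    bond_order <- as.integer(substr(bond_lines, 7L, 9L))
  }
  # M  CHG overrides the atom-block charge column
  chg_lines <- grep("^M  CHG", rec, value = TRUE)
  for (cl in chg_lines) {
    f <- as.integer(strsplit(trimws(sub("^M  CHG", "", cl)), "[ ]+")[[1]])
    npairs <- f[1L]
    if (npairs > 0L) charge[f[seq(2L, by = 2L, length.out = npairs)]] <-
      f[seq(3L, by = 2L, length.out = npairs)]
  }
  mol <- molecule(element, bond_a, bond_b, bond_order, charge = charge,
                  name = if (nzchar(name)) name else NULL)
  perceive_aromaticity(mol)
}

#' Write molecules to a SMILES or SDF file
#'
#' Round-tripping through either format preserves element counts, bond orders,
#' formal charges and valence verdicts.
#'
#' @param mols list of `molecule` objects.
#' @param path output file path.
#' @param format `"smi"` or `"sdf"`.
#' @return number of records written, invisibly.
#' @export
write_molecules <- function(mols, path, format = c("smi", "sdf")) {
  format <- match.arg(format)
  if (format == "smi") {
    lines <- vapply(mols, function(m) {
      smi <- write_smiles(m)
      if (!is.null(m$name)) paste(smi, m$name) else smi
    }, character(1))
    writeLines(lines, path)
  } else {
    blocks <- vapply(mols, sdf_block, character(1))
    writeLines(paste0(blocks, collapse = ""), path, sep = "")
  }
  invisible(length(mols))
}

sdf_block <- function(mol) {
  m <- kekulize(mol) # V2000 written kekulized; aromaticity re-perceived on read
  na <- n_atoms(m); nb <- n_bonds(m)
  header <- c(m$name %||% "", "  decoygen", "", sprintf(
    "%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb))
  atoms <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                   0, 0, 0, m$element)
  bonds <- if (nb) sprintf("%3d%3d%3d  0", m$bond_a, m$bond_b, m$bond_order)
           else character()
  chg <- which(m$charge != 0L)
  chg_lines <- if (length(chg)) {
    sprintf("M  CHG%3d%s", length(chg),
            paste(sprintf("%4d%4d", chg, m$charge[chg]), collapse = ""))
  } else character()
  paste0(paste(c(header, atoms, bonds, chg_lines, "M  END", "$$$$"),
               collapse = "\n"), "\n")
}
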