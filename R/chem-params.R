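#' Load an atom-chemistry parameter table
#'
#' Reads a CSV with header
#' `key_residue,key_atom,covalent_radius,vdw_radius,charge,donor,acceptor`.
#' Rows with `key_residue == "*"` are per-element defaults (the key_atom
#' column then holds the element symbol); all other rows are residue+atom
#' specific entries.  The shipped element defaults always back the loaded
#' table, so lookup stays total over recognised elements: user `*` rows
#' override shipped defaults, and residue+atom entries override element
#' defaults at query time.
#'
#' @param csv path to a CSV file, or the CSV content itself as a
#'   character vector (detected by the presence of a newline/comma
#'   header line).
#' @return A [ParameterSet-class].
#' @details Malformed rows are rejected with their row number: a
#'   non-numeric or non-positive radius, a covalent radius not strictly
#'   below the van der Waals radius, a charge outside \{-1, 0, +1\},
#'   non-0/1 donor/acceptor flags, or a duplicate key.
#' @examples
#' ps <- loadParams("ALA,CB,0.76,1.70,0,0,0")
#' lookupChemistry(ps, "ALA", "CB", "C")
#' @export
loadParams <- function(csv) {
  lines <- chemCsvLines(csv)
  header <- strsplit(lines[1L], ",", fixed = TRUE)[[1L]]
  if (!identical(trimws(header), CHEM_COLS))
    stop("parameter CSV header must be: ", paste(CHEM_COLS, collapse = ","))
  body <- lines[-1L]
  body <- body[nzchar(trimws(body))]
  df <- parseChemRows(body)
  shipped <- shippedChemTable()
  defaults <- df[df$key_residue == "*", , drop = FALSE]
  entries <- df[df$key_residue != "*", , drop = FALSE]
  # user element defaults override the shipped ones
  base <- shipped[shipped$key_residue == "*", , drop = FALSE]
  base <- base[!base$key_atom %in% defaults$key_atom, , drop = FALSE]
  defaults <- rbind(defaults, base)
  rownames(entries) <- rownames(defaults) <- NULL
  new("ParameterSet", entries = entries, defaults = defaults)
}

#' The shipped default parameter set
#'
#' Covalent radii follow standard published single-bond covalent radii
#' and van der Waals radii the standard crystallographic compilations;
#' formal charge signs and donor/acceptor flags are assigned from
#' amino-acid side-chain templates (carboxylate oxygens -1 acceptors,
#' Lys/Arg side-chain nitrogens +1 donors, hydroxyl oxygens
#' donor+acceptor, His ring nitrogens neutral donor+acceptor, backbone
#' N/O donor/acceptor via the element defaults) and from common
#' monatomic-ion component codes.  Replace wholesale with [loadParams()]
#' if a different calibration is required.
#'
#' @return A [ParameterSet-class].
#' @export
defaultParams <- function() {
  cached <- get0(".defaultParams", envir = pkgCache)
  if (!is.null(cached)) return(cached)
  ps <- loadParams(system.file("extdata", "atom_chemistry.csv",
                               package = "DomainContacts", mustWork = TRUE))
  assign(".defaultParams", ps, envir = pkgCache)
  ps
}

pkgCache <- new.env(parent = emptyenv())

#' Look up the chemistry of one atom
#'
#' Returns the residue+atom specific entry when present, otherwise the
#' element default.  Deterministic: identical queries always return the
#' identical row.
#'
#' @param params a [ParameterSet-class].
#' @param resname residue name (3-character code).
#' @param atomname PDB atom name.
#' @param element chemical element symbol.
#' @return One-row data.frame with covalent_radius, vdw_radius, charge,
#'   donor, acceptor.
#' @details An element absent from the defaults raises an error of class
#'   `unparameterizedAtom`; bulk callers (bond detection) catch this
#'   policy-wise by skipping the atom with a warning.
#' @export
lookupChemistry <- function(params, resname, atomname, element) {
  row <- chemLookup(params, resname, atomname, element)
  if (is.na(row$covalent_radius)) {
    stop(structure(class = c("unparameterizedAtom", "error", "condition"),
                   list(message = sprintf(
                     "unparameterized atom: %s/%s element '%s'",
                     resname, atomname, element), call = sys.call(-1L))))
  }
  row
}

# Vectorised lookup: returns a data.frame aligned with the inputs;
# unparameterized atoms come back as NA rows (caller decides policy).
chemLookup <- function(params, resname, atomname, element) {
  n <- max(length(resname), length(atomname), length(element))
  resname <- rep_len(toupper(trimws(resname)), n)
  atomname <- rep_len(toupper(trimws(atomname)), n)
  element <- rep_len(toupper(trimws(element)), n)
  ek <- paste(params@entries$key_residue, params@entries$key_atom)
  hit <- match(paste(resname, atomname), ek)
  dflt <- match(element, params@defaults$key_atom)
  out <- data.frame(covalent_radius = NA_real_, vdw_radius = NA_real_,
                    charge = NA_integer_, donor = NA_integer_,
                    acceptor = NA_integer_)[rep(1L, n), , drop = FALSE]
  cols <- c("covalent_radius", "vdw_radius", "charge", "donor", "acceptor")
  useD <- is.na(hit) & !is.na(dflt)
  if (any(useD)) out[useD, cols] <- params@defaults[dflt[useD], cols]
  useE <- !is.na(hit)
  if (any(useE)) out[useE, cols] <- params@entries[hit[useE], cols]
  rownames(out) <- NULL
  out
}

chemCsvLines <- function(csv) {
  if (length(csv) == 1L && !grepl("[,\n]", csv)) {
    if (!file.exists(csv)) stop("parameter CSV not found: ", csv)
    return(readLines(csv, warn = FALSE))
  }
  if (length(csv) == 1L && grepl("\n", csv, fixed = TRUE))
    csv <- strsplit(csv, "\n", fixed = TRUE)[[1L]]
  # bare data rows without a header are accepted for convenience
  if (!grepl("^\\s*key_residue\\s*,", csv[1L]))
    csv <- c(paste(CHEM_COLS, collapse = ","), csv)
  csv
}

parseChemRows <- function(body) {
  df <- data.frame(key_residue = character(0), key_atom = character(0),
                   covalent_radius = numeric(0), vdw_radius = numeric(0),
                   charge = integer(0), donor = integer(0),
                   acceptor = integer(0), stringsAsFactors = FALSE)
  if (length(body) == 0L) return(df)
  seen <- character(0)
  rows <- vector("list", length(body))
  for (i in seq_along(body)) {
    f <- trimws(strsplit(body[i], ",", fixed = TRUE)[[1L]])
    rowno <- i + 1L                       # header is row 1
    if (length(f) != 7L)
      stop(sprintf("row %d: expected 7 fields, found %d", rowno, length(f)))
    num <- suppressWarnings(as.numeric(f[3:7]))
    if (any(is.na(num)))
      stop(sprintf("row %d: non-numeric value '%s'",
                   rowno, f[3:7][is.na(num)][1L]))
    if (num[1L] <= 0 || num[2L] <= 0)
      stop(sprintf("row %d: radii must be > 0", rowno))
    if (num[1L] >= num[2L])
      stop(sprintf("row %d: covalent radius (%g) must be < vdW radius (%g)",
                   rowno, num[1L], num[2L]))
    if (!num[3L] %in% c(-1, 0, 1))
      stop(sprintf("row %d: charge must be -1, 0 or +1", rowno))
    if (!all(num[4:5] %in% c(0, 1)))
      stop(sprintf("row %d: donor/acceptor must be 0 or 1", rowno))
    key <- toupper(paste(f[1L], f[2L]))
    if (key %in% seen) stop(sprintf("row %d: duplicate key '%s %s'",
                                    rowno, f[1L], f[2L]))
    seen <- c(seen, key)
    rows[[i]] <- data.frame(key_residue = toupper(f[1L]),
                            key_atom = toupper(f[2L]),
                            covalent_radius = num[1L], vdw_radius = num[2L],
                            charge = as.integer(num[3L]),
                            donor = as.integer(num[4L]),
                            acceptor = as.integer(num[5L]),
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

shippedChemTable <- function() {
  cached <- get0(".shippedChem", envir = pkgCache)
  if (!is.null(cached)) return(cached)
  path <- system.file("extdata", "atom_chemistry.csv",
                      package = "DomainContacts", mustWork = TRUE)
  lines <- readLines(path, warn = FALSE)
  df <- parseChemRows(lines[-1L])
  assign(".shippedChem", df, envir = pkgCache)
  df
}
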