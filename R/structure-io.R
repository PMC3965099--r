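#' Parse a legacy PDB coordinate file
#'
#' Reads the fixed-column ATOM/HETATM/MODRES/LINK/TER/MODEL/ENDMDL
#' dialect into a [PDBStructure-class].  Only the first MODEL of a
#' multi-model file is kept, matching single-conformer analysis of the
#' asymmetric unit.  The element symbol is taken from columns 77-78 when
#' present, otherwise inferred from the atom name.
#'
#' @param input path to a PDB file, or the file content as a character
#'   vector of lines (or one string containing newlines).
#' @param pdbId identifier to attach; defaults to "" (fixtures) unless
#'   the input is a file whose basename looks like a 4-character id.
#' @return A [PDBStructure-class].
#' @details Coordinate records are validated field-by-field before
#'   parsing; an unparseable record raises an error naming its line
#'   number.  A file with zero coordinate records is an error.
#' @export
readPDBStructure <- function(input, pdbId = NULL) {
  lines <- pdbInputLines(input)
  if (is.null(pdbId)) pdbId <- ""
  # restrict to the first model
  mstart <- grep("^MODEL ", lines)
  if (length(mstart) > 0L) {
    mend <- grep("^ENDMDL", lines)
    last <- if (length(mend) > 0L) mend[1L] else length(lines)
    keep <- c(seq_len(mstart[1L] - 1L),
              seq.int(mstart[1L], last),
              which(seq_along(lines) > last &
                    !grepl("^(ATOM  |HETATM|MODEL |ENDMDL|TER)", lines)))
    lines <- lines[sort(unique(keep))]
  }
  validateCoordLines(lines)
  coord <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(coord)) stop("no ATOM/HETATM records found (zero atoms)")

  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  writeLines(lines, tmp)
  pdb <- bio3d::read.pdb(tmp, multi = FALSE, rm.alt = FALSE,
                         verbose = FALSE)
  a <- pdb$atom
  blank <- function(v) ifelse(is.na(v), "", v)
  atoms <- data.frame(record = a$type, serial = as.integer(a$eleno),
                      name = trimws(a$elety), altloc = blank(a$alt),
                      resname = trimws(a$resid), chain = blank(a$chain),
                      resno = as.integer(a$resno), icode = blank(a$insert),
                      x = a$x, y = a$y, z = a$z,
                      occupancy = ifelse(is.na(a$o), 1, a$o),
                      element = toupper(blank(trimws(a$elesy))),
                      stringsAsFactors = FALSE)
  noel <- !nzchar(atoms$element)
  if (any(noel))
    atoms$element[noel] <- inferElement(atoms$name[noel],
                                        atoms$resname[noel])
  new("PDBStructure", pdbId = pdbId, atoms = atoms,
      modres = parseModres(lines), links = parseLinks(lines))
}

pdbInputLines <- function(input) {
  if (length(input) == 1L && !grepl("\n", input, fixed = TRUE) &&
      file.exists(input))
    return(readLines(input, warn = FALSE))
  if (length(input) == 1L && grepl("\n", input, fixed = TRUE))
    return(strsplit(input, "\n", fixed = TRUE)[[1L]])
  if (length(input) == 1L && !grepl("^(ATOM|HETATM|MODEL|HEADER|MODRES|LINK|TER|REMARK|CRYST|END)", input))
    stop("PDB input not found: ", input)
  input
}

validateCoordLines <- function(lines) {
  idx <- grep("^(ATOM  |HETATM)", lines)
  for (i in idx) {
    ln <- lines[i]
    if (nchar(ln) < 54L)
      stop(sprintf("line %d: coordinate record too short (%d columns)",
                   i, nchar(ln)))
    fields <- c(serial = substr(ln, 7, 11), resno = substr(ln, 23, 26),
                x = substr(ln, 31, 38), y = substr(ln, 39, 46),
                z = substr(ln, 47, 54))
    num <- suppressWarnings(as.numeric(fields))
    if (any(is.na(num)))
      stop(sprintf("line %d: unparseable field '%s' in fixed columns",
                   i, trimws(fields[is.na(num)][1L])))
  }
  invisible(TRUE)
}

# Element inference from the PDB atom name when columns 77-78 are blank.
# Two-letter elements are recognised when the first column (col 13) is
# occupied by a letter matching a known symbol; otherwise the first
# alphabetic character is the element.
inferElement <- function(name, resname) {
  two <- c("FE", "ZN", "MG", "MN", "CU", "NA", "CL", "BR", "SE", "CO",
           "NI", "CA")
  vapply(seq_along(name), function(i) {
    nm <- toupper(gsub("[^A-Z0-9]", "", toupper(name[i])))
    # monatomic ion residues: atom name equals the component code
    if (toupper(trimws(resname[i])) == nm && nm %in% two) return(nm)
    first <- regmatches(nm, regexpr("[A-Z]", nm))
    if (length(first) == 0L) return("")
    first
  }, character(1))
}

parseModres <- function(lines) {
  mr <- lines[startsWith(lines, "MODRES")]
  if (length(mr) == 0L)
    return(data.frame(chain = character(0), resno = integer(0),
                      icode = character(0), resname = character(0),
                      stringsAsFactors = FALSE))
  data.frame(chain = trimws(substr(mr, 17, 17)),
             resno = as.integer(substr(mr, 19, 22)),
             icode = trimws(substr(mr, 23, 23)),
             resname = trimws(substr(mr, 13, 15)),
             stringsAsFactors = FALSE)
}

parseLinks <- function(lines) {
  lk <- lines[startsWith(lines, "LINK")]
  empty <- data.frame(name1 = character(0), resname1 = character(0),
                      chain1 = character(0), resno1 = integer(0),
                      icode1 = character(0), name2 = character(0),
                      resname2 = character(0), chain2 = character(0),
                      resno2 = integer(0), icode2 = character(0),
                      stringsAsFactors = FALSE)
  if (length(lk) == 0L) return(empty)
  lk <- formatC(lk, width = 72, flag = "-")
  data.frame(name1 = trimws(substr(lk, 13, 16)),
             resname1 = trimws(substr(lk, 18, 20)),
             chain1 = trimws(substr(lk, 22, 22)),
             resno1 = as.integer(substr(lk, 23, 26)),
             icode1 = trimws(substr(lk, 27, 27)),
             name2 = trimws(substr(lk, 43, 46)),
             resname2 = trimws(substr(lk, 48, 50)),
             chain2 = trimws(substr(lk, 52, 52)),
             resno2 = as.integer(substr(lk, 53, 56)),
             icode2 = trimws(substr(lk, 57, 57)),
             stringsAsFactors = FALSE)
}

#' Select one alternate location per atom
#'
#' For every (residue, atom name) modelled in multiple alternate
#' locations, retains exactly one: the highest occupancy, ties broken by
#' the alphabetically smallest altloc indicator.  Atoms with a blank
#' altloc are untouched.
#'
#' @param structure a [PDBStructure-class].
#' @return A [PDBStructure-class] with unique (residue, atom name) pairs.
#' @export
selectAltloc <- function(structure) {
  at <- structure@atoms
  alt <- nzchar(at$altloc)
  if (!any(alt)) return(structure)
  key <- paste(at$chain, at$resno, at$icode, at$name, sep = "\r")
  drop <- logical(nrow(at))
  for (k in unique(key[alt])) {
    idx <- which(key == k & alt)
    if (length(idx) < 2L) next
    best <- idx[order(-at$occupancy[idx], at$altloc[idx])][1L]
    drop[setdiff(idx, best)] <- TRUE
  }
  structure@atoms <- at[!drop, , drop = FALSE]
  rownames(structure@atoms) <- NULL
  validObject(structure)
  structure
}

#' Write a structure as legacy PDB text
#'
#' Emits fixed-column ATOM/HETATM records (plus MODRES/LINK/TER/END)
#' such that parsing the output reproduces the structure up to the
#' 3-decimal coordinate precision of the format.
#'
#' @param structure a [PDBStructure-class].
#' @param file optional path; when NULL the text is returned invisibly.
#' @return Character vector of PDB lines (invisibly when `file` given).
#' @export
writePDBStructure <- function(structure, file = NULL) {
  at <- structure@atoms
  if (nrow(at) == 0L) stop("cannot write a structure with zero atoms")
  if (any(abs(c(at$x, at$y, at$z)) > 9999.999))
    stop("coordinate magnitude exceeds the fixed-column field (|v| > 9999.999)")
  name4 <- ifelse(nchar(at$name) >= 4L, substr(at$name, 1, 4),
                  ifelse(nchar(at$element) == 2L,
                         formatC(at$name, width = -4),
                         formatC(paste0(" ", at$name), width = -4)))
  rec <- sprintf("%-6s%5d %4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                 at$record, at$serial %% 100000L, name4, at$altloc,
                 formatC(at$resname, width = 3),
                 ifelse(nzchar(at$chain), at$chain, " "),
                 at$resno, ifelse(nzchar(at$icode), at$icode, " "),
                 at$x, at$y, at$z, at$occupancy, 0, at$element)
  mr <- structure@modres
  modres <- if (nrow(mr) > 0L)
    sprintf("MODRES %4s %3s %1s %4d%1s  %3s", "XXXX", mr$resname, mr$chain,
            mr$resno, ifelse(nzchar(mr$icode), mr$icode, " "), "ALA")
  else character(0)
  lk <- structure@links
  links <- if (nrow(lk) > 0L)
    sprintf("LINK        %-4s %3s %1s%4d%1s               %-4s %3s %1s%4d%1s",
            lk$name1, lk$resname1, lk$chain1, lk$resno1,
            ifelse(nzchar(lk$icode1), lk$icode1, " "),
            lk$name2, lk$resname2, lk$chain2, lk$resno2,
            ifelse(nzchar(lk$icode2), lk$icode2, " "))
  else character(0)
  out <- c(modres, links, rec, "END")
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}
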