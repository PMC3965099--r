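#' Run the full interaction-calling pipeline
#'
#' parse -> altloc selection -> obsolete/overlap filtering -> domain
#' attachment -> ligand identification -> interaction calling ->
#' tab-separated outputs.  Output files (written when `outDir` is
#' given): `interactions.tsv`, `bonds.tsv`, `residue_contacts.tsv` and
#' `summary.tsv`; re-running on identical input produces byte-identical
#' files.
#'
#' @param pdb path to (or text of) a legacy PDB file.
#' @param domains path to (or text of) a domain-region TSV.
#' @param params optional parameter CSV path; NULL uses the shipped
#'   defaults.
#' @param criteria a [BondCriteria-class].
#' @param outDir optional output directory (created if needed).
#' @param validPdbIds optional set of current PDB ids; regions on other
#'   ids are dropped as obsolete references.  NULL skips the check.
#' @param solventExtra,nucleicExtra extra ligand-exclusion codes.
#' @param verbose log stage-by-stage counts via message().
#' @return Invisibly, a list with structure, domains, ligands,
#'   interactions, summary and (when written) the file paths.
#' @export
runPipeline <- function(pdb, domains, params = NULL,
                        criteria = bondCriteria(), outDir = NULL,
                        validPdbIds = NULL,
                        solventExtra = character(0),
                        nucleicExtra = character(0), verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  ps <- if (is.null(params)) defaultParams() else loadParams(params)
  structure <- selectAltloc(readPDBStructure(pdb))
  say("parsed %d atoms on %d chain(s)", nrow(structure@atoms),
      length(unique(structure@atoms$chain)))
  reg <- readDomainRegions(domains)
  if (!is.null(validPdbIds)) reg <- filterObsolete(reg, validPdbIds)
  perChain <- split(reg, paste(reg$pdb_id, reg$chain))
  reg <- do.call(rbind, c(lapply(perChain, resolveOverlaps),
                          make.row.names = FALSE))
  if (is.null(reg)) reg <- emptyRegions()
  say("%d domain region(s) after overlap resolution", nrow(reg))
  doms <- attachDomains(structure, reg)
  ligs <- identifyLigands(structure, solventExtra, nucleicExtra)
  say("%d domain instance(s), %d ligand(s)", length(doms), length(ligs))
  if (length(doms) == 0L)
    warning("no domain regions resolved on this structure; outputs will be empty")
  ints <- callInteractions(structure, doms, ligs, ps, criteria)
  say("%d interaction(s) called", length(ints))
  res <- list(structure = structure, domains = doms, ligands = ligs,
              interactions = ints,
              summary = summarizeInteractions(ints))
  if (!is.null(outDir))
    res$files <- writeInteractionTables(ints, outDir)
  invisible(res)
}

#' Write interaction result tables
#'
#' Serialises interaction calls as four TSV files with deterministic
#' row order.  Van der Waals bonds appear only as residue-contact flags
#' -- never as rows of `bonds.tsv` -- enforcing residue-level storage of
#' van der Waals contacts at the format level.
#'
#' @param interactions list of [Interaction-class].
#' @param outDir output directory, created if needed.
#' @return Named character vector of the four file paths.
#' @export
writeInteractionTables <- function(interactions, outDir) {
  if (!dir.exists(outDir) &&
      !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outDir)
  probe <- file.path(outDir, ".write-probe")
  ok <- tryCatch({ file.create(probe, showWarnings = FALSE) },
                 error = function(e) FALSE)
  if (!isTRUE(ok)) stop("output directory not writable: ", outDir)
  unlink(probe)

  partnerId <- function(x, side) {
    if (side == "a" || x@kind == "DDI") {
      p <- if (side == "a") x@partnerA else x@partnerB
      c(fam = p@region$pfam_acc,
        chain = paste(sort(unique(sub("\\|.*", "", p@residueKeys))),
                      collapse = ","))
    } else c(fam = x@partnerB@hetCode, chain = x@partnerB@chain)
  }
  irows <- list(); brows <- list(); crows <- list()
  for (idx in seq_along(interactions)) {
    x <- interactions[[idx]]
    id <- sprintf("I%03d", idx)
    a <- partnerId(x, "a"); b <- partnerId(x, "b")
    n <- x@nBondsByType
    irows[[idx]] <- data.frame(
      interaction_id = id, kind = x@kind, family_a = a[["fam"]],
      chain_a = a[["chain"]], family_b_or_het = b[["fam"]],
      chain_b = b[["chain"]], topology = x@topology,
      relation = ifelse(is.na(x@relation), ".", x@relation),
      n_covalent = n[["covalent"]],
      n_electrostatic = n[["electrostatic"]],
      n_hydrogen = n[["hydrogen"]],
      n_residue_pairs_vdw = n[["vdw_residue_pairs"]],
      stringsAsFactors = FALSE)
    bd <- x@bonds
    if (nrow(bd) > 0L)
      brows[[idx]] <- data.frame(
        interaction_id = id, chain_a = bd$chain_a, resnum_a = bd$resno_a,
        icode_a = dotBlank(bd$icode_a), resname_a = bd$resname_a,
        atom_a = bd$name_a, chain_b = bd$chain_b, resnum_b = bd$resno_b,
        icode_b = dotBlank(bd$icode_b), resname_b = bd$resname_b,
        atom_b = bd$name_b, bond_type = bd$bond_type,
        distance = sprintf("%.3f", bd$distance),
        hbond_angle = ifelse(is.na(bd$hbond_angle), ".",
                             sprintf("%.1f", bd$hbond_angle)),
        stringsAsFactors = FALSE)
    rc <- x@residueContacts
    crows[[idx]] <- data.frame(
      interaction_id = id, chain_a = rc$chain_a, resnum_a = rc$resno_a,
      icode_a = dotBlank(rc$icode_a), chain_b = rc$chain_b,
      resnum_b = rc$resno_b, icode_b = dotBlank(rc$icode_b),
      bond_types_present = rc$bond_types_present,
      vdw_flag = ifelse(rc$vdw_flag, "1", "0"),
      most_significant_bond = rc$most_significant_bond,
      stringsAsFactors = FALSE)
  }
  emptyTsv <- function(cols) stats::setNames(
    as.data.frame(matrix(character(0), ncol = length(cols))), cols)
  itab <- if (length(irows)) do.call(rbind, irows) else
    emptyTsv(c("interaction_id", "kind", "family_a", "chain_a",
               "family_b_or_het", "chain_b", "topology", "relation",
               "n_covalent", "n_electrostatic", "n_hydrogen",
               "n_residue_pairs_vdw"))
  btab <- if (length(brows)) do.call(rbind, brows) else
    emptyTsv(c("interaction_id", "chain_a", "resnum_a", "icode_a",
               "resname_a", "atom_a", "chain_b", "resnum_b", "icode_b",
               "resname_b", "atom_b", "bond_type", "distance",
               "hbond_angle"))
  ctab <- if (length(crows)) do.call(rbind, crows) else
    emptyTsv(c("interaction_id", "chain_a", "resnum_a", "icode_a",
               "chain_b", "resnum_b", "icode_b", "bond_types_present",
               "vdw_flag", "most_significant_bond"))
  sm <- summarizeInteractions(interactions)
  stab <- data.frame(topology = rownames(sm),
                     homodomain = sm[, "homodomain"],
                     heterodomain = sm[, "heterodomain"],
                     ligand = sm[, "ligand"], stringsAsFactors = FALSE)
  files <- c(interactions = file.path(outDir, "interactions.tsv"),
             bonds = file.path(outDir, "bonds.tsv"),
             residue_contacts = file.path(outDir, "residue_contacts.tsv"),
             summary = file.path(outDir, "summary.tsv"))
  writeTsv(itab, files[["interactions"]])
  writeTsv(btab, files[["bonds"]])
  writeTsv(ctab, files[["residue_contacts"]])
  writeTsv(stab, files[["summary"]])
  files
}

dotBlank <- function(v) ifelse(nzchar(v), v, ".")

writeTsv <- function(df, path) {
  con <- file(path, open = "wb")        # fixed \n EOL on every platform
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
}

#' Command-line entry point
#'
#' Thin argument-parsing wrapper over [runPipeline()]; the installed
#' script `inst/scripts/calc.R` calls this.  Usage:
#' `calc.R run --pdb <file> --domains <tsv> [--params <csv>]
#' [--hbond-max 3.6] [--hbond-angle-min 90] [--hbond-angle-max 140]
#' [--vdw-margin 1.5] --out <dir> [-v]`
#'
#' @param args character vector of command-line arguments.
#' @return Integer exit status: 0 on success (including the
#'   zero-interaction case), 2 on unreadable/missing inputs.
#' @export
cliMain <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) > 0L && args[1L] == "run") args <- args[-1L]
  spec <- list(
    optparse::make_option("--pdb", type = "character"),
    optparse::make_option("--domains", type = "character"),
    optparse::make_option("--params", type = "character",
                          default = NULL),
    optparse::make_option("--hbond-max", type = "double", default = 3.6,
                          dest = "hbond_max"),
    optparse::make_option("--hbond-angle-min", type = "double",
                          default = 90, dest = "hbond_angle_min"),
    optparse::make_option("--hbond-angle-max", type = "double",
                          default = 140, dest = "hbond_angle_max"),
    optparse::make_option("--vdw-margin", type = "double",
                          default = 1.5, dest = "vdw_margin"),
    optparse::make_option("--out", type = "character"),
    optparse::make_option(c("-v", "--verbose"), action = "store_true",
                          default = FALSE))
  opt <- tryCatch(
    optparse::parse_args(optparse::OptionParser(option_list = spec),
                         args = args),
    error = function(e) { message("argument error: ",
                                  conditionMessage(e)); NULL })
  if (is.null(opt)) return(2L)
  for (need in c("pdb", "domains", "out")) {
    if (is.null(opt[[need]])) {
      message("missing required --", need)
      return(2L)
    }
  }
  for (p in c(opt$pdb, opt$domains, opt$params)) {
    if (!file.exists(p)) {
      message("input not readable: ", p)
      return(2L)
    }
  }
  crit <- bondCriteria(hbondMaxDist = opt$hbond_max,
                       hbondAngleMin = opt$hbond_angle_min,
                       hbondAngleMax = opt$hbond_angle_max,
                       vdwMargin = opt$vdw_margin)
  status <- tryCatch({
    runPipeline(opt$pdb, opt$domains, params = opt$params,
                criteria = crit, outDir = opt$out,
                verbose = isTRUE(opt$verbose))
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  status
}
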