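#' Acceptor-side hydrogen-bond angle
#'
#' The planar angle at the acceptor between the acceptor-to-donor vector
#' and the acceptor-to-antecedent vector, where the antecedent is the
#' acceptor's covalently bonded heavy atom within its own residue.
#'
#' @param donor,acceptor,antecedent numeric xyz vectors of length 3 (or
#'   one-row atom data.frames with x, y, z columns).
#' @return Angle in degrees, in [0, 180].
#' @examples
#' acceptorAngle(c(0, 0, 3), c(0, 0, 0), c(sin(pi / 3) * 3, 0, -cos(pi / 3) * 3))
#' @export
acceptorAngle <- function(donor, acceptor, antecedent) {
  xyz <- function(p) {
    if (is.data.frame(p)) p <- c(p$x[1L], p$y[1L], p$z[1L])
    as.numeric(p)
  }
  d <- xyz(donor); a <- xyz(acceptor); t <- xyz(antecedent)
  v1 <- d - a; v2 <- t - a
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0)
    stop("degenerate geometry: coincident atoms give a zero-length vector")
  acos(pmin(1, pmax(-1, sum(v1 * v2) / (n1 * n2)))) * 180 / pi
}

#' Classify one atom pair into a bond type
#'
#' Applies the geometric/chemical rules in precedence order and returns
#' the first that fires, for inter-atomic distance d and per-atom
#' covalent radii (cov), van der Waals radii (vdw), formal charges and
#' donor/acceptor flags:
#' \enumerate{
#'   \item covalent: d < cov(a) + cov(b);
#'   \item electrostatic: cov(a) + cov(b) < d < vdw(a) + vdw(b) and the
#'     formal charges have opposite signs;
#'   \item hydrogen: for a pair failing both previous rules, one atom a
#'     donor and the other an acceptor, d below the donor--acceptor
#'     cutoff, and the acceptor-side angle (see [acceptorAngle()])
#'     inside the criteria window (both ends inclusive);
#'   \item van der Waals: vdw(a) + vdw(b) < d < vdw(a) + vdw(b) + margin.
#' }
#' All window boundaries are strict, so a boundary-equal distance
#' classifies as none; likewise a pair inside the electrostatic distance
#' window with compatible charges is never reported as hydrogen.
#'
#' @param a,b atoms: lists or one-row data.frames with x, y, z,
#'   covalent_radius, vdw_radius, charge, donor, acceptor.
#' @param criteria a [BondCriteria-class].
#' @param antecedentA,antecedentB xyz of each atom's bonded heavy-atom
#'   antecedent (needed only when that atom could act as the acceptor of
#'   a hydrogen bond); NULL when unknown, in which case the hydrogen
#'   rule is skipped for that orientation with a warning.
#' @return List with `type` ("covalent", "electrostatic", "hydrogen",
#'   "vdw" or "none"), `distance` (Angstrom) and `angle` (degrees, NA
#'   unless hydrogen).
#' @export
classifyAtomPair <- function(a, b, criteria = bondCriteria(),
                             antecedentA = NULL, antecedentB = NULL) {
  f <- function(p, what) as.numeric(if (is.data.frame(p)) p[[what]][1L]
                                    else p[[what]])
  ax <- c(f(a, "x"), f(a, "y"), f(a, "z"))
  bx <- c(f(b, "x"), f(b, "y"), f(b, "z"))
  antA <- if (is.null(antecedentA)) c(NA_real_, NA_real_, NA_real_) else
    as.numeric(antecedentA)
  antB <- if (is.null(antecedentB)) c(NA_real_, NA_real_, NA_real_) else
    as.numeric(antecedentB)
  res <- classifyPairsVec(
    ax = ax[1L], ay = ax[2L], az = ax[3L],
    bx = bx[1L], by = bx[2L], bz = bx[3L],
    covA = f(a, "covalent_radius"), covB = f(b, "covalent_radius"),
    vdwA = f(a, "vdw_radius"), vdwB = f(b, "vdw_radius"),
    qA = f(a, "charge"), qB = f(b, "charge"),
    dA = f(a, "donor"), dB = f(b, "donor"),
    accA = f(a, "acceptor"), accB = f(b, "acceptor"),
    antAx = antA[1L], antAy = antA[2L], antAz = antA[3L],
    antBx = antB[1L], antBy = antB[2L], antBz = antB[3L],
    criteria = criteria)
  if (res$skippedAcceptors > 0L)
    warning("hydrogen-bond rule skipped: acceptor without a resolvable antecedent")
  list(type = res$type, distance = res$distance, angle = res$angle)
}

# Vectorised rule core shared by the scalar API and detectBonds().
classifyPairsVec <- function(ax, ay, az, bx, by, bz, covA, covB, vdwA,
                             vdwB, qA, qB, dA, dB, accA, accB,
                             antAx, antAy, antAz, antBx, antBy, antBz,
                             criteria) {
  d <- sqrt((ax - bx)^2 + (ay - by)^2 + (az - bz)^2)
  covsum <- covA + covB
  vdwsum <- vdwA + vdwB
  n <- length(d)
  type <- rep("none", n)
  angle <- rep(NA_real_, n)
  covalent <- d < covsum
  elec <- !covalent & d > covsum & d < vdwsum & (qA * qB < 0)
  rem <- !covalent & !elec

  vecAngle <- function(px, py, pz, qx, qy, qz, tx, ty, tz) {
    # angle at q between q->p and q->t
    v1x <- px - qx; v1y <- py - qy; v1z <- pz - qz
    v2x <- tx - qx; v2y <- ty - qy; v2z <- tz - qz
    n1 <- sqrt(v1x^2 + v1y^2 + v1z^2)
    n2 <- sqrt(v2x^2 + v2y^2 + v2z^2)
    cosv <- (v1x * v2x + v1y * v2y + v1z * v2z) / (n1 * n2)
    acos(pmin(1, pmax(-1, cosv))) * 180 / pi
  }
  inWin <- function(ang) !is.na(ang) & ang >= criteria@hbondAngleMin &
    ang <= criteria@hbondAngleMax
  close <- rem & d < criteria@hbondMaxDist & d > 0
  tryAB <- close & dA == 1 & accB == 1          # a donates, b accepts
  tryBA <- close & dB == 1 & accA == 1          # b donates, a accepts
  missAB <- tryAB & is.na(antBx)
  missBA <- tryBA & is.na(antAx)
  angAB <- rep(NA_real_, n)
  angBA <- rep(NA_real_, n)
  iAB <- which(tryAB & !missAB)
  if (length(iAB) > 0L)
    angAB[iAB] <- vecAngle(ax[iAB], ay[iAB], az[iAB],
                           bx[iAB], by[iAB], bz[iAB],
                           antBx[iAB], antBy[iAB], antBz[iAB])
  iBA <- which(tryBA & !missBA)
  if (length(iBA) > 0L)
    angBA[iBA] <- vecAngle(bx[iBA], by[iBA], bz[iBA],
                           ax[iBA], ay[iBA], az[iBA],
                           antAx[iBA], antAy[iBA], antAz[iBA])
  okAB <- tryAB & inWin(angAB)
  okBA <- tryBA & inWin(angBA)
  hyd <- okAB | okBA
  # when both donor/acceptor orientations validate, keep the smaller
  # angle -- symmetric in the argument order
  cand1 <- ifelse(okAB, angAB, Inf)
  cand2 <- ifelse(okBA, angBA, Inf)
  angle[hyd] <- pmin(cand1, cand2)[hyd]
  vdw <- rem & !hyd & d > vdwsum & d < vdwsum + criteria@vdwMargin
  type[covalent] <- "covalent"
  type[elec] <- "electrostatic"
  type[hyd] <- "hydrogen"
  type[vdw] <- "vdw"
  list(type = type, distance = d, angle = angle,
       skippedAcceptors = sum(missAB & !okBA) + sum(missBA & !okAB))
}

#' Detect all inter-molecular bonds between two atom sets
#'
#' Enumerates atom pairs between two molecules (a grid-based spatial
#' index prunes candidates; the result is identical to the exhaustive
#' all-pairs scan) and classifies each with [classifyAtomPair()] rules.
#' Hydrogen/deuterium atoms are excluded from enumeration: donors and
#' acceptors are identified on heavy atoms only.  Atoms whose element
#' has no parameter row are skipped with a warning.
#'
#' @param atomsA,atomsB atom data.frames in [PDBStructure-class] layout
#'   (rows of `atoms(structure)`), belonging to two different molecules.
#' @param params a [ParameterSet-class].
#' @param criteria a [BondCriteria-class].
#' @param method "grid" (default) or "exhaustive"; both must agree, the
#'   exhaustive scan being the reference.
#' @return data.frame of bonds: identity columns for both atoms,
#'   `bond_type`, `distance` and `hbond_angle` (NA unless hydrogen),
#'   one row per bonded unordered atom pair, deterministically ordered.
#' @export
detectBonds <- function(atomsA, atomsB, params = defaultParams(),
                        criteria = bondCriteria(),
                        method = c("grid", "exhaustive")) {
  method <- match.arg(method)
  pa <- prepAtoms(atomsA, params)
  pb <- prepAtoms(atomsB, params)
  if (nrow(pa) == 0L || nrow(pb) == 0L) return(emptyBonds())
  cutoff <- max(pa$vdw_radius) + max(pb$vdw_radius) + criteria@vdwMargin
  cutoff <- max(cutoff, criteria@hbondMaxDist)
  pairs <- if (method == "grid") gridPairs(pa, pb, cutoff)
           else cbind(rep(seq_len(nrow(pa)), times = nrow(pb)),
                      rep(seq_len(nrow(pb)), each = nrow(pa)))
  if (nrow(pairs) == 0L) return(emptyBonds())
  i <- pairs[, 1L]; j <- pairs[, 2L]
  res <- classifyPairsVec(
    ax = pa$x[i], ay = pa$y[i], az = pa$z[i],
    bx = pb$x[j], by = pb$y[j], bz = pb$z[j],
    covA = pa$covalent_radius[i], covB = pb$covalent_radius[j],
    vdwA = pa$vdw_radius[i], vdwB = pb$vdw_radius[j],
    qA = pa$charge[i], qB = pb$charge[j],
    dA = pa$donor[i], dB = pb$donor[j],
    accA = pa$acceptor[i], accB = pb$acceptor[j],
    antAx = pa$ant_x[i], antAy = pa$ant_y[i], antAz = pa$ant_z[i],
    antBx = pb$ant_x[j], antBy = pb$ant_y[j], antBz = pb$ant_z[j],
    criteria = criteria)
  if (res$skippedAcceptors > 0L)
    warning(sprintf("hydrogen-bond rule skipped for %d pair(s): acceptor without a resolvable antecedent",
                    res$skippedAcceptors))
  hit <- res$type != "none"
  if (!any(hit)) return(emptyBonds())
  i <- i[hit]; j <- j[hit]
  side <- function(p, k, suff) {
    out <- p[k, c("serial", "name", "resname", "chain", "resno", "icode"),
             drop = FALSE]
    names(out) <- paste0(names(out), suff)
    out
  }
  bonds <- cbind(side(pa, i, "_a"), side(pb, j, "_b"),
                 data.frame(bond_type = res$type[hit],
                            distance = res$distance[hit],
                            hbond_angle = res$angle[hit]))
  ord <- order(bonds$chain_a, bonds$resno_a, bonds$icode_a, bonds$name_a,
               bonds$serial_a, bonds$chain_b, bonds$resno_b,
               bonds$icode_b, bonds$name_b, bonds$serial_b)
  bonds <- bonds[ord, , drop = FALSE]
  rownames(bonds) <- NULL
  bonds
}

emptyBonds <- function() {
  data.frame(serial_a = integer(0), name_a = character(0),
             resname_a = character(0), chain_a = character(0),
             resno_a = integer(0), icode_a = character(0),
             serial_b = integer(0), name_b = character(0),
             resname_b = character(0), chain_b = character(0),
             resno_b = integer(0), icode_b = character(0),
             bond_type = character(0), distance = numeric(0),
             hbond_angle = numeric(0), stringsAsFactors = FALSE)
}

# Attach chemistry parameters and antecedent coordinates; drop
# hydrogens and unparameterized atoms.
prepAtoms <- function(atoms, params) {
  stopifnot(is.data.frame(atoms))
  heavy <- !(atoms$element %in% c("H", "D"))
  atoms <- atoms[heavy, , drop = FALSE]
  if (nrow(atoms) == 0L) return(atoms)
  chem <- chemLookup(params, atoms$resname, atoms$name, atoms$element)
  bad <- is.na(chem$covalent_radius)
  if (any(bad)) {
    warning(sprintf("skipping %d unparameterized atom(s) (e.g. %s/%s element '%s')",
                    sum(bad), atoms$resname[bad][1L], atoms$name[bad][1L],
                    atoms$element[bad][1L]))
    atoms <- atoms[!bad, , drop = FALSE]
    chem <- chem[!bad, , drop = FALSE]
  }
  out <- cbind(atoms, chem)
  rownames(out) <- NULL
  antecedents(out)
}

# For each atom, the nearest heavy atom of the same residue lying
# within covalent-bond distance; NA when the residue offers none.
antecedents <- function(atoms) {
  n <- nrow(atoms)
  atoms$ant_x <- atoms$ant_y <- atoms$ant_z <- rep(NA_real_, n)
  key <- residueKey(atoms$chain, atoms$resno, atoms$icode)
  for (k in unique(key)) {
    idx <- which(key == k)
    if (length(idx) < 2L) next
    xyz <- as.matrix(atoms[idx, c("x", "y", "z")])
    dm <- as.matrix(stats::dist(xyz))
    covsum <- outer(atoms$covalent_radius[idx], atoms$covalent_radius[idx],
                    "+")
    diag(dm) <- Inf
    dm[dm >= covsum] <- Inf
    best <- apply(dm, 1L, which.min)
    has <- is.finite(apply(dm, 1L, min))
    atoms$ant_x[idx[has]] <- xyz[best[has], 1L]
    atoms$ant_y[idx[has]] <- xyz[best[has], 2L]
    atoms$ant_z[idx[has]] <- xyz[best[has], 3L]
  }
  atoms
}

# Candidate pairs from cubic binning at the cutoff radius; a superset
# of all pairs within `cutoff`.
gridPairs <- function(pa, pb, cutoff) {
  cell <- function(v) as.integer(floor(v / cutoff))
  ka <- cbind(cell(pa$x), cell(pa$y), cell(pa$z))
  kb <- cbind(cell(pb$x), cell(pb$y), cell(pb$z))
  bmap <- split(seq_len(nrow(pb)),
                paste(kb[, 1L], kb[, 2L], kb[, 3L]))
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  ii <- integer(0); jj <- integer(0)
  for (i in seq_len(nrow(pa))) {
    keys <- paste(ka[i, 1L] + off[, 1L], ka[i, 2L] + off[, 2L],
                  ka[i, 3L] + off[, 3L])
    cand <- unlist(bmap[keys], use.names = FALSE)
    if (length(cand) > 0L) {
      ii <- c(ii, rep.int(i, length(cand)))
      jj <- c(jj, cand)
    }
  }
  cbind(ii, jj)
}
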