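#' @include geometry.R structio.R
NULL

#' Side-chain chi angles of a residue
#'
#' Measures every chi torsion of a residue from its canonical 4-atom
#' quadruple.  Terminal chis with 2-fold symmetric end groups (Asp chi2,
#' Glu chi3, Phe/Tyr chi2) are normalized to (-90, 90] so that the two
#' equivalent atom namings measure as the same angle.  When an atom of a
#' quadruple is missing, that chi and all deeper chis are NA and the vector
#' is flagged incomplete.
#'
#' @param residue atom data.frame of one residue (as from
#'   \code{residueAtoms}).
#' @param tables a \linkS4class{ChemistryTables}.
#' @return list with \code{resType}, \code{chis} (numeric, degrees),
#'   \code{complete} (logical).
#' @export
computeChis <- function(residue, tables = chemistryTables()) {
  resType <- toupper(residue$resname[1])
  defs <- tables@chiAtoms[[resType]]
  if (is.null(defs)) stop("no chi definitions for residue type ", resType)
  symIdx <- tables@chiSymmetric[[resType]]
  chis <- rep(NA_real_, length(defs))
  broken <- FALSE
  for (i in seq_along(defs)) {
    quad <- defs[[i]]
    idx <- match(quad, residue$name)
    if (anyNA(idx)) { broken <- TRUE; break }
    pts <- as.matrix(residue[idx, c("x", "y", "z")])
    chis[i] <- dihedralAngle(pts[1, ], pts[2, ], pts[3, ], pts[4, ])
  }
  if (!is.null(symIdx) && length(symIdx) && !is.na(chis[symIdx]))
    chis[symIdx] <- wrapAngleSym(chis[symIdx])
  list(resType = resType, chis = chis, complete = !broken && !anyNA(chis))
}

## per-chi circular deviations of observed chis from a library row
.chiDeviations <- function(chis, libRow, symIdx) {
  nchi <- libRow$nchi
  means <- as.numeric(libRow[paste0("chi", seq_len(nchi))])
  hw <- as.numeric(libRow[paste0("hw", seq_len(nchi))])
  dev <- numeric(nchi)
  for (i in seq_len(nchi)) {
    dev[i] <- if (length(symIdx) && i %in% symIdx)
      abs(circDiffSym(chis[i], means[i])) else abs(circDiff(chis[i], means[i]))
  }
  list(dev = dev, hw = hw)
}

#' Assign a rotamer to an observed chi vector
#'
#' Candidate rotamers of the residue's type are filtered by requiring every
#' chi to lie within the rotamer's admission window (|delta chi| <= half-width,
#' boundary inclusive, 30 degrees unless the library overrides it).  No
#' survivor means the side chain is non-rotameric (NR).  When overlapping
#' windows leave several survivors, the nearest by maximum per-chi deviation
#' wins, with library frequency as the final tie-break.
#'
#' @param chiVec result of \code{\link{computeChis}} (must be complete).
#' @param library rotamer library data.frame; defaults to the shipped one.
#' @param tables a \linkS4class{ChemistryTables}.
#' @return list with \code{resType}, \code{rotamer} (id or NA for NR),
#'   \code{nr} (logical), \code{deviations} (per-chi, for the assigned
#'   rotamer; NA for NR).
#' @export
assignRotamer <- function(chiVec, library = NULL, tables = chemistryTables()) {
  if (is.null(library)) library <- tables@rotamerLibrary
  if (!chiVec$complete) stop("incomplete chi vector; filter before assigning")
  cand <- library[library$res_type == chiVec$resType, , drop = FALSE]
  if (!nrow(cand)) stop("no library rotamers for type ", chiVec$resType)
  symIdx <- tables@chiSymmetric[[chiVec$resType]]
  if (is.null(symIdx)) symIdx <- integer(0)
  devs <- lapply(seq_len(nrow(cand)), function(r)
    .chiDeviations(chiVec$chis, cand[r, ], symIdx))
  ok <- vapply(devs, function(d) all(d$dev <= d$hw), logical(1))
  if (!any(ok)) {
    return(list(resType = chiVec$resType, rotamer = NA_character_, nr = TRUE,
                deviations = rep(NA_real_, length(chiVec$chis))))
  }
  surv <- which(ok)
  maxDev <- vapply(devs[surv], function(d) max(d$dev), numeric(1))
  best <- surv[order(maxDev, -cand$freq[surv])][1]
  list(resType = chiVec$resType, rotamer = cand$rotamer[best], nr = FALSE,
       deviations = devs[[best]]$dev)
}

#' Quality filter for non-rotameric observations
#'
#' NR conformations are kept only when they are trustworthy: an NR side chain
#' with any heavy atom having B-factor > 40, occupancy < 1.0 or an alternate
#' location is excluded from the statistics.  Rotameric side chains are not
#' subject to this filter.
#'
#' @param assignment result of \code{\link{assignRotamer}}.
#' @param residueInfo one row of \code{\link{residueTable}} for the residue
#'   (provides maxB, minOcc, hasAlt of the side chain).
#' @param maxB,minOcc filter thresholds.
#' @return "ok" or "excluded_quality".
#' @export
qualityFilter <- function(assignment, residueInfo, maxB = 40, minOcc = 1.0) {
  if (!assignment$nr) return("ok")
  if (residueInfo$maxB > maxB || residueInfo$minOcc < minOcc ||
      residueInfo$hasAlt) "excluded_quality" else "ok"
}

#' Classify a residue as flexible or rigid across the Apo/Holo pair
#'
#' Flexible means the two forms occupy different rotameric states: different
#' rotamer ids, or exactly one form non-rotameric.  Both forms NR is excluded
#' (no energetic-state call can be made); a quality-failing NR observation
#' excludes the residue as well.
#'
#' @param apoAssign,holoAssign results of \code{\link{assignRotamer}}.
#' @param apoQuality,holoQuality verdicts from \code{\link{qualityFilter}}.
#' @return one of "flexible", "rigid", "excluded_NR_NR", "excluded_quality".
#' @export
classifyFlexibility <- function(apoAssign, holoAssign,
                                apoQuality = "ok", holoQuality = "ok") {
  if (apoQuality != "ok" || holoQuality != "ok") return("excluded_quality")
  if (apoAssign$nr && holoAssign$nr) return("excluded_NR_NR")
  if (apoAssign$nr || holoAssign$nr) return("flexible")
  if (identical(apoAssign$rotamer, holoAssign$rotamer)) "rigid" else "flexible"
}

#' Per-type flexibility probability with binomial error
#'
#' P_i = N_R / N_T, the fraction of observations of residue type i whose
#' rotamer differs between the Apo and Holo forms, with the binomial standard
#' error sqrt(P (1 - P) / N_T).
#'
#' @param nR flexible observation count.
#' @param nT total observation count (> 0).
#' @return list with \code{P} and \code{error}.
#' @examples
#' flexibilityProbability(10, 40)  # P = 0.25, error ~ 0.068
#' @export
flexibilityProbability <- function(nR, nT) {
  if (nT <= 0) stop("N_T must be positive")
  if (nR > nT) stop("N_R cannot exceed N_T")
  p <- nR / nT
  list(P = p, error = sqrt(p * (1 - p) / nT))
}

#' Dihedral-threshold flexibility call
#'
#' The older criterion: a side chain counts as changed when any chi differs
#' by at least \code{threshold} degrees between the two forms (circular
#' difference; the same 2-fold symmetry convention as the rotamer method is
#' applied to terminal chis).
#'
#' @param apoChis,holoChis matched chi-vector lists from
#'   \code{\link{computeChis}}.
#' @param threshold degrees (inclusive), default 60.
#' @param tables a \linkS4class{ChemistryTables}.
#' @return logical flag.
#' @export
deltaChiFlexible <- function(apoChis, holoChis, threshold = 60,
                             tables = chemistryTables()) {
  if (length(apoChis$chis) != length(holoChis$chis))
    stop("mismatched chi vector lengths")
  symIdx <- tables@chiSymmetric[[apoChis$resType]]
  if (is.null(symIdx)) symIdx <- integer(0)
  d <- maxAbsDeltaChiVec(apoChis$chis, holoChis$chis, symIdx)
  any(d >= threshold)
}

## per-chi absolute circular differences honouring terminal symmetry
maxAbsDeltaChiVec <- function(a, b, symIdx = integer(0)) {
  vapply(seq_along(a), function(i) {
    if (i %in% symIdx) abs(circDiffSym(a[i], b[i])) else abs(circDiff(a[i], b[i]))
  }, numeric(1))
}

#' Detect disulfide-bonded cysteines
#'
#' Cys side chains whose SG is within 2.5 Angstrom of another Cys SG are
#' conformationally locked and are excluded from flexibility statistics.
#'
#' @param model a \linkS4class{StructureModel}.
#' @return character vector of residue keys in disulfide bridges.
#' @export
disulfideCysteines <- function(model) {
  a <- model@atoms
  sg <- a[a$category == "protein" & a$resname == "CYS" & a$name == "SG", ,
          drop = FALSE]
  if (nrow(sg) < 2) return(character(0))
  d <- as.matrix(stats::dist(as.matrix(sg[, c("x", "y", "z")])))
  hit <- which(d < 2.5 & upper.tri(d), arr.ind = TRUE)
  if (!nrow(hit)) return(character(0))
  unique(resKey(sg)[c(hit[, 1], hit[, 2])])
}
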