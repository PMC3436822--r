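#' @include geometry.R structio.R
NULL

#' Curation thresholds for Apo/Holo pairing
#'
#' Default values implement the study gates: resolution at or better than
#' 2.50 Angstrom for both structures, 100% sequence identity over at least
#' 80% of the length of either chain, non-subject ligands differing by at
#' most 10 residue contacts between forms, ligands with at least 5 heavy
#' atoms contacting at least 5 residues, burial fraction at least 0.70, and
#' a binding-site backbone RMSD of at most 2.50 Angstrom.
#'
#' @param maxResolution Angstrom.
#' @param minIdentity fraction over aligned columns.
#' @param minOverlap fraction of either sequence length.
#' @param maxExtraLigandContactDiff residue-contact count difference.
#' @param minLigandHeavyAtoms count.
#' @param minContactedResidues count.
#' @param minFc burial fraction.
#' @param maxSiteRMSD Angstrom.
#' @return named list of criteria.
#' @export
pairingCriteria <- function(maxResolution = 2.50, minIdentity = 1.00,
                            minOverlap = 0.80, maxExtraLigandContactDiff = 10,
                            minLigandHeavyAtoms = 5, minContactedResidues = 5,
                            minFc = 0.70, maxSiteRMSD = 2.50) {
  crit <- list(maxResolution = maxResolution, minIdentity = minIdentity,
               minOverlap = minOverlap,
               maxExtraLigandContactDiff = maxExtraLigandContactDiff,
               minLigandHeavyAtoms = minLigandHeavyAtoms,
               minContactedResidues = minContactedResidues,
               minFc = minFc, maxSiteRMSD = maxSiteRMSD)
  stopifnot(all(unlist(crit) > 0),
            minIdentity <= 1, minOverlap <= 1, minFc <= 1)
  crit
}

#' Global sequence alignment of the two forms
#'
#' Needleman-Wunsch global alignment (via Biostrings) of the sequences
#' extracted from the coordinate records.  Identity is computed over aligned
#' non-gap columns; the overlap criterion passes when the aligned identical
#' stretch covers the required fraction of *either* sequence.  The residue
#' correspondence maps each Holo residue to its aligned Apo counterpart.
#'
#' @param apo,holo \linkS4class{StructureModel}s with at least one protein
#'   residue each.
#' @return list with \code{identity}, \code{overlapApo}, \code{overlapHolo},
#'   \code{overlap} (the larger of the two) and \code{correspondence}
#'   (data.frame holoKey, apoKey, resname).
#' @export
alignSequences <- function(apo, holo) {
  sa <- extractSequence(apo)
  sh <- extractSequence(holo)
  if (!nchar(sa$seq) || !nchar(sh$seq)) stop("no alignable residues")
  ## ends-free global alignment so that terminal tags align as overhangs
  ## (identity is computed over aligned columns only)
  subMat <- matrix(-1, 26, 26, dimnames = list(LETTERS, LETTERS))
  diag(subMat) <- 2
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(sh$seq), Biostrings::AAString(sa$seq),
    type = "overlap", substitutionMatrix = subMat,
    gapOpening = 10, gapExtension = 0.5)
  pat <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  ## offsets for flanks clipped by the ends-free alignment
  iH <- BiocGenerics::start(Biostrings::pattern(al)) - 1L
  iA <- BiocGenerics::start(Biostrings::subject(al)) - 1L
  holoIdx <- integer(0); apoIdx <- integer(0)
  for (k in seq_along(pat)) {
    if (pat[k] != "-") iH <- iH + 1L
    if (sub[k] != "-") iA <- iA + 1L
    if (pat[k] != "-" && sub[k] != "-" && pat[k] == sub[k]) {
      holoIdx <- c(holoIdx, iH); apoIdx <- c(apoIdx, iA)
    }
  }
  alignedCols <- sum(pat != "-" & sub != "-")
  identical_ <- length(holoIdx)
  identity <- if (alignedCols) identical_ / alignedCols else 0
  corr <- data.frame(holoKey = sh$keys[holoIdx], apoKey = sa$keys[apoIdx],
                     resname = sh$resname[holoIdx])
  list(identity = identity,
       overlapHolo = identical_ / length(sh$keys),
       overlapApo = identical_ / length(sa$keys),
       overlap = max(identical_ / length(sh$keys),
                     identical_ / length(sa$keys)),
       correspondence = corr)
}

#' Define the binding site of a ligand
#'
#' The binding pocket is the set of residues with at least one atom in
#' surface contact with an atom of the ligand (see
#' \code{\link{atomContacts}}).
#'
#' @param holo the Holo \linkS4class{StructureModel}.
#' @param ligand a \linkS4class{LigandInstance} of that structure.
#' @param probe probe radius.
#' @param tables a \linkS4class{ChemistryTables}.
#' @return character vector of residue keys (chain:resno:insert).
#' @export
defineBindingSite <- function(holo, ligand, probe = 1.4,
                              tables = chemistryTables()) {
  ct <- atomContacts(holo, ligand, probe = probe, tables = tables)
  ks <- names(ct$perResidue)
  if (is.null(ks)) character(0) else ks
}

## residue-level contact counts of every non-subject ligand, by het identity
.extraLigandContacts <- function(model, subjectKey, tables) {
  ligs <- ligandInstances(model)
  out <- list()
  for (lg in ligs) {
    k <- paste(lg@hetCode, resKey(lg@atoms)[1])
    if (k == subjectKey) next
    out[[paste(lg@hetCode, length(out) + 1)]] <-
      list(code = lg@hetCode,
           contacts = sum(atomContacts(model, lg, tables = tables)$perResidue))
  }
  out
}

#' Validate an Apo/Holo/ligand triple
#'
#' Applies the curation gates in a fixed order, recording the first failing
#' check as the verdict's reason code: resolution (both forms), sequence
#' identity, overlap, buffer ligand, ligand heavy-atom count, covalent
#' attachment, binding-site size, single-chain burial, burial fraction Fc,
#' binding-site side-chain completeness (both forms), extra-ligand contact
#' consistency, and binding-site backbone RMSD after superposition.
#' Rejection is a verdict, not an error: the returned
#' \linkS4class{ApoHoloPair} always carries the measurements made up to the
#' failing gate.
#'
#' @param apo,holo \linkS4class{StructureModel}s.
#' @param ligand a \linkS4class{LigandInstance} from the Holo form.
#' @param criteria a \code{\link{pairingCriteria}} list.
#' @param pairID label for the pair.
#' @param tables a \linkS4class{ChemistryTables}.
#' @param stopAtFirst stop at the first failing gate (default) or collect all
#'   reason codes.
#' @return An \linkS4class{ApoHoloPair}.
#' @export
validatePair <- function(apo, holo, ligand, criteria = pairingCriteria(),
                         pairID = paste(pdbID(apo), pdbID(holo), sep = "-"),
                         tables = chemistryTables(), stopAtFirst = TRUE) {
  reasons <- character(0)
  metrics <- list()
  corr <- data.frame(holoKey = character(0), apoKey = character(0),
                     resname = character(0))
  site <- character(0)
  fail <- function(code) reasons <<- c(reasons, code)
  done <- function() stopAtFirst && length(reasons) > 0

  ## 1. resolution gate on both forms
  for (m in list(apo, holo)) {
    r <- crystalResolution(m)
    if (!is.na(r) && r > criteria$maxResolution) { fail("resolution"); break }
  }

  ## 2. sequence identity / overlap
  if (!done()) {
    al <- alignSequences(apo, holo)
    metrics$identity <- al$identity
    metrics$overlap <- al$overlap
    corr <- al$correspondence
    if (al$identity < criteria$minIdentity) fail("identity")
    else if (al$overlap < criteria$minOverlap) fail("overlap")
  }

  ## 3. buffer-ligand exclusion
  if (!done() && isBufferLigand(hetCode(ligand), tables)) fail("buffer")

  ## 4. ligand size
  heavy <- sum(ligand@atoms$element != "H")
  metrics$ligandHeavyAtoms <- heavy
  if (!done() && heavy < criteria$minLigandHeavyAtoms) fail("heavy_atoms")

  ## 5. covalent attachment to the protein
  if (!done()) {
    prot <- holo@atoms[holo@atoms$category == "protein" &
                       holo@atoms$element != "H", , drop = FALSE]
    lat <- ligand@atoms[ligand@atoms$element != "H", , drop = FALSE]
    if (nrow(prot) && nrow(lat)) {
      pxyz <- as.matrix(prot[, c("x", "y", "z")])
      lxyz <- as.matrix(lat[, c("x", "y", "z")])
      d2 <- outer(rowSums(lxyz^2), rowSums(pxyz^2), "+") -
        2 * lxyz %*% t(pxyz)
      cutoff <- outer(covalentRadius(lat$element, tables),
                      covalentRadius(prot$element, tables), "+") + 0.4
      if (any(d2 <= cutoff^2)) fail("covalent")
    }
  }

  ## 6. binding-site definition: size and single-chain burial
  if (!done() || !stopAtFirst) {
    site <- defineBindingSite(holo, ligand, tables = tables)
    metrics$siteSize <- length(site)
    if (!done()) {
      if (length(site) < criteria$minContactedResidues)
        fail("contacted_residues")
      else if (length(unique(sub(":.*", "", site))) > 1) fail("multi_chain")
    }
  }

  ## 7. burial fraction
  if (!done()) {
    fc <- fractionInContact(ligand, holo, tables = tables)
    metrics$fc <- fc
    if (fc < criteria$minFc) fail("fc")
  }

  ## 8. binding-site side-chain completeness in both forms
  if (!done()) {
    rtH <- residueTable(holo, tables)
    rtA <- residueTable(apo, tables)
    apoSite <- corr$apoKey[match(site, corr$holoKey)]
    if (anyNA(apoSite)) fail("missing_atoms")
    else {
      okH <- rtH$sideChainComplete[match(site, rtH$key)]
      okA <- rtA$sideChainComplete[match(apoSite, rtA$key)]
      if (anyNA(okH) || anyNA(okA) || !all(okH) || !all(okA))
        fail("missing_atoms")
    }
  }

  ## 9. extra-ligand consistency
  if (!done()) {
    subjKey <- paste(hetCode(ligand), resKey(ligand@atoms)[1])
    exH <- .extraLigandContacts(holo, subjKey, tables)
    exA <- .extraLigandContacts(apo, "", tables)
    codesH <- vapply(exH, `[[`, character(1), "code")
    codesA <- vapply(exA, `[[`, character(1), "code")
    bad <- FALSE
    for (code in unique(codesH)) {
      cH <- sum(vapply(exH[codesH == code], `[[`, numeric(1), "contacts"))
      cA <- sum(vapply(exA[codesA == code], `[[`, numeric(1), "contacts"))
      if (!code %in% codesA ||
          abs(cH - cA) > criteria$maxExtraLigandContactDiff) bad <- TRUE
    }
    if (bad) fail("extra_ligand")
  }

  ## 10. binding-site backbone RMSD after superposition
  if (!done()) {
    bb <- .siteBackbone(apo, holo, corr, site)
    if (is.null(bb)) fail("missing_atoms")
    else {
      fit <- superpose(bb$apo, bb$holo)
      metrics$siteRMSD <- fit$rmsd
      if (fit$rmsd > criteria$maxSiteRMSD) fail("site_rmsd")
    }
  }

  new("ApoHoloPair", pairID = pairID, apo = apo, holo = holo,
      ligand = ligand, correspondence = corr, site = site,
      verdict = if (length(reasons)) "rejected" else "accepted",
      reasons = reasons, metrics = metrics)
}

## matched backbone (N, CA, C, O) coordinates of the site residues
.siteBackbone <- function(apo, holo, corr, site) {
  bbNames <- c("N", "CA", "C", "O")
  apoM <- NULL; holoM <- NULL
  for (hk in site) {
    ak <- corr$apoKey[match(hk, corr$holoKey)]
    if (is.na(ak)) return(NULL)
    ha <- residueAtoms(holo, hk)
    aa <- residueAtoms(apo, ak)
    for (nm in bbNames) {
      ih <- match(nm, ha$name); ia <- match(nm, aa$name)
      if (is.na(ih) || is.na(ia)) return(NULL)
      holoM <- rbind(holoM, as.numeric(ha[ih, c("x", "y", "z")]))
      apoM <- rbind(apoM, as.numeric(aa[ia, c("x", "y", "z")]))
    }
  }
  list(apo = apoM, holo = holoM)
}

#' Representative selection within a redundancy group
#'
#' Within a group of pairs sharing a domain label and ligand code, the
#' representative is the member with the largest ligand burial fraction;
#' ties break to the lexicographically smallest pair id.
#'
#' @param group data.frame with columns \code{pairID} and \code{fc}.
#' @return the selected pairID.
#' @examples
#' selectRepresentative(data.frame(pairID = c("b", "a"), fc = c(0.8, 0.8)))
#' @export
selectRepresentative <- function(group) {
  stopifnot(nrow(group) >= 1, all(c("pairID", "fc") %in% names(group)))
  group$pairID[order(-group$fc, group$pairID)][1]
}
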