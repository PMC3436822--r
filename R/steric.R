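#' @include curation.R rotamer.R
NULL

#' Parameters of the wall clash potential
#'
#' @param kWall penalty constant (default 1e6).
#' @param siteThreshold total-score threshold above which the transplanted
#'   ligand pose is no longer acceptable (default 150).
#' @param residueThreshold per-residue threshold for critical side-chain
#'   clashes (default 25).
#' @param form functional form of the per-pair penalty: "quartic" (default;
#'   kWall * (relative overlap)^4), "quadratic" or "step".
#' @return named list of parameters.
#' @export
wallParameters <- function(kWall = 1e6, siteThreshold = 150,
                           residueThreshold = 25,
                           form = c("quartic", "quadratic", "step")) {
  stopifnot(kWall > 0, siteThreshold > 0, residueThreshold > 0)
  list(kWall = kWall, siteThreshold = siteThreshold,
       residueThreshold = residueThreshold, form = match.arg(form))
}

## penalty of a vector of overlapping pairs given distances and radii sums
.wallTerm <- function(d, rsum, params) {
  overlap <- pmax(0, rsum - d)
  rel <- overlap / rsum
  switch(params$form,
         quartic = params$kWall * rel^4,
         quadratic = params$kWall * rel^2,
         step = ifelse(overlap > 0, params$kWall * 1e-5, 0))
}

#' Wall steric clash potential between a ligand and protein atoms
#'
#' Soft-wall overlap penalty summed over ligand-protein heavy-atom pairs.
#' A pair contributes only when its distance is below the sum of the van der
#' Waals radii; the default quartic form is
#' kWall * ((r_i + r_j - r_ij) / (r_i + r_j))^4, zero at the touching
#' distance and strictly increasing with overlap depth.  Each pair's penalty
#' is credited to the protein atom's residue.
#'
#' @param model \linkS4class{StructureModel} providing the protein atoms.
#' @param ligand \linkS4class{LigandInstance} (or an atom data.frame).
#' @param params a \code{\link{wallParameters}} list.
#' @param restrict optional character vector of residue keys to restrict the
#'   protein side to (e.g. the binding site).
#' @param tables a \linkS4class{ChemistryTables}.
#' @return A \linkS4class{WallScore}.
#' @export
wallPotential <- function(model, ligand, params = wallParameters(),
                          restrict = NULL, tables = chemistryTables()) {
  prot <- model@atoms[model@atoms$category == "protein" &
                      model@atoms$element != "H", , drop = FALSE]
  if (!is.null(restrict))
    prot <- prot[resKey(prot) %in% restrict, , drop = FALSE]
  lat <- if (is(ligand, "LigandInstance")) ligand@atoms else ligand
  lat <- lat[lat$element != "H", , drop = FALSE]
  empty <- new("WallScore", total = 0, perResidue = stats::setNames(
    numeric(0), character(0)), clashes = data.frame(
      ligandAtom = character(0), proteinAtom = character(0),
      residueKey = character(0), distance = numeric(0), radiiSum = numeric(0)))
  if (!nrow(prot) || !nrow(lat)) return(empty)
  pxyz <- as.matrix(prot[, c("x", "y", "z")])
  lxyz <- as.matrix(lat[, c("x", "y", "z")])
  d2 <- outer(rowSums(lxyz^2), rowSums(pxyz^2), "+") - 2 * lxyz %*% t(pxyz)
  d2[d2 < 0] <- 0
  if (any(d2 < 1e-12)) stop("coincident ligand and protein atoms")
  rsum <- outer(vdwRadius(lat$element, tables),
                vdwRadius(prot$element, tables), "+")
  hit <- which(d2 < rsum^2, arr.ind = TRUE)
  if (!nrow(hit)) return(empty)
  d <- sqrt(d2[hit])
  rs <- rsum[hit]
  pen <- .wallTerm(d, rs, params)
  keys <- resKey(prot)[hit[, 2]]
  perRes <- tapply(pen, keys, sum)
  new("WallScore", total = sum(pen),
      perResidue = stats::setNames(as.numeric(perRes), names(perRes)),
      clashes = data.frame(ligandAtom = lat$name[hit[, 1]],
                           proteinAtom = prot$name[hit[, 2]],
                           residueKey = keys, distance = d, radiiSum = rs))
}

#' Build the Apo-bound form
#'
#' Superposes the Holo form onto the Apo form on the binding-site backbone
#' (N, CA, C, O of site residues) and transplants the ligand through the
#' fitted transform.  The result is the Apo structure carrying the Holo
#' ligand: the construct used to ask whether the Apo side-chain conformation
#' could sterically accommodate the observed ligand pose.
#'
#' @param pair an accepted \linkS4class{ApoHoloPair}.
#' @return list with \code{model} (the Apo-bound
#'   \linkS4class{StructureModel}), \code{ligand} (the transplanted
#'   \linkS4class{LigandInstance}) and \code{transform}.
#' @export
buildApoBound <- function(pair) {
  if (verdict(pair) != "accepted") stop("pair must be accepted")
  bb <- .siteBackbone(pair@apo, pair@holo, pair@correspondence, pair@site)
  if (is.null(bb)) stop("incomplete site backbone correspondence")
  fit <- superpose(ref = bb$apo, mov = bb$holo)
  lig <- pair@ligand
  lxyz <- applyTransform(as.matrix(lig@atoms[, c("x", "y", "z")]), fit)
  lig@atoms$x <- lxyz[, 1]; lig@atoms$y <- lxyz[, 2]; lig@atoms$z <- lxyz[, 3]
  model <- pair@apo
  model@atoms <- rbind(model@atoms, lig@atoms)
  list(model = model, ligand = lig, transform = fit)
}

#' Holo to Apo-bound wall differences
#'
#' Computes the wall potential of the ligand against the binding site in the
#' Holo form and in the Apo-bound form, and reports the signed difference
#' (Apo-bound minus Holo), total and per site residue.  Positive values mean
#' the Apo conformation is less sterically compatible with the ligand pose
#' than the Holo one, i.e. the observed side-chain movement relieves a clash.
#' Per-residue differences are indexed by Holo residue key via the pair's
#' correspondence.
#'
#' @param pair an accepted \linkS4class{ApoHoloPair}.
#' @param params a \code{\link{wallParameters}} list.
#' @param tables a \linkS4class{ChemistryTables}.
#' @return list with \code{siteDelta}, \code{perResidue} (named by Holo
#'   residue key), \code{holoScore}, \code{apoBoundScore},
#'   \code{apoBound} (the built form).
#' @export
deltaWall <- function(pair, params = wallParameters(),
                      tables = chemistryTables()) {
  ab <- buildApoBound(pair)
  corr <- pair@correspondence
  apoSite <- corr$apoKey[match(pair@site, corr$holoKey)]
  holoScore <- wallPotential(pair@holo, pair@ligand, params,
                             restrict = pair@site, tables = tables)
  apoScore <- wallPotential(ab$model, ab$ligand, params,
                            restrict = apoSite, tables = tables)
  per <- stats::setNames(numeric(length(pair@site)), pair@site)
  for (i in seq_along(pair@site)) {
    hk <- pair@site[i]; ak <- apoSite[i]
    h <- if (hk %in% names(holoScore@perResidue))
      holoScore@perResidue[[hk]] else 0
    a <- if (ak %in% names(apoScore@perResidue))
      apoScore@perResidue[[ak]] else 0
    per[[hk]] <- a - h
  }
  list(siteDelta = apoScore@total - holoScore@total, perResidue = per,
       holoScore = holoScore, apoBoundScore = apoScore, apoBound = ab)
}

#' Classify steric criticality of a site and its residues
#'
#' The site is critical when the total wall difference exceeds the site
#' threshold (default 150): without the observed rearrangements the ligand
#' pose would not be acceptable in the Apo form.  A residue is critical when
#' its own wall difference exceeds the residue threshold (default 25).
#' Each critical residue is annotated with its flexibility call and, when chi
#' vectors are supplied, with the minimal-rotation flag.
#'
#' @param deltas result of \code{\link{deltaWall}}.
#' @param calls named character vector of flexibility calls (by Holo residue
#'   key), as produced by \code{\link{classifyFlexibility}}.
#' @param params a \code{\link{wallParameters}} list.
#' @param maxDeltaChi optional named numeric of max |delta chi| per residue
#'   (degrees) for the minimal-rotation annotation.
#' @return list with \code{siteCritical} (logical) and \code{records}
#'   (data.frame: residueKey, deltaWall, critical, call, minimalRotation).
#' @export
classifyCriticality <- function(deltas, calls = NULL,
                                params = wallParameters(),
                                maxDeltaChi = NULL) {
  per <- deltas$perResidue
  rec <- data.frame(residueKey = names(per), deltaWall = as.numeric(per),
                    critical = as.numeric(per) > params$residueThreshold)
  rec$call <- if (!is.null(calls)) unname(calls[rec$residueKey])
              else NA_character_
  rec$minimalRotation <- NA
  if (!is.null(maxDeltaChi)) {
    idx <- which(rec$critical)
    mdc <- unname(maxDeltaChi[rec$residueKey[idx]])
    rec$minimalRotation[idx] <- !is.na(mdc) & mdc < 15
  }
  list(siteCritical = deltas$siteDelta > params$siteThreshold, records = rec)
}

#' Minimal-rotation test
#'
#' TRUE when every chi angle differs by strictly less than 15 degrees between
#' the two forms: the side chain accommodated the ligand with only a minimal
#' rotation.
#'
#' @param apoChis,holoChis matched chi-vector lists from
#'   \code{\link{computeChis}}.
#' @param threshold degrees (exclusive), default 15.
#' @param tables a \linkS4class{ChemistryTables}.
#' @return logical flag.
#' @export
minimalRotationTest <- function(apoChis, holoChis, threshold = 15,
                                tables = chemistryTables()) {
  symIdx <- tables@chiSymmetric[[apoChis$resType]]
  if (is.null(symIdx)) symIdx <- integer(0)
  d <- maxAbsDeltaChiVec(apoChis$chis, holoChis$chis, symIdx)
  max(d) < threshold
}
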