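#' @include internal-coords.R structio.R rotamer.R curation.R hbond.R
NULL

.defaultRoster <- c("SER", "VAL", "LEU", "ASP", "LYS", "PHE", "THR", "GLN")

#' Plan for one synthetic Apo/Holo pair
#'
#' Describes a ground-truthed test pocket: a shell of residues built at ideal
#' internal geometry around a buried synthetic ligand, with controllable
#' plants.  Flexible plants swap the residue between two genuine library
#' rotamers; NR plants put the Apo side chain at chi angles maximally distant
#' from every library rotamer; the clash plant moves a flexible residue
#' radially until its Apo side chain overlaps the transplanted ligand by the
#' stated depth; hydrogen-bond plants position an acceptor (ligand or water
#' oxygen) at an exact distance/angle from a Trp indole donor, or a donor
#' water at an exact heavy-atom distance from an Asp carboxylate.  B-factor
#' and occupancy exceptions exercise the non-rotameric quality filter.
#'
#' @param nResidues number of pocket residues (>= 5).
#' @param residueTypes 3-letter codes recycled over the pocket; the default
#'   roster mixes 1-4-chi types.
#' @param flexibleIdx indices of residues planted as flexible.
#' @param nrIdx indices planted non-rotameric in the Apo form.
#' @param clashIdx index of the planted clash residue (NA for none); implies
#'   a flexible plant there.
#' @param clashDepth target Apo-bound overlap depth in Angstrom.
#' @param hbondPlants data.frame with columns idx, entity ("ligand", "water"
#'   or "water_donor"), dHA (Angstrom), theta (degrees).  Rows with entity
#'   "water_donor" interpret dHA as the heavy-atom O...O distance.
#' @param bfactorExceptions data.frame with columns idx, bfactor, occupancy,
#'   hasAlt.
#' @param resolution stated crystallographic resolution for both forms.
#' @param ligandCode het code of the synthetic ligand (non-buffer).
#' @param radius starting C-alpha shell radius; each residue is then moved
#'   radially until its side-chain tip sits at a fixed 0.5 Angstrom van der
#'   Waals clearance from the ligand, which keeps the ligand buried
#'   (Fc > 0.8) with no steric overlap in either form.
#' @param seed integer seed making the pair reproducible.
#' @return a validated plan (list) for \code{\link{generatePair}}.
#' @export
syntheticPlan <- function(nResidues = 8, residueTypes = NULL,
                          flexibleIdx = integer(0), nrIdx = integer(0),
                          clashIdx = NA_integer_, clashDepth = 0.5,
                          hbondPlants = NULL, bfactorExceptions = NULL,
                          resolution = 1.8, ligandCode = "FLX",
                          radius = 9, seed = 1) {
  stopifnot(nResidues >= 5)
  if (is.null(residueTypes))
    residueTypes <- rep_len(.defaultRoster, nResidues)
  else residueTypes <- rep_len(toupper(residueTypes), nResidues)
  plan <- list(nResidues = nResidues, residueTypes = residueTypes,
               flexibleIdx = sort(unique(as.integer(flexibleIdx))),
               nrIdx = sort(unique(as.integer(nrIdx))),
               clashIdx = as.integer(clashIdx), clashDepth = clashDepth,
               hbondPlants = hbondPlants,
               bfactorExceptions = bfactorExceptions,
               resolution = resolution, ligandCode = toupper(ligandCode),
               radius = radius, seed = as.integer(seed))
  planted <- c(plan$flexibleIdx, plan$nrIdx,
               if (!is.na(plan$clashIdx)) plan$clashIdx,
               if (!is.null(hbondPlants)) hbondPlants$idx,
               if (!is.null(bfactorExceptions)) bfactorExceptions$idx)
  if (length(planted) && (min(planted) < 1 || max(planted) > nResidues))
    stop("planted indices outside 1..nResidues")
  if (!is.na(plan$clashIdx) && clashDepth <= 0)
    stop("clash depth must be positive")
  if (length(intersect(plan$flexibleIdx, plan$nrIdx)))
    stop("a residue cannot be planted both flexible and NR")
  plan
}

## rotamers of a type ordered by decreasing library frequency
.rotamersByFreq <- function(type, lib) {
  cand <- lib[lib$res_type == type, , drop = FALSE]
  cand[order(-cand$freq, cand$rotamer), , drop = FALSE]
}

.rotamerChis <- function(libRow) {
  as.numeric(libRow[paste0("chi", seq_len(libRow$nchi))])
}

## chi targets outside every rotamer's chi1 admission window: grid search for
## the chi1 angle maximizing the minimal circular distance to all library
## chi1 means (all other chis stay at the top rotamer's values, which keeps
## every rotamer excluded through chi1 alone)
.nrChiTarget <- function(type, lib) {
  cand <- .rotamersByFreq(type, lib)
  means1 <- cand$chi1
  grid <- seq(-179, 180, by = 1)
  minDist <- vapply(grid, function(g) min(abs(circDiff(g, means1))),
                    numeric(1))
  best <- grid[which.max(minDist)]
  if (max(minDist) < 31)
    stop("cannot plant NR for type ", type, ": chi1 means too dense")
  chis <- .rotamerChis(cand[1, ])
  chis[1] <- best
  chis
}

## build a residue's atom data.frame at given chis / placement
.residueDF <- function(type, chis, caPos, direction, resno,
                       bfactor = 15, occupancy = 1, hasAlt = FALSE) {
  m <- buildResidueCoords(type, chis, caPos, direction)
  data.frame(record = "ATOM", name = rownames(m), altloc = "",
             hasAlt = hasAlt, resname = type, chain = "A", resno = resno,
             insert = "", x = m[, 1], y = m[, 2], z = m[, 3],
             occupancy = occupancy, bfactor = bfactor,
             element = guessElement(rownames(m)), category = "protein")
}

## compact 7-heavy-atom synthetic ligand centred at the origin
.syntheticLigandDF <- function(code, resno = 500) {
  xyz <- rbind(
    C1 = c(0.00, 0.00, 0.00),
    C2 = c(1.50, 0.00, 0.20),
    N1 = c(-0.75, 1.25, 0.10),
    O1 = c(0.70, -1.20, 0.60),
    C3 = c(-0.80, -1.10, -0.70),
    C4 = c(2.25, 1.20, 0.00),
    O2 = c(-2.10, 0.95, -0.35))
  data.frame(record = "HETATM", name = rownames(xyz), altloc = "",
             hasAlt = FALSE, resname = code, chain = "A", resno = resno,
             insert = "", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             occupancy = 1, bfactor = 10,
             element = substr(rownames(xyz), 1, 1), category = "ligand")
}

## overlap depth of a residue's side chain against ligand atoms when the
## residue is built at the given radial shift
.clashOverlap <- function(type, chis, unit, radius, shift, resno, lig,
                          tables) {
  df <- .residueDF(type, chis, unit * (radius - shift), -unit, resno)
  sc <- df[!df$name %in% c("N", "CA", "C", "O"), , drop = FALSE]
  lxyz <- as.matrix(lig[, c("x", "y", "z")])
  sxyz <- as.matrix(sc[, c("x", "y", "z")])
  rsum <- outer(vdwRadius(sc$element, tables),
                vdwRadius(lig$element, tables), "+")
  d <- sqrt(pmax(0, outer(rowSums(sxyz^2), rowSums(lxyz^2), "+") -
                    2 * sxyz %*% t(lxyz)))
  max(rsum - d)
}

## Radially place a residue so the closest side-chain atom of any listed
## conformer sits `gap` Angstrom outside van der Waals contact with the
## ligand.  Fixed-point iteration (the tip distance is essentially linear in
## the radial coordinate), then an outward nudge if any conformer still
## overlaps.
.calibrateRadius <- function(type, confs, unit, startRadius, resno, lig,
                             tables, gap = 0.5) {
  R <- startRadius
  minGap <- function(R) min(vapply(confs, function(ch)
    -.clashOverlap(type, ch, unit, R, 0, resno, lig, tables), numeric(1)))
  for (it in 1:3) R <- R - (minGap(R) - gap)
  tries <- 0
  while (minGap(R) < 0.05 && tries < 20) { R <- R + 0.25; tries <- tries + 1 }
  R
}

#' Build a residue with target chi angles
#'
#' Constructs a residue at ideal internal geometry whose measured chi angles
#' (via \code{\link{computeChis}}) reproduce the targets to within 0.5
#' degrees.
#'
#' @param type 3-letter residue type.
#' @param chis target chi vector (degrees).
#' @param caPos C-alpha position.
#' @param direction unit vector for the C-alpha to C-beta direction.
#' @param resno residue number.
#' @return atom data.frame in the StructureModel layout.
#' @export
buildResidue <- function(type, chis, caPos = c(0, 0, 0),
                         direction = c(0, 0, 1), resno = 1) {
  .residueDF(toupper(type), chis, caPos, direction, resno)
}

#' Generate one ground-truthed synthetic Apo/Holo pair
#'
#' Realizes a \code{\link{syntheticPlan}}: residues are placed on a spherical
#' Fibonacci shell around the buried ligand with side chains pointing inward,
#' the Holo form uses each residue's most frequent library rotamer, and the
#' plants (flexible, NR, clash, hydrogen-bond, quality) are applied as
#' described there.  Backbones are identical between the two forms, so the
#' binding-site backbone RMSD is zero by construction and all differences are
#' side-chain effects.
#'
#' @param plan a \code{\link{syntheticPlan}}.
#' @param tables a \linkS4class{ChemistryTables}.
#' @return list with \code{apo}, \code{holo} (StructureModels),
#'   \code{ligand} (\linkS4class{LigandInstance} of the Holo form) and
#'   \code{truth}: per-residue expected calls (data.frame: idx, key, type,
#'   call, critical, hbond plants) plus \code{siteFlexibleCount}.
#' @export
generatePair <- function(plan, tables = chemistryTables()) {
  lib <- tables@rotamerLibrary
  n <- plan$nResidues
  units <- fibonacciSphere(n)
  lig <- .syntheticLigandDF(plan$ligandCode)
  apoRows <- list(); holoRows <- list()
  truth <- list()
  extraLigRows <- NULL; waterRows <- NULL
  hb <- plan$hbondPlants
  bfe <- plan$bfactorExceptions

  for (i in seq_len(n)) {
    type <- plan$residueTypes[i]
    ## hydrogen-bond plant residues get fixed donor/acceptor types
    if (!is.null(hb) && i %in% hb$idx) {
      ent <- hb$entity[match(i, hb$idx)]
      type <- if (ent == "water_donor") "ASP" else "TRP"
    }
    rots <- .rotamersByFreq(type, lib)
    holoChis <- .rotamerChis(rots[1, ])
    flexible <- i %in% plan$flexibleIdx ||
      (!is.na(plan$clashIdx) && i == plan$clashIdx)
    apoChis <- if (i %in% plan$nrIdx) .nrChiTarget(type, lib)
               else if (flexible) .rotamerChis(rots[2, ])
               else holoChis
    unit <- units[i, ]
    isClash <- !is.na(plan$clashIdx) && i == plan$clashIdx
    if (isClash) {
      ## pick the rotamer pair whose Apo conformer points most directly at
      ## the ligand relative to its Holo conformer, so a radial shift can
      ## create the planted overlap while the Holo form stays clash-free
      R0 <- .calibrateRadius(type, list(holoChis), unit, plan$radius, i,
                             lig, tables)
      best <- NULL; bestDelta <- -Inf
      for (ha in seq_len(nrow(rots))) for (aa in seq_len(nrow(rots))) {
        if (ha == aa) next
        gH <- -.clashOverlap(type, .rotamerChis(rots[ha, ]), unit, R0, 0,
                             i, lig, tables)
        gA <- -.clashOverlap(type, .rotamerChis(rots[aa, ]), unit, R0, 0,
                             i, lig, tables)
        if (gH - gA > bestDelta) { bestDelta <- gH - gA; best <- c(ha, aa) }
      }
      if (bestDelta <= plan$clashDepth)
        stop("infeasible clash plan for residue ", i, " (type ", type, ")")
      holoChis <- .rotamerChis(rots[best[1], ])
      apoChis <- .rotamerChis(rots[best[2], ])
      ## radial root-find: Apo side chain overlaps the ligand by clashDepth
      f <- function(s) .clashOverlap(type, apoChis, unit, R0, s, i, lig,
                                     tables) - plan$clashDepth
      lo <- -4; hi <- R0 - 3
      if (f(lo) * f(hi) > 0) stop("infeasible clash plan for residue ", i)
      shift <- stats::uniroot(f, c(lo, hi), tol = 1e-6)$root
      if (.clashOverlap(type, holoChis, unit, R0, shift, i, lig,
                        tables) > 0)
        stop("clash plan also clashes in the Holo form; pick another residue")
      caPos <- unit * (R0 - shift)
    } else {
      ## calibrate the radial position so that every conformer's side-chain
      ## tip sits at a fixed van der Waals clearance from the ligand
      confs <- unique(list(holoChis, apoChis))
      R <- .calibrateRadius(type, confs, unit, plan$radius, i, lig, tables)
      caPos <- unit * R
    }
    bfac <- 15; occ <- 1; halt <- FALSE
    if (!is.null(bfe) && i %in% bfe$idx) {
      j <- match(i, bfe$idx)
      bfac <- bfe$bfactor[j]; occ <- bfe$occupancy[j]; halt <- bfe$hasAlt[j]
    }
    apoRows[[i]] <- .residueDF(type, apoChis, caPos, -unit, i,
                               bfactor = bfac, occupancy = occ,
                               hasAlt = halt)
    holoRows[[i]] <- .residueDF(type, holoChis, caPos, -unit, i,
                                bfactor = bfac, occupancy = occ,
                                hasAlt = halt)
    excluded <- !is.null(bfe) && i %in% bfe$idx && i %in% plan$nrIdx
    truth[[i]] <- data.frame(
      idx = i, key = paste("A", i, ".", sep = ":"), type = type,
      call = if (excluded) "excluded_quality"
             else if (flexible || i %in% plan$nrIdx) "flexible" else "rigid",
      critical = !is.na(plan$clashIdx) && i == plan$clashIdx)
  }

  ## hydrogen-bond plants: geometric placement of the partner atom
  if (!is.null(hb)) {
    for (r in seq_len(nrow(hb))) {
      i <- hb$idx[r]; ent <- hb$entity[r]
      res <- holoRows[[i]]
      p3 <- function(nm) as.numeric(res[match(nm, res$name),
                                        c("x", "y", "z")])
      if (ent == "water_donor") {
        ## water oxygen at the stated heavy-atom distance from Asp OD1,
        ## displaced along the CG -> OD1 direction
        od1 <- p3("OD1"); cg <- p3("CG")
        u <- od1 - cg; u <- u / sqrt(sum(u^2))
        wpos <- od1 + hb$dHA[r] * u
        waterRows <- rbind(waterRows, .waterDF(wpos, 600 + r))
      } else {
        ## acceptor at exact (dHA, theta) from the Trp indole H
        ne1 <- p3("NE1"); cd1 <- p3("CD1"); ce2 <- p3("CE2")
        h <- .bisectorH(ne1, cd1, ce2, .NH_BOND)
        uDH <- (ne1 - h) / sqrt(sum((ne1 - h)^2))
        w <- cross3(uDH, cd1 - h)
        w <- w / sqrt(sum(w^2))
        th <- hb$theta[r] * pi / 180
        apos <- h + hb$dHA[r] * (cos(th) * uDH + sin(th) * w)
        if (ent == "ligand") {
          k <- if (is.null(extraLigRows)) 0L else nrow(extraLigRows)
          extraLigRows <- rbind(extraLigRows,
                                .ligandExtraO(apos, plan$ligandCode, k))
        } else {
          waterRows <- rbind(waterRows, .waterDF(apos, 600 + r))
        }
      }
    }
  }

  ligAll <- rbind(lig, extraLigRows)
  protApo <- do.call(rbind, apoRows)
  protHolo <- do.call(rbind, holoRows)
  holoAtoms <- rbind(protHolo, ligAll, waterRows)
  apoAtoms <- rbind(protApo, waterRows)
  holo <- structureModel(holoAtoms, pdbID = sprintf("syn%04dh", plan$seed),
                         resolution = plan$resolution)
  apo <- structureModel(apoAtoms, pdbID = sprintf("syn%04da", plan$seed),
                        resolution = plan$resolution)
  ligand <- ligandInstances(holo, subset = plan$ligandCode)[[1]]
  truthDF <- do.call(rbind, truth)
  list(apo = apo, holo = holo, ligand = ligand,
       truth = list(perResidue = truthDF,
                    siteFlexibleCount = sum(truthDF$call == "flexible"),
                    hbondPlants = hb))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.waterDF <- function(pos, resno) {
  data.frame(record = "HETATM", name = "O", altloc = "", hasAlt = FALSE,
             resname = "HOH", chain = "A", resno = resno, insert = "",
             x = pos[1], y = pos[2], z = pos[3], occupancy = 1, bfactor = 20,
             element = "O", category = "water")
}

.ligandExtraO <- function(pos, code, k) {
  data.frame(record = "HETATM", name = paste0("O", 8 + k), altloc = "",
             hasAlt = FALSE, resname = code, chain = "A", resno = 500,
             insert = "", x = pos[1], y = pos[2], z = pos[3], occupancy = 1,
             bfactor = 10, element = "O", category = "ligand")
}

#' Generate an ensemble of synthetic pairs
#'
#' Draws per-pair planted flexible-residue counts from a Poisson
#' distribution (truncated at the pocket size), assigns the flexible
#' residues uniformly at random, and generates one pair per draw.  All
#' randomness derives from \code{seed}, so a fixed seed reproduces the
#' ensemble exactly.
#'
#' @param n number of pairs (>= 1).
#' @param lambda Poisson mean of the planted flexible count per site.
#' @param seed integer seed.
#' @param nResidues pocket size per pair.
#' @return list of \code{\link{generatePair}} results.
#' @export
generateEnsemble <- function(n, lambda = 1.5, seed = 42, nResidues = 8) {
  stopifnot(n >= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  counts <- pmin(stats::rpois(n, lambda), nResidues)
  picks <- lapply(counts, function(k) sort(sample.int(nResidues, k)))
  lapply(seq_len(n), function(j)
    generatePair(syntheticPlan(nResidues = nResidues,
                               flexibleIdx = picks[[j]],
                               seed = seed + j)))
}
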