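#' @include internal-coords.R structio.R rotamer.R
NULL

## geometry constants for ideal hydrogen placement
.HB_EPS <- 1e-9  # numerical guard on the inclusive detection boundaries
.NH_BOND <- 1.01
.OH_BOND <- 0.96
.ROTOR_STEPS <- seq(0, 330, by = 30)

## exterior-bisector placement for an H on an atom with two heavy neighbours
.bisectorH <- function(center, nb1, nb2, bond) {
  u <- center - nb1; u <- u / sqrt(sum(u^2))
  v <- center - nb2; v <- v / sqrt(sum(v^2))
  w <- u + v
  center + bond * w / sqrt(sum(w^2))
}

## candidate acceptor atoms for rotor optimization and flip scoring:
## N/O heavy atoms excluding the residue itself
.polarNeighbours <- function(atoms, exceptKey) {
  keys <- resKey(atoms)
  atoms[atoms$element %in% c("N", "O") & keys != exceptKey, , drop = FALSE]
}

#' Add polar hydrogens at ideal geometry
#'
#' Deterministic standard-geometry placement of the hydrogens needed for
#' hydrogen-bond detection: backbone amide H, side-chain N-H hydrogens of
#' Lys, Arg, Asn, Gln, Trp (1.01 Angstrom N-H) and hydroxyl hydrogens of
#' Ser, Thr, Tyr (0.96 Angstrom O-H).  Hydroxyl rotors are oriented by an
#' exhaustive scan over 12 discrete positions (30-degree steps), keeping the
#' position that forms the most hydrogen bonds to nearby N/O acceptors (ties
#' break to the smallest torsion; 180 degrees when no position bonds).
#' Carboxylates and phosphates stay unprotonated, and His ring nitrogens get
#' no explicit hydrogen: they are treated as ambident donor/acceptor at
#' detection time.  Existing hydrogens are left in place; residues already
#' carrying the hydrogen are not re-protonated.
#'
#' @param model a \linkS4class{StructureModel}.
#' @param tables a \linkS4class{ChemistryTables}.
#' @return the model with hydrogens appended.
#' @export
placePolarHydrogens <- function(model, tables = chemistryTables()) {
  a <- model@atoms
  prot <- a[a$category == "protein", , drop = FALSE]
  if (!nrow(prot)) return(model)
  keys <- resKey(prot)
  polar <- a[a$element %in% c("N", "O") & a$element != "H", , drop = FALSE]
  newRows <- list()
  addH <- function(res, name, xyz) {
    row <- res[1, , drop = FALSE]
    row$name <- name; row$element <- "H"
    row$x <- xyz[1]; row$y <- xyz[2]; row$z <- xyz[3]
    row$bfactor <- 0; row$occupancy <- 1; row$hasAlt <- FALSE
    newRows[[length(newRows) + 1]] <<- row
  }
  p3 <- function(res, nm) {
    i <- match(nm, res$name)
    if (is.na(i)) NULL else as.numeric(res[i, c("x", "y", "z")])
  }
  for (k in unique(keys)) {
    res <- prot[keys == k, , drop = FALSE]
    type <- res$resname[1]
    have <- res$name
    ## backbone amide H (Pro has none)
    if (type != "PRO" && !"H" %in% have &&
        !is.null(p3(res, "N")) && !is.null(p3(res, "CA")) &&
        !is.null(p3(res, "C")))
      addH(res, "H", nerfPlace(p3(res, "C"), p3(res, "CA"), p3(res, "N"),
                               .NH_BOND, 119, 180))
    sc <- switch(type,
      LYS = {
        if (all(c("CD", "CE", "NZ") %in% have) && !"HZ1" %in% have)
          for (i in 1:3)
            addH(res, paste0("HZ", i),
                 nerfPlace(p3(res, "CD"), p3(res, "CE"), p3(res, "NZ"),
                           .NH_BOND, 109.5, c(60, 180, -60)[i]))
      },
      ARG = {
        if (all(c("CD", "CZ", "NE") %in% have) && !"HE" %in% have)
          addH(res, "HE", .bisectorH(p3(res, "NE"), p3(res, "CD"),
                                     p3(res, "CZ"), .NH_BOND))
        if (all(c("NE", "CZ", "NH1") %in% have) && !"HH11" %in% have) {
          addH(res, "HH11", nerfPlace(p3(res, "NE"), p3(res, "CZ"),
                                      p3(res, "NH1"), .NH_BOND, 120, 0))
          addH(res, "HH12", nerfPlace(p3(res, "NE"), p3(res, "CZ"),
                                      p3(res, "NH1"), .NH_BOND, 120, 180))
        }
        if (all(c("NE", "CZ", "NH2") %in% have) && !"HH21" %in% have) {
          addH(res, "HH21", nerfPlace(p3(res, "NE"), p3(res, "CZ"),
                                      p3(res, "NH2"), .NH_BOND, 120, 0))
          addH(res, "HH22", nerfPlace(p3(res, "NE"), p3(res, "CZ"),
                                      p3(res, "NH2"), .NH_BOND, 120, 180))
        }
      },
      ASN = {
        if (all(c("OD1", "CG", "ND2") %in% have) && !"HD21" %in% have) {
          addH(res, "HD21", nerfPlace(p3(res, "OD1"), p3(res, "CG"),
                                      p3(res, "ND2"), .NH_BOND, 120, 0))
          addH(res, "HD22", nerfPlace(p3(res, "OD1"), p3(res, "CG"),
                                      p3(res, "ND2"), .NH_BOND, 120, 180))
        }
      },
      GLN = {
        if (all(c("OE1", "CD", "NE2") %in% have) && !"HE21" %in% have) {
          addH(res, "HE21", nerfPlace(p3(res, "OE1"), p3(res, "CD"),
                                      p3(res, "NE2"), .NH_BOND, 120, 0))
          addH(res, "HE22", nerfPlace(p3(res, "OE1"), p3(res, "CD"),
                                      p3(res, "NE2"), .NH_BOND, 120, 180))
        }
      },
      TRP = {
        if (all(c("CD1", "NE1", "CE2") %in% have) && !"HE1" %in% have)
          addH(res, "HE1", .bisectorH(p3(res, "NE1"), p3(res, "CD1"),
                                      p3(res, "CE2"), .NH_BOND))
      },
      SER = .placeRotorH(res, "OG", c("CA", "CB"), "HG", polar, k, addH, p3),
      THR = .placeRotorH(res, "OG1", c("CA", "CB"), "HG1", polar, k, addH, p3),
      TYR = .placeRotorH(res, "OH", c("CE1", "CZ"), "HH", polar, k, addH, p3),
      NULL)
  }
  if (length(newRows)) {
    model@atoms <- rbind(a, do.call(rbind, newRows))
    rownames(model@atoms) <- NULL
  }
  model
}

## hydroxyl rotor scan: keep the torsion that makes the most hydrogen bonds
.placeRotorH <- function(res, oName, frame, hName, polar, key, addH, p3) {
  if (!all(c(frame, oName) %in% res$name) || hName %in% res$name)
    return(invisible(NULL))
  a <- p3(res, frame[1]); b <- p3(res, frame[2]); o <- p3(res, oName)
  acc <- polar[resKey(polar) != key, , drop = FALSE]
  if (nrow(acc)) {
    axyz <- as.matrix(acc[, c("x", "y", "z")])
    near <- rowSums(sweep(axyz, 2, o)^2) < 5.5^2
    axyz <- axyz[near, , drop = FALSE]
  } else axyz <- matrix(0, 0, 3)
  best <- 180; bestScore <- -1
  for (tor in .ROTOR_STEPS) {
    h <- nerfPlace(a, b, o, .OH_BOND, 109.5, tor)
    score <- 0L
    if (nrow(axyz)) {
      dha <- sqrt(rowSums(sweep(axyz, 2, h)^2))
      for (j in which(dha >= 1.5 & dha <= 2.7)) {
        u <- o - h; v <- axyz[j, ] - h
        th <- acos(pmin(1, pmax(-1, sum(u * v) /
                                  sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
        if (th >= 90) score <- score + 1L
      }
    }
    if (score > bestScore) { bestScore <- score; best <- tor }
  }
  if (bestScore <= 0) best <- 180
  addH(res, hName, nerfPlace(a, b, o, .OH_BOND, 109.5, best))
  invisible(NULL)
}

#' Correct Asn/Gln amide and His imidazole flips
#'
#' At typical resolutions the electron density cannot distinguish the N and O
#' (or ring C and N) atoms of Asn/Gln amides and His imidazoles, so the
#' terminal group orientation may be misassigned by 180 degrees.  For each
#' such residue both orientations (the input and the group rotated 180
#' degrees about its chi-terminal axis) are scored by (1) fewer heavy-atom
#' clashes with non-bonded neighbours, then (2) more potential hydrogen-bond
#' partners at complementary roles within range; the input orientation is
#' kept on ties.
#'
#' @param model a \linkS4class{StructureModel} (heavy atoms; hydrogens, if
#'   present, are rotated along with the group).
#' @param tables a \linkS4class{ChemistryTables}.
#' @return list with \code{model} (corrected) and \code{flips} (data.frame:
#'   residueKey, resname, flipped).
#' @export
correctFlips <- function(model, tables = chemistryTables()) {
  a <- model@atoms
  prot <- which(a$category == "protein")
  keys <- resKey(a)
  flipSpec <- list(
    ASN = list(axis = c("CB", "CG"), group = c("OD1", "ND2", "HD21", "HD22")),
    GLN = list(axis = c("CG", "CD"), group = c("OE1", "NE2", "HE21", "HE22")),
    HIS = list(axis = c("CB", "CG"),
               group = c("ND1", "CD2", "CE1", "NE2", "HD1", "HE2")))
  report <- list()
  for (k in unique(keys[prot])) {
    idx <- which(keys == k & a$category == "protein")
    type <- a$resname[idx[1]]
    spec <- flipSpec[[type]]
    if (is.null(spec)) next
    axIdx <- match(spec$axis, a$name[idx])
    grpIdx <- idx[a$name[idx] %in% spec$group]
    if (anyNA(axIdx) || length(grpIdx) < 2) next
    p1 <- as.numeric(a[idx[axIdx[1]], c("x", "y", "z")])
    p2 <- as.numeric(a[idx[axIdx[2]], c("x", "y", "z")])
    orig <- as.matrix(a[grpIdx, c("x", "y", "z")])
    flip <- rotateAboutAxis(orig, p1, p2, 180)
    s0 <- .flipScore(a, grpIdx, orig, k, type, tables)
    s1 <- .flipScore(a, grpIdx, flip, k, type, tables)
    doFlip <- s1$clashes < s0$clashes ||
      (s1$clashes == s0$clashes && s1$hbonds > s0$hbonds)
    if (doFlip) {
      a$x[grpIdx] <- flip[, 1]; a$y[grpIdx] <- flip[, 2]
      a$z[grpIdx] <- flip[, 3]
    }
    report[[k]] <- data.frame(residueKey = k, resname = type,
                              flipped = doFlip)
  }
  model@atoms <- a
  flips <- if (length(report)) do.call(rbind, report)
           else data.frame(residueKey = character(0), resname = character(0),
                           flipped = logical(0))
  rownames(flips) <- NULL
  list(model = model, flips = flips)
}

## clash count and complementary-partner count for one flip orientation
.flipScore <- function(a, grpIdx, coords, key, type, tables) {
  keys <- resKey(a)
  other <- which(keys != key & a$element != "H")
  if (!length(other)) return(list(clashes = 0L, hbonds = 0L))
  oxyz <- as.matrix(a[other, c("x", "y", "z")])
  orad <- vdwRadius(a$element[other], tables)
  heavy <- which(a$element[grpIdx] != "H")
  clashes <- 0L; hbonds <- 0L
  da <- tables@donorAcceptor
  for (gi in heavy) {
    p <- coords[gi, ]
    el <- a$element[grpIdx[gi]]
    d <- sqrt(rowSums(sweep(oxyz, 2, p)^2))
    clashes <- clashes + sum(d < orad + vdwRadius(el, tables) - 0.6)
    if (el %in% c("N", "O")) {
      role <- da$role[da$res_type == type &
                      da$atom == a$name[grpIdx[gi]]]
      partners <- d >= 2.5 & d <= 3.5 & a$element[other] %in% c("N", "O")
      if (length(role) && any(partners)) {
        ## a donor needs acceptors in range and vice versa; water counts both
        pn <- other[partners]
        pw <- a$category[pn] == "water"
        pRole <- mapply(function(rt, at) {
          r <- da$role[da$res_type == rt & da$atom == at]
          if (length(r)) r else if (at %in% c("O", "OXT")) "acceptor"
          else if (at == "N") "donor" else "both"
        }, a$resname[pn], a$name[pn])
        pRole[pw] <- "both"
        compat <- switch(role[1],
          donor = pRole %in% c("acceptor", "both"),
          acceptor = pRole %in% c("donor", "both"),
          both = rep(TRUE, length(pRole)))
        hbonds <- hbonds + sum(compat)
      }
    }
  }
  list(clashes = clashes, hbonds = hbonds)
}

#' Detect strong hydrogen bonds of binding-site side chains
#'
#' Enumerates donor-H...acceptor triples in which both donor and acceptor are
#' nitrogen or oxygen and at least one endpoint is a side-chain atom of a
#' binding-site residue from the active residue list (Arg, Asn, Asp, Gln,
#' Glu, His, Lys, Ser, Trp, Tyr, plus Thr when \code{includeThr}).  A bond is
#' called when 1.5 <= d(H...A) <= 2.7 Angstrom and theta(D-H...A) >= 90
#' degrees, boundaries inclusive.  Water donors carry no explicit hydrogen
#' and are treated as always able to present one in optimal geometry: a
#' water-donated bond is called on the heavy-atom distance alone
#' (2.5 <= d(Ow...A) <= 3.5 Angstrom).  His ring nitrogens are ambident and
#' resolved per contact, counting once.  Each bond is labelled by the partner
#' entity seen from the side chain: water, ligand or protein (backbone atoms
#' and other residues' side chains both count as protein).
#'
#' @param model a hydrogenated \linkS4class{StructureModel} (see
#'   \code{\link{placePolarHydrogens}}).
#' @param ligand optional \linkS4class{LigandInstance}; its N/O atoms are
#'   offered as partners labelled "ligand".
#' @param siteKeys residue keys of the binding site.
#' @param includeThr include Thr side chains in the active list.
#' @param tables a \linkS4class{ChemistryTables}.
#' @return data.frame of bonds: residueKey (the site side chain), partner
#'   entity, donorAtom, acceptorAtom, dHA, theta, waterDonated.
#' @export
detectHBonds <- function(model, ligand = NULL, siteKeys,
                         includeThr = TRUE, tables = chemistryTables()) {
  active <- c("ARG", "ASN", "ASP", "GLN", "GLU", "HIS", "LYS", "SER",
              "TRP", "TYR", if (includeThr) "THR")
  a <- model@atoms
  keys <- resKey(a)
  da <- tables@donorAcceptor
  bbN <- c("N", "CA", "C", "O", "OXT", "H")

  ## ---- assemble endpoint tables -------------------------------------
  ## protein side-chain polar atoms with their roles
  scPolar <- which(a$category == "protein" & a$element %in% c("N", "O") &
                   !a$name %in% bbN)
  scRole <- mapply(function(rt, at) {
    r <- da$role[da$res_type == rt & da$atom == at]
    if (length(r)) r else NA_character_
  }, a$resname[scPolar], a$name[scPolar])
  scPolar <- scPolar[!is.na(scRole)]; scRole <- scRole[!is.na(scRole)]
  isSite <- keys[scPolar] %in% siteKeys & a$resname[scPolar] %in% active

  ## backbone polar atoms (partners only)
  bbDon <- which(a$category == "protein" & a$name == "N")
  bbAcc <- which(a$category == "protein" & a$name %in% c("O", "OXT"))
  waters <- which(a$category == "water")
  ligAtoms <- if (!is.null(ligand))
    ligand@atoms[ligand@atoms$element %in% c("N", "O"), , drop = FALSE]
  else NULL

  hIdx <- which(a$element == "H")
  xyz <- as.matrix(a[, c("x", "y", "z")])
  ## map each hydrogen to its bonded heavy donor
  hDonor <- vapply(hIdx, function(h) {
    cand <- which(a$element %in% c("N", "O"))
    d <- sqrt(rowSums(sweep(xyz[cand, , drop = FALSE], 2, xyz[h, ])^2))
    cand[which.min(d)]
  }, integer(1))
  ok <- sqrt(rowSums((xyz[hIdx, , drop = FALSE] -
                      xyz[hDonor, , drop = FALSE])^2)) < 1.25
  hIdx <- hIdx[ok]; hDonor <- hDonor[ok]

  ## virtual donor hydrogens for His ring nitrogens (ambident, no explicit H)
  hisN <- scPolar[a$resname[scPolar] == "HIS" &
                  a$name[scPolar] %in% c("ND1", "NE2")]
  hisH <- lapply(hisN, function(i) {
    res <- a[keys == keys[i] & a$category == "protein", , drop = FALSE]
    nb <- if (a$name[i] == "ND1") c("CG", "CE1") else c("CD2", "CE1")
    j1 <- match(nb[1], res$name); j2 <- match(nb[2], res$name)
    if (is.na(j1) || is.na(j2)) return(NULL)
    .bisectorH(xyz[i, ], as.numeric(res[j1, c("x", "y", "z")]),
               as.numeric(res[j2, c("x", "y", "z")]), .NH_BOND)
  })

  ## acceptor candidates: index, entity, key
  accIdx <- c(scPolar[scRole %in% c("acceptor", "both")], bbAcc, waters)
  accEnt <- c(rep("protein", sum(scRole %in% c("acceptor", "both"))),
              rep("protein", length(bbAcc)), rep("water", length(waters)))
  accXYZ <- xyz[accIdx, , drop = FALSE]
  accKey <- keys[accIdx]
  accName <- a$name[accIdx]
  if (!is.null(ligAtoms) && nrow(ligAtoms)) {
    accXYZ <- rbind(accXYZ, as.matrix(ligAtoms[, c("x", "y", "z")]))
    accEnt <- c(accEnt, rep("ligand", nrow(ligAtoms)))
    accKey <- c(accKey, rep("ligand", nrow(ligAtoms)))
    accName <- c(accName, ligAtoms$name)
  }

  bonds <- list()
  emit <- function(residueKey, entity, donorAtom, acceptorAtom, dHA, theta,
                   waterDonated = FALSE) {
    bonds[[length(bonds) + 1]] <<- data.frame(
      residueKey = residueKey, entity = entity, donorAtom = donorAtom,
      acceptorAtom = acceptorAtom, dHA = dHA, theta = theta,
      waterDonated = waterDonated)
  }

  ## ---- explicit-H donors ---------------------------------------------
  siteKeysActive <- unique(keys[scPolar[isSite]])
  for (t in seq_along(hIdx)) {
    h <- hIdx[t]; dn <- hDonor[t]
    donorSide <- !a$name[dn] %in% bbN && keys[dn] %in% siteKeysActive &&
      dn %in% scPolar[scRole %in% c("donor", "both")]
    dha <- sqrt(rowSums(sweep(accXYZ, 2, xyz[h, ])^2))
    cand <- which(dha >= 1.5 - .HB_EPS & dha <= 2.7 + .HB_EPS)
    for (j in cand) {
      if (accKey[j] == keys[dn] && accEnt[j] == "protein") next  # intra-residue
      accSide <- accEnt[j] == "protein" && accKey[j] %in% siteKeysActive &&
        !accName[j] %in% c("O", "OXT")
      if (!donorSide && !accSide) next
      u <- xyz[dn, ] - xyz[h, ]; v <- accXYZ[j, ] - xyz[h, ]
      th <- acos(pmin(1, pmax(-1, sum(u * v) /
                                sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
      if (th < 90 - .HB_EPS) next
      if (donorSide)
        emit(keys[dn], accEnt[j], a$name[dn], accName[j], dha[j], th)
      if (accSide && !(donorSide && accKey[j] == keys[dn]))
        emit(accKey[j], if (a$category[dn] == "water") "water" else "protein",
             a$name[dn], accName[j], dha[j], th)
    }
  }

  ## ---- His virtual donors --------------------------------------------
  for (t in seq_along(hisN)) {
    i <- hisN[t]; h <- hisH[[t]]
    if (is.null(h) || !(keys[i] %in% siteKeysActive)) next
    dha <- sqrt(rowSums(sweep(accXYZ, 2, h)^2))
    cand <- which(dha >= 1.5 - .HB_EPS & dha <= 2.7 + .HB_EPS)
    for (j in cand) {
      if (accKey[j] == keys[i] && accEnt[j] == "protein") next
      u <- xyz[i, ] - h; v <- accXYZ[j, ] - h
      th <- acos(pmin(1, pmax(-1, sum(u * v) /
                                sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
      if (th >= 90 - .HB_EPS)
        emit(keys[i], accEnt[j], a$name[i], accName[j], dha[j], th)
    }
  }

  ## ---- water donors (virtual optimal hydrogen: distance-only rule) ----
  scAcc <- scPolar[scRole %in% c("acceptor", "both") & isSite]
  if (length(waters) && length(scAcc)) {
    wxyz <- xyz[waters, , drop = FALSE]
    for (i in scAcc) {
      d <- sqrt(rowSums(sweep(wxyz, 2, xyz[i, ])^2))
      for (w in which(d >= 2.5 - .HB_EPS & d <= 3.5 + .HB_EPS))
        emit(keys[i], "water", "OW", a$name[i], d[w] - .OH_BOND, 180,
             waterDonated = TRUE)
    }
  }

  out <- if (length(bonds)) do.call(rbind, bonds)
         else data.frame(residueKey = character(0), entity = character(0),
                         donorAtom = character(0), acceptorAtom = character(0),
                         dHA = numeric(0), theta = numeric(0),
                         waterDonated = logical(0))
  ## de-duplicate ambident double counting (same residue, donor, acceptor)
  out <- out[!duplicated(out[, c("residueKey", "entity", "donorAtom",
                                 "acceptorAtom")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-residue hydrogen-bond counts by partner entity
#'
#' @param bonds data.frame from \code{\link{detectHBonds}}.
#' @param siteKeys residue keys to report (zero counts included).
#' @return data.frame: residueKey, water, protein, ligand.
#' @export
hbondCounts <- function(bonds, siteKeys) {
  out <- data.frame(residueKey = siteKeys, water = 0L, protein = 0L,
                    ligand = 0L)
  if (nrow(bonds)) {
    for (ent in c("water", "protein", "ligand")) {
      tb <- table(bonds$residueKey[bonds$entity == ent])
      m <- match(names(tb), out$residueKey)
      out[[ent]][m[!is.na(m)]] <- as.integer(tb)[!is.na(m)]
    }
  }
  out
}

#' Conserved/gain/loss classification of hydrogen-bond changes
#'
#' Per entity (water, protein, ligand): equal counts in the two forms is
#' conserved (including zero in both), more bonds in the Holo form is a gain,
#' fewer is a loss.
#'
#' @param apoCounts,holoCounts rows of \code{\link{hbondCounts}} for the same
#'   residue (matched by position).
#' @return data.frame: residueKey, entity, apo, holo, call.
#' @export
hbondDelta <- function(apoCounts, holoCounts) {
  stopifnot(nrow(apoCounts) == nrow(holoCounts))
  out <- list()
  for (i in seq_len(nrow(apoCounts))) {
    for (ent in c("water", "protein", "ligand")) {
      na <- apoCounts[[ent]][i]; nh <- holoCounts[[ent]][i]
      out[[length(out) + 1]] <- data.frame(
        residueKey = holoCounts$residueKey[i], entity = ent,
        apo = na, holo = nh,
        call = if (nh == na) "conserved" else if (nh > na) "gain" else "loss")
    }
  }
  do.call(rbind, out)
}
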