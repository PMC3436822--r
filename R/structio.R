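#' @include chemistry.R
NULL

.waterNames <- c("HOH", "WAT", "DOD")

#' Construct a StructureModel from an atom table
#'
#' Builds a validated \linkS4class{StructureModel} from a raw atom
#' data.frame, filling defaulted columns (altloc, occupancy = 1, B = 0,
#' element guessed from the atom name) and deriving the
#' protein/ligand/water category partition when absent.
#'
#' @param atoms data.frame with at least record, name, resname, chain,
#'   resno, x, y, z.
#' @param pdbID identifier.
#' @param resolution crystallographic resolution (Angstrom) or NA.
#' @return a \linkS4class{StructureModel}.
#' @export
structureModel <- function(atoms, pdbID = "anon", resolution = NA_real_) {
  if (is.null(atoms$altloc)) atoms$altloc <- ""
  if (is.null(atoms$hasAlt)) atoms$hasAlt <- FALSE
  if (is.null(atoms$insert)) atoms$insert <- ""
  if (is.null(atoms$occupancy)) atoms$occupancy <- 1
  if (is.null(atoms$bfactor)) atoms$bfactor <- 0
  atoms$occupancy[is.na(atoms$occupancy)] <- 1
  atoms$bfactor[is.na(atoms$bfactor)] <- 0
  atoms$insert[is.na(atoms$insert)] <- ""
  atoms$altloc[is.na(atoms$altloc)] <- ""
  if (is.null(atoms$element) || any(!nzchar(atoms$element)) ||
      anyNA(atoms$element)) {
    guess <- guessElement(atoms$name, hetero = atoms$record != "ATOM")
    if (is.null(atoms$element)) atoms$element <- guess
    bad <- is.na(atoms$element) | !nzchar(atoms$element)
    atoms$element[bad] <- guess[bad]
  }
  atoms$element <- toupper(atoms$element)
  if (is.null(atoms$category)) {
    atoms$category <- ifelse(
      atoms$resname %in% .waterNames, "water",
      ifelse(atoms$record == "ATOM" & atoms$resname %in% names(aminoAcids3()),
             "protein", "ligand"))
  }
  rownames(atoms) <- NULL
  new("StructureModel", pdbID = pdbID, resolution = as.numeric(resolution),
      atoms = atoms)
}

#' Read a PDB-format structure
#'
#' Parses a PDB file into a \linkS4class{StructureModel}.  Coordinate records
#' are partitioned into protein (standard amino-acid ATOM records), waters
#' (HOH/WAT/DOD) and ligands (all remaining HETATM groups).  The resolution is
#' taken from the REMARK 2 header when present.  When a residue carries
#' alternate locations, the highest-occupancy conformer is kept (code "A",
#' then lexicographic, on ties) and the residue is flagged as having had
#' alternates, which the non-rotameric quality filter consumes later.
#'
#' @param path path to a PDB file.
#' @param pdbID identifier to store; defaults to the file name.
#' @return A \linkS4class{StructureModel}.
#' @examples
#' pdb <- writePDB(generatePair(syntheticPlan(seed = 1))$holo, tempfile())
#' readPDB(pdb)
#' @export
readPDB <- function(path, pdbID = sub("\\.pdb$", "", basename(path))) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty file: ", path)
  coord <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(coord)) stop("no ATOM/HETATM records in ", path)
  ## light validation pass so parse errors can name the offending line
  for (i in which(coord)) {
    xyz <- suppressWarnings(as.numeric(c(substr(lines[i], 31, 38),
                                         substr(lines[i], 39, 46),
                                         substr(lines[i], 47, 54))))
    if (anyNA(xyz) || nchar(lines[i]) < 54)
      stop("malformed coordinate record at line ", i, " of ", path)
  }
  resolution <- NA_real_
  rem2 <- grep("^REMARK   2 RESOLUTION\\.", lines, value = TRUE)
  if (length(rem2)) {
    tail2 <- sub("^REMARK   2 RESOLUTION\\.", "", rem2[1])
    num <- regmatches(tail2, regexpr("[0-9]+\\.?[0-9]*", tail2))
    if (length(num)) resolution <- as.numeric(num)
  }
  pdb <- bio3d::read.pdb(path, verbose = FALSE, multi = FALSE)
  a <- pdb$atom
  atoms <- data.frame(
    record = a$type, name = a$elety,
    altloc = ifelse(is.na(a$alt), "", a$alt), hasAlt = FALSE,
    resname = a$resid,
    chain = ifelse(is.na(a$chain), "A", a$chain),
    resno = a$resno,
    insert = ifelse(is.na(a$insert), "", a$insert),
    x = a$x, y = a$y, z = a$z,
    occupancy = a$o, bfactor = a$b,
    element = if (!is.null(a$elesy)) a$elesy else NA_character_,
    stringsAsFactors = FALSE)
  atoms <- collapseAltlocs(atoms)
  structureModel(atoms, pdbID = pdbID, resolution = resolution)
}

## keep the highest-occupancy altloc per (residue, atom name); flag survivors
collapseAltlocs <- function(atoms) {
  key <- paste(resKey(atoms), atoms$resname, atoms$name)
  dup <- key %in% key[duplicated(key)]
  if (!any(dup)) return(atoms)
  keep <- rep(TRUE, nrow(atoms))
  for (k in unique(key[dup])) {
    idx <- which(key == k)
    occ <- atoms$occupancy[idx]
    occ[is.na(occ)] <- 1
    best <- idx[order(-occ, atoms$altloc[idx])][1]
    keep[setdiff(idx, best)] <- FALSE
    atoms$hasAlt[best] <- TRUE
  }
  atoms <- atoms[keep, , drop = FALSE]
  atoms$altloc <- ""
  rownames(atoms) <- NULL
  atoms
}

#' Write a structure to PDB format
#'
#' @param model a \linkS4class{StructureModel}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writePDB <- function(model, path) {
  a <- model@atoms
  bio3d::write.pdb(file = path,
                   type = a$record,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$resno, resid = a$resname,
                   eleno = seq_len(nrow(a)), elety = a$name,
                   chain = a$chain, insert = a$insert,
                   alt = ifelse(nzchar(a$altloc), a$altloc, NA),
                   o = a$occupancy, b = a$bfactor, elesy = a$element)
  if (!is.na(model@resolution)) {
    body <- readLines(path, warn = FALSE)
    writeLines(c(sprintf("REMARK   2 RESOLUTION.    %.2f ANGSTROMS.",
                         model@resolution), body), path)
  }
  invisible(path)
}

#' Is a het code a common crystallization-buffer component?
#'
#' Buffer molecules (sulphate, phosphate, glycerol, ammonium, citrate, MPD,
#' TRIS, MES by default) bind non-specifically and are excluded from the
#' analysis.
#'
#' @param hetCode character vector of 1-3 letter het codes.
#' @param tables a \linkS4class{ChemistryTables}; the buffer list can be
#'   extended through \code{chemistryTables(bufferCodes = ...)}.
#' @return logical vector.
#' @examples
#' isBufferLigand(c("SO4", "ATP"))
#' @export
isBufferLigand <- function(hetCode, tables = chemistryTables()) {
  stopifnot(all(nchar(hetCode) >= 1 & nchar(hetCode) <= 3))
  toupper(hetCode) %in% tables@bufferCodes
}

#' @rdname accessors
#' @param subset optional het code to restrict to.
#' @export
setMethod("ligandInstances", "StructureModel", function(x, subset = NULL) {
  lig <- x@atoms[x@atoms$category == "ligand", , drop = FALSE]
  if (!is.null(subset)) lig <- lig[lig$resname %in% subset, , drop = FALSE]
  if (!nrow(lig)) return(list())
  grp <- paste(lig$resname, resKey(lig), sep = "|")
  lapply(split(seq_len(nrow(lig)), grp), function(idx) {
    at <- lig[idx, , drop = FALSE]
    rownames(at) <- NULL
    new("LigandInstance", hetCode = at$resname[1], atoms = at,
        connectivity = perceiveBonds(at))
  })
})

#' Distance-based bond perception
#'
#' Calls a bond between two atoms when their distance is at most the sum of
#' covalent radii plus 0.4 Angstrom.  Used for ligand connectivity when no
#' chemical-component dictionary entry is supplied.
#'
#' @param atoms atom data.frame (needs name, x, y, z, element).
#' @param tables a \linkS4class{ChemistryTables}.
#' @return 2-column character matrix of bonded atom-name pairs.
#' @export
perceiveBonds <- function(atoms, tables = chemistryTables()) {
  n <- nrow(atoms)
  empty <- matrix(character(0), ncol = 2,
                  dimnames = list(NULL, c("atom1", "atom2")))
  if (n < 2) return(empty)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  r <- covalentRadius(atoms$element, tables)
  cutoff <- outer(r, r, "+") + 0.4
  hit <- which(d <= cutoff & upper.tri(d), arr.ind = TRUE)
  if (!nrow(hit)) return(empty)
  cbind(atom1 = atoms$name[hit[, 1]], atom2 = atoms$name[hit[, 2]])
}

#' Remove hydrogens from carboxylate and phosphate groups
#'
#' Carboxylic acids and phosphates are predominantly deprotonated at
#' physiological pH, so hydrogens bonded to their oxygens are stripped before
#' hydrogen-bond analysis.  A hydrogen is removed when its covalently bonded
#' partner is an oxygen whose other neighbour is either a phosphorus or a
#' carbon bearing at least two oxygen substituents (carboxylate-like); this
#' single rule covers Asp/Glu side chains, C-termini and ligand carboxyl or
#' phosphate groups identified through connectivity.  Other hydrogens (e.g.
#' Ser OG hydroxyls) are untouched; structures without hydrogens pass through
#' unchanged.
#'
#' @param model a \linkS4class{StructureModel}.
#' @param tables a \linkS4class{ChemistryTables}.
#' @return The model with acidic hydrogens removed.
#' @export
stripAcidicHydrogens <- function(model, tables = chemistryTables()) {
  a <- model@atoms
  hIdx <- which(a$element == "H")
  if (!length(hIdx)) return(model)
  heavy <- which(a$element != "H")
  xyz <- as.matrix(a[, c("x", "y", "z")])
  rcov <- covalentRadius(a$element, tables)
  drop <- logical(nrow(a))
  for (h in hIdx) {
    dh <- sqrt(colSums((t(xyz[heavy, , drop = FALSE]) - xyz[h, ])^2))
    bonded <- heavy[dh <= rcov[heavy] + rcov[h] + 0.4]
    if (!length(bonded)) next
    o <- bonded[which.min(dh[match(bonded, heavy)])]
    if (a$element[o] != "O") next
    dOther <- sqrt(colSums((t(xyz[heavy, , drop = FALSE]) - xyz[o, ])^2))
    nb <- heavy[dOther <= rcov[heavy] + rcov[o] + 0.4 & heavy != o]
    nb <- setdiff(nb, h)
    for (c in nb) {
      if (a$element[c] == "P") { drop[h] <- TRUE; break }
      if (a$element[c] == "C") {
        dC <- sqrt(colSums((t(xyz[heavy, , drop = FALSE]) - xyz[c, ])^2))
        oNb <- heavy[dC <= rcov[heavy] + rcov[c] + 0.4 & heavy != c]
        if (sum(a$element[oNb] == "O") >= 2) { drop[h] <- TRUE; break }
      }
    }
  }
  if (any(drop)) {
    a <- a[!drop, , drop = FALSE]
    rownames(a) <- NULL
    model@atoms <- a
  }
  model
}

#' Per-residue summary of a structure's protein component
#'
#' One row per protein residue with completeness and quality bookkeeping:
#' backbone completeness (N, CA, C, O all present), missing heavy side-chain
#' atoms, the side chain's maximum B-factor and minimum occupancy, and whether
#' any side-chain atom carried an alternate location.
#'
#' @param model a \linkS4class{StructureModel}.
#' @param tables a \linkS4class{ChemistryTables}.
#' @return data.frame with columns key, resname, chain, resno, insert,
#'   backboneComplete, missingSideChain, sideChainComplete, maxB, minOcc,
#'   hasAlt.
#' @export
residueTable <- function(model, tables = chemistryTables()) {
  p <- model@atoms[model@atoms$category == "protein", , drop = FALSE]
  if (!nrow(p)) {
    return(data.frame(key = character(0), resname = character(0),
                      chain = character(0), resno = integer(0),
                      insert = character(0), backboneComplete = logical(0),
                      missingSideChain = character(0),
                      sideChainComplete = logical(0), maxB = numeric(0),
                      minOcc = numeric(0), hasAlt = logical(0)))
  }
  keys <- resKey(p)
  ord <- order(p$chain, p$resno, p$insert)
  ukeys <- unique(keys[ord])
  rows <- lapply(ukeys, function(k) {
    at <- p[keys == k, , drop = FALSE]
    sc <- at[!at$name %in% c("N", "CA", "C", "O", "OXT") & at$element != "H", ,
             drop = FALSE]
    expected <- tables@sideChainAtoms[[at$resname[1]]]
    missing <- if (is.null(expected)) character(0)
               else setdiff(expected, at$name)
    data.frame(key = k, resname = at$resname[1], chain = at$chain[1],
               resno = at$resno[1], insert = at$insert[1],
               backboneComplete = all(c("N", "CA", "C", "O") %in% at$name),
               missingSideChain = paste(missing, collapse = ","),
               sideChainComplete = length(missing) == 0,
               maxB = if (nrow(sc)) max(sc$bfactor) else 0,
               minOcc = if (nrow(sc)) min(sc$occupancy) else 1,
               hasAlt = any(at$hasAlt))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## one-letter sequence and residue keys, in chain/resno order
extractSequence <- function(model) {
  rt <- residueTable(model)
  aa <- aminoAcids3()
  one <- aa[rt$resname]
  one[is.na(one)] <- "X"
  list(seq = paste(one, collapse = ""), keys = rt$key, resname = rt$resname)
}

## fetch the atoms of one residue by key
residueAtoms <- function(model, key) {
  a <- model@atoms[model@atoms$category == "protein", , drop = FALSE]
  a[resKey(a) == key, , drop = FALSE]
}
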