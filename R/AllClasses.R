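#' @import methods
NULL

#' Chemistry reference tables
#'
#' Container for the chemistry knowledge the pipeline needs: van der Waals and
#' covalent radii by element, side-chain chi-angle atom quadruples, 2-fold
#' symmetric terminal chi flags, hydrogen-bond donor/acceptor roles, the
#' crystallization-buffer het-code exclusion list, expected side-chain heavy
#' atoms per residue type and the rotamer library.
#'
#' @slot vdw named numeric, element -> van der Waals radius (Angstrom).
#' @slot covalent named numeric, element -> covalent radius (Angstrom).
#' @slot chiAtoms named list, residue type -> list of 4-atom-name vectors, one
#'   per chi angle in order.
#' @slot chiSymmetric named list, residue type -> integer index of the terminal
#'   chi compared modulo 180 degrees (or integer(0)).
#' @slot donorAcceptor data.frame with columns res_type, atom, role
#'   ("donor", "acceptor" or "both").
#' @slot bufferCodes character, excluded het codes.
#' @slot sideChainAtoms named list, residue type -> expected heavy side-chain
#'   atom names.
#' @slot rotamerLibrary data.frame as read from the library TSV.
#' @export
setClass("ChemistryTables", representation(
  vdw = "numeric",
  covalent = "numeric",
  chiAtoms = "list",
  chiSymmetric = "list",
  donorAcceptor = "data.frame",
  bufferCodes = "character",
  sideChainAtoms = "list",
  rotamerLibrary = "data.frame"
))

setValidity("ChemistryTables", function(object) {
  msg <- NULL
  analyzed <- setdiff(names(aminoAcids3()), c("GLY", "ALA"))
  if (!all(analyzed %in% names(object@chiAtoms)))
    msg <- c(msg, "chi definitions missing for some analyzed residue types")
  needed <- c("SO4", "PO4", "GOL", "NH4", "CIT", "MPD", "TRS", "MES")
  if (!all(needed %in% object@bufferCodes))
    msg <- c(msg, "buffer code list must contain the eight standard codes")
  if (is.null(msg)) TRUE else msg
})

#' Parsed macromolecular structure
#'
#' A single PDB-format model: one flat atom table plus identifying metadata.
#' Coordinate records are partitioned into protein (ATOM), ligand (non-water
#' HETATM) and water categories; alternate locations are collapsed to the
#' highest-occupancy conformer at read time, with per-atom bookkeeping of
#' whether alternates were present (needed by the non-rotameric quality
#' filter).
#'
#' @slot pdbID character identifier.
#' @slot resolution crystallographic resolution in Angstrom (NA when the
#'   header does not state one).
#' @slot atoms data.frame with columns record, name, altloc, hasAlt, resname,
#'   chain, resno, insert, x, y, z, occupancy, bfactor, element, category.
#' @export
setClass("StructureModel", representation(
  pdbID = "character",
  resolution = "numeric",
  atoms = "data.frame"
))

setValidity("StructureModel", function(object) {
  a <- object@atoms
  msg <- NULL
  need <- c("record", "name", "altloc", "hasAlt", "resname", "chain", "resno",
            "insert", "x", "y", "z", "occupancy", "bfactor", "element",
            "category")
  if (!all(need %in% names(a)))
    return(paste("atom table missing columns:",
                 paste(setdiff(need, names(a)), collapse = ", ")))
  if (nrow(a)) {
    if (!all(is.finite(c(a$x, a$y, a$z))))
      msg <- c(msg, "non-finite atom coordinates")
    occ <- a$occupancy[!is.na(a$occupancy)]
    if (any(occ < 0 | occ > 1))
      msg <- c(msg, "occupancy outside [0, 1]")
    if (any(!nzchar(a$element)))
      msg <- c(msg, "empty element symbols")
    w <- a[a$category == "water", , drop = FALSE]
    if (nrow(w) && !all(w$element == "O"))
      msg <- c(msg, "waters must contain only oxygen positions")
    if (!is.na(object@resolution) && object@resolution <= 0)
      msg <- c(msg, "resolution must be > 0 when known")
  }
  if (is.null(msg)) TRUE else msg
})

#' A ligand instance extracted from a structure
#'
#' @slot hetCode 3-letter PDB chemical-component id.
#' @slot atoms data.frame in the StructureModel atom-table layout.
#' @slot connectivity 2-column character matrix of bonded atom-name pairs.
#' @export
setClass("LigandInstance", representation(
  hetCode = "character",
  atoms = "data.frame",
  connectivity = "matrix"
))

setValidity("LigandInstance", function(object) {
  if (nrow(object@atoms) < 1) return("ligand must have at least one atom")
  if (nrow(object@connectivity) &&
      !all(object@connectivity %in% object@atoms$name))
    return("connectivity references atoms absent from the ligand")
  TRUE
})

#' A validated Apo/Holo structure pair
#'
#' The unit of analysis: an unbound (Apo) and a ligand-bound (Holo) structure
#' of the same protein, the subject ligand, the residue correspondence from
#' the sequence alignment, the binding site (residues of the Holo form in
#' surface contact with the ligand) and the curation verdict.
#'
#' @slot pairID character label.
#' @slot apo,holo StructureModel.
#' @slot ligand LigandInstance (from the Holo form).
#' @slot correspondence data.frame with columns holoKey, apoKey, resname.
#' @slot site character vector of Holo residue keys (chain:resno:insert).
#' @slot verdict "accepted" or "rejected".
#' @slot reasons character vector of reason codes (empty when accepted).
#' @slot metrics list of curation measurements (identity, overlap, fc,
#'   siteRMSD, ...).
#' @export
setClass("ApoHoloPair", representation(
  pairID = "character",
  apo = "StructureModel",
  holo = "StructureModel",
  ligand = "LigandInstance",
  correspondence = "data.frame",
  site = "character",
  verdict = "character",
  reasons = "character",
  metrics = "list"
))

setValidity("ApoHoloPair", function(object) {
  if (!object@verdict %in% c("accepted", "rejected"))
    return("verdict must be 'accepted' or 'rejected'")
  if (object@verdict == "rejected" && !length(object@reasons))
    return("rejected pairs must carry at least one reason code")
  TRUE
})

#' Steric wall-potential score
#'
#' @slot total total penalty (wall units).
#' @slot perResidue named numeric, residue key -> contribution.
#' @slot clashes data.frame of overlapping pairs (ligand atom, protein atom,
#'   residue key, distance, radii sum).
#' @export
setClass("WallScore", representation(
  total = "numeric",
  perResidue = "numeric",
  clashes = "data.frame"
))

setValidity("WallScore", function(object) {
  if (length(object@perResidue) &&
      abs(object@total - sum(object@perResidue)) > 1e-9 * max(1, object@total))
    return("total must equal the sum of per-residue contributions")
  if (any(object@perResidue < 0)) return("negative wall contribution")
  TRUE
})
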