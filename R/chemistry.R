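#' @include AllClasses.R
NULL

## package-local cache for the chemistry tables (read once per session)
.chemCache <- new.env(parent = emptyenv())

#' Three-letter amino acid codes
#'
#' @return Named character vector mapping 3-letter codes to 1-letter codes.
#' @export
aminoAcids3 <- function() {
  c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
    GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
    MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
    TYR = "Y", VAL = "V")
}

## chi-angle atom quadruples, standard IUPAC definitions
.chiAtomDefs <- function() {
  list(
    SER = list(c("N", "CA", "CB", "OG")),
    THR = list(c("N", "CA", "CB", "OG1")),
    CYS = list(c("N", "CA", "CB", "SG")),
    VAL = list(c("N", "CA", "CB", "CG1")),
    ILE = list(c("N", "CA", "CB", "CG1"), c("CA", "CB", "CG1", "CD1")),
    LEU = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
    PRO = list(c("N", "CA", "CB", "CG")),
    ASP = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "OD1")),
    ASN = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "OD1")),
    GLU = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
               c("CB", "CG", "CD", "OE1")),
    GLN = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
               c("CB", "CG", "CD", "OE1")),
    MET = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "SD"),
               c("CB", "CG", "SD", "CE")),
    LYS = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
               c("CB", "CG", "CD", "CE"), c("CG", "CD", "CE", "NZ")),
    ARG = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
               c("CB", "CG", "CD", "NE"), c("CG", "CD", "NE", "CZ")),
    HIS = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "ND1")),
    PHE = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
    TYR = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
    TRP = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1"))
  )
}

## index of the terminal chi whose end group is 2-fold symmetric
.chiSymDefs <- function() {
  list(ASP = 2L, GLU = 3L, PHE = 2L, TYR = 2L)
}

## expected heavy side-chain atoms (completeness checks)
.sideChainAtomDefs <- function() {
  list(
    ALA = "CB",
    ARG = c("CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
    ASN = c("CB", "CG", "OD1", "ND2"),
    ASP = c("CB", "CG", "OD1", "OD2"),
    CYS = c("CB", "SG"),
    GLN = c("CB", "CG", "CD", "OE1", "NE2"),
    GLU = c("CB", "CG", "CD", "OE1", "OE2"),
    GLY = character(0),
    HIS = c("CB", "CG", "ND1", "CD2", "CE1", "NE2"),
    ILE = c("CB", "CG1", "CG2", "CD1"),
    LEU = c("CB", "CG", "CD1", "CD2"),
    LYS = c("CB", "CG", "CD", "CE", "NZ"),
    MET = c("CB", "CG", "SD", "CE"),
    PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
    PRO = c("CB", "CG", "CD"),
    SER = c("CB", "OG"),
    THR = c("CB", "OG1", "CG2"),
    TRP = c("CB", "CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
    TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"),
    VAL = c("CB", "CG1", "CG2")
  )
}

## side-chain N/O hydrogen-bond roles (strong H-bonds only)
.donorAcceptorDefs <- function() {
  d <- rbind(
    c("ARG", "NE",  "donor"),    c("ARG", "NH1", "donor"),
    c("ARG", "NH2", "donor"),
    c("ASN", "OD1", "acceptor"), c("ASN", "ND2", "donor"),
    c("ASP", "OD1", "acceptor"), c("ASP", "OD2", "acceptor"),
    c("GLN", "OE1", "acceptor"), c("GLN", "NE2", "donor"),
    c("GLU", "OE1", "acceptor"), c("GLU", "OE2", "acceptor"),
    c("HIS", "ND1", "both"),     c("HIS", "NE2", "both"),
    c("LYS", "NZ",  "donor"),
    c("SER", "OG",  "both"),
    c("THR", "OG1", "both"),
    c("TRP", "NE1", "donor"),
    c("TYR", "OH",  "both"))
  data.frame(res_type = d[, 1], atom = d[, 2], role = d[, 3])
}

.readRadiusTable <- function(file) {
  tab <- utils::read.table(file, header = TRUE, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE)
  stats::setNames(tab$radius, tab$element)
}

#' Load the rotamer library
#'
#' Reads a rotamer-library TSV (columns \code{res_type}, \code{rotamer},
#' \code{nchi}, \code{chi1..chi4}, \code{hw1..hw4}, \code{freq}) such as the
#' condensed backbone-independent snapshot shipped with the package.
#'
#' @param file path to the TSV; default is the shipped library.
#' @return data.frame with one row per rotamer.
#' @export
readRotamerLibrary <- function(file = system.file("extdata",
                                                  "rotamer_library.tsv",
                                                  package = "ApoHoloFlex")) {
  lib <- utils::read.table(file, header = TRUE, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE, na.strings = "NA")
  stopifnot(all(c("res_type", "rotamer", "nchi", "chi1", "freq") %in% names(lib)))
  lib
}

#' Assemble the chemistry reference tables
#'
#' Reads the shipped radius tables and rotamer library and bundles them with
#' the built-in chi definitions, donor/acceptor roles and buffer-ligand
#' exclusion list into a \linkS4class{ChemistryTables} object.  The result is
#' cached for the session.
#'
#' @param bufferCodes het codes treated as crystallization-buffer components;
#'   the default is the standard eight (sulphate, phosphate, glycerol,
#'   ammonium, citrate, MPD, TRIS, MES) and may only be extended.
#' @param rotamerLibraryFile optional alternative rotamer library TSV.
#' @return A \linkS4class{ChemistryTables} object.
#' @export
chemistryTables <- function(bufferCodes = NULL, rotamerLibraryFile = NULL) {
  custom <- !is.null(bufferCodes) || !is.null(rotamerLibraryFile)
  if (!custom && !is.null(.chemCache$tables)) return(.chemCache$tables)
  base <- c("SO4", "PO4", "GOL", "NH4", "CIT", "MPD", "TRS", "MES")
  tabs <- new("ChemistryTables",
    vdw = .readRadiusTable(system.file("extdata", "vdw_radii.tsv",
                                       package = "ApoHoloFlex")),
    covalent = .readRadiusTable(system.file("extdata", "covalent_radii.tsv",
                                            package = "ApoHoloFlex")),
    chiAtoms = .chiAtomDefs(),
    chiSymmetric = .chiSymDefs(),
    donorAcceptor = .donorAcceptorDefs(),
    bufferCodes = union(base, toupper(bufferCodes)),
    sideChainAtoms = .sideChainAtomDefs(),
    rotamerLibrary = if (is.null(rotamerLibraryFile)) readRotamerLibrary()
                     else readRotamerLibrary(rotamerLibraryFile))
  validObject(tabs)
  if (!custom) .chemCache$tables <- tabs
  tabs
}

#' Van der Waals radii for a vector of elements
#'
#' Unknown elements fall back to the carbon radius.
#'
#' @param elements character vector of element symbols.
#' @param tables a \linkS4class{ChemistryTables} object.
#' @return numeric vector of radii (Angstrom).
#' @export
vdwRadius <- function(elements, tables = chemistryTables()) {
  r <- tables@vdw[toupper(elements)]
  r[is.na(r)] <- tables@vdw[["C"]]
  unname(r)
}

covalentRadius <- function(elements, tables = chemistryTables()) {
  r <- tables@covalent[toupper(elements)]
  r[is.na(r)] <- tables@covalent[["C"]]
  unname(r)
}

#' Number of chi angles for a residue type
#' @param resType 3-letter code(s).
#' @return integer vector (0 for types without chi definitions).
#' @export
nChi <- function(resType) {
  defs <- .chiAtomDefs()
  vapply(toupper(resType),
         function(t) if (t %in% names(defs)) length(defs[[t]]) else 0L,
         integer(1), USE.NAMES = FALSE)
}

## residue key: chain:resno:insert uniquely identifies a residue in a model
resKey <- function(atoms) {
  paste(atoms$chain, atoms$resno,
        ifelse(is.na(atoms$insert) | atoms$insert == "", ".", atoms$insert),
        sep = ":")
}

## best-effort element from a PDB atom name (used when no element column)
guessElement <- function(name, hetero = FALSE) {
  nm <- toupper(gsub("[^A-Za-z]", "", name))
  two <- substr(nm, 1, 2)
  one <- substr(nm, 1, 1)
  twoLetter <- c("CL", "BR", "SE", "ZN", "FE", "MG", "MN", "NA")
  ifelse(hetero & two %in% twoLetter, two, one)
}

## circular difference a - b wrapped to (-180, 180]
circDiff <- function(a, b) {
  d <- (a - b) %% 360
  d[d > 180] <- d[d > 180] - 360
  ## represent the half-turn as +180
  d[d == -180] <- 180
  d
}

## circular difference under 2-fold end-group symmetry, wrapped to (-90, 90]
circDiffSym <- function(a, b) {
  d <- (a - b) %% 180
  d[d > 90] <- d[d > 90] - 180
  d[d == -90] <- 90
  d
}

## normalize an angle to (-180, 180]
wrapAngle <- function(a) {
  d <- a %% 360
  d[d > 180] <- d[d > 180] - 360
  d[d == -180] <- 180
  d
}

## normalize a 2-fold symmetric terminal chi to (-90, 90]
wrapAngleSym <- function(a) {
  d <- a %% 180
  d[d > 90] <- d[d > 90] - 180
  d[d == -90] <- 90
  d
}
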