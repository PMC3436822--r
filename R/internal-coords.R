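#' @include geometry.R
NULL

## Natural extension reference frame: place a new atom at the given bond
## length from c, bond angle (b-c-new, degrees) and torsion (a-b-c-new,
## degrees, IUPAC sign convention).
nerfPlace <- function(a, b, c, bond, angle, torsion) {
  th <- angle * pi / 180
  ph <- torsion * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- cross3(ab, bc)
  nn <- sqrt(sum(n^2))
  if (nn < 1e-10) stop("collinear reference atoms in internal-coordinate placement")
  n <- n / nn
  m <- cross3(n, bc)
  c + bond * (-cos(th) * bc + sin(th) * cos(ph) * m + sin(th) * sin(ph) * n)
}

## Rodrigues rotation of points (n x 3) about the axis p1 -> p2
rotateAboutAxis <- function(xyz, p1, p2, angleDeg) {
  k <- p2 - p1; k <- k / sqrt(sum(k^2))
  th <- angleDeg * pi / 180
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  sweep(sweep(as.matrix(xyz), 2, p1) %*% t(R), 2, p1, "+")
}

## Side-chain z-matrix templates.  Each entry: atom name, three reference
## atoms (torsion measured as dihedral(a, b, c, new)), bond length (A), bond
## angle (deg) and a torsion spec: list(chi = i, offset = o) uses chi_i + o;
## a plain number is a fixed torsion.
.sideChainTemplates <- function() {
  chi <- function(i, o = 0) list(chi = i, offset = o)
  T <- function(name, a, b, c, bond, angle, tor)
    list(name = name, a = a, b = b, c = c, bond = bond, angle = angle,
         tor = tor)
  list(
    SER = list(T("OG", "N", "CA", "CB", 1.42, 110.8, chi(1))),
    CYS = list(T("SG", "N", "CA", "CB", 1.81, 114.0, chi(1))),
    THR = list(T("OG1", "N", "CA", "CB", 1.43, 109.6, chi(1)),
               T("CG2", "N", "CA", "CB", 1.52, 110.5, chi(1, -122))),
    VAL = list(T("CG1", "N", "CA", "CB", 1.53, 110.5, chi(1)),
               T("CG2", "N", "CA", "CB", 1.53, 110.5, chi(1, 122))),
    ILE = list(T("CG1", "N", "CA", "CB", 1.53, 110.4, chi(1)),
               T("CG2", "N", "CA", "CB", 1.53, 110.5, chi(1, -122)),
               T("CD1", "CA", "CB", "CG1", 1.51, 113.9, chi(2))),
    LEU = list(T("CG", "N", "CA", "CB", 1.53, 116.3, chi(1)),
               T("CD1", "CA", "CB", "CG", 1.52, 110.7, chi(2)),
               T("CD2", "CA", "CB", "CG", 1.52, 110.7, chi(2, 122))),
    PRO = list(T("CG", "N", "CA", "CB", 1.49, 104.5, chi(1)),
               T("CD", "CA", "CB", "CG", 1.50, 105.0, -35)),
    ASP = list(T("CG", "N", "CA", "CB", 1.52, 113.0, chi(1)),
               T("OD1", "CA", "CB", "CG", 1.25, 118.3, chi(2)),
               T("OD2", "CA", "CB", "CG", 1.25, 118.3, chi(2, 180))),
    ASN = list(T("CG", "N", "CA", "CB", 1.52, 112.7, chi(1)),
               T("OD1", "CA", "CB", "CG", 1.23, 120.8, chi(2)),
               T("ND2", "CA", "CB", "CG", 1.33, 116.5, chi(2, 180))),
    GLU = list(T("CG", "N", "CA", "CB", 1.52, 114.1, chi(1)),
               T("CD", "CA", "CB", "CG", 1.52, 112.6, chi(2)),
               T("OE1", "CB", "CG", "CD", 1.25, 118.3, chi(3)),
               T("OE2", "CB", "CG", "CD", 1.25, 118.3, chi(3, 180))),
    GLN = list(T("CG", "N", "CA", "CB", 1.52, 114.1, chi(1)),
               T("CD", "CA", "CB", "CG", 1.52, 112.6, chi(2)),
               T("OE1", "CB", "CG", "CD", 1.23, 120.8, chi(3)),
               T("NE2", "CB", "CG", "CD", 1.33, 116.5, chi(3, 180))),
    MET = list(T("CG", "N", "CA", "CB", 1.52, 114.1, chi(1)),
               T("SD", "CA", "CB", "CG", 1.80, 112.7, chi(2)),
               T("CE", "CB", "CG", "SD", 1.79, 100.9, chi(3))),
    LYS = list(T("CG", "N", "CA", "CB", 1.52, 114.1, chi(1)),
               T("CD", "CA", "CB", "CG", 1.52, 111.3, chi(2)),
               T("CE", "CB", "CG", "CD", 1.52, 111.3, chi(3)),
               T("NZ", "CG", "CD", "CE", 1.49, 112.0, chi(4))),
    ARG = list(T("CG", "N", "CA", "CB", 1.52, 114.1, chi(1)),
               T("CD", "CA", "CB", "CG", 1.52, 111.3, chi(2)),
               T("NE", "CB", "CG", "CD", 1.46, 112.0, chi(3)),
               T("CZ", "CG", "CD", "NE", 1.33, 124.2, chi(4)),
               T("NH1", "CD", "NE", "CZ", 1.33, 120.0, 0),
               T("NH2", "CD", "NE", "CZ", 1.33, 120.0, 180)),
    HIS = list(T("CG", "N", "CA", "CB", 1.50, 113.8, chi(1)),
               T("ND1", "CA", "CB", "CG", 1.38, 122.7, chi(2)),
               T("CD2", "CA", "CB", "CG", 1.36, 131.0, chi(2, 180)),
               T("CE1", "CB", "CG", "ND1", 1.32, 109.0, 180),
               T("NE2", "CB", "CG", "CD2", 1.37, 107.0, 180)),
    PHE = list(T("CG", "N", "CA", "CB", 1.50, 113.8, chi(1)),
               T("CD1", "CA", "CB", "CG", 1.39, 120.7, chi(2)),
               T("CD2", "CA", "CB", "CG", 1.39, 120.7, chi(2, 180)),
               T("CE1", "CB", "CG", "CD1", 1.39, 120.7, 180),
               T("CE2", "CB", "CG", "CD2", 1.39, 120.7, 180),
               T("CZ", "CG", "CD1", "CE1", 1.39, 120.0, 0)),
    TYR = list(T("CG", "N", "CA", "CB", 1.51, 113.9, chi(1)),
               T("CD1", "CA", "CB", "CG", 1.39, 120.8, chi(2)),
               T("CD2", "CA", "CB", "CG", 1.39, 120.8, chi(2, 180)),
               T("CE1", "CB", "CG", "CD1", 1.39, 121.1, 180),
               T("CE2", "CB", "CG", "CD2", 1.39, 121.1, 180),
               T("CZ", "CG", "CD1", "CE1", 1.38, 119.6, 0),
               T("OH", "CD1", "CE1", "CZ", 1.38, 119.9, 180)),
    TRP = list(T("CG", "N", "CA", "CB", 1.50, 113.6, chi(1)),
               T("CD1", "CA", "CB", "CG", 1.37, 127.0, chi(2)),
               T("CD2", "CA", "CB", "CG", 1.43, 126.6, chi(2, 180)),
               T("NE1", "CB", "CG", "CD1", 1.38, 110.2, 180),
               T("CE2", "CB", "CG", "CD2", 1.41, 107.2, 180),
               T("CE3", "CB", "CG", "CD2", 1.40, 133.9, 0),
               T("CZ2", "CG", "CD2", "CE2", 1.40, 122.4, 180),
               T("CZ3", "CG", "CD2", "CE3", 1.39, 118.8, 180),
               T("CH2", "CD2", "CE2", "CZ2", 1.37, 117.5, 0))
  )
}

## Build one residue at ideal internal geometry with the requested chi
## angles.  The backbone sits in a local frame (CA at the origin) and the
## whole residue is then rigidly moved so that CA lands on `caPos` and the
## CA -> CB vector points along `direction`.
buildResidueCoords <- function(type, chis, caPos = c(0, 0, 0),
                               direction = c(0, 0, 1)) {
  type <- toupper(type)
  tpl <- .sideChainTemplates()[[type]]
  nchis <- nChi(type)
  if (type %in% c("GLY", "ALA")) nchis <- 0L
  if (is.null(tpl) && !type %in% c("GLY", "ALA"))
    stop("no ideal-geometry template for type ", type)
  if (length(chis) != nchis)
    stop("expected ", nchis, " chi angles for ", type, ", got ", length(chis))
  pos <- list(
    CA = c(0, 0, 0),
    N = c(0, 1.458, 0),
    C = 1.525 * c(sin(111 * pi / 180), cos(111 * pi / 180), 0))
  pos$O <- nerfPlace(pos$N, pos$CA, pos$C, 1.231, 120.5, 150)
  if (type != "GLY")
    pos$CB <- nerfPlace(pos$C, pos$N, pos$CA, 1.53, 110.4, -122)
  for (e in tpl) {
    tor <- if (is.list(e$tor)) wrapAngle(chis[e$tor$chi] + e$tor$offset)
           else e$tor
    pos[[e$name]] <- nerfPlace(pos[[e$a]], pos[[e$b]], pos[[e$c]],
                               e$bond, e$angle, tor)
  }
  m <- do.call(rbind, pos)
  ## orient: CA -> CB (CA -> N for Gly) along `direction`
  ref <- if (type == "GLY") pos$N else pos$CB
  v <- ref - pos$CA; v <- v / sqrt(sum(v^2))
  d <- direction / sqrt(sum(direction^2))
  ax <- cross3(v, d)
  s <- sqrt(sum(ax^2)); cth <- sum(v * d)
  if (s > 1e-12) {
    K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0),
                3, 3) / s
    R <- diag(3) + s * K + (1 - cth) * (K %*% K)
    m <- m %*% t(R)
  } else if (cth < 0) {
    ## antiparallel: proper 180-degree rotation about any axis orthogonal to v
    u <- if (abs(v[1]) < 0.9) cross3(v, c(1, 0, 0)) else cross3(v, c(0, 1, 0))
    u <- u / sqrt(sum(u^2))
    m <- m %*% t(2 * outer(u, u) - diag(3))
  }
  sweep(m, 2, caPos, "+")
}
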