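## shared fixtures and independent oracles for the test suite

tabs <- chemistryTables()

## independent dihedral formulation: project bond vectors onto the plane
## perpendicular to the central bond and measure the signed angle there
dihedralOracle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  b2n <- b2 / sqrt(sum(b2^2))
  u <- -(b1 - sum(b1 * b2n) * b2n)  # p2 -> p1 direction, projected off b2
  w <- b3 - sum(b3 * b2n) * b2n
  ## signed angle between the in-plane projections, about the b2 axis
  uxw <- c(u[2] * w[3] - u[3] * w[2],
           u[3] * w[1] - u[1] * w[3],
           u[1] * w[2] - u[2] * w[1])
  ang <- atan2(sum(b2n * uxw), sum(u * w)) * 180 / pi
  if (ang <= -180) ang + 360 else ang
}

## brute-force SASA for one atom by uniform random sphere sampling
sasaOracleAtom <- function(atoms, i, probe = 1.4, n = 1e6, seed = 7) {
  set.seed(seed)
  r <- vdwRadius(atoms$element, tabs) + probe
  ctr <- as.numeric(atoms[i, c("x", "y", "z")])
  z <- runif(n, -1, 1); phi <- runif(n, 0, 2 * pi)
  s <- sqrt(1 - z^2)
  pts <- cbind(s * cos(phi), s * sin(phi), z) * r[i]
  pts <- sweep(pts, 2, ctr, "+")
  acc <- rep(TRUE, n)
  for (j in seq_len(nrow(atoms))[-i]) {
    cj <- as.numeric(atoms[j, c("x", "y", "z")])
    acc <- acc & (pts[, 1] - cj[1])^2 + (pts[, 2] - cj[2])^2 +
      (pts[, 3] - cj[3])^2 >= r[j]^2
  }
  mean(acc) * 4 * pi * r[i]^2
}

## naive double-loop wall potential (independent of the vectorized path)
wallOracle <- function(protAtoms, ligAtoms, kWall = 1e6) {
  total <- 0
  for (i in seq_len(nrow(ligAtoms))) for (j in seq_len(nrow(protAtoms))) {
    ri <- vdwRadius(ligAtoms$element[i], tabs)
    rj <- vdwRadius(protAtoms$element[j], tabs)
    d <- sqrt(sum((as.numeric(ligAtoms[i, c("x", "y", "z")]) -
                   as.numeric(protAtoms[j, c("x", "y", "z")]))^2))
    if (d < ri + rj) total <- total + kWall * ((ri + rj - d) / (ri + rj))^4
  }
  total
}

## minimal fake atom row(s)
atomRow <- function(name, el, x, y, z, resname = "LIG", resno = 1,
                    record = "HETATM", chain = "A",
                    category = if (record == "ATOM") "protein" else "ligand",
                    bfactor = 15, occupancy = 1) {
  data.frame(record = record, name = name, altloc = "", hasAlt = FALSE,
             resname = resname, chain = chain, resno = resno, insert = "",
             x = x, y = y, z = z, occupancy = occupancy, bfactor = bfactor,
             element = el, category = category)
}

## a clean synthetic pair used across curation tests
cleanPair <- function(seed = 11, ...) generatePair(syntheticPlan(seed = seed, ...))

## rigid motion helper: rotate + translate a whole atom table
rigidMove <- function(atoms, angleDeg = 33, axis = c(1, 2, 3),
                      shift = c(5, -3, 2)) {
  axis <- axis / sqrt(sum(axis^2))
  th <- angleDeg * pi / 180
  K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(R)
  atoms$x <- xyz[, 1] + shift[1]
  atoms$y <- xyz[, 2] + shift[2]
  atoms$z <- xyz[, 3] + shift[3]
  atoms
}

rigidMoveModel <- function(model, ...) {
  model@atoms <- rigidMove(model@atoms, ...)
  model
}
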