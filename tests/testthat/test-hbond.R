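test_that("polar hydrogens are placed at ideal geometry on the right atoms", {
  lys <- buildResidue("LYS", c(-67, 180, 180, 180))
  m <- placePolarHydrogens(structureModel(lys, "lys"))
  a <- m@atoms
  hz <- a[a$name %in% c("HZ1", "HZ2", "HZ3"), ]
  expect_equal(nrow(hz), 3)
  nz <- as.numeric(a[a$name == "NZ", c("x", "y", "z")])
  ce <- as.numeric(a[a$name == "CE", c("x", "y", "z")])
  for (i in seq_len(3)) {
    h <- as.numeric(hz[i, c("x", "y", "z")])
    expect_equal(sqrt(sum((h - nz)^2)), 1.01, tolerance = 1e-6)
    u <- ce - nz; v <- h - nz
    ang <- acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
    expect_equal(ang, 109.5, tolerance = 0.1)
  }
  ## Asp carboxylate oxygens stay unprotonated
  asp <- placePolarHydrogens(structureModel(buildResidue("ASP",
                                                         c(-70, -20)), "asp"))
  expect_false(any(grepl("^HD", asp@atoms$name)))
  ## Trp indole: one NE1 hydrogen
  trp <- placePolarHydrogens(structureModel(
    buildResidue("TRP", c(-177, 90)), "trp"))
  expect_equal(sum(trp@atoms$name == "HE1"), 1)
})

test_that("hydroxyl rotors orient toward an available acceptor", {
  ser <- buildResidue("SER", 62)
  og <- as.numeric(ser[ser$name == "OG", c("x", "y", "z")])
  cb <- as.numeric(ser[ser$name == "CB", c("x", "y", "z")])
  ca <- as.numeric(ser[ser$name == "CA", c("x", "y", "z")])
  ## put a carbonyl-like acceptor at H-bond range in one specific rotor
  ## direction (perpendicular-ish to the CB-OG axis)
  axis <- og - cb; axis <- axis / sqrt(sum(axis^2))
  perp <- ApoHoloFlex:::cross3(axis, ca - cb)
  perp <- perp / sqrt(sum(perp^2))
  accPos <- og + 1.8 * perp + 1.2 * axis
  acc <- atomRow("O", "O", accPos[1], accPos[2], accPos[3], "GLY", 5,
                 record = "ATOM")
  m <- placePolarHydrogens(structureModel(rbind(ser, acc), "serh"))
  h <- as.numeric(m@atoms[m@atoms$name == "HG", c("x", "y", "z")])
  dHA <- sqrt(sum((h - accPos)^2))
  th <- acos(sum((og - h) * (accPos - h)) /
               sqrt(sum((og - h)^2) * sum((accPos - h)^2))) * 180 / pi
  expect_lte(dHA, 2.7)
  expect_gte(th, 90)
  ## exhaustive scan confirms the chosen rotor is among the bonding ones
  bonds <- detectHBonds(m, NULL, "A:1:.")
  expect_equal(nrow(bonds), 1)
  expect_equal(bonds$entity, "protein")
})

test_that("amide/imidazole flips are chosen by clash count then H-bond count", {
  res <- buildResidue("ASN", c(-65, -40))
  od1 <- as.numeric(res[res$name == "OD1", c("x", "y", "z")])
  cg <- as.numeric(res[res$name == "CG", c("x", "y", "z")])
  u <- od1 - cg; u <- u / sqrt(sum(u^2))
  p <- od1 + 2.9 * u
  ## an acceptor facing OD1: flipping puts the donor ND2 there instead
  acc <- atomRow("OE1", "O", p[1], p[2], p[3], "GLN", 2, record = "ATOM")
  cf <- correctFlips(structureModel(rbind(res, acc), "flip"))
  expect_true(cf$flips$flipped)
  ## a donor facing OD1: the input orientation is already right
  don <- atomRow("NZ", "N", p[1], p[2], p[3], "LYS", 2, record = "ATOM")
  cf2 <- correctFlips(structureModel(rbind(res, don), "keep"))
  expect_false(cf2$flips$flipped)
  ## isolated residue: tie, keep input
  cf3 <- correctFlips(structureModel(res, "iso"))
  expect_false(cf3$flips$flipped)
  ## His: the orientation forming bonds wins
  his <- buildResidue("HIS", c(-65, -70))
  ne2 <- as.numeric(his[his$name == "NE2", c("x", "y", "z")])
  cgH <- as.numeric(his[his$name == "CG", c("x", "y", "z")])
  v <- ne2 - cgH; v <- v / sqrt(sum(v^2))
  q <- ne2 + 2.9 * v
  accH <- atomRow("O", "O", q[1], q[2], q[3], "GLY", 3, record = "ATOM")
  cfH <- correctFlips(structureModel(rbind(his, accH), "his"))
  expect_equal(nrow(cfH$flips), 1)  # evaluated; orientation choice scored
})

test_that("detection respects the distance and angle criteria inclusively", {
  ## planted geometries on both sides of each boundary via the generator
  hb <- data.frame(idx = c(1, 2, 3, 5, 7),
                   entity = c("ligand", "water", "ligand", "ligand", "water"),
                   dHA = c(2.0, 2.7, 1.5, 2.8, 1.4),
                   theta = c(180, 90, 120, 180, 180))
  g <- generatePair(syntheticPlan(seed = 61, hbondPlants = hb))
  pair <- asAcceptedPair(g$apo, g$holo, g$ligand)
  res <- analyzePair(pair, wall = FALSE, hbonds = TRUE)
  d <- res$hbondDeltas
  pick <- function(i, ent) d[d$residueKey == paste0("A:", i, ":.") &
                             d$entity == ent, ]
  ## in-range plants are found; ligand plants are holo-only gains
  expect_equal(pick(1, "ligand")$call, "gain")
  expect_equal(pick(1, "ligand")$holo, 1)
  expect_equal(pick(3, "ligand")$call, "gain")   # d = 1.5 boundary admits
  ## the d = 2.7 / theta = 90 water plant is present in both forms
  expect_equal(pick(2, "water")$apo, 1)
  expect_equal(pick(2, "water")$call, "conserved")
  ## out-of-range plants yield nothing
  expect_equal(pick(5, "ligand")$holo, 0)        # d = 2.8 too far
  expect_equal(pick(7, "water")$holo, 0)         # d = 1.4 clashes
})

test_that("theta below 90 degrees rejects an otherwise perfect contact", {
  hb <- data.frame(idx = 1, entity = "ligand", dHA = 2.0, theta = 85)
  g <- generatePair(syntheticPlan(seed = 62, hbondPlants = hb))
  res <- analyzePair(asAcceptedPair(g$apo, g$holo, g$ligand),
                     wall = FALSE, hbonds = TRUE)
  d <- res$hbondDeltas
  expect_equal(d$holo[d$residueKey == "A:1:." & d$entity == "ligand"], 0)
})

test_that("water donors follow the distance-only virtual-hydrogen rule", {
  hb <- data.frame(idx = c(1, 3), entity = c("water_donor", "water_donor"),
                   dHA = c(3.0, 3.8), theta = c(NA, NA))
  g <- generatePair(syntheticPlan(seed = 63, hbondPlants = hb))
  res <- analyzePair(asAcceptedPair(g$apo, g$holo, g$ligand),
                     wall = FALSE, hbonds = TRUE)
  d <- res$hbondDeltas
  expect_equal(d$holo[d$residueKey == "A:1:." & d$entity == "water"], 1)
  expect_equal(d$call[d$residueKey == "A:1:." & d$entity == "water"],
               "conserved")  # waters are present in both forms
  expect_equal(d$holo[d$residueKey == "A:3:." & d$entity == "water"], 0)
})

test_that("only the active residue list can carry counted bonds", {
  ## a pocket with a planted Trp-donor bond so detection is non-vacuous
  hb <- data.frame(idx = 4, entity = "ligand", dHA = 2.0, theta = 160)
  g <- generatePair(syntheticPlan(seed = 64, hbondPlants = hb))
  holoH <- placePolarHydrogens(g$holo)
  site <- paste("A", 1:8, ".", sep = ":")
  bonds <- detectHBonds(holoH, g$ligand, site)
  expect_gte(nrow(bonds), 1)
  active <- c("ARG", "ASN", "ASP", "GLN", "GLU", "HIS", "LYS", "SER",
              "TRP", "TYR", "THR")
  rt <- residueTable(g$holo)
  types <- rt$resname[match(bonds$residueKey, rt$key)]
  expect_true(all(types %in% active))
  ## entity labels partition the counts
  ct <- hbondCounts(bonds, site)
  expect_equal(sum(ct$water + ct$protein + ct$ligand), nrow(bonds))
  ## with Thr disabled, no bond involves a Thr side chain
  bonds2 <- detectHBonds(holoH, g$ligand, site, includeThr = FALSE)
  if (nrow(bonds2)) {
    types2 <- rt$resname[match(bonds2$residueKey, rt$key)]
    expect_false(any(types2 == "THR"))
  }
  expect_true(all(bonds$residueKey %in% site))
})

test_that("entity counts partition the bonds and the delta calls follow counts", {
  counts <- function(w, p, l)
    data.frame(residueKey = "A:1:.", water = w, protein = p, ligand = l)
  d <- hbondDelta(counts(2, 1, 0), counts(2, 3, 1))
  expect_equal(d$call[d$entity == "water"], "conserved")
  expect_equal(d$call[d$entity == "protein"], "gain")
  expect_equal(d$call[d$entity == "ligand"], "gain")
  d2 <- hbondDelta(counts(1, 0, 0), counts(0, 0, 0))
  expect_equal(d2$call[d2$entity == "water"], "loss")
  ## no bonds in either form: conserved everywhere
  d3 <- hbondDelta(counts(0, 0, 0), counts(0, 0, 0))
  expect_true(all(d3$call == "conserved"))
  ## detection is invariant under rigid motion
  hb <- data.frame(idx = 2, entity = "ligand", dHA = 2.0, theta = 150)
  g <- generatePair(syntheticPlan(seed = 65, hbondPlants = hb))
  site <- paste("A", 1:8, ".", sep = ":")
  b1 <- detectHBonds(placePolarHydrogens(g$holo), g$ligand, site)
  holoM <- rigidMoveModel(g$holo)
  ligM <- g$ligand; ligM@atoms <- rigidMove(ligM@atoms)
  b2 <- detectHBonds(placePolarHydrogens(holoM), ligM, site)
  expect_equal(b1[, c("residueKey", "entity", "donorAtom", "acceptorAtom")],
               b2[, c("residueKey", "entity", "donorAtom", "acceptorAtom")])
  expect_equal(b1$dHA, b2$dHA, tolerance = 1e-6)
})
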