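## fixtures: a clean synthetic pair plus targeted single-gate violations

test_that("sequence alignment: identity, tags, mutations", {
  g <- cleanPair(seed = 41)
  al <- alignSequences(g$apo, g$holo)
  expect_equal(al$identity, 1)
  expect_equal(al$overlap, 1)
  expect_equal(nrow(al$correspondence), 8)
  ## an N-terminal-tag-like extension on the holo form: identity stays 1,
  ## the overlap criterion passes through the shorter form
  tag <- do.call(rbind, lapply(1:2, function(i)
    buildResidue("GLY", numeric(0), c(30 + 3 * i, 0, 0), c(0, 0, 1),
                 100 + i)))
  holoTag <- structureModel(rbind(g$holo@atoms, tag), "tagged", 1.8)
  al2 <- alignSequences(g$apo, holoTag)
  expect_equal(al2$identity, 1)
  expect_equal(al2$overlapHolo, 8 / 10)
  expect_equal(al2$overlap, 1)  # "either" rule: full overlap of the apo form
  ## a point mutation breaks 100% identity
  a <- g$apo@atoms
  sel <- a$resno == 2 & a$category == "protein"
  a$resname[sel] <- "ALA"
  a <- a[!(sel & !a$name %in% c("N", "CA", "C", "O", "CB")), ]
  al3 <- alignSequences(structureModel(a, "mut", 1.8), g$holo)
  expect_equal(al3$identity, 7 / 8)
})

test_that("binding-site definition is the atom-contact rule and is rigid-motion invariant", {
  g <- cleanPair(seed = 42)
  site <- defineBindingSite(g$holo, g$ligand)
  expect_setequal(site, paste("A", 1:8, ".", sep = ":"))
  ## displaced ligand: empty site
  lig <- g$ligand; lig@atoms$x <- lig@atoms$x + 20
  expect_length(defineBindingSite(g$holo, lig), 0)
  ## rigid motion of the whole complex preserves the site
  holoM <- rigidMoveModel(g$holo)
  ligM <- g$ligand; ligM@atoms <- rigidMove(ligM@atoms)
  expect_setequal(defineBindingSite(holoM, ligM), site)
})

test_that("a single contacting atom suffices for site membership", {
  ## one residue reaching the ligand through its CB only
  lig <- new("LigandInstance", hetCode = "LIG",
             atoms = atomRow("C1", "C", 0, 0, 0),
             connectivity = matrix(character(0), ncol = 2))
  res <- buildResidue("SER", 62, c(0, 0, 5.5), c(0, 0, -1))
  m <- structureModel(res, "one")
  cb <- as.numeric(res[res$name == "CB", c("x", "y", "z")])
  stopifnot(sqrt(sum(cb^2)) < 6.02)  # CB inside the contact shell
  expect_equal(defineBindingSite(m, lig), "A:1:.")
})

test_that("each curation gate rejects with its reason code; the clean pair passes", {
  g <- cleanPair(seed = 43)
  crit <- pairingCriteria()
  ok <- validatePair(g$apo, g$holo, g$ligand, crit)
  expect_equal(verdict(ok), "accepted")
  expect_length(reasonCodes(ok), 0)
  expect_gte(pairMetrics(ok)$fc, 0.70)
  expect_lte(pairMetrics(ok)$siteRMSD, 1e-9)

  firstReason <- function(apo, holo, lig)
    reasonCodes(validatePair(apo, holo, lig, crit))[1]

  ## 1. resolution worse than 2.50 on the apo form
  apoBad <- g$apo; apoBad@resolution <- 2.6
  expect_equal(firstReason(apoBad, g$holo, g$ligand), "resolution")

  ## 2. identity below 100%
  a <- g$apo@atoms
  sel <- a$resno == 2 & a$category == "protein"
  a$resname[sel] <- "ALA"
  a <- a[!(sel & !a$name %in% c("N", "CA", "C", "O", "CB")), ]
  expect_equal(firstReason(structureModel(a, "mut", 1.8), g$holo, g$ligand),
               "identity")

  ## 3. overlap below 80% of either form (dovetail overhangs, identity 1)
  gg <- do.call(rbind, lapply(1:4, function(i)
    buildResidue("GLY", numeric(0), c(-40 - 3 * i, 0, 0), c(0, 0, 1),
                 -5 + i)))
  mm <- do.call(rbind, lapply(1:4, function(i)
    buildResidue("MET", c(-67, 180, 75), c(40 + 4 * i, 0, 0), c(0, 0, 1),
                 300 + i)))
  apoOv <- structureModel(rbind(gg, g$apo@atoms), "aov", 1.8)
  holoOv <- structureModel(rbind(g$holo@atoms, mm), "hov", 1.8)
  expect_equal(firstReason(apoOv, holoOv, g$ligand), "overlap")

  ## 4. buffer ligand
  gBuf <- generatePair(syntheticPlan(seed = 43, ligandCode = "GOL"))
  expect_equal(firstReason(gBuf$apo, gBuf$holo, gBuf$ligand), "buffer")

  ## 5. too few heavy atoms
  small <- g$ligand
  small@atoms <- small@atoms[1:4, ]
  expect_equal(firstReason(g$apo, g$holo, small), "heavy_atoms")

  ## 6. covalent attachment: one ligand atom moved to bonding distance
  cov <- g$ligand
  prot <- g$holo@atoms[g$holo@atoms$category == "protein", ]
  cb <- prot[prot$name == "CB", ][1, ]
  cov@atoms$x[1] <- cb$x + 1.5; cov@atoms$y[1] <- cb$y
  cov@atoms$z[1] <- cb$z
  expect_equal(firstReason(g$apo, g$holo, cov), "covalent")

  ## 7. too few contacted residues (ligand displaced out of the pocket)
  far <- g$ligand; far@atoms$x <- far@atoms$x + 20
  expect_equal(firstReason(g$apo, g$holo, far), "contacted_residues")

  ## 8. site split over two chains
  twoChain <- function(m) {
    m@atoms$chain[m@atoms$category == "protein" & m@atoms$resno > 4] <- "B"
    m
  }
  expect_equal(firstReason(twoChain(g$apo), twoChain(g$holo), g$ligand),
               "multi_chain")

  ## 9. insufficient burial: thin the pocket wall in both forms
  dropRes <- function(m, idx) {
    m@atoms <- m@atoms[!(m@atoms$category == "protein" &
                         m@atoms$resno %in% idx), ]
    m
  }
  expect_equal(firstReason(dropRes(g$apo, 1:3), dropRes(g$holo, 1:3),
                           g$ligand), "fc")

  ## 10. missing binding-site side-chain atoms in the apo form
  a2 <- g$apo@atoms
  drop <- a2$category == "protein" & a2$resno == 1 & a2$name == "OG"
  expect_equal(firstReason(structureModel(a2[!drop, ], "gap", 1.8), g$holo,
                           g$ligand), "missing_atoms")

  ## 11. an extra het group present only in the holo form
  xtr <- atomRow("C1", "C", 25, 25, 25, "XTR", 700)
  holoX <- g$holo; holoX@atoms <- rbind(holoX@atoms, xtr)
  expect_equal(firstReason(g$apo, holoX, g$ligand), "extra_ligand")

  ## 12. binding-site backbone displacement above 2.50 A (opposed shifts so
  ## no rigid fit can absorb them)
  a3 <- g$apo@atoms
  mv1 <- a3$category == "protein" & a3$resno %in% 1:2
  mv2 <- a3$category == "protein" & a3$resno %in% 3:4
  a3$x[mv1] <- a3$x[mv1] + 10
  a3$x[mv2] <- a3$x[mv2] - 10
  expect_equal(firstReason(structureModel(a3, "shift", 1.8), g$holo,
                           g$ligand), "site_rmsd")
})

test_that("validation is deterministic and monotone in the criteria", {
  g <- cleanPair(seed = 44)
  v1 <- validatePair(g$apo, g$holo, g$ligand)
  v2 <- validatePair(g$apo, g$holo, g$ligand)
  expect_identical(verdict(v1), verdict(v2))
  expect_identical(reasonCodes(v1), reasonCodes(v2))
  ## accepted at the defaults implies accepted at strictly looser criteria
  loose <- pairingCriteria(maxResolution = 3.0, minOverlap = 0.5,
                           minFc = 0.5, maxSiteRMSD = 5)
  expect_equal(verdict(validatePair(g$apo, g$holo, g$ligand, loose)),
               "accepted")
})

test_that("representative selection maximizes Fc with a lexicographic tie-break", {
  grp <- data.frame(pairID = c("1abc", "2def", "3ghi"),
                    fc = c(0.72, 0.91, 0.85))
  expect_equal(selectRepresentative(grp), "2def")
  expect_equal(selectRepresentative(grp[1, ]), "1abc")
  tie <- data.frame(pairID = c("2xyz", "1uvw"), fc = c(0.80, 0.80))
  expect_equal(selectRepresentative(tie), "1uvw")
})
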