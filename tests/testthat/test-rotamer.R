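chiTypes <- setdiff(names(tabs@chiAtoms), "PRO")

test_that("chi vectors have the canonical length and recover built angles", {
  expect_equal(length(computeChis(buildResidue("VAL", 175))$chis), 1)
  expect_equal(length(computeChis(buildResidue("LYS",
                                               c(-67, 180, 180, 180)))$chis), 4)
  ## construction round-trip within 0.5 degrees
  ser <- computeChis(buildResidue("SER", 62))
  expect_lt(abs(ser$chis - 62), 0.5)
  expect_true(ser$complete)
  ## missing atom: that chi and deeper chis are NA, flagged incomplete
  lys <- buildResidue("LYS", c(-67, 180, 180, 180))
  lys <- lys[lys$name != "CD", ]
  cv <- computeChis(lys)
  expect_false(cv$complete)
  expect_true(all(is.na(cv$chis[2:4])))
  expect_false(is.na(cv$chis[1]))
})

test_that("2-fold symmetric terminal chis are normalized to (-90, 90]", {
  ## a Phe built at chi2 = 150 measures as -30 under ring symmetry
  phe <- computeChis(buildResidue("PHE", c(-65, 150)))
  expect_lt(abs(phe$chis[2] - (-30)), 0.5)
  asp <- computeChis(buildResidue("ASP", c(-70, 160)))
  expect_lt(abs(asp$chis[2] - (-20)), 0.5)
})

test_that("rotamer assignment: exact means, boundary inclusivity, NR", {
  lib <- tabs@rotamerLibrary
  ## every library rotamer's own means assign back to itself, deviations 0
  for (ri in seq_len(nrow(lib))) {
    row <- lib[ri, ]
    chis <- as.numeric(row[paste0("chi", seq_len(row$nchi))])
    sym <- tabs@chiSymmetric[[row$res_type]]
    if (!is.null(sym)) chis[sym] <- ApoHoloFlex:::wrapAngleSym(chis[sym])
    as <- assignRotamer(list(resType = row$res_type, chis = chis,
                             complete = TRUE))
    expect_equal(as$rotamer, row$rotamer)
    expect_equal(max(as$deviations), 0)
  }
  ## +30 exactly is still admitted (closed interval); +31 away from every
  ## mean is NR
  as30 <- assignRotamer(list(resType = "SER", chis = 62 + 30,
                             complete = TRUE))
  expect_equal(as30$rotamer, "p")
  as31 <- assignRotamer(list(resType = "SER", chis = 62 + 45,
                             complete = TRUE))
  expect_true(as31$nr)
  expect_error(assignRotamer(list(resType = "SER", chis = NA_real_,
                                  complete = FALSE)), "incomplete")
  ## determinism
  x <- list(resType = "LEU", chis = c(-60, 170), complete = TRUE)
  expect_identical(assignRotamer(x), assignRotamer(x))
})

test_that("round-trip recovery: noisy means assign perfectly, offsets never do", {
  set.seed(2025)
  lib <- tabs@rotamerLibrary
  n <- 200
  types <- sample(chiTypes, n, replace = TRUE)
  okNoise <- 0; okNR <- 0; matchOrig <- 0
  for (i in seq_len(n)) {
    cand <- lib[lib$res_type == types[i], ]
    row <- cand[sample.int(nrow(cand), 1), ]
    chis <- as.numeric(row[paste0("chi", seq_len(row$nchi))])
    noisy <- ApoHoloFlex:::wrapAngle(chis + rnorm(length(chis), sd = 5))
    cv <- computeChis(buildResidue(types[i], noisy))
    as1 <- assignRotamer(cv)
    if (!as1$nr && as1$rotamer == row$rotamer) okNoise <- okNoise + 1
    ## 45-degree offset from every mean: chi targets at the offset means
    off <- ApoHoloFlex:::wrapAngle(chis + 45)
    cv2 <- computeChis(buildResidue(types[i], off))
    as2 <- assignRotamer(cv2)
    if (as2$nr) okNR <- okNR + 1
    if (!as2$nr && identical(as2$rotamer, row$rotamer))
      matchOrig <- matchOrig + 1
  }
  expect_equal(okNoise, n)    # 100% correct under sigma = 5 noise
  expect_equal(matchOrig, 0)  # 0% match the original rotamer at +45
  expect_equal(okNR, n)       # and all are non-rotameric
})

test_that("the quality filter eliminates untrustworthy NR side chains only", {
  nr <- list(resType = "SER", rotamer = NA_character_, nr = TRUE,
             deviations = NA_real_)
  rot <- list(resType = "SER", rotamer = "p", nr = FALSE, deviations = 0)
  info <- function(maxB, minOcc = 1, hasAlt = FALSE)
    data.frame(maxB = maxB, minOcc = minOcc, hasAlt = hasAlt)
  expect_equal(qualityFilter(nr, info(45)), "excluded_quality")
  expect_equal(qualityFilter(nr, info(35)), "ok")
  expect_equal(qualityFilter(nr, info(35, minOcc = 0.9)), "excluded_quality")
  expect_equal(qualityFilter(nr, info(35, hasAlt = TRUE)), "excluded_quality")
  ## rotameric side chains are untouched even at B = 80
  expect_equal(qualityFilter(rot, info(80, 0.5, TRUE)), "ok")
})

test_that("flexibility calls follow the rotamer-state comparison", {
  mk <- function(rot, nr = FALSE) list(resType = "PHE", rotamer = rot,
                                       nr = nr, deviations = 0)
  expect_equal(classifyFlexibility(mk("m-85"), mk("m-85")), "rigid")
  expect_equal(classifyFlexibility(mk("t80"), mk("p90")), "flexible")
  expect_equal(classifyFlexibility(mk(NA, TRUE), mk("t80")), "flexible")
  expect_equal(classifyFlexibility(mk(NA, TRUE), mk(NA, TRUE)),
               "excluded_NR_NR")
  expect_equal(classifyFlexibility(mk("t80"), mk("t80"), "excluded_quality",
                                   "ok"), "excluded_quality")
})

test_that("flexibility probability is the binomial fraction with its SE", {
  expect_equal(flexibilityProbability(0, 50), list(P = 0, error = 0))
  expect_equal(flexibilityProbability(40, 40), list(P = 1, error = 0))
  pe <- flexibilityProbability(10, 40)
  expect_equal(pe$P, 0.25)
  expect_equal(pe$error, sqrt(0.25 * 0.75 / 40))
  ## cross-check the closed form against a bootstrap
  set.seed(99)
  obs <- rep(c(1, 0), c(10, 30))
  boots <- replicate(1e5, mean(sample(obs, replace = TRUE)))
  expect_lt(abs(sd(boots) - pe$error) / pe$error, 0.02)
  expect_error(flexibilityProbability(1, 0), "positive")
  expect_error(flexibilityProbability(5, 4), "exceed")
})

test_that("the delta-chi threshold method uses inclusive circular differences", {
  mk <- function(type, chis) list(resType = type, chis = chis,
                                  complete = TRUE)
  expect_true(deltaChiFlexible(mk("LEU", c(5, 60)), mk("LEU", c(0, 0))))
  expect_false(deltaChiFlexible(mk("SER", 59), mk("SER", 0)))
  ## wraparound: -170 vs 170 is a 20-degree change
  expect_false(deltaChiFlexible(mk("SER", -170), mk("SER", 170)))
  expect_error(deltaChiFlexible(mk("SER", 10), mk("LEU", c(0, 0))),
               "mismatched")
})

test_that("disulfide cysteines are detected by the SG-SG distance rule", {
  c1 <- buildResidue("CYS", -65, c(0, 0, 0), c(0, 0, 1), 1)
  sg <- as.numeric(c1[c1$name == "SG", c("x", "y", "z")])
  c2 <- buildResidue("CYS", -65, sg + c(0, 0, 4), c(0, 0, 1), 2)
  ## place the partner so its SG sits ~2.05 A from the first SG
  sg2 <- as.numeric(c2[c2$name == "SG", c("x", "y", "z")])
  delta <- (sg + c(2.05, 0, 0)) - sg2
  c2$x <- c2$x + delta[1]; c2$y <- c2$y + delta[2]; c2$z <- c2$z + delta[3]
  m <- structureModel(rbind(c1, c2), "ss")
  expect_setequal(disulfideCysteines(m), c("A:1:.", "A:2:."))
  ## far apart: no bridge
  c3 <- buildResidue("CYS", -65, c(20, 0, 0), c(0, 0, 1), 3)
  m2 <- structureModel(rbind(c1, c3), "noss")
  expect_length(disulfideCysteines(m2), 0)
})
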