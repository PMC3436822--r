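test_that("dihedral handles planar cis/trans and matches an independent formulation", {
  ## planar cis quadruple -> 0; trans -> 180
  expect_equal(dihedralAngle(c(1, 1, 0), c(0, 1, 0), c(0, 0, 0), c(1, 0, 0)), 0)
  expect_equal(abs(dihedralAngle(c(-1, 1, 0), c(0, 1, 0), c(0, 0, 0),
                                 c(1, 0, 0))), 180)
  set.seed(101)
  for (i in 1:1000) {
    q <- matrix(rnorm(12, sd = 2), 4, 3)
    ## reject near-degenerate draws the contract excludes, and
    ## ill-conditioned near-collinear planes where 1e-9 agreement is
    ## numerically meaningless
    if (min(sqrt(rowSums(diff(q)^2))) < 0.3) next
    n1 <- ApoHoloFlex:::cross3(q[2, ] - q[1, ], q[3, ] - q[2, ])
    n2 <- ApoHoloFlex:::cross3(q[3, ] - q[2, ], q[4, ] - q[3, ])
    if (sqrt(sum(n1^2)) < 0.5 || sqrt(sum(n2^2)) < 0.5) next
    a1 <- try(dihedralAngle(q[1, ], q[2, ], q[3, ], q[4, ]), silent = TRUE)
    if (inherits(a1, "try-error")) next
    a2 <- dihedralOracle(q[1, ], q[2, ], q[3, ], q[4, ])
    d <- abs(a1 - a2); d <- min(d, 360 - d)
    expect_lt(d, 1e-9)
  }
  ## the torsion is invariant under point-order reversal and flips sign
  ## under mirror reflection
  q <- matrix(c(1, 0, 0, 0, 0, 0, 0, 1, 0, 1, 1, 1), 4, 3, byrow = TRUE)
  expect_equal(dihedralAngle(q[1, ], q[2, ], q[3, ], q[4, ]),
               dihedralAngle(q[4, ], q[3, ], q[2, ], q[1, ]))
  qm <- q; qm[, 3] <- -qm[, 3]
  expect_equal(dihedralAngle(qm[1, ], qm[2, ], qm[3, ], qm[4, ]),
               -dihedralAngle(q[1, ], q[2, ], q[3, ], q[4, ]))
  ## degenerate inputs error
  expect_error(dihedralAngle(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)),
               "degenerate")
  expect_error(dihedralAngle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
               "degenerate")
})

test_that("superposition recovers exact rigid motions and reports honest rmsd", {
  set.seed(7)
  A <- matrix(rnorm(150), 50, 3)
  f0 <- superpose(A, A)
  expect_equal(f0$rotation, diag(3), tolerance = 1e-10)
  expect_equal(f0$rmsd, 0, tolerance = 1e-10)
  ## known rotation + translation -> rmsd 0, det +1
  th <- 37 * pi / 180
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  B <- A %*% Rz + matrix(rep(c(4, -2, 9), each = 50), 50, 3)
  fit <- superpose(ref = B, mov = A)
  expect_lt(fit$rmsd, 1e-10)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  expect_equal(applyTransform(A, fit), B, tolerance = 1e-8)
  ## noisy copy: reported rmsd equals direct recomputation from the fit
  N <- B + matrix(rnorm(150, sd = 0.1), 50, 3)
  fit2 <- superpose(ref = N, mov = A)
  fitted <- applyTransform(A, fit2)
  expect_equal(fit2$rmsd, sqrt(mean(rowSums((fitted - N)^2))),
               tolerance = 1e-12)
  expect_lt(abs(fit2$rmsd - 0.1 * sqrt(3)) / (0.1 * sqrt(3)), 0.2)
  ## cross-check against bio3d's independent least-squares fit
  xyzA <- as.numeric(t(A)); xyzN <- as.numeric(t(N))
  fitted3 <- matrix(bio3d::fit.xyz(fixed = xyzN, mobile = xyzA,
                                   fixed.inds = 1:150, mobile.inds = 1:150),
                    ncol = 3, byrow = TRUE)
  expect_equal(sqrt(mean(rowSums((fitted3 - N)^2))), fit2$rmsd,
               tolerance = 1e-6)
  ## failure modes
  expect_error(superpose(A[1:2, ], A[1:2, ]), "3 matched points")
  line <- cbind(1:5, 0, 0)
  expect_error(superpose(line, line), "collinear")
})

test_that("SASA matches closed forms and a dense numerical oracle", {
  ## isolated carbon sphere: 4 pi (1.7 + 1.4)^2
  one <- atomRow("C1", "C", 0, 0, 0)
  s1 <- sasa(one)
  expect_equal(s1$total, 4 * pi * 3.1^2, tolerance = 0.005 * 4 * pi * 3.1^2)
  ## an atom caged by a tight octahedral shell of big neighbours -> 0
  cage <- do.call(rbind, lapply(seq_len(6), function(i) {
    d <- rbind(c(2, 0, 0), c(-2, 0, 0), c(0, 2, 0), c(0, -2, 0),
               c(0, 0, 2), c(0, 0, -2))[i, ]
    atomRow(paste0("S", i), "S", d[1], d[2], d[3])
  }))
  s2 <- sasa(rbind(one, cage))
  expect_equal(s2$perAtom[1], 0)
  ## two-sphere overlaps against a 1e6-point random-sampling oracle
  for (d in c(2.0, 3.0)) {
    two <- rbind(atomRow("C1", "C", 0, 0, 0), atomRow("O1", "O", d, 0, 0))
    s <- sasa(two)
    for (i in 1:2) {
      ref <- sasaOracleAtom(two, i)
      expect_lt(abs(s$perAtom[i] - ref) / ref, 0.01)
    }
  }
  ## total equals the per-atom sum
  expect_equal(s2$total, sum(s2$perAtom), tolerance = 1e-9)
})

test_that("SASA is invariant under rigid motion within sampling tolerance", {
  g <- cleanPair(seed = 31)
  at <- g$holo@atoms[g$holo@atoms$category == "protein", ][1:30, ]
  ## the lattice is fixed in space, so rotation re-samples each sphere; at
  ## 2000 points the total is stable to 0.1%
  s1 <- sasa(at, nPoints = 2000)
  s2 <- sasa(rigidMove(at), nPoints = 2000)
  expect_lt(abs(s2$total - s1$total) / s1$total, 0.001)
})

test_that("the contact criterion is the stated distance inequality", {
  m <- structureModel(atomRow("CB", "C", 0, 0, 0, "ALA", 1, record = "ATOM"),
                      "one")
  mkLig <- function(x) new("LigandInstance", hetCode = "LIG",
                           atoms = atomRow("O1", "O", x, 0, 0),
                           connectivity = matrix(character(0), ncol = 2))
  ## C (1.7) + O (1.52) + 2 * 1.4 = 6.02
  expect_equal(nrow(atomContacts(m, mkLig(3.0))$pairs), 1)
  expect_equal(nrow(atomContacts(m, mkLig(6.01))$pairs), 1)
  expect_equal(nrow(atomContacts(m, mkLig(6.5))$pairs), 0)
  ## a ligand far from everything yields an empty ContactSet
  g <- cleanPair(seed = 32)
  lig <- g$ligand
  lig@atoms$x <- lig@atoms$x + 50
  ct <- atomContacts(g$holo, lig)
  expect_equal(nrow(ct$pairs), 0)
  expect_equal(length(ct$perResidue), 0)
})

test_that("burial fraction follows its definition and is monotone in occlusion", {
  lig <- new("LigandInstance", hetCode = "LIG",
             atoms = atomRow("C1", "C", 0, 0, 0),
             connectivity = matrix(character(0), ncol = 2))
  vac <- structureModel(atomRow("CA", "C", 90, 90, 90, "GLY", 1,
                                record = "ATOM"), "far")
  expect_equal(fractionInContact(lig, vac), 0, tolerance = 1e-6)
  ## fully caged -> 1
  cage <- do.call(rbind, lapply(seq_len(6), function(i) {
    d <- rbind(c(2, 0, 0), c(-2, 0, 0), c(0, 2, 0), c(0, -2, 0),
               c(0, 0, 2), c(0, 0, -2))[i, ]
    atomRow(paste0("S", i), "S", d[1], d[2], d[3], "CYS", i, record = "ATOM")
  }))
  expect_equal(fractionInContact(lig, structureModel(cage, "cage")), 1)
  ## definition recomputation on a synthetic pocket
  g <- cleanPair(seed = 33)
  fc <- fractionInContact(g$ligand, g$holo)
  lat <- g$ligand@atoms
  free <- sasa(lat)$total
  occl <- g$holo@atoms[g$holo@atoms$category == "protein", ]
  bound <- sasa(rbind(lat, occl))
  sasB <- sum(bound$perAtom[seq_len(nrow(lat))])
  expect_equal(fc, 1 - sasB / free, tolerance = 1e-9)
  ## printed convention is the complementary ratio
  expect_equal(fractionInContact(g$ligand, g$holo, convention = "printed"),
               sasB / free, tolerance = 1e-9)
  ## monotone non-decreasing as occluders are added
  half <- g$holo
  keep <- half@atoms$category != "protein" |
    half@atoms$resno <= 4
  half@atoms <- half@atoms[keep, ]
  expect_lte(fractionInContact(g$ligand, half), fc + 1e-9)
})
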