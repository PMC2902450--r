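test_that("dihedral: planar references, rigid-motion invariance,
           antisymmetry, degenerate error", {
  p <- list(c(1, 1, 0), c(0, 1, 0), c(0, 0, 0), c(1, 0, 0))
  expect_equal(dihedral_angle(p[[1]], p[[2]], p[[3]], p[[4]]), 0,
               tolerance = 1e-12)
  expect_equal(dihedral_angle(p[[1]], p[[2]], p[[3]], c(-1, 0, 0)), -pi,
               tolerance = 1e-12)  # trans reports -pi (half-open interval)
  set.seed(7)
  for (r in 1:5) {
    pts <- matrix(stats::rnorm(12), 4, 3)
    d0 <- dihedral_angle(pts[1, ], pts[2, ], pts[3, ], pts[4, ])
    th <- stats::runif(3, -pi, pi)
    Rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])),
                c(0, sin(th[1]), cos(th[1])))
    Rz <- rbind(c(cos(th[2]), -sin(th[2]), 0),
                c(sin(th[2]), cos(th[2]), 0), c(0, 0, 1))
    M <- Rx %*% Rz
    shift <- stats::rnorm(3)
    q <- t(M %*% t(pts)) + rep(shift, each = 4)
    expect_lt(abs(angle_diff(dihedral_angle(q[1, ], q[2, ], q[3, ], q[4, ]),
                             d0)), 1e-10)
    # reversing the chain preserves the dihedral; mirroring negates it
    expect_lt(abs(angle_diff(dihedral_angle(pts[4, ], pts[3, ], pts[2, ],
                                            pts[1, ]), d0)), 1e-10)
    mir <- pts
    mir[, 3] <- -mir[, 3]
    expect_lt(abs(angle_diff(dihedral_angle(mir[1, ], mir[2, ], mir[3, ],
                                            mir[4, ]), -d0)), 1e-10)
  }
  expect_error(dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),
                              c(3, 1, 0)), "colinear")
})

test_that("build-then-extract chi round trip across all amino acids", {
  set.seed(11)
  grid <- c(-120, 0, 120) * pi / 180
  for (aa in names(chi_counts())) {
    nchi <- chi_counts()[[aa]]
    bb <- build_backbone(c("ALA", aa, "ALA"), rep(-2, 3), rep(2.3, 3))
    chis <- rbind(as.matrix(expand.grid(rep(list(grid), nchi))),
                  matrix(stats::runif(5 * nchi, -pi, pi), 5))
    for (r in seq_len(nrow(chis))) {
      full <- rebuild_side_chains(bb, stats::setNames(list(chis[r, ]), "2"))
      got <- residue_angles(full)
      err <- max(abs(angle_diff(
        as.numeric(got[2, paste0("chi", seq_len(nchi))]), chis[r, ])))
      expect_lt(err, 1e-6)
    }
  }
})

test_that("built side chains respect topology bond lengths", {
  bb <- build_backbone(c("ALA", "ARG", "ALA"), rep(-2, 3), rep(2.3, 3))
  full <- rebuild_side_chains(bb, list(`2` = c(-1, 2, 3, -2)))
  topo <- sidechain_topology("ARG")
  xyz <- function(at) as.numeric(full[full$resno == 2 & full$atom == at,
                                      c("x", "y", "z")])
  for (i in seq_len(nrow(topo))) {
    d <- sqrt(sum((xyz(topo$atom[i]) - xyz(topo$r3[i]))^2))
    expect_equal(d, topo$bond[i], tolerance = 1e-6)
  }
})

test_that("rotating chi1 rigidly rotates exactly the distal atoms", {
  bb <- build_backbone(c("ALA", "LYS", "ALA"), rep(-2, 3), rep(2.3, 3))
  chi0 <- c(-1.2, 0.8, 2.0, -2.4)
  delta <- 0.7
  s0 <- rebuild_side_chains(bb, list(`2` = chi0))
  s1 <- rebuild_side_chains(bb, list(`2` = chi0 + c(delta, 0, 0, 0)))
  # CB is proximal to the chi1 axis: unmoved
  cb0 <- as.numeric(s0[s0$atom == "CB", c("x", "y", "z")])
  cb1 <- as.numeric(s1[s1$atom == "CB", c("x", "y", "z")])
  expect_equal(cb0, cb1, tolerance = 1e-9)
  # distal atoms move but pairwise distances within the side chain persist
  for (at in c("CG", "CD", "CE", "NZ")) {
    a0 <- as.numeric(s0[s0$atom == at, c("x", "y", "z")])
    a1 <- as.numeric(s1[s1$atom == at, c("x", "y", "z")])
    expect_gt(sqrt(sum((a0 - a1)^2)), 0.1)
    expect_equal(sqrt(sum((a0 - cb0)^2)), sqrt(sum((a1 - cb1)^2)),
                 tolerance = 1e-9)
  }
  # chi2..chi4 extracted from the rotated chain are unchanged
  got <- residue_angles(s1)
  expect_equal(as.numeric(got[2, c("chi2", "chi3", "chi4")]), chi0[2:4],
               tolerance = 1e-6)
})

test_that("a built leucine at a library-typical rotamer has no internal
           clash", {
  bb <- build_backbone(c("ALA", "LEU", "ALA"), rep(-2, 3), rep(2.3, 3))
  s <- rebuild_side_chains(bb, list(`2` = c(-60, 180) * pi / 180))
  sc <- s[s$resno == 2 & !s$atom %in% c("N", "CA", "C", "O"), ]
  X <- as.matrix(sc[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(X))
  diag(d) <- Inf
  # non-bonded intra-side-chain pairs (bonds are ~1.5 A)
  expect_gt(min(d[d > 1.6]), 2.0)
})

test_that("PDB write/read round trip is idempotent at format precision", {
  toy <- make_toy_protein("dipeptide")
  p1 <- withr::local_tempfile(fileext = ".pdb")
  p2 <- withr::local_tempfile(fileext = ".pdb")
  write_structure(toy$structure, p1)
  s1 <- read_structure(p1)
  expect_identical(nrow(s1), nrow(toy$structure))
  expect_lt(max(abs(as.matrix(s1[, c("x", "y", "z")]) -
                      as.matrix(toy$structure[, c("x", "y", "z")]))),
            5e-4 + 1e-9)
  write_structure(s1, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("reader options: backbone_only strip and chain-end conventions", {
  toy <- make_toy_protein("helix_clash")
  p <- withr::local_tempfile(fileext = ".pdb")
  write_structure(toy$structure, p)
  bb <- read_structure(p, backbone_only = TRUE)
  expect_identical(sort(unique(bb$atom)), c("C", "CA", "N", "O"))
  expect_identical(nrow(bb), 4L * length(unique(toy$structure$resno)))
  ang <- residue_angles(bb)
  expect_true(is.na(ang$phi[1]))
  expect_false(is.na(ang$psi[1]))
  expect_true(is.na(ang$psi[nrow(ang)]))
  # Ala rows never get chi values
  expect_true(all(is.na(ang$chi1[ang$aa == "ALA"])))
})

test_that("residues with missing side-chain atoms are flagged, not fatal", {
  toy <- make_toy_protein("helix_clash")
  s <- toy$structure[!(toy$structure$resno == 2 &
                         toy$structure$atom == "CD1"), ]
  ang <- residue_angles(s)
  expect_true(2 %in% attr(ang, "flagged"))
  expect_true(all(is.na(ang[ang$resno == 2, paste0("chi", 1:4)])))
  expect_false(is.na(ang$chi1[ang$resno == 4]))
})

test_that("backbone builder hits requested phi/psi and ideal geometry", {
  phi <- c(-1.8, -1.1, -2.4)
  psi <- c(2.4, 2.0, -0.5)
  bb <- build_backbone(c("ALA", "ALA", "ALA"), phi, psi)
  ang <- residue_angles(bb)
  expect_equal(ang$phi[2], phi[2], tolerance = 1e-9)
  expect_equal(ang$psi[1:2], psi[1:2], tolerance = 1e-9)
  ca <- bb[bb$atom == "CA", c("x", "y", "z")]
  d <- sqrt(rowSums((ca[-1, ] - ca[-3, ])^2))
  expect_true(all(d > 3.7 & d < 3.9))  # trans peptide CA-CA spacing
})
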