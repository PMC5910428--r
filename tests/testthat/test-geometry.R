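# local alias: apply a canonical frame to one point
frame_applied <- function(fr, p) fr$rotation %*% p + fr$translation

test_that("planar cis and trans arrangements give 0 and 180 degrees", {
  expect_equal(dihedral(c(1, 1, 0), c(0, 0, 0), c(1, 0, 0), c(2, 1, 0)), 0)
  expect_equal(abs(dihedral(c(1, 1, 0), c(0, 0, 0), c(1, 0, 0),
                            c(2, -1, 0))), 180)
  expect_error(dihedral(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
               "collinear")
})

test_that("dihedral is invariant under point-order reversal, flips under mirror", {
  # IUPAC torsions look the same from either end of the central bond;
  # chirality (mirror reflection), not traversal order, flips the sign.
  set.seed(21)
  for (k in 1:25) {
    p <- matrix(rnorm(12), 4, 3)
    d1 <- tryCatch(dihedral(p[1, ], p[2, ], p[3, ], p[4, ]),
                   error = function(e) NULL)
    if (is.null(d1)) next
    d2 <- dihedral(p[4, ], p[3, ], p[2, ], p[1, ])
    expect_equal(d2, d1, tolerance = 1e-9)
    m <- p; m[, 1] <- -m[, 1]
    d3 <- dihedral(m[1, ], m[2, ], m[3, ], m[4, ])
    expect_lt(min(abs(d3 + d1), abs(abs(d1) - 180) + abs(abs(d3) - 180)),
              1e-9)
    expect_gt(d1, -180)
    expect_lte(d1, 180)
  }
})

test_that("building a backbone and recomputing its dihedrals round-trips", {
  set.seed(33)
  circ_err <- function(a, b) {
    d <- abs(a - b) %% 360
    pmin(d, 360 - d)
  }
  for (k in 1:10) {
    n <- sample(4:10, 1)
    phi <- runif(n, -170, 170)
    psi <- runif(n, -170, 170)
    omg <- runif(n, 150, 210)
    omg[omg > 180] <- omg[omg > 180] - 360
    s <- build_ideal_backbone(phi, psi, omg)
    d <- backbone_dihedrals(s)$angles
    expect_lt(max(circ_err(d$phi[-1], phi[-1])), 1e-6)
    expect_lt(max(circ_err(d$psi[-n], psi[-n])), 1e-6)
    expect_lt(max(circ_err(d$omega[-1], omg[-1])), 1e-6)
  }
})

test_that("termini have undefined angles with the (0,0) sentinel encoding", {
  s <- fix_helix()
  d <- backbone_dihedrals(s)
  n <- nrow(s$residues)
  expect_true(is.na(d$angles$phi[1]))
  expect_true(is.na(d$angles$omega[1]))
  expect_true(is.na(d$angles$psi[n]))
  expect_equal(unname(d$encoding[1, c("cos_phi", "sin_phi")]), c(0, 0))
  # defined angles sit on the unit circle
  def <- !is.na(d$angles$phi)
  expect_equal(d$encoding[def, "cos_phi"]^2 + d$encoding[def, "sin_phi"]^2,
               rep(1, sum(def)), tolerance = 1e-9)
  # trans construction gives omega = 180
  expect_equal(abs(d$angles$omega[2]), 180, tolerance = 1e-6)
})

test_that("chain breaks sever dihedral continuity", {
  a <- build_ideal_helix(4)
  b <- transform_structure(build_ideal_helix(4, start_seq = 5),
                           diag(3), c(25, 0, 0))
  s <- combine_structures(list(a, b))
  s$residues$chain <- "A"  # same chain, but a 25 A gap between 4 and 5
  s$meta$chains <- c(A = 8L)
  d <- backbone_dihedrals(s)$angles
  expect_true(is.na(d$phi[5]))
  expect_true(is.na(d$omega[5]))
  expect_true(is.na(d$psi[4]))
})

test_that("canonical frame satisfies its placement contract", {
  s <- fix_random_coil()
  for (i in seq_len(nrow(s$residues))) {
    fr <- canonical_frame(s$coords$N[i, ], s$coords$CA[i, ], s$coords$C[i, ])
    expect_equal(fr$rotation %*% t(fr$rotation), diag(3), tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_equal(det(fr$rotation), 1, tolerance = 1e-9)
    ca <- as.numeric(frame_applied(fr, s$coords$CA[i, ]))
    nn <- as.numeric(frame_applied(fr, s$coords$N[i, ]))
    cc <- as.numeric(frame_applied(fr, s$coords$C[i, ]))
    expect_equal(ca, c(0, 0, 0), tolerance = 1e-12)
    expect_equal(nn[2:3], c(0, 0), tolerance = 1e-12)
    expect_lt(nn[1], 0)
    expect_equal(cc[3], 0, tolerance = 1e-12)
    expect_gt(cc[2], 0)
  }
})

test_that("canonical frame matches an explicit Gram-Schmidt construction", {
  n <- c(1.46, 0, 0); ca <- c(0, 0, 0); cc <- c(-0.55, 1.42, 0)
  fr <- canonical_frame(n, ca, cc)
  # independent construction: ex toward -N, ey = orthogonalized C
  ex <- -(n - ca) / sqrt(sum((n - ca)^2))
  v <- (cc - ca) - sum((cc - ca) * ex) * ex
  ey <- v / sqrt(sum(v^2))
  ez <- c(ex[2] * ey[3] - ex[3] * ey[2],
          ex[3] * ey[1] - ex[1] * ey[3],
          ex[1] * ey[2] - ex[2] * ey[1])
  expect_equal(fr$rotation, rbind(ex, ey, ez), tolerance = 1e-12,
               ignore_attr = TRUE)
  cc_t <- as.numeric(fr$rotation %*% (cc - ca))
  expect_equal(cc_t, c(sum((cc - ca) * ex), sqrt(sum(v^2)), 0),
               tolerance = 1e-12)
  expect_error(canonical_frame(c(1, 0, 0), c(0, 0, 0), c(2, 0, 0)),
               "collinear")
})

test_that("mirror-imaging flips dihedral signs, preserves distances and SASA", {
  s <- fix_random_coil()
  m <- mirror_structure(s)
  d0 <- backbone_dihedrals(s)$angles
  d1 <- backbone_dihedrals(m)$angles
  def <- !is.na(d0$phi)
  expect_equal(d1$phi[def], -d0$phi[def], tolerance = 1e-9)
  expect_equal(d1$psi[!is.na(d0$psi)], -d0$psi[!is.na(d0$psi)],
               tolerance = 1e-9)
  ca0 <- dist(s$coords$CA)
  ca1 <- dist(m$coords$CA)
  expect_equal(as.numeric(ca1), as.numeric(ca0), tolerance = 1e-12)
  # SASA agrees up to surface-sampling resolution
  expect_equal(backbone_sasa(m), backbone_sasa(s), tolerance = 0.02)
})
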