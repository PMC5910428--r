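# Backbone solvent accessible surface area, Shrake-Rupley style.
#
# Atomic radii follow the backbone subset used for feature extraction
# (N 1.65, C and CA 1.76, O 1.40 A), probe radius 1.4 A, 960 test points per
# atom. The test-point sphere of each atom is oriented in its residue's
# canonical local frame rather than the laboratory frame, which makes the
# computed areas exactly covariant under rigid motion of the structure --
# a requirement for the feature-invariance contract that lab-frame sampling
# cannot meet.

SASA_RADII <- c(N = 1.65, CA = 1.76, C = 1.76, O = 1.40)
SASA_PROBE <- 1.4
SASA_POINTS <- 960L

# Deterministic near-uniform unit-sphere points (Fibonacci / golden-angle
# lattice).
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- pi * (1 + sqrt(5)) * i
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Exposed surface area of a set of spheres
#'
#' Shrake-Rupley numerical surface area: for each sphere, test points are
#' placed on its solvent-expanded surface (radius + probe) and the exposed
#' fraction -- points inside no other expanded sphere -- is converted to
#' area. This low-level routine underlies [backbone_sasa()] and is exported
#' so its accuracy can be checked against analytic and Monte-Carlo oracles.
#'
#' @param centers m x 3 matrix of sphere centers (Angstrom).
#' @param radii Length-m vector of sphere radii.
#' @param probe Probe radius added to every sphere.
#' @param n_points Test points per sphere.
#' @param orientations Optional list of m rotation matrices; sphere `i`'s
#'   test points are `P %*% t(orientations[[i]])`. NULL keeps the lab frame.
#' @return Length-m vector of exposed areas in square Angstrom.
#' @export
sasa_spheres <- function(centers, radii, probe = SASA_PROBE,
                         n_points = SASA_POINTS, orientations = NULL) {
  if (is.null(dim(centers))) centers <- matrix(centers, nrow = 1L)
  m <- nrow(centers)
  stopifnot(length(radii) == m, all(radii > 0), probe >= 0)
  P <- fibonacci_sphere(n_points)
  rext <- radii + probe
  out <- numeric(m)
  for (i in seq_len(m)) {
    Pi <- if (is.null(orientations) || is.null(orientations[[i]]))
      P else P %*% t(orientations[[i]])
    pts <- sweep(Pi * rext[i], 2L, centers[i, ], "+")
    exposed <- rep(TRUE, n_points)
    d2c <- rowSums(sweep(centers, 2L, centers[i, ], "-")^2)
    nb <- which(d2c > 0 & d2c < (rext[i] + rext)^2)
    for (j in nb) {
      live <- which(exposed)
      if (!length(live)) break
      dj <- sweep(pts[live, , drop = FALSE], 2L, centers[j, ], "-")
      exposed[live[rowSums(dj * dj) < rext[j]^2 - 1e-12]] <- FALSE
    }
    out[i] <- 4 * pi * rext[i]^2 * sum(exposed) / n_points
  }
  out
}

#' Backbone solvent accessible surface area per residue
#'
#' Computes the total SASA of the backbone atoms (N, CA, C, O) of each
#' residue on the whole structure, with sidechain atoms removed from both
#' the measured and the occluding set -- the sidechain-agnostic surface a
#' design method sees before residue identities are chosen. Probe radius
#' 1.4 A; radii N 1.65, CA/C 1.76, O 1.40 A; 960 test points per atom,
#' oriented in each residue's canonical local frame (see [canonical_frame()])
#' so areas are invariant under rigid motion of the input.
#'
#' @param structure A `protein_structure`.
#' @param on_missing What to do for residues missing a backbone atom:
#'   `"error"` (default) names the residue and stops; `"na"` reports NA for
#'   that residue while still letting its present atoms occlude.
#' @return Numeric vector: one area (square Angstrom) per residue.
#' @export
backbone_sasa <- function(structure, on_missing = c("error", "na")) {
  on_missing <- match.arg(on_missing)
  res <- structure$residues
  n <- nrow(res)
  if (!all(res$complete) && on_missing == "error") {
    bad <- which(!res$complete)[1L]
    stop(sprintf("missing backbone atom(s) in residue %s %d%s",
                 res$chain[bad], res$seq_index[bad], res$icode[bad]))
  }
  centers <- NULL
  radii <- numeric()
  owner <- integer()
  orients <- list()
  for (a in BACKBONE_ATOMS) {
    M <- structure$coords[[a]]
    ok <- which(!is.na(M[, 1L]))
    centers <- rbind(centers, M[ok, , drop = FALSE])
    radii <- c(radii, rep(SASA_RADII[[a]], length(ok)))
    owner <- c(owner, ok)
  }
  if (!length(owner)) return(rep(NA_real_, n))
  # Orient each atom's test sphere in its residue's canonical frame
  # (transpose: lab directions of frame axes), so sampling co-rotates with
  # the structure.
  frames <- vector("list", n)
  for (i in unique(owner)) {
    if (res$complete[i]) {
      fr <- canonical_frame(structure$coords$N[i, ],
                            structure$coords$CA[i, ],
                            structure$coords$C[i, ])
      frames[[i]] <- t(fr$rotation)
    }
  }
  areas <- sasa_spheres(centers, radii, orientations = frames[owner])
  out <- as.numeric(tapply(areas, owner, sum)[as.character(seq_len(n))])
  out[!res$complete] <- NA_real_
  out
}
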