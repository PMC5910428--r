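# Vector helpers ------------------------------------------------------------

vcross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

vnorm <- function(a) sqrt(sum(a * a))

vunit <- function(a) {
  n <- vnorm(a)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  a / n
}

# Row-wise cross product and norms for matrix inputs (used by the vectorized
# dihedral path).
rowcross <- function(A, B) {
  cbind(A[, 2L] * B[, 3L] - A[, 3L] * B[, 2L],
        A[, 3L] * B[, 1L] - A[, 1L] * B[, 3L],
        A[, 1L] * B[, 2L] - A[, 2L] * B[, 1L])
}

rownorm <- function(A) sqrt(rowSums(A * A))

#' Dihedral angle of four points
#'
#' Computes the torsion angle defined by points `p1-p2-p3-p4` in degrees, in
#' the IUPAC sign convention (positive clockwise when looking from `p2`
#' towards `p3`), on the half-open interval (-180, 180].
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors (Angstrom, but any consistent unit).
#' @return Angle in degrees in (-180, 180].
#' @details The torsion is invariant under reversing the point order
#'   (`dihedral(p4,p3,p2,p1)` equals `dihedral(p1,p2,p3,p4)`: the angle looks
#'   the same from either end of the central bond) and changes sign under
#'   mirror reflection. Collinear consecutive triples make the torsion
#'   undefined and raise an error.
#' @examples
#' dihedral(c(1, 1, 0), c(0, 0, 0), c(1, 0, 0), c(2, 1, 0)) # 0 (cis)
#' dihedral(c(1, 1, 0), c(0, 0, 0), c(1, 0, 0), c(2, -1, 0)) # 180 (trans)
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  if (vnorm(n1) < 1e-10 || vnorm(n2) < 1e-10)
    stop("undefined dihedral: three consecutive points are collinear")
  m1 <- vcross(b2 / vnorm(b2), n1)
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

# Vectorized torsion over rows of four n x 3 matrices; returns degrees in
# (-180, 180], NA where any input row has an NA.
dihedral_rows <- function(P1, P2, P3, P4) {
  b1 <- P2 - P1
  b2 <- P3 - P2
  b3 <- P4 - P3
  n1 <- rowcross(b1, b2)
  n2 <- rowcross(b2, b3)
  b2u <- b2 / rownorm(b2)
  m1 <- rowcross(b2u, n1)
  ang <- atan2(rowSums(m1 * n2), rowSums(n1 * n2)) * 180 / pi
  ang[!is.na(ang) & ang <= -180] <- ang[!is.na(ang) & ang <= -180] + 360
  ang
}

# Chain breaks ---------------------------------------------------------------

# Peptide-bond continuity between consecutive residues of the same chain:
# C(i)-N(i+1) distance must be <= 2.0 A and both atoms present. Returns a
# logical vector `linked[i]` saying residue i is peptide-bonded to residue
# i+1 (length n, last entry FALSE).
peptide_links <- function(structure) {
  res <- structure$residues
  n <- nrow(res)
  linked <- rep(FALSE, n)
  if (n < 2L) return(linked)
  same_chain <- res$chain[-n] == res$chain[-1L]
  cc <- structure$coords$C[-n, , drop = FALSE]
  nn <- structure$coords$N[-1L, , drop = FALSE]
  d <- rownorm(cc - nn)
  linked[-n] <- same_chain & !is.na(d) & d <= 2.0
  linked
}

#' Backbone dihedral angles of every residue
#'
#' Computes phi, psi and omega for each residue of a parsed structure, plus
#' the (cos, sin) encoding used as network input. Angles follow the standard
#' definitions: phi(i) = C(i-1)-N(i)-CA(i)-C(i), psi(i) =
#' N(i)-CA(i)-C(i)-N(i+1), and omega(i) = CA(i-1)-C(i-1)-N(i)-CA(i), i.e.
#' omega(i) describes the peptide bond *preceding* residue i. Angles are
#' undefined at chain termini and across chain breaks (peptide C-N distance
#' > 2 A); undefined angles are NA and encode as (cos, sin) = (0, 0), a
#' sentinel off the unit circle.
#'
#' @param structure A `protein_structure`.
#' @return A list with `angles` (data.frame: phi, psi, omega in degrees) and
#'   `encoding` (n x 6 matrix: cos/sin of phi, psi, omega).
#' @export
backbone_dihedrals <- function(structure) {
  res <- structure$residues
  n <- nrow(res)
  N <- structure$coords$N
  CA <- structure$coords$CA
  C <- structure$coords$C
  linked <- peptide_links(structure)
  prev_ok <- c(FALSE, linked[-n])   # residue i bonded to i-1
  next_ok <- linked                 # residue i bonded to i+1

  shift_up <- function(M) rbind(NA_real_, M[-n, , drop = FALSE])
  shift_dn <- function(M) rbind(M[-1L, , drop = FALSE], NA_real_)

  phi <- rep(NA_real_, n); psi <- rep(NA_real_, n); omega <- rep(NA_real_, n)
  if (n >= 1L) {
    Cprev <- shift_up(C); CAprev <- shift_up(CA); Nnext <- shift_dn(N)
    idx_phi <- prev_ok & res$complete & !is.na(Cprev[, 1L])
    idx_psi <- next_ok & res$complete & !is.na(Nnext[, 1L])
    idx_omg <- prev_ok & res$complete & !is.na(CAprev[, 1L])
    if (any(idx_phi))
      phi[idx_phi] <- dihedral_rows(Cprev[idx_phi, , drop = FALSE],
                                    N[idx_phi, , drop = FALSE],
                                    CA[idx_phi, , drop = FALSE],
                                    C[idx_phi, , drop = FALSE])
    if (any(idx_psi))
      psi[idx_psi] <- dihedral_rows(N[idx_psi, , drop = FALSE],
                                    CA[idx_psi, , drop = FALSE],
                                    C[idx_psi, , drop = FALSE],
                                    Nnext[idx_psi, , drop = FALSE])
    if (any(idx_omg))
      omega[idx_omg] <- dihedral_rows(CAprev[idx_omg, , drop = FALSE],
                                      Cprev[idx_omg, , drop = FALSE],
                                      N[idx_omg, , drop = FALSE],
                                      CA[idx_omg, , drop = FALSE])
  }
  enc <- matrix(0, n, 6L,
                dimnames = list(NULL, c("cos_phi", "sin_phi", "cos_psi",
                                        "sin_psi", "cos_omega", "sin_omega")))
  for (j in seq_along(list(phi, psi, omega))) {
    a <- list(phi, psi, omega)[[j]]
    ok <- !is.na(a)
    enc[ok, 2L * j - 1L] <- cos(a[ok] * pi / 180)
    enc[ok, 2L * j] <- sin(a[ok] * pi / 180)
  }
  list(angles = data.frame(phi = phi, psi = psi, omega = omega),
       encoding = enc)
}

# Canonical local frame ------------------------------------------------------

#' Canonical local frame of a residue
#'
#' The rigid transform that places a residue's CA at the origin, its N on the
#' negative x axis, and its C in the z = 0 plane with positive y (the
#' positive-y choice removes the remaining two-fold ambiguity). The returned
#' rotation is proper (determinant +1).
#'
#' @param n,ca,c Numeric 3-vectors: backbone N, CA and C coordinates.
#' @return A list with `rotation` (3 x 3 orthonormal matrix, rows are the
#'   frame axes) and `translation` such that a point `p` maps to
#'   `rotation %*% (p - ca)`, i.e. `rotation %*% p + translation`.
#' @export
canonical_frame <- function(n, ca, c) {
  v1 <- n - ca
  v2 <- c - ca
  if (vnorm(v1) < 1e-8 || vnorm(v2) < 1e-8)
    stop("degenerate residue geometry: coincident backbone atoms")
  ex <- -v1 / vnorm(v1)                  # N sits on -x
  v2p <- v2 - sum(v2 * ex) * ex
  if (vnorm(v2p) < 1e-8)
    stop("degenerate residue geometry: N, CA, C are collinear")
  ey <- v2p / vnorm(v2p)                 # C gets positive y
  ez <- vcross(ex, ey)
  R <- rbind(ex, ey, ez)
  dimnames(R) <- NULL
  list(rotation = R, translation = as.numeric(-R %*% ca))
}

# Apply a frame to a point matrix (rows = points).
frame_apply <- function(frame, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  sweep(X %*% t(frame$rotation), 2L, -frame$translation, "-")
}

# Rigid motions on whole structures ------------------------------------------

#' Apply a rigid motion to a structure
#'
#' Rotates and translates every atom of a structure: `x -> R x + t`. Used for
#' frame-invariance checks and for assembling multi-chain fixtures.
#'
#' @param structure A `protein_structure`.
#' @param rotation 3 x 3 rotation matrix.
#' @param translation Numeric 3-vector.
#' @return The transformed `protein_structure`.
#' @export
transform_structure <- function(structure,
                                rotation = diag(3),
                                translation = c(0, 0, 0)) {
  tr <- function(M) {
    ok <- !is.na(M[, 1L])
    M[ok, ] <- sweep(M[ok, , drop = FALSE] %*% t(rotation), 2L,
                     translation, "+")
    M
  }
  for (nm in names(structure$coords))
    structure$coords[[nm]] <- tr(structure$coords[[nm]])
  if (nrow(structure$atoms)) {
    xyz <- tr(as.matrix(structure$atoms[, c("x", "y", "z")]))
    structure$atoms$x <- xyz[, 1L]
    structure$atoms$y <- xyz[, 2L]
    structure$atoms$z <- xyz[, 3L]
  }
  structure
}

#' Mirror-image of a structure
#'
#' Reflects all coordinates through the x = 0 plane. Useful as a chirality
#' probe: mirroring flips the sign of every backbone dihedral while leaving
#' distances and surface areas unchanged.
#'
#' @param structure A `protein_structure`.
#' @return The reflected `protein_structure`.
#' @export
mirror_structure <- function(structure) {
  for (nm in names(structure$coords))
    structure$coords[[nm]][, 1L] <- -structure$coords[[nm]][, 1L]
  if (nrow(structure$atoms)) structure$atoms$x <- -structure$atoms$x
  structure
}

# Deterministic random rotation from a seed-free RNG draw (callers manage
# seeding); uniform over SO(3) via quaternion normalization.
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3L, 3L, byrow = TRUE)
}
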