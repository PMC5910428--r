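# Per-residue feature context and the 31-dimensional target-neighbor pair
# feature vector that feeds the subnetworks.

PAIR_FEATURE_NAMES <- c(
  "c_cos_phi", "c_sin_phi", "c_cos_psi", "c_sin_psi", "c_cos_omega",
  "c_sin_omega",
  "c_sasa",
  "c_ss_helix", "c_ss_sheet", "c_ss_loop",
  "n_cos_phi", "n_sin_phi", "n_cos_psi", "n_sin_psi", "n_cos_omega",
  "n_sin_omega",
  "n_sasa",
  "n_ss_helix", "n_ss_sheet", "n_ss_loop",
  "ca_dist",
  "u_ca_x", "u_ca_y", "u_ca_z",
  "u_n_x", "u_n_y", "u_n_z",
  "u_c_x", "u_c_y", "u_c_z",
  "n_hbonds")

N_PAIR_FEATURES <- length(PAIR_FEATURE_NAMES) # 31

#' Precompute the per-structure feature context
#'
#' Bundles everything pair-feature extraction needs -- backbone dihedrals
#' and their (cos, sin) encoding, backbone SASA, three-state secondary
#' structure, the backbone hydrogen-bond table, and each residue's canonical
#' local frame -- so repeated [pair_features()] calls on one structure are
#' cheap.
#'
#' @param structure A `protein_structure`.
#' @return A list of class `feature_context`.
#' @export
feature_context <- function(structure) {
  dih <- backbone_dihedrals(structure)
  hb <- backbone_hbond_pairs(structure)
  ss <- assign_secondary_structure(structure, dih, hb)
  sasa <- backbone_sasa(structure, on_missing = "na")
  res <- structure$residues
  n <- nrow(res)
  frames <- vector("list", n)
  for (i in which(res$complete))
    frames[[i]] <- canonical_frame(structure$coords$N[i, ],
                                   structure$coords$CA[i, ],
                                   structure$coords$C[i, ])
  hb_counts <- matrix(0L, 0L, 0L)
  structure(list(structure = structure, dihedrals = dih, hbonds = hb,
                 ss = ss, ss1h = ss_one_hot(ss), sasa = sasa,
                 frames = frames),
            class = "feature_context")
}

hbond_count_fast <- function(ctx, i, j) {
  hb <- ctx$hbonds
  if (!nrow(hb)) return(0L)
  sum((hb$donor == i & hb$acceptor == j) | (hb$donor == j & hb$acceptor == i))
}

#' Target-neighbor pair features
#'
#' The 31 numeric inputs describing one target-neighbor residue pair, in
#' fixed documented order: target dihedral cos/sin (6), target backbone SASA
#' (1), target secondary-structure one-hot (3), the same 10 for the
#' neighbor, CA-CA distance (1), unit vector from target CA to neighbor CA
#' (3), the neighbor's CA-to-N unit vector (3) and CA-to-C unit vector (3),
#' all three expressed in the target's canonical frame, and the
#' backbone-backbone hydrogen-bond count between the two residues (1).
#' Undefined dihedrals (termini, chain breaks) encode as (cos, sin) = (0, 0).
#'
#' @param ctx A [feature_context()].
#' @param target,neighbor Residue row indices.
#' @return Named numeric vector of length 31.
#' @export
pair_features <- function(ctx, target, neighbor) {
  res <- ctx$structure$residues
  for (idx in c(target, neighbor)) {
    if (!res$complete[idx])
      stop(sprintf("feature error: residue %s %d is missing backbone atoms",
                   res$chain[idx], res$seq_index[idx]))
    if (is.na(ctx$sasa[idx]))
      stop(sprintf("feature error: SASA unavailable for residue %s %d",
                   res$chain[idx], res$seq_index[idx]))
  }
  if (target == neighbor) stop("feature error: target equals neighbor")
  fr <- ctx$frames[[target]]
  ca_t <- ctx$structure$coords$CA[target, ]
  ca_n <- ctx$structure$coords$CA[neighbor, ]
  d <- ca_n - ca_t
  dist <- vnorm(d)
  if (dist < 1e-6) stop("feature error: coincident CA atoms")
  R <- fr$rotation
  u_ca <- as.numeric(R %*% (d / dist))
  u_n <- as.numeric(R %*% vunit(ctx$structure$coords$N[neighbor, ] - ca_n))
  u_c <- as.numeric(R %*% vunit(ctx$structure$coords$C[neighbor, ] - ca_n))
  out <- c(ctx$dihedrals$encoding[target, ],
           ctx$sasa[target],
           ctx$ss1h[target, ],
           ctx$dihedrals$encoding[neighbor, ],
           ctx$sasa[neighbor],
           ctx$ss1h[neighbor, ],
           dist, u_ca, u_n, u_c,
           hbond_count_fast(ctx, target, neighbor))
  names(out) <- PAIR_FEATURE_NAMES
  out
}

#' Feature matrix of a structural cluster
#'
#' Stacks [pair_features()] for a target against each of its neighbors, in
#' the given (ascending CA-CA distance) neighbor order.
#'
#' @param ctx A [feature_context()].
#' @param target Target residue row index.
#' @param neighbors Integer vector of neighbor row indices.
#' @return Numeric matrix, `length(neighbors)` x 31.
#' @export
cluster_features <- function(ctx, target, neighbors) {
  out <- t(vapply(neighbors, function(j) pair_features(ctx, target, j),
                  numeric(N_PAIR_FEATURES)))
  dimnames(out) <- list(NULL, PAIR_FEATURE_NAMES)
  out
}
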