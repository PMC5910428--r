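# Three-state secondary structure (helix / sheet / loop) from backbone
# dihedrals and backbone hydrogen bonds.
#
# Rules (a compact dihedral + H-bond assignment; only three states are
# needed downstream):
#   helix: runs of >= 3 consecutive residues that are helix candidates,
#          where a candidate has phi in (-100, -30) and psi in (-80, -5),
#          or participates in an (i, i+4) backbone H-bond within its chain.
#   sheet: a non-helix residue with extended dihedrals -- phi in (-180, -40)
#          and psi in (60, 180] or (-180, -150) -- that forms at least one
#          backbone H-bond with a residue more than 2 apart in sequence (or
#          on another chain).
#   loop:  everything else; residues with undefined phi or psi (termini,
#          chain breaks) are loop.

SS_LEVELS <- c("helix", "sheet", "loop")

#' Assign three-state secondary structure
#'
#' @param structure A `protein_structure`.
#' @param dihedrals Optional precomputed [backbone_dihedrals()] result.
#' @param hbonds Optional precomputed [backbone_hbond_pairs()] table.
#' @return Character vector (one of `"helix"`, `"sheet"`, `"loop"` per
#'   residue).
#' @export
assign_secondary_structure <- function(structure, dihedrals = NULL,
                                       hbonds = NULL) {
  if (is.null(dihedrals)) dihedrals <- backbone_dihedrals(structure)
  if (is.null(hbonds)) hbonds <- backbone_hbond_pairs(structure)
  res <- structure$residues
  n <- nrow(res)
  phi <- dihedrals$angles$phi
  psi <- dihedrals$angles$psi

  defined <- !is.na(phi) & !is.na(psi)
  helical_dih <- defined & phi > -100 & phi < -30 & psi > -80 & psi < -5

  # (i, i+4) helical H-bond participation within a chain.
  helix_hb <- rep(FALSE, n)
  if (nrow(hbonds)) {
    d <- hbonds$donor; a <- hbonds$acceptor
    same <- res$chain[d] == res$chain[a]
    i4 <- same & abs(res$seq_index[d] - res$seq_index[a]) == 4L
    helix_hb[unique(c(d[i4], a[i4]))] <- TRUE
  }
  cand <- helical_dih | (helix_hb & defined)

  ss <- rep("loop", n)
  # helix: runs of >= 3 candidates, broken at chain boundaries.
  run_id <- cumsum(c(TRUE, res$chain[-1L] != res$chain[-n] |
                       cand[-1L] != cand[-n]))
  for (g in split(seq_len(n), run_id)) {
    if (length(g) >= 3L && all(cand[g])) ss[g] <- "helix"
  }

  # sheet among non-helix residues.
  extended <- defined & phi > -180 & phi < -40 &
    ((psi > 60 & psi <= 180) | (psi > -180 & psi < -150))
  long_range <- rep(FALSE, n)
  if (nrow(hbonds)) {
    d <- hbonds$donor; a <- hbonds$acceptor
    lr <- res$chain[d] != res$chain[a] |
      abs(res$seq_index[d] - res$seq_index[a]) > 2L
    long_range[unique(c(d[lr], a[lr]))] <- TRUE
  }
  sheet <- ss != "helix" & extended & long_range
  ss[sheet] <- "sheet"
  ss
}

ss_one_hot <- function(ss) {
  m <- matrix(0, length(ss), 3L,
              dimnames = list(NULL, paste0("ss_", SS_LEVELS)))
  m[cbind(seq_along(ss), match(ss, SS_LEVELS))] <- 1
  m
}
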