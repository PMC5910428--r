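# Backbone-backbone hydrogen bonds, by the DSSP electrostatic criterion:
# E = 0.084 * 332 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN) kcal/mol, bond when
# E < -0.5. The amide hydrogen is reconstructed 1.0 A from N along the
# direction opposite the bisector of C(i-1)-N and CA-N; prolines and
# chain-start residues (no preceding carbonyl) are never donors.

HBOND_E_CUT <- -0.5
HBOND_CA_CUTOFF <- 10 # Angstrom; pairs farther apart by CA-CA never bond

# Reconstruct amide H positions; returns an n x 3 matrix with NA rows where
# no H exists (prolines, chain starts, incomplete residues).
amide_hydrogens <- function(structure) {
  res <- structure$residues
  n <- nrow(res)
  H <- matrix(NA_real_, n, 3L)
  if (n == 0L) return(H)
  linked <- peptide_links(structure)
  prev_ok <- c(FALSE, linked[-n])
  for (i in seq_len(n)) {
    if (!prev_ok[i] || res$resname[i] == "PRO") next
    if (!res$complete[i] || !res$complete[i - 1L]) next
    Ni <- structure$coords$N[i, ]
    u <- vunit(Ni - structure$coords$C[i - 1L, ]) +
      vunit(Ni - structure$coords$CA[i, ])
    if (vnorm(u) < 1e-8) next
    H[i, ] <- Ni + vunit(u)
  }
  H
}

#' Backbone hydrogen-bond table
#'
#' Enumerates donor-to-acceptor backbone hydrogen bonds over a whole
#' structure using the DSSP electrostatic energy with a -0.5 kcal/mol
#' threshold. A donor is the amide N-H of a residue (H reconstructed at 1 A
#' from N); an acceptor is the carbonyl C=O. Pairs closer than 2 in sequence
#' on the same chain, and pairs with CA-CA distance above 10 A, are skipped.
#'
#' @param structure A `protein_structure`.
#' @return A data.frame with columns `donor`, `acceptor` (residue row
#'   indices) and `energy` (kcal/mol).
#' @export
backbone_hbond_pairs <- function(structure) {
  res <- structure$residues
  n <- nrow(res)
  empty <- data.frame(donor = integer(), acceptor = integer(),
                      energy = numeric())
  if (n < 2L) return(empty)
  H <- amide_hydrogens(structure)
  CA <- structure$coords$CA
  Nm <- structure$coords$N
  Cm <- structure$coords$C
  Om <- structure$coords$O

  donors <- which(!is.na(H[, 1L]))
  acceptors <- which(res$complete)
  if (!length(donors) || !length(acceptors)) return(empty)

  out_d <- integer(); out_a <- integer(); out_e <- numeric()
  for (i in donors) {
    dca <- rownorm(sweep(CA[acceptors, , drop = FALSE], 2L, CA[i, ], "-"))
    near <- acceptors[!is.na(dca) & dca <= HBOND_CA_CUTOFF]
    near <- near[near != i]
    same <- res$chain[near] == res$chain[i]
    near <- near[!(same & abs(res$seq_index[near] - res$seq_index[i]) < 2L)]
    if (!length(near)) next
    r_on <- rownorm(sweep(Om[near, , drop = FALSE], 2L, Nm[i, ], "-"))
    r_ch <- rownorm(sweep(Cm[near, , drop = FALSE], 2L, H[i, ], "-"))
    r_oh <- rownorm(sweep(Om[near, , drop = FALSE], 2L, H[i, ], "-"))
    r_cn <- rownorm(sweep(Cm[near, , drop = FALSE], 2L, Nm[i, ], "-"))
    e <- 0.084 * 332 * (1 / r_on + 1 / r_ch - 1 / r_oh - 1 / r_cn)
    hit <- which(e < HBOND_E_CUT)
    if (length(hit)) {
      out_d <- c(out_d, rep(i, length(hit)))
      out_a <- c(out_a, near[hit])
      out_e <- c(out_e, e[hit])
    }
  }
  data.frame(donor = out_d, acceptor = out_a, energy = out_e)
}

#' Count backbone hydrogen bonds between two residues
#'
#' Counts donor-acceptor backbone hydrogen bonds in both directions between
#' residues `i` and `j` (so an idealized alpha-helical (i, i+4) pair counts
#' 1, a doubly bonded antiparallel sheet pair counts 2). Residues closer
#' than 2 in sequence on the same chain never count.
#'
#' @param structure A `protein_structure`.
#' @param i,j Residue row indices.
#' @param pairs Optional precomputed [backbone_hbond_pairs()] table.
#' @return Nonnegative integer.
#' @export
count_backbone_hbonds <- function(structure, i, j, pairs = NULL) {
  if (is.null(pairs)) pairs <- backbone_hbond_pairs(structure)
  sum((pairs$donor == i & pairs$acceptor == j) |
        (pairs$donor == j & pairs$acceptor == i))
}
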