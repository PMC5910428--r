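# Synthetic structures and datasets: idealized backbones built from internal
# coordinates (NeRF chain extension), a toy PDB writer, and a separable
# synthetic training set, so the whole pipeline runs with no external data.

# Standard peptide geometry (Engh-Huber-like averages), Angstrom / degrees.
PEPTIDE_GEOMETRY <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
  a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7, a_ca_c_o = 120.5
)

# Place atom d from reference atoms a-b-c given bond |c-d|, angle b-c-d and
# dihedral a-b-c-d (degrees). Sequential natural-extension placement.
nerf_place <- function(a, b, c, bond, angle, dihedral) {
  th <- angle * pi / 180
  chi <- dihedral * pi / 180
  d2 <- bond * c(-cos(th), sin(th) * cos(chi), sin(th) * sin(chi))
  bc <- vunit(c - b)
  n <- vunit(vcross(b - a, bc))
  M <- cbind(bc, vcross(n, bc), n)
  as.numeric(c + M %*% d2)
}

structure_from_backbone <- function(N, CA, C, O, chain = "A", aa = "A",
                                    start_seq = 1L, pdb_id = "") {
  n <- nrow(N)
  aa <- rep_len(aa, n)
  resname <- unname(AA3[aa])
  if (anyNA(resname)) stop("unknown one-letter amino-acid code in `aa`")
  seq_index <- seq.int(start_seq, length.out = n)
  residues <- data.frame(chain = chain, seq_index = seq_index, icode = "",
                         resname = resname, aa = aa, is_standard = TRUE,
                         is_d_amino = FALSE, occ_min = 1,
                         stringsAsFactors = FALSE)
  coords <- list(N = N, CA = CA, C = C, O = O)
  atoms <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(chain = chain, seq_index = seq_index[i], icode = "",
               resname = resname[i], atom = BACKBONE_ATOMS,
               element = c("N", "C", "C", "O"), altloc = " ",
               x = c(N[i, 1], CA[i, 1], C[i, 1], O[i, 1]),
               y = c(N[i, 2], CA[i, 2], C[i, 2], O[i, 2]),
               z = c(N[i, 3], CA[i, 3], C[i, 3], O[i, 3]),
               occupancy = 1, res_idx = i, stringsAsFactors = FALSE)
  }))
  meta <- list(pdb_id = pdb_id, method = NA_character_,
               resolution = NA_real_, has_nucleic = FALSE,
               has_d_amino = FALSE,
               chains = stats::setNames(n, chain),
               chain_sequences = stats::setNames(paste(aa, collapse = ""),
                                                 chain))
  new_structure(meta, residues, atoms)
}

#' Build an idealized backbone from dihedral angles
#'
#' Places backbone atoms N, CA, C, O sequentially from internal coordinates:
#' standard peptide bond lengths (N-CA 1.458, CA-C 1.525, C-N 1.329 A) and
#' angles (N-CA-C 111.2, CA-C-N 116.2, C-N-CA 121.7 deg), with the supplied
#' per-residue (phi, psi, omega). Recomputing the dihedrals from the built
#' coordinates recovers the specification to numerical precision, which makes
#' the builder its own round-trip oracle. The carbonyl O is placed in the
#' CA-C-N(next) plane at 1.231 A, 120.5 deg from CA-C, anti to the next N
#' (the last residue uses its psi the same way).
#'
#' @param phi,psi,omega Numeric vectors of equal length (degrees). `phi[1]`
#'   and `omega[1]` are ignored (undefined at the N terminus).
#' @param chain Chain identifier for the emitted residues.
#' @param aa One-letter amino-acid code(s), recycled along the chain.
#' @param start_seq First author residue number.
#' @return A `protein_structure` with backbone atoms only, all occupancies 1.
#' @examples
#' hx <- build_ideal_backbone(rep(-57, 8), rep(-47, 8), rep(180, 8))
#' @export
build_ideal_backbone <- function(phi, psi, omega, chain = "A", aa = "A",
                                 start_seq = 1L) {
  n <- length(phi)
  stopifnot(n >= 2L, length(psi) == n, length(omega) == n)
  g <- PEPTIDE_GEOMETRY
  N <- CA <- C <- O <- matrix(NA_real_, n, 3L,
                              dimnames = list(NULL, c("x", "y", "z")))
  N[1L, ] <- c(0, 0, 0)
  CA[1L, ] <- c(g$b_n_ca, 0, 0)
  a <- g$a_n_ca_c * pi / 180
  C[1L, ] <- CA[1L, ] + g$b_ca_c * c(-cos(a), sin(a), 0)
  for (i in seq_len(n - 1L)) {
    N[i + 1L, ] <- nerf_place(N[i, ], CA[i, ], C[i, ],
                              g$b_c_n, g$a_ca_c_n, psi[i])
    CA[i + 1L, ] <- nerf_place(CA[i, ], C[i, ], N[i + 1L, ],
                               g$b_n_ca, g$a_c_n_ca, omega[i + 1L])
    C[i + 1L, ] <- nerf_place(C[i, ], N[i + 1L, ], CA[i + 1L, ],
                              g$b_ca_c, g$a_n_ca_c, phi[i + 1L])
  }
  for (i in seq_len(n)) {
    o_dih <- psi[i] + 180
    if (o_dih > 180) o_dih <- o_dih - 360
    O[i, ] <- nerf_place(N[i, ], CA[i, ], C[i, ],
                         g$b_c_o, g$a_ca_c_o, o_dih)
  }
  structure_from_backbone(N, CA, C, O, chain = chain, aa = aa,
                          start_seq = start_seq)
}

#' Idealized secondary-structure fragments
#'
#' Convenience builders over [build_ideal_backbone()]: `build_ideal_helix()`
#' uses alpha-helical dihedrals (phi = -57, psi = -47), `build_ideal_strand()`
#' extended-strand dihedrals (phi = -120, psi = +120), both with trans
#' peptide bonds.
#'
#' @param n Number of residues.
#' @inheritParams build_ideal_backbone
#' @return A `protein_structure`.
#' @export
build_ideal_helix <- function(n = 12L, chain = "A", aa = "A", start_seq = 1L) {
  build_ideal_backbone(rep(-57, n), rep(-47, n), rep(180, n),
                       chain = chain, aa = aa, start_seq = start_seq)
}

#' @rdname build_ideal_helix
#' @export
build_ideal_strand <- function(n = 10L, chain = "A", aa = "A",
                               start_seq = 1L) {
  build_ideal_backbone(rep(-120, n), rep(120, n), rep(180, n),
                       chain = chain, aa = aa, start_seq = start_seq)
}

#' Three-stranded sheet fixture
#'
#' Builds an ideal extended strand and two rigidly translated copies (chains
#' A, B, C), with the inter-strand translation chosen by a deterministic
#' scan over carbonyl directions and spacings that maximizes the number of
#' inter-strand backbone hydrogen bonds. In any single two-strand ladder
#' only alternate residues hydrogen-bond directly, so the middle strand of
#' three -- whose residues bond alternately to the two flanking strands --
#' is the one where every interior residue carries an inter-strand hydrogen
#' bond and is labeled sheet.
#'
#' @param n Residues per strand.
#' @param aa One-letter code(s) for the strand residues.
#' @return A three-chain `protein_structure`; the middle strand is chain B.
#' @export
build_ideal_sheet <- function(n = 8L, aa = "A") {
  key <- sprintf("sheet_%d", n)
  cached <- .fixture_cache[[key]]
  if (!is.null(cached)) {
    strands <- lapply(seq_len(3L), function(k)
      transform_structure(
        build_ideal_strand(n, chain = LETTERS[k], aa = aa),
        diag(3), (k - 1L) * cached$d * cached$u))
    return(combine_structures(strands))
  }
  a <- build_ideal_strand(n, chain = "A")
  mid <- max(2L, n %/% 2L)
  dirs <- list(vunit(a$coords$O[mid, ] - a$coords$C[mid, ]),
               -vunit(a$coords$O[mid, ] - a$coords$C[mid, ]),
               vunit(a$coords$O[mid + 1L, ] - a$coords$C[mid + 1L, ]),
               -vunit(a$coords$O[mid + 1L, ] - a$coords$C[mid + 1L, ]))
  best <- NULL
  best_bonds <- -1L
  for (u in dirs) {
    for (d in seq(4.2, 5.4, by = 0.1)) {
      b <- transform_structure(
        build_ideal_strand(n, chain = "B"), diag(3), d * u)
      cc <- transform_structure(
        build_ideal_strand(n, chain = "C"), diag(3), 2 * d * u)
      cand <- combine_structures(list(a, b, cc))
      hb <- backbone_hbond_pairs(cand)
      inter <- sum(cand$residues$chain[hb$donor] !=
                     cand$residues$chain[hb$acceptor])
      if (inter > best_bonds) {
        best_bonds <- inter
        best <- list(u = u, d = d)
      }
    }
  }
  if (best_bonds < 2L * (n - 2L))
    stop("sheet construction failed to form inter-strand hydrogen bonds")
  .fixture_cache[[key]] <- best
  build_ideal_sheet(n, aa = aa)
}

.fixture_cache <- new.env(parent = emptyenv())

#' Merge structures into one multi-chain structure
#'
#' @param structures List of `protein_structure` objects with distinct chain
#'   identifiers.
#' @return A single `protein_structure`.
#' @export
combine_structures <- function(structures) {
  stopifnot(length(structures) >= 1L)
  residues <- do.call(rbind, lapply(structures, `[[`, "residues"))
  offs <- cumsum(c(0L, vapply(structures,
                              function(s) nrow(s$residues), integer(1))))
  atoms <- do.call(rbind, lapply(seq_along(structures), function(i) {
    at <- structures[[i]]$atoms
    at$res_idx <- at$res_idx + offs[i]
    at
  }))
  ord <- order(residues$chain, residues$seq_index, residues$icode)
  if (!identical(ord, seq_along(ord))) {
    atoms$res_idx <- match(atoms$res_idx, ord)
    residues <- residues[ord, , drop = FALSE]
    rownames(residues) <- NULL
  }
  chains <- table(residues$chain)
  seqs <- vapply(split(residues$aa, residues$chain), paste, "",
                 collapse = "")
  meta <- structures[[1L]]$meta
  meta$chains <- stats::setNames(as.integer(chains), names(chains))
  meta$chain_sequences <- seqs
  new_structure(meta, residues, atoms)
}

#' Set the occupancy of selected atoms
#'
#' Fixture helper for exercising the occupancy-based cluster rejection rule.
#'
#' @param structure A `protein_structure`.
#' @param chain,seq_index Residue address.
#' @param atom Atom name(s) to modify, or NULL for all atoms of the residue.
#' @param value New occupancy in `[0, 1]`.
#' @return The modified `protein_structure`.
#' @export
set_occupancy <- function(structure, chain, seq_index, atom = NULL,
                          value = 0.5) {
  stopifnot(value >= 0, value <= 1)
  sel <- structure$atoms$chain == chain &
    structure$atoms$seq_index == seq_index
  if (!is.null(atom)) sel <- sel & structure$atoms$atom %in% atom
  if (!any(sel)) stop("no matching atoms")
  structure$atoms$occupancy[sel] <- value
  ridx <- unique(structure$atoms$res_idx[sel])
  for (i in ridx)
    structure$residues$occ_min[i] <-
      min(structure$atoms$occupancy[structure$atoms$res_idx == i])
  structure
}

#' Perturb atomic coordinates with Gaussian noise
#'
#' Adds iid N(0, sd^2) noise to every coordinate (draws from the current RNG
#' stream; seed at the call site for reproducibility).
#'
#' @param structure A `protein_structure`.
#' @param sd Noise standard deviation in Angstrom.
#' @return The perturbed `protein_structure`.
#' @export
add_coordinate_noise <- function(structure, sd = 0.05) {
  at <- structure$atoms
  noise <- matrix(stats::rnorm(3L * nrow(at), sd = sd), ncol = 3L)
  at$x <- at$x + noise[, 1L]
  at$y <- at$y + noise[, 2L]
  at$z <- at$z + noise[, 3L]
  out <- new_structure(structure$meta, structure$residues, at)
  out
}

#' Serialize a structure as PDB text
#'
#' Writes ATOM records (with element and occupancy fields), a TER record per
#' chain, and END. Output parses back through [parse_structure()] with
#' identical residue identities and backbone coordinates (to the 3-decimal
#' precision of the PDB fixed-column format).
#'
#' @param structure A `protein_structure`.
#' @param path Optional output file; when NULL the text is only returned.
#' @return Character vector of PDB lines, invisibly when `path` is given.
#' @export
make_toy_pdb <- function(structure, path = NULL) {
  at <- structure$atoms
  lines <- character()
  serial <- 0L
  for (ch in unique(at$chain)) {
    rows <- which(at$chain == ch)
    for (i in rows) {
      serial <- serial + 1L
      name4 <- if (nchar(at$atom[i]) <= 3L)
        sprintf(" %-3s", at$atom[i]) else sprintf("%-4s", at$atom[i])
      lines <- c(lines, sprintf(
        "ATOM  %5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, name4, at$altloc[i], at$resname[i], at$chain[i],
        at$seq_index[i], ifelse(nzchar(at$icode[i]), at$icode[i], " "),
        at$x[i], at$y[i], at$z[i], at$occupancy[i], 0, at$element[i]))
    }
    serial <- serial + 1L
    last <- rows[length(rows)]
    lines <- c(lines, sprintf("TER   %5d      %3s %1s%4d", serial,
                              at$resname[last], at$chain[last],
                              at$seq_index[last]))
  }
  lines <- c(lines, "END")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Separable synthetic training set
#'
#' Generates structural clusters from idealized secondary-structure
#' geometries with small Gaussian coordinate noise, labeled by the geometry
#' that generated them: helix fragments are labeled Ala ("A", class 0),
#' sheet fragments Cys ("C", class 1), loop fragments Asp ("D", class 2) --
#' three well-separated classes embedded in the 20-class label space. The
#' loop generator draws backbone dihedrals from the left-handed region
#' (phi, psi in 40-80 degrees), disjoint from the helical and extended
#' basins, so the label is a deterministic function of the target's
#' dihedral/secondary-structure features and the Bayes-optimal accuracy is 1
#' by construction. Targets are interior residues (defined phi and psi).
#'
#' Class marginals are met by quota: the requested fractions are converted
#' to per-class cluster counts, so realized marginals deviate from the
#' request only by block rounding (each generated fragment contributes
#' several clusters). The default noise (sd 0.05 Angstrom) emulates
#' coordinate uncertainty of a high-resolution crystal structure.
#'
#' @param n_clusters Total clusters (at least 100).
#' @param N Neighbors per cluster.
#' @param seed Integer seed; the archive is bit-identical for a given seed.
#' @param marginals Length-3 nonnegative weights (helix, sheet, loop
#'   fractions), normalized internally. Use e.g. `c(0.95, 0.05, 0)` for
#'   imbalance experiments.
#' @param noise_sd Coordinate noise standard deviation in Angstrom.
#' @param name Dataset name stem.
#' @param k Cross-validation folds.
#' @return A `cluster_dataset`.
#' @export
learnable_dataset <- function(n_clusters = 2000L, N = 5L, seed = 0L,
                              marginals = c(helix = 1/3, sheet = 1/3,
                                            loop = 1/3),
                              noise_sd = 0.05, name = "learnable", k = 5L) {
  stopifnot(n_clusters >= 100L, N >= 1L, length(marginals) == 3L,
            all(marginals >= 0), sum(marginals) > 0)
  p <- marginals / sum(marginals)
  quota <- floor(n_clusters * p)
  rem <- n_clusters - sum(quota)
  if (rem > 0) {
    extra <- order(n_clusters * p - quota, decreasing = TRUE)[seq_len(rem)]
    quota[extra] <- quota[extra] + 1L
  }
  labels3 <- c("A", "C", "D")

  with_preserved_seed({
    set.seed(seed)
    sets <- list()
    for (cls in 1:3) {
      got <- 0L
      while (got < quota[cls]) {
        s <- switch(cls,
          build_ideal_helix(12L, aa = labels3[1L]),
          build_ideal_sheet(8L, aa = labels3[2L]),
          build_ideal_backbone(stats::runif(12L, 40, 80),
                               stats::runif(12L, 40, 80),
                               rep(180, 12L), aa = labels3[3L]))
        s <- add_coordinate_noise(s, sd = noise_sd)
        cs <- extract_clusters(s, N,
                               target_chains = unique(s$residues$chain))
        # interior targets only: phi and psi both defined
        dih <- backbone_dihedrals(s)$angles
        keep <- vapply(cs$clusters, function(cl) {
          !is.na(dih$phi[cl$target]) && !is.na(dih$psi[cl$target])
        }, logical(1))
        cs$clusters <- cs$clusters[keep]
        take <- min(length(cs$clusters), quota[cls] - got)
        cs$clusters <- cs$clusters[seq_len(take)]
        got <- got + take
        sets[[length(sets) + 1L]] <- cs
      }
    }
    build_dataset(sets, name = sprintf("%s_N%d", name, N), k = k,
                  seed = seed)
  })
}
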