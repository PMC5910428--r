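# PDB parsing, the in-memory structure container, and structure-level filters.

BACKBONE_ATOMS <- c("N", "CA", "C", "O")

new_structure <- function(meta, residues, atoms) {
  n <- nrow(residues)
  coords <- lapply(BACKBONE_ATOMS, function(a)
    matrix(NA_real_, n, 3L, dimnames = list(NULL, c("x", "y", "z"))))
  names(coords) <- BACKBONE_ATOMS
  if (nrow(atoms)) {
    for (a in BACKBONE_ATOMS) {
      sel <- atoms$atom == a
      idx <- atoms$res_idx[sel]
      coords[[a]][idx, ] <- as.matrix(atoms[sel, c("x", "y", "z")])
    }
  }
  residues$complete <- !is.na(coords$N[, 1L]) & !is.na(coords$CA[, 1L]) &
    !is.na(coords$C[, 1L]) & !is.na(coords$O[, 1L])
  if (!is.null(residues$res_idx)) residues$res_idx <- NULL
  structure(list(meta = meta, residues = residues, coords = coords,
                 atoms = atoms),
            class = "protein_structure")
}

#' @export
print.protein_structure <- function(x, ...) {
  res <- x$residues
  chains <- split(res, res$chain)
  cat(sprintf("<protein_structure> %s: %d residue(s), %d chain(s)\n",
              if (nzchar(x$meta$pdb_id)) x$meta$pdb_id else "(unnamed)",
              nrow(res), length(chains)))
  for (ch in names(chains))
    cat(sprintf("  chain %s: %d residues\n", ch, nrow(chains[[ch]])))
  if (!is.na(x$meta$resolution))
    cat(sprintf("  %s, %.2f Angstrom\n", x$meta$method, x$meta$resolution))
  invisible(x)
}

pdb_num <- function(s) {
  s <- trimws(s)
  ifelse(nzchar(s), suppressWarnings(as.numeric(s)), NA_real_)
}

#' Parse a PDB-format structure
#'
#' Reads ATOM/HETATM records into per-residue records and header metadata.
#' Water, ions and other non-protein HETATM residues are removed; nucleic
#' acid chains are noted in the metadata (for the structure filter) but not
#' retained as residues. Only the first MODEL of a multi-model file is read.
#'
#' Alternate locations: atoms with altloc blank or 'A' are kept; for a
#' residue whose atoms carry only other altloc codes, the highest-occupancy
#' location of each atom is used.
#'
#' @param text PDB text: a path to a file, a single string (with embedded
#'   newlines), or a character vector of lines.
#' @return A `protein_structure`: a list with `meta` (pdb_id, method,
#'   resolution, has_nucleic, has_d_amino, chains, chain_sequences),
#'   `residues` (one row per residue, ordered by chain, author residue
#'   number, insertion code), `coords` (N/CA/C/O coordinate matrices) and
#'   `atoms` (every retained atom).
#' @export
parse_structure <- function(text) {
  if (length(text) == 1L && !grepl("\n", text, fixed = TRUE) &&
      file.exists(text)) {
    lines <- readLines(text, warn = FALSE)
  } else if (length(text) == 1L) {
    lines <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  } else {
    lines <- text
  }

  rec <- substr(lines, 1L, 6L)
  # Truncate to the first model when MODEL/ENDMDL present.
  endmdl <- which(rec == "ENDMDL")
  if (length(endmdl)) {
    lines <- lines[seq_len(endmdl[1L] - 1L)]
    rec <- rec[seq_len(endmdl[1L] - 1L)]
  }

  meta <- list(pdb_id = "", method = NA_character_, resolution = NA_real_,
               has_nucleic = FALSE, has_d_amino = FALSE,
               chains = integer(), chain_sequences = character())
  hdr <- lines[rec == "HEADER"]
  if (length(hdr) && nchar(hdr[1L]) >= 66L)
    meta$pdb_id <- trimws(substr(hdr[1L], 63L, 66L))
  exp <- lines[rec == "EXPDTA"]
  if (length(exp)) {
    m <- toupper(trimws(substr(exp[1L], 11L, nchar(exp[1L]))))
    meta$method <- if (grepl("X-RAY", m)) "x-ray" else tolower(m)
  }
  rem2 <- lines[rec == "REMARK" & grepl("^REMARK   2 RESOLUTION", lines)]
  if (length(rem2)) {
    mm <- regmatches(rem2[1L],
                     regexpr("[0-9]+\\.?[0-9]*(?=[[:space:]]*ANGSTROM)",
                             rem2[1L], perl = TRUE))
    if (length(mm)) meta$resolution <- as.numeric(mm)
  }

  is_atom <- rec == "ATOM  " | rec == "HETATM"
  atom_lines <- lines[is_atom]
  atom_lineno <- which(is_atom)
  if (!length(atom_lines)) stop("empty structure: no ATOM/HETATM records")

  short <- nchar(atom_lines) < 54L
  if (any(short))
    stop(sprintf("unreadable ATOM/HETATM record at line %d: too short",
                 atom_lineno[which(short)[1L]]))

  resname <- trimws(substr(atom_lines, 18L, 20L))
  het <- substr(atom_lines, 1L, 6L) == "HETATM"
  meta$has_nucleic <- any(resname %in% NUCLEIC_NAMES & !het)
  meta$has_d_amino <- any(resname %in% D_AMINO_NAMES)

  # Retain protein residues only: canonical and D-amino names always; other
  # names only when they arrive as ATOM records (nonstandard residues in the
  # polymer, kept as UNK). HETATM water/ion/ligand records are dropped.
  keep <- resname %in% AA3 | resname %in% D_AMINO_NAMES |
    (!het & !(resname %in% NUCLEIC_NAMES) & !(resname %in% WATER_NAMES))
  if (!any(keep)) stop("empty structure: no protein residues")

  al <- atom_lines[keep]
  ln <- atom_lineno[keep]
  resname <- resname[keep]

  x <- pdb_num(substr(al, 31L, 38L))
  y <- pdb_num(substr(al, 39L, 46L))
  z <- pdb_num(substr(al, 47L, 54L))
  bad <- is.na(x) | is.na(y) | is.na(z)
  if (any(bad))
    stop(sprintf("unreadable coordinates at line %d", ln[which(bad)[1L]]))
  occ <- pdb_num(substr(al, 55L, 60L))
  occ[is.na(occ)] <- 1
  seq_index <- suppressWarnings(as.integer(trimws(substr(al, 23L, 26L))))
  if (anyNA(seq_index))
    stop(sprintf("unreadable residue number at line %d",
                 ln[which(is.na(seq_index))[1L]]))
  atom <- trimws(substr(al, 13L, 16L))
  altloc <- substr(al, 17L, 17L)
  chain <- substr(al, 22L, 22L)
  chain[chain == " "] <- "_"
  icode <- trimws(substr(al, 27L, 27L))
  element <- trimws(substr(al, 77L, 78L))
  noel <- !nzchar(element)
  element[noel] <- substr(gsub("[^A-Za-z].*", "", atom[noel]), 1L, 1L)

  atoms <- data.frame(chain = chain, seq_index = seq_index, icode = icode,
                      resname = resname, atom = atom, element = toupper(element),
                      altloc = altloc, x = x, y = y, z = z, occupancy = occ,
                      stringsAsFactors = FALSE)

  # Altloc resolution per (residue, atom name): prefer blank/'A'; otherwise
  # the highest-occupancy location. File order within a residue is kept.
  atoms$ord0 <- seq_len(nrow(atoms))
  key <- paste(atoms$chain, atoms$seq_index, atoms$icode, atoms$atom,
               sep = "\r")
  pref <- atoms$altloc %in% c(" ", "A", "")
  ord <- order(key, !pref, -atoms$occupancy)
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(key[ord]), , drop = FALSE]

  # Residue table, ordered by (chain, seq_index, icode).
  atoms <- atoms[order(atoms$chain, atoms$seq_index, atoms$icode,
                       atoms$ord0), , drop = FALSE]
  atoms$ord0 <- NULL
  rkey <- paste(atoms$chain, atoms$seq_index, atoms$icode, sep = "\r")
  first <- !duplicated(rkey)
  residues <- data.frame(chain = atoms$chain[first],
                         seq_index = atoms$seq_index[first],
                         icode = atoms$icode[first],
                         resname = atoms$resname[first],
                         stringsAsFactors = FALSE)
  residues$aa <- aa1_from_resname(residues$resname)
  residues$is_standard <- residues$resname %in% AA3
  residues$is_d_amino <- residues$resname %in% D_AMINO_NAMES
  atoms$res_idx <- match(rkey, rkey[first])
  occ_min <- tapply(atoms$occupancy, atoms$res_idx, min)
  residues$occ_min <- as.numeric(occ_min[as.character(seq_len(nrow(residues)))])
  rownames(residues) <- NULL
  rownames(atoms) <- NULL

  counts <- table(residues$chain)
  meta$chains <- stats::setNames(as.integer(counts), names(counts))
  meta$chain_sequences <- vapply(split(residues$aa, residues$chain),
                                 paste, "", collapse = "")

  new_structure(meta, residues, atoms)
}

#' Read a PDB file from disk
#'
#' @param path Path to a PDB-format file.
#' @return A `protein_structure` (see [parse_structure()]).
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  parse_structure(readLines(path, warn = FALSE))
}

# Filters ---------------------------------------------------------------------

#' Structure-filter configuration
#'
#' Thresholds for [filter_structure()]. Defaults reproduce the training-set
#' curation rules: x-ray structures only, resolution better than 2 Angstrom,
#' longest chain above 50 residues, no nucleic acids, no D-amino acids.
#'
#' @param xray_only Require the experimental method to be x-ray
#'   crystallography.
#' @param max_resolution Resolution threshold in Angstrom (structures at or
#'   above it are rejected).
#' @param min_chain_length Minimum length of the longest chain (strictly
#'   greater than).
#' @param allow_nucleic,allow_d_amino Permit structures containing DNA/RNA or
#'   D-amino acids.
#' @param require_metadata When FALSE (default), structures without method or
#'   resolution metadata -- e.g. synthetic fixture files -- skip the checks
#'   that need the missing field; an x-ray structure without a recorded
#'   resolution is still rejected. When TRUE, missing metadata rejects.
#' @param exclude_ids Character vector of PDB identifiers to reject outright
#'   (e.g. a user-supplied membrane-protein list).
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(xray_only = TRUE, max_resolution = 2.0,
                          min_chain_length = 50L, allow_nucleic = FALSE,
                          allow_d_amino = FALSE, require_metadata = FALSE,
                          exclude_ids = character()) {
  stopifnot(max_resolution > 0, min_chain_length >= 0)
  structure(list(xray_only = xray_only, max_resolution = max_resolution,
                 min_chain_length = as.integer(min_chain_length),
                 allow_nucleic = allow_nucleic,
                 allow_d_amino = allow_d_amino,
                 require_metadata = require_metadata,
                 exclude_ids = toupper(exclude_ids)),
            class = "filter_config")
}

#' Keep-or-reject decision for a structure
#'
#' Applies the dataset curation rules to structure metadata. Rules are tested
#' in a fixed order (excluded id, method, resolution, chain length, nucleic
#' acids, D-amino acids) and the first failure is reported.
#'
#' @param meta The `meta` element of a `protein_structure` (or a whole
#'   `protein_structure`).
#' @param config A [filter_config()].
#' @return A list with `keep` (logical) and `reason` (NA when kept; one of
#'   `"excluded"`, `"method"`, `"resolution"`, `"resolution_missing"`,
#'   `"length"`, `"nucleic"`, `"d_amino"`).
#' @export
filter_structure <- function(meta, config = filter_config()) {
  if (inherits(meta, "protein_structure")) meta <- meta$meta
  reject <- function(reason) list(keep = FALSE, reason = reason)
  if (nzchar(meta$pdb_id) && toupper(meta$pdb_id) %in% config$exclude_ids)
    return(reject("excluded"))
  if (config$xray_only) {
    if (is.na(meta$method)) {
      if (config$require_metadata) return(reject("method"))
    } else if (meta$method != "x-ray") {
      return(reject("method"))
    }
  }
  if (is.na(meta$resolution)) {
    if ((!is.na(meta$method) && meta$method == "x-ray") ||
        config$require_metadata)
      return(reject("resolution_missing"))
  } else if (meta$resolution >= config$max_resolution) {
    return(reject("resolution"))
  }
  if (length(meta$chains) == 0L || max(meta$chains) <= config$min_chain_length)
    return(reject("length"))
  if (!config$allow_nucleic && isTRUE(meta$has_nucleic))
    return(reject("nucleic"))
  if (!config$allow_d_amino && isTRUE(meta$has_d_amino))
    return(reject("d_amino"))
  list(keep = TRUE, reason = NA_character_)
}

#' Drop duplicate subunits
#'
#' Among chains with identical (or near-identical) sequences, retains only
#' the first by chain identifier, so that a homo-oligomer contributes each
#' environment once. With the default threshold of 1 duplicates must match
#' exactly; below 1, global pairwise alignment identity (Biostrings) is used.
#'
#' @param structure A `protein_structure`, or a named character vector of
#'   chain sequences.
#' @param identity_threshold Fraction in (0, 1]; chains at least this
#'   identical are considered copies of one subunit.
#' @return Character vector of retained chain identifiers.
#' @export
deduplicate_chains <- function(structure, identity_threshold = 1.0) {
  seqs <- if (inherits(structure, "protein_structure"))
    structure$meta$chain_sequences else structure
  stopifnot(identity_threshold > 0, identity_threshold <= 1)
  ids <- sort(names(seqs))
  seqs <- seqs[ids]
  if (length(ids) <= 1L) return(ids)

  same <- function(a, b) {
    if (identity_threshold >= 1) return(a == b)
    if (!requireNamespace("Biostrings", quietly = TRUE))
      stop("identity_threshold < 1 requires the Biostrings package")
    aln <- Biostrings::pairwiseAlignment(a, b, type = "global")
    Biostrings::pid(aln, type = "PID1") / 100 >= identity_threshold
  }
  keep <- character()
  for (id in ids) {
    dup <- any(vapply(keep, function(k) same(seqs[[k]], seqs[[id]]), logical(1)))
    if (!dup) keep <- c(keep, id)
  }
  keep
}
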