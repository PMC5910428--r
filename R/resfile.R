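# Design export: top-K residue-type restraints and the Rosetta resfile
# format (header "NATAA" / "start", one PIKAA line per restrained position).

#' Top-K residue-type restraints from a profile
#'
#' For each eligible position, the allowed amino-acid set is the K
#' highest-probability residue types of its profile, with probability ties
#' broken alphabetically.
#'
#' @param profiles A `prediction_profile`, or an n x 20 probability matrix
#'   (positions are then numbered 1..n on chain A).
#' @param K Number of allowed types per position, 1..20.
#' @return A `restraint_set`: data.frame with `chain`, `seq_index`, `icode`,
#'   `allowed` (alphabetically sorted string of one-letter codes).
#' @export
top_k_restraints <- function(profiles, K) {
  if (length(K) != 1L || is.na(K) || K < 1L || K > 20L)
    stop("K must be a single integer in 1..20")
  if (inherits(profiles, "prediction_profile")) {
    keep <- profiles$eligible
    P <- as.matrix(profiles[keep, AA1, drop = FALSE])
    pos <- profiles[keep, c("chain", "seq_index", "icode")]
  } else {
    P <- as_profile_matrix(profiles)$P
    pos <- data.frame(chain = "A", seq_index = seq_len(nrow(P)), icode = "")
  }
  allowed <- vapply(seq_len(nrow(P)), function(i) {
    top <- AA1[order(-P[i, ])[seq_len(K)]]
    paste(sort(top), collapse = "")
  }, character(1))
  out <- data.frame(chain = pos$chain, seq_index = pos$seq_index,
                    icode = pos$icode, allowed = allowed,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("restraint_set", "data.frame")
  out
}

#' Write a Rosetta resfile
#'
#' Emits the default command `NATAA` (keep native unless restrained), the
#' `start` separator, and one line per restrained position in the form
#' `<resnum> <chain> PIKAA <letters>` with the allowed letters sorted
#' alphabetically. Insertion codes are appended to the residue number.
#'
#' @param restraints A `restraint_set` ([top_k_restraints()]).
#' @param path Optional output file.
#' @return Character vector of resfile lines (invisibly when `path` given).
#' @export
write_resfile <- function(restraints, path = NULL) {
  key <- paste(restraints$chain, restraints$seq_index, restraints$icode)
  if (anyDuplicated(key))
    stop("duplicate positions in restraint set: ",
         key[anyDuplicated(key)])
  bad <- !grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", restraints$allowed)
  if (any(bad)) stop("invalid allowed amino-acid set: ",
                     restraints$allowed[which(bad)[1L]])
  lines <- c("NATAA", "start",
             sprintf("%s%s %s PIKAA %s", restraints$seq_index,
                     restraints$icode, restraints$chain,
                     restraints$allowed))
  if (nrow(restraints) == 0L) lines <- c("NATAA", "start")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Parse a resfile written by [write_resfile()]
#'
#' Reads the PIKAA layout back into a `restraint_set`; the write-read round
#' trip is lossless.
#'
#' @param text Path to a resfile, or its lines as a character vector.
#' @return A `restraint_set`.
#' @export
read_resfile <- function(text) {
  lines <- if (length(text) == 1L && file.exists(text))
    readLines(text, warn = FALSE) else text
  start <- which(trimws(lines) == "start")
  if (!length(start)) stop("resfile parse error: no 'start' separator")
  body <- lines[-seq_len(start[1L])]
  body <- body[nzchar(trimws(body))]
  if (!length(body))
    return(structure(data.frame(chain = character(), seq_index = integer(),
                                icode = character(), allowed = character(),
                                stringsAsFactors = FALSE),
                     class = c("restraint_set", "data.frame")))
  m <- regmatches(body,
                  regexec("^\\s*(\\d+)([A-Za-z]?)\\s+(\\S)\\s+PIKAA\\s+([A-Z]+)\\s*$",
                          body))
  bad <- vapply(m, length, integer(1)) == 0L
  if (any(bad))
    stop("resfile parse error at line: ", body[which(bad)[1L]])
  out <- data.frame(
    chain = vapply(m, `[`, "", 4L),
    seq_index = as.integer(vapply(m, `[`, "", 2L)),
    icode = vapply(m, `[`, "", 3L),
    allowed = vapply(m, `[`, "", 5L),
    stringsAsFactors = FALSE)
  class(out) <- c("restraint_set", "data.frame")
  out
}

#' Maximal possible identity under residue-type restraints
#'
#' The ceiling on design sequence identity given a restraint set: the
#' fraction of positions whose allowed set contains the native residue.
#' For top-K restraints computed from the same profiles this equals the
#' top-K accuracy by definition.
#'
#' @param restraints A `restraint_set` covering every native position.
#' @param native Native one-letter labels (vector or single string) in
#'   restraint-row order.
#' @return Fraction in `[0, 1]`.
#' @export
max_possible_identity <- function(restraints, native) {
  if (length(native) == 1L && nchar(native) != 1L)
    native <- strsplit(native, "")[[1L]]
  if (length(native) != nrow(restraints))
    stop(sprintf("restraints cover %d positions but %d natives given",
                 nrow(restraints), length(native)))
  if (!nrow(restraints)) stop("empty restraint set")
  mean(mapply(grepl, native, restraints$allowed, MoreArgs = list(fixed = TRUE)))
}
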