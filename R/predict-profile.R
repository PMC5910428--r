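# Whole-structure prediction: one 20-way profile per residue.

#' Predict a per-position residue-type profile for a structure
#'
#' Runs the fitted network over every residue of a backbone structure: each
#' eligible residue (backbone-complete, full occupancy, with N extractable
#' neighbors) gets a 20-way probability profile. Ineligible residues are
#' flagged with a reason rather than silently dropped, so the output always
#' has one row per residue. Targets need not be standard amino acids --
#' prediction uses only backbone features.
#'
#' @param structure A `protein_structure`.
#' @param fit A fitted `profile_net` (or `profile_net_params`).
#' @param N Neighbor count; must match the model configuration (defaults to
#'   it).
#' @param ctx Optional precomputed [feature_context()].
#' @return A `prediction_profile`: data.frame with `chain`, `seq_index`,
#'   `icode`, `native` (one-letter, `"X"` for nonstandard), `eligible`,
#'   `reason`, and 20 probability columns in alphabetical amino-acid order.
#' @export
predict_profile <- function(structure, fit, N = NULL, ctx = NULL) {
  params <- as_params(fit)
  if (is.null(N)) N <- params$config$N
  if (N != params$config$N)
    stop(sprintf("N mismatch: requested %d neighbors, model expects %d",
                 N, params$config$N))
  res <- structure$residues
  cs <- extract_clusters(structure, N,
                         target_chains = unique(res$chain), ctx = ctx,
                         require_standard_target = FALSE)
  out <- data.frame(chain = res$chain, seq_index = res$seq_index,
                    icode = res$icode, native = res$aa,
                    eligible = FALSE, reason = NA_character_,
                    stringsAsFactors = FALSE)
  probs <- matrix(NA_real_, nrow(res), 20L, dimnames = list(NULL, AA1))
  if (length(cs$clusters)) {
    feats <- array(NA_real_,
                   dim = c(length(cs$clusters), N, N_PAIR_FEATURES))
    tgt <- integer(length(cs$clusters))
    for (i in seq_along(cs$clusters)) {
      feats[i, , ] <- cs$clusters[[i]]$features
      tgt[i] <- cs$clusters[[i]]$target
    }
    probs[tgt, ] <- forward_full(feats, params)
    out$eligible[tgt] <- TRUE
  }
  if (nrow(cs$dropped)) {
    key <- paste(cs$dropped$chain, cs$dropped$seq_index)
    m <- match(paste(out$chain, out$seq_index), key)
    out$reason[!is.na(m)] <- cs$dropped$reason[m[!is.na(m)]]
  }
  out <- cbind(out, as.data.frame(probs))
  class(out) <- c("prediction_profile", "data.frame")
  attr(out, "N") <- N
  out
}

#' @export
print.prediction_profile <- function(x, ...) {
  cat(sprintf("<prediction_profile> %d position(s), %d eligible, N = %s\n",
              nrow(x), sum(x$eligible), attr(x, "N")))
  if (sum(x$eligible)) {
    top <- predicted_letters(x)
    cat("  top-1 sequence: ",
        paste(ifelse(x$eligible, top, "-"), collapse = ""), "\n", sep = "")
  }
  invisible(x)
}

# Internal: probability matrix + native labels from a prediction_profile or
# a bare matrix (rows on the 20-simplex).
as_profile_matrix <- function(profiles, natives = NULL) {
  if (inherits(profiles, "prediction_profile")) {
    keep <- profiles$eligible
    P <- as.matrix(profiles[keep, AA1, drop = FALSE])
    natives <- profiles$native[keep]
  } else {
    P <- as.matrix(profiles)
    if (ncol(P) != 20L) stop("profile matrix must have 20 columns")
    if (is.null(colnames(P))) colnames(P) <- AA1
  }
  if (!is.null(natives) && is.character(natives) && length(natives) == 1L &&
      nchar(natives) == nrow(P))
    natives <- strsplit(natives, "")[[1L]]
  list(P = P, natives = natives)
}

# Top-1 letters (alphabetical tie-break) for profile rows.
predicted_letters <- function(profiles) {
  pm <- as_profile_matrix(profiles)
  AA1[max.col(pm$P, ties.method = "first")]
}

#' Write / read profile TSV files
#'
#' Tab-separated exchange format for prediction profiles: position id
#' (chain, residue number, insertion code), native letter (if known),
#' eligibility, and 20 probability columns in alphabetical order.
#'
#' @param profiles A `prediction_profile`.
#' @param path Output file.
#' @return `write_profile_tsv` returns `path` invisibly; `read_profile_tsv`
#'   a `prediction_profile`.
#' @export
write_profile_tsv <- function(profiles, path) {
  stopifnot(inherits(profiles, "prediction_profile"))
  df <- as.data.frame(profiles)
  utils::write.table(format(df, digits = 8, scientific = FALSE,
                            trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile_tsv
#' @export
read_profile_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = c(chain = "character",
                                         icode = "character",
                                         native = "character"))
  df$icode[is.na(df$icode)] <- ""
  if (!all(AA1 %in% colnames(df)))
    stop("schema error: profile file lacks the 20 probability columns")
  class(df) <- c("prediction_profile", "data.frame")
  df
}
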