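# Prediction-quality metrics: overall/top-K accuracy, per-class recall and
# precision, native-vs-predicted confusion probabilities, sequence identity,
# profile RMSE, and contact-rank coverage of the N-nearest-neighbor
# environment definition.

profiles_with_natives <- function(profiles, natives = NULL) {
  pm <- as_profile_matrix(profiles, natives)
  if (is.null(pm$natives))
    stop("native labels are required for this metric")
  if (length(pm$natives) != nrow(pm$P))
    stop("length mismatch between profiles and native labels")
  pm
}

#' Overall prediction accuracy
#'
#' Fraction of positions whose top-1 predicted residue type (argmax of the
#' profile; ties broken alphabetically) equals the native type.
#'
#' @param profiles A `prediction_profile` (with native labels), or an
#'   n x 20 probability matrix.
#' @param natives Native one-letter labels (vector or single string) when
#'   `profiles` is a bare matrix.
#' @return Fraction in `[0, 1]`.
#' @export
overall_accuracy <- function(profiles, natives = NULL) {
  pm <- profiles_with_natives(profiles, natives)
  if (!nrow(pm$P)) stop("no positions to score")
  mean(AA1[max.col(pm$P, ties.method = "first")] == pm$natives)
}

#' Top-K prediction accuracy
#'
#' A position counts as correct when its native residue type is among the K
#' highest-probability types of its profile (ties broken alphabetically).
#' Nondecreasing in K and exactly 1 at K = 20.
#'
#' @inheritParams overall_accuracy
#' @param K Integer in 1..20.
#' @return Fraction in `[0, 1]`.
#' @export
top_k_accuracy <- function(profiles, K, natives = NULL) {
  if (length(K) != 1L || is.na(K) || K < 1L || K > 20L)
    stop("K must be a single integer in 1..20")
  pm <- profiles_with_natives(profiles, natives)
  if (!nrow(pm$P)) stop("no positions to score")
  hits <- vapply(seq_len(nrow(pm$P)), function(i) {
    ord <- order(-pm$P[i, ])     # stable: ties resolve alphabetically
    match(pm$natives[i], AA1[ord]) <= K
  }, logical(1))
  mean(hits)
}

#' Per-residue-type recall and precision
#'
#' Recall of a type is the fraction of its native occurrences recovered by
#' the top-1 prediction; precision is the fraction of its predictions that
#' are correct. Types with no native occurrences (recall) or no predictions
#' (precision) are reported as NA -- missing, not zero -- so per-class
#' averages are not biased.
#'
#' @inheritParams overall_accuracy
#' @return data.frame with `aa`, `recall`, `precision`, `support` (native
#'   count) and `predicted` (prediction count), one row per amino acid.
#' @export
recall_precision <- function(profiles, natives = NULL) {
  pm <- profiles_with_natives(profiles, natives)
  pred <- AA1[max.col(pm$P, ties.method = "first")]
  out <- data.frame(aa = AA1, recall = NA_real_, precision = NA_real_,
                    support = 0L, predicted = 0L)
  for (i in seq_along(AA1)) {
    a <- AA1[i]
    nat <- pm$natives == a
    prd <- pred == a
    out$support[i] <- sum(nat)
    out$predicted[i] <- sum(prd)
    if (any(nat)) out$recall[i] <- sum(nat & prd) / sum(nat)
    if (any(prd)) out$precision[i] <- sum(nat & prd) / sum(prd)
  }
  out
}

#' Native-vs-predicted confusion probability matrix
#'
#' Entry (a, b) is the probability that a native residue of type a is
#' predicted (top-1) as type b: row-normalized confusion counts. Rows with
#' no native samples are NA.
#'
#' @inheritParams overall_accuracy
#' @return 20 x 20 matrix, rows = native, columns = predicted, alphabetical
#'   order.
#' @export
confusion_probability_matrix <- function(profiles, natives = NULL) {
  pm <- profiles_with_natives(profiles, natives)
  pred <- AA1[max.col(pm$P, ties.method = "first")]
  counts <- table(factor(pm$natives, levels = AA1),
                  factor(pred, levels = AA1))
  M <- unclass(counts / rowSums(counts))  # rows without natives become NaN
  M[is.nan(M)] <- NA_real_
  dimnames(M) <- list(native = AA1, predicted = AA1)
  M
}

#' Position-wise sequence identity
#'
#' Fraction of positions at which two equal-length sequences agree; no
#' alignment is performed.
#'
#' @param predicted,native Character vectors of single letters, or single
#'   strings.
#' @return Fraction in `[0, 1]`.
#' @export
sequence_identity <- function(predicted, native) {
  tochar <- function(s) if (length(s) == 1L && nchar(s) != 1L)
    strsplit(s, "")[[1L]] else s
  a <- tochar(predicted)
  b <- tochar(native)
  if (!length(a) || !length(b)) stop("empty sequence")
  if (length(a) != length(b))
    stop(sprintf("sequence length mismatch: %d vs %d", length(a), length(b)))
  mean(a == b)
}

#' RMSE between two probability profiles
#'
#' Root mean square difference over all 20 x L entries of two row-stochastic
#' profile matrices for the same positions.
#'
#' @param profile_a,profile_b n x 20 probability matrices (or
#'   `prediction_profile` objects over the same positions).
#' @return Nonnegative scalar.
#' @export
profile_rmse <- function(profile_a, profile_b) {
  A <- as_profile_matrix(profile_a)$P
  B <- as_profile_matrix(profile_b)$P
  if (!all(dim(A) == dim(B)))
    stop(sprintf("profile shape mismatch: %d x %d vs %d x %d",
                 nrow(A), ncol(A), nrow(B), ncol(B)))
  for (M in list(A, B))
    if (max(abs(rowSums(M) - 1)) > 1e-6)
      stop("profiles must be row-stochastic")
  sqrt(mean((A - B)^2))
}

#' Contact coverage of the distance-rank neighborhood
#'
#' For every residue, neighbors are ranked by CA-CA distance; a neighbor's
#' rank M is its position in that ordering. A neighbor is a contact when any
#' pair of heavy atoms between the two residues is closer than the cutoff.
#' The returned value is the fraction of all contacting (target, neighbor)
#' pairs whose rank satisfies M <= `rank_n` -- i.e. how much of the true
#' contact environment an N-nearest-neighbor cluster definition captures.
#'
#' @param structure A `protein_structure` (sidechain heavy atoms are used
#'   when present).
#' @param rank_n Neighbor-rank threshold N.
#' @param cutoff Heavy-atom contact distance in Angstrom.
#' @return Fraction in `[0, 1]`, or NA when the structure has no contacts.
#' @export
contact_rank_coverage <- function(structure, rank_n, cutoff = 4.5) {
  stopifnot(rank_n >= 1L, cutoff > 0)
  res <- structure$residues
  n <- nrow(res)
  at <- structure$atoms[structure$atoms$element != "H", , drop = FALSE]
  if (!nrow(at) || n < 2L) return(NA_real_)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  ridx <- at$res_idx
  CA <- structure$coords$CA

  covered <- 0L
  total <- 0L
  for (i in seq_len(n)) {
    if (is.na(CA[i, 1L])) next
    d <- rownorm(sweep(CA, 2L, CA[i, ], "-"))
    d[i] <- Inf
    d[is.na(d)] <- Inf
    rk <- integer(n)
    rk[order(d, res$chain, res$seq_index, res$icode)] <- seq_len(n)
    # heavy-atom contacts of residue i
    mine <- xyz[ridx == i, , drop = FALSE]
    if (!nrow(mine)) next
    cand <- unique(ridx[ridx != i])
    for (j in cand) {
      if (!is.finite(d[j])) next
      if (d[j] > cutoff + 25) next   # CA-CA prefilter, generous bound
      other <- xyz[ridx == j, , drop = FALSE]
      mind <- min(vapply(seq_len(nrow(other)), function(k)
        min(rownorm(sweep(mine, 2L, other[k, ], "-"))), numeric(1)))
      if (mind < cutoff) {
        total <- total + 1L
        if (rk[j] <= rank_n) covered <- covered + 1L
      }
    }
  }
  if (total == 0L) return(NA_real_)
  covered / total
}

#' Write a metrics report
#'
#' Emits a flat key-value text file of scalar metrics and a per-class TSV
#' (class, recall, precision, support).
#'
#' @param profiles A `prediction_profile` with native labels.
#' @param path_prefix Output prefix; writes `<prefix>_metrics.txt` and
#'   `<prefix>_per_class.tsv`.
#' @param top_k K values to report.
#' @return Named list of the scalar metrics, invisibly.
#' @export
write_metrics_report <- function(profiles, path_prefix,
                                 top_k = c(1L, 2L, 3L, 5L, 10L)) {
  metrics <- c(
    list(n_positions = nrow(as_profile_matrix(profiles)$P),
         overall_accuracy = overall_accuracy(profiles)),
    stats::setNames(lapply(top_k, function(k) top_k_accuracy(profiles, k)),
                    sprintf("top_%d_accuracy", top_k)))
  txt <- sprintf("%s\t%s", names(metrics),
                 vapply(metrics, function(v) format(v, digits = 8),
                        character(1)))
  writeLines(txt, paste0(path_prefix, "_metrics.txt"))
  rp <- recall_precision(profiles)
  utils::write.table(rp, paste0(path_prefix, "_per_class.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(metrics)
}
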