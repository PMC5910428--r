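# Structural-cluster extraction and training-dataset assembly.

#' Extract structural clusters
#'
#' One cluster per eligible target residue: the target plus its `N` nearest
#' neighbor residues by CA-CA distance, drawn from all retained protein
#' residues of the structure (all chains of the assembly, so interfaces are
#' represented). Ties in distance are broken by (chain, residue number).
#' A cluster is discarded -- with a logged reason -- when any member residue
#' has an atom with occupancy below 1 or is missing a backbone atom, or when
#' the target is not one of the 20 canonical amino acids (no trainable
#' label). Chain-terminal targets remain eligible; their undefined dihedrals
#' use the (0, 0) sentinel encoding.
#'
#' @param structure A `protein_structure`.
#' @param N Number of neighbors per cluster (must be below the residue
#'   count).
#' @param target_chains Chains whose residues may serve as targets; default
#'   is the [deduplicate_chains()] result, so one copy of each identical
#'   subunit contributes targets while all chains provide the environment.
#' @param ctx Optional precomputed [feature_context()].
#' @param require_standard_target Drop targets that are not one of the 20
#'   canonical amino acids (the default; training needs labels). Prediction
#'   paths set this to FALSE since features need no target identity.
#' @return An object of class `cluster_set`: a list with `clusters` (each
#'   holding `target` (row index), `chain`, `seq_index`, `icode`, `label`
#'   (one-letter), `neighbors` (row indices, ascending distance),
#'   `distances`, and `features` (N x 31 matrix)), `dropped` (data.frame of
#'   rejected targets and reasons), and `N`.
#' @export
extract_clusters <- function(structure, N, target_chains = NULL, ctx = NULL,
                             require_standard_target = TRUE) {
  res <- structure$residues
  n <- nrow(res)
  stopifnot(N >= 1L)
  if (N >= n)
    stop(sprintf("N = %d neighbors requested but structure has only %d residues",
                 N, n))
  if (is.null(target_chains)) target_chains <- deduplicate_chains(structure)
  if (is.null(ctx)) ctx <- feature_context(structure)

  CA <- structure$coords$CA
  member_ok <- res$complete & res$occ_min >= 1
  clusters <- list()
  dropped <- data.frame(chain = character(), seq_index = integer(),
                        reason = character())
  drop <- function(i, reason) {
    dropped[nrow(dropped) + 1L, ] <<- list(res$chain[i], res$seq_index[i],
                                           reason)
  }

  for (i in which(res$chain %in% target_chains)) {
    if (require_standard_target && !res$is_standard[i]) {
      drop(i, "nonstandard"); next
    }
    if (!res$complete[i]) { drop(i, "missing_backbone"); next }
    if (res$occ_min[i] < 1) { drop(i, "occupancy"); next }
    d <- rownorm(sweep(CA, 2L, CA[i, ], "-"))
    d[i] <- Inf
    d[is.na(d)] <- Inf
    ord <- order(d, res$chain, res$seq_index, res$icode)[seq_len(N)]
    if (any(!is.finite(d[ord]))) { drop(i, "too_few_residues"); next }
    if (any(!res$complete[ord])) { drop(i, "missing_backbone"); next }
    if (any(res$occ_min[ord] < 1)) { drop(i, "occupancy"); next }
    clusters[[length(clusters) + 1L]] <- list(
      target = i, chain = res$chain[i], seq_index = res$seq_index[i],
      icode = res$icode[i], label = res$aa[i],
      neighbors = ord, distances = d[ord],
      features = cluster_features(ctx, i, ord))
  }
  structure(list(clusters = clusters, dropped = dropped, N = as.integer(N)),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> %d cluster(s), N = %d, %d dropped\n",
              length(x$clusters), x$N, nrow(x$dropped)))
  if (nrow(x$dropped))
    print(table(x$dropped$reason))
  invisible(x)
}

#' Class weights from per-class counts
#'
#' Training-sample weights `W_i = N_max / N_i`, where `N_max` is the count
#' of the most abundant residue type: the most abundant class gets weight 1
#' and rarer classes proportionally more. Classes absent from the counts get
#' weight 0.
#'
#' @param counts Named integer vector of per-class sample counts (names are
#'   one-letter amino-acid codes; missing classes are taken as 0).
#' @return Named numeric vector of weights over the full 20-letter alphabet.
#' @examples
#' class_weights(c(A = 100, G = 50)) # A 1, G 2
#' @export
class_weights <- function(counts) {
  full <- stats::setNames(rep(0, length(AA1)), AA1)
  if (length(counts)) {
    if (is.null(names(counts)) || !all(names(counts) %in% AA1))
      stop("counts must be named by one-letter amino-acid codes")
    full[names(counts)] <- counts
  }
  if (all(full == 0)) stop("all class counts are zero")
  w <- rep(0, length(full))
  names(w) <- names(full)
  pos <- full > 0
  w[pos] <- max(full) / full[pos]
  w
}

#' Random k-fold assignment
#'
#' Partitions `n` items into `k` folds whose sizes differ by at most one,
#' deterministically for a given seed (the global RNG state is restored on
#' exit).
#'
#' @param n Number of items (or a `cluster_set`).
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold ids in `1:k`.
#' @export
kfold_split <- function(n, k = 5L, seed = 0L) {
  if (inherits(n, "cluster_set")) n <- length(n$clusters)
  stopifnot(k >= 2L)
  if (n < k) stop(sprintf("cannot split %d clusters into %d folds", n, k))
  with_preserved_seed({
    set.seed(seed)
    sample(rep(seq_len(k), length.out = n))
  })
}

with_preserved_seed <- function(expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  expr
}

#' Assemble a training dataset from cluster sets
#'
#' Stacks cluster feature matrices into a `clusters x N x 31` array with
#' integer labels (0-19, alphabetical `ACDEFGHIKLMNPQRSTVWY` order), builds
#' the manifest (name, neighbor count, per-class counts, fold assignment)
#' and returns the archive object that [save_dataset()] writes.
#'
#' @param cluster_sets A `cluster_set` or list of them (e.g. one per
#'   structure), all with the same `N`.
#' @param name Dataset name (the `SI30N15`-style tag is conventional).
#' @param k Number of cross-validation folds.
#' @param seed Seed for the fold assignment.
#' @return An object of class `cluster_dataset`: list with `manifest`
#'   (`name`, `N`, `n_clusters`, `counts`, `folds`), `features`, `labels`
#'   and `format_version`.
#' @export
build_dataset <- function(cluster_sets, name = "dataset", k = 5L, seed = 0L) {
  if (inherits(cluster_sets, "cluster_set"))
    cluster_sets <- list(cluster_sets)
  Ns <- unique(vapply(cluster_sets, `[[`, integer(1), "N"))
  if (length(Ns) != 1L) stop("cluster sets disagree on N")
  clusters <- do.call(c, lapply(cluster_sets, `[[`, "clusters"))
  n <- length(clusters)
  if (!n) stop("no clusters to assemble")
  feats <- array(NA_real_, dim = c(n, Ns, N_PAIR_FEATURES),
                 dimnames = list(NULL, NULL, PAIR_FEATURE_NAMES))
  labels <- integer(n)
  for (i in seq_len(n)) {
    feats[i, , ] <- clusters[[i]]$features
    labels[i] <- match(clusters[[i]]$label, AA1) - 1L
  }
  counts <- table(factor(AA1[labels + 1L], levels = AA1))
  folds <- kfold_split(n, k = k, seed = seed)
  structure(list(
    manifest = list(name = name, N = Ns, n_clusters = n,
                    counts = stats::setNames(as.integer(counts), AA1),
                    folds = folds),
    features = feats, labels = labels, format_version = 1L),
    class = "cluster_dataset")
}

#' @export
print.cluster_dataset <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("<cluster_dataset> %s: %d clusters, N = %d, %d folds\n",
              m$name, m$n_clusters, m$N, length(unique(m$folds))))
  invisible(x)
}

DATASET_FORMAT_VERSION <- 1L

#' Save / load a dataset archive
#'
#' Single-file archive (RDS serialization of the `cluster_dataset` object
#' plus a format version). `load_dataset(save_dataset(x))` reproduces the
#' feature array bit-exactly and every manifest field exactly; loading
#' validates the format version, array dimensions against the manifest,
#' label range and fold partition.
#'
#' @param dataset A `cluster_dataset`.
#' @param path File path for the archive.
#' @return `save_dataset` returns `path` invisibly; `load_dataset` returns
#'   the validated `cluster_dataset`.
#' @export
save_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "cluster_dataset"))
  saveRDS(dataset, path)
  invisible(path)
}

#' @rdname save_dataset
#' @export
load_dataset <- function(path) {
  x <- tryCatch(readRDS(path), error = function(e)
    stop("corrupted or unreadable dataset archive: ", conditionMessage(e)))
  validate_dataset(x)
  x
}

validate_dataset <- function(x) {
  if (!inherits(x, "cluster_dataset") || is.null(x$format_version))
    stop("schema error: not a cluster_dataset archive")
  if (x$format_version != DATASET_FORMAT_VERSION)
    stop(sprintf("dataset format version mismatch: archive %s, supported %s",
                 x$format_version, DATASET_FORMAT_VERSION))
  m <- x$manifest
  for (f in c("name", "N", "n_clusters", "counts", "folds"))
    if (is.null(m[[f]])) stop("schema error: manifest missing field ", f)
  if (is.null(x$labels)) stop("schema error: archive missing labels")
  if (is.null(x$features)) stop("schema error: archive missing features")
  d <- dim(x$features)
  if (length(d) != 3L || d[1L] != m$n_clusters || d[2L] != m$N ||
      d[3L] != N_PAIR_FEATURES)
    stop(sprintf(
      "consistency error: feature array is %s but manifest declares %d x %d x %d",
      paste(d, collapse = " x "), m$n_clusters, m$N, N_PAIR_FEATURES))
  if (length(x$labels) != m$n_clusters ||
      any(x$labels < 0L | x$labels > 19L))
    stop("consistency error: labels must be one 0-19 integer per cluster")
  if (length(m$folds) != m$n_clusters)
    stop("consistency error: fold assignment does not cover the clusters")
  if (sum(m$counts) != m$n_clusters)
    stop("consistency error: per-class counts do not sum to cluster count")
  invisible(x)
}
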