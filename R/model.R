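# The shared-subnetwork residue-profile architecture and its training.
#
# Two subnetworks read the same 31-feature target-neighbor pair vector: the
# residue-probability subnet outputs a 20-way softmax over residue types,
# the weight subnet outputs a single scalar importance weight. Both are
# applied with the *same parameters* to every neighbor slot of a cluster
# (parameter sharing, as a 1D convolution over neighbors). Each slot's
# probability vector is multiplied by its weight, the N weighted 20-vectors
# are concatenated in ascending-distance order, and a fully-connected head
# with a final 20-way softmax produces the target residue-type profile.
# Training minimizes class-weighted categorical cross entropy with SGD plus
# Nesterov momentum; gradients are derived and applied in closed form here
# (plain matrix algebra, no autodiff dependency).

relu <- function(Z) Z * (Z > 0)

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

softplus <- function(z) {
  # numerically stable log(1 + exp(z))
  pmax(z, 0) + log1p(exp(-abs(z)))
}

he_layers <- function(sizes) {
  lapply(seq_len(length(sizes) - 1L), function(l) {
    fan_in <- sizes[l]
    lim <- sqrt(6 / fan_in)
    list(W = matrix(stats::runif(fan_in * sizes[l + 1L], -lim, lim),
                    fan_in, sizes[l + 1L]),
         b = rep(0, sizes[l + 1L]))
  })
}

mlp_forward <- function(X, layers) {
  L <- length(layers)
  A <- vector("list", L + 1L)
  Z <- vector("list", L)
  A[[1L]] <- X
  for (l in seq_len(L)) {
    Z[[l]] <- sweep(A[[l]] %*% layers[[l]]$W, 2L, layers[[l]]$b, "+")
    A[[l + 1L]] <- if (l < L) relu(Z[[l]]) else Z[[l]]
  }
  list(A = A, Z = Z, out = Z[[L]])
}

# Backprop through an MLP given d(loss)/d(output logits); returns parameter
# gradients and d(loss)/d(input).
mlp_backward <- function(cache, layers, dOut) {
  L <- length(layers)
  grads <- vector("list", L)
  dZ <- dOut
  for (l in rev(seq_len(L))) {
    grads[[l]] <- list(W = crossprod(cache$A[[l]], dZ), b = colSums(dZ))
    if (l > 1L) {
      dA <- dZ %*% t(layers[[l]]$W)
      dZ <- dA * (cache$Z[[l - 1L]] > 0)
    } else {
      dA <- dZ %*% t(layers[[l]]$W)
    }
  }
  list(grads = grads, dX = dA)
}

#' Initialize model parameters
#'
#' He-uniform initialization of the three components (probability subnet,
#' weight subnet, head), seeded for reproducibility. Hidden-layer widths are
#' configuration, not architecture contract: the probability subnet ends in
#' 20 units (softmax), the weight subnet in 1 unit (softplus by default, so
#' the neighbor weight is nonnegative and interpretable), the head in 20
#' units (softmax).
#'
#' @param N Neighbors per cluster the model consumes.
#' @param hidden_prob,hidden_weight,hidden_head Integer vectors of hidden
#'   widths for the three components.
#' @param weight_activation `"softplus"` (default) or `"linear"` output
#'   activation of the weight subnet.
#' @param seed Integer seed for the initialization draws.
#' @return A list of class `profile_net_params` with elements `prob`, `wt`,
#'   `head` (lists of `W`/`b` layers), `center`/`scale` (feature
#'   standardization, identity until fitted) and `config`.
#' @export
init_profile_params <- function(N, hidden_prob = c(64L, 64L),
                                hidden_weight = c(32L, 32L),
                                hidden_head = c(256L, 256L),
                                weight_activation = c("softplus", "linear"),
                                seed = 0L) {
  weight_activation <- match.arg(weight_activation)
  with_preserved_seed({
    set.seed(seed)
    params <- list(
      prob = he_layers(c(N_PAIR_FEATURES, hidden_prob, 20L)),
      wt = he_layers(c(N_PAIR_FEATURES, hidden_weight, 1L)),
      head = he_layers(c(20L * N, hidden_head, 20L)),
      center = rep(0, N_PAIR_FEATURES),
      scale = rep(1, N_PAIR_FEATURES),
      config = list(N = as.integer(N), n_features = N_PAIR_FEATURES,
                    hidden_prob = hidden_prob,
                    hidden_weight = hidden_weight,
                    hidden_head = hidden_head,
                    weight_activation = weight_activation,
                    feature_version = 1L))
    class(params) <- "profile_net_params"
    params
  })
}

check_pair_input <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != N_PAIR_FEATURES)
    stop(sprintf("shape error: expected %d pair features, got %d",
                 N_PAIR_FEATURES, ncol(x)))
  x
}

standardize_input <- function(x, params) {
  sweep(sweep(x, 2L, params$center, "-"), 2L, params$scale, "/")
}

#' Residue-probability subnetwork forward pass
#'
#' Maps one (or several) 31-feature target-neighbor pair vectors to a 20-way
#' probability distribution over residue types (ReLU hidden layers, softmax
#' output: components are nonnegative and sum to one).
#'
#' @param pair Numeric vector of length 31 or matrix with 31 columns.
#' @param params A `profile_net_params` (or fitted `profile_net`).
#' @return Probability vector of length 20 (or matrix, one row per input),
#'   alphabetical amino-acid order.
#' @export
forward_prob_subnet <- function(pair, params) {
  params <- as_params(params)
  X <- standardize_input(check_pair_input(pair), params)
  P <- softmax_rows(mlp_forward(X, params$prob)$out)
  colnames(P) <- AA1
  if (nrow(P) == 1L && is.null(dim(pair))) P[1L, ] else P
}

#' Weight subnetwork forward pass
#'
#' Maps a pair-feature vector to the scalar importance weight of that
#' neighbor (softplus output by default, so weights are nonnegative).
#'
#' @inheritParams forward_prob_subnet
#' @return Scalar (or numeric vector, one per input row).
#' @export
forward_weight_subnet <- function(pair, params) {
  params <- as_params(params)
  X <- standardize_input(check_pair_input(pair), params)
  z <- mlp_forward(X, params$wt)$out[, 1L]
  if (params$config$weight_activation == "softplus") softplus(z) else z
}

#' Full-network forward pass
#'
#' Applies the probability and weight subnets (shared parameters) to each of
#' the N neighbor slots, multiplies each slot's 20-vector by its weight,
#' concatenates the N weighted vectors in neighbor (ascending-distance)
#' order, and passes the 20N values through the fully-connected head to a
#' final 20-way softmax.
#'
#' @param cluster An N x 31 feature matrix ([cluster_features()]), or an
#'   n x N x 31 array of many clusters.
#' @param params A `profile_net_params` or fitted `profile_net`.
#' @return Probability vector of length 20, or an n x 20 matrix.
#' @export
forward_full <- function(cluster, params) {
  params <- as_params(params)
  N <- params$config$N
  if (is.matrix(cluster)) {
    if (nrow(cluster) != N)
      stop(sprintf("shape error: cluster has %d neighbor rows, model expects %d",
                   nrow(cluster), N))
    feats <- array(cluster, dim = c(1L, N, ncol(cluster)))
    out <- forward_full_batch(feats, params)$Q
    return(out[1L, ])
  }
  d <- dim(cluster)
  if (length(d) != 3L || d[2L] != N || d[3L] != N_PAIR_FEATURES)
    stop(sprintf("shape error: expected n x %d x %d feature array", N,
                 N_PAIR_FEATURES))
  forward_full_batch(cluster, params)$Q
}

# Batched forward with caches for backprop. feats: n x N x 31.
forward_full_batch <- function(feats, params) {
  n <- dim(feats)[1L]
  N <- dim(feats)[2L]
  X <- matrix(aperm(feats, c(2L, 1L, 3L)), nrow = n * N)
  X <- standardize_input(X, params)
  cp <- mlp_forward(X, params$prob)
  P <- softmax_rows(cp$out)
  cw <- mlp_forward(X, params$wt)
  zw <- cw$out[, 1L]
  s <- if (params$config$weight_activation == "softplus")
    softplus(zw) else zw
  V <- P * s
  Hin <- t(matrix(array(t(V), dim = c(20L, N, n)), nrow = 20L * N))
  ch <- mlp_forward(Hin, params$head)
  Q <- softmax_rows(ch$out)
  colnames(Q) <- AA1
  list(Q = Q, X = X, cp = cp, P = P, cw = cw, zw = zw, s = s, Hin = Hin,
       ch = ch, n = n, N = N)
}

# Gradients of the weighted cross-entropy loss w.r.t. all parameters.
backward_full_batch <- function(fw, params, labels, sample_w) {
  n <- fw$n; N <- fw$N
  wsum <- sum(sample_w)
  Y <- matrix(0, n, 20L)
  Y[cbind(seq_len(n), labels + 1L)] <- 1
  dLh <- (fw$Q - Y) * (sample_w / wsum)
  bh <- mlp_backward(fw$ch, params$head, dLh)
  dHin <- bh$dX
  dV <- t(matrix(array(t(dHin), dim = c(20L, N, n)), nrow = 20L))
  ds <- rowSums(dV * fw$P)
  dP <- dV * fw$s
  dZp <- fw$P * (dP - rowSums(dP * fw$P))
  bp <- mlp_backward(fw$cp, params$prob, dZp)
  dzw <- if (params$config$weight_activation == "softplus")
    ds * stats::plogis(fw$zw) else ds
  bw <- mlp_backward(fw$cw, params$wt, matrix(dzw, ncol = 1L))
  list(head = bh$grads, prob = bp$grads, wt = bw$grads)
}

#' Categorical cross entropy
#'
#' Mean (optionally sample-weighted) negative log probability of the true
#' class. With uniform predictions the unweighted loss is `log(20)` exactly.
#'
#' @param probs n x 20 probability matrix.
#' @param labels Integer labels 0-19 or one-letter codes.
#' @param weights Optional per-sample weights (weighted mean is used).
#' @return Scalar loss (nats).
#' @export
cross_entropy <- function(probs, labels, weights = NULL) {
  if (is.character(labels)) labels <- match(labels, AA1) - 1L
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1L)
  p <- probs[cbind(seq_len(nrow(probs)), labels + 1L)]
  ce <- -log(pmax(p, 1e-300))
  if (is.null(weights)) mean(ce) else sum(weights * ce) / sum(weights)
}

#' Training configuration
#'
#' Optimizer and architecture settings for [fit_profile_net()]. The
#' optimizer defaults are the full-scale settings (SGD, learning rate 0.01,
#' Nesterov momentum 0.9, batch size 40000, 1000 epochs); desk-scale fits on
#' synthetic fixtures override `batch_size` and `epochs` (256 and at most
#' 200 are typical).
#'
#' @param learning_rate,momentum SGD step size and Nesterov momentum.
#' @param batch_size Minibatch size (capped at the training-set size).
#' @param epochs Training epochs.
#' @param seed Seed controlling initialization and shuffling.
#' @param class_weighting Weight samples by `W_i = N_max / N_i` computed on
#'   the training labels (multiplicative per-sample loss weights, not
#'   resampling).
#' @param hidden_prob,hidden_weight,hidden_head,weight_activation Passed to
#'   [init_profile_params()].
#' @param standardize Standardize the 31 input features (z-score estimated
#'   on the training rows, stored in the model, applied at prediction).
#' @return A list of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.01, momentum = 0.9,
                         batch_size = 40000L, epochs = 1000L, seed = 0L,
                         class_weighting = TRUE,
                         hidden_prob = c(64L, 64L),
                         hidden_weight = c(32L, 32L),
                         hidden_head = c(256L, 256L),
                         weight_activation = c("softplus", "linear"),
                         standardize = TRUE) {
  stopifnot(learning_rate > 0, momentum >= 0, momentum < 1,
            batch_size >= 1, epochs >= 1)
  structure(list(learning_rate = learning_rate, momentum = momentum,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 class_weighting = isTRUE(class_weighting),
                 hidden_prob = hidden_prob, hidden_weight = hidden_weight,
                 hidden_head = hidden_head,
                 weight_activation = match.arg(weight_activation),
                 standardize = isTRUE(standardize)),
            class = "train_config")
}

#' Fit the residue-profile network
#'
#' Trains the shared-subnetwork architecture on a cluster dataset by
#' stochastic gradient descent with Nesterov momentum, minimizing
#' class-weighted categorical cross entropy (weights `W_i = N_max / N_i`
#' from the training labels). Deterministic for a given configuration seed
#' up to floating-point reduction order.
#'
#' @param dataset A `cluster_dataset` ([build_dataset()], [load_dataset()],
#'   [learnable_dataset()]).
#' @param train_folds Folds (from the dataset manifest) to train on; NULL
#'   uses every cluster.
#' @param config A [train_config()].
#' @param verbose Print the loss every 10 epochs.
#' @return An object of class `profile_net`: `params`, `trace` (per-epoch
#'   data.frame with loss and training accuracy), `class_weights`,
#'   `train_folds`, `config` and `call`. Supports `print`, `summary`,
#'   `coef`, `plot` and `predict`.
#' @export
fit_profile_net <- function(dataset, train_folds = NULL,
                            config = train_config(), verbose = FALSE) {
  validate_dataset(dataset)
  N <- dataset$manifest$N
  idx <- if (is.null(train_folds)) seq_len(dataset$manifest$n_clusters)
  else which(dataset$manifest$folds %in% train_folds)
  if (!length(idx)) stop("empty training fold selection")
  feats <- dataset$features[idx, , , drop = FALSE]
  labels <- dataset$labels[idx]
  n <- length(idx)

  params <- init_profile_params(
    N, hidden_prob = config$hidden_prob,
    hidden_weight = config$hidden_weight,
    hidden_head = config$hidden_head,
    weight_activation = config$weight_activation, seed = config$seed)

  if (config$standardize) {
    Xall <- matrix(aperm(feats, c(2L, 1L, 3L)), nrow = n * N)
    params$center <- colMeans(Xall)
    sds <- apply(Xall, 2L, stats::sd)
    sds[!is.finite(sds) | sds < 1e-8] <- 1
    params$scale <- sds
  }

  cw <- if (config$class_weighting) {
    counts <- table(factor(AA1[labels + 1L], levels = AA1))
    class_weights(stats::setNames(as.integer(counts), AA1))
  } else stats::setNames(rep(1, 20L), AA1)
  sample_w <- unname(cw[labels + 1L])

  vel <- rapply(params[c("prob", "wt", "head")],
                function(x) x * 0, how = "replace")
  lr <- config$learning_rate
  mu <- config$momentum
  bs <- min(config$batch_size, n)
  trace <- data.frame(epoch = integer(), loss = numeric(),
                      accuracy = numeric())

  for (epoch in seq_len(config$epochs)) {
    ord <- with_preserved_seed({
      set.seed(config$seed + epoch)
      sample.int(n)
    })
    ep_loss <- 0
    ep_w <- 0
    for (start in seq(1L, n, by = bs)) {
      b <- ord[start:min(start + bs - 1L, n)]
      fw <- forward_full_batch(feats[b, , , drop = FALSE], params)
      loss <- cross_entropy(fw$Q, labels[b], sample_w[b])
      if (!is.finite(loss))
        stop(sprintf(
          "NaN/Inf loss at epoch %d (lr = %g, batch = %d); try a smaller learning rate",
          epoch, lr, bs))
      g <- backward_full_batch(fw, params, labels[b], sample_w[b])
      for (comp in c("prob", "wt", "head")) {
        for (l in seq_along(params[[comp]])) {
          for (pn in c("W", "b")) {
            vel[[comp]][[l]][[pn]] <- mu * vel[[comp]][[l]][[pn]] -
              lr * g[[comp]][[l]][[pn]]
            params[[comp]][[l]][[pn]] <- params[[comp]][[l]][[pn]] +
              mu * vel[[comp]][[l]][[pn]] - lr * g[[comp]][[l]][[pn]]
          }
        }
      }
      wb <- sum(sample_w[b])
      ep_loss <- ep_loss + loss * wb
      ep_w <- ep_w + wb
    }
    Q <- forward_full_batch(feats, params)$Q
    acc <- mean(max.col(Q, ties.method = "first") == labels + 1L)
    trace[nrow(trace) + 1L, ] <- list(epoch, ep_loss / ep_w, acc)
    if (verbose && (epoch %% 10L == 0L || epoch == 1L))
      message(sprintf("epoch %4d  loss %.4f  acc %.3f", epoch,
                      ep_loss / ep_w, acc))
  }

  structure(list(params = params, trace = trace, class_weights = cw,
                 train_folds = train_folds,
                 dataset_name = dataset$manifest$name,
                 config = config, call = match.call()),
            class = "profile_net")
}

as_params <- function(x) {
  if (inherits(x, "profile_net")) x$params
  else if (inherits(x, "profile_net_params")) x
  else stop("expected a profile_net or profile_net_params object")
}

#' @export
print.profile_net <- function(x, ...) {
  cfg <- x$params$config
  cat(sprintf("<profile_net> N = %d neighbors, trained %d epoch(s) on %s\n",
              cfg$N, nrow(x$trace), x$dataset_name))
  cat(sprintf("  subnets: prob %s -> 20, weight %s -> 1 (%s), head %s -> 20\n",
              paste(cfg$hidden_prob, collapse = "/"),
              paste(cfg$hidden_weight, collapse = "/"),
              cfg$weight_activation,
              paste(cfg$hidden_head, collapse = "/")))
  last <- x$trace[nrow(x$trace), ]
  cat(sprintf("  final training loss %.4f, accuracy %.3f\n",
              last$loss, last$accuracy))
  invisible(x)
}

#' @export
summary.profile_net <- function(object, ...) {
  n_par <- sum(rapply(object$params[c("prob", "wt", "head")], length,
                      how = "unlist"))
  out <- list(n_parameters = n_par, trace = object$trace,
              class_weights = object$class_weights,
              config = object$config)
  class(out) <- "summary.profile_net"
  out
}

#' @export
print.summary.profile_net <- function(x, ...) {
  cat(sprintf("Residue-profile network: %d trainable parameters\n",
              x$n_parameters))
  last <- x$trace[nrow(x$trace), ]
  cat(sprintf("Final epoch %d: loss %.4f, training accuracy %.3f\n",
              last$epoch, last$loss, last$accuracy))
  nz <- x$class_weights[x$class_weights > 0]
  cat("Class weights (W_i = N_max/N_i): ",
      paste(sprintf("%s %.2f", names(nz), nz), collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.profile_net <- function(object, ...) object$params

#' @export
plot.profile_net <- function(x, ...) {
  graphics::par(mfrow = c(1L, 2L))
  on.exit(graphics::par(mfrow = c(1L, 1L)))
  graphics::plot(x$trace$epoch, x$trace$loss, type = "l",
                 xlab = "epoch", ylab = "weighted cross entropy", ...)
  graphics::plot(x$trace$epoch, x$trace$accuracy, type = "l",
                 xlab = "epoch", ylab = "training accuracy", ...)
  invisible(x)
}

#' Predict residue-type probabilities
#'
#' @param object A fitted `profile_net`.
#' @param newdata A `cluster_dataset`, an n x N x 31 feature array, a single
#'   N x 31 cluster matrix, or a `protein_structure` (which routes through
#'   [predict_profile()]).
#' @param ... Unused.
#' @return An n x 20 probability matrix (or a `prediction_profile` for
#'   structure input).
#' @export
predict.profile_net <- function(object, newdata, ...) {
  if (inherits(newdata, "protein_structure"))
    return(predict_profile(newdata, object))
  if (inherits(newdata, "cluster_dataset")) {
    if (newdata$manifest$N != object$params$config$N)
      stop(sprintf("N mismatch: dataset has %d neighbors, model expects %d",
                   newdata$manifest$N, object$params$config$N))
    newdata <- newdata$features
  }
  forward_full(newdata, object$params)
}
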