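# local: top-1 letters from a prediction profile
predicted_top1 <- function(prof) {
  P <- as.matrix(prof[, aa_alphabet()])
  aa_alphabet()[max.col(P, ties.method = "first")]
}

make_params <- function(N = 3L, seed = 1L, ...)
  init_profile_params(N, hidden_prob = c(16L, 16L),
                      hidden_weight = c(8L, 8L), hidden_head = c(32L, 32L),
                      seed = seed, ...)

zero_params <- function(params) {
  for (comp in c("prob", "wt", "head"))
    params[[comp]] <- lapply(params[[comp]], function(l)
      list(W = l$W * 0, b = l$b * 0))
  params
}

test_that("probability subnet outputs live on the 20-simplex", {
  p <- make_params()
  set.seed(2)
  X <- matrix(rnorm(10 * 31), 10, 31)
  P <- forward_prob_subnet(X, p)
  expect_true(all(P >= 0))
  expect_equal(rowSums(P), rep(1, 10), tolerance = 1e-6)
  # zero parameters give the uniform distribution
  expect_equal(unname(forward_prob_subnet(X[1, ], zero_params(p))),
               rep(0.05, 20))
  # determinism
  expect_identical(forward_prob_subnet(X, p), forward_prob_subnet(X, p))
  expect_error(forward_prob_subnet(X[, 1:30], p), "shape error")
})

test_that("weight subnet is a shared scalar map", {
  p <- make_params(weight_activation = "linear")
  expect_equal(forward_weight_subnet(rnorm(31), zero_params(p)), 0)
  set.seed(3)
  x <- rnorm(31)
  # parameter sharing: identical pairs get identical weights
  w2 <- forward_weight_subnet(rbind(x, x), p)
  expect_identical(w2[1], w2[2])
  y <- rnorm(31)
  expect_false(forward_weight_subnet(x, p) == forward_weight_subnet(y, p))
  # default softplus keeps weights nonnegative
  ps <- make_params()
  set.seed(4)
  W <- forward_weight_subnet(matrix(rnorm(50 * 31), 50), ps)
  expect_true(all(W >= 0))
})

test_that("full network output is an ordered weighted concatenation", {
  p <- make_params(N = 3L)
  set.seed(5)
  cl <- matrix(rnorm(3 * 31), 3, 31)
  q <- forward_full(cl, p)
  expect_equal(sum(q), 1, tolerance = 1e-6)
  expect_true(all(q >= 0))
  # neighbor order matters: permuting rows changes the output
  expect_false(isTRUE(all.equal(q, forward_full(cl[c(2, 1, 3), ], p))))
  expect_error(forward_full(cl[1:2, ], p), "shape error")
})

test_that("N = 1 full network equals brute-force composition of the sub-maps", {
  p <- make_params(N = 1L, seed = 7L)
  set.seed(8)
  x <- rnorm(31)
  full <- forward_full(matrix(x, 1, 31), p)

  # oracle: hand-rolled forward pass with explicit loops/matrix products
  relu_o <- function(z) pmax(z, 0)
  mlp_o <- function(v, layers) {
    for (l in seq_along(layers)) {
      v <- as.numeric(v %*% layers[[l]]$W) + layers[[l]]$b
      if (l < length(layers)) v <- relu_o(v)
    }
    v
  }
  softmax_o <- function(z) exp(z - max(z)) / sum(exp(z - max(z)))
  xs <- (x - p$center) / p$scale
  prob <- softmax_o(mlp_o(xs, p$prob))
  wt <- log1p(exp(mlp_o(xs, p$wt)))
  head_in <- wt * prob
  oracle <- softmax_o(mlp_o(head_in, p$head))
  expect_equal(unname(full), oracle, tolerance = 1e-9)
})

test_that("uniform predictions give cross entropy ln 20", {
  P <- matrix(1 / 20, 50, 20)
  labels <- sample(0:19, 50, replace = TRUE)
  expect_equal(cross_entropy(P, labels), log(20), tolerance = 1e-9)
  # weighted version is a weighted mean, equal here by symmetry
  expect_equal(cross_entropy(P, labels, runif(50, 1, 3)), log(20),
               tolerance = 1e-9)
})

test_that("training reduces the loss on a learnable task", {
  ds <- fix_learnable()
  fit <- fit_profile_net(
    ds, train_folds = 1:4,
    config = train_config(batch_size = 256L, epochs = 30L, seed = 0L))
  tr <- fit$trace
  expect_lt(mean(tail(tr$loss, 10)), mean(head(tr$loss, 10)))
  expect_gt(tr$accuracy[nrow(tr)], 0.95)
  # held-out fold
  ho <- which(ds$manifest$folds == 5L)
  Q <- predict(fit, ds$features[ho, , , drop = FALSE])
  expect_equal(rowSums(Q), rep(1, length(ho)), tolerance = 1e-6)
  acc <- mean(max.col(Q, ties.method = "first") == ds$labels[ho] + 1L)
  expect_gt(acc, 0.9)
  # beats the majority-class baseline by a wide margin
  base <- max(table(ds$labels[ho])) / length(ho)
  expect_gt(acc, base + 0.3)
})

test_that("training is deterministic for a fixed seed and aborts on bad folds", {
  ds <- fix_learnable()
  cfg <- train_config(batch_size = 128L, epochs = 3L, seed = 9L)
  f1 <- fit_profile_net(ds, config = cfg)
  f2 <- fit_profile_net(ds, config = cfg)
  expect_identical(f1$params$head, f2$params$head)
  expect_identical(f1$trace, f2$trace)
  expect_error(fit_profile_net(ds, train_folds = 99L), "empty training fold")
})

test_that("whole-structure prediction yields one simplex row per residue", {
  ds <- fix_learnable()
  fit <- fit_profile_net(
    ds, config = train_config(batch_size = 256L, epochs = 10L, seed = 0L))
  s <- build_ideal_helix(9)
  prof <- predict_profile(s, fit)
  expect_s3_class(prof, "prediction_profile")
  expect_equal(nrow(prof), 9L)
  expect_true(all(prof$eligible))   # termini included, sentinel encoding
  P <- as.matrix(prof[, aa_alphabet()])
  expect_equal(rowSums(P), rep(1, 9), tolerance = 1e-6)
  expect_identical(prof, predict_profile(s, fit))
  expect_error(predict_profile(s, fit, N = 7), "N mismatch")
  # helix-trained model recovers the helix label (Ala) away from termini
  expect_equal(unique(predicted_top1(prof)[3:7]), "A")
})
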