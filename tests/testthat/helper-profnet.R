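# Shared fixtures and independent mini-oracles for the test suite.
# Heavier fixtures are memoized so several test files can share one build.

.memo <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.memo[[key]])) .memo[[key]] <- force(expr)
  .memo[[key]]
}

fix_helix <- function(n = 12L) memo(paste0("helix", n), build_ideal_helix(n))

fix_sheet <- function() memo("sheet8", build_ideal_sheet(8L))

fix_learnable <- function() memo(
  "learn300", learnable_dataset(300L, N = 5L, seed = 11L))

# Random rows on the 20-simplex (independent of package code).
random_simplex_rows <- function(n, seed) {
  set.seed(seed)
  g <- matrix(stats::rgamma(n * 20L, shape = 0.5), n, 20L)
  P <- g / rowSums(g)
  colnames(P) <- aa_alphabet()
  P
}

# Independent uniform random rotation (Gram-Schmidt on Gaussian vectors,
# deliberately a different construction from the package's).
indep_rotation <- function() {
  repeat {
    A <- matrix(stats::rnorm(9), 3, 3)
    q <- qr(A)
    R <- qr.Q(q)
    R <- R %*% diag(sign(diag(qr.R(q))))
    if (det(R) < 0) R[, 3] <- -R[, 3]
    if (abs(det(R) - 1) < 1e-9) return(R)
  }
}

# A wiggly single-chain loop structure with seeded dihedrals.
fix_random_coil <- function(n = 14L, seed = 5L) {
  memo(paste0("coil", n, "_", seed), {
    set.seed(seed)
    build_ideal_backbone(stats::runif(n, -150, 150),
                         stats::runif(n, -150, 150),
                         rep(180, n))
  })
}
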