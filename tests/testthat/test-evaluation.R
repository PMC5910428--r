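AA <- aa_alphabet()

test_that("overall accuracy counts top-1 argmax matches", {
  P <- random_simplex_rows(10, seed = 1)
  nat <- AA[max.col(P, ties.method = "first")]
  expect_equal(overall_accuracy(P, nat), 1.0)
  # force exactly 4 of 10 correct
  nat2 <- nat
  wrong <- AA[ifelse(match(nat[1:6], AA) == 1L, 2L, 1L)]
  nat2[1:6] <- wrong
  expect_equal(overall_accuracy(P, nat2), 0.4)
  # uniform rows: the alphabetical tie rule predicts Ala everywhere
  U <- matrix(1 / 20, 8, 20)
  nat3 <- c("A", "A", "C", "D", "E", "F", "G", "H")
  expect_equal(overall_accuracy(U, nat3), 0.25)
  expect_error(overall_accuracy(P[0, , drop = FALSE], character(0)))
})

test_that("top-K accuracy matches brute-force membership and is monotone", {
  P <- random_simplex_rows(25, seed = 2)
  nat <- sample(AA, 25, replace = TRUE)
  # brute force: sort each row, take the K best letters
  brute <- function(K) {
    mean(vapply(seq_len(nrow(P)), function(i) {
      top <- AA[order(-P[i, ])][1:K]
      nat[i] %in% top
    }, logical(1)))
  }
  for (K in c(1, 3, 5, 10, 20))
    expect_equal(top_k_accuracy(P, K, nat), brute(K))
  accs <- vapply(1:20, function(K) top_k_accuracy(P, K, nat), numeric(1))
  expect_true(all(diff(accs) >= 0))
  expect_equal(accs[20], 1.0)
  expect_equal(accs[1], overall_accuracy(P, nat))
  expect_error(top_k_accuracy(P, 0, nat), "1..20")
  expect_error(top_k_accuracy(P, 21, nat), "1..20")
})

test_that("recall and precision follow the hand-counted example", {
  # natives: A x4 (predicted A,A,A,G), G x1 (predicted A)
  P <- matrix(0, 5, 20, dimnames = list(NULL, AA))
  P[1, "A"] <- 1; P[2, "A"] <- 1; P[3, "A"] <- 1; P[4, "G"] <- 1
  P[5, "A"] <- 1
  nat <- c("A", "A", "A", "A", "G")
  rp <- recall_precision(P, nat)
  expect_equal(rp$recall[rp$aa == "A"], 0.75)
  expect_equal(rp$precision[rp$aa == "A"], 0.75)
  expect_equal(rp$recall[rp$aa == "G"], 0)
  expect_equal(rp$precision[rp$aa == "G"], 0)  # one G prediction, wrong
  # class never seen nor predicted: both missing (NA), not zero
  expect_true(is.na(rp$recall[rp$aa == "W"]))
  expect_true(is.na(rp$precision[rp$aa == "W"]))
  # perfect predictions give recall = precision = 1 on present classes
  rp2 <- recall_precision(diag(20)[1:5, ], AA[1:5])
  expect_equal(rp2$recall[1:5], rep(1, 5))
  expect_equal(rp2$precision[1:5], rep(1, 5))
})

test_that("micro-averaged recall equals overall accuracy", {
  P <- random_simplex_rows(40, seed = 3)
  nat <- sample(AA, 40, replace = TRUE)
  rp <- recall_precision(P, nat)
  micro <- sum(rp$recall * rp$support, na.rm = TRUE) / sum(rp$support)
  expect_equal(micro, overall_accuracy(P, nat), tolerance = 1e-12)
})

test_that("confusion probability matrix is row-normalized counts", {
  P <- matrix(0, 5, 20, dimnames = list(NULL, AA))
  P[1, "A"] <- 1; P[2, "A"] <- 1; P[3, "A"] <- 1; P[4, "G"] <- 1
  P[5, "A"] <- 1
  M <- confusion_probability_matrix(P, c("A", "A", "A", "A", "G"))
  expect_equal(M["A", "A"], 0.75)
  expect_equal(M["A", "G"], 0.25)
  expect_equal(M["G", "A"], 1)
  expect_true(all(is.na(M["W", ])))
  present <- rowSums(!is.na(M)) > 0
  expect_equal(unname(rowSums(M[present, ])), rep(1, sum(present)),
               tolerance = 1e-9)
})

test_that("sequence identity is the position-wise match fraction", {
  expect_equal(sequence_identity("ACDE", "ACDE"), 1.0)
  expect_equal(sequence_identity("ACDE", "ACDG"), 0.75)
  expect_error(sequence_identity("", ""), "empty")
  expect_error(sequence_identity("ACD", "AC"), "mismatch")
})

test_that("profile RMSE follows the direct formula and is symmetric", {
  A <- random_simplex_rows(6, seed = 4)
  expect_equal(profile_rmse(A, A), 0)
  a <- matrix(0, 1, 20); a[1] <- 1
  b <- matrix(0, 1, 20); b[2] <- 1
  expect_equal(profile_rmse(a, b), sqrt(2 / 20))
  B <- random_simplex_rows(6, seed = 5)
  expect_equal(profile_rmse(A, B), profile_rmse(B, A))
  expect_error(profile_rmse(A, B[1:3, ]), "mismatch")
})

test_that("contact-rank coverage counts contacts within the rank cutoff", {
  # compact helix: all contacts are among the closest neighbors
  s <- fix_helix()
  cov_all <- contact_rank_coverage(s, rank_n = 11)
  expect_equal(cov_all, 1.0)
  covs <- vapply(c(2, 4, 6, 11), function(k)
    contact_rank_coverage(s, k), numeric(1))
  expect_true(all(diff(covs) >= 0))
  # constructed case: one far contact ranked beyond the cutoff.
  # chain B's residue sits close in heavy-atom distance to A's residue 1
  # but several CA-ranks away.
  a <- build_ideal_strand(6, chain = "A")
  cov5 <- contact_rank_coverage(a, 5)
  expect_equal(cov5, 1.0)  # sequential contacts only, all rank <= 2
  expect_true(is.na(contact_rank_coverage(
    combine_structures(list(
      build_ideal_backbone(rep(60, 2), rep(60, 2), rep(180, 2)))), 1,
    cutoff = 0.1)))
})

test_that("metrics report files carry the scalar and per-class tables", {
  P <- random_simplex_rows(15, seed = 6)
  nat <- AA[max.col(P, ties.method = "first")]
  prefix <- withr::local_tempfile()
  m <- write_metrics_report(structure(
    cbind(data.frame(chain = "A", seq_index = 1:15, icode = "",
                     native = nat, eligible = TRUE, reason = NA),
          as.data.frame(P)),
    class = c("prediction_profile", "data.frame")), prefix)
  expect_equal(m$overall_accuracy, 1.0)
  lines <- readLines(paste0(prefix, "_metrics.txt"))
  expect_true(any(grepl("^overall_accuracy\t", lines)))
  tab <- read.delim(paste0(prefix, "_per_class.tsv"))
  expect_equal(nrow(tab), 20L)
  expect_named(tab, c("aa", "recall", "precision", "support", "predicted"))
})
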