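test_that("a 16-residue chain with N = 15 uses every other residue, sorted", {
  s <- fix_random_coil(16L, seed = 2L)
  cs <- extract_clusters(s, 15L)
  expect_length(cs$clusters, 16L)
  cl <- cs$clusters[[8]]
  expect_setequal(cl$neighbors, setdiff(1:16, 8))
  expect_false(8 %in% cl$neighbors)
  expect_true(all(diff(cl$distances) >= 0))
  expect_error(extract_clusters(s, 16L), "only 16 residues")
})

test_that("neighbor order equals a brute-force distance sort", {
  s <- fix_random_coil(14L, seed = 6L)
  cs <- extract_clusters(s, 6L)
  CA <- s$coords$CA
  for (cl in cs$clusters) {
    d <- sqrt(rowSums(sweep(CA, 2, CA[cl$target, ], "-")^2))
    d[cl$target] <- Inf
    expect_identical(cl$neighbors, order(d)[1:6])
  }
})

test_that("clusters touching occupancy < 1 or missing backbone are dropped", {
  s <- fix_random_coil(16L, seed = 2L)
  flawed <- set_occupancy(s, "A", 5L, atom = "CA", value = 0.5)
  cs <- extract_clusters(flawed, 15L)
  # residue 5 is in every cluster's neighborhood: everything is dropped
  expect_length(cs$clusters, 0L)
  expect_true(all(cs$dropped$reason == "occupancy"))
  # with a small N only nearby targets lose their cluster
  cs2 <- extract_clusters(flawed, 3L)
  expect_false(5L %in% vapply(cs2$clusters, `[[`, 1L, "target"))
  expect_true(all(c("occupancy") %in% cs2$dropped$reason))
  # missing backbone: drop an O atom via the PDB route
  txt <- make_toy_pdb(s)
  txt <- txt[!grepl("^ATOM.{8} O   ALA A   9", txt)]
  broken <- parse_structure(txt)
  cs3 <- extract_clusters(broken, 3L)
  expect_false(9L %in% vapply(cs3$clusters, `[[`, 1L, "target"))
  expect_true("missing_backbone" %in% cs3$dropped$reason)
  # audit identity: clusters + dropped = attempted targets
  expect_equal(length(cs3$clusters) + nrow(cs3$dropped), 16L)
})

test_that("class weights follow W_i = N_max / N_i", {
  w <- class_weights(c(A = 100, G = 50))
  expect_equal(unname(w[c("A", "G")]), c(1, 2))
  expect_true(all(w[setdiff(names(w), c("A", "G"))] == 0))
  w2 <- class_weights(stats::setNames(rep(7, 20), aa_alphabet()))
  expect_equal(unname(w2), rep(1, 20))
  w3 <- class_weights(c(A = 7, C = 3, D = 2))
  expect_equal(unname(w3[c("A", "C", "D")]), c(1, 7 / 3, 3.5))
  # scale invariance
  expect_equal(class_weights(c(A = 70, C = 30, D = 20)), w3)
  expect_error(class_weights(c(A = 0)), "zero")
})

test_that("k-fold assignment is balanced and deterministic", {
  f <- kfold_split(10L, k = 5L, seed = 4L)
  expect_equal(sort(unique(f)), 1:5)
  expect_true(all(table(f) == 2L))
  expect_identical(f, kfold_split(10L, k = 5L, seed = 4L))
  expect_false(identical(f, kfold_split(10L, k = 5L, seed = 5L)))
  f11 <- kfold_split(11L, k = 5L, seed = 0L)
  expect_equal(sort(as.integer(table(f11))), c(2L, 2L, 2L, 2L, 3L))
  expect_error(kfold_split(4L, k = 5L), "cannot split")
})

test_that("dataset archives round-trip bit-exactly and validate on load", {
  s <- fix_random_coil(12L, seed = 3L)
  ds <- build_dataset(extract_clusters(s, 5L), name = "toy", seed = 1L)
  path <- withr::local_tempfile(fileext = ".rds")
  save_dataset(ds, path)
  back <- load_dataset(path)
  expect_identical(back$features, ds$features)
  expect_identical(back$manifest, ds$manifest)
  expect_identical(back$labels, ds$labels)
  # declared-N tamper is caught
  bad <- ds; bad$manifest$N <- 7L
  saveRDS(bad, path)
  expect_error(load_dataset(path), "consistency error")
  # missing labels is a schema error
  bad2 <- ds; bad2$labels <- NULL
  saveRDS(bad2, path)
  expect_error(load_dataset(path), "schema error")
  writeLines("not an archive", path)
  expect_error(load_dataset(path), "corrupted|schema")
})
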