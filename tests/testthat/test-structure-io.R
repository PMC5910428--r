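test_that("toy PDB text parses into backbone-complete residues and round-trips", {
  s <- build_ideal_backbone(c(0, -60, -70), c(140, -40, 150), rep(180, 3),
                            aa = c("A", "G", "V"))
  txt <- make_toy_pdb(s)
  p <- parse_structure(txt)
  expect_equal(nrow(p$residues), 3L)
  expect_true(all(p$residues$complete))
  expect_equal(p$residues$aa, c("A", "G", "V"))
  # serialize -> parse -> serialize is idempotent
  expect_identical(make_toy_pdb(p), txt)
  # backbone coordinates survive to PDB precision
  expect_equal(p$coords$CA, s$coords$CA, tolerance = 1e-3,
               ignore_attr = TRUE)
})

test_that("water, ion and ligand HETATM records are removed", {
  txt <- make_toy_pdb(fix_helix())
  het <- c(
    "HETATM  900  O   HOH A 201      10.000  10.000  10.000  1.00  0.00           O",
    "HETATM  901 ZN    ZN A 202       5.000   5.000   5.000  1.00  0.00          ZN",
    "HETATM  902  C1  GOL A 203       8.000   1.000   2.000  1.00  0.00           C")
  p <- parse_structure(c(txt[-length(txt)], het, "END"))
  expect_equal(nrow(p$residues), 12L)
  expect_false(any(p$residues$resname %in% c("HOH", "ZN", "GOL")))
})

test_that("malformed ATOM records raise a parse error naming the line", {
  txt <- make_toy_pdb(fix_helix())
  txt[3] <- substr(txt[3], 1, 10)
  expect_error(parse_structure(txt), "line 3")
  expect_error(parse_structure("REMARK only"), "empty structure")
})

test_that("altloc atoms resolve to blank/'A' or highest occupancy", {
  base <- make_toy_pdb(build_ideal_helix(3))
  # duplicate residue 2's N with altlocs B (occ 0.4) and A (occ 0.6)
  idx <- grep("^ATOM.{8} N   ALA A   2", base)
  a <- base[idx]; substr(a, 17, 17) <- "A"; substr(a, 55, 60) <- "  0.60"
  b <- base[idx]; substr(b, 17, 17) <- "B"; substr(b, 55, 60) <- "  0.40"
  txt <- append(base[-idx], c(b, a), after = idx - 1L)
  p <- parse_structure(txt)
  expect_equal(sum(p$atoms$seq_index == 2 & p$atoms$atom == "N"), 1L)
  expect_equal(p$atoms$altloc[p$atoms$seq_index == 2 & p$atoms$atom == "N"],
               "A")
})

test_that("structure filter applies the curation rules in order", {
  meta <- list(pdb_id = "1ABC", method = "x-ray", resolution = 1.8,
               has_nucleic = FALSE, has_d_amino = FALSE,
               chains = c(A = 120L), chain_sequences = c(A = ""))
  expect_true(filter_structure(meta)$keep)

  m2 <- meta; m2$resolution <- 2.3
  expect_equal(filter_structure(m2)$reason, "resolution")
  m3 <- meta; m3$has_nucleic <- TRUE
  expect_equal(filter_structure(m3)$reason, "nucleic")
  m4 <- meta; m4$method <- "solution nmr"
  expect_equal(filter_structure(m4)$reason, "method")
  m5 <- meta; m5$chains <- c(A = 50L)
  expect_equal(filter_structure(m5)$reason, "length")
  m6 <- meta; m6$has_d_amino <- TRUE
  expect_equal(filter_structure(m6)$reason, "d_amino")
  m7 <- meta; m7$resolution <- NA_real_
  expect_equal(filter_structure(m7)$reason, "resolution_missing")

  # purity: identical inputs give identical decisions
  expect_identical(filter_structure(meta), filter_structure(meta))
  # fixture files without metadata flow through unless metadata is required
  fx <- fix_helix()$meta; fx$chains <- c(A = 120L)
  expect_true(filter_structure(fx)$keep)
  expect_false(filter_structure(fx, filter_config(require_metadata = TRUE))$keep)
})

test_that("duplicate subunits collapse to the first chain", {
  expect_equal(deduplicate_chains(c(A = "ACDEFG", B = "ACDEFG")), "A")
  expect_equal(deduplicate_chains(c(A = "ACDEFG", B = "ACDEFW")),
               c("A", "B"))
  expect_equal(deduplicate_chains(c(C = "MKV", A = "MKV", B = "MKV")), "A")
  skip_if_not_installed("Biostrings")
  # near-identical chains merge under a relaxed threshold
  expect_equal(
    deduplicate_chains(c(A = "ACDEFGHIKL", B = "ACDEFGHIKV"),
                       identity_threshold = 0.9), "A")
})
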