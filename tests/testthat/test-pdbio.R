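test_that("a minimal one-atom record parses to a one-atom model", {
  line <- "ATOM      1  CA  ALA A   1      10.000  20.000  30.000  1.00 10.00           C"
  m <- parse_pdb(line)
  expect_equal(nrow(m$atoms), 1)
  expect_length(m$seqres, 0)
  expect_equal(m$atoms$chain, "A")
  expect_equal(m$atoms$x, 10)
})

test_that("parsing rejects text without coordinate records", {
  expect_error(parse_pdb("REMARK   2 RESOLUTION. 2.00 ANGSTROMS."),
               "empty structure")
})

test_that("multi-model entries keep model 1 only; SEQRES keeps all chains", {
  txt <- fixture_entry("9MOD", list(
    list(label = "L", seq = fixture_sequence("L"), role = "L"),
    list(label = "H", seq = fixture_sequence("H"), role = "H")),
    models = 2)
  m <- parse_pdb(txt)
  expect_setequal(names(m$seqres), c("L", "H"))
  # single copy of each chain's atoms
  n_ca_l <- sum(m$atoms$chain == "L" & m$atoms$name == "CA")
  expect_equal(n_ca_l, nchar(fixture_sequence("L")))
})

test_that("ATOM-derived sequences map residues and skip gaps and waters", {
  hdr <- function(i, res, resno, ch = "A", rec = "ATOM  ") {
    sprintf("%-6s%5d  CA  %3s %1s%4d    %8.3f%8.3f%8.3f  1.00 10.00           C",
            rec, i, res, ch, resno, i * 5, 0, 0)
  }
  txt <- c(hdr(1, "ALA", 1), hdr(2, "GLY", 2), hdr(3, "CYS", 3))
  expect_equal(as.character(sequence_from_atoms(parse_pdb(txt), "A")), "AGC")

  # a numbering gap (missing loop) yields no gap characters
  txt2 <- c(hdr(1, "ALA", 1), hdr(2, "GLY", 2), hdr(3, "CYS", 10))
  expect_equal(as.character(sequence_from_atoms(parse_pdb(txt2), "A")),
               "AGC")

  # selenomethionine deposited as HETATM is part of the polymer
  txt3 <- c(hdr(1, "ALA", 1), hdr(2, "MSE", 2, rec = "HETATM"),
            hdr(3, "CYS", 3), hdr(4, "HOH", 90, rec = "HETATM"))
  expect_equal(as.character(sequence_from_atoms(parse_pdb(txt3), "A")),
               "AMC")
})

test_that("alternate locations reduce to the highest-occupancy conformer", {
  txt <- c(
    "ATOM      1  CA AALA A   1      10.000   0.000   0.000  0.40 10.00           C",
    "ATOM      2  CA BALA A   1      11.000   0.000   0.000  0.60 10.00           C",
    "ATOM      3  CA  GLY A   2      15.000   0.000   0.000  1.00 10.00           C")
  m <- parse_pdb(txt)
  expect_equal(sum(m$atoms$resno == 1), 1)  # residue count unchanged
  expect_equal(m$atoms$x[m$atoms$resno == 1], 11)  # occ 0.6 wins
  # tie goes to the first record in the file
  txt2 <- sub("0.40", "0.60", txt, fixed = TRUE)
  m2 <- parse_pdb(txt2)
  expect_equal(m2$atoms$x[m2$atoms$resno == 1], 10)
})

test_that("CONECT pairs referencing unknown serials are dropped with warning", {
  txt <- c(
    "HETATM    1  C1  HPT A 501      10.000   0.000   0.000  1.00 10.00           C",
    "ATOM      2  CA  ALA A   1      12.000   0.000   0.000  1.00 10.00           C",
    "CONECT    1    2",
    "CONECT    1   99")
  expect_warning(m <- parse_pdb(txt), "CONECT")
  expect_equal(nrow(m$conect), 1)
  expect_equal(m$conect[1, ], c(1L, 2L))
})

test_that("symmetry expansion preserves geometry exactly", {
  m <- corpus_model("9LDM")
  expect_length(m$transforms, 2)  # identity + C2
  m2 <- expand_symmetry(m)
  copies <- attr(m2, "symmetry_copies")
  expect_length(copies, 1)
  new_ch <- names(copies)[1]
  a0 <- m$atoms[m$atoms$chain == "A", ]
  a1 <- m2$atoms[m2$atoms$chain == new_ch, ]
  expect_equal(nrow(a1), nrow(a0))
  # identity copy preserved bit-for-bit
  expect_identical(m2$atoms[m2$atoms$chain == "A", ], a0)
  # applying the inverse transform recovers the original coordinates
  tr <- Filter(function(t) !abfv:::is_identity_transform(t),
               m$transforms)[[1]]
  xyz <- as.matrix(a1[, c("x", "y", "z")])
  back <- sweep(xyz, 2, tr$trans, "-") %*% tr$rot  # R^-1 = t(R)
  expect_lt(max(abs(back - as.matrix(a0[, c("x", "y", "z")]))), 1e-6)
  # two-fold: applying the transform twice returns the original
  fwd2 <- sweep(as.matrix(a1[, c("x", "y", "z")]) %*% t(tr$rot), 2,
                tr$trans, "+")
  expect_lt(max(abs(fwd2 - as.matrix(a0[, c("x", "y", "z")]))), 1e-6)
  # intra-chain pairwise distances preserved
  idx <- seq(1, nrow(a0), by = 37)
  d0 <- dist(a0[idx, c("x", "y", "z")])
  d1 <- dist(a1[idx, c("x", "y", "z")])
  expect_lt(max(abs(d0 - d1)), 1e-6)
})

test_that("expansion without transforms returns the model unchanged", {
  m <- corpus_model("9FRE")
  expect_identical(expand_symmetry(m)$atoms, m$atoms)
})

test_that("written Fv files round-trip and are byte-stable", {
  res <- process_entry(corpus_model("9HAP"), "9HAP")
  s <- res$sets[[1]]
  t1 <- write_fv_file(s, "kabat")
  t2 <- write_fv_file(s, "kabat")
  expect_identical(t1, t2)
  expect_true(any(grepl("^REMARK 950 SCHEME Kabat$", t1)))
  # hapten originally on chain H is written as chain h, mapping recorded
  expect_true(any(grepl("^REMARK 950 CHAIN h H$", t1)))
  m2 <- parse_pdb(t1)
  n_written <- sum(grepl("^(ATOM|HETATM)", t1))
  expect_equal(nrow(m2$atoms), n_written)
  expect_setequal(unique(m2$atoms$chain), c("L", "H", "h"))
  # free antibody: no antigen annotation lines
  free <- write_fv_file(process_entry(corpus_model("9FRE"),
                                      "9FRE")$sets[[1]], "martin")
  expect_false(any(grepl("AGNAME|CHAIN [a-z]", free)))
})

test_that("blank chain labels are mapped to an addressable sentinel", {
  txt <- "ATOM      1  CA  ALA     1      10.000   0.000   0.000  1.00 10.00           C"
  m <- parse_pdb(txt)
  expect_equal(m$atoms$chain, "0")
})
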