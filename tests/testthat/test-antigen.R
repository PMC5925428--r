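params <- pipeline_params()

ab_numbered <- function(res) res$sets[[1]]$numbered$kabat

test_that("framework binders are not antigens and the antibody stays free", {
  m <- corpus_model("9DEE")
  res <- process_entry(m, "9DEE")
  expect_equal(res$sets[[1]]$complex_class, "free")
  expect_true("S" %in% res$binding_proteins)
  cls <- classify_polymer_antigen(m, ab_numbered(res), "S", params)
  expect_equal(as.character(cls), "antibody_binding_protein")
  prof <- attr(cls, "profile")
  expect_equal(unname(prof["cdr"]), 2L)
  expect_equal(unname(prof["framework"]), 30L)
})

test_that("CDR-dominant chains classify as antigen", {
  m <- corpus_model("9PRC")
  res <- process_entry(m, "9PRC")
  cls <- classify_polymer_antigen(m, ab_numbered(res), "A", params)
  expect_equal(as.character(cls), "antigen")
  prof <- attr(cls, "profile")
  expect_equal(unname(prof["cdr"]), 20L)
  expect_equal(unname(prof["framework"]), 3L)
  # raising the CDR minimum above the count is monotone: antigen set shrinks
  strict <- pipeline_params(min_cdr_contacts = 21)
  expect_equal(as.character(
    classify_polymer_antigen(m, ab_numbered(res), "A", strict)),
    "antibody_binding_protein")
})

test_that("an antigen spanning two chains is captured by the summed rule", {
  sl <- fixture_sequence("L"); sh <- fixture_sequence("H")
  ag <- abfv:::fixture_protein_seq(50, 77)
  txt <- fixture_entry("9GP2", list(
    list(label = "L", seq = sl, role = "L"),
    list(label = "H", seq = sh, role = "H"),
    list(label = "A", seq = ag, role = "AG"),
    list(label = "B", seq = ag, role = "AG")),
    interfaces = list(
      list(a = "L", b = "H", n = 40, side_a = "fw", side_b = "fw"),
      list(a = "H", b = "A", n = 10, side_a = "cdr", side_b = "any"),
      list(a = "H", b = "B", n = 10, side_a = "cdr", side_b = "any")))
  res <- process_entry(parse_pdb(txt), "9GP2")
  expect_length(res$sets, 1)
  expect_setequal(unlist(res$sets[[1]]$ag_chains), c("A", "B"))
  expect_equal(res$sets[[1]]$complex_class, "protein")
})

test_that("haptens bind through CDR contacts unless covalently linked", {
  m <- corpus_model("9HAP")
  res <- process_entry(m, "9HAP")
  expect_equal(res$sets[[1]]$complex_class, "non_protein")
  grp <- het_groups(m)[[1]]
  out <- classify_het_antigen(m, ab_numbered(res), grp, params)
  expect_equal(as.character(out), "antigen")

  mc <- corpus_model("9HCV")
  resc <- process_entry(mc, "9HCV")
  expect_equal(resc$sets[[1]]$complex_class, "free")
  grpc <- het_groups(mc)[[1]]
  outc <- classify_het_antigen(mc, resc$sets[[1]]$numbered$kabat, grpc,
                               params)
  expect_equal(as.character(outc), "none")
  expect_true(attr(outc, "covalent"))
})

test_that("a glycan contacting only framework is not an antigen", {
  txt <- fixture_hapten_complex("9GLY", side = "fw", n_contacts = 4)
  res <- process_entry(parse_pdb(txt), "9GLY")
  expect_equal(res$sets[[1]]$complex_class, "free")
})

test_that("anti-idiotype pairs become mutual antibody/antigen sets", {
  res <- process_entry(corpus_model("9DVF"), "9DVF")
  expect_length(res$sets, 2)
  expect_true(all(vapply(res$sets, `[[`, character(1),
                         "complex_class") == "protein"))
  expect_setequal(unlist(res$sets[[1]]$ag_chains), c("C", "D"))
  expect_setequal(unlist(res$sets[[2]]$ag_chains), c("A", "B"))
})

test_that("identical antibody copies stay free", {
  res <- process_entry(corpus_model("9FQR"), "9FQR")
  expect_length(res$sets, 12)
  expect_true(all(vapply(res$sets, `[[`, character(1),
                         "complex_class") == "free"))
})

test_that("different antibodies packed without CDR contact stay free", {
  sl1 <- fixture_sequence("L"); sh1 <- fixture_sequence("H")
  sl2 <- fixture_sequence("L", n_mut = 6, seed = 5)
  sh2 <- fixture_sequence("H", n_mut = 6, seed = 6)
  txt <- fixture_entry("9PKD", list(
    list(label = "A", seq = sl1, role = "L"),
    list(label = "B", seq = sh1, role = "H"),
    list(label = "C", seq = sl2, role = "L"),
    list(label = "D", seq = sh2, role = "H")),
    interfaces = list(
      list(a = "A", b = "B", n = 30, side_a = "fw", side_b = "fw"),
      list(a = "C", b = "D", n = 30, side_a = "fw", side_b = "fw"),
      # lattice packing: framework-framework only
      list(a = "B", b = "C", n = 12, side_a = "fw", side_b = "fw")))
  res <- process_entry(parse_pdb(txt), "9PKD")
  expect_length(res$sets, 2)
  expect_true(all(vapply(res$sets, `[[`, character(1),
                         "complex_class") == "free"))
})

test_that("classification is a pure function of the contact profile", {
  m <- corpus_model("9PRC")
  res <- process_entry(m, "9PRC")
  # permute atom order: same classification
  m2 <- m
  set.seed(3)
  m2$atoms <- m2$atoms[sample(nrow(m2$atoms)), ]
  c1 <- classify_polymer_antigen(m, ab_numbered(res), "A", params)
  c2 <- classify_polymer_antigen(m2, ab_numbered(res), "A", params)
  expect_equal(as.character(c1), as.character(c2))
  expect_equal(attr(c1, "profile"), attr(c2, "profile"))
})

test_that("complex classes finalize by antigen kind", {
  expect_equal(finalize_complex_class(character(0)), "free")
  expect_equal(finalize_complex_class("protein"), "protein")
  expect_equal(finalize_complex_class("nucleic"), "non_protein")
  expect_equal(finalize_complex_class("het"), "non_protein")
  expect_equal(finalize_complex_class(c("protein", "het")), "protein")
  res <- process_entry(corpus_model("9DNA"), "9DNA")
  expect_equal(res$sets[[1]]$complex_class, "non_protein")
})
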