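profile <- consensus_profile()

test_that("a chain equal to a consensus scores 100 against it", {
  expect_equal(unname(score_chain(profile$light, profile)["light"]), 100)
  expect_equal(unname(score_chain(profile$heavy, profile)["heavy"]), 100)
})

test_that("random sequences never approach the 80 percent threshold", {
  # 1000 random non-antibody sequences: in an entry with a genuine
  # antibody every one of these would be demoted, so none may reach the
  # threshold that protects a chain from demotion
  worst <- 0
  set.seed(42)
  for (s in 1:1000) {
    seq <- paste(sample(names(abfv:::.AA1TO3), 100, replace = TRUE),
                 collapse = "")
    worst <- max(worst, score_chain(seq, profile))
  }
  expect_lt(worst, 80)
  expect_lt(worst, 40)  # typically far below
})

test_that("a mutated heavy domain still scores heavier than light", {
  set.seed(7)
  chars <- strsplit(profile$heavy, "")[[1]]
  pos <- sample(length(chars), 10)
  for (p in pos) chars[p] <- sample(setdiff(names(abfv:::.AA1TO3),
                                            chars[p]), 1)
  sc <- score_chain(paste(chars, collapse = ""), profile)
  expect_gte(sc[["heavy"]], sc[["light"]])
  expect_gte(sc[["heavy"]], 80)
})

test_that("an antibody-antigen entry gets light, heavy and antigen calls", {
  m <- corpus_model("9PRC")
  calls <- assign_chain_types(m, profile)
  expect_equal(nrow(calls), 3)
  expect_equal(calls$final[calls$chain == "L"], "light")
  expect_equal(calls$final[calls$chain == "H"], "heavy")
  expect_equal(calls$final[calls$chain == "A"], "antigen")
  # the leader-bearing light chain is scored from SEQRES
  expect_equal(calls$source[calls$chain == "L"], "seqres")
})

test_that("identical light-chain copies tie and neither is demoted", {
  m <- corpus_model("9BJD")
  calls <- assign_chain_types(m, profile)
  expect_true(all(calls$final == "light"))
})

test_that("a high-scoring non-top light chain is not demoted", {
  sl1 <- fixture_sequence("L")
  sl2 <- fixture_sequence("L", n_mut = 12, seed = 3)  # still > 80%
  m <- parse_pdb(fixture_entry("9TWO", list(
    list(label = "A", seq = sl1, role = "L"),
    list(label = "B", seq = sl2, role = "L"))))
  calls <- assign_chain_types(m, profile)
  sc2 <- calls$light_score[calls$chain == "B"]
  expect_lt(sc2, 100)
  expect_gte(sc2, 80)
  expect_equal(calls$final[calls$chain == "B"], "light")
})

test_that("demotion is monotone in the chain's own score", {
  # the random antigen chain in 9PRC is demoted; an 85%-scoring chain in
  # the same entry would not be (threshold clause unmet)
  m <- corpus_model("9PRC")
  calls <- assign_chain_types(m, profile)
  ag <- calls[calls$chain == "A", ]
  expect_equal(ag$final, "antigen")
  expect_lt(max(ag$light_score, ag$heavy_score), 80)
})

test_that("forms classify as complete, light-only and heavy-only", {
  cases <- list(c("9PRC", "complete"), c("9BJD", "light_only"),
                c("9VHH", "heavy_only"))
  for (cs in cases) {
    m <- corpus_model(cs[1])
    fm <- classify_form(assign_chain_types(m, profile), m, profile)
    expect_equal(fm$form, cs[2])
    expect_equal(fm$reject_reason, "none")
  }
})

test_that("single light chain with symmetry partner is light-only", {
  m <- corpus_model("9LDM")
  fm <- classify_form(assign_chain_types(m, profile), m, profile)
  expect_equal(fm$form, "light_only")
})

test_that("fused single-label scFv chains are rejected as hybrids", {
  m <- corpus_model("9SCF")
  fm <- classify_form(assign_chain_types(m, profile), m, profile)
  expect_equal(fm$form, "rejected")
  expect_equal(fm$reject_reason, "scfv_hybrid")
})

test_that("entries without a variable domain are rejected as Fc-only", {
  m <- corpus_model("9FCO")
  fm <- classify_form(assign_chain_types(m, profile), m, profile)
  expect_equal(fm$form, "rejected")
  expect_equal(fm$reject_reason, "fc_only")
})

test_that("random non-antibody chains are never typed antibody at the 80% rule", {
  # random chains alongside a genuine antibody: the demotion rule must
  # push every one of them to antigen
  n_false <- 0
  for (s in 1:25) {
    set.seed(1000 + s)
    chains <- list(
      list(label = "L", seq = fixture_sequence("L"), role = "L"),
      list(label = "H", seq = fixture_sequence("H"), role = "H"))
    for (k in 1:5) {
      chains[[length(chains) + 1]] <- list(
        label = LETTERS[k], role = "AG",
        seq = paste(sample(names(abfv:::.AA1TO3), 90, replace = TRUE),
                    collapse = ""))
    }
    m <- parse_pdb(fixture_entry("9RND", chains))
    calls <- assign_chain_types(m, profile)
    rnd <- calls[!calls$chain %in% c("L", "H"), ]
    n_false <- n_false + sum(rnd$final != "antigen")
  }
  expect_equal(n_false, 0)
})
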