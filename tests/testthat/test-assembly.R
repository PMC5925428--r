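test_that("contact counts equal the brute-force all-pairs oracle", {
  set.seed(5)
  for (k in 1:20) {
    xa <- matrix(runif(3 * 30, 0, 12), ncol = 3)
    xb <- matrix(runif(3 * 30, 0, 12), ncol = 3)
    m <- toy_structure(list(A = xa, B = xb))
    expect_equal(count_contacts(m, "A", "B")$n_contacts,
                 oracle_contacts(xa, xb, 4.0))
  }
})

test_that("distant chains have zero contacts and counts are symmetric", {
  xa <- matrix(runif(30), ncol = 3)
  xb <- xa + 100
  m <- toy_structure(list(A = xa, B = xb))
  expect_equal(count_contacts(m, "A", "B")$n_contacts, 0L)
  xa2 <- matrix(runif(60, 0, 8), ncol = 3)
  xb2 <- matrix(runif(45, 0, 8), ncol = 3)
  m2 <- toy_structure(list(A = xa2, B = xb2))
  expect_equal(count_contacts(m2, "A", "B")$n_contacts,
               count_contacts(m2, "B", "A")$n_contacts)
})

test_that("the engineered anti-idiotype entry reproduces its contact matrix", {
  m <- corpus_model("9DVF")
  expect_equal(count_contacts(m, "A", "B")$n_contacts, 128L)
  expect_equal(count_contacts(m, "A", "D")$n_contacts, 20L)
  expect_equal(count_contacts(m, "C", "B")$n_contacts, 10L)
  expect_equal(count_contacts(m, "C", "D")$n_contacts, 117L)
  pairs <- pair_light_heavy(m, c("A", "C"), c("B", "D"))
  expect_equal(pairs$light, c("A", "C"))
  expect_equal(pairs$heavy, c("B", "D"))
})

test_that("greedy pairing ignores zero-contact pairs and reports leftovers", {
  # three translated copies: block-diagonal contact structure, three pairs
  m <- parse_pdb(fixture_free_antibody("9CP3", n_copies = 3))
  lights <- c("A", "C", "E"); heavies <- c("B", "D", "F")
  pairs <- pair_light_heavy(m, lights, heavies)
  expect_equal(nrow(pairs), 3)
  expect_equal(pairs$heavy[match(lights, pairs$light)], heavies)
  cm <- attr(pairs, "contact_matrix")
  expect_true(all(diag(cm[lights, heavies]) > 0))
  expect_true(all(cm[upper.tri(cm)] == 0 | row(cm)[upper.tri(cm)] == 0))
  # all-zero matrix is an error
  m0 <- toy_structure(list(A = matrix(0, 3, 3),
                           B = matrix(100, 3, 3)))
  expect_error(pair_light_heavy(m0, "A", "B"), "no physical pairing")
})

test_that("pairing is stable under chain-label permutation", {
  mk <- function(order) {
    sl1 <- fixture_sequence("L"); sh1 <- fixture_sequence("H")
    sl2 <- fixture_sequence("L", n_mut = 6, seed = 9)
    sh2 <- fixture_sequence("H", n_mut = 6, seed = 10)
    chains <- list(A = list(label = "A", seq = sl1, role = "L"),
                   B = list(label = "B", seq = sh1, role = "H"),
                   C = list(label = "C", seq = sl2, role = "L"),
                   D = list(label = "D", seq = sh2, role = "H"))
    ifaces <- list(list(a = "A", b = "B", n = 30, side_a = "fw",
                        side_b = "fw"),
                   list(a = "C", b = "D", n = 25, side_a = "fw",
                        side_b = "fw"))
    parse_pdb(fixture_entry("9PRM", chains[order], ifaces))
  }
  p1 <- pair_light_heavy(mk(c("A", "B", "C", "D")), c("A", "C"),
                         c("B", "D"))
  p2 <- pair_light_heavy(mk(c("D", "C", "B", "A")), c("A", "C"),
                         c("B", "D"))
  key <- function(p) sort(paste(p$light, p$heavy))
  expect_identical(key(p1), key(p2))
})

test_that("light-chain dimers pair through L36/L87 geometry", {
  m <- corpus_model("9BJD")
  res <- process_entry(m, "9BJD")
  expect_length(res$sets, 1)
  expect_setequal(unlist(res$sets[[1]]$ab_chains), c("A", "B"))

  # chains far apart do not pair
  sl <- fixture_sequence("L")
  m2 <- parse_pdb(fixture_entry("9FAR", list(
    list(label = "A", seq = sl, role = "L", origin = c(0, 0, 0)),
    list(label = "B", seq = sl, role = "L", origin = c(0, 50, 0)))))
  res2 <- process_entry(m2, "9FAR")
  expect_length(res2$sets, 2)  # two unpaired single-chain antibodies
  expect_true(all(vapply(res2$sets, function(s) length(s$ab_chains),
                         integer(1)) == 1))
})

test_that("a BIOMT-reconstructed light chain pairs with its generator", {
  res <- process_entry(corpus_model("9LDM"), "9LDM")
  expect_length(res$sets, 1)
  expect_equal(res$sets[[1]]$form, "light_only")
  expect_length(res$sets[[1]]$ab_chains, 2)
  expect_equal(res$sets[[1]]$ab_chains$L, "A")
})

test_that("entries split with shared antigens replicated", {
  res <- process_entry(corpus_model("9AFV"), "9AFV")
  expect_length(res$sets, 2)
  expect_equal(res$sets[[1]]$set_id, "9AFV_1")
  expect_setequal(unlist(res$sets[[1]]$ab_chains), c("L", "H"))
  expect_equal(unlist(res$sets[[1]]$ag_chains), c(A = "A"))
  expect_setequal(unlist(res$sets[[2]]$ab_chains), c("K", "M"))
  expect_equal(unlist(res$sets[[2]]$ag_chains), c(B = "B"))

  res3 <- process_entry(corpus_model("9ULU"), "9ULU")
  expect_length(res3$sets, 3)
  for (s in res3$sets) expect_equal(unlist(s$ag_chains), c(A = "A"))

  free <- process_entry(corpus_model("9FRE"), "9FRE")
  expect_length(free$sets, 1)
  expect_equal(free$sets[[1]]$complex_class, "free")
})
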