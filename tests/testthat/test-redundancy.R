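mkseq <- function(aa_by_label) {
  stats::setNames(as.character(aa_by_label), names(aa_by_label))
}

test_that("redundancy compares amino acids on shared labels only", {
  a <- mkseq(c(L24 = "R", L25 = "A", H95 = "D"))
  expect_true(redundant_pair(a, a))
  b <- a; b["L24"] <- "K"
  expect_false(redundant_pair(a, b))      # differs at L24
  c <- a[c("L25", "H95")]                 # L24 missing: ignored
  expect_true(redundant_pair(a, c))
  expect_false(redundant_pair(a, mkseq(c(H100 = "Y"))))  # nothing shared
})

test_that("clustering is the transitive closure of pairwise redundancy", {
  base <- stats::setNames(rep("A", 20), paste0("L", 1:20))
  a <- base
  b <- base[1:10]              # missing half: redundant with both a and c
  c <- base; c["L15"] <- "W"   # differs from a outside b's labels
  seqs <- list(S1_1 = a, S2_1 = b, S3_1 = c)
  expect_true(redundant_pair(a, b))
  expect_true(redundant_pair(b, c))
  expect_false(redundant_pair(a, c))
  cl <- cluster_redundant(seqs)
  expect_length(cl, 1)
  expect_equal(cl[[1]]$members, c("S1_1", "S2_1", "S3_1"))

  distinct <- list(X1_1 = mkseq(c(L1 = "A")), X2_1 = mkseq(c(L1 = "C")),
                   X3_1 = mkseq(c(L1 = "D")))
  expect_length(cluster_redundant(distinct), 3)
})

test_that("clustering agrees with a union-find oracle on random inputs", {
  set.seed(21)
  labels <- paste0("L", 1:30)
  for (rep in 1:10) {
    n <- sample(10:50, 1)
    base_pool <- lapply(1:4, function(i) {
      stats::setNames(sample(c("A", "C", "D", "E"), 30, replace = TRUE),
                      labels)
    })
    seqs <- stats::setNames(lapply(1:n, function(i) {
      s <- base_pool[[sample(4, 1)]]
      # random observation mask and occasional mutation
      s <- s[sample(30, sample(15:30, 1))]
      if (runif(1) < 0.3) s[sample(length(s), 1)] <- "W"
      s
    }), paste0("E", sprintf("%02d", 1:n), "_1"))
    got <- cluster_redundant(seqs)
    want <- oracle_clusters(seqs)
    expect_equal(lapply(got, `[[`, "members"), want)
  }
})

test_that("representatives prefer longest, then best resolution, then id", {
  md <- data.frame(set_id = c("A1_1", "B1_1", "C1_1"),
                   length = c(110, 112, 112),
                   resolution = c(1.8, 2.5, 1.9))
  expect_equal(select_representative(md$set_id, md), "C1_1")
  expect_equal(select_representative("B1_1", md), "B1_1")
  md2 <- data.frame(set_id = c("A1_1", "B1_1"), length = c(100, 100),
                    resolution = c(2.0, 2.0))
  expect_equal(select_representative(md2$set_id, md2), "A1_1")
  # structures without resolution rank after all with one
  md3 <- data.frame(set_id = c("A1_1", "B1_1"), length = c(100, 100),
                    resolution = c(NA, 3.5))
  expect_equal(select_representative(md3$set_id, md3), "B1_1")
})

test_that("labelled sequences come from observed residues of numbered atoms", {
  res <- process_entry(corpus_model("9PRC"), "9PRC")
  ls <- labeled_sequence(res$sets[[1]])
  expect_true(all(grepl("^[LH]", names(ls))))
  # the four unobserved CDR-H3 residues carry no entry
  full <- process_entry(corpus_model("9FRE"), "9FRE")
  ls_full <- labeled_sequence(full$sets[[1]])
  expect_equal(sum(grepl("^H", names(ls_full))) -
                 sum(grepl("^H", names(ls))), 4)
})

test_that("identical antibodies cluster across and within entries", {
  run <- corpus_run()
  cl <- run$clusters_by_form$complete$clusters
  members <- lapply(cl, `[[`, "members")
  # internal redundancy: the two copies in the two-antibody entry
  afv <- Filter(function(m) any(grepl("^9AFV", m)), members)
  expect_length(afv, 1)
  expect_setequal(afv[[1]], c("9AFV_1", "9AFV_2"))
  # the twelve copies form one cluster
  fqr <- Filter(function(m) any(grepl("^9FQR", m)), members)
  expect_length(fqr, 1)
  expect_length(fqr[[1]], 12)
  # the same consensus antibody seen free and complexed clusters together
  cons <- Filter(function(m) "9FRE_1" %in% m, members)[[1]]
  expect_true(all(c("9PRC_1", "9HAP_1") %in% cons))
})

test_that("free/complexed lists pair antibodies available in both states", {
  out <- corpus_out()
  fc <- utils::read.delim(file.path(out, "lists",
                                    "free_complexed_complete.tsv"))
  expect_true(nrow(fc) > 0)
  # every listed cluster has at least one free and one complexed member
  for (k in unique(fc$cluster)) {
    st <- fc$status[fc$cluster == k]
    expect_true(any(st == "Free antibody"))
    expect_true(any(st != "Free antibody"))
  }
  expect_true(all(c("9FRE_1", "9PRC_1") %in% fc$set_id))
})

test_that("non-redundant dataset sizes equal cluster counts", {
  run <- corpus_run()
  out <- corpus_out()
  for (fm in names(run$clusters_by_form)) {
    red <- utils::read.delim(file.path(out, "lists",
                                       paste0("redundancy_", fm,
                                              "_all.tsv")))
    nr_files <- list.files(file.path(out, paste0("NR_", fm), "all",
                                     "kabat"))
    expect_equal(length(nr_files), length(unique(red$cluster)))
    expect_equal(length(nr_files),
                 length(run$clusters_by_form[[fm]]$clusters))
    expect_equal(sum(red$representative == "yes"),
                 length(unique(red$cluster)))
  }
})
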