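# Shared, lazily built fixtures: the synthetic corpus and one full pipeline
# run are expensive, so they are generated once per test session.

.corpus_cache <- new.env()

corpus_dir <- function() {
  if (is.null(.corpus_cache$dir)) {
    d <- file.path(tempdir(), "abfv-corpus")
    .corpus_cache$expected <- fixture_corpus(d, seed = 1)
    .corpus_cache$dir <- d
  }
  .corpus_cache$dir
}

corpus_expected <- function() {
  corpus_dir()
  .corpus_cache$expected
}

corpus_run <- function() {
  if (is.null(.corpus_cache$run)) {
    out <- file.path(tempdir(), "abfv-out")
    .corpus_cache$run <- run_pipeline(corpus_expected()$code, corpus_dir(),
                                      out)
    .corpus_cache$out <- out
  }
  .corpus_cache$run
}

corpus_out <- function() {
  corpus_run()
  .corpus_cache$out
}

corpus_rerun_out <- function() {
  if (is.null(.corpus_cache$out2)) {
    d2 <- file.path(tempdir(), "abfv-corpus2")
    out2 <- file.path(tempdir(), "abfv-out2")
    fixture_corpus(d2, seed = 1)
    run_pipeline(corpus_expected()$code, d2, out2)
    .corpus_cache$out2 <- out2
  }
  .corpus_cache$out2
}

corpus_model <- function(code) {
  read_pdb_file(file.path(corpus_dir(), paste0(tolower(code), ".pdb")))
}

# brute-force all-pairs contact oracle, deliberately independent of the
# blocked implementation
oracle_contacts <- function(xyz_a, xyz_b, cutoff) {
  n <- 0L
  for (i in seq_len(nrow(xyz_a))) {
    d <- sqrt((xyz_a[i, 1] - xyz_b[, 1])^2 +
                (xyz_a[i, 2] - xyz_b[, 2])^2 +
                (xyz_a[i, 3] - xyz_b[, 3])^2)
    n <- n + sum(d <= cutoff)
  }
  n
}

# minimal structure object around bare coordinates, for contact tests
toy_structure <- function(xyz_by_chain) {
  atoms <- do.call(rbind, lapply(names(xyz_by_chain), function(ch) {
    xyz <- xyz_by_chain[[ch]]
    data.frame(serial = seq_len(nrow(xyz)), name = "CA", alt = "",
               resname = "ALA", chain = ch, resno = seq_len(nrow(xyz)),
               icode = "", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
               occ = 1, b = 0, element = "C", het = FALSE,
               stringsAsFactors = FALSE)
  }))
  atoms$serial <- seq_len(nrow(atoms))
  structure(list(header = list(pdb_code = "TOYS", method = NA,
                               resolution = NA, r_factor = NA,
                               r_free = NA),
                 atoms = atoms, seqres = character(0),
                 conect = matrix(integer(0), ncol = 2),
                 transforms = list(), compnd = character(0),
                 source = character(0),
                 nucleic = stats::setNames(
                   rep(FALSE, length(xyz_by_chain)),
                   names(xyz_by_chain))),
            class = "abfv_structure")
}

# union-find transitive-closure oracle for redundancy clustering
oracle_clusters <- function(seqs) {
  ids <- sort(names(seqs))
  groups <- lapply(ids, function(i) i)
  changed <- TRUE
  while (changed) {
    changed <- FALSE
    for (i in seq_along(groups)) {
      if (i > length(groups)) break
      j <- i + 1
      while (j <= length(groups)) {
        linked <- any(outer(groups[[i]], groups[[j]],
                            Vectorize(function(a, b)
                              redundant_pair(seqs[[a]], seqs[[b]]))))
        if (linked) {
          groups[[i]] <- sort(c(groups[[i]], groups[[j]]))
          groups[[j]] <- NULL
          changed <- TRUE
        } else {
          j <- j + 1
        }
      }
    }
  }
  groups[order(vapply(groups, `[`, character(1), 1))]
}
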