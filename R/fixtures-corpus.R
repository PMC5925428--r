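# Canned synthetic entries covering every pipeline branch, and the standard
# test corpus. Codes beginning with 9 are synthetic stand-ins, not PDB
# depositions.

fx_chain <- function(label, seq, role, ...) {
  c(list(label = label, seq = seq, role = role), list(...))
}

fixture_protein_seq <- function(len, seed = 1) {
  with_seed(seed, paste(sample(names(.AA1TO3), len, replace = TRUE),
                        collapse = ""))
}

#' Canned synthetic entries
#'
#' Each generator returns the PDB text (character vector of lines) of a
#' synthetic entry exercising one pipeline scenario. All geometry is
#' engineered (see [fixture_entry()]), so designed contact counts are
#' exact ground truth.
#'
#' \describe{
#'   \item{free antibody}{1..n identical or mutated light/heavy copies with
#'     an engineered VL-VH packing interface; no antigen.}
#'   \item{protein complex}{antibody plus a protein chain contacting the
#'     CDRs; options add a SEQRES leader sequence and residues missing from
#'     the coordinates.}
#'   \item{anti-idiotype}{two different antibodies in mutual CDR contact,
#'     with a designed inter-chain contact matrix.}
#'   \item{framework binder}{a protein-A-like domain contacting framework
#'     only, so the antibody must stay free.}
#'   \item{haptens, DNA, dimers, VHH, scFv, Fc}{the remaining branches.}
#' }
#'
#' @param code Entry code.
#' @param seed Seed controlling sequence variation.
#' @param n_copies Number of antibody copies (free antibody generator).
#' @param n_mut CDR mutations relative to the consensus.
#' @name fixture_generators
NULL

#' @rdname fixture_generators
#' @export
fixture_free_antibody <- function(code = "9FRE", seed = 1, n_copies = 1,
                                  n_mut = 0) {
  sl <- fixture_sequence("L", n_mut = n_mut, seed = seed)
  sh <- fixture_sequence("H", n_mut = n_mut, seed = seed + 1000)
  labs <- if (n_copies == 1) list(c("L", "H")) else {
    lapply(seq_len(n_copies), function(k) LETTERS[c(2 * k - 1, 2 * k)])
  }
  chains <- list()
  interfaces <- list()
  for (k in seq_len(n_copies)) {
    chains <- c(chains, list(fx_chain(labs[[k]][1], sl, "L"),
                             fx_chain(labs[[k]][2], sh, "H")))
    interfaces <- c(interfaces, list(list(a = labs[[k]][1], b = labs[[k]][2],
                                          n = 40, side_a = "fw",
                                          side_b = "fw")))
  }
  fixture_entry(code, chains, interfaces,
                waters = if (n_copies == 1) 2 else 0,
                altloc = n_copies == 1)
}

#' @rdname fixture_generators
#' @export
fixture_protein_complex <- function(code = "9PRC", seed = 1, n_mut = 0,
                                    n_cdr = 20, n_fw = 3, leader = FALSE,
                                    missing_h3 = FALSE) {
  sl <- fixture_sequence("L", n_mut = n_mut, seed = seed)
  sh <- fixture_sequence("H", n_mut = n_mut, seed = seed + 1000)
  ag <- fixture_protein_seq(60, seed + 2000)
  chains <- list(
    fx_chain("L", sl, "L",
             leader = if (leader) "MGWSCIILFLVATATGVHS" else NULL),
    fx_chain("H", sh, "H", missing = if (missing_h3) 100:103 else NULL,
             name = "SYNTHETIC FAB HYFIX", species = "MUS MUSCULUS"),
    fx_chain("A", ag, "AG", name = "SYNTHETIC LYSOZYME-LIKE ANTIGEN",
             species = "GALLUS GALLUS"))
  interfaces <- list(
    list(a = "L", b = "H", n = 40, side_a = "fw", side_b = "fw"),
    list(a = "H", b = "A", n = n_cdr, side_a = "cdr", side_b = "any"))
  if (n_fw > 0) {
    interfaces <- c(interfaces, list(
      list(a = "H", b = "A", n = n_fw, side_a = "fw", side_b = "any")))
  }
  fixture_entry(code, chains, interfaces, resolution = 1.9)
}

#' @rdname fixture_generators
#' @export
fixture_anti_idiotype <- function(code = "9DVF", seed = 11,
                                  contact_matrix = c(128, 20, 10, 117)) {
  s1l <- fixture_sequence("L", n_mut = 0, seed = seed)
  s1h <- fixture_sequence("H", n_mut = 0, seed = seed)
  s2l <- fixture_sequence("L", n_mut = 8, seed = seed + 1)
  s2h <- fixture_sequence("H", n_mut = 8, seed = seed + 2)
  chains <- list(fx_chain("A", s1l, "L"), fx_chain("B", s1h, "H"),
                 fx_chain("C", s2l, "L"), fx_chain("D", s2h, "H"))
  interfaces <- list(
    list(a = "A", b = "B", n = contact_matrix[1], side_a = "fw",
         side_b = "fw"),
    list(a = "A", b = "D", n = contact_matrix[2], side_a = "cdr",
         side_b = "cdr"),
    list(a = "C", b = "B", n = contact_matrix[3], side_a = "cdr",
         side_b = "cdr"),
    list(a = "C", b = "D", n = contact_matrix[4], side_a = "fw",
         side_b = "fw"))
  fixture_entry(code, chains, interfaces)
}

#' @rdname fixture_generators
#' @export
fixture_multi_antibody_shared_antigen <- function(code = "9ULU",
                                                  seed = 21) {
  chains <- list()
  interfaces <- list()
  labs <- list(c("L", "H"), c("C", "D"), c("E", "F"))
  for (k in 1:3) {
    sl <- fixture_sequence("L", n_mut = 6, seed = seed + 10 * k)
    sh <- fixture_sequence("H", n_mut = 6, seed = seed + 10 * k + 5)
    chains <- c(chains, list(fx_chain(labs[[k]][1], sl, "L"),
                             fx_chain(labs[[k]][2], sh, "H")))
    interfaces <- c(interfaces, list(
      list(a = labs[[k]][1], b = labs[[k]][2], n = 40, side_a = "fw",
           side_b = "fw"),
      list(a = labs[[k]][2], b = "A", n = 20, side_a = "cdr",
           side_b = "any")))
  }
  chains <- c(chains, list(fx_chain("A", fixture_protein_seq(90, seed),
                                    "AG",
                                    name = "SYNTHETIC RECEPTOR ANTIGEN")))
  fixture_entry(code, chains, interfaces)
}

#' @rdname fixture_generators
#' @export
fixture_two_copies_two_antigens <- function(code = "9AFV", seed = 31) {
  sl <- fixture_sequence("L", n_mut = 4, seed = seed)
  sh <- fixture_sequence("H", n_mut = 4, seed = seed + 1)
  ag <- fixture_protein_seq(70, seed + 2)
  chains <- list(
    fx_chain("L", sl, "L"), fx_chain("H", sh, "H"),
    fx_chain("K", sl, "L"), fx_chain("M", sh, "H"),
    fx_chain("A", ag, "AG", name = "SYNTHETIC CAPSID ANTIGEN"),
    fx_chain("B", ag, "AG", name = "SYNTHETIC CAPSID ANTIGEN"))
  interfaces <- list(
    list(a = "L", b = "H", n = 40, side_a = "fw", side_b = "fw"),
    list(a = "K", b = "M", n = 40, side_a = "fw", side_b = "fw"),
    list(a = "H", b = "A", n = 20, side_a = "cdr", side_b = "any"),
    list(a = "M", b = "B", n = 20, side_a = "cdr", side_b = "any"))
  fixture_entry(code, chains, interfaces)
}

#' @rdname fixture_generators
#' @export
fixture_framework_binder <- function(code = "9DEE", seed = 1, n_fw = 30,
                                     n_cdr = 2) {
  chains <- list(
    fx_chain("L", fixture_sequence("L", seed = seed), "L"),
    fx_chain("H", fixture_sequence("H", seed = seed), "H"),
    fx_chain("S", fixture_protein_seq(60, seed + 3000), "AG",
             name = "SYNTHETIC PROTEIN A DOMAIN",
             species = "STAPHYLOCOCCUS AUREUS"))
  interfaces <- list(
    list(a = "L", b = "H", n = 40, side_a = "fw", side_b = "fw"),
    list(a = "H", b = "S", n = n_fw, side_a = "fw", side_b = "any"))
  if (n_cdr > 0) {
    interfaces <- c(interfaces, list(
      list(a = "H", b = "S", n = n_cdr, side_a = "cdr", side_b = "any")))
  }
  fixture_entry(code, chains, interfaces)
}

#' @rdname fixture_generators
#' @export
fixture_hapten_complex <- function(code = "9HAP", seed = 1,
                                   covalent = FALSE, side = "cdr",
                                   n_contacts = 3) {
  chains <- list(fx_chain("L", fixture_sequence("L", seed = seed), "L"),
                 fx_chain("H", fixture_sequence("H", seed = seed), "H"))
  interfaces <- list(list(a = "L", b = "H", n = 40, side_a = "fw",
                          side_b = "fw"))
  hets <- list(list(resname = "HPT", chain = "H", resno = 501L,
                    n_atoms = 6, target = "H", n_contacts = n_contacts,
                    side = side, covalent = covalent))
  fixture_entry(code, chains, interfaces, hets)
}

#' @rdname fixture_generators
#' @export
fixture_dna_complex <- function(code = "9DNA", seed = 1) {
  chains <- list(fx_chain("L", fixture_sequence("L", seed = seed), "L"),
                 fx_chain("H", fixture_sequence("H", seed = seed), "H"),
                 fx_chain("B", "GATTACAGATTACA", "DNA"))
  interfaces <- list(
    list(a = "L", b = "H", n = 40, side_a = "fw", side_b = "fw"),
    list(a = "H", b = "B", n = 16, side_a = "cdr", side_b = "any"))
  fixture_entry(code, chains, interfaces)
}

#' @rdname fixture_generators
#' @export
fixture_light_dimer_biomt <- function(code = "9LDM", seed = 1) {
  sl <- fixture_sequence("L", seed = seed)
  # C2 axis through the midpoint of the L36/L87 C-alpha positions, so the
  # symmetry copy satisfies the 20 A dimer rule
  p36 <- snake_center(36, c(0, 0, 0))
  p87 <- snake_center(87, c(0, 0, 0))
  mid <- (p36 + p87) / 2
  biomt <- list(list(rot = diag(c(-1, -1, 1)),
                     trans = c(2 * mid[1], 2 * mid[2], 0),
                     chains = "A"))
  fixture_entry(code, list(fx_chain("A", sl, "L")), biomt = biomt)
}

#' @rdname fixture_generators
#' @export
fixture_bence_jones <- function(code = "9BJD", seed = 1,
                                antigen = c("none", "protein", "hapten")) {
  antigen <- match.arg(antigen)
  sl <- fixture_sequence("L", seed = seed)
  chains <- list(fx_chain("A", sl, "L", origin = c(0, 0, 0)),
                 fx_chain("B", sl, "L", origin = c(0, 15, 0)))
  interfaces <- list()
  hets <- list()
  if (antigen == "protein") {
    chains <- c(chains, list(fx_chain("G", fixture_protein_seq(50, seed + 7),
                                      "AG")))
    interfaces <- list(list(a = "A", b = "G", n = 20, side_a = "cdr",
                            side_b = "any"))
  } else if (antigen == "hapten") {
    hets <- list(list(resname = "HPT", chain = "A", resno = 401L,
                      n_atoms = 5, target = "A", n_contacts = 3,
                      side = "cdr", covalent = FALSE))
  }
  fixture_entry(code, chains, interfaces, hets)
}

#' @rdname fixture_generators
#' @export
fixture_vhh <- function(code = "9VHH", seed = 1,
                        antigen = c("none", "protein", "hapten")) {
  antigen <- match.arg(antigen)
  sh <- fixture_sequence("H", seed = seed)
  chains <- list(fx_chain("H", sh, "H"))
  interfaces <- list()
  hets <- list()
  if (antigen == "protein") {
    chains <- c(chains, list(fx_chain("G", fixture_protein_seq(55, seed + 9),
                                      "AG")))
    interfaces <- list(list(a = "H", b = "G", n = 20, side_a = "cdr",
                            side_b = "any"))
  } else if (antigen == "hapten") {
    hets <- list(list(resname = "HPT", chain = "H", resno = 301L,
                      n_atoms = 5, target = "H", n_contacts = 3,
                      side = "cdr", covalent = FALSE))
  }
  fixture_entry(code, chains, interfaces, hets)
}

#' @rdname fixture_generators
#' @export
fixture_scfv_hybrid <- function(code = "9SCF", seed = 1) {
  fused <- paste0(fixture_sequence("L", seed = seed), "GGGGSGGGGSGGGGS",
                  fixture_sequence("H", seed = seed))
  fixture_entry(code, list(fx_chain("A", fused, "AG")))
}

#' @rdname fixture_generators
#' @export
fixture_fc_only <- function(code = "9FCO", seed = 1) {
  fixture_entry(code, list(
    fx_chain("A", fixture_protein_seq(100, seed + 100), "AG"),
    fx_chain("B", fixture_protein_seq(100, seed + 101), "AG")))
}

#' @rdname fixture_generators
#' @export
fixture_numbering_failure <- function(code = "9NMF", seed = 1) {
  sl <- fixture_sequence("L", seed = seed)
  sh <- substr(fixture_sequence("H", seed = seed), 1, 60)  # ends inside H2
  fixture_entry(code, list(fx_chain("L", sl, "L"),
                           fx_chain("H", sh, "AG")),
                interfaces = list())
}

#' Write the standard synthetic test corpus
#'
#' Generates one entry per pipeline scenario into a directory, covering all
#' three antibody forms, all complex classes, anti-idiotypes, symmetry
#' dimers, rejection branches and redundancy across entries (free and
#' complexed copies of the same antibody).
#'
#' @param dir Output directory (created if needed).
#' @param seed Master seed.
#' @return Data frame describing the corpus: \code{code}, expected
#'   \code{form}, expected \code{class}, expected number of sets
#'   (\code{n_sets}; NA for rejected entries) and \code{reject_reason}.
#' @export
fixture_corpus <- function(dir, seed = 1) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  put <- function(code, lines) {
    writeLines(lines, file.path(dir, paste0(tolower(code), ".pdb")))
  }
  put("9FRE", fixture_free_antibody("9FRE", seed = seed))
  put("9PRC", fixture_protein_complex("9PRC", seed = seed, leader = TRUE,
                                      missing_h3 = TRUE))
  put("9DVF", fixture_anti_idiotype("9DVF", seed = seed + 10))
  put("9ULU", fixture_multi_antibody_shared_antigen("9ULU",
                                                    seed = seed + 20))
  put("9AFV", fixture_two_copies_two_antigens("9AFV", seed = seed + 30))
  put("9FQR", fixture_free_antibody("9FQR", seed = seed + 40,
                                    n_copies = 12, n_mut = 3))
  put("9DEE", fixture_framework_binder("9DEE", seed = seed))
  put("9HAP", fixture_hapten_complex("9HAP", seed = seed))
  put("9HCV", fixture_hapten_complex("9HCV", seed = seed, covalent = TRUE))
  put("9DNA", fixture_dna_complex("9DNA", seed = seed))
  put("9LDM", fixture_light_dimer_biomt("9LDM", seed = seed))
  put("9BJD", fixture_bence_jones("9BJD", seed = seed))
  put("9LDP", fixture_bence_jones("9LDP", seed = seed,
                                  antigen = "protein"))
  put("9LDN", fixture_bence_jones("9LDN", seed = seed,
                                  antigen = "hapten"))
  put("9VHH", fixture_vhh("9VHH", seed = seed))
  put("9VHC", fixture_vhh("9VHC", seed = seed, antigen = "protein"))
  put("9VHN", fixture_vhh("9VHN", seed = seed, antigen = "hapten"))
  put("9SCF", fixture_scfv_hybrid("9SCF", seed = seed))
  put("9FCO", fixture_fc_only("9FCO", seed = seed))
  put("9NMF", fixture_numbering_failure("9NMF", seed = seed))
  data.frame(
    code = c("9FRE", "9PRC", "9DVF", "9ULU", "9AFV", "9FQR", "9DEE",
             "9HAP", "9HCV", "9DNA", "9LDM", "9BJD", "9LDP", "9LDN",
             "9VHH", "9VHC", "9VHN", "9SCF", "9FCO", "9NMF"),
    form = c("complete", "complete", "complete", "complete", "complete",
             "complete", "complete", "complete", "complete", "complete",
             "light_only", "light_only", "light_only", "light_only",
             "heavy_only", "heavy_only", "heavy_only", NA, NA, NA),
    class = c("free", "protein", "protein", "protein", "protein", "free",
              "free", "non_protein", "free", "non_protein", "free",
              "free", "protein", "non_protein", "free", "protein",
              "non_protein", NA, NA, NA),
    n_sets = c(1, 1, 2, 3, 2, 12, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1,
               NA, NA, NA),
    reject_reason = c(rep(NA, 17), "scfv_hybrid", "fc_only",
                      "numbering_failure"),
    stringsAsFactors = FALSE)
}
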