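# Antigen classification: CDR-versus-framework contact rules.

# Fv atom table of an antibody with per-atom CDR membership, from the
# Kabat-numbered renumbering results of its chains.
fv_atom_table <- function(numbered_kabat, cdr_definition = "kabat") {
  parts <- lapply(numbered_kabat, function(rn) {
    if (is.null(rn)) return(NULL)
    a <- rn$atoms
    a <- a[!a$element %in% c("H", "D"), , drop = FALSE]
    lab <- paste0(a$resno, a$icode)
    a$cdr <- cdr_membership(lab, rn$role, cdr_definition) != "framework"
    a$fv_role <- rn$role
    a
  })
  do.call(rbind, parts)
}

# Contacts between an antibody's Fv atoms and a partner atom set, split by
# CDR membership of the antibody residue.
cdr_contact_profile <- function(fv_atoms, partner_atoms, cutoff) {
  p <- as.matrix(partner_atoms[, c("x", "y", "z")])
  cdr <- count_pairs_within(
    as.matrix(fv_atoms[fv_atoms$cdr, c("x", "y", "z"), drop = FALSE]), p,
    cutoff)
  fw <- count_pairs_within(
    as.matrix(fv_atoms[!fv_atoms$cdr, c("x", "y", "z"), drop = FALSE]), p,
    cutoff)
  c(cdr = cdr, framework = fw)
}

#' Classify a candidate polymer chain against an antibody
#'
#' A non-antibody chain is antigen when it makes more contacts with the
#' antibody's CDRs than with its framework and at least
#' \code{min_cdr_contacts} contacts with the CDRs. A chain that touches the
#' antibody without satisfying this rule is an antibody-binding protein
#' (e.g. protein A binding framework residues of the VH domain), and the
#' antibody stays uncomplexed. A chain with no contacts is unrelated.
#' Nucleic-acid chains follow the same rule but are routed to the
#' non-protein class downstream.
#'
#' @param model An \code{abfv_structure}.
#' @param numbered_kabat Named list (roles) of [renumber_structure()]
#'   results for the antibody's chains under Kabat numbering.
#' @param chain Candidate chain label.
#' @param params Pipeline parameters.
#' @return \code{"antigen"}, \code{"antibody_binding_protein"} or
#'   \code{"unrelated"}; contact counts in \code{attr(, "profile")}.
#' @export
classify_polymer_antigen <- function(model, numbered_kabat, chain,
                                     params = pipeline_params()) {
  fv <- fv_atom_table(numbered_kabat, params$cdr_definition)
  partner <- chain_atoms(model, chain)
  prof <- cdr_contact_profile(fv, partner, params$contact_cutoff)
  out <- if (prof["cdr"] > prof["framework"] &&
             prof["cdr"] >= params$min_cdr_contacts) {
    "antigen"
  } else if (sum(prof) > 0) {
    "antibody_binding_protein"
  } else {
    "unrelated"
  }
  attr(out, "profile") <- prof
  out
}

#' Classify a HETATM group against a free antibody
#'
#' Haptens, lipids and carbohydrates are HETATM groups. A group is antigen
#' when at least one of its atoms contacts a CDR-residue atom within the
#' cutoff and no CONECT record covalently links the group to the antibody
#' (a covalently bound group is a chemical modification, not an antigen).
#' Because haptens are small, a single CDR-involving contact suffices; the
#' 15-contact minimum applies only to polymer antigens.
#'
#' @param model An \code{abfv_structure}.
#' @param numbered_kabat Renumbering results of the antibody's chains.
#' @param group A HETATM group from [het_groups()].
#' @param params Pipeline parameters.
#' @return \code{"antigen"} or \code{"none"}; contact counts in
#'   \code{attr(, "profile")}.
#' @export
classify_het_antigen <- function(model, numbered_kabat, group,
                                 params = pipeline_params()) {
  fv <- fv_atom_table(numbered_kabat, params$cdr_definition)
  ga <- group$atoms[!group$atoms$element %in% c("H", "D"), , drop = FALSE]
  prof <- cdr_contact_profile(fv, ga, params$contact_cutoff)
  ab_serials <- unlist(lapply(numbered_kabat,
                              function(rn) if (!is.null(rn)) rn$atoms$serial))
  covalent <- conect_links(model, group$atoms$serial, ab_serials)
  out <- if (prof["cdr"] >= 1 && !covalent) "antigen" else "none"
  attr(out, "profile") <- prof
  attr(out, "covalent") <- covalent
  out
}

#' Resolve anti-idiotype antibody/antibody complexes
#'
#' For an entry containing two or more antibodies and no non-antibody
#' polymer chains: if all antibody sequences are identical the antibodies
#' are simply multiple copies and all remain free. Otherwise each antibody
#' in turn is treated as a potential two-chain antigen for each other
#' antibody and tested with the polymer-antigen CDR rule; a passing ordered
#' pair yields a protein-complex set in each direction, so each antibody of
#' an anti-idiotype pair appears once as antibody and once as antigen.
#'
#' @param antibodies List of antibody descriptors, each with elements
#'   \code{chains} (original chain labels), \code{numbered_kabat} and
#'   \code{sequence} (concatenated chain sequence).
#' @param model An \code{abfv_structure}.
#' @param params Pipeline parameters.
#' @return Integer-indexed list: for each antibody either \code{NULL} (stays
#'   free) or the index of the partner antibody acting as its antigen.
#' @export
resolve_anti_idiotype <- function(antibodies, model,
                                  params = pipeline_params()) {
  n <- length(antibodies)
  out <- vector("list", n)
  if (n < 2) return(out)
  seqs <- vapply(antibodies, `[[`, character(1), "sequence")
  if (length(unique(seqs)) == 1L) return(out)
  for (i in seq_len(n)) {
    best_j <- NULL
    best_cdr <- -1
    for (j in setdiff(seq_len(n), i)) {
      fv <- fv_atom_table(antibodies[[i]]$numbered_kabat,
                          params$cdr_definition)
      partner <- do.call(rbind, lapply(antibodies[[j]]$chains,
                                       function(ch) chain_atoms(model, ch)))
      prof <- cdr_contact_profile(fv, partner, params$contact_cutoff)
      if (prof["cdr"] > prof["framework"] &&
          prof["cdr"] >= params$min_cdr_contacts &&
          prof["cdr"] > best_cdr) {
        best_j <- j
        best_cdr <- prof["cdr"]
      }
    }
    if (!is.null(best_j)) out[[i]] <- best_j
  }
  out
}

#' Final complex class of an antibody-antigen set
#'
#' No antigen is a free antibody; protein antigen chains give the protein
#' class; nucleic-acid chains and HETATM groups give the non-protein class.
#' A mixed protein-plus-HETATM antigen is classed protein (the dominant
#' polymer).
#'
#' @param antigen_kind Character vector of the kinds present:
#'   \code{"protein"}, \code{"nucleic"}, \code{"het"} (empty for none).
#' @return \code{"free"}, \code{"protein"} or \code{"non_protein"}.
#' @export
finalize_complex_class <- function(antigen_kind) {
  if (!length(antigen_kind)) return("free")
  if ("protein" %in% antigen_kind) return("protein")
  "non_protein"
}
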