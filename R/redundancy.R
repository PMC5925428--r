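# Redundancy: identical-antibody clustering over numbered sequences.

#' Labelled sequence of an antibody set
#'
#' The amino acid at every observed (ATOM-derived) numbered position of the
#' antibody's chains, keyed by role-prefixed position label (e.g.
#' \code{L24}, \code{H100A}). Redundancy comparisons are made on these
#' labels, so residues missing from one structure are simply ignored when
#' comparing it with another.
#'
#' @param set An \code{abfv_set}.
#' @param scheme Scheme whose labels key the comparison (default
#'   \code{"martin"}; any single scheme gives a consistent label space).
#' @return Named character vector label -> amino acid.
#' @export
labeled_sequence <- function(set, scheme = "martin") {
  numbered <- set$numbered[[scheme]]
  out <- character(0)
  for (role in names(numbered)) {
    rn <- numbered[[role]]
    if (is.null(rn)) next
    out[paste0(role, rn$map$label)] <- rn$map$aa
  }
  out
}

#' Are two antibodies redundant?
#'
#' TRUE when the amino acids agree at every position label present in both
#' antibodies (over all chains of the form); positions observed in only one
#' of the two are ignored. Two antibodies sharing no labels are not
#' redundant.
#'
#' @param a,b Named character vectors from [labeled_sequence()].
#' @return Logical.
#' @export
redundant_pair <- function(a, b) {
  shared <- intersect(names(a), names(b))
  length(shared) > 0 && all(a[shared] == b[shared])
}

#' Cluster antibodies into redundancy classes
#'
#' Single-linkage transitive closure of [redundant_pair()]: if A is
#' redundant with B and B with C, all three fall in one cluster even when A
#' and C share a difference masked by missing residues. Clusters partition
#' the input; member ordering is deterministic by set id.
#'
#' @param seqs Named list: set id -> labelled sequence.
#' @return List of clusters, each a list with \code{members} (sorted ids)
#'   and \code{representative} (NA until selected).
#' @export
cluster_redundant <- function(seqs) {
  ids <- sort(names(seqs))
  n <- length(ids)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (redundant_pair(seqs[[ids[i]]], seqs[[ids[j]]])) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  lapply(unname(split(ids, roots)), function(members) {
    list(members = sort(members), representative = NA_character_)
  })
}

#' Select the representative of a redundancy cluster
#'
#' Members with fewer observed residues are discarded first (shorter
#' sequences carry less structural information); among the longest, the
#' best (numerically smallest) resolution wins. Members without a
#' resolution (NMR/EM) rank after all members that have one. Remaining ties
#' go to the lexicographically smallest set id.
#'
#' @param members Character vector of set ids.
#' @param metadata Data frame with columns \code{set_id}, \code{length}
#'   (total observed residues) and \code{resolution} (Angstrom or NA).
#' @return The representative set id.
#' @export
select_representative <- function(members, metadata) {
  md <- metadata[match(members, metadata$set_id), , drop = FALSE]
  stopifnot(!anyNA(md$set_id))
  md <- md[md$length == max(md$length), , drop = FALSE]
  res <- ifelse(is.na(md$resolution), Inf, md$resolution)
  md <- md[res == min(res), , drop = FALSE]
  sort(md$set_id)[1]
}
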