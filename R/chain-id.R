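#' Consensus variable-domain profile for chain typing
#'
#' Loads the frozen consensus light- and heavy-chain variable-domain
#' sequences shipped with the package (human germline derived; ~107 and
#' ~116 aa) together with the exchange matrix and gap penalties used for
#' the Smith-Waterman-style scoring.
#'
#' @param file FASTA file with entries \code{light_consensus} and
#'   \code{heavy_consensus}; defaults to the packaged profile.
#' @param gap_open,gap_ext Gap penalties for the local alignment.
#' @return Object of class \code{abfv_profile}.
#' @export
consensus_profile <- function(file = NULL, gap_open = 10, gap_ext = 0.5) {
  if (is.null(file)) {
    file <- system.file("extdata", "consensus_fv.fasta", package = "abfv",
                        mustWork = TRUE)
  }
  fa <- readLines(file)
  hdr <- grep("^>", fa)
  seqs <- stats::setNames(
    vapply(seq_along(hdr), function(i) {
      to <- if (i < length(hdr)) hdr[i + 1] - 1 else length(fa)
      paste(fa[(hdr[i] + 1):to], collapse = "")
    }, character(1)),
    sub("^>", "", fa[hdr]))
  stopifnot(all(c("light_consensus", "heavy_consensus") %in% names(seqs)))
  structure(list(light = unname(seqs["light_consensus"]),
                 heavy = unname(seqs["heavy_consensus"]),
                 gap_open = gap_open, gap_ext = gap_ext),
            class = "abfv_profile")
}

#' Score a sequence against the light and heavy consensus
#'
#' Each score is 100 x (identities in the best local alignment) / (consensus
#' length), so a chain identical to a consensus scores 100 and unrelated
#' sequences score low. Deterministic for a fixed profile.
#'
#' @param seq Amino-acid sequence.
#' @param profile An \code{abfv_profile}.
#' @return Named numeric vector \code{c(light = , heavy = )} in percent.
#' @export
score_chain <- function(seq, profile = consensus_profile()) {
  s <- score_chain_full(seq, profile)
  c(light = s$light$score, heavy = s$heavy$score)
}

score_chain_full <- function(seq, profile) {
  one <- function(ref) {
    if (is.null(seq) || is.na(seq) || !nzchar(sanitize_aa(seq))) {
      return(list(score = 0, qstart = NA, qend = NA))
    }
    aln <- align_local(seq, ref, profile$gap_open, profile$gap_ext)
    list(score = 100 * aln$nmatch / nchar(ref),
         qstart = aln$qstart, qend = aln$qend)
  }
  list(light = one(profile$light), heavy = one(profile$heavy))
}

#' Assign chain types (light, heavy, antigen) to every polymer chain
#'
#' Scores each chain's SEQRES- and ATOM-derived sequences against the
#' consensus profile and keeps the higher-scoring source (this deals with
#' residues missing from the coordinates and with SEQRES leader sequences).
#' Each chain is provisionally typed by whichever consensus scores higher,
#' then demoted to antigen when another chain scores strictly higher against
#' that consensus and its own score is below the threshold. Identical copies
#' tie on the highest score, so none of them is demoted. Nucleic-acid chains
#' are always antigen.
#'
#' @param model An \code{abfv_structure}.
#' @param profile Consensus profile.
#' @param threshold Score (percent) below which a non-top chain is demoted;
#'   default 80.
#' @return Data frame of class \code{abfv_chain_calls}: one row per polymer
#'   chain with \code{chain}, \code{light_score}, \code{heavy_score},
#'   \code{provisional}, \code{final}, \code{source}, \code{nucleic}.
#' @export
assign_chain_types <- function(model, profile = consensus_profile(),
                               threshold = 80) {
  chains <- polymer_chains(model)
  rows <- lapply(chains, function(ch) {
    if (isTRUE(model$nucleic[[ch]])) {
      return(data.frame(chain = ch, light_score = 0, heavy_score = 0,
                        provisional = "antigen", final = "antigen",
                        source = "atom", nucleic = TRUE,
                        stringsAsFactors = FALSE))
    }
    seq_a <- tryCatch(as.character(sequence_from_atoms(model, ch)),
                      error = function(e) "")
    seq_s <- if (ch %in% names(model$seqres)) model$seqres[[ch]] else ""
    sa <- score_chain(seq_a, profile)
    ss <- if (nzchar(seq_s)) score_chain(seq_s, profile) else c(light = -1,
                                                                heavy = -1)
    use_seqres <- max(ss) >= max(sa)
    sc <- if (use_seqres) ss else sa
    prov <- if (sc["light"] >= sc["heavy"]) "light" else "heavy"
    data.frame(chain = ch, light_score = unname(sc["light"]),
               heavy_score = unname(sc["heavy"]),
               provisional = prov, final = prov,
               source = if (use_seqres) "seqres" else "atom",
               nucleic = FALSE, stringsAsFactors = FALSE)
  })
  calls <- do.call(rbind, rows)
  # demotion pass
  for (i in seq_len(nrow(calls))) {
    if (calls$nucleic[i]) next
    own <- if (calls$provisional[i] == "light") calls$light_score[i] else
      calls$heavy_score[i]
    others <- if (calls$provisional[i] == "light")
      calls$light_score[-i] else calls$heavy_score[-i]
    if (own < threshold && length(others) && any(others > own)) {
      calls$final[i] <- "antigen"
    }
  }
  class(calls) <- c("abfv_chain_calls", class(calls))
  calls
}

#' Classify the antibody form of an entry
#'
#' From the per-chain type calls: at least one light and one heavy chain
#' gives a complete antibody; only light chains a light-chain-only antibody
#' (e.g. a Bence-Jones dimer); only heavy chains a heavy-chain-only antibody
#' (e.g. a camelid VHH). An entry with no chain reaching the
#' variable-domain score threshold is rejected as \code{fc_only}; a single
#' chain carrying both a light-scoring and a heavy-scoring segment (an scFv
#' with one chain label) is rejected as \code{scfv_hybrid}, since it cannot
#' be split and numbered reliably.
#'
#' @param calls Result of [assign_chain_types()].
#' @param model,profile Needed for the hybrid re-scoring check; when omitted
#'   the hybrid check is skipped.
#' @param threshold Score threshold (percent), default 80.
#' @return List of class \code{abfv_form}: \code{form} (one of
#'   \code{"complete"}, \code{"light_only"}, \code{"heavy_only"},
#'   \code{"rejected"}) and \code{reject_reason} (\code{"none"},
#'   \code{"fc_only"} or \code{"scfv_hybrid"}).
#' @export
classify_form <- function(calls, model = NULL, profile = NULL,
                          threshold = 80) {
  stopifnot(nrow(calls) > 0)
  best <- pmax(calls$light_score, calls$heavy_score)
  if (!any(best >= threshold)) {
    return(structure(list(form = "rejected", reject_reason = "fc_only"),
                     class = "abfv_form"))
  }
  if (!is.null(model) && !is.null(profile)) {
    ab <- which(calls$final %in% c("light", "heavy") & best >= threshold)
    for (i in ab) {
      seq <- chain_best_sequence(model, calls[i, ])
      if (is_hybrid_chain(seq, profile, threshold)) {
        return(structure(list(form = "rejected",
                              reject_reason = "scfv_hybrid"),
                         class = "abfv_form"))
      }
    }
  }
  has_l <- any(calls$final == "light")
  has_h <- any(calls$final == "heavy")
  form <- if (has_l && has_h) "complete"
          else if (has_l) "light_only"
          else if (has_h) "heavy_only"
          else "rejected"
  structure(list(form = form,
                 reject_reason = if (form == "rejected") "fc_only" else "none"),
            class = "abfv_form")
}

#' @export
print.abfv_form <- function(x, ...) {
  cat("antibody form:", x$form,
      if (x$form == "rejected") paste0("(", x$reject_reason, ")"), "\n")
  invisible(x)
}

# The sequence behind a chain call, honouring the chosen source.
chain_best_sequence <- function(model, call) {
  if (call$source == "seqres" && call$chain %in% names(model$seqres)) {
    model$seqres[[call$chain]]
  } else {
    as.character(sequence_from_atoms(model, call$chain))
  }
}

# scFv detection: mask the best-scoring segment and re-score the remainder
# against the other consensus; both segments above threshold means a fused
# hybrid chain.
is_hybrid_chain <- function(seq, profile, threshold = 80) {
  s <- score_chain_full(seq, profile)
  first <- if (s$light$score >= s$heavy$score) "light" else "heavy"
  win <- s[[first]]
  if (win$score < threshold || is.na(win$qstart)) return(FALSE)
  chars <- strsplit(sanitize_aa(seq), "")[[1]]
  chars[win$qstart:win$qend] <- "X"
  masked <- paste(chars, collapse = "")
  other <- score_chain(masked, profile)
  other_role <- if (first == "light") "heavy" else "light"
  unname(other[other_role]) >= threshold
}
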