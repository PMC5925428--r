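# Smith-Waterman-style local alignment helpers built on Biostrings.

sanitize_aa <- function(seq) {
  seq <- toupper(gsub("[^A-Za-z]", "", seq))
  # letters absent from BLOSUM62 become X
  gsub("[UOJ]", "X", seq)
}

blosum62 <- local({
  env <- new.env()
  function() {
    if (is.null(env$m)) {
      e2 <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e2)
      env$m <- get("BLOSUM62", envir = e2)
    }
    env$m
  }
})

# Local alignment of query against a reference; returns per-column mapping.
align_local <- function(query, ref, gap_open = 10, gap_ext = 0.5) {
  query <- sanitize_aa(query)
  ref <- sanitize_aa(ref)
  if (!nzchar(query) || !nzchar(ref)) {
    return(list(nmatch = 0L, qstart = NA_integer_, qend = NA_integer_,
                pairs = data.frame(q = integer(0), r = integer(0),
                                   match = logical(0))))
  }
  aln <- Biostrings::pairwiseAlignment(
    pattern = query, subject = ref, type = "local",
    substitutionMatrix = blosum62(),
    gapOpening = gap_open, gapExtension = gap_ext)
  pg <- strsplit(as.character(Biostrings::pattern(aln)), "")[[1]]
  sg <- strsplit(as.character(Biostrings::subject(aln)), "")[[1]]
  qi <- Biostrings::start(Biostrings::pattern(aln)) - 1L
  ri <- Biostrings::start(Biostrings::subject(aln)) - 1L
  q <- integer(0); r <- integer(0); mt <- logical(0)
  for (k in seq_along(pg)) {
    pq <- pg[k] != "-"
    pr <- sg[k] != "-"
    if (pq) qi <- qi + 1L
    if (pr) ri <- ri + 1L
    q <- c(q, if (pq) qi else NA_integer_)
    r <- c(r, if (pr) ri else NA_integer_)
    mt <- c(mt, pq && pr && pg[k] == sg[k])
  }
  list(nmatch = Biostrings::nmatch(aln),
       qstart = Biostrings::start(Biostrings::pattern(aln)),
       qend = Biostrings::end(Biostrings::pattern(aln)),
       pairs = data.frame(q = q, r = r, match = mt))
}
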