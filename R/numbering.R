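#' Scheme tables for antibody variable-domain numbering
#'
#' Loads the versioned data tables defining the Kabat, Chothia and Martin
#' numbering conventions used by the package: the ordered canonical position
#' labels per chain role (light positions 1-107; heavy positions 1-113
#' including the canonical 82A-82C framework insertions), the hypervariable
#' regions with their scheme-specific insertion anchors, and the CDR ranges
#' used by the contact rules.
#'
#' @param scheme One of \code{"kabat"}, \code{"chothia"}, \code{"martin"}.
#' @return A list with \code{scheme}, \code{labels} (list L/H of ordered
#'   label vectors), \code{regions} (data frame: region, first, last,
#'   anchor per role), \code{ref} (list L/H of reference sequences) and
#'   \code{cdrs} (data frame of CDR label ranges per definition).
#' @export
scheme_table <- function(scheme = c("kabat", "chothia", "martin")) {
  scheme <- match.arg(scheme)
  cache <- scheme_cache()
  if (!is.null(cache[[scheme]])) return(cache[[scheme]])
  ext <- function(...) system.file("extdata", ..., package = "abfv",
                                   mustWork = TRUE)
  labels <- list(
    L = utils::read.csv(ext("schemes", "labels_light.csv"),
                        colClasses = "character")$label,
    H = utils::read.csv(ext("schemes", "labels_heavy.csv"),
                        colClasses = "character")$label)
  regions <- utils::read.csv(ext("schemes", "regions.csv"),
                             stringsAsFactors = FALSE)
  regions <- regions[regions$scheme == scheme, , drop = FALSE]
  cdrs <- utils::read.csv(ext("schemes", "cdrs.csv"),
                          stringsAsFactors = FALSE)
  fa <- readLines(ext("consensus_fv.fasta"))
  hdr <- grep("^>", fa)
  seqs <- stats::setNames(
    vapply(seq_along(hdr), function(i) {
      to <- if (i < length(hdr)) hdr[i + 1] - 1 else length(fa)
      paste(fa[(hdr[i] + 1):to], collapse = "")
    }, character(1)),
    sub("^>", "", fa[hdr]))
  tab <- list(scheme = scheme, labels = labels, regions = regions,
              ref = list(L = unname(seqs["light_consensus"]),
                         H = unname(seqs["heavy_consensus"])),
              cdrs = cdrs)
  cache[[scheme]] <- tab
  tab
}

scheme_cache <- local({
  env <- new.env()
  function() env
})

label_num <- function(label) as.integer(sub("[A-Z]+$", "", label))

#' Number a variable-domain sequence under a scheme
#'
#' Aligns the sequence against the role's reference variable domain and
#' transfers canonical position labels. Framework positions are labelled by
#' direct alignment transfer; hypervariable regions are labelled by loop
#' length, with insertion codes placed after the scheme's anchor position
#' (e.g. two extra CDR-L1 residues under Kabat become L27A and L27B) and
#' shortfalls removed C-terminal of the anchor. Residues N-terminal of the
#' domain (leader sequences) and C-terminal of the last variable position
#' (constant domains) receive no label and are trimmed. Numbering fails
#' cleanly (returns \code{NULL}) rather than mis-numbering: failure occurs
#' when fewer than half of the framework positions align or when a region
#' cannot be resolved.
#'
#' @param seq Amino-acid sequence (one-letter string).
#' @param role \code{"L"} or \code{"H"}.
#' @param scheme Numbering scheme id.
#' @param table Scheme table (defaults to \code{scheme_table(scheme)}).
#' @return An object of class \code{abfv_numbered} with a \code{residues}
#'   data frame (\code{label}, \code{aa}, \code{qpos}), or \code{NULL} on
#'   failure.
#' @export
number_chain <- function(seq, role = c("L", "H"),
                         scheme = c("kabat", "chothia", "martin"),
                         table = NULL) {
  role <- match.arg(role)
  scheme <- match.arg(scheme)
  if (is.null(table)) table <- scheme_table(scheme)
  seq <- sanitize_aa(seq)
  if (!nzchar(seq)) return(NULL)
  ref <- table$ref[[role]]
  labels <- table$labels[[role]]
  nref <- nchar(ref)
  regions <- table$regions[table$regions$role == role, , drop = FALSE]
  regions <- regions[order(regions$first), , drop = FALSE]
  # reference index ranges of the hypervariable regions
  lab_nums <- label_num(labels)
  reg_idx <- lapply(seq_len(nrow(regions)), function(k) {
    which(lab_nums >= regions$first[k] & lab_nums <= regions$last[k])
  })
  in_region <- rep(FALSE, nref)
  for (ix in reg_idx) in_region[ix] <- TRUE

  aln <- align_local(seq, ref)
  pairs <- aln$pairs
  ok <- !is.na(pairs$q) & !is.na(pairs$r)
  aligned_r <- pairs$r[ok]
  aligned_q <- pairs$q[ok]
  fw_idx <- which(!in_region)
  if (length(intersect(aligned_r, fw_idx)) < 0.5 * length(fw_idx)) {
    return(NULL)
  }

  out_q <- integer(0)
  out_lab <- character(0)
  claimed <- rep(FALSE, nchar(seq))

  # hypervariable regions: label the query window between the flanking
  # aligned framework positions by loop length
  for (k in seq_len(nrow(regions))) {
    ix <- reg_idx[[k]]
    r1 <- min(ix); r2 <- max(ix)
    left <- aligned_q[aligned_r < r1]
    right <- aligned_q[aligned_r > r2]
    if (!length(left) || !length(right)) {
      inside <- any(aligned_r >= r1 & aligned_r <= r2)
      if (inside) return(NULL)  # truncated inside a loop: fail cleanly
      next                      # region entirely absent
    }
    qL <- max(left); qR <- min(right)
    n <- qR - qL - 1L
    sel <- region_labels(labels[ix], regions$anchor[k], n)
    if (is.null(sel)) return(NULL)
    if (n > 0) {
      qs <- (qL + 1L):(qR - 1L)
      out_q <- c(out_q, qs)
      out_lab <- c(out_lab, sel)
      claimed[qs] <- TRUE
    }
  }

  # framework: direct transfer of aligned positions
  fw_pairs <- ok & pairs$r %in% fw_idx
  fq <- pairs$q[fw_pairs]
  fr <- pairs$r[fw_pairs]
  keep <- !claimed[fq]
  out_q <- c(out_q, fq[keep])
  out_lab <- c(out_lab, labels[fr[keep]])
  claimed[fq[keep]] <- TRUE

  # framework insertions: unlabelled residues between two labelled ones
  o <- order(out_q)
  out_q <- out_q[o]; out_lab <- out_lab[o]
  span <- range(out_q)
  gaps <- setdiff(seq(span[1], span[2]), out_q)
  if (length(gaps)) {
    add_q <- integer(0); add_lab <- character(0)
    for (run in split(gaps, cumsum(c(1, diff(gaps) != 1)))) {
      prev <- max(out_q[out_q < run[1]])
      base <- out_lab[match(prev, out_q)]
      if (length(run) > 26) return(NULL)
      add_q <- c(add_q, run)
      add_lab <- c(add_lab, paste0(base, LETTERS[seq_along(run)]))
    }
    out_q <- c(out_q, add_q); out_lab <- c(out_lab, add_lab)
    o <- order(out_q)
    out_q <- out_q[o]; out_lab <- out_lab[o]
  }

  if (anyDuplicated(out_lab)) return(NULL)
  res <- data.frame(label = out_lab,
                    aa = strsplit(seq, "")[[1]][out_q],
                    qpos = out_q, stringsAsFactors = FALSE)
  structure(list(role = role, scheme = scheme, residues = res,
                 source_chain = NA_character_, source = NA_character_),
            class = "abfv_numbered")
}

# Labels for a hypervariable region of observed length n. Insertions get
# letter codes after the anchor; deletions remove labels C-terminal of the
# anchor first, then from the anchor backwards.
region_labels <- function(region_labs, anchor, n) {
  m <- length(region_labs)
  if (n == 0) return(character(0))
  ia <- match(as.character(anchor), region_labs)
  if (is.na(ia)) ia <- m
  if (n == m) return(region_labs)
  if (n < m) {
    d <- m - n
    back <- if (ia < m) region_labs[(ia + 1):m] else character(0)
    front <- region_labs[1:ia]
    if (d <= length(back)) {
      return(c(front, back[-seq_len(d)]))
    }
    d2 <- d - length(back)
    if (d2 >= length(front)) return(NULL)
    return(front[1:(length(front) - d2)])
  }
  ins <- n - m
  if (ins > 26) return(NULL)
  c(region_labs[1:ia], paste0(region_labs[ia], LETTERS[seq_len(ins)]),
    if (ia < m) region_labs[(ia + 1):m])
}

#' @export
print.abfv_numbered <- function(x, ...) {
  cat("Numbered", x$role, "chain (", x$scheme, "):",
      nrow(x$residues), "Fv residues,",
      x$residues$label[1], "..", x$residues$label[nrow(x$residues)], "\n")
  invisible(x)
}

#' CDR membership of a numbered position
#'
#' Deterministic lookup of a scheme position label against the CDR ranges
#' (Kabat CDR definitions by default; insertion codes inherit the membership
#' of their parent position, so H100A lies in CDR-H3).
#'
#' @param label Position label, with or without the role prefix
#'   (\code{"27A"} or \code{"L27A"}).
#' @param role \code{"L"} or \code{"H"}.
#' @param definition CDR definition: \code{"kabat"} (default) or
#'   \code{"chothia"}.
#' @return The CDR id (\code{"L1"}...\code{"H3"}) or \code{"framework"}.
#' @export
cdr_membership <- function(label, role = c("L", "H"),
                           definition = c("kabat", "chothia")) {
  role <- match.arg(role)
  definition <- match.arg(definition)
  tab <- scheme_table("kabat")$cdrs
  tab <- tab[tab$definition == definition & tab$role == role, , drop = FALSE]
  label <- sub(paste0("^", role), "", label)
  num <- suppressWarnings(label_num(label))
  if (any(is.na(num))) stop("invalid position label")
  out <- rep("framework", length(num))
  for (k in seq_len(nrow(tab))) {
    hit <- num >= tab$first[k] & num <= tab$last[k]
    out[hit] <- tab$cdr[k]
  }
  out
}

#' Renumber the atoms of a chain under a numbered variable domain
#'
#' Maps each observed (ATOM) residue of the chain onto the numbered
#' sequence, relabels the atoms of the variable-domain residues with the new
#' chain label and the scheme position (number plus insertion code), and
#' drops constant-domain and leader atoms. When the numbering was computed
#' from the SEQRES sequence, observed residues are matched by aligning the
#' ATOM-derived sequence against it, which handles residues missing from the
#' coordinates. An observed residue inside the variable-domain window that
#' cannot be mapped makes the whole chain fail (returns \code{NULL}), so an
#' entry is rejected rather than mis-numbered.
#'
#' @param model An \code{abfv_structure}.
#' @param chain Source chain label.
#' @param numbered An \code{abfv_numbered} for that chain.
#' @param new_label Output chain label (normally \code{"L"} or \code{"H"}).
#' @param source_seq The sequence the numbering was computed from; defaults
#'   to the chain's ATOM-derived sequence.
#' @return List with \code{atoms} (renumbered Fv atom records), \code{map}
#'   (data frame: label, aa, orig_resno, orig_icode), \code{orig_chain},
#'   \code{role}, \code{scheme}; or \code{NULL} on mapping failure.
#' @export
renumber_structure <- function(model, chain, numbered, new_label,
                               source_seq = NULL) {
  aseq <- sequence_from_atoms(model, chain)
  resinfo <- attr(aseq, "residues")
  aseq_chr <- as.character(aseq)
  if (is.null(source_seq)) source_seq <- aseq_chr
  if (identical(source_seq, aseq_chr)) {
    src_of_obs <- seq_len(nchar(aseq_chr))
  } else {
    aln <- align_local(aseq_chr, source_seq)
    src_of_obs <- rep(NA_integer_, nchar(aseq_chr))
    okp <- !is.na(aln$pairs$q) & !is.na(aln$pairs$r)
    src_of_obs[aln$pairs$q[okp]] <- aln$pairs$r[okp]
  }
  lab_of_src <- stats::setNames(numbered$residues$label,
                                numbered$residues$qpos)
  obs_label <- lab_of_src[as.character(src_of_obs)]
  # unmapped observed residues inside the Fv window: refuse to renumber
  mapped <- which(!is.na(obs_label))
  if (!length(mapped)) return(NULL)
  inside <- seq(min(mapped), max(mapped))
  if (any(is.na(obs_label[inside]))) return(NULL)

  ord <- match(numbered$residues$label, obs_label)
  keep <- which(!is.na(ord))  # numbered residues with observed atoms
  map <- data.frame(
    label = numbered$residues$label[keep],
    aa = numbered$residues$aa[keep],
    orig_resno = resinfo$resno[ord[keep]],
    orig_icode = resinfo$icode[ord[keep]],
    stringsAsFactors = FALSE)

  a <- model$atoms[model$atoms$chain == chain & !model$atoms$het, ,
                   drop = FALSE]
  amod <- model$atoms[model$atoms$chain == chain &
                        model$atoms$resname %in% .MODIFIED_AA, , drop = FALSE]
  a <- unique(rbind(a, amod))
  out <- list()
  for (i in seq_len(nrow(map))) {
    ra <- a[a$resno == map$orig_resno[i] & a$icode == map$orig_icode[i], ,
            drop = FALSE]
    if (!nrow(ra)) next
    ra$chain <- new_label
    ra$resno <- label_num(map$label[i])
    ra$icode <- sub("^[0-9]+", "", map$label[i])
    out[[length(out) + 1L]] <- ra
  }
  atoms <- do.call(rbind, out)
  list(atoms = atoms, map = map, orig_chain = chain,
       role = numbered$role, scheme = numbered$scheme)
}
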