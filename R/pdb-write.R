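#' Write an antibody-antigen set as an annotated Fv PDB file
#'
#' Emits the canonical output format: the bulk PDB header is replaced by
#' REMARK 950 records carrying the numbering scheme, experimental method,
#' resolution/R-factor/R-free where present, the mapping from the new chain
#' labels (L/H for the antibody; original labels for the antigen, with L and
#' H lowered to l and h) to the labels in the source file, and the antibody
#' and antigen molecule names and species. ATOM/HETATM records follow, with
#' antibody atoms renumbered under the requested scheme. Output is
#' byte-stable for identical input.
#'
#' @param set An \code{abfv_set} produced by the pipeline (see
#'   [process_entry()]).
#' @param scheme One of \code{"kabat"}, \code{"chothia"}, \code{"martin"}.
#' @param file Optional path; when given the text is also written there.
#' @return The PDB-format text as a character vector of lines (invisibly
#'   when \code{file} is given).
#' @export
write_fv_file <- function(set, scheme = "kabat", file = NULL) {
  scheme <- match.arg(scheme, c("kabat", "chothia", "martin"))
  numbered <- set$numbered[[scheme]]
  if (is.null(numbered) || !length(numbered)) {
    stop("antibody chains of ", set$set_id, " are not numbered under ",
         scheme)
  }
  meta <- set$meta
  rem <- c(
    sprintf("REMARK 950 SCHEME %s",
            c(kabat = "Kabat", chothia = "Chothia", martin = "Martin")[scheme]),
    if (!is.na(meta$method)) sprintf("REMARK 950 METHOD %s", meta$method),
    if (!is.na(meta$resolution))
      sprintf("REMARK 950 RESOLUTION %.2f", meta$resolution),
    if (!is.na(meta$r_factor))
      sprintf("REMARK 950 RFACTOR %.3f", meta$r_factor),
    if (!is.na(meta$r_free)) sprintf("REMARK 950 RFREE %.3f", meta$r_free)
  )
  for (nl in names(set$ab_chains)) {
    rem <- c(rem, sprintf("REMARK 950 CHAIN %s %s", nl, set$ab_chains[[nl]]))
  }
  for (nl in names(set$ag_chains)) {
    rem <- c(rem, sprintf("REMARK 950 CHAIN %s %s", nl, set$ag_chains[[nl]]))
  }
  ann <- function(key, val) {
    if (!is.null(val) && !is.na(val) && nzchar(val)) {
      sprintf("REMARK 950 %s %s", key, val)
    }
  }
  rem <- c(rem,
           ann("ABNAME", set$abname), ann("ABSPECIES", set$abspecies),
           ann("AGNAME", set$agname), ann("AGSPECIES", set$agspecies))

  body <- character(0)
  serial <- 0L
  emit <- function(atoms, ter = TRUE) {
    ln <- character(nrow(atoms) + as.integer(ter && nrow(atoms) > 0))
    for (i in seq_len(nrow(atoms))) {
      serial <<- serial + 1L
      ln[i] <- format_atom_line(atoms[i, ], serial)
    }
    if (ter && nrow(atoms) > 0) {
      serial <<- serial + 1L
      last <- atoms[nrow(atoms), ]
      ln[length(ln)] <- sprintf("TER   %5d      %3s %1s%4d%1s",
                                serial, last$resname, last$chain,
                                last$resno, ifelse(last$icode == "", " ",
                                                   last$icode))
    }
    body <<- c(body, ln)
  }
  for (role in c("L", "H")) {
    if (!is.null(numbered[[role]])) emit(numbered[[role]]$atoms)
  }
  if (!is.null(set$antigen_atoms) && nrow(set$antigen_atoms)) {
    for (ch in unique(set$antigen_atoms$chain)) {
      ca <- set$antigen_atoms[set$antigen_atoms$chain == ch, , drop = FALSE]
      emit(ca, ter = !all(ca$het))
    }
  }
  text <- c(rem, body, "END")
  if (!is.null(file)) {
    writeLines(text, file)
    return(invisible(text))
  }
  text
}

format_atom_line <- function(a, serial = a$serial) {
  name <- a$name
  if (nchar(name) < 4) name <- paste0(" ", name)
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          ifelse(a$het, "HETATM", "ATOM"), serial, name,
          ifelse(a$alt == "", " ", a$alt), a$resname, a$chain, a$resno,
          ifelse(a$icode == "", " ", a$icode),
          a$x, a$y, a$z, a$occ, a$b, a$element)
}
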