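#' Parse a legacy PDB-format file into a structure model
#'
#' Reads ATOM/HETATM coordinates (first model only), SEQRES sequences,
#' CONECT covalent links, REMARK 350 BIOMT transformation matrices and the
#' header metadata (experimental method, resolution, R-factor, R-free,
#' COMPND/SOURCE molecule names and species) used downstream for chain
#' typing, symmetry expansion and output annotation.
#'
#' Alternate-location duplicates are reduced to the highest-occupancy
#' conformer (ties: first in file). Blank chain labels are mapped to
#' \code{"0"} so that every chain is addressable. Waters are retained in the
#' atom table but are never considered hapten candidates.
#'
#' @param file Path to a PDB-format file.
#' @return An object of class \code{abfv_structure}: a list with elements
#'   \code{header} (list: \code{pdb_code}, \code{method}, \code{resolution},
#'   \code{r_factor}, \code{r_free}), \code{atoms} (data frame of atom
#'   records), \code{seqres} (named character vector of one-letter chain
#'   sequences), \code{conect} (two-column matrix of serial pairs),
#'   \code{transforms} (list of BIOMT transforms), \code{compnd} and
#'   \code{source} (named character vectors keyed by chain label) and
#'   \code{nucleic} (named logical, per-chain nucleic-acid flag).
#' @seealso [parse_pdb()] for parsing in-memory text,
#'   [sequence_from_atoms()], [expand_symmetry()], [write_fv_file()]
#' @export
read_pdb_file <- function(file) {
  if (!file.exists(file)) stop("PDB file not found: ", file)
  lines <- readLines(file, warn = FALSE)
  parse_pdb_lines(lines)
}

#' Parse PDB-format text into a structure model
#'
#' @param text A single string (or character vector of lines) of legacy
#'   PDB-format text containing at least one ATOM or HETATM record.
#' @return See [read_pdb_file()].
#' @export
parse_pdb <- function(text) {
  lines <- if (length(text) == 1L && grepl("\n", text, fixed = TRUE)) {
    strsplit(text, "\n", fixed = TRUE)[[1]]
  } else {
    text
  }
  parse_pdb_lines(lines)
}

parse_pdb_lines <- function(lines) {
  rec <- substr(lines, 1, 6)
  if (!any(rec %in% c("ATOM  ", "HETATM"))) {
    stop("empty structure: no ATOM or HETATM records")
  }
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(lines, tmp)
  pdb <- suppressWarnings(bio3d::read.pdb(tmp, multi = FALSE, rm.alt = FALSE,
                                          verbose = FALSE))
  at <- pdb$atom
  atoms <- data.frame(
    serial  = as.integer(at$eleno),
    name    = trimws(at$elety),
    alt     = ifelse(is.na(at$alt), "", at$alt),
    resname = trimws(at$resid),
    chain   = ifelse(is.na(at$chain) | at$chain == " " | at$chain == "",
                     "0", at$chain),
    resno   = as.integer(at$resno),
    icode   = ifelse(is.na(at$insert), "", at$insert),
    x = at$x, y = at$y, z = at$z,
    occ = ifelse(is.na(at$o), 1, at$o),
    b   = ifelse(is.na(at$b), 0, at$b),
    element = toupper(ifelse(is.na(at$elesy), "", trimws(at$elesy))),
    het = at$type == "HETATM",
    stringsAsFactors = FALSE
  )
  bad <- !is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)
  if (any(bad)) {
    warning(sum(bad), " atom record(s) with non-finite coordinates skipped")
    atoms <- atoms[!bad, , drop = FALSE]
  }
  # infer missing element symbols from the atom name
  noel <- atoms$element == ""
  if (any(noel)) {
    atoms$element[noel] <-
      toupper(substr(gsub("[0-9']", "", atoms$name[noel]), 1, 1))
  }
  atoms <- reduce_alt_loc(atoms)

  seqres3 <- pdb$seqres
  seqres <- character(0)
  nucleic_seqres <- logical(0)
  if (length(seqres3)) {
    ch <- names(seqres3)
    ch[is.na(ch) | ch == " " | ch == ""] <- "0"
    seqres <- vapply(split(unname(seqres3), ch), function(rr) {
      paste(aa3to1(trimws(rr)), collapse = "")
    }, character(1))
    nucleic_seqres <- vapply(split(unname(seqres3), ch), function(rr) {
      mean(is_nucleic_res(trimws(rr))) > 0.5
    }, logical(1))
    # preserve file order of chains
    ord <- unique(ch)
    seqres <- seqres[ord]
    nucleic_seqres <- nucleic_seqres[ord]
  }

  conect <- parse_conect(lines, atoms$serial)
  transforms <- parse_biomt(lines)
  header <- parse_header_meta(lines)
  cs <- parse_compnd_source(lines)

  chains <- unique(c(atoms$chain, names(seqres)))
  nucleic <- stats::setNames(logical(length(chains)), chains)
  for (c1 in chains) {
    ca <- atoms[atoms$chain == c1 & !is_water(atoms$resname), , drop = FALSE]
    res <- unique(ca$resname)
    from_atoms <- length(res) > 0 && mean(is_nucleic_res(res)) > 0.5
    from_seq <- isTRUE(nucleic_seqres[c1])
    nucleic[c1] <- from_atoms || from_seq
  }

  structure(list(
    header = header, atoms = atoms, seqres = seqres, conect = conect,
    transforms = transforms, compnd = cs$compnd, source = cs$source,
    nucleic = nucleic
  ), class = "abfv_structure")
}

# Keep the highest-occupancy alternate conformer per atom; ties go to the
# first record in the file. Never changes the residue count.
reduce_alt_loc <- function(atoms) {
  if (!any(atoms$alt != "")) return(atoms)
  key <- paste(atoms$chain, atoms$resno, atoms$icode, atoms$name, sep = "\r")
  keep <- rep(TRUE, nrow(atoms))
  for (idx in split(seq_len(nrow(atoms)), key)) {
    if (length(idx) > 1L) {
      best <- idx[which.max(atoms$occ[idx])]
      keep[setdiff(idx, best)] <- FALSE
    }
  }
  atoms[keep, , drop = FALSE]
}

parse_conect <- function(lines, serials) {
  cl <- lines[substr(lines, 1, 6) == "CONECT"]
  if (!length(cl)) return(matrix(integer(0), ncol = 2))
  pairs <- list()
  for (ln in cl) {
    flds <- suppressWarnings(as.integer(c(
      substr(ln, 7, 11), substr(ln, 12, 16), substr(ln, 17, 21),
      substr(ln, 22, 26), substr(ln, 27, 31))))
    flds <- flds[!is.na(flds)]
    if (length(flds) >= 2) {
      base <- flds[1]
      for (other in flds[-1]) {
        pairs[[length(pairs) + 1L]] <- sort(c(base, other))
      }
    }
  }
  if (!length(pairs)) return(matrix(integer(0), ncol = 2))
  m <- unique(do.call(rbind, pairs))
  known <- m[, 1] %in% serials & m[, 2] %in% serials
  if (any(!known)) {
    warning("dropped ", sum(!known),
            " CONECT pair(s) referencing unknown atom serials")
    m <- m[known, , drop = FALSE]
  }
  m
}

parse_biomt <- function(lines) {
  rl <- lines[substr(lines, 1, 10) == "REMARK 350"]
  transforms <- list()
  biomol <- NA_integer_
  chains <- character(0)
  rows <- list()  # transform index -> list of up to 3 rows
  flush_rows <- function() {
    for (nm in names(rows)) {
      r <- rows[[nm]]
      if (length(r) == 3L) {
        m <- do.call(rbind, r)
        transforms[[length(transforms) + 1L]] <<- list(
          biomolecule = biomol, chains = chains,
          rot = m[, 1:3, drop = FALSE], trans = m[, 4])
      }
    }
    rows <<- list()
  }
  for (ln in rl) {
    body <- substr(ln, 11, nchar(ln))
    if (grepl("BIOMOLECULE:", body)) {
      flush_rows()
      biomol <- suppressWarnings(as.integer(sub(".*BIOMOLECULE:\\s*", "", body)))
      chains <- character(0)
    } else if (grepl("CHAINS:", body)) {
      cc <- sub(".*CHAINS:\\s*", "", body)
      chains <- c(chains, trimws(strsplit(cc, ",")[[1]]))
      chains <- chains[chains != ""]
    } else if (grepl("^\\s*BIOMT[123]", body)) {
      row_i <- as.integer(substr(sub("^\\s*BIOMT", "", body), 1, 1))
      rest <- sub("^\\s*BIOMT[123]\\s+", "", body)
      vals <- suppressWarnings(as.numeric(strsplit(trimws(rest), "\\s+")[[1]]))
      # first value is the transform serial number
      if (length(vals) >= 5 && !anyNA(vals[1:5])) {
        id <- as.character(vals[1])
        if (is.null(rows[[id]])) rows[[id]] <- list()
        rows[[id]][[row_i]] <- vals[2:5]
      }
    }
  }
  flush_rows()
  transforms
}

parse_header_meta <- function(lines) {
  rec <- substr(lines, 1, 6)
  pdb_code <- NA_character_
  hl <- lines[rec == "HEADER"]
  if (length(hl)) {
    code <- trimws(substr(hl[1], 63, 66))
    if (nchar(code) == 4) pdb_code <- toupper(code)
  }
  method <- NA_character_
  el <- lines[rec == "EXPDTA"]
  if (length(el)) method <- trimws(substr(el[1], 11, nchar(el[1])))
  resolution <- NA_real_
  r2 <- lines[substr(lines, 1, 10) == "REMARK   2"]
  r2 <- r2[grepl("RESOLUTION", r2)]
  if (length(r2)) {
    v <- regmatches(r2[1], regexpr("[0-9]+\\.[0-9]+", r2[1]))
    if (length(v)) resolution <- as.numeric(v)
  }
  r_factor <- NA_real_
  r_free <- NA_real_
  r3 <- lines[substr(lines, 1, 10) == "REMARK   3"]
  rw <- r3[grepl("R VALUE", r3) & grepl("WORKING", r3)]
  if (length(rw)) {
    v <- regmatches(rw[1], regexpr("[0-9]+\\.[0-9]+", rw[1]))
    if (length(v)) r_factor <- as.numeric(v)
  }
  rf <- r3[grepl("FREE R VALUE", r3) & !grepl("ERROR|COUNT|SELECTION", r3)]
  if (length(rf)) {
    v <- regmatches(rf[1], regexpr("[0-9]+\\.[0-9]+", rf[1]))
    if (length(v)) r_free <- as.numeric(v)
  }
  list(pdb_code = pdb_code, method = method, resolution = resolution,
       r_factor = r_factor, r_free = r_free)
}

# COMPND/SOURCE token records: MOL_ID / MOLECULE / CHAIN /
# ORGANISM_SCIENTIFIC. Returns per-chain named vectors.
parse_compnd_source <- function(lines) {
  pull <- function(recname, field) {
    rl <- lines[substr(lines, 1, 6) == recname]
    if (!length(rl)) return(character(0))
    body <- paste(trimws(substr(rl, 11, 80)), collapse = " ")
    mols <- strsplit(body, "MOL_ID:")[[1]]
    mols <- mols[nzchar(trimws(mols))]
    out <- character(0)
    for (m in mols) {
      toks <- strsplit(m, ";")[[1]]
      val <- NA_character_
      chains <- character(0)
      for (tk in toks) {
        tk <- trimws(tk)
        if (startsWith(tk, paste0(field, ":"))) {
          val <- trimws(sub(paste0(field, ":"), "", tk, fixed = TRUE))
        } else if (startsWith(tk, "CHAIN:")) {
          chains <- trimws(strsplit(sub("CHAIN:", "", tk, fixed = TRUE),
                                    ",")[[1]])
        }
      }
      if (!is.na(val) && length(chains)) {
        out[chains] <- val
      }
    }
    out
  }
  list(compnd = pull("COMPND", "MOLECULE"),
       source = pull("SOURCE", "ORGANISM_SCIENTIFIC"))
}

#' @export
print.abfv_structure <- function(x, ...) {
  cat("PDB structure", x$header$pdb_code %||% "", "\n")
  cat("  method:", x$header$method %||% "unknown",
      " resolution:", x$header$resolution, "\n")
  ch <- unique(x$atoms$chain)
  cat("  chains:", paste(ch, collapse = " "), "\n")
  cat("  atoms:", nrow(x$atoms),
      " (", sum(x$atoms$het), "HETATM )\n")
  cat("  transforms:", length(x$transforms),
      " conect pairs:", nrow(x$conect), "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

#' Extract the amino-acid sequence of a chain from its ATOM records
#'
#' Polymer residues of the chain are taken in residue order; non-standard
#' residues are mapped through a 3-to-1 letter table (e.g. MSE to M) and
#' unknown ATOM residue names become \code{X}. HETATM-only groups (ligands,
#' waters) are excluded, as are nucleic-acid residues.
#'
#' @param model An \code{abfv_structure}.
#' @param chain Chain label.
#' @return One-letter sequence string, with attribute \code{residues}: a
#'   data frame (\code{resno}, \code{icode}, \code{resname}, \code{aa}) of
#'   the contributing residues in order.
#' @export
sequence_from_atoms <- function(model, chain) {
  a <- model$atoms
  if (!chain %in% a$chain) stop("chain not present: ", chain)
  a <- a[a$chain == chain, , drop = FALSE]
  a <- a[!is_water(a$resname) & !is_nucleic_res(a$resname), , drop = FALSE]
  # a residue is polymer if it has any ATOM record, or is a known
  # modified amino acid deposited as HETATM
  key <- paste(a$resno, a$icode, a$resname, sep = "\r")
  first <- !duplicated(key)
  info <- a[first, c("resno", "icode", "resname"), drop = FALSE]
  has_atom <- vapply(split(!a$het, factor(key, levels = key[first])), any,
                     logical(1))
  polymer <- has_atom | info$resname %in% .MODIFIED_AA
  info <- info[polymer, , drop = FALSE]
  info$aa <- ifelse(is_polymer_aa(info$resname), aa3to1(info$resname), "X")
  seq <- paste(info$aa, collapse = "")
  attr(seq, "residues") <- info
  seq
}

# Non-hydrogen polymer atoms of a chain (used for contact computations).
chain_atoms <- function(model, chain, polymer_only = TRUE, heavy_only = TRUE) {
  a <- model$atoms[model$atoms$chain == chain, , drop = FALSE]
  a <- a[!is_water(a$resname), , drop = FALSE]
  if (polymer_only) {
    a <- a[!a$het | a$resname %in% .MODIFIED_AA | is_nucleic_res(a$resname), ,
           drop = FALSE]
  }
  if (heavy_only) a <- a[!a$element %in% c("H", "D"), , drop = FALSE]
  a
}

#' Enumerate non-water HETATM groups of a structure
#'
#' Groups HETATM records by (residue name, chain, residue number, insertion
#' code), excluding waters and modified amino acids that belong to polymer
#' chains. These groups are the hapten/carbohydrate/lipid antigen candidates.
#'
#' @param model An \code{abfv_structure}.
#' @return List of groups; each has \code{group_id}, \code{resname},
#'   \code{chain}, \code{resno}, \code{icode} and \code{atoms} (data frame).
#' @export
het_groups <- function(model) {
  a <- model$atoms
  a <- a[a$het & !is_water(a$resname) & !a$resname %in% .MODIFIED_AA &
           !is_nucleic_res(a$resname), , drop = FALSE]
  if (!nrow(a)) return(list())
  key <- paste(a$resname, a$chain, a$resno, a$icode, sep = "_")
  lapply(split(seq_len(nrow(a)), factor(key, levels = unique(key))),
         function(idx) {
    g <- a[idx, , drop = FALSE]
    list(group_id = paste(g$resname[1], g$chain[1], g$resno[1], g$icode[1],
                          sep = "_"),
         resname = g$resname[1], chain = g$chain[1], resno = g$resno[1],
         icode = g$icode[1], atoms = g)
  })
}

# TRUE if a CONECT pair links any atom of `serials_a` to any of `serials_b`.
conect_links <- function(model, serials_a, serials_b) {
  m <- model$conect
  if (!nrow(m)) return(FALSE)
  any((m[, 1] %in% serials_a & m[, 2] %in% serials_b) |
      (m[, 1] %in% serials_b & m[, 2] %in% serials_a))
}

# Polymer (non-het, non-water, non-nucleic) chains in file order.
polymer_chains <- function(model) {
  a <- model$atoms
  a <- a[!is_water(a$resname), , drop = FALSE]
  keep <- !a$het | a$resname %in% .MODIFIED_AA | is_nucleic_res(a$resname)
  unique(a$chain[keep])
}
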