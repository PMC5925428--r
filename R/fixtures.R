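# Seeded generator of synthetic PDB entries.
#
# Chains are laid out as pseudo-physical residue grids ("snakes") kept far
# apart, and inter-chain contacts are engineered explicitly: designated
# side-chain/carbonyl atoms are relocated in pairs to isolated grid sites
# 3.5 A apart, one interface per zone, zones and chain bodies separated by
# far more than the contact cutoff. The number of atom pairs within 4 A
# between two chains therefore equals the designed count exactly, and the
# residues contributing contacts (CDR or framework) are under full control.
# The rules being exercised depend only on distances, labels and sequences,
# so idealized geometry is sufficient; nothing here attempts real folds.

.AA1TO3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
             Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
             L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
             S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

.DNA1TO3 <- c(A = "DA", C = "DC", G = "DG", T = "DT")

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate a numberable variable-domain sequence variant
#'
#' Starts from the packaged consensus and applies seeded point mutations at
#' CDR positions and optional CDR length changes (insertions or deletions
#' applied inside the loops), producing realistic distinct antibodies that
#' still number under all three schemes.
#'
#' @param role \code{"L"} or \code{"H"}.
#' @param n_mut Number of CDR point mutations.
#' @param cdr_delta Named integer vector of loop length changes, e.g.
#'   \code{c(L1 = 2, L3 = -1)}.
#' @param seed Seed for reproducibility.
#' @return Amino-acid sequence string.
#' @export
fixture_sequence <- function(role = c("L", "H"), n_mut = 0,
                             cdr_delta = integer(0), seed = 1) {
  role <- match.arg(role)
  tab <- scheme_table("kabat")
  seq <- strsplit(tab$ref[[role]], "")[[1]]
  regions <- if (role == "L") {
    list(L1 = 24:34, L2 = 50:56, L3 = 89:97)
  } else {
    list(H1 = 31:35, H2 = 50:65, H3 = 98:105)
  }
  with_seed(seed, {
    # apply length changes from the C-terminal loop backwards so indices
    # of earlier regions stay valid
    for (rg in rev(names(regions))) {
      d <- if (rg %in% names(cdr_delta)) cdr_delta[[rg]] else 0
      if (d == 0) next
      ix <- regions[[rg]]
      mid <- ix[ceiling(length(ix) / 2)]
      if (d > 0) {
        ins <- sample(names(.AA1TO3), d, replace = TRUE)
        seq <- append(seq, ins, after = mid)
      } else {
        seq <- seq[-(mid + seq_len(-d) - 1)]
      }
    }
    cdr_pos <- unlist(regions)
    cdr_pos <- cdr_pos[cdr_pos <= length(seq)]
    if (n_mut > 0) {
      pos <- sample(cdr_pos, min(n_mut, length(cdr_pos)))
      for (p in pos) {
        seq[p] <- sample(setdiff(names(.AA1TO3), seq[p]), 1)
      }
    }
  })
  paste(seq, collapse = "")
}

# Residue grid: residue i sits at origin + (5*col, 5*row, 0), rows of 17.
# Keeps L36 and L87 C-alphas ~15 A apart, as in a folded light chain.
snake_center <- function(i, origin) {
  c(origin[1] + 5 * ((i - 1) %% 17),
    origin[2] + 5 * ((i - 1) %/% 17),
    origin[3])
}

fixture_chain_atoms <- function(seq, chain, origin, nucleic = FALSE) {
  aas <- strsplit(seq, "")[[1]]
  rows <- list()
  for (i in seq_along(aas)) {
    ctr <- snake_center(i, origin)
    if (nucleic) {
      resname <- .DNA1TO3[[aas[i]]]
      at <- data.frame(
        name = c("P", "C1'", "N1"),
        x = ctr[1] + c(-1.5, 0, 1.5), y = ctr[2] + c(0, 0, 0.9),
        z = ctr[3], element = c("P", "C", "N"),
        stringsAsFactors = FALSE)
    } else {
      resname <- .AA1TO3[[aas[i]]]
      if (is.null(resname)) resname <- "UNK"
      nm <- c("N", "CA", "C", "O", if (aas[i] != "G") "CB")
      at <- data.frame(
        name = nm,
        x = ctr[1] + c(-1.5, 0, 1.5, 1.5, 0)[seq_along(nm)],
        y = ctr[2] + c(0, 0, 0, 1.1, 1.4)[seq_along(nm)],
        z = ctr[3] + c(0.3, 0, 0.3, 0.3, 0.8)[seq_along(nm)],
        element = substr(nm, 1, 1),
        stringsAsFactors = FALSE)
    }
    at$resname <- resname
    at$chain <- chain
    at$resno <- i
    rows[[i]] <- at
  }
  do.call(rbind, rows)
}

# CDR / framework residue indices of a sequence, via the package's own
# Kabat numbering (the fixture must agree with the pipeline's definition).
fixture_residue_classes <- function(seq, role) {
  nc <- number_chain(seq, role, "kabat")
  if (is.null(nc)) stop("fixture sequence is not numberable")
  cdr <- nc$residues$qpos[
    cdr_membership(nc$residues$label, role) != "framework"]
  fw <- nc$residues$qpos[
    cdr_membership(nc$residues$label, role) == "framework"]
  list(cdr = cdr, fw = fw)
}

# Interface engineering state: allocates (residue, atom) slots per chain and
# zone grid sites per interface.
new_entry_state <- function() {
  env <- new.env()
  env$zone <- 0L
  env$used <- list()
  env
}

next_slots <- function(state, chain, residues, atoms_df, n) {
  used <- state$used[[chain]]
  if (is.null(used)) used <- character(0)
  slot_names <- if (any(atoms_df$resname %in% .NUCLEIC_RES)) {
    c("P", "C1'", "N1")
  } else {
    c("O", "C", "CB")
  }
  out <- list()
  for (r in residues) {
    for (nm in slot_names) {
      key <- paste(r, nm)
      if (key %in% used) next
      if (!any(atoms_df$resno == r & atoms_df$name == nm)) next
      out[[length(out) + 1L]] <- c(r, nm)
      used <- c(used, key)
      if (length(out) == n) {
        state$used[[chain]] <- used
        return(out)
      }
    }
  }
  stop("not enough relocatable atoms on chain ", chain)
}

zone_sites <- function(state, n) {
  state$zone <- state$zone + 1L
  k <- seq_len(n) - 1L
  cbind(300 * (state$zone - 1L) + 12 * (k %% 12L),
        -500 - 12 * (k %/% 12L),
        0)
}

# Relocate designated atoms of two chains onto paired zone sites, creating
# exactly `n` inter-chain contacts at 3.5 A.
apply_interface <- function(state, chains, a, b, n, side_a, side_b,
                            classes) {
  pick <- function(lab, side) {
    if (side == "any") sort(unique(chains[[lab]]$resno))
    else classes[[lab]][[side]]
  }
  slots_a <- next_slots(state, a, pick(a, side_a), chains[[a]], n)
  slots_b <- next_slots(state, b, pick(b, side_b), chains[[b]], n)
  sites <- zone_sites(state, n)
  for (k in seq_len(n)) {
    ia <- which(chains[[a]]$resno == as.integer(slots_a[[k]][1]) &
                  chains[[a]]$name == slots_a[[k]][2])
    ib <- which(chains[[b]]$resno == as.integer(slots_b[[k]][1]) &
                  chains[[b]]$name == slots_b[[k]][2])
    chains[[a]][ia, c("x", "y", "z")] <- sites[k, ]
    chains[[b]][ib, c("x", "y", "z")] <- sites[k, ] + c(3.5, 0, 0)
  }
  chains
}

#' Generate idealized Fv coordinates for a light/heavy pair
#'
#' Places the two chains on separated residue grids and engineers a
#' framework-framework packing interface between them so that contact-based
#' pairing fires; the L36/L87 geometry of the light chain matches a folded
#' domain closely enough for the dimer rules.
#'
#' @param seq_l,seq_h Sequences (numberable under the shipped schemes).
#' @param origin Numeric xyz offset of the antibody.
#' @param chain_l,chain_h Chain labels.
#' @param n_interface Engineered light-heavy contact count.
#' @return List \code{atoms} (data frame for both chains) and
#'   \code{classes} (CDR/framework residue indices per chain).
#' @export
fixture_fv_coordinates <- function(seq_l, seq_h, origin = c(0, 0, 0),
                                   chain_l = "L", chain_h = "H",
                                   n_interface = 40) {
  state <- new_entry_state()
  chains <- list()
  chains[[chain_l]] <- fixture_chain_atoms(seq_l, chain_l, origin)
  chains[[chain_h]] <- fixture_chain_atoms(seq_h, chain_h,
                                           origin + c(0, 100, 0))
  classes <- list()
  classes[[chain_l]] <- fixture_residue_classes(seq_l, "L")
  classes[[chain_h]] <- fixture_residue_classes(seq_h, "H")
  chains <- apply_interface(state, chains, chain_l, chain_h, n_interface,
                            "fw", "fw", classes)
  list(atoms = do.call(rbind, chains), classes = classes)
}

#' Assemble a synthetic PDB entry
#'
#' The generic constructor behind the canned fixture generators. Takes
#' chain descriptions, engineered interfaces, HETATM groups, optional
#' REMARK 350 BIOMT transforms and header metadata, and emits complete
#' legacy PDB text (HEADER, COMPND, SOURCE, EXPDTA, REMARK 2/3/350, SEQRES,
#' ATOM/HETATM, CONECT, END). Chain emission order is taken as given, so
#' callers can scramble it deliberately.
#'
#' @param code Four-character entry code (synthetic codes look like real
#'   ones but are not PDB depositions).
#' @param chains List of chain descriptions: \code{label}, \code{seq},
#'   \code{role} (\code{"L"}, \code{"H"}, \code{"AG"}, \code{"DNA"});
#'   optional \code{missing} (residue indices absent from ATOM records),
#'   \code{leader} (extra N-terminal SEQRES sequence), \code{name},
#'   \code{species}.
#' @param interfaces List of \code{list(a =, b =, n =, side_a =,
#'   side_b =)}; sides are \code{"cdr"}, \code{"fw"} or \code{"any"}.
#' @param hets List of HETATM group descriptions: \code{resname},
#'   \code{chain}, \code{resno}, \code{n_atoms}, \code{target} (antibody
#'   chain), \code{n_contacts}, \code{side}, \code{covalent}.
#' @param biomt Optional list of transforms
#'   (\code{list(rot = , trans = , chains = )}); an identity transform is
#'   always emitted first.
#' @param resolution,r_factor,r_free Header metadata (NA to omit).
#' @param waters Number of far-away water molecules to add.
#' @param altloc Add an alternate-location pair on the first residue.
#' @param models Emit the coordinates this many times as MODEL blocks.
#' @return Character vector of PDB lines.
#' @export
fixture_entry <- function(code, chains, interfaces = list(), hets = list(),
                          biomt = NULL, resolution = 2.0, r_factor = 0.193,
                          r_free = 0.221, waters = 0, altloc = FALSE,
                          models = 1) {
  state <- new_entry_state()
  atoms <- list()
  classes <- list()
  for (k in seq_along(chains)) {
    ch <- chains[[k]]
    origin <- ch$origin %||% c(0, 200 * (k - 1), 0)
    atoms[[ch$label]] <- fixture_chain_atoms(ch$seq, ch$label, origin,
                                             nucleic = ch$role == "DNA")
    if (ch$role %in% c("L", "H")) {
      classes[[ch$label]] <- fixture_residue_classes(ch$seq, ch$role)
    }
  }
  for (iface in interfaces) {
    atoms <- apply_interface(state, atoms, iface$a, iface$b, iface$n,
                             iface$side_a %||% "any",
                             iface$side_b %||% "any", classes)
  }

  het_atoms <- list()
  conect_keys <- list()  # list of (key_het, key_ab)
  for (g in hets) {
    side <- g$side %||% "cdr"
    res_pool <- classes[[g$target]][[side]]
    slots <- next_slots(state, g$target, res_pool, atoms[[g$target]],
                        g$n_contacts)
    sites <- zone_sites(state, g$n_contacts)
    ga <- data.frame(
      name = paste0("C", seq_len(g$n_atoms)),
      x = NA_real_, y = NA_real_, z = NA_real_, element = "C",
      resname = g$resname, chain = g$chain, resno = g$resno,
      stringsAsFactors = FALSE)
    for (k in seq_len(g$n_contacts)) {
      ia <- which(atoms[[g$target]]$resno == as.integer(slots[[k]][1]) &
                    atoms[[g$target]]$name == slots[[k]][2])
      atoms[[g$target]][ia, c("x", "y", "z")] <- sites[k, ]
      ga[k, c("x", "y", "z")] <- c(sites[k, 1] + 3.5, sites[k, 2],
                                   sites[k, 3])
    }
    if (g$n_atoms > g$n_contacts) {
      extra <- seq(g$n_contacts + 1, g$n_atoms)
      ga$x[extra] <- sites[1, 1] + 3.5
      ga$y[extra] <- sites[1, 2] + 5 * seq_along(extra)
      ga$z[extra] <- sites[1, 3]
    }
    ga$het <- TRUE
    het_atoms[[length(het_atoms) + 1L]] <- ga
    if (isTRUE(g$covalent)) {
      conect_keys[[length(conect_keys) + 1L]] <- list(
        het = paste(g$chain, g$resno, "C1", "het"),
        ab = paste(g$target, slots[[1]][1], slots[[1]][2], "atom"))
    }
  }

  # header records
  lines <- c(
    sprintf("HEADER    IMMUNE SYSTEM                           01-JAN-20   %s", code),
    compnd_source_lines(chains),
    "EXPDTA    X-RAY DIFFRACTION",
    if (!is.na(resolution))
      sprintf("REMARK   2 RESOLUTION. %7.2f ANGSTROMS.", resolution),
    if (!is.na(r_factor))
      sprintf("REMARK   3   R VALUE            (WORKING SET) : %.3f", r_factor),
    if (!is.na(r_free))
      sprintf("REMARK   3   FREE R VALUE                     : %.3f", r_free)
  )
  if (!is.null(biomt)) {
    lines <- c(lines, biomt_lines(biomt))
  }
  for (ch in chains) {
    if (ch$role == "AGHET") next
    seqres_seq <- paste0(ch$leader %||% "", ch$seq)
    lines <- c(lines, seqres_lines(ch$label, seqres_seq,
                                   nucleic = ch$role == "DNA"))
  }

  # coordinates: assign serials in emission order
  serial <- 0L
  key_serial <- list()
  coord_lines <- character(0)
  emit_atom <- function(a, het) {
    serial <<- serial + 1L
    key_serial[[paste(a$chain, a$resno, a$name,
                      if (het) "het" else "atom")]] <<- serial
    rec <- list(name = a$name, alt = "", resname = a$resname,
                chain = a$chain, resno = a$resno, icode = "",
                x = a$x, y = a$y, z = a$z, occ = 1, b = 20,
                element = a$element, het = het)
    coord_lines <<- c(coord_lines, format_atom_line(rec, serial))
  }
  for (ch in chains) {
    a <- atoms[[ch$label]]
    if (!is.null(ch$missing) && length(ch$missing)) {
      a <- a[!a$resno %in% ch$missing, , drop = FALSE]
    }
    if (altloc && ch$label == chains[[1]]$label) {
      # alternate-location pair on the first CA: B conformer wins on occupancy
      i <- which(a$resno == 1 & a$name == "CA")[1]
      serial <- serial + 1L
      recA <- list(name = a$name[i], alt = "A", resname = a$resname[i],
                   chain = a$chain[i], resno = 1L, icode = "",
                   x = a$x[i] + 0.3, y = a$y[i], z = a$z[i],
                   occ = 0.4, b = 20, element = a$element[i], het = FALSE)
      coord_lines <- c(coord_lines, format_atom_line(recA, serial))
      serial <- serial + 1L
      recB <- list(name = a$name[i], alt = "B", resname = a$resname[i],
                   chain = a$chain[i], resno = 1L, icode = "",
                   x = a$x[i], y = a$y[i], z = a$z[i],
                   occ = 0.6, b = 20, element = a$element[i], het = FALSE)
      coord_lines <- c(coord_lines, format_atom_line(recB, serial))
      a <- a[-i, , drop = FALSE]
    }
    for (i in seq_len(nrow(a))) emit_atom(a[i, ], het = FALSE)
    last <- a[nrow(a), ]
    serial <- serial + 1L
    coord_lines <- c(coord_lines,
                     sprintf("TER   %5d      %3s %1s%4d ", serial,
                             last$resname, last$chain, last$resno))
  }
  for (ga in het_atoms) {
    for (i in seq_len(nrow(ga))) emit_atom(ga[i, ], het = TRUE)
  }
  if (waters > 0) {
    for (w in seq_len(waters)) {
      serial <- serial + 1L
      rec <- list(name = "O", alt = "", resname = "HOH", chain = "0",
                  resno = 900 + w, icode = "", x = 5000 + 10 * w, y = 5000,
                  z = 5000, occ = 1, b = 30, element = "O", het = TRUE)
      coord_lines <- c(coord_lines, format_atom_line(rec, serial))
    }
  }
  if (models > 1) {
    blocks <- unlist(lapply(seq_len(models), function(m) {
      c(sprintf("MODEL     %4d", m), coord_lines, "ENDMDL")
    }))
    coord_lines <- blocks
  }
  lines <- c(lines, coord_lines)
  for (ck in conect_keys) {
    lines <- c(lines, sprintf("CONECT%5d%5d", key_serial[[ck$het]],
                              key_serial[[ck$ab]]))
  }
  c(lines, "END")
}

compnd_source_lines <- function(chains) {
  # group consecutive chains sharing a molecule name into MOL_ID blocks
  nm <- vapply(chains, function(ch) ch$name %||% default_mol_name(ch$role),
               character(1))
  sp <- vapply(chains, function(ch) ch$species %||% "SYNTHETIC CONSTRUCT",
               character(1))
  lab <- vapply(chains, `[[`, character(1), "label")
  grp <- cumsum(c(TRUE, nm[-1] != nm[-length(nm)] |
                    sp[-1] != sp[-length(sp)]))
  compnd <- character(0); source <- character(0)
  cn <- 0L; sn <- 0L
  cline <- function(txt) {
    cn <<- cn + 1L
    if (cn == 1) sprintf("COMPND    %s", txt)
    else sprintf("COMPND %3d %s", cn, txt)
  }
  sline <- function(txt) {
    sn <<- sn + 1L
    if (sn == 1) sprintf("SOURCE    %s", txt)
    else sprintf("SOURCE %3d %s", sn, txt)
  }
  for (g in unique(grp)) {
    ix <- which(grp == g)
    compnd <- c(compnd, cline(sprintf("MOL_ID: %d;", g)),
                cline(sprintf("MOLECULE: %s;", nm[ix[1]])),
                cline(sprintf("CHAIN: %s;", paste(lab[ix], collapse = ", "))))
    source <- c(source, sline(sprintf("MOL_ID: %d;", g)),
                sline(sprintf("ORGANISM_SCIENTIFIC: %s;", sp[ix[1]])),
                sline(sprintf("CHAIN: %s;", paste(lab[ix], collapse = ", "))))
  }
  c(compnd, source)
}

default_mol_name <- function(role) {
  switch(role, L = "SYNTHETIC ANTIBODY LIGHT CHAIN",
         H = "SYNTHETIC ANTIBODY HEAVY CHAIN",
         DNA = "SYNTHETIC DNA", "SYNTHETIC ANTIGEN")
}

seqres_lines <- function(label, seq, nucleic = FALSE) {
  aas <- strsplit(seq, "")[[1]]
  res3 <- if (nucleic) .DNA1TO3[aas] else {
    r <- .AA1TO3[aas]
    r[is.na(r)] <- "UNK"
    r
  }
  n <- length(res3)
  out <- character(0)
  for (s in seq_len(ceiling(n / 13))) {
    chunk <- res3[((s - 1) * 13 + 1):min(s * 13, n)]
    out <- c(out, sprintf("SEQRES %3d %1s %4d  %s", s, label, n,
                          paste(sprintf("%-3s", chunk), collapse = " ")))
  }
  out
}

biomt_lines <- function(biomt) {
  out <- c("REMARK 350 BIOMOLECULE: 1")
  chains <- biomt[[1]]$chains
  out <- c(out, sprintf("REMARK 350 APPLY THE FOLLOWING TO CHAINS: %s",
                        paste(chains, collapse = ", ")))
  mats <- c(list(list(rot = diag(3), trans = c(0, 0, 0))), biomt)
  for (m in seq_along(mats)) {
    for (r in 1:3) {
      out <- c(out, sprintf(
        "REMARK 350   BIOMT%d %3d%10.6f%10.6f%10.6f     %10.5f",
        r, m, mats[[m]]$rot[r, 1], mats[[m]]$rot[r, 2], mats[[m]]$rot[r, 3],
        mats[[m]]$trans[r]))
    }
  }
  out
}
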