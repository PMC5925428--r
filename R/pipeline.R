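#' Process one PDB entry into antibody-antigen sets
#'
#' Runs the full per-entry pipeline: chain typing against the consensus
#' profile, antibody-form classification, light-dimer symmetry expansion
#' where the partner chain exists only through REMARK 350 BIOMT records,
#' numbering under all requested schemes (an entry in which any antibody
#' chain fails to number is rejected whole, never mis-numbered), chain
#' pairing by maximal contacts (or by L36/L87 geometry for light dimers),
#' antigen assignment with the CDR-versus-framework rules, anti-idiotype
#' resolution, and splitting into one set per antibody with shared antigens
#' replicated into every set that binds them.
#'
#' @param file Path to a PDB file (or an already parsed
#'   \code{abfv_structure}).
#' @param code Entry code; defaults to the HEADER record, then to the file
#'   name.
#' @param profile Consensus profile.
#' @param params Pipeline parameters.
#' @param schemes Numbering schemes to apply.
#' @return List of class \code{abfv_entry_result}: \code{status}
#'   (\code{"ok"} or \code{"rejected"}), \code{reason}, \code{sets} (list of
#'   \code{abfv_set}), \code{calls}, \code{form}, \code{unassigned} (chains
#'   in no set) and \code{binding_proteins}.
#' @export
process_entry <- function(file, code = NULL,
                          profile = consensus_profile(),
                          params = pipeline_params(),
                          schemes = c("kabat", "chothia", "martin")) {
  model <- if (inherits(file, "abfv_structure")) file else read_pdb_file(file)
  if (is.null(code)) {
    code <- model$header$pdb_code
    if (is.na(code) && is.character(file)) {
      code <- toupper(tools::file_path_sans_ext(basename(file)))
    }
  }
  reject <- function(reason) {
    structure(list(status = "rejected", reason = reason, code = code,
                   sets = list()), class = "abfv_entry_result")
  }

  calls <- assign_chain_types(model, profile, params$chain_score_threshold)
  form <- classify_form(calls, model, profile, params$chain_score_threshold)
  if (form$form == "rejected") return(reject(form$reject_reason))

  lights <- calls$chain[calls$final == "light"]
  heavies <- calls$chain[calls$final == "heavy"]

  # reconstruct the second chain of a light dimer present only through
  # crystallographic symmetry
  if (form$form == "light_only" && length(lights) == 1 &&
      any(!vapply(model$transforms, is_identity_transform, logical(1)))) {
    model <- expand_symmetry(model, chains = lights)
    copies <- attr(model, "symmetry_copies")
    for (new_ch in names(copies)) {
      src_row <- calls[calls$chain == copies[[new_ch]], , drop = FALSE]
      src_row$chain <- new_ch
      calls <- rbind(calls, src_row)
      lights <- c(lights, new_ch)
    }
  }

  # number every antibody chain under every scheme
  ab_chains <- c(lights, heavies)
  numbered <- list()
  for (ch in ab_chains) {
    call_row <- calls[calls$chain == ch, ][1, ]
    role <- if (call_row$final == "light") "L" else "H"
    src_seq <- chain_best_sequence(model, call_row)
    numbered[[ch]] <- list()
    for (sc in schemes) {
      nc <- number_chain(src_seq, role, sc)
      if (is.null(nc)) return(reject("numbering_failure"))
      rn <- renumber_structure(model, ch, nc, new_label = role,
                               source_seq = src_seq)
      if (is.null(rn)) return(reject("numbering_failure"))
      numbered[[ch]][[sc]] <- rn
    }
  }

  # assemble antibodies
  antibodies <- list()  # each: chains (named by role label), roles
  if (form$form == "complete") {
    pairs <- pair_light_heavy(model, lights, heavies, params)
    for (k in seq_len(nrow(pairs))) {
      antibodies[[length(antibodies) + 1L]] <-
        list(chains = c(L = pairs$light[k], H = pairs$heavy[k]))
    }
    unassigned <- attr(pairs, "unmatched")
  } else if (form$form == "light_only") {
    kmaps <- lapply(numbered, `[[`, "kabat")
    pairs <- pair_light_dimer(model, lights, kmaps, params)
    used <- c(pairs$chain_a, pairs$chain_b)
    for (k in seq_len(nrow(pairs))) {
      antibodies[[length(antibodies) + 1L]] <-
        list(chains = c(L = pairs$chain_a[k], H = pairs$chain_b[k]))
    }
    for (ch in setdiff(lights, used)) {
      antibodies[[length(antibodies) + 1L]] <- list(chains = c(L = ch))
    }
    unassigned <- character(0)
  } else {
    for (ch in heavies) {
      antibodies[[length(antibodies) + 1L]] <- list(chains = c(H = ch))
    }
    unassigned <- character(0)
  }
  if (!length(antibodies)) return(reject("no_antibody_assembled"))

  # deterministic order: file appearance of each antibody's first atoms
  first_serial <- vapply(antibodies, function(ab) {
    min(model$atoms$serial[model$atoms$chain %in% ab$chains])
  }, numeric(1))
  antibodies <- antibodies[order(first_serial)]

  for (i in seq_along(antibodies)) {
    chs <- antibodies[[i]]$chains
    antibodies[[i]]$numbered_kabat <- stats::setNames(
      lapply(chs, function(ch) numbered[[ch]][["kabat"]]), names(chs))
    antibodies[[i]]$sequence <- paste(vapply(chs, function(ch) {
      chain_best_sequence(model, calls[calls$chain == ch, ][1, ])
    }, character(1)), collapse = "|")
  }

  # antigen candidates: non-antibody polymer chains
  cand <- setdiff(polymer_chains(model), ab_chains)
  binding_proteins <- character(0)
  antigen_of <- vector("list", length(antibodies))
  if (length(cand)) {
    for (i in seq_along(antibodies)) {
      cls <- lapply(cand, function(ch) {
        classify_polymer_antigen(model, antibodies[[i]]$numbered_kabat, ch,
                                 params)
      })
      names(cls) <- cand
      pass <- cand[vapply(cls, function(x) x == "antigen", logical(1))]
      touching <- cand[vapply(cls, function(x)
        x == "antibody_binding_protein", logical(1))]
      chosen <- pass
      if (params$joint_antigen_rule == "summed") {
        profs <- lapply(cls, attr, "profile")
        joint <- cand[vapply(profs, function(p)
          p["cdr"] >= 1 && p["cdr"] > p["framework"], logical(1))]
        if (length(joint)) {
          tot <- Reduce(`+`, profs[joint])
          if (tot["cdr"] >= params$min_cdr_contacts &&
              tot["cdr"] > tot["framework"]) {
            chosen <- union(pass, joint)
          }
        }
      }
      binding_proteins <- union(binding_proteins, setdiff(touching, chosen))
      if (length(chosen)) {
        antigen_of[[i]] <- list(kind = "polymer", chains = sort(chosen))
      }
    }
  } else if (length(antibodies) >= 2) {
    partner <- resolve_anti_idiotype(antibodies, model, params)
    for (i in seq_along(antibodies)) {
      if (!is.null(partner[[i]])) {
        antigen_of[[i]] <- list(kind = "antibody",
                                chains = unname(
                                  antibodies[[partner[[i]]]]$chains))
      }
    }
  }

  # HETATM antigens for antibodies still free
  groups <- het_groups(model)
  if (length(groups)) {
    for (i in seq_along(antibodies)) {
      if (!is.null(antigen_of[[i]])) next
      best <- NULL; best_cdr <- 0
      for (g in groups) {
        res <- classify_het_antigen(model, antibodies[[i]]$numbered_kabat,
                                    g, params)
        if (res == "antigen" && attr(res, "profile")["cdr"] > best_cdr) {
          best <- g
          best_cdr <- attr(res, "profile")["cdr"]
        }
      }
      if (!is.null(best)) antigen_of[[i]] <- list(kind = "het", group = best)
    }
  }

  sets <- lapply(seq_along(antibodies), function(i) {
    build_set(model, code, i, antibodies[[i]], antigen_of[[i]], numbered,
              calls, form$form, schemes)
  })
  assigned <- unique(unlist(lapply(sets, function(s)
    c(unname(s$ab_chains), unname(s$ag_chains)))))
  unassigned <- setdiff(c(unassigned,
                          setdiff(cand, c(assigned, binding_proteins))),
                        assigned)
  structure(list(status = "ok", reason = "none", code = code, sets = sets,
                 calls = calls, form = form$form, unassigned = unassigned,
                 binding_proteins = binding_proteins),
            class = "abfv_entry_result")
}

build_set <- function(model, code, ordinal, antibody, antigen, numbered,
                      calls, form, schemes) {
  chs <- antibody$chains  # named by role label (L/H)
  num <- list()
  for (sc in schemes) {
    num[[sc]] <- list()
    for (rl in names(chs)) {
      rn <- numbered[[chs[[rl]]]][[sc]]
      rn$atoms$chain <- rl  # dimer second chain is written under label H
      num[[sc]][[rl]] <- rn
    }
  }
  ag_chains <- character(0)
  antigen_atoms <- NULL
  kinds <- character(0)
  if (!is.null(antigen)) {
    if (antigen$kind %in% c("polymer", "antibody")) {
      taken <- c(names(chs))
      for (ch in antigen$chains) {
        new_lab <- if (ch %in% c("L", "H")) tolower(ch) else ch
        if (new_lab %in% taken ||
            new_lab %in% names(ag_chains)) {
          stop("antigen chain label collision for ", ch, " in ", code)
        }
        ag_chains[new_lab] <- ch
        aa <- chain_atoms(model, ch, polymer_only = TRUE, heavy_only = FALSE)
        aa$chain <- new_lab
        antigen_atoms <- rbind(antigen_atoms, aa)
        kinds <- c(kinds,
                   if (isTRUE(model$nucleic[[ch]])) "nucleic" else "protein")
      }
    } else if (antigen$kind == "het") {
      g <- antigen$group
      new_lab <- if (g$chain %in% c("L", "H")) tolower(g$chain) else g$chain
      ag_chains[new_lab] <- g$chain
      aa <- g$atoms
      aa$chain <- new_lab
      antigen_atoms <- aa
      kinds <- "het"
    }
  }
  martin_maps <- num[["martin"]] %||% num[[schemes[1]]]
  len <- sum(vapply(martin_maps, function(rn) nrow(rn$map), numeric(1)))
  ag_orig <- unname(ag_chains)
  joined <- function(map, labels) {
    v <- unique(stats::na.omit(unname(map[labels])))
    if (length(v)) paste(v, collapse = "; ") else NA_character_
  }
  structure(list(
    set_id = paste0(code, "_", ordinal), pdb_code = code, ordinal = ordinal,
    form = form,
    complex_class = finalize_complex_class(kinds),
    ab_chains = as.list(chs),
    ag_chains = as.list(ag_chains),
    numbered = num, antigen_atoms = antigen_atoms, antigen_kinds = kinds,
    abname = joined(model$compnd, unlist(chs)),
    abspecies = joined(model$source, unlist(chs)),
    agname = joined(model$compnd, ag_orig),
    agspecies = joined(model$source, ag_orig),
    meta = model$header, length = len
  ), class = "abfv_set")
}

#' @export
print.abfv_set <- function(x, ...) {
  cat(x$set_id, ": ", x$form, " antibody (",
      paste(names(x$ab_chains), "=", unlist(x$ab_chains), collapse = ", "),
      "), class ", x$complex_class, "\n", sep = "")
  invisible(x)
}

#' Split a single PDB entry into its antibody-antigen sets
#'
#' Convenience wrapper over [process_entry()] returning just the sets.
#'
#' @inheritParams process_entry
#' @return List of \code{abfv_set} (empty when the entry is rejected, with
#'   the reason in \code{attr(, "reason")}).
#' @export
split_entry <- function(file, code = NULL, profile = consensus_profile(),
                        params = pipeline_params(),
                        schemes = c("kabat", "chothia", "martin")) {
  res <- process_entry(file, code, profile, params, schemes)
  sets <- res$sets
  attr(sets, "reason") <- res$reason
  sets
}

.FORMS <- c("complete", "light_only", "heavy_only")
.CLASSES <- c("free", "protein", "non_protein", "all")

#' Run the full pipeline over a list of entry codes
#'
#' Processes every entry, lays out the 36 redundant and 36 non-redundant
#' datasets (three antibody forms x four complex classes x three numbering
#' schemes), and writes the 12 redundancy lists, the three free/complexed
#' lists, the chain-mapping list and a search manifest. Failures never
#' abort the run; each failed entry is recorded with its rejection reason.
#' Output is deterministic: re-running on identical input reproduces
#' byte-identical files.
#'
#' @param codes Character vector of entry codes.
#' @param pdb_dir Directory holding \code{<code>.pdb} files.
#' @param out_dir Output directory.
#' @param params Pipeline parameters.
#' @param profile Consensus profile.
#' @param schemes Numbering schemes.
#' @return A run report of class \code{abfv_report}.
#' @export
run_pipeline <- function(codes, pdb_dir, out_dir,
                         params = pipeline_params(),
                         profile = consensus_profile(),
                         schemes = c("kabat", "chothia", "martin")) {
  rejections <- list()
  all_sets <- list()
  results <- list()
  for (code in codes) {
    f <- file.path(pdb_dir, paste0(tolower(code), ".pdb"))
    if (!file.exists(f)) f <- file.path(pdb_dir, paste0(toupper(code), ".pdb"))
    if (!file.exists(f)) {
      rejections[["missing"]] <- c(rejections[["missing"]], code)
      next
    }
    res <- tryCatch(process_entry(f, code, profile, params, schemes),
                    error = function(e) {
                      structure(list(status = "rejected",
                                     reason = paste0("error: ",
                                                     conditionMessage(e)),
                                     code = code, sets = list()),
                                class = "abfv_entry_result")
                    })
    if (res$status == "rejected") {
      key <- sub(":.*", "", res$reason)
      rejections[[key]] <- c(rejections[[key]], code)
    } else {
      results[[code]] <- res
      all_sets <- c(all_sets, res$sets)
    }
  }

  clusters_by_form <- list()
  cluster_of <- character(0)
  if (length(all_sets)) {
    ids <- vapply(all_sets, `[[`, character(1), "set_id")
    names(all_sets) <- ids
    for (fm in .FORMS) {
      members <- Filter(function(s) s$form == fm, all_sets)
      if (!length(members)) next
      seqs <- lapply(members, labeled_sequence)
      cl <- cluster_redundant(seqs)
      md <- data.frame(
        set_id = names(members),
        length = vapply(members, `[[`, numeric(1), "length"),
        resolution = vapply(members, function(s)
          s$meta$resolution %||% NA_real_, numeric(1)),
        stringsAsFactors = FALSE)
      for (k in seq_along(cl)) {
        cl[[k]]$representative <- select_representative(cl[[k]]$members, md)
        cluster_of[cl[[k]]$members] <- paste0(fm, "_", k)
      }
      clusters_by_form[[fm]] <- list(clusters = cl, metadata = md)
    }
    write_outputs(all_sets, clusters_by_form, cluster_of, out_dir, schemes)
  }

  n_rej <- length(unlist(rejections))
  per_form <- vapply(.FORMS, function(fm)
    sum(vapply(all_sets, function(s) s$form == fm, logical(1))), integer(1))
  structure(list(
    n_input_codes = length(codes),
    n_processed = length(results),
    n_sets = length(all_sets),
    per_form = per_form,
    rejections = rejections,
    clusters_by_form = clusters_by_form,
    cluster_of = cluster_of,
    out_dir = out_dir
  ), class = "abfv_report")
}

#' @export
print.abfv_report <- function(x, ...) {
  cat("pipeline run:", x$n_input_codes, "input codes,",
      x$n_processed, "processed,", x$n_sets, "antibody sets\n")
  cat("  per form:", paste(names(x$per_form), x$per_form, collapse = ", "),
      "\n")
  if (length(x$rejections)) {
    for (r in names(x$rejections)) {
      cat("  rejected (", r, "): ",
          paste(x$rejections[[r]], collapse = " "), "\n", sep = "")
    }
  }
  invisible(x)
}

write_outputs <- function(all_sets, clusters_by_form, cluster_of, out_dir,
                          schemes) {
  for (fm in .FORMS) for (cl in .CLASSES) for (sc in schemes) {
    dir.create(file.path(out_dir, fm, cl, sc), recursive = TRUE,
               showWarnings = FALSE)
    dir.create(file.path(out_dir, paste0("NR_", fm), cl, sc),
               recursive = TRUE, showWarnings = FALSE)
  }
  dir.create(file.path(out_dir, "lists"), recursive = TRUE,
             showWarnings = FALSE)

  set_class <- vapply(all_sets, `[[`, character(1), "complex_class")
  set_form <- vapply(all_sets, `[[`, character(1), "form")
  for (id in names(all_sets)) {
    s <- all_sets[[id]]
    for (sc in schemes) {
      txt <- write_fv_file(s, sc)
      for (cl in c(s$complex_class, "all")) {
        writeLines(txt, file.path(out_dir, s$form, cl, sc,
                                  paste0(id, ".pdb")))
      }
    }
  }

  # non-redundant mirrors + 12 redundancy lists
  for (fm in names(clusters_by_form)) {
    info <- clusters_by_form[[fm]]
    for (cl in .CLASSES) {
      in_ds <- names(all_sets)[set_form == fm &
                                 (cl == "all" | set_class == cl)]
      lines <- "set_id\tstatus\tcluster\trepresentative"
      k_ds <- 0
      for (k in seq_along(info$clusters)) {
        members <- intersect(info$clusters[[k]]$members, in_ds)
        if (!length(members)) next
        k_ds <- k_ds + 1
        rep_ds <- select_representative(members, info$metadata)
        for (m in members) {
          lines <- c(lines, paste(m, status_label(set_class[[m]]), k_ds,
                                  ifelse(m == rep_ds, "yes", "no"),
                                  sep = "\t"))
          if (m == rep_ds) {
            for (sc in schemes) {
              file.copy(file.path(out_dir, fm, cl, sc, paste0(m, ".pdb")),
                        file.path(out_dir, paste0("NR_", fm), cl, sc,
                                  paste0(m, ".pdb")),
                        overwrite = TRUE)
            }
          }
        }
      }
      writeLines(lines, file.path(out_dir, "lists",
                                  paste0("redundancy_", fm, "_", cl,
                                         ".tsv")))
    }
    # free + complexed pairings
    lines <- "cluster\tset_id\tstatus"
    k_fc <- 0
    for (k in seq_along(info$clusters)) {
      members <- info$clusters[[k]]$members
      st <- set_class[members]
      if (any(st == "free") && any(st != "free")) {
        k_fc <- k_fc + 1
        for (m in members) {
          lines <- c(lines, paste(k_fc, m, status_label(st[[m]]),
                                  sep = "\t"))
        }
      }
    }
    writeLines(lines, file.path(out_dir, "lists",
                                paste0("free_complexed_", fm, ".tsv")))
  }

  # chain-mapping list and search manifest
  map_lines <- "set_id\tnew_label\torig_label"
  man_lines <- paste("set_id", "pdb_code", "form", "class", "scheme_files",
                     "ab_chains", "ag_chains", "abname", "abspecies",
                     "agname", "agspecies", "method", "resolution",
                     "r_factor", "cluster", sep = "\t")
  for (id in names(all_sets)) {
    s <- all_sets[[id]]
    for (nl in names(s$ab_chains)) {
      map_lines <- c(map_lines, paste(id, nl, s$ab_chains[[nl]], sep = "\t"))
    }
    for (nl in names(s$ag_chains)) {
      map_lines <- c(map_lines, paste(id, nl, s$ag_chains[[nl]], sep = "\t"))
    }
    paths <- paste(vapply(schemes, function(sc)
      file.path(s$form, s$complex_class, sc, paste0(id, ".pdb")),
      character(1)), collapse = ",")
    man_lines <- c(man_lines, paste(
      id, s$pdb_code, s$form, s$complex_class, paths,
      paste(unlist(s$ab_chains), collapse = ","),
      paste(unlist(s$ag_chains), collapse = ","),
      s$abname %||% "", s$abspecies %||% "",
      s$agname %||% "", s$agspecies %||% "",
      s$meta$method %||% "",
      ifelse(is.na(s$meta$resolution), "", s$meta$resolution),
      ifelse(is.na(s$meta$r_factor), "", s$meta$r_factor),
      cluster_of[[id]] %||% "", sep = "\t"))
  }
  writeLines(map_lines, file.path(out_dir, "lists", "chain_mapping.tsv"))
  writeLines(man_lines, file.path(out_dir, "manifest.tsv"))
}

status_label <- function(cls) {
  c(free = "Free antibody", protein = "Protein complex",
    non_protein = "Non-protein complex")[[cls]]
}

#' Query a built dataset index
#'
#' Searches the manifest written by [run_pipeline()] by entry code, keyword
#' (matched case-insensitively against the antibody and antigen molecule
#' names) or species, and returns the matching sets together with every set
#' redundant with them.
#'
#' @param out_dir The pipeline output directory.
#' @param by One of \code{"code"}, \code{"keyword"}, \code{"species"}.
#' @param term Search term.
#' @return Data frame of manifest rows (zero rows when nothing matches).
#' @export
query_sets <- function(out_dir, by = c("code", "keyword", "species"), term) {
  by <- match.arg(by)
  man_file <- file.path(out_dir, "manifest.tsv")
  if (!file.exists(man_file)) stop("no manifest found in ", out_dir)
  man <- utils::read.delim(man_file, stringsAsFactors = FALSE,
                           colClasses = "character")
  hit <- switch(by,
    code = toupper(man$pdb_code) == toupper(term) |
      toupper(man$set_id) == toupper(term),
    keyword = grepl(term, man$abname, ignore.case = TRUE) |
      grepl(term, man$agname, ignore.case = TRUE),
    species = grepl(term, man$abspecies, ignore.case = TRUE) |
      grepl(term, man$agspecies, ignore.case = TRUE))
  clusters <- unique(man$cluster[hit])
  clusters <- clusters[nzchar(clusters)]
  man[hit | man$cluster %in% clusters, , drop = FALSE]
}
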