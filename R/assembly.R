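#' Pipeline parameters
#'
#' The numeric constants of the processing rules: the contact distance
#' cutoff (atom centres within 4 A), the C-alpha distance cutoff for
#' pairing the two chains of a light-chain dimer through positions L36 and
#' L87 (20 A), the minimum number of CDR contacts for a chain to qualify as
#' antigen (15), and the chain-typing score threshold (80 percent).
#'
#' @param contact_cutoff Contact distance in Angstrom (default 4.0).
#' @param dimer_ca_cutoff L36/L87 C-alpha cutoff in Angstrom (default 20).
#' @param min_cdr_contacts Minimum CDR contacts for a polymer antigen
#'   (default 15).
#' @param chain_score_threshold Chain-typing threshold in percent
#'   (default 80).
#' @param cdr_definition CDR definition used by the contact rules
#'   (\code{"kabat"} default, or \code{"chothia"}).
#' @param joint_antigen_rule For multi-chain antigens, whether the
#'   minimum-CDR-contact rule applies to the \code{"summed"} profile
#'   (default) or \code{"per_chain"}.
#' @return List of class \code{abfv_params}.
#' @export
pipeline_params <- function(contact_cutoff = 4.0, dimer_ca_cutoff = 20.0,
                            min_cdr_contacts = 15L,
                            chain_score_threshold = 80,
                            cdr_definition = c("kabat", "chothia"),
                            joint_antigen_rule = c("summed", "per_chain")) {
  stopifnot(contact_cutoff > 0, dimer_ca_cutoff > 0, min_cdr_contacts > 0,
            chain_score_threshold > 0)
  structure(list(contact_cutoff = contact_cutoff,
                 dimer_ca_cutoff = dimer_ca_cutoff,
                 min_cdr_contacts = as.integer(min_cdr_contacts),
                 chain_score_threshold = chain_score_threshold,
                 cdr_definition = match.arg(cdr_definition),
                 joint_antigen_rule = match.arg(joint_antigen_rule)),
            class = "abfv_params")
}

# Number of atom pairs within `cutoff`, computed block-wise to bound memory.
count_pairs_within <- function(xyz_a, xyz_b, cutoff) {
  na <- nrow(xyz_a); nb <- nrow(xyz_b)
  if (!na || !nb) return(0L)
  total <- 0L
  block <- max(1L, 20000L %/% max(1L, nb))
  for (s in seq(1, na, by = block)) {
    e <- min(s + block - 1L, na)
    dx <- outer(xyz_a[s:e, 1], xyz_b[, 1], "-")
    dy <- outer(xyz_a[s:e, 2], xyz_b[, 2], "-")
    dz <- outer(xyz_a[s:e, 3], xyz_b[, 3], "-")
    total <- total + sum(dx * dx + dy * dy + dz * dz <= cutoff^2)
  }
  as.integer(total)
}

#' Count inter-chain atomic contacts
#'
#' The number of atom pairs, one atom from each chain, whose centres lie
#' within the cutoff distance. Hydrogens are excluded and alternate
#' locations have already been reduced at parse time, so the count does not
#' depend on deposition details.
#'
#' @param model An \code{abfv_structure}.
#' @param chain_a,chain_b Chain labels.
#' @param cutoff Distance cutoff in Angstrom (default 4.0).
#' @return List of class \code{abfv_contacts}: \code{chain_a},
#'   \code{chain_b}, \code{n_contacts}, \code{cutoff}.
#' @export
count_contacts <- function(model, chain_a, chain_b, cutoff = 4.0) {
  a <- chain_atoms(model, chain_a)
  b <- chain_atoms(model, chain_b)
  n <- count_pairs_within(as.matrix(a[, c("x", "y", "z")]),
                          as.matrix(b[, c("x", "y", "z")]), cutoff)
  structure(list(chain_a = chain_a, chain_b = chain_b,
                 n_contacts = n, cutoff = cutoff),
            class = "abfv_contacts")
}

#' Pair light and heavy chains by maximal contacts
#'
#' Builds the light-by-heavy contact matrix at the contact cutoff and pairs
#' chains greedily: the unused pair with the most contacts is taken first,
#' ties broken by chain-label order. Pairs with zero contacts are never
#' formed; chains left over are reported in \code{attr(, "unmatched")}.
#'
#' @param model An \code{abfv_structure}.
#' @param lights,heavies Chain labels typed light and heavy.
#' @param params Pipeline parameters.
#' @return Data frame (\code{light}, \code{heavy}, \code{contacts}) with
#'   the contact matrix in \code{attr(, "contact_matrix")}.
#' @export
pair_light_heavy <- function(model, lights, heavies,
                             params = pipeline_params()) {
  stopifnot(length(lights) >= 1, length(heavies) >= 1)
  lights <- sort(lights); heavies <- sort(heavies)
  m <- matrix(0L, length(lights), length(heavies),
              dimnames = list(lights, heavies))
  for (l in lights) for (h in heavies) {
    m[l, h] <- count_contacts(model, l, h, params$contact_cutoff)$n_contacts
  }
  if (all(m == 0)) stop("no physical pairing: all contact counts are zero")
  mm <- m
  out <- list()
  while (any(mm > 0)) {
    best <- which(mm == max(mm), arr.ind = TRUE)
    best <- best[order(rownames(mm)[best[, 1]],
                       colnames(mm)[best[, 2]])[1], , drop = FALSE]
    l <- rownames(mm)[best[1, 1]]; h <- colnames(mm)[best[1, 2]]
    out[[length(out) + 1L]] <- data.frame(light = l, heavy = h,
                                          contacts = mm[l, h],
                                          stringsAsFactors = FALSE)
    mm[l, ] <- -1L
    mm[, h] <- -1L
  }
  pairs <- do.call(rbind, out)
  attr(pairs, "contact_matrix") <- m
  attr(pairs, "unmatched") <- c(setdiff(lights, pairs$light),
                                setdiff(heavies, pairs$heavy))
  pairs
}

#' Pair the chains of light-chain dimers
#'
#' Two light chains form a dimer when the C-alpha atoms of their L36
#' residues lie within the cutoff of one another and the C-alpha atoms of
#' the two L87 residues do likewise (Kabat numbering). When more than one
#' pairing is possible each chain joins at most one pair, closest
#' distance-sum first. Chains lacking an observed L36 or L87 are skipped
#' with a warning.
#'
#' @param model An \code{abfv_structure}.
#' @param lights Light-chain labels.
#' @param maps Named list (by chain) of [renumber_structure()] results under
#'   Kabat numbering, used to resolve L36/L87 to source residues.
#' @param params Pipeline parameters.
#' @return Data frame (\code{chain_a}, \code{chain_b}, \code{dist_sum}).
#' @export
pair_light_dimer <- function(model, lights, maps,
                             params = pipeline_params()) {
  ca36 <- lapply(lights, function(ch) ca_coord(model, maps[[ch]], "36"))
  ca87 <- lapply(lights, function(ch) ca_coord(model, maps[[ch]], "87"))
  names(ca36) <- names(ca87) <- lights
  usable <- vapply(lights, function(ch) {
    ok <- !is.null(ca36[[ch]]) && !is.null(ca87[[ch]])
    if (!ok) warning("chain ", ch, ": L36 or L87 not observed; ",
                     "skipped for dimer pairing")
    ok
  }, logical(1))
  cand <- list()
  ls <- lights[usable]
  if (length(ls) >= 2) {
    for (i in seq_len(length(ls) - 1)) for (j in (i + 1):length(ls)) {
      d36 <- sqrt(sum((ca36[[ls[i]]] - ca36[[ls[j]]])^2))
      d87 <- sqrt(sum((ca87[[ls[i]]] - ca87[[ls[j]]])^2))
      if (d36 <= params$dimer_ca_cutoff && d87 <= params$dimer_ca_cutoff) {
        cand[[length(cand) + 1L]] <- data.frame(
          chain_a = ls[i], chain_b = ls[j], dist_sum = d36 + d87,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(cand)) {
    return(data.frame(chain_a = character(0), chain_b = character(0),
                      dist_sum = numeric(0)))
  }
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand$dist_sum, cand$chain_a, cand$chain_b), ,
               drop = FALSE]
  used <- character(0)
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    if (!cand$chain_a[k] %in% used && !cand$chain_b[k] %in% used) {
      keep[k] <- TRUE
      used <- c(used, cand$chain_a[k], cand$chain_b[k])
    }
  }
  cand[keep, , drop = FALSE]
}

# C-alpha coordinates of a numbered position, via the renumbering map.
ca_coord <- function(model, renum, label) {
  if (is.null(renum)) return(NULL)
  i <- match(label, renum$map$label)
  if (is.na(i)) return(NULL)
  a <- model$atoms
  hit <- a$chain == renum$orig_chain & a$resno == renum$map$orig_resno[i] &
    a$icode == renum$map$orig_icode[i] & a$name == "CA"
  if (!any(hit)) return(NULL)
  as.numeric(a[which(hit)[1], c("x", "y", "z")])
}
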