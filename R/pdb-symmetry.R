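#' Expand crystallographic symmetry copies from REMARK 350 BIOMT records
#'
#' Applies the non-identity biological-assembly transforms to the requested
#' chains and appends the transformed copies under fresh chain labels. The
#' identity copy is preserved bit-for-bit. This is how a light-chain dimer
#' whose second chain is only present through symmetry is reconstructed.
#'
#' @param model An \code{abfv_structure}.
#' @param chains Chain labels to copy; default: the chains named by each
#'   transform's REMARK 350 CHAINS list (all chains if the list is empty).
#' @return The model with transformed copies appended. The mapping from new
#'   to generator chain labels is in \code{attr(, "symmetry_copies")}.
#' @export
expand_symmetry <- function(model, chains = NULL) {
  trs <- Filter(function(tr) !is_identity_transform(tr), model$transforms)
  if (!length(trs)) return(model)
  used <- unique(c(model$atoms$chain, names(model$seqres)))
  pool <- setdiff(c(LETTERS, letters, as.character(0:9)), used)
  copies <- character(0)
  atoms <- model$atoms
  serial_max <- max(atoms$serial)
  for (tr in trs) {
    targets <- if (!is.null(chains)) chains
               else if (length(tr$chains)) tr$chains
               else unique(model$atoms$chain)
    targets <- intersect(targets, unique(model$atoms$chain))
    for (ch in targets) {
      if (!length(pool)) stop("no chain labels left for symmetry copies")
      new_label <- pool[1]
      pool <- pool[-1]
      src <- model$atoms[model$atoms$chain == ch, , drop = FALSE]
      xyz <- as.matrix(src[, c("x", "y", "z")]) %*% t(tr$rot)
      xyz <- sweep(xyz, 2, tr$trans, "+")
      src$x <- xyz[, 1]; src$y <- xyz[, 2]; src$z <- xyz[, 3]
      src$chain <- new_label
      src$serial <- serial_max + seq_len(nrow(src))
      serial_max <- serial_max + nrow(src)
      atoms <- rbind(atoms, src)
      copies[new_label] <- ch
      if (ch %in% names(model$seqres)) {
        model$seqres[new_label] <- model$seqres[[ch]]
      }
      if (ch %in% names(model$nucleic)) {
        model$nucleic[new_label] <- model$nucleic[[ch]]
      }
      if (ch %in% names(model$compnd)) model$compnd[new_label] <- model$compnd[[ch]]
      if (ch %in% names(model$source)) model$source[new_label] <- model$source[[ch]]
    }
  }
  model$atoms <- atoms
  attr(model, "symmetry_copies") <- copies
  model
}

is_identity_transform <- function(tr, tol = 1e-6) {
  all(abs(tr$rot - diag(3)) < tol) && all(abs(tr$trans) < tol)
}
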