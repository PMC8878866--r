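#' Construct a molecule
#'
#' A molecule is a labeled molecular graph: a vector of atoms (element symbol,
#' formal charge, 1-based source index recording the position of the atom in
#' the file it was read from) plus a bond list with integer bond orders.
#' Hydrogens may be present explicitly but are never required; all carbon
#' bookkeeping in this package operates on the heavy-atom graph.
#'
#' @param name Metabolite name (the MOL title line).
#' @param elements Character vector of element symbols in atom order.
#' @param bonds Integer matrix with columns `a1`, `a2`, `order` (1-based atom
#'   indices into `elements`); zero-row matrix for an unbonded atom.
#' @param charges Integer formal charges, recycled to the number of atoms.
#' @param source_index Original 1-based file indices of the atoms; defaults to
#'   the current order.
#' @param canonical_order Optional permutation: `canonical_order[k]` is the
#'   (current) index of the atom at canonical position `k`.
#' @return An object of class `molecule`.
#' @seealso [read_mol()], [canonical_order()]
#' @export
molecule <- function(name, elements, bonds = NULL, charges = 0L,
                     source_index = NULL, canonical_order = NULL) {
  n <- length(elements)
  if (n < 1L) parse_error("molecule must contain at least one atom")
  if (is.null(bonds) || NROW(bonds) == 0L) {
    bonds <- matrix(integer(0), ncol = 3L)
  } else {
    bonds <- matrix(as.integer(as.matrix(bonds)), ncol = 3L)
  }
  colnames(bonds) <- c("a1", "a2", "order")
  charges <- as.integer(rep_len(charges, n))
  source_index <- as.integer(source_index %||% seq_len(n))
  m <- structure(
    list(
      name = as.character(name),
      elements = as.character(elements),
      charges = charges,
      bonds = bonds,
      source_index = source_index,
      canonical_order = if (!is.null(canonical_order)) as.integer(canonical_order)
    ),
    class = "molecule"
  )
  validate_molecule(m)
  m
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("<molecule> %s: %d atoms (%d C), %d bonds%s\n",
              x$name, n_atoms(x), carbon_count(x), nrow(x$bonds),
              if (is.null(x$canonical_order)) "" else ", canonical order set"))
  invisible(x)
}

validate_molecule <- function(m) {
  n <- n_atoms(m)
  b <- m$bonds
  if (nrow(b) > 0L) {
    if (any(b[, 1:2] < 1L) || any(b[, 1:2] > n))
      parse_error(sprintf("molecule '%s': bond endpoint outside 1..%d", m$name, n))
    if (any(b[, 1] == b[, 2]))
      parse_error(sprintf("molecule '%s': self-bond", m$name))
    if (any(b[, 3] < 1L))
      parse_error(sprintf("molecule '%s': non-positive bond order", m$name))
  }
  if (!setequal(m$source_index, seq_len(n)))
    parse_error(sprintf("molecule '%s': source indices are not 1..%d", m$name, n))
  if (!is.null(m$canonical_order) && !setequal(m$canonical_order, seq_len(n)))
    parse_error(sprintf("molecule '%s': canonical_order is not a permutation", m$name))
  invisible(m)
}

#' Atom and carbon counts
#'
#' @param m A [molecule()].
#' @return Integer count.
#' @export
n_atoms <- function(m) length(m$elements)

#' @rdname n_atoms
#' @export
carbon_count <- function(m) sum(m$elements == "C")

# Positions (current atom order) of the carbons, in canonical order when a
# canonical order is attached, otherwise in current order.
carbon_positions <- function(m, canonical = !is.null(m$canonical_order)) {
  idx <- if (canonical) {
    if (is.null(m$canonical_order))
      model_error(sprintf("molecule '%s' has no canonical order", m$name))
    m$canonical_order
  } else {
    seq_len(n_atoms(m))
  }
  idx[m$elements[idx] == "C"]
}

#' Reorder a molecule's atoms into its canonical order
#'
#' Physically permutes the atom list so that atom `k` is the atom at canonical
#' position `k`; bonds are remapped and original file indices preserved in
#' `source_index`. Requires [canonical_order()] to have been computed (it is
#' computed on the fly otherwise).
#'
#' @param m A [molecule()].
#' @return The molecule with atoms in canonical order and
#'   `canonical_order = 1..n`.
#' @export
canonicalize <- function(m) {
  if (is.null(m$canonical_order)) m <- canonical_order(m)
  perm <- m$canonical_order
  inv <- integer(length(perm))
  inv[perm] <- seq_along(perm)
  b <- m$bonds
  if (nrow(b) > 0L) {
    b[, 1] <- inv[b[, 1]]
    b[, 2] <- inv[b[, 2]]
    swap <- b[, 1] > b[, 2]
    tmp <- b[swap, 1]
    b[swap, 1] <- b[swap, 2]
    b[swap, 2] <- tmp
    b <- b[order(b[, 1], b[, 2]), , drop = FALSE]
  }
  molecule(m$name, m$elements[perm], b, m$charges[perm],
           source_index = m$source_index[perm],
           canonical_order = seq_along(perm))
}

# Map between source-file carbon numbering and canonical carbon positions.
# Fixture MOL files list carbons first, in conventional chemical numbering,
# so "source carbon k" is the chemical position k there.

#' Convert between source and canonical carbon numbering
#'
#' `carbon_canonical_position()` gives the 1-based position, within the
#' canonical carbon sequence, of the carbon that was atom `source_carbon` in
#' the source file. `carbon_source_number()` is the inverse. Fixture
#' structures list carbons first in conventional chemical numbering, so for
#' them the source number is the chemical carbon number.
#'
#' @param m A [molecule()] with a canonical order.
#' @param source_carbon,canonical_pos 1-based carbon identifiers.
#' @return Integer position/number.
#' @export
carbon_canonical_position <- function(m, source_carbon) {
  cp <- carbon_positions(m, canonical = TRUE)
  src <- m$source_index[cp]
  pos <- match(as.integer(source_carbon), src)
  if (anyNA(pos))
    model_error(sprintf("molecule '%s': no carbon with source index %s",
                        m$name, paste(source_carbon[is.na(pos)], collapse = ",")))
  pos
}

#' @rdname carbon_canonical_position
#' @export
carbon_source_number <- function(m, canonical_pos) {
  cp <- carbon_positions(m, canonical = TRUE)
  if (any(canonical_pos < 1L | canonical_pos > length(cp)))
    model_error(sprintf("molecule '%s': carbon position out of range", m$name))
  m$source_index[cp[as.integer(canonical_pos)]]
}

# Adjacency list representation used by the canonical/orbit code:
# list with nbr[[i]] = neighbor indices, ord[[i]] = matching bond orders.
adjacency <- function(m) {
  n <- n_atoms(m)
  nbr <- vector("list", n)
  ord <- vector("list", n)
  for (i in seq_len(n)) {
    nbr[[i]] <- integer(0)
    ord[[i]] <- integer(0)
  }
  b <- m$bonds
  for (k in seq_len(nrow(b))) {
    i <- b[k, 1]; j <- b[k, 2]; o <- b[k, 3]
    nbr[[i]] <- c(nbr[[i]], j); ord[[i]] <- c(ord[[i]], o)
    nbr[[j]] <- c(nbr[[j]], i); ord[[j]] <- c(ord[[j]], o)
  }
  list(nbr = nbr, ord = ord)
}

is_connected_molecule <- function(m) {
  n <- n_atoms(m)
  if (n == 1L) return(TRUE)
  adj <- adjacency(m)
  seen <- logical(n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue) > 0L) {
    v <- queue[1L]
    queue <- queue[-1L]
    for (w in adj$nbr[[v]]) {
      if (!seen[w]) {
        seen[w] <- TRUE
        queue <- c(queue, w)
      }
    }
  }
  all(seen)
}
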