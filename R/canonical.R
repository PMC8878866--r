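# Canonical atom ordering and symmetry orbits.
#
# The ordering is a deterministic, isomorphism-invariant ranking of the
# heavy-atom graph in the spirit of InChI numbering: atoms are first keyed by
# (element, charge, heavy degree, multiset of (neighbor element, bond order)),
# carbon sorting before other elements, and the partition is then refined by
# iterated neighbor ranks (Morgan-style). If refinement leaves ties, the
# order is completed by individualization with full branching: every member
# of the first tied cell is tried in turn, and the order whose relabeled
# graph certificate is lexicographically smallest wins. Branching makes the
# result invariant to the input atom order even on symmetric molecules;
# within a symmetry class the atom with the smallest certificate (and, among
# truly interchangeable atoms, effectively the smallest original index) is
# placed first. Stereochemistry (wedge/hash) is ignored throughout.

canonical_core <- function(elements, charges, adj) {
  n <- length(elements)
  if (n == 1L) return(1L)
  nbr <- adj$nbr
  ord <- adj$ord
  deg <- lengths(nbr)
  seed <- vapply(seq_len(n), function(i) {
    pairs <- paste0(element_sort_key(elements[nbr[[i]]]), ord[[i]])
    paste(element_sort_key(elements[i]),
          sprintf("%+03d", charges[i]),
          sprintf("%02d", deg[i]),
          paste(sort(pairs), collapse = ","),
          sep = "|")
  }, "")
  ranks <- match(seed, sort(unique(seed)))

  refine <- function(ranks) {
    repeat {
      sig <- vapply(seq_len(n), function(i) {
        paste(sprintf("%04d", ranks[i]),
              paste(sort(sprintf("%04d.%d", ranks[nbr[[i]]], ord[[i]])),
                    collapse = ","))
      }, "")
      new_ranks <- match(sig, sort(unique(sig)))
      if (identical(new_ranks, ranks)) return(ranks)
      ranks <- new_ranks
    }
  }

  certificate <- function(perm) {
    inv <- integer(n); inv[perm] <- seq_len(n)
    edges <- character(0)
    for (i in seq_len(n)) {
      for (k in seq_along(nbr[[i]])) {
        j <- nbr[[i]][k]
        if (i < j) {
          a <- sort(c(inv[i], inv[j]))
          edges <- c(edges, sprintf("%03d-%03d:%d", a[1], a[2], ord[[i]][k]))
        }
      }
    }
    paste(paste0(element_sort_key(elements[perm]), sprintf("%+03d", charges[perm]),
                 collapse = ";"),
          paste(sort(edges), collapse = ";"), sep = "#")
  }

  best_perm <- NULL
  best_cert <- NULL
  search <- function(ranks) {
    ranks <- refine(ranks)
    if (max(ranks) == n) {
      perm <- order(ranks)
      cert <- certificate(perm)
      if (is.null(best_cert) || cert < best_cert) {
        best_cert <<- cert
        best_perm <<- perm
      }
      return(invisible(NULL))
    }
    tab <- tabulate(ranks)
    cell_rank <- which(tab > 1L)[1]
    members <- which(ranks == cell_rank)
    for (a in members) {
      r2 <- ranks * 2L
      r2[a] <- r2[a] - 1L
      r2 <- match(r2, sort(unique(r2)))
      search(r2)
    }
    invisible(NULL)
  }
  search(ranks)
  best_perm
}

#' Compute the canonical atom ordering of a molecule
#'
#' Assigns a deterministic, isomorphism-invariant ordering of the atoms: any
#' permutation of the input atom order yields the same canonical sequence of
#' (element, charge, degree, bonded-element multiset), so carbon positions
#' extracted in canonical order are reproducible across files and tools.
#' Requires a connected structure; split multi-fragment inputs first.
#'
#' @param m A [molecule()].
#' @return `m` with `canonical_order` set (`canonical_order[k]` = current
#'   index of the atom at canonical position `k`).
#' @seealso [canonicalize()] to physically reorder, [symmetry_orbits()]
#' @export
#' @examples
#' m <- canonical_order(read_mol(write_mol(molecule("co2", c("C", "O", "O"),
#'   rbind(c(1, 2, 2), c(1, 3, 2))))))
#' m$canonical_order
canonical_order <- function(m) {
  validate_molecule(m)
  if (!is_connected_molecule(m))
    model_error(sprintf(
      "molecule '%s' is disconnected: split it into fragments and canonicalize each",
      m$name))
  m$canonical_order <- canonical_core(m$elements, m$charges, adjacency(m))
  m
}

#' Symmetry orbits of a molecule
#'
#' Partitions the atoms into equivalence classes under graph automorphisms
#' that preserve element, charge, and bond order: two atoms share an orbit
#' iff some automorphism maps one onto the other (e.g. the two carboxyl
#' carbons of fumarate). Automorphism generators are obtained from igraph
#' (BLISS) on an auxiliary graph in which every bond is subdivided by a
#' vertex colored with its bond order, which reduces the edge-colored problem
#' to a vertex-colored one.
#'
#' @param m A [molecule()]; its canonical order is computed if absent.
#' @return An object of class `symmetry_orbits`: a list with `orbits` (list of
#'   integer atom-index vectors, each sorted, ordered by smallest member) and
#'   `carbon_orbits` (the same restricted to carbons).
#' @export
symmetry_orbits <- function(m) {
  if (is.null(m$canonical_order)) m <- canonical_order(m)
  n <- n_atoms(m)
  gens <- automorphism_generators(m)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  for (g in gens) {
    for (i in seq_len(n)) {
      a <- find(i); b <- find(g[i])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  orbits <- unname(split(seq_len(n), roots))
  orbits <- orbits[order(vapply(orbits, min, 0L))]
  carbon_orbits <- lapply(orbits, function(o) o[m$elements[o] == "C"])
  carbon_orbits <- carbon_orbits[lengths(carbon_orbits) > 0L]
  structure(list(molecule = m$name, orbits = orbits,
                 carbon_orbits = carbon_orbits),
            class = "symmetry_orbits")
}

#' @export
print.symmetry_orbits <- function(x, ...) {
  cat(sprintf("<symmetry_orbits> %s: %d orbits\n", x$molecule, length(x$orbits)))
  for (o in x$orbits) cat("  {", paste(o, collapse = ", "), "}\n")
  invisible(x)
}

# Automorphism generators of the element/charge/bond-order labeled graph,
# as permutations of atom indices.
automorphism_generators <- function(m) {
  n <- n_atoms(m)
  b <- m$bonds
  nb <- nrow(b)
  if (n == 1L) return(list())
  atom_key <- paste(m$elements, m$charges)
  atom_col <- match(atom_key, sort(unique(atom_key)))
  bond_col <- max(atom_col) + b[, 3]
  edges <- integer(0)
  for (k in seq_len(nb)) {
    bv <- n + k
    edges <- c(edges, b[k, 1], bv, bv, b[k, 2])
  }
  g <- igraph::make_graph(edges, n = n + nb, directed = FALSE)
  gens <- igraph::automorphism_group(g, colors = c(atom_col, bond_col))
  lapply(gens, function(p) as.integer(p)[seq_len(n)])
}

# All distinct permutations of the canonical carbon positions induced by the
# automorphism group (closure of the generators' action). Used by symmetry
# expansion in the ABC builder. `m` must be canonicalized (atom index ==
# canonical position).
carbon_symmetry_perms <- function(m, max_perms = 5000L) {
  cp <- carbon_positions(m, canonical = TRUE)
  nc <- length(cp)
  if (nc == 0L) return(list())
  gens <- automorphism_generators(m)
  gens_c <- lapply(gens, function(g) match(g[cp], cp))
  gens_c <- Filter(function(p) !anyNA(p), gens_c)
  seen <- new.env(parent = emptyenv())
  id <- seq_len(nc)
  key <- function(p) paste(p, collapse = ",")
  assign(key(id), TRUE, envir = seen)
  out <- list(id)
  queue <- list(id)
  while (length(queue) > 0L) {
    p <- queue[[1]]
    queue <- queue[-1]
    for (g in gens_c) {
      q <- p[g]
      k <- key(q)
      if (!exists(k, envir = seen)) {
        assign(k, TRUE, envir = seen)
        out <- c(out, list(q))
        queue <- c(queue, list(q))
        if (length(out) > max_perms)
          capacity_error(sprintf("symmetry group of '%s' too large to expand", m$name))
      }
    }
  }
  out
}
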