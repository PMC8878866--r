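#' Construct a mapped reaction
#'
#' A reaction with an atom-atom map: ordered substrate and product molecule
#' instances plus a bijection over the mapped atoms. Stoichiometric
#' coefficients are represented by repeated molecule instances, matching how
#' RXN files repeat MOL blocks.
#'
#' @param reaction_id Reaction name.
#' @param substrates,products Lists of [molecule()] objects (one entry per
#'   stoichiometric instance).
#' @param atom_map Data frame with integer columns `s_inst`, `s_atom`,
#'   `p_inst`, `p_atom`: instance and atom indices of each mapped
#'   substrate/product atom pair. Atoms absent from the map are unmapped.
#' @param reversible Logical reversibility flag.
#' @param external_ids Data frame with columns `database`, `identifier`.
#' @return An object of class `mapped_reaction`.
#' @seealso [read_rxn()], [carbon_balance()], [validate_mapping()]
#' @export
mapped_reaction <- function(reaction_id, substrates, products, atom_map,
                            reversible = FALSE, external_ids = NULL) {
  if (length(substrates) < 1L || length(products) < 1L)
    model_error(sprintf("reaction '%s': needs at least one substrate and one product",
                        reaction_id))
  atom_map <- as.data.frame(atom_map)
  if (nrow(atom_map) == 0L) {
    atom_map <- data.frame(s_inst = integer(0), s_atom = integer(0),
                           p_inst = integer(0), p_atom = integer(0))
  }
  atom_map[] <- lapply(atom_map, as.integer)
  r <- structure(
    list(
      reaction_id = as.character(reaction_id),
      external_ids = external_ids %||%
        data.frame(database = character(0), identifier = character(0)),
      substrates = substrates,
      products = products,
      atom_map = atom_map,
      reversible = isTRUE(reversible)
    ),
    class = "mapped_reaction"
  )
  validate_reaction_structure(r)
  r
}

validate_reaction_structure <- function(r) {
  am <- r$atom_map
  if (nrow(am) == 0L) return(invisible(r))
  check_side <- function(inst, atom, side, mols) {
    if (any(inst < 1L) || any(inst > length(mols)))
      mapping_error(sprintf("reaction '%s': %s instance index out of range",
                            r$reaction_id, side))
    for (i in unique(inst)) {
      a <- atom[inst == i]
      if (any(a < 1L) || any(a > n_atoms(mols[[i]])))
        mapping_error(sprintf("reaction '%s': %s atom index out of range for '%s'",
                              r$reaction_id, side, mols[[i]]$name))
    }
    key <- paste(inst, atom)
    if (anyDuplicated(key))
      mapping_error(sprintf("reaction '%s': %s atom mapped more than once",
                            r$reaction_id, side))
  }
  check_side(am$s_inst, am$s_atom, "substrate", r$substrates)
  check_side(am$p_inst, am$p_atom, "product", r$products)
  se <- mapply(function(i, a) r$substrates[[i]]$elements[a], am$s_inst, am$s_atom)
  pe <- mapply(function(i, a) r$products[[i]]$elements[a], am$p_inst, am$p_atom)
  if (any(se != pe))
    mapping_error(sprintf(
      "reaction '%s': atom map pairs atoms of different elements (%s)",
      r$reaction_id,
      paste(unique(paste0(se[se != pe], "/", pe[se != pe])), collapse = ", ")))
  invisible(r)
}

#' @export
print.mapped_reaction <- function(x, ...) {
  side <- function(mols) paste(vapply(mols, `[[`, "", "name"), collapse = " + ")
  cat(sprintf("<mapped_reaction> %s: %s %s %s (%d mapped atom pairs)\n",
              x$reaction_id, side(x$substrates),
              if (x$reversible) "<->" else "->", side(x$products),
              nrow(x$atom_map)))
  invisible(x)
}

# Total carbons on one side, all instances counted.
side_carbons <- function(mols) sum(vapply(mols, carbon_count, 0L))

#' Canonicalize all molecules of a reaction
#'
#' Reorders every substrate and product instance into its canonical atom
#' order and re-expresses the atom map over the new indices. After this the
#' atom index of a carbon equals its canonical position in the molecule.
#'
#' @param r A [mapped_reaction()].
#' @return The canonicalized reaction.
#' @export
canonicalize_reaction <- function(r) {
  canon_side <- function(mols) {
    out <- vector("list", length(mols))
    inv <- vector("list", length(mols))
    for (i in seq_along(mols)) {
      m <- canonical_order(mols[[i]])
      perm <- m$canonical_order
      iv <- integer(length(perm))
      iv[perm] <- seq_along(perm)
      out[[i]] <- canonicalize(m)
      inv[[i]] <- iv
    }
    list(mols = out, inv = inv)
  }
  s <- canon_side(r$substrates)
  p <- canon_side(r$products)
  am <- r$atom_map
  if (nrow(am) > 0L) {
    am$s_atom <- mapply(function(i, a) s$inv[[i]][a], am$s_inst, am$s_atom)
    am$p_atom <- mapply(function(i, a) p$inv[[i]][a], am$p_inst, am$p_atom)
  }
  mapped_reaction(r$reaction_id, s$mols, p$mols, am,
                  reversible = r$reversible, external_ids = r$external_ids)
}
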