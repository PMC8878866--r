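# Assembly of a network-wide ABC carbon atom-mapping model from a metabolic
# model plus a mapping store.
#
# Per reaction: the stored atom mapping is looked up by identifier, matched
# to the model's metabolites (by compound identifier, alias, or exact name;
# stoichiometric instances in order), and any stored metabolite the model
# does not list — cofactors, water, by-products — is omitted, dropping its
# map pairs. Substrate carbons are then lettered a, b, c, ... in substrate
# order and canonical carbon order; product letters are induced by the atom
# map. Product carbons whose map partner was omitted receive the next
# unused letters of the reaction. Reversible reactions are emitted once
# with `<->`; the reverse mapping is the inverse relation by construction.

expand_instances <- function(tokens) {
  out <- list()
  for (t in tokens) {
    for (k in seq_len(t$coefficient)) out[[length(out) + 1L]] <- t
  }
  out
}

#' Omit metabolites from a mapped reaction
#'
#' Removes every instance of the named metabolites from a reaction —
#' the simplification used to drop cofactors such as ATP/ADP — and drops
#' the atom-map pairs that touch them. Downstream, product carbons that
#' lost their substrate partner receive fresh letters; letters of omitted
#' substrates simply vanish.
#'
#' @param r A [mapped_reaction()].
#' @param names Metabolite names to omit; every name must occur in the
#'   reaction.
#' @return The reduced [mapped_reaction()] (an empty substrate or product
#'   side is an error).
#' @export
omit_metabolites <- function(r, names) {
  if (length(names) == 0L) return(r)
  all_names <- c(vapply(r$substrates, `[[`, "", "name"),
                 vapply(r$products, `[[`, "", "name"))
  missing <- setdiff(names, all_names)
  if (length(missing) > 0L)
    model_error(sprintf("reaction '%s': cannot omit absent metabolite(s) %s",
                        r$reaction_id, paste(missing, collapse = ", ")))
  s_keep <- which(!(vapply(r$substrates, `[[`, "", "name") %in% names))
  p_keep <- which(!(vapply(r$products, `[[`, "", "name") %in% names))
  omit_instances(r, s_keep, p_keep)
}

# Keep only the given instance indices (renumbering the atom map).
omit_instances <- function(r, s_keep, p_keep) {
  if (length(s_keep) == 0L || length(p_keep) == 0L)
    model_error(sprintf("reaction '%s': omission would empty one reaction side",
                        r$reaction_id))
  am <- r$atom_map
  am <- am[am$s_inst %in% s_keep & am$p_inst %in% p_keep, , drop = FALSE]
  am$s_inst <- match(am$s_inst, s_keep)
  am$p_inst <- match(am$p_inst, p_keep)
  mapped_reaction(r$reaction_id, r$substrates[s_keep], r$products[p_keep], am,
                  reversible = r$reversible, external_ids = r$external_ids)
}

flip_reaction <- function(r) {
  am <- r$atom_map[, c("p_inst", "p_atom", "s_inst", "s_atom")]
  names(am) <- c("s_inst", "s_atom", "p_inst", "p_atom")
  mapped_reaction(r$reaction_id, r$products, r$substrates, am,
                  reversible = r$reversible, external_ids = r$external_ids)
}

match_instances <- function(wanted, have) {
  used <- logical(length(have))
  out <- integer(length(wanted))
  for (i in seq_along(wanted)) {
    j <- which(!used & have == wanted[i])
    if (length(j) == 0L) return(NULL)
    out[i] <- j[1]
    used[j[1]] <- TRUE
  }
  out
}

#' Build an ABC atom-mapping model
#'
#' The core workflow: for every reaction of the metabolic model, resolve
#' its atom mapping (from the store by identifier, or from user-supplied
#' ABC strings for custom reactions), match and omit metabolites, assign
#' letters, and optionally expand or canonicalize symmetric metabolites.
#'
#' @param model A [parse_model_csv()] result.
#' @param store A [load_store()] result.
#' @param omit Metabolite names omitted from every reaction (cofactor
#'   simplification).
#' @param symmetry `"ignore"` (default), `"expand"` (one additional entry
#'   per distinct symmetry-induced relabeling), or `"canonical"` (single
#'   entry with the lexicographically smallest relabeling).
#' @param allow_unbalanced Permit carbon-unbalanced stored reactions;
#'   orphan product carbons get fresh letters.
#' @return An `abc_model`.
#' @export
#' @examples
#' dir <- tempfile()
#' build_fixture_store(dir)
#' store <- load_store(dir)
#' model <- parse_model_csv(file.path(dir, "glutamine_model.csv"))
#' abc <- build_abc_model(model, store)
#' cat(abc_equation(abc$entries[[1]]), "\n")
build_abc_model <- function(model, store, omit = character(0),
                            symmetry = c("ignore", "expand", "canonical"),
                            allow_unbalanced = FALSE) {
  symmetry <- match.arg(symmetry)
  sym_cache <- new.env(parent = emptyenv())
  entries <- list()
  for (row in model$reactions) {
    entry <- build_entry(row, store, omit, allow_unbalanced)
    if (symmetry != "ignore") {
      syms <- entry_symmetry_perms(entry, store, sym_cache)
      variants <- apply_symmetry(entry, syms, symmetry)
      entries <- c(entries, variants)
    } else {
      entries <- c(entries, list(entry))
    }
  }
  new_abc_model(entries)
}

build_entry <- function(row, store, omit, allow_unbalanced) {
  subs <- Filter(function(t) !(t$name %in% omit), expand_instances(row$substrates))
  prods <- Filter(function(t) !(t$name %in% omit), expand_instances(row$products))
  if (length(subs) == 0L || length(prods) == 0L)
    model_error(sprintf("reaction '%s': omission leaves an empty reaction side",
                        row$name))
  if (any(vapply(c(subs, prods), function(t) !is.null(t$user_abc), NA)))
    return(merge_custom_mapping(
      list(name = row$name, id = row$id, substrates = subs, products = prods,
           reversible = row$reversible), store))
  if (is.null(row$id))
    model_error(sprintf(
      "reaction '%s' has no identifier and no user ABC mapping", row$name))
  key <- if (is.na(row$id$database)) row$id$identifier else
    paste0(row$id$database, ":", row$id$identifier)
  stored <- store_lookup(store, key)
  if (!carbon_balance(stored)$carbon_balanced && !allow_unbalanced)
    model_error(sprintf(
      "reaction '%s' [%s]: stored mapping is carbon-unbalanced (use allow_unbalanced to letter orphans)",
      row$name, key))

  sub_names <- vapply(subs, function(t) resolve_metabolite(store, t$name, t$id), "")
  prod_names <- vapply(prods, function(t) resolve_metabolite(store, t$name, t$id), "")
  orient <- function(r) {
    si <- match_instances(sub_names, vapply(r$substrates, `[[`, "", "name"))
    pi <- match_instances(prod_names, vapply(r$products, `[[`, "", "name"))
    if (is.null(si) || is.null(pi)) NULL else list(r = r, si = si, pi = pi)
  }
  m <- orient(stored) %||% orient(flip_reaction(stored))
  if (is.null(m)) {
    have <- c(vapply(stored$substrates, `[[`, "", "name"),
              vapply(stored$products, `[[`, "", "name"))
    missing <- setdiff(c(sub_names, prod_names), have)
    model_error(sprintf(
      "reaction '%s' [%s]: metabolite(s) %s not found in the stored reaction",
      row$name, key,
      paste(if (length(missing)) missing else "(instance count mismatch)",
            collapse = ", ")))
  }
  stored <- m$r

  for (k in seq_along(subs)) {
    lim <- subs[[k]]$carbon_limit
    if (!is.null(lim) && carbon_count(stored$substrates[[m$si[k]]]) != lim)
      model_error(sprintf(
        "reaction '%s': '%s' declares %d carbons but the stored structure has %d",
        row$name, subs[[k]]$name, lim, carbon_count(stored$substrates[[m$si[k]]])))
  }
  for (k in seq_along(prods)) {
    lim <- prods[[k]]$carbon_limit
    if (!is.null(lim) && carbon_count(stored$products[[m$pi[k]]]) != lim)
      model_error(sprintf(
        "reaction '%s': '%s' declares %d carbons but the stored structure has %d",
        row$name, prods[[k]]$name, lim, carbon_count(stored$products[[m$pi[k]]])))
  }

  alphabet <- abc_alphabet()
  nxt <- 1L
  take_letters <- function(n) {
    if (n == 0L) return(character(0))
    if (nxt + n - 1L > length(alphabet))
      capacity_error(sprintf(
        "reaction '%s': more than 52 carbons on one side exhausts the letter alphabet",
        row$name))
    out <- alphabet[nxt:(nxt + n - 1L)]
    nxt <<- nxt + n
    out
  }
  sub_letters <- list()  # keyed by stored substrate instance: atom -> letter
  entry_subs <- list()
  for (k in seq_along(subs)) {
    mol <- stored$substrates[[m$si[k]]]
    cp <- carbon_positions(mol, canonical = TRUE)
    lets <- take_letters(length(cp))
    sub_letters[[as.character(m$si[k])]] <- stats::setNames(lets, cp)
    entry_subs[[k]] <- list(name = subs[[k]]$name,
                            letters = paste(lets, collapse = ""))
  }
  am <- stored$atom_map
  entry_prods <- list()
  orphans <- 0L
  for (k in seq_along(prods)) {
    mol <- stored$products[[m$pi[k]]]
    cp <- carbon_positions(mol, canonical = TRUE)
    lets <- character(length(cp))
    for (q in seq_along(cp)) {
      w <- which(am$p_inst == m$pi[k] & am$p_atom == cp[q])
      l <- NA_character_
      if (length(w) == 1L) {
        lu <- sub_letters[[as.character(am$s_inst[w])]]
        if (!is.null(lu)) l <- unname(lu[as.character(am$s_atom[w])])
      }
      if (is.na(l)) {
        l <- take_letters(1L)
        orphans <- orphans + 1L
      }
      lets[q] <- l
    }
    entry_prods[[k]] <- list(name = prods[[k]]$name,
                             letters = paste(lets, collapse = ""))
  }
  e <- abc_entry(row$name, entry_subs, entry_prods, row$reversible,
                 provenance = paste0("store:", key), id = key)
  # Letter conservation must hold whenever nothing was omitted or orphaned.
  if (orphans == 0L &&
      length(stored$substrates) == length(subs) &&
      length(stored$products) == length(prods)) {
    sl <- unlist(strsplit(vapply(entry_subs, `[[`, "", "letters"), ""))
    pl <- unlist(strsplit(vapply(entry_prods, `[[`, "", "letters"), ""))
    if (!setequal(sl, pl))
      mapping_error(sprintf(
        "reaction '%s': internal letter-conservation failure", row$name))
  }
  e
}

#' Accept a user-supplied ABC mapping for a custom reaction
#'
#' Custom reactions (simplified or absent from the store) carry ABC letter
#' strings written by the user directly in the model CSV. A mapping is
#' accepted iff every metabolite instance of the reaction has a string, no
#' letter repeats on one side, every product letter stems from a substrate,
#' and — for metabolites whose structure the store knows — the string
#' length equals the canonical carbon count. The count check is what
#' protects users from the classic pitfall of guessing a sorting the rest
#' of the model does not use.
#'
#' @param row List with `name`, `id`, `substrates`, `products` (instance
#'   lists with `user_abc` strings), `reversible`.
#' @param store Optional [load_store()] result used for carbon-count
#'   validation; metabolites unknown to the store are accepted as written.
#' @return An `abc_model` entry with provenance `"user"`.
#' @export
merge_custom_mapping <- function(row, store = NULL) {
  check_side <- function(side, label) {
    lapply(side, function(t) {
      if (is.null(t$user_abc))
        model_error(sprintf(
          "reaction '%s': %s '%s' lacks a user ABC string", row$name, label, t$name))
      if (!is.null(store)) {
        mol <- tryCatch(store_molecule(store, t$name), error = function(e) NULL)
        if (!is.null(mol) && nchar(t$user_abc) != carbon_count(mol))
          model_error(sprintf(
            "reaction '%s': '%s' has %d carbons but the user string '%s' has %d letters",
            row$name, t$name, carbon_count(mol), t$user_abc, nchar(t$user_abc)))
      }
      list(name = t$name, letters = t$user_abc)
    })
  }
  subs <- check_side(row$substrates, "substrate")
  prods <- check_side(row$products, "product")
  sl <- unlist(strsplit(vapply(subs, `[[`, "", "letters"), ""))
  pl <- unlist(strsplit(vapply(prods, `[[`, "", "letters"), ""))
  bad <- setdiff(pl, sl)
  if (length(bad) > 0L)
    model_error(sprintf(
      "reaction '%s': product letter(s) %s do not occur on the substrate side",
      row$name, paste(bad, collapse = ", ")))
  id <- if (is.null(row$id)) NA_character_ else
    paste0(if (!is.na(row$id$database)) paste0(row$id$database, ":") else "",
           row$id$identifier)
  abc_entry(row$name, subs, prods, row$reversible, provenance = "user", id = id)
}

# Symmetry permutations (on canonical carbon positions) for every
# metabolite participating in an entry, cached per metabolite name.
entry_symmetry_perms <- function(entry, store, cache = new.env()) {
  names <- unique(vapply(c(entry$substrates, entry$products), `[[`, "", "name"))
  syms <- list()
  for (nm in names) {
    if (!exists(nm, envir = cache)) {
      mol <- tryCatch(store_molecule(store, nm), error = function(e) NULL)
      perms <- if (is.null(mol)) list() else carbon_symmetry_perms(mol)
      assign(nm, perms, envir = cache)
    }
    syms[[nm]] <- get(nm, envir = cache)
  }
  syms
}

# The mapping relation an entry encodes, as a canonical string: used to
# deduplicate symmetry variants that render differently but express the
# same substrate-to-product carbon correspondence.
entry_relation <- function(entry) {
  pos <- list()
  for (side in c("substrates", "products")) {
    for (i in seq_along(entry[[side]])) {
      m <- entry[[side]][[i]]
      lets <- strsplit(m$letters, "")[[1]]
      for (k in seq_along(lets)) {
        slot <- sprintf("%s|%s.%d.%d", side, m$name, i, k)
        pos[[lets[k]]] <- c(pos[[lets[k]]], slot)
      }
    }
  }
  pairs <- vapply(pos, function(x) paste(sort(x), collapse = ">"), "")
  paste(sort(pairs), collapse = ";")
}

#' Expand or canonicalize symmetric metabolites in an ABC entry
#'
#' Molecular symmetry (e.g. the two-fold axis of fumarate) makes several
#' letter assignments chemically equivalent. `expand` emits one additional
#' entry per distinct symmetry-induced relabeling (distinct as a mapping
#' relation, so a simultaneous relabeling of both sides that reproduces the
#' original correspondence is not duplicated); `canonical` keeps the single
#' lexicographically smallest relabeling; `ignore` returns the entry
#' unchanged.
#'
#' @param entry An `abc_model` entry.
#' @param syms Named list: for each metabolite name, the list of canonical
#'   carbon-position permutations induced by its automorphism group (see
#'   [symmetry_orbits()]); missing or length-<=1 lists mean "asymmetric".
#' @param mode `"ignore"`, `"expand"`, or `"canonical"`.
#' @return List of entries (length 1 unless expanding).
#' @export
apply_symmetry <- function(entry, syms, mode = c("ignore", "expand", "canonical")) {
  mode <- match.arg(mode)
  if (mode == "ignore") return(list(entry))
  slots <- list()
  for (side in c("substrates", "products")) {
    for (i in seq_along(entry[[side]])) {
      nm <- entry[[side]][[i]]$name
      p <- syms[[nm]]
      if (!is.null(p) && length(p) > 1L)
        slots[[length(slots) + 1L]] <- list(side = side, i = i, perms = p)
    }
  }
  if (length(slots) == 0L) return(list(entry))
  n_combo <- prod(vapply(slots, function(s) length(s$perms), 0))
  if (n_combo > 10000L)
    capacity_error(sprintf("reaction '%s': too many symmetry variants", entry$name))
  grid <- expand.grid(lapply(slots, function(s) seq_along(s$perms)))
  variants <- list()
  relations <- character(0)
  for (g in seq_len(nrow(grid))) {
    e <- entry
    for (s in seq_along(slots)) {
      slot <- slots[[s]]
      perm <- slot$perms[[grid[g, s]]]
      lets <- strsplit(e[[slot$side]][[slot$i]]$letters, "")[[1]]
      e[[slot$side]][[slot$i]]$letters <- paste(lets[perm], collapse = "")
    }
    rel <- entry_relation(e)
    if (!(rel %in% relations)) {
      relations <- c(relations, rel)
      e$variant <- length(variants) + 1L
      variants[[length(variants) + 1L]] <- e
    }
  }
  if (mode == "canonical") {
    eqs <- vapply(variants, abc_equation, "")
    e <- variants[[which(eqs == min(eqs))[1]]]
    e$variant <- 1L
    return(list(e))
  }
  variants
}
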