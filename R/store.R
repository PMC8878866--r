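# The local mapping store: a directory of RXN files plus an index CSV,
# standing in for a hosted atom-mapping database. Several external
# identifiers may point to the same stored reaction (cross-database
# linking). Every reaction is canonicalized at load time (atoms reordered
# into canonical order, atom map re-expressed over canonical indices) and
# must pass carbon balance and mapping validation; `lenient = TRUE` skips
# dirty entries with a warning instead of refusing to load.

#' Load a mapping store from disk
#'
#' Expects `index.csv` with columns `database`, `identifier`, `file`,
#' `reversible`, referencing RXN files in the same directory. Optional
#' `compounds.csv` (`database`, `identifier`, `name`) resolves metabolite
#' identifiers, and optional `aliases.csv` (`alias`, `name`) maps metabolite
#' name synonyms.
#'
#' @param dir Store directory.
#' @param lenient Skip (with a warning) reactions that fail validation
#'   instead of raising.
#' @return An object of class `mapping_store`.
#' @export
load_store <- function(dir, lenient = FALSE) {
  index_path <- file.path(dir, "index.csv")
  if (!file.exists(index_path))
    lookup_error(sprintf("no index.csv in '%s'", dir))
  index <- utils::read.csv(index_path, colClasses = "character")
  needed <- c("database", "identifier", "file", "reversible")
  if (!all(needed %in% names(index)))
    parse_error(sprintf("store index must have columns %s",
                        paste(needed, collapse = ", ")))
  index$reversible <- toupper(index$reversible) %in% c("TRUE", "T", "1", "R")
  reactions <- list()
  keep <- rep(TRUE, nrow(index))
  for (file in unique(index$file)) {
    path <- file.path(dir, file)
    ids <- index[index$file == file, , drop = FALSE]
    label <- paste(paste0(ids$database, ":", ids$identifier), collapse = ", ")
    if (!file.exists(path))
      lookup_error(sprintf("store entry %s references missing file '%s'",
                           label, file))
    r <- read_rxn(path, reversible = ids$reversible[1])
    r <- canonicalize_reaction(r)
    r$external_ids <- ids[, c("database", "identifier")]
    if (!reaction_is_clean(r)) {
      msg <- sprintf("store entry %s ('%s') fails validation", label, file)
      if (!lenient) atomtrail_error(msg, "atomtrail_validation_error")
      warning(paste0(msg, "; skipped"), call. = FALSE)
      keep[index$file == file] <- FALSE
      next
    }
    reactions[[file]] <- r
  }
  index <- index[keep, , drop = FALSE]
  compounds <- NULL
  cpath <- file.path(dir, "compounds.csv")
  if (file.exists(cpath)) compounds <- utils::read.csv(cpath, colClasses = "character")
  aliases <- NULL
  apath <- file.path(dir, "aliases.csv")
  if (file.exists(apath)) aliases <- utils::read.csv(apath, colClasses = "character")
  molecules <- list()
  for (r in reactions) {
    for (m in c(r$substrates, r$products)) {
      prev <- molecules[[m$name]]
      if (is.null(prev)) {
        molecules[[m$name]] <- m
      } else if (carbon_count(prev) != carbon_count(m)) {
        atomtrail_error(sprintf(
          "metabolite '%s' has inconsistent carbon counts across stored reactions (%d vs %d)",
          m$name, carbon_count(prev), carbon_count(m)),
          "atomtrail_validation_error")
      } else if (!identical(prev$charges, m$charges)) {
        warning(sprintf(
          "metabolite '%s': charge/protonation variants across stored reactions; carbon skeletons match",
          m$name), call. = FALSE)
      }
    }
  }
  structure(list(dir = dir, index = index, reactions = reactions,
                 compounds = compounds, aliases = aliases,
                 molecules = molecules),
            class = "mapping_store")
}

#' @export
print.mapping_store <- function(x, ...) {
  cat(sprintf("<mapping_store> %s: %d reactions, %d identifiers, %d metabolites\n",
              x$dir, length(x$reactions), nrow(x$index), length(x$molecules)))
  invisible(x)
}

#' Look up a stored reaction by identifier
#'
#' @param store A [load_store()] result.
#' @param key Either `"DB:ID"` (DB one of BRENDA, KEGG, MetaCyc) or a bare
#'   identifier searched across all namespaces. A bare identifier matching
#'   different reactions in different namespaces is an ambiguity error.
#' @return A [mapped_reaction()], canonicalized.
#' @export
store_lookup <- function(store, key) {
  idx <- store$index
  if (grepl(":", key, fixed = TRUE)) {
    parts <- strsplit(key, ":", fixed = TRUE)[[1]]
    hit <- idx[toupper(idx$database) == toupper(parts[1]) &
                 idx$identifier == paste(parts[-1], collapse = ":"), , drop = FALSE]
  } else {
    hit <- idx[idx$identifier == key, , drop = FALSE]
  }
  files <- unique(hit$file)
  if (length(files) == 0L)
    lookup_error(sprintf("no stored atom mapping for identifier '%s'", key))
  if (length(files) > 1L)
    lookup_error(sprintf(
      "identifier '%s' is ambiguous across namespaces: %s",
      key, paste(paste0(hit$database, ":", hit$identifier, " -> ", hit$file),
                 collapse = ", ")))
  store$reactions[[files]]
}

#' List the contents of a mapping store
#'
#' @param store A [load_store()] result.
#' @return Data frame: database, identifier, reaction, reversible, equation.
#' @export
store_list <- function(store) {
  do.call(rbind, lapply(seq_len(nrow(store$index)), function(i) {
    r <- store$reactions[[store$index$file[i]]]
    eq <- sprintf("%s %s %s",
                  paste(vapply(r$substrates, `[[`, "", "name"), collapse = " + "),
                  if (r$reversible) "<->" else "->",
                  paste(vapply(r$products, `[[`, "", "name"), collapse = " + "))
    data.frame(database = store$index$database[i],
               identifier = store$index$identifier[i],
               reaction = r$reaction_id,
               reversible = r$reversible,
               equation = eq, stringsAsFactors = FALSE)
  }))
}

#' Write a store back to disk
#'
#' Serializes the (canonicalized) reactions and index of a loaded store into
#' a directory. Loading, writing and reloading a store leaves every atom
#' map unchanged, since canonicalization is idempotent.
#'
#' @param store A [load_store()] result.
#' @param dir Target directory.
#' @return `dir`, invisibly.
#' @export
write_store <- function(store, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (file in names(store$reactions)) {
    writeLines(write_rxn(store$reactions[[file]]), file.path(dir, file))
  }
  utils::write.csv(store$index, file.path(dir, "index.csv"), row.names = FALSE)
  if (!is.null(store$compounds))
    utils::write.csv(store$compounds, file.path(dir, "compounds.csv"),
                     row.names = FALSE)
  if (!is.null(store$aliases))
    utils::write.csv(store$aliases, file.path(dir, "aliases.csv"),
                     row.names = FALSE)
  invisible(dir)
}

# Resolve a model metabolite (name + optional id) to the stored metabolite
# name: by compound identifier when given, else via the alias table, else by
# exact name.
resolve_metabolite <- function(store, name, id = NULL) {
  if (!is.null(id)) {
    cp <- store$compounds
    if (!is.null(cp)) {
      hit <- if (is.na(id$database)) {
        cp[cp$identifier == id$identifier, , drop = FALSE]
      } else {
        cp[toupper(cp$database) == toupper(id$database) &
             cp$identifier == id$identifier, , drop = FALSE]
      }
      if (nrow(hit) > 0L) {
        if (length(unique(hit$name)) > 1L)
          lookup_error(sprintf("compound identifier '%s' is ambiguous",
                               id$identifier))
        return(hit$name[1])
      }
    }
  }
  al <- store$aliases
  if (!is.null(al)) {
    hit <- al[al$alias == name, , drop = FALSE]
    if (nrow(hit) > 0L) return(hit$name[1])
  }
  name
}

#' Fetch a stored metabolite structure by name
#'
#' @param store A [load_store()] result.
#' @param name Metabolite name (aliases are resolved).
#' @return The canonicalized [molecule()].
#' @export
store_molecule <- function(store, name) {
  nm <- resolve_metabolite(store, name)
  m <- store$molecules[[nm]]
  if (is.null(m))
    lookup_error(sprintf("no metabolite named '%s' in the store", name))
  m
}
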