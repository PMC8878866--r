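# Positional label tracing through an ABC model, plus single-error
# injection and model diffing.
#
# The tracer is deterministic and positional: it follows labeled carbon
# positions letter-by-letter through successive reaction entries, with no
# fractional enrichments and no flux weighting (isotopomer simulation is a
# job for dedicated flux-analysis software). Labels that move into a
# metabolite the entry does not retain (an omitted cofactor) are reported
# as lost fates rather than silently dropped; labels reaching a metabolite
# like CO2 simply sit there as their terminal fate. When a reaction has
# several symmetry-expanded variant entries, the union of the variants'
# fates is taken.

#' Create a label state
#'
#' A set of labeled carbon positions: metabolite name, instance tag, and
#' 1-based carbon position *in canonical carbon order*. Use
#' [carbon_canonical_position()] to convert a source-file (chemical) carbon
#' number into a canonical position and [carbon_source_number()] for the
#' way back.
#'
#' @param metabolite,position,instance Vectors (recycled) describing the
#'   labeled positions.
#' @return A `label_state` data frame.
#' @export
label_state <- function(metabolite, position, instance = 1L) {
  df <- data.frame(metabolite = as.character(metabolite),
                   instance = as.integer(instance),
                   position = as.integer(position),
                   stringsAsFactors = FALSE)
  if (any(df$position < 1L)) model_error("carbon positions are 1-based")
  class(df) <- c("label_state", class(df))
  df
}

entries_named <- function(abc, name) {
  Filter(function(e) e$name == name, abc$entries)
}

side_occurrences <- function(side, name) {
  which(vapply(side, `[[`, "", "name") == name)
}

#' Trace labeled carbons along a reaction path
#'
#' Moves each labeled carbon through the entries named in `path`, in order:
#' at every step the label's letter is read off the substrate string and
#' the label jumps to the product position carrying the same letter.
#' Reversible entries are traversed backwards when the labeled metabolite
#' sits on their product side. Labels in metabolites a step does not touch
#' are carried along unchanged, but a step that touches no label at all is
#' an error (a gap in the path). Letters without a product position (their
#' partner was omitted from the entry) become lost fates.
#'
#' @param abc An `abc_model`.
#' @param start A [label_state()].
#' @param path Character vector of reaction (entry) names.
#' @return A `label_trace`: list with `final` (label state, plus an
#'   `origin` and a `route` column recording the reactions that moved each
#'   label), `lost` (data frame of lost fates), and `steps`.
#' @export
trace_labels <- function(abc, start, path) {
  labels <- as.data.frame(start)
  labels$origin <- sprintf("%s:%d", labels$metabolite, labels$position)
  labels$route <- ""
  lost <- data.frame(reaction = character(0), metabolite = character(0),
                     position = integer(0), letter = character(0),
                     origin = character(0), stringsAsFactors = FALSE)
  steps <- list()
  for (rxn in path) {
    entries <- entries_named(abc, rxn)
    if (length(entries) == 0L)
      model_error(sprintf("reaction '%s' is not part of the model", rxn))
    new_labels <- labels[0, , drop = FALSE]
    touched_any <- FALSE
    for (li in seq_len(nrow(labels))) {
      lab <- labels[li, , drop = FALSE]
      moved <- FALSE
      for (e in entries) {
        mv <- move_label(e, lab, rxn)
        if (is.null(mv)) next
        moved <- TRUE
        if (nrow(mv$moved) > 0L) new_labels <- rbind(new_labels, mv$moved)
        if (nrow(mv$lost) > 0L) lost <- rbind(lost, mv$lost)
      }
      if (!moved) new_labels <- rbind(new_labels, lab)
      touched_any <- touched_any || moved
    }
    if (!touched_any)
      model_error(sprintf(
        "reaction '%s' does not connect to any current label position (%s)",
        rxn, paste(unique(labels$metabolite), collapse = ", ")))
    labels <- unique(new_labels)
    steps[[length(steps) + 1L]] <- list(reaction = rxn, labels = labels)
  }
  structure(list(final = labels, lost = unique(lost), steps = steps),
            class = "label_trace")
}

# Move one label through one entry; NULL if the entry does not touch the
# label's metabolite. Returns moved labels and lost fates.
move_label <- function(e, lab, rxn) {
  res_moved <- lab[0, , drop = FALSE]
  res_lost <- data.frame(reaction = character(0), metabolite = character(0),
                         position = integer(0), letter = character(0),
                         origin = character(0), stringsAsFactors = FALSE)
  hop <- function(from_side, to_side) {
    occ <- side_occurrences(e[[from_side]], lab$metabolite)
    if (length(occ) == 0L) return(FALSE)
    inst <- if (lab$instance <= length(occ)) occ[lab$instance] else occ[1]
    str <- e[[from_side]][[inst]]$letters
    if (lab$position > nchar(str))
      model_error(sprintf(
        "label position %d exceeds the %d carbons of '%s' in reaction '%s'",
        lab$position, nchar(str), lab$metabolite, rxn))
    letter <- substr(str, lab$position, lab$position)
    for (j in seq_along(e[[to_side]])) {
      hitpos <- regexpr(letter, e[[to_side]][[j]]$letters, fixed = TRUE)
      if (hitpos > 0L) {
        nm <- e[[to_side]][[j]]$name
        occ_to <- side_occurrences(e[[to_side]], nm)
        row <- lab
        row$metabolite <- nm
        row$instance <- match(j, occ_to)
        row$position <- as.integer(hitpos)
        row$route <- if (lab$route == "") rxn else paste(lab$route, rxn, sep = ",")
        res_moved <<- rbind(res_moved, row)
        return(TRUE)
      }
    }
    res_lost <<- rbind(res_lost, data.frame(
      reaction = rxn, metabolite = lab$metabolite, position = lab$position,
      letter = letter, origin = lab$origin, stringsAsFactors = FALSE))
    TRUE
  }
  if (hop("substrates", "products")) return(list(moved = res_moved, lost = res_lost))
  if (e$reversible && hop("products", "substrates"))
    return(list(moved = res_moved, lost = res_lost))
  NULL
}

#' @export
print.label_trace <- function(x, ...) {
  cat("<label_trace>\n final positions:\n")
  for (i in seq_len(nrow(x$final))) {
    f <- x$final[i, ]
    cat(sprintf("  %s -> %s C%d (instance %d; via %s)\n",
                f$origin, f$metabolite, f$position, f$instance,
                if (f$route == "") "-" else f$route))
  }
  if (nrow(x$lost) > 0L) {
    cat(" lost fates:\n")
    for (i in seq_len(nrow(x$lost))) {
      l <- x$lost[i, ]
      cat(sprintf("  %s: letter '%s' left the retained metabolites at %s\n",
                  l$origin, l$letter, l$reaction))
    }
  }
  invisible(x)
}

#' Inject a single atom-mapping error into an ABC model
#'
#' Exchanges the product-side positions of two letters in the named
#' reaction's entries. The resulting entry is still letter-conserving —
#' well-formed but chemically wrong — which is exactly the kind of error a
#' mapping algorithm can make and a validator cannot catch.
#'
#' @param abc An `abc_model`.
#' @param reaction Entry name.
#' @param letters Character vector of two letters, both present on the
#'   product side of the entry; swapping a letter with itself is a no-op.
#' @return The modified `abc_model`.
#' @export
inject_error <- function(abc, reaction, letters) {
  stopifnot(length(letters) == 2L)
  idx <- which(vapply(abc$entries, function(e) e$name == reaction, NA))
  if (length(idx) == 0L)
    lookup_error(sprintf("no entry named '%s' in the model", reaction))
  for (i in idx) {
    e <- abc$entries[[i]]
    all_letters <- unlist(strsplit(vapply(e$products, `[[`, "", "letters"), ""))
    missing <- setdiff(letters, all_letters)
    if (length(missing) > 0L)
      lookup_error(sprintf(
        "letter(s) %s absent from the product side of reaction '%s'",
        paste(missing, collapse = ", "), reaction))
    if (letters[1] == letters[2]) next
    for (j in seq_along(e$products)) {
      lets <- strsplit(e$products[[j]]$letters, "")[[1]]
      lets[lets == letters[1]] <- ""
      lets[lets == letters[2]] <- letters[1]
      lets[lets == ""] <- letters[2]
      e$products[[j]]$letters <- paste(lets, collapse = "")
    }
    abc$entries[[i]] <- e
  }
  abc
}

#' Diff two ABC models
#'
#' Position-by-position comparison of the letter strings of two models
#' over the same reaction set; used e.g. to verify that [inject_error()]
#' changed exactly one reaction.
#'
#' @param a,b `abc_model`s over the same reaction set. Symmetry-expanded
#'   variant entries present in only one model are reported as whole-entry
#'   differences (position `NA`) rather than an error.
#' @return Data frame with one row per differing position: reaction,
#'   variant, side, metabolite, instance, position, letter_a, letter_b.
#'   Zero rows iff the models are identical.
#' @export
diff_models <- function(a, b) {
  key <- function(m) vapply(m$entries, function(e) sprintf("%s@%d", e$name, e$variant), "")
  nm <- function(m) vapply(m$entries, `[[`, "", "name")
  ka <- key(a)
  kb <- key(b)
  if (!setequal(nm(a), nm(b)) || anyDuplicated(ka) || anyDuplicated(kb))
    model_error("models do not share the same reaction set")
  out <- NULL
  for (k in setdiff(union(ka, kb), intersect(ka, kb))) {
    e <- if (k %in% ka) a$entries[[which(ka == k)]] else b$entries[[which(kb == k)]]
    out <- rbind(out, data.frame(
      reaction = e$name, variant = e$variant, side = "entry",
      metabolite = NA_character_, instance = NA_integer_, position = NA_integer_,
      letter_a = if (k %in% ka) "present" else "absent",
      letter_b = if (k %in% kb) "present" else "absent",
      stringsAsFactors = FALSE))
  }
  for (k in intersect(ka, kb)) {
    ea <- a$entries[[which(ka == k)]]
    eb <- b$entries[[which(kb == k)]]
    for (side in c("substrates", "products")) {
      if (length(ea[[side]]) != length(eb[[side]]))
        model_error(sprintf("entry '%s': different %s counts", k, side))
      for (i in seq_along(ea[[side]])) {
        la <- strsplit(ea[[side]][[i]]$letters, "")[[1]]
        lb <- strsplit(eb[[side]][[i]]$letters, "")[[1]]
        if (length(la) != length(lb))
          model_error(sprintf("entry '%s': different carbon counts for '%s'",
                              k, ea[[side]][[i]]$name))
        d <- which(la != lb)
        for (p in d) {
          out <- rbind(out, data.frame(
            reaction = ea$name, variant = ea$variant, side = side,
            metabolite = ea[[side]][[i]]$name, instance = i, position = p,
            letter_a = la[p], letter_b = lb[p], stringsAsFactors = FALSE))
        }
      }
    }
  }
  out %||% data.frame(reaction = character(0), variant = integer(0),
                      side = character(0), metabolite = character(0),
                      instance = integer(0), position = integer(0),
                      letter_a = character(0), letter_b = character(0),
                      stringsAsFactors = FALSE)
}
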