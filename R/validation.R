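# Reaction quality filters: carbon balance and atom-mapping integrity.
#
# Both operations *report*; they never raise on bad chemistry. A reaction
# whose substrate and product carbon totals differ is recorded as
# unbalanced, mirroring the filter that removes carbon-unbalanced reactions
# from model building. Mapping validation requires mappings to be
# well-formed on heavy atoms and *complete on carbons* (for balanced
# reactions); unmapped oxygens/nitrogens are accepted, since the ABC model
# is carbon-only. Note that a chemically wrong but well-formed mapping
# passes these checks by design — that is precisely why curation (and the
# error-injection tracer) exists.

new_validation_report <- function(reaction_id, sc, pc, unmapped, violations) {
  structure(
    list(
      reaction_id = reaction_id,
      carbon_balanced = sc == pc,
      substrate_carbons = sc,
      product_carbons = pc,
      carbons_unmapped = unmapped,
      violations = violations
    ),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %s: %s (%d -> %d C), %d carbons unmapped\n",
              x$reaction_id,
              if (x$carbon_balanced) "balanced" else "UNBALANCED",
              x$substrate_carbons, x$product_carbons, x$carbons_unmapped))
  for (v in x$violations) cat(sprintf("  [%s] %s\n", v$code, v$detail))
  invisible(x)
}

violation <- function(code, detail) list(code = code, detail = detail)

#' Check the carbon balance of a reaction
#'
#' Sums the carbons of all substrate instances and all product instances
#' (stoichiometry is respected, since coefficients are represented as
#' repeated instances) and records whether the totals agree. A full-element
#' comparison is attached as an informational finding when other elements
#' are out of balance, but only carbon decides `carbon_balanced`.
#'
#' @param r A [mapped_reaction()].
#' @return A `validation_report`.
#' @export
carbon_balance <- function(r) {
  sc <- side_carbons(r$substrates)
  pc <- side_carbons(r$products)
  violations <- list()
  if (sc != pc)
    violations <- c(violations, list(violation(
      "carbon_unbalanced",
      sprintf("%d substrate vs %d product carbons", sc, pc))))
  tab <- function(mols) table(unlist(lapply(mols, `[[`, "elements")))
  st <- tab(r$substrates); pt <- tab(r$products)
  els <- setdiff(union(names(st), names(pt)), c("H", "C"))
  for (el in els) {
    a <- if (el %in% names(st)) st[[el]] else 0L
    b <- if (el %in% names(pt)) pt[[el]] else 0L
    if (a != b)
      violations <- c(violations, list(violation(
        "element_imbalance_info",
        sprintf("%s: %d vs %d (informational)", el, a, b))))
  }
  new_validation_report(r$reaction_id, sc, pc, NA_integer_, violations)
}

#' Validate the atom mapping of a reaction
#'
#' Flags element-mismatched map pairs, duplicated endpoints, and — for
#' carbon-balanced reactions — carbons on either side that are absent from
#' the atom map. `carbons_unmapped` counts unmapped carbons over both sides.
#'
#' @param r A [mapped_reaction()].
#' @return A `validation_report`.
#' @export
validate_mapping <- function(r) {
  am <- r$atom_map
  violations <- list()
  dup_check <- function(inst, atom, side) {
    key <- paste(inst, atom)
    if (anyDuplicated(key))
      violations <<- c(violations, list(violation(
        "duplicate_endpoint",
        sprintf("a %s atom appears in more than one map pair", side))))
  }
  dup_check(am$s_inst, am$s_atom, "substrate")
  dup_check(am$p_inst, am$p_atom, "product")
  if (nrow(am) > 0L) {
    se <- mapply(function(i, a) r$substrates[[i]]$elements[a], am$s_inst, am$s_atom)
    pe <- mapply(function(i, a) r$products[[i]]$elements[a], am$p_inst, am$p_atom)
    bad <- which(se != pe)
    for (k in bad)
      violations <- c(violations, list(violation(
        "element_mismatch",
        sprintf("pair %d joins %s with %s", k, se[k], pe[k]))))
  }
  count_unmapped <- function(mols, inst, atom) {
    total <- 0L
    for (i in seq_along(mols)) {
      carbons <- which(mols[[i]]$elements == "C")
      total <- total + sum(!(carbons %in% atom[inst == i]))
    }
    total
  }
  unmapped <- count_unmapped(r$substrates, am$s_inst, am$s_atom) +
    count_unmapped(r$products, am$p_inst, am$p_atom)
  sc <- side_carbons(r$substrates)
  pc <- side_carbons(r$products)
  if (sc == pc && unmapped > 0L)
    violations <- c(violations, list(violation(
      "carbon_unmapped",
      sprintf("%d carbons missing from the atom map", unmapped))))
  new_validation_report(r$reaction_id, sc, pc, unmapped, violations)
}

# TRUE when a stored reaction is clean enough to enter a mapping store:
# balanced and carbon-complete with no mapping violations.
reaction_is_clean <- function(r) {
  cb <- carbon_balance(r)
  vm <- validate_mapping(r)
  real <- Filter(function(v) v$code != "element_imbalance_info", cb$violations)
  cb$carbon_balanced && vm$carbons_unmapped == 0L &&
    length(vm$violations) == 0L && length(real) == 0L
}
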