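# MDL MOL / RXN (V2000) reading and writing.
#
# Only the fields this package needs are interpreted: element symbol, charge
# (old-style atom-block codes and M CHG property lines), bond block, and the
# atom-atom mapping number field of RXN atom blocks. V3000 input is rejected.

KNOWN_ELEMENTS <- c(
  "H", "B", "C", "N", "O", "F", "Na", "Mg", "Si", "P", "S", "Cl", "K", "Ca",
  "Mn", "Fe", "Co", "Ni", "Cu", "Zn", "As", "Se", "Br", "Mo", "I"
)

# Old-style V2000 charge codes (field ccc of the atom line).
charge_from_code <- function(code) {
  c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L, `5` = -1L, `6` = -2L,
    `7` = -3L)[as.character(code)]
}

as_text_lines <- function(text) {
  if (length(text) == 1L && !grepl("\n", text, fixed = TRUE) && file.exists(text))
    return(readLines(text, warn = FALSE))
  if (length(text) == 1L) return(strsplit(text, "\n", fixed = TRUE)[[1]])
  text
}

field <- function(line, from, to) {
  if (nchar(line) < from) "" else trimws2(substr(line, from, min(to, nchar(line))))
}

int_field <- function(line, from, to, default = 0L) {
  x <- field(line, from, to)
  if (x == "") return(default)
  suppressWarnings(v <- as.integer(x))
  if (is.na(v)) NA_integer_ else v
}

# Parse one V2000 MOL block. `offset` is the file line number of the block's
# first line, used for error messages. Returns the molecule plus the raw
# atom-atom map numbers (0 = unmapped).
read_molblock <- function(lines, offset = 0L) {
  if (length(lines) < 4L) parse_error("MOL block shorter than header", offset + 1L)
  name <- trimws2(lines[1])
  counts <- lines[4]
  if (grepl("V3000", counts, fixed = TRUE))
    parse_error("V3000 MOL blocks are not supported; supply V2000", offset + 4L)
  na <- int_field(counts, 1, 3)
  nb <- int_field(counts, 4, 6)
  if (is.na(na) || is.na(nb) || na < 1L || nb < 0L)
    parse_error("malformed counts line", offset + 4L)
  if (length(lines) < 4L + na + nb)
    parse_error(sprintf("MOL block truncated: counts line promises %d atoms, %d bonds",
                        na, nb), offset + 4L)
  elements <- character(na)
  charges <- integer(na)
  maps <- integer(na)
  for (i in seq_len(na)) {
    ln <- lines[4L + i]
    lineno <- offset + 4L + i
    el <- field(ln, 32, 34)
    if (el == "") {  # tolerate whitespace-collapsed atom lines
      parts <- strsplit(trimws2(ln), "\\s+")[[1]]
      if (length(parts) >= 4L) el <- parts[4]
    }
    if (!(el %in% KNOWN_ELEMENTS))
      parse_error(sprintf("unknown element symbol '%s'", el), lineno)
    elements[i] <- el
    code <- int_field(ln, 37, 39)
    chg <- charge_from_code(code %||% 0L)
    charges[i] <- if (is.na(chg)) 0L else chg
    maps[i] <- int_field(ln, 61, 63, default = 0L)
    if (is.na(maps[i])) parse_error("malformed atom-atom map field", lineno)
  }
  bonds <- matrix(integer(0), ncol = 3L)
  if (nb > 0L) {
    bonds <- matrix(0L, nrow = nb, ncol = 3L)
    for (i in seq_len(nb)) {
      ln <- lines[4L + na + i]
      lineno <- offset + 4L + na + i
      a1 <- int_field(ln, 1, 3); a2 <- int_field(ln, 4, 6); o <- int_field(ln, 7, 9)
      if (anyNA(c(a1, a2, o)) || a1 < 1L || a2 < 1L || a1 > na || a2 > na)
        parse_error("malformed bond line", lineno)
      bonds[i, ] <- c(a1, a2, o)
    }
  }
  # Property block: honor M CHG; ignore other properties.
  rest <- lines[seq.int(4L + na + nb + 1L, length.out = max(0L, length(lines) - 4L - na - nb))]
  ignored <- character(0)
  for (k in seq_along(rest)) {
    ln <- rest[k]
    tag <- substr(ln, 1, 6)
    if (tag == "M  END") break
    if (tag == "M  CHG") {
      parts <- as.integer(strsplit(trimws2(substr(ln, 7, nchar(ln))), "\\s+")[[1]])
      nn <- parts[1]
      for (j in seq_len(nn)) {
        at <- parts[2L * j]; ch <- parts[2L * j + 1L]
        if (is.na(at) || at < 1L || at > na)
          parse_error("M CHG references missing atom", offset + 4L + na + nb + k)
        charges[at] <- ch
      }
    } else if (grepl("^M  ", ln)) {
      ignored <- c(ignored, trimws2(substr(ln, 4, 6)))
    }
  }
  if (length(ignored) > 0L)
    warning(sprintf("MOL block '%s': ignoring property lines: %s",
                    name, paste(unique(ignored), collapse = ", ")),
            call. = FALSE)
  list(molecule = molecule(name, elements, bonds, charges), maps = maps)
}

#' Read an MDL MOL (V2000) file
#'
#' @param text MOL file content (single string or character vector of lines)
#'   or a path to a file.
#' @return A [molecule()] with atoms and bonds in file order and no canonical
#'   order attached.
#' @export
#' @examples
#' m <- read_mol(write_mol(molecule("methane", "C")))
read_mol <- function(text) {
  read_molblock(as_text_lines(text))$molecule
}

#' Write a molecule as an MDL MOL (V2000) block
#'
#' Atoms are emitted in canonical order when one is attached, otherwise in
#' current order. Coordinates are written as zeros (this package carries
#' connectivity only). Formal charges are written as `M CHG` property lines.
#'
#' @param m A [molecule()].
#' @param maps Optional integer vector of atom-atom map numbers, one per atom
#'   in `m`'s current order (used by [write_rxn()]).
#' @return A single string with the MOL block text (including `M END`).
#' @export
write_mol <- function(m, maps = NULL) {
  validate_molecule(m)
  perm <- m$canonical_order %||% seq_len(n_atoms(m))
  n <- length(perm)
  if (n > 999L || nrow(m$bonds) > 999L)
    capacity_error("V2000 supports at most 999 atoms/bonds")
  maps <- (maps %||% integer(n))[perm]
  inv <- integer(n); inv[perm] <- seq_len(n)
  out <- c(m$name, "  atomtrail", "",
           sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nrow(m$bonds)))
  for (k in seq_len(n)) {
    i <- perm[k]
    out <- c(out, sprintf(
      "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0%3d  0  0",
      0, 0, 0, m$elements[i], maps[k]))
  }
  b <- m$bonds
  for (k in seq_len(nrow(b))) {
    out <- c(out, sprintf("%3d%3d%3d  0  0  0  0", inv[b[k, 1]], inv[b[k, 2]], b[k, 3]))
  }
  chg <- which(m$charges[perm] != 0L)
  for (k in chg) {
    out <- c(out, sprintf("M  CHG%3d%4d%4d", 1L, k, m$charges[perm[k]]))
  }
  out <- c(out, "M  END")
  paste(out, collapse = "\n")
}

#' Read an MDL RXN (V2000) file with atom-atom map numbers
#'
#' The atom map is reconstructed from shared nonzero map numbers: a number
#' must occur on exactly one substrate atom and exactly one product atom
#' (map number 0 marks an unmapped atom). Violations raise a
#' mapping-integrity error.
#'
#' @param text RXN file content or a path.
#' @param reversible Reversibility flag to attach (RXN files do not carry one).
#' @return A [mapped_reaction()].
#' @export
read_rxn <- function(text, reversible = FALSE) {
  lines <- as_text_lines(text)
  if (length(lines) < 5L || trimws2(lines[1]) != "$RXN")
    parse_error("not an RXN file: missing $RXN header", 1L)
  if (any(grepl("V3000", lines[1:5], fixed = TRUE)))
    parse_error("V3000 RXN files are not supported; supply V2000", 1L)
  name <- trimws2(lines[2])
  ns <- int_field(lines[5], 1, 3)
  np <- int_field(lines[5], 4, 6)
  if (is.na(ns) || is.na(np) || ns < 1L || np < 1L)
    parse_error("malformed RXN counts line", 5L)
  starts <- which(trimws2(lines) == "$MOL")
  if (length(starts) != ns + np)
    parse_error(sprintf("RXN header promises %d molecules, found %d MOL blocks",
                        ns + np, length(starts)), 5L)
  ends <- c(starts[-1] - 1L, length(lines))
  blocks <- lapply(seq_along(starts), function(i) {
    read_molblock(lines[(starts[i] + 1L):ends[i]], offset = starts[i])
  })
  subs <- blocks[seq_len(ns)]
  prods <- blocks[ns + seq_len(np)]
  collect <- function(side) {
    do.call(rbind, lapply(seq_along(side), function(i) {
      maps <- side[[i]]$maps
      w <- which(maps > 0L)
      if (length(w) == 0L) return(NULL)
      data.frame(inst = i, atom = w, map = maps[w])
    }))
  }
  sm <- collect(subs)
  pm <- collect(prods)
  am <- data.frame(s_inst = integer(0), s_atom = integer(0),
                   p_inst = integer(0), p_atom = integer(0))
  if (!is.null(sm) || !is.null(pm)) {
    nums <- sort(unique(c(sm$map, pm$map)))
    for (nmb in nums) {
      si <- which(sm$map == nmb)
      pi <- which(pm$map == nmb)
      if (length(si) != 1L || length(pi) != 1L)
        mapping_error(sprintf(
          "reaction '%s': map number %d appears on %d substrate and %d product atoms (expected 1 and 1)",
          name, nmb, length(si), length(pi)))
      am <- rbind(am, data.frame(s_inst = sm$inst[si], s_atom = sm$atom[si],
                                 p_inst = pm$inst[pi], p_atom = pm$atom[pi]))
    }
  }
  mapped_reaction(name, lapply(subs, `[[`, "molecule"),
                  lapply(prods, `[[`, "molecule"), am, reversible = reversible)
}

#' Write a mapped reaction as an MDL RXN (V2000) file
#'
#' Atom-atom map numbers are regenerated from the reaction's atom map
#' (sequential numbering of the map pairs); molecules are emitted via
#' [write_mol()], so canonically ordered molecules stay in canonical order.
#'
#' @param r A [mapped_reaction()].
#' @return A single string with the RXN file text.
#' @export
write_rxn <- function(r) {
  validate_reaction_structure(r)
  am <- r$atom_map
  side_maps <- function(mols, inst_col, atom_col) {
    lapply(seq_along(mols), function(i) {
      maps <- integer(n_atoms(mols[[i]]))
      w <- which(am[[inst_col]] == i)
      maps[am[[atom_col]][w]] <- w
      maps
    })
  }
  smaps <- side_maps(r$substrates, "s_inst", "s_atom")
  pmaps <- side_maps(r$products, "p_inst", "p_atom")
  out <- c("$RXN", r$reaction_id, "  atomtrail", "",
           sprintf("%3d%3d", length(r$substrates), length(r$products)))
  for (i in seq_along(r$substrates))
    out <- c(out, "$MOL", write_mol(r$substrates[[i]], maps = smaps[[i]]))
  for (i in seq_along(r$products))
    out <- c(out, "$MOL", write_mol(r$products[[i]], maps = pmaps[[i]]))
  paste(out, collapse = "\n")
}
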