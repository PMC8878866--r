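# The user-facing metabolic-model CSV format and the ABC text format.
#
# Model CSV: four columns — (1) reaction name, (2) substrates,
# (3) reversibility, (4) products. Database identifiers are given in square
# brackets after the reaction or metabolite name, `[DB:ID]` with DB one of
# BRENDA, KEGG, MetaCyc (or a custom tag / bare `[ID]`). Multiple
# metabolites in one column are separated by `+` with optional surrounding
# whitespace; a leading integer is a stoichiometric coefficient. Two
# optional per-metabolite annotations: `(letters)` supplies a user ABC
# mapping for custom reactions, `{n}` asserts the carbon count (used for
# moiety-restricted metabolites such as acetyl-CoA limited to its acetyl
# group). A header row is recognized by the literal `reaction` in the first
# cell. This dialect is self-defined and documented here; it is not claimed
# to be byte-compatible with any web upload format.

MODEL_DATABASES <- c("BRENDA", "KEGG", "MetaCyc")

parse_id_token <- function(token) {
  if (is.na(token) || token == "") return(NULL)
  if (grepl(":", token, fixed = TRUE)) {
    parts <- strsplit(token, ":", fixed = TRUE)[[1]]
    db <- parts[1]
    known <- MODEL_DATABASES[match(toupper(db), toupper(MODEL_DATABASES))]
    list(database = if (is.na(known)) db else known,
         identifier = paste(parts[-1], collapse = ":"),
         custom = is.na(known))
  } else {
    list(database = NA_character_, identifier = token, custom = FALSE)
  }
}

parse_metabolite_token <- function(token, row) {
  tok <- trimws2(token)
  carbon_limit <- NULL
  m <- regmatches(tok, regexec("\\{(\\d+)\\}", tok))[[1]]
  if (length(m) > 0L) {
    carbon_limit <- as.integer(m[2])
    tok <- trimws2(sub("\\{\\d+\\}", "", tok))
  }
  user_abc <- NULL
  m <- regmatches(tok, regexec("\\(([a-zA-Z]*)\\)\\s*$", tok))[[1]]
  if (length(m) > 0L) {
    user_abc <- m[2]
    tok <- trimws2(sub("\\([a-zA-Z]*\\)\\s*$", "", tok))
  }
  id <- NULL
  m <- regmatches(tok, regexec("\\[([^]]+)\\]", tok))[[1]]
  if (length(m) > 0L) {
    id <- parse_id_token(trimws2(m[2]))
    tok <- trimws2(sub("\\[[^]]+\\]", "", tok))
  }
  coefficient <- 1L
  m <- regmatches(tok, regexec("^(\\d+)\\s+(.*)$", tok))[[1]]
  if (length(m) > 0L) {
    coefficient <- as.integer(m[2])
    tok <- trimws2(m[3])
  }
  if (tok == "")
    model_error(sprintf("row %d: empty metabolite name", row))
  if (coefficient < 1L)
    model_error(sprintf("row %d: non-positive coefficient for '%s'", row, tok))
  list(name = tok, id = id, coefficient = coefficient,
       user_abc = user_abc, carbon_limit = carbon_limit)
}

parse_side <- function(cell, row, side) {
  cell <- trimws2(cell)
  if (cell == "")
    model_error(sprintf("row %d: empty %s list", row, side))
  tokens <- strsplit(cell, "\\s*\\+\\s*")[[1]]
  tokens <- tokens[tokens != ""]
  if (length(tokens) == 0L)
    model_error(sprintf("row %d: empty %s list", row, side))
  lapply(tokens, parse_metabolite_token, row = row)
}

parse_reversibility <- function(token, row) {
  t <- toupper(trimws2(token))
  if (t %in% c("REVERSIBLE", "R", "1")) return(TRUE)
  if (t %in% c("IRREVERSIBLE", "IR", "0")) return(FALSE)
  model_error(sprintf("row %d: unparseable reversibility token '%s'", row, token))
}

#' Parse a 4-column metabolic-model CSV
#'
#' See the format description in `vignette("atom-mapping-models")`: columns
#' are reaction name, substrates, reversibility, products; identifiers in
#' square brackets; `+`-separated metabolites with optional integer
#' coefficients, user ABC strings in parentheses, and `{n}` carbon-count
#' annotations.
#'
#' @param text CSV content (string or lines) or a file path.
#' @return An object of class `metabolic_model`: a list with `reactions`,
#'   one element per row, each carrying `name`, `id`, `substrates`,
#'   `reversible`, `products`.
#' @export
parse_model_csv <- function(text) {
  lines <- as_text_lines(text)
  lines <- lines[trimws2(lines) != "" & !grepl("^\\s*#", lines)]
  if (length(lines) == 0L) {
    warning("empty model file: returning an empty model", call. = FALSE)
    return(structure(list(reactions = list()), class = "metabolic_model"))
  }
  nf <- utils::count.fields(textConnection(lines), sep = ",", quote = "\"")
  bad <- which(nf != 4L)
  if (length(bad) > 0L)
    model_error(sprintf("row %d: expected 4 columns, found %d", bad[1], nf[bad[1]]))
  df <- utils::read.csv(text = lines, header = FALSE, colClasses = "character",
                        quote = "\"")
  start <- 1L
  if (grepl("^\\s*reaction", df[1, 1], ignore.case = TRUE)) start <- 2L
  reactions <- list()
  seen <- character(0)
  for (row in seq.int(start, length.out = max(0L, nrow(df) - start + 1L))) {
    name_cell <- trimws2(df[row, 1])
    id <- NULL
    m <- regmatches(name_cell, regexec("\\[([^]]+)\\]", name_cell))[[1]]
    if (length(m) > 0L) {
      id <- parse_id_token(trimws2(m[2]))
      name_cell <- trimws2(sub("\\[[^]]+\\]", "", name_cell))
    }
    if (name_cell == "")
      model_error(sprintf("row %d: empty reaction name", row))
    if (name_cell %in% seen)
      model_error(sprintf("row %d: duplicate reaction name '%s'", row, name_cell))
    seen <- c(seen, name_cell)
    reactions[[length(reactions) + 1L]] <- list(
      name = name_cell,
      id = id,
      substrates = parse_side(df[row, 2], row, "substrate"),
      reversible = parse_reversibility(df[row, 3], row),
      products = parse_side(df[row, 4], row, "product")
    )
  }
  structure(list(reactions = reactions), class = "metabolic_model")
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("<metabolic_model> %d reactions\n", length(x$reactions)))
  for (r in x$reactions) {
    side <- function(s) paste(vapply(s, function(t) {
      paste0(if (t$coefficient > 1L) paste0(t$coefficient, " ") else "", t$name)
    }, ""), collapse = " + ")
    cat(sprintf("  %s: %s %s %s\n", r$name, side(r$substrates),
                if (r$reversible) "<->" else "->", side(r$products)))
  }
  invisible(x)
}

# ---- ABC model ------------------------------------------------------------

abc_entry <- function(name, substrates, products, reversible,
                      provenance = NA_character_, id = NA_character_,
                      variant = 1L) {
  e <- list(name = name, id = id, reversible = isTRUE(reversible),
            substrates = substrates, products = products,
            provenance = provenance, variant = as.integer(variant))
  validate_abc_entry(e)
  e
}

validate_abc_entry <- function(e) {
  for (side in list(e$substrates, e$products)) {
    all_letters <- unlist(lapply(side, function(m) strsplit(m$letters, "")[[1]]))
    if (length(all_letters) > 52L)
      capacity_error(sprintf(
        "reaction '%s': more than 52 carbons on one side exhausts the letter alphabet",
        e$name))
    if (anyDuplicated(all_letters))
      model_error(sprintf("reaction '%s': letter '%s' occurs twice on one side",
                          e$name, all_letters[duplicated(all_letters)][1]))
  }
  invisible(e)
}

new_abc_model <- function(entries) {
  structure(list(entries = entries), class = "abc_model")
}

#' Render one ABC entry as its reaction equation
#'
#' @param e An entry of an `abc_model`.
#' @return String like `"glutamine (abcde) -> glutamate (abcde)"`.
#' @export
abc_equation <- function(e) {
  side <- function(s) paste(vapply(s, function(m) {
    sprintf("%s (%s)", m$name, m$letters)
  }, ""), collapse = " + ")
  sprintf("%s %s %s", side(e$substrates),
          if (e$reversible) "<->" else "->", side(e$products))
}

#' @export
print.abc_model <- function(x, ...) {
  cat(sprintf("<abc_model> %d entries\n", length(x$entries)))
  cat(write_abc(x), "\n")
  invisible(x)
}

#' Serialize / parse the ABC text format
#'
#' One line per entry: `name[@variant] [id]: equation  # provenance`, with
#' each metabolite instance rendered as `name (letters)` (one case-sensitive
#' letter per carbon, in the metabolite's canonical carbon order) and the
#' arrow `->` (irreversible) or `<->` (reversible). `@k` suffixes mark
#' symmetry-expanded variant entries. `parse_abc(write_abc(m))` restores the
#' model.
#'
#' @param model An `abc_model`.
#' @param text ABC text or a path.
#' @return `write_abc()`: a single string. `parse_abc()`: an `abc_model`.
#' @export
write_abc <- function(model) {
  lines <- vapply(model$entries, function(e) {
    validate_abc_entry(e)
    nm <- e$name
    if (e$variant > 1L) nm <- sprintf("%s@%d", nm, e$variant)
    if (!is.na(e$id)) nm <- sprintf("%s [%s]", nm, e$id)
    prov <- if (is.na(e$provenance)) "" else sprintf("  # %s", e$provenance)
    sprintf("%s: %s%s", nm, abc_equation(e), prov)
  }, "")
  paste(lines, collapse = "\n")
}

#' @rdname write_abc
#' @export
parse_abc <- function(text) {
  lines <- as_text_lines(text)
  lines <- lines[trimws2(lines) != "" & !grepl("^\\s*#", lines)]
  entries <- lapply(seq_along(lines), function(k) {
    ln <- lines[k]
    prov <- NA_character_
    m <- regexec("\\s+#\\s*(.*)$", ln)[[1]]
    if (m[1] != -1L) {
      prov <- trimws2(regmatches(ln, list(regexec("\\s+#\\s*(.*)$", ln)[[1]]))[[1]][2])
      ln <- sub("\\s+#.*$", "", ln)
    }
    # header ends at the first ": " (identifier brackets may contain bare colons)
    cut <- regexpr(": ", ln, fixed = TRUE)
    if (cut < 1L)
      parse_error("malformed ABC entry (missing ':')", k)
    nm <- trimws2(substr(ln, 1L, cut - 1L))
    body <- substr(ln, cut + 2L, nchar(ln))
    id <- NA_character_
    mm <- regmatches(nm, regexec("\\[([^]]+)\\]", nm))[[1]]
    if (length(mm) > 0L) {
      id <- mm[2]
      nm <- trimws2(sub("\\[[^]]+\\]", "", nm))
    }
    variant <- 1L
    mm <- regmatches(nm, regexec("^(.*)@(\\d+)$", nm))[[1]]
    if (length(mm) > 0L) {
      nm <- mm[2]
      variant <- as.integer(mm[3])
    }
    reversible <- grepl("<->", body, fixed = TRUE)
    halves <- strsplit(body, if (reversible) "<->" else "->", fixed = TRUE)[[1]]
    if (length(halves) != 2L)
      parse_error("malformed ABC entry (expected one reaction arrow)", k)
    parse_abc_side <- function(s) {
      toks <- strsplit(trimws2(s), "\\s*\\+\\s*")[[1]]
      lapply(toks, function(t) {
        mm <- regmatches(t, regexec("^(.*\\S)\\s*\\(([a-zA-Z]*)\\)$", t))[[1]]
        if (length(mm) == 0L)
          parse_error(sprintf("malformed metabolite term '%s'", t), k)
        list(name = mm[2], letters = mm[3])
      })
    }
    abc_entry(nm, parse_abc_side(halves[1]), parse_abc_side(halves[2]),
              reversible, provenance = prov, id = id, variant = variant)
  })
  new_abc_model(entries)
}

#' Tabular view of an ABC model
#'
#' @param model An `abc_model`.
#' @return A data frame with one row per entry: reaction, variant, id,
#'   reversibility, equation (the mapping column), provenance.
#' @export
abc_as_table <- function(model) {
  do.call(rbind, lapply(model$entries, function(e) {
    data.frame(reaction = e$name, variant = e$variant,
               id = e$id, reversible = e$reversible,
               mapping = abc_equation(e), provenance = e$provenance,
               stringsAsFactors = FALSE)
  }))
}
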