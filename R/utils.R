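# Internal helpers shared across the package.

atomtrail_error <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "atomtrail_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

parse_error <- function(msg, line = NA_integer_) {
  if (!is.na(line)) msg <- sprintf("%s (line %d)", msg, line)
  atomtrail_error(msg, "atomtrail_parse_error", line = line)
}

mapping_error <- function(msg) atomtrail_error(msg, "atomtrail_mapping_error")
capacity_error <- function(msg) atomtrail_error(msg, "atomtrail_capacity_error")
lookup_error <- function(msg) atomtrail_error(msg, "atomtrail_lookup_error")
model_error <- function(msg) atomtrail_error(msg, "atomtrail_model_error")

#' The ABC letter alphabet
#'
#' Letters used for carbon positions in ABC entries: `a`..`z` then `A`..`Z`.
#' One reaction side can therefore carry at most 52 carbons.
#'
#' @return Character vector of 52 single letters.
#' @keywords internal
abc_alphabet <- function() c(letters, LETTERS)

# Sort key that puts carbon first, then other elements alphabetically
# (Hill-order style), so canonical orders list the carbon backbone first.
element_sort_key <- function(el) {
  ifelse(el == "C", "0C", paste0("1", el))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

trimws2 <- function(x) gsub("^\\s+|\\s+$", "", x)
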