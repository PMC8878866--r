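# Curated toy central-carbon fixture set, generated entirely offline.
#
# Structures are embedded as hand-verified connection tables (heavy atoms
# only). Atom-numbering convention: carbons come first, in conventional
# chemical numbering (glucose C1 = aldehyde carbon, pyruvate C1 = carboxyl,
# acetyl-CoA moiety C1 = carbonyl, GABA C1 = carboxyl), followed by
# heteroatoms. "Source carbon k" of a fixture molecule is therefore its
# chemical carbon number. Glycolysis is condensed to single-compartment,
# cofactor-free skeleton reactions; a separate cofactor-bearing hexokinase
# entry (glucose + ATP) exists to demonstrate cofactor omission. Acetyl-CoA
# is deliberately restricted to its 2-carbon acetyl moiety. Reaction carbon
# maps encode the textbook fates: aldolase cleaves fructose-1,6-bisphosphate
# between C3 and C4 (C1-C3 -> DHAP, C4-C6 -> GAP), triose-phosphate
# isomerase inverts the triose (DHAP C1 -> GAP C3), so glucose C1 ends in
# pyruvate C3 and, past pyruvate dehydrogenase, in acetyl-CoA C2 while
# pyruvate C1 leaves as CO2. Glutamate decarboxylase releases the
# alpha-carboxyl (glutamate C1) as CO2.

fixture_structures <- function() {
  B <- function(...) matrix(as.integer(unlist(list(...))), ncol = 3, byrow = TRUE)
  list(
    glucose = list(
      elements = c(rep("C", 6), rep("O", 6)),
      bonds = B(1, 7, 2, 1, 2, 1, 2, 8, 1, 2, 3, 1, 3, 9, 1, 3, 4, 1,
                4, 10, 1, 4, 5, 1, 5, 11, 1, 5, 6, 1, 6, 12, 1)),
    G6P = list(
      elements = c(rep("C", 6), rep("O", 6), "P", rep("O", 3)),
      bonds = B(1, 7, 2, 1, 2, 1, 2, 8, 1, 2, 3, 1, 3, 9, 1, 3, 4, 1,
                4, 10, 1, 4, 5, 1, 5, 11, 1, 5, 6, 1, 6, 12, 1,
                12, 13, 1, 13, 14, 2, 13, 15, 1, 13, 16, 1)),
    F6P = list(
      elements = c(rep("C", 6), rep("O", 6), "P", rep("O", 3)),
      bonds = B(1, 7, 1, 1, 2, 1, 2, 8, 2, 2, 3, 1, 3, 9, 1, 3, 4, 1,
                4, 10, 1, 4, 5, 1, 5, 11, 1, 5, 6, 1, 6, 12, 1,
                12, 13, 1, 13, 14, 2, 13, 15, 1, 13, 16, 1)),
    FBP = list(
      elements = c(rep("C", 6), rep("O", 6), "P", rep("O", 3), "P", rep("O", 3)),
      bonds = B(1, 7, 1, 1, 2, 1, 2, 8, 2, 2, 3, 1, 3, 9, 1, 3, 4, 1,
                4, 10, 1, 4, 5, 1, 5, 11, 1, 5, 6, 1, 6, 12, 1,
                12, 13, 1, 13, 14, 2, 13, 15, 1, 13, 16, 1,
                7, 17, 1, 17, 18, 2, 17, 19, 1, 17, 20, 1)),
    DHAP = list(  # C1 = phosphate-bearing carbon (the FBP C1 lineage)
      elements = c(rep("C", 3), rep("O", 3), "P", rep("O", 3)),
      bonds = B(1, 4, 1, 4, 7, 1, 7, 8, 2, 7, 9, 1, 7, 10, 1,
                1, 2, 1, 2, 5, 2, 2, 3, 1, 3, 6, 1)),
    GAP = list(  # C1 = aldehyde, C3 = phosphate carbon
      elements = c(rep("C", 3), rep("O", 3), "P", rep("O", 3)),
      bonds = B(1, 4, 2, 1, 2, 1, 2, 5, 1, 2, 3, 1, 3, 6, 1,
                6, 7, 1, 7, 8, 2, 7, 9, 1, 7, 10, 1)),
    BPG = list(  # 1,3-bisphosphoglycerate
      elements = c(rep("C", 3), rep("O", 4), "P", rep("O", 3), "P", rep("O", 3)),
      bonds = B(1, 4, 2, 1, 5, 1, 5, 8, 1, 8, 9, 2, 8, 10, 1, 8, 11, 1,
                1, 2, 1, 2, 6, 1, 2, 3, 1, 3, 7, 1,
                7, 12, 1, 12, 13, 2, 12, 14, 1, 12, 15, 1)),
    `3PG` = list(
      elements = c(rep("C", 3), rep("O", 4), "P", rep("O", 3)),
      bonds = B(1, 4, 2, 1, 5, 1, 1, 2, 1, 2, 6, 1, 2, 3, 1, 3, 7, 1,
                7, 8, 1, 8, 9, 2, 8, 10, 1, 8, 11, 1)),
    `2PG` = list(
      elements = c(rep("C", 3), rep("O", 4), "P", rep("O", 3)),
      bonds = B(1, 4, 2, 1, 5, 1, 1, 2, 1, 2, 6, 1, 6, 8, 1, 2, 3, 1,
                3, 7, 1, 8, 9, 2, 8, 10, 1, 8, 11, 1)),
    PEP = list(
      elements = c(rep("C", 3), rep("O", 3), "P", rep("O", 3)),
      bonds = B(1, 4, 2, 1, 5, 1, 1, 2, 1, 2, 6, 1, 6, 7, 1, 2, 3, 2,
                7, 8, 2, 7, 9, 1, 7, 10, 1)),
    pyruvate = list(  # C1 carboxyl, C2 carbonyl, C3 methyl
      elements = c(rep("C", 3), rep("O", 3)),
      bonds = B(1, 4, 2, 1, 5, 1, 1, 2, 1, 2, 6, 2, 2, 3, 1)),
    `acetyl-CoA` = list(  # acetyl moiety only: C1 carbonyl, C2 methyl
      elements = c("C", "C", "O", "S"),
      bonds = B(1, 3, 2, 1, 2, 1, 1, 4, 1)),
    CO2 = list(
      elements = c("C", "O", "O"),
      bonds = B(1, 2, 2, 1, 3, 2)),
    water = list(elements = "O", bonds = NULL),
    ammonia = list(elements = "N", bonds = NULL),
    glutamine = list(  # C1 alpha-carboxyl ... C5 amide carbon
      elements = c(rep("C", 5), "O", "O", "N", "O", "N"),
      bonds = B(1, 6, 2, 1, 7, 1, 1, 2, 1, 2, 8, 1, 2, 3, 1, 3, 4, 1,
                4, 5, 1, 5, 9, 2, 5, 10, 1)),
    glutamate = list(  # C1 alpha-carboxyl ... C5 gamma-carboxyl
      elements = c(rep("C", 5), "O", "O", "N", "O", "O"),
      bonds = B(1, 6, 2, 1, 7, 1, 1, 2, 1, 2, 8, 1, 2, 3, 1, 3, 4, 1,
                4, 5, 1, 5, 9, 2, 5, 10, 1)),
    AKG = list(  # alpha-ketoglutarate
      elements = c(rep("C", 5), rep("O", 5)),
      bonds = B(1, 6, 2, 1, 7, 1, 1, 2, 1, 2, 8, 2, 2, 3, 1, 3, 4, 1,
                4, 5, 1, 5, 9, 2, 5, 10, 1)),
    GABA = list(  # C1 carboxyl (ex glutamate C5), C4 amine carbon (ex C2)
      elements = c(rep("C", 4), "O", "O", "N"),
      bonds = B(1, 5, 2, 1, 6, 1, 1, 2, 1, 2, 3, 1, 3, 4, 1, 4, 7, 1)),
    fumarate = list(
      elements = c(rep("C", 4), rep("O", 4)),
      bonds = B(1, 5, 2, 1, 6, 1, 1, 2, 1, 2, 3, 2, 3, 4, 1, 4, 7, 2, 4, 8, 1)),
    malate = list(
      elements = c(rep("C", 4), rep("O", 4), "O"),
      bonds = B(1, 5, 2, 1, 6, 1, 1, 2, 1, 2, 9, 1, 2, 3, 1, 3, 4, 1,
                4, 7, 2, 4, 8, 1)),
    benzene = list(  # Kekule form; orbit tests only
      elements = rep("C", 6),
      bonds = B(1, 2, 2, 2, 3, 1, 3, 4, 2, 4, 5, 1, 5, 6, 2, 6, 1, 1)),
    ATP = list(
      # C1..C10 = adenine C2, C4, C5, C6, C8 then ribose C1'..C5';
      # N11 = N1, N12 = N3, N13 = N7, N14 = N9, N15 = exocyclic N6;
      # O16 = O4', O17 = O2', O18 = O3', O19 = O5'; then alpha/beta/gamma
      # phosphates (P, =O, -OH, bridging O).
      elements = c(rep("C", 10), rep("N", 5), rep("O", 4),
                   "P", "O", "O", "O", "P", "O", "O", "O", "P", "O", "O", "O"),
      bonds = B(11, 1, 1, 1, 12, 2, 12, 2, 1, 2, 3, 2, 3, 4, 1, 4, 11, 2,
                4, 15, 1, 3, 13, 1, 13, 5, 2, 5, 14, 1, 14, 2, 1,
                14, 6, 1, 6, 16, 1, 16, 9, 1, 6, 7, 1, 7, 17, 1, 7, 8, 1,
                8, 18, 1, 8, 9, 1, 9, 10, 1, 10, 19, 1,
                19, 20, 1, 20, 21, 2, 20, 22, 1, 20, 23, 1,
                23, 24, 1, 24, 25, 2, 24, 26, 1, 24, 27, 1,
                27, 28, 1, 28, 29, 2, 28, 30, 1, 28, 31, 1)),
    ADP = list(
      elements = c(rep("C", 10), rep("N", 5), rep("O", 4),
                   "P", "O", "O", "O", "P", "O", "O", "O"),
      bonds = B(11, 1, 1, 1, 12, 2, 12, 2, 1, 2, 3, 2, 3, 4, 1, 4, 11, 2,
                4, 15, 1, 3, 13, 1, 13, 5, 2, 5, 14, 1, 14, 2, 1,
                14, 6, 1, 6, 16, 1, 16, 9, 1, 6, 7, 1, 7, 17, 1, 7, 8, 1,
                8, 18, 1, 8, 9, 1, 9, 10, 1, 10, 19, 1,
                19, 20, 1, 20, 21, 2, 20, 22, 1, 20, 23, 1,
                23, 24, 1, 24, 25, 2, 24, 26, 1, 24, 27, 1))
  )
}

#' Fixture metabolite structures
#'
#' `fixture_names()` lists the embedded toy-network structures;
#' `fixture_molecule()` instantiates one as a [molecule()] (atoms in source
#' order: carbons first, chemical numbering).
#'
#' @param name Structure name, e.g. `"glucose"`.
#' @return A [molecule()] / character vector of names.
#' @export
fixture_molecule <- function(name) {
  s <- fixture_structures()[[name]]
  if (is.null(s)) lookup_error(sprintf("no fixture structure named '%s'", name))
  molecule(name, s$elements, s$bonds)
}

#' @rdname fixture_molecule
#' @export
fixture_names <- function() names(fixture_structures())

# Per-reaction fixture definitions. cmap columns: substrate instance,
# substrate (source) carbon, product instance, product carbon. Identity maps
# are generated with ident(). External identifiers are plausible database
# accessions used purely as fixture keys.
fixture_reactions <- function() {
  M <- function(...) matrix(as.integer(unlist(list(...))), ncol = 4, byrow = TRUE)
  ident <- function(n, s_inst = 1L, p_inst = 1L) cbind(s_inst, seq_len(n), p_inst, seq_len(n))
  list(
    list(id = "HK", ids = list(c("MetaCyc", "GLUCOKIN-RXN"), c("KEGG", "R00299")),
         substrates = "glucose", products = "G6P", reversible = FALSE,
         cmap = ident(6)),
    list(id = "HK_ATP", ids = list(c("BRENDA", "2.7.1.1")),
         substrates = c("glucose", "ATP"), products = c("G6P", "ADP"),
         reversible = FALSE,
         cmap = rbind(ident(6), ident(10, 2L, 2L))),
    list(id = "PGI", ids = list(c("MetaCyc", "PGLUCISOM-RXN"), c("KEGG", "R00771")),
         substrates = "G6P", products = "F6P", reversible = TRUE,
         cmap = ident(6)),
    list(id = "PFK", ids = list(c("MetaCyc", "6PFRUCTPHOS-RXN")),
         substrates = "F6P", products = "FBP", reversible = FALSE,
         cmap = ident(6)),
    list(id = "ALDO", ids = list(c("MetaCyc", "F16ALDOLASE-RXN")),
         substrates = "FBP", products = c("DHAP", "GAP"), reversible = TRUE,
         cmap = M(1, 1, 1, 1,  1, 2, 1, 2,  1, 3, 1, 3,
                  1, 4, 2, 1,  1, 5, 2, 2,  1, 6, 2, 3)),
    list(id = "TPI", ids = list(c("MetaCyc", "TRIOSEPISOMERIZATION-RXN")),
         substrates = "DHAP", products = "GAP", reversible = TRUE,
         cmap = M(1, 1, 1, 3,  1, 2, 1, 2,  1, 3, 1, 1)),
    list(id = "GAPDH", ids = list(c("MetaCyc", "GAPOXNPHOSPHN-RXN")),
         substrates = "GAP", products = "BPG", reversible = TRUE,
         cmap = ident(3)),
    list(id = "PGK", ids = list(c("MetaCyc", "PHOSGLYPHOS-RXN")),
         substrates = "BPG", products = "3PG", reversible = TRUE,
         cmap = ident(3)),
    list(id = "PGM", ids = list(c("MetaCyc", "3PGAREARR-RXN")),
         substrates = "3PG", products = "2PG", reversible = TRUE,
         cmap = ident(3)),
    list(id = "ENO", ids = list(c("MetaCyc", "2PGADEHYDRAT-RXN")),
         substrates = "2PG", products = c("PEP", "water"), reversible = TRUE,
         cmap = ident(3)),
    list(id = "PK", ids = list(c("MetaCyc", "PEPDEPHOS-RXN")),
         substrates = "PEP", products = "pyruvate", reversible = FALSE,
         cmap = ident(3)),
    list(id = "PDH", ids = list(c("MetaCyc", "PYRUVDEH-RXN")),
         substrates = "pyruvate", products = c("acetyl-CoA", "CO2"),
         reversible = FALSE,
         cmap = M(1, 1, 2, 1,  1, 2, 1, 1,  1, 3, 1, 2)),
    list(id = "GLS", ids = list(c("MetaCyc", "GLUTAMIN-RXN"), c("KEGG", "R00256")),
         substrates = c("glutamine", "water"),
         products = c("glutamate", "ammonia"), reversible = FALSE,
         cmap = ident(5)),
    list(id = "GLUD", ids = list(c("MetaCyc", "GLUTAMATE-DEHYDROGENASE-RXN")),
         substrates = c("glutamate", "water"),
         products = c("AKG", "ammonia"), reversible = TRUE,
         cmap = ident(5)),
    list(id = "GAD", ids = list(c("MetaCyc", "GLUTDECARBOX-RXN")),
         substrates = "glutamate", products = c("GABA", "CO2"),
         reversible = FALSE,
         cmap = M(1, 1, 2, 1,  1, 2, 1, 4,  1, 3, 1, 3,
                  1, 4, 1, 2,  1, 5, 1, 1)),
    list(id = "FH", ids = list(c("MetaCyc", "FUMHYDR-RXN"), c("KEGG", "R01082")),
         substrates = c("fumarate", "water"), products = "malate",
         reversible = TRUE,
         cmap = ident(4))
  )
}

# Instantiate a fixture reaction as a mapped_reaction (source atom order,
# carbon-only atom map — heteroatoms are left unmapped, which the validator
# accepts since the carbon set is complete).
fixture_reaction <- function(def) {
  subs <- lapply(def$substrates, fixture_molecule)
  prods <- lapply(def$products, fixture_molecule)
  am <- data.frame(s_inst = def$cmap[, 1], s_atom = def$cmap[, 2],
                   p_inst = def$cmap[, 3], p_atom = def$cmap[, 4])
  ids <- do.call(rbind, lapply(def$ids, function(x)
    data.frame(database = x[1], identifier = x[2])))
  mapped_reaction(def$id, subs, prods, am, reversible = def$reversible,
                  external_ids = ids)
}

fixture_compound_ids <- function() {
  data.frame(
    database = c("MetaCyc", "KEGG", "MetaCyc", "MetaCyc", "KEGG", "MetaCyc"),
    identifier = c("GLC", "C00031", "GLN", "GLT", "C00022", "FUM"),
    name = c("glucose", "glucose", "glutamine", "glutamate", "pyruvate",
             "fumarate"),
    stringsAsFactors = FALSE
  )
}

#' Build the fixture mapping store on disk
#'
#' Writes the toy central-carbon reaction set (glycolysis, pyruvate
#' dehydrogenase, glutaminase, glutamate dehydrogenase, glutamate
#' decarboxylase, fumarase, and a cofactor-bearing hexokinase) as RXN files
#' with atom-atom map numbers, plus `index.csv` (database, identifier, file,
#' reversible), `compounds.csv` (metabolite identifier table) and example
#' model CSVs (`glycolysis_model.csv`, `glutamine_model.csv`). Every written
#' reaction passes carbon balance and mapping validation by construction.
#'
#' @param dir Target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
build_fixture_store <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir))
    atomtrail_error(sprintf("cannot create fixture directory '%s'", dir),
                    "atomtrail_io_error")
  index <- NULL
  for (def in fixture_reactions()) {
    r <- fixture_reaction(def)
    stopifnot(reaction_is_clean(r))
    file <- paste0(def$id, ".rxn")
    writeLines(write_rxn(r), file.path(dir, file))
    for (x in def$ids) {
      index <- rbind(index, data.frame(
        database = x[1], identifier = x[2], file = file,
        reversible = def$reversible, stringsAsFactors = FALSE))
    }
  }
  utils::write.csv(index, file.path(dir, "index.csv"), row.names = FALSE)
  utils::write.csv(fixture_compound_ids(), file.path(dir, "compounds.csv"),
                   row.names = FALSE)
  writeLines(fixture_glycolysis_csv(), file.path(dir, "glycolysis_model.csv"))
  writeLines(fixture_glutamine_csv(), file.path(dir, "glutamine_model.csv"))
  invisible(dir)
}

fixture_glycolysis_csv <- function() {
  c("HK [MetaCyc:GLUCOKIN-RXN],glucose [MetaCyc:GLC],irreversible,G6P",
    "PGI [MetaCyc:PGLUCISOM-RXN],G6P,reversible,F6P",
    "PFK [MetaCyc:6PFRUCTPHOS-RXN],F6P,irreversible,FBP",
    "ALDO [MetaCyc:F16ALDOLASE-RXN],FBP,reversible,DHAP + GAP",
    "TPI [MetaCyc:TRIOSEPISOMERIZATION-RXN],DHAP,reversible,GAP",
    "GAPDH [MetaCyc:GAPOXNPHOSPHN-RXN],GAP,reversible,BPG",
    "PGK [MetaCyc:PHOSGLYPHOS-RXN],BPG,reversible,3PG",
    "PGM [MetaCyc:3PGAREARR-RXN],3PG,reversible,2PG",
    "ENO [MetaCyc:2PGADEHYDRAT-RXN],2PG,reversible,PEP",
    "PK [MetaCyc:PEPDEPHOS-RXN],PEP,irreversible,pyruvate",
    "PDH [MetaCyc:PYRUVDEH-RXN],pyruvate,irreversible,acetyl-CoA {2} + CO2")
}

fixture_glutamine_csv <- function() {
  c("GLS [MetaCyc:GLUTAMIN-RXN],glutamine [MetaCyc:GLN],irreversible,glutamate [MetaCyc:GLT]",
    "GLUD [MetaCyc:GLUTAMATE-DEHYDROGENASE-RXN],glutamate,reversible,AKG",
    "GAD [custom:GAD1],glutamate (abcde),irreversible,GABA (abcd) + CO2 (e)")
}

#' The documented aldolase error swap
#'
#' Returns the two product-side letters of the aldolase entry whose exchange
#' misroutes the fructose-1,6-bisphosphate C1 lineage: the letters sitting
#' on DHAP source carbons 1 and 3. Injecting this swap with
#' [inject_error()] reproduces the classic single-error scenario in which
#' glucose C1 ends up on pyruvate C1 (and leaves as CO2 at pyruvate
#' dehydrogenase) instead of pyruvate C3.
#'
#' @param abc An `abc_model` containing an `ALDO` entry built from the
#'   fixture store.
#' @param reaction Name of the aldolase entry.
#' @return Character vector of two letters.
#' @export
aldolase_error_letters <- function(abc, reaction = "ALDO") {
  e <- Filter(function(x) x$name == reaction & x$variant == 1L, abc$entries)
  if (length(e) == 0L)
    lookup_error(sprintf("no entry named '%s' in the model", reaction))
  e <- e[[1]]
  dhap <- Filter(function(m) m$name == "DHAP", e$products)
  if (length(dhap) == 0L)
    lookup_error(sprintf("entry '%s' has no DHAP product", reaction))
  mol <- canonicalize(canonical_order(fixture_molecule("DHAP")))
  pos <- carbon_canonical_position(mol, c(1L, 3L))
  letters <- strsplit(dhap[[1]]$letters, "")[[1]]
  letters[pos]
}

#' Generate a deterministic random molecule
#'
#' Builds a connected, valence-plausible heavy-atom graph (C/N/O atoms,
#' single/double bonds, a random spanning tree plus at most one ring
#' closure), deterministically per seed. Used by the property-test suites;
#' the global RNG state is left untouched.
#'
#' @param seed Integer seed.
#' @param n_heavy Number of heavy atoms (>= 1).
#' @return A [molecule()].
#' @export
random_molecule <- function(seed, n_heavy = 8L) {
  n_heavy <- as.integer(n_heavy)
  if (n_heavy < 1L) model_error("n_heavy must be >= 1")
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  valence <- c(C = 4L, N = 3L, O = 2L)
  elements <- c("C", sample(c("C", "C", "C", "N", "O"), n_heavy - 1L,
                            replace = TRUE))
  remaining <- valence[elements]
  bonds <- NULL
  for (i in seq_len(n_heavy)[-1]) {
    candidates <- which(remaining[seq_len(i - 1L)] >= 1L)
    if (length(candidates) == 0L) candidates <- i - 1L  # should not happen
    j <- candidates[sample.int(length(candidates), 1L)]
    ord <- if (remaining[i] >= 2L && remaining[j] >= 2L &&
               stats::runif(1) < 0.2) 2L else 1L
    bonds <- rbind(bonds, c(j, i, ord))
    remaining[i] <- remaining[i] - ord
    remaining[j] <- remaining[j] - ord
  }
  if (n_heavy >= 4L && stats::runif(1) < 0.3) {
    free <- which(remaining >= 1L)
    if (length(free) >= 2L) {
      pair <- sort(free[sample.int(length(free), 2L)])
      bonded <- any(bonds[, 1] == pair[1] & bonds[, 2] == pair[2])
      if (!bonded) bonds <- rbind(bonds, c(pair[1], pair[2], 1L))
    }
  }
  molecule(sprintf("random-%d", seed), elements, bonds)
}
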