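# ABC model assembly: lettering, omission, custom mappings, symmetry.

test_that("the glutaminase entry is the identity letter string", {
  model <- parse_model_csv(file.path(fx_store_dir(), "glutamine_model.csv"))
  abc <- build_abc_model(model, fx_store())
  gls <- find_entry(abc, "GLS")
  expect_identical(abc_equation(gls), "glutamine (abcde) -> glutamate (abcde)")
  expect_equal(gls$provenance, "store:MetaCyc:GLUTAMIN-RXN")
})

test_that("an identity transport reaction letters both sides identically", {
  dir <- withr::local_tempdir()
  glc <- fixture_molecule("glucose")
  n <- n_atoms(glc)
  tr <- mapped_reaction("GLCt", list(glc), list(glc),
                        data.frame(s_inst = 1L, s_atom = seq_len(n),
                                   p_inst = 1L, p_atom = seq_len(n)),
                        reversible = TRUE)
  writeLines(write_rxn(tr), file.path(dir, "GLCt.rxn"))
  writeLines(c("database,identifier,file,reversible",
               "KEGG,RT0001,GLCt.rxn,TRUE"), file.path(dir, "index.csv"))
  store <- load_store(dir)
  abc <- build_abc_model(parse_model_csv("GLCt [KEGG:RT0001],glucose,reversible,glucose"),
                         store)
  e <- abc$entries[[1]]
  expect_identical(e$substrates[[1]]$letters, e$products[[1]]$letters)
  expect_identical(abc_equation(e), "glucose (abcdef) <-> glucose (abcdef)")
})

test_that("decarboxylation drops one letter and preserves the rest in order", {
  abc <- build_abc_model(
    parse_model_csv("GAD [MetaCyc:GLUTDECARBOX-RXN],glutamate,irreversible,GABA + CO2"),
    fx_store())
  e <- abc$entries[[1]]
  glu <- e$substrates[[1]]$letters
  gaba <- Filter(function(m) m$name == "GABA", e$products)[[1]]$letters
  co2 <- Filter(function(m) m$name == "CO2", e$products)[[1]]$letters
  expect_equal(nchar(gaba), 4L)
  expect_equal(nchar(co2), 1L)
  # GABA string = glutamate string minus the released carboxyl letter
  expect_identical(gaba, gsub(co2, "", glu, fixed = TRUE))
})

test_that("cofactor omission keeps the sugar mapping intact", {
  store <- fx_store()
  # implicit omission: the model row simply does not list ATP/ADP
  abc <- build_abc_model(
    parse_model_csv("HK2 [BRENDA:2.7.1.1],glucose,irreversible,G6P"), store)
  e <- abc$entries[[1]]
  expect_identical(abc_equation(e), "glucose (abcdef) -> G6P (abcdef)")
  expect_setequal(entry_letters(e, "substrates"), entry_letters(e, "products"))

  # explicit omission on the mapped reaction itself
  r <- store_lookup(store, "BRENDA:2.7.1.1")
  r2 <- omit_metabolites(r, c("ATP", "ADP"))
  expect_equal(length(r2$substrates), 1L)
  expect_equal(length(r2$products), 1L)
  expect_equal(nrow(r2$atom_map), 6L)
  expect_true(atomtrail:::reaction_is_clean(r2))
})

test_that("omission edge cases behave", {
  r <- fx_store()$reactions[["HK_ATP.rxn"]]
  expect_identical(omit_metabolites(r, character(0)), r)
  expect_error(omit_metabolites(r, "NADH"), "absent metabolite")
  expect_error(omit_metabolites(r, c("glucose", "ATP")), "empty one reaction side")
})

test_that("a custom reaction with consistent user letters is accepted", {
  model <- parse_model_csv(file.path(fx_store_dir(), "glutamine_model.csv"))
  abc <- build_abc_model(model, fx_store())
  gad <- find_entry(abc, "GAD")
  expect_equal(gad$provenance, "user")
  expect_identical(abc_equation(gad), "glutamate (abcde) -> GABA (abcd) + CO2 (e)")
})

test_that("user strings are validated against canonical carbon counts", {
  expect_error(build_abc_model(
    parse_model_csv("GAD [custom:G1],glutamate (abcd),irreversible,GABA (abc) + CO2 (d)"),
    fx_store()), "'glutamate' has 5 carbons.*4 letters")
  # product letters must stem from substrates
  expect_error(build_abc_model(
    parse_model_csv("GAD [custom:G1],glutamate (abcde),irreversible,GABA (abcf) + CO2 (e)"),
    fx_store()), "do not occur on the substrate side")
  # novel metabolites with self-consistent letters are accepted
  abc <- build_abc_model(
    parse_model_csv("X1 [custom:X1],widgetol (ab),irreversible,gadgetol (ab)"),
    fx_store())
  expect_equal(abc$entries[[1]]$provenance, "user")
})

test_that("every metabolite instance of a custom reaction needs a string", {
  expect_error(build_abc_model(
    parse_model_csv("X1 [custom:X1],widgetol (ab) + helperol,irreversible,gadgetol (ab)"),
    fx_store()), "lacks a user ABC string")
})

test_that("the acetyl-CoA moiety restriction conserves 3 = 2 + 1 letters", {
  abc <- fx_abc()
  pdh <- find_entry(abc, "PDH")
  expect_equal(nchar(Filter(function(m) m$name == "acetyl-CoA", pdh$products)[[1]]$letters), 2L)
  expect_setequal(entry_letters(pdh, "substrates"), entry_letters(pdh, "products"))
  # the {n} annotation is validated against the stored structure
  expect_error(build_abc_model(
    parse_model_csv("PDH [MetaCyc:PYRUVDEH-RXN],pyruvate,irreversible,acetyl-CoA {3} + CO2"),
    fx_store()), "declares 3 carbons but the stored structure has 2")
})

test_that("letter conservation holds on every balanced entry", {
  for (abc in list(fx_abc(),
                   build_abc_model(parse_model_csv(
                     file.path(fx_store_dir(), "glutamine_model.csv")), fx_store()))) {
    for (e in abc$entries) {
      sl <- entry_letters(e, "substrates")
      pl <- entry_letters(e, "products")
      expect_setequal(sl, pl)
      expect_equal(anyDuplicated(sl), 0L, label = paste(e$name, "substrate letters"))
      expect_equal(anyDuplicated(pl), 0L, label = paste(e$name, "product letters"))
    }
  }
})

test_that("building the same model twice is byte-identical", {
  model <- fx_glycolysis_model()
  a <- write_abc(build_abc_model(model, fx_store()))
  b <- write_abc(build_abc_model(model, fx_store()))
  expect_identical(a, b)
})

test_that("unresolved reactions and absent metabolites raise named errors", {
  expect_error(build_abc_model(
    parse_model_csv("XX [KEGG:R99999],glucose,irreversible,G6P"), fx_store()),
    "R99999")
  expect_error(build_abc_model(
    parse_model_csv("HK [MetaCyc:GLUCOKIN-RXN],fumarate,irreversible,G6P"),
    fx_store()), "fumarate.*not found in the stored reaction")
  expect_error(build_abc_model(
    parse_model_csv("HK,glucose,irreversible,G6P"), fx_store()),
    "no identifier and no user ABC mapping")
})

test_that("a reaction written in the reverse orientation still matches", {
  abc <- build_abc_model(
    parse_model_csv("ALDOr [MetaCyc:F16ALDOLASE-RXN],DHAP + GAP,reversible,FBP"),
    fx_store())
  e <- abc$entries[[1]]
  expect_equal(vapply(e$substrates, `[[`, "", "name"), c("DHAP", "GAP"))
  expect_setequal(entry_letters(e, "substrates"), entry_letters(e, "products"))
})

test_that("symmetry expansion adds the orbit-relabeled fumarate variant", {
  model <- parse_model_csv("FH [MetaCyc:FUMHYDR-RXN],fumarate,reversible,malate")
  ign <- build_abc_model(model, fx_store(), symmetry = "ignore")
  exp_ <- build_abc_model(model, fx_store(), symmetry = "expand")
  expect_length(ign$entries, 1L)
  expect_length(exp_$entries, 2L)
  base <- exp_$entries[[1]]
  var <- exp_$entries[[2]]
  expect_equal(var$variant, 2L)
  # the variant permutes fumarate's letters by the nonidentity automorphism
  perms <- atomtrail:::carbon_symmetry_perms(store_molecule(fx_store(), "fumarate"))
  nontriv <- Filter(function(p) !identical(p, seq_along(p)), perms)[[1]]
  expect_identical(
    var$substrates[[1]]$letters,
    paste(strsplit(base$substrates[[1]]$letters, "")[[1]][nontriv], collapse = ""))
  # the diff between expand and ignore touches only the symmetric entry
  d <- diff_models(ign, exp_)
  expect_true(all(d$reaction == "FH"))

  # canonical mode gives a single, lexicographically smallest entry
  canon <- build_abc_model(model, fx_store(), symmetry = "canonical")
  expect_length(canon$entries, 1L)
  eqs <- vapply(exp_$entries, abc_equation, "")
  expect_identical(abc_equation(canon$entries[[1]]), min(eqs))
})

test_that("asymmetric metabolites are unchanged by any symmetry mode", {
  model <- parse_model_csv(file.path(fx_store_dir(), "glutamine_model.csv"))
  for (mode in c("ignore", "expand", "canonical")) {
    abc <- build_abc_model(model, fx_store(), symmetry = mode)
    expect_length(abc$entries, 3L)
    expect_identical(abc_equation(find_entry(abc, "GLS")),
                     "glutamine (abcde) -> glutamate (abcde)")
  }
})

test_that("a symmetric transport deduplicates relation-equivalent variants", {
  dir <- withr::local_tempdir()
  fum <- fixture_molecule("fumarate")
  n <- n_atoms(fum)
  tr <- mapped_reaction("FUMt", list(fum), list(fum),
                        data.frame(s_inst = 1L, s_atom = seq_len(n),
                                   p_inst = 1L, p_atom = seq_len(n)),
                        reversible = TRUE)
  writeLines(write_rxn(tr), file.path(dir, "FUMt.rxn"))
  writeLines(c("database,identifier,file,reversible",
               "KEGG,RT0002,FUMt.rxn,TRUE"), file.path(dir, "index.csv"))
  store <- load_store(dir)
  abc <- build_abc_model(
    parse_model_csv("FUMt [KEGG:RT0002],fumarate,reversible,fumarate"),
    store, symmetry = "expand")
  # 2x2 relabelings collapse to 2 distinct mapping relations
  expect_length(abc$entries, 2L)
})
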