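# Label tracing, error injection, and model diffing.

glc_start <- function(carbon = 1L) {
  glc <- store_molecule(fx_store(), "glucose")
  label_state("glucose", carbon_canonical_position(glc, carbon))
}

final_source_carbon <- function(tr, metabolite) {
  stopifnot(nrow(tr$final) == 1L, tr$final$metabolite == metabolite)
  carbon_source_number(store_molecule(fx_store(), metabolite), tr$final$position)
}

test_that("glucose C1 traces to pyruvate C3 through correct glycolysis", {
  tr <- trace_labels(fx_abc(), glc_start(1L), glycolysis_path)
  expect_equal(final_source_carbon(tr, "pyruvate"), 3L)
})

test_that("the label continues to acetyl-CoA C2 through pyruvate dehydrogenase", {
  tr <- trace_labels(fx_abc(), glc_start(1L), c(glycolysis_path, "PDH"))
  expect_equal(final_source_carbon(tr, "acetyl-CoA"), 2L)
  expect_equal(nrow(tr$lost), 0L)
})

test_that("a label through an identity transport is unchanged", {
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
  for (pos in 1:6) {
    res <- trace_labels(abc, label_state("glucose", pos), "GLCt")
    expect_equal(res$final$position, pos)
    expect_equal(res$final$metabolite, "glucose")
  }
})

test_that("the injected aldolase error reroutes glucose C1 to pyruvate C1 and CO2", {
  abc <- fx_abc()
  sw <- aldolase_error_letters(abc)
  bad <- inject_error(abc, "ALDO", sw)

  d <- diff_models(abc, bad)
  expect_gt(nrow(d), 0L)
  expect_true(all(d$reaction == "ALDO"))

  tr <- trace_labels(bad, glc_start(1L), glycolysis_path)
  expect_equal(final_source_carbon(tr, "pyruvate"), 1L)

  tr2 <- trace_labels(bad, glc_start(1L), c(glycolysis_path, "PDH"))
  expect_equal(tr2$final$metabolite, "CO2")
})

test_that("injection no-ops and failures behave", {
  abc <- fx_abc()
  same <- inject_error(abc, "ALDO", c("a", "a"))
  expect_equal(nrow(diff_models(abc, same)), 0L)
  expect_error(inject_error(abc, "ALDO", c("a", "z")), "absent from the product side")
  expect_error(inject_error(abc, "NOPE", c("a", "b")), "no entry named")
  # the corrupted entry is still well-formed and letter-conserving
  bad <- inject_error(abc, "ALDO", aldolase_error_letters(abc))
  e <- find_entry(bad, "ALDO")
  expect_setequal(entry_letters(e, "substrates"), entry_letters(e, "products"))
})

test_that("tracing through a reversible reaction and back is the identity", {
  abc <- fx_abc()
  for (pos in 1:6) {
    start <- label_state("G6P", pos)
    there <- trace_labels(abc, start, "PGI")
    expect_equal(there$final$metabolite, "F6P")
    back <- trace_labels(abc, label_state("F6P", there$final$position), "PGI")
    expect_equal(back$final$metabolite, "G6P")
    expect_equal(back$final$position, pos)
  }
})

test_that("the six glucose carbons partition into six distinct fates", {
  glc <- store_molecule(fx_store(), "glucose")
  for (model in list(correct = fx_abc(),
                     error = inject_error(fx_abc(), "ALDO",
                                          aldolase_error_letters(fx_abc())))) {
    fates <- character(0)
    for (src in 1:6) {
      start <- label_state("glucose", carbon_canonical_position(glc, src))
      # the C1-C3 lineage passes through TPI; C4-C6 goes directly to GAP
      tr <- tryCatch(trace_labels(model, start, glycolysis_path),
                     error = function(e) trace_labels(
                       model, start, setdiff(glycolysis_path, "TPI")))
      via_tpi <- grepl("TPI", tr$final$route)
      fates <- c(fates, sprintf("%s:%d:%s", tr$final$metabolite,
                                tr$final$position, via_tpi))
    }
    expect_equal(anyDuplicated(fates), 0L)
    # within each lineage the three positions are a bijection onto pyruvate
    expect_setequal(as.integer(sub(".*:(\\d+):.*", "\\1", fates)), rep(1:3, 2))
  }
})

test_that("a path reaction that touches no label is a gap error", {
  expect_error(trace_labels(fx_abc(), glc_start(1L), c("PGI")),
               "does not connect")
  expect_error(trace_labels(fx_abc(), glc_start(1L), c("NOPE")),
               "not part of the model")
})

test_that("letters leaving the retained metabolites are reported as lost fates", {
  # a model whose PDH row omits CO2: the carboxyl letter has nowhere to go
  model <- parse_model_csv(c(
    "PK [MetaCyc:PEPDEPHOS-RXN],PEP,irreversible,pyruvate",
    "PDH [MetaCyc:PYRUVDEH-RXN],pyruvate,irreversible,acetyl-CoA {2}"))
  abc <- build_abc_model(model, fx_store())
  pyr <- store_molecule(fx_store(), "pyruvate")
  start <- label_state("pyruvate", carbon_canonical_position(pyr, 1L))
  tr <- trace_labels(abc, start, "PDH")
  expect_equal(nrow(tr$final), 0L)
  expect_equal(nrow(tr$lost), 1L)
  expect_equal(tr$lost$reaction, "PDH")
})

test_that("symmetry-expanded entries union their fates", {
  model <- parse_model_csv("FH [MetaCyc:FUMHYDR-RXN],fumarate,reversible,malate")
  exp_ <- build_abc_model(model, fx_store(), symmetry = "expand")
  fum <- store_molecule(fx_store(), "fumarate")
  # a label on fumarate C1 can end on either end of malate
  start <- label_state("fumarate", carbon_canonical_position(fum, 1L))
  tr <- trace_labels(exp_, start, "FH")
  expect_equal(nrow(tr$final), 2L)
  mal <- store_molecule(fx_store(), "malate")
  expect_setequal(carbon_source_number(mal, tr$final$position), c(1L, 4L))
})

test_that("diff_models semantics", {
  abc <- fx_abc()
  expect_equal(nrow(diff_models(abc, abc)), 0L)
  other <- build_abc_model(parse_model_csv(
    file.path(fx_store_dir(), "glutamine_model.csv")), fx_store())
  expect_error(diff_models(abc, other), "same reaction set")
})
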