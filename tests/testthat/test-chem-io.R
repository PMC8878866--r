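# MOL/RXN V2000 reading and writing, including atom-atom map handling.

test_that("a minimal single-atom MOL file parses", {
  txt <- paste(c("methane", "  test", "",
                 "  1  0  0  0  0  0  0  0  0  0999 V2000",
                 "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
                 "M  END"), collapse = "\n")
  m <- read_mol(txt)
  expect_s3_class(m, "molecule")
  expect_equal(n_atoms(m), 1L)
  expect_equal(nrow(m$bonds), 0L)
  expect_null(m$canonical_order)
})

test_that("fixture structures read back with the expected composition", {
  gln <- read_mol(write_mol(fixture_molecule("glutamine")))
  expect_equal(carbon_count(gln), 5L)

  fum <- read_mol(write_mol(fixture_molecule("fumarate")))
  expect_equal(carbon_count(fum), 4L)
  expect_equal(sum(fum$elements == "O"), 4L)
  # hand count on the drawn structure: 3 C-C bonds + 4 C-O bonds
  expect_equal(nrow(fum$bonds), 7L)
})

test_that("MOL parse errors name the offending line", {
  bad_counts <- paste(c("x", "", "", "  a  0  0999 V2000", "M  END"),
                      collapse = "\n")
  expect_error(read_mol(bad_counts), "counts line.*line 4")

  bad_element <- paste(c("x", "", "", "  1  0  0  0  0  0  0  0  0  0999 V2000",
                         "    0.0000    0.0000    0.0000 Xx  0  0",
                         "M  END"), collapse = "\n")
  expect_error(read_mol(bad_element), "unknown element symbol 'Xx'.*line 5")

  truncated <- paste(c("x", "", "", "  2  1  0  0  0  0  0  0  0  0999 V2000",
                       "    0.0000    0.0000    0.0000 C   0  0"),
                     collapse = "\n")
  expect_error(read_mol(truncated), "truncated")
})

test_that("V3000 input is rejected with a clear error", {
  v3 <- paste(c("x", "", "", "  0  0  0  0  0  0  0  0  0  0999 V3000"),
              collapse = "\n")
  expect_error(read_mol(v3), "V3000")
  rxn3 <- paste(c("$RXN", "r", "", "", "  1  1 V3000"), collapse = "\n")
  expect_error(read_rxn(rxn3), "V3000")
})

test_that("charges survive a round trip via M CHG lines", {
  m <- molecule("acetate-ish", c("C", "C", "O", "O"),
                rbind(c(1, 2, 1), c(2, 3, 2), c(2, 4, 1)),
                charges = c(0L, 0L, 0L, -1L))
  m2 <- read_mol(write_mol(m))
  expect_equal(m2$charges, c(0L, 0L, 0L, -1L))
})

test_that("an identity reaction round-trips to the identity atom pairing", {
  glc <- fixture_molecule("glucose")
  n <- n_atoms(glc)
  r <- mapped_reaction("transport", list(glc), list(glc),
                       data.frame(s_inst = 1L, s_atom = seq_len(n),
                                  p_inst = 1L, p_atom = seq_len(n)))
  r2 <- read_rxn(write_rxn(r))
  expect_equal(nrow(r2$atom_map), n)
  expect_equal(r2$atom_map$s_atom, r2$atom_map$p_atom)
  expect_equal(r2$atom_map$s_inst, rep(1L, n))
})

test_that("the glutaminase fixture RXN maps all five carbons, element-matched", {
  r <- read_rxn(file.path(fx_store_dir(), "GLS.rxn"))
  am <- r$atom_map
  se <- mapply(function(i, a) r$substrates[[i]]$elements[a], am$s_inst, am$s_atom)
  pe <- mapply(function(i, a) r$products[[i]]$elements[a], am$p_inst, am$p_atom)
  expect_equal(sum(se == "C"), 5L)
  expect_true(all(se == pe))
  expect_equal(validate_mapping(r)$carbons_unmapped, 0L)
})

test_that("a duplicated map number raises a mapping-integrity error", {
  molblock <- function(maps) {
    c("ethane", "", "", "  2  1  0  0  0  0  0  0  0  0999 V2000",
      sprintf("    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0%3d  0  0", maps[1]),
      sprintf("    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0%3d  0  0", maps[2]),
      "  1  2  1  0  0  0  0", "M  END")
  }
  rxn <- paste(c("$RXN", "dup", "", "", "  1  1",
                 "$MOL", molblock(c(3, 3)), "$MOL", molblock(c(3, 0))),
               collapse = "\n")
  expect_error(read_rxn(rxn), "map number 3 appears on 2 substrate")
})

test_that("RXN header and MOL block counts must agree", {
  r <- fx_store()$reactions[["GLS.rxn"]]
  txt <- strsplit(write_rxn(r), "\n")[[1]]
  txt[5] <- "  3  2"
  expect_error(read_rxn(paste(txt, collapse = "\n")), "promises 5 molecules")
})

test_that("writing then reading preserves every fixture reaction", {
  for (file in names(fx_store()$reactions)) {
    r1 <- read_rxn(file.path(fx_store_dir(), file))
    r2 <- read_rxn(write_rxn(r1))
    expect_equal(lapply(r2$substrates, `[[`, "elements"),
                 lapply(r1$substrates, `[[`, "elements"))
    expect_equal(lapply(r2$products, `[[`, "elements"),
                 lapply(r1$products, `[[`, "elements"))
    bond_multiset <- function(r) lapply(c(r$substrates, r$products), function(m)
      sort(apply(m$bonds, 1, function(x)
        paste(sort(x[1:2]), x[3], collapse = "-"))))
    expect_equal(bond_multiset(r2), bond_multiset(r1))
    rel <- function(r) sort(sprintf("%d.%d>%d.%d", r$atom_map$s_inst,
                                    r$atom_map$s_atom, r$atom_map$p_inst,
                                    r$atom_map$p_atom))
    expect_equal(rel(r2), rel(r1))
  }
})

test_that("canonically ordered output stays in canonical order after rereading", {
  glu <- canonical_order(fixture_molecule("glutamate"))
  reread <- read_mol(write_mol(glu))
  expect_equal(reread$elements, glu$elements[glu$canonical_order])
})

test_that("the V2000 atom-count capacity is enforced", {
  n <- 1000L
  big <- molecule("too-big", rep("C", n),
                  cbind(seq_len(n - 1L), 2:n, 1L))
  expect_error(write_mol(big), "999")
})
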