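# atomtrail

Carbon atom-mapping models for metabolic networks.

13C metabolic flux analysis (13C-MFA) needs an *atom-mapping model*: a
metabolic network in which every reaction records which substrate carbon
becomes which product carbon, conventionally written in the ABC format —
one case-sensitive letter per carbon, e.g.

```
glutamine (abcde) -> glutamate (abcde)
```

The notation is compact but dangerously ambiguous: nothing in `abcde` says
which structural carbon of glutamine the letter `a` denotes, and a single
wrong letter in one reaction silently corrupts every downstream label
prediction. atomtrail makes these models buildable and checkable:

* **chem I/O** — read/write MDL MOL and RXN (V2000) files, preserving
  atom-atom map numbers (the output format of reaction mappers such as the
  Reaction Decoder Tool).
* **canonical numbering** — a deterministic, isomorphism-invariant atom
  ordering per molecule (Morgan-style refinement with individualization
  branching), so the k-th carbon of a metabolite means the same structural
  atom in every reaction, every file, every run; `symmetry_orbits()`
  reports which atoms are genuinely interchangeable.
* **validation** — carbon balance and atom-mapping integrity reports (the
  standard database quality filters).
* **mapping store** — a local directory of per-reaction RXN mappings
  indexed by BRENDA / KEGG / MetaCyc identifiers, canonicalized and
  validated at load.
* **ABC assembly** — `build_abc_model()` turns a 4-column CSV network
  description plus the store into a network-wide ABC model: substrate
  carbons lettered `a, b, c, ...` in canonical order, product letters
  induced by the atom maps, cofactors omitted simply by not listing them,
  user-supplied mappings for custom reactions, optional symmetry
  expansion.
* **tracing** — `trace_labels()` follows a labeled carbon position through
  a reaction path; `inject_error()` / `diff_models()` demonstrate (and
  detect) how one well-formed but wrong mapping reroutes a label.

A bundled, fully offline fixture set (condensed glycolysis, pyruvate
dehydrogenase, glutamine/glutamate/GABA reactions, fumarate for symmetry)
drives all tests and the examples below.

## Worked example

Build the fixture store, assemble a small glutamine model (two database
reactions plus one user-mapped custom reaction), and print it:

```r
library(atomtrail)
dir <- file.path(tempdir(), "store")
build_fixture_store(dir)
store <- load_store(dir)
abc <- build_abc_model(parse_model_csv(file.path(dir, "glutamine_model.csv")), store)
cat(write_abc(abc))
#> GLS [MetaCyc:GLUTAMIN-RXN]: glutamine (abcde) -> glutamate (abcde)  # store:MetaCyc:GLUTAMIN-RXN
#> GLUD [MetaCyc:GLUTAMATE-DEHYDROGENASE-RXN]: glutamate (abcde) <-> AKG (abcde)  # store:MetaCyc:GLUTAMATE-DEHYDROGENASE-RXN
#> GAD [custom:GAD1]: glutamate (abcde) -> GABA (abcd) + CO2 (e)  # user
```

The glutaminase line says the carbon backbone is unchanged; the
decarboxylase line says GABA keeps glutamate's letters `abcd` while letter
`e` — the alpha-carboxyl carbon under the canonical numbering — leaves as
CO2.

Now trace a [1-13C1]glucose label through glycolysis and pyruvate
dehydrogenase, first in the correct model, then after injecting a single
letter swap into the aldolase reaction:

```r
gly <- build_abc_model(parse_model_csv(file.path(dir, "glycolysis_model.csv")), store)
glc <- store_molecule(store, "glucose")
start <- label_state("glucose", carbon_canonical_position(glc, 1))  # glucose C1
path <- c("HK","PGI","PFK","ALDO","TPI","GAPDH","PGK","PGM","ENO","PK","PDH")

trace_labels(gly, start, path)
#> <label_trace>
#>  final positions:
#>   glucose:2 -> acetyl-CoA C1 (instance 1; via HK,PGI,PFK,ALDO,TPI,GAPDH,PGK,PGM,ENO,PK,PDH)

bad <- inject_error(gly, "ALDO", aldolase_error_letters(gly))
trace_labels(bad, start, path)
#> <label_trace>
#>  final positions:
#>   glucose:2 -> CO2 C1 (instance 1; via HK,PGI,PFK,ALDO,TPI,GAPDH,PGK,PGM,ENO,PK,PDH)
```

Positions in a `label_trace` are canonical; converting back to structure
numbering (`carbon_source_number(store_molecule(store, "acetyl-CoA"),
...)`) gives acetyl-CoA **C2** (the methyl-adjacent carbon) for the
correct model — i.e. [2-13C1]acetyl-CoA — while stopping the correct trace
at pyruvate gives **C3** and the error model gives **C1**, whose carbon
leaves as CO2 at pyruvate dehydrogenase. One local mapping error, a
qualitatively different global prediction: that is why atom-mapping models
need validation and tracing.

`diff_models(gly, bad)` confirms the two models differ in exactly the
aldolase entry.

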