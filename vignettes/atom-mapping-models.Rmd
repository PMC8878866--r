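---
title: "Building and checking carbon atom-mapping models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and checking carbon atom-mapping models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

13C metabolic flux analysis infers intracellular fluxes by combining
measured isotopic enrichment patterns with a *carbon atom-mapping model*: a
metabolic network in which every reaction carries a one-to-one
correspondence between substrate and product carbons. Writing such a model
by hand requires mechanistic knowledge of every reaction and is notoriously
error-prone, because the conventional ABC notation — one case-sensitive
letter per carbon, as in `glutamine (abcde) -> glutamate (abcde)` — does not
say *which* structural carbon each letter denotes. Two syntactically
different ABC models can encode the same chemistry, and a single wrong
letter in one reaction silently corrupts every downstream prediction.

atomtrail addresses both halves of the problem:

* it anchors every letter to a **canonical, isomorphism-invariant atom
  numbering** computed from the molecular graph, so that a metabolite's
  k-th carbon means the same structural atom in every reaction and every
  file; and
* it **assembles network-wide ABC models automatically** from a simple
  4-column CSV description of the network plus a store of per-reaction
  atom mappings (MDL RXN files with atom-atom map numbers, the output
  format of mapping tools such as the Reaction Decoder Tool), and provides
  a positional tracer to verify the result — or to demonstrate how a
  single injected mapping error propagates.

## The canonical ordering

`canonical_order()` ranks the heavy atoms of a connected molecular graph by
iterated neighborhood refinement. Atoms are seeded with the invariant
(element, formal charge, heavy-atom degree, multiset of (neighbor element,
bond order)), with carbon sorting before all other elements; the partition
is then refined Morgan-style by replacing each atom's key with its rank
plus the sorted multiset of its neighbors' ranks until a fixpoint. If ties
remain, the order is completed by individualization with full branching:
each member of the first tied cell is individualized in turn, refinement
resumes, and the completed order whose relabeled-graph certificate is
lexicographically smallest wins. Branching makes the result a pure function
of the labeled graph — permuting the input atoms cannot change the
canonical sequence — while atoms tied at the end of a full refinement are
genuinely symmetric, so choosing among them is safe. Symmetry is reported
explicitly instead: `symmetry_orbits()` partitions atoms into equivalence
classes under automorphisms that preserve element, charge, and bond order
(computed from igraph/BLISS generators on a bond-subdivided auxiliary
graph, verified in the test suite against brute-force enumeration).

Design choices worth knowing:

* **Stereochemistry is ignored** (wedge/hash bonds are dropped). Carbon
  skeleton tracing does not need it, and mapping tools emit flat graphs.
* **Explicit hydrogens** are read but never required; all bookkeeping is
  on heavy atoms, and mapping validation requires completeness only on
  carbons (unmapped oxygens are accepted — the model is carbon-only).
* **Disconnected inputs are an error**, not a warning: a multi-fragment
  MOL file almost always indicates a salt or a drawing mistake, and the
  caller should split it deliberately.
* The ordering is *a* canonical numbering with the same role as InChI
  numbers — deterministic and reproducible across files — but it is this
  package's own algorithm, so positions are not interchangeable with
  numbers from other software. Conversions between a file's original atom
  numbering and canonical positions are provided
  (`carbon_canonical_position()`, `carbon_source_number()`).

## Validation

Two reporting (never raising) filters mirror standard database practice:
`carbon_balance()` checks that total substrate and product carbon counts
agree (other elements are reported informationally only — condensed,
cofactor-free reactions are legitimately unbalanced in O and P), and
`validate_mapping()` flags element-mismatched pairs, duplicated endpoints,
and — for balanced reactions — carbons missing from the atom map. A
mapping store refuses to load entries failing either check (unless
`lenient = TRUE`). Note the deliberate limitation: a *chemically wrong but
well-formed* mapping passes both filters. That is not a defect of the
validator but the reason curation and tracing exist; `inject_error()`
produces exactly such mappings on purpose.

## Model format and ABC assembly

The network is described in a 4-column CSV: reaction name, substrates,
reversibility (`reversible|irreversible|R|IR|1|0`), products. Database
identifiers appear in square brackets (`[MetaCyc:GLUTAMIN-RXN]`, `[KEGG:
R00256]`, `[BRENDA:...]`, or bare `[ID]` searched across namespaces);
metabolites are separated by `+`, a leading integer is a stoichiometric
coefficient, `(letters)` supplies a user ABC mapping for custom reactions,
and `{n}` asserts a carbon count. The dialect is self-defined here (comma
as CSV delimiter, standard quoting, optional header starting with
`reaction`).

`build_abc_model()` letters each reaction's substrate carbons
`a, b, c, ...` in substrate order and canonical carbon order, then induces
the product letters through the stored atom map re-expressed over
canonical indices. Stored metabolites the model row does not mention are
omitted automatically — that is how cofactors like ATP/ADP are dropped —
and product carbons whose partner was omitted receive the next unused
letters. Custom reactions supply their own strings, which are accepted
only if letters are unique per side, every product letter stems from a
substrate, and string lengths match the canonical carbon counts of any
metabolite the store knows; that length check is what prevents the classic
mistake of writing a manual mapping against an unknown sorting.
Moiety-restricted metabolites are handled by storing the moiety structure
(the shipped acetyl-CoA fixture is its 2-carbon acetyl group, C1 =
carbonyl) and asserting the count in the model (`acetyl-CoA {2}`).

Symmetric metabolites (fumarate's two-fold axis, benzene's ring) make
several letter assignments chemically equivalent. `symmetry = "expand"`
emits one additional entry per distinct relabeling — distinct *as a
mapping relation*, so a simultaneous relabeling of both sides of a
symmetric transport that reproduces the original correspondence is not
duplicated — while `"canonical"` keeps the lexicographically smallest
variant and `"ignore"` (the default) leaves entries as assigned.

## Tracing and error injection

`trace_labels()` is positional and deterministic: a labeled carbon moves,
at each step of a user-given reaction path, to the product position
carrying its letter. Reversible entries are traversed backwards when the
label sits on their product side; letters whose position was omitted from
an entry are reported as lost fates rather than dropped; symmetry-expanded
variants contribute the union of their fates. There are no fractional
enrichments and no flux weighting — isotopomer simulation belongs to
dedicated flux-analysis software; this tracer answers the purely
structural question "where can this atom go", which is what model
verification needs. Each label carries its origin and the route that moved
it, so the two triose lineages of a hexose can be distinguished even
though flux software would pool them.

`inject_error()` swaps two product-side letters of one reaction, producing
a well-formed but wrong model; `diff_models()` verifies the change is
confined to that reaction. On the shipped toy glycolysis this reproduces
the textbook demonstration: a correct model routes glucose C1 to pyruvate
C3 and on to acetyl-CoA C2, while a single aldolase swap reroutes it to
pyruvate C1, from where pyruvate dehydrogenase releases it as CO2 — one
local error, a qualitatively different global prediction.

## The fixture set: what it emulates and what it does not

All tests run against a generated, fully offline fixture store
(`build_fixture_store()`): condensed single-compartment glycolysis
(glucose through pyruvate, cofactor-free), pyruvate dehydrogenase with the
acetyl moiety convention, glutaminase / glutamate dehydrogenase /
glutamate decarboxylase, fumarase (for symmetry), and one cofactor-bearing
hexokinase (glucose + ATP) to exercise omission. Structures are embedded
as hand-verified connection tables, carbons first in conventional chemical
numbering; reaction maps encode the textbook fates (aldolase cleaves
fructose-1,6-bisphosphate between C3 and C4; triose-phosphate isomerase
inverts the triose). External identifiers are real-looking database
accessions used purely as lookup keys.

This toy set exercises every code path at desk scale; it does *not*
emulate database-scale heterogeneity — protonation-state merging across
sources, inconsistent MOL quality, mapper non-convergence, or genome-scale
model sizes. Passing tests show the machinery is correct on curated
input, not that arbitrary harvested mappings are chemically right.
`random_molecule()` complements the curated set with seed-deterministic,
valence-plausible connected graphs for the invariance property suites.

## Numerical and scale choices

Everything in the pipeline is discrete and deterministic: no tolerances,
no RNG in any user-facing computation (the random-molecule generator
restores the global RNG state). Canonicalization cost is dominated by the
branching search, which is negligible for metabolite-sized molecules
(about 1.5 ms for an 8-heavy-atom structure). The invariance property
suite therefore runs the *exhaustive* permutation oracle — all n! atom
orders — for fixtures up to 8 heavy atoms (about 46,000 canonicalizations,
under two minutes), and deterministic permutation samples for larger
structures such as ATP (31 heavy atoms). Orbit soundness is checked
against brute-force enumeration of label-preserving bijections up to 8
heavy atoms. Letter capacity is 52 carbons per reaction side (`a..z` then
`A..Z`); V2000 caps structures at 999 atoms.

## Known limitations

* V2000 only; V3000 files are rejected with a clear error.
* Carbon-only ABC emission (all heavy atoms are canonicalized, but no
  per-element models for N/O/P are produced).
* No SBML import, no stoichiometric-matrix or flux-balance structures, no
  isotopomer/EMU simulation, and no export adapters for specific
  flux-analysis file formats.
* Stoichiometric coefficients in RXN files are supported as repeated MOL
  blocks only, matching mapper output; coefficient fields are not.
* Canonical positions are internally consistent but not exchangeable with
  numberings from other software; use the conversion helpers at
  boundaries.
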