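---
title: "Cross-link assisted spatial proteomics: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-link assisted spatial proteomics: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clasp)
```

## The spatial model

`clasp` treats an organelle as an ordered alternation of aqueous
compartments and membranes. The built-in mitochondrial model is

```{r}
defaultMitoModel()
```

Three physical constants drive all inference, each with a clear
experimental meaning:

* **Labeling radius, 40 Å.** A lysine-reactive cross-linker (DSSO: spacer
  10.3 Å; lysine side chain 7.6 Å; ~10 Å of in-solution flexibility) can
  bridge Cα atoms up to roughly 4 nm apart. The three components do not
  sum to an exact bound, so the 40 Å cap is treated as an independent
  constant (`radiusModel()`), configurable per cross-linker; DSSO and
  DSBSO share the default.
* **Membrane thickness, 70 Å.** Biological membranes are thicker than the
  labeling radius, hence no cross-link can span a membrane. This is the
  single assumption that converts cross-links into spatial evidence:
  `mayCrosslink()` admits a residue pair only when both residues occupy
  the *same aqueous compartment*.
* **Inter-membrane gap, 200 Å** (outer to inner mitochondrial membrane,
  from electron tomography). Membrane-anchored proteins can only bridge
  this gap if their protrusions into the shared space are long enough:
  feasible iff `gap − 3.5·n₁ − 3.5·n₂ ≤ 40` (Å, with 3.5 Å per residue of
  extended chain). `protrusionFeasible()` implements the rule;
  `gapDistance()` supplies the configured gap.

The model is configuration, not code: `readCompartmentModel()` /
`writeCompartmentModel()` handle a YAML layout, and `svModel()` ships a
single-membrane preset (lumen | membrane | cytosol) for vesicle-like
systems.

## Localization markers and their validation

Markers (LMs) are proteins — or soluble regions of membrane proteins —
with established compartment assignments. They can be supplied manually
(`makeMarkers()`) or auto-selected from annotations
(`autoSelectCandidates()`): a protein qualifies when its location text
normalizes to exactly one aqueous compartment (entries with multiple
location terms or `Note=` qualifiers are treated as equivocal and
excluded), or when its TM features plus topological-domain side notes
yield a fully oriented topology.

`validateCandidates()` then tests the candidates against each other:
for every unique LM–LM residue pair both locales are resolved and pairs
failing `mayCrosslink()` are contradictions. **Both endpoints of a
contradictory link are removed.** The rationale is that a contradiction
cannot, from the link alone, be attributed to one endpoint — either
protein may be dually localized or the identification may be a false
positive — so both are suspect. This is deliberately conservative; it can
remove a correctly annotated marker that a noisy link touches, which we
accept because marker fidelity matters more than marker count. Links
through membrane-embedded marker residues carry no compartment information
and are skipped from the tally (warned, counted in the report).
Validation is idempotent: removing both endpoints of every contradiction
leaves no LM–LM contradiction behind.

`augmentCandidates()` re-validates manual additions against the
cross-links before acceptance, so a previously removed contradictory
candidate cannot be smuggled back in. An optional abundance vector only
orders reports; it never influences acceptance.

## Prediction

`runClasp()` chains the stages: network construction and filtering,
marker validation, first-tier extraction, per-target voting.

* **Votes are counted at unique residue-pair level**, not at spectrum
  (CSM) level — FDR control and the consistency statistic live at the
  unique-pair level, and spectral counts would overweight abundant
  proteins.
* **One vote suffices** for a prediction, but `n_votes` and
  `n_supporting_lms` are reported so users can filter.
* A prediction is **unambiguous** iff all its votes name one compartment.
  Classification against the prior is `confirms` / `contradicts` /
  `novel`; ambiguous predictions are not classified. Rather than modeling
  dual localization, multi-compartment support is surfaced as ambiguity.
* **Membrane targets** are predicted per soluble region. Regions with
  unambiguous votes anchor the topology; `orientTopology()` propagates
  sides by alternation. With anchors on two different compartments the
  membrane is identified outright. With anchors on a single compartment
  the opposite side is known only if the membrane is (from the prior
  annotation, or because only one membrane borders that compartment —
  e.g. cytosol-anchored regions imply the outer membrane); otherwise the
  orientation stays `partial` and only even-parity regions (those an even
  number of TM segments away from an anchor) inherit the anchored
  compartment. This is exactly the even-TM-count termini rule: both
  termini of an even-TM protein share a side regardless of which membrane
  it sits in. Topology-completed regions are reported with basis
  `"topology"` and zero votes, distinct from vote-based rows; summary
  ambiguity fractions are computed over vote-based rows only.
* **Corroborating neighbors**: non-marker neighbors whose own unambiguous
  prediction shares a compartment are counted
  (`n_consistent_neighbors`) in a single propagation round. They are
  never used as votes — inference stays strictly first-tier, avoiding
  error propagation through transitive hops.
* A soluble target supported only by the outermost aqueous compartment
  and lacking a prior is noted as *membrane-associated* (bound to the
  outer membrane's cytosolic face rather than imported).

## Topology construction

TM segments come from two sources: annotation intervals and TMHMM-style
predicted segments with posterior probabilities. `classifyTM()` applies
the calibrated bands — posterior > 0.75 high confidence, 0.037–0.75
potential, < 0.037 soluble. High and potential segments both enter region
building (`buildRegions()` merges overlapping intervals with IRanges;
a merged segment keeps the strongest evidence class, annotation
outranking prediction), but predictions whose topology rests on
potential-only segments carry a `potential TM topology` note. Residues
exactly on a TM boundary belong to the TM segment — conservative, since
boundary residues are excluded from voting rather than contributing
possibly wrong compartment evidence.

## Network choices

* Edges carry the number of unique inter-protein residue pairs; intra-
  protein links are kept in the `CrossLinkSet` but never become edges.
* `filterNetwork()` removes isolated nodes and components below
  `min_component_size`. The literature-scale datasets this mirrors never
  state the cutoff; the default is 3 (discarding trivial pairs) and the
  value is recorded in the filter report and run manifest so it is
  auditable per run.
* Coverage counts markers themselves plus their first-tier interactors in
  the numerator: markers are localized by definition, so they are covered.
* Degree ties break by accession lexicographic order, making rankings and
  reruns deterministic. All inference is seed-free; rerunning a command
  on identical inputs yields byte-identical outputs.

## The simulator, and what passing tests do not show

`generateOrganelle()` emulates: compartment-resident soluble proteins
(weights default to an innermost-compartment-heavy mix, mirroring the
matrix-dominated mitochondrial proteome), membrane proteins with 1–6
oriented TM segments, lysines at ~7% of positions (the frequency the
lysine-reactive chemistry sees), and a marker subset.
`simulateCrossLinks()` draws residue pairs sharing an aqueous compartment,
with an independent per-link noise probability that instead samples a
compartment-violating pair; the truth table records every link's class.

On noise-free data the whole pipeline must be exact: 100% marker
consistency, 100% unambiguous predictions, 100% accuracy against ground
truth, an empty cross-membrane audit. The test suite asserts these, plus
brute-force-oracle equivalence for filtering, first-tier extraction,
ranking, orientation and admissibility (100 random instances of up to 50
proteins), and the termini parity law over 1000 simulated membrane
proteins. Test and acceptance problem sizes (200 proteins / 3000 links
for recovery runs; smaller for unit fixtures) were chosen to exercise
every code path at desk scale.

What the simulator does *not* emulate — and hence what green tests cannot
certify about real data: abundance-dependent detectability, residue-level
reactivity and digestibility biases, search-engine score distributions,
dual-localized proteins, contact-site geometry beyond the pairwise gap
distance, and sub-membrane microdomains. Real-data error modes (FDR
leakage, isoform ambiguity) enter only through the noise fraction, which
is a crude aggregate of them.

## Degenerate inputs and numerical conventions

* Residue coordinates are 1-based, intervals inclusive on both ends
  (Swiss-Prot convention). Accessions are opaque keys; isoform suffixes
  are not stripped.
* Duplicate unique pairs merge with summed spectral counts and the
  maximum score (conservative retention of the best evidence).
* An empty cross-link set or an empty validated marker set aborts
  `runClasp()`; an empty network makes coverage undefined (error), and
  zero mappable links make structural satisfaction undefined (error).
  Unresolvable locales are *indeterminate*, never silently counted as
  violations or as support.
* Consistency on zero tallied LM–LM links is reported as 100% (nothing
  contradicts), with the zero tally visible in the report.

## Known limitations

* Single-anchor membrane proteins in membranes whose both neighbors also
  border another membrane (e.g. IMS-only anchors) remain partially
  oriented unless the prior names the membrane.
* The contradiction-removal policy can discard a correct marker linked to
  one bad identification; with very noisy data this shrinks the marker
  set quickly. The consistency report makes the removals explicit.
* Prediction counts are reported both per protein and per region; users
  comparing against resources that count proteins should use the protein
  summary.
* Cα–Cα validation uses a fixed per-linker cap, not conformational
  ensembles, and homolog mappings are trusted as given.
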