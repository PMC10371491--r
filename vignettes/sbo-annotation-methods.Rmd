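---
title: "Methods: how sbotagger assigns SBO terms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: how sbotagger assigns SBO terms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sbotagger)
```

This vignette documents the classification scheme, the knowledge sources it
relies on, the decisions taken where the design was genuinely open, and what
the shipped tests do and do not establish.

## The classification scheme

### Reaction triage

Every reaction receives exactly one of six classes. The decision list is
ordered, and the order is load-bearing:

1. **BIOMASS** — the reaction is part of the active fbc objective, or
   "biomass" occurs (case-insensitively) in its id or name. Objective
   membership is the principled signal; the id pattern is a fallback because
   many published models carry several biomass variants of which only one is
   the active objective, and a biomass reaction that is not the current
   objective is still a biomass pseudo-reaction.
2. **One-sided reactions** (an empty reactant or product side) are
   boundary pseudo-reactions. `EX_`-prefixed ids, boundary-condition
   species, or species sitting in the extracellular compartment mark an
   **EXCHANGE**; otherwise `SK_`/`sink_` prefixes mark a **SINK** and `DM_`
   a **DEMAND**. With no prefix information the community convention
   decides: reversible drains are sinks, irreversible drains are demands.
   Prefixes always win over reversibility, since an explicitly labelled
   `DM_` reaction that happens to be reversible is still a demand.
3. **TRANSPORT** — the reactants and products together span at least two
   distinct compartments. Modifiers are deliberately excluded: the
   compartment of an annotated enzyme must not turn a cytosolic conversion
   into a transporter.
4. **BIOCHEMICAL** — everything else.

Biomass precedes the one-sided and transport rules so that a biomass
function that drains precursors from several compartments is not
misclassified as transport. A reaction with no participants at all is a
hard classification error rather than a silent bucket: such a reaction is
structurally meaningless and the model should be fixed, not annotated.

The extracellular compartment is identified once per model: the compartment
used by the sole participants of `EX_`-prefixed reactions, else the
compartment with id `e` or an id/name containing "extracellular". This lets
a structurally identical exchange reaction without the `EX_` prefix receive
the same class, which the test suite checks explicitly.

### Transport mechanism typing

The mechanism assignment is built on *translocation events*: base species
ids (compartment suffix stripped) appearing as a reactant in one compartment
and a product in another. On top of the events, the decision order is

`ACTIVE_ATP` &gt; `ACTIVE_PEP` &gt; `SYMPORT`/`ANTIPORT` &gt; `PASSIVE` &gt;
`GENERIC`.

* `ACTIVE_ATP` requires the full hydrolysis couple — ATP consumed, **both**
  ADP and Pi produced (water optional) — plus something actually crossing.
  Requiring Pi distinguishes ABC-style pumps from kinases that happen to
  span compartments; the test suite carries that counter-example.
* `ACTIVE_PEP` recognizes the phosphotransferase system: PEP consumed,
  pyruvate produced, and a sugar crossing compartments *possibly changing
  identity in transit* (glucose in, glucose-6-phosphate out). The
  sugar/phospho-product pairs live in a configurable table
  (`inst/extdata/pts_sugars.tsv`) because this is chemistry knowledge, not
  algorithm.
* With two or more events, opposite directions make an `ANTIPORT`, a single
  shared direction a `SYMPORT`.
* `PASSIVE` is a single event with no co-substrate — the one-participant
  case.
* Everything else (identity-changing crossings outside the PTS table,
  mixed-direction multi-compartment movements) is `GENERIC` transport.

Energy coupling is placed first because it is the most informative signal:
a pump that also looks antiport-shaped is still primarily ATP-driven. A
proton counts as a translocation event like any other species, so a
substrate-plus-proton importer types as symport while a bare proton uniport
is passive; both behaviours are property-tested.

Moiety detection works on base ids (`atp`, `adp`, `pi`, `pep`, `pyr`) with
compartments ignored and an optional `M_` SId prefix stripped. BiGG
universal metabolite ids are stable enough to make this reliable without
parsing chemical formulae.

### EC resolution for biochemical reactions

The mapping store is a relational table `(ec_pattern, sbo_label, sbo_id,
category, class_label)` seeded from a human-editable TSV. Patterns are EC
prefixes; matching is most-specific-wins (exact four-field entry, then
depth-3, depth-2, depth-1 prefixes). The three categories mirror how
enzymatic function maps onto ontology terms: whole sub-subclasses
(*one-to-one*, e.g. transamination for 2.6.1.-), small explicit sets
(*one-to-few*, e.g. myristoylation), and larger explicit subsets of one
sub-subclass (*one-to-many*, e.g. acetylation). The shipped seed
distinguishes 18 enzymatic-function classes; ligases (EC class 6) map to
the covalent-bond-formation term `SBO:0000695`. EC class 7 (translocases)
is deliberately absent from the biochemical map — translocase chemistry is
transport and is handled by the transport typing path.

A reaction with several EC numbers that map to different terms receives the
deepest common ancestor of those terms in the is-a graph, with two
safeguards: ties at equal depth resolve to the smaller term id (pure
determinism, no semantic claim), and the result is clipped at the generic
biochemical-reaction term — an ancestor above `SBO:0000176` would leave the
reaction branch entirely. Reactions with no (mappable) EC numbers get the
generic term. The resolver is tested against a brute-force oracle that
enumerates all common ancestors on randomized DAGs.

### Non-reaction entities and preservation

Species receive *simple chemical*, fbc gene products *gene*, and modifiers
of EC-carrying reactions *enzymatic catalyst* — with enzymatic evidence the
modifier's role is defined through the is-a relationship even though the
exact catalytic mechanism stays unspecified. Modifiers of EC-less reactions
receive nothing: they could equally be inhibitors. Species sub-typing
(macromolecule patterns) exists but is off by default; id heuristics for
macromolecules are too model-specific to enable blindly.

Pre-existing `sboTerm` values that are *strict descendants* of what would
be assigned are preserved by default (`--force` overrides): a curated,
more specific annotation must never be downgraded by an automated pass.
Anything equal or less specific is replaced.

## Anti-hallucination configuration

All numeric SBO ids live in label-keyed configuration tables
(`term_labels.tsv`, `ec_sbo_seed.tsv`). At load time every (label, id) pair
is asserted against the ontology graph: a mismatch is a configuration
error before any assignment happens. The package bundles a condensed
**synthetic subset** of SBO (`sbo_subset_synthetic.obo`) containing only the
referenced terms and their ancestor chains — enough for the is-a reasoning
the annotator performs. Users with a full SBO release in OBO format can
point `sbo_config(obo = ...)` at it; the same assertions then run against
the authoritative hierarchy.

## What the fixture forge emulates — and what it does not

`build_fixture()` assembles miniature SBML L3V1+fbc models from archetype
reactions (one per classification branch) with BiGG-style identifiers, by
deterministic string assembly: the same spec yields byte-identical files.
`random_model_doc()` additionally samples randomized models (mixed classes,
random compartments, ids, reversibility, including deliberately odd
"weird" reactions) for the partition property.

These fixtures exercise every rule branch, but they are not biologically
realistic networks: stoichiometric consistency, mass balance, realistic
network topology, exotic compartment layouts (organelles, multi-membrane
systems) and non-BiGG identifier schemes are absent. A passing suite
therefore demonstrates rule correctness and round-trip fidelity, not that
every reaction in an arbitrary real model is classified as its curator
intended — in particular, models whose ids do not follow BiGG conventions
lose the prefix and moiety heuristics and degrade towards generic terms.

## Numerical and procedural choices

* **Depth** in the ontology is the longest path from a root; common-ancestor
  ties break to the smaller id.
* **Serialization**: `sboTerm` is always `SBO:` + seven zero-padded digits;
  output files are `<stem>_SBOannotated.xml` in the chosen output
  directory; writing is re-serialization of the source document, so
  applying the same assignments twice is byte-identical and non-annotation
  content round-trips untouched.
* **Degenerate inputs**: participant-less reactions error at triage;
  malformed EC strings in annotations are skipped with a warning;
  an invalid EC in a lookup resolves to nothing rather than erroring.
* **Offline by default**: the BiGG gateway is injectable; the offline
  gateway short-circuits before any call, which a counting stub asserts.
  Fetched EC numbers (when a remote gateway is supplied) are cached on disk
  — including negative results — and written back into the output model as
  controlled-vocabulary annotations.

## Problem sizes used by the test suite

The suite runs entirely on generated inputs: the full-branch fixture
(18 reactions, 40 species), 200 randomized models of 4–12 reactions for the
partition property, 50 randomized DAGs of 6–13 terms for the
common-ancestor oracle, and 25 randomized stores for lookup specificity.
These sizes keep the whole suite in single-digit seconds while covering
every branch; the algorithms are linear or near-linear in model size, so
behaviour on genome-scale models differs in runtime, not logic.

## Known limitations

* The bundled ontology subset covers only the configured terms; reasoning
  about terms outside it requires supplying a full OBO release.
* The EC seed is a curated default spanning 18 enzymatic classes; it is
  intentionally editable and does not claim completeness over the whole EC
  hierarchy (unmatched ECs fall back to the generic term, never to a wrong
  specific one).
* Transport typing ignores membrane topology and does not separate primary
  from secondary active transport beyond the ATP/PEP signals; light- or
  redox-driven pumps type as generic transport.
* Kinetic-law, parameter and mathematics-branch terms are out of scope; the
  focus is constraint-based models.
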