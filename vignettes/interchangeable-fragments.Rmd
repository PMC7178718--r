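---
title: "Interchangeable-fragment structure generation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interchangeable-fragment structure generation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(molgraft)
```

## The model

molgraft generates new small molecules by swapping fragments that are
*interchangeable*: two fragments are considered interchangeable when they
occur, somewhere in a reference corpus, in the same local chemical
environment. The environment -- the *context* -- is the set of atoms within
a bond-topology radius `r` of a fragment's attachment points, encoded as a
canonical SMILES string. Because a replacement only ever re-forms single
bonds whose valence was freed by the corresponding cut, every product is
chemically valid by construction; validity is a structural property of the
algorithm, not a post-hoc filter.

The pipeline has three stages:

1. **Fragmentation.** Every corpus molecule is cut on all subsets of up to
   four acyclic single bonds between heavy atoms; hydrogens are cut by a
   separate pathway. Each cut set yields a *core* (the component incident to
   all cuts, carrying numbered attachment dummies `[*:i]`) and its context
   (everything else). Ring bonds, double/triple bonds and bonds to hydrogen
   are never cut, which is why the method cannot invent ring systems absent
   from the corpus -- an inherited, acknowledged limitation.
2. **Database.** For each record and each radius, the truncated context is
   canonicalized with atom maps excluded from the ranking; attachment
   points are renumbered 1..k by first appearance in the canonical string
   and the renumbering is pushed onto the core. When two attachment points
   sit in symmetry-equivalent environments, every distinct permutation of
   their labels is stored as a separate core variant, so that symmetric
   sites can accept either orientation of an asymmetric replacement. Rows
   are `(radius, context, core, heavy-atom count, occurrence count)`.
3. **Generation.** MUTATE fragments the parent, looks each canonical
   context up, filters candidate cores, and splices them into the
   *untruncated* remainder. GROW is MUTATE restricted to hydrogen cores;
   LINK replaces one hydrogen in each of two molecules and queries a single
   combined two-attachment context key.

## Parameters that matter

| parameter | default | units | effect |
|---|---|---|---|
| `radius` | 3 | bonds | Specificity of interchange. Radius 1 barely distinguishes functional groups; radius 3 separates, e.g., amides from amines; radius 5 is very conservative. Outputs are nested: radius r+1 products are a subset of radius r products. |
| `min_size`, `max_size` | 0, 10 | heavy atoms | Bounds on the replaced core; 0 makes hydrogens replaceable. |
| `min_inc`, `max_inc` | -2, +2 | heavy atoms | Signed bounds on the size difference replacing - replaced; small symmetric windows take small steps in chemical space. |
| `min_freq` | 0 | count | Minimum occurrence of the replacing core among distinct corpus molecules; raising it biases toward common (plausibly easier-to-make) fragments and shrinks output. |
| `max_rel_size` | unset | fraction | Cap on replaced-core size relative to the parent (0.3 in the stochastic-exploration setup). |
| `max_replacements` | unset | count | Seeded uniform sample over (site, candidate) pairs; unset = exhaustive. |

The stochastic-exploration bundle (`exploration_params()`) fixes the
published setup: replaced size 0-8, relative size <= 0.3, size delta +/-1,
25,000 sampled replacements, 500 Da weight cap, 5 equal-count MW bins with
one random survivor each, 100 iterations. The optimizer bundle
(`optimizer_params()`) encodes the adaptive windows (score <= 0.3: +/-10;
score > 0.8: +/-4; interpolated over 9..5 between) and the three patience
levels (3 stalled iterations: window +1, replacements +100; 10: window +10,
replacements +500; 33: reseed, keeping the best).

## Numerical and representational choices

* **Self-contained toolkit.** No cheminformatics toolkit exists in the host
  R environment, so SMILES parsing, sanitization, canonical ranking and
  fingerprints are implemented in the package. Canonical ranking uses
  iterative invariant refinement with automorphism-safe tie-breaking; the
  canonical string is invariant under any permutation of input atom order
  (property-tested, and cross-checked against RDKit's equivalence classes
  in the test suite). Canonical strings are comparable only within
  databases produced by this package -- cross-toolkit key compatibility is
  a non-goal.
* **Attachment points** are dummy atoms with atom-map numbers (`[*:1]`);
  the map numbers, not isotopes, carry the context/core pairing.
* **Context frontier.** Truncation opens valences at the frontier; they are
  filled with implicit hydrogens (one per single or aromatic bond, two per
  double, three per triple). Truncated contexts may contain aromatic atoms
  outside a complete ring; they are keys, not molecules, and the parser
  accepts them without ring-aromaticity checks.
* **Stereochemistry and isotopes** are stripped on input. This maximizes
  context matches and keeps keys stable; enantio- and E/Z-selective
  replacement is out of scope.
* **Symmetry of attachment points** is decided by equal refined canonical
  ranks of the dummies in the map-agnostic ranking -- a deterministic,
  toolkit-level definition of "identical context".
* **Occurrence counts** increase at most once per distinct source molecule
  per `(radius, context, core)` triple, making counts robust to the
  combinatorial multiplicity of cut sets inside one molecule. Each stored
  permutation variant keeps its own row and count.
* **Cut-set pruning.** A core of `s` heavy atoms touching every cut bond
  bounds the pairwise bond distance of the cuts by `s - 1`, so generation
  prunes cut sets whose bonds are farther apart than `max_size - 1` before
  doing any canonicalization. This is exact (no qualifying record is ever
  lost) and is what keeps mutate affordable on long acyclic chains.
* **Aromaticity.** Simple 5-7-membered Kekule rings are perceived
  (4n+2 over ring double bonds and lone-pair donors) so Kekule and aromatic
  inputs share one canonical form. Exotic aromatic systems should be
  supplied in aromatic (lowercase) SMILES.
* **Patience semantics.** One stall counter counts consecutive
  non-improving iterations and resets on improvement and after the level-3
  reseed. Escalations fire when it reaches 3, 10 and 33; the alternative
  (resetting after every escalation) can never reach the 10-stall level and
  contradicts the published thresholds. The visited-compound list is
  cleared whenever the generator knobs change.
* **MW bins** are equal-count, not equal-width (the published procedure
  does not say; equal-count keeps every bin non-empty and the selection
  pressure uniform).

## What the synthetic corpora emulate -- and what they do not

`synth_corpus()` builds four deterministic families: n-alkylbenzene
homologs, benzene rings with 1-3 sampled substituents, alpha,omega-capped
alkyl chains, and a "purged" union of the latter two from which every
molecule matching a designated SMARTS (default: aryl alkyl ether) is
removed. These give the tests known interchangeability structure: homolog
series guarantee size-delta candidates, decorated aromatics exercise
symmetric attachment points, linkers provide two-attachment cores for LINK,
and the purged corpus provides the motif-exclusion world (the motif's
diameter is 2 bonds, so radius >= 2 generation can never assemble it while
radius 1 can).

They do **not** emulate real screening libraries: no macrocycles, no fused
or bridged ring variety, no stereochemistry, no charge states, and property
distributions far narrower than ChEMBL's. A green test therefore
establishes algorithmic correctness (exact agreement with a brute-force
oracle, exclusion guarantees, contract properties) -- not chemical coverage
or transferability of, e.g., synthetic-accessibility calibrations.

The brute-force oracle re-derives every `(context, core)` pair and every
mutate output by direct enumeration, sharing only the SMILES toolkit with
the pipeline; ring detection, component labelling and truncation use
adjacency-matrix reachability instead of the pipeline's DFS/BFS, precisely
to catch order-dependent bugs.

## Metrics

Novelty is the mean Tanimoto distance to the parent on hashed circular
fingerprints (2048 bits, radius 2, binary); diversity is the mean pairwise
distance, estimated on five seeded 1000-molecule subsamples when the set is
larger. Corpus novelty is canonical-string set membership. The fingerprint
is self-consistent but its bit positions are not interchangeable with any
other toolkit's Morgan bits; since all metrics are ratios of bit-set
overlaps computed within one implementation, this affects absolute values
only mildly and comparisons not at all. The property panel follows standard
definitions (TPSA from the published N/O fragment contributions; logP from
a coarse Crippen-style atom-contribution scheme that is indicative rather
than toolkit-identical). The built-in synthetic-accessibility score
implements the published heuristic's functional form (fragment-frequency
term, size/spiro/bridge/macrocycle penalties, symmetry correction, rescaled
to [1, 10]) but calibrates fragment contributions on a small built-in
reference set instead of a million-compound PubChem table; treat it as a
relative ordering, not an absolute scale. A learned complexity model can be
plugged in through `register_scorer()`.

## Known limitations

* No new ring systems, by design.
* Stereochemistry is discarded.
* The SMARTS matcher covers the primitive subset documented in
  `parse_smarts()`; the bundled alert catalog is a small curated
  illustration, not the full published PAINS list.
* Unbounded growth: with symmetric size deltas the mean molecular weight
  drifts upward over iterations (databases hold more large fragments than
  small ones), which is why the exploration workflow applies a weight cap
  and the test suite treats growth as a reported, not asserted, property.
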