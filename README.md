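# molgraft

Fragment-based de novo molecular structure generation in R, built on
databases of *interchangeable fragments*.

## The problem

De novo design tools must propose new molecules that are chemically valid
and, ideally, not absurd to synthesize. Atom-based generators and many
generative neural models can emit invalid structures; reaction-based
generators are valid but limited by their rule sets. molgraft takes the
matched-molecular-pair route: it fragments a corpus of known compounds by
cutting up to four acyclic single bonds (hydrogens separately), records
each fragment together with the canonical SMILES of its *context* — the
atoms within a bond-topology radius r of the attachment points — and treats
two fragments as interchangeable when their contexts are string-identical.
Replacing a fragment with an interchangeable one only ever re-forms single
bonds whose valence the cut freed, so **every generated structure is valid
by construction**. The context radius is a conservatism dial: motifs whose
graph diameter is at most the radius can never be assembled unless they
already occur in the corpus, which gives indirect control over chemotypes
(e.g. generating from a corpus purged of assay-interference substructures).

Three generation modes share this machinery: **MUTATE** (replace an
arbitrary fragment), **GROW** (replace a hydrogen), **LINK** (join two
molecules through a two-attachment fragment). On top sit evaluation
metrics (Tanimoto novelty/diversity on 2048-bit radius-2 circular
fingerprints, corpus novelty, a nine-descriptor property panel,
Bemis–Murcko scaffold analysis, SMARTS-based alert screening, a pluggable
synthetic-accessibility score), a stochastic chemical-space exploration
workflow with molecular-weight binning, and a greedy goal-directed
optimizer with adaptive fragment-size windows and three patience levels.

The molecular toolkit (SMILES parser/writer, sanitizer, canonicalizer,
fingerprints, subset SMARTS matcher) is self-contained R; no external
cheminformatics toolkit is required.

## Worked example

```r
library(molgraft)

db <- build_db(c("Cc1ccccc1", "CCc1ccccc1"), radii = 1)
db
#> <frag_db: 8 entries, radii {1}, corpus of 2 molecules>
db_stats(db)
#>   radius n_pairs
#> 1      1       8

out <- mutate("Cc1ccccc1", db,
              generation_params(radius = 1, min_size = 1, max_size = 2,
                                min_inc = -1, max_inc = 1))
out
#> [1] "c1ccccc1"   "CCc1ccccc1"
```

Toluene's methyl group sits in a single-aromatic-carbon context; the
two-molecule corpus knows three cores for that context (methyl, ethyl,
hydrogen), so within the size windows the methyl becomes ethyl
(ethylbenzene) or hydrogen (benzene) — and nothing else. Ring positions are
untouched because `min_size = 1` excludes hydrogen as the *replaced*
fragment. Metrics on the output:

```r
novelty("Cc1ccccc1", out)            # mean Tanimoto distance to the parent
#> [1] 0.7
corpus_novelty(out, c("Cc1ccccc1", "CCc1ccccc1"))  # % not in the corpus
#> [1] 50
property_panel(out[1])
#>   HBD HBA     MW logP RTB TPSA NumRings Csp3 fmf
#> 1   0   0 78.114 1.68   0    0        1    0   1
```

Larger workflows: `stochastic_explore()` iterates MUTATE from a seed
molecule, discards products above 500 Da, and carries one molecule per
molecular-weight bin forward; `goal_directed_optimize()` hill-climbs a
`[0,1]` score with fragment-step sizes adapted to the current best score
and patience escalations after 3/10/33 stalled iterations. A command-line
interface covers database building, the three generation modes, metrics
reports, exploration and fixture generation:

```sh
Rscript -e 'molgraft::molgraft_cli()' fragdb-build --in corpus.smi --out db.tsv --radius 1 2 3
Rscript -e 'molgraft::molgraft_cli()' mutate --in parents.smi --db db.tsv --radius 2 --out out.smi
```

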