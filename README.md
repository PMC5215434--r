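# ubisitevol

Comparative-evolution analysis of protein ubiquitination sites in R.

Ubiquitination of lysine residues drives most regulated protein degradation
in eukaryotes and a broad range of signalling processes. Whether the
modified lysines themselves are under stronger purifying selection than
their sequence neighbourhood — and which functional contexts impose that
constraint — is a question about *rates*: how fast does the modified
position accumulate substitutions relative to its local background across
a ladder of increasingly distant organisms? This package implements that
analysis end to end for users studying PTM-site evolution, together with a
synthetic-data generator with recorded ground truth so every stage can be
validated without access to external databases.

## The statistics at the core

For a group of sites compared between human and a reference organism *o*,
with *n<sup>d</sup>* of *n* pooled residues differing, the difference
proportion and the Poisson-corrected distance are

  p = n<sup>d</sup>/n,  var(p) = p(1−p)/n,
  d = −ln(1−p),  var(d) = var(p)/(1−p)²,

where *d* corrects for multiple substitutions at one position and grows
linearly with divergence time under a Poisson substitution model. Sites are
contrasted with their flanking background (the ten residues centered on the
site, five each side, site excluded) by

  z = (d<sub>sites</sub> − d<sub>flanks</sub>) / √(var<sub>sites</sub> + var<sub>flanks</sub>),

with Σ<sub>o</sub> z<sub>o</sub>² ~ χ²<sub>n</sub> combining the organisms.
Protein groups (pathway categories, expression classes, network hubs) are
compared through the relative Poisson distance r = d<sub>sites</sub>/d<sub>flanks</sub>
with its delta-method variance, which removes whole-protein conservation
differences between groups. Tissue specificity is scored by relative
entropy, TSPS = Σ<sub>j</sub> p<sub>j</sub> log₂(p<sub>j</sub>/q<sub>j</sub>)
against a uniform null (facilitators < 1 bit ≤ specifiers); hubs are
proteins with more than 20 distinct interaction partners. Site gains are
timed by first appearance of the conserved lysine along the organism
ladder, and gained-site proteins are tested for category enrichment with a
hypergeometric test under Bonferroni correction.

## Worked example

The `analysis/` scripts run the full study on synthetic data and write
their tables under `results/`:

```sh
Rscript analysis/01_simulate.R          # generate the two study bundles
Rscript analysis/02_site_vs_flank.R     # Poisson distances, z, chi-square
Rscript analysis/03_categories.R        # category / TSPS / hub contrasts
Rscript analysis/04_gains_enrichment.R  # gain timing and enrichment
```

Stage 2, run on a 200-protein dataset in which sites evolve at half the
background rate, prints (excerpt):

```
organism          d_site  d_flank       z  stars
G.gorilla         0.0101   0.0203   -2.94  **
M.mulatta         0.0356   0.0637   -4.28  ***
R.norvegicus      0.1020   0.2237  -10.56  ***
...
S.pombe           1.2730   2.2792  -17.12  ***
combined: chi2 = 2497.7 (df 14), p = 0, mean z = -12.68
14 of 14 organisms show sites more conserved than flanks (z < 0)
```

Negative z means ubiquitination sites accumulated fewer substitutions than
their flanking background in that organism; the combined chi-square
aggregates the evidence across the ladder. Stage 3 recovers the planted
category structure — the "metabolism" group, whose sites were simulated
with relaxed constraint, shows a significantly larger relative distance
than the rest (`mean z = 2.61, p = 3.9e-18`) while the whole-protein rate
difference is absorbed by the ratio — and stage 4 re-derives 100% of the
planted gain epochs, with strict mode abstaining on every profile carrying
a planted secondary loss.

The same functions run on provided data: put FASTA sequences, a site
table, ortholog pairings, alignments, annotations, an expression matrix
and an edge list in the layout written by `write_bundle()` and call
`run_pipeline(pipeline_config(mode = "provided", input_dir = ...))`.

## Package layout

- `R/`, `src/` — estimators, aligner, generator, pipeline (see the
  methods vignette in `vignettes/` for the modelling choices)
- `analysis/` — the numbered study scripts above
- `tests/testthat/` — unit, property and end-to-end statistical tests,
  including independent brute-force oracles for the aligner and the
  hypergeometric tails
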