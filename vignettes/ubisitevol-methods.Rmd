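---
title: "Methods: modelling the evolution of ubiquitination sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modelling the evolution of ubiquitination sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ubisitevol)
```

This vignette documents the models, the tunable parameters, the numerical
conventions, and the design choices behind the package, and states what the
synthetic-data tests do and do not establish about real data.

## The estimation model

All comparisons are human-anchored. For each human protein carrying
ubiquitinated lysines, one ortholog per reference organism is aligned
pairwise to the human sequence; the residue in the alignment column of each
human site is the observation. Observations are pooled over all sites of a
protein group — never averaged per site — giving a count pair
$(n^d, n)$ per organism and region. The difference proportion
$p = n^d/n$ is treated as binomial, $\mathrm{var}(p) = p(1-p)/n$, and
transformed to the Poisson-corrected distance

$$d = -\ln(1-p), \qquad \mathrm{var}(d) = \frac{\mathrm{var}(p)}{(1-p)^2},$$

which corrects for multiple substitutions at one position and is linear in
time under a Poisson substitution process. The site-versus-flank contrast
in one organism is the two-sample z-score
$z = (d_s - d_f)/\sqrt{\mathrm{var}(d_s) + \mathrm{var}(d_f)}$, and
evidence is combined across $n$ organisms as $\sum_o z_o^2 \sim \chi^2_n$
under the null of equal rates, with the mean $z$ reported as direction.
Group contrasts replace $d$ with the relative distance $r = d_s/d_f$,
whose variance follows from the delta method:
$\mathrm{var}(r) = \mathrm{var}(d_s)/d_f^2 + d_s^2\,\mathrm{var}(d_f)/d_f^4$.
The ratio removes whole-protein conservation differences between groups
(demonstrated in `analysis/03_categories.R`, where a planted 1.3x
whole-protein rate excess does not shift the contrast but a site-specific
relaxation does).

Assumptions worth keeping in mind: pooling treats residues as independent
Bernoulli draws, so linkage between nearby sites (and flank overlap, see
below) is ignored in the variance; the z and chi-square references are
asymptotic and need group sizes in the hundreds to be trustworthy; and the
Poisson correction assumes a homogeneous rate within a pooled group — rate
heterogeneity (e.g. Gamma-distributed rates) is deliberately out of scope.

## Flanking-region background

The background of a site is the ten residues centered on it: five on each
side, the site itself excluded, truncated at the protein termini
(`flank_positions()`, `flank.half_width = 5`). Flank conservation means
exact amino-acid identity with the human residue — the same criterion as
for sites, where identity means retaining the lysine. Two conventions were
genuinely open:

* **Lysines inside the flank.** The flank is used *instead of* other
  lysines as background, which we read as retaining flank lysines; the
  alternative reading (drop lysines from flanks) is available as
  `exclude_lysines = TRUE`.
* **Overlapping flanks** of nearby sites are pooled with repetition — each
  site contributes its full flank — matching the "extract and concatenate"
  description of pooling. This slightly understates the variance when
  sites cluster; at the default five sites per 300–600-residue protein the
  effect is negligible.
* **Gaps.** An alignment gap at the orthologous position counts as
  "different" by default (`gap_as_diff = TRUE`): a deleted lysine cannot
  be ubiquitinated. The alternative (exclude gapped columns) is a switch.
  Orthologs absent in an organism contribute nothing.
* **Saturated groups** ($p = 1$, possible in tiny cells) have infinite
  distance; they are clamped to $p = (n - 0.5)/n$ with a warning so pooled
  pipelines keep running, or can be made a hard error.

## Alignment

The internal aligner is a Needleman–Wunsch/Gotoh global aligner with
affine gaps (Rcpp), BLOSUM62 (as distributed with Biostrings), gap open
10, gap extend 1, a gap of length $L$ costing $10 + L$. Traceback ties are
broken by preferring match, then a gap in the ortholog, then a gap in the
human sequence, making alignments deterministic. Downstream statistics use
only residue identity at aligned positions, so the precise scoring
convention is immaterial as long as it is fixed; the test suite verifies
optimality against an independent pure-R dynamic-programming oracle and
against `Biostrings::pairwiseAlignment` scores. Pre-aligned pairs (the
generator's true alignments, or user-provided aligned FASTA) bypass the
aligner; the "multiple alignment" used for gain timing is the stack of
pairwise alignments indexed by human positions, since every question asked
of it is human-referenced.

## Tissue specificity, hubs

TSPS is the relative entropy, in bits, between a protein's fractional
expression across tissues and the uniform distribution, with
$0 \log 0 = 0$. Base 2 is chosen so that the single-tissue maximum over
~32 tissues is $\log_2 32 = 5$, matching the conventional "maximum near
5" anchor; natural log would not. Facilitators are proteins with
TSPS < 1 bit, specifiers TSPS ≥ 1. All-zero expression rows are excluded
with a warning. Degree is the number of distinct interaction partners
after collapsing duplicate undirected edges and removing self-loops; hubs
have degree strictly greater than 20.

## Gain timing

A site's emergence epoch is the boundary just beyond the most distant
organism still carrying the lysine ("first appearance"). Parsimony
reconstruction over a true tree is deliberately not attempted: the ladder
view is human-anchored and no loss model is assumed. Missing orthologs are
uninformative and skipped; a site whose coverage is entirely missing
beyond its boundary is assigned the youngest consistent epoch and flagged
`low_coverage`. `mode = "strict"` additionally requires the lysine in
every observed organism inside the boundary and otherwise reports the site
unresolved — it trades coverage for a guarantee against mistiming
secondary losses. Enrichment of gained-site proteins uses all
ubiquitinated proteins in the dataset as background (not a whole
proteome), hypergeometric tails in both directions with the smaller tail
reported, and Bonferroni correction across the categories tested at one
epoch. Contrasts between protein categories elsewhere in the package are
reported *uncorrected* across the many category pairs, mirroring the
per-contrast significance-star convention of this analysis style; the
output tables state this.

## The synthetic-data generator

The generator is the package's instrument for validation, and its defaults
are the study conditions used by the tests and the `analysis/` scripts.

* **Substitution process.** Each residue accumulates $N \sim
  \mathrm{Poisson}(\lambda \cdot m)$ replacement events, where $\lambda$
  is the organism's divergence depth (expected background substitutions
  per residue) and $m$ the position's rate multiplier (site, flank,
  background, scaled per category). Each event replaces the residue
  uniformly among the 19 alternatives. The implementation samples the
  exact closed-form marginal of this jump chain,
  $P(\text{unchanged} \mid N = k) = \tfrac{1}{20} + \tfrac{19}{20}(-\tfrac{1}{19})^k$,
  which is distributionally identical to iterating the events; the test
  suite's oracle iterates them literally. This matches the assumptions of
  the Poisson-correction estimator on purpose; real amino-acid
  exchangeability (BLOSUM-like biases), codon structure, and tree-shaped
  covariance between organisms are deliberately absent.
* **The ladder.** Fourteen organisms, *G. gorilla* to *S. pombe*, with
  depths 0.02–2.6 expected substitutions per residue chosen to span from
  near-identity to deep saturation, and the five classical boundaries
  (primate, mammalian, vertebrate, animal, eukaryote) placed between the
  corresponding clades. Depths are a linear divergence order, not a real
  phylogeny.
* **Expression.** Facilitator proteins draw Dirichlet-style profiles with
  concentration 20 (near-uniform, TSPS well below 1 bit), specifiers with
  0.15 (spiky, TSPS mostly above 1), so the TSPS classifier is recoverable
  by construction; real expression data are noisier and not Dirichlet.
* **Network.** Each protein draws a target degree (planted hubs uniform in
  21–60; others power-law with exponent 2.2, truncated at 15) and samples
  that many distinct partners; the union of draws keeps realized degree at
  or above target, so planted hubs stay above the threshold of 20.
* **Gains and losses.** Planted gain sites override the substitution
  process at the site column: lysine in every organism inside the epoch,
  a random non-lysine beyond. Secondary losses are planted at organisms
  strictly *interior* to the conserved span. A loss at the span boundary
  is observationally identical to a younger gain — no inference rule could
  distinguish them — so the generator does not create such unidentifiable
  cases; this is what makes "strict mode never mistimes a lossy profile"
  a meaningful, testable guarantee rather than an impossible one.
* **Indels** are optional geometric-length (mean 3) insertions or
  deletions in the ortholog only; the true alignment is recorded so
  re-alignment can be validated against it.

Passing tests on these data establish that the estimators, contrasts and
inference rules do what they claim under the model they assume. They do
not establish robustness to misaligned orthologs, co-ortholog choice,
compositional biases, or expression platform effects in real data.

## Problem sizes and numerical checks

The end-to-end checks use 200-protein datasets (1,000 sites, 14 organisms,
roughly 10,000 flank residues per organism), 2,000-replicate null
calibrations at $\lambda = 0.2$ with 5,000 residues per region, and
10,000-draw Monte-Carlo validation of the delta-method ratio variance —
sizes at which the asymptotic references are accurate and a full run of
the suite stays within a few minutes on one core. Confidence-interval
coverage of the true rate is checked at $n = 500$ pooled residues where
the small negative bias of $-\ln(1-p)$ relative to $\lambda$ (induced by
back-substitution at high rates) costs at most about one coverage point;
at much larger $n$ that bias dominates the shrinking standard error and
coverage of $\lambda$ (not of the estimand $-\ln(1-p_\infty)$) degrades —
a property of the estimator worth knowing, not a defect of the variance
formula. The hypergeometric implementation is compared exhaustively
against a summation oracle for every configuration with background size
up to 25, and against full enumeration of all $\binom{20}{8}$ draws in
one case.
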