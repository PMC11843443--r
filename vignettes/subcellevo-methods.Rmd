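---
title: "Methods: gene age, subcellular localization, and their joint analysis"
author: "subcellevo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene age, subcellular localization, and their joint analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subcellevo)
```

## The model

`subcellevo` analyzes the relationship between when a gene originated and
where its protein product localizes in the cell. Gene age is expressed on
an ordered nine-branch scale, `br-2` (oldest; a cap — genes detectable in
the most distant outgroup are *at least* that old) through `br6`
(species-specific), collapsed when convenient into four age classes:
oldest (`br-2`), older (`br-1`), old (`br0`, the last branch before the
focal radiation split into subgenera), and young (`br1`–`br6`).

### Parsimony age dating

The dating core consumes a gene × outgroup-clade presence/absence matrix
of syntenic orthologs. Upstream steps — whole-genome alignment, chaining
and netting, reciprocal-best filtering — are external tools whose output
is that matrix; they are deliberately out of scope. Under parsimony, a
gene is as old as the oldest-diverging clade that retains an ortholog
(`assign_age()`); a gene absent from every clade is species-specific.
Because a single intervening outgroup species can lose a gene and make it
look younger, `apply_loss_correction()` consults a secondary outgroup at
the older level: genes dated to the younger branch but present in the
secondary outgroup are pushed back, and the number moved doubles as a
death count for fixation-rate correction. Genes whose exons are mostly
repeat-masked give unreliable alignments; `masked_exon_filter()` excludes
genes with a masked fraction strictly above 0.70 (the boundary itself is
retained).

Fixation rates are (births − deaths) / span in genes per million years.
Branch spans are configuration (`default_branch_spans()`), with the young
branches totalling 62 MY, the pre-split branch 7 MY (69 to 62 MY), and
the terminal branch 5 MY. Reported rates use round-half-up at the printed
precision; the raw value is always retained.

### Localization calling and enrichment

Localization probability tables (one probability per protein per
compartment, as produced by modern predictors) are thresholded at 0.5
with strict inequality; a protein may carry several compartments, or none
(such proteins are excluded from enrichment denominators and counted
separately — the choice of denominator is ours, made explicit because the
upstream convention is ambiguous). The nine-compartment vocabulary drops
the plant-specific plastid class on read. Enrichment compares observed
per-(group, compartment) counts with `E = total_c · n_g / N`, which
conserves compartment totals exactly; the excess percentage is
`(O − E)/E × 100` and each cell gets a Fisher exact test (raw and BH
adjusted — the adjusted column is an addition, since raw thresholds alone
invite multiplicity artifacts). Enrichment counts proteins; where a single
record per gene is required the longest transcript (summed exon length,
ties by smallest transcript id) is the representative.

### Pairwise statistics

*Co-localization.* For a target branch, the number of within-branch
protein pairs sharing a compartment is compared against repeated
equal-size samples of comparison pairs (100 iterations, sampling without
replacement): strategy A pools target × other-branch pairs, strategy B
all pairs. Only single-compartment proteins enter. Iterations whose
sample contains no co-localized pair are excluded from the mean rather
than smoothed, because smoothing biases small toys. When a branch holds
most of the dataset its within-branch pair count can exceed the
comparison pool; the sampler then uses the full pool and rescales, with a
warning — the alternative (an error) would make the statistic undefined
exactly where the data are most abundant.

*Co-function.* With `P(Kᵢ)` the fraction of annotated proteins on pathway
`Kᵢ`, the null probability that a random pair shares a pathway is
`p_co = Σᵢ P²(Kᵢ)` (single-membership arithmetic; with multi-pathway
proteins this conventional simplification can exceed the true pair
probability, and is kept deliberately). Per group, `E = C(n,2) · p_co`
and `O` counts pairs with intersecting pathway sets.

### Interaction density and the WC/BC simulation

Physical links with score strictly above 700 are deduplicated (both
orientations merged, self-loops dropped with counts). The density matrix
reports average interactions per gene: diagonal cells count edges whose
endpoints share the compartment, divided by genes carrying it;
off-diagonal cells count pure between-compartment edges (endpoint sets
disjoint), divided by the union of the two gene sets so that the diagonal
and off-diagonal share a scale (the alternative sum-of-sizes denominator
is a documented flag-level variant). Multi-localized proteins contribute
to every compartment they carry; a single-localized restriction mirrors
the co-localization filter. The WC/BC simulation samples 50,000
interaction pairs (reduced with a warning on smaller graphs) 50 times,
splits them by whether endpoint compartment sets intersect, computes
per-simulation per-gene frequencies for each side, and compares the two
collections with a two-sided rank-sum test.

### Sequence divergence by compartment

Greedy incremental clustering reproduces the CD-HIT contract: sequences
sorted by decreasing length join the first cluster whose founder they
match at ≥ 0.5 identity, where identity is identical aligned columns over
the shorter sequence; a shared-3-mer prefilter may skip alignments. The
banded-alignment and word-statistics heuristics of the original tool are
not reproduced — only the greedy core that defines the clustering.
Clusters need ≥ 2 members, all single-localized to one common compartment
(the stricter reading; it is what lets a cluster be assigned a
compartment at all), and compartments need strictly more than 40
surviving clusters. Divergence per pair is mismatching columns over
columns where both sequences carry a residue (indel columns excluded);
`D` is the mean over member pairs, computed from all-pairs pairwise
global alignments rather than one multiple alignment — for sequences
within a 0.5-identity cluster the column sets agree closely, and the
oracle tests pin the implemented definition, which is normative for this
package. An age-constrained subset (clusters composed entirely of
oldest/older members) removes the confounding of divergence by
origination time.

### Paralog relocalization

Raw paralog pairs are joined to ages; genes participating in more than
one pair are dropped (the literal one-to-one reading), pairs on equal
branches are dropped with a count (the parent must be strictly older),
and the older gene becomes the parent. Ancient duplications are the three
deep configurations (br-2→br-1, br-2→br0, br-1→br0); everything else is
recent. Localization changes partition into K (same set), KE (superset),
S (proper subset), E (disjoint), SE (partial overlap with gain and
loss). Sequence comparisons use the package aligner: one-sided (greater)
rank-sum on K vs non-K identity, two-sided rank-sum on pooled relative
mutation positions, with thirds binning (N-terminal bin closed at 1/3);
indel columns are not counted as mutations by default since the
biological reading of "mutated position" is a substitution.

### Alignment

`global_align()` is an affine-gap Needleman–Wunsch over BLOSUM62 with
gap open −10 (the first gap column) and extension −1 (each further
column), end gaps penalized, and a deterministic traceback preference
(match/mismatch, then gap in the first sequence, then gap in the second).
The test suite checks it against an exhaustive enumeration oracle that
scores every monotone alignment of short sequence pairs.

## The synthetic-data generator

`simulate_dataset()` emulates the statistical structure the analysis is
designed to detect, with defaults that are the study conditions:

* 4,000 genes (a scaled-down proteome; the real annotation is ~3.5×
  larger) with branch birth weights proportional to the reported
  per-branch counts, ~79% of genes on the cap branch;
* compartment preferences per age class skewing young genes toward the
  extracellular space (35% primary) and deep-branch genes intracellular;
  a geometric multi-label rate (0.5 for the oldest class down to 0.15 for
  young) that reproduces the broader localization of old genes — about a
  quarter of oldest-class proteins carry more than two compartments;
* probabilities for assigned compartments drawn strictly above 0.5 and
  others strictly below, so the calling rule is unambiguous on synthetic
  data;
* 10,000 interaction edges with within-compartment pairs upweighted 5×,
  scores uniform in [701, 999];
* 50 pathways with a co-function boost of 2 for non-cap branches,
  implemented as adoption of a branch-preferred pathway with probability
  `sqrt((boost − 1)/K)`, which makes the within-branch co-function
  probability ≈ boost/K, i.e. boost × the uniform baseline, while the cap
  branch stays at baseline (matching the observation that the oldest
  genes show no co-function excess);
* per-compartment substitution rates of 0.05 per site (0.15 — 3× — for
  extracellular) applied within sequence families of 2–3 members per
  common ancestor, up to 60 families per compartment, ancestor lengths
  70–110 residues; sequences are emitted for family and paralog genes
  (the divergence and paralog analyses are the consumers of the FASTA);
* 200 paralog pairs with a designated pattern mix (K = 66.7%), offspring
  localization sets constructed to realize the designated pattern and
  offspring sequences derived from the parent (rate 0.03 for K, 3× and
  70% N-terminal-concentrated for non-K);
* a sex-chromosome boost of 1.5 on young-gene chromosome assignment.

Every generator draws from its own substream derived from the master
seed, so adding draws to one generator never perturbs another's output.
What the generator does **not** emulate: realistic protein composition or
structure, genome alignment artifacts, predictor calibration error,
isoform-level effects, or evidence-channel structure in interaction
scores. Passing tests therefore demonstrate that the statistics recover
planted structure of the stated kind at the stated sizes — not that the
biological conclusions hold for any particular real dataset.

## Numerical choices and test calibration

* Reported rates round half away from zero; raw values are kept.
* Strict inequalities at every threshold (0.5 probability, 700 score,
  0.70 masked fraction, "more than 40" clusters) follow the stated rules;
  boundary cases are covered by tests.
* The null (permuted-label) co-localization check calibrates its
  tolerance with a permutation-derived standard error: the excess
  statistic fluctuates mainly through the compartment composition of the
  permuted branch (pair counts are quadratic in per-compartment counts),
  so an iteration-only or Poisson-count SE understates the null spread by
  an order of magnitude for large branches and would reject a correct
  null. Branches with fewer than 50 co-localized pairs are excluded from
  that check because the ratio statistic is far from linear there.
* Enrichment null checks use the hypergeometric variance of each cell and
  a 3-SE band, restricted to cells with expectation ≥ 10.
* Problem sizes in the test suite (2,000 genes for recovery, 5,000 for
  null calibration, the default 4,000-gene conditions across a three-seed
  ladder for directional recovery) were chosen so the full suite runs
  comfortably on a laptop-class single core.

## Known limitations

* The greedy clustering is a faithful stand-in for the published
  CD-HIT contract but not a reimplementation of its heuristics; on real
  proteomes the two can split borderline clusters differently.
* `D` from all-pairs pairwise alignments can differ slightly from an
  MSA-column definition for gappy clusters.
* The co-function expectation inherits the single-membership Σ P²
  simplification; with heavily multi-annotated proteins the expected
  counts are conservative.
* Dataset-dependent headline values from any particular real study
  (concordance percentages, observed K fractions, regression
  coefficients, extreme rank-sum p-values) depend on external genomes and
  annotations and are not reproduced here; the package validates the
  operations that produce them via oracle equivalence and synthetic
  recovery instead.
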