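# subcellevo

Gene age dating and the evolution of protein subcellular localization.

`subcellevo` is an R package for studying how the age of a gene — the
phylogenetic branch on which it originated — relates to where its protein
lives in the cell. It implements, as reusable and tested components, a
complete analysis pipeline of the kind used for *Drosophila melanogaster*
phylostratigraphy:

* **Parsimony gene-age dating.** Given a gene × outgroup-clade
  presence/absence matrix of syntenic orthologs and an ordered clade map,
  each gene is assigned the branch implied by the oldest-diverging clade
  that retains an ortholog (`assign_age()`, `assign_ages()`), with a
  secondary-outgroup correction for gene loss (`apply_loss_correction()`),
  a masked-exon reliability filter, and fixation-rate arithmetic
  (rate = (births − deaths) / branch span, in genes per million years).
* **Localization calling and enrichment.** DeepLoc-2.0-style probability
  tables are thresholded at 0.5 (strict) into multi-label compartment
  calls over nine compartments; per-branch excess over the random
  expectation `E[b, c] = total_c · n_b / N` is reported with Fisher exact
  tests, at nine-compartment or intracellular/membrane/extracellular
  resolution, plus localization breadth by age class.
* **Co-localization and co-function statistics.** Resampling excess of
  same-compartment pairs within a branch against equal-size samples of
  cross-branch pairs (100 iterations, two pooling strategies), and the
  Σᵢ P²(Kᵢ) co-function expectation with observed/expected excess per
  branch.
* **Interaction density by compartment.** STRING-style physical links
  (score > 700) summarized as average interactions per gene within and
  between the nine compartments, and a within-/between-compartment (WC/BC)
  sampling simulation with a rank-sum comparison.
* **Sequence divergence by compartment.** CD-HIT-style greedy identity
  clustering (0.5 identity over the shorter sequence, 3-mer prefilter),
  cluster filters, and the average pairwise divergence D per
  single-compartment cluster.
* **Paralog relocalization.** Duplication-age classification
  (ancient/recent), the K / KE / S / E / SE partition of localization
  changes between parent and offspring genes, pattern spectra, and K vs
  non-K sequence similarity and mutation-position comparisons built on an
  affine-gap Needleman–Wunsch aligner (BLOSUM62, −10/−1).
* **A seeded synthetic-data generator** (`simulate_dataset()`) that
  emulates all six input classes — presence matrices, localization
  probability tables, physical-link files, pathway annotations, paralog
  tables, protein FASTA, plus a toy GTF — with controllable branch birth
  weights, outgroup loss, compartment preferences, within-compartment edge
  preference, co-function boost, and compartment-dependent substitution
  rates, retaining ground truth for recovery testing.

## Worked example

```r
library(subcellevo)

# fixation rates from per-branch gene counts and branch spans
fixation_rate(1134, span = 62)$reported   # 18 genes/MY on the young branches
fixation_rate(714, 218, 7)$reported       # 71 genes/MY, loss-corrected

# a full synthetic run
res <- run_pipeline(default_run_config(seed = 1))
enr <- res$enrich$compartment$table
subset(enr, group == "br4" & compartment == "Extracellular")
```

On the default synthetic conditions (4,000 genes, young genes skewed
extracellular), a seed-1 run prints, among other things:

```
young_extracellular_excess_percent : 106.0
wc_over_bc_frequency_ratio         : 2.13
extracellular_mean_divergence      : 0.282   (rank 1 of 6 compartments)
paralog_k_fraction_percent         : 71.9
```

meaning: proteins of young genes are observed in the extracellular space
about twice as often as random localization predicts; within-compartment
interactions are about twice as frequent per gene as between-compartment
ones; extracellular protein clusters are the most diverged; and ~72% of
paralog pairs keep identical localization (the generator designates 66.7%,
recovered within multinomial noise).

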