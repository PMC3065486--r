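# bcaudit

Species-discrimination audits for DNA barcode reference libraries.

A barcode reference library links a standardised marker — for animals,
~658 bp of mitochondrial COI — to named species so unknown specimens can
be identified by sequence. Before such a library is used for
biodiversity monitoring or invasive-species detection, it has to be
audited: which species does the marker actually diagnose, where do
barcodes fail (shared haplotypes, para-/polyphyly, overlapping
clusters), and which species hide deep divergences that may be cryptic
species? `bcaudit` implements that audit for aligned COI barcodes, for
curators of regional reference libraries and for anyone validating
barcode-based identification.

## What it computes

* **Kimura 2-parameter distances** with pairwise deletion,
  `d = -½ ln[(1 − 2P − Q)·√(1 − 2Q)]`, where `P` and `Q` are the
  transition and transversion proportions over sites unambiguous in both
  sequences; comparable-site counts are kept per pair.
* **Neighbour-joining tree** (Saitou–Nei criterion, reproducible
  tie-breaking, negative branches clamped and logged), outgroup or
  midpoint rooting, Newick export with proper label quoting.
* **Per-species diagnosability**: success requires a monophyletic
  cluster and no haplotype shared with another species; failures are
  classified as paraphyletic, polyphyletic, identical, overlapping, or
  identical-and-overlapping via a documented decision cascade.
* **Deep intraspecific splits**: single-linkage clusters at a divergence
  threshold (default 3%), with per-species cluster sizes (`"1/20"`
  style) and mean divergence.
* **Barcode-gap summaries**: intra- vs congeneric-interspecific
  divergence distributions, histograms, global means and ranges.
* **Sampling-bias regression**: OLS of mean intraspecific divergence on
  individuals sampled, with the slope t-test.
* **A seeded community simulator** with ground-truth labels (shared
  haplotypes, paraphyly, 2-/3-cluster deep splits) so every stage is
  testable without real data.

## Worked example

```r
library(bcaudit)
sim <- simulate_community(n_genera = 25, n_shared_haplotype = 2,
                          n_paraphyly = 2, n_deep_split_2 = 4,
                          n_deep_split_3 = 1, seed = 42)
audit <- barcode_audit(sim$dataset, outgroup = sim$outgroup)
summary(audit)
```

```
Barcode library audit
  654 specimens, 99 species, 25 genera; alignment 658 bp
  diagnosable species: 93/99 (93.9%)
  deep splits (>3%): 7 species

Conditions:
  DISTINCT                   78
  SINGLETON_DISTINCT         15
  PARAPHYLETIC               2
  IDENTICAL_SHARED           4

Divergence summary (K2P, %)
  intraspecific: mean 0.98% (range 0.00-9.71), 4176 comparisons in 84 species
  congeneric:    mean 10.28% (range 0.00-21.57), 8578 comparisons
  fold ratio (congeneric/intraspecific): 10.5

Sampling-bias regression (mean intraspecific % ~ n):
  OLS: slope 0.006348, intercept 0.862, R^2 = 0.002, P = 0.719 (n = 84)

Deep intraspecific splits:
       species n_specimens cluster_sizes mean_intra_pct
 Genus004 sp01           8         3/4/1       4.667010
 Genus005 sp02          13          1/12       1.805605
 ...
```

Reading: 93 of 99 species (93.9%) are diagnosable by barcode — they form
non-overlapping monophyletic clusters (15 of them untested singletons).
The two injected paraphyly pairs and two shared-haplotype pairs are
recovered as the 2 + 4 failing species. Congeneric divergence is ~10×
intraspecific, the barcode gap that makes identification work, and the
flat regression (P = 0.72) shows sampling effort does not bias apparent
intraspecific variation. The deep-split table lists species whose
specimens break into clusters more than 3% apart — candidate cryptic
species, including the injected `3/4/1` three-cluster case.

For file-based libraries:

```r
audit <- run_pipeline(fasta = "barcodes.fasta", metadata = "specimens.tsv",
                      out_dir = "audit_out", outgroup = "Callizzia amorata")
```

writes the full bundle: `qc_report.tsv`, `assessments.tsv`,
`deep_splits.tsv`, `histogram.tsv`, `regression.tsv`, `tree.nwk`,
`summary.json`.

## Documentation

The methods vignette (`vignettes/barcode-library-audit.Rmd`) describes
the model, the classification cascade, the generator's assumptions and
the package's numerical choices in detail.
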