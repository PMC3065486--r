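---
title: "Auditing a DNA barcode reference library with bcaudit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing a DNA barcode reference library with bcaudit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcaudit)
```

## The problem

A DNA barcode reference library maps a standardised marker — for animals,
~658 bp of mitochondrial COI — onto named species, so that an unknown
specimen can be identified by sequence similarity. The library is only as
good as the discrimination it affords: if two species share barcodes, or
one species' barcodes are scattered among a congener's on the tree, the
marker cannot diagnose them. `bcaudit` implements the standard audit of
such a library for a regional fauna: it quantifies the separation of
intra- and interspecific variation (the *barcode gap*), classifies every
species' diagnosability, flags deep intraspecific splits that may hide
cryptic species, and checks whether sampling effort biases the apparent
intraspecific variation.

The audit operates on aligned sequences plus a specimen metadata table
(specimen, genus, species, region). COI barcodes are effectively
indel-free in most insect groups, so alignment is assumed done; the
package deliberately contains no aligner.

## Model and procedure

**Distances.** Pairwise divergence uses the Kimura 2-parameter model,
which separates transitions (A↔G, C↔T) from transversions. With *P* and
*Q* the proportions of comparable sites differing by a transition and a
transversion,

$$d = -\tfrac12 \ln\!\big[(1 - 2P - Q)\sqrt{1 - 2Q}\big].$$

Comparable sites are those where both sequences carry an unambiguous
A/C/G/T (*pairwise deletion*). We chose pairwise over complete deletion
because real libraries mix full-length barcodes with short
"mini-barcode" rescues from old specimens (down to ~238 bp); complete
deletion would discard most of the alignment for every pair. The
comparable-site count is retained per pair. Two numerical policies
matter: a pair whose substitution proportions leave the model's domain
(log argument ≤ 0) is an *error*, not a clamped or `NaN` value — silent
clamping would corrupt the divergence histograms; and a pair with zero
comparable sites is likewise an error naming the pair. No
gamma-rate correction and no other substitution models are offered: the
audit replicates the field's standard K2P convention.

**Tree.** Neighbour joining on the distance matrix, with the
rate-corrected criterion $Q(i,j) = (r-2)\,d(i,j) - R_i - R_j$. Ties on
$Q$ (measure-zero for real data, common in toy examples) are broken by
the lexicographically smallest active-node pair, so runs are exactly
reproducible. NJ can produce negative branch lengths; these are clamped
to zero with the deficit transferred to the sister branch (preserving the
joined pair's path length) and the pre-clamp values are logged on the
returned tree. Rooting uses a designated outgroup when one is supplied —
regional barcode surveys typically carry a sister-family representative
for this — and midpoint rooting otherwise; the choice is recorded
because it can shift paraphyly/polyphyly labels in pathological cases.
The diagnosability logic itself reads only the unrooted topology
(bipartitions), so rooting affects just the congener-counting step and
reporting.

**Diagnosability.** A species is successfully discriminated when its
barcodes form a monophyletic cluster and are shared with no other
species. Monophyly on the unrooted tree means some single edge separates
exactly the species' leaves. Haplotype *sharing* means identity at every
site where both sequences are unambiguous, **and** at least a floor of
comparable sites (default 400): without the floor, a 238-bp fragment
would "match" any sequence it happens to agree with over its short span,
and a single N would break a true full-length match under strict string
equality.

Failures are assigned one of five conditions. The verbal definitions
used in barcode audits (paraphyletic with one congener; polyphyletic
with several; identical barcodes; overlapping barcodes; identical and
overlapping) are not operational, so the package fixes a decision
cascade, documented here as an interpretation:

1. one specimen, no sharing → `SINGLETON_DISTINCT` (a success, but
   untested by replication — without a second specimen monophyly cannot
   fail, so singletons can only fail by identity);
2. monophyletic, no sharing → `DISTINCT`;
3. sharing *and* still non-monophyletic after removing every specimen
   involved in a cross-species identical pair →
   `IDENTICAL_AND_OVERLAPPING` (the blending is not attributable to the
   shared haplotypes alone);
4. sharing otherwise → `IDENTICAL_SHARED`;
5. otherwise non-monophyletic: root the tree, take the MRCA of the
   species' leaves and collect other species with leaves inside it —
   exactly one, itself monophyletic → `PARAPHYLETIC`; two or more →
   `POLYPHYLETIC`; exactly one with mutual non-monophyly →
   `OVERLAPPING`.

Counting singletons as successes is deliberate: excluding them would
make the headline success proportion unreachable for any library with
substantial singleton representation, and reports carry their count so
readers can discount them.

**Deep splits.** Species whose intraspecific divergence exceeds a
threshold (default 3%, a conventional value that generally falls inside
the barcode gap) are flagged as candidate cryptic species or
misidentifications. Clusters are formed by single-linkage chaining at
the threshold — specimens joined by any chain of pairwise distances ≤
threshold share a cluster — because this reproduces "individuals per
lineage" partitions from distances alone, without depending on the
tree's arbitrary resolution of star-like radiations. The per-species
mean divergence reported alongside is the mean over *all* intraspecific
pairs, not between-cluster pairs only; this choice is recorded in the
report metadata. The threshold comparison is strict (`>`).

**Sampling bias.** Ordinary least squares of per-species mean
intraspecific divergence on the number of individuals sampled, excluding
singletons (their mean is undefined), with a two-sided t-test on the
slope. A flat slope supports the adequacy of sampling effort across
taxa.

## The synthetic community generator

Real reference libraries are large and access-controlled, so the
package ships a generator that emulates the statistical shape of a
regional moth library and carries ground-truth labels:

* 125 genera with 1 + Poisson species each (mean 3.2, ≈400 species);
* specimens per species 1 + geometric with mean 6, truncated at 46 —
  a strongly skewed sampling-effort distribution with many singletons;
* 658 bp sequences evolved site-independently under the K2P process
  (default κ = 4, a typical mitochondrial transition bias);
* species ancestors star-like around each genus ancestor at the
  congeneric scale (default mean 9%), specimens star-like around the
  species ancestor at the intraspecific scale (default mean 0.56%),
  with unit-mean lognormal branch scatter;
* genera radiate from a single family root (branch 0.08
  substitutions/site) so cross-genus distances stay inside the K2P
  domain, and one deeply divergent outgroup lineage is included for
  rooting, as real surveys do.

Failure scenarios are injected last and recorded in a truth table:
shared-haplotype pairs (copy one specimen's sequence into a congener),
paraphyly pairs (the host species gets a basal subgroup plus a derived
lineage, and the nested congener radiates tightly inside that derived
lineage, so the host brackets it on the tree), and deep splits with 2 or
3 intraspecific subclusters separated by ~6% expected divergence —
comfortably past the 3% flag with zero chaining risk. Default injection
counts (5 shared pairs, 8 paraphyly pairs, 22 two-cluster and 4
three-cluster splits) mirror the published failure profile of a
comprehensive regional Geometridae library.

What the generator does *not* emulate — and therefore what passing
recovery tests do not show about real data: within-genus phylogenetic
structure (species ancestors are star-like), rate variation across
sites and lineages, indels, misidentified vouchers, geographic
population structure, and polyphyly/overlap scenarios beyond the
injected ones. The generator validates the *logic* of the pipeline, not
the biology of any particular fauna.

## Numerical and design choices

* Distances are stored as proportions and rendered as percent only in
  reports.
* Quality flags use the inclusive boundary (unambiguous length ≥ 500)
  and never filter: short records are retained everywhere, flagged as
  below the community data standard.
* Ambiguity codes other than N (R, Y, …) are kept in sequences but
  count as ambiguous both for quality length and pairwise deletion; the
  gap character behaves the same.
* `n = 2` and `n = 3` trees degenerate to a single split edge and a
  closed-form star.
* Monophyly of a singleton is true by convention; the complement of a
  singleton is likewise always monophyletic (terminal edge).
* All randomness flows through R's RNG; `simulate_community(seed = )`
  makes communities byte-reproducible, and report bundles contain no
  timestamps, so identical configurations diff cleanly.

## Validation problem sizes

The test-suite and acceptance checks use: exact-oracle comparison of the
K2P kernel on random 30–658 bp pairs; NJ consistency on 200 additive
matrices from random binary trees (n ≤ 12) plus agreement with a naive
NJ re-implementation on noisy matrices (n ≤ 25); recovery of injected
condition labels and cluster counts on 20 seeded communities of 50
genera / ~150 species at the default divergence scales (≥95% required);
OLS agreement with a matrix-algebra oracle and an empirical size check
of the slope test over 500 null replicates. These sizes give stable
pass/fail behaviour while keeping a full run in the low minutes on a
single core.

## Known limitations

* The paraphyly/polyphyly/overlap cascade is a reproducible proxy for
  judgements historically made by eye on large NJ trees; borderline
  topologies (e.g. a species spanning the midpoint root) can shift
  between `PARAPHYLETIC` and `POLYPHYLETIC`.
* Whether public barcode platforms use pairwise or complete deletion for
  their K2P summaries is not documented; replication of published
  summary decimals can therefore differ in the second decimal place.
* No bootstrap support, no likelihood or Bayesian trees, no algorithmic
  OTU delimitation (ABGD/ASAP/GMYC-style) — the audit reproduces the
  threshold-and-monophyly procedure only.

## A worked run

```{r example, eval = FALSE}
library(bcaudit)
sim <- simulate_community(seed = 1)         # study-scale community
audit <- barcode_audit(sim$dataset, outgroup = sim$outgroup)
summary(audit)
plot(audit)
write_audit_reports(audit, "audit_out")     # TSV/Newick/JSON bundle
```

For file-based data the entry point is
`run_pipeline(fasta, metadata, out_dir = ...)`, which reads, audits and
writes the same bundle in one call.
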