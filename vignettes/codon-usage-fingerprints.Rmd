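---
title: "Codon usage fingerprints: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Codon usage fingerprints: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonfp)
```

## The quantity being computed

With the exception of methionine (AUG) and tryptophan (UGG), every amino
acid is encoded by 2, 3, 4 or 6 synonymous codons. The codon usage (CU)
value of a codon in a gene is its count divided by the total count of all
synonymous codons of the same amino acid in that gene. Normalization is done
independently within each amino-acid family, so CU values measure codon
*choice* conditional on protein composition, not amino-acid abundance.
Excluding Met and Trp (whose CU value would always be 1) and the stop
codons leaves 18 degenerate families covering 59 sense codons; these 59
values form a gene's CU vector. Stop-codon usage is tracked separately, as
the frequency of UAA/UAG/UGA among terminal stops of a cohort.

A **zero-codon** is a sense codon with zero occurrences — codon usage bias
(CUB) at its extreme. Two policies are exported because "unused" is
ambiguous for genes that lack an amino acid entirely:

* `family_present` (default): a codon counts as a zero-codon only when its
  amino acid does occur in the gene. An absent family reflects protein
  composition, not codon choice, so its codons are not "avoided".
* `raw`: every unused sense codon counts.

The distinction matters for monotonicity too: under `raw`, extending a CDS
can only remove zero-codons, while under `family_present` the first codon
of a previously absent family *creates* zero-codons (the family's other
members become visible as unused). Both behaviors are property-tested.

**Extremely biased codons** generalize zero-codons to a threshold: codon
`c` in a family of degeneracy `d` is flagged when `cu(c) < t(d)`. The
default `t(d) = 0.5/d` — half the uniform expectation, i.e. 0.25, 0.167,
0.125, 0.083 for `d` = 2, 3, 4, 6 — is a natural redundancy-based rule; it
is exposed per degeneracy (`cutoff = c("2" = 0.25, ...)`) because published
analyses of this kind cite external cutoff conventions without a single
agreed value.

## Fingerprints and clustering

A cohort's **CUB fingerprint** is its genes × 59-codon CU matrix. Rows are
listed in decreasing exon-count order (ties broken by gene id) — the
display convention for this analysis family — and columns in a fixed
canonical order (families alphabetical by amino acid, codons alphabetical
within family). Cells of absent families are stored as 0 with a parallel
mask: on a heat map such cells render as the lowest color, and the mask
lets a user re-run with another imputation if their data have many short
genes. Distances are plain Euclidean on rows or columns; clustering is
complete-linkage agglomeration (`hclust`'s "complete" method), whose merge
heights are monotone. Dendrograms export as Newick with heights as branch
lengths. The package does not try to reproduce any particular heat-map
aesthetic; the matrix, mask and trees are the interface, and any heat-map
package (`pheatmap`, `ComplexHeatmap`, `stats::heatmap`) can render them.

## Cohort comparisons

Per-codon differences between two gene groups (disease-causing vs
non-disease-causing, tissue vs tissue) use the two-sided Wilcoxon rank-sum
test on the codon's CU values across genes, with masked cells dropped. The
p-value is exact (full enumeration) when the combined sample size is at
most 12 with no ties — where enumeration is cheap and unambiguous — and
otherwise uses the normal approximation with midranks, tie-corrected
variance and continuity correction. Codons with `p < alpha` (default 0.05,
raw) are prioritized by ascending p. Raw thresholding is the default
because it matches common practice in this analysis family; since 59
simultaneous tests invite correction, a Benjamini–Hochberg mode
(`adjust = "BH"`) is provided and documented, off by default. Agreement
between cohorts is summarized by Spearman correlation on midranks with the
two-sided t-approximation p-value; zero-variance input yields `NA` with a
warning rather than a fabricated rho.

## Mapping-on-codons

Coding substitutions (1-based CDS coordinates, HGVS `c.` numbering; no
genomic arithmetic anywhere) are placed on the codon containing them:
`codon_number = floor((pos-1)/3)+1`, `offset = (pos-1) mod 3`. Each variant
is validated against the CDS — out-of-range positions and reference
mismatches are excluded with explicit reasons — and classified by
translating the substituted codon: sense→stop is nonsense, stop→sense is
stop-loss, unchanged product is synonymous, any other change is missense.
Tallies accumulate at the *reference* codon type (the mutated site), for
missense and nonsense changes only; synonymous and stop-loss variants are
excluded with their own reasons so the scope can be widened later without
structural change. The burden table joins, per codon type, the raw count,
its share of all accepted variants, and the occurrence-normalized rate
(count per occurrence of the codon in the CDS) with the gene's CU values;
whether burden tracks usage is reported (e.g. as a Spearman rho), never
asserted, because the two normalizations can rank codons very differently.

## The synthetic cohort generator

`generate_cohort()` emulates the structure the analysis assumes: each gene
draws a length (default 300–1500 codons, typical of tissue-specific disease
genes), amino acids i.i.d. from a composition over the 18 considered
families (default uniform), each codon from its family's preference vector,
then prepends AUG and appends a stop drawn from a stop distribution
(default uniform over UAA/UAG/UGA). Injected zero-codons get preference
mass 0, giving exact ground truth for zero-codon detection. Everything is a
pure function of spec + seed.

`generate_fingerprint_pair()` creates the study contrast used throughout
the tests: a low-bias cohort with uniform preferences (disease-causing-like
— full codon redundancy in use) against a high-bias cohort concentrating
mass 0.9 on one preferred codon per family (non-disease-causing-like). At
the default study scale (20 genes × 400 codons per cohort), a
degeneracy-6 family shows each non-preferred codon ~0.02 per site, so
high-bias genes carry many zero-codons while low-bias genes carry few —
the generator-level analogue of the observation that disease gene cohorts
retain multiple codon usage while matched non-disease cohorts do not.

What the generator deliberately does **not** emulate: phylogenetic
correlation between species cohorts (each cohort is independent;
cross-species conservation can be imitated only by sharing preference
vectors), amino-acid composition differences between cohorts, length–bias
correlations, and GC-content gradients. Passing tests therefore show the
pipeline recovers known structure of this kind; they do not certify
behavior on real genes, where composition and bias are confounded.

`generate_variants()` samples variant sites with probability proportional
to `intensity(codon type) × occurrences`, then a uniform missense- or
nonsense-producing substitution within the codon (every sense codon has at
least one such substitution in the standard code), recording exact
per-codon-type tallies. `map_variants()` must reproduce them exactly — the
round-trip is part of the acceptance suite.

## Numerical and design choices

* **Canonical spelling is RNA**; DNA input (`T`) is transliterated on
  ingestion, outputs always print RNA codons. Ambiguity codes (`N`, ...)
  do not reject a gene: the containing codon is excluded from counts with
  a warning, preserving the rest of the sequence.
* **18 considered families.** Excluding Met and Trp from the 20 amino
  acids leaves 18 families over 59 sense codons (61 − AUG − UGG).
  Literature in this area sometimes states "19 amino acids" for the same
  59-codon analysis; the arithmetic supports 18, which is what the package
  documents and tests.
* **Validation.** CDS length must be a multiple of 3; internal in-frame
  stops are errors (downgradeable to warnings with `permissive = TRUE`
  for dumps known to contain read-through annotations). The terminal stop
  is optional; genes without one simply leave the stop-usage denominator.
* **Isoform selection** keeps the longest CDS per (gene, species), ties
  broken by the lexicographically smallest accession — deterministic
  across platforms.
* **Clustering ties.** `hclust` resolves equal-distance merges by its own
  deterministic rule; merge heights (the quantity tested against a naive
  agglomeration oracle) are unaffected by tie order on continuous data.
* **Family normalization tolerance** is exact to floating point: CU values
  of a present family sum to 1 within 1e-12, enforced in tests.
* **Problem sizes.** The validation suite runs the counting oracle on 1000
  random CDS of 2–2000 codons, the clustering oracle on 200 instances with
  up to 12 leaves, null calibration of the rank-sum wrapper on 5000
  replicates of 20 vs 20, and 100 seeded fingerprint replicates at the
  20 × 400 study scale — sizes chosen so the whole suite completes in
  about a minute on a laptop while keeping Monte Carlo noise well below
  the asserted margins.

## Worked example

```{r example}
fa <- system.file("extdata", "toy_cds.fasta", package = "codonfp")
md <- system.file("extdata", "toy_metadata.tsv", package = "codonfp")
cds <- select_longest_isoform(read_cds_fasta(fa, md))
prof <- cu_values(count_codons(cds[cds$gene_id == "TOYA", ]))
prof$cu["CUG"]                 # the only Leu codon in use
zero_codons(count_codons(cds[1, ]))$zero_codons
```

A full run — synthetic or file-driven — goes through `run_pipeline()`,
which writes the per-gene CU table, the fingerprint matrix, gene and codon
dendrograms (Newick), the zero-codon cohort table, differential-codon
results and (with variants) the mutation burden and exclusion tables, plus
a JSON manifest; identical config and seed give byte-identical outputs.

## Known limitations

* Cohort composition (which genes are DC vs NDC, tissue labels, expression
  classes) is caller-supplied metadata; the package takes no position on
  gene curation.
* The rank-sum exact/approximate switch at combined n = 12 is a
  convenience threshold, not an optimality claim; near the boundary the
  two routes can differ in the third decimal.
* Masked cells enter Euclidean distances as 0; cohorts with many absent
  families (very short genes) will cluster partly by family presence. The
  mask is exported precisely so users can check and re-impute.
* The optional dystrophin check (`scripts/fetch_dmd.R` +
  `cds_bias_summary()`) needs network access to fetch the reference CDS
  and is therefore not part of the default test suite.
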