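---
title: "Measuring relative X expression: models, treatments and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring relative X expression: models, treatments and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rxekit)
```

## The model

Dosage compensation asks whether genes on the single active X chromosome
are expressed at the level of the diploid autosomes. With expression in
FPKM, the package works on the log2 scale and defines relative X expression
as

$$\mathrm{RXE} = s\big(\log_2 \mathrm{FPKM}_X\big) - s\big(\log_2 \mathrm{FPKM}_A\big),$$

where $s$ is the mean (default) or median, the X side runs over X-linked
genes, and the autosomal side pools the gene-level values of all autosomes
with equal gene weight. RXE = 0 means compensation, RXE = −1 means X
expression at half the autosomal level, and $2^{\mathrm{RXE}}$ is the
linear X:A ratio. The Y chromosome and the mitochondrial genome are
excluded before any computation.

Log2 transformation is not cosmetic: raw FPKM distributions pile up near
zero, so moment-based summaries are dominated by a handful of highly
expressed genes and by how the low tail is truncated. On the log scale the
distributions are near-normal and the mean is a stable location estimate.

### A-side pooling

The autosomal reference pools genes rather than averaging per-chromosome
means. Pooling weights every autosomal gene equally, which matches the
mean-of-log-FPKM framing of the statistic; a gene-rich chromosome should
count for more than a gene-poor one. `chromosome_relative_expression()`
provides the complementary view — each chromosome against the pooled rest,
leave-one-out for autosomes — which places the X value inside the natural
chromosome-to-chromosome variation.

## Treatments

`treatment_spec()` fixes the treatment pipeline order: prefilter, zero
policy, log2, outlier policy.

* **Zeros.** `drop_zeros` (default): log2(0) is undefined and the natural
  gene universe is genes with FPKM > 0. A pseudocount mode
  (`log2(FPKM + eps)`) is available for sensitivity analysis; it mostly
  relocates the zero spike rather than removing the problem.
* **Outliers.** Tukey fences at $[Q_1 - k\,\mathrm{IQR},\; Q_3 +
  k\,\mathrm{IQR}]$ with $k = 1.5$, computed from box-plot hinges (medians
  of the half-samples, median included in both halves for odd n) — the
  convention box plots actually draw. The fence interval is closed, so
  constant data lose nothing. Quartiles by linear interpolation (type 7)
  are available via `quartile_method = "quantile"`. The default scope is
  per chromosome, because the distributions being summarized (and plotted)
  are per-chromosome; whether outlier removal should instead be global over
  the dataset is genuinely open, so both scopes are implemented and the
  choice is recorded in the result's treatment provenance.
* **Prefilters.** `min_fpkm` (conventional thresholds 1 or 3) and
  `zero_balanced_trim` — count the zeros, drop them, and drop an equal
  number of the largest values — reproduce trimming schemes used in the
  dosage-compensation literature. They are applied over the whole table
  (they are dataset-level schemes, not per-chromosome ones) and are
  deliberately *alternatives* to distribution-based outlier removal: each
  published scheme was a complete strategy, and composing them would blur
  the comparison the package exists to make.

Expression-level trimming is biased whenever compensation status correlates
with expression level. If the X carries the heavier low-expression tail —
exactly what an uncompensated X produces — removing low-FPKM genes removes
proportionally more X genes and pushes RXE toward compensation. The test
suite asserts this direction on simulations with a planted ratio of 0.5.

## Mapping policies

`assign_fragments()` abstracts the alignment step down to the decision that
matters for chromosome-level statistics: what happens to a fragment that
maps to several genes, or across an exon junction.

* `UNIQUE` discards multi-mapped and junction-spanning fragments.
* `NONUNIQUE` discards junction fragments (the aligner is unspliced) and
  assigns each multi-mapped fragment wholly to one candidate chosen
  uniformly at random. In the simulation all family copies align equally
  well by construction, so the uniform choice is the faithful limit of
  best-hit tie-breaking; modeling mismatch or quality-score ranking would
  add machinery without changing the chromosome-level behavior. A
  `report_cap` parameter (default infinite) discards fragments whose
  ambiguity set exceeds an aligner's reporting cap; simulated family sizes
  are far below the caps real aligners use, so it is off by default.
* `NONUNIQUE_SPLICED` keeps junction fragments and splits a k-fold
  ambiguous fragment as 1/k per candidate — the standard equal division of
  multi-mapped reads. It conserves count mass exactly.

Because paralog families are enriched on the X (roughly two-fold in human),
unique-only mapping discards disproportionately many X fragments and biases
RXE downward; the non-unique policies rescue them. Random whole-fragment
assignment and 1/k splitting agree in expectation, but the random policy
adds per-gene variance which the concavity of the log converts into a small
downward bias, so the expected ordering of mean RXE is
UNIQUE < NONUNIQUE ≤ NONUNIQUE_SPLICED. The suite checks this over 20
simulation seeds.

## The synthetic-data generator

The generator emulates the statistical structure the analysis is sensitive
to, not sequencing mechanics. No sequences, alignment scores or error
models are produced; a "mapped library" is a table of fragments with a
source gene, an ambiguity set, and a junction flag.

* **Catalog** (`generate_catalog`): `n_autosomes` autosomes plus an X;
  exon counts and summed exon lengths uniform over configurable ranges;
  biotypes drawn from a four-class mix (protein-coding, small RNA,
  riboprotein, other). Paralog families of fixed size are placed so that
  the X paralog-member fraction is `paralog_x_enrichment` times the
  autosomal fraction; `cis_fraction` of X families keep all members on the
  X, the rest place one member on X with partners spread uniformly over
  autosomes. Family similarity is uniform over `similarity_range`
  (bounded below by the 0.70 identity cutoff conventionally used to call
  paralogs), and the fraction of a member's sequence shared with its
  family — the cross-mapping probability — defaults to
  `(similarity − 0.70)/0.30`, a monotone map sending the cutoff to no
  ambiguity and identity to full ambiguity. Nothing quantitative is known
  about this relationship beyond monotonicity, so the simplest monotone
  map is used and is overridable per family.
* **Expression** (`simulate_true_expression`): log2 abundance per gene is
  normal with mean `log2_mean` and sd `log2_sd` (default 2, giving the
  heavy low-expression tail real FPKM distributions show), scaled by exon
  length so FPKM recovers molarity, by the compensation parameter
  `x_to_a_ratio` on the X, and by the protocol's biotype factor. The
  baseline draw is centered within the X and within the autosomes so that
  the configured ratio is the *realized* catalog offset: in a finite
  catalog the raw-draw offset fluctuates by `log2_sd / sqrt(n_x_genes)`
  (≈ 0.06 at 1,000 X genes), which would make the compensation parameter a
  random variable rather than a study condition.
* **Fragments** (`sample_fragments`): multinomial over abundances;
  ambiguity is a per-fragment Bernoulli with the family's shared-sequence
  fraction — the analysis depends on which policy keeps, drops or splits
  ambiguous fragments, not on alignment mechanics. Junction spanning uses
  the uniform-start approximation
  `min(1, (n_exons − 1)(fragment_length − 1)/exon_length_bp)`.
* **Protocol biases**: ribo-depletion libraries enrich small RNAs (default
  factor 8) and poly-A selection enriches riboprotein transcripts (factor
  8) while suppressing non-polyadenylated small RNAs (factor 0.05). The
  factors reproduce the qualitative composition differences seen between
  the two preparation chemistries in top-expressed-gene tallies; poly-A
  3'-bias has no quantitative model and is represented only through these
  biotype-level multipliers.

Every stage draws from an RNG stream derived from `(seed, stage name)`, so
each stage is independently reproducible and adding a stage never perturbs
another's draws.

What passing simulations do *not* show: real libraries have correlated
gene expression, positional coverage bias, annotation errors, and
alignment-score structure none of which are modeled. The simulator
demonstrates that the pipeline responds to planted structure in the
documented direction and magnitude; it cannot certify real-data estimates.

## Numerical choices and problem sizes

* FPKM uses the fragments retained *after* policy assignment as its
  denominator; discarded fragments are unmapped.
* The annotation-free read-weighting estimate divides each chromosome's
  assigned reads by its gene count and contrasts log2 of the X value with
  the log2 mean of the autosomal values; its exact averaging order is
  stated ambiguously in the literature it mirrors, and this reading is the
  one consistent with the RXE scale.
* Zero-balanced trimming breaks ties at the upper cut by input order
  (earliest removed first), making the operation deterministic.
* Top-expressed composition breaks FPKM ties lexicographically by gene id.
* In `rxe_by_group`, a label with no X or no autosomal genes after
  treatment yields `NA`, not an error: sparse gene sets are expected.
* Test and acceptance simulations use 300–20,000 genes and libraries of
  5×10^4 to 5×10^6 fragments. Parameter recovery is assessed at 20,000
  genes and 5×10^6 fragments on a paralog-free, single-biotype catalog
  with `log2_sd = 1.5`: cross-chromosome families under 1/k splitting
  transfer expression between X and autosomes by construction (that policy
  bias is studied separately), and at this depth-to-dispersion ratio the
  zero-truncation bias of the mean-of-log estimator stays well inside the
  ±0.05 recovery band. With the default heavier tail (`log2_sd = 2`) the
  same estimator shows a visible truncation bias at 5×10^6 fragments —
  itself an instance of the detection-limit effects the package measures.

## Known limitations

* Gene-level only; no isoform deconvolution.
* No sequence-level simulation, error models, or positional bias beyond
  biotype multipliers; no BAM/FASTQ input.
* Paralog tables are supplied or simulated, never queried from a database;
  GO-style analyses take user-supplied gene-set maps with no ontology
  traversal.
* The rank-sum comparison (`ranksum_test`) is exact only for tie-free
  samples with `n1*n2 <= 400`; otherwise it uses the tie-corrected normal
  approximation.
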