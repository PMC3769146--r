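# rxekit

Chromosome-level relative X expression (RXE) analysis for RNA-seq.

## The problem

Whether the mammalian X chromosome is dosage-compensated — expressed at the
diploid autosomal level despite being present in a single active copy — is
usually assessed from RNA-seq by comparing X-linked to autosomal expression.
Published analyses of near-identical data have reached opposite conclusions,
because the answer is remarkably sensitive to analytical choices: how
multi-mapped and junction-spanning reads are handled, which gene annotation
is used, how zeros, outliers and lowly expressed genes are treated, how the
library was prepared, and how deep it was sequenced.

`rxekit` is for researchers who want to measure these effects rather than
inherit them silently. It implements the RXE statistic and every analytical
knob around it, plus a synthetic-data generator with the statistical
structure that makes those knobs matter (a paralog-enriched X, a heavy
low-expression tail, multi-exon genes, protocol-specific biotype
enrichment), so each effect can be reproduced and quantified at desk scale
without any sequencing data.

## The statistic

Gene expression is measured in FPKM (fragments per kilobase of exon per
million fragments mapped). After log2 transformation, relative X expression
is

```
RXE = summary( log2 FPKM, X genes ) − summary( log2 FPKM, pooled autosomal genes )
```

with `summary` the mean (or median). RXE = 0 indicates dosage compensation,
RXE = −1 indicates X expression at half the autosomal level (no
compensation), and the linear X:A ratio is recovered as `2^RXE`.

Around the statistic the package provides:

* **Mapping policies** (`assign_fragments`): `UNIQUE` discards multi-mapped
  and junction-spanning fragments; `NONUNIQUE` assigns a multi-mapped
  fragment wholly to one randomly chosen candidate; `NONUNIQUE_SPLICED`
  keeps junction fragments and splits a fragment mapping to k genes as 1/k
  per gene.
* **Treatments** (`treatment_spec`): zero handling (drop or pseudocount),
  Tukey-fence outlier removal (per chromosome or global, box-plot hinges),
  expression-threshold prefilters (`min_fpkm`, `zero_balanced_trim`), mean
  or median summaries.
* **Quantification** (`fpkm_from_counts`, `chromosome_read_rxe`) and
  **stratification** (`classify_paralog_status`, `rxe_by_group`,
  `paralog_enrichment`, `top_expressed_composition`, `depth_titration`).
* **Simulation** (`sim_config`, `generate_catalog`,
  `simulate_true_expression`, `sample_fragments`) and an experiment driver
  (`run_experiment`) for the policy × treatment × annotation matrix.

## Worked example

Simulate an uncompensated X (true X:A ratio 0.5, so true RXE = −1) on a
genome whose X is two-fold enriched for high-similarity paralog families,
then estimate RXE under all three mapping policies:

```r
library(rxekit)

cfg <- sim_config(x_to_a_ratio = 0.5, paralog_x_enrichment = 2,
                  similarity_range = c(0.85, 1), library_size = 1e6, seed = 20L)
report <- run_experiment(config = cfg,
                         policies = c("UNIQUE", "NONUNIQUE", "NONUNIQUE_SPLICED"),
                         treatments = treatment_spec())
report[, c("policy", "rxe", "n_x", "n_a", "total_assigned", "n_discarded")]
#>              policy    rxe n_x  n_a total_assigned n_discarded
#> 1            UNIQUE -1.641 113 1600         506186      493814
#> 2         NONUNIQUE -0.672 133 1679         658919      341081
#> 3 NONUNIQUE_SPLICED -0.849 148 1965        1000000           0
```

The planted truth is −1. Unique-only mapping discards every ambiguous and
junction-spanning fragment — and discards disproportionately on the
paralog-enriched X — driving the estimate down to −1.64 and dropping a
third of the X genes (113 vs 148 detected). The non-unique policies rescue
those fragments and move the estimate toward, here past, the truth;
single-seed estimates scatter around it.

The same pipeline piece by piece:

```r
catalog   <- generate_catalog(cfg)
abundance <- simulate_true_expression(catalog, cfg)
fragments <- sample_fragments(abundance, catalog, config = cfg)
counts    <- assign_fragments(fragments, "NONUNIQUE_SPLICED")
tab       <- fpkm_from_counts(counts, catalog$annotation)
estimate_rxe(tab, catalog$annotation, treatment_spec())
#> <rxe_result> RXE = -0.8487 (X:A ratio 0.555; mean of 148 X and 1965 autosomal genes) [NONUNIQUE_SPLICED]
paralog_enrichment(catalog$annotation, catalog$families)
#> [1] 2.01
```

Real FPKM tables enter through `read_expression_table()` (TSV:
`gene_id`, `fpkm`) with a GTF/GFF or TSV annotation through
`read_annotation()`, and flow through the identical treatment and
stratification machinery via `run_experiment(tables = ..., annotations = ...)`.

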