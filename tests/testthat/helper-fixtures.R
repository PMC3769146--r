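# Fixtures built in code: tiny annotations, expression tables and simulation
# configs shared across the suite.

tiny_annotation <- function() {
  data.frame(
    gene_id = sprintf("g%02d", 1:9),
    chromosome = c("1", "1", "1", "2", "2", "2", "X", "X", "X"),
    exon_length_bp = c(1000L, 2000L, 1500L, 1000L, 2500L, 800L, 1200L, 900L, 2000L),
    n_exons = c(1L, 3L, 2L, 1L, 5L, 2L, 4L, 1L, 3L),
    biotype = c("protein_coding", "small_rna", "protein_coding", "riboprotein",
                "protein_coding", "other", "protein_coding", "small_rna",
                "protein_coding"),
    stringsAsFactors = FALSE
  )
}

make_table <- function(gene_id, fpkm, ...) {
  expression_table(data.frame(gene_id = gene_id, fpkm = fpkm,
                              stringsAsFactors = FALSE), ...)
}

# Expression table whose log2 values are exactly `x_log2` on X and `a_log2`
# split across two autosomes, against a matching annotation.
log2_fixture <- function(x_log2, a_log2) {
  n_x <- length(x_log2)
  n_a <- length(a_log2)
  chrom_a <- rep(c("1", "2"), length.out = n_a)
  ann <- data.frame(
    gene_id = sprintf("g%03d", seq_len(n_x + n_a)),
    chromosome = c(chrom_a, rep("X", n_x)),
    exon_length_bp = 1000L, n_exons = 1L, biotype = "protein_coding",
    stringsAsFactors = FALSE
  )
  tab <- make_table(ann$gene_id, 2^c(a_log2, x_log2))
  list(annotation = ann, table = tab)
}

no_treatment <- function(summary = "mean") {
  treatment_spec(summary = summary, outlier = "none")
}

small_sim <- function(...) {
  args <- list(n_autosomes = 4L, genes_per_autosome = 100L, n_x_genes = 80L,
               library_size = 5e4)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

# One fragment table built by hand, with explicit ambiguity and junction
# structure: family "famA" = {gA1, gA2} ambiguous, gU unique, gJ junction.
handmade_fragments <- function(n_amb = 3, n_unique = 4, n_junction = 2,
                               family = c("gA1", "gA2")) {
  n <- n_amb + n_unique + n_junction
  df <- data.frame(
    fragment_id = seq_len(n),
    source_gene = c(rep("gA1", n_amb), rep("gU", n_unique),
                    rep("gJ", n_junction)),
    ambiguity_family = c(rep("famA", n_amb), rep(NA_character_,
                                                 n_unique + n_junction)),
    junction_spanning = c(rep(FALSE, n_amb + n_unique), rep(TRUE, n_junction)),
    stringsAsFactors = FALSE
  )
  attr(df, "family_members") <- list(famA = family)
  class(df) <- c("fragment_table", "data.frame")
  df
}
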