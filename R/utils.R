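# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
.biotype_levels <- c("protein_coding", "small_rna", "riboprotein", "other")

# GTF/GFF biotype strings that collapse into the small-RNA class.
.small_rna_biotypes <- c("snoRNA", "miRNA", "snRNA", "scaRNA", "piRNA", "sRNA")

# Collapse arbitrary biotype strings onto the package's four-class vocabulary.
.normalize_biotype <- function(x) {
  x <- as.character(x)
  out <- rep("other", length(x))
  out[x %in% .biotype_levels] <- x[x %in% .biotype_levels]
  out[x %in% .small_rna_biotypes] <- "small_rna"
  out
}

# Chromosome labels excluded before any relative-expression computation.
.excluded_chromosomes <- c("Y", "MT", "M", "chrY", "chrM")

# Deterministic 31-bit string hash; seeds per-operation RNG streams so each
# simulation stage is independently reproducible from (seed, operation name).
.str_hash <- function(x) {
  h <- 0
  for (ch in utf8ToInt(x)) h <- (h * 31 + ch) %% 2147483647
  h
}

.stream_seed <- function(seed, op) {
  as.integer((as.numeric(seed) %% 2147483647 + .str_hash(op)) %% 2147483647)
}

# Evaluate `code` under the RNG stream derived from (seed, op), restoring the
# caller's RNG state afterwards.
with_stream <- function(seed, op, code) {
  withr::with_seed(.stream_seed(seed, op), code)
}

# Default cross-mapping ambiguity for a paralog family: a monotone map sending
# the 70% identity cutoff to zero shared sequence and full identity to 1.
.default_shared_block_fraction <- function(similarity) {
  pmax(0, (similarity - 0.70) / 0.30)
}

.assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
}
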