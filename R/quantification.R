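# Quantification: per-gene counts to FPKM, plus the annotation-free
# chromosome read-weighting estimate of relative X expression.

#' Convert per-gene counts to an FPKM expression table
#'
#' `FPKM_g = count_g * 1e9 / (exon_length_bp_g * total_assigned)`. The
#' denominator is the number of fragments retained after policy assignment —
#' discarded fragments are unmapped, mirroring "per million fragments
#' mapped". Annotated genes with no counted fragments get FPKM 0.
#'
#' @param counts A `fragment_counts` object (see [assign_fragments()]).
#' @param annotation Annotation covering every counted gene.
#' @param protocol,label Metadata forwarded to the [expression_table()].
#' @return An `expression_table` over all annotated genes with
#'   `library_size = total_assigned`.
#' @export
fpkm_from_counts <- function(counts, annotation,
                             protocol = c("ribo_depletion", "polyA"),
                             label = counts$policy) {
  protocol <- match.arg(protocol)
  annotation <- validate_annotation(annotation)
  if (counts$total_assigned <= 0) {
    stop("no assigned fragments: FPKM is undefined", call. = FALSE)
  }
  unknown <- setdiff(names(counts$counts), annotation$gene_id)
  if (length(unknown)) {
    stop(sprintf("counted gene(s) absent from annotation: %s",
                 paste(utils::head(unknown, 5), collapse = ", ")), call. = FALSE)
  }
  cnt <- counts$counts[annotation$gene_id]
  cnt[is.na(cnt)] <- 0
  fpkm <- as.numeric(cnt) * 1e9 /
    (annotation$exon_length_bp * counts$total_assigned)
  expression_table(data.frame(gene_id = annotation$gene_id, fpkm = fpkm,
                              stringsAsFactors = FALSE),
                   library_size = counts$total_assigned,
                   protocol = protocol, label = label)
}

#' Annotation-free chromosome read-weighting RXE estimate
#'
#' Weights each chromosome's assigned read count by its gene count,
#' `w_c = reads_c / n_genes_c`, and returns
#' `log2(w_X) - log2(mean over autosomes of w_c)` — the gene-density-corrected
#' relative X expression computed from mapped reads alone, with no exon
#' annotation of lengths. Y and MT are excluded first.
#'
#' @param counts A `fragment_counts` object.
#' @param annotation Annotation supplying the per-chromosome gene inventory.
#' @return RXE estimate in log2 units.
#' @export
chromosome_read_rxe <- function(counts, annotation) {
  annotation <- validate_annotation(annotation)
  annotation <- annotation[!annotation$chromosome %in% .excluded_chromosomes, ]
  n_genes <- table(annotation$chromosome)
  if (any(n_genes == 0)) stop("chromosome with zero genes", call. = FALSE)
  cnt <- counts$counts[annotation$gene_id]
  cnt[is.na(cnt)] <- 0
  reads <- tapply(as.numeric(cnt), annotation$chromosome, sum)
  chroms <- names(reads)
  if (!"X" %in% chroms) stop("X chromosome absent from annotation", call. = FALSE)
  autosomes <- setdiff(chroms, "X")
  if (!length(autosomes)) stop("at least one autosome required", call. = FALSE)
  w <- reads / as.numeric(n_genes[chroms])
  log2(w[["X"]]) - log2(mean(w[autosomes]))
}
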