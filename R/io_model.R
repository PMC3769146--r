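# Domain types and readers/writers: gene annotations, paralog families,
# expression tables and gene-set maps. All tabular formats are tab-separated
# with "#" comment lines skipped.

#' Validate a gene annotation table
#'
#' An annotation is a plain `data.frame` with one row per gene and columns
#' `gene_id` (unique), `chromosome` (autosome labels, `"X"`; `"Y"`/`"MT"`
#' permitted on input but excluded from analysis), `exon_length_bp` (summed
#' exonic length, >= 1), `n_exons` (>= 1), `biotype` (one of
#' `protein_coding`, `small_rna`, `riboprotein`, `other`) and optionally
#' `paralog_family` (`NA` for singletons).
#'
#' @param annotation A data.frame as described above.
#' @return The validated annotation, invisibly usable downstream.
#' @export
validate_annotation <- function(annotation) {
  .assert_columns(annotation,
                  c("gene_id", "chromosome", "exon_length_bp", "n_exons", "biotype"),
                  "annotation")
  dup <- annotation$gene_id[duplicated(annotation$gene_id)]
  if (length(dup)) {
    stop(sprintf("duplicate gene_id in annotation: %s",
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  }
  if (any(!is.finite(annotation$exon_length_bp) | annotation$exon_length_bp < 1)) {
    stop("exon_length_bp must be >= 1 for every gene", call. = FALSE)
  }
  if (any(!is.finite(annotation$n_exons) | annotation$n_exons < 1)) {
    stop("n_exons must be >= 1 for every gene", call. = FALSE)
  }
  if (is.null(annotation$paralog_family)) annotation$paralog_family <- NA_character_
  annotation$biotype <- .normalize_biotype(annotation$biotype)
  annotation
}

#' Read a gene annotation from GTF/GFF or TSV
#'
#' GTF/GFF input (detected by file extension) is parsed with
#' \pkg{rtracklayer}; exon records are aggregated per `gene_id`, with
#' `exon_length_bp` the length of the union of a gene's exon intervals
#' (1-based inclusive coordinates, the GTF standard) and `n_exons` the number
#' of disjoint exonic blocks after union. Strand is ignored. TSV input must
#' carry columns `gene_id`, `chromosome`, `exon_length_bp`, `n_exons`,
#' `biotype` (and optionally `paralog_family`). Unknown biotype strings
#' collapse to `"other"`.
#'
#' @param path Path to a `.gtf`/`.gff`/`.gff3` file or a TSV.
#' @return A validated annotation data.frame (see [validate_annotation()]).
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop(sprintf("annotation file not found: %s", path))
  if (grepl("\\.(gtf|gff|gff2|gff3)$", path, ignore.case = TRUE)) {
    .read_annotation_gtf(path)
  } else {
    .read_annotation_tsv(path)
  }
}

.read_annotation_tsv <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  validate_annotation(df)
}

.read_annotation_gtf <- function(path) {
  gr <- rtracklayer::import(path)
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "exon"]
  if (!length(gr)) stop("no exon records found in annotation file")
  ids <- as.character(gr$gene_id)
  if (anyNA(ids)) stop("exon record without gene_id attribute")
  by_gene <- GenomicRanges::reduce(GenomicRanges::split(gr, ids))
  exon_length <- sum(GenomicRanges::width(by_gene))
  n_exons <- S4Vectors::elementNROWS(by_gene)
  chrom_by_gene <- vapply(split(as.character(GenomicRanges::seqnames(gr)), ids),
                          function(x) x[[1]], character(1))
  raw_biotype <- gr$gene_biotype %||% gr$gene_type %||% rep(NA_character_, length(gr))
  biotype_by_gene <- vapply(split(as.character(raw_biotype), ids),
                            function(x) x[[1]], character(1))
  genes <- names(by_gene)
  validate_annotation(data.frame(
    gene_id = genes,
    chromosome = sub("^chr", "", unname(chrom_by_gene[genes])),
    exon_length_bp = as.integer(exon_length[genes]),
    n_exons = as.integer(n_exons[genes]),
    biotype = .normalize_biotype(unname(biotype_by_gene[genes])),
    stringsAsFactors = FALSE
  ))
}

#' Write a gene annotation as TSV
#'
#' @param annotation Annotation data.frame.
#' @param path Output path.
#' @export
write_annotation <- function(annotation, path) {
  annotation <- validate_annotation(annotation)
  utils::write.table(annotation, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a paralog family table
#'
#' Long-format TSV with columns `family_id`, `gene_id`, `similarity` (fraction
#' in (0, 1], one value per family) and optionally `shared_block_fraction`
#' (the portion of each member's exonic sequence lying in blocks identical
#' across the family). Families at or below `min_similarity` are dropped
#' entirely (the similarity cutoff is strict, so a family at exactly 0.70 is
#' excluded under the default). When an annotation is supplied, members absent
#' from it are dropped with a warning; families left with fewer than two
#' members are removed. A missing `shared_block_fraction` defaults to
#' `max(0, (similarity - 0.70) / 0.30)`.
#'
#' @param path TSV path.
#' @param min_similarity Strict lower similarity cutoff (default 0.70).
#' @param annotation Optional annotation to join members against.
#' @return A data.frame with columns `family_id`, `gene_id`, `similarity`,
#'   `shared_block_fraction`.
#' @export
read_paralog_table <- function(path, min_similarity = 0.70, annotation = NULL) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  .assert_columns(df, c("family_id", "gene_id", "similarity"), "paralog table")
  if (any(!is.finite(df$similarity) | df$similarity <= 0 | df$similarity > 1)) {
    stop("similarity must lie in (0, 1]", call. = FALSE)
  }
  if (is.null(df$shared_block_fraction)) {
    df$shared_block_fraction <- .default_shared_block_fraction(df$similarity)
  }
  if (any(df$shared_block_fraction < 0 | df$shared_block_fraction > 1)) {
    stop("shared_block_fraction must lie in [0, 1]", call. = FALSE)
  }
  df <- df[df$similarity > min_similarity, , drop = FALSE]
  if (!is.null(annotation)) {
    known <- df$gene_id %in% annotation$gene_id
    if (any(!known)) {
      warning(sprintf("dropping %d paralog member(s) absent from annotation",
                      sum(!known)))
      df <- df[known, , drop = FALSE]
    }
  }
  sizes <- table(df$family_id)
  df <- df[df$family_id %in% names(sizes)[sizes >= 2], , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Construct an expression table
#'
#' The pipeline's central record: per-gene FPKM values for one library plus
#' library metadata. Zero FPKM values are retained here — filtering is a
#' downstream statistical treatment, never an I/O default.
#'
#' @param values data.frame with columns `gene_id`, `fpkm` (all >= 0).
#' @param library_size Total assigned fragments (positive; `NA` allowed when
#'   unknown, e.g. for externally quantified tables).
#' @param protocol Library preparation protocol, `"ribo_depletion"` or
#'   `"polyA"`.
#' @param label Free-text library label.
#' @return An object of class `expression_table`.
#' @export
expression_table <- function(values, library_size = NA_real_,
                             protocol = c("ribo_depletion", "polyA"),
                             label = "") {
  protocol <- match.arg(protocol)
  .assert_columns(values, c("gene_id", "fpkm"), "expression values")
  if (any(!is.finite(values$fpkm) | values$fpkm < 0)) {
    stop("FPKM values must be finite and >= 0", call. = FALSE)
  }
  dup <- values$gene_id[duplicated(values$gene_id)]
  if (length(dup)) {
    stop(sprintf("duplicate gene_id in expression table: %s",
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  }
  if (!is.na(library_size) && library_size < 1) {
    stop("library_size must be positive", call. = FALSE)
  }
  structure(list(values = values[, c("gene_id", "fpkm")],
                 library_size = library_size,
                 protocol = protocol, label = label),
            class = "expression_table")
}

#' @export
print.expression_table <- function(x, ...) {
  cat(sprintf("<expression_table> %s: %d genes, protocol %s, library size %s\n",
              if (nzchar(x$label)) x$label else "(unlabeled)",
              nrow(x$values), x$protocol,
              ifelse(is.na(x$library_size), "NA",
                     format(x$library_size, big.mark = ","))))
  invisible(x)
}

#' Read a per-gene expression table (TSV: gene_id, fpkm)
#'
#' Negative FPKM values and unparsable rows are hard errors (the error names
#' the offending data row). An empty file yields an empty table with a
#' warning.
#'
#' @inheritParams expression_table
#' @param path TSV path with columns `gene_id`, `fpkm`.
#' @return An `expression_table`.
#' @export
read_expression_table <- function(path, library_size = NA_real_,
                                  protocol = c("ribo_depletion", "polyA"),
                                  label = "") {
  protocol <- match.arg(protocol)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(lines) <= 1) {
    warning(sprintf("empty expression table: %s", path))
    return(expression_table(data.frame(gene_id = character(0), fpkm = numeric(0)),
                            library_size, protocol, label))
  }
  df <- utils::read.delim(text = lines, colClasses = "character")
  .assert_columns(df, c("gene_id", "fpkm"), "expression table")
  fpkm <- suppressWarnings(as.numeric(df$fpkm))
  bad <- which(is.na(fpkm))
  if (length(bad)) {
    stop(sprintf("unparsable fpkm value '%s' at data row %d of %s",
                 df$fpkm[bad[1]], bad[1], path), call. = FALSE)
  }
  if (any(fpkm < 0)) {
    stop(sprintf("negative fpkm value at data row %d of %s",
                 which(fpkm < 0)[1], path), call. = FALSE)
  }
  expression_table(data.frame(gene_id = df$gene_id, fpkm = fpkm,
                              stringsAsFactors = FALSE),
                   library_size, protocol, label)
}

#' Write an expression table as TSV with full precision
#'
#' @param table An `expression_table`.
#' @param path Output path.
#' @export
write_expression_table <- function(table, path) {
  stopifnot(inherits(table, "expression_table"))
  df <- data.frame(gene_id = table$values$gene_id,
                   fpkm = sprintf("%.17g", table$values$fpkm))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-set (e.g. GO term) map
#'
#' Two-column TSV (`gene_id`, `label`); a gene may carry several labels.
#' Unknown gene ids are rejected when an annotation is supplied (join-time
#' validation).
#'
#' @param path TSV path.
#' @param annotation Optional annotation; unknown gene ids are a hard error.
#' @return data.frame with columns `gene_id`, `label`, usable as a group map
#'   for [rxe_by_group()].
#' @export
read_gene_set_map <- function(path, annotation = NULL) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("gene-set map requires two columns: gene_id, label")
  names(df)[1:2] <- c("gene_id", "label")
  if (!is.null(annotation)) {
    unknown <- setdiff(df$gene_id, annotation$gene_id)
    if (length(unknown)) {
      stop(sprintf("gene-set map references unknown gene_id(s): %s",
                   paste(utils::head(unknown, 5), collapse = ", ")),
           call. = FALSE)
    }
  }
  df[, c("gene_id", "label")]
}
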