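# Stratified RXE analyses: paralog cis/trans status, arbitrary gene-set
# strata, paralog enrichment, top-expressed composition, and library-depth
# titration.

#' Classify genes as cis-paralogs, trans-paralogs or non-paralogs
#'
#' A gene with no family is `non_paralog`. A family member with at least one
#' same-chromosome partner is `cis` (duplicated on the same chromosome); a
#' member whose partners all lie on other chromosomes is `trans` (duplicated
#' or translocated across chromosomes). Mixed families yield member-wise
#' labels.
#'
#' @param annotation Annotation data.frame.
#' @param families Paralog family table (`family_id`, `gene_id`, ...). Every
#'   member must exist in the annotation.
#' @return data.frame with columns `gene_id`, `status` — one row per
#'   annotated gene, usable as a group map for [rxe_by_group()].
#' @export
classify_paralog_status <- function(annotation, families) {
  annotation <- validate_annotation(annotation)
  status <- stats::setNames(rep("non_paralog", nrow(annotation)),
                            annotation$gene_id)
  if (!is.null(families) && nrow(families)) {
    missing <- setdiff(families$gene_id, annotation$gene_id)
    if (length(missing)) {
      stop(sprintf("family member(s) absent from annotation: %s",
                   paste(utils::head(missing, 5), collapse = ", ")),
           call. = FALSE)
    }
    chrom <- annotation$chromosome[match(families$gene_id, annotation$gene_id)]
    # cis when the member's (family, chromosome) combination appears >= 2x
    combo <- paste(families$family_id, chrom, sep = "\r")
    n_same <- table(combo)[combo]
    status[families$gene_id] <- ifelse(n_same >= 2, "cis", "trans")
  }
  data.frame(gene_id = annotation$gene_id,
             status = unname(status[annotation$gene_id]),
             stringsAsFactors = FALSE)
}

#' RXE stratified by gene groups
#'
#' Computes RXE restricted to each label's genes; genes without a label are
#' skipped, and a gene may carry several labels (e.g. GO terms). A label
#' whose restricted table has no X genes or no autosomal genes after
#' treatment yields an undefined result (`rxe = NA`), not an error.
#'
#' @param table An `expression_table`.
#' @param annotation Annotation resolving the table.
#' @param group_map data.frame with columns `gene_id`, `label` (or a
#'   `gene_id`/`status` frame from [classify_paralog_status()]).
#' @param treatment A [treatment_spec()].
#' @return data.frame with one row per label: `label`, `rxe`, `n_x`, `n_a`,
#'   `x_summary`, `a_summary`.
#' @export
rxe_by_group <- function(table, annotation, group_map,
                         treatment = treatment_spec()) {
  stopifnot(inherits(table, "expression_table"))
  if ("status" %in% names(group_map) && !"label" %in% names(group_map)) {
    names(group_map)[names(group_map) == "status"] <- "label"
  }
  .assert_columns(group_map, c("gene_id", "label"), "group map")
  labels <- unique(group_map$label)
  rows <- lapply(labels, function(lab) {
    genes <- group_map$gene_id[group_map$label == lab]
    sub <- table$values[table$values$gene_id %in% genes, , drop = FALSE]
    sub_table <- expression_table(sub, table$library_size, table$protocol,
                                  label = lab)
    res <- tryCatch({
      grouped <- suppressWarnings(prepare_values(sub_table, annotation, treatment))
      compute_rxe(grouped, summary = treatment$summary, label = lab)
    }, error = function(e) NULL)
    if (is.null(res)) {
      data.frame(label = lab, rxe = NA_real_, n_x = 0L, n_a = 0L,
                 x_summary = NA_real_, a_summary = NA_real_)
    } else {
      data.frame(label = lab, rxe = res$rxe, n_x = res$n_x, n_a = res$n_a,
                 x_summary = res$x_summary, a_summary = res$a_summary)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Paralog-family enrichment of the X chromosome
#'
#' The fraction of X genes belonging to a paralog family divided by the mean
#' over autosomes of the per-chromosome family-member fraction. Y and MT are
#' excluded.
#'
#' @param annotation Annotation data.frame.
#' @param families Paralog family table.
#' @return Fold enrichment (positive real; 0 when no X gene is in a family,
#'   `Inf` with a warning when autosomes carry no paralogs but X does).
#' @export
paralog_enrichment <- function(annotation, families) {
  annotation <- validate_annotation(annotation)
  annotation <- annotation[!annotation$chromosome %in% .excluded_chromosomes, ]
  in_family <- annotation$gene_id %in% families$gene_id
  on_x <- annotation$chromosome == "X"
  if (!any(!on_x)) stop("at least one autosome with genes is required")
  x_fraction <- mean(in_family[on_x])
  auto_fraction <- tapply(in_family[!on_x], annotation$chromosome[!on_x], mean)
  mean_auto <- mean(auto_fraction)
  if (x_fraction == 0) return(0)
  if (mean_auto == 0) {
    warning("no autosomal paralogs: enrichment is infinite")
    return(Inf)
  }
  x_fraction / mean_auto
}

#' Biotype composition of the top expressed genes
#'
#' Takes the `n` highest-FPKM genes with no consideration of chromosomal
#' location (ties at the boundary broken by lexicographic gene id) and counts
#' them by biotype category. Protein-coding genes fall in the `other` bucket:
#' only small RNAs and riboprotein genes are called out, so the categories
#' are `small_rna`, `riboprotein` and `other`.
#'
#' @param table An `expression_table`.
#' @param annotation Annotation supplying biotypes.
#' @param n Number of top genes (default 250).
#' @return Named integer vector over `small_rna`, `riboprotein`, `other`,
#'   summing to `min(n, number of genes)`.
#' @export
top_expressed_composition <- function(table, annotation, n = 250L) {
  stopifnot(inherits(table, "expression_table"), n >= 1)
  annotation <- validate_annotation(annotation)
  idx <- match(table$values$gene_id, annotation$gene_id)
  if (anyNA(idx)) stop("expression table gene(s) absent from annotation")
  biotype <- annotation$biotype[idx]
  ord <- order(-table$values$fpkm, table$values$gene_id)
  top <- utils::head(ord, n)
  category <- ifelse(biotype[top] %in% c("small_rna", "riboprotein"),
                     biotype[top], "other")
  tab <- table(factor(category, levels = c("small_rna", "riboprotein", "other")))
  stats::setNames(as.integer(tab), names(tab))
}

#' RXE as a function of library depth
#'
#' Subsamples the fragment table without replacement at each requested depth
#' (seeded, so the curve is reproducible), reassigns fragments under the
#' given policy, quantifies FPKM and computes RXE. At the full library depth
#' the result equals the un-subsampled pipeline exactly.
#'
#' @param fragments A `fragment_table`.
#' @param depths Integer vector of depths, each between 1 and the fragment
#'   count.
#' @param policy Mapping policy (see [assign_fragments()]).
#' @param annotation Annotation for quantification.
#' @param treatment A [treatment_spec()].
#' @param seed Integer seed for the subsampling and policy tie-breaks.
#' @return data.frame with one row per depth: `depth`, `rxe`, `n_x`, `n_a`,
#'   `total_assigned`.
#' @export
depth_titration <- function(fragments, depths, policy = "NONUNIQUE_SPLICED",
                            annotation, treatment = treatment_spec(),
                            seed = 1L) {
  n <- nrow(fragments)
  if (any(depths < 1)) stop("depths must be >= 1", call. = FALSE)
  if (any(depths > n)) stop("depth exceeds fragment count", call. = FALSE)
  rows <- lapply(depths, function(d) {
    idx <- with_stream(seed, paste0("titration_", d), sample.int(n, d))
    sub <- fragments[idx, , drop = FALSE]
    attr(sub, "family_members") <- attr(fragments, "family_members")
    class(sub) <- class(fragments)
    counts <- assign_fragments(sub, policy, seed = seed)
    et <- fpkm_from_counts(counts, annotation)
    res <- estimate_rxe(et, annotation, treatment,
                        label = sprintf("depth_%d", d))
    data.frame(depth = d, rxe = res$rxe, n_x = res$n_x, n_a = res$n_a,
               total_assigned = counts$total_assigned)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
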