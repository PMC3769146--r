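# The statistical core: data treatments, the relative X expression (RXE)
# statistic, competing trimming schemes, and the chromosome-relative null
# distribution.

#' Specify a statistical treatment of an expression table
#'
#' A treatment is applied in a fixed order: prefilter, zero policy, log2
#' transform, outlier policy. Defaults follow the analysis this package
#' implements: drop zeros (log2 of 0 is undefined; the gene universe is genes
#' with FPKM > 0), remove Tukey-fence outliers per chromosome at k = 1.5
#' using box-plot hinges, and summarize with the mean.
#'
#' @param summary Central-tendency summary, `"mean"` or `"median"`.
#' @param zero_policy `"drop_zeros"` (default) or `"pseudocount"` (adds
#'   `pseudocount` to every FPKM before the log).
#' @param pseudocount Positive offset used when `zero_policy = "pseudocount"`.
#' @param outlier `"tukey"` (default) or `"none"`.
#' @param tukey_k Fence multiplier (conventionally 1.5).
#' @param outlier_scope `"per_chromosome"` (default; box plots are drawn per
#'   chromosome) or `"global"`.
#' @param quartile_method `"hinges"` (box-plot hinges, default) or
#'   `"quantile"` (linear interpolation, type 7).
#' @param prefilter `"none"` (default), `"min_fpkm"` (drop genes below a
#'   threshold) or `"zero_balanced_trim"` (see [zero_balanced_trim()]).
#' @param min_fpkm Threshold for the `min_fpkm` prefilter; conventional
#'   values are 1 and 3.
#' @return An object of class `treatment_spec`.
#' @export
treatment_spec <- function(summary = c("mean", "median"),
                           zero_policy = c("drop_zeros", "pseudocount"),
                           pseudocount = 1e-3,
                           outlier = c("tukey", "none"),
                           tukey_k = 1.5,
                           outlier_scope = c("per_chromosome", "global"),
                           quartile_method = c("hinges", "quantile"),
                           prefilter = c("none", "min_fpkm", "zero_balanced_trim"),
                           min_fpkm = 1) {
  spec <- list(summary = match.arg(summary),
               zero_policy = match.arg(zero_policy),
               pseudocount = pseudocount,
               outlier = match.arg(outlier),
               tukey_k = tukey_k,
               outlier_scope = match.arg(outlier_scope),
               quartile_method = match.arg(quartile_method),
               prefilter = match.arg(prefilter),
               min_fpkm = min_fpkm)
  if (spec$zero_policy == "pseudocount" && spec$pseudocount <= 0) {
    stop("pseudocount must be > 0")
  }
  if (spec$tukey_k <= 0) stop("tukey_k must be positive")
  if (spec$min_fpkm < 0) stop("min_fpkm must be >= 0")
  structure(spec, class = "treatment_spec")
}

#' @export
format.treatment_spec <- function(x, ...) {
  pre <- switch(x$prefilter,
                none = "none",
                min_fpkm = sprintf("min_fpkm:%g", x$min_fpkm),
                zero_balanced_trim = "zero_balanced_trim")
  out <- switch(x$outlier,
                none = "none",
                tukey = sprintf("tukey:%g:%s", x$tukey_k, x$outlier_scope))
  zp <- if (x$zero_policy == "pseudocount") {
    sprintf("pseudocount:%g", x$pseudocount)
  } else {
    "drop_zeros"
  }
  sprintf("%s|%s|%s|%s", x$summary, zp, out, pre)
}

#' @export
print.treatment_spec <- function(x, ...) {
  cat("<treatment_spec>", format(x), "\n")
  invisible(x)
}

#' Remove Tukey-fence outliers
#'
#' Removes values outside the closed interval
#' `[Q1 - k*IQR, Q3 + k*IQR]`, where `Q1`/`Q3` are by default the box-plot
#' hinges (medians of the lower/upper halves, the median included in both
#' halves for odd n) and `IQR = Q3 - Q1`. Boundary values are retained and
#' the input order of survivors is preserved.
#'
#' @param values Numeric vector.
#' @param k Positive fence multiplier; `Inf` retains everything.
#' @param method `"hinges"` (default) or `"quantile"` (type-7 linear
#'   interpolation).
#' @return The retained values, in input order.
#' @export
tukey_outliers <- function(values, k = 1.5, method = c("hinges", "quantile")) {
  method <- match.arg(method)
  if (!length(values)) return(values)
  if (!is.finite(k)) return(values)
  if (method == "hinges") {
    fn <- stats::fivenum(values)
    q1 <- fn[2]
    q3 <- fn[4]
  } else {
    q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
    q1 <- q[1]
    q3 <- q[2]
  }
  iqr <- q3 - q1
  values[values >= q1 - k * iqr & values <= q3 + k * iqr]
}

#' Zero-balanced trimming of an expression distribution
#'
#' Counts the zeros (`z`), removes them, and removes a compensatory `z`
#' largest values from the upper end of the distribution — the symmetric-trim
#' scheme used in earlier dosage-compensation reports in place of
#' distribution-based outlier removal. Ties at the upper cut are broken by
#' input order, earliest removed first; the input order of survivors is
#' preserved.
#'
#' @param values Numeric FPKM vector.
#' @return The trimmed values. Warns when zeros make up at least half the
#'   nonzero count (the result may be empty).
#' @export
zero_balanced_trim <- function(values) {
  z <- sum(values == 0)
  if (z == 0) return(values)
  nz_idx <- which(values != 0)
  if (z >= length(nz_idx)) {
    warning("zero count exceeds nonzero count: zero-balanced trim empties the data")
    return(values[0])
  }
  if (z >= length(nz_idx) / 2) {
    warning("zero count is at least half the nonzero count: aggressive trim")
  }
  drop <- nz_idx[order(-values[nz_idx], seq_along(nz_idx))[seq_len(z)]]
  values[sort(setdiff(nz_idx, drop))]
}

#' Prepare per-chromosome log2 expression values
#'
#' Joins an expression table against an annotation, excludes Y and MT before
#' any computation, then applies the treatment in order: prefilter (over the
#' whole table), zero policy, log2 transform, outlier policy at its scope.
#' Chromosomes left empty after treatment are excluded with a warning.
#'
#' @param table An `expression_table`.
#' @param annotation Annotation resolving every gene in the table.
#' @param treatment A [treatment_spec()].
#' @return Named list, chromosome -> numeric vector of log2 FPKM values.
#' @export
prepare_values <- function(table, annotation, treatment = treatment_spec()) {
  stopifnot(inherits(table, "expression_table"),
            inherits(treatment, "treatment_spec"))
  annotation <- validate_annotation(annotation)
  idx <- match(table$values$gene_id, annotation$gene_id)
  if (anyNA(idx)) {
    stop(sprintf("expression table gene(s) absent from annotation: %s",
                 paste(utils::head(table$values$gene_id[is.na(idx)], 5),
                       collapse = ", ")), call. = FALSE)
  }
  chrom <- annotation$chromosome[idx]
  fpkm <- table$values$fpkm
  keep <- !chrom %in% .excluded_chromosomes
  chrom <- chrom[keep]
  fpkm <- fpkm[keep]
  # Prefilter over the whole table (dataset-level trimming schemes).
  keep <- switch(treatment$prefilter,
                 none = rep(TRUE, length(fpkm)),
                 min_fpkm = fpkm >= treatment$min_fpkm,
                 zero_balanced_trim = .zero_balanced_keep(fpkm))
  chrom <- chrom[keep]
  fpkm <- fpkm[keep]
  if (treatment$zero_policy == "drop_zeros") {
    chrom <- chrom[fpkm > 0]
    fpkm <- fpkm[fpkm > 0]
  } else {
    fpkm <- fpkm + treatment$pseudocount
  }
  vals <- log2(fpkm)
  grouped <- split(vals, chrom)
  if (treatment$outlier == "tukey") {
    if (treatment$outlier_scope == "per_chromosome") {
      grouped <- lapply(grouped, tukey_outliers, k = treatment$tukey_k,
                        method = treatment$quartile_method)
    } else {
      pooled <- unlist(grouped, use.names = FALSE)
      kept <- tukey_outliers(pooled, k = treatment$tukey_k,
                             method = treatment$quartile_method)
      # Global fences applied to each chromosome's values.
      lo <- suppressWarnings(min(kept))
      hi <- suppressWarnings(max(kept))
      grouped <- lapply(grouped, function(v) v[v >= lo & v <= hi])
    }
  }
  empty <- lengths(grouped) == 0
  if (any(empty)) {
    warning(sprintf("chromosome(s) left empty after treatment: %s",
                    paste(names(grouped)[empty], collapse = ", ")))
    grouped <- grouped[!empty]
  }
  grouped
}

.zero_balanced_keep <- function(values) {
  z <- sum(values == 0)
  if (z == 0) return(rep(TRUE, length(values)))
  nz_idx <- which(values != 0)
  keep <- rep(FALSE, length(values))
  if (z >= length(nz_idx)) {
    warning("zero count exceeds nonzero count: zero-balanced trim empties the data")
    return(keep)
  }
  if (z >= length(nz_idx) / 2) {
    warning("zero count is at least half the nonzero count: aggressive trim")
  }
  drop <- nz_idx[order(-values[nz_idx], seq_along(nz_idx))[seq_len(z)]]
  keep[setdiff(nz_idx, drop)] <- TRUE
  keep
}

.summary_fun <- function(summary) {
  switch(summary, mean = mean, median = stats::median,
         stop("summary must be 'mean' or 'median'"))
}

#' Compute relative X expression (RXE)
#'
#' `RXE = summary(X log2 values) - summary(pooled autosomal log2 values)`.
#' The autosomal side pools gene-level values across all autosomes with equal
#' gene weight. A value of 0 indicates dosage compensation (equal X and
#' autosomal means); -1 indicates X expression at half the autosomal level
#' (no compensation); +1 indicates twice the autosomal level.
#'
#' @param grouped Named list, chromosome -> log2 values (from
#'   [prepare_values()]).
#' @param summary `"mean"` or `"median"`.
#' @param label Free-text label recorded on the result.
#' @return An object of class `rxe_result` with elements `rxe`, `n_x`, `n_a`,
#'   `x_summary`, `a_summary`, `summary`, `label` and (when set by a
#'   higher-level wrapper) `treatment`.
#' @export
compute_rxe <- function(grouped, summary = c("mean", "median"), label = "") {
  summary <- match.arg(summary)
  if (!"X" %in% names(grouped) || !length(grouped[["X"]])) {
    stop("X chromosome values are required to compute RXE", call. = FALSE)
  }
  autosomes <- setdiff(names(grouped), c("X", .excluded_chromosomes))
  a_values <- unlist(grouped[autosomes], use.names = FALSE)
  if (!length(a_values)) {
    stop("at least one autosome with values is required", call. = FALSE)
  }
  sfun <- .summary_fun(summary)
  x_s <- sfun(grouped[["X"]])
  a_s <- sfun(a_values)
  structure(list(rxe = x_s - a_s,
                 n_x = length(grouped[["X"]]),
                 n_a = length(a_values),
                 x_summary = x_s, a_summary = a_s,
                 summary = summary, label = label,
                 treatment = NULL),
            class = "rxe_result")
}

#' @export
print.rxe_result <- function(x, ...) {
  cat(sprintf("<rxe_result> RXE = %.4f (X:A ratio %.3f; %s of %d X and %d autosomal genes)%s\n",
              x$rxe, rxe_to_ratio(x$rxe), x$summary, x$n_x, x$n_a,
              if (nzchar(x$label)) paste0(" [", x$label, "]") else ""))
  invisible(x)
}

#' Back-transform RXE to the linear X:A ratio
#'
#' `2^RXE`: an RXE of -1 corresponds to an X:A ratio of 0.5 (autosomal
#' expression twice the X), 0 to parity, +1 to a ratio of 2.
#'
#' @param rxe Finite RXE value (log2 units).
#' @return The linear X:A ratio.
#' @export
rxe_to_ratio <- function(rxe) {
  stopifnot(is.finite(rxe))
  2^rxe
}

#' Chromosome-to-chromosome relative expression
#'
#' For each chromosome, the summary of its values minus the summary of the
#' pooled values of all autosomes excluding that chromosome (leave-one-out
#' for autosomes; for X nothing is excluded, since X is not an autosome).
#' Places the RXE value in the context of the natural chromosome-to-
#' chromosome variation: under compensation the X falls within the normal
#' range of autosome-vs-rest values.
#'
#' @inheritParams compute_rxe
#' @return Named numeric vector, chromosome -> relative expression (log2).
#' @export
chromosome_relative_expression <- function(grouped,
                                           summary = c("mean", "median")) {
  summary <- match.arg(summary)
  sfun <- .summary_fun(summary)
  autosomes <- setdiff(names(grouped), c("X", .excluded_chromosomes))
  if (length(autosomes) < 2) {
    stop("at least 2 autosomes are required for leave-one-out reference",
         call. = FALSE)
  }
  vapply(names(grouped), function(chr) {
    ref <- grouped[setdiff(autosomes, chr)]
    sfun(grouped[[chr]]) - sfun(unlist(ref, use.names = FALSE))
  }, numeric(1))
}

#' Rank-sum (Mann-Whitney U) comparison of X and autosomal values
#'
#' Exact when `n1 * n2 <= 400` and the data are tie-free; otherwise the
#' normal approximation with tie correction (and continuity correction) is
#' used. The U statistic counts, over all cross pairs, how often an X value
#' exceeds an autosomal value (ties count 1/2).
#'
#' @param x_values,a_values Non-empty numeric vectors.
#' @return List with elements `U` and `p` (two-sided).
#' @export
ranksum_test <- function(x_values, a_values) {
  if (!length(x_values) || !length(a_values)) {
    stop("both value lists must be non-empty", call. = FALSE)
  }
  exact <- length(x_values) * length(a_values) <= 400 &&
    !anyDuplicated(c(x_values, a_values))
  wt <- suppressWarnings(
    stats::wilcox.test(x_values, a_values, exact = exact, correct = !exact))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Estimate RXE from an expression table
#'
#' Convenience wrapper chaining [prepare_values()] and [compute_rxe()]; the
#' treatment provenance is recorded on the result.
#'
#' @inheritParams prepare_values
#' @param label Label recorded on the result (defaults to the table label).
#' @return An `rxe_result`.
#' @export
estimate_rxe <- function(table, annotation, treatment = treatment_spec(),
                         label = table$label) {
  grouped <- prepare_values(table, annotation, treatment)
  res <- compute_rxe(grouped, summary = treatment$summary, label = label)
  res$treatment <- treatment
  res
}
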