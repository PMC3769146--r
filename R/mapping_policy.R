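# Abstract read mapping policies: turn a fragment table into per-gene
# (possibly fractional) counts under the three regimes an aligner induces —
# unique-only, non-unique unspliced, and non-unique spliced with 1/k
# multi-map splitting.

#' @noRd
.mapping_policies <- c("UNIQUE", "NONUNIQUE", "NONUNIQUE_SPLICED")

#' Assign fragments to genes under a mapping policy
#'
#' * `UNIQUE` — ambiguous (multi-mapping) fragments and junction-spanning
#'   fragments are discarded; every surviving fragment adds 1 to its source
#'   gene. This mirrors unspliced unique-only alignment, which excludes any
#'   read mapping to multiple positions.
#' * `NONUNIQUE` — junction-spanning fragments are discarded (the aligner is
#'   unspliced); an ambiguous fragment is assigned wholly (weight 1) to one
#'   member of its ambiguity set chosen uniformly at random under `seed`. In
#'   the simulation all family copies align equally well by construction, so
#'   a uniform choice is the faithful limit of best-hit tie-breaking.
#' * `NONUNIQUE_SPLICED` — junction fragments are retained and an ambiguous
#'   fragment contributes `1/k` to each of the `k` members of its ambiguity
#'   set, the standard equal split of multi-mapped reads.
#'
#' Each fragment contributes total weight 1 when retained, so
#' `total_assigned + n_discarded` equals the input fragment count.
#'
#' @param fragments A `fragment_table` (see [sample_fragments()]).
#' @param policy One of `"UNIQUE"`, `"NONUNIQUE"`, `"NONUNIQUE_SPLICED"`.
#' @param seed Integer seed for the random tie-break under `NONUNIQUE`.
#' @param report_cap Maximum ambiguity-set size an aligner would report;
#'   fragments whose set exceeds the cap are discarded under non-unique
#'   policies. Default `Inf` (no cap).
#' @return An object of class `fragment_counts`: list with `counts` (named
#'   numeric, gene -> count), `total_assigned`, `n_discarded`, `policy`.
#' @export
assign_fragments <- function(fragments, policy = .mapping_policies, seed = 1L,
                             report_cap = Inf) {
  policy <- match.arg(policy, .mapping_policies)
  n_in <- nrow(fragments)
  members <- attr(fragments, "family_members") %||% list()
  if (n_in == 0) {
    return(.fragment_counts(numeric(0), 0, 0L, policy))
  }
  amb <- !is.na(fragments$ambiguity_family)
  junction <- fragments$junction_spanning
  if (is.finite(report_cap) && any(amb)) {
    k <- lengths(members)[fragments$ambiguity_family[amb]]
    over <- rep(FALSE, n_in)
    over[which(amb)[k > report_cap]] <- TRUE
  } else {
    over <- rep(FALSE, n_in)
  }
  if (policy == "UNIQUE") {
    keep <- !amb & !junction
    counts <- c(table(fragments$source_gene[keep]))
    total <- sum(keep)
  } else if (policy == "NONUNIQUE") {
    keep <- !junction & !over
    assigned <- fragments$source_gene[keep & !amb]
    amb_fam <- fragments$ambiguity_family[keep & amb]
    if (length(amb_fam)) {
      by_fam <- split(seq_along(amb_fam), amb_fam)
      picks <- with_stream(seed, "assign_nonunique", unlist(
        Map(function(fam, idx) sample(members[[fam]], length(idx), replace = TRUE),
            names(by_fam), by_fam),
        use.names = FALSE))
      assigned <- c(assigned, picks)
    }
    counts <- c(table(assigned))
    total <- sum(keep)
  } else {
    keep <- !over
    counts_env <- c(table(fragments$source_gene[keep & !amb]))
    counts <- as.numeric(counts_env)
    names(counts) <- names(counts_env)
    amb_fam <- fragments$ambiguity_family[keep & amb]
    if (length(amb_fam)) {
      fam_tab <- table(amb_fam)
      mem_list <- members[names(fam_tab)]
      k <- lengths(mem_list)
      add <- rep(as.numeric(fam_tab) / k, k)
      genes <- unlist(mem_list, use.names = FALSE)
      frac <- tapply(add, genes, sum)
      all_genes <- union(names(counts), names(frac))
      merged <- stats::setNames(numeric(length(all_genes)), all_genes)
      merged[names(counts)] <- counts
      merged[names(frac)] <- merged[names(frac)] + as.numeric(frac)
      counts <- merged
    }
    total <- sum(keep)
  }
  .fragment_counts(counts, total, n_in - sum(keep), policy)
}

.fragment_counts <- function(counts, total_assigned, n_discarded, policy) {
  counts <- stats::setNames(as.numeric(counts), names(counts))
  structure(list(counts = counts,
                 total_assigned = as.numeric(total_assigned),
                 n_discarded = as.integer(n_discarded),
                 policy = policy),
            class = "fragment_counts")
}

#' @export
print.fragment_counts <- function(x, ...) {
  cat(sprintf("<fragment_counts> policy %s: %s assigned over %d genes, %d discarded\n",
              x$policy, format(x$total_assigned, big.mark = ","),
              length(x$counts), x$n_discarded))
  invisible(x)
}

#' Write per-gene counts as TSV
#'
#' The mapping policy is recorded in a header comment line.
#'
#' @param counts A `fragment_counts` object.
#' @param path Output path.
#' @export
write_fragment_counts <- function(counts, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# policy=%s total_assigned=%.6f n_discarded=%d",
                     counts$policy, counts$total_assigned, counts$n_discarded),
             con)
  writeLines("gene_id\tcount", con)
  writeLines(sprintf("%s\t%.17g", names(counts$counts), counts$counts), con)
  invisible(path)
}
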