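# Synthetic-data generator: genome catalogs, true expression and fragment
# tables carrying the statistical structure the RXE analysis assumes —
# log-normal expression with a heavy low tail, an X chromosome enriched for
# paralog families, a compensation parameter controlling the X:A offset,
# junction-spanning fragments from multi-exon genes, and protocol-specific
# biotype enrichment.

#' Simulation configuration
#'
#' Captures the genome layout and statistical structure of a simulated
#' RNA-seq study. The X:A compensation parameter `x_to_a_ratio` is the
#' expected linear ratio of mean X to mean autosomal expression: 0.5 models
#' no dosage compensation (a single active X against diploid autosomes), 1
#' models full compensation.
#'
#' @param n_autosomes Number of autosomes (labeled `"1"`, `"2"`, ...).
#' @param genes_per_autosome Genes per autosome.
#' @param n_x_genes Genes on the X chromosome.
#' @param paralog_fraction_autosome Fraction of autosomal genes in paralog
#'   families.
#' @param paralog_x_enrichment Fold enrichment of the X paralog fraction over
#'   the autosomal fraction (the human X shows roughly 2-fold).
#' @param family_size Members per paralog family (>= 2).
#' @param cis_fraction Share of X paralog families whose partners are also on
#'   the X (cis); the rest place exactly one member on X with partners spread
#'   uniformly over autosomes (trans).
#' @param similarity_range Range of family sequence similarity, within
#'   (0.70, 1].
#' @param x_to_a_ratio Expected linear X:A mean-expression ratio (rho).
#' @param log2_mean,log2_sd Baseline log2-normal expression parameters.
#' @param exon_count_range Integer range of exons per gene.
#' @param gene_length_range Integer range of summed exonic length (bp).
#' @param fragment_length Sequenced fragment length (bp).
#' @param biotype_mix Named proportions over the four biotypes, summing to 1.
#' @param protocol Library preparation protocol used when simulating
#'   expression (`"ribo_depletion"` or `"polyA"`).
#' @param protocol_bias Per-protocol multiplicative biotype factors; the
#'   defaults enrich small RNAs under ribo-depletion and riboprotein genes
#'   under poly-A selection.
#' @param library_size Number of fragments to sample per library.
#' @param seed Integer master seed; each simulation stage draws from an RNG
#'   stream derived from `(seed, stage name)` so stages are independently
#'   reproducible.
#' @return An object of class `sim_config` (a validated named list).
#' @export
sim_config <- function(n_autosomes = 10L,
                       genes_per_autosome = 200L,
                       n_x_genes = 150L,
                       paralog_fraction_autosome = 0.2,
                       paralog_x_enrichment = 2,
                       family_size = 3L,
                       cis_fraction = 0.5,
                       similarity_range = c(0.75, 1),
                       x_to_a_ratio = 1,
                       log2_mean = 3,
                       log2_sd = 2,
                       exon_count_range = c(1L, 20L),
                       gene_length_range = c(300L, 10000L),
                       fragment_length = 200L,
                       biotype_mix = c(protein_coding = 0.85, small_rna = 0.05,
                                       riboprotein = 0.03, other = 0.07),
                       protocol = c("ribo_depletion", "polyA"),
                       protocol_bias = list(
                         ribo_depletion = c(protein_coding = 1, small_rna = 8,
                                            riboprotein = 1, other = 1),
                         polyA = c(protein_coding = 1, small_rna = 0.05,
                                   riboprotein = 8, other = 1)),
                       library_size = 1e6,
                       seed = 1L) {
  protocol <- match.arg(protocol)
  cfg <- list(n_autosomes = as.integer(n_autosomes),
              genes_per_autosome = as.integer(genes_per_autosome),
              n_x_genes = as.integer(n_x_genes),
              paralog_fraction_autosome = paralog_fraction_autosome,
              paralog_x_enrichment = paralog_x_enrichment,
              family_size = as.integer(family_size),
              cis_fraction = cis_fraction,
              similarity_range = similarity_range,
              x_to_a_ratio = x_to_a_ratio,
              log2_mean = log2_mean, log2_sd = log2_sd,
              exon_count_range = as.integer(exon_count_range),
              gene_length_range = as.integer(gene_length_range),
              fragment_length = as.integer(fragment_length),
              biotype_mix = biotype_mix,
              protocol = protocol,
              protocol_bias = protocol_bias,
              library_size = as.integer(library_size),
              seed = as.integer(seed))
  .validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

.validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_autosomes >= 1, cfg$genes_per_autosome >= 1,
            cfg$n_x_genes >= 1, cfg$family_size >= 2,
            cfg$x_to_a_ratio > 0, cfg$log2_sd > 0,
            cfg$fragment_length >= 1, cfg$library_size >= 1)
  if (cfg$paralog_fraction_autosome < 0 || cfg$paralog_fraction_autosome >= 1) {
    stop("paralog_fraction_autosome must lie in [0, 1)")
  }
  if (cfg$paralog_x_enrichment < 0) stop("paralog_x_enrichment must be >= 0")
  if (cfg$cis_fraction < 0 || cfg$cis_fraction > 1) {
    stop("cis_fraction must lie in [0, 1]")
  }
  for (rng in list(cfg$similarity_range, cfg$exon_count_range,
                   cfg$gene_length_range)) {
    if (length(rng) != 2 || rng[1] > rng[2]) stop("ranges must be ordered pairs")
  }
  if (cfg$similarity_range[1] <= 0.70 || cfg$similarity_range[2] > 1) {
    stop("similarity_range must lie within (0.70, 1]")
  }
  if (abs(sum(cfg$biotype_mix) - 1) > 1e-9) {
    stop("biotype_mix proportions must sum to 1")
  }
  if (!setequal(names(cfg$biotype_mix), .biotype_levels)) {
    stop("biotype_mix must name exactly the four biotype classes")
  }
  invisible(cfg)
}

#' Read a simulation configuration from YAML or JSON
#'
#' Fields are passed to [sim_config()]; unspecified fields keep their
#' defaults.
#'
#' @param path YAML (or JSON, a YAML subset) file.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  fields <- yaml::read_yaml(path)
  if (!is.null(fields$biotype_mix)) fields$biotype_mix <- unlist(fields$biotype_mix)
  if (!is.null(fields$protocol_bias)) {
    fields$protocol_bias <- lapply(fields$protocol_bias, unlist)
  }
  do.call(sim_config, fields)
}

#' Write a simulation configuration as YAML
#'
#' @param config A [sim_config()].
#' @param path Output path.
#' @export
write_sim_config <- function(config, path) {
  x <- unclass(config)
  x$biotype_mix <- as.list(x$biotype_mix)
  x$protocol_bias <- lapply(x$protocol_bias, as.list)
  yaml::write_yaml(x, path)
  invisible(path)
}

.config_digest <- function(config) {
  .str_hash(paste(utils::capture.output(utils::str(unclass(config))),
                  collapse = "\n"))
}

#' Generate a synthetic gene catalog with a paralog-enriched X
#'
#' Produces an annotation (chromosomes `"1"`..`n_autosomes` and `"X"`) and a
#' paralog family table. The X paralog-member count targets
#' `paralog_x_enrichment * paralog_fraction_autosome * n_x_genes`; cis
#' families place all members on the X, trans families place one member on X
#' with partners drawn uniformly from autosomal genes, and the remaining
#' autosomal family budget is filled with single-chromosome autosomal
#' families. Deterministic under `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A list with elements `annotation` and `families`.
#' @export
generate_catalog <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  p_x <- config$paralog_x_enrichment * config$paralog_fraction_autosome
  if (p_x > 1) {
    stop("infeasible X paralog target: enrichment x autosomal fraction exceeds 1")
  }
  with_stream(config$seed, "catalog", {
    chromosome <- c(rep(as.character(seq_len(config$n_autosomes)),
                        each = config$genes_per_autosome),
                    rep("X", config$n_x_genes))
    n <- length(chromosome)
    gene_id <- sprintf("g%06d", seq_len(n))
    ann <- data.frame(
      gene_id = gene_id,
      chromosome = chromosome,
      exon_length_bp = sample(seq(config$gene_length_range[1],
                                  config$gene_length_range[2]), n, replace = TRUE),
      n_exons = sample(seq(config$exon_count_range[1],
                           config$exon_count_range[2]), n, replace = TRUE),
      biotype = sample(names(config$biotype_mix), n, replace = TRUE,
                       prob = config$biotype_mix),
      paralog_family = NA_character_,
      stringsAsFactors = FALSE
    )
    fs <- config$family_size
    cfrac <- config$cis_fraction
    target_x <- round(p_x * config$n_x_genes)
    if (target_x > 0) {
      f_ideal <- target_x / (cfrac * fs + (1 - cfrac))
      n_cis <- min(round(cfrac * f_ideal), floor(target_x / fs))
      n_trans <- if (cfrac < 1) max(0, target_x - n_cis * fs) else 0L
    } else {
      n_cis <- n_trans <- 0L
    }
    x_pool <- sample(which(chromosome == "X"))
    auto_pool <- sample(which(chromosome != "X"))
    fam_rows <- list()
    fam_counter <- 0L
    take_x <- function(k) {
      out <- x_pool[seq_len(k)]
      x_pool <<- x_pool[-seq_len(k)]
      out
    }
    take_auto <- function(k) {
      out <- auto_pool[seq_len(k)]
      auto_pool <<- auto_pool[-seq_len(k)]
      out
    }
    new_family <- function(members) {
      fam_counter <<- fam_counter + 1L
      id <- sprintf("fam%04d", fam_counter)
      ann$paralog_family[members] <<- id
      fam_rows[[fam_counter]] <<- data.frame(
        family_id = id, gene_id = ann$gene_id[members],
        stringsAsFactors = FALSE)
    }
    for (i in seq_len(n_cis)) new_family(take_x(fs))
    for (i in seq_len(n_trans)) new_family(c(take_x(1L), take_auto(fs - 1L)))
    # Fill remaining autosomal paralog budget with single-chromosome families.
    target_a <- round(config$paralog_fraction_autosome *
                        (config$n_autosomes * config$genes_per_autosome))
    remaining <- target_a - n_trans * (fs - 1L)
    n_auto_fam <- max(0L, round(remaining / fs))
    for (i in seq_len(n_auto_fam)) {
      by_chr <- split(auto_pool, chromosome[auto_pool])
      by_chr <- by_chr[lengths(by_chr) >= fs]
      if (!length(by_chr)) break
      chr <- sample(names(by_chr), 1L,
                    prob = lengths(by_chr) / sum(lengths(by_chr)))
      members <- by_chr[[chr]][seq_len(fs)]
      auto_pool <- setdiff(auto_pool, members)
      new_family(members)
    }
    families <- if (fam_counter > 0) do.call(rbind, fam_rows) else
      data.frame(family_id = character(0), gene_id = character(0))
    if (fam_counter > 0) {
      sim_by_family <- stats::runif(fam_counter, config$similarity_range[1],
                                    config$similarity_range[2])
      names(sim_by_family) <- sprintf("fam%04d", seq_len(fam_counter))
      families$similarity <- unname(sim_by_family[families$family_id])
      families$shared_block_fraction <-
        .default_shared_block_fraction(families$similarity)
    } else {
      families$similarity <- numeric(0)
      families$shared_block_fraction <- numeric(0)
    }
    list(annotation = validate_annotation(ann), families = families)
  })
}

#' Simulate true per-gene abundance (expected fragments)
#'
#' Base abundance per gene is `2^z * exon_length_bp / 1000` with
#' `z ~ Normal(log2_mean, log2_sd^2)` — abundance proportional to transcript
#' molarity times length, so length-normalized FPKM recovers molarity. X-linked
#' genes are scaled by the compensation parameter `x_to_a_ratio`, and the
#' protocol's biotype multiplier is applied last. The baseline draw is
#' centered within the X and within the autosomes (both to `log2_mean`), so
#' the configured ratio is the realized chromosome-class mean offset of the
#' catalog rather than only its expectation — in a finite catalog the
#' realized offset would otherwise carry sampling noise of order
#' `log2_sd / sqrt(n_x_genes)`, and the compensation parameter is meant to
#' define the condition being simulated, not a random draw around it.
#' Deterministic under `config$seed`; the baseline draw does not depend on
#' the protocol, so protocol effects are purely multiplicative.
#'
#' @param catalog Output of [generate_catalog()] (or an annotation data.frame).
#' @param config The [sim_config()].
#' @return Named numeric vector `gene_id -> abundance` (>= 0).
#' @export
simulate_true_expression <- function(catalog, config) {
  ann <- if (is.data.frame(catalog)) catalog else catalog$annotation
  z <- with_stream(config$seed, "true_expression",
                   stats::rnorm(nrow(ann), config$log2_mean, config$log2_sd))
  on_x <- ann$chromosome == "X"
  z[on_x] <- z[on_x] - mean(z[on_x]) + config$log2_mean
  z[!on_x] <- z[!on_x] - mean(z[!on_x]) + config$log2_mean
  abundance <- 2^z * ann$exon_length_bp / 1000
  abundance[on_x] <- abundance[on_x] * config$x_to_a_ratio
  bias <- config$protocol_bias[[config$protocol]]
  abundance <- abundance * unname(bias[ann$biotype])
  stats::setNames(abundance, ann$gene_id)
}

#' Sample a fragment table from true abundances
#'
#' Draws exactly `library_size` fragments multinomially with probabilities
#' proportional to abundance. A fragment from a paralog-family gene is
#' ambiguous (its ambiguity set is the full family) with probability equal to
#' the family's `shared_block_fraction`, else it maps uniquely. A fragment is
#' junction-spanning with probability
#' `min(1, (n_exons - 1) * (fragment_length - 1) / exon_length_bp)` (the
#' uniform-start approximation). Deterministic under `config$seed`.
#'
#' @param abundance Named abundance vector from [simulate_true_expression()].
#' @param catalog Output of [generate_catalog()].
#' @param families Paralog family table; defaults to `catalog$families`.
#' @param library_size Number of fragments to draw; defaults to
#'   `config$library_size`.
#' @param config The [sim_config()].
#' @return A `fragment_table`: data.frame with columns `fragment_id`,
#'   `source_gene`, `ambiguity_family` (`NA` when the fragment maps uniquely)
#'   and `junction_spanning`, carrying the family membership map and
#'   provenance (seed, config digest) as attributes.
#' @export
sample_fragments <- function(abundance, catalog, families = NULL,
                             library_size = NULL, config) {
  ann <- if (is.data.frame(catalog)) catalog else catalog$annotation
  families <- families %||% (if (is.data.frame(catalog)) NULL else catalog$families)
  library_size <- library_size %||% config$library_size
  stopifnot(library_size >= 1)
  abundance <- abundance[ann$gene_id]
  if (anyNA(abundance)) stop("abundance is missing values for annotated genes")
  if (all(abundance <= 0)) stop("all-zero abundance: nothing to sample")
  sbf <- rep(0, nrow(ann))
  if (!is.null(families) && nrow(families)) {
    idx <- match(ann$gene_id, families$gene_id)
    hit <- !is.na(idx)
    sbf[hit] <- families$shared_block_fraction[idx[hit]]
  }
  p_junction <- pmin(1, (ann$n_exons - 1) * (config$fragment_length - 1) /
                       ann$exon_length_bp)
  with_stream(config$seed, "fragments", {
    counts <- as.vector(stats::rmultinom(1, library_size,
                                         abundance / sum(abundance)))
    gi <- rep(seq_len(nrow(ann)), counts)
    n <- length(gi)
    ambiguous <- stats::runif(n) < sbf[gi]
    junction <- stats::runif(n) < p_junction[gi]
    fam <- ann$paralog_family[gi]
    fam[!ambiguous] <- NA_character_
    out <- data.frame(fragment_id = seq_len(n),
                      source_gene = ann$gene_id[gi],
                      ambiguity_family = fam,
                      junction_spanning = junction,
                      stringsAsFactors = FALSE)
    attr(out, "family_members") <-
      if (!is.null(families) && nrow(families)) {
        split(families$gene_id, families$family_id)
      } else {
        list()
      }
    attr(out, "seed") <- config$seed
    attr(out, "config_digest") <- .config_digest(config)
    class(out) <- c("fragment_table", "data.frame")
    out
  })
}

#' Materialize per-fragment ambiguity sets
#'
#' Expands the compact family-reference representation into an explicit list
#' of gene-id sets, one per fragment (the source gene alone for unambiguous
#' fragments, the full family otherwise). Intended for inspection and
#' serialization of small tables.
#'
#' @param fragments A `fragment_table`.
#' @return List of character vectors, one per fragment.
#' @export
fragment_ambiguity_sets <- function(fragments) {
  members <- attr(fragments, "family_members")
  out <- as.list(fragments$source_gene)
  amb <- which(!is.na(fragments$ambiguity_family))
  out[amb] <- members[fragments$ambiguity_family[amb]]
  out
}

#' Write a fragment table as TSV
#'
#' The ambiguity set is serialized as a comma-joined member list.
#'
#' @param fragments A `fragment_table`.
#' @param path Output path.
#' @export
write_fragment_table <- function(fragments, path) {
  sets <- vapply(fragment_ambiguity_sets(fragments),
                 paste, character(1), collapse = ",")
  df <- data.frame(fragment_id = fragments$fragment_id,
                   source_gene = fragments$source_gene,
                   ambiguity_set = sets,
                   junction_spanning = fragments$junction_spanning)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
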