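test_that("paralog status is assigned member-wise", {
  ann <- tiny_annotation()
  fam <- data.frame(
    family_id = c("f1", "f1", "f2", "f2", "f3", "f3", "f3"),
    gene_id = c("g07", "g08",          # both on X -> cis
                "g01", "g09",          # chr1 and X -> both trans
                "g02", "g03", "g04"),  # {1, 1, 2}: mixed
    stringsAsFactors = FALSE)
  st <- classify_paralog_status(ann, fam)
  status <- stats::setNames(st$status, st$gene_id)
  expect_equal(unname(status[c("g07", "g08")]), c("cis", "cis"))
  expect_equal(unname(status[c("g01", "g09")]), c("trans", "trans"))
  expect_equal(unname(status[c("g02", "g03")]), c("cis", "cis"))
  expect_equal(unname(status["g04"]), "trans")
  expect_equal(unname(status[c("g05", "g06")]), rep("non_paralog", 2))

  # invariant to member order and row order
  fam_shuffled <- fam[c(5, 2, 7, 1, 4, 3, 6), ]
  expect_equal(classify_paralog_status(ann, fam_shuffled), st)

  bad <- data.frame(family_id = "f9", gene_id = c("g01", "missing"))
  expect_error(classify_paralog_status(ann, bad), "absent")
})

test_that("rxe_by_group reduces to the unstratified RXE for a no-op partition", {
  fx <- log2_fixture(x_log2 = c(2, 3, 4), a_log2 = c(3, 4, 5, 6))
  all_map <- data.frame(gene_id = fx$annotation$gene_id, label = "all")
  by_grp <- rxe_by_group(fx$table, fx$annotation, all_map, no_treatment())
  expect_equal(nrow(by_grp), 1)
  expect_equal(by_grp$rxe,
               estimate_rxe(fx$table, fx$annotation, no_treatment())$rxe)
})

test_that("rxe_by_group marks one-sided labels undefined, not an error", {
  fx <- log2_fixture(x_log2 = c(2, 3), a_log2 = c(3, 4))
  auto_only <- fx$annotation$gene_id[fx$annotation$chromosome != "X"]
  gm <- rbind(data.frame(gene_id = auto_only, label = "autosomal_only"),
              data.frame(gene_id = fx$annotation$gene_id, label = "all"))
  out <- rxe_by_group(fx$table, fx$annotation, gm, no_treatment())
  expect_true(is.na(out$rxe[out$label == "autosomal_only"]))
  expect_false(is.na(out$rxe[out$label == "all"]))
})

test_that("a full partition recombines to the unstratified RXE", {
  cfg <- small_sim(seed = 18L)
  cat_ <- generate_catalog(cfg)
  ab <- simulate_true_expression(cat_, cfg)
  fr <- sample_fragments(ab, cat_, library_size = 30000L, config = cfg)
  et <- fpkm_from_counts(assign_fragments(fr, "NONUNIQUE_SPLICED"),
                         cat_$annotation)
  trt <- no_treatment()
  gm <- classify_paralog_status(cat_$annotation, cat_$families)
  out <- rxe_by_group(et, cat_$annotation, gm, trt)
  out <- out[!is.na(out$rxe), ]
  x_mean <- sum(out$x_summary * out$n_x) / sum(out$n_x)
  a_mean <- sum(out$a_summary * out$n_a) / sum(out$n_a)
  whole <- estimate_rxe(et, cat_$annotation, trt)
  expect_equal(x_mean - a_mean, whole$rxe, tolerance = 1e-9)
  expect_equal(sum(out$n_x), whole$n_x)
  expect_equal(sum(out$n_a), whole$n_a)
})

test_that("compensation planted on family genes is recovered by strata", {
  # simulate expression where only paralog-family X genes are compensated:
  # families should show a higher RXE than non-paralogs
  cfg <- small_sim(seed = 25L, n_x_genes = 120L, genes_per_autosome = 150L)
  cat_ <- generate_catalog(cfg)
  ab <- simulate_true_expression(cat_, cfg)
  on_x <- cat_$annotation$chromosome == "X"
  in_fam <- !is.na(cat_$annotation$paralog_family)
  ab[on_x & !in_fam] <- ab[on_x & !in_fam] * 0.5  # non-paralog X uncompensated
  tab <- make_table(cat_$annotation$gene_id,
                    ab / cat_$annotation$exon_length_bp)
  gm <- classify_paralog_status(cat_$annotation, cat_$families)
  gm$label <- ifelse(gm$status == "non_paralog", "non_paralog", "paralog")
  out <- rxe_by_group(tab, cat_$annotation, gm[, c("gene_id", "label")],
                      no_treatment())
  expect_gt(out$rxe[out$label == "paralog"],
            out$rxe[out$label == "non_paralog"])
})

test_that("paralog enrichment is the X fraction over the mean autosomal fraction", {
  ann <- data.frame(gene_id = sprintf("g%02d", 1:30),
                    chromosome = rep(c("1", "2", "X"), each = 10),
                    exon_length_bp = 1000L, n_exons = 1L,
                    biotype = "protein_coding")
  fam_for <- function(genes) data.frame(family_id = "f1", gene_id = genes)
  # X fraction 0.4, autosomal fractions {0.2, 0.2} -> 2.0
  fam <- fam_for(c(sprintf("g%02d", 1:2), sprintf("g%02d", 11:12),
                   sprintf("g%02d", 21:24)))
  expect_equal(paralog_enrichment(ann, fam), 2.0)
  # identical fractions -> 1.0
  fam_eq <- fam_for(c("g01", "g11", "g21"))
  expect_equal(paralog_enrichment(ann, fam_eq), 1.0)
  # no X paralogs -> 0
  expect_equal(paralog_enrichment(ann, fam_for(c("g01", "g02"))), 0)
  # X-only paralogs -> infinite with warning
  expect_warning(res <- paralog_enrichment(ann, fam_for(c("g21", "g22"))),
                 "infinite")
  expect_identical(res, Inf)
})

test_that("top-expressed composition counts categories with deterministic ties", {
  ann <- tiny_annotation()
  tab <- make_table(ann$gene_id, c(9, 8, 7, 6, 5, 4, 3, 2, 1))
  comp <- top_expressed_composition(tab, ann, n = 4)
  expect_equal(sum(comp), 4)
  expect_equal(unname(comp["small_rna"]), 1)   # g02
  expect_equal(unname(comp["riboprotein"]), 1) # g04
  # n larger than the table: counts sum to the table size
  comp_all <- top_expressed_composition(tab, ann, n = 250)
  expect_equal(sum(comp_all), 9)
  # boundary tie broken by lexicographic gene id
  tab_tie <- make_table(ann$gene_id, c(5, 5, 5, 5, 5, 5, 5, 5, 5))
  comp_tie <- top_expressed_composition(tab_tie, ann, n = 2)
  expect_equal(unname(comp_tie["small_rna"]), 1)  # g01 then g02 (small_rna)
})

test_that("ribo-depletion bias makes small RNAs the plurality of top genes", {
  cfg <- small_sim(seed = 41L,
                   biotype_mix = c(protein_coding = 0.7, small_rna = 0.15,
                                   riboprotein = 0.05, other = 0.1),
                   protocol_bias = list(
                     ribo_depletion = c(protein_coding = 1, small_rna = 200,
                                        riboprotein = 1, other = 1),
                     polyA = c(protein_coding = 1, small_rna = 0.05,
                               riboprotein = 200, other = 1)))
  cat_ <- generate_catalog(cfg)
  ab <- simulate_true_expression(cat_, cfg)
  fr <- sample_fragments(ab, cat_, library_size = 50000L, config = cfg)
  et <- fpkm_from_counts(assign_fragments(fr, "NONUNIQUE"), cat_$annotation)
  comp <- top_expressed_composition(et, cat_$annotation, n = 50)
  expect_equal(names(which.max(comp)), "small_rna")
})

test_that("depth titration is seeded and exact at full depth", {
  cfg <- small_sim(seed = 51L)
  cat_ <- generate_catalog(cfg)
  ab <- simulate_true_expression(cat_, cfg)
  fr <- sample_fragments(ab, cat_, library_size = 20000L, config = cfg)
  trt <- no_treatment()
  full <- estimate_rxe(fpkm_from_counts(
    assign_fragments(fr, "NONUNIQUE_SPLICED", seed = 2L), cat_$annotation),
    cat_$annotation, trt)
  curve <- depth_titration(fr, c(2000L, 20000L), "NONUNIQUE_SPLICED",
                           cat_$annotation, trt, seed = 2L)
  expect_equal(curve$rxe[curve$depth == 20000], full$rxe)
  curve2 <- depth_titration(fr, c(2000L, 20000L), "NONUNIQUE_SPLICED",
                            cat_$annotation, trt, seed = 2L)
  expect_identical(curve, curve2)
  expect_error(depth_titration(fr, 0L, "UNIQUE", cat_$annotation, trt), ">= 1")
  expect_error(depth_titration(fr, 1e7, "UNIQUE", cat_$annotation, trt),
               "exceeds")
})

test_that("RXE increases with sequencing depth on a paralog-enriched X", {
  # shallow libraries lack the power to assess lowly expressed genes and
  # paralogs: under the spliced multi-mapping pipeline the mean RXE at
  # shallow depth should not exceed the deep-depth mean
  diffs <- vapply(1:10, function(s) {
    cfg <- small_sim(seed = 600L + s, similarity_range = c(0.9, 1),
                     library_size = 1e5)
    cat_ <- generate_catalog(cfg)
    ab <- simulate_true_expression(cat_, cfg)
    fr <- sample_fragments(ab, cat_, config = cfg)
    curve <- depth_titration(fr, c(1000L, 100000L), "NONUNIQUE_SPLICED",
                             cat_$annotation, treatment_spec(), seed = s)
    curve$rxe[2] - curve$rxe[1]
  }, numeric(1))
  expect_gte(mean(diffs), 0)
})
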