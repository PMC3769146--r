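test_that("prepare_values applies treatments in order and excludes Y/MT", {
  ann <- rbind(tiny_annotation(),
               data.frame(gene_id = c("y1", "m1"), chromosome = c("Y", "MT"),
                          exon_length_bp = 1000L, n_exons = 1L,
                          biotype = "protein_coding"))
  tab <- make_table(ann$gene_id, c(4, 0, 8, 2, 2, 2, 4, 0, 8, 100, 100))
  grouped <- prepare_values(tab, ann, no_treatment())
  expect_false(any(c("Y", "MT") %in% names(grouped)))
  # drop_zeros then log2: chromosome 1 had FPKM {4, 0, 8} -> log2 {2, 3}
  expect_equal(grouped[["1"]], c(2, 3))
  expect_equal(grouped[["X"]], c(2, 3))

  # min_fpkm prefilter leaves no retained FPKM < 1
  trt <- treatment_spec(outlier = "none", prefilter = "min_fpkm", min_fpkm = 1)
  tab2 <- make_table(ann$gene_id, c(0.5, 0.9, 8, 2, 2, 2, 0.2, 1, 8, 10, 10))
  grouped2 <- prepare_values(tab2, ann, trt)
  expect_true(all(unlist(grouped2) >= 0))  # log2(fpkm >= 1) >= 0

  # deterministic: identical runs give identical output
  expect_identical(prepare_values(tab, ann, treatment_spec()),
                   prepare_values(tab, ann, treatment_spec()))
})

test_that("tukey_outliers removes values outside the hinge fences", {
  # hinges of {10,11,12,12,13,120} are 11 and 13 -> fences [8, 16]
  expect_equal(tukey_outliers(c(10, 11, 12, 12, 13, 120), k = 1.5),
               c(10, 11, 12, 12, 13))
  # constant data: IQR 0, closed fences retain everything
  expect_equal(tukey_outliers(rep(5, 10)), rep(5, 10))
  # infinite k retains everything
  v <- c(-100, 0, 1e6)
  expect_equal(tukey_outliers(v, k = Inf), v)
  expect_equal(tukey_outliers(numeric(0)), numeric(0))
})

test_that("tukey_outliers agrees with an exhaustive fence-check oracle", {
  oracle <- function(values, k) {
    s <- sort(values)
    n <- length(s)
    half <- ceiling(n / 2)
    q1 <- stats::median(s[seq_len(half)])
    q3 <- stats::median(s[seq(n - half + 1, n)])
    keep <- logical(length(values))
    for (i in seq_along(values)) {
      keep[i] <- values[i] >= q1 - k * (q3 - q1) &&
        values[i] <= q3 + k * (q3 - q1)
    }
    values[keep]
  }
  withr::with_seed(20240917, {
    for (i in 1:1000) {
      n <- sample(1:25, 1)
      v <- round(stats::rnorm(n, sd = sample(c(0.5, 2, 20), 1)), 2)
      k <- sample(c(0.5, 1.5, 3), 1)
      expect_identical(tukey_outliers(v, k = k), oracle(v, k))
    }
  })
})

test_that("compute_rxe matches hand-computed group differences", {
  # X one log2 unit below the autosomes: no compensation, RXE = -1
  expect_equal(compute_rxe(list(`1` = c(3, 4), `2` = 5, X = c(2, 3, 4)))$rxe, -1)
  # identical distributions: full compensation, RXE = 0
  expect_equal(compute_rxe(list(`1` = c(1, 2, 3), X = c(1, 2, 3)))$rxe, 0)
  # X one unit above: twice the autosomal expression, RXE = +1
  expect_equal(compute_rxe(list(`1` = c(3, 4), `2` = 5, X = c(4, 5, 6)))$rxe, 1)
  res <- compute_rxe(list(`1` = c(3, 4), `2` = 5, X = c(2, 3, 4)))
  expect_equal(res$n_x, 3)
  expect_equal(res$n_a, 3)
  expect_error(compute_rxe(list(`1` = c(1, 2))), "X chromosome")
})

test_that("compute_rxe pools autosomal genes and matches a brute-force oracle", {
  withr::with_seed(42, {
    for (i in 1:25) {
      n_chr <- sample(2:5, 1)
      grouped <- c(
        stats::setNames(lapply(seq_len(n_chr),
                               function(i) stats::rnorm(sample(1:15, 1))),
                        as.character(seq_len(n_chr))),
        list(X = stats::rnorm(sample(1:15, 1))))
      # brute force: sum/count difference over pooled gene-level values
      a <- unlist(grouped[as.character(seq_len(n_chr))])
      oracle <- sum(grouped$X) / length(grouped$X) - sum(a) / length(a)
      expect_equal(compute_rxe(grouped)$rxe, oracle, tolerance = 1e-12)
    }
  })
})

test_that("compute_rxe is location-equivariant in the X values", {
  withr::with_seed(7, {
    grouped <- list(`1` = stats::rnorm(20), `2` = stats::rnorm(10),
                    X = stats::rnorm(15))
    base <- compute_rxe(grouped)$rxe
    for (delta in c(-2, 0.5, 3.14)) {
      shifted <- grouped
      shifted$X <- shifted$X + delta
      expect_equal(compute_rxe(shifted)$rxe, base + delta, tolerance = 1e-12)
    }
  })
})

test_that("rxe_to_ratio back-transforms to the linear X:A scale", {
  expect_equal(rxe_to_ratio(-1), 0.5)
  expect_equal(rxe_to_ratio(0), 1)
  expect_equal(round(rxe_to_ratio(-1.43), 2), 0.37)
  expect_equal(round(rxe_to_ratio(-0.32), 2), 0.8)
})

test_that("chromosome_relative_expression uses leave-one-out autosome references", {
  # identical chromosomes: all relative values 0
  grouped <- list(`1` = c(1, 2, 3), `2` = c(1, 2, 3), `3` = c(1, 2, 3),
                  X = c(1, 2, 3))
  expect_equal(unname(chromosome_relative_expression(grouped)), rep(0, 4))

  # equal-sized autosomes with means {3,4,5}: rel of mean-3 autosome = -1.5
  g2 <- list(`1` = c(2.5, 3.5), `2` = c(3.5, 4.5), `3` = c(4.5, 5.5),
             X = c(4, 4))
  rel <- chromosome_relative_expression(g2)
  expect_equal(rel[["1"]], 3 - 4.5)
  # for X the reference pools all autosomes: agreement with compute_rxe
  expect_equal(rel[["X"]], compute_rxe(g2)$rxe)
  expect_error(chromosome_relative_expression(list(`1` = 1, X = 1)),
               "2 autosomes")
})

test_that("zero_balanced_trim removes zeros plus a compensatory upper tail", {
  expect_equal(zero_balanced_trim(c(0, 0, 1, 2, 3, 9, 10)), c(1, 2, 3))
  v <- c(5, 1, 3)
  expect_equal(zero_balanced_trim(v), v)  # no zeros: unchanged
  expect_warning(out <- zero_balanced_trim(c(0, 0, 0)), "empt")
  expect_length(out, 0)
  # ties at the cut: earliest input removed first
  expect_equal(zero_balanced_trim(c(5, 0, 5, 2)), c(5, 2))
  expect_warning(out2 <- zero_balanced_trim(c(7, 0, 7, 0, 1)), "half")
  expect_equal(out2, 1)
})

test_that("ranksum_test matches exact enumeration and degenerate cases", {
  res <- ranksum_test(c(1, 2), c(3, 4))
  expect_equal(res$U, 0)
  expect_equal(res$p, 1 / 3, tolerance = 1e-12)  # 2/6 rank arrangements
  expect_equal(ranksum_test(c(1, 2, 3), c(4, 5, 6))$U, 0)
  # identical lists: U = n1 * n2 / 2
  expect_equal(ranksum_test(c(1, 2, 3), c(1, 2, 3))$U, 4.5)
  expect_error(ranksum_test(numeric(0), 1), "non-empty")
})

test_that("min_fpkm trimming never decreases mean RXE when X has the heavier low tail", {
  withr::with_seed(99, {
    for (i in 1:10) {
      n <- 120
      ann <- data.frame(gene_id = sprintf("g%03d", 1:(2 * n)),
                        chromosome = rep(c("1", "2", "X", "X"), each = n / 2),
                        exon_length_bp = 1000L, n_exons = 1L,
                        biotype = "protein_coding")
      # X shifted down: heavier mass below the FPKM = 1 cutoff
      fpkm <- 2^c(stats::rnorm(n, 1, 2), stats::rnorm(n, 0, 2))
      tab <- make_table(ann$gene_id, fpkm)
      base <- estimate_rxe(tab, ann, no_treatment())$rxe
      trimmed <- estimate_rxe(tab, ann,
                              treatment_spec(outlier = "none",
                                             prefilter = "min_fpkm",
                                             min_fpkm = 1))$rxe
      expect_gte(trimmed, base)
    }
  })
})
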