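# hand-built de_result for container-level signature tests
mk_de <- function(genes, log2fc, padj, fpkm_a = 50, fpkm_b = 50,
                  p = padj / 2, status = "tested",
                  contrast = c("TG", "WT")) {
  de <- data.frame(gene_id = genes, log2fc = log2fc, p = p, padj = padj,
                   stringsAsFactors = FALSE)
  de[[paste0("mean_fpkm_", contrast[2])]] <- fpkm_a
  de[[paste0("mean_fpkm_", contrast[1])]] <- fpkm_b
  de$status <- status
  attr(de, "contrast") <- contrast
  class(de) <- c("de_result", "data.frame")
  de
}

test_that("core overlap intersects per-model significant sets", {
  genes <- paste0("g", 1:10)
  padjA <- rep(0.5, 10); padjA[1:3] <- 0.01   # up in A: g1 g2 g3
  padjB <- rep(0.5, 10); padjB[2:4] <- 0.01   # up in B: g2 g3 g4
  deA <- mk_de(genes, rep(1, 10), padjA)
  deB <- mk_de(genes, rep(1, 10), padjB)
  res <- core_overlap(deA, deB, "up")
  expect_setequal(res$core$members, c("g2", "g3"))
  expect_equal(res$enrichment$p, oracle_fisher_p(2, 1, 1, 6))
  # symmetry
  rev <- core_overlap(deB, deA, "up")
  expect_setequal(rev$core$members, res$core$members)
  expect_equal(rev$enrichment$p, res$enrichment$p)
  expect_equal(rev$enrichment$odds_ratio, res$enrichment$odds_ratio)
})

test_that("core overlap handles disjoint and identical inputs", {
  genes <- paste0("g", 1:10)
  padjA <- rep(0.5, 10); padjA[1:2] <- 0.01
  padjB <- rep(0.5, 10); padjB[5:6] <- 0.01
  res <- core_overlap(mk_de(genes, rep(1, 10), padjA),
                      mk_de(genes, rep(1, 10), padjB), "up")
  expect_length(res$core$members, 0)
  expect_lte(res$enrichment$odds_ratio, 1)
  deA <- mk_de(genes, rep(1, 10), padjA)
  same <- core_overlap(deA, deA, "up")
  expect_setequal(same$core$members, c("g1", "g2"))
  expect_error(core_overlap(deA, mk_de(paste0("x", 1:5), rep(1, 5),
                                       rep(0.5, 5)), "up"),
               "disjoint")
})

test_that("cross-species mapping keeps 1:1 orthologs and filters on FPKM", {
  orth <- data.frame(
    human_gene = c("H1", "H2", "H2", "H3", "H4", "H5", "H6"),
    mouse_gene = c("m1", "m2a", "m2b", "m3", "m4", "m5", "m6"),
    one_to_one = c(TRUE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE)
  )
  genes <- c("m1", "m3", "m4", "m5", "m6", "m7")
  # m5, m6 below the 10 FPKM filter; m1, m3 significant in A only
  pA <- c(0.01, 0.02, 0.5, 0.5, 0.5, 0.5)
  lowf <- c(50, 50, 50, 1, 2, 50)
  deA <- mk_de(genes, rep(1, 6), padj = pA * 2, p = pA,
               fpkm_a = lowf, fpkm_b = lowf)
  deB <- mk_de(genes, rep(1, 6), padj = rep(0.9, 6), p = rep(0.45, 6),
               fpkm_a = lowf, fpkm_b = lowf)
  res <- cross_species_compare(c("H1", "H2", "H3", "H4", "H5", "H6"),
                               orth, deA, deB, min_fpkm = 10)
  # H2 has two mouse orthologs -> dropped by the 1:1 rule
  expect_false(any(c("m2a", "m2b") %in% res$mapped))
  expect_setequal(res$filtered, c("m1", "m3", "m4"))
  tab <- res$table
  expect_equal(sort(tab$category_raw), sort(c("A_only", "A_only",
                                              "neither")))
  # tally partition: categories sum to the filtered genes
  expect_equal(res$tally_raw$total, nrow(tab))
  # raw-p tally is never smaller than the adjusted-p tally
  expect_gte(res$tally_raw$induced, res$tally_adj$induced)
  # min_fpkm = 0 keeps every mapped gene present in the DE tables
  res0 <- cross_species_compare(c("H1", "H3", "H4", "H5", "H6"),
                                orth, deA, deB, min_fpkm = 0)
  expect_setequal(res0$filtered, c("m1", "m3", "m4", "m5", "m6"))
})

test_that("category tallies always partition the filtered genes", {
  set.seed(33)
  genes <- paste0("m", 1:60)
  orth <- data.frame(human_gene = paste0("H", 1:60), mouse_gene = genes,
                     one_to_one = TRUE)
  pA <- runif(60); pB <- runif(60)
  deA <- mk_de(genes, rnorm(60), padj = pmin(1, pA * 2), p = pA)
  deB <- mk_de(genes, rnorm(60), padj = pmin(1, pB * 2), p = pB)
  res <- cross_species_compare(paste0("H", 1:60), orth, deA, deB,
                               min_fpkm = 10)
  counts <- table(factor(res$table$category_raw,
                         c("both", "A_only", "B_only", "neither")))
  expect_equal(sum(counts), length(res$filtered))
})

test_that("precocity test recovers a scaled early response", {
  # late signature: strong genes; early response planted at 0.3 x late
  set.seed(12)
  n <- 200
  genes <- paste0("g", 1:n)
  late_l2 <- runif(n, 1.2, 3)
  de <- mk_de(genes, late_l2, padj = rep(0.001, n))
  wt <- runif(n, 5, 50)
  tg <- wt * 2^(0.3 * late_l2) * exp(rnorm(n, 0, 0.05))
  early <- data.frame(gene_id = genes, fpkm_wt = wt, fpkm_tg = tg)
  res <- precocity_test(de, early, fold_threshold = 2)
  expect_equal(res$df, length(res$genes) - 1)
  expect_lt(res$p, 1e-6)
  expect_equal(res$mean_early_log2fc, 0.3 * mean(late_l2[2^late_l2 > 2]),
               tolerance = 0.05)
  # invariant to gene ordering
  perm <- sample.int(n)
  res_perm <- precocity_test(de[perm, ], early, fold_threshold = 2)
  expect_equal(res_perm$t, res$t)
  # approximately invariant to uniform rescaling (pseudocount is the
  # only absolute-scale term)
  early_scaled <- transform(early, fpkm_wt = fpkm_wt * 100,
                            fpkm_tg = fpkm_tg * 100)
  res_scaled <- precocity_test(de, early_scaled, fold_threshold = 2)
  expect_equal(res_scaled$t, res$t, tolerance = 0.05)
})

test_that("precocity test refuses degenerate inputs", {
  de3 <- mk_de(paste0("g", 1:2), c(2, 2), c(0.001, 0.001))
  early <- data.frame(gene_id = paste0("g", 1:2), fpkm_wt = c(1, 1),
                      fpkm_tg = c(2, 2))
  expect_error(precocity_test(de3, early), "fewer than 3")
  de4 <- mk_de(paste0("g", 1:4), rep(2, 4), rep(0.001, 4))
  flat <- data.frame(gene_id = paste0("g", 1:4), fpkm_wt = rep(2, 4),
                     fpkm_tg = rep(2, 4))
  expect_error(precocity_test(de4, flat), "degenerate")
})

test_that("regional concordance recovers correlation and slope", {
  genes <- paste0("g", 1:1000)
  set.seed(21)
  a <- rnorm(1000, 0, 1)
  deA <- mk_de(genes, a, padj = rep(0.5, 1000))
  # identical vectors: r = 1, slope = 1
  res_same <- suppressWarnings(regional_concordance(deA, deA))
  expect_equal(res_same$r, 1)
  expect_equal(res_same$slope, 1)
  # planted slope 0.33 with small noise
  b <- 0.33 * a + rnorm(1000, 0, 0.05)
  deB <- mk_de(genes, b, padj = rep(0.5, 1000))
  res <- regional_concordance(deA, deB)
  expect_equal(res$slope, 0.33, tolerance = 0.05)
  expect_true(res$slope_ci[1] < res$slope & res$slope < res$slope_ci[2])
  # independent vectors: r within 2/sqrt(n) of zero
  deC <- mk_de(genes, rnorm(1000), padj = rep(0.5, 1000))
  expect_lt(abs(regional_concordance(deA, deC)$r), 2 / sqrt(1000))
  # zero variance is an error
  deZ <- mk_de(genes, rep(1, 1000), padj = rep(0.5, 1000))
  expect_error(regional_concordance(deA, deZ), "variance")
})
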