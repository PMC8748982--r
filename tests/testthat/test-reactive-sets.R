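test_that("probe collapse averages multi-probe genes and drops unannotated", {
  tab <- data.frame(
    probe_id = paste0("p", 1:5),
    gene_symbol = c("A", "A", "B", NA, ""),
    fc_stimA = c(2, 4, 5, 9, 9),
    fc_stimB = c(1, 3, 2, 9, 9)
  )
  got <- collapse_probes(tab)
  expect_equal(got$fc_stimA[got$gene_symbol == "A"], 3)  # mean(2, 4)
  expect_equal(got$fc_stimB[got$gene_symbol == "A"], 2)
  expect_setequal(got$gene_symbol, c("A", "B"))

  # single-probe tables pass through (minus unannotated rows)
  tab1 <- data.frame(probe_id = paste0("p", 1:3),
                     gene_symbol = c("X", "Y", NA),
                     fc_stimA = c(3, 7, 1), fc_stimB = c(2, 5, 1))
  got1 <- collapse_probes(tab1)
  expect_equal(got1[order(got1$gene_symbol), ]$fc_stimA, c(3, 7))

  # random tables with 1-3 probes per gene match the loop oracle
  set.seed(7)
  for (rep in 1:5) {
    genes <- paste0("G", 1:40)
    npp <- sample(1:3, 40, replace = TRUE)
    tb <- data.frame(
      probe_id = paste0("p", seq_len(sum(npp))),
      gene_symbol = rep(genes, npp),
      fc_stimA = runif(sum(npp), 0.5, 20),
      fc_stimB = runif(sum(npp), 0.5, 20)
    )
    got <- collapse_probes(tb)
    ora <- oracle_collapse(tb)
    expect_equal(got[order(got$gene_symbol), ],
                 ora[order(ora$gene_symbol), ],
                 ignore_attr = TRUE)
  }

  expect_warning(collapse_probes(
    data.frame(probe_id = "p1", gene_symbol = NA, fc_stimA = 1,
               fc_stimB = 1)), "unannotated")
})

test_that("ranking is 1 = highest fold change with lexicographic ties", {
  ctb <- data.frame(gene_symbol = c("a", "b", "c"),
                    fc_stimA = c(5, 3, 8), fc_stimB = c(1, 2, 3))
  rk <- rank_genes(ctb)
  expect_equal(rk$rank_stimA, c(2, 3, 1))
  expect_equal(rk$rank_stimB, c(3, 2, 1))

  tie <- data.frame(gene_symbol = c("Bbb", "Aaa"),
                    fc_stimA = c(4, 4), fc_stimB = c(4, 4))
  rk2 <- rank_genes(tie)
  expect_equal(rk2$rank_stimA[rk2$gene_symbol == "Aaa"], 1)
  expect_equal(rk2$rank_stimA[rk2$gene_symbol == "Bbb"], 2)

  single <- rank_genes(data.frame(gene_symbol = "only",
                                  fc_stimA = 2, fc_stimB = 2))
  expect_equal(single$rank_stimA, 1)
  expect_equal(single$rank_stimB, 1)

  expect_error(rank_genes(data.frame(gene_symbol = c("x", "x"),
                                     fc_stimA = 1:2, fc_stimB = 1:2)),
               "duplicate")
})

# a ranked table where most genes sit on the diagonal and selected
# genes get the rank pairs under test
ranked_with <- function(pairs, n = 300) {
  ra <- seq_len(n); rb <- seq_len(n)
  for (p in pairs) {  # swap to keep rb a permutation
    i <- p[1]; j <- p[2]
    rb[c(i, j)] <- c(j, i)
  }
  data.frame(gene_symbol = sprintf("g%03d", seq_len(n)),
             fc_stimA = n:1, fc_stimB = n:1,
             rank_stimA = ra, rank_stimB = rb)
}

test_that("classification applies the rank windows and separation rules", {
  rk <- ranked_with(list(c(120, 140)))
  sets <- classify_reactive(rk)
  # both ranks within 250 and 20 apart, neither specific rule met
  expect_true("g120" %in% sets$pan$members)

  # boundary: separation exactly met goes specific, not pan
  rk50 <- ranked_with(list(c(40, 90)))
  s50 <- classify_reactive(rk50)
  expect_true("g040" %in% s50$lps$members)
  expect_false("g040" %in% s50$pan$members)

  expect_error(classify_reactive(rk, separation = -1), "separation")
  bad <- rk; bad$rank_stimA[1] <- 999
  expect_error(classify_reactive(bad), "permutation")
})

test_that("the three reactive sets are pairwise disjoint on any input", {
  for (seed in c(11, 12, 13)) {
    sim <- simulate_stimulus_fc_table(random_stimulus_config(seed))
    sets <- classify_reactive(rank_genes(collapse_probes(sim$table)))
    expect_length(intersect(sets$lps$members, sets$mcao$members), 0)
    expect_length(intersect(sets$lps$members, sets$pan$members), 0)
    expect_length(intersect(sets$mcao$members, sets$pan$members), 0)
  }
})

test_that("enlarging the specific window only grows the specific sets", {
  sim <- simulate_stimulus_fc_table(random_stimulus_config(21))
  rk <- rank_genes(collapse_probes(sim$table))
  s100 <- classify_reactive(rk, top_specific = 100)
  s150 <- classify_reactive(rk, top_specific = 150)
  expect_true(all(s100$lps$members %in% s150$lps$members))
  expect_true(all(s100$mcao$members %in% s150$mcao$members))
})

test_that("classification is invariant to input row order", {
  sim <- simulate_stimulus_fc_table(stimulus_config(seed = 31))
  rk <- rank_genes(collapse_probes(sim$table))
  set.seed(1)
  rk_shuf <- rk[sample.int(nrow(rk)), ]
  a <- classify_reactive(rk)
  b <- classify_reactive(rk_shuf)
  expect_setequal(a$lps$members, b$lps$members)
  expect_setequal(a$mcao$members, b$mcao$members)
  expect_setequal(a$pan$members, b$pan$members)
})

test_that("expression filtering removes set genes below the cut-off", {
  sets <- classify_reactive(ranked_with(list(c(10, 30))))
  pan_genes <- sets$pan$members
  # build an expression table where one pan gene dips below 1 FPKM in
  # one condition
  drop_gene <- pan_genes[1]
  genes <- sets$audit$gene_symbol
  cnt <- matrix(1000L, nrow = length(genes), ncol = 4,
                dimnames = list(genes, NULL))
  cnt[drop_gene, 3:4] <- 0L
  cm <- count_matrix(cnt, setNames(rep(1000L, length(genes)), genes),
                     data.frame(sample_id = paste0("s", 1:4),
                                genotype = c("WT", "WT", "TG", "TG")))
  expr <- compute_fpkm(cm)
  filt <- filter_expressed(sets, expr, min_fpkm = 1)
  expect_false(drop_gene %in% filt$pan$members)
  expect_setequal(filt$pan$members, setdiff(pan_genes, drop_gene))
  # and is the identity when everything is expressed
  cnt[drop_gene, 3:4] <- 1000L
  expr_all <- compute_fpkm(count_matrix(
    cnt, setNames(rep(1000L, length(genes)), genes), cm$samples))
  filt_all <- filter_expressed(sets, expr_all, min_fpkm = 1)
  expect_setequal(filt_all$pan$members, pan_genes)
})

test_that("marker upregulation fractions count k of m expressed markers", {
  # strong, low-noise effects so every planted marker is detectable
  cfg <- sim_config(n_genes = 500, frac_induced = 0.1,
                    frac_repressed = 0, effect_log2fc = 2,
                    dispersion = 0.01,
                    mean_log10_expr_range = c(2.5, 3.5), seed = 77)
  sim <- simulate_translatome(cfg)
  de <- differential_expression(sim$counts, c("TG", "WT"))
  ind <- sim$truth$gene_id[sim$truth$label == "induced"]
  # all markers planted induced at high expression: k = m
  res <- marker_upregulation_fraction(ind, de)
  expect_equal(res$k, res$m)
  expect_equal(res$m, length(ind))
  # markers below the expression filter are discarded from m
  null_genes <- sim$truth$gene_id[sim$truth$label == "null"][1:10]
  res2 <- marker_upregulation_fraction(c(ind[1:4], null_genes), de)
  expect_equal(res2$k, 4)
  expect_equal(res2$m, 14)
  expect_error(marker_upregulation_fraction(character(0), de), "empty")
})
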