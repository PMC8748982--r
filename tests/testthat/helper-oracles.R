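# Independent brute-force oracles used across the suite.

`%||%` <- function(a, b) if (is.null(a)) b else a

# two-sided Fisher exact p by enumeration of the hypergeometric
# distribution (minimum-likelihood rule): sum of the probabilities of
# all tables, at the observed margins, no more likely than the observed
oracle_fisher_p <- function(a, b, c, d) {
  N <- a + b + c + d
  K <- a + c          # reference-set margin
  nq <- a + b         # query margin
  x <- max(0, nq - (N - K)):min(K, nq)
  dens <- dhyper(x, K, N - K, nq)
  d_obs <- dhyper(a, K, N - K, nq)
  sum(dens[dens <= d_obs * (1 + 1e-7)])
}

# Benjamini-Hochberg step-up, written as the textbook procedure
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

# group-by-mean collapse oracle (explicit loop, no tapply)
oracle_collapse <- function(tab) {
  tb <- tab[!is.na(tab$gene_symbol) & tab$gene_symbol != "", ]
  genes <- sort(unique(tb$gene_symbol))
  data.frame(
    gene_symbol = genes,
    fc_stimA = vapply(genes, function(g)
      mean(tb$fc_stimA[tb$gene_symbol == g]), 0),
    fc_stimB = vapply(genes, function(g)
      mean(tb$fc_stimB[tb$gene_symbol == g]), 0),
    row.names = NULL
  )
}

# a random feasible configuration for the two-stimulus simulator;
# alternates between the null-free compact layout and the banded
# layout with null padding
random_stimulus_config <- function(seed) {
  set.seed(seed)
  if (runif(1) < 0.5) {
    nS <- sample(50:150, 1)
    nA <- sample(0:100, 1)
    nB <- sample(max(0, nA - 49):min(100, nA + 49), 1)
    stimulus_config(nA, nB, nS, n_null = 0, seed = seed)
  } else {
    nA <- sample(0:100, 1)
    nB <- sample(max(0, nA - 49):min(100, nA + 49), 1)
    nS <- sample((100 - min(nA, nB)):(250 - max(nA, nB)), 1)
    pad <- (250 - nA - nS) + (250 - nB - nS)
    stimulus_config(nA, nB, nS, n_null = pad + sample(0:200, 1),
                    seed = seed)
  }
}

# small deterministic count matrix for container-level tests
toy_count_matrix <- function() {
  counts <- matrix(
    c(1000L, 0L, 30L, 40L,
      500L, 2L, 35L, 45L,
      0L, 0L, 0L, 0L,
      1100L, 3L, 60L, 80L),
    nrow = 4, byrow = TRUE,
    dimnames = list(paste0("g", 1:4), NULL)
  )
  count_matrix(counts, c(g1 = 1000L, g2 = 2000L, g3 = 500L, g4 = 4000L),
               data.frame(sample_id = paste0("s", 1:4),
                          genotype = c("WT", "WT", "TG", "TG")))
}
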