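#' Simulation configuration
#'
#' Holds the study conditions for the synthetic translatome and rescue
#' generators. Defaults mirror the emulated experimental design: four
#' mice per genotype, a modest induced/repressed fraction with a planted
#' |log2FC| of 1, negative-binomial noise with dispersion 0.05 (variance
#' mu + alpha mu^2), baseline expression spanning roughly three decades,
#' and complete rescue in the intervention cross.
#'
#' @param n_genes number of genes (> 0).
#' @param n_per_group replicates per genotype (default 4).
#' @param frac_induced,frac_repressed proportions of genes planted
#'   induced / repressed; their sum must not exceed 1.
#' @param effect_log2fc planted |log2 fold change|.
#' @param dispersion NB dispersion alpha (> 0).
#' @param mean_log10_expr_range range of log10 baseline mean counts at
#'   the reference library size (1e7).
#' @param rescue_factor in `[0, 1]`: 1 = the disease signature is fully
#'   rescued in the disease x intervention genotype, 0 = not at all.
#' @param seed integer seed; identical seeds give bit-identical output.
#' @return object of class `sim_config` (validated list).
#' @export
sim_config <- function(n_genes = 2000, n_per_group = 4,
                       frac_induced = 0.05, frac_repressed = 0.05,
                       effect_log2fc = 1, dispersion = 0.05,
                       mean_log10_expr_range = c(0.5, 3),
                       rescue_factor = 1, seed = 1) {
  if (n_genes < 1 || n_genes != round(n_genes)) {
    stop("n_genes must be a positive integer")
  }
  if (n_per_group < 1 || n_per_group != round(n_per_group)) {
    stop("n_per_group must be a positive integer")
  }
  if (frac_induced < 0 || frac_repressed < 0 ||
      frac_induced + frac_repressed > 1) {
    stop("frac_induced + frac_repressed must lie in [0, 1]")
  }
  if (dispersion <= 0) stop("dispersion must be positive")
  if (rescue_factor < 0 || rescue_factor > 1) {
    stop("rescue_factor must lie in [0, 1]")
  }
  stopifnot(length(mean_log10_expr_range) == 2)
  structure(list(n_genes = as.integer(n_genes),
                 n_per_group = as.integer(n_per_group),
                 frac_induced = frac_induced,
                 frac_repressed = frac_repressed,
                 effect_log2fc = effect_log2fc,
                 dispersion = dispersion,
                 mean_log10_expr_range = mean_log10_expr_range,
                 rescue_factor = rescue_factor,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# shared machinery: baseline means, lengths, labels, NB counts
sim_backbone <- function(config) {
  n <- config$n_genes
  gene_id <- sprintf("gene%05d", seq_len(n))
  length_bp <- round(10^runif(n, log10(500), log10(10000)))
  base <- 10^runif(n, config$mean_log10_expr_range[1],
                   config$mean_log10_expr_range[2])
  n_ind <- round(config$frac_induced * n)
  n_rep <- round(config$frac_repressed * n)
  lab <- rep("null", n)
  pick <- sample.int(n, n_ind + n_rep)
  lab[pick[seq_len(n_ind)]] <- "induced"
  if (n_rep > 0) lab[pick[n_ind + seq_len(n_rep)]] <- "repressed"
  sign <- ifelse(lab == "induced", 1, ifelse(lab == "repressed", -1, 0))
  list(gene_id = gene_id, length_bp = length_bp, base = base,
       label = lab, sign = sign)
}

nb_counts <- function(mu, dispersion) {
  matrix(rnbinom(length(mu), mu = mu, size = 1 / dispersion),
         nrow = nrow(mu), dimnames = dimnames(mu))
}

#' Simulate a two-genotype translatome count matrix with planted truth
#'
#' Two groups (WT, TG) of `n_per_group` samples each. Planted induced
#' genes have expected log2FC `+effect_log2fc` in TG, repressed genes
#' the negative, null genes zero. Gene lengths are log-uniform in
#' 0.5-10 kb; library sizes log-normal around 1e7, and expected counts
#' scale with library size so that median-of-ratios normalisation is
#' exercised.
#'
#' @param config a [sim_config()].
#' @return list with `counts` (a [count_matrix()]) and `truth`
#'   (data.frame `gene_id`, `label` in induced/repressed/null).
#' @export
simulate_translatome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    bb <- sim_backbone(config)
    np <- config$n_per_group
    lib <- rlnorm(2 * np, log(1e7), 0.15)
    geno <- rep(c("WT", "TG"), each = np)
    fc <- 2^(bb$sign * config$effect_log2fc)
    mu <- outer(bb$base, lib / 1e7) *
      cbind(matrix(1, config$n_genes, np),
            matrix(fc, config$n_genes, np))
    dimnames(mu) <- list(bb$gene_id,
                         paste0(geno, rep(seq_len(np), 2)))
    cm <- count_matrix(
      nb_counts(mu, config$dispersion), bb$length_bp,
      data.frame(sample_id = colnames(mu), genotype = geno,
                 region = "cortex", stage = "late")
    )
    list(counts = cm,
         truth = data.frame(gene_id = bb$gene_id, label = bb$label,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate a four-genotype factorial rescue experiment
#'
#' Genotypes WT, NRF2 (intervention alone), TG (disease) and TGxNRF2
#' (disease x intervention), `n_per_group` samples each. TG vs WT
#' carries the planted signature (`+/- effect_log2fc`); TGxNRF2 vs NRF2
#' carries it attenuated to `(1 - rescue_factor)` of the effect on the
#' log2 scale; NRF2 vs WT is null for signature genes (the intervention
#' leaves basal expression unaffected).
#'
#' @param config a [sim_config()].
#' @return list with `counts` (a [count_matrix()] over the four
#'   genotypes) and `truth` as in [simulate_translatome()].
#' @export
simulate_rescue_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed + 3L, {
    bb <- sim_backbone(config)
    np <- config$n_per_group
    genos <- c("WT", "NRF2", "TG", "TGxNRF2")
    lib <- rlnorm(4 * np, log(1e7), 0.15)
    geno <- rep(genos, each = np)
    eff <- bb$sign * config$effect_log2fc
    mult <- cbind(WT = rep(1, config$n_genes), NRF2 = 1,
                  TG = 2^eff, TGxNRF2 = 2^(eff * (1 - config$rescue_factor)))
    mu <- outer(bb$base, lib / 1e7) * mult[, geno]
    dimnames(mu) <- list(bb$gene_id,
                         paste0(geno, rep(seq_len(np), 4)))
    cm <- count_matrix(
      nb_counts(mu, config$dispersion), bb$length_bp,
      data.frame(sample_id = colnames(mu), genotype = geno,
                 region = "cortex", stage = "late")
    )
    list(counts = cm,
         truth = data.frame(gene_id = bb$gene_id, label = bb$label,
                            stringsAsFactors = FALSE))
  })
}

#' Configuration for the two-stimulus fold-change simulator
#'
#' Class sizes for the planted stimulus-A-specific, stimulus-B-specific,
#' shared (pan-reactive) and null genes, plus a probes-per-gene
#' distribution. Defaults mirror the published set sizes (70 / 70 / 42)
#' with 400 null genes.
#'
#' Exact recoverability constrains the class sizes: every gene ranked
#' within the specific window in either stimulus is necessarily
#' classified, so the planted non-null genes must tile both top-100s
#' (the "banded" layout, requiring `n_specific + n_shared >= 100` per
#' stimulus and enough null genes to pad the rank bands), or the table
#' must contain no null genes at all (the "compact" layout for small
#' tables). Infeasible combinations are rejected with an informative
#' error.
#'
#' @param n_stimA_specific,n_stimB_specific,n_shared,n_null class
#'   sizes.
#' @param max_probes_per_gene probes per gene are uniform on
#'   1..`max_probes_per_gene` (default 3).
#' @param frac_unannotated fraction of additional unannotated probes
#'   added to the table (default 0.05).
#' @param top_specific,top_pan,separation the classifier windows the
#'   layout is built for (defaults 100 / 250 / 50).
#' @param seed integer seed.
#' @return object of class `stimulus_config`.
#' @export
stimulus_config <- function(n_stimA_specific = 70, n_stimB_specific = 70,
                            n_shared = 42, n_null = 400,
                            max_probes_per_gene = 3,
                            frac_unannotated = 0.05,
                            top_specific = 100, top_pan = 250,
                            separation = 50, seed = 1) {
  cfg <- structure(
    list(nA = as.integer(n_stimA_specific),
         nB = as.integer(n_stimB_specific),
         nS = as.integer(n_shared), nNull = as.integer(n_null),
         max_probes_per_gene = as.integer(max_probes_per_gene),
         frac_unannotated = frac_unannotated,
         top_specific = top_specific, top_pan = top_pan,
         separation = separation, seed = as.integer(seed)),
    class = "stimulus_config")
  validate_stimulus_layout(cfg)   # fail fast on infeasible configs
  cfg
}

# decide which rank layout a config admits; error when neither does
validate_stimulus_layout <- function(cfg) {
  ts <- cfg$top_specific; tp <- cfg$top_pan; sep <- cfg$separation
  nA <- cfg$nA; nB <- cfg$nB; nS <- cfg$nS; nNull <- cfg$nNull
  if (min(nA, nB, nS, nNull) < 0) stop("negative class size")
  if (nA + nB + nS == 0) stop("no non-null genes requested")
  if (nA > ts || nB > ts) {
    stop("specific class sizes cannot exceed top_specific (", ts, ")")
  }
  if (nS > 0 && abs(nA - nB) > sep - 1) {
    stop("|n_stimA_specific - n_stimB_specific| must be < separation ",
         "when shared genes are planted")
  }
  if (nNull == 0) {
    ok <- (nA == 0 || nB + nS >= sep) && (nB == 0 || nA + nS >= sep) &&
      (max(nA, nB) + nS <= tp)
    if (!ok) {
      stop("infeasible null-free layout: need >= ", sep,
           " genes ranked between a specific gene's two ranks, and ",
           "shared genes within top_pan")
    }
    return("compact")
  }
  if (nA + nS < ts || nB + nS < ts) {
    stop("with null genes present, specific + shared must cover the ",
         "top ", ts, " of each stimulus (every gene ranked there is ",
         "necessarily classified)")
  }
  if (nA + nS > tp || nB + nS > tp) {
    stop("specific + shared classes exceed top_pan (", tp, ")")
  }
  pad <- (tp - nA - nS) + (tp - nB - nS)
  if (nNull < pad) {
    stop("need at least ", pad, " null genes to pad the rank bands ",
         "between the planted classes and ", tp)
  }
  "banded"
}

# build the rank permutation realising the planted classes
stimulus_rank_layout <- function(cfg) {
  scheme <- validate_stimulus_layout(cfg)
  nA <- cfg$nA; nB <- cfg$nB; nS <- cfg$nS; nNull <- cfg$nNull
  tp <- cfg$top_pan
  n <- nA + nB + nS + nNull
  label <- c(rep("stimA_specific", nA), rep("stimB_specific", nB),
             rep("shared", nS), rep("null", nNull))
  ra <- rb <- integer(n)
  iA <- seq_len(nA); iB <- nA + seq_len(nB); iS <- nA + nB + seq_len(nS)
  iN <- nA + nB + nS + seq_len(nNull)
  if (scheme == "compact") {
    ra[iA] <- iA;            rb[iA] <- nB + nS + seq_len(nA)
    rb[iB] <- seq_len(nB);   ra[iB] <- nA + nS + seq_len(nB)
    ra[iS] <- nA + seq_len(nS); rb[iS] <- nB + seq_len(nS)
  } else {
    c1 <- tp - nA - nS; c2 <- tp - nB - nS
    ra[iA] <- iA;            rb[iA] <- tp + seq_len(nA)
    rb[iB] <- seq_len(nB);   ra[iB] <- tp + seq_len(nB)
    ra[iS] <- nA + seq_len(nS); rb[iS] <- nB + seq_len(nS)
    # null genes pad the 101..250 band of each stimulus (their other
    # rank sits beyond top_pan), remainder sink below both top_pans
    n1 <- iN[seq_len(c1)]
    n2 <- iN[c1 + seq_len(c2)]
    nr <- iN[-seq_len(c1 + c2)]
    ra[n1] <- nA + nS + seq_len(c1); rb[n1] <- tp + nA + seq_len(c1)
    rb[n2] <- nB + nS + seq_len(c2); ra[n2] <- tp + nB + seq_len(c2)
    ra[nr] <- tp + nB + c2 + seq_along(nr)
    rb[nr] <- tp + nA + c1 + seq_along(nr)
  }
  list(label = label, rank_stimA = ra, rank_stimB = rb)
}

#' Simulate a probe-level two-stimulus fold-change table
#'
#' Generates probe-level fold changes for two acute stimuli such that,
#' after [collapse_probes()] and [rank_genes()], the planted
#' stimulus-specific genes satisfy the stimulus-specific rule, shared
#' genes the pan rule, and null genes neither. Fold changes are drawn
#' strictly decreasing along the constructed rank layout; genes may be
#' carried by several probes whose values average exactly to the gene
#' value, and a fraction of unannotated probes is mixed in. The emitted
#' table is verified internally by running the classifier and comparing
#' with the planted truth before being returned.
#'
#' @param config a [stimulus_config()].
#' @return list with `table` (probe-level data.frame: `probe_id`,
#'   `gene_symbol`, `fc_stimA`, `fc_stimB`, in shuffled row order) and
#'   `truth` (data.frame `gene_symbol`, `label`).
#' @export
simulate_stimulus_fc_table <- function(config) {
  stopifnot(inherits(config, "stimulus_config"))
  withr::with_seed(config$seed + 1L, {
    lay <- stimulus_rank_layout(config)
    n <- length(lay$label)
    gene <- sprintf("Gene%05d", seq_len(n))
    # strictly decreasing positive fold changes indexed by rank
    fc_of_rank <- function() {
      sort(exp(runif(n, log(1.02), log(60))), decreasing = TRUE)
    }
    fa <- fc_of_rank()[lay$rank_stimA]
    fb <- fc_of_rank()[lay$rank_stimB]

    npp <- sample.int(config$max_probes_per_gene, n, replace = TRUE)
    idx <- rep.int(seq_len(n), npp)
    # per-probe multiplicative jitter averaging to exactly 1 per gene
    jit <- unlist(lapply(npp, function(k) {
      u <- runif(k); 1 + (u - mean(u)) * 0.05
    }), use.names = FALSE)
    tab <- data.frame(
      gene_symbol = gene[idx],
      fc_stimA = fa[idx] * jit,
      fc_stimB = fb[idx] * jit,
      stringsAsFactors = FALSE
    )
    n_un <- round(config$frac_unannotated * n)
    if (n_un > 0) {
      tab <- rbind(tab, data.frame(
        gene_symbol = NA_character_,
        fc_stimA = exp(runif(n_un, log(1.02), log(60))),
        fc_stimB = exp(runif(n_un, log(1.02), log(60)))
      ))
    }
    tab <- tab[sample.int(nrow(tab)), , drop = FALSE]
    tab <- data.frame(probe_id = sprintf("probe%06d", seq_len(nrow(tab))),
                      tab, row.names = NULL, stringsAsFactors = FALSE)
    truth <- data.frame(gene_symbol = gene, label = lay$label,
                        stringsAsFactors = FALSE)

    # internal verification: the emitted table must be recoverable
    sets <- classify_reactive(
      rank_genes(collapse_probes(tab)),
      top_specific = config$top_specific, top_pan = config$top_pan,
      separation = config$separation)
    ok <- setequal(sets$lps$members,
                   gene[lay$label == "stimA_specific"]) &&
      setequal(sets$mcao$members,
               gene[lay$label == "stimB_specific"]) &&
      setequal(sets$pan$members, gene[lay$label == "shared"])
    if (!ok) stop("internal error: emitted table is not ",
                  "classifier-recoverable")
    list(table = tab, truth = truth)
  })
}

#' Simulate a gene-level GWAS p-value table with planted enrichment
#'
#' Each gene is marked a risk gene with baseline probability
#' `risk_fraction`; for genes listed in `induced_genes` the odds of
#' being a risk gene are multiplied by `induced_bias` (1 = no planted
#' enrichment, the null table). Risk genes receive p values below the
#' smallest sweep cutoff (uniform on `[0, 0.05 / n_genes)`), non-risk
#' genes uniform p values on `[0, 1]`.
#'
#' @param genes character vector of gene identifiers (non-empty).
#' @param risk_fraction baseline risk probability, in `[0, 1]`.
#' @param induced_bias odds multiplier for induced genes (>= 1).
#' @param seed integer seed.
#' @param induced_genes character vector of planted induced genes.
#' @return list with `gwas` (data.frame `gene_id`, `p`) and `truth`
#'   (data.frame `gene_id`, `label` in risk/non_risk).
#' @export
simulate_gwas_table <- function(genes, risk_fraction = 0.02,
                                induced_bias = 1, seed = 1,
                                induced_genes = character()) {
  if (!length(genes)) stop("genes must be non-empty")
  if (risk_fraction < 0 || risk_fraction > 1) {
    stop("risk_fraction must lie in [0, 1]")
  }
  if (induced_bias < 1) stop("induced_bias must be >= 1")
  withr::with_seed(as.integer(seed) + 2L, {
    n <- length(genes)
    pr <- rep(risk_fraction, n)
    if (risk_fraction > 0 && risk_fraction < 1) {
      odds <- risk_fraction / (1 - risk_fraction) * induced_bias
      pr[genes %in% induced_genes] <- odds / (1 + odds)
    }
    risk <- rbinom(n, 1, pr) == 1
    p <- runif(n)
    p[risk] <- runif(sum(risk), 0, 0.05 / n * 0.99)
    list(gwas = data.frame(gene_id = genes, p = p,
                           stringsAsFactors = FALSE),
         truth = data.frame(gene_id = genes,
                            label = ifelse(risk, "risk", "non_risk"),
                            stringsAsFactors = FALSE))
  })
}

#' Simulate reads spanning a two-allele locus
#'
#' The mutant read count is Binomial(`n_reads`, `mutant_fraction`);
#' each read embeds exactly one of the two motifs in i.i.d. uniform
#' random flanking sequence of `flank` nucleotides per side (flanks are
#' rejection-sampled so that neither motif occurs by chance).
#'
#' @param n_reads number of reads (>= 0).
#' @param mutant_fraction true mutant-allele fraction, in `[0, 1]`.
#' @param wt_motif,mut_motif equal-length, distinct motif strings.
#' @param seed integer seed.
#' @param flank flank length per side (default 40).
#' @return named character vector of reads (empty for `n_reads = 0`).
#' @export
simulate_locus_reads <- function(n_reads, mutant_fraction, wt_motif,
                                 mut_motif, seed = 1, flank = 40) {
  check_motifs(wt_motif, mut_motif)
  if (mutant_fraction < 0 || mutant_fraction > 1) {
    stop("mutant_fraction must lie in [0, 1]")
  }
  if (n_reads == 0) return(character(0))
  withr::with_seed(as.integer(seed) + 4L, {
    n_mut <- rbinom(1, n_reads, mutant_fraction)
    is_mut <- sample(rep(c(TRUE, FALSE), c(n_mut, n_reads - n_mut)))
    reads <- vapply(is_mut, function(m) {
      motif <- if (m) mut_motif else wt_motif
      other <- if (m) wt_motif else mut_motif
      repeat {
        read <- paste0(
          paste(sample(c("A", "C", "G", "T"), flank, TRUE), collapse = ""),
          motif,
          paste(sample(c("A", "C", "G", "T"), flank, TRUE), collapse = ""))
        if (!grepl(other, read, fixed = TRUE) &&
            length(gregexpr(motif, read, fixed = TRUE)[[1]]) == 1) {
          return(read)
        }
      }
    }, character(1))
    names(reads) <- sprintf("read%06d", seq_len(n_reads))
    reads
  })
}
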