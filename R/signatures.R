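#' Core signature shared by two disease models
#'
#' The core set comprises genes significantly changed (`padj <
#' max_padj`) in the stated direction in both models, over the universe
#' of genes tested in both. Overlap significance comes from
#' [fisher_enrichment()] of one model's significant set in the other's,
#' within the jointly tested universe; the operation is symmetric in its
#' two inputs.
#'
#' @param deA,deB `de_result`s for the two models.
#' @param direction `"up"` or `"down"`.
#' @param max_padj significance threshold (default 0.05).
#' @return list with `core` ([gene_set()]), `enrichment`
#'   (`enrichment_result`), and the per-model significant sets.
#' @export
core_overlap <- function(deA, deB, direction = c("up", "down"),
                         max_padj = 0.05) {
  direction <- match.arg(direction)
  u <- intersect(deA$gene_id[deA$status == "tested"],
                 deB$gene_id[deB$status == "tested"])
  if (!length(u)) stop("disjoint test universes: no gene tested in both")
  sig <- function(de) {
    ok <- de$status == "tested" & !is.na(de$padj) & de$padj < max_padj &
      (if (direction == "up") de$log2fc > 0 else de$log2fc < 0)
    intersect(de$gene_id[ok], u)
  }
  sa <- sig(deA); sb <- sig(deB)
  core <- intersect(sa, sb)
  list(
    core = gene_set(paste0("core_", direction), core,
                    list(direction = direction, max_padj = max_padj,
                         universe_size = length(u))),
    enrichment = fisher_enrichment(sa, sb, u),
    setA = sa, setB = sb, universe = u
  )
}

#' Compare a human-derived gene set with mouse model responses
#'
#' The human set is mapped to mouse through 1:1 orthologs only
#' (human genes with several mouse orthologs, or vice versa, are
#' dropped), then restricted to genes expressed above `min_fpkm` in
#' either model's data. Each surviving gene is categorised by whether it
#' is significantly induced in model A, model B, both, or neither; both
#' the raw-p and the adjusted-p tallies are reported, since cross-species
#' scatter displays conventionally use raw p while set construction uses
#' adjusted p. Enrichment of the mapped set in each model's induced set
#' and in the core set is computed over the jointly tested universe.
#'
#' @param human_set [gene_set()] or character of human gene symbols.
#' @param orthologs data.frame with columns `human_gene`, `mouse_gene`,
#'   `one_to_one` (logical).
#' @param deA,deB `de_result`s of the two mouse models.
#' @param min_fpkm expression threshold, strict `>`, applied to the max
#'   group-mean FPKM in either model (default 10).
#' @param max_padj threshold for the adjusted-p tally (default 0.05).
#' @return list with `table` (per-gene categories under raw and
#'   adjusted p), `tally_raw`, `tally_adj`, `mapped` (mouse genes after
#'   1:1 mapping), `filtered` (after expression filter), and
#'   `enrichment` (list modelA / modelB / core).
#' @export
cross_species_compare <- function(human_set, orthologs, deA, deB,
                                  min_fpkm = 10, max_padj = 0.05) {
  stopifnot(is.data.frame(orthologs),
            all(c("human_gene", "mouse_gene", "one_to_one")
                %in% names(orthologs)))
  hs <- set_members(human_set)
  map <- orthologs[orthologs$one_to_one & orthologs$human_gene %in% hs, ]
  mapped <- unique(map$mouse_gene)
  fa <- de_mean_fpkm(deA); fb <- de_mean_fpkm(deB)
  max_f <- function(m, g) {
    v <- rep(0, length(g))
    hit <- g %in% rownames(m)
    v[hit] <- apply(m[g[hit], , drop = FALSE], 1, max)
    v
  }
  filtered <- mapped[pmax(max_f(fa, mapped), max_f(fb, mapped)) > min_fpkm]
  if (!length(filtered)) {
    warning("no human gene survives 1:1 mapping and expression filter")
  }
  induced <- function(de, pcol, thr) {
    idx <- match(filtered, de$gene_id)
    val <- de[[pcol]][idx]
    !is.na(val) & val < thr & de$log2fc[idx] > 0
  }
  categ <- function(inA, inB) {
    ifelse(inA & inB, "both",
           ifelse(inA, "A_only", ifelse(inB, "B_only", "neither")))
  }
  tab <- data.frame(
    mouse_gene = filtered,
    category_raw = categ(induced(deA, "p", 0.05),
                         induced(deB, "p", 0.05)),
    category_adj = categ(induced(deA, "padj", max_padj),
                         induced(deB, "padj", max_padj)),
    stringsAsFactors = FALSE
  )
  tally <- function(col) {
    n_ind <- sum(tab[[col]] != "neither")
    list(induced = n_ind, total = nrow(tab))
  }
  u <- intersect(deA$gene_id[deA$status == "tested"],
                 deB$gene_id[deB$status == "tested"])
  ind_set <- function(de) {
    intersect(de$gene_id[de$status == "tested" & !is.na(de$padj) &
                           de$padj < max_padj & de$log2fc > 0], u)
  }
  qry <- intersect(filtered, u)
  core <- intersect(ind_set(deA), ind_set(deB))
  enr <- list(
    modelA = fisher_enrichment(qry, ind_set(deA), u),
    modelB = fisher_enrichment(qry, ind_set(deB), u),
    core = fisher_enrichment(qry, core, u)
  )
  list(table = tab, tally_raw = tally("category_raw"),
       tally_adj = tally("category_adj"),
       mapped = mapped, filtered = filtered, enrichment = enr)
}

#' Test whether a late-stage signature is precociously induced early
#'
#' Takes the genes induced above `fold_threshold` (padj < `max_padj`)
#' at the late stage and asks whether they are already shifted at the
#' early stage: per gene, the early log2 fold change is
#' `log2((mean FPKM TG + pc) / (mean FPKM WT + pc))` with pseudocount
#' `pc`, and a ratio paired t-test — a one-sample t on the per-gene
#' log-ratios against 0 — is reported with `df = n_genes - 1`. (The
#' per-gene pairing convention is this package's; published df
#' conventions for such tests vary by one or two.)
#'
#' @param late_de `de_result` at the late stage.
#' @param early_fpkm data.frame with columns `gene_id`, `fpkm_wt`,
#'   `fpkm_tg`: early-stage group-mean FPKM.
#' @param fold_threshold late-stage fold threshold (strict `>`,
#'   default 2).
#' @param max_padj late-stage significance threshold.
#' @param pseudocount added to both means (default 0.1).
#' @return list with `t`, `df`, `p`, `mean_early_log2fc`,
#'   `early_log2fc` (named per-gene vector), `genes`.
#' @export
precocity_test <- function(late_de, early_fpkm, fold_threshold = 2,
                           max_padj = 0.05, pseudocount = 0.1) {
  stopifnot(inherits(late_de, "de_result"), is.data.frame(early_fpkm),
            all(c("gene_id", "fpkm_wt", "fpkm_tg") %in% names(early_fpkm)))
  sel <- late_de$status == "tested" & !is.na(late_de$padj) &
    late_de$padj < max_padj & late_de$log2fc > 0 &
    2^late_de$log2fc > fold_threshold
  genes <- late_de$gene_id[sel]
  if (length(genes) < 3) {
    stop("fewer than 3 late-stage signature genes (", length(genes),
         "); test refused")
  }
  idx <- match(genes, early_fpkm$gene_id)
  if (anyNA(idx)) {
    stop("early FPKM missing for: ",
         paste(head(genes[is.na(idx)], 10), collapse = ", "))
  }
  l2 <- log2((early_fpkm$fpkm_tg[idx] + pseudocount) /
               (early_fpkm$fpkm_wt[idx] + pseudocount))
  names(l2) <- genes
  if (var(l2) == 0) {
    stop("degenerate input: all early log-ratios identical")
  }
  tt <- t.test(l2, mu = 0)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_early_log2fc = mean(l2),
       early_log2fc = l2, genes = genes)
}

#' Concordance of fold changes between two CNS regions
#'
#' Pearson correlation of per-gene log2 fold changes on the shared,
#' expressed universe (max group-mean FPKM >= `min_fpkm` in both
#' regions), plus the ordinary least-squares slope of region B on
#' region A with a normal-theory 95% confidence interval.
#'
#' @param deA,deB `de_result`s for the two regions.
#' @param min_fpkm expression threshold for the shared universe.
#' @return list with `r`, `slope`, `slope_ci` (length 2), `n`.
#' @export
regional_concordance <- function(deA, deB, min_fpkm = 1) {
  expr_ok <- function(de) {
    de$gene_id[de$status == "tested" &
                 apply(de_mean_fpkm(de), 1, max) >= min_fpkm]
  }
  shared <- intersect(expr_ok(deA), expr_ok(deB))
  if (length(shared) < 3) stop("fewer than 3 shared expressed genes")
  x <- deA$log2fc[match(shared, deA$gene_id)]
  y <- deB$log2fc[match(shared, deB$gene_id)]
  if (var(x) == 0 || var(y) == 0) {
    stop("zero variance in a fold-change vector")
  }
  fit <- lm(y ~ x)
  ci <- confint(fit, "x", level = 0.95)
  list(r = cor(x, y), slope = unname(coef(fit)["x"]),
       slope_ci = as.numeric(ci), n = length(shared))
}
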