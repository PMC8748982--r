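#' Collapse probe-level fold changes to gene level
#'
#' Probes without a gene annotation are dropped ("fully annotated genes"
#' only). For genes carried by several probes the arithmetic mean fold
#' change per stimulus is taken as the gene's value; single-probe genes
#' pass through unchanged. `top_n` documents the convention that probe
#' averaging is what produces the values competing for the top ranks;
#' the mean is applied uniformly, which is equivalent wherever the rank
#' cut-offs downstream can be affected.
#'
#' @param table data.frame with columns `probe_id`, `gene_symbol`,
#'   `fc_stimA`, `fc_stimB`. Missing (`NA` or empty) `gene_symbol` marks
#'   an unannotated probe.
#' @param top_n rank window the averaging convention targets
#'   (default 250).
#' @return data.frame with columns `gene_symbol`, `fc_stimA`,
#'   `fc_stimB`, one row per annotated gene.
#' @export
collapse_probes <- function(table, top_n = 250) {
  stopifnot(is.data.frame(table), nrow(table) > 0,
            all(c("probe_id", "gene_symbol", "fc_stimA", "fc_stimB")
                %in% names(table)))
  if (anyDuplicated(table$probe_id)) stop("duplicate probe_id")
  ann <- !is.na(table$gene_symbol) & table$gene_symbol != ""
  if (!any(ann)) {
    warning("all probes unannotated; empty output")
    return(data.frame(gene_symbol = character(0), fc_stimA = numeric(0),
                      fc_stimB = numeric(0)))
  }
  tb <- table[ann, , drop = FALSE]
  fa <- tapply(tb$fc_stimA, tb$gene_symbol, mean)
  fb <- tapply(tb$fc_stimB, tb$gene_symbol, mean)
  data.frame(gene_symbol = names(fa),
             fc_stimA = as.numeric(fa),
             fc_stimB = as.numeric(fb[names(fa)]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Rank genes by fold change under each stimulus
#'
#' Rank 1 is the highest fold change. Ranks form a permutation of
#' 1..n_genes per stimulus; ties in fold change are broken
#' lexicographically by gene symbol for a deterministic total order.
#'
#' @param collapsed per-gene fold-change table from [collapse_probes()].
#' @return data.frame with `gene_symbol`, `fc_stimA`, `fc_stimB`,
#'   `rank_stimA`, `rank_stimB`.
#' @export
rank_genes <- function(collapsed) {
  stopifnot(is.data.frame(collapsed), nrow(collapsed) >= 1)
  if (anyDuplicated(collapsed$gene_symbol)) {
    stop("duplicate gene symbols; collapse probes first")
  }
  out <- collapsed
  oa <- order(-collapsed$fc_stimA, collapsed$gene_symbol)
  ob <- order(-collapsed$fc_stimB, collapsed$gene_symbol)
  out$rank_stimA[oa] <- seq_len(nrow(out))
  out$rank_stimB[ob] <- seq_len(nrow(out))
  out
}

#' Classify genes into stimulus-specific and pan-reactive sets
#'
#' A gene is stimulus-A specific when it is ranked within the top
#' `top_specific` genes for stimulus A and at least `separation` ranking
#' places lower for stimulus B (`rank_stimB - rank_stimA >= separation`);
#' symmetrically for stimulus B. A gene is pan-reactive when it is
#' within the top `top_pan` for both stimuli with no more than
#' `separation` ranking positions between them. At the boundary
#' (difference exactly `separation`) a gene can satisfy both rules;
#' specific sets take precedence and the pan set excludes genes already
#' assigned, so the three sets are always pairwise disjoint.
#'
#' @param ranked a [rank_genes()] table.
#' @param top_specific rank window for the specific rule (default 100).
#' @param top_pan rank window for the pan rule (default 250).
#' @param separation rank-difference threshold (default 50), must be
#'   non-negative.
#' @param stim_labels length-2 character, names for the two stimuli
#'   (default `c("LPS", "MCAO")`).
#' @return object of class `reactive_sets`: list with [gene_set()]s
#'   `lps`, `mcao`, `pan` and an `audit` data.frame (gene, ranks,
#'   assigned set).
#' @export
classify_reactive <- function(ranked, top_specific = 100, top_pan = 250,
                              separation = 50,
                              stim_labels = c("LPS", "MCAO")) {
  stopifnot(is.data.frame(ranked),
            all(c("gene_symbol", "rank_stimA", "rank_stimB")
                %in% names(ranked)))
  if (separation < 0) stop("separation must be >= 0")
  n <- nrow(ranked)
  for (col in c("rank_stimA", "rank_stimB")) {
    if (!setequal(ranked[[col]], seq_len(n))) {
      stop(col, " is not a permutation of 1..n_genes")
    }
  }
  ra <- ranked$rank_stimA; rb <- ranked$rank_stimB
  is_a <- ra <= top_specific & (rb - ra) >= separation
  is_b <- rb <= top_specific & (ra - rb) >= separation
  is_pan <- ra <= top_pan & rb <= top_pan &
    abs(ra - rb) <= separation & !is_a & !is_b

  assigned <- rep("none", n)
  assigned[is_pan] <- "pan"
  assigned[is_a] <- stim_labels[1]
  assigned[is_b] <- stim_labels[2]
  prov <- list(top_specific = top_specific, top_pan = top_pan,
               separation = separation)
  structure(
    list(
      lps = gene_set(paste0(stim_labels[1], "_specific"),
                     ranked$gene_symbol[is_a], prov),
      mcao = gene_set(paste0(stim_labels[2], "_specific"),
                      ranked$gene_symbol[is_b], prov),
      pan = gene_set("pan_reactive", ranked$gene_symbol[is_pan], prov),
      audit = data.frame(gene_symbol = ranked$gene_symbol,
                         rank_stimA = ra, rank_stimB = rb,
                         assigned = assigned,
                         stringsAsFactors = FALSE)
    ),
    class = "reactive_sets"
  )
}

#' @export
print.reactive_sets <- function(x, ...) {
  cat("reactive_sets:",
      x$lps$name, length(x$lps$members), "|",
      x$mcao$name, length(x$mcao$members), "|",
      "pan", length(x$pan$members), "\n")
  invisible(x)
}

#' Restrict reactive sets to genes expressed in every condition
#'
#' When interrogating a dataset with externally derived sets, only set
#' genes whose group-mean FPKM exceeds `min_fpkm` in every condition
#' group of the target dataset are retained.
#'
#' @param sets a `reactive_sets` object.
#' @param expr `expression_table` of the interrogated dataset.
#' @param min_fpkm expression threshold (default 1, strict `>`).
#' @param by metadata column defining condition groups.
#' @return a `reactive_sets` object with filtered member sets.
#' @export
filter_expressed <- function(sets, expr, min_fpkm = 1, by = "genotype") {
  stopifnot(inherits(sets, "reactive_sets"))
  gm <- group_mean_fpkm(expr, by = by)
  ok <- rownames(gm)[apply(gm > min_fpkm, 1, all)]
  for (nm in c("lps", "mcao", "pan")) {
    s <- sets[[nm]]
    s$members <- intersect(s$members, ok)
    s$provenance$min_fpkm_all_conditions <- min_fpkm
    sets[[nm]] <- s
  }
  sets
}

#' Fraction of marker genes significantly upregulated
#'
#' Of `m` markers passing the expression filter (group-mean FPKM >
#' `min_fpkm` in every condition), `k` are significantly induced
#' (`padj < max_padj` and log2fc > 0). Reported as the pair (k, m),
#' the "k of m" format used when checking published marker panels.
#'
#' @param markers a [gene_set()] or character vector.
#' @param de a `de_result` for the interrogated contrast.
#' @param expr optional `expression_table`; defaults to the group-mean
#'   FPKM stored in `de`.
#' @param min_fpkm expression threshold (strict `>`, default 1).
#' @param max_padj significance threshold (default 0.05).
#' @return list with `k`, `m`, `fraction`, and the vector of markers
#'   counted in each.
#' @export
marker_upregulation_fraction <- function(markers, de, expr = NULL,
                                         min_fpkm = 1, max_padj = 0.05) {
  mk <- set_members(markers)
  if (!length(mk)) stop("empty marker list")
  gm <- if (is.null(expr)) de_mean_fpkm(de) else group_mean_fpkm(expr)
  present <- intersect(mk, rownames(gm))
  expressed <- present[apply(gm[present, , drop = FALSE] > min_fpkm,
                             1, all)]
  m <- length(expressed)
  if (m == 0) {
    stop("no marker passes the expression filter; fraction undefined")
  }
  idx <- match(expressed, de$gene_id)
  up <- !is.na(de$padj[idx]) & de$padj[idx] < max_padj &
    de$log2fc[idx] > 0
  list(k = sum(up), m = m, fraction = sum(up) / m,
       upregulated = expressed[up], expressed = expressed)
}
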