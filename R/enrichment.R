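#' Two-by-two Fisher enrichment with Woolf confidence interval
#'
#' Tests over-representation of a reference set within a query set
#' against a stated gene universe. The 2x2 table is
#' `a` = query AND reference, `b` = query not reference, `c` = reference
#' not query, `d` = neither. Significance is the two-sided Fisher exact
#' test (minimum-likelihood rule). Fold enrichment is reported as the
#' sample odds ratio (a d)/(b c) with a 95% Woolf (log-OR normal)
#' interval, `exp(ln OR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`. When any
#' cell is zero, the Haldane-Anscombe correction (+0.5 on every cell) is
#' applied to the odds ratio and interval only; the exact p value is
#' never corrected.
#'
#' @param query,reference [gene_set()]s or character vectors. `query`
#'   must be contained in `universe`; `reference` is intersected with
#'   it.
#' @param universe the gene universe ([gene_set()] or character).
#' @param conf_level confidence level of the Woolf interval.
#' @return object of class `enrichment_result`: list with cells `a, b,
#'   c, d`, `odds_ratio`, `ci_low`, `ci_high`, `p`, `log_or`, `se_log_or`
#'   (on the possibly corrected cells), and `corrected` flag.
#' @export
fisher_enrichment <- function(query, reference, universe,
                              conf_level = 0.95) {
  q <- set_members(query); r <- set_members(reference)
  u <- set_members(universe)
  if (!length(u)) stop("empty universe")
  extra <- setdiff(q, u)
  if (length(extra)) {
    stop("query genes outside the universe: ",
         paste(head(extra, 10), collapse = ", "),
         if (length(extra) > 10) " ...")
  }
  r <- intersect(r, u)
  a <- length(intersect(q, r))
  b <- length(q) - a
  c <- length(r) - a
  d <- length(u) - a - b - c
  enrichment_from_cells(a, b, c, d, conf_level)
}

# core 2x2 computation shared by fisher_enrichment and the sweep
enrichment_from_cells <- function(a, b, c, d, conf_level = 0.95) {
  p <- fisher.test(matrix(c(a, c, b, d), nrow = 2))$p.value
  corrected <- any(c(a, b, c, d) == 0)
  cc <- c(a, b, c, d) + if (corrected) 0.5 else 0
  log_or <- log(cc[1]) + log(cc[4]) - log(cc[2]) - log(cc[3])
  se <- sqrt(sum(1 / cc))
  zq <- qnorm(1 - (1 - conf_level) / 2)
  structure(
    list(a = a, b = b, c = c, d = d,
         odds_ratio = exp(log_or),
         ci_low = exp(log_or - zq * se),
         ci_high = exp(log_or + zq * se),
         p = p,
         log_or = log_or, se_log_or = se, corrected = corrected),
    class = "enrichment_result"
  )
}

#' @export
print.enrichment_result <- function(x, digits = 3, ...) {
  cat(sprintf(
    "2x2 enrichment: a=%d b=%d c=%d d=%d | OR %.3g [%.3g, %.3g], p = %.3g%s\n",
    x$a, x$b, x$c, x$d, x$odds_ratio, x$ci_low, x$ci_high, x$p,
    if (x$corrected) " (Haldane-Anscombe corrected OR/CI)" else ""))
  invisible(x)
}

#' Compare two enrichments via the difference in log odds ratios
#'
#' Normal approximation: `z = (ln OR1 - ln OR2) / sqrt(SE1^2 + SE2^2)`
#' with `SE^2 = sum(1/cell)`; two-sided normal p value. Uses the
#' corrected cells whenever a zero-cell correction was applied.
#'
#' @param e1,e2 `enrichment_result`s from non-degenerate tables.
#' @return list with `z` and `p`.
#' @export
compare_enrichments <- function(e1, e2) {
  stopifnot(inherits(e1, "enrichment_result"),
            inherits(e2, "enrichment_result"))
  z <- (e1$log_or - e2$log_or) / sqrt(e1$se_log_or^2 + e2$se_log_or^2)
  list(z = z, p = 2 * pnorm(-abs(z)))
}

#' GWAS risk-gene enrichment across relaxing p-value cutoffs
#'
#' The universe is the set of genes expressed above `min_fpkm`
#' (maximum group-mean FPKM, strict `>`) for which a gene-level GWAS p
#' value is available. For each cutoff, the reference set is the
#' universe genes with GWAS p below the cutoff and enrichment of the
#' induced query set is computed by [fisher_enrichment()]. The `"auto"`
#' grid is `c(0.05 / |universe|, 5e-5, 5e-4, 5e-3, 5e-2)`: the
#' study-wide Bonferroni threshold followed by sequentially relaxed
#' sub-threshold cutoffs.
#'
#' @param induced query [gene_set()] (typically genes induced >
#'   1.5-fold at padj < 0.05); intersected with the universe.
#' @param gwas data.frame with columns `gene_id`, `p`, one row per gene.
#' @param expr `expression_table` of the interrogated dataset (or a
#'   `de_result`, whose stored group-mean FPKM are then used).
#' @param cutoffs numeric vector of p-value cutoffs, or `"auto"`.
#' @param min_fpkm expression threshold for the universe (default 1).
#' @return data.frame of class `risk_sweep` with one row per cutoff
#'   (cells, OR, CI, p); the full `enrichment_result` objects are in
#'   `attr(, "results")`, the universe size in `attr(, "universe_size")`.
#' @export
risk_enrichment_sweep <- function(induced, gwas, expr, cutoffs = "auto",
                                  min_fpkm = 1) {
  stopifnot(is.data.frame(gwas),
            all(c("gene_id", "p") %in% names(gwas)))
  if (anyDuplicated(gwas$gene_id)) stop("duplicate gene_id in GWAS table")
  gm <- if (inherits(expr, "de_result")) de_mean_fpkm(expr)
        else group_mean_fpkm(expr)
  expressed <- rownames(gm)[apply(gm, 1, max) > min_fpkm]
  u <- intersect(expressed, gwas$gene_id)
  if (!length(u)) stop("empty universe: no expressed gene with a GWAS p")
  if (identical(cutoffs, "auto")) {
    cutoffs <- c(0.05 / length(u), 5e-5, 5e-4, 5e-3, 5e-2)
  }
  cutoffs <- sort(as.numeric(cutoffs))
  q <- intersect(set_members(induced), u)
  gp <- setNames(gwas$p, gwas$gene_id)[u]
  results <- lapply(cutoffs, function(ct) {
    fisher_enrichment(q, u[gp < ct], u)
  })
  out <- data.frame(
    cutoff = cutoffs,
    a = vapply(results, `[[`, 0, "a"),
    b = vapply(results, `[[`, 0, "b"),
    c = vapply(results, `[[`, 0, "c"),
    d = vapply(results, `[[`, 0, "d"),
    odds_ratio = vapply(results, `[[`, 0, "odds_ratio"),
    ci_low = vapply(results, `[[`, 0, "ci_low"),
    ci_high = vapply(results, `[[`, 0, "ci_high"),
    p = vapply(results, `[[`, 0, "p")
  )
  attr(out, "results") <- results
  attr(out, "universe_size") <- length(u)
  class(out) <- c("risk_sweep", "data.frame")
  out
}

#' Over-representation of a query set in GMT annotation terms
#'
#' Flat-set over-representation: each term is clipped to the universe,
#' terms matching any `excluded_terms` pattern are dropped (e.g. disease
#' pathways when focusing on biological ones), terms whose overlap with
#' the query is below `min_genes` are dropped before testing, remaining
#' terms get a one-sided hypergeometric p value and BH adjustment across
#' the tested terms only.
#'
#' @param query [gene_set()] or character; intersected with the
#'   universe.
#' @param annotation named list of character vectors (see [read_gmt()]).
#' @param universe gene universe.
#' @param min_genes minimum query overlap for a term to be tested
#'   (default 5).
#' @param excluded_terms character vector of regular expressions matched
#'   (case-insensitively) against term names.
#' @return data.frame of class `ora_result`, ranked by adjusted p:
#'   `term`, `term_size`, `overlap`, `p`, `padj`, `members`
#'   (comma-separated overlap genes). Use [top_terms()] for the
#'   conventional truncated report.
#' @export
overrepresentation <- function(query, annotation, universe,
                               min_genes = 5, excluded_terms = NULL) {
  stopifnot(is.list(annotation), length(annotation) > 0)
  u <- set_members(universe)
  q <- intersect(set_members(query), u)
  keep <- rep(TRUE, length(annotation))
  for (pat in excluded_terms) {
    keep <- keep & !grepl(pat, names(annotation), ignore.case = TRUE)
  }
  annotation <- annotation[keep]
  rows <- lapply(names(annotation), function(nm) {
    term <- intersect(annotation[[nm]], u)
    ov <- intersect(q, term)
    if (length(ov) < min_genes) return(NULL)
    p <- phyper(length(ov) - 1, length(term), length(u) - length(term),
                length(q), lower.tail = FALSE)
    data.frame(term = nm, term_size = length(term),
               overlap = length(ov), p = p,
               members = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(term = character(0), term_size = integer(0),
                      overlap = integer(0), p = numeric(0),
                      members = character(0))
  }
  out$padj <- p.adjust(out$p, method = "BH")
  out <- out[order(out$padj, out$p, out$term),
             c("term", "term_size", "overlap", "p", "padj", "members")]
  rownames(out) <- NULL
  class(out) <- c("ora_result", "data.frame")
  out
}

#' @importFrom stats phyper
NULL

#' Truncated over-representation report
#'
#' The conventional display rule: the top `n` terms by adjusted p are
#' reported, unless fewer than `n` reach `max_padj`, in which case only
#' the significant terms are shown.
#'
#' @param ora an `ora_result`.
#' @param n maximum number of terms (default 10).
#' @param max_padj significance threshold (default 0.05).
#' @return the truncated `ora_result` rows.
#' @export
top_terms <- function(ora, n = 10, max_padj = 0.05) {
  stopifnot(inherits(ora, "ora_result"))
  n_sig <- sum(ora$padj < max_padj)
  head(ora, min(n, n_sig))
}
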