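# per-gene log2 fold change between two genotype groups, from
# group-mean FPKM with a pseudocount
contrast_log2fc <- function(gm, contrast, genes, pseudocount = 0.1) {
  missing_lv <- setdiff(contrast, colnames(gm))
  if (length(missing_lv)) {
    stop("genotype level(s) absent: ", paste(missing_lv, collapse = ", "))
  }
  absent <- setdiff(genes, rownames(gm))
  if (length(absent)) {
    stop("signature gene(s) absent from expression table: ",
         paste(head(absent, 10), collapse = ", "))
  }
  log2((gm[genes, contrast[1]] + pseudocount) /
         (gm[genes, contrast[2]] + pseudocount))
}

#' Quantify transcriptomic rescue of a perturbation signature
#'
#' For each signature gene, the log2 fold change is computed from
#' group-mean FPKM (pseudocount-guarded) under a primary contrast
#' (disease vs wild type) and an intervention contrast (disease x
#' intervention vs intervention). A ratio paired t-test — a paired t on
#' the per-gene log2 fold changes, i.e. a one-sample t on their
#' differences — asks whether the intervention attenuates the
#' signature, and the attenuation is estimated as
#' `1 - mean(log2fc_intervention) / mean(log2fc_primary)` (1 = complete
#' rescue, 0 = none). Gene-paired on group means: the per-gene scatter
#' presentation, not a per-animal test.
#'
#' @param signature [gene_set()] or character of signature genes.
#' @param expr `expression_table` covering all four genotypes.
#' @param primary_contrast character pair, default `c("TG", "WT")`.
#' @param intervention_contrast character pair, default
#'   `c("TGxNRF2", "NRF2")`.
#' @param by metadata column holding genotypes.
#' @param pseudocount added to group-mean FPKM (default 0.1).
#' @return object of class `rescue_summary`: list with `per_gene`
#'   data.frame (`gene_id`, `log2fc_primary`, `log2fc_intervention`),
#'   `t`, `df`, `p`, `attenuation`, `mean_primary`,
#'   `mean_intervention`, and the contrasts.
#' @export
rescue_fold_change_test <- function(signature, expr,
                                    primary_contrast = c("TG", "WT"),
                                    intervention_contrast =
                                      c("TGxNRF2", "NRF2"),
                                    by = "genotype", pseudocount = 0.1) {
  genes <- set_members(signature)
  if (length(genes) < 3) stop("need >= 3 signature genes")
  gm <- group_mean_fpkm(expr, by = by)
  l2p <- contrast_log2fc(gm, primary_contrast, genes, pseudocount)
  l2i <- contrast_log2fc(gm, intervention_contrast, genes, pseudocount)
  d <- l2p - l2i
  if (var(d) == 0) {
    stop("degenerate case: per-gene differences have zero variance",
         if (all(d == 0)) " (intervention identical to primary)" else "")
  }
  tt <- t.test(l2p, l2i, paired = TRUE)
  mp <- mean(l2p)
  structure(
    list(per_gene = data.frame(gene_id = genes, log2fc_primary = l2p,
                               log2fc_intervention = l2i,
                               row.names = NULL),
         t = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value,
         attenuation = if (mp != 0) 1 - mean(l2i) / mp else NA_real_,
         mean_primary = mp, mean_intervention = mean(l2i),
         primary_contrast = primary_contrast,
         intervention_contrast = intervention_contrast),
    class = "rescue_summary"
  )
}

#' @export
print.rescue_summary <- function(x, ...) {
  cat(sprintf(
    "rescue (%s vs %s): n = %d genes, paired t = %.3g (df = %d, p = %.3g)\n",
    paste(x$primary_contrast, collapse = "/"),
    paste(x$intervention_contrast, collapse = "/"),
    nrow(x$per_gene), x$t, x$df, x$p))
  cat(sprintf("attenuation estimate: %.3f\n", x$attenuation))
  invisible(x)
}

#' Check for baseline shifts of signature genes
#'
#' Control for the rescue comparison: the intervention alone should
#' leave the basal expression of the signature genes largely unaffected
#' (otherwise the denominator of the intervention contrast is itself
#' shifted). Per-gene baseline log2 fold change with a one-sample t
#' against 0; non-significance supports the no-baseline-shift reading.
#'
#' @inheritParams rescue_fold_change_test
#' @param baseline_contrast character pair, default `c("NRF2", "WT")`.
#' @return list with `per_gene` (named log2fc vector), `mean`, `t`,
#'   `df`, `p`.
#' @export
baseline_shift_check <- function(signature, expr,
                                 baseline_contrast = c("NRF2", "WT"),
                                 by = "genotype", pseudocount = 0.1) {
  genes <- set_members(signature)
  if (!length(genes)) stop("empty signature")
  if (length(genes) < 3) stop("need >= 3 signature genes")
  gm <- group_mean_fpkm(expr, by = by)
  l2 <- contrast_log2fc(gm, baseline_contrast, genes, pseudocount)
  if (var(l2) == 0) stop("degenerate case: zero variance in log-ratios")
  tt <- t.test(l2, mu = 0)
  list(per_gene = l2, mean = mean(l2), t = unname(tt$statistic),
       df = unname(tt$parameter), p = tt$p.value)
}

#' Score reads spanning a two-allele locus as WT or mutant
#'
#' Each read is searched (exact substring, forward strand) for the
#' wild-type and mutant motifs spanning the locus; reads containing
#' exactly one motif are scored accordingly, reads containing neither
#' or both are counted as unscored. The mutant percentage is
#' `100 * mutant / (mutant + wt)` with a Wilson 95% confidence
#' interval.
#'
#' @param reads character vector of read sequences (A/C/G/T), or a
#'   `Biostrings::DNAStringSet`.
#' @param wt_motif,mut_motif equal-length motif strings differing at
#'   one or more positions.
#' @return list with `percent_mutant`, `ci` (length-2, percent scale),
#'   `n_mutant`, `n_wt`, `n_unscored`.
#' @export
allele_fraction <- function(reads, wt_motif, mut_motif) {
  reads <- as.character(reads)
  check_motifs(wt_motif, mut_motif)
  has_wt <- grepl(wt_motif, reads, fixed = TRUE)
  has_mut <- grepl(mut_motif, reads, fixed = TRUE)
  n_wt <- sum(has_wt & !has_mut)
  n_mut <- sum(has_mut & !has_wt)
  n_unscored <- length(reads) - n_wt - n_mut
  n <- n_wt + n_mut
  if (n == 0) stop("no scored reads; mutant fraction undefined")
  ci <- as.numeric(prop.test(n_mut, n, correct = FALSE)$conf.int) * 100
  list(percent_mutant = 100 * n_mut / n, ci = ci,
       n_mutant = n_mut, n_wt = n_wt, n_unscored = n_unscored)
}

check_motifs <- function(wt_motif, mut_motif) {
  stopifnot(is.character(wt_motif), is.character(mut_motif))
  if (nchar(wt_motif) != nchar(mut_motif)) {
    stop("motifs must have equal length")
  }
  if (wt_motif == mut_motif) stop("motifs must differ at >= 1 position")
  invisible(TRUE)
}

#' Horizontal bar trial score
#'
#' Converts the recorded time of a horizontal-bar trial into the 0-10
#' score: falling quickly scores low, reaching the platform quickly
#' scores high, and either outcome at the 60 s cut-off scores 5.
#' Times are truncated to whole seconds before band lookup (the scoring
#' table is specified in whole seconds).
#'
#' Bands — fell: 0-5 s -> 0, 6-10 -> 1, 11-20 -> 2, 21-40 -> 3,
#' 41-59 -> 4, 60 -> 5; reached platform: 0-5 s -> 10, 6-10 -> 9,
#' 11-20 -> 8, 21-30 -> 7, 31-59 -> 6, 60 -> 5.
#'
#' @param outcome `"fell"` or `"reached_platform"` (vectorised).
#' @param time_s time in seconds, in `[0, 60]`.
#' @return integer score(s) in 0..10.
#' @seealso [bar_session_score()] for the per-animal session mean.
#' @export
bar_score <- function(outcome, time_s) {
  outcome <- match.arg(outcome, c("fell", "reached_platform"),
                       several.ok = TRUE)
  if (length(outcome) == 1) outcome <- rep(outcome, length(time_s))
  stopifnot(length(outcome) == length(time_s))
  if (any(time_s < 0 | time_s > 60)) {
    stop("time_s must be within [0, 60]")
  }
  t <- floor(time_s)
  fell <- c(`0` = 0, `6` = 1, `11` = 2, `21` = 3, `41` = 4, `60` = 5)
  reach <- c(`0` = 10, `6` = 9, `11` = 8, `21` = 7, `31` = 6, `60` = 5)
  band <- function(edges, tt) edges[findInterval(tt, as.numeric(names(edges)))]
  out <- integer(length(t))
  out[outcome == "fell"] <- band(fell, t[outcome == "fell"])
  out[outcome == "reached_platform"] <-
    band(reach, t[outcome == "reached_platform"])
  as.integer(out)
}

#' Mean horizontal-bar score for one testing session
#'
#' A session comprises three trials; the per-animal session score is
#' the mean of the three trial scores, the primary datum for
#' longitudinal analysis.
#'
#' @param outcomes character vector of trial outcomes.
#' @param times_s numeric vector of trial times.
#' @return mean score.
#' @export
bar_session_score <- function(outcomes, times_s) {
  mean(bar_score(outcomes, times_s))
}
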