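#' Construct a gene set with provenance
#'
#' @param name set name.
#' @param members character vector of gene identifiers; duplicates are
#'   removed, order preserved.
#' @param provenance named list recording how the set was derived
#'   (thresholds, source contrast, ...). Always populated, `list()` at
#'   minimum.
#' @return object of class `gene_set`.
#' @export
gene_set <- function(name, members, provenance = list()) {
  structure(
    list(name = as.character(name),
         members = unique(as.character(members)),
         provenance = provenance),
    class = "gene_set"
  )
}

#' @export
print.gene_set <- function(x, ...) {
  cat("gene_set '", x$name, "': ", length(x$members), " genes\n", sep = "")
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$members)

# coerce gene_set or character to a character vector of members
set_members <- function(x) {
  if (inherits(x, "gene_set")) x$members else unique(as.character(x))
}

#' Simplified negative-binomial Wald differential expression
#'
#' A deliberately simple two-group NB test in the spirit of standard
#' RNA-seq DE tools, documented as such: median-of-ratios size factors
#' computed from the contrast samples, per-gene dispersion by method of
#' moments on normalised counts (floored at 1e-8, no shrinkage), a Wald
#' statistic on the log2 fold change with a delta-method standard error,
#' referred to a t distribution on `n1 + n2 - 2` degrees of freedom (the
#' small-sample correction for the plug-in variance; a normal reference
#' is anti-conservative at typical replicate numbers), and
#' Benjamini-Hochberg adjustment across tested genes. Genes with zero
#' counts in every sample of the contrast are flagged `low_count` and
#' excluded from testing and adjustment.
#'
#' Gene-level p values will differ from shrinkage-based tools; set-level
#' behaviour (type-I calibration, log2FC recovery) is validated by
#' simulation in the package tests.
#'
#' @param counts a [count_matrix()].
#' @param contrast character pair `c(test, reference)`; log2fc > 0 means
#'   higher in the test level.
#' @param by metadata column holding the contrast levels (default
#'   `"genotype"`).
#' @param pseudocount added to normalised group means for the log2 fold
#'   change (default 0.5).
#' @return data.frame of class `de_result` with columns `gene_id`,
#'   `log2fc`, `p`, `padj`, `mean_fpkm_<reference>`, `mean_fpkm_<test>`,
#'   `status`; attribute `contrast`.
#' @export
differential_expression <- function(counts, contrast, by = "genotype",
                                    pseudocount = 0.5) {
  stopifnot(inherits(counts, "count_matrix"), length(contrast) == 2)
  groups <- counts$samples[[by]]
  missing_lv <- setdiff(contrast, groups)
  if (length(missing_lv)) {
    stop("contrast level(s) absent from metadata: ",
         paste(missing_lv, collapse = ", "))
  }
  test_lv <- contrast[1]; ref_lv <- contrast[2]
  keep <- groups %in% contrast
  k <- counts$counts[, keep, drop = FALSE]
  grp <- groups[keep]
  n1 <- sum(grp == ref_lv); n2 <- sum(grp == test_lv)
  if (n1 < 2 || n2 < 2) stop("need >= 2 samples per contrast level")

  sf <- size_factors(k)
  norm <- sweep(k, 2, sf, "/")
  g1 <- norm[, grp == ref_lv, drop = FALSE]
  g2 <- norm[, grp == test_lv, drop = FALSE]
  m1 <- rowMeans(g1); m2 <- rowMeans(g2)
  low <- rowSums(k) == 0

  # method-of-moments dispersion on pooled within-group variance
  s2 <- (apply(g1, 1, var) + apply(g2, 1, var)) / 2
  mu <- (m1 + m2) / 2
  alpha <- pmax((s2 - mu) / pmax(mu, 1e-8)^2, 1e-8)

  log2fc <- log2((m2 + pseudocount) / (m1 + pseudocount))
  v1 <- m1 + alpha * m1^2
  v2 <- m2 + alpha * m2^2
  se <- sqrt(v1 / (n1 * pmax(m1, 1e-8)^2) +
             v2 / (n2 * pmax(m2, 1e-8)^2)) / log(2)
  z <- log2fc / se
  p <- 2 * pt(-abs(z), df = n1 + n2 - 2)
  p[low] <- NA_real_
  padj <- rep(NA_real_, length(p))
  padj[!low] <- p.adjust(p[!low], method = "BH")

  # group-mean FPKM over the contrast samples
  cm_sub <- count_matrix(k, counts$length_bp,
                         counts$samples[keep, , drop = FALSE])
  gm <- group_mean_fpkm(compute_fpkm(cm_sub), by = by)

  out <- data.frame(
    gene_id = rownames(k),
    log2fc = log2fc,
    p = p,
    padj = padj,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  out[[paste0("mean_fpkm_", ref_lv)]] <- gm[, ref_lv]
  out[[paste0("mean_fpkm_", test_lv)]] <- gm[, test_lv]
  out$status <- ifelse(low, "low_count", "tested")
  attr(out, "contrast") <- contrast
  attr(out, "by") <- by
  class(out) <- c("de_result", "data.frame")
  out
}

# median-of-ratios size factors (geometric mean reference over genes
# with no zero count)
size_factors <- function(k) {
  pos <- rowSums(k == 0) == 0
  if (!any(pos)) stop("no gene with nonzero counts in all samples; ",
                      "cannot estimate size factors")
  logref <- rowMeans(log(k[pos, , drop = FALSE]))
  sf <- apply(k[pos, , drop = FALSE], 2,
              function(col) exp(median(log(col) - logref)))
  sf / exp(mean(log(sf)))
}

# group-mean FPKM columns of a de_result, as a genes x 2 matrix
de_mean_fpkm <- function(de) {
  cols <- grep("^mean_fpkm_", names(de), value = TRUE)
  m <- as.matrix(de[, cols, drop = FALSE])
  rownames(m) <- de$gene_id
  colnames(m) <- sub("^mean_fpkm_", "", cols)
  m
}

#' Threshold-based gene-set selection from a DE result
#'
#' Members are the tested genes with fold change at least `min_fold` in
#' the stated direction (applied to the point estimate, fold =
#' 2^log2fc), `padj < max_padj`, and maximum group-mean FPKM at least
#' `min_fpkm` (the permissive reading of an expression cut-off: the gene
#' must be expressed in at least one condition).
#'
#' @param de a `de_result`.
#' @param expr optional `expression_table` used for the FPKM filter;
#'   defaults to the group-mean FPKM columns stored in `de`.
#' @param min_fold fold-change threshold, must be >= 1.
#' @param max_padj BH-adjusted p threshold.
#' @param min_fpkm expression threshold on the max group-mean FPKM.
#' @param direction `"up"` or `"down"`.
#' @return a [gene_set()] whose provenance records all thresholds.
#' @export
select_genes <- function(de, expr = NULL, min_fold = 1.5, max_padj = 0.05,
                         min_fpkm = 1, direction = c("up", "down")) {
  direction <- match.arg(direction)
  stopifnot(inherits(de, "de_result"))
  if (min_fold < 1) stop("min_fold must be >= 1")
  if (is.null(expr)) {
    gm <- de_mean_fpkm(de)
  } else {
    gm <- group_mean_fpkm(expr)[de$gene_id, , drop = FALSE]
  }
  max_fpkm <- apply(gm, 1, max)
  fold_ok <- if (direction == "up") {
    de$log2fc > 0 & 2^de$log2fc >= min_fold
  } else {
    de$log2fc < 0 & 2^(-de$log2fc) >= min_fold
  }
  sel <- de$status == "tested" & !is.na(de$padj) &
    fold_ok & de$padj < max_padj & max_fpkm >= min_fpkm
  ctr <- attr(de, "contrast")
  gene_set(
    name = paste0(paste(ctr, collapse = "_vs_"), "_", direction),
    members = de$gene_id[sel],
    provenance = list(contrast = ctr, direction = direction,
                      min_fold = min_fold, max_padj = max_padj,
                      min_fpkm = min_fpkm)
  )
}
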