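#' Construct a gene-by-sample count matrix with metadata
#'
#' The universal input container of the pipeline: integer counts, per-gene
#' transcript lengths, and per-sample metadata (genotype, CNS region,
#' disease stage).
#'
#' @param counts integer matrix, genes in rows, samples in columns.
#'   Dimnames are taken as gene and sample identifiers if `gene_id` /
#'   sample metadata do not supply them.
#' @param length_bp positive integer vector of transcript lengths, one per
#'   gene (recycled names from `counts` rownames if unnamed).
#' @param samples data.frame with columns `sample_id`, `genotype` and
#'   optionally `region`, `stage`; one row per column of `counts`.
#'
#' @return An object of class `count_matrix`: a list with elements
#'   `counts`, `length_bp`, `samples`.
#' @examples
#' cm <- count_matrix(
#'   matrix(0:5, nrow = 2, dimnames = list(c("g1", "g2"), NULL)),
#'   length_bp = c(1000L, 2000L),
#'   samples = data.frame(sample_id = paste0("s", 1:3),
#'                        genotype = c("WT", "WT", "TG"))
#' )
#' @export
count_matrix <- function(counts, length_bp, samples) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) {
    stop("counts must have gene identifiers as rownames")
  }
  if (anyDuplicated(rownames(counts))) {
    stop("duplicate gene_id in counts")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  storage.mode(counts) <- "integer"
  if (is.null(names(length_bp))) names(length_bp) <- rownames(counts)
  length_bp <- length_bp[rownames(counts)]
  if (any(is.na(length_bp)) || any(length_bp <= 0)) {
    stop("length_bp must be positive for every gene")
  }
  samples <- as.data.frame(samples)
  if (!all(c("sample_id", "genotype") %in% names(samples))) {
    stop("samples needs at least columns sample_id and genotype")
  }
  if (nrow(samples) != ncol(counts)) {
    stop("samples must have one row per column of counts")
  }
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample_id")
  if (!"region" %in% names(samples)) samples$region <- NA_character_
  if (!"stage" %in% names(samples)) samples$stage <- NA_character_
  colnames(counts) <- samples$sample_id
  structure(
    list(counts = counts, length_bp = length_bp, samples = samples),
    class = "count_matrix"
  )
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "genes x", ncol(x$counts),
      "samples\n")
  cat("genotypes:",
      paste(sprintf("%s(%d)", names(table(x$samples$genotype)),
                    table(x$samples$genotype)), collapse = " "), "\n")
  invisible(x)
}

#' Convert counts to FPKM
#'
#' FPKM(g, s) = counts(g, s) * 1e9 / (length_bp(g) * library_size(s)),
#' where the library size is the column sum of raw counts. An FPKM of
#' zero occurs exactly where the count is zero.
#'
#' @param counts a [count_matrix()].
#' @return An object of class `expression_table`: list with the `fpkm`
#'   matrix and the `samples` metadata.
#' @export
compute_fpkm <- function(counts) {
  stopifnot(inherits(counts, "count_matrix"))
  lib <- colSums(counts$counts)
  if (any(lib == 0)) {
    stop("zero library size for sample(s): ",
         paste(counts$samples$sample_id[lib == 0], collapse = ", "))
  }
  fpkm <- counts$counts * 1e9 /
    outer(as.numeric(counts$length_bp), as.numeric(lib))
  dimnames(fpkm) <- dimnames(counts$counts)
  structure(list(fpkm = fpkm, samples = counts$samples),
            class = "expression_table")
}

#' @export
print.expression_table <- function(x, ...) {
  cat("expression_table:", nrow(x$fpkm), "genes x", ncol(x$fpkm),
      "samples (FPKM)\n")
  invisible(x)
}

#' Per-group mean FPKM
#'
#' @param expr an `expression_table`.
#' @param by metadata column defining the groups (default `"genotype"`).
#' @return numeric matrix, genes x groups, of group-mean FPKM.
#' @export
group_mean_fpkm <- function(expr, by = "genotype") {
  stopifnot(inherits(expr, "expression_table"))
  groups <- expr$samples[[by]]
  if (is.null(groups)) stop("no metadata column called ", by)
  lv <- unique(groups)
  out <- vapply(lv, function(g) {
    rowMeans(expr$fpkm[, groups == g, drop = FALSE])
  }, numeric(nrow(expr$fpkm)))
  colnames(out) <- lv
  out
}
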