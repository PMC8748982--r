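# Plain-text I/O: counts + metadata TSV, GMT gene-set collections,
# DE/GWAS/ortholog/probe tables, FASTA reads.

#' Read a count matrix and sample metadata from TSV
#'
#' The counts file has columns `gene_id`, `length_bp`, then one column
#' per sample; the metadata file has columns `sample_id`, `genotype`
#' and optionally `region`, `stage`.
#'
#' @param counts_file,meta_file paths to the two TSV files.
#' @return a [count_matrix()].
#' @export
read_counts_tsv <- function(counts_file, meta_file) {
  tab <- tryCatch(
    read.delim(counts_file, check.names = FALSE, stringsAsFactors = FALSE),
    error = function(e) stop("malformed counts TSV '", counts_file,
                             "': ", conditionMessage(e)))
  if (!all(c("gene_id", "length_bp") %in% names(tab))) {
    stop("counts TSV '", counts_file,
         "' must have columns gene_id and length_bp")
  }
  meta <- read.delim(meta_file, stringsAsFactors = FALSE)
  cnt <- as.matrix(tab[, setdiff(names(tab), c("gene_id", "length_bp")),
                       drop = FALSE])
  if (!all(meta$sample_id %in% colnames(cnt))) {
    stop("metadata sample_id not all present in counts TSV columns")
  }
  rownames(cnt) <- tab$gene_id
  count_matrix(cnt[, meta$sample_id, drop = FALSE],
               setNames(tab$length_bp, tab$gene_id), meta)
}

#' Write a count matrix (and its metadata) as TSV
#'
#' @param counts a [count_matrix()].
#' @param counts_file,meta_file output paths.
#' @return invisibly, the counts file path.
#' @export
write_counts_tsv <- function(counts, counts_file, meta_file) {
  out <- data.frame(gene_id = rownames(counts$counts),
                    length_bp = as.integer(counts$length_bp),
                    counts$counts, check.names = FALSE)
  write.table(out, counts_file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(counts$samples, meta_file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(counts_file)
}

#' Read a GMT gene-set collection
#'
#' @param file GMT path (tab-separated: name, description, members...).
#' @return named list of character vectors; descriptions in
#'   `attr(, "description")`.
#' @export
read_gmt <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3
  if (any(bad)) {
    stop("malformed GMT '", file, "': line(s) ",
         paste(which(bad), collapse = ", "), " have fewer than 3 fields")
  }
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[[`, "", 1)
  attr(sets, "description") <- vapply(parts, `[[`, "", 2)
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets a [gene_set()], a list of them, or a named list of
#'   character vectors.
#' @param file output path.
#' @return invisibly, the file path.
#' @export
write_gmt <- function(sets, file) {
  if (inherits(sets, "gene_set")) sets <- list(sets)
  lines <- vapply(seq_along(sets), function(i) {
    s <- sets[[i]]
    if (inherits(s, "gene_set")) {
      nm <- s$name
      desc <- paste(names(s$provenance),
                    vapply(s$provenance, function(v)
                      paste(format(v), collapse = "/"), ""),
                    sep = "=", collapse = ";")
      if (!nzchar(desc)) desc <- "na"
      members <- s$members
    } else {
      nm <- names(sets)[i]; desc <- "na"; members <- s
    }
    paste(c(nm, desc, members), collapse = "\t")
  }, character(1))
  writeLines(lines, file)
  invisible(file)
}

#' Write a DE result as TSV
#' @param de a `de_result`.
#' @param file output path.
#' @return invisibly, the file path.
#' @export
write_de_tsv <- function(de, file) {
  write.table(de, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a probe-level fold-change table
#'
#' Expects columns `probe_id`, `gene_symbol`, `fc_stimA`, `fc_stimB`.
#' @param file TSV path.
#' @return data.frame suitable for [collapse_probes()].
#' @export
read_probe_fc_tsv <- function(file) {
  tab <- read.delim(file, stringsAsFactors = FALSE)
  need <- c("probe_id", "gene_symbol", "fc_stimA", "fc_stimB")
  if (!all(need %in% names(tab))) {
    stop("probe FC TSV '", file, "' must have columns: ",
         paste(need, collapse = ", "))
  }
  tab
}

#' Read a gene-level GWAS p-value table
#' @param file TSV path with columns `gene_id`, `p`.
#' @return data.frame.
#' @export
read_gwas_tsv <- function(file) {
  tab <- read.delim(file, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "p") %in% names(tab))) {
    stop("GWAS TSV '", file, "' must have columns gene_id and p")
  }
  tab
}

#' Read a human-mouse ortholog map
#' @param file TSV path with columns `human_gene`, `mouse_gene`,
#'   `one_to_one` (logical or 0/1).
#' @return data.frame.
#' @export
read_ortholog_tsv <- function(file) {
  tab <- read.delim(file, stringsAsFactors = FALSE)
  need <- c("human_gene", "mouse_gene", "one_to_one")
  if (!all(need %in% names(tab))) {
    stop("ortholog TSV '", file, "' must have columns: ",
         paste(need, collapse = ", "))
  }
  tab$one_to_one <- as.logical(tab$one_to_one)
  tab
}

#' Write reads as FASTA
#' @param reads named character vector of sequences.
#' @param file output path.
#' @return invisibly, the file path.
#' @export
write_fasta <- function(reads, file) {
  x <- Biostrings::DNAStringSet(reads)
  if (is.null(names(x))) names(x) <- sprintf("read%06d", seq_along(x))
  Biostrings::writeXStringSet(x, file)
  invisible(file)
}

#' Read a FASTA file of reads
#' @param file FASTA path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(file) {
  x <- Biostrings::readDNAStringSet(file)
  setNames(as.character(x), names(x))
}
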