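# Readers and writers for the flat tabular inputs: differential-expression
# tables, replicate counts matrices, protein FASTA, BLAST tabular hits, and
# the package's own assignment TSV.

#' Read a differential-expression table
#'
#' Expects a TSV with a header naming at least `gene`, `log2fc` and `fdr`
#' (case-insensitive; `log2FC` and `FDR` are accepted).
#'
#' @param path Path to the TSV.
#' @param condition Condition label attached to the table.
#' @return A data frame of class `expression_table` with columns `gene`,
#'   `log2fc`, `fdr` and attribute `condition`.
#' @export
read_de_table <- function(path, condition) {
  check_file(path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           check.names = FALSE)
  names(tab) <- tolower(names(tab))
  need <- c("gene", "log2fc", "fdr")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop_agestrat("DE table %s is missing column(s): %s", path,
                  paste(miss, collapse = ", "))
  }
  expression_table(tab$gene, tab$log2fc, tab$fdr, condition = condition)
}

#' Construct a differential-expression table
#'
#' @param gene Gene identifiers (unique).
#' @param log2fc Log2 fold-changes (stress vs control).
#' @param fdr False discovery rates in `[0, 1]`.
#' @param condition Condition label.
#' @return A data frame of class `expression_table`.
#' @export
expression_table <- function(gene, log2fc, fdr, condition) {
  gene <- as.character(gene)
  log2fc <- suppressWarnings(as.numeric(log2fc))
  fdr <- suppressWarnings(as.numeric(fdr))
  if (anyNA(log2fc)) stop_agestrat("non-numeric log2FC value(s)")
  if (anyNA(fdr) || any(fdr < 0 | fdr > 1)) {
    stop_agestrat("FDR values must be numeric and within [0, 1]")
  }
  if (anyDuplicated(gene)) {
    stop_agestrat("duplicated gene in DE table: %s",
                  gene[duplicated(gene)][1L])
  }
  structure(
    data.frame(gene = gene, log2fc = log2fc, fdr = fdr,
               stringsAsFactors = FALSE),
    condition = as.character(condition),
    class = c("expression_table", "data.frame")
  )
}

#' Read a replicate counts matrix
#'
#' The TSV carries one row per gene with columns `gene`, `length_bp`, then
#' one column per sample named `<condition>_<replicate>` (the condition may
#' itself contain underscores; the replicate label follows the last one).
#'
#' @param path Path to the TSV.
#' @return A `counts_matrix` object (see [counts_matrix()]).
#' @export
read_counts <- function(path) {
  check_file(path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           check.names = FALSE)
  need <- c("gene", "length_bp")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop_agestrat("counts table %s is missing column(s): %s", path,
                  paste(miss, collapse = ", "))
  }
  samples <- setdiff(names(tab), need)
  if (!length(samples)) stop_agestrat("counts table %s has no sample columns", path)
  counts <- as.matrix(tab[samples])
  rownames(counts) <- as.character(tab$gene)
  counts_matrix(counts, length_bp = tab$length_bp)
}

#' Construct a counts matrix
#'
#' @param counts Numeric gene x sample matrix with row and column names;
#'   column names follow `<condition>_<replicate>`.
#' @param length_bp Gene lengths in bp, positive, one per row.
#' @param condition,replicate Optional explicit per-sample labels,
#'   overriding the column-name parse.
#' @return A list of class `counts_matrix` with elements `counts`,
#'   `length_bp`, `condition`, `replicate`.
#' @export
counts_matrix <- function(counts, length_bp, condition = NULL, replicate = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (anyNA(counts) || any(counts < 0)) {
    stop_agestrat("counts must be non-negative and complete")
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop_agestrat("counts matrix needs gene row names and sample column names")
  }
  length_bp <- as.numeric(length_bp)
  if (length(length_bp) != nrow(counts) || anyNA(length_bp) || any(length_bp <= 0)) {
    stop_agestrat("length_bp must be strictly positive, one per gene")
  }
  if (is.null(condition) || is.null(replicate)) {
    parsed <- regmatches(colnames(counts),
                         regexec("^(.*)_([^_]+)$", colnames(counts)))
    bad <- colnames(counts)[lengths(parsed) != 3L]
    if (length(bad)) {
      stop_agestrat("sample column not of the form <condition>_<replicate>: %s",
                    bad[1L])
    }
    if (is.null(condition)) condition <- vapply(parsed, `[`, character(1), 2L)
    if (is.null(replicate)) replicate <- vapply(parsed, `[`, character(1), 3L)
  }
  structure(list(counts = counts, length_bp = length_bp,
                 condition = as.character(condition),
                 replicate = as.character(replicate)),
            class = "counts_matrix")
}

#' @export
print.counts_matrix <- function(x, ...) {
  cat(sprintf("Counts matrix: %d genes x %d samples (%d condition(s))\n",
              nrow(x$counts), ncol(x$counts), length(unique(x$condition))))
  invisible(x)
}

#' Read a protein FASTA into a named character vector
#'
#' @param path Path to an (uncompressed) FASTA file.
#' @return Named character vector of sequences; names are the first
#'   whitespace-delimited token of each header.
#' @export
read_fasta <- function(path) {
  check_file(path)
  set <- Biostrings::readBStringSet(path)
  seqs <- as.character(set)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' Write a named character vector of sequences as FASTA
#' @param seqs Named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a BLAST tabular (outfmt 6) hit table
#'
#' Standard 12-column layout: qseqid, sseqid, pident, length, mismatch,
#' gapopen, qstart, qend, sstart, send, evalue, bitscore. No header row.
#'
#' @param path Path to the tab-separated hit table.
#' @return A data frame of class `homolog_hits` with columns `query`,
#'   `subject`, `pct_identity`, `aln_len`, `evalue`, `bitscore`.
#' @export
read_blast_tab <- function(path) {
  check_file(path)
  tab <- utils::read.delim(path, header = FALSE, sep = "\t", quote = "",
                           comment.char = "#")
  if (ncol(tab) < 12L) {
    stop_agestrat("BLAST tabular file %s has %d columns; outfmt 6 needs 12",
                  path, ncol(tab))
  }
  homolog_hits(query = tab[[1L]], subject = tab[[2L]],
               pct_identity = tab[[3L]], aln_len = tab[[4L]],
               evalue = tab[[11L]], bitscore = tab[[12L]])
}

#' Construct a homolog hit table
#'
#' @param query,subject Identifiers.
#' @param pct_identity Percent identity in `[0, 100]`.
#' @param aln_len Alignment length, positive integers.
#' @param bitscore Hit score used for best-hit ranking.
#' @param evalue Optional E-values.
#' @return A data frame of class `homolog_hits`.
#' @export
homolog_hits <- function(query, subject, pct_identity, aln_len, bitscore,
                         evalue = NA_real_) {
  pct_identity <- as.numeric(pct_identity)
  if (anyNA(pct_identity) || any(pct_identity < 0 | pct_identity > 100)) {
    stop_agestrat("pct_identity must lie in [0, 100]")
  }
  aln_len <- as.integer(aln_len)
  if (anyNA(aln_len) || any(aln_len <= 0)) {
    stop_agestrat("aln_len must be a positive integer")
  }
  structure(
    data.frame(query = as.character(query), subject = as.character(subject),
               pct_identity = pct_identity, aln_len = aln_len,
               evalue = as.numeric(evalue), bitscore = as.numeric(bitscore),
               stringsAsFactors = FALSE),
    class = c("homolog_hits", "data.frame")
  )
}

#' Write gene assignments to TSV
#'
#' One row per gene with columns `gene`, `conservation_class`, `age_group`,
#' `basis`, `orthogroup_id`; missing fields are written as `NA`.
#'
#' @param assignments A data frame holding at least a `gene` column; any of
#'   the other columns that are absent are filled with `NA`. The outputs of
#'   [classify_conservation()] and [stratify_genome()] (or their merge) are
#'   accepted directly.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_assignments <- function(assignments, path) {
  if (!is.data.frame(assignments) || !"gene" %in% names(assignments)) {
    stop_agestrat("assignments must be a data frame with a 'gene' column")
  }
  cols <- c("gene", "conservation_class", "age_group", "basis", "orthogroup_id")
  out <- assignments
  for (cc in setdiff(cols, names(out))) out[[cc]] <- NA_character_
  out <- out[cols]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read an assignment TSV written by [write_assignments()]
#' @param path Path to the TSV.
#' @return Data frame with the five assignment columns.
#' @export
read_assignments <- function(path) {
  check_file(path)
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    colClasses = "character", na.strings = "NA")
}
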