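# Adaptation rates: amino-acid identity lost per million years against the
# closest homolog from a congeneric species, summarized per age group.

#' Best homolog of a query protein
#'
#' Selects the hit with maximal bitscore; ties are broken by higher percent
#' identity, then lexicographically smaller subject identifier. Output does
#' not depend on the row order of the hit table.
#'
#' @param hits A [homolog_hits()] table.
#' @param query Query identifier.
#' @return A one-row data frame (the winning hit), or `NULL` when the query
#'   has no hits.
#' @export
best_homolog <- function(hits, query) {
  sub <- hits[hits$query == query, , drop = FALSE]
  if (!nrow(sub)) return(NULL)
  ord <- order(-sub$bitscore, -sub$pct_identity, sub$subject)
  sub[ord[1L], , drop = FALSE]
}

#' Identity loss rate
#'
#' Percent amino-acid identity lost per million years:
#' `(100 - pct_identity) / divergence_myr`.
#'
#' @param pct_identity Percent identity in `[0, 100]`.
#' @param divergence_myr Divergence time of the species pair in million
#'   years, strictly positive.
#' @return Numeric rate(s) in % identity lost per Myr.
#' @export
#' @examples
#' identity_loss_rate(92, 40)  # 0.2
identity_loss_rate <- function(pct_identity, divergence_myr) {
  if (any(!is.finite(divergence_myr)) || any(divergence_myr <= 0)) {
    stop_agestrat("divergence_myr must be strictly positive")
  }
  if (any(pct_identity < 0 | pct_identity > 100)) {
    stop_agestrat("pct_identity must lie in [0, 100]")
  }
  (100 - pct_identity) / divergence_myr
}

#' Per-gene adaptation rates from a homolog hit table
#'
#' Takes each query's best congeneric hit (see [best_homolog()]), discards
#' queries whose best hit scores below `min_bitscore` (a weak hit is not
#' evidence of genuine homology), and converts percent identity into
#' % identity lost per Myr using the divergence time of the species pair.
#'
#' @param hits A [homolog_hits()] table (one species pair per table).
#' @param divergence_myr Divergence time in Myr for the species pair,
#'   strictly positive.
#' @param min_bitscore Bitscore floor for the best hit, default 50.
#' @return A data frame of class `adaptation_records`: `gene`,
#'   `best_subject`, `pct_identity`, `divergence_myr`, `id_lost_per_myr`.
#'   Queries without an acceptable hit are absent.
#' @export
adaptation_rates <- function(hits, divergence_myr, min_bitscore = 50) {
  stopifnot(is.data.frame(hits))
  if (length(divergence_myr) != 1L || !is.finite(divergence_myr) ||
      divergence_myr <= 0) {
    stop_agestrat("divergence_myr must be a single positive number")
  }
  queries <- sort(unique(hits$query))
  best <- do.call(rbind, lapply(queries, function(q) best_homolog(hits, q)))
  if (is.null(best)) best <- hits[0L, , drop = FALSE]
  best <- best[best$bitscore >= min_bitscore, , drop = FALSE]
  structure(
    data.frame(gene = best$query, best_subject = best$subject,
               pct_identity = best$pct_identity,
               divergence_myr = rep(divergence_myr, nrow(best)),
               id_lost_per_myr = if (nrow(best))
                 identity_loss_rate(best$pct_identity, divergence_myr)
               else numeric(0),
               stringsAsFactors = FALSE, row.names = NULL),
    class = c("adaptation_records", "data.frame")
  )
}

#' Summarize adaptation rates per age group
#'
#' Joins per-gene rates to age assignments and reports, per requested
#' group, the median % identity lost per Myr with a percentile-bootstrap
#' confidence interval (see [median_ci()]).
#'
#' @param records An [adaptation_rates()] result.
#' @param ages An age assignment data frame (`gene`, `age_group`).
#' @param groups Group labels to summarize, default `c("I", "IV")` (the
#'   classic ancient-vs-young contrast).
#' @param level Confidence level, default 0.95.
#' @param reps Bootstrap replicates, default 10000.
#' @param seed Optional seed for the bootstrap.
#' @return Data frame: `age_group`, `n`, `median`, `lo`, `hi`. Groups with
#'   no records get `n = 0` and `NA` summaries.
#' @export
group_rate_summary <- function(records, ages, groups = c("I", "IV"),
                               level = 0.95, reps = 10000, seed = NULL) {
  stopifnot(is.data.frame(records), is.data.frame(ages))
  grp <- ages$age_group[match(records$gene, ages$gene)]
  out <- lapply(seq_along(groups), function(i) {
    g <- groups[i]
    vals <- records$id_lost_per_myr[!is.na(grp) & grp == g]
    if (!length(vals)) {
      return(data.frame(age_group = g, n = 0L, median = NA_real_,
                        lo = NA_real_, hi = NA_real_))
    }
    ci <- median_ci(vals, level = level, reps = reps,
                    seed = if (is.null(seed)) NULL else seed + i)
    data.frame(age_group = g, n = length(vals), median = ci[["median"]],
               lo = ci[["lo"]], hi = ci[["hi"]])
  })
  do.call(rbind, out)
}

#' Percent identity by global alignment of two protein sequences
#'
#' Needleman-Wunsch global alignment (BLOSUM62, affine gaps) with identity
#' computed as matches divided by alignment columns including internal
#' gaps. For small FASTA inputs this offers an in-package alternative to an
#' external aligner's hit table; note the denominator differs from the
#' local-alignment convention of BLAST tabular output.
#'
#' @param query,subject Protein sequences as single character strings.
#' @return A list with `pct_identity`, `score`, `aln_len`.
#' @export
align_identity <- function(query, subject) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(subject),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5
  )
  p <- as.character(Biostrings::alignedPattern(aln))
  s <- as.character(Biostrings::alignedSubject(aln))
  pc <- strsplit(p, "")[[1L]]
  sc <- strsplit(s, "")[[1L]]
  ncol_aln <- length(pc)
  matches <- sum(pc == sc & pc != "-")
  list(pct_identity = 100 * matches / ncol_aln,
       score = Biostrings::score(aln),
       aln_len = ncol_aln)
}

#' Build a homolog hit table by aligning FASTA sequence sets
#'
#' Aligns every query against every subject (all pairs; intended for small
#' inputs) and reports global-alignment identity, with the alignment score
#' standing in for the bitscore in best-hit ranking.
#'
#' @param query_seqs,subject_seqs Named character vectors of protein
#'   sequences, e.g. from [read_fasta()].
#' @return A [homolog_hits()] table.
#' @export
align_hit_table <- function(query_seqs, subject_seqs) {
  rows <- list()
  for (q in names(query_seqs)) {
    for (s in names(subject_seqs)) {
      a <- align_identity(query_seqs[[q]], subject_seqs[[s]])
      rows[[length(rows) + 1L]] <- data.frame(
        query = q, subject = s, pct_identity = a$pct_identity,
        aln_len = a$aln_len, evalue = NA_real_, bitscore = a$score,
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  homolog_hits(df$query, df$subject, df$pct_identity, df$aln_len,
               df$bitscore, df$evalue)
}
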