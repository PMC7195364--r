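# Differential-expression filters and per-age-group enrichment statistics:
# strict DE flagging, replicate-noise (RSD) filtering, normalized enrichment
# ratios with two-sided Fisher exact tests, cross-condition overlap counts,
# TPM normalization and bootstrap confidence intervals of the median.

#' Flag differentially expressed genes
#'
#' A gene is differentially expressed when `|log2FC| > lfc_cut` and
#' `FDR < fdr_cut`, both strict; the direction is the sign of the fold
#' change. Defaults are the conventional cutoffs |log2FC| > 1, FDR < 0.01.
#'
#' @param expr An [expression_table()].
#' @param lfc_cut Absolute log2 fold-change cutoff (strict), default 1.
#' @param fdr_cut FDR cutoff (strict), default 0.01.
#' @return A data frame of class `de_flags` with columns `gene`, `is_de`,
#'   `direction` (`"up"`, `"down"`, `"none"`) and attribute `condition`.
#' @export
flag_de <- function(expr, lfc_cut = 1, fdr_cut = 0.01) {
  if (!all(c("gene", "log2fc", "fdr") %in% names(expr))) {
    stop_agestrat("expr must have columns gene, log2fc, fdr")
  }
  is_de <- abs(expr$log2fc) > lfc_cut & expr$fdr < fdr_cut
  direction <- ifelse(!is_de, "none", ifelse(expr$log2fc > 0, "up", "down"))
  structure(
    data.frame(gene = expr$gene, is_de = is_de, direction = direction,
               stringsAsFactors = FALSE),
    condition = attr(expr, "condition"),
    class = c("de_flags", "data.frame")
  )
}

#' Filter genes by relative standard deviation across replicates
#'
#' Removes genes whose expression is too noisy to interpret: a gene is
#' retained only if, in every condition, the relative standard deviation
#' (sample sd / mean) across replicates is at most `threshold` and the mean
#' is positive. Genes at zero mean in any condition (RSD undefined) are
#' removed.
#'
#' @param counts A [counts_matrix()].
#' @param threshold RSD cutoff, default 1.
#' @param conditions Optional subset of conditions under comparison;
#'   defaults to all conditions in the matrix.
#' @return Character vector of retained gene identifiers.
#' @export
filter_rsd <- function(counts, threshold = 1, conditions = NULL) {
  stopifnot(inherits(counts, "counts_matrix"))
  if (is.null(conditions)) conditions <- unique(counts$condition)
  keep <- rep(TRUE, nrow(counts$counts))
  for (cond in conditions) {
    cols <- which(counts$condition == cond)
    if (length(cols) < 2L) {
      stop_agestrat("condition '%s' has %d replicate(s); RSD needs at least 2",
                    cond, length(cols))
    }
    sub <- counts$counts[, cols, drop = FALSE]
    m <- rowMeans(sub)
    s <- apply(sub, 1L, stats::sd)
    keep <- keep & m > 0 & (s / m) <= threshold
  }
  rownames(counts$counts)[keep]
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Conditional exact test: the two-sided p-value sums the hypergeometric
#' probabilities of every table with the observed margins whose probability
#' does not exceed that of the observed table (ties resolved within a
#' relative tolerance of 1e-7).
#'
#' @param a,b,c,d Non-negative integer cell counts, row-wise:
#'   `matrix(c(a, b, c, d), 2, byrow = TRUE)`.
#' @return The two-sided p-value in `(0, 1]`.
#' @export
#' @examples
#' fisher_two_sided(10, 0, 0, 10)
fisher_two_sided <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (anyNA(cells) || any(cells < 0) || any(cells != floor(cells))) {
    stop_agestrat("Fisher cells must be non-negative integers")
  }
  m <- matrix(as.integer(cells), nrow = 2L, byrow = TRUE)
  min(1, stats::fisher.test(m, alternative = "two.sided")$p.value)
}

#' Normalized DE enrichment per age group
#'
#' For each group the DE fraction inside the group is divided by the overall
#' DE fraction among all measured genes, so that 1 means no enrichment.
#' Each group is also tested against the rest of the genome with a
#' two-sided Fisher exact test on the 2x2 table (DE in group, non-DE in
#' group; DE outside, non-DE outside), and p-values are Benjamini-Hochberg
#' adjusted across the groups of each condition.
#'
#' @param ages An [stratify_genome()] result (or any data frame with
#'   columns `gene` and `age_group`) defining the measured genes and their
#'   groups. A [classify_conservation()] result is also accepted (its
#'   `conservation_class` column is used as the grouping).
#' @param flags A [flag_de()] result, or a list of them (one per
#'   condition). Flags must cover every measured gene.
#' @param scope `"all"` counts any DE gene; `"up"`/`"down"` count only that
#'   direction.
#' @return A data frame of class `enrichment_table`, one row per group per
#'   condition: `condition`, `age_group`, `n_group`, `de_group`, `ratio`,
#'   `p_value`, `p_adjusted`. When a condition has no DE genes the ratio is
#'   `NA` but rows are still emitted.
#' @export
enrichment_table <- function(ages, flags, scope = c("all", "up", "down")) {
  scope <- match.arg(scope)
  if (inherits(flags, "de_flags") || (is.data.frame(flags) &&
                                      "is_de" %in% names(flags))) {
    flags <- list(flags)
  }
  group_col <- if ("age_group" %in% names(ages)) "age_group"
               else if ("conservation_class" %in% names(ages)) "conservation_class"
               else stop_agestrat("ages must have an age_group or conservation_class column")
  lv <- attr(ages, "ladder_labels")
  groups <- if (!is.null(lv)) intersect(lv, unique(ages[[group_col]]))
            else unique(ages[[group_col]])

  rows <- lapply(seq_along(flags), function(k) {
    fl <- flags[[k]]
    cond <- attr(fl, "condition")
    if (is.null(cond)) cond <- if (!is.null(names(flags))) names(flags)[k]
                               else paste0("cond", k)
    j <- match(ages$gene, fl$gene)
    if (anyNA(j)) {
      stop_agestrat("DE flags for condition '%s' do not cover measured gene '%s'",
                    cond, ages$gene[which(is.na(j))[1L]])
    }
    de <- switch(scope,
                 all = fl$is_de[j],
                 up = fl$direction[j] == "up",
                 down = fl$direction[j] == "down")
    n_total <- length(de)
    de_total <- sum(de)
    g <- factor(ages[[group_col]], levels = groups)
    n_group <- as.integer(table(g))
    de_group <- as.integer(tapply(de, g, sum, default = 0L))
    ratio <- if (de_total > 0) {
      (de_group / n_group) / (de_total / n_total)
    } else rep(NA_real_, length(groups))
    p <- vapply(seq_along(groups), function(i) {
      fisher_two_sided(de_group[i], n_group[i] - de_group[i],
                       de_total - de_group[i],
                       (n_total - n_group[i]) - (de_total - de_group[i]))
    }, numeric(1))
    data.frame(condition = cond, age_group = groups, n_group = n_group,
               de_group = de_group, ratio = ratio, p_value = p,
               p_adjusted = stats::p.adjust(p, method = "BH"),
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows),
            scope = scope,
            class = c("enrichment_table", "data.frame"))
}

#' Cross-condition overlap counts of DE genes
#'
#' Counts, for every non-empty combination of conditions, the genes flagged
#' in the requested direction in exactly that combination (the cells of a
#' Venn/UpSet diagram). Typically applied to the young age groups to ask how
#' condition-specific the young stress response is.
#'
#' @param flags_by_condition A named list of [flag_de()] results.
#' @param gene_subset Optional character vector restricting the genes
#'   considered (e.g. the genes of the two youngest groups).
#' @param direction `"up"`, `"down"`, or `"any"`.
#' @return A data frame with one row per non-empty condition combination:
#'   `combination` (condition names joined by `"&"`), `n_conditions`,
#'   `count`. Counts over all combinations sum to the union size.
#' @export
overlap_counts <- function(flags_by_condition, gene_subset = NULL,
                           direction = c("up", "down", "any")) {
  direction <- match.arg(direction)
  if (!is.list(flags_by_condition) || length(flags_by_condition) < 2L) {
    stop_agestrat("overlap_counts needs at least 2 conditions")
  }
  conds <- names(flags_by_condition)
  if (is.null(conds)) {
    conds <- vapply(seq_along(flags_by_condition), function(k) {
      cond <- attr(flags_by_condition[[k]], "condition")
      if (is.null(cond)) paste0("cond", k) else cond
    }, character(1))
  }
  sets <- lapply(flags_by_condition, function(fl) {
    sel <- switch(direction,
                  up = fl$direction == "up",
                  down = fl$direction == "down",
                  any = fl$is_de)
    g <- fl$gene[sel]
    if (!is.null(gene_subset)) g <- intersect(g, gene_subset)
    g
  })
  k <- length(sets)
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1L, , drop = FALSE]
  universe <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L)
  if (length(universe) == 0L) member <- matrix(logical(0), ncol = k)
  counts <- apply(combos, 1L, function(want) {
    if (!nrow(member)) return(0L)
    sum(apply(member, 1L, function(row) all(row == want)))
  })
  data.frame(
    combination = apply(combos, 1L, function(w) paste(conds[unlist(w)],
                                                      collapse = "&")),
    n_conditions = rowSums(combos),
    count = as.integer(counts),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Transcripts-per-million normalization
#'
#' Counts are divided by gene length and rescaled so that every sample sums
#' to one million: `tpm = 1e6 * (count/length) / sum(count/length)`.
#'
#' @param counts A [counts_matrix()].
#' @return Numeric gene x sample matrix of TPM values.
#' @export
tpm <- function(counts) {
  stopifnot(inherits(counts, "counts_matrix"))
  rate <- counts$counts / counts$length_bp
  tot <- colSums(rate)
  if (any(tot == 0)) {
    stop_agestrat("sample '%s' has zero total counts",
                  colnames(counts$counts)[tot == 0][1L])
  }
  sweep(rate, 2L, tot, "/") * 1e6
}

#' Percentile bootstrap confidence interval of the median
#'
#' @param values Numeric vector (at least one value).
#' @param level Confidence level, default 0.95.
#' @param reps Bootstrap replicates, default 10000.
#' @param seed Optional integer seed; when given, the result is
#'   reproducible and the caller's RNG state is left untouched.
#' @return Named numeric vector `median`, `lo`, `hi`.
#' @export
median_ci <- function(values, level = 0.95, reps = 10000, seed = NULL) {
  values <- as.numeric(values)
  values <- values[!is.na(values)]
  if (!length(values)) stop_agestrat("median_ci needs at least one value")
  med <- stats::median(values)
  if (length(values) == 1L || length(unique(values)) == 1L) {
    return(c(median = med, lo = med, hi = med))
  }
  n <- length(values)
  boots <- with_seed(seed, {
    idx <- sample.int(n, n * reps, replace = TRUE)
    apply(matrix(values[idx], nrow = reps), 1L, stats::median)
  })
  alpha <- (1 - level) / 2
  qs <- stats::quantile(boots, c(alpha, 1 - alpha), names = FALSE)
  c(median = med, lo = qs[1L], hi = qs[2L])
}

#' @export
print.enrichment_table <- function(x, ...) {
  cat(sprintf("DE enrichment by age group (scope: %s)\n",
              attr(x, "scope")))
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' @export
plot.enrichment_table <- function(x, ...) {
  conds <- unique(x$condition)
  groups <- unique(x$age_group)
  m <- matrix(x$ratio[order(match(x$condition, conds),
                            match(x$age_group, groups))],
              nrow = length(groups), dimnames = list(groups, conds))
  graphics::barplot(m, beside = TRUE, legend.text = groups,
                    ylab = "normalized DE enrichment ratio", ...)
  graphics::abline(h = 1, lty = 2)
  invisible(x)
}
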