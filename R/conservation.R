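# Conservation-class partition: single-core / multi-core / non-core.

#' Partition focal-species genes into conservation classes
#'
#' Every focal gene is assigned exactly one of three classes from an
#' orthogroup table. A gene is `non_core` when its orthogroup has zero
#' members in at least one query species (or it belongs to no orthogroup at
#' all); among the remaining core genes, `single_core` genes are encoded by
#' a single focal copy in their orthogroup and `multi_core` genes by two or
#' more. The classic yeast examples: a one-copy biosynthesis gene conserved
#' across the queried species is single-core; a duplicated pair such as the
#' galactokinase paralogs sharing one orthogroup with orthologs in every
#' query is multi-core.
#'
#' @param ortho An [orthogroup_table()].
#' @param focal Focal species identifier (a species column of `ortho`).
#' @param queries Character vector of query species (non-empty, species
#'   columns of `ortho`).
#' @param genes Optional character vector of focal genes to classify,
#'   possibly including identifiers absent from the table (measured genes
#'   that the orthology tool left unassigned; these come out `non_core`).
#'   Defaults to the focal genes present in the table.
#' @param noncore_mode `"any"` (default): non-core when absent from at
#'   least one query species. `"all"`: non-core only when absent from every
#'   query species.
#' @return A data frame of class `conservation_assignment` with columns
#'   `gene`, `conservation_class`, `orthogroup_id` (`NA` for genes in no
#'   orthogroup).
#' @export
#' @examples
#' ms <- data.frame(
#'   orthogroup = c("OG1", "OG1", "OG1", "OG2", "OG2"),
#'   species    = c("A", "B", "C", "A", "A"),
#'   gene       = c("a1", "b1", "c1", "a2", "a3"))
#' ortho <- orthogroup_table(ms, species = c("A", "B", "C"))
#' classify_conservation(ortho, focal = "A", queries = c("B", "C"))
classify_conservation <- function(ortho, focal, queries, genes = NULL,
                                  noncore_mode = c("any", "all")) {
  stopifnot(inherits(ortho, "orthogroup_table"))
  noncore_mode <- match.arg(noncore_mode)
  if (!length(queries)) stop_agestrat("queries must be non-empty")
  missing_sp <- setdiff(c(focal, queries), ortho$species)
  if (length(missing_sp)) {
    stop_agestrat("species not in orthogroup table: %s",
                  paste(missing_sp, collapse = ", "))
  }
  if (is.null(genes)) genes <- focal_genes(ortho, focal)
  genes <- as.character(genes)
  if (anyDuplicated(genes)) {
    stop_agestrat("duplicated gene in classification request: %s",
                  genes[duplicated(genes)][1L])
  }

  cn <- copy_number_matrix(ortho)
  q_present <- cn[, queries, drop = FALSE] > 0
  absent_ct <- ncol(q_present) - rowSums(q_present)
  noncore_og <- if (noncore_mode == "any") absent_ct > 0 else
    absent_ct == ncol(q_present)
  focal_n <- cn[, focal]

  ms <- ortho$membership
  og_of_gene <- ms$orthogroup[match(genes, ms$gene)]
  in_focal <- !is.na(og_of_gene) &
    genes %in% ms$gene[ms$species == focal]
  # a requested gene found in the table under a non-focal species is an error
  wrong_sp <- !is.na(og_of_gene) & !in_focal
  if (any(wrong_sp)) {
    stop_agestrat("gene '%s' belongs to species other than the focal '%s'",
                  genes[wrong_sp][1L], focal)
  }

  cls <- rep("non_core", length(genes))
  idx <- match(og_of_gene, rownames(cn))
  core <- in_focal & !noncore_og[ifelse(is.na(idx), 1L, idx)]
  core[is.na(og_of_gene)] <- FALSE
  cls[core & focal_n[idx] == 1L] <- "single_core"
  cls[core & focal_n[idx] >= 2L] <- "multi_core"

  structure(
    data.frame(gene = genes, conservation_class = cls,
               orthogroup_id = og_of_gene, stringsAsFactors = FALSE),
    class = c("conservation_assignment", "data.frame")
  )
}

#' @export
summary.conservation_assignment <- function(object, ...) {
  tab <- table(factor(object$conservation_class,
                      levels = c("single_core", "multi_core", "non_core")))
  cat("Conservation partition:\n")
  print(tab)
  invisible(tab)
}
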