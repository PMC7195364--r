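# Age stratification: assign each focal gene one evolutionary age group by
# combining the timing of de novo origin (single-copy genes: deepest rung
# with any ortholog) with the timing of duplication (multi-copy genes:
# deepest rung where some species shares the focal copy number), plus an
# optional whole-genome-duplication class supplied as an ohnolog pair list.

# Internal engine: per-orthogroup rung statistics against a ladder.
# Returns a list with, per orthogroup: focal copy number, the deepest rung
# with any non-focal ortholog (origin dating), and the duplication rung
# under both supported rules.
rung_profiles <- function(ortho, ladder) {
  cn <- copy_number_matrix(ortho)
  focal <- ladder$focal
  if (!focal %in% ortho$species) {
    stop_agestrat("focal species '%s' is not a column of the orthogroup table",
                  focal)
  }
  sp_rung <- rung_of_species(ladder)
  unmapped <- setdiff(ortho$species, names(sp_rung))
  if (length(unmapped)) {
    stop_agestrat("species in orthogroup table not mapped to any rung: %s",
                  paste(unmapped, collapse = ", "))
  }
  nr <- n_rungs(ladder)
  ng <- nrow(cn)
  focal_n <- cn[, focal]

  deepest <- rep(1L, ng)        # origin rung: any ortholog presence
  dup_oldest <- rep(1L, ng)     # deepest rung with an exact focal-copy match
  dup_yc <- rep(1L, ng)         # youngest contiguous run of exact matches
  contig <- rep(TRUE, ng)
  if (nr >= 2L) {
    for (r in 2:nr) {
      cols <- intersect(names(sp_rung)[sp_rung == r], ortho$species)
      if (!length(cols)) {
        pres <- rep(FALSE, ng)
        eqn <- rep(FALSE, ng)
      } else {
        sub <- cn[, cols, drop = FALSE]
        pres <- rowSums(sub > 0) > 0
        eqn <- rowSums(sub == focal_n) > 0   # column-wise recycle of focal_n
      }
      deepest[pres] <- r
      dup_oldest[eqn] <- r
      contig <- contig & eqn
      dup_yc[contig] <- r
    }
  }
  list(ids = rownames(cn), focal_n = focal_n, deepest = deepest,
       dup_oldest = dup_oldest, dup_yc = dup_yc)
}

#' Focal copy number of a gene
#'
#' Number of focal-species members in the gene's orthogroup; genes absent
#' from every orthogroup count as singletons (copy number 1).
#'
#' @param ortho An [orthogroup_table()].
#' @param focal Focal species identifier.
#' @param gene Gene identifier.
#' @return Integer copy number, at least 1.
#' @export
focal_copy_number <- function(ortho, focal, gene) {
  stopifnot(inherits(ortho, "orthogroup_table"))
  ms <- ortho$membership
  og <- ms$orthogroup[match(gene, ms$gene)]
  if (is.na(og)) return(1L)
  sum(ms$orthogroup == og & ms$species == focal)
}

#' Date a single-copy gene by its most distant ortholog
#'
#' Returns the deepest (oldest) rung of the ladder in which at least one
#' species carries a member of the gene's orthogroup; a gene with no
#' ortholog outside the focal species dates to rung 1 (species-specific).
#'
#' @param ortho An [orthogroup_table()].
#' @param ladder A [species_ladder()].
#' @param gene Gene identifier (focal copy number must be 1).
#' @return Rung index (integer).
#' @export
assign_single_copy_age <- function(ortho, ladder, gene) {
  prof <- rung_profiles(ortho, ladder)
  ms <- ortho$membership
  og <- ms$orthogroup[match(gene, ms$gene)]
  if (is.na(og)) return(1L)
  i <- match(og, prof$ids)
  if (prof$focal_n[i] != 1L) {
    stop_agestrat("gene '%s' has focal copy number %d; expected 1",
                  gene, prof$focal_n[i])
  }
  prof$deepest[i]
}

#' Date a duplication by shared copy number along the ladder
#'
#' For a gene with `n >= 2` focal copies, scans the rungs and dates the
#' duplication to the deepest rung in which at least one species carries
#' exactly `n` members of the orthogroup (the duplication preceded that
#' split). When no species matches `n`, the duplication postdates every
#' sampled split and the gene dates to rung 1.
#'
#' @inheritParams assign_single_copy_age
#' @param rule `"oldest"` (default): the deepest rung with an exact-copy
#'   match anywhere. `"youngest_contiguous"`: the deepest rung reachable
#'   through an unbroken run of exact-copy matches starting at rung 2;
#'   robust to convergent copy-number coincidences in distant rungs.
#' @return Rung index (integer).
#' @export
assign_multicopy_age <- function(ortho, ladder, gene,
                                 rule = c("oldest", "youngest_contiguous")) {
  rule <- match.arg(rule)
  prof <- rung_profiles(ortho, ladder)
  ms <- ortho$membership
  og <- ms$orthogroup[match(gene, ms$gene)]
  if (is.na(og)) stop_agestrat("gene '%s' not found in any orthogroup", gene)
  i <- match(og, prof$ids)
  if (prof$focal_n[i] < 2L) {
    stop_agestrat("gene '%s' has focal copy number %d; expected >= 2",
                  gene, prof$focal_n[i])
  }
  if (rule == "oldest") prof$dup_oldest[i] else prof$dup_yc[i]
}

#' Assign every measured focal gene one evolutionary age group
#'
#' Genes are split into three subsets and dated hierarchically:
#' ohnolog pairs named in `wgd` form their own `"WGD"` group; the remaining
#' single-copy genes are dated by the most distant rung holding an ortholog
#' (de novo origin timing); the remaining multi-copy genes are dated by the
#' deepest rung where some species shares the focal copy number (duplication
#' timing). Rung indices are reported through the ladder's labels, so a
#' 5-rung ladder yields groups I (oldest) through V (species-specific),
#' plus "WGD" when an ohnolog list is supplied. For species without a
#' recent whole-genome duplication simply omit `wgd`.
#'
#' @param ortho An [orthogroup_table()].
#' @param ladder A [species_ladder()].
#' @param wgd Optional ohnolog list: a data frame with columns `gene_a`,
#'   `gene_b` (or a character vector of genes). Genes must be known focal
#'   genes and unique across pairs.
#' @param measured_genes Optional character vector restricting the output to
#'   the genes actually measured; identifiers absent from every orthogroup
#'   are treated as species-specific singletons. Defaults to all focal genes
#'   in the table.
#' @param dup_rule Duplication dating rule, see [assign_multicopy_age()].
#' @return A data frame of class `age_assignment` with one row per measured
#'   gene: `gene`, `age_group` (rung label or `"WGD"`), `basis` (one of
#'   `origin_single_copy`, `duplication_timing`, `wgd`), `deepest_rung`
#'   (integer rung index; `NA` for WGD genes), `focal_copy_number`,
#'   `orthogroup_id`.
#' @export
stratify_genome <- function(ortho, ladder, wgd = NULL, measured_genes = NULL,
                            dup_rule = c("oldest", "youngest_contiguous")) {
  stopifnot(inherits(ortho, "orthogroup_table"),
            inherits(ladder, "species_ladder"))
  dup_rule <- match.arg(dup_rule)
  focal <- ladder$focal
  known <- focal_genes(ortho, focal)
  if (is.null(measured_genes)) measured_genes <- known
  measured_genes <- as.character(measured_genes)
  if (!length(measured_genes)) stop_agestrat("measured_genes is empty")
  if (anyDuplicated(measured_genes)) {
    stop_agestrat("duplicated measured gene: %s",
                  measured_genes[duplicated(measured_genes)][1L])
  }
  ms <- ortho$membership
  in_table <- measured_genes %in% ms$gene
  not_focal <- in_table & !(measured_genes %in% known)
  if (any(not_focal)) {
    stop_agestrat("measured gene '%s' is not a focal-species gene",
                  measured_genes[not_focal][1L])
  }

  wgd_genes <- character(0)
  if (!is.null(wgd)) {
    wgd_genes <- if (is.data.frame(wgd)) c(wgd$gene_a, wgd$gene_b)
                 else as.character(wgd)
    wgd_genes <- as.character(wgd_genes)
    if (anyDuplicated(wgd_genes)) {
      stop_agestrat("gene repeated in WGD ohnolog list: %s",
                    wgd_genes[duplicated(wgd_genes)][1L])
    }
    unknown <- setdiff(wgd_genes, known)
    if (length(unknown)) {
      stop_agestrat("WGD ohnolog not a known focal gene: %s",
                    paste(utils::head(unknown, 5L), collapse = ", "))
    }
  }

  prof <- rung_profiles(ortho, ladder)
  og_of_gene <- ms$orthogroup[match(measured_genes, ms$gene)]
  i <- match(og_of_gene, prof$ids)

  n <- ifelse(is.na(i), 1L, prof$focal_n[i])
  rung <- ifelse(is.na(i), 1L, prof$deepest[i])
  dup_rung <- if (dup_rule == "oldest") prof$dup_oldest else prof$dup_yc
  is_multi <- !is.na(i) & n >= 2L
  rung[is_multi] <- dup_rung[i[is_multi]]
  basis <- ifelse(is_multi, "duplication_timing", "origin_single_copy")

  is_wgd <- measured_genes %in% wgd_genes
  basis[is_wgd] <- "wgd"
  age_group <- rung_label(ladder, rung)
  age_group[is_wgd] <- "WGD"
  rung[is_wgd] <- NA_integer_

  structure(
    data.frame(gene = measured_genes, age_group = age_group, basis = basis,
               deepest_rung = as.integer(rung),
               focal_copy_number = as.integer(n),
               orthogroup_id = og_of_gene, stringsAsFactors = FALSE),
    ladder_labels = c(ladder$rungs$label,
                      if (length(wgd_genes)) "WGD"),
    class = c("age_assignment", "data.frame")
  )
}

#' @export
summary.age_assignment <- function(object, ...) {
  lv <- attr(object, "ladder_labels")
  if (is.null(lv)) lv <- unique(object$age_group)
  tab <- table(factor(object$age_group, levels = rev(lv)))
  cat("Age-group sizes (oldest first):\n")
  print(tab)
  invisible(tab)
}

#' @export
print.age_assignment <- function(x, ...) {
  cat(sprintf("Age assignment for %d genes\n", nrow(x)))
  print.data.frame(utils::head(x, 10L))
  if (nrow(x) > 10L) cat(sprintf("... and %d more rows\n", nrow(x) - 10L))
  invisible(x)
}
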