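# Orthogroup tables: per-species gene membership, the raw material for both
# the conservation partition and the age stratification.

#' Construct an orthogroup table
#'
#' @param membership A data frame with columns `orthogroup`, `species`,
#'   `gene` (one row per gene), the long form of an orthology result.
#' @param species Optional character vector fixing the species universe and
#'   column order; defaults to the species present in `membership`. Species
#'   listed here but absent from every orthogroup are legal (they simply
#'   contribute zero counts).
#'
#' @return An object of class `orthogroup_table`: list with `species`
#'   (character) and `membership` (the validated long data frame).
#' @details Gene identifiers are opaque, case-sensitive strings and must be
#'   globally unique: the same identifier in two orthogroups (or twice in
#'   one) is a validation error. Every orthogroup must have at least one
#'   member.
#' @seealso [read_orthogroups()]
#' @export
orthogroup_table <- function(membership, species = NULL) {
  need <- c("orthogroup", "species", "gene")
  if (!is.data.frame(membership) || !all(need %in% names(membership))) {
    stop_agestrat("membership must be a data frame with columns %s",
                  paste(need, collapse = ", "))
  }
  membership <- data.frame(
    orthogroup = as.character(membership$orthogroup),
    species = as.character(membership$species),
    gene = as.character(membership$gene),
    stringsAsFactors = FALSE
  )
  if (any(!nzchar(membership$gene))) stop_agestrat("empty gene identifier")
  dup <- unique(membership$gene[duplicated(membership$gene)])
  if (length(dup)) {
    stop_agestrat("gene assigned to more than one orthogroup (or listed twice): %s",
                  paste(utils::head(dup, 5L), collapse = ", "))
  }
  if (is.null(species)) species <- sort(unique(membership$species))
  species <- as.character(species)
  unknown <- setdiff(membership$species, species)
  if (length(unknown)) {
    stop_agestrat("membership names species outside the declared set: %s",
                  paste(unknown, collapse = ", "))
  }
  structure(list(species = species, membership = membership),
            class = "orthogroup_table")
}

#' Read an orthogroup table
#'
#' Two dialects are supported. `orthofinder_tsv` is the standard
#' `Orthogroups.tsv` layout: first column the orthogroup id, one column per
#' species, cells holding `", "`-separated gene identifiers, empty cell
#' meaning no members in that species. `generic_tsv` is the long layout with
#' header columns `orthogroup`, `species`, `gene`.
#'
#' @param path Path to the TSV file.
#' @param dialect `"orthofinder_tsv"` (default) or `"generic_tsv"`.
#' @return An [orthogroup_table()].
#' @export
read_orthogroups <- function(path, dialect = c("orthofinder_tsv", "generic_tsv")) {
  check_file(path)
  if (!is.character(dialect)) stop_agestrat("unknown orthogroup dialect")
  dialect <- dialect[1L]
  if (!dialect %in% c("orthofinder_tsv", "generic_tsv")) {
    stop_agestrat("unknown orthogroup dialect: %s", dialect)
  }
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           quote = "", comment.char = "")
  if (dialect == "generic_tsv") {
    need <- c("orthogroup", "species", "gene")
    if (!all(need %in% names(tab))) {
      stop_agestrat("generic_tsv requires columns %s: %s",
                    paste(need, collapse = ", "), path)
    }
    return(orthogroup_table(tab[need]))
  }
  if (ncol(tab) < 2L) {
    stop_agestrat("orthofinder_tsv requires an id column plus species columns: %s",
                  path)
  }
  species <- names(tab)[-1L]
  og <- tab[[1L]]
  if (anyDuplicated(og)) stop_agestrat("duplicated orthogroup ids in %s", path)
  pieces <- lapply(species, function(sp) {
    genes <- strsplit(tab[[sp]], ",[ ]?")
    genes <- lapply(genes, function(g) g[nzchar(g)])
    data.frame(orthogroup = rep(og, lengths(genes)),
               species = sp,
               gene = unlist(genes, use.names = FALSE),
               stringsAsFactors = FALSE)
  })
  membership <- do.call(rbind, pieces)
  empty <- setdiff(og, membership$orthogroup)
  if (length(empty)) {
    stop_agestrat("orthogroup with no members: %s", paste(empty, collapse = ", "))
  }
  orthogroup_table(membership, species = species)
}

#' @export
print.orthogroup_table <- function(x, ...) {
  cat(sprintf("Orthogroup table: %d orthogroups, %d genes, %d species (%s)\n",
              length(unique(x$membership$orthogroup)), nrow(x$membership),
              length(x$species), paste(x$species, collapse = ", ")))
  invisible(x)
}

#' Copy-number matrix of an orthogroup table
#'
#' @param ortho An [orthogroup_table()].
#' @return Integer matrix, orthogroups x species, counting members.
#' @export
copy_number_matrix <- function(ortho) {
  stopifnot(inherits(ortho, "orthogroup_table"))
  ms <- ortho$membership
  og <- sort(unique(ms$orthogroup))
  m <- table(factor(ms$orthogroup, levels = og),
             factor(ms$species, levels = ortho$species))
  m <- matrix(as.integer(m), nrow = length(og),
              dimnames = list(og, ortho$species))
  m
}

#' Write an orthogroup table in OrthoFinder layout
#'
#' @param ortho An [orthogroup_table()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_orthogroups <- function(ortho, path) {
  stopifnot(inherits(ortho, "orthogroup_table"))
  ms <- ortho$membership
  og <- sort(unique(ms$orthogroup))
  out <- data.frame(Orthogroup = og, stringsAsFactors = FALSE,
                    check.names = FALSE)
  for (sp in ortho$species) {
    sub <- ms[ms$species == sp, ]
    cells <- vapply(split(sub$gene, factor(sub$orthogroup, levels = og)),
                    paste, character(1), collapse = ", ")
    out[[sp]] <- unname(cells)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Focal genes present in the table, in first-appearance order.
focal_genes <- function(ortho, focal) {
  if (!focal %in% ortho$species) {
    stop_agestrat("focal species '%s' is not a column of the orthogroup table",
                  focal)
  }
  ortho$membership$gene[ortho$membership$species == focal]
}
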