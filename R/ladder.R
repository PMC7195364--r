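# Species ladder: the ordered taxon rungs against which gene ages are read.

#' Construct a species ladder
#'
#' A species ladder orders the taxa used for orthology queries into rungs of
#' increasing evolutionary distance from a focal species. Rung 1 holds the
#' focal species alone; each deeper rung holds the species that diverged from
#' the focal lineage at that point. A gene's age group is the label of the
#' deepest rung reached by its orthologs (single-copy genes) or by orthologs
#' at matching copy number (duplicates), so a 5-rung ladder yields the age
#' groups V (species-specific, youngest) through I (oldest).
#'
#' @param focal Identifier of the focal species.
#' @param rungs A list of character vectors of species identifiers, ordered
#'   youngest to oldest. The first element must be `c(focal)` (it is added
#'   for you when you start the list at the second rung and pass
#'   `include_focal_rung = TRUE`, the default).
#' @param divergence_myr Optional numeric vector, one value per rung, giving
#'   the divergence time of each rung from the focal lineage in million
#'   years. Must be non-decreasing with depth. The focal rung is
#'   conventionally 0.
#' @param labels Optional character labels, one per rung; defaults to Roman
#'   numerals with I as the oldest rung.
#' @param include_focal_rung If `TRUE`, `rungs` describes only the non-focal
#'   rungs and rung 1 = the focal species is prepended.
#'
#' @return An object of class `species_ladder`: a list with elements
#'   `focal`, and a data frame `rungs` with columns `rung_index`, `label`,
#'   `species` (list column), `divergence_myr`.
#' @seealso [read_ladder()], [stratify_genome()]
#' @export
#' @examples
#' species_ladder("Scer", rungs = list(c("Spar", "Seub"), c("Klac", "Kmar")),
#'                divergence_myr = c(0, 20, 100))
species_ladder <- function(focal, rungs, divergence_myr = NULL, labels = NULL,
                           include_focal_rung = TRUE) {
  if (!is.character(focal) || length(focal) != 1L || !nzchar(focal)) {
    stop_agestrat("focal species must be a single non-empty identifier")
  }
  if (!is.list(rungs)) rungs <- as.list(rungs)
  if (include_focal_rung) rungs <- c(list(focal), rungs)
  n <- length(rungs)
  if (n < 1L) stop_agestrat("a ladder needs at least one rung")
  rungs <- lapply(rungs, as.character)
  if (!identical(rungs[[1L]], focal)) {
    stop_agestrat("rung 1 must contain exactly the focal species '%s'", focal)
  }
  all_sp <- unlist(rungs, use.names = FALSE)
  dup <- unique(all_sp[duplicated(all_sp)])
  if (length(dup)) {
    stop_agestrat("species assigned to more than one rung: %s",
                  paste(dup, collapse = ", "))
  }
  if (is.null(labels)) labels <- default_rung_labels(n)
  labels <- as.character(labels)
  if (length(labels) != n || anyDuplicated(labels)) {
    stop_agestrat("rung labels must be unique and one per rung")
  }
  if (!is.null(divergence_myr)) {
    divergence_myr <- as.numeric(divergence_myr)
    if (length(divergence_myr) != n) {
      stop_agestrat("divergence_myr must have one value per rung")
    }
    dd <- divergence_myr[!is.na(divergence_myr)]
    if (any(dd < 0)) stop_agestrat("divergence_myr must be non-negative")
    if (is.unsorted(dd)) {
      stop_agestrat("divergence_myr must be non-decreasing with rung depth")
    }
  } else {
    divergence_myr <- rep(NA_real_, n)
  }
  out <- list(
    focal = focal,
    rungs = data.frame(
      rung_index = seq_len(n),
      label = labels,
      divergence_myr = divergence_myr,
      stringsAsFactors = FALSE
    )
  )
  out$rungs$species <- rungs
  structure(out, class = "species_ladder")
}

#' Read a species ladder from a YAML config file
#'
#' The config lists the focal species and the rungs youngest to oldest:
#' ```yaml
#' focal: Scer
#' rungs:
#'   - {label: V, species: [Scer], divergence_myr: 0}
#'   - {label: IV, species: [Spar, Seub], divergence_myr: 20}
#'   - {label: I, species: [Anid], divergence_myr: 400}
#' ```
#' `label` and `divergence_myr` are optional per rung. The first rung must
#' contain exactly the focal species; omitting it entirely is also accepted,
#' in which case it is prepended.
#'
#' @param path Path to the YAML file.
#' @return A [species_ladder()].
#' @export
read_ladder <- function(path) {
  check_file(path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$focal) || is.null(cfg$rungs)) {
    stop_agestrat("ladder config must have 'focal' and 'rungs' keys: %s", path)
  }
  focal <- as.character(cfg$focal)
  rungs <- lapply(cfg$rungs, function(r) as.character(r$species))
  labels <- vapply(cfg$rungs, function(r)
    if (is.null(r$label)) NA_character_ else as.character(r$label),
    character(1))
  div <- vapply(cfg$rungs, function(r)
    if (is.null(r$divergence_myr)) NA_real_ else as.numeric(r$divergence_myr),
    numeric(1))
  has_focal_rung <- identical(rungs[[1L]], focal)
  if (has_focal_rung) {
    first <- list(rungs = rungs, labels = labels, div = div)
  } else {
    first <- list(rungs = c(list(focal), rungs),
                  labels = c(NA_character_, labels),
                  div = c(if (all(is.na(div))) NA_real_ else 0, div))
  }
  labels <- first$labels
  if (all(is.na(labels))) labels <- NULL
  else if (anyNA(labels)) stop_agestrat("either label every rung or none: %s", path)
  div <- first$div
  if (all(is.na(div))) div <- NULL
  species_ladder(focal, first$rungs, divergence_myr = div, labels = labels,
                 include_focal_rung = FALSE)
}

#' @export
print.species_ladder <- function(x, ...) {
  cat(sprintf("Species ladder: focal '%s', %d rungs (youngest to oldest)\n",
              x$focal, nrow(x$rungs)))
  for (i in seq_len(nrow(x$rungs))) {
    div <- x$rungs$divergence_myr[i]
    cat(sprintf("  %2d [%s]%s: %s\n", i, x$rungs$label[i],
                if (is.na(div)) "" else sprintf(" %g Myr", div),
                paste(x$rungs$species[[i]], collapse = ", ")))
  }
  invisible(x)
}

#' Number of rungs in a ladder
#' @param ladder A [species_ladder()].
#' @return Integer count of rungs.
#' @export
n_rungs <- function(ladder) {
  stopifnot(inherits(ladder, "species_ladder"))
  nrow(ladder$rungs)
}

# Named integer vector: species -> rung index.
rung_of_species <- function(ladder) {
  sp <- ladder$rungs$species
  idx <- rep(ladder$rungs$rung_index, lengths(sp))
  stats::setNames(idx, unlist(sp, use.names = FALSE))
}

# Rung index -> display label, with "WGD" passed through.
rung_label <- function(ladder, rung) {
  ladder$rungs$label[match(rung, ladder$rungs$rung_index)]
}
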