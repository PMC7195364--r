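# Gene birth-duplication-loss simulator along a species ladder, with
# stress-expression tables carrying a planted age-dependent DE probability.
# Provides exact ground truth for validating the sorting method and the
# enrichment statistics.

#' Default simulation ladder
#'
#' Five rungs, two species per non-focal rung, with divergence times on the
#' scale typical of a well-sampled fungal ladder: congeners at 20 Myr, a
#' family at 100 Myr, an old subphylum ancestor at 325 Myr and filamentous
#' outgroups at 400 Myr.
#'
#' @param n_rungs Number of rungs including the focal rung, default 5.
#' @param species_per_rung Species per non-focal rung, default 2.
#' @return A [species_ladder()].
#' @export
default_ladder <- function(n_rungs = 5, species_per_rung = 2) {
  if (n_rungs < 2L) stop_agestrat("a simulation ladder needs >= 2 rungs")
  rungs <- lapply(2:n_rungs, function(r)
    sprintf("rung%d_sp%s", r, letters[seq_len(species_per_rung)]))
  div_full <- c(0, 20, 100, 325, 400)
  div <- if (n_rungs <= 5L) div_full[seq_len(n_rungs)]
         else c(div_full, seq(500, by = 100, length.out = n_rungs - 5L))
  species_ladder("focal", rungs, divergence_myr = div)
}

#' Simulation configuration
#'
#' Defines the conditions of a simulated study: how many genes, where on
#' the ladder they originate, how often and when they duplicate, how much
#' stochastic gene loss blurs the record, and how strongly the probability
#' of stress differential expression depends on gene age.
#'
#' Defaults emulate a conserved-gene-rich yeast genome: origin
#' probabilities (youngest rung to oldest) `0.02, 0.03, 0.15, 0.25, 0.55`,
#' so about 5% of genes are young (restricted to the genus or species);
#' 30% of genes carry one duplication; DE probability rises from 0.02 in
#' the oldest group to 0.30 in the youngest, the planted signal that young
#' genes respond to stress more often.
#'
#' @param ladder A [species_ladder()]; default [default_ladder()].
#' @param n_genes Number of focal genes, default 2000.
#' @param origin_probs Per-rung origin probabilities (youngest to oldest),
#'   summing to 1.
#' @param dup_prob Probability a gene carries one duplication, default 0.3.
#' @param loss_rate Per-species, per-gene probability that a non-focal
#'   species has lost the gene, default 0.
#' @param de_prob_by_group Per-rung DE probability (youngest to oldest).
#' @param lfc_magnitude Baseline absolute log2FC of DE genes; must exceed
#'   the DE cutoff of 1 so flagged genes recover the planted truth exactly.
#' @param n_conditions Number of stress conditions, default 3.
#' @param seed Integer seed driving every random draw.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(ladder = default_ladder(), n_genes = 2000,
                              origin_probs = NULL, dup_prob = 0.3,
                              loss_rate = 0, de_prob_by_group = NULL,
                              lfc_magnitude = 2, n_conditions = 3,
                              seed = 1) {
  stopifnot(inherits(ladder, "species_ladder"))
  nr <- n_rungs(ladder)
  if (is.null(origin_probs)) {
    origin_probs <- if (nr == 5L) c(0.02, 0.03, 0.15, 0.25, 0.55)
                    else rep(1 / nr, nr)
  }
  if (is.null(de_prob_by_group)) {
    de_prob_by_group <- if (nr == 5L) c(0.30, 0.20, 0.10, 0.05, 0.02)
                        else rep(0.1, nr)
  }
  if (!is_count(n_genes)) stop_agestrat("n_genes must be a non-negative integer")
  if (length(origin_probs) != nr || any(origin_probs < 0) ||
      abs(sum(origin_probs) - 1) > 1e-9) {
    stop_agestrat("origin_probs must be one probability per rung summing to 1")
  }
  if (dup_prob < 0 || dup_prob > 1) stop_agestrat("dup_prob must be in [0, 1]")
  if (loss_rate < 0 || loss_rate > 1) stop_agestrat("loss_rate must be in [0, 1]")
  if (length(de_prob_by_group) != nr ||
      any(de_prob_by_group < 0 | de_prob_by_group > 1)) {
    stop_agestrat("de_prob_by_group must be one probability in [0,1] per rung")
  }
  if (lfc_magnitude < 1) {
    stop_agestrat("lfc_magnitude must be >= 1 so DE genes pass |log2FC| > 1")
  }
  if (!is_count(n_conditions) || n_conditions < 1) {
    stop_agestrat("n_conditions must be a positive integer")
  }
  structure(list(ladder = ladder, n_genes = as.integer(n_genes),
                 origin_probs = origin_probs, dup_prob = dup_prob,
                 loss_rate = loss_rate, de_prob_by_group = de_prob_by_group,
                 lfc_magnitude = lfc_magnitude,
                 n_conditions = as.integer(n_conditions),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate gene histories along the ladder
#'
#' Each gene originates at a rung sampled from `origin_probs` and, absent
#' loss, is present as a single copy in every species of every rung from
#' its origin down to the focal species. With probability `dup_prob` the
#' gene carries one duplication at a rung drawn uniformly between its
#' origin and the focal rung; species of rungs at or below the duplication
#' rung then carry two copies. Each non-focal species independently loses
#' the gene with probability `loss_rate` (the focal species never does, so
#' every simulated gene stays measurable). Draws are made in gene-index
#' order, then species in rung order, so output is deterministic given the
#' seed.
#'
#' @param cfg A [simulation_config()].
#' @return A list with `ortho` (an [orthogroup_table()]) and `truth`, a
#'   data frame with one row per focal gene copy: `gene`, `orthogroup_id`,
#'   `origin_rung`, `dup_rung` (`NA` when not duplicated), `age_rung` (the
#'   rung the sorting method should recover: duplication rung for
#'   duplicates, origin rung otherwise).
#' @export
simulate_gene_histories <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  ladder <- cfg$ladder
  nr <- n_rungs(ladder)
  n <- cfg$n_genes
  focal <- ladder$focal
  with_seed(cfg$seed, {
    o <- sample.int(nr, n, replace = TRUE, prob = cfg$origin_probs)
    isdup <- stats::runif(n) < cfg$dup_prob
    d <- ifelse(isdup, floor(stats::runif(n) * o) + 1L, NA_integer_)

    base <- sprintf("g%05d", seq_len(n))
    og <- sprintf("OG%05d", seq_len(n))

    parts <- list(
      data.frame(orthogroup = og, species = rep(focal, n), gene = base,
                 stringsAsFactors = FALSE)
    )
    dup_sel <- which(isdup)
    if (length(dup_sel)) {
      parts[[length(parts) + 1L]] <- data.frame(
        orthogroup = og[dup_sel], species = rep(focal, length(dup_sel)),
        gene = paste0(base[dup_sel], "_d"), stringsAsFactors = FALSE)
    }
    for (r in if (nr >= 2L) 2:nr else integer(0)) {
      for (sp in ladder$rungs$species[[r]]) {
        lost <- stats::runif(n) < cfg$loss_rate
        present <- o >= r & !lost
        two <- present & isdup & !is.na(d) & d >= r
        i1 <- which(present)
        if (length(i1)) {
          parts[[length(parts) + 1L]] <- data.frame(
            orthogroup = og[i1], species = sp,
            gene = paste(sp, base[i1], sep = "|"), stringsAsFactors = FALSE)
        }
        i2 <- which(two)
        if (length(i2)) {
          parts[[length(parts) + 1L]] <- data.frame(
            orthogroup = og[i2], species = sp,
            gene = paste(sp, paste0(base[i2], "_d"), sep = "|"),
            stringsAsFactors = FALSE)
        }
      }
    }
    membership <- do.call(rbind, parts)
    species <- c(focal,
                 unlist(ladder$rungs$species[-1L], use.names = FALSE))
    ortho <- orthogroup_table(membership, species = species)

    age <- as.integer(ifelse(isdup, d, o))
    dup_names <- if (length(dup_sel)) paste0(base[dup_sel], "_d")
                 else character(0)
    truth <- data.frame(
      gene = c(base, dup_names),
      orthogroup_id = c(og, og[dup_sel]),
      origin_rung = c(o, o[dup_sel]),
      dup_rung = as.integer(c(d, d[dup_sel])),
      age_rung = c(age, age[dup_sel]),
      stringsAsFactors = FALSE
    )
    list(ortho = ortho, truth = truth)
  })
}

#' Simulate stress differential-expression tables with planted age effects
#'
#' Each gene is differentially expressed in each condition with probability
#' `de_prob_by_group[age_rung]`. DE genes draw `|log2FC| =
#' lfc_magnitude + |N(0, 0.5)|` with random sign and an FDR uniform below
#' 0.01; non-DE genes fail one or both cutoffs (half get `|log2FC| < 1`,
#' half a non-significant FDR), so [flag_de()] at the default cutoffs
#' recovers the planted truth exactly.
#'
#' @param cfg A [simulation_config()].
#' @param truth The `truth` data frame from [simulate_gene_histories()].
#' @return A list with `tables` (a named list of [expression_table()]s, one
#'   per condition) and `true_de` (logical gene x condition matrix).
#' @export
simulate_expression <- function(cfg, truth) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (is.null(truth$gene) || is.null(truth$age_rung)) {
    stop_agestrat("truth must come from simulate_gene_histories()")
  }
  m <- nrow(truth)
  p <- cfg$de_prob_by_group[truth$age_rung]
  conds <- sprintf("cond%d", seq_len(cfg$n_conditions))
  with_seed(cfg$seed + 1L, {
    true_de <- matrix(FALSE, m, cfg$n_conditions,
                      dimnames = list(truth$gene, conds))
    tables <- stats::setNames(vector("list", cfg$n_conditions), conds)
    for (k in seq_len(cfg$n_conditions)) {
      de <- stats::runif(m) < p
      sign <- ifelse(stats::runif(m) < 0.5, -1, 1)
      lfc <- numeric(m)
      fdr <- numeric(m)
      lfc[de] <- sign[de] * (cfg$lfc_magnitude + abs(stats::rnorm(sum(de), 0, 0.5)))
      fdr[de] <- stats::runif(sum(de), 0, 0.0099)
      nd <- which(!de)
      small_lfc <- stats::runif(length(nd)) < 0.5
      lfc[nd[small_lfc]] <- sign[nd[small_lfc]] *
        stats::runif(sum(small_lfc), 0, 0.999)
      fdr[nd[small_lfc]] <- stats::runif(sum(small_lfc), 0, 1)
      lfc[nd[!small_lfc]] <- sign[nd[!small_lfc]] *
        stats::runif(sum(!small_lfc), 0, 4)
      fdr[nd[!small_lfc]] <- stats::runif(sum(!small_lfc), 0.0101, 1)
      true_de[, k] <- de
      tables[[k]] <- expression_table(truth$gene, lfc, fdr, condition = conds[k])
    }
    list(tables = tables, true_de = true_de)
  })
}

#' Simulate a complete dataset
#'
#' Convenience wrapper: gene histories plus expression tables.
#'
#' @param cfg A [simulation_config()].
#' @return A list with `ortho`, `truth`, `tables`, `true_de`.
#' @export
simulate_dataset <- function(cfg) {
  hist <- simulate_gene_histories(cfg)
  expr <- simulate_expression(cfg, hist$truth)
  c(hist, expr)
}
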