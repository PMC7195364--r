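# Fixtures built in code: a hand-enumerated 12-gene genome, small ladders,
# and independent brute-force oracles for the operations under test.

# Three-rung ladder: focal F; congener B at rung 2; distant relative C at
# rung 3. Labels III (youngest) .. I (oldest).
fixture_ladder3 <- function() {
  species_ladder("F", rungs = list("B", "C"), divergence_myr = c(0, 20, 100))
}

# Hand-built 12-gene fixture. Expected partition 4/4/4 and per-gene age
# labels enumerated by hand:
#   s1..s4  single-core, orthologs in B and C          -> age I
#   m1a/m1b multi-core, no species matches 2 copies    -> age III
#   m2a/m2b multi-core, B matches 2 copies             -> age II
#   n1      focal-only orthogroup                      -> non-core, age III
#   n2      ortholog in B only (absent from C)         -> non-core, age II
#   n3      ortholog in C only (absent from B)         -> non-core, age I
#   n4      in no orthogroup                           -> non-core, age III
fixture_12gene <- function() {
  rows <- rbind(
    c("OGs1", "F", "s1"), c("OGs1", "B", "b_s1"), c("OGs1", "C", "c_s1"),
    c("OGs2", "F", "s2"), c("OGs2", "B", "b_s2"), c("OGs2", "C", "c_s2"),
    c("OGs3", "F", "s3"), c("OGs3", "B", "b_s3"), c("OGs3", "C", "c_s3"),
    c("OGs4", "F", "s4"), c("OGs4", "B", "b_s4"), c("OGs4", "C", "c_s4"),
    c("OGm1", "F", "m1a"), c("OGm1", "F", "m1b"),
    c("OGm1", "B", "b_m1"), c("OGm1", "C", "c_m1"),
    c("OGm2", "F", "m2a"), c("OGm2", "F", "m2b"),
    c("OGm2", "B", "b_m2a"), c("OGm2", "B", "b_m2b"), c("OGm2", "C", "c_m2"),
    c("OGn1", "F", "n1"),
    c("OGn2", "F", "n2"), c("OGn2", "B", "b_n2"),
    c("OGn3", "F", "n3"), c("OGn3", "C", "c_n3")
  )
  ms <- data.frame(orthogroup = rows[, 1], species = rows[, 2],
                   gene = rows[, 3], stringsAsFactors = FALSE)
  ortho <- orthogroup_table(ms, species = c("F", "B", "C"))
  genes <- c("s1", "s2", "s3", "s4", "m1a", "m1b", "m2a", "m2b",
             "n1", "n2", "n3", "n4")
  expected <- data.frame(
    gene = genes,
    conservation_class = c(rep("single_core", 4), rep("multi_core", 4),
                           rep("non_core", 4)),
    age_group = c(rep("I", 4), "III", "III", "II", "II",
                  "III", "II", "I", "III"),
    stringsAsFactors = FALSE
  )
  list(ortho = ortho, ladder = fixture_ladder3(), genes = genes,
       expected = expected)
}

# Independent oracle for the age assignment: enumerates rungs directly from
# the raw membership table, one gene at a time.
brute_force_age <- function(ortho, ladder, gene) {
  ms <- ortho$membership
  og <- unique(ms$orthogroup[ms$gene == gene])
  if (!length(og)) return(1L)
  sub <- ms[ms$orthogroup == og, ]
  n_focal <- sum(sub$species == ladder$focal)
  best <- 1L
  for (r in seq_len(nrow(ladder$rungs))[-1]) {
    counts <- vapply(ladder$rungs$species[[r]],
                     function(s) sum(sub$species == s), integer(1))
    hit <- if (n_focal == 1L) any(counts >= 1L) else any(counts == n_focal)
    if (hit) best <- r
  }
  best
}

# Independent oracle for the two-sided Fisher exact test: exhaustive
# hypergeometric enumeration from binomial coefficients, summing every
# table at the observed margins whose probability does not exceed the
# observed one (relative tie tolerance 1e-7).
fisher_enumeration <- function(a, b, c, d) {
  m <- a + b
  n2 <- c + d
  k <- a + c
  if (k == 0 || k == m + n2 || m == 0 || n2 == 0) return(1)
  xs <- max(0, k - n2):min(k, m)
  probs <- choose(m, xs) * choose(n2, k - xs) / choose(m + n2, k)
  p_obs <- probs[match(a, xs)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# Random small orthogroup tables for property tests.
random_ortho_fixture <- function(n_groups, ladder, seed) {
  set.seed(seed)
  nr <- nrow(ladder$rungs)
  rows <- list()
  for (g in seq_len(n_groups)) {
    og <- sprintf("OG%03d", g)
    nf <- sample(1:3, 1)
    rows[[length(rows) + 1L]] <- data.frame(
      orthogroup = og, species = ladder$focal,
      gene = sprintf("%s_f%d", og, seq_len(nf)), stringsAsFactors = FALSE)
    for (r in 2:nr) {
      for (sp in ladder$rungs$species[[r]]) {
        k <- sample(0:3, 1)
        if (k > 0) {
          rows[[length(rows) + 1L]] <- data.frame(
            orthogroup = og, species = sp,
            gene = sprintf("%s_%s_%d", og, sp, seq_len(k)),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  orthogroup_table(do.call(rbind, rows),
                   species = c(ladder$focal,
                               unlist(ladder$rungs$species[-1L])))
}

# Age-recovery accuracy of the stratification against simulator truth.
recovery_accuracy <- function(sim, ladder, ...) {
  ages <- stratify_genome(sim$ortho, ladder, ...)
  got <- ages$deepest_rung[match(sim$truth$gene, ages$gene)]
  mean(got == sim$truth$age_rung)
}
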