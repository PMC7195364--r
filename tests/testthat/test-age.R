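# Age stratification: single-copy origin dating, duplication dating by
# shared copy number, WGD handling, and the partition/oracle properties.

test_that("focal copy number counts members and defaults to 1 for singletons", {
  fx <- fixture_12gene()
  expect_equal(focal_copy_number(fx$ortho, "F", "s1"), 1L)
  expect_equal(focal_copy_number(fx$ortho, "F", "m1a"), 2L)
  expect_equal(focal_copy_number(fx$ortho, "F", "not_in_any_group"), 1L)
})

test_that("single-copy genes date to the most distant rung with an ortholog", {
  fx <- fixture_12gene()
  # orthologs out to the oldest rung -> oldest rung
  expect_equal(assign_single_copy_age(fx$ortho, fx$ladder, "s1"), 3L)
  # no ortholog outside the focal species -> rung 1 (species-specific)
  expect_equal(assign_single_copy_age(fx$ortho, fx$ladder, "n1"), 1L)
  # ortholog only in the congener rung -> that rung, agreeing with the
  # exhaustive rung-scan oracle
  expect_equal(assign_single_copy_age(fx$ortho, fx$ladder, "n2"), 2L)
  expect_equal(brute_force_age(fx$ortho, fx$ladder, "n2"), 2L)
  expect_error(assign_single_copy_age(fx$ortho, fx$ladder, "m1a"),
               class = "agestrat_error")
})

test_that("duplications date to the deepest rung sharing the focal copy number", {
  fx <- fixture_12gene()
  # congener also has 2 copies, distant species 1 -> congener rung
  expect_equal(assign_multicopy_age(fx$ortho, fx$ladder, "m2a"), 2L)
  # no other species matches 2 copies -> rung 1 (youngest)
  expect_equal(assign_multicopy_age(fx$ortho, fx$ladder, "m1a"), 1L)
  expect_error(assign_multicopy_age(fx$ortho, fx$ladder, "s1"),
               class = "agestrat_error")
})

test_that("non-monotone copy-number profiles separate the two dating rules", {
  # focal has 3 copies; copy counts along the ladder: rung2 3, rung3 1,
  # rung4 3. Oldest-match dates the duplication to rung 4; the contiguous
  # rule stops at the rung-3 break and dates it to rung 2.
  lad <- species_ladder("F", list("B", "C", "D"))
  ms <- data.frame(
    orthogroup = "OG1",
    species = c("F", "F", "F", "B", "B", "B", "C", "D", "D", "D"),
    gene = paste0("g", 1:10),
    stringsAsFactors = FALSE
  )
  ortho <- orthogroup_table(ms, species = c("F", "B", "C", "D"))
  expect_equal(assign_multicopy_age(ortho, lad, "g1", rule = "oldest"), 4L)
  expect_equal(assign_multicopy_age(ortho, lad, "g1",
                                    rule = "youngest_contiguous"), 2L)
})

test_that("the 12-gene fixture gets the hand-enumerated age labels", {
  fx <- fixture_12gene()
  ages <- stratify_genome(fx$ortho, fx$ladder, measured_genes = fx$genes)
  expect_equal(setNames(ages$age_group, ages$gene),
               setNames(fx$expected$age_group, fx$expected$gene))
  expect_equal(ages$basis[ages$gene == "s1"], "origin_single_copy")
  expect_equal(ages$basis[ages$gene == "m2a"], "duplication_timing")
})

test_that("stratification is an exactly-one-group partition of measured genes", {
  lad <- default_ladder()
  ortho <- random_ortho_fixture(30, lad, seed = 21)
  measured <- ortho$membership$gene[ortho$membership$species == "focal"]
  ages <- stratify_genome(ortho, lad, measured_genes = measured)
  expect_equal(sort(ages$gene), sort(measured))
  expect_false(anyDuplicated(ages$gene) > 0)
  expect_true(all(table(ages$age_group) >= 0))
  expect_equal(sum(table(ages$age_group)), length(measured))
})

test_that("WGD labels appear only when an ohnolog list is supplied", {
  fx <- fixture_12gene()
  no_wgd <- stratify_genome(fx$ortho, fx$ladder, measured_genes = fx$genes)
  expect_false(any(no_wgd$age_group == "WGD"))
  wgd <- data.frame(gene_a = "m1a", gene_b = "m1b")
  with_wgd <- stratify_genome(fx$ortho, fx$ladder, wgd = wgd,
                              measured_genes = fx$genes)
  expect_equal(sort(with_wgd$gene[with_wgd$age_group == "WGD"]),
               c("m1a", "m1b"))
  expect_true(all(with_wgd$basis[with_wgd$age_group == "WGD"] == "wgd"))
  # the rest of the genome is dated as before
  keep <- with_wgd$age_group != "WGD"
  expect_equal(with_wgd$age_group[keep],
               no_wgd$age_group[match(with_wgd$gene[keep], no_wgd$gene)])
  expect_error(stratify_genome(fx$ortho, fx$ladder,
                               wgd = data.frame(gene_a = "ghost",
                                                gene_b = "m1b"),
                               measured_genes = fx$genes),
               class = "agestrat_error")
})

test_that("adding an ortholog in a deeper rung can only age a single-copy gene", {
  lad <- fixture_ladder3()
  base <- data.frame(
    orthogroup = c("OG1", "OG1"), species = c("F", "B"),
    gene = c("g1", "b1"), stringsAsFactors = FALSE)
  o1 <- orthogroup_table(base, species = c("F", "B", "C"))
  grown <- rbind(base, data.frame(orthogroup = "OG1", species = "C",
                                  gene = "c1"))
  o2 <- orthogroup_table(grown, species = c("F", "B", "C"))
  a1 <- assign_single_copy_age(o1, lad, "g1")
  a2 <- assign_single_copy_age(o2, lad, "g1")
  expect_gte(a2, a1)
})

test_that("assignments match the brute-force rung enumeration on random tables", {
  lad <- default_ladder()
  for (seed in c(2, 8, 31)) {
    ortho <- random_ortho_fixture(20, lad, seed = seed)
    ages <- stratify_genome(ortho, lad)
    for (g in ages$gene) {
      expect_equal(ages$deepest_rung[ages$gene == g],
                   brute_force_age(ortho, lad, g),
                   info = sprintf("seed %d gene %s", seed, g))
    }
  }
})

test_that("lossless simulated histories are recovered perfectly", {
  lad <- default_ladder()
  cfg <- simulation_config(n_genes = 400, loss_rate = 0, seed = 13)
  sim <- simulate_gene_histories(cfg)
  expect_equal(recovery_accuracy(sim, lad), 1)
})
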