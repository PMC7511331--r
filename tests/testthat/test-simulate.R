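test_that("config validation rejects bad fields by name", {
  expect_error(sim_config(n_circulating_clones = 0), "n_circulating_clones")
  expect_error(sim_config(tcf_dermis = 1.2), "tcf_dermis")
  expect_error(sim_config(shared_clone_rate = -0.1), "shared_clone_rate")
  expect_error(sim_config(seeding_mode = "infiltration",
                          n_seeded_dermis = 4, n_seeded_epidermis = 10),
               "n_seeded_epidermis")
  expect_error(sim_config(n_circulating_clones = 5, n_seeded_epidermis = 9),
               "n_circulating_clones")
})

test_that("circulating pool is deterministic, unique and in frame", {
  cfg <- small_config(n_circulating_clones = 1L, n_seeded_dermis = 1L,
                      n_seeded_epidermis = 1L, rng_seed = 7L)
  expect_identical(simulate_circulating_pool(cfg),
                   simulate_circulating_pool(cfg))
  big <- sim_config(n_circulating_clones = 10000L, rng_seed = 11L)
  pool <- simulate_circulating_pool(big)
  expect_equal(nrow(pool), 10000L)
  expect_false(anyDuplicated(pool$barcode) > 0)
  len <- nchar(pool$barcode)
  expect_true(all(len >= 24 & len <= 60))
  expect_true(all(len %% 3 == 0))
  expect_true(all(pool$v_gene %in% skinclones:::TRBV_CATALOG))
  expect_true(all(pool$j_gene %in% skinclones:::TRBJ_CATALOG))
})

test_that("infiltration seeding nests the epidermal set in the dermal set", {
  cfg <- small_config(seeding_mode = "infiltration", n_seeded_dermis = 10L,
                      n_seeded_epidermis = 4L)
  pool <- simulate_circulating_pool(cfg)
  sets <- simulate_seeding(pool, cfg)
  expect_length(sets$epidermis, 4L)
  expect_true(all(sets$epidermis %in% sets$dermis))
  expect_setequal(sets$blood, pool$barcode)
})

test_that("independent seeding with zero sharing gives disjoint sets", {
  for (s in 1:5) {
    cfg <- small_config(shared_clone_rate = 0, rng_seed = s)
    sets <- simulate_seeding(simulate_circulating_pool(cfg), cfg)
    expect_length(intersect(sets$epidermis, sets$dermis), 0L)
  }
})

test_that("shared-draw construction hits the expected sharing rate", {
  # E[shared] = n_epi * rate = 25 * 0.2 = 5; SE of the mean over 300
  # replicates = sqrt(25 * .2 * .8 / 300) ~ 0.12
  shared <- vapply(1:300, function(s) {
    cfg <- sim_config(n_circulating_clones = 100L, n_seeded_dermis = 40L,
                      n_seeded_epidermis = 25L, shared_clone_rate = 0.2,
                      rng_seed = s)
    sets <- simulate_seeding(simulate_circulating_pool(cfg), cfg)
    length(intersect(sets$epidermis, sets$dermis))
  }, numeric(1))
  expect_lt(abs(mean(shared) - 5), 0.5)
})

test_that("seeding rejects a pool smaller than a compartment", {
  cfg <- small_config()
  pool <- simulate_circulating_pool(cfg)[1:2, ]
  expect_error(simulate_seeding(pool, cfg), "pool")
})

test_that("branched evolution respects the pigeonhole constraint everywhere", {
  for (s in 1:10) {
    cfg <- small_config(rng_seed = s, n_generations = 3L,
                        seeding_mode = if (s %% 2) "independent" else "infiltration",
                        n_seeded_dermis = 5L, n_seeded_epidermis = 3L)
    trees <- simulate_branched_evolution(
      simulate_seeding(simulate_circulating_pool(cfg), cfg), cfg)
    joint <- attr(trees, "joint")
    expect_true(isTRUE(check_pigeonhole(joint)))
    expect_true(oracle_pigeonhole_ok(joint$parent, joint$prevalence))
    expect_true(isTRUE(check_pigeonhole(trees$epidermis)))
    expect_true(isTRUE(check_pigeonhole(trees$dermis)))
  }
})

test_that("mutations obey the infinite-sites assumption", {
  cfg <- small_config(rng_seed = 42L, n_generations = 3L)
  trees <- simulate_branched_evolution(
    simulate_seeding(simulate_circulating_pool(cfg), cfg), cfg)
  ids <- unlist(attr(trees, "joint")$mutations)
  expect_false(anyDuplicated(ids) > 0)
})

test_that("degenerate configurations yield fully clonal trees", {
  cfg <- small_config(n_generations = 0L, rng_seed = 3L)
  trees <- simulate_branched_evolution(
    simulate_seeding(simulate_circulating_pool(cfg), cfg), cfg)
  for (cp in c("epidermis", "dermis")) {
    part <- partition_stem_clade(trees[[cp]])
    expect_equal(part$stem_fraction, 1)
    expect_length(part$clade_ids, 0L)
  }
  # branch rate zero: every mutation is clonal even with deep branching
  cfg2 <- small_config(mutation_rate_branch = 0, mutation_rate_stem = 50,
                       n_generations = 3L, rng_seed = 4L)
  trees2 <- simulate_branched_evolution(
    simulate_seeding(simulate_circulating_pool(cfg2), cfg2), cfg2)
  expect_equal(partition_stem_clade(trees2$dermis)$stem_fraction, 1)
})

test_that("infiltration-mode truth nests epidermal clones for every seed", {
  for (s in 1:20) {
    cfg <- small_config(seeding_mode = "infiltration", n_seeded_dermis = 6L,
                        n_seeded_epidermis = 3L, rng_seed = s)
    truth <- simulate_lesion(cfg)$truth
    expect_true(all(truth$compartment_clones$epidermis %in%
                      truth$compartment_clones$dermis))
  }
})

test_that("rendered VAF approaches the purity closed form at high coverage", {
  # clonal het diploid variant at TCF 0.6: expected VAF = 0.6 / 2 = 0.30
  catalog <- data.frame(
    id = "m1", chrom = "chr1", pos = 1000L, ref = "A", alt = "G",
    gene = "TP53", consequence = "missense", subclone = "s1",
    phi_epidermis = 1, phi_dermis = 1, stringsAsFactors = FALSE
  )
  truth <- structure(list(
    sample_id = "T", circulating_pool = simulate_circulating_pool(small_config()),
    compartment_clones = list(epidermis = "X", dermis = "X", blood = "X"),
    clone_frequencies = list(epidermis = 1, dermis = 1, blood = 1),
    mutation_catalog = catalog,
    cna = data.frame(chrom = character(0), start = integer(0),
                     end = integer(0), major_cn = integer(0),
                     minor_cn = integer(0)),
    tcf = c(epidermis = 0.6, dermis = 0.6, blood = 0.2)
  ), class = "lesion_truth")
  truth$compartment_clones <- lapply(truth$compartment_clones, function(x)
    truth$circulating_pool$barcode[1])
  cfg <- small_config(mean_coverage = 1e6, tcf_epidermis = 0.6,
                      tcf_dermis = 0.6)
  obs <- render_observations(truth, cfg)
  v <- obs$variants[obs$variants$compartment == "epidermis", ]
  vaf <- v$alt_depth / (v$alt_depth + v$ref_depth)
  expect_lt(abs(vaf - 0.30), 0.002)
})

test_that("a pure single-clone sample renders a frequency-1 clonotype", {
  cfg <- small_config(n_circulating_clones = 1L, n_seeded_dermis = 1L,
                      n_seeded_epidermis = 1L, tcf_epidermis = 1,
                      reactive_clone_count = 0L, partial_read_rate = 0,
                      clonotype_reads_per_sample = 100000L)
  lesion <- simulate_lesion(cfg)
  tab <- lesion$observed$clonotypes$epidermis
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$readFraction, 1)
})

test_that("identical config and seed reproduce byte-identical datasets", {
  cfg <- small_config(rng_seed = 99L, partial_read_rate = 0.1)
  l1 <- simulate_lesion(cfg, "REP")
  l2 <- simulate_lesion(cfg, "REP")
  d1 <- file.path(tempfile(), "a")
  d2 <- file.path(tempfile(), "b")
  write_observed_dataset(l1$observed, d1, l1$truth)
  write_observed_dataset(l2$observed, d2, l2$truth)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("observed clonotype frequencies converge to the truth with depth", {
  cfg <- small_config(n_circulating_clones = 8L, n_seeded_epidermis = 8L,
                      n_seeded_dermis = 1L, tcf_epidermis = 1,
                      reactive_clone_count = 0L, partial_read_rate = 0,
                      clonotype_reads_per_sample = 100000L, rng_seed = 5L)
  lesion <- simulate_lesion(cfg)
  truth_freq <- lesion$truth$clone_frequencies$epidermis
  names(truth_freq) <- lesion$truth$compartment_clones$epidermis
  tab <- lesion$observed$clonotypes$epidermis
  obs <- setNames(tab$readFraction, tab$nSeqCDR3)
  expect_lt(max(abs(obs[names(truth_freq)] - truth_freq)), 0.01)
})
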