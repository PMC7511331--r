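mk_subclones <- function(prev_epi, prev_derm = NULL) {
  prev <- if (is.null(prev_derm)) {
    cbind(epidermis = prev_epi, dermis = prev_epi)
  } else {
    cbind(epidermis = prev_epi, dermis = prev_derm)
  }
  rownames(prev) <- paste0("c", seq_len(nrow(prev)))
  list(prevalence = prev,
       mutations = lapply(seq_len(nrow(prev)), function(i) {
         sprintf("m%d_%d", i, seq_len(3))
       }))
}

test_that("strictly nested prevalences force a linear chain", {
  tr <- build_tree(mk_subclones(c(1, 0.6, 0.3)))
  expect_true(attr(tr, "feasible"))
  expect_equal(tr$parent, c(NA, 1L, 2L))
})

test_that("children summing to the parent force a branch", {
  tr <- build_tree(mk_subclones(c(1, 0.5, 0.5)))
  expect_true(attr(tr, "feasible"))
  expect_equal(tr$parent, c(NA, 1L, 1L))
})

test_that("build_tree equals brute-force enumeration on small instances", {
  set.seed(19)
  for (i in 1:60) {
    k <- sample(2:4, 1)
    prev <- random_feasible_instance(k)
    tr <- build_tree(list(prevalence = prev), epsilon = 0.05)
    oracle <- oracle_best_tree(prev, epsilon = 0.05)
    expect_true(attr(tr, "feasible"))
    expect_equal(tr$parent, as.integer(oracle$parent))
    expect_equal(attr(tr, "slack"), oracle$slack, tolerance = 1e-9)
    expect_true(oracle_pigeonhole_ok(tr$parent, tr$prevalence,
                                     tol = 0.05 * ncol(prev) + 1e-9))
  }
})

test_that("emitted feasible trees satisfy the independent pigeonhole check", {
  set.seed(29)
  for (i in 1:20) {
    k <- sample(3:7, 1)
    prev <- random_feasible_instance(k)
    tr <- build_tree(list(prevalence = prev), epsilon = 0.05)
    expect_true(attr(tr, "feasible"))
    # epsilon-feasibility verified by the independently coded checker
    ok <- TRUE
    for (n in seq_len(k)) {
      kids <- which(!is.na(tr$parent) & tr$parent == n)
      if (length(kids) &&
          any(colSums(tr$prevalence[kids, , drop = FALSE]) >
              tr$prevalence[n, ] + 0.05)) ok <- FALSE
    }
    expect_true(ok)
  }
})

test_that("an infeasible instance is flagged and still returns a tree", {
  # two incomparable high-prevalence clusters cannot both descend from the
  # third
  prev <- cbind(epidermis = c(0.5, 0.9, 0.1), dermis = c(0.5, 0.1, 0.9))
  rownames(prev) <- paste0("c", 1:3)
  tr <- build_tree(list(prevalence = prev))
  expect_false(attr(tr, "feasible"))
  expect_equal(n_subclones(tr), 3L)
})

test_that("stem/clade partition fractions always sum to one", {
  chain <- subclone_tree(c(NA, 1L, 2L), cbind(epidermis = c(1, .6, .3)),
                         list(letters[1:5], letters[6:7], letters[8:10]))
  p <- partition_stem_clade(chain)
  expect_equal(p$stem_fraction, 1)
  expect_equal(p$stem_fraction + p$clade_fraction, 1)
  branch <- subclone_tree(c(NA, 1L, 1L), cbind(epidermis = c(1, .5, .4)),
                          list(sprintf("s%d", 1:10), sprintf("a%d", 1:15),
                               sprintf("b%d", 1:15)))
  pb <- partition_stem_clade(branch)
  expect_equal(pb$stem_fraction, 0.25)
  expect_equal(pb$clade_fraction, 0.75)
})

test_that("stem fractions pass through exactly from true assignments", {
  for (s in 1:10) {
    cfg <- small_config(rng_seed = s, n_generations = 2L)
    trees <- simulate_branched_evolution(
      simulate_seeding(simulate_circulating_pool(cfg), cfg), cfg)
    for (cp in c("epidermis", "dermis")) {
      tree <- trees[[cp]]
      part <- partition_stem_clade(tree)
      # independent recomputation: stem nodes are ancestral to every leaf
      k <- n_subclones(tree)
      leaves <- setdiff(seq_len(k), tree$parent[!is.na(tree$parent)])
      anc_of_all <- vapply(seq_len(k), function(n) {
        all(vapply(leaves, function(l) {
          p <- l
          while (!is.na(p)) {
            if (p == n) return(TRUE)
            p <- tree$parent[p]
          }
          FALSE
        }, logical(1)))
      }, logical(1))
      n_stem <- sum(lengths(tree$mutations[anc_of_all]))
      total <- sum(lengths(tree$mutations))
      expect_equal(part$stem_fraction,
                   if (total == 0) 1 else n_stem / total)
    }
  }
})

test_that("compartment separation scores the canonical patterns", {
  # all subclones in both compartments: ancestor present, no separation
  both <- subclone_tree(c(NA, 1L, 1L),
                        cbind(epidermis = c(1, .5, .4),
                              dermis = c(1, .45, .5)))
  s <- compartment_separation(both)
  expect_true(s$common_ancestor_present)
  expect_equal(s$separation_score, 0)
  # fully private clades, shared stem
  split <- subclone_tree(c(NA, 1L, 1L),
                         cbind(epidermis = c(1, .8, 0),
                               dermis = c(1, 0, .9)))
  s2 <- compartment_separation(split)
  expect_true(s2$common_ancestor_present)
  expect_equal(s2$separation_score, 1)
  # no subclone present in both compartments at all: no common ancestor
  apart <- subclone_tree(c(NA, 1L, 1L),
                         cbind(epidermis = c(1, .8, 0),
                               dermis = c(0.02, 0, .9)))
  expect_false(compartment_separation(apart)$common_ancestor_present)
})

test_that("newick export round-trips through ape", {
  skip_if_not_installed("ape")
  tr <- subclone_tree(c(NA, 1L, 1L, 2L),
                      cbind(epidermis = c(1, .6, .3, .2),
                            dermis = c(1, .5, .4, .1)))
  nwk <- tree_to_newick(tr)
  parsed <- ape::read.tree(text = nwk)
  expect_equal(parsed$Nnode + length(parsed$tip.label), 4L)
})

test_that("the seeding verdict follows the decision rules", {
  sep_hi <- list(separation_score = 1, common_ancestor_present = TRUE)
  sep_lo <- list(separation_score = 0.2, common_ancestor_present = TRUE)
  ov0 <- list(jaccard = 0)
  expect_equal(classify_seeding_model(ov0, sep_hi,
                                      epi_set = letters[1:5],
                                      derm_set = letters[10:14])$verdict,
               "independent")
  expect_equal(classify_seeding_model(list(jaccard = 0.6), sep_lo,
                                      epi_set = letters[1:3],
                                      derm_set = letters[1:10])$verdict,
               "infiltration")
  expect_equal(classify_seeding_model(list(jaccard = 0.6), sep_hi,
                                      epi_set = letters[1:5],
                                      derm_set = letters[3:10])$verdict,
               "ambiguous")
  expect_error(classify_seeding_model(NULL, sep_hi, "a", "b"),
               "pipeline-order")
})
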