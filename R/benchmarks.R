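# Recovery benchmarks: the package's own evaluation suite. Each benchmark
# simulates data under fixed, documented study conditions and measures how
# well the analysis chain recovers the generative truth. The conditions are
# part of the package design (see the methods vignette) and are shared by the
# test suite and the acceptance script.

#' Benchmark: recovery of the neoplastic clonotype count
#'
#' Simulates single-compartment repertoires in which the malignant clone
#' frequencies are well separated from the reactive background (high tumour
#' cell fraction, flat reactive tail) and checks how often the TCF-matched
#' estimator recovers the true number of seeded clones to within one.
#'
#' @param n_reps Number of replicates; replicate `i` uses seed `seeds[i]` and
#'   a true clone count of `((i - 1) %% 50) + 1`.
#' @param seeds Integer vector of master seeds (recycled to `n_reps`).
#' @param tcf Tumor cell fraction of the simulated samples.
#' @param reactive_clone_count,zipf_exponent Reactive background shape.
#' @param reads Total clonotype reads per repertoire.
#' @return Data.frame with columns `seed`, `n_true`, `n_hat`, `ok`
#'   (within +/- 1), plus attribute `recovery_rate`.
#' @export
benchmark_estimator_recovery <- function(n_reps = 200, seeds = seq_len(n_reps),
                                         tcf = 0.9,
                                         reactive_clone_count = 2000L,
                                         zipf_exponent = 0.8,
                                         reads = 100000L) {
  seeds <- rep_len(seeds, n_reps)
  out <- data.frame(seed = seeds, n_true = ((seq_len(n_reps) - 1L) %% 50L) + 1L,
                    n_hat = NA_integer_)
  for (i in seq_len(n_reps)) {
    n_true <- out$n_true[i]
    cfg <- sim_config(
      n_circulating_clones = n_true, n_seeded_epidermis = n_true,
      n_seeded_dermis = 1L, tcf_epidermis = tcf,
      reactive_clone_count = reactive_clone_count,
      zipf_exponent = zipf_exponent, dirichlet_alpha = 30,
      clonotype_reads_per_sample = reads, partial_read_rate = 0.05,
      rng_seed = seeds[i]
    )
    pool <- simulate_circulating_pool(cfg)
    freqs <- with_seed(derive_seed(cfg$rng_seed, "catalog"),
                       rdirichlet1(n_true, cfg$dirichlet_alpha))
    tab <- with_seed(derive_seed(cfg$rng_seed, "render"),
                     render_repertoire_reads(pool, pool$barcode, freqs, tcf,
                                             cfg))
    rep <- clonotype_repertoire_from_df(tab, tcf)
    out$n_hat[i] <- estimate_neoplastic_clonotype_count(rep)$n
  }
  out$ok <- abs(out$n_hat - out$n_true) <= 1L
  structure(out, recovery_rate = mean(out$ok))
}

#' Benchmark: recovery of the subclone number and prevalences
#'
#' Draws lesions from the branched-evolution simulator, conditioned on 4-8
#' subclones whose two-compartment prevalence vectors are pairwise separated
#' by at least `min_gap` (Chebyshev distance) and that each carry at least
#' `min_mutations` mutations; renders allele depths at `mean_coverage`; and
#' clusters the mutations with [cluster_subclones()]. Reports how often the
#' BIC-selected component number equals the true subclone number, and the
#' prevalence error when it does.
#'
#' The benchmark lesions are high purity (TCF 0.9 in both compartments):
#' a prevalence gap maps to a VAF gap of `gap * TCF / 2`, so at depth 150 a
#' 0.1 gap is ~1.4 binomial standard deviations at TCF 0.9 but only ~0.7 at
#' TCF 0.5 — below any mixture model's resolution limit. Calibrating the
#' clustering machinery requires conditions where the stated gap is
#' informative; the vignette discusses the detection limit.
#'
#' @param n_reps Number of accepted replicates.
#' @param seed Master seed; rejected draws advance a deterministic sub-seed.
#' @param mean_coverage Sequencing depth for the rendered allele counts.
#' @param min_gap Minimum pairwise prevalence separation between subclones.
#' @param min_mutations Minimum mutations per subclone.
#' @param k_max,n_restarts Clustering controls.
#' @return Data.frame with `k_true`, `k_hat`, `max_abs_err` (maximum absolute
#'   prevalence error over matched clusters, `NA` when `k_hat != k_true`);
#'   attributes `k_accuracy` and `mean_prevalence_error`.
#' @export
benchmark_subclone_recovery <- function(n_reps = 50, seed = 1,
                                        mean_coverage = 150, min_gap = 0.1,
                                        min_mutations = 40, k_max = 10,
                                        n_restarts = 3) {
  res <- vector("list", n_reps)
  sub <- 0L
  for (i in seq_len(n_reps)) {
    repeat {
      sub <- sub + 1L
      cfg <- sim_config(
        seeding_mode = "independent", n_circulating_clones = 10L,
        n_seeded_dermis = 2L, n_seeded_epidermis = 2L,
        n_generations = 1L, ancestral_mutation_rate = 100,
        mutation_rate_stem = 100, mutation_rate_branch = 60,
        tcf_epidermis = 0.9, tcf_dermis = 0.9,
        mean_coverage = mean_coverage, cna_segment_count = 0L,
        rng_seed = derive_seed(seed, paste0("rep", sub))
      )
      lesion <- simulate_lesion(cfg)
      joint <- lesion$truth$joint_tree
      prev <- joint$prevalence
      k_true <- nrow(prev)
      nmut <- vapply(joint$mutations, length, integer(1))
      gaps <- as.matrix(stats::dist(prev, method = "maximum"))
      diag(gaps) <- Inf
      if (k_true >= 4L && k_true <= 8L && all(nmut >= min_mutations) &&
          min(gaps) >= min_gap) break
    }
    cl <- cluster_subclones(lesion$observed$variants,
                            lesion$truth$tcf[c("epidermis", "dermis")],
                            cna = NULL, k_max = k_max,
                            n_restarts = n_restarts,
                            seed = derive_seed(seed, paste0("fit", sub)))
    err <- NA_real_
    if (cl$k == k_true) {
      # match inferred clusters to true nodes greedily by prevalence
      d <- as.matrix(stats::dist(rbind(cl$prevalence, prev)))
      d <- d[seq_len(cl$k), cl$k + seq_len(k_true), drop = FALSE]
      err <- 0
      for (j in seq_len(k_true)) {
        hit <- which(d == min(d), arr.ind = TRUE)[1, ]
        err <- max(err, max(abs(cl$prevalence[hit[1], ] - prev[hit[2], ])))
        d[hit[1], ] <- Inf
        d[, hit[2]] <- Inf
      }
    }
    res[[i]] <- data.frame(k_true = k_true, k_hat = cl$k, max_abs_err = err)
  }
  out <- do.call(rbind, res)
  structure(out,
            k_accuracy = mean(out$k_hat == out$k_true),
            mean_prevalence_error = mean(out$max_abs_err, na.rm = TRUE))
}

#' Study conditions for the seeding-model discrimination benchmark
#'
#' Configuration used to contrast the two seeding models: moderate clone
#' numbers, a flat reactive background and tumour cell fractions high enough
#' that the TCF-matched clonotype sets are informative. See the methods
#' vignette for the rationale behind each value.
#'
#' @param mode `"independent"` or `"infiltration"`.
#' @param seed Master seed.
#' @return A [sim_config()].
#' @export
verdict_benchmark_config <- function(mode, seed) {
  if (mode == "independent") {
    sim_config(
      seeding_mode = "independent", n_circulating_clones = 100L,
      n_seeded_dermis = 20L, n_seeded_epidermis = 20L,
      shared_clone_rate = 0.1, tcf_dermis = 0.6, tcf_epidermis = 0.9,
      reactive_clone_count = 2000L, zipf_exponent = 0.8,
      dirichlet_alpha = 20, n_generations = 1L,
      ancestral_mutation_rate = 5, mutation_rate_stem = 40,
      mutation_rate_branch = 15, mean_coverage = 150,
      clonotype_reads_per_sample = 100000L, cna_segment_count = 0L,
      rng_seed = seed
    )
  } else {
    sim_config(
      seeding_mode = "infiltration", n_circulating_clones = 100L,
      n_seeded_dermis = 20L, n_seeded_epidermis = 15L,
      tcf_dermis = 0.6, tcf_epidermis = 0.9,
      reactive_clone_count = 2000L, zipf_exponent = 0.8,
      dirichlet_alpha = 20, n_generations = 1L,
      ancestral_mutation_rate = 5, mutation_rate_stem = 40,
      mutation_rate_branch = 15, mean_coverage = 150,
      clonotype_reads_per_sample = 100000L, cna_segment_count = 0L,
      rng_seed = seed
    )
  }
}

#' Benchmark: seeding-model discrimination
#'
#' Simulates lesions under both generative modes
#' (see [verdict_benchmark_config()]), runs the clonotype and phylogenetic
#' analyses and the rule-based verdict, and scores the verdict against the
#' generative truth.
#'
#' @param n_per_mode Lesions per seeding mode.
#' @param seed Master seed.
#' @param k_max,n_restarts Clustering controls.
#' @return Data.frame with one row per lesion (`mode`, `verdict`, `jaccard`,
#'   `separation`, `subset_pattern`, `epi_subset_truth`); attributes
#'   `accuracy` and `infiltration_subset_rate`.
#' @export
benchmark_verdict <- function(n_per_mode = 100, seed = 1, k_max = 6,
                              n_restarts = 2) {
  rows <- list()
  for (mode in c("independent", "infiltration")) {
    for (i in seq_len(n_per_mode)) {
      cfg <- verdict_benchmark_config(
        mode, derive_seed(seed, paste0(mode, i)))
      lesion <- simulate_lesion(cfg)
      obs <- lesion$observed
      reps <- list(
        epidermis = clonotype_repertoire_from_df(
          obs$clonotypes$epidermis, cfg$tcf_epidermis),
        dermis = clonotype_repertoire_from_df(
          obs$clonotypes$dermis, cfg$tcf_dermis)
      )
      sets <- lapply(reps, function(r) {
        clonotype_key(estimate_neoplastic_clonotype_count(r)$selected)
      })
      ov <- overlap_clonotypes(reps$epidermis, reps$dermis)
      cl <- cluster_subclones(obs$variants,
                              lesion$truth$tcf[c("epidermis", "dermis")],
                              k_max = k_max, n_restarts = n_restarts,
                              seed = derive_seed(seed, paste0("fit", mode, i)))
      tree <- build_tree(cl)
      sep <- compartment_separation(tree)
      v <- classify_seeding_model(ov, sep, sets$epidermis, sets$dermis)
      truth_subset <- all(lesion$truth$compartment_clones$epidermis %in%
                            lesion$truth$compartment_clones$dermis)
      rows[[length(rows) + 1L]] <- data.frame(
        mode = mode, verdict = v$verdict, jaccard = ov$jaccard,
        separation = sep$separation_score,
        subset_pattern = v$evidence$subset_pattern,
        epi_subset_truth = truth_subset
      )
    }
  }
  out <- do.call(rbind, rows)
  structure(out,
            accuracy = mean(out$verdict == out$mode),
            infiltration_subset_rate =
              mean(out$epi_subset_truth[out$mode == "infiltration"]))
}
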