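# small, fast configurations used across tests

small_config <- function(...) {
  args <- list(...)
  defaults <- list(
    n_circulating_clones = 12L, n_seeded_dermis = 3L,
    n_seeded_epidermis = 5L, reactive_clone_count = 40L,
    mutation_rate_stem = 12, mutation_rate_branch = 6,
    ancestral_mutation_rate = 4, n_generations = 1L,
    mean_coverage = 120, clonotype_reads_per_sample = 2000L,
    cna_segment_count = 2L, rng_seed = 1L
  )
  defaults[names(args)] <- args
  do.call(sim_config, defaults)
}

# a clonotype table data.frame in the MiXCR-style dialect
clonotype_df <- function(barcodes, counts, v = "TRBV9", j = "TRBJ1-1",
                         partial = FALSE) {
  n <- length(barcodes)
  data.frame(
    cloneId = seq_len(n) - 1L,
    readCount = counts,
    readFraction = counts / sum(counts),
    nSeqCDR3 = barcodes,
    aaSeqCDR3 = rep_len("KAF", n),
    allVHitsWithScore = rep_len(v, n),
    allJHitsWithScore = rep_len(j, n),
    isPartial = rep_len(partial, n),
    stringsAsFactors = FALSE
  )
}

# long-format variant rows for both compartments
variant_rows <- function(n, phi_epi, phi_derm, tcf_epi = 0.9, tcf_derm = 0.6,
                         depth = 150, consequence = "missense",
                         gene = NULL, seed = NULL, start_pos = 1L) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(gene)) gene <- sprintf("G%04d", seq_len(n))
  rows <- list()
  for (i in seq_len(n)) {
    for (cp in c("epidermis", "dermis")) {
      tcf <- if (cp == "epidermis") tcf_epi else tcf_derm
      phi <- if (cp == "epidermis") phi_epi[min(i, length(phi_epi))] else
        phi_derm[min(i, length(phi_derm))]
      vaf <- phi * tcf / 2
      d <- rpois(1, depth)
      a <- rbinom(1, d, vaf)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = "chr1", pos = start_pos + i - 1L, ref = "A", alt = "G",
        gene = rep_len(gene, n)[i], consequence = consequence,
        compartment = cp, ref_depth = d - a, alt_depth = a,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}
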