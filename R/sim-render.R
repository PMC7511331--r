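# Rendering a simulated lesion truth into observed data files: multinomial
# clonotype read sampling, binomial allele-depth sampling, partial-read
# injection, CNA table and truth JSON.

CONSEQ_NONSYN <- c("missense", "frameshift", "inframe_indel", "stop_gain",
                   "stop_loss")
CONSEQ_OTHER <- c("synonymous", "utr3", "utr5", "other")

sample_consequence <- function(n, fraction_nonsynonymous) {
  nonsyn <- runif(n) < fraction_nonsynonymous
  out <- character(n)
  out[nonsyn] <- sample(CONSEQ_NONSYN, sum(nonsyn), replace = TRUE,
                        prob = c(0.70, 0.10, 0.12, 0.06, 0.02))
  out[!nonsyn] <- sample(CONSEQ_OTHER, sum(!nonsyn), replace = TRUE,
                         prob = c(0.60, 0.20, 0.10, 0.10))
  out
}

BASES <- c("A", "C", "G", "T")

sample_alleles <- function(consequence) {
  n <- length(consequence)
  ref <- sample(BASES, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(BASES, r), 1L), character(1))
  indel <- consequence %in% c("frameshift", "inframe_indel")
  for (i in which(indel)) {
    dl <- if (consequence[i] == "frameshift") {
      sample(c(1L, 2L, 4L, 5L), 1L, prob = c(0.5, 0.3, 0.1, 0.1))
    } else {
      # includes >= 6 bp in-frame events, which are *not* "damaging"
      sample(c(3L, 6L, 9L), 1L, prob = c(0.7, 0.2, 0.1))
    }
    ins <- runif(1) < 0.5
    tail <- paste(sample(BASES, dl, replace = TRUE), collapse = "")
    if (ins) alt[i] <- paste0(ref[i], tail) else {
      alt[i] <- ref[i]
      ref[i] <- paste0(ref[i], tail)
    }
  }
  list(ref = unname(ref), alt = unname(alt))
}

# Clonal copy-number segments with integer allele-specific states.
simulate_cna_segments <- function(config) {
  n <- config$cna_segment_count
  if (n == 0L) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), major_cn = integer(0),
                      minor_cn = integer(0)))
  }
  states <- matrix(c(1L, 0L, 2L, 1L, 2L, 0L, 3L, 1L), ncol = 2, byrow = TRUE)
  pick <- sample(nrow(states), n, replace = TRUE)
  start <- sample.int(2e8L, n)
  data.frame(
    chrom = paste0("chr", sample(1:22, n, replace = TRUE)),
    start = start,
    end = start + sample.int(2e7L, n),
    major_cn = states[pick, 1], minor_cn = states[pick, 2]
  )
}

# Build the generative mutation catalog: genomic coordinates, alleles, gene
# and consequence annotation for every mutation in the joint tree.
build_mutation_catalog <- function(joint, config) {
  ids <- unlist(joint$mutations)
  node_of <- rep(seq_along(joint$mutations),
                 vapply(joint$mutations, length, integer(1)))
  n <- length(ids)
  cna <- simulate_cna_segments(config)
  if (n == 0L) {
    return(list(catalog = data.frame(), cna = cna))
  }
  consequence <- sample_consequence(n, config$fraction_nonsynonymous)
  al <- sample_alleles(consequence)
  is_driver <- runif(n) < config$driver_hit_rate &
    length(config$driver_gene_list) > 0
  gene <- sprintf("GENE%04d", sample.int(5000L, n, replace = TRUE))
  if (any(is_driver)) {
    gene[is_driver] <- sample(config$driver_gene_list, sum(is_driver),
                              replace = TRUE)
  }
  chrom <- paste0("chr", sample(1:22, n, replace = TRUE))
  pos <- sample.int(2.2e8, n)
  while (anyDuplicated(paste(chrom, pos))) {
    dup <- duplicated(paste(chrom, pos))
    pos[dup] <- sample.int(2.2e8, sum(dup))
  }
  catalog <- data.frame(
    id = ids, chrom = chrom, pos = pos, ref = al$ref, alt = al$alt,
    gene = gene, consequence = consequence,
    subclone = joint$id[node_of],
    phi_epidermis = joint$prevalence[node_of, "epidermis"],
    phi_dermis = joint$prevalence[node_of, "dermis"],
    stringsAsFactors = FALSE
  )
  list(catalog = catalog, cna = cna)
}

# Total copy number at each catalog position given clonal CNA segments
# (default diploid outside segments).
total_cn_at <- function(catalog, cna) {
  cn <- rep(2L, nrow(catalog))
  if (nrow(cna) == 0L) return(cn)
  for (s in seq_len(nrow(cna))) {
    hit <- catalog$chrom == cna$chrom[s] &
      catalog$pos > cna$start[s] & catalog$pos <= cna$end[s]
    cn[hit] <- cna$major_cn[s] + cna$minor_cn[s]
  }
  cn
}

expected_vaf <- function(phi, tcf, cn_tumor, multiplicity = 1) {
  denom <- tcf * cn_tumor + (1 - tcf) * 2
  ifelse(denom > 0, phi * tcf * multiplicity / denom, 0)
}

# Draw one compartment's clonotype table: malignant clones occupy the TCF
# mass (Dirichlet-distributed), reactive background the rest (Zipf tail);
# read counts are multinomial; partial V-only/J-only rows are injected.
render_repertoire_reads <- function(pool, clones, frequencies, tcf, config) {
  mal <- pool[match(clones, pool$barcode), , drop = FALSE]
  n_reactive <- config$reactive_clone_count
  freq <- c(frequencies * tcf,
            zipf_frequencies(n_reactive, config$zipf_exponent, 1 - tcf))
  if (tcf == 1) freq <- freq[seq_along(clones)]
  n_all <- length(freq)
  reads <- as.vector(rmultinom(1L, config$clonotype_reads_per_sample, freq))
  n_mal <- length(clones)
  if (n_all > n_mal) {
    reac_idx <- seq.int(n_mal + 1L, n_all)
    reac_cdr3 <- random_cdr3_nt(length(reac_idx))
    df <- data.frame(
      nSeqCDR3 = c(mal$barcode, reac_cdr3),
      aaSeqCDR3 = c(mal$cdr3_aa, translate_cdr3(reac_cdr3)),
      v_gene = c(mal$v_gene,
                 sample(TRBV_CATALOG, length(reac_idx), replace = TRUE)),
      j_gene = c(mal$j_gene,
                 sample(TRBJ_CATALOG, length(reac_idx), replace = TRUE)),
      readCount = reads, stringsAsFactors = FALSE
    )
  } else {
    df <- data.frame(nSeqCDR3 = mal$barcode, aaSeqCDR3 = mal$cdr3_aa,
                     v_gene = mal$v_gene, j_gene = mal$j_gene,
                     readCount = reads, stringsAsFactors = FALSE)
  }
  df <- df[df$readCount > 0L, , drop = FALSE]
  df$isPartial <- FALSE
  # inject partial (V-only / J-only) capture rows
  n_partial <- rpois(1L, config$partial_read_rate * nrow(df))
  if (n_partial > 0L && nrow(df) > 0L) {
    src <- sample.int(nrow(df), n_partial, replace = TRUE)
    v_only <- runif(n_partial) < 0.5
    frag <- ifelse(v_only, substr(df$nSeqCDR3[src], 1L, 12L),
                   substring(df$nSeqCDR3[src],
                             nchar(df$nSeqCDR3[src]) - 11L))
    part <- data.frame(
      nSeqCDR3 = frag, aaSeqCDR3 = "",
      v_gene = ifelse(v_only, df$v_gene[src], ""),
      j_gene = ifelse(v_only, "", df$j_gene[src]),
      readCount = 1L + rpois(n_partial, 2), isPartial = TRUE,
      stringsAsFactors = FALSE
    )
    df <- rbind(df, part)
  }
  total <- sum(df$readCount)
  df <- df[order(-df$readCount, df$nSeqCDR3), , drop = FALSE]
  data.frame(
    cloneId = seq_len(nrow(df)) - 1L,
    readCount = df$readCount,
    readFraction = df$readCount / total,
    nSeqCDR3 = df$nSeqCDR3,
    aaSeqCDR3 = df$aaSeqCDR3,
    allVHitsWithScore = ifelse(nzchar(df$v_gene),
                               paste0(df$v_gene, "*00(100)"), ""),
    allJHitsWithScore = ifelse(nzchar(df$j_gene),
                               paste0(df$j_gene, "*00(100)"), ""),
    isPartial = df$isPartial,
    stringsAsFactors = FALSE
  )
}

#' Render a simulated lesion truth as observed data tables
#'
#' Applies the sampling layer that links the generative truth to the file
#' formats the analysis chain consumes: clonotype read counts per compartment
#' are drawn multinomially from the true clone frequencies mixed with a
#' reactive background occupying the `1 - TCF` fraction; variant alt/ref
#' depths are drawn binomially at `Poisson(mean_coverage)` total depth with
#' expected VAF `phi * TCF * m / (TCF * CN + (1 - TCF) * 2)`; partial
#' clonotype capture rows are injected (and flagged) so downstream filtering
#' is exercised.
#'
#' @param truth A `lesion_truth` from [simulate_lesion()] (or assembled
#'   manually with the same structure).
#' @param config The [sim_config()] used to generate `truth`.
#' @return A list of class `observed_dataset`: `clonotypes` (named list of
#'   MiXCR-style data.frames for epidermis, dermis, blood), `variants` (flat
#'   per-compartment depth table), `cna`, `tcf`, `sample_id`.
#' @export
render_observations <- function(truth, config) {
  validate_sim_config(config)
  with_seed(derive_seed(config$rng_seed, "render"), {
    tcf <- truth$tcf
    clon <- list(
      epidermis = render_repertoire_reads(
        truth$circulating_pool, truth$compartment_clones$epidermis,
        truth$clone_frequencies$epidermis, tcf[["epidermis"]], config),
      dermis = render_repertoire_reads(
        truth$circulating_pool, truth$compartment_clones$dermis,
        truth$clone_frequencies$dermis, tcf[["dermis"]], config),
      blood = render_repertoire_reads(
        truth$circulating_pool, truth$compartment_clones$blood,
        truth$clone_frequencies$blood, tcf[["blood"]], config)
    )
    cat <- truth$mutation_catalog
    variants <- NULL
    if (nrow(cat) > 0L) {
      cn <- total_cn_at(cat, truth$cna)
      rows <- lapply(c("epidermis", "dermis"), function(cp) {
        phi <- cat[[paste0("phi_", cp)]]
        vaf <- expected_vaf(phi, tcf[[cp]], cn)
        depth <- rpois(nrow(cat), config$mean_coverage)
        alt <- rbinom(nrow(cat), depth, pmin(vaf, 1))
        data.frame(
          chrom = cat$chrom, pos = cat$pos, ref = cat$ref, alt = cat$alt,
          gene = cat$gene, consequence = cat$consequence, compartment = cp,
          ref_depth = depth - alt, alt_depth = alt, stringsAsFactors = FALSE
        )
      })
      variants <- do.call(rbind, rows)
    }
    structure(
      list(sample_id = truth$sample_id, clonotypes = clon,
           variants = variants, cna = truth$cna, tcf = tcf),
      class = "observed_dataset"
    )
  })
}

#' Simulate a complete two-compartment lesion
#'
#' Runs the full generative chain: circulating pool, compartment seeding,
#' neutral branched evolution, mutation catalog annotation, and observation
#' rendering.
#'
#' @param config A [sim_config()].
#' @param sample_id Sample label used in file names and reports.
#' @return List with `truth` (class `lesion_truth`) and `observed`
#'   (class `observed_dataset`).
#' @export
#' @examples
#' lesion <- simulate_lesion(sim_config(rng_seed = 42,
#'   clonotype_reads_per_sample = 5000, reactive_clone_count = 100))
#' head(lesion$observed$clonotypes$epidermis)
simulate_lesion <- function(config, sample_id = "SIM") {
  validate_sim_config(config)
  pool <- simulate_circulating_pool(config)
  clones <- simulate_seeding(pool, config)
  trees <- simulate_branched_evolution(clones, config)
  joint <- attr(trees, "joint")
  truth <- with_seed(derive_seed(config$rng_seed, "catalog"), {
    cc <- build_mutation_catalog(joint, config)
    freqs <- list(
      epidermis = rdirichlet1(length(clones$epidermis), config$dirichlet_alpha),
      dermis = rdirichlet1(length(clones$dermis), config$dirichlet_alpha),
      blood = rdirichlet1(length(clones$blood), config$dirichlet_alpha)
    )
    structure(
      list(sample_id = sample_id,
           circulating_pool = pool,
           compartment_clones = clones,
           clone_frequencies = freqs,
           true_trees = trees[c("epidermis", "dermis")],
           joint_tree = joint,
           mutation_catalog = cc$catalog,
           cna = cc$cna,
           tcf = c(epidermis = config$tcf_epidermis,
                   dermis = config$tcf_dermis,
                   blood = config$tcf_blood),
           seeding_mode = config$seeding_mode),
      class = "lesion_truth"
    )
  })
  list(truth = truth, observed = render_observations(truth, config))
}

# one symmetric-Dirichlet draw
rdirichlet1 <- function(n, alpha) {
  if (n == 0L) return(numeric(0))
  g <- rgamma(n, shape = alpha)
  g / sum(g)
}
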