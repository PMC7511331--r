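#' Run the full lesion analysis pipeline on a dataset directory
#'
#' Orchestrates the analysis chain on one simulated or real dataset directory
#' (as written by [write_observed_dataset()], or assembled from upstream
#' tools in the same layout): reads the samples manifest and per-compartment
#' clonotype tables, counts neoplastic clonotypes by TCF matching, computes
#' compartment/blood clonotype overlap and Venn counts, reads the somatic
#' variant and CNA tables, counts non-synonymous mutations and their
#' cross-compartment overlap, builds the driver-gene matrix, clusters
#' mutations into subclones, reconstructs the subclone tree, partitions stem
#' versus clade mutations, scores compartment separation and issues the
#' seeding-model verdict.
#'
#' Re-running with the same inputs and parameters reproduces a byte-identical
#' report.
#'
#' @param input_dir Directory containing `manifest.tsv` and the data files it
#'   references.
#' @param out_dir Optional output directory; when given, the per-sample
#'   report is written as `<sample>.report.json` and the tree as
#'   `<sample>.tree.nwk`.
#' @param overlap_key Clonotype identity key (see [overlap_clonotypes()]).
#' @param min_alt_reads Variant presence threshold per compartment.
#' @param driver_gene_list Driver panel (default: packaged panel).
#' @param k_max,n_restarts,seed Subclone clustering controls
#'   (see [cluster_subclones()]).
#' @param epsilon Pigeonhole tolerance for [build_tree()].
#' @param eps_presence Presence threshold for [compartment_separation()].
#' @param j_max,s_min,subset_tol Verdict thresholds
#'   (see [classify_seeding_model()]).
#' @return A report list (one entry per sample) with all computed statistics
#'   and the parameter block used.
#' @export
run_pipeline <- function(input_dir, out_dir = NULL,
                         overlap_key = "nt+vj", min_alt_reads = 1L,
                         driver_gene_list = driver_genes(),
                         k_max = 10, n_restarts = 10, seed = 1,
                         epsilon = 0.05, eps_presence = 0.05,
                         j_max = 0.2, s_min = 0.8, subset_tol = 0.1) {
  manifest_path <- file.path(input_dir, "manifest.tsv")
  if (!file.exists(manifest_path)) {
    stop(sprintf("stage manifest: file not found: %s", manifest_path),
         call. = FALSE)
  }
  manifest <- read.delim(manifest_path, stringsAsFactors = FALSE)
  required <- c("sample_id", "compartment", "tcf", "path")
  if (length(setdiff(required, names(manifest))) > 0L) {
    stop("stage manifest: manifest.tsv must have columns sample_id, compartment, tcf, path",
         call. = FALSE)
  }
  params <- list(overlap_key = overlap_key, min_alt_reads = min_alt_reads,
                 k_max = k_max, n_restarts = n_restarts, seed = seed,
                 epsilon = epsilon, eps_presence = eps_presence,
                 j_max = j_max, s_min = s_min, subset_tol = subset_tol,
                 driver_gene_list = driver_gene_list)
  reports <- list()
  for (sid in unique(manifest$sample_id)) {
    reports[[sid]] <- analyse_sample(input_dir, manifest[manifest$sample_id == sid, ],
                                     params)
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      jsonlite::write_json(reports[[sid]],
                           file.path(out_dir, sprintf("%s.report.json", sid)),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE,
                           na = "null")
      writeLines(reports[[sid]]$phylogeny$newick,
                 file.path(out_dir, sprintf("%s.tree.nwk", sid)))
    }
  }
  if (!is.null(out_dir)) {
    summary <- do.call(rbind, lapply(reports, function(r) {
      data.frame(
        sample_id = r$sample_id,
        n_clonotypes_epidermis = r$clonotypes$n_neoplastic$epidermis,
        n_clonotypes_dermis = r$clonotypes$n_neoplastic$dermis,
        n_shared_clonotypes = r$clonotypes$overlap$n_shared,
        nonsyn_epidermis = r$mutations$n_nonsynonymous$epidermis,
        nonsyn_dermis = r$mutations$n_nonsynonymous$dermis,
        percent_overlap = r$mutations$overlap$percent_overlap,
        n_subclones = r$phylogeny$n_subclones,
        stem_fraction = r$phylogeny$stem_fraction,
        separation_score = r$phylogeny$separation_score,
        verdict = r$verdict$verdict
      )
    }))
    write_tsv(summary, file.path(out_dir, "cohort_summary.tsv"))
  }
  invisible(reports)
}

analyse_sample <- function(input_dir, mani, params) {
  sid <- mani$sample_id[1]
  reps <- list()
  for (r in seq_len(nrow(mani))) {
    path <- file.path(input_dir, mani$path[r])
    if (!file.exists(path)) {
      stop(sprintf("stage clonotypes: file not found: %s", path),
           call. = FALSE)
    }
    reps[[mani$compartment[r]]] <-
      read_clonotype_table(path, mani$tcf[r], sid, mani$compartment[r])
  }
  if (is.null(reps$epidermis) || is.null(reps$dermis)) {
    stop("stage clonotypes: manifest must provide epidermis and dermis samples",
         call. = FALSE)
  }
  est <- lapply(reps, estimate_neoplastic_clonotype_count)
  sets <- lapply(est, function(e) clonotype_key(e$selected, params$overlap_key))
  ov <- overlap_clonotypes(reps$epidermis, reps$dermis,
                           key = params$overlap_key)
  venn <- if (!is.null(reps$blood)) {
    venn_counts(sets$epidermis, sets$dermis, sets$blood)
  } else {
    NULL
  }

  vpath <- file.path(input_dir, sprintf("%s.variants.tsv", sid))
  if (!file.exists(vpath)) {
    vpath <- file.path(input_dir, sprintf("%s.variants.vcf", sid))
  }
  if (!file.exists(vpath)) {
    stop(sprintf("stage variants: no variant table for sample %s", sid),
         call. = FALSE)
  }
  variants <- read_variant_table(vpath)
  nonsyn <- lapply(
    setNames(c("epidermis", "dermis"), c("epidermis", "dermis")),
    function(cp) count_nonsynonymous(variants, cp, params$min_alt_reads))
  mut_ov <- compartment_mutation_overlap(variants, params$min_alt_reads)
  drv <- driver_matrix(variants, params$driver_gene_list,
                       params$min_alt_reads)

  cna_path <- file.path(input_dir, sprintf("%s.cna.tsv", sid))
  cna <- if (file.exists(cna_path)) {
    read.delim(cna_path, stringsAsFactors = FALSE)
  } else {
    NULL
  }
  tcf <- setNames(mani$tcf, mani$compartment)
  clustering <- cluster_subclones(variants, tcf, cna, k_max = params$k_max,
                                  n_restarts = params$n_restarts,
                                  seed = params$seed)
  tree <- build_tree(clustering, epsilon = params$epsilon)
  part <- partition_stem_clade(tree)
  sep <- compartment_separation(tree, params$eps_presence)
  verdict <- classify_seeding_model(ov, sep, sets$epidermis, sets$dermis,
                                    params$j_max, params$s_min,
                                    params$subset_tol)
  list(
    sample_id = sid,
    parameters = params[names(params) != "driver_gene_list"],
    clonotypes = list(
      n_neoplastic = lapply(est, `[[`, "n"),
      tcf = as.list(tcf),
      overlap = ov[c("n_shared", "jaccard", "n_a", "n_b")],
      shared = ov$shared,
      venn = venn
    ),
    mutations = list(
      n_nonsynonymous = nonsyn,
      overlap = mut_ov,
      driver_counts = drv$counts,
      driver_matrix = cbind(gene = rownames(drv$matrix), drv$matrix)
    ),
    phylogeny = list(
      n_subclones = clustering$k,
      n_subclones_epidermis = sum(clustering$prevalence[, "epidermis"] >=
                                    params$eps_presence),
      n_subclones_dermis = sum(clustering$prevalence[, "dermis"] >=
                                 params$eps_presence),
      prevalence = as.data.frame(round(clustering$prevalence, 4)),
      feasible = attr(tree, "feasible"),
      stem_fraction = part$stem_fraction,
      clade_fraction = part$clade_fraction,
      stem_fraction_epidermis = partition_stem_clade(
        restrict_tree(tree, "epidermis", params$eps_presence))$stem_fraction,
      stem_fraction_dermis = partition_stem_clade(
        restrict_tree(tree, "dermis", params$eps_presence))$stem_fraction,
      separation_score = sep$separation_score,
      common_ancestor_present = sep$common_ancestor_present,
      newick = tree_to_newick(tree)
    ),
    verdict = verdict
  )
}
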