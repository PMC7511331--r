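# Writers for the observed dataset: MiXCR-style clonotype TSVs, a VCF v4.2
# with per-compartment AD plus an equivalent flat TSV, a BED-like CNA table,
# the truth JSON and a samples manifest.

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

# Minimal VCF v4.2 emitter: one line per variant, FORMAT AD (ref,alt) with one
# sample column per compartment.
write_variant_vcf <- function(variants, path) {
  cps <- sort(unique(variants$compartment))
  key <- paste(variants$chrom, variants$pos, variants$ref, variants$alt)
  uk <- !duplicated(key)
  base <- variants[uk, c("chrom", "pos", "ref", "alt", "gene", "consequence")]
  ord <- order(chrom_rank(base$chrom), base$pos)
  base <- base[ord, , drop = FALSE]
  bkey <- paste(base$chrom, base$pos, base$ref, base$alt)
  ad <- sapply(cps, function(cp) {
    sub <- variants[variants$compartment == cp, , drop = FALSE]
    skey <- paste(sub$chrom, sub$pos, sub$ref, sub$alt)
    m <- match(bkey, skey)
    ifelse(is.na(m), ".", paste0(sub$ref_depth[m], ",", sub$alt_depth[m]))
  })
  ad <- matrix(ad, ncol = length(cps))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=skinclones",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref,alt)\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Consequence\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", cps), collapse = "\t")
  )
  info <- sprintf("GENE=%s;CSQ=%s", base$gene, base$consequence)
  body <- apply(cbind(base$chrom, base$pos, ".", base$ref, base$alt, ".",
                      "PASS", info, "AD", ad), 1, paste, collapse = "\t")
  writeLines(c(header, body), path)
}

chrom_rank <- function(chrom) {
  x <- sub("^chr", "", chrom)
  suppressWarnings(n <- as.numeric(x))
  n[is.na(n)] <- 100 + as.numeric(factor(x[is.na(n)]))
  n
}

truth_to_list <- function(truth) {
  tree_list <- function(tree) {
    list(
      id = tree$id,
      parent = ifelse(is.na(tree$parent), NA_character_, tree$id[tree$parent]),
      prevalence = as.data.frame(tree$prevalence),
      mutations = setNames(tree$mutations, tree$id)
    )
  }
  list(
    sample_id = truth$sample_id,
    seeding_mode = truth$seeding_mode,
    tcf = as.list(truth$tcf),
    circulating_pool = truth$circulating_pool,
    compartment_clones = truth$compartment_clones,
    clone_frequencies = truth$clone_frequencies,
    joint_tree = tree_list(truth$joint_tree),
    true_trees = lapply(truth$true_trees, tree_list),
    mutation_catalog = truth$mutation_catalog,
    cna = truth$cna
  )
}

#' Write an observed dataset (and its truth) to a directory
#'
#' Produces one MiXCR-style clonotype TSV per compartment, a VCF v4.2 plus an
#' equivalent flat variant TSV, a BED-like copy-number table, a samples
#' manifest, and — when `truth` is supplied — a structured truth JSON.
#'
#' @param observed An `observed_dataset` from [render_observations()].
#' @param dir Output directory (created if missing).
#' @param truth Optional `lesion_truth` written alongside as `truth.json`.
#' @return Invisibly, the manifest data.frame (columns `sample_id`,
#'   `compartment`, `tcf`, `path`).
#' @export
write_observed_dataset <- function(observed, dir, truth = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sid <- observed$sample_id
  manifest <- data.frame(sample_id = character(0), compartment = character(0),
                         tcf = numeric(0), path = character(0))
  for (cp in names(observed$clonotypes)) {
    fn <- sprintf("%s_%s.clonotypes.tsv", sid, cp)
    write_tsv(observed$clonotypes[[cp]], file.path(dir, fn))
    manifest <- rbind(manifest, data.frame(
      sample_id = sid, compartment = cp, tcf = observed$tcf[[cp]], path = fn))
  }
  if (!is.null(observed$variants)) {
    write_tsv(observed$variants, file.path(dir, sprintf("%s.variants.tsv", sid)))
    write_variant_vcf(observed$variants,
                      file.path(dir, sprintf("%s.variants.vcf", sid)))
  }
  write_tsv(observed$cna, file.path(dir, sprintf("%s.cna.tsv", sid)))
  write_tsv(manifest, file.path(dir, "manifest.tsv"))
  if (!is.null(truth)) {
    jsonlite::write_json(truth_to_list(truth),
                         file.path(dir, sprintf("%s.truth.json", sid)),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
  }
  invisible(manifest)
}
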