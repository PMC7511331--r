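#' Read a somatic variant table (VCF or flat TSV)
#'
#' Accepts either a VCF v4.2 with a per-sample `AD` (ref,alt depths) FORMAT
#' field — one sample column per compartment — or the equivalent flat TSV with
#' columns `chrom`, `pos`, `ref`, `alt`, `gene`, `consequence`,
#' `compartment`, `ref_depth`, `alt_depth`. Multi-allelic VCF rows are split
#' into one record per alternate allele. The result is a long-format
#' data.frame with one row per variant x compartment.
#'
#' @param path Path to the `.vcf` or `.tsv` file.
#' @param compartment_map Optional named character vector mapping VCF sample
#'   column names to compartment labels (defaults to using the column names
#'   themselves).
#' @return Data.frame with columns `chrom`, `pos`, `ref`, `alt`, `gene`,
#'   `consequence`, `compartment`, `ref_depth`, `alt_depth`.
#' @export
read_variant_table <- function(path, compartment_map = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("variant table not found: %s", path), call. = FALSE)
  }
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    read_variant_vcf(path, compartment_map)
  } else {
    df <- read.delim(path, stringsAsFactors = FALSE)
    required <- c("chrom", "pos", "ref", "alt", "gene", "consequence",
                  "compartment", "ref_depth", "alt_depth")
    missing <- setdiff(required, names(df))
    if (length(missing) > 0L) {
      stop(sprintf("variant table format error: missing column(s) %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
    df[required]
  }
}

read_variant_vcf <- function(path, compartment_map = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix[, , drop = FALSE], stringsAsFactors = FALSE)
  ad <- vcfR::extract.gt(vcf, element = "AD")
  if (is.null(ad)) {
    stop("variant table format error: VCF has no AD FORMAT field",
         call. = FALSE)
  }
  samples <- colnames(ad)
  comp <- if (is.null(compartment_map)) {
    setNames(samples, samples)
  } else {
    unknown <- setdiff(samples, names(compartment_map))
    if (length(unknown) > 0L) {
      stop(sprintf("manifest error: VCF sample(s) %s have no compartment label",
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
    compartment_map[samples]
  }
  gene <- vcfR::extract.info(vcf, "GENE")
  csq <- vcfR::extract.info(vcf, "CSQ")
  out <- list()
  for (r in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[r], ",", fixed = TRUE)[[1]]
    for (a in seq_along(alts)) {
      for (s in seq_along(samples)) {
        adv <- ad[r, s]
        if (is.na(adv) || adv == ".") next
        depths <- suppressWarnings(as.integer(strsplit(adv, ",")[[1]]))
        out[[length(out) + 1L]] <- data.frame(
          chrom = fix$CHROM[r], pos = as.integer(fix$POS[r]),
          ref = fix$REF[r], alt = alts[a],
          gene = if (is.null(gene) || is.na(gene[r])) "" else gene[r],
          consequence = if (is.null(csq) || is.na(csq[r])) "other" else csq[r],
          compartment = unname(comp[s]),
          ref_depth = depths[1], alt_depth = depths[1 + a],
          stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, out)
}

CONSEQUENCE_LEVELS <- c("missense", "frameshift", "inframe_indel",
                        "stop_gain", "stop_loss", "synonymous", "utr3",
                        "utr5", "other")

#' Classify a variant consequence as missense, damaging or other
#'
#' Frameshifts, insertions or deletions shorter than 6 bp, and stop gain/loss
#' events are classified as damaging (likely deleterious); missense variants
#' as missense; everything else — including in-frame indels of 6 bp or more —
#' as other.
#'
#' @param consequence Character vector of consequence terms (see
#'   `CONSEQUENCE_LEVELS`).
#' @param ref,alt Optional allele strings, used to measure indel length for
#'   the `< 6 bp` rule on `inframe_indel` records.
#' @return Character vector over `{"missense", "damaging", "other"}`.
#' @export
#' @examples
#' classify_consequence(c("frameshift", "missense", "synonymous"))
classify_consequence <- function(consequence, ref = NULL, alt = NULL) {
  out <- rep("other", length(consequence))
  out[consequence == "missense"] <- "missense"
  out[consequence %in% c("frameshift", "stop_gain", "stop_loss")] <- "damaging"
  infr <- which(consequence == "inframe_indel")
  if (length(infr) > 0L) {
    if (is.null(ref) || is.null(alt)) {
      out[infr] <- "damaging"  # no alleles to measure: assume < 6 bp
    } else {
      dl <- abs(nchar(ref[infr]) - nchar(alt[infr]))
      out[infr] <- ifelse(dl < 6, "damaging", "other")
    }
  }
  out
}

NONSYNONYMOUS_SET <- c("missense", "frameshift", "inframe_indel", "stop_gain",
                       "stop_loss")

variant_key <- function(variants) {
  paste(variants$chrom, variants$pos, variants$ref, variants$alt, sep = ":")
}

present_in <- function(variants, compartment, min_alt_reads = 1L) {
  variants$compartment == compartment & variants$alt_depth >= min_alt_reads
}

#' Count non-synonymous variants present in a compartment
#'
#' A variant is counted when its alternate-allele depth in the compartment
#' reaches `min_alt_reads` and its consequence is protein-altering
#' (`nonsyn_set`, by default missense, frameshift, in-frame indel, stop
#' gain/loss; UTR and synonymous changes are excluded).
#'
#' @param variants Long-format variant data.frame (see
#'   [read_variant_table()]).
#' @param compartment Compartment label.
#' @param min_alt_reads Presence threshold on alt depth (default 1).
#' @param nonsyn_set Consequence terms counted as non-synonymous.
#' @return Integer count.
#' @export
count_nonsynonymous <- function(variants, compartment, min_alt_reads = 1L,
                                nonsyn_set = NONSYNONYMOUS_SET) {
  sel <- present_in(variants, compartment, min_alt_reads) &
    variants$consequence %in% nonsyn_set
  length(unique(variant_key(variants[sel, , drop = FALSE])))
}

#' Cross-compartment mutation overlap
#'
#' Shares variants between the epidermis and the dermis on the
#' `(chrom, pos, ref, alt)` key and reports the overlap as a percentage of the
#' union of the two compartment mutation sets.
#'
#' @inheritParams count_nonsynonymous
#' @param compartments Length-2 character vector of compartment labels.
#' @return List with `n_epi_only`, `n_derm_only`, `n_shared`,
#'   `percent_overlap`.
#' @export
compartment_mutation_overlap <- function(variants, min_alt_reads = 1L,
                                         compartments = c("epidermis",
                                                          "dermis")) {
  a <- unique(variant_key(
    variants[present_in(variants, compartments[1], min_alt_reads), ,
             drop = FALSE]))
  b <- unique(variant_key(
    variants[present_in(variants, compartments[2], min_alt_reads), ,
             drop = FALSE]))
  if (length(a) == 0L && length(b) == 0L) {
    stop("no variants present in either compartment", call. = FALSE)
  }
  shared <- length(intersect(a, b))
  list(
    n_epi_only = length(a) - shared,
    n_derm_only = length(b) - shared,
    n_shared = shared,
    percent_overlap = 100 * shared / length(union(a, b))
  )
}

#' Driver-gene mutation matrix
#'
#' For each driver gene and compartment, reports the worst mutation
#' classification observed (`damaging` > `missense` > `absent`), and derives
#' the counts of driver genes mutated in both compartments or exclusively in
#' one.
#'
#' @inheritParams compartment_mutation_overlap
#' @param driver_gene_list Character vector of driver gene symbols.
#' @param include_utr Count UTR variants as (non-classifying) hits shown as
#'   `"other"`? Default `FALSE`: UTR/synonymous hits are ignored.
#' @return List with `matrix` (data.frame gene x compartment classifications)
#'   and `counts` (`both`, `epi_only`, `derm_only`).
#' @export
driver_matrix <- function(variants, driver_gene_list, min_alt_reads = 1L,
                          compartments = c("epidermis", "dermis"),
                          include_utr = FALSE) {
  cls <- classify_consequence(variants$consequence, variants$ref,
                              variants$alt)
  consider <- cls %in% c("missense", "damaging")
  if (include_utr) {
    consider <- consider | variants$consequence %in% c("utr3", "utr5")
  }
  rank_of <- c(absent = 0L, other = 1L, missense = 2L, damaging = 3L)
  mat <- matrix("absent", nrow = length(driver_gene_list),
                ncol = length(compartments),
                dimnames = list(driver_gene_list, compartments))
  for (cp in compartments) {
    sel <- consider & present_in(variants, cp, min_alt_reads) &
      variants$gene %in% driver_gene_list
    sub <- variants[sel, , drop = FALSE]
    sub_cls <- cls[sel]
    sub_cls[!(sub_cls %in% c("missense", "damaging"))] <- "other"
    for (g in unique(sub$gene)) {
      hits <- sub_cls[sub$gene == g]
      mat[g, cp] <- names(rank_of)[max(rank_of[hits]) + 1L]
    }
  }
  hit <- mat != "absent"
  list(
    matrix = as.data.frame(mat, stringsAsFactors = FALSE),
    counts = list(
      both = sum(hit[, 1] & hit[, 2]),
      epi_only = sum(hit[, 1] & !hit[, 2]),
      derm_only = sum(!hit[, 1] & hit[, 2])
    )
  )
}
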