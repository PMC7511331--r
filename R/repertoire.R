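#' Read a MiXCR-style clonotype table
#'
#' Reads one sample x compartment clonotype TSV (columns `cloneId`,
#' `readCount`, `readFraction`, `nSeqCDR3`, `aaSeqCDR3`, `allVHitsWithScore`,
#' `allJHitsWithScore`, and optionally `isPartial`). Partial capture rows
#' (V-only or J-only fragments) are filtered out before ranking, because they
#' may represent captures of only the V or only the J segment rather than a
#' complete CDR3; frequencies are then renormalised over the retained complete
#' records. Rows sharing the same barcode (CDR3 nucleotide sequence + V + J)
#' are merged by summing read counts. Records are sorted by decreasing
#' frequency with ties broken lexicographically by barcode, so downstream
#' ranking is deterministic.
#'
#' @param path Path to the clonotype TSV.
#' @param tcf Tumor cell fraction of the sample, in `[0, 1]`.
#' @param sample_id,compartment Optional metadata labels.
#' @return A `clonotype_repertoire`: list with `sample_id`, `compartment`,
#'   `tcf` and `records` (data.frame with `barcode`, `cdr3_aa`, `v_gene`,
#'   `j_gene`, `read_count`, `frequency`).
#' @export
read_clonotype_table <- function(path, tcf, sample_id = NA_character_,
                                 compartment = NA_character_) {
  if (!file.exists(path)) {
    stop(sprintf("clonotype table not found: %s", path), call. = FALSE)
  }
  df <- read.delim(path, stringsAsFactors = FALSE)
  required <- c("cloneId", "readCount", "readFraction", "nSeqCDR3",
                "aaSeqCDR3", "allVHitsWithScore", "allJHitsWithScore")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("clonotype table format error: missing column(s) %s in %s",
                 paste(missing, collapse = ", "), path), call. = FALSE)
  }
  if (is.null(df$isPartial)) df$isPartial <- FALSE
  clonotype_repertoire_from_df(df, tcf, sample_id, compartment)
}

#' Build a clonotype repertoire from an in-memory data.frame
#'
#' Same semantics as [read_clonotype_table()] (partial filtering, barcode
#' merging, renormalisation, deterministic ordering) for tables already in
#' memory, e.g. straight from the simulator.
#'
#' @param df Data.frame in the clonotype TSV dialect.
#' @inheritParams read_clonotype_table
#' @return A `clonotype_repertoire`.
#' @export
clonotype_repertoire_from_df <- function(df, tcf, sample_id = NA_character_,
                                         compartment = NA_character_) {
  stopifnot(is_fraction(tcf))
  if (is.null(df$isPartial)) df$isPartial <- FALSE
  df <- df[!isTRUE_vec(df$isPartial), , drop = FALSE]
  if (nrow(df) == 0L) {
    rec <- data.frame(barcode = character(0), cdr3_aa = character(0),
                      v_gene = character(0), j_gene = character(0),
                      read_count = integer(0), frequency = numeric(0))
  } else {
    v <- strip_hit(df$allVHitsWithScore)
    j <- strip_hit(df$allJHitsWithScore)
    key <- paste(df$nSeqCDR3, v, j, sep = "|")
    agg <- rowsum(as.numeric(df$readCount), key)
    first <- !duplicated(key)
    meta <- data.frame(key = key[first], barcode = df$nSeqCDR3[first],
                       cdr3_aa = df$aaSeqCDR3[first], v_gene = v[first],
                       j_gene = j[first], stringsAsFactors = FALSE)
    meta$read_count <- agg[match(meta$key, rownames(agg)), 1]
    meta$frequency <- meta$read_count / sum(meta$read_count)
    rec <- meta[order(-meta$frequency, meta$barcode),
                c("barcode", "cdr3_aa", "v_gene", "j_gene", "read_count",
                  "frequency")]
    rownames(rec) <- NULL
  }
  structure(list(sample_id = sample_id, compartment = compartment, tcf = tcf,
                 records = rec),
            class = "clonotype_repertoire")
}

isTRUE_vec <- function(x) {
  if (is.logical(x)) return(x & !is.na(x))
  tolower(as.character(x)) %in% c("true", "t", "1")
}

# "TRBV9*00(100)" -> "TRBV9"; keeps only the first hit.
strip_hit <- function(x) {
  x <- sub(",.*$", "", x)
  sub("\\*.*$", "", x)
}

#' @export
print.clonotype_repertoire <- function(x, ...) {
  cat(sprintf("<clonotype_repertoire> %s / %s: %d clonotypes, TCF %.2f\n",
              x$sample_id, x$compartment, nrow(x$records), x$tcf))
  print(head(x$records), row.names = FALSE)
  invisible(x)
}

#' Count neoplastic clonotypes by TCF matching
#'
#' The malignant clonotypes of a sample are identified as the top-ranked
#' clonotypes whose cumulative frequency matches the tumour cell fraction:
#' the returned `n` minimises `|sum_{i=1..n} f_i - TCF|` over all prefixes of
#' the frequency-ranked repertoire (including the empty prefix), with ties
#' broken toward the smaller `n`. By allelic exclusion each clonotype marks
#' one malignant T-cell clone, so `n` equals the number of malignant clones.
#' If the TCF exceeds the total repertoire frequency mass, every record is
#' selected and a warning is issued.
#'
#' @param repertoire A `clonotype_repertoire`.
#' @return List with `n` (integer) and `selected` (data.frame of the top-`n`
#'   records).
#' @export
#' @examples
#' rep <- clonotype_repertoire_from_df(data.frame(
#'   cloneId = 0:2, readCount = c(50, 30, 20), readFraction = NA,
#'   nSeqCDR3 = c("AAA", "CCC", "GGG"), aaSeqCDR3 = "",
#'   allVHitsWithScore = "TRBV9", allJHitsWithScore = "TRBJ1-1"), tcf = 0.5)
#' estimate_neoplastic_clonotype_count(rep)$n
estimate_neoplastic_clonotype_count <- function(repertoire) {
  stopifnot(inherits(repertoire, "clonotype_repertoire"))
  f <- repertoire$records$frequency
  tcf <- repertoire$tcf
  cum <- c(0, cumsum(f))
  dev <- abs(cum - tcf)
  n <- which.min(dev) - 1L  # which.min takes the first (smallest n) on ties
  if (length(f) > 0L && tcf > cum[length(cum)] + 1e-9) {
    warning("TCF exceeds total clonotype frequency mass; selecting all records")
    n <- length(f)
  }
  list(n = n, selected = repertoire$records[seq_len(n), , drop = FALSE])
}

clonotype_key <- function(records, key = c("nt+vj", "nt", "aa")) {
  key <- match.arg(key)
  switch(key,
         "nt" = records$barcode,
         "aa" = records$cdr3_aa,
         "nt+vj" = paste(records$barcode, records$v_gene, records$j_gene,
                         sep = "|"))
}

#' Clonotype overlap between two repertoires
#'
#' Compares the neoplastic (TCF-selected) clonotype sets of two repertoires
#' under a configurable identity key and reports the shared set and the
#' Jaccard index.
#'
#' @param rep_a,rep_b `clonotype_repertoire` objects.
#' @param key Identity key: `"nt+vj"` (CDR3 nucleotide + V + J, default),
#'   `"nt"`, or `"aa"`.
#' @param select If `TRUE` (default) restrict each repertoire to its
#'   TCF-matched neoplastic records first.
#' @return List with `shared` (character vector of keys), `n_shared`,
#'   `jaccard`, `n_a`, `n_b`.
#' @export
overlap_clonotypes <- function(rep_a, rep_b, key = c("nt+vj", "nt", "aa"),
                               select = TRUE) {
  key <- match.arg(key)
  get_set <- function(r) {
    rec <- if (select) estimate_neoplastic_clonotype_count(r)$selected else r$records
    unique(clonotype_key(rec, key))
  }
  a <- get_set(rep_a)
  b <- get_set(rep_b)
  shared <- intersect(a, b)
  uni <- union(a, b)
  list(shared = shared, n_shared = length(shared),
       jaccard = if (length(uni) == 0L) 0 else length(shared) / length(uni),
       n_a = length(a), n_b = length(b))
}

#' Three-set Venn counts of neoplastic clonotypes
#'
#' Standard inclusion-exclusion over the neoplastic clonotype sets of the
#' epidermis, dermis and blood of one sample.
#'
#' @param epi,derm,blood Character vectors (clonotype keys) or
#'   `clonotype_repertoire` objects (reduced to their neoplastic sets).
#' @param key Identity key used when repertoires are passed.
#' @return Named list of the 7 region counts (`epi_only`, `derm_only`,
#'   `blood_only`, `epi_derm`, `epi_blood`, `derm_blood`, `all_three`) plus
#'   `union_size`.
#' @export
venn_counts <- function(epi, derm, blood, key = "nt+vj") {
  as_set <- function(x) {
    if (inherits(x, "clonotype_repertoire")) {
      unique(clonotype_key(estimate_neoplastic_clonotype_count(x)$selected,
                           key))
    } else {
      unique(as.character(x))
    }
  }
  e <- as_set(epi); d <- as_set(derm); b <- as_set(blood)
  u <- union(union(e, d), b)
  ine <- u %in% e; ind <- u %in% d; inb <- u %in% b
  list(
    epi_only = sum(ine & !ind & !inb),
    derm_only = sum(!ine & ind & !inb),
    blood_only = sum(!ine & !ind & inb),
    epi_derm = sum(ine & ind & !inb),
    epi_blood = sum(ine & !ind & inb),
    derm_blood = sum(!ine & ind & inb),
    all_three = sum(ine & ind & inb),
    union_size = length(u)
  )
}

#' Per-compartment clonotype diversity summary
#'
#' Median and range of neoplastic clonotype counts per compartment, plus the
#' per-sample (TCF, count) pairs underlying TCF-versus-diversity displays.
#'
#' @param repertoires List of `clonotype_repertoire` objects.
#' @return List with `per_sample` (data.frame: sample_id, compartment, tcf,
#'   n_neoplastic, top_frequency) and `by_compartment` (data.frame: median,
#'   min, max, n_samples).
#' @export
diversity_summary <- function(repertoires) {
  if (length(repertoires) == 0L) {
    stop("empty repertoire group", call. = FALSE)
  }
  per <- do.call(rbind, lapply(repertoires, function(r) {
    est <- estimate_neoplastic_clonotype_count(r)
    data.frame(sample_id = r$sample_id, compartment = r$compartment,
               tcf = r$tcf, n_neoplastic = est$n,
               top_frequency = if (nrow(r$records)) r$records$frequency[1] else NA_real_,
               stringsAsFactors = FALSE)
  }))
  by_cp <- do.call(rbind, lapply(split(per, per$compartment), function(g) {
    data.frame(compartment = g$compartment[1], n_samples = nrow(g),
               median = median(g$n_neoplastic), min = min(g$n_neoplastic),
               max = max(g$n_neoplastic))
  }))
  rownames(by_cp) <- NULL
  list(per_sample = per, by_compartment = by_cp)
}
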