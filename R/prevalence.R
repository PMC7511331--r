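#' Cellular prevalence from VAF, purity and copy number
#'
#' Converts a variant allele fraction into the fraction of tumour cells
#' carrying the variant:
#' `phi = VAF * (TCF * CN_tumor + (1 - TCF) * 2) / (TCF * m)`,
#' where `CN_tumor` is the total tumour copy number at the locus (2 outside
#' CNA segments), the normal contamination is assumed diploid, and `m` is the
#' mutation multiplicity (1 by default; set to the major allele copy number
#' when phasing evidence warrants it). Values exceeding 1 are clipped to 1
#' with a warning.
#'
#' @param vaf Variant allele fraction(s) in `[0, 1]`.
#' @param tcf Tumor cell fraction in `(0, 1]`.
#' @param cn_tumor Total tumour copy number at the locus (default 2).
#' @param multiplicity Mutation multiplicity `m` (default 1).
#' @return Numeric vector of cellular prevalences in `[0, 1]`.
#' @export
#' @examples
#' cellular_prevalence(0.25, tcf = 0.5)        # 1.0: clonal
#' cellular_prevalence(0.5, tcf = 1.0)         # 1.0: pure-tumour het
cellular_prevalence <- function(vaf, tcf, cn_tumor = 2, multiplicity = 1) {
  if (!is.numeric(tcf) || any(is.na(tcf)) || any(tcf <= 0) || any(tcf > 1)) {
    stop("tcf must be in (0, 1]", call. = FALSE)
  }
  phi <- vaf * (tcf * cn_tumor + (1 - tcf) * 2) / (tcf * multiplicity)
  if (any(phi > 1 + 1e-6, na.rm = TRUE)) {
    warning("cellular prevalence exceeded 1 and was clipped")
  }
  pmin(pmax(phi, 0), 1)
}

# VAF-space conversion factor: expected VAF = phi * vaf_factor
vaf_factor <- function(tcf, cn_tumor = 2, multiplicity = 1) {
  tcf * multiplicity / (tcf * cn_tumor + (1 - tcf) * 2)
}

#' Cellular prevalence from allele depths
#'
#' Convenience wrapper around [cellular_prevalence()] operating on raw
#' ref/alt depths. Zero total depth is an error (the prevalence is
#' undefined).
#'
#' @param ref_depth,alt_depth Integer depths.
#' @inheritParams cellular_prevalence
#' @return Numeric vector of cellular prevalences.
#' @export
prevalence_from_depths <- function(ref_depth, alt_depth, tcf, cn_tumor = 2,
                                   multiplicity = 1) {
  depth <- ref_depth + alt_depth
  if (any(depth == 0)) {
    stop("undefined prevalence: zero total depth", call. = FALSE)
  }
  suppressWarnings(
    cellular_prevalence(alt_depth / depth, tcf, cn_tumor, multiplicity)
  )
}

# Per-variant tumour total copy number from a BED-like CNA segment table
# (start 0-based half-open), defaulting to diploid.
cn_from_segments <- function(chrom, pos, cna) {
  cn <- rep(2L, length(chrom))
  if (is.null(cna) || nrow(cna) == 0L) return(cn)
  for (s in seq_len(nrow(cna))) {
    hit <- chrom == cna$chrom[s] & pos > cna$start[s] & pos <= cna$end[s]
    cn[hit] <- cna$major_cn[s] + cna$minor_cn[s]
  }
  cn
}
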