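# V/J gene catalogs used for clone barcodes. A fixed, representative subset of
# human TRBV/TRBJ segment names; V(D)J recombination realism is out of scope.
TRBV_CATALOG <- c(
  "TRBV2", "TRBV4-1", "TRBV5-1", "TRBV6-1", "TRBV6-5", "TRBV7-2", "TRBV7-9",
  "TRBV9", "TRBV11-2", "TRBV12-3", "TRBV13", "TRBV15", "TRBV18", "TRBV19",
  "TRBV20-1", "TRBV24-1", "TRBV25-1", "TRBV27", "TRBV28", "TRBV29-1",
  "TRBV30"
)
TRBJ_CATALOG <- c(
  "TRBJ1-1", "TRBJ1-2", "TRBJ1-3", "TRBJ1-4", "TRBJ1-5", "TRBJ1-6",
  "TRBJ2-1", "TRBJ2-2", "TRBJ2-3", "TRBJ2-4", "TRBJ2-5", "TRBJ2-6",
  "TRBJ2-7"
)

random_cdr3_nt <- function(n) {
  # in-frame CDR3s: lengths multiple of 3 within [24, 60] nt
  len <- 3L * sample(8:20, n, replace = TRUE)
  vapply(len, function(l) {
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = "")
  }, character(1))
}

#' Simulate the circulating pool of malignant T-cell clones
#'
#' Generates `n_circulating_clones` distinct clone barcodes. Each barcode is a
#' CDR3 nucleotide sequence (in frame: length a multiple of 3, between 24 and
#' 60 nt) together with V and J segment labels drawn from a fixed catalog. By
#' allelic exclusion a T-cell clone carries a single productive TCRB
#' rearrangement, so the CDR3 acts as a one-per-clone molecular barcode.
#'
#' @param config A [sim_config()].
#' @return A data.frame with columns `barcode` (CDR3 nucleotide string),
#'   `cdr3_aa`, `v_gene`, `j_gene`; one row per circulating clone, all barcodes
#'   pairwise distinct.
#' @export
simulate_circulating_pool <- function(config) {
  validate_sim_config(config)
  n <- config$n_circulating_clones
  with_seed(derive_seed(config$rng_seed, "pool"), {
    barcodes <- character(0)
    while (length(barcodes) < n) {
      barcodes <- unique(c(barcodes, random_cdr3_nt(n - length(barcodes))))
    }
    data.frame(
      barcode = barcodes,
      cdr3_aa = translate_cdr3(barcodes),
      v_gene = sample(TRBV_CATALOG, n, replace = TRUE),
      j_gene = sample(TRBJ_CATALOG, n, replace = TRUE),
      stringsAsFactors = FALSE
    )
  })
}

translate_cdr3 <- function(nt) {
  as.character(Biostrings::translate(Biostrings::DNAStringSet(nt),
                                     no.init.codon = TRUE))
}

#' Seed the skin compartments from the circulating pool
#'
#' Distributes circulating clones into the dermis and the epidermis according
#' to the configured seeding model. In `independent` mode the two compartments
#' draw their clones independently, except that an expected fraction
#' `shared_clone_rate` of epidermal clones is explicitly drawn from the dermal
#' set (so the expected shared count is `shared_clone_rate * n_seeded_epidermis`
#' by construction, not by chance). In `infiltration` mode the epidermal set is
#' a uniform random subset of the dermal set, mirroring emigration of dermal
#' clones into the epidermis. The blood compartment always carries the full
#' pool.
#'
#' @param pool Data.frame from [simulate_circulating_pool()].
#' @param config A [sim_config()].
#' @return Named list of character vectors of barcodes:
#'   `epidermis`, `dermis`, `blood`.
#' @export
simulate_seeding <- function(pool, config) {
  validate_sim_config(config)
  if (nrow(pool) < max(config$n_seeded_dermis, config$n_seeded_epidermis)) {
    stop("simulation error: circulating pool smaller than a seeded compartment",
         call. = FALSE)
  }
  with_seed(derive_seed(config$rng_seed, "seeding"), {
    derm <- sample(pool$barcode, config$n_seeded_dermis)
    n_epi <- config$n_seeded_epidermis
    if (config$seeding_mode == "infiltration") {
      epi <- sample(derm, n_epi)
    } else {
      # explicit shared-draw construction: each epidermal slot is shared with
      # the dermis with probability shared_clone_rate
      n_shared <- rbinom(1L, n_epi, config$shared_clone_rate)
      n_shared <- min(n_shared, length(derm))
      shared <- if (n_shared > 0L) sample(derm, n_shared) else character(0)
      rest_pool <- setdiff(pool$barcode, derm)
      n_private <- n_epi - n_shared
      private <- if (n_private > 0L) {
        if (n_private > length(rest_pool)) {
          # pool barely larger than the compartments: overlap is unavoidable,
          # top up from dermal clones not yet picked
          c(rest_pool, sample(setdiff(derm, shared),
                              n_private - length(rest_pool)))
        } else {
          sample(rest_pool, n_private)
        }
      } else {
        character(0)
      }
      epi <- c(shared, private)
    }
    list(epidermis = epi, dermis = derm, blood = pool$barcode)
  })
}
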