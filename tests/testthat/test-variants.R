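test_that("VCF allele depths parse into per-compartment records", {
  vcf <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"g\">",
    "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"c\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "epidermis", "dermis", sep = "\t"),
    paste("chr1", "100", ".", "A", "G", ".", "PASS", "GENE=TP53;CSQ=missense",
          "AD", "40,10", "55,0", sep = "\t")
  )
  path <- tempfile(fileext = ".vcf")
  writeLines(vcf, path)
  v <- read_variant_table(path)
  epi <- v[v$compartment == "epidermis", ]
  expect_equal(epi$ref_depth, 40L)
  expect_equal(epi$alt_depth, 10L)
  expect_equal(epi$gene, "TP53")
  expect_equal(v[v$compartment == "dermis", "alt_depth"], 0L)
})

test_that("multi-allelic VCF rows split into one record per alternate", {
  vcf <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "epidermis", sep = "\t"),
    paste("chr2", "500", ".", "A", "C,T", ".", "PASS", ".",
          "AD", "30,5,12", sep = "\t")
  )
  path <- tempfile(fileext = ".vcf")
  writeLines(vcf, path)
  v <- read_variant_table(path)
  expect_equal(nrow(v), 2L)
  # by-hand decomposition: ref depth 30 for both, alts 5 and 12
  expect_equal(v$alt[order(v$alt_depth)], c("C", "T"))
  expect_equal(sort(v$alt_depth), c(5L, 12L))
  expect_equal(v$ref_depth, c(30L, 30L))
})

test_that("the VCF and TSV encodings round-trip to the same records", {
  cfg <- small_config(rng_seed = 17L)
  lesion <- simulate_lesion(cfg)
  dir <- tempfile()
  write_observed_dataset(lesion$observed, dir)
  tsv <- read_variant_table(file.path(dir, "SIM.variants.tsv"))
  vcf <- read_variant_table(file.path(dir, "SIM.variants.vcf"))
  key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt, d$compartment)
  tsv <- tsv[order(key(tsv)), ]
  vcf <- vcf[order(key(vcf)), ]
  rownames(tsv) <- rownames(vcf) <- NULL
  expect_equal(vcf[, c("chrom", "pos", "ref", "alt", "gene", "consequence",
                       "compartment", "ref_depth", "alt_depth")],
               tsv)
})

test_that("consequence classification follows the damaging rule", {
  expect_equal(classify_consequence("frameshift"), "damaging")
  expect_equal(classify_consequence("stop_gain"), "damaging")
  expect_equal(classify_consequence("stop_loss"), "damaging")
  expect_equal(classify_consequence("missense"), "missense")
  expect_equal(classify_consequence("synonymous"), "other")
  # indel length boundary: < 6 bp damaging, >= 6 bp other
  expect_equal(classify_consequence("inframe_indel", "A", "AGGG"), "damaging")
  expect_equal(classify_consequence("inframe_indel", "AGGGGGGGGG", "A"),
               "other")
  # total over the whole consequence enum
  out <- classify_consequence(skinclones:::CONSEQUENCE_LEVELS,
                              ref = rep("A", 9), alt = rep("AGGG", 9))
  expect_true(all(out %in% c("missense", "damaging", "other")))
})

test_that("non-synonymous counting applies the presence rule", {
  v <- rbind(
    variant_rows(5, 1, 1, consequence = "missense", seed = 1),
    variant_rows(3, 1, 1, consequence = "synonymous", seed = 2,
                 start_pos = 100L)
  )
  expect_equal(count_nonsynonymous(v, "dermis"), 5L)
  # a variant absent from one compartment is counted only in the other
  v2 <- variant_rows(1, 1, 1, consequence = "missense", seed = 3,
                     start_pos = 200L)
  v2$alt_depth[v2$compartment == "epidermis"] <- 0L
  expect_equal(count_nonsynonymous(v2, "epidermis"), 0L)
  expect_equal(count_nonsynonymous(v2, "dermis"), 1L)
})

test_that("non-synonymous counting equals a brute-force filter", {
  set.seed(13)
  for (i in 1:20) {
    n <- 30
    v <- variant_rows(n, runif(n), runif(n), seed = i)
    v$consequence <- sample(skinclones:::CONSEQUENCE_LEVELS, 2 * n,
                            replace = TRUE)
    for (cp in c("epidermis", "dermis")) {
      manual <- 0L
      seen <- character(0)
      for (r in seq_len(nrow(v))) {
        row <- v[r, ]
        k <- paste(row$chrom, row$pos, row$ref, row$alt)
        if (row$compartment == cp && row$alt_depth >= 1 &&
            row$consequence %in% c("missense", "frameshift", "inframe_indel",
                                   "stop_gain", "stop_loss") &&
            !(k %in% seen)) {
          manual <- manual + 1L
          seen <- c(seen, k)
        }
      }
      expect_equal(count_nonsynonymous(v, cp), manual)
    }
  }
})

test_that("mutation overlap percent uses the union and is symmetric", {
  v <- variant_rows(5, c(1, 1, 1, 0, 0), c(0, 0, 1, 1, 0), seed = 5,
                    depth = 500)
  # epi has variants 1,2,3; dermis 3,4; variant 5 in neither
  v$alt_depth[v$pos == 5] <- 0L
  ov <- compartment_mutation_overlap(v)
  expect_equal(ov$n_shared, 1L)
  expect_equal(ov$percent_overlap, 25)
  swapped <- v
  swapped$compartment <- ifelse(v$compartment == "epidermis", "dermis",
                                "epidermis")
  expect_equal(compartment_mutation_overlap(swapped)$percent_overlap, 25)
  # extremes
  vd <- variant_rows(4, c(1, 1, 0, 0), c(0, 0, 1, 1), seed = 6, depth = 500)
  expect_equal(compartment_mutation_overlap(vd)$percent_overlap, 0)
  vi <- variant_rows(4, 1, 1, seed = 7, depth = 500)
  expect_equal(compartment_mutation_overlap(vi)$percent_overlap, 100)
  empty <- variant_rows(2, 0, 0, seed = 8)
  empty$alt_depth <- 0L
  expect_error(compartment_mutation_overlap(empty), "no variants")
})

test_that("driver matrix takes the worst classification per gene", {
  v <- rbind(
    variant_rows(1, 1, 0, consequence = "missense", gene = "PLCG1", seed = 1,
                 depth = 500),
    variant_rows(1, 0, 1, consequence = "missense", gene = "STAT3", seed = 2,
                 depth = 500, start_pos = 10L),
    variant_rows(1, 0, 1, consequence = "frameshift", gene = "STAT3",
                 seed = 3, depth = 500, start_pos = 20L)
  )
  v$ref <- "A"
  v$alt <- ifelse(v$consequence == "frameshift", "AG", "G")
  dm <- driver_matrix(v, c("PLCG1", "STAT3", "TP53"))
  expect_equal(dm$matrix["PLCG1", "epidermis"], "missense")
  expect_equal(dm$matrix["PLCG1", "dermis"], "absent")
  expect_equal(dm$matrix["STAT3", "dermis"], "damaging")
  expect_equal(dm$matrix["TP53", "epidermis"], "absent")
  expect_equal(dm$counts$epi_only, 1L)
  expect_equal(dm$counts$derm_only, 1L)
  expect_equal(dm$counts$both, 0L)
})

test_that("driver matrix equals the exhaustive per-gene tabulation", {
  set.seed(23)
  genes <- c("TP53", "STAT3", "PLCG1", "NF1", "TET2")
  for (i in 1:20) {
    n <- 25
    v <- variant_rows(n, round(runif(n)), round(runif(n)), seed = 100 + i,
                      depth = 300)
    v$gene <- sample(c(genes, sprintf("BG%02d", 1:5)), 2 * n, replace = TRUE)
    v$consequence <- sample(skinclones:::CONSEQUENCE_LEVELS, 2 * n,
                            replace = TRUE)
    v$ref <- "A"
    v$alt <- ifelse(v$consequence == "inframe_indel",
                    sample(c("AGGG", "AGGGGGG"), 2 * n, replace = TRUE), "G")
    got <- driver_matrix(v, genes)$matrix
    want <- oracle_driver_matrix(v, genes)
    expect_equal(as.matrix(got), want)
  }
})
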