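write_lines_vcf <- function(lines, path = tempfile(fileext = ".vcf")) {
  writeLines(lines, path)
  path
}

minimal_vcf <- function(body, samples = c("S1", "S2", "S3")) {
  write_lines_vcf(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=1>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    body))
}

test_that("read_genotypes encodes dosage, missing and rejects multiallelics", {
  path <- minimal_vcf(c(
    "1\t100\t.\tA\tG\t.\t.\t.\tGT\t0/1\t0/0\t./.",
    "1\t200\t.\tC\tT,G\t.\t.\t.\tGT\t0/1\t1/2\t0/0",
    "chr1\t300\t.\tAT\tA\t.\t.\t.\tGT\t1/1\t0/0\t0/1"))
  vset <- read_genotypes(path, c("S1", "S2", "S3"))
  expect_equal(nrow(vset$variants), 2)                 # multiallelic rejected
  expect_equal(unname(vset$rejected["multiallelic"]), 1L)
  expect_equal(unname(vset$geno[1, ]), c(1L, 0L, NA))  # ./. is NA, not 0
  expect_equal(unname(vset$geno[2, ]), c(2L, 0L, 1L))
  expect_equal(vset$variants$chrom, c("1", "1"))       # chr prefix stripped
  expect_equal(vset$variants$key[2], "1:300:AT:A")
  # accepted + rejected = total records
  expect_equal(nrow(vset$variants) + sum(vset$rejected), 3L)
})

test_that("read_genotypes agrees with the VariantAnnotation oracle", {
  # independent reader cross-check on a small fixture (incl. a FORMAT with
  # extra keys and phased separators)
  path <- write_lines_vcf(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=1>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "S1", "S2"), collapse = "\t"),
    "1\t100\t.\tA\tG\t.\t.\t.\tGT:DP\t0|1:10\t1/1:12",
    "1\t200\t.\tC\tT\t.\t.\t.\tGT:DP\t./.:0\t0/0:9"))
  vset <- read_genotypes(path, c("S1", "S2"))
  vcf <- VariantAnnotation::readVcf(path)
  gt <- VariantAnnotation::geno(vcf)$GT
  oracle <- matrix(NA_integer_, nrow(gt), ncol(gt))
  oracle[] <- c(`0/0` = 0L, `0|1` = 1L, `1/1` = 2L, `./.` = NA)[gt]
  expect_equal(unname(vset$geno), oracle)
})

test_that("read_genotypes errors when subjects are missing from the VCF", {
  path <- minimal_vcf("1\t100\t.\tA\tG\t.\t.\t.\tGT\t0/1\t0/0\t0/0")
  expect_error(read_genotypes(path, c("S1", "S2", "S3", "S4")), "S4")
})

test_that("annotation join drops unannotated and unknown-consequence variants", {
  vset <- toy_vset(matrix(0:1, 2, 2), consequence = "missense_variant")
  anno <- data.frame(chrom = c("1", "1"), pos = c(100, 300), ref = "A",
                     alt = "G", gene = "G1", transcript = "T1",
                     consequence = c("missense_variant", "made_up"),
                     stringsAsFactors = FALSE)
  anno$aa_change <- NA_character_
  anno$key <- sprintf("%s:%d:%s:%s", anno$chrom, anno$pos, anno$ref, anno$alt)
  vset$variants[c("gene", "transcript", "consequence", "aa_change")] <- NULL
  out <- annotate_variants(vset, anno)
  expect_equal(nrow(out$variants), 1)             # pos 200 unannotated
  expect_equal(unname(out$rejected["unannotated"]), 1L)
  expect_equal(out$variants$consequence, "missense_variant")
})

test_that("read_cohort parses and validates the documented dialect", {
  tsv <- tempfile(fileext = ".tsv")
  pcs <- paste0("PC", 1:20)
  header <- c("subject_id", "sex", pcs, "self_report_migraine",
              "icd10_codes", "medication_codes")
  rows <- c(
    paste(c("A1", "female", rep("0.5", 20), "1", "G43.1;I10", ""), collapse = "\t"),
    paste(c("A2", "male", rep("-1.25", 20), "0", "", "sumatriptan"), collapse = "\t"))
  writeLines(c(paste(header, collapse = "\t"), rows), tsv)
  co <- read_cohort(tsv)
  expect_equal(co$sex, c(1, 0))
  expect_equal(co$icd10_codes[[1]], c("G43.1", "I10"))
  expect_equal(co$icd10_codes[[2]], character(0))      # empty list is valid
  expect_equal(co$medication_codes[[2]], "sumatriptan")
  expect_equal(co$PC20, c(0.5, -1.25))

  # missing PC column named in the error
  writeLines(c(paste(setdiff(header, "PC17"), collapse = "\t"),
               paste(c("A1", "female", rep("0.5", 19), "1", "", ""),
                     collapse = "\t")), tsv)
  expect_error(read_cohort(tsv), "PC17")

  # duplicated subject id named in the error
  writeLines(c(paste(header, collapse = "\t"), rows,
               rows[1]), tsv)
  expect_error(read_cohort(tsv), "A1")

  # non-numeric PC names the offending row
  bad <- paste(c("A3", "male", "oops", rep("0", 19), "0", "", ""),
               collapse = "\t")
  writeLines(c(paste(header, collapse = "\t"), rows[2], bad), tsv)
  expect_error(read_cohort(tsv), "A3")
})

test_that("fixture round trip reproduces genotypes and covariates exactly", {
  cfg <- sim_config(n_subjects = 60,
                    genes = list(sim_gene("GA", 5), sim_gene("GB", 4)),
                    missing_rate = 0.05, seed = 11)
  sim <- simulate_cohort(cfg)
  out <- tempfile()
  paths <- render_fixture(sim, out)
  co <- read_cohort(paths[["cohort"]])
  vset <- read_genotypes(paths[["vcf"]], co$subject_id)
  vset <- annotate_variants(vset, read_annotations(paths[["anno"]]))

  expect_identical(vset$geno, sim$vset$geno)
  expect_identical(vset$variants[, colnames(sim$vset$variants)],
                   sim$vset$variants)
  pcs <- grep("^PC", names(co), value = TRUE)
  expect_identical(as.matrix(co[pcs]), as.matrix(sim$cohort[pcs]))
  expect_identical(co$sex, as.numeric(sim$cohort$sex))
  expect_identical(co$icd10_codes, sim$cohort$icd10_codes)
  expect_identical(co$medication_codes, sim$cohort$medication_codes)
})

test_that("write_results renders the published table shapes", {
  out <- tempfile()
  gene <- data.frame(gene = "ATP1A2", slp = 1.5821, beta = 0.1, se = 0.05,
                     p = 0.026, n_qualifying_variants = 10,
                     score_mean_cases = 1, score_mean_controls = 0.9,
                     flag = "ok")
  var <- data.frame(gene = "CACNA1A", transcript = "ENST00000638029",
                    aa_change = "p.(Glu1018Lys)",
                    case_carriers = 88, case_n = 7194,
                    case_freq = 88 / 7194,
                    control_carriers = 2442, control_n = 193433,
                    control_freq = 2442 / 193433,
                    chi2 = 0.1, p_value = 0.7, pooled = FALSE)
  write_results(gene, NULL, var, out)
  g <- readLines(file.path(out, "gene_results.tsv"))
  expect_match(g[2], "^ATP1A2\t1\\.58\t")
  v <- readLines(file.path(out, "variant_results.tsv"))
  expect_match(v[2], "0\\.01262")             # 2442/193433 to 5 decimals
  expect_match(v[2], "0\\.01223")             # 88/7194
  cats <- readLines(file.path(out, "category_results.tsv"))
  expect_length(cats, 1)                      # empty set -> header only
})
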