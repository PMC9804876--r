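## Input/output: VCF genotypes, annotation TSV, cohort TSV, result tables.
## Internal variant key: "chrom:pos:ref:alt" with any "chr" prefix stripped,
## so GRCh38 naming dialects join consistently.

variant_key <- function(chrom, pos, ref, alt) {
  paste(sub("^chr", "", chrom), pos, ref, alt, sep = ":")
}

#' Read biallelic genotypes from a VCF file
#'
#' Reads per-subject GT fields into a minor-allele dosage matrix aligned to
#' `subject_order`. Dosage is counted against the ALT allele (0, 1, 2);
#' missing genotypes (`./.` or `.`) are kept as `NA`, distinct from 0.
#' Multiallelic records are rejected (not split) and counted in
#' `$rejected$multiallelic`; folding to the minor allele happens later in
#' the weighting step, keeping this reader deterministic.
#'
#' The GT field is parsed directly with a tabular parser whose memory
#' footprint is proportional to the file: generic VCF readers that
#' pre-allocate per-field arrays were measured to over-allocate by orders
#' of magnitude on cohort-width files (tens of thousands of sample
#' columns). Agreement with `VariantAnnotation::readVcf()` is asserted in
#' the test suite on small fixtures.
#'
#' @param vcf_path Path to a VCF (v4.x) file, plain or gzipped.
#' @param subject_order Character vector of subject ids; the VCF must
#'   contain a sample column for every one of them.
#' @return A `variant_set`: a list with `variants` (data.frame: key, chrom,
#'   pos, ref, alt), `geno` (integer matrix, variants x subjects, `NA` for
#'   missing) and `rejected` (named counts of discarded records).
#' @export
read_genotypes <- function(vcf_path, subject_order) {
  if (!file.exists(vcf_path)) stop("VCF not found: ", vcf_path)
  body <- data.table::fread(vcf_path, skip = "#CHROM", sep = "\t",
                            header = TRUE, colClasses = "character",
                            na.strings = NULL)
  cols <- names(body)
  if (length(cols) < 10 || cols[9] != "FORMAT")
    stop("VCF lacks a FORMAT column (no per-subject genotypes)")
  vcf_samples <- cols[-(1:9)]
  missing_subj <- setdiff(subject_order, vcf_samples)
  if (length(missing_subj))
    stop("subjects absent from VCF: ", paste(missing_subj, collapse = ", "))
  if (nrow(body) && !all(startsWith(body$FORMAT, "GT")))
    stop("VCF records without leading GT in FORMAT are not supported")

  multi <- grepl(",", body$ALT, fixed = TRUE)
  n_multi <- sum(multi)
  body <- body[!multi, ]

  chrom <- body[["#CHROM"]]
  pos <- as.integer(body$POS)
  ref <- body$REF
  alt <- body$ALT

  gt <- as.matrix(body[, subject_order, with = FALSE])
  # GT is the leading colon-separated field when other FORMAT keys follow
  if (any(grepl(":", gt, fixed = TRUE)))
    gt[] <- sub(":.*$", "", gt)
  geno <- gt_to_dosage(gt)

  variants <- data.frame(
    key = variant_key(chrom, pos, ref, alt),
    chrom = sub("^chr", "", chrom), pos = pos, ref = ref, alt = alt,
    stringsAsFactors = FALSE
  )
  rownames(geno) <- variants$key
  if (anyDuplicated(variants$key))
    stop("duplicated variant key(s) in VCF: ",
         paste(unique(variants$key[duplicated(variants$key)]), collapse = ", "))

  structure(
    list(variants = variants, geno = geno,
         rejected = c(multiallelic = n_multi)),
    class = "variant_set"
  )
}

## GT string matrix -> ALT dosage matrix; tolerates phased separators.
gt_to_dosage <- function(gt) {
  d <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt),
              dimnames = dimnames(gt))
  clean <- gsub("\\|", "/", gt)
  d[clean %in% c("0/0", "0")] <- 0L
  d[clean %in% c("0/1", "1/0")] <- 1L
  d[clean %in% c("1/1", "1")] <- 2L
  bad <- !(clean %in% c("0/0", "0/1", "1/0", "1/1", "0", "1", "./.", ".", ".|."))
  if (any(bad))
    stop("unparseable GT value(s): ",
         paste(utils::head(unique(gt[bad]), 5), collapse = ", "))
  d
}

#' @export
print.variant_set <- function(x, ...) {
  cat(sprintf("<variant_set> %d variants x %d subjects\n",
              nrow(x$geno), ncol(x$geno)))
  if (!is.null(x$rejected) && any(x$rejected > 0))
    cat("  rejected:", paste(names(x$rejected), x$rejected,
                             sep = "=", collapse = ", "), "\n")
  if ("gene" %in% names(x$variants))
    cat("  genes:", paste(sort(unique(x$variants$gene)), collapse = ", "), "\n")
  invisible(x)
}

#' Read a variant annotation table
#'
#' Expected TSV columns: `chrom`, `pos`, `ref`, `alt`, `gene`, `transcript`,
#' `consequence`, and optionally `aa_change` (protein-change label such as
#' `"p.(Glu492Lys)"`).
#'
#' @param path Path to the annotation TSV.
#' @return data.frame with a `key` column for joining.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("annotation table not found: ", path)
  anno <- as.data.frame(data.table::fread(path, sep = "\t",
                                          colClasses = list(character = "chrom")))
  req <- c("chrom", "pos", "ref", "alt", "gene", "transcript", "consequence")
  miss <- setdiff(req, names(anno))
  if (length(miss))
    stop("annotation table lacks column(s): ", paste(miss, collapse = ", "))
  if (!"aa_change" %in% names(anno)) anno$aa_change <- NA_character_
  anno$key <- variant_key(anno$chrom, anno$pos, anno$ref, anno$alt)
  if (anyDuplicated(anno$key))
    stop("duplicated annotation key(s): ",
         paste(unique(anno$key[duplicated(anno$key)]), collapse = ", "))
  anno
}

#' Join annotations onto a variant set
#'
#' Joining is by exact (chrom, pos, ref, alt) key. Unannotated variants and
#' variants whose consequence term is not in the weight configuration are
#' excluded and counted in `$rejected` (`unannotated`,
#' `unknown_consequence`): only annotated variants with a configured weight
#' enter the analysis.
#'
#' @param vset A `variant_set` from [read_genotypes()].
#' @param anno Annotation data.frame from [read_annotations()].
#' @param weight_config A `weight_config` defining the consequence
#'   vocabulary.
#' @return The annotated `variant_set` (gene/transcript/consequence/
#'   aa_change columns added; rejected counters updated).
#' @export
annotate_variants <- function(vset, anno,
                              weight_config = default_weight_config()) {
  stopifnot(inherits(vset, "variant_set"))
  idx <- match(vset$variants$key, anno$key)
  unann <- is.na(idx)
  v <- vset$variants[!unann, , drop = FALSE]
  a <- anno[idx[!unann], , drop = FALSE]
  v$gene <- a$gene
  v$transcript <- a$transcript
  v$consequence <- a$consequence
  v$aa_change <- a$aa_change
  known <- v$consequence %in% names(weight_config$functional_weight)
  vset$rejected <- c(vset$rejected,
                     unannotated = sum(unann),
                     unknown_consequence = sum(!known))
  vset$variants <- v[known, , drop = FALSE]
  vset$geno <- vset$geno[vset$variants$key, , drop = FALSE]
  vset
}

#' Read a cohort table
#'
#' Expected TSV columns: `subject_id`, `sex` (`female`/`male`, `F`/`M` or
#' 1/0 with 1 = female), `PC1` ... `PC<n_pcs>`, `self_report_migraine`
#' (0/1 or TRUE/FALSE), `icd10_codes` and `medication_codes`
#' (semicolon-delimited lists, empty cell = none), optional `age`.
#'
#' @param path Path to the cohort TSV.
#' @param n_pcs Number of principal-component columns required (default 20).
#' @return data.frame with numeric `sex` (1 = female), numeric PCs, logical
#'   `self_report_migraine` and list columns `icd10_codes`,
#'   `medication_codes`. Case status is assigned later by
#'   [classify_cohort()].
#' @export
read_cohort <- function(path, n_pcs = 20) {
  if (!file.exists(path)) stop("cohort table not found: ", path)
  raw <- as.data.frame(data.table::fread(path, sep = "\t", colClasses = "character",
                                         na.strings = NULL))
  req <- c("subject_id", "sex", "self_report_migraine",
           "icd10_codes", "medication_codes")
  miss <- setdiff(req, names(raw))
  if (length(miss))
    stop("cohort table lacks column(s): ", paste(miss, collapse = ", "))
  pc_cols <- paste0("PC", seq_len(n_pcs))
  miss_pc <- setdiff(pc_cols, names(raw))
  if (length(miss_pc))
    stop("cohort table lacks PC column(s): ", paste(miss_pc, collapse = ", "))
  if (anyDuplicated(raw$subject_id))
    stop("duplicated subject_id(s): ",
         paste(unique(raw$subject_id[duplicated(raw$subject_id)]), collapse = ", "))

  cohort <- data.frame(subject_id = raw$subject_id, stringsAsFactors = FALSE)
  cohort$sex <- parse_sex(raw$sex)
  for (pc in pc_cols) {
    val <- suppressWarnings(as.numeric(raw[[pc]]))
    if (anyNA(val))
      stop("non-numeric ", pc, " for subject(s): ",
           paste(raw$subject_id[is.na(val)], collapse = ", "))
    cohort[[pc]] <- val
  }
  cohort$self_report_migraine <-
    raw$self_report_migraine %in% c("1", "TRUE", "true", "T")
  cohort$icd10_codes <- split_codes(raw$icd10_codes)
  cohort$medication_codes <- split_codes(raw$medication_codes)
  if ("age" %in% names(raw))
    cohort$age <- suppressWarnings(as.numeric(raw$age))
  cohort
}

parse_sex <- function(x) {
  out <- rep(NA_real_, length(x))
  out[tolower(x) %in% c("female", "f", "1")] <- 1
  out[tolower(x) %in% c("male", "m", "0")] <- 0
  if (anyNA(out))
    stop("unparseable sex value(s): ",
         paste(utils::head(unique(x[is.na(out)]), 5), collapse = ", "))
  out
}

split_codes <- function(x) {
  lapply(strsplit(x, ";", fixed = TRUE),
         function(v) v[nzchar(trimws(v))])
}

#' Read a gene panel (JSON array of gene symbols)
#' @param path Path to a JSON file.
#' @return Character vector of gene symbols.
#' @export
read_gene_panel <- function(path) {
  if (!file.exists(path)) stop("gene panel not found: ", path)
  genes <- unlist(jsonlite::read_json(path, simplifyVector = TRUE))
  if (!length(genes)) stop("gene panel is empty")
  as.character(genes)
}

#' Read a literature-variant list
#'
#' TSV with columns `gene`, `transcript`, `aa_change` and optionally
#' `chrom`, `pos`, `ref`, `alt` for coordinate-based matching.
#'
#' @param path Path to the TSV.
#' @return data.frame (with a `key` column when coordinates are present).
#' @export
read_literature_variants <- function(path) {
  if (!file.exists(path)) stop("literature-variant list not found: ", path)
  lit <- as.data.frame(data.table::fread(path, sep = "\t"))
  req <- c("gene", "transcript", "aa_change")
  miss <- setdiff(req, names(lit))
  if (length(miss))
    stop("literature-variant list lacks column(s): ",
         paste(miss, collapse = ", "))
  if (all(c("chrom", "pos", "ref", "alt") %in% names(lit)))
    lit$key <- variant_key(lit$chrom, lit$pos, lit$ref, lit$alt)
  lit
}

#' Write the three result tables
#'
#' Writes `gene_results.tsv` (gene, SLP to 2 decimals, plus diagnostics),
#' `category_results.tsv` and `variant_results.tsv` (carrier counts with
#' frequencies rendered to 5 decimal places, as in `2442 (0.01262)`).
#' Empty result sets produce headers-only files.
#'
#' @param gene_results,category_results,variant_results data.frames as
#'   produced by [gene_burden_test()], [category_regression()] and
#'   [literature_variant_tests()]; any may be `NULL`.
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_results <- function(gene_results = NULL, category_results = NULL,
                          variant_results = NULL, out_dir) {
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)

  paths <- character(0)
  g <- empty_if_null(gene_results, c("gene", "slp", "beta", "se", "p",
                                     "n_qualifying_variants",
                                     "score_mean_cases", "score_mean_controls",
                                     "flag"))
  g$slp <- round(as.numeric(g$slp), 2)
  paths["gene"] <- file.path(out_dir, "gene_results.tsv")
  write_tsv(g, paths["gene"])

  cg <- empty_if_null(category_results,
                      c("gene", "category", "odds_ratio", "se_log_or", "slp",
                        "test_used", "occurrences"))
  paths["category"] <- file.path(out_dir, "category_results.tsv")
  write_tsv(cg, paths["category"])

  v <- empty_if_null(variant_results,
                     c("gene", "transcript", "aa_change",
                       "case_carriers", "case_n", "case_freq",
                       "control_carriers", "control_n", "control_freq",
                       "chi2", "p_value", "pooled"))
  if (nrow(v)) {
    v$case_freq <- sprintf("%.5f", as.numeric(v$case_freq))
    v$control_freq <- sprintf("%.5f", as.numeric(v$control_freq))
  }
  paths["variant"] <- file.path(out_dir, "variant_results.tsv")
  write_tsv(v, paths["variant"])
  invisible(paths)
}

empty_if_null <- function(df, cols) {
  if (is.null(df) || !nrow(df)) {
    out <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols))
    return(out)
  }
  df[, intersect(cols, names(df)), drop = FALSE]
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
}
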