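## Synthetic cohort generator.
##
## Emulates the structure of a large exome-sequenced biobank case/control
## analysis: a heavily imbalanced cohort (~3.6% cases), female excess among
## cases, a panel of genes each carrying rare variants (MAF <= 0.01) of
## mixed consequence types, 20 genotype-derived principal components, and a
## logistic liability linking weighted burden, sex and (optionally) PC1 to
## case probability. Variants are independent (no LD) with Hardy-Weinberg
## dosages; see the methods vignette for what this does and does not
## emulate.

#' Per-gene simulation settings
#'
#' @param name Gene symbol.
#' @param n_variants Number of rare variants to simulate.
#' @param consequence_probs Named probability vector over consequence
#'   terms; defaults to a mix dominated by missense with a minority of
#'   loss-of-function, splice-region, synonymous and intronic variants.
#' @param maf_shape1,maf_shape2 Beta-distribution shapes for the variant
#'   minor allele frequency, scaled onto (0, 0.01]; the default (0.5, 4)
#'   concentrates mass near zero, as observed for rare exome variants.
#' @return A list of class `sim_gene`.
#' @export
sim_gene <- function(name, n_variants = 30,
                     consequence_probs = default_consequence_probs(),
                     maf_shape1 = 0.5, maf_shape2 = 4) {
  stopifnot(is.character(name), n_variants >= 1)
  if (abs(sum(consequence_probs) - 1) > 1e-8)
    stop("consequence_probs must sum to 1")
  structure(list(name = name, n_variants = as.integer(n_variants),
                 consequence_probs = consequence_probs,
                 maf_shape1 = maf_shape1, maf_shape2 = maf_shape2),
            class = "sim_gene")
}

#' @rdname sim_gene
#' @export
default_consequence_probs <- function() {
  c(missense_variant = 0.45, synonymous_variant = 0.20,
    intron_variant = 0.15, splice_region_variant = 0.06,
    frameshift_variant = 0.06, stop_gained = 0.04,
    splice_donor_variant = 0.02, splice_acceptor_variant = 0.02)
}

default_sim_genes <- function() {
  panel <- c("ATP1A2", "CACNA1A", "CSNK1D", "KCNK18", "NOTCH3",
             "PNKD", "PRRT2", "SCN1A", "SLC1A3", "TREX1")
  lapply(panel, sim_gene)
}

#' Full parameterization of a synthetic cohort
#'
#' Defaults state the cohort structure the generator emulates: 200,627
#' subjects, target case prevalence 0.036, 55.1% female overall with a
#' female case odds ratio of 3.0 (reproducing a ~78% female share among
#' cases against ~54% among controls), a 10-gene panel of rare variants,
#' and 20 standard-normal principal components. The burden effect is null
#' by default.
#'
#' @param n_subjects Cohort size.
#' @param target_prevalence Expected case fraction; the liability
#'   intercept is solved numerically to achieve it.
#' @param female_fraction Overall female fraction.
#' @param female_case_or Case odds multiplier for females.
#' @param genes List of [sim_gene()] settings.
#' @param burden_beta Log-odds per unit of total weighted burden score
#'   (scores use the weight configuration in `weight_config` with the
#'   variants' true simulated MAFs).
#' @param category_betas Optional named log-odds per variant-allele count,
#'   by category label.
#' @param pc_effect Optional liability loading on PC1 (confounding).
#' @param n_pcs Number of principal components (default 20).
#' @param missing_rate Uniform genotype missingness rate (default 0).
#' @param indicator_probs Named probabilities (`self`, `icd`, `med`) with
#'   which each case receives each phenotype indicator; a case drawing
#'   none is assigned self-report, so classification recovers status
#'   exactly.
#' @param weight_config Weight configuration used for the true scores.
#' @param seed Integer seed (mandatory; the generator draws from a single
#'   stream in a fixed, documented order).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 200627,
                       target_prevalence = 0.036,
                       female_fraction = 0.551,
                       female_case_or = 3.0,
                       genes = default_sim_genes(),
                       burden_beta = 0,
                       category_betas = NULL,
                       pc_effect = 0,
                       n_pcs = 20,
                       missing_rate = 0,
                       indicator_probs = c(self = 0.70, icd = 0.25, med = 0.40),
                       weight_config = default_weight_config(),
                       seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_subjects >= 2,
            target_prevalence > 0, target_prevalence < 1,
            female_fraction >= 0, female_fraction <= 1,
            female_case_or > 0, n_pcs >= 0,
            missing_rate >= 0, missing_rate < 1,
            all(indicator_probs >= 0), all(indicator_probs <= 1),
            all(c("self", "icd", "med") %in% names(indicator_probs)))
  if (inherits(genes, "sim_gene")) genes <- list(genes)
  structure(
    list(n_subjects = as.integer(n_subjects),
         target_prevalence = target_prevalence,
         female_fraction = female_fraction,
         female_case_or = female_case_or,
         genes = genes, burden_beta = burden_beta,
         category_betas = category_betas, pc_effect = pc_effect,
         n_pcs = as.integer(n_pcs), missing_rate = missing_rate,
         indicator_probs = indicator_probs,
         weight_config = weight_config,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Simulate a cohort: genotypes, annotations, covariates, phenotype
#'
#' Draws, in order: sex; principal components; per gene, consequence terms,
#' true MAFs and Hardy-Weinberg dosages `Binomial(2, MAF)`; the liability
#' intercept (solved so expected prevalence equals the target); case
#' status; phenotype indicators for cases plus non-qualifying decoy codes
#' scattered over the cohort; and an optional missingness mask. The same
#' seed reproduces the same objects exactly.
#'
#' @param cfg A [sim_config()].
#' @return A list with `vset` (annotated `variant_set`), `cohort`
#'   (covariates and phenotype-source fields; run [classify_cohort()] to
#'   derive `is_case`), and `truth` (true per-variant MAFs and weights,
#'   true status, true total score, solved intercept, and the config).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_subjects
  subject_id <- sprintf("S%06d", seq_len(n))

  sex <- stats::rbinom(n, 1, cfg$female_fraction)
  pcs <- if (cfg$n_pcs > 0) {
    matrix(stats::rnorm(n * cfg$n_pcs), nrow = n,
           dimnames = list(NULL, paste0("PC", seq_len(cfg$n_pcs))))
  } else NULL

  vrows <- list(); geno_rows <- list()
  for (gi in seq_along(cfg$genes)) {
    g <- cfg$genes[[gi]]
    cons <- sample(names(g$consequence_probs), g$n_variants, replace = TRUE,
                   prob = g$consequence_probs)
    maf <- cfg$weight_config$maf_cap *
      stats::rbeta(g$n_variants, g$maf_shape1, g$maf_shape2)
    dos <- matrix(0L, nrow = g$n_variants, ncol = n)
    for (vi in seq_len(g$n_variants))
      dos[vi, ] <- stats::rbinom(n, 2, maf[vi])
    indel <- cons %in% c("frameshift_variant", "inframe_insertion",
                         "inframe_deletion")
    vrows[[gi]] <- data.frame(
      chrom = as.character(gi),
      pos = 1000L + 100L * seq_len(g$n_variants),
      ref = ifelse(indel, "AT", "A"),
      alt = ifelse(indel, "A", "G"),
      gene = g$name,
      transcript = sprintf("ENSTSIM%04d", gi),
      consequence = cons,
      aa_change = ifelse(cons == "missense_variant",
                         sprintf("p.(Sim%dVar%d)", gi, seq_len(g$n_variants)),
                         NA_character_),
      true_maf = maf,
      stringsAsFactors = FALSE
    )
    geno_rows[[gi]] <- dos
  }
  variants <- do.call(rbind, vrows)
  variants$key <- variant_key(variants$chrom, variants$pos,
                              variants$ref, variants$alt)
  geno <- do.call(rbind, geno_rows)
  rownames(geno) <- variants$key
  colnames(geno) <- subject_id

  # true weighted burden score over the whole panel, from true MAFs
  w <- assign_functional_weight(variants$consequence, cfg$weight_config) *
    maf_weight(variants$true_maf, cfg$weight_config)
  score <- drop(crossprod(geno, w))

  eta <- cfg$burden_beta * score + log(cfg$female_case_or) * sex
  if (cfg$pc_effect != 0 && cfg$n_pcs > 0)
    eta <- eta + cfg$pc_effect * pcs[, 1]
  if (!is.null(cfg$category_betas)) {
    cat_of <- variant_category(variants$consequence, cfg$weight_config)
    for (cat_k in names(cfg$category_betas)) {
      rows <- which(cat_of == cat_k)
      if (length(rows))
        eta <- eta + cfg$category_betas[[cat_k]] *
          colSums(geno[rows, , drop = FALSE])
    }
  }

  intercept <- solve_intercept(eta, cfg$target_prevalence)
  status <- stats::rbinom(n, 1, stats::plogis(intercept + eta))

  # phenotype indicators: cases draw each source independently; a case with
  # none is assigned self-report so the composite definition recovers status
  ind <- matrix(FALSE, n, 3, dimnames = list(NULL, c("self", "icd", "med")))
  n_case <- sum(status)
  if (n_case > 0) {
    draws <- matrix(stats::runif(n_case * 3), ncol = 3) <=
      matrix(cfg$indicator_probs[c("self", "icd", "med")],
             n_case, 3, byrow = TRUE)
    draws[rowSums(draws) == 0, 1] <- TRUE
    ind[status == 1, ] <- draws
  }
  icd_pool <- c("G43.0", "G43.1", "G431", "G43.9")
  med_pool <- default_medication_codes()
  decoy_icd <- c("I10", "G44.2", "J45.9", "M54.5")
  decoy_med <- c("paracetamol", "ibuprofen", "amitriptyline_generic")

  icd_codes <- replicate(n, character(0), simplify = FALSE)
  med_codes <- replicate(n, character(0), simplify = FALSE)
  case_icd <- which(ind[, "icd"])
  icd_codes[case_icd] <- as.list(sample(icd_pool, length(case_icd),
                                        replace = TRUE))
  case_med <- which(ind[, "med"])
  med_codes[case_med] <- as.list(sample(med_pool, length(case_med),
                                        replace = TRUE))
  has_decoy_icd <- stats::runif(n) < 0.25
  has_decoy_med <- stats::runif(n) < 0.15
  for (i in which(has_decoy_icd))
    icd_codes[[i]] <- c(icd_codes[[i]], sample(decoy_icd, 1))
  for (i in which(has_decoy_med))
    med_codes[[i]] <- c(med_codes[[i]], sample(decoy_med, 1))

  age <- round(stats::rnorm(n, 56.4, 8.1), 1)

  if (cfg$missing_rate > 0) {
    mask <- matrix(stats::runif(length(geno)) < cfg$missing_rate,
                   nrow = nrow(geno))
    geno[mask] <- NA_integer_
  }

  cohort <- data.frame(subject_id = subject_id, sex = sex,
                       stringsAsFactors = FALSE)
  if (!is.null(pcs)) cohort <- cbind(cohort, as.data.frame(pcs))
  cohort$self_report_migraine <- ind[, "self"]
  cohort$icd10_codes <- icd_codes
  cohort$medication_codes <- med_codes
  cohort$age <- age

  vset <- structure(
    list(variants = variants[, c("key", "chrom", "pos", "ref", "alt",
                                 "gene", "transcript", "consequence",
                                 "aa_change")],
         geno = geno, rejected = c(multiallelic = 0L)),
    class = "variant_set"
  )
  truth <- list(variants = variants, true_weight = w, score = score,
                status = status, intercept = intercept, config = cfg)
  list(vset = vset, cohort = cohort, truth = truth)
}

## Solve the liability intercept so that mean(plogis(c + eta)) hits the
## target prevalence. Monotone in c, so uniroot on a wide bracket.
solve_intercept <- function(eta, target) {
  f <- function(c0) mean(stats::plogis(c0 + eta)) - target
  lo <- -40; hi <- 40
  if (f(lo) > 0 || f(hi) < 0)
    stop("target prevalence unattainable with the configured effects")
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Write a simulated cohort to analysis-ready input files
#'
#' Emits `genotypes.vcf` (VCF v4.2, one GT column per subject),
#' `annotations.tsv`, `cohort.tsv` and `truth.tsv` in `out_dir`, in the
#' exact dialects that [read_genotypes()], [read_annotations()] and
#' [read_cohort()] consume.
#'
#' @param sim Output of [simulate_cohort()].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, named paths of the four files.
#' @export
render_fixture <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(vcf = file.path(out_dir, "genotypes.vcf"),
             anno = file.path(out_dir, "annotations.tsv"),
             cohort = file.path(out_dir, "cohort.tsv"),
             truth = file.path(out_dir, "truth.tsv"))
  write_vcf(sim$vset, paths[["vcf"]])

  anno <- sim$vset$variants[, c("chrom", "pos", "ref", "alt", "gene",
                                "transcript", "consequence", "aa_change")]
  write_tsv(anno, paths[["anno"]])

  co <- sim$cohort
  flat <- data.frame(subject_id = co$subject_id,
                     sex = ifelse(co$sex == 1, "female", "male"),
                     stringsAsFactors = FALSE)
  # 17 significant digits so doubles survive the text round trip exactly
  for (pc in grep("^PC[0-9]+$", names(co), value = TRUE))
    flat[[pc]] <- sprintf("%.17g", co[[pc]])
  flat$self_report_migraine <- as.integer(co$self_report_migraine)
  flat$icd10_codes <- vapply(co$icd10_codes, paste, "", collapse = ";")
  flat$medication_codes <- vapply(co$medication_codes, paste, "", collapse = ";")
  if ("age" %in% names(co)) flat$age <- co$age
  write_tsv(flat, paths[["cohort"]])

  truth <- sim$truth$variants
  truth$true_weight <- sim$truth$true_weight
  write_tsv(truth, paths[["truth"]])
  invisible(paths)
}

#' Write a variant set as a minimal VCF v4.2 file
#' @param vset A `variant_set`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(vset, path) {
  v <- vset$variants
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste0("##contig=<ID=", unique(v$chrom), ">"),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(vset$geno)), collapse = "\t")
  ), con)
  gt_map <- c("0/0", "0/1", "1/1")
  for (i in seq_len(nrow(v))) {
    d <- vset$geno[i, ]
    gt <- ifelse(is.na(d), "./.", gt_map[d + 1L])
    writeLines(paste(c(v$chrom[i], v$pos[i], ".", v$ref[i], v$alt[i], ".",
                       ".", ".", "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}
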