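#' Run configuration for the end-to-end pipeline
#'
#' Validation is manifest-first: every referenced file must exist before
#' any computation starts, so failures are early and attributable.
#'
#' @param vcf,annotations,cohort Paths to the three primary inputs.
#' @param genes Path to a gene-panel JSON, or a character vector of gene
#'   symbols; `NULL` tests every annotated gene.
#' @param weights Path to a weight-config JSON; `NULL` uses the default.
#' @param phenotype Path to a phenotype-config JSON; `NULL` uses the
#'   default.
#' @param literature_variants Path to a literature-variant TSV; `NULL`
#'   skips those tests.
#' @param frameshift_genes Genes for which to run the frameshift
#'   aggregation (default: none).
#' @param run_burden,run_categories,run_variants Toggles for the three
#'   test families.
#' @param out_dir Output directory.
#' @param log_level `"info"` or `"quiet"`.
#' @return A list of class `run_config`.
#' @export
run_config <- function(vcf, annotations, cohort, out_dir,
                       genes = NULL, weights = NULL, phenotype = NULL,
                       literature_variants = NULL,
                       frameshift_genes = character(0),
                       run_burden = TRUE, run_categories = TRUE,
                       run_variants = TRUE, log_level = "info") {
  cfg <- structure(
    list(vcf = vcf, annotations = annotations, cohort = cohort,
         genes = genes, weights = weights, phenotype = phenotype,
         literature_variants = literature_variants,
         frameshift_genes = frameshift_genes,
         run_burden = run_burden, run_categories = run_categories,
         run_variants = run_variants, out_dir = out_dir,
         log_level = log_level),
    class = "run_config"
  )
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  paths <- c(vcf = cfg$vcf, annotations = cfg$annotations,
             cohort = cfg$cohort)
  if (is.character(cfg$weights)) paths["weights"] <- cfg$weights
  if (is.character(cfg$phenotype)) paths["phenotype"] <- cfg$phenotype
  if (is.character(cfg$literature_variants))
    paths["literature_variants"] <- cfg$literature_variants
  if (is.character(cfg$genes) && length(cfg$genes) == 1 &&
      grepl("\\.json$", cfg$genes))
    paths["genes"] <- cfg$genes
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("input file(s) not found: ",
         paste(names(missing), missing, sep = "=", collapse = ", "))
  cfg
}

pipe_log <- function(cfg, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible())
  message("[burdenscan] ", ...)
}

#' Run the full association pipeline
#'
#' Reads and validates all inputs, derives case status, applies the
#' rare-variant filter and weights, runs the enabled test families
#' (gene-wise burden, per-gene category regression, literature-variant and
#' frameshift carrier tests), and writes the three result TSVs plus a run
#' manifest (input MD5 hashes, package version, config echo, phenotype
#' summary). Deterministic: identical inputs produce identical outputs.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list with the in-memory result tables and the
#'   manifest.
#' @export
run_pipeline <- function(cfg) {
  cfg <- validate_run_config(cfg)
  wc <- if (is.null(cfg$weights)) default_weight_config()
        else read_weight_config(cfg$weights)
  pc <- if (is.null(cfg$phenotype)) phenotype_config()
        else read_phenotype_config(cfg$phenotype)

  pipe_log(cfg, "reading cohort: ", cfg$cohort)
  cohort <- read_cohort(cfg$cohort)
  pipe_log(cfg, "reading genotypes: ", cfg$vcf)
  vset <- read_genotypes(cfg$vcf, cohort$subject_id)
  anno <- read_annotations(cfg$annotations)
  vset <- annotate_variants(vset, anno, wc)
  pipe_log(cfg, nrow(vset$variants), " annotated variants; rejected: ",
           paste(names(vset$rejected), vset$rejected, sep = "=",
                 collapse = ", "))

  cohort <- classify_cohort(cohort, pc)
  summ <- phenotype_summary(cohort)
  pipe_log(cfg, sprintf("%d cases (%.1f%% female), %d controls (%.1f%% female)",
                        summ$n_cases, summ$pct_female_cases,
                        summ$n_controls, summ$pct_female_controls))

  genes <- cfg$genes
  if (is.character(genes) && length(genes) == 1 && grepl("\\.json$", genes))
    genes <- read_gene_panel(genes)
  if (is.null(genes)) genes <- sort(unique(vset$variants$gene))

  wv <- weight_variants(vset, cohort$is_case, wc)
  pipe_log(cfg, nrow(wv$variants), " qualifying rare variants (",
           wv$n_excluded, " excluded by the MAF filter)")

  gene_results <- category_results <- variant_results <- NULL
  if (cfg$run_burden) {
    gene_results <- gene_burden_test(wv, cohort, genes = genes)
    pipe_log(cfg, "burden tests done; max |SLP| = ",
             round(max(abs(gene_results$slp)), 2))
  }
  if (cfg$run_categories) {
    category_results <- do.call(rbind, lapply(genes, function(g)
      category_regression(wv, cohort, g, wc)))
  }
  if (cfg$run_variants) {
    rows <- list()
    if (!is.null(cfg$literature_variants)) {
      lit <- read_literature_variants(cfg$literature_variants)
      rows[[1]] <- literature_variant_tests(lit, vset, cohort)
    }
    fs <- lapply(cfg$frameshift_genes, frameshift_aggregate,
                 vset = vset, cohort = cohort)
    variant_results <- do.call(rbind, c(rows, fs))
  }

  paths <- write_results(gene_results, category_results, variant_results,
                         cfg$out_dir)
  manifest <- list(
    package_version = as.character(utils::packageVersion("burdenscan")),
    inputs = as.list(tools::md5sum(c(vcf = cfg$vcf,
                                     annotations = cfg$annotations,
                                     cohort = cfg$cohort))),
    config = cfg[setdiff(names(cfg), "log_level")],
    phenotype_summary = list(
      n_cases = summ$n_cases, n_controls = summ$n_controls,
      pct_female_cases = summ$pct_female_cases,
      pct_female_controls = summ$pct_female_controls,
      breakdown = as.list(summ$breakdown)),
    rejected_variants = as.list(vset$rejected),
    n_qualifying_variants = nrow(wv$variants),
    bonferroni_p = 0.05 / length(genes)
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE,
                       digits = NA)
  pipe_log(cfg, "results written to ", cfg$out_dir)
  invisible(list(gene_results = gene_results,
                 category_results = category_results,
                 variant_results = variant_results,
                 manifest = manifest, paths = paths))
}
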