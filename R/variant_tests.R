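#' Pearson chi-squared test on a carrier-by-status 2x2 table
#'
#' One degree of freedom, no continuity correction — this is required to
#' reproduce published carrier statistics computed the same way. A table
#' with a zero margin (e.g. zero carriers in both strata) is returned as
#' `chi2 = 0, p = 1`.
#'
#' @param case_carriers,control_carriers Carrier counts (a carrier has at
#'   least one copy of the variant allele and is counted once).
#' @param case_n,control_n Stratum sizes.
#' @return list with `chi2` and `p`.
#' @examples
#' carrier_chisq(10, 7194, 196, 193433)  # chi2 ~ 0.96, p ~ 0.33
#' @export
carrier_chisq <- function(case_carriers, case_n, control_carriers, control_n) {
  if (case_n < 1 || control_n < 1)
    stop("empty stratum: case_n and control_n must be positive")
  if (case_carriers > case_n || control_carriers > control_n)
    stop("carrier count exceeds stratum size")
  if (case_carriers < 0 || control_carriers < 0)
    stop("negative carrier count")
  a <- case_carriers;    b <- case_n - case_carriers
  c_ <- control_carriers; d <- control_n - control_carriers
  n <- case_n + control_n
  margins <- c(a + b, c_ + d, a + c_, b + d)
  if (any(margins == 0)) return(list(chi2 = 0, p = 1))
  chi2 <- n * (a * d - b * c_)^2 / prod(margins)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

## carriers (dosage >= 1) of any variant in the given geno rows, per stratum;
## missing genotypes count as non-carrier; a subject is counted once.
carrier_counts <- function(geno, is_case) {
  if (is.null(dim(geno))) geno <- matrix(geno, nrow = 1)
  carrier <- colSums(geno >= 1, na.rm = TRUE) > 0
  c(cases = sum(carrier & is_case), controls = sum(carrier & !is_case))
}

variant_result_row <- function(gene, transcript, aa_change, cc, is_case,
                               pooled) {
  case_n <- sum(is_case); control_n <- sum(!is_case)
  ct <- carrier_chisq(cc[["cases"]], case_n, cc[["controls"]], control_n)
  data.frame(
    gene = gene, transcript = transcript, aa_change = aa_change,
    case_carriers = cc[["cases"]], case_n = case_n,
    case_freq = cc[["cases"]] / case_n,
    control_carriers = cc[["controls"]], control_n = control_n,
    control_freq = cc[["controls"]] / control_n,
    chi2 = ct$chi2, p_value = ct$p, pooled = pooled,
    stringsAsFactors = FALSE
  )
}

#' Contingency tests for a curated list of literature variants
#'
#' Each listed variant is resolved against the annotated records by
#' coordinate key when `chrom/pos/ref/alt` are given, otherwise by
#' gene + amino-acid change. Variants observed in at least `min_carriers`
#' subjects (total carriers across the full sample) are tested
#' individually with [carrier_chisq()]; the rarer ones are pooled per gene
#' into a single carrier count per stratum — a subject carrying more than
#' one pooled variant is counted once — and tested per gene. Listed
#' variants absent from the data count as observed-zero (they join the
#' pooled group but contribute no carriers).
#'
#' @param variant_list data.frame from [read_literature_variants()].
#' @param vset Annotated `variant_set`.
#' @param cohort Classified cohort (`is_case`).
#' @param min_carriers Individual-test threshold (default 20).
#' @return data.frame of variant results; pooled rows have
#'   `pooled = TRUE` and an `aa_change` of the form `"pooled(<k>)"`.
#' @export
literature_variant_tests <- function(variant_list, vset, cohort,
                                     min_carriers = 20) {
  stopifnot(inherits(vset, "variant_set"), "is_case" %in% names(cohort))
  is_case <- cohort$is_case
  v <- vset$variants

  idx <- if (!is.null(variant_list$key)) {
    match(variant_list$key, v$key)
  } else {
    match(paste(variant_list$gene, variant_list$aa_change),
          paste(v$gene, v$aa_change))
  }

  n_carriers <- integer(nrow(variant_list))
  cc_list <- vector("list", nrow(variant_list))
  for (i in seq_len(nrow(variant_list))) {
    if (is.na(idx[i])) {
      cc_list[[i]] <- c(cases = 0L, controls = 0L)
    } else {
      cc_list[[i]] <- carrier_counts(vset$geno[idx[i], ], is_case)
    }
    n_carriers[i] <- sum(cc_list[[i]])
  }

  single <- which(n_carriers >= min_carriers)
  rows <- lapply(single, function(i)
    variant_result_row(variant_list$gene[i], variant_list$transcript[i],
                       variant_list$aa_change[i], cc_list[[i]], is_case,
                       pooled = FALSE))

  pooled_idx <- setdiff(seq_len(nrow(variant_list)), single)
  for (g in unique(variant_list$gene[pooled_idx])) {
    members <- pooled_idx[variant_list$gene[pooled_idx] == g]
    found <- idx[members][!is.na(idx[members])]
    cc <- if (length(found)) {
      carrier_counts(vset$geno[found, , drop = FALSE], is_case)
    } else c(cases = 0L, controls = 0L)
    tx <- unique(variant_list$transcript[members])[1]
    rows[[length(rows) + 1]] <- variant_result_row(
      g, tx, sprintf("pooled(%d)", length(members)), cc, is_case,
      pooled = TRUE)
  }
  do.call(rbind, rows)
}

#' Aggregate carrier test over all frameshift variants in a gene
#'
#' Takes the union of carriers of any `frameshift_variant` in the gene
#' (overlapping carriers counted once) and tests it against case status
#' with [carrier_chisq()].
#'
#' @param gene Gene symbol.
#' @param vset Annotated `variant_set`.
#' @param cohort Classified cohort.
#' @return One-row variant-result data.frame (`aa_change =
#'   "all_frameshift"`).
#' @export
frameshift_aggregate <- function(gene, vset, cohort) {
  sel <- vset$variants$gene == gene &
    vset$variants$consequence == "frameshift_variant"
  cc <- if (any(sel)) {
    carrier_counts(vset$geno[sel, , drop = FALSE], cohort$is_case)
  } else c(cases = 0L, controls = 0L)
  tx <- unique(vset$variants$transcript[sel])
  variant_result_row(gene, if (length(tx)) tx[1] else NA_character_,
                     "all_frameshift", cc, cohort$is_case, pooled = TRUE)
}

#' Category-level regression within a gene
#'
#' Fits one joint logistic model per gene with a per-subject allele-count
#' predictor for each variant category (plus sex and principal components),
#' then reports per-category odds ratios. The p-value comes from the Wald
#' statistic when the category's variant alleles occur at least 50 times in
#' the sample; for sparser categories Fisher's exact test on the
#' carrier-by-status 2x2 table is used instead. SLPs are signed positive
#' when the mean count is higher in cases. Categories with zero
#' occurrences are omitted from the model and reported as NA rows;
#' collinear (aliased) category columns are pruned with a warning.
#'
#' @param wv A `weighted_variants` object (same rare-variant filter as the
#'   burden analysis).
#' @param cohort Classified cohort.
#' @param gene Gene symbol.
#' @param weight_config A `weight_config`; defines the full set of
#'   categories, so categories absent from the gene still appear as NA
#'   rows.
#' @param wald_min_occurrences Threshold switching Wald -> Fisher
#'   (default 50).
#' @return data.frame: `gene`, `category`, `odds_ratio`, `se_log_or`,
#'   `slp`, `test_used` (`"wald"`/`"fisher"`/`NA`), `occurrences`.
#' @export
category_regression <- function(wv, cohort, gene,
                                weight_config = default_weight_config(),
                                wald_min_occurrences = 50) {
  stopifnot(inherits(wv, "weighted_variants"))
  is_case <- cohort$is_case
  y <- as.numeric(is_case)
  sel <- wv$variants$gene == gene
  v <- wv$variants[sel, , drop = FALSE]
  geno <- wv$geno_minor[sel, , drop = FALSE]
  categories <- sort(unique(weight_config$category_of))

  counts <- matrix(0, nrow = length(y), ncol = length(categories),
                   dimnames = list(NULL, categories))
  for (k in seq_along(categories)) {
    rows <- which(v$category == categories[k])
    if (length(rows)) {
      g <- geno[rows, , drop = FALSE]
      g[is.na(g)] <- 0L
      counts[, k] <- colSums(g)
    }
  }
  occurrences <- colSums(counts)

  na_row <- function(cat, occ) data.frame(
    gene = gene, category = cat, odds_ratio = NA_real_,
    se_log_or = NA_real_, slp = NA_real_, test_used = NA_character_,
    occurrences = occ, stringsAsFactors = FALSE)

  active <- occurrences > 0
  out <- list()
  beta <- se <- setNames(rep(NA_real_, length(categories)), categories)
  if (any(active)) {
    x <- cbind(`(Intercept)` = 1, counts[, active, drop = FALSE],
               covariate_matrix(cohort))
    fit <- logit_fit(x, y)
    aliased <- names(which(is.na(fit$coef[categories[active]])))
    if (length(aliased))
      warning("collinear category count(s) pruned in ", gene, ": ",
              paste(aliased, collapse = ", "))
    beta[categories[active]] <- fit$coef[categories[active]]
    se[categories[active]] <- fit$se[categories[active]]
  }

  for (k in seq_along(categories)) {
    cat_k <- categories[k]
    if (!active[k]) { out[[k]] <- na_row(cat_k, 0); next }
    if (is.na(beta[cat_k])) { out[[k]] <- na_row(cat_k, occurrences[k]); next }
    higher_in_cases <- mean(counts[is_case, k]) > mean(counts[!is_case, k])
    if (occurrences[k] >= wald_min_occurrences) {
      p <- 2 * stats::pnorm(abs(beta[cat_k] / se[cat_k]), lower.tail = FALSE)
      test_used <- "wald"
    } else {
      carrier <- counts[, k] > 0
      tab <- matrix(c(sum(carrier & is_case), sum(!carrier & is_case),
                      sum(carrier & !is_case), sum(!carrier & !is_case)),
                    nrow = 2)
      p <- stats::fisher.test(tab)$p.value
      test_used <- "fisher"
    }
    out[[k]] <- data.frame(
      gene = gene, category = cat_k, odds_ratio = exp(beta[cat_k]),
      se_log_or = se[cat_k],
      slp = if (p >= 1) 0 else slp_from_p(p, higher_in_cases),
      test_used = test_used, occurrences = occurrences[k],
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
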