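#' Stratified minor allele frequencies for each variant
#'
#' The allele frequency in a stratum is (sum of dosages) / (2 x non-missing
#' subjects), folded to the minor allele as `min(f, 1 - f)`. Frequencies are
#' computed in cases, in controls, and in the full sample; folding is
#' decided per stratum on the raw ALT frequency.
#'
#' @param vset An annotated `variant_set`.
#' @param is_case Logical vector, one entry per subject (cohort order).
#' @return data.frame with `key`, `maf_cases`, `maf_controls`,
#'   `maf_overall`, and `alt_is_minor` (TRUE when the ALT allele is the
#'   minor allele in the full sample).
#' @export
compute_mafs <- function(vset, is_case) {
  stopifnot(inherits(vset, "variant_set"))
  if (length(is_case) != ncol(vset$geno))
    stop("is_case length (", length(is_case),
         ") does not match cohort size (", ncol(vset$geno), ")")
  f_case <- alt_freq(vset$geno[, is_case, drop = FALSE], "cases")
  f_ctrl <- alt_freq(vset$geno[, !is_case, drop = FALSE], "controls")
  f_all <- alt_freq(vset$geno, "full sample")
  data.frame(
    key = vset$variants$key,
    maf_cases = pmin(f_case, 1 - f_case),
    maf_controls = pmin(f_ctrl, 1 - f_ctrl),
    maf_overall = pmin(f_all, 1 - f_all),
    alt_is_minor = f_all <= 0.5,
    stringsAsFactors = FALSE
  )
}

alt_freq <- function(geno, stratum) {
  n_obs <- rowSums(!is.na(geno))
  if (any(n_obs == 0))
    stop("variant(s) with zero non-missing genotypes in ", stratum)
  rowSums(geno, na.rm = TRUE) / (2 * n_obs)
}

#' Weight qualifying rare variants
#'
#' Applies the rare-variant inclusion filter (minor allele frequency at or
#' below `maf_cap` in cases AND in controls), then assigns each retained
#' variant `overall_weight = functional_weight x maf_weight`. The
#' functional weight comes from the consequence term; the MAF weight is
#' computed from the full-sample MAF (the filter is stratified, the weight
#' is not). Genotypes are re-expressed as minor-allele dosage, so for the
#' (rare) case where the ALT allele is the major allele the dosage is
#' flipped to `2 - dosage`.
#'
#' @param vset An annotated `variant_set`.
#' @param is_case Logical vector per subject.
#' @param weight_config A `weight_config`.
#' @return A list of class `weighted_variants`: `variants` (annotation plus
#'   maf/weight columns for the included variants), `geno_minor` (minor
#'   dosage matrix for included variants), `n_excluded` (variants failing
#'   the MAF filter).
#' @export
weight_variants <- function(vset, is_case,
                            weight_config = default_weight_config()) {
  mafs <- compute_mafs(vset, is_case)
  keep <- mafs$maf_cases <= weight_config$maf_cap &
    mafs$maf_controls <= weight_config$maf_cap
  v <- cbind(vset$variants[keep, , drop = FALSE],
             mafs[keep, c("maf_cases", "maf_controls", "maf_overall"),
                  drop = FALSE])
  v$category <- variant_category(v$consequence, weight_config)
  v$functional_weight <- assign_functional_weight(v$consequence, weight_config)
  v$maf_weight <- maf_weight(v$maf_overall, weight_config)
  v$overall_weight <- v$functional_weight * v$maf_weight

  geno <- vset$geno[keep, , drop = FALSE]
  flip <- !mafs$alt_is_minor[keep]
  if (any(flip))
    geno[flip, ] <- 2L - geno[flip, , drop = FALSE]

  structure(
    list(variants = v, geno_minor = geno, n_excluded = sum(!keep)),
    class = "weighted_variants"
  )
}

#' @export
print.weighted_variants <- function(x, ...) {
  cat(sprintf("<weighted_variants> %d qualifying variants (%d excluded by MAF filter)\n",
              nrow(x$variants), x$n_excluded))
  invisible(x)
}
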