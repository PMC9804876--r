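#' Per-subject weighted burden scores
#'
#' For each subject, sums `minor-allele dosage x overall_weight` over the
#' qualifying variants (optionally restricted to one gene). Missing
#' genotypes contribute 0, so every subject keeps a score and the sample
#' size is the same for every gene.
#'
#' @param wv A `weighted_variants` object from [weight_variants()].
#' @param gene Optional gene symbol to restrict to.
#' @return Named numeric vector of non-negative scores, one per subject.
#' @examples
#' # a het carrier of one missense variant at MAF exactly 0.01 scores
#' # 1 x 5 x 1 = 5; a hom carrier scores 10
#' @export
burden_scores <- function(wv, gene = NULL) {
  stopifnot(inherits(wv, "weighted_variants"))
  sel <- if (is.null(gene)) rep(TRUE, nrow(wv$variants)) else wv$variants$gene == gene
  g <- wv$geno_minor[sel, , drop = FALSE]
  w <- wv$variants$overall_weight[sel]
  if (!nrow(g)) return(setNames(numeric(ncol(wv$geno_minor)),
                                colnames(wv$geno_minor)))
  g[is.na(g)] <- 0L
  drop(crossprod(g, w))[seq_len(ncol(g))] |>
    setNames(colnames(g))
}

#' Signed log10 p-value
#'
#' `SLP = -log10(p)`, given a positive sign when the burden (or count) is
#' higher in cases and a negative sign when higher in controls.
#'
#' @param p p-value in (0, 1].
#' @param higher_in_cases Logical sign indicator.
#' @return Signed log p-value.
#' @examples
#' slp_from_p(0.026, TRUE)   # +1.585
#' slp_from_p(0.33, FALSE)   # -0.481
#' @export
slp_from_p <- function(p, higher_in_cases) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("p must lie in (0, 1]")
  ifelse(higher_in_cases, 1, -1) * (-log10(p))
}

#' Invert an SLP back to its two-sided p-value
#' @param slp Signed log10 p-value.
#' @return `10^(-|slp|)`.
#' @examples
#' p_from_slp(1.58)  # 0.0263
#' @export
p_from_slp <- function(slp) 10^(-abs(slp))

#' Logistic burden test for one score vector
#'
#' Fits a maximum-likelihood logistic regression of case status on
#' `[score, sex, PC...]` (all `PC<k>` columns present in the cohort are
#' used) and tests the score coefficient with a 1-df likelihood-ratio test;
#' a Wald p-value is also reported for diagnostics. The result is
#' summarised as `SLP = sign(beta) x (-log10 p)` — positive when the
#' adjusted score is higher in cases.
#'
#' Degenerate inputs (constant score, or a score aliased with the
#' covariates) yield SLP 0 with `flag = "degenerate"`. Apparent complete
#' separation or non-convergence is flagged, not dropped.
#'
#' @param scores Numeric score vector, one per subject (cohort order).
#' @param cohort Classified cohort data.frame (`is_case`, `sex`, PCs).
#' @param gene Gene label carried into the result.
#' @param n_qualifying_variants Count carried into the result.
#' @return One-row data.frame: `gene`, `slp`, `beta`, `se`, `p`, `p_wald`,
#'   `n_qualifying_variants`, `score_mean_cases`, `score_mean_controls`,
#'   `flag`.
#' @export
fit_burden_model <- function(scores, cohort, gene = "gene",
                             n_qualifying_variants = NA_integer_) {
  stopifnot("is_case" %in% names(cohort))
  y <- as.numeric(cohort$is_case)
  if (length(scores) != length(y))
    stop("scores length does not match cohort size")
  if (!any(y == 1) || !any(y == 0))
    stop("need at least one case and one control")

  res <- data.frame(
    gene = gene, slp = 0, beta = NA_real_, se = NA_real_,
    p = NA_real_, p_wald = NA_real_,
    n_qualifying_variants = n_qualifying_variants,
    score_mean_cases = mean(scores[y == 1]),
    score_mean_controls = mean(scores[y == 0]),
    flag = "ok", stringsAsFactors = FALSE
  )
  if (stats::var(scores) == 0) {
    res$flag <- "degenerate"
    return(res)
  }

  covs <- covariate_matrix(cohort)
  x_null <- cbind(`(Intercept)` = 1, covs)
  x_full <- cbind(`(Intercept)` = 1, score = scores, covs)
  fit_full <- logit_fit(x_full, y)
  fit_null <- logit_fit(x_null, y)

  beta <- fit_full$coef["score"]
  if (is.na(beta)) {      # score aliased with covariates
    res$flag <- "degenerate"
    return(res)
  }
  lrt <- max(fit_null$deviance - fit_full$deviance, 0)
  p <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  res$beta <- beta
  res$se <- fit_full$se["score"]
  res$p <- p
  res$p_wald <- 2 * stats::pnorm(abs(beta / res$se), lower.tail = FALSE)
  res$slp <- if (p >= 1 || beta == 0) 0 else
    slp_from_p(p, higher_in_cases = beta > 0)
  if (!fit_full$converged) res$flag <- "nonconverged"
  else if (abs(beta) > 15) res$flag <- "separation_suspect"
  res
}

## sex + PC columns, zero-variance columns dropped (e.g. single-sex cohorts)
covariate_matrix <- function(cohort) {
  pc_cols <- grep("^PC[0-9]+$", names(cohort), value = TRUE)
  covs <- as.matrix(cohort[, c(intersect("sex", names(cohort)), pc_cols),
                           drop = FALSE])
  keep <- apply(covs, 2, function(v) stats::var(v) > 0)
  covs[, keep, drop = FALSE]
}

## IRLS logistic fit on an explicit design matrix; aliased columns get NA.
logit_fit <- function(x, y, maxit = 50) {
  fit <- suppressWarnings(
    stats::glm.fit(x, y, family = stats::binomial(), control = stats::glm.control(maxit = maxit))
  )
  coefs <- fit$coefficients
  se <- rep(NA_real_, length(coefs))
  names(se) <- names(coefs)
  ok <- !is.na(coefs)
  if (any(ok)) {
    w <- fit$weights
    xw <- x[, ok, drop = FALSE] * sqrt(w)
    xtx <- crossprod(xw)
    cov <- tryCatch(chol2inv(chol(xtx)), error = function(e) NULL)
    if (!is.null(cov)) se[ok] <- sqrt(diag(cov))
  }
  list(coef = coefs, se = se, deviance = fit$deviance,
       converged = fit$converged, fitted = fit$fitted.values)
}

#' Gene-wise weighted burden analysis
#'
#' Runs [burden_scores()] + [fit_burden_model()] for each gene in a panel
#' and returns one row per gene, ordered by gene symbol. The Bonferroni
#' p-value threshold for the panel size is attached as attribute
#' `bonferroni_p` (no correction is applied to the SLPs themselves).
#'
#' @param wv A `weighted_variants` object.
#' @param cohort Classified cohort.
#' @param genes Character vector of genes to test; defaults to every gene
#'   present among the qualifying variants.
#' @return data.frame of gene results (see [fit_burden_model()]).
#' @export
gene_burden_test <- function(wv, cohort, genes = NULL) {
  if (is.null(genes)) genes <- sort(unique(wv$variants$gene))
  rows <- lapply(genes, function(g) {
    fit_burden_model(burden_scores(wv, gene = g), cohort, gene = g,
                     n_qualifying_variants = sum(wv$variants$gene == g))
  })
  out <- do.call(rbind, rows)
  attr(out, "bonferroni_p") <- 0.05 / length(genes)
  out
}
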