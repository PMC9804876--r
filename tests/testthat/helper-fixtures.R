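# In-code fixture builders shared across test files.

# Cohort with explicit case status; n_pcs standard-normal PCs.
toy_cohort <- function(status, sex = NULL, n_pcs = 2, seed = 1) {
  n <- length(status)
  set.seed(seed)
  co <- data.frame(subject_id = sprintf("S%04d", seq_len(n)),
                   sex = if (is.null(sex)) stats::rbinom(n, 1, 0.5) else sex,
                   stringsAsFactors = FALSE)
  for (k in seq_len(n_pcs)) co[[paste0("PC", k)]] <- stats::rnorm(n)
  co$is_case <- as.logical(status)
  co
}

# Annotated variant_set from a dosage matrix (variants x subjects).
toy_vset <- function(geno, consequence, gene = "G1",
                     transcript = "ENST0001", aa_change = NA) {
  geno <- as.matrix(geno)
  nv <- nrow(geno)
  variants <- data.frame(
    key = sprintf("1:%d:A:G", 100 * seq_len(nv)),
    chrom = "1", pos = 100 * seq_len(nv), ref = "A", alt = "G",
    gene = rep_len(gene, nv), transcript = rep_len(transcript, nv),
    consequence = rep_len(consequence, nv),
    aa_change = rep_len(aa_change, nv),
    stringsAsFactors = FALSE
  )
  rownames(geno) <- variants$key
  colnames(geno) <- sprintf("S%04d", seq_len(ncol(geno)))
  structure(list(variants = variants, geno = geno,
                 rejected = c(multiallelic = 0L)),
            class = "variant_set")
}

# One simulate+analyse Monte-Carlo replicate for the burden test.
# Uses the simulator's true status directly (classification is proven
# discordance-free elsewhere) to keep replicate loops fast.
burden_mc_rep <- function(n, seed, burden_beta = 0, n_variants = 10,
                          consequence = "synonymous_variant") {
  cfg <- sim_config(
    n_subjects = n,
    genes = list(sim_gene("G1", n_variants = n_variants,
                          consequence_probs = stats::setNames(1, consequence))),
    burden_beta = burden_beta, seed = seed)
  sim <- simulate_cohort(cfg)
  cohort <- sim$cohort
  cohort$is_case <- sim$truth$status == 1
  wv <- weight_variants(sim$vset, cohort$is_case)
  fit_burden_model(burden_scores(wv, "G1"), cohort, "G1",
                   n_qualifying_variants = nrow(wv$variants))
}

# Independent maximum-likelihood oracle: direct optimisation of the
# Bernoulli log-likelihood with analytic gradient (no IRLS).
oracle_logistic_deviance <- function(x, y) {
  nll <- function(b) {
    eta <- drop(x %*% b)
    -sum(y * eta - log1p(exp(eta)))
  }
  grad <- function(b) {
    eta <- drop(x %*% b)
    -drop(crossprod(x, y - stats::plogis(eta)))
  }
  fit <- stats::optim(rep(0, ncol(x)), nll, grad, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-16))
  2 * fit$value   # deviance up to the saturated-model constant (0 here)
}
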