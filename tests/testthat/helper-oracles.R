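# Independent oracles and small fixture builders shared across tests.

# 1:1 conditional likelihood oracle: logistic regression with no intercept
# on within-pair covariate differences, all responses 1.  Independent of the
# package's Newton solver.
oracle_conditional <- function(diffs) {
  diffs <- as.matrix(diffs)
  dat <- as.data.frame(diffs)
  dat$y <- 1
  fit <- suppressWarnings(
    glm(y ~ . - 1, data = dat, family = binomial()))
  unname(coef(fit))
}

# Minimal association-table builder in the package's summary-stat dialect.
make_assoc <- function(snp_id, effect_allele, other_allele, beta, se,
                       eaf = 0.3, pval = 2 * pnorm(-abs(beta / se)),
                       n = 1000L) {
  out <- data.frame(snp_id = snp_id, effect_allele = effect_allele,
                    other_allele = other_allele, eaf = eaf, beta = beta,
                    se = se, pval = pval, n = n, stringsAsFactors = FALSE)
  class(out) <- c("assoc_table", "data.frame")
  out
}

# Harmonized-instrument frame for MR estimator tests (already aligned).
make_harmonized <- function(beta_gp, se_gp, beta_gd, se_gd,
                            snp_id = sprintf("rs%03d", seq_along(beta_gp))) {
  out <- data.frame(snp_id = snp_id, effect_allele = "A",
                    other_allele = "G", beta_gp = beta_gp, se_gp = se_gp,
                    beta_gd = beta_gd, se_gd = se_gd,
                    eaf_exposure = 0.3, eaf_outcome = 0.3,
                    palindromic = FALSE, action = "kept",
                    stringsAsFactors = FALSE)
  class(out) <- c("harmonized", "data.frame")
  out
}

# Hand-made cohort object for matched-pair edge cases.
make_toy_cohort <- function(disease, confounder,
                            smoking_group = NULL,
                            methylation = NULL, n_pairs = 10L) {
  n <- length(disease)
  if (is.null(methylation)) methylation <- seq(0.2, 0.8, length.out = n)
  if (is.null(smoking_group))
    smoking_group <- factor(rep(c("never", "former", "current"),
                                length.out = n))
  structure(list(
    genotypes = matrix(1L, n, 1L, dimnames = list(NULL, "rs001")),
    alleles = data.frame(snp_id = "rs001", effect_allele = "A",
                         other_allele = "G"),
    confounder = confounder, smoking_group = smoking_group,
    mvalue = qlogis(methylation) / log(2), methylation = methylation,
    disease = as.integer(disease),
    config = sim_config(n_individuals = max(n, 2L * n_pairs),
                        n_pairs = n_pairs, n_snps = 1L)),
    class = "cohort")
}

# Synthetic cell-type methylation reference (CpGs x cell types).
make_cell_reference <- function(n_probes = 40L, n_types = 3L, seed = 11L) {
  set.seed(seed)
  ref <- matrix(runif(n_probes * n_types, 0.05, 0.95), n_probes, n_types)
  dimnames(ref) <- list(paste0("cg", seq_len(n_probes)),
                        paste0("cell", seq_len(n_types)))
  ref
}

# quick p-value of a simple linear association (oracle-side convenience)
assoc_p <- function(y, x) stats::cor.test(x, y)$p.value
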