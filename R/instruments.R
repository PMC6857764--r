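#' Greedy LD pruning of candidate mQTLs
#'
#' Retains approximately independent SNPs: candidates are visited in
#' ascending p-value order (ties broken lexicographically by SNP id for
#' determinism) and a candidate is dropped if its LD r-squared with any
#' already-retained SNP is at or above the threshold.
#'
#' @param pvals Named numeric vector of candidate p-values (names = SNP
#'   ids), or a data frame with `snp_id` and `pval` columns.
#' @param ld_r2 Square symmetric LD r-squared matrix with unit diagonal and
#'   SNP ids as dimnames, covering all candidates.
#' @param threshold Independence threshold on r-squared (default 0.01).
#' @return Character vector of retained SNP ids.
#' @export
ld_prune <- function(pvals, ld_r2, threshold = 0.01) {
  if (is.data.frame(pvals))
    pvals <- setNames(pvals$pval, pvals$snp_id)
  ids <- names(pvals)
  if (is.null(ids)) stop("candidates must be named by snp_id")
  if (is.null(dimnames(ld_r2)) || !all(ids %in% rownames(ld_r2)) ||
      !all(ids %in% colnames(ld_r2)))
    stop("LD matrix is missing entries for some candidates")
  ld <- as.matrix(ld_r2)[ids, ids, drop = FALSE]
  if (any(abs(ld - t(ld)) > 1e-8)) stop("LD matrix must be symmetric")
  ord <- ids[order(pvals, ids)]
  keep <- character(0)
  for (s in ord) {
    if (!length(keep) || all(ld[s, keep] < threshold))
      keep <- c(keep, s)
  }
  keep
}

#' Instrument strength: variance explained and F statistic
#'
#' For an exposure in SD units, `t = beta/se` gives
#' `r2 = t^2 / (t^2 + n - 2)` and `F = r2 (n-2) / (1 - r2) = t^2`.
#' This t-statistic identity is robust to scaling conventions; the
#' allele-frequency route `r2 = 2 maf (1-maf) beta^2` is available via
#' [r2_from_beta_maf()].
#'
#' @param beta,se mQTL effect and standard error (exposure in SD units).
#' @param n Sample size (> 2).
#' @return Data frame with columns `r2` and `F`.
#' @export
instrument_strength <- function(beta, se, n) {
  if (any(se <= 0)) stop("se must be positive")
  if (any(n <= 2)) stop("n must exceed 2")
  t2 <- (beta / se)^2
  data.frame(r2 = t2 / (t2 + n - 2), F = t2)
}

#' @rdname instrument_strength
#' @param maf Effect-allele frequency.
#' @export
r2_from_beta_maf <- function(beta, maf) 2 * maf * (1 - maf) * beta^2

#' F statistic from variance explained
#'
#' `F = r2 (n - 2) / (1 - r2)`; inverse of the [instrument_strength()]
#' identity, useful for reproducing strength metrics from published r2.
#'
#' @param r2 Variance in the exposure explained by the instrument, in
#'   \[0, 1).
#' @param n Sample size.
#' @return F statistic.
#' @export
f_from_r2 <- function(r2, n) {
  if (any(r2 < 0 | r2 >= 1)) stop("r2 must lie in [0, 1)")
  r2 * (n - 2) / (1 - r2)
}

#' Assemble an instrument set for one CpG
#'
#' Takes candidate mQTL summary statistics, prunes them to approximate
#' linkage independence, attaches strength metrics and flags cis status
#' (SNP within a window of the CpG).  Trans SNPs are excluded unless
#' explicitly admitted.
#'
#' @param cpg_id CpG identifier.
#' @param assoc `assoc_table` of SNP-methylation associations (exposure in
#'   SD units) with columns `snp_id`, `effect_allele`, `other_allele`,
#'   `beta`, `se`, `pval`, `n`.
#' @param ld_r2 LD matrix for [ld_prune()]; `NULL` treats candidates as
#'   independent.
#' @param snp_pos,cpg_pos Optional base-pair positions used for the cis
#'   flag (`|pos_SNP - pos_CpG| <= cis_window`, 1-based inclusive).
#' @param cis_window Cis window in base pairs (default 1 Mb).
#' @param allow_trans Admit SNPs outside the cis window (default `FALSE`).
#' @param ld_threshold Pruning threshold (default 0.01).
#' @return An `instrument_set` data frame: `cpg_id`, `snp_id`,
#'   `effect_allele`, `other_allele`, `beta_gp`, `se_gp`, `pval`, `n`,
#'   `r2`, `F`, `cis`, `replicated` (initialized `"untested"`).
#' @export
instrument_set <- function(cpg_id, assoc, ld_r2 = NULL, snp_pos = NULL,
                           cpg_pos = NULL, cis_window = 1e6,
                           allow_trans = FALSE, ld_threshold = 0.01) {
  assoc <- assoc[!is.na(assoc$beta), , drop = FALSE]
  if (!nrow(assoc)) stop("no usable candidate mQTLs")
  keep <- if (is.null(ld_r2)) {
    assoc$snp_id
  } else ld_prune(setNames(assoc$pval, assoc$snp_id), ld_r2, ld_threshold)
  assoc <- assoc[match(keep, assoc$snp_id), , drop = FALSE]
  cis <- rep(TRUE, nrow(assoc))
  if (!is.null(snp_pos) && !is.null(cpg_pos)) {
    pos <- snp_pos[assoc$snp_id]
    cis <- abs(pos - cpg_pos) <= cis_window
  }
  if (!allow_trans) {
    assoc <- assoc[cis, , drop = FALSE]
    cis <- cis[cis]
    if (!nrow(assoc)) stop("no cis mQTLs within the window")
  }
  st <- instrument_strength(assoc$beta, assoc$se, assoc$n)
  out <- data.frame(cpg_id = cpg_id, snp_id = assoc$snp_id,
                    effect_allele = assoc$effect_allele,
                    other_allele = assoc$other_allele,
                    beta_gp = assoc$beta, se_gp = assoc$se,
                    pval = assoc$pval, n = assoc$n,
                    r2 = st$r2, F = st$F, cis = cis,
                    replicated = "untested", stringsAsFactors = FALSE)
  class(out) <- c("instrument_set", "data.frame")
  out
}

#' Flag instrument replication in an independent sample
#'
#' An mQTL replicates when its association in the replication set is below
#' the FDR threshold (Benjamini-Hochberg within the replication set) *and*
#' the direction of effect is concordant with the primary estimate.
#' Pairs absent from the replication table stay `"untested"`.
#'
#' @param instruments An [instrument_set()] data frame.
#' @param replication Data frame keyed on (`snp_id`, `cpg_id`) with `beta`
#'   and `pval` columns from the replication cohort.
#' @param fdr_threshold Replication FDR threshold (default 0.05).
#' @return The instrument set with `replicated` set to `"replicated"`,
#'   `"not_replicated"` or `"untested"`.
#' @export
replicate_instruments <- function(instruments, replication,
                                  fdr_threshold = 0.05) {
  if (!nrow(replication)) return(instruments)
  if (is.null(replication$cpg_id))
    replication$cpg_id <- instruments$cpg_id[1L]
  replication$fdr <- bh_fdr(replication$pval)
  key_i <- paste(instruments$snp_id, instruments$cpg_id)
  key_r <- paste(replication$snp_id, replication$cpg_id)
  m <- match(key_i, key_r)
  hit <- !is.na(m)
  ok <- replication$fdr[m[hit]] < fdr_threshold &
    sign(replication$beta[m[hit]]) == sign(instruments$beta_gp[hit])
  instruments$replicated[hit] <- ifelse(ok, "replicated", "not_replicated")
  instruments
}

#' Scan instruments against behaviour-trait GWAS summary statistics
#'
#' Checks whether instrument SNPs are associated with potentially
#' confounding behavioural traits (e.g. cigarettes per day, smoking
#' initiation) using summary-level trait tables.  FDR is controlled across
#' the whole SNP x trait scan; nominal hits (p < 0.05 but FDR above
#' threshold) are distinguished from significant ones.
#'
#' @param snps Character vector of instrument SNP ids.
#' @param trait_tables Named list of data frames keyed by `snp_id` with
#'   `beta`, `se`, `pval` columns (one table per trait).
#' @param fdr_threshold Significance threshold on the scan-wide FDR.
#' @return Data frame with one row per SNP x trait: `snp_id`, `trait`,
#'   `beta`, `se`, `pval`, `fdr`, `class` in
#'   `{"significant", "nominal", "none", "untested"}`.
#' @export
confounder_scan <- function(snps, trait_tables, fdr_threshold = 0.05) {
  if (is.null(names(trait_tables)) && length(trait_tables))
    names(trait_tables) <- paste0("trait", seq_along(trait_tables))
  rows <- lapply(names(trait_tables), function(tr) {
    tab <- trait_tables[[tr]]
    m <- if (nrow(tab)) match(snps, tab$snp_id) else
      rep(NA_integer_, length(snps))
    data.frame(snp_id = snps, trait = tr,
               beta = ifelse(is.na(m), NA_real_, tab$beta[m]),
               se = ifelse(is.na(m), NA_real_, tab$se[m]),
               pval = ifelse(is.na(m), NA_real_, tab$pval[m]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame())
  out$fdr <- bh_fdr(out$pval)
  out$class <- ifelse(is.na(out$pval), "untested",
                      ifelse(out$fdr < fdr_threshold, "significant",
                             ifelse(out$pval < 0.05, "nominal", "none")))
  out
}
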