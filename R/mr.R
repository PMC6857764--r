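.complement <- c(A = "T", T = "A", C = "G", G = "C")

.is_palindromic <- function(a1, a2) .complement[a1] == a2

.mr_row <- function(method, estimate, se, n_instruments,
                    Q = NA_real_, Q_df = NA_integer_, Q_pval = NA_real_,
                    egger_intercept = NA_real_,
                    egger_intercept_se = NA_real_) {
  pval <- if (is.finite(se) && se > 0) 2 * pnorm(-abs(estimate / se)) else
    ifelse(estimate == 0, 1, 0)
  out <- data.frame(method = method, estimate = estimate, se = se,
                    ci_lo = estimate - 1.96 * se,
                    ci_hi = estimate + 1.96 * se,
                    pval = pval, n_instruments = n_instruments,
                    Q = Q, Q_df = Q_df, Q_pval = Q_pval,
                    egger_intercept = egger_intercept,
                    egger_intercept_se = egger_intercept_se,
                    stringsAsFactors = FALSE)
  class(out) <- c("mr_result", "data.frame")
  out
}

#' @export
print.mr_result <- function(x, digits = 3, ...) {
  for (i in seq_len(nrow(x))) {
    cat(sprintf(
      "MR (%s, %d instrument%s): OR per SD = %.*f (95%% CI %.*f, %.*f), p = %.3g\n",
      x$method[i], x$n_instruments[i],
      if (x$n_instruments[i] == 1) "" else "s",
      digits, exp(x$estimate[i]), digits, exp(x$ci_lo[i]),
      digits, exp(x$ci_hi[i]), x$pval[i]))
    if (!is.na(x$Q[i]))
      cat(sprintf("  heterogeneity: Q = %.3f (df %d, p = %.3g)\n",
                  x$Q[i], x$Q_df[i], x$Q_pval[i]))
    if (!is.na(x$egger_intercept[i]))
      cat(sprintf("  Egger intercept = %.4f (se %.4f)\n",
                  x$egger_intercept[i], x$egger_intercept_se[i]))
  }
  invisible(x)
}

#' Harmonize exposure and outcome summary statistics
#'
#' Expresses the SNP-exposure (beta_GP) and SNP-outcome (beta_GD) effects
#' for a shared effect allele.  When the outcome's effect allele is the
#' exposure's other allele the outcome effect sign is flipped (and its
#' frequency complemented); strand flips are resolved through base
#' complements; palindromic SNPs (A/T, C/G) whose effect-allele frequency
#' on either side lies in (0.42, 0.58) are dropped as strand-ambiguous,
#' otherwise allele frequency is used to orient them.  Every action is
#' recorded.
#'
#' @param exposure,outcome `assoc_table` data frames (see
#'   [export_summary_stats()] / [read_summary_stats()]) sharing `snp_id`.
#' @param ambiguous_eaf_range Frequency window in which a palindromic SNP
#'   is considered unresolvable (default `c(0.42, 0.58)`).
#' @return A `harmonized` data frame: `snp_id`, `effect_allele`,
#'   `other_allele`, `beta_gp`, `se_gp`, `beta_gd`, `se_gd`,
#'   `eaf_exposure`, `eaf_outcome`, `palindromic`, `action`.  Dropped SNPs
#'   and their reasons are in `attr(, "dropped")`.
#' @export
harmonize <- function(exposure, outcome,
                      ambiguous_eaf_range = c(0.42, 0.58)) {
  shared <- intersect(exposure$snp_id, outcome$snp_id)
  if (!length(shared)) stop("no shared snp_ids to harmonize")
  ex <- exposure[match(shared, exposure$snp_id), , drop = FALSE]
  ou <- outcome[match(shared, outcome$snp_id), , drop = FALSE]
  n <- length(shared)
  beta_gd <- ou$beta
  eaf_out <- if (!is.null(ou$eaf)) ou$eaf else rep(NA_real_, n)
  eaf_exp <- if (!is.null(ex$eaf)) ex$eaf else rep(NA_real_, n)
  action <- character(n)
  keep <- rep(TRUE, n)
  reason <- rep(NA_character_, n)
  pal <- .is_palindromic(ex$effect_allele, ex$other_allele)
  for (i in seq_len(n)) {
    ea_x <- ex$effect_allele[i]; oa_x <- ex$other_allele[i]
    ea_o <- ou$effect_allele[i]; oa_o <- ou$other_allele[i]
    if (pal[i]) {
      # alleles carry no strand information; orient by frequency
      amb <- function(f) is.na(f) || (f > ambiguous_eaf_range[1L] &&
                                        f < ambiguous_eaf_range[2L])
      if (amb(eaf_exp[i]) || amb(eaf_out[i])) {
        keep[i] <- FALSE
        reason[i] <- "palindromic_ambiguous_frequency"
        action[i] <- "dropped"
        next
      }
      if ((eaf_exp[i] - 0.5) * (eaf_out[i] - 0.5) < 0) {
        beta_gd[i] <- -beta_gd[i]
        eaf_out[i] <- 1 - eaf_out[i]
        action[i] <- "sign_flipped_by_frequency"
      } else action[i] <- "kept"
      next
    }
    if (ea_o == ea_x && oa_o == oa_x) {
      action[i] <- "kept"
    } else if (ea_o == oa_x && oa_o == ea_x) {
      beta_gd[i] <- -beta_gd[i]
      eaf_out[i] <- 1 - eaf_out[i]
      action[i] <- "sign_flipped"
    } else if (identical(unname(.complement[ea_o]), ea_x) &&
               identical(unname(.complement[oa_o]), oa_x)) {
      action[i] <- "strand_flipped"
    } else if (identical(unname(.complement[ea_o]), oa_x) &&
               identical(unname(.complement[oa_o]), ea_x)) {
      beta_gd[i] <- -beta_gd[i]
      eaf_out[i] <- 1 - eaf_out[i]
      action[i] <- "strand_and_sign_flipped"
    } else {
      keep[i] <- FALSE
      reason[i] <- "irreconcilable_alleles"
      action[i] <- "dropped"
    }
  }
  out <- data.frame(snp_id = shared,
                    effect_allele = ex$effect_allele,
                    other_allele = ex$other_allele,
                    beta_gp = ex$beta, se_gp = ex$se,
                    beta_gd = beta_gd, se_gd = ou$se,
                    eaf_exposure = eaf_exp, eaf_outcome = eaf_out,
                    palindromic = pal, action = action,
                    stringsAsFactors = FALSE)
  dropped <- data.frame(snp_id = shared[!keep], reason = reason[!keep],
                        stringsAsFactors = FALSE)
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("harmonized", "data.frame")
  attr(out, "dropped") <- dropped
  out
}

#' Wald ratio causal estimate for a single instrument
#'
#' The single-instrument causal estimate `beta_GD / beta_GP` (log odds
#' ratio per SD unit increase in methylation) with a delta-method standard
#' error.  The default first-order SE is
#' `|est| * sqrt(SE_GD^2/beta_GD^2 + SE_GP^2/beta_GP^2)` (computed in the
#' algebraically equivalent form `sqrt(SE_GD^2/beta_GP^2 +
#' beta_GD^2 SE_GP^2 / beta_GP^4)`, which also covers beta_GD = 0, where
#' it reduces to `SE_GD/|beta_GP|`).  `"delta2"` adds the second-order
#' term `SE_GP^2 SE_GD^2 / beta_GP^4`; `"outcome"` ignores exposure
#' uncertainty (the weighting the inverse-variance combination across
#' instruments is built on).
#'
#' @param beta_gp,se_gp SNP-exposure effect and SE (exposure in SD units),
#'   or a `harmonized` data frame as first argument.
#' @param beta_gd,se_gd SNP-outcome effect and SE (log-odds per allele).
#' @param se_method `"delta1"` (default), `"delta2"` or `"outcome"`.
#' @return An `mr_result` data frame, one row per instrument, method
#'   `"wald"`.
#' @export
wald_ratio <- function(beta_gp, se_gp = NULL, beta_gd = NULL,
                       se_gd = NULL,
                       se_method = c("delta1", "delta2", "outcome")) {
  se_method <- match.arg(se_method)
  if (is.data.frame(beta_gp)) {
    h <- beta_gp
    beta_gp <- h$beta_gp; se_gp <- h$se_gp
    beta_gd <- h$beta_gd; se_gd <- h$se_gd
  }
  if (any(beta_gp == 0))
    stop("undefined Wald ratio: beta_GP is zero")
  est <- beta_gd / beta_gp
  v <- switch(se_method,
    outcome = se_gd^2 / beta_gp^2,
    delta1 = se_gd^2 / beta_gp^2 + beta_gd^2 * se_gp^2 / beta_gp^4,
    delta2 = se_gd^2 / beta_gp^2 + beta_gd^2 * se_gp^2 / beta_gp^4 +
      se_gp^2 * se_gd^2 / beta_gp^4)
  out <- do.call(rbind, lapply(seq_along(est), function(i)
    .mr_row("wald", est[i], sqrt(v[i]), 1L)))
  out
}

#' Inverse-variance-weighted combination of Wald ratios
#'
#' Fixed-effects pooling of per-instrument ratio estimates weighted by
#' their inverse variance (the same arithmetic as
#' [fixed_effects_meta()]), with Cochran's Q across instruments attached
#' when two or more are supplied.  A single ratio is passed through
#' unchanged.
#'
#' @param ratios An `mr_result` data frame of [wald_ratio()] rows (or any
#'   data frame with `estimate` and `se` columns).
#' @return A one-row `mr_result`, method `"ivw"` (or the untouched input
#'   row when only one instrument is supplied).
#' @export
ivw_combine <- function(ratios) {
  if (!nrow(ratios)) stop("no ratios to combine")
  if (nrow(ratios) == 1L) return(ratios)
  m <- fixed_effects_meta(ratios$estimate, ratios$se)
  .mr_row("ivw", m$estimate, m$se, nrow(ratios),
          Q = m$Q, Q_df = m$Q_df, Q_pval = m$Q_pval)
}

#' MR-Egger regression
#'
#' Weighted regression of outcome effects on exposure effects with a free
#' intercept (weights `1/SE_GD^2`); the slope is the causal estimate and
#' the intercept estimates average directional pleiotropy.  Instruments
#' are first oriented so every exposure effect is positive (sign-flipping
#' both members of a pair leaves the causal slope unchanged).
#'
#' @param h A `harmonized` data frame with at least 3 instruments.
#' @return A one-row `mr_result`, method `"egger"`, with
#'   `egger_intercept` and `egger_intercept_se` filled in.
#' @export
mr_egger <- function(h) {
  if (nrow(h) < 3L) stop("MR-Egger requires at least 3 instruments")
  if (any(h$beta_gp == 0)) stop("beta_GP of zero cannot be oriented")
  s <- sign(h$beta_gp)
  x <- h$beta_gp * s
  y <- h$beta_gd * s
  w <- 1 / h$se_gd^2
  fit <- lm(y ~ x, weights = w)
  sm <- summary(fit)$coefficients
  .mr_row("egger", sm["x", 1L], sm["x", 2L], nrow(h),
          egger_intercept = sm["(Intercept)", 1L],
          egger_intercept_se = sm["(Intercept)", 2L])
}

#' IVW accounting for correlation between instruments
#'
#' Generalized weighted estimate for correlated instruments (e.g. mQTLs in
#' residual LD): the ratio regression of `beta_GD` on `beta_GP` through
#' the origin under outcome-effect covariance
#' `Omega_ij = SE_GD_i * SE_GD_j * rho_ij`.  With `rho` the identity this
#' reduces exactly to the inverse-variance-weighted combination with
#' outcome-only weights.
#'
#' @param h A `harmonized` data frame.
#' @param rho Instrument correlation matrix (positive definite), ordered
#'   as `h` or with matching dimnames.
#' @return A one-row `mr_result`, method `"ivw_correlated"`.
#' @export
ivw_correlated <- function(h, rho) {
  rho <- as.matrix(rho)
  if (!is.null(rownames(rho)) && all(h$snp_id %in% rownames(rho)))
    rho <- rho[h$snp_id, h$snp_id, drop = FALSE]
  if (nrow(rho) != nrow(h))
    stop("rho must cover exactly the instruments in h")
  ev <- eigen(rho, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10)
    stop("rho is not positive definite; eigenvalues: ",
         paste(signif(ev, 4), collapse = ", "))
  omega <- outer(h$se_gd, h$se_gd) * rho
  oi <- solve(omega)
  x <- h$beta_gp
  y <- h$beta_gd
  xox <- drop(crossprod(x, oi %*% x))
  est <- drop(crossprod(x, oi %*% y)) / xox
  .mr_row("ivw_correlated", est, sqrt(1 / xox), nrow(h))
}

#' Z test for a difference between two estimates
#'
#' `z = (b1 - b2) / sqrt(se1^2 + se2^2)` with a two-sided normal p-value;
#' used to compare observational with MR estimates and ever- with
#' never-smoker subgroup estimates.
#'
#' @param b1,se1,b2,se2 Estimates and standard errors on a common scale.
#' @return List with `z` and `pval`.
#' @export
z_difference <- function(b1, se1, b2, se2) {
  if (any(c(se1, se2) <= 0)) stop("standard errors must be positive")
  z <- (b1 - b2) / sqrt(se1^2 + se2^2)
  list(z = z, pval = 2 * pnorm(-abs(z)))
}

#' A-priori power of a two-sample MR study with a binary outcome
#'
#' Non-centrality-parameter approximation: with `N` total subjects, case
#' fraction `K` and instrument strength `r2`,
#' `ncp = N K (1-K) r2 (ln OR)^2` and
#' `power = Phi(-z_{a/2} + sqrt(ncp)) + Phi(-z_{a/2} - sqrt(ncp))`.
#'
#' @param n_cases,n_controls Outcome-sample counts.
#' @param r2 Variance in the exposure explained by the instrument(s),
#'   in \[0, 1).
#' @param or_per_sd Detectable odds ratio per SD of the exposure.
#' @param alpha Two-sided type-I error rate (default 0.05).
#' @return Power in \[alpha, 1\].
#' @export
#' @examples
#' mr_power(29863, 55586, r2 = 0.008, or_per_sd = 0.474)
mr_power <- function(n_cases, n_controls, r2, or_per_sd, alpha = 0.05) {
  if (any(r2 < 0 | r2 >= 1)) stop("r2 must lie in [0, 1)")
  if (n_cases <= 0 || n_controls <= 0 || or_per_sd <= 0 ||
      alpha <= 0 || alpha >= 1)
    stop("invalid power inputs")
  N <- n_cases + n_controls
  K <- n_cases / N
  ncp <- N * K * (1 - K) * r2 * log(or_per_sd)^2
  z <- qnorm(1 - alpha / 2)
  pnorm(-z + sqrt(ncp)) + pnorm(-z - sqrt(ncp))
}
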