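#' Build a methylation-increasing allele score
#'
#' Weighted count of methylation-increasing alleles: each SNP is oriented
#' so that its weight acts in the direction of higher methylation (dosages
#' of SNPs with negative weight are reflected to `2 - d` and the weight's
#' absolute value used).  Individuals with missing dosages are dropped and
#' reported.
#'
#' @param genotypes Individuals x SNPs dosage matrix (0/1/2).
#' @param weights Per-SNP weights (e.g. `beta_gp`); sign encodes the
#'   methylation direction of the coded allele.
#' @param weighted If `FALSE`, use unit weights after orientation (a plain
#'   allele count).
#' @return An `allele_score` list: `score` (per retained individual),
#'   `kept` (row indices retained), `weights` (oriented, non-negative),
#'   `flipped` (logical per SNP), `n_dropped`.
#' @export
build_allele_score <- function(genotypes, weights, weighted = TRUE) {
  genotypes <- as.matrix(genotypes)
  if (ncol(genotypes) != length(weights))
    stop("one weight per SNP column is required")
  keep <- complete.cases(genotypes)
  G <- genotypes[keep, , drop = FALSE]
  flip <- weights < 0
  G[, flip] <- 2 - G[, flip, drop = FALSE]
  w <- abs(weights)
  if (!weighted) w <- rep(1, length(w))
  structure(list(score = drop(G %*% w), kept = which(keep), weights = w,
                 flipped = flip, n_dropped = sum(!keep)),
            class = "allele_score")
}

#' Allele score-exposure association and instrument strength
#'
#' Linear regression of methylation on the allele score, reported per
#' allele on the percentage-point scale (beta value x 100) and in SD
#' units, with variance explained and F statistic via the
#' [instrument_strength()] identities.
#'
#' @param score An [build_allele_score()] object or numeric vector.
#' @param methylation Beta-value methylation vector, aligned with the
#'   score.
#' @return List with `beta_pct`, `se_pct` (percentage points per allele),
#'   `beta_sd`, `se_sd` (SD units per allele), `pval`, `r2`, `F`, `n`.
#' @export
score_exposure <- function(score, methylation) {
  s <- if (inherits(score, "allele_score")) score$score else score
  if (length(s) != length(methylation))
    stop("score and methylation must be aligned")
  if (length(s) < 3L) stop("need at least 3 individuals")
  if (var(s) == 0) stop("allele score is constant")
  pct <- .lin_assoc(methylation * 100, s)
  sds <- .lin_assoc(as.vector(scale(methylation)), s)
  st <- instrument_strength(sds[1L], sds[2L], length(s))
  list(beta_pct = pct[1L], se_pct = pct[2L], beta_sd = sds[1L],
       se_sd = sds[2L], pval = pct[3L], r2 = st$r2, F = st$F,
       n = length(s))
}

#' Confounder balance across the allele score
#'
#' Regresses each potential confounder on the allele score (linear for
#' numeric confounders, logistic for binary/factor ones) to check the
#' exchangeability assumption of one-sample MR: a valid score should not
#' predict confounders.
#'
#' @param score An [build_allele_score()] object or numeric vector.
#' @param confounders Data frame of candidate confounders, aligned with
#'   the score.
#' @return Data frame with `confounder`, `type`, `beta`, `se`, `pval`;
#'   the minimum p-value is in `attr(, "min_pval")`.
#' @export
confounder_balance <- function(score, confounders) {
  s <- if (inherits(score, "allele_score")) score$score else score
  if (!ncol(as.data.frame(confounders))) {
    out <- data.frame(confounder = character(), type = character(),
                      beta = numeric(), se = numeric(), pval = numeric())
    attr(out, "min_pval") <- NA_real_
    return(out)
  }
  confounders <- as.data.frame(confounders)
  rows <- lapply(names(confounders), function(v) {
    x <- confounders[[v]]
    if (is.numeric(x) && length(unique(x)) > 2L) {
      fit <- .lin_assoc(x, s)
      type <- "linear"
    } else {
      y <- as.integer(as.factor(x)) - 1L
      fit <- .logistic_assoc(y, s)
      type <- "logistic"
    }
    data.frame(confounder = v, type = type, beta = fit[1L], se = fit[2L],
               pval = fit[3L], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "min_pval") <- min(out$pval)
  out
}

#' Two-stage Cox regression: hazard ratio per SD of methylation
#'
#' One-sample Mendelian randomization on a survival outcome.  Stage 1
#' regresses methylation (SD units) on the allele score plus adjustment
#' covariates; stage 2 fits a Cox proportional-hazards model of the
#' outcome on the stage-1 fitted methylation plus the same covariates.
#' The confidence interval comes from a nonparametric bootstrap over
#' individuals (both stages refitted per resample); the naive model-based
#' interval, which ignores stage-1 uncertainty, is reported alongside
#' with that caveat.
#'
#' @param records Data frame with columns `time` (> 0), `event` (0/1),
#'   `methylation`, `score`, plus any adjustment covariates.
#' @param covariates Covariate names adjusted for in both stages
#'   (default `c("age", "sex")`; silently restricted to columns present).
#' @param n_boot Bootstrap resamples (default 500); `0` skips the
#'   bootstrap.
#' @param seed Seed for the bootstrap.
#' @param min_events Minimum number of events required (default 10).
#' @return A `two_stage_cox` list: `log_hr`, `hr`, `se_naive`,
#'   `ci_naive`, `se_boot`, `ci_boot` (percentile), `n`, `n_events`,
#'   `converged`.
#' @export
two_stage_cox <- function(records, covariates = c("age", "sex"),
                          n_boot = 500L, seed = 1L, min_events = 10L) {
  covariates <- intersect(covariates, names(records))
  if (any(records$time <= 0)) stop("follow-up times must be positive")
  if (!any(records$event == 1L)) stop("no events observed")
  if (sum(records$event) < min_events)
    stop("fewer than ", min_events, " events")
  fit_once <- function(dat) {
    dat$meth_sd <- as.vector(scale(dat$methylation))
    f1 <- stats::as.formula(paste("meth_sd ~ score",
                                  paste(c("", covariates), collapse = " + ")))
    stage1 <- lm(f1, data = dat)
    dat$fitted_meth <- stats::fitted(stage1)
    f2 <- stats::as.formula(paste("survival::Surv(time, event) ~ fitted_meth",
                                  paste(c("", covariates), collapse = " + ")))
    fit <- survival::coxph(f2, data = dat)
    list(log_hr = unname(coef(fit)["fitted_meth"]),
         se = unname(sqrt(diag(fit$var))[1L]),
         converged = is.null(fit$info) || fit$iter < fit$control$iter.max)
  }
  main <- fit_once(records)
  out <- list(log_hr = main$log_hr, hr = exp(main$log_hr),
              se_naive = main$se,
              ci_naive = main$log_hr + c(-1.96, 1.96) * main$se,
              se_boot = NA_real_, ci_boot = c(NA_real_, NA_real_),
              n = nrow(records), n_events = sum(records$event),
              converged = main$converged)
  if (n_boot > 0L) {
    set.seed(as.integer(seed))
    boots <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(nrow(records), replace = TRUE)
      tryCatch(fit_once(records[idx, , drop = FALSE])$log_hr,
               error = function(e) NA_real_)
    }, numeric(1))
    boots <- boots[is.finite(boots)]
    out$se_boot <- sd(boots)
    out$ci_boot <- unname(quantile(boots, c(0.025, 0.975)))
  }
  structure(out, class = "two_stage_cox")
}

#' @export
print.two_stage_cox <- function(x, ...) {
  cat(sprintf("Two-stage Cox MR: HR per SD = %.3f", x$hr))
  if (is.finite(x$se_boot)) {
    cat(sprintf(" (bootstrap 95%% CI %.3f, %.3f)\n",
                exp(x$ci_boot[1L]), exp(x$ci_boot[2L])))
  } else {
    cat(sprintf(" (naive 95%% CI %.3f, %.3f; ignores stage-1 error)\n",
                exp(x$ci_naive[1L]), exp(x$ci_naive[2L])))
  }
  cat(sprintf("  n = %d, events = %d\n", x$n, x$n_events))
  invisible(x)
}

#' Smoking-stratified two-stage Cox MR
#'
#' Fits [two_stage_cox()] independently within each stratum (e.g.
#' never/former/current smokers) and tests across-strata heterogeneity of
#' the log hazard ratios with Cochran's Q.  Strata failing the
#' preconditions (too few events, constant score) are reported as missing,
#' leaving the others untouched.
#'
#' @param records As in [two_stage_cox()], plus a stratum column.
#' @param stratum Name of the stratum column (default `"smoking"`).
#' @inheritParams two_stage_cox
#' @return List with `strata` (data frame of `stratum`, `log_hr`, `se`,
#'   `hr`, `n`, `n_events`, `ok`) and `heterogeneity` (Q list across the
#'   successful strata, or `NULL` when fewer than two).
#' @export
stratified_two_stage_cox <- function(records, stratum = "smoking",
                                     covariates = c("age", "sex"),
                                     n_boot = 0L, seed = 1L,
                                     min_events = 10L) {
  if (is.null(records[[stratum]]))
    stop("unknown stratum variable: ", stratum)
  lab <- as.factor(records[[stratum]])
  rows <- lapply(levels(lab), function(lev) {
    sub <- records[lab == lev, , drop = FALSE]
    fit <- tryCatch(
      two_stage_cox(sub, covariates = covariates, n_boot = n_boot,
                    seed = seed, min_events = min_events),
      error = function(e) NULL)
    if (is.null(fit)) {
      data.frame(stratum = lev, log_hr = NA_real_, se = NA_real_,
                 hr = NA_real_, n = nrow(sub),
                 n_events = sum(sub$event), ok = FALSE,
                 stringsAsFactors = FALSE)
    } else {
      se <- if (is.finite(fit$se_boot)) fit$se_boot else fit$se_naive
      data.frame(stratum = lev, log_hr = fit$log_hr, se = se,
                 hr = fit$hr, n = fit$n, n_events = fit$n_events,
                 ok = TRUE, stringsAsFactors = FALSE)
    }
  })
  strata <- do.call(rbind, rows)
  ok <- strata$ok & is.finite(strata$se) & strata$se > 0
  het <- if (sum(ok) >= 2L)
    heterogeneity(strata$log_hr[ok], strata$se[ok]) else NULL
  list(strata = strata, heterogeneity = het)
}
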