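#' Inverse-variance-weighted fixed-effects meta-analysis
#'
#' Pools per-study effect estimates with weights `w_i = 1/se_i^2`
#' (METAL-style fixed effects).  With two or more studies Cochran's Q,
#' I-squared and the heterogeneity p-value are attached.
#'
#' @param effects Per-study effects (any common log scale).
#' @param ses Per-study standard errors, all positive.
#' @param labels Optional study labels for the direction string.
#' @return A `meta_result` list: `estimate`, `se`, `pval`, `k`, `weights`,
#'   `direction` (one sign glyph per study), and for k >= 2 `Q`, `Q_df`,
#'   `I2`, `Q_pval`.
#' @export
#' @examples
#' fixed_effects_meta(c(0.5, 0.3), c(0.1, 0.2))
fixed_effects_meta <- function(effects, ses, labels = NULL) {
  if (!length(effects) || length(effects) != length(ses))
    stop("effects and ses must be non-empty and equal length")
  if (!all(is.finite(effects)) || !all(is.finite(ses)))
    stop("non-finite effects or standard errors")
  if (any(ses <= 0)) stop("standard errors must be positive")
  w <- 1 / ses^2
  est <- sum(w * effects) / sum(w)
  se <- sqrt(1 / sum(w))
  out <- list(estimate = est, se = se,
              pval = 2 * pnorm(-abs(est / se)),
              k = length(effects), weights = w,
              direction = direction_consistency(effects)$direction)
  if (length(effects) >= 2L)
    out <- c(out, heterogeneity(effects, ses))
  structure(out, class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("Fixed-effects meta-analysis of %d studies\n", x$k))
  cat(sprintf("  pooled = %.4f (se %.4f), p = %.3g, direction %s\n",
              x$estimate, x$se, x$pval, x$direction))
  if (!is.null(x$Q))
    cat(sprintf("  Q = %.3f (df %d, p = %.3g), I2 = %.1f%%\n",
                x$Q, x$Q_df, x$Q_pval, 100 * x$I2))
  invisible(x)
}

#' Cochran's Q and I-squared heterogeneity
#'
#' `Q = sum w_i (b_i - pooled)^2` with `w_i = 1/se_i^2`,
#' `df = k - 1`, `I2 = max(0, (Q - df)/Q)`, p from a chi-square.
#'
#' @inheritParams fixed_effects_meta
#' @return List with `Q`, `Q_df`, `I2`, `Q_pval`.
#' @export
heterogeneity <- function(effects, ses) {
  if (length(effects) < 2L) stop("heterogeneity needs at least 2 studies")
  if (any(ses <= 0) || !all(is.finite(c(effects, ses))))
    stop("invalid effects or standard errors")
  w <- 1 / ses^2
  pooled <- sum(w * effects) / sum(w)
  Q <- sum(w * (effects - pooled)^2)
  df <- length(effects) - 1L
  list(Q = Q, Q_df = df,
       I2 = if (Q > 0) max(0, (Q - df) / Q) else 0,
       Q_pval = pchisq(Q, df, lower.tail = FALSE))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, capped at one, monotone over the sorted
#' p-values; the input order is preserved in the output.  `NA` entries are
#' left `NA` and excluded from the effective number of tests.
#'
#' @param pvals Numeric p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order as the input.
#' @export
bh_fdr <- function(pvals) {
  ok <- !is.na(pvals)
  p <- pvals[ok]
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  out <- rep(NA_real_, length(pvals))
  if (m) {
    o <- order(p)
    adj <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
    out[ok][o] <- adj
  }
  out
}

#' Direction-of-effect string across studies
#'
#' One glyph per study: `+` for positive, `-` for negative, `0` for an
#' exactly zero effect.  Zeros are sign-neutral: the set is consistent iff
#' all non-zero effects share a sign.
#'
#' @param effects Per-study effects.
#' @return List with `direction` (string) and `consistent` (logical).
#' @export
direction_consistency <- function(effects) {
  if (!length(effects)) stop("at least one study required")
  glyph <- ifelse(effects > 0, "+", ifelse(effects < 0, "-", "0"))
  nz <- sign(effects)[effects != 0]
  list(direction = paste(glyph, collapse = ""),
       consistent = length(unique(nz)) <= 1L)
}

#' Kruskal-Wallis and post hoc Dunn comparison of effect-size sets
#'
#' Compares distributions of per-CpG effect sizes between adjustment models
#' (or any grouped values): tie-corrected Kruskal-Wallis H, then Dunn's
#' pairwise z tests on mean ranks with (by default) Bonferroni-adjusted
#' p-values.
#'
#' @param groups Named list of numeric vectors.
#' @param p_adjust `"bonferroni"` (default) or `"none"` for the pairwise
#'   Dunn p-values.
#' @return List with `H`, `df`, `pval` and a `pairwise` data frame
#'   (`group1`, `group2`, `z`, `pval`, `pval_adj`).
#' @export
compare_models <- function(groups, p_adjust = c("bonferroni", "none")) {
  p_adjust <- match.arg(p_adjust)
  if (length(groups) < 2L || any(!lengths(groups)))
    stop("need at least 2 non-empty groups")
  if (is.null(names(groups)))
    names(groups) <- paste0("group", seq_along(groups))
  x <- unlist(groups, use.names = FALSE)
  g <- rep(names(groups), lengths(groups))
  N <- length(x)
  r <- rank(x)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties)
  rank_sums <- tapply(r, g, sum)[names(groups)]
  n_i <- lengths(groups)
  H <- 12 / (N * (N + 1)) * sum(rank_sums^2 / n_i) - 3 * (N + 1)
  corr <- 1 - tie_term / (N^3 - N)
  if (corr <= 0)
    stop("all values identical: H undefined under tie correction")
  H <- H / corr
  df <- length(groups) - 1L
  mean_ranks <- rank_sums / n_i
  sigma2 <- (N * (N + 1) / 12 - tie_term / (12 * (N - 1)))
  combs <- utils::combn(names(groups), 2L)
  pw <- apply(combs, 2L, function(pr) {
    z <- (mean_ranks[pr[1L]] - mean_ranks[pr[2L]]) /
      sqrt(sigma2 * (1 / n_i[pr[1L]] + 1 / n_i[pr[2L]]))
    unname(z)
  })
  pv <- 2 * pnorm(-abs(pw))
  m <- ncol(combs)
  pairwise <- data.frame(group1 = combs[1L, ], group2 = combs[2L, ],
                         z = pw, pval = pv,
                         pval_adj = if (p_adjust == "bonferroni")
                           pmin(1, pv * m) else pv,
                         stringsAsFactors = FALSE)
  list(H = H, df = df, pval = pchisq(H, df, lower.tail = FALSE),
       pairwise = pairwise)
}

#' Heterogeneity across stratum-level meta-analyses
#'
#' Applies the Cochran's Q machinery to the pooled estimates of several
#' strata (e.g. never/former/current smoking meta-analyses) to test whether
#' the stratum effects are mutually consistent.
#'
#' @param estimates Stratum pooled effects, or a list of `meta_result`
#'   objects.
#' @param ses Stratum pooled standard errors (ignored when `estimates` is a
#'   list of `meta_result`s).
#' @return List with `Q`, `Q_df`, `I2`, `Q_pval`.
#' @export
strata_heterogeneity <- function(estimates, ses = NULL) {
  if (is.list(estimates) && all(vapply(estimates, inherits, logical(1),
                                       "meta_result"))) {
    ses <- vapply(estimates, `[[`, numeric(1), "se")
    estimates <- vapply(estimates, `[[`, numeric(1), "estimate")
  }
  if (length(estimates) < 2L) stop("need at least 2 strata")
  heterogeneity(estimates, ses)
}
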