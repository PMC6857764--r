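#' Conditional logistic regression for 1:1 matched pairs
#'
#' Estimates the per-CpG methylation-disease association from matched
#' case-control pairs by maximizing the 1:1 conditional likelihood
#' \deqn{\prod_i \frac{e^{x_i^{case}\beta}}{e^{x_i^{case}\beta} +
#'       e^{x_i^{ctrl}\beta}}}
#' by Newton-Raphson on the within-pair differences (for 1:1 strata the
#' conditional likelihood is a logistic likelihood, without intercept, on
#' case-minus-control covariate differences with all responses 1).
#' Methylation is scaled to SD units (pooled over cases and controls)
#' before fitting, so the reported effect is an odds ratio per SD increase
#' in methylation.
#'
#' @param pairs A [make_matched_pairs()] result, or any data frame with
#'   `meth_case`/`meth_control` plus `<v>_case`/`<v>_control` columns for
#'   each covariate.
#' @param covariates Character vector of covariate names to adjust for.
#' @param scale_sd Scale methylation to SD units first (default `TRUE`;
#'   disable for raw-scale analyses).
#' @param cpg_id Label carried into the result.
#' @param model,stratum Tags carried into the result row.
#' @param max_iter,tol Newton-Raphson controls.
#' @return One-row `ewas_result` data frame: `cpg_id`, `log_or`,
#'   `or_per_sd`, `se`, `pval`, `n_pairs`, `model`, `stratum`, `converged`.
#'   Covariate coefficients are kept in `attr(, "coefficients")`.
#' @export
conditional_logistic <- function(pairs, covariates = character(),
                                 scale_sd = TRUE, cpg_id = "cpg_1",
                                 model = "basic", stratum = "all",
                                 max_iter = 50L, tol = 1e-10) {
  meth <- c(pairs$meth_case, pairs$meth_control)
  s <- if (scale_sd) sd(meth) else 1
  if (!is.finite(s) || s == 0) s <- 1
  d <- (pairs$meth_case - pairs$meth_control) / s
  X <- cbind(methylation = d)
  for (v in covariates) {
    ca <- pairs[[paste0(v, "_case")]]
    co <- pairs[[paste0(v, "_control")]]
    if (is.null(ca) || is.null(co))
      stop("pair columns for covariate '", v, "' not found")
    X <- cbind(X, as.numeric(ca) - as.numeric(co))
    colnames(X)[ncol(X)] <- v
  }
  if (all(abs(X) < 1e-12))
    stop("no information: all within-pair differences are zero")
  beta <- rep(0, ncol(X))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- plogis(eta)
    score <- crossprod(X, 1 - p)
    w <- p * (1 - p)
    info <- crossprod(X, X * w)
    step <- tryCatch(solve(info, score), error = function(e) NULL)
    if (is.null(step)) break
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) { converged <- TRUE; break }
  }
  separated <- !converged || max(abs(beta)) > 15
  if (separated)
    warning("conditional likelihood did not converge cleanly; ",
            "possible complete separation (max |beta| = ",
            signif(max(abs(beta)), 3), ")")
  eta <- drop(X %*% beta)
  p <- plogis(eta)
  info <- crossprod(X, X * (p * (1 - p)))
  vc <- tryCatch(chol2inv(chol(info)), error = function(e)
    matrix(NA_real_, ncol(X), ncol(X)))
  se <- sqrt(diag(vc))
  z <- beta / se
  out <- data.frame(cpg_id = cpg_id, log_or = beta[1L],
                    or_per_sd = exp(beta[1L]), se = se[1L],
                    pval = 2 * pnorm(-abs(z[1L])),
                    n_pairs = nrow(pairs), model = model, stratum = stratum,
                    converged = converged && !separated,
                    stringsAsFactors = FALSE)
  class(out) <- c("ewas_result", "data.frame")
  attr(out, "coefficients") <-
    data.frame(term = colnames(X), estimate = beta, se = se,
               pval = 2 * pnorm(-abs(z)))
  out
}

#' Surrogate variables by residual principal components
#'
#' Captures unmodelled sample-level structure in a methylation matrix
#' (batch, cell composition, lifestyle) as the leading principal components
#' of the matrix after residualizing every probe on a protected model.
#' This is a deterministic stand-in for iterative surrogate variable
#' analysis: it preserves the testable contract (orthonormal components
#' ordered by variance explained that capture structure not in the
#' protected model) without the full algorithm.
#'
#' @param meth Methylation matrix, probes x samples.
#' @param protected Optional sample-level design (vector, matrix or data
#'   frame) whose signal must be preserved; an intercept is always added.
#' @param k Number of surrogate variables (default 10).
#' @return samples x k matrix with orthonormal columns;
#'   `attr(, "var_explained")` gives the residual-variance fractions.
#' @export
surrogate_variables <- function(meth, protected = NULL, k = 10L) {
  if (k <= 0) stop("k must be positive")
  X <- t(meth)                       # samples x probes
  n <- nrow(X)
  if (k >= min(dim(X))) stop("k must be smaller than min(samples, probes)")
  D <- cbind(rep(1, n))
  if (!is.null(protected)) {
    D <- cbind(D, model.matrix(~., data = as.data.frame(protected))[, -1,
                                                                    drop = FALSE])
  }
  qr_d <- qr(D)
  R <- X - qr.fitted(qr_d, X)
  sv <- svd(R, nu = k, nv = 0)
  if (max(sv$d) < 1e-12)
    stop("methylation matrix has no residual variance")
  out <- sv$u[, seq_len(k), drop = FALSE]
  colnames(out) <- paste0("SV", seq_len(k))
  attr(out, "var_explained") <- (sv$d^2 / sum(sv$d^2))[seq_len(k)]
  out
}

#' Reference-based cell-type proportion estimation
#'
#' Projects a whole-blood methylation profile onto a reference matrix of
#' cell-type-specific methylation signatures by constrained least squares
#' (proportions non-negative, summing to one) - the reference-based
#' deconvolution used to derive blood cell counts from methylation.
#'
#' @param profile Numeric vector of methylation values for the reference
#'   probes (names, if present, must cover the reference rows).
#' @param reference CpGs x cell-types matrix of reference methylation.
#' @param sum_weight Weight of the sum-to-one constraint row in the
#'   augmented least-squares system.
#' @return Named proportion vector (non-negative, sums to one).  A
#'   rank-deficient reference is flagged with a warning and
#'   `attr(, "rank_deficient")`.
#' @export
estimate_cell_proportions <- function(profile, reference,
                                      sum_weight = 1000) {
  reference <- as.matrix(reference)
  if (!is.null(names(profile)) && !is.null(rownames(reference))) {
    if (!all(rownames(reference) %in% names(profile)))
      stop("profile does not cover all reference probes")
    profile <- profile[rownames(reference)]
  }
  if (length(profile) != nrow(reference))
    stop("profile length must match reference rows")
  deficient <- qr(reference)$rank < ncol(reference)
  if (deficient)
    warning("reference matrix is rank deficient; proportions not unique")
  A <- rbind(reference, rep(sum_weight, ncol(reference)))
  b <- c(profile, sum_weight)
  x <- .nnls(A, b)
  if (sum(x) == 0) x <- rep(1 / length(x), length(x)) else x <- x / sum(x)
  names(x) <- colnames(reference)
  attr(x, "rank_deficient") <- deficient
  x
}

# Lawson-Hanson non-negative least squares (small dense systems).
.nnls <- function(A, b, tol = 1e-12, max_iter = 200L) {
  p <- ncol(A)
  x <- rep(0, p)
  passive <- rep(FALSE, p)
  for (outer in seq_len(max_iter)) {
    w <- drop(crossprod(A, b - A %*% x))
    cand <- which(!passive & w > tol * max(1, max(abs(w))))
    if (!length(cand)) break
    passive[cand[which.max(w[cand])]] <- TRUE
    repeat {
      z <- rep(0, p)
      idx <- which(passive)
      z[idx] <- qr.solve(A[, idx, drop = FALSE], b)
      if (all(z[idx] > tol)) { x <- z; break }
      neg <- idx[z[idx] <= tol]
      alpha <- min(x[neg] / (x[neg] - z[neg]))
      x <- x + alpha * (z - x)
      passive[x <= tol & passive] <- FALSE
      x[!passive] <- 0
      if (!any(passive)) { x <- rep(0, p); break }
    }
  }
  x
}

#' Smoking-stratified EWAS
#'
#' Runs [conditional_logistic()] independently within each level of a
#' per-pair stratum variable (typically the smoking group both members of
#' a matched pair share).  Strata without informative pairs are reported
#' as missing rows, never dropped silently.
#'
#' @param pairs A [make_matched_pairs()] result.
#' @param stratum Name of the stratum variable; the pair-level label is
#'   taken from `<stratum>_case` (cases and controls share it when pairs
#'   were matched on the variable).
#' @inheritParams conditional_logistic
#' @return `ewas_result` data frame with one row per stratum level.
#' @export
stratified_ewas <- function(pairs, stratum, covariates = character(),
                            cpg_id = "cpg_1") {
  col <- paste0(stratum, "_case")
  if (is.null(pairs[[col]]))
    stop("unknown stratum variable: ", stratum)
  lab <- as.factor(pairs[[col]])
  rows <- lapply(levels(lab), function(lev) {
    sub <- pairs[lab == lev, , drop = FALSE]
    fit <- tryCatch(
      conditional_logistic(sub, covariates = covariates, cpg_id = cpg_id,
                           model = "basic", stratum = lev),
      error = function(e) NULL)
    if (is.null(fit)) {
      fit <- data.frame(cpg_id = cpg_id, log_or = NA_real_,
                        or_per_sd = NA_real_, se = NA_real_,
                        pval = NA_real_, n_pairs = nrow(sub),
                        model = "basic", stratum = lev, converged = FALSE,
                        stringsAsFactors = FALSE)
    }
    fit
  })
  out <- do.call(rbind, rows)
  class(out) <- c("ewas_result", "data.frame")
  out
}

# logit2 with clipping to keep M-values finite
.beta_to_m <- function(b, eps = 1e-6) {
  b <- pmin(pmax(b, eps), 1 - eps)
  log2(b / (1 - b))
}

#' Paired tumour/normal methylation comparison
#'
#' Per-CpG paired t-test of tumour versus adjacent-normal methylation.
#' Tests are computed on M-values (logit2 of beta values, variance
#' stabilized); the beta-scale mean difference is reported alongside.
#' P-values are adjusted across CpGs by Benjamini-Hochberg.
#'
#' @param tumour,normal Methylation (beta value) matrices, CpGs x subjects,
#'   with matching subject columns (reordered by name when available).
#' @return Data frame with one row per CpG: `cpg_id`, `mean_diff_beta`
#'   (tumour minus normal), `mean_diff_m`, `statistic`, `df`, `pval`, `fdr`.
#' @export
paired_tissue_difference <- function(tumour, normal) {
  tumour <- as.matrix(tumour)
  normal <- as.matrix(normal)
  if (!is.null(colnames(tumour)) && !is.null(colnames(normal))) {
    if (!setequal(colnames(tumour), colnames(normal)))
      stop("tumour and normal matrices cover different subjects")
    normal <- normal[, colnames(tumour), drop = FALSE]
  }
  if (!all(dim(tumour) == dim(normal)))
    stop("tumour and normal matrices must have identical dimensions")
  n <- ncol(tumour)
  if (n < 3L) stop("need at least 3 subject pairs")
  dm <- .beta_to_m(tumour) - .beta_to_m(normal)
  mean_m <- rowMeans(dm)
  sd_m <- apply(dm, 1L, sd)
  stat <- ifelse(sd_m > 0, mean_m / (sd_m / sqrt(n)),
                 ifelse(mean_m == 0, 0, Inf))
  pval <- ifelse(is.finite(stat), 2 * pt(-abs(stat), n - 1L),
                 0)
  pval[sd_m == 0 & mean_m == 0] <- 1
  out <- data.frame(
    cpg_id = if (!is.null(rownames(tumour))) rownames(tumour) else
      paste0("cpg_", seq_len(nrow(tumour))),
    mean_diff_beta = rowMeans(tumour - normal),
    mean_diff_m = mean_m, statistic = stat, df = n - 1L,
    pval = pval, fdr = bh_fdr(pval), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
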