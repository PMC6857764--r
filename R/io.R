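#' Read a summary-statistics table
#'
#' Reads a TSV of per-SNP associations into a typed `assoc_table`.
#' Non-standard column names can be mapped; malformed rows (non-numeric
#' effect, SE or p-value) are collected into a reject report rather than
#' silently dropped.
#'
#' @param path TSV path.  Lines starting with `#` are treated as comments
#'   (provenance headers).
#' @param column_map Named character vector mapping canonical names to the
#'   file's column names, e.g. `c(beta = "b", se = "se_b")`.  Canonical
#'   columns: `snp_id`, `effect_allele`, `other_allele`, `eaf`, `beta`,
#'   `se`, `pval`, `n` (the first and `beta`/`se` are mandatory).
#' @return An `assoc_table` data frame; rejected rows (with reasons) are in
#'   `attr(, "rejects")`.
#' @export
read_summary_stats <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    colClasses = "character")
  canon <- c("snp_id", "effect_allele", "other_allele", "eaf", "beta",
             "se", "pval", "n")
  for (nm in names(column_map)) {
    src <- column_map[[nm]]
    if (!src %in% names(raw))
      stop("mapped column '", src, "' not present in ", path)
    names(raw)[names(raw) == src] <- nm
  }
  mandatory <- c("snp_id", "beta", "se")
  missing <- setdiff(mandatory, names(raw))
  if (length(missing))
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "))
  numcols <- intersect(c("eaf", "beta", "se", "pval", "n"), names(raw))
  parsed <- raw
  for (v in numcols) parsed[[v]] <- suppressWarnings(as.numeric(raw[[v]]))
  bad <- rep(FALSE, nrow(parsed))
  reason <- rep(NA_character_, nrow(parsed))
  for (v in intersect(c("beta", "se"), numcols)) {
    b <- is.na(parsed[[v]]) & !(raw[[v]] %in% c("", "NA"))
    reason[b & !bad] <- paste0("non-numeric ", v)
    bad <- bad | b
  }
  rejects <- cbind(raw[bad, , drop = FALSE],
                   reason = reason[bad])
  out <- parsed[!bad, intersect(canon, names(parsed)), drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("assoc_table", "data.frame")
  attr(out, "rejects") <- rejects
  out
}

#' Write a table with provenance headers
#'
#' Writes a TSV preceded by `#`-prefixed provenance lines (inputs,
#' thresholds, seed, package version) so every artifact records how it was
#' made.  Numeric columns are written at full precision; a write/read
#' round trip reproduces values exactly.
#'
#' @param x Data frame.
#' @param path Output path.
#' @param provenance Named list or vector written as `# name: value`.
#' @return `path`, invisibly.
#' @export
write_tsv_provenance <- function(x, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  prov <- c(list(package = paste0("mqtlmr ", packageVersion("mqtlmr"))),
            as.list(provenance))
  for (nm in names(prov))
    writeLines(sprintf("# %s: %s", nm,
                       paste(format(prov[[nm]], digits = 15),
                             collapse = " ")), con)
  is_num <- vapply(x, is.numeric, logical(1))
  x[is_num] <- lapply(x[is_num], format, digits = 17, trim = TRUE,
                      scientific = FALSE)
  write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a numeric matrix TSV (methylation, LD, dosages)
#'
#' First column is taken as row names when non-numeric; `#` lines are
#' comments.
#'
#' @param path TSV path.
#' @return Numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE)
  if (ncol(raw) > 1L &&
      !is.numeric(raw[[1L]]) &&
      all(is.na(suppressWarnings(as.numeric(raw[[1L]]))))) {
    rn <- raw[[1L]]
    raw <- raw[, -1L, drop = FALSE]
    m <- as.matrix(raw)
    rownames(m) <- rn
  } else m <- as.matrix(raw)
  storage.mode(m) <- "double"
  m
}

#' Read a dosage matrix from TSV or VCF
#'
#' TSV: individuals x SNPs numeric table (see [read_matrix_tsv()]).
#' VCF: extracts the `DS` FORMAT field when present, otherwise counts
#' alternate alleles in `GT`; multi-allelic records are rejected with a
#' reason, not silently dropped (see `attr(, "rejected")`).  VCF support
#' requires the VariantAnnotation package.
#'
#' @param path File path.
#' @param format `"tsv"` or `"vcf"`.
#' @return Individuals x SNPs dosage matrix.
#' @export
read_dosages <- function(path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "tsv") return(read_matrix_tsv(path))
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("VCF input requires the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(path)
  alt <- VariantAnnotation::alt(vcf)
  multi <- lengths(alt) > 1L
  rejected <- data.frame(
    snp_id = names(vcf)[multi],
    reason = "multi-allelic record")
  vcf <- vcf[!multi]
  gtypes <- VariantAnnotation::geno(vcf)
  if ("DS" %in% names(gtypes)) {
    dos <- gtypes$DS
  } else if ("GT" %in% names(gtypes)) {
    gt <- gtypes$GT
    dos <- apply(gt, c(1, 2), function(g) {
      if (g %in% c(".", "./.", ".|.")) return(NA_real_)
      sum(as.integer(strsplit(g, "[/|]")[[1L]]) > 0L)
    })
  } else stop("VCF has neither DS nor GT genotype fields")
  out <- t(dos)                        # individuals x SNPs
  attr(out, "rejected") <- rejected
  out
}

#' Read a key-value run configuration file
#'
#' Minimal YAML-like `key: value` format (one pair per line, `#` comments);
#' values that parse as numbers become numeric, comma-separated values
#' become vectors.
#'
#' @param path Config file path.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- regmatches(ln, regexec("^([^:]+):(.*)$", ln))[[1L]]
    if (length(kv) != 3L) stop("malformed config line: ", ln)
    key <- trimws(kv[2L])
    val <- trimws(strsplit(kv[3L], ",")[[1L]])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!anyNA(num)) num else val
  }
  out
}

#' Default run configuration
#'
#' Thresholds default to the analysis' standard values: FDR 0.05, LD
#' r-squared 0.01, cis window 1 Mb, alpha 0.05.  All defaults are written
#' into every artifact's provenance header.
#'
#' @param stages Stages to run, a subset of
#'   `c("simulate", "ewas", "meta", "instruments", "mr")` (dependency
#'   order is enforced).
#' @param out_dir Output directory for artifacts.
#' @param seed Master seed; all pipeline randomness derives from it.
#' @param fdr,ld_r2,cis_window,alpha Analysis thresholds.
#' @param n_studies Number of EWAS studies to simulate.
#' @param study_pairs Matched pairs per study (defaults to the four-cohort
#'   design: 185, 367, 132, 234).
#' @param sim Optional overrides for [sim_config()] fields.
#' @return A `run_config` list.
#' @export
run_config <- function(stages = c("simulate", "ewas", "meta",
                                  "instruments", "mr"),
                       out_dir = tempfile("mqtlmr_run_"), seed = 1L,
                       fdr = 0.05, ld_r2 = 0.01, cis_window = 1e6,
                       alpha = 0.05, n_studies = 4L,
                       study_pairs = c(185L, 367L, 132L, 234L),
                       sim = list()) {
  stages <- match.arg(stages, several.ok = TRUE)
  structure(list(stages = stages, out_dir = out_dir,
                 seed = as.integer(seed), fdr = fdr, ld_r2 = ld_r2,
                 cis_window = cis_window, alpha = alpha,
                 n_studies = as.integer(n_studies),
                 study_pairs = rep_len(as.integer(study_pairs), n_studies),
                 sim = sim),
            class = "run_config")
}

.stage_order <- c("simulate", "ewas", "meta", "instruments", "mr")

#' Run the analysis pipeline on synthetic data
#'
#' Executes the requested stages in dependency order
#' (simulate -> ewas -> meta -> instruments -> mr), writing each stage's
#' artifact as a TSV with provenance headers into `config$out_dir`.
#' `simulate` draws per-study case-control cohorts plus independent
#' exposure (mQTL) and outcome (GWAS) cohorts and exports their summary
#' statistics; `ewas` fits the per-study conditional logistic models;
#' `meta` pools them; `instruments` builds the pruned instrument set with
#' strength metrics; `mr` harmonizes the two samples and reports Wald/IVW
#' estimates.  A missing upstream artifact raises an actionable error.
#' Reruns with the same config are byte-identical.
#'
#' @param config A [run_config()].
#' @return Named list of artifact paths, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    exposure = file.path(config$out_dir, "exposure_summary.tsv"),
    outcome = file.path(config$out_dir, "outcome_summary.tsv"),
    ewas = file.path(config$out_dir, "ewas_per_study.tsv"),
    meta = file.path(config$out_dir, "ewas_meta.tsv"),
    instruments = file.path(config$out_dir, "instruments.tsv"),
    mr = file.path(config$out_dir, "mr_results.tsv"))
  stages <- .stage_order[.stage_order %in% config$stages]
  need <- function(stage, file) {
    if (!file.exists(file))
      stop("stage '", stage, "' needs artifact ", basename(file),
           "; run the upstream stage first (stages = c(\"",
           paste(.stage_order[seq_len(match(stage, .stage_order))],
                 collapse = "\", \""), "\"))")
  }
  prov <- list(seed = config$seed, fdr = config$fdr, ld_r2 = config$ld_r2,
               cis_window = config$cis_window, alpha = config$alpha)
  sim_args <- function(extra) {
    args <- c(extra, config$sim)          # stage overrides win
    do.call(sim_config, args[!duplicated(names(args))])
  }

  for (stage in stages) {
    if (stage == "simulate") {
      exp_cfg <- sim_args(list(seed = config$seed * 1000L + 1L))
      out_cfg <- sim_args(list(seed = config$seed * 1000L + 2L))
      exp_cohort <- simulate_cohort(exp_cfg)
      out_cohort <- simulate_cohort(out_cfg)
      write_tsv_provenance(export_summary_stats(exp_cohort, "exposure"),
                           paths$exposure, c(prov, side = "exposure"))
      write_tsv_provenance(export_summary_stats(out_cohort, "outcome"),
                           paths$outcome, c(prov, side = "outcome"))
      for (s in seq_len(config$n_studies)) {
        cfg_s <- sim_args(list(seed = config$seed * 1000L + 10L + s,
                               n_pairs = config$study_pairs[s]))
        coh <- simulate_cohort(cfg_s)
        prs <- make_matched_pairs(coh, seed = cfg_s$seed)
        write_tsv_provenance(
          data.frame(pair_id = prs$pair_id, case_id = prs$case_id,
                     control_id = prs$control_id,
                     meth_case = prs$meth_case,
                     meth_control = prs$meth_control),
          file.path(config$out_dir, sprintf("study%d_pairs.tsv", s)),
          c(prov, study = s, seed_study = cfg_s$seed))
      }
    } else if (stage == "ewas") {
      study_files <- file.path(config$out_dir,
                               sprintf("study%d_pairs.tsv",
                                       seq_len(config$n_studies)))
      for (f in study_files) need("ewas", f)
      rows <- lapply(seq_along(study_files), function(s) {
        tab <- read.delim(study_files[s], comment.char = "#")
        fit <- conditional_logistic(tab)
        fit$study <- s
        fit
      })
      write_tsv_provenance(do.call(rbind, rows), paths$ewas, prov)
    } else if (stage == "meta") {
      need("meta", paths$ewas)
      ew <- read.delim(paths$ewas, comment.char = "#")
      m <- fixed_effects_meta(ew$log_or, ew$se)
      out <- data.frame(cpg_id = ew$cpg_id[1L], log_or = m$estimate,
                        or_per_sd = exp(m$estimate), se = m$se,
                        pval = m$pval, Q = m$Q, I2 = m$I2,
                        direction = m$direction)
      out$fdr <- bh_fdr(out$pval)
      write_tsv_provenance(out, paths$meta, prov)
    } else if (stage == "instruments") {
      need("instruments", paths$exposure)
      expo <- read_summary_stats(paths$exposure)
      inst <- instrument_set("cpg_1", expo, ld_threshold = config$ld_r2,
                             cis_window = config$cis_window)
      write_tsv_provenance(inst, paths$instruments, prov)
    } else if (stage == "mr") {
      need("mr", paths$instruments)
      need("mr", paths$outcome)
      inst <- read.delim(paths$instruments, comment.char = "#")
      outc <- read_summary_stats(paths$outcome)
      expo <- data.frame(snp_id = inst$snp_id,
                         effect_allele = inst$effect_allele,
                         other_allele = inst$other_allele,
                         eaf = NA_real_, beta = inst$beta_gp,
                         se = inst$se_gp, pval = inst$pval, n = inst$n)
      h <- harmonize(expo, outc)
      w <- wald_ratio(h)
      res <- rbind(w, ivw_combine(w))
      res$cpg_id <- inst$cpg_id[1L]
      write_tsv_provenance(res, paths$mr, prov)
    }
  }
  invisible(paths)
}
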