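#' Variant/sample QC thresholds
#'
#' Defaults follow the study's post-calling filter chain: drop indels, keep
#' biallelic loci, mask genotypes with GQ < 6 or DP < 2, drop samples with
#' call rate < 50%, drop variants with call rate < 90% or minor-allele
#' frequency < 0.01. All inequalities are strict, exactly as stated.
#'
#' @param gq_min,dp_min genotypes with GQ/DP strictly below these are set
#'   missing.
#' @param ind_call_min samples with call rate strictly below this fraction
#'   are removed.
#' @param var_call_min variants with call rate strictly below this fraction
#'   are removed.
#' @param maf_min variants with MAF strictly below this are removed.
#' @param drop_indels,biallelic_only flags for the first two steps.
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(gq_min = 6L, dp_min = 2L, ind_call_min = 0.50,
                          var_call_min = 0.90, maf_min = 0.01,
                          drop_indels = TRUE, biallelic_only = TRUE) {
  assert_that(gq_min >= 0 && dp_min >= 0, "integer thresholds must be >= 0")
  for (f in c(ind_call_min, var_call_min, maf_min)) {
    assert_that(f >= 0 && f <= 1, "fraction thresholds must be in [0, 1]")
  }
  structure(list(gq_min = as.integer(gq_min), dp_min = as.integer(dp_min),
                 ind_call_min = ind_call_min, var_call_min = var_call_min,
                 maf_min = maf_min, drop_indels = isTRUE(drop_indels),
                 biallelic_only = isTRUE(biallelic_only)),
            class = "qc_thresholds")
}

#' Filter a VCF into a QC'd genotype matrix
#'
#' Applies, in this fixed order: (1) drop indels; (2) keep biallelic loci;
#' (3) set genotypes missing where GQ < `gq_min`; (4) set missing where
#' DP < `dp_min`; (5) drop samples with call rate < `ind_call_min`;
#' (6) drop variants with call rate < `var_call_min`; (7) drop variants with
#' MAF < `maf_min`. MAF is recomputed after sample removal so frequencies
#' reflect the retained samples. A VCF without GT is fatal; absent GQ or DP
#' skips those steps with a warning.
#'
#' @param vcf path to a VCF file, or a [genotype_matrix()] carrying `gq`/`dp`
#'   attributes (as returned by the internal VCF reader).
#' @param thr a [qc_thresholds()].
#' @return `list(geno = genotype_matrix, report = qc_report)`; the report
#'   counts removals per step and genotypes masked by GQ/DP.
#' @export
filter_variants <- function(vcf, thr = qc_thresholds()) {
  geno <- if (is.character(vcf)) read_vcf_genotypes(vcf) else vcf
  assert_that(inherits(geno, "genotype_matrix"), "vcf must be a path or genotype_matrix")
  dos <- geno$dosage
  meta <- attr(geno, "vcf_meta")
  report <- list(n_variants_in = ncol(dos), n_samples_in = nrow(dos),
                 removed_indel = 0L, removed_multiallelic = 0L,
                 masked_gq = 0L, masked_dp = 0L,
                 removed_sample = 0L, removed_var_callrate = 0L,
                 removed_var_maf = 0L)

  keep <- rep(TRUE, ncol(dos))
  if (!is.null(meta)) {
    if (isTRUE(thr$drop_indels)) {
      is_indel <- nchar(meta$ref) != 1 | (nchar(meta$alt) != 1 &
                                            !grepl(",", meta$alt))
      # multi-base REF or single ALT of length != 1 is an indel
      report$removed_indel <- sum(is_indel & keep)
      keep <- keep & !is_indel
    }
    if (isTRUE(thr$biallelic_only)) {
      multi <- grepl(",", meta$alt)
      report$removed_multiallelic <- sum(multi & keep)
      keep <- keep & !multi
    }
  }
  dos <- dos[, keep, drop = FALSE]
  gq <- attr(geno, "gq"); dp <- attr(geno, "dp")
  if (!is.null(gq)) gq <- gq[, keep, drop = FALSE]
  if (!is.null(dp)) dp <- dp[, keep, drop = FALSE]

  if (is.null(gq)) {
    warning("VCF lacks GQ; genotype-quality masking skipped")
  } else {
    mask <- !is.na(dos) & !is.na(gq) & gq < thr$gq_min
    report$masked_gq <- sum(mask)
    dos[mask] <- NA
  }
  if (is.null(dp)) {
    warning("VCF lacks DP; depth masking skipped")
  } else {
    mask <- !is.na(dos) & !is.na(dp) & dp < thr$dp_min
    report$masked_dp <- sum(mask)
    dos[mask] <- NA
  }

  cr_sample <- rowMeans(!is.na(dos))
  drop_s <- cr_sample < thr$ind_call_min
  report$removed_sample <- sum(drop_s)
  report$samples_removed <- rownames(dos)[drop_s]
  dos <- dos[!drop_s, , drop = FALSE]

  cr_var <- colMeans(!is.na(dos))
  drop_v <- cr_var < thr$var_call_min
  report$removed_var_callrate <- sum(drop_v)
  dos <- dos[, !drop_v, drop = FALSE]

  af <- colMeans(dos, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  drop_m <- maf < thr$maf_min | is.nan(maf)
  report$removed_var_maf <- sum(drop_m)
  dos <- dos[, !drop_m, drop = FALSE]

  report$n_variants_out <- ncol(dos)
  report$n_samples_out <- nrow(dos)
  class(report) <- "qc_report"
  list(geno = genotype_matrix(dos), report = report)
}

#' @exportS3Method base::print
print.qc_report <- function(x, ...) {
  cat("QC report\n")
  cat(sprintf("  variants: %d in -> %d out (indel %d, multiallelic %d, call rate %d, MAF %d)\n",
              x$n_variants_in, x$n_variants_out, x$removed_indel,
              x$removed_multiallelic, x$removed_var_callrate, x$removed_var_maf))
  cat(sprintf("  samples:  %d in -> %d out (%d removed)\n",
              x$n_samples_in, x$n_samples_out, x$removed_sample))
  cat(sprintf("  genotypes masked: GQ %d, DP %d\n", x$masked_gq, x$masked_dp))
  invisible(x)
}

#' Genotype discordance between technical replicate pairs
#'
#' For each pair, the fraction of markers non-missing in both members whose
#' dosages differ; returns the mean over pairs. Pairs with no jointly called
#' marker are excluded with a warning.
#'
#' @param geno [genotype_matrix()].
#' @param pairs list of length-2 character vectors of sample ids, or a
#'   2-column matrix/data.frame.
#' @return Mean discordance (scalar); per-pair values as attribute
#'   `per_pair`.
#' @export
replicate_discordance <- function(geno, pairs) {
  if (is.matrix(pairs) || is.data.frame(pairs)) {
    pairs <- lapply(seq_len(nrow(pairs)), function(i) as.character(unlist(pairs[i, 1:2])))
  }
  vals <- vapply(pairs, function(pr) {
    assert_that(all(pr %in% geno$ids),
                paste0("replicate pair member missing: ", paste(pr, collapse = ",")))
    a <- geno$dosage[pr[1], ]
    b <- geno$dosage[pr[2], ]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) return(NA_real_)
    mean(a[ok] != b[ok])
  }, numeric(1))
  if (anyNA(vals)) {
    warning(sprintf("%d pair(s) with no jointly called markers excluded",
                    sum(is.na(vals))))
  }
  out <- mean(vals, na.rm = TRUE)
  attr(out, "per_pair") <- vals
  out
}

#' Impute missing dosages
#'
#' `mean` imputation replaces a missing dosage with `2 p_i` (real-valued
#' dosages are allowed downstream, e.g. in the G matrix); `random`
#' imputation draws from `{0, 1, 2}` with Hardy-Weinberg probabilities at
#' the marker's observed allele frequency. Markers that are 100% missing
#' are dropped with a warning.
#'
#' @param geno [genotype_matrix()].
#' @param method `"mean"` or `"random"`.
#' @return A complete [genotype_matrix()].
#' @export
impute_missing <- function(geno, method = c("mean", "random")) {
  method <- match.arg(method)
  dos <- geno$dosage
  all_miss <- colSums(!is.na(dos)) == 0
  if (any(all_miss)) {
    warning(sprintf("%d marker(s) 100%% missing dropped", sum(all_miss)))
    dos <- dos[, !all_miss, drop = FALSE]
  }
  af <- colMeans(dos, na.rm = TRUE) / 2
  miss <- which(is.na(dos), arr.ind = TRUE)
  if (nrow(miss)) {
    p <- af[miss[, 2]]
    dos[miss] <- if (method == "mean") {
      2 * p
    } else {
      stats::rbinom(nrow(miss), 2L, p)
    }
  }
  genotype_matrix(dos)
}
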