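pearson_or_flag <- function(x, y) {
  assert_that(length(x) == length(y), "length mismatch")
  nx <- names(x); ny <- names(y)
  if (!is.null(nx) && !is.null(ny)) {
    assert_that(all(nx == ny) || setequal(nx, ny), "id mismatch between vectors")
    if (!all(nx == ny)) y <- y[nx]
  }
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  assert_that(length(x) >= 3, "need at least 3 paired observations")
  if (sd(x) == 0 || sd(y) == 0) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  cor(x, y)
}

#' Prediction accuracy
#'
#' Pearson correlation between cross-validated (G)EBVs and the reference
#' EBVs treated as true breeding values. Undefined (NA, flagged via
#' attribute `undefined`) when either vector is constant.
#'
#' @param gebv predicted breeding values (named by id).
#' @param ebv_ref reference breeding values.
#' @return Scalar correlation.
#' @export
accuracy <- function(gebv, ebv_ref) pearson_or_flag(gebv, ebv_ref)

#' Predictive ability
#'
#' Pearson correlation between (G)EBVs and adjusted phenotypes `y'`.
#'
#' @param gebv predicted breeding values (named by id).
#' @param yprime adjusted phenotypes.
#' @return Scalar correlation (NA-flagged when undefined).
#' @export
predictive_ability <- function(gebv, yprime) pearson_or_flag(gebv, yprime)

#' Relative efficiency of genomic over conventional selection
#'
#' `RE = accuracy(GS) / accuracy(conventional BLUP selection)`; flagged
#' undefined when the denominator is not positive.
#'
#' @param acc_gs genomic-selection accuracy.
#' @param acc_tbs conventional (pedigree BLUP) selection accuracy.
#' @return Scalar ratio.
#' @export
relative_efficiency <- function(acc_gs, acc_tbs) {
  if (any(acc_tbs <= 0)) {
    out <- rep(NA_real_, length(acc_gs))
    attr(out, "undefined") <- TRUE
    return(out)
  }
  acc_gs / acc_tbs
}

#' Relative efficiency per year
#'
#' `RE/year = RE * t_conventional / t_gs`: the efficiency ratio scaled by
#' the breeding-cycle lengths. Defaults assume genomic selection halves a
#' 25-year conifer cycle to 12.5 years.
#'
#' @param re relative efficiency.
#' @param t_tbs conventional breeding-cycle length in years (default 25).
#' @param t_gs genomic-selection cycle length in years (default 12.5).
#' @return Scalar.
#' @export
re_per_year <- function(re, t_tbs = 25, t_gs = 12.5) {
  assert_that(all(c(t_tbs, t_gs) > 0), "cycle lengths must be positive")
  re * t_tbs / t_gs
}

#' Summarize cross-validation metrics
#'
#' Mean and standard error of accuracy and predictive ability over
#' replicates per (model, scope, split, subset, trait) cell; undefined
#' correlations are excluded from the means and counted. When both a
#' genomic and an `ablup` cell are present for the same stratum, RE and
#' RE/year are computed from the cell means (matching how a single ratio
#' is reported next to replicate-averaged accuracies).
#'
#' @param records data frame from [run_scenario()] (rows may be
#'   concatenated over scenarios).
#' @param t_tbs,t_gs cycle lengths for RE/year.
#' @return Data frame with one row per cell: means, standard errors,
#'   replicate and undefined counts, and (for genomic models) `re` and
#'   `re_per_year` relative to the matching `ablup` cell.
#' @export
summarize_metrics <- function(records, t_tbs = 25, t_gs = 12.5) {
  recs <- records[!records$failed, , drop = FALSE]
  key <- c("model", "scope", "split", "split_param", "subset", "m_markers",
           "trait")
  key <- intersect(key, names(recs))
  se <- function(v) if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_
  agg <- function(v) c(mean = mean(v, na.rm = TRUE), se = se(v[!is.na(v)]),
                       n = sum(!is.na(v)), n_undef = sum(is.na(v)))
  cells <- unique(recs[key])
  rownames(cells) <- NULL
  out <- cbind(cells, accuracy = NA_real_, accuracy_se = NA_real_,
               pa = NA_real_, pa_se = NA_real_,
               n_rep = NA_integer_, n_undefined = NA_integer_)
  for (i in seq_len(nrow(cells))) {
    sel <- rep(TRUE, nrow(recs))
    for (k in key) {
      sel <- sel & (recs[[k]] %in% cells[i, k] |
                      (is.na(cells[i, k]) & is.na(recs[[k]])))
    }
    a <- agg(recs$accuracy[sel])
    p <- agg(recs$pa[sel])
    out$accuracy[i] <- a["mean"]; out$accuracy_se[i] <- a["se"]
    out$pa[i] <- p["mean"]; out$pa_se[i] <- p["se"]
    out$n_rep[i] <- a["n"]; out$n_undefined[i] <- a["n_undef"]
  }
  # RE against the matching ablup cell within the same stratum
  strat <- c(setdiff(key, "model"))
  out$re <- NA_real_
  out$re_per_year <- NA_real_
  for (i in seq_len(nrow(out))) {
    if (out$model[i] == "ablup") next
    ref <- rep(TRUE, nrow(out))
    for (k in strat) {
      ref <- ref & (out[[k]] %in% out[i, k] |
                      (is.na(out[i, k]) & is.na(out[[k]])))
    }
    ref <- ref & out$model == "ablup"
    if (sum(ref) == 1 && is.finite(out$accuracy[ref]) &&
        out$accuracy[ref] > 0) {
      out$re[i] <- out$accuracy[i] / out$accuracy[ref]
      out$re_per_year[i] <- re_per_year(out$re[i], t_tbs, t_gs)
    }
  }
  out
}
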