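# Delta-method SE of a scalar function of the REML parameters, using the
# numerical-Hessian covariance stored on the fit.
fit_delta_se <- function(fit, fun) {
  if (is.null(fit$vcov_theta)) return(NA_real_)
  th <- fit$theta
  g0 <- fun(fit$par$unpack(th))
  eps <- pmax(abs(th), 1) * 1e-5
  grad <- vapply(seq_along(th), function(i) {
    tp <- th; tp[i] <- tp[i] + eps[i]
    tm <- th; tm[i] <- tm[i] - eps[i]
    (fun(fit$par$unpack(tp)) - fun(fit$par$unpack(tm))) / (2 * eps[i])
  }, numeric(1))
  v <- drop(t(grad) %*% fit$vcov_theta %*% grad)
  if (!is.finite(v) || v < 0) return(NA_real_)
  sqrt(v)
}

#' Narrow-sense heritability
#'
#' `h2 = sigma2_a / (sigma2_a + sigma2_e)`: the denominator is additive plus
#' residual variance only (post-block variance is excluded, matching how
#' progeny-trial variance-component tables are conventionally reported).
#' For a joint-site fit with unstructured additive covariance, `site`
#' selects the per-site heritability; for the homogeneous model the
#' site-by-additive variance is excluded from the denominator unless
#' `include_sa = TRUE`.
#'
#' @param x a `gs_fit` from [fit_reml()], or any list with `sigma2_a` and
#'   `sigma2_e` elements (worked-example arithmetic; no SE).
#' @param site site index (1 or 2) for unstructured joint fits.
#' @param include_sa include the site-by-additive variance in the
#'   denominator of a homogeneous joint fit.
#' @return Scalar heritability with attribute `se` (delta-method standard
#'   error where a fitted covariance is available, otherwise `NA`).
#' @export
heritability <- function(x, site = NULL, include_sa = FALSE) {
  if (inherits(x, "gs_fit")) {
    model <- x$model
    fun <- switch(model,
      single = function(v) v$Sg[1, 1] / (v$Sg[1, 1] + v$sig2_e[1]),
      joint_us = ,
      joint_us_r1 = {
        assert_that(!is.null(site), "site (1 or 2) required for unstructured joint fits")
        s <- as.integer(site)
        function(v) v$Sg[s, s] / (v$Sg[s, s] + v$sig2_e[s])
      },
      joint_hom = function(v) {
        den <- v$sigma2_a + v$sig2_e[1] + if (include_sa) v$sigma2_sa else 0
        v$sigma2_a / den
      })
    val <- fun(x$par$unpack(x$theta))
    attr(val, "se") <- fit_delta_se(x, fun)
    return(val)
  }
  va <- x$sigma2_a %||% x$additive
  ve <- x$sigma2_e %||% x$residual
  assert_that(!is.null(va) && !is.null(ve),
              "x needs sigma2_a/additive and sigma2_e/residual")
  den <- va + ve
  assert_that(den > 0, "zero phenotypic variance: heritability undefined")
  val <- va / den
  attr(val, "se") <- NA_real_
  val
}

#' Type-B genetic correlation between sites
#'
#' `r12 = sigma_a12 / sqrt(sigma2_a1 * sigma2_a2)` from an unstructured
#' joint-site fit: the correlation of additive effects of the same trait
#' expressed at the two sites. Values well below 1 indicate
#' genotype-by-environment interaction. For the homogeneous model the
#' implied correlation `sigma2_a / (sigma2_a + sigma2_sa)` is returned.
#'
#' @param x a `gs_fit`, or a list with `sigma2_a1`, `sigma2_a2`,
#'   `sigma_a12`.
#' @return Correlation in `[-1, 1]` with attribute `se`; `NA` (flagged via
#'   attribute `undefined`) if either site variance is effectively zero.
#' @export
type_b_correlation <- function(x) {
  if (inherits(x, "gs_fit")) {
    if (x$model == "joint_hom") {
      fun <- function(v) v$sigma2_a / (v$sigma2_a + v$sigma2_sa)
    } else {
      assert_that(x$model %in% c("joint_us", "joint_us_r1"),
                  "type-B requires a joint-site fit")
      fun <- function(v) v$Sg[1, 2] / sqrt(v$Sg[1, 1] * v$Sg[2, 2])
    }
    v <- x$par$unpack(x$theta)
    tiny <- 1e-8 * mean(v$sig2_e)
    if (x$model != "joint_hom" &&
        (v$Sg[1, 1] < tiny || v$Sg[2, 2] < tiny)) {
      out <- NA_real_
      attr(out, "undefined") <- TRUE
      return(out)
    }
    val <- fun(v)
    attr(val, "se") <- fit_delta_se(x, fun)
    return(val)
  }
  v1 <- x$sigma2_a1; v2 <- x$sigma2_a2; c12 <- x$sigma_a12
  if (v1 <= 0 || v2 <= 0) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  c12 / sqrt(v1 * v2)
}

#' One-tailed boundary LRT of type-B correlation against 1
#'
#' Compares the unstructured joint fit with the constrained fit fixing the
#' additive cross-site correlation at 1. Because the null lies on the
#' boundary of the parameter space, the p-value uses the 50:50 mixture of
#' chi-square with 0 and 1 degrees of freedom:
#' `p = 0.5 P(chi2_1 >= LRT)` (so identical likelihoods give p = 0.5).
#'
#' @param full unstructured joint `gs_fit`.
#' @param constrained the matching fit with `constrain_type_b = 1`.
#' @return `list(statistic, p_value)`.
#' @export
lrt_type_b_vs_one <- function(full, constrained) {
  assert_that(full$model == "joint_us", "full must be an unstructured joint fit")
  assert_that(constrained$model == "joint_us_r1",
              "constrained must fix the correlation at 1")
  stat <- 2 * (full$vc$loglik - constrained$vc$loglik)
  if (stat < -1e-4) {
    stop(sprintf(
      "constrained log-likelihood exceeds full by %.3g: optimizer failure, refit (e.g. type_b_test())",
      -stat), call. = FALSE)
  }
  stat <- max(stat, 0)
  list(statistic = stat, p_value = 0.5 * pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Fit both type-B models and test the correlation against 1
#'
#' Convenience wrapper fitting the unstructured joint model and its
#' correlation-1 constrained version (started from the full fit's optimum,
#' and refit from default starts if the constrained likelihood comes out
#' higher), then applying [lrt_type_b_vs_one()].
#'
#' @param pheno,K,trait as in [fit_reml()].
#' @param kinship kinship tag for the model spec.
#' @param ... passed to [fit_reml()].
#' @return `list(full, constrained, statistic, p_value, type_b)`.
#' @export
type_b_test <- function(pheno, K, trait, kinship = "A", ...) {
  spec <- model_spec(trait, kinship = kinship, scope = "joint",
                     joint_cov = "unstructured")
  full <- fit_reml(pheno, K, spec, ...)
  init_c <- full$theta[c(1, 2, 4, 5, 6)]
  constrained <- fit_reml(pheno, K, spec, constrain_type_b = 1,
                          init = init_c, ...)
  if (constrained$vc$loglik > full$vc$loglik + 1e-4) {
    # full optimum missed; restart it from the constrained solution
    init_f <- c(constrained$theta[1:2], atanh(0.999),
                constrained$theta[3:5])
    refit <- fit_reml(pheno, K, spec, init = init_f, ...)
    if (refit$vc$loglik > full$vc$loglik) full <- refit
  }
  lrt <- lrt_type_b_vs_one(full, constrained)
  list(full = full, constrained = constrained,
       statistic = lrt$statistic, p_value = lrt$p_value,
       type_b = type_b_correlation(full))
}

#' Adjust phenotypes for block effects and standardize per site
#'
#' `y' = y - block BLUP`, then each site is centred to zero mean and scaled
#' to unit variance. This is the response used by the whole-genome marker
#' regressions and by joint-scope cross-validation.
#'
#' @param pheno phenotype table.
#' @param fit a `gs_fit` whose `block_blup` covers the blocks present (fit
#'   on the same or a superset of the data).
#' @param trait trait column; defaults to the fit's trait.
#' @return Named numeric vector (tree ids) with attribute `site`; entries
#'   for blocks unseen by the fit use a zero block effect.
#' @export
adjust_phenotypes <- function(pheno, fit, trait = fit$spec$trait) {
  y <- pheno[[trait]]
  b <- fit$block_blup[pheno$block]
  b[is.na(b)] <- 0
  y1 <- y - b
  out <- numeric(length(y1))
  for (s in unique(pheno$site)) {
    rows <- which(pheno$site == s)
    if (length(rows) < 2) {
      stop(sprintf("site %s has fewer than 2 trees: cannot standardize", s),
           call. = FALSE)
    }
    out[rows] <- (y1[rows] - mean(y1[rows])) / sd(y1[rows])
  }
  names(out) <- pheno$tree
  attr(out, "site") <- pheno$site
  out
}
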