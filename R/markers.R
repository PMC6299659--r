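#' MCMC settings for the whole-genome regression samplers
#'
#' The `paper` preset (150,000 iterations, 50,000 burn-in, thinning 1000,
#' 100 retained samples) mirrors the long chains used for the field-scale
#' analysis; the `desk` preset (15,000 / 5,000 / 10, 1000 retained) gives
#' tighter Monte Carlo error per minute and is the default for simulation
#' work and tests.
#'
#' @param n_iter,burn_in,thin chain length, burn-in, thinning interval.
#' @param seed RNG seed applied before sampling.
#' @param preset `"desk"` or `"paper"`; overrides the three chain numbers.
#' @return An `mcmc_settings` list; warns when fewer than 50 samples would
#'   be retained.
#' @export
mcmc_settings <- function(n_iter = 15000, burn_in = 5000, thin = 10,
                          seed = 1L, preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("desk", "paper"))
    if (preset == "paper") {
      n_iter <- 150000; burn_in <- 50000; thin <- 1000
    } else {
      n_iter <- 15000; burn_in <- 5000; thin <- 10
    }
  }
  assert_that(burn_in < n_iter, "burn_in must be smaller than n_iter")
  assert_that(thin >= 1, "thin must be >= 1")
  kept <- floor((n_iter - burn_in) / thin)
  if (kept < 50) {
    warning(sprintf("only %d retained samples; >= 50 recommended", kept))
  }
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = as.integer(seed),
                 n_kept = kept),
            class = "mcmc_settings")
}

#' Prior specification for the Bayesian marker models
#'
#' Scaled-inverse-chi-square priors on the marker and residual variances
#' (BRR, RKHS) and a Gamma prior on the LASSO regularisation `lambda^2`.
#' Scale parameters left `NULL` are resolved from the data at fit time so
#' that the prior mode splits the phenotypic variance evenly between the
#' genetic and residual components -- a weakly informative default.
#'
#' @param df_a,S_m degrees of freedom and scale for the marker/genetic
#'   variance.
#' @param df_e,S_e degrees of freedom and scale for the residual variance.
#' @param lambda_shape,lambda_rate Gamma prior on `lambda^2` (Bayesian
#'   LASSO); a `NULL` rate is set so the prior mode equals `2 p`.
#' @param h Gaussian-kernel bandwidth for RKHS.
#' @return A `prior_spec` list.
#' @export
prior_spec <- function(df_a = 5, S_m = NULL, df_e = 5, S_e = NULL,
                       lambda_shape = 1.1, lambda_rate = NULL, h = 0.25) {
  assert_that(df_a > 0 && df_e > 0, "degrees of freedom must be positive")
  assert_that(h > 0, "kernel bandwidth h must be positive")
  structure(list(df_a = df_a, S_m = S_m, df_e = df_e, S_e = S_e,
                 lambda_shape = lambda_shape, lambda_rate = lambda_rate,
                 h = h),
            class = "prior_spec")
}

resolve_prior <- function(prior, y, X) {
  vy <- var(y)
  p <- ncol(X)
  msx <- sum(apply(X, 2, var))
  if (msx <= 0) msx <- 1
  list(df_a = prior$df_a,
       S_a = prior$S_m %||% (0.5 * vy * (prior$df_a + 2) / msx),
       df_e = prior$df_e,
       S_e = prior$S_e %||% (0.5 * vy * (prior$df_e + 2)),
       lambda_shape = prior$lambda_shape,
       lambda_rate = prior$lambda_rate %||%
         (max(prior$lambda_shape - 1, 0.1) / (2 * p)))
}

# Indicator coding used by the Bayesian/RKHS models: dosage - 1 in
# {-1, 0, 1} (real-valued after mean imputation).
code_indicator <- function(geno, markers = NULL) {
  X <- geno$dosage
  if (!is.null(markers)) {
    miss <- setdiff(markers, colnames(X))
    assert_that(length(miss) == 0,
                paste0("markers absent from genotypes: ",
                       paste(utils::head(miss, 5), collapse = ", ")))
    X <- X[, markers, drop = FALSE]
  }
  X - 1
}

run_wgr <- function(y, X, model, prior, mcmc, store_effects) {
  assert_that(all(is.finite(y)), "non-finite adjusted phenotypes")
  pr <- resolve_prior(prior, y, X)
  set.seed(mcmc$seed)
  res <- .gibbs_wgr(y, X, model, mcmc$n_iter, mcmc$burn_in, mcmc$thin,
                    pr$df_a, pr$S_a, pr$df_e, pr$S_e,
                    pr$lambda_shape, pr$lambda_rate, store_effects)
  res
}

#' Bayesian ridge regression on adjusted phenotypes
#'
#' Gibbs sampler for `y' = mu + X a + e` with a common marker-effect
#' variance: `a_j ~ N(0, sigma2_m)`, `sigma2_m` and `sigma2_e` with
#' scaled-inverse-chi-square full conditionals, all conditionals sampled
#' exactly. Markers are coded -1/0/1; zero-variance markers keep effect 0.
#'
#' @param yprime named vector of adjusted phenotypes (training trees).
#' @param geno [genotype_matrix()] covering the training trees.
#' @param prior [prior_spec()].
#' @param mcmc [mcmc_settings()].
#' @param store_effects keep the thinned effect samples (needed for
#'   Monte-Carlo-error checks; off by default to save memory).
#' @return A `marker_effects` object: intercept, posterior-mean per-marker
#'   effects, posterior effect variances, variance chains, settings.
#' @export
fit_brr <- function(yprime, geno, prior = prior_spec(),
                    mcmc = mcmc_settings(), store_effects = FALSE) {
  X <- code_indicator(geno)[names(yprime), , drop = FALSE]
  res <- run_wgr(as.numeric(yprime), X, "brr", prior, mcmc, store_effects)
  marker_effects(res, colnames(X), "brr", mcmc)
}

#' Bayesian LASSO on adjusted phenotypes
#'
#' Gibbs sampler with marker-specific shrinkage: `a_j ~ N(0, tau2_j
#' sigma2_e)`, `1/tau2_j` inverse-Gaussian given the current effect, and
#' `lambda^2` updated from its Gamma full conditional (Park-Casella).
#' Combines shrinkage with soft variable selection: small effects are
#' pulled to zero harder than large ones.
#'
#' @inheritParams fit_brr
#' @return A `marker_effects` object (also carries the posterior-mean
#'   `tau2` and the `lambda2` chain).
#' @export
fit_blasso <- function(yprime, geno, prior = prior_spec(),
                       mcmc = mcmc_settings(), store_effects = FALSE) {
  X <- code_indicator(geno)[names(yprime), , drop = FALSE]
  res <- run_wgr(as.numeric(yprime), X, "blasso", prior, mcmc, store_effects)
  marker_effects(res, colnames(X), "blasso", mcmc)
}

marker_effects <- function(res, markers, model, mcmc) {
  eff <- setNames(as.numeric(res$effects), markers)
  structure(list(model = model,
                 intercept = res$mu,
                 effects = eff,
                 effects_var = setNames(as.numeric(res$effects_var), markers),
                 mu_chain = res$mu_chain,
                 sigma2_e_chain = res$sigma2_e_chain,
                 sigma2_m_chain = res$sigma2_m_chain,
                 lambda2_chain = res$lambda2_chain,
                 tau2 = setNames(as.numeric(res$tau2), markers),
                 samples = if (nrow(res$samples)) res$samples else NULL,
                 n_kept = res$n_kept,
                 markers = markers,
                 coding = "indicator(-1,0,1)",
                 settings = mcmc),
            class = "marker_effects")
}

#' @exportS3Method base::print
print.marker_effects <- function(x, ...) {
  cat(sprintf("marker_effects (%s): %d markers, %d retained samples\n",
              x$model, length(x$effects), x$n_kept))
  invisible(x)
}

#' Gaussian kernel on genotype distances
#'
#' `K_ij = exp(-h d_ij)` with `d_ij` the squared Euclidean distance between
#' dosage rows. By default the distances are divided by their off-diagonal
#' mean before exponentiation, which puts the bandwidth `h` on a
#' marker-count-free scale (raw squared distances over tens of thousands of
#' markers would underflow the kernel to zero); set
#' `scale_distance = FALSE` for the literal unscaled form. The diagonal is
#' exactly 1.
#'
#' @param geno complete [genotype_matrix()].
#' @param h positive bandwidth (default 0.25).
#' @param scale_distance divide `d` by its off-diagonal mean (default TRUE).
#' @return Symmetric kernel matrix with attribute `kind = "K"`.
#' @export
gaussian_kernel <- function(geno, h = 0.25, scale_distance = TRUE) {
  assert_that(h > 0, "h must be positive")
  assert_that(!anyNA(geno$dosage), "kernel requires complete dosages")
  Z <- geno$dosage
  sq <- rowSums(Z^2)
  D <- outer(sq, sq, "+") - 2 * tcrossprod(Z)
  D[D < 0] <- 0
  diag(D) <- 0
  if (scale_distance && nrow(D) > 1) {
    md <- mean(D[upper.tri(D)])
    if (md > 0) D <- D / md
  }
  K <- exp(-h * D)
  dimnames(K) <- list(geno$ids, geno$ids)
  attr(K, "kind") <- "K"
  K
}

#' RKHS kernel regression via a Gibbs sampler
#'
#' Genetic values `a ~ N(0, K sigma2_a)` with scaled-inverse-chi-square
#' priors on `sigma2_a` and `sigma2_e` (single-kernel model). Implemented
#' through the eigendecomposition of `K`: regression coefficients on the
#' scaled eigenvectors carry an i.i.d. normal prior, which reproduces the
#' kernel covariance exactly and lets the same exact Gibbs sampler as
#' [fit_brr()] do the work. Individuals in `K` without phenotypes receive
#' predictions through their kernel rows.
#'
#' @param yprime named vector of adjusted phenotypes (training trees).
#' @param K kernel or relationship matrix over training and prediction ids
#'   (symmetric PSD; small negative eigenvalues are truncated at zero).
#' @param prior [prior_spec()].
#' @param mcmc [mcmc_settings()].
#' @return `list(gvalues, intercept, sigma2_a_chain, sigma2_e_chain,
#'   n_kept)`; `gvalues` is the posterior-mean genetic value for every id
#'   in `K`.
#' @export
fit_rkhs <- function(yprime, K, prior = prior_spec(), mcmc = mcmc_settings()) {
  ids_t <- names(yprime)
  assert_that(all(ids_t %in% rownames(K)), "training ids missing from K")
  eg <- eigen((K + t(K)) / 2, symmetric = TRUE)
  tol <- 1e-8 * max(eg$values)
  if (min(eg$values) < -1e-4 * max(eg$values)) {
    stop("K is not positive semi-definite beyond repair", call. = FALSE)
  }
  keep <- eg$values > tol
  assert_that(any(keep), "kernel has no positive eigenvalues")
  B <- eg$vectors[, keep, drop = FALSE] %*% diag(sqrt(eg$values[keep]),
                                                 sum(keep))
  rownames(B) <- rownames(K)
  Xt <- B[ids_t, , drop = FALSE]
  res <- run_wgr(as.numeric(yprime), Xt, "brr", prior, mcmc,
                 store_effects = TRUE)
  # posterior-mean genetic values for all individuals through B
  gv <- drop(B %*% res$effects)
  names(gv) <- rownames(K)
  gsd <- if (!is.null(res$samples) && nrow(res$samples)) {
    gs <- res$samples %*% t(B)
    apply(gs, 2, sd)
  } else NULL
  list(gvalues = gv, gvalues_sd = gsd, intercept = res$mu,
       sigma2_a_chain = res$sigma2_m_chain,
       sigma2_e_chain = res$sigma2_e_chain, n_kept = res$n_kept)
}

#' Assemble GEBVs from estimated marker effects
#'
#' `g_i = sum_j Z'_ij a_j` with `Z'` the -1/0/1 indicator coding of the
#' validation genotypes; the intercept is excluded (it does not affect
#' ranking or correlations). Marker sets must match exactly.
#'
#' @param effects a `marker_effects` object.
#' @param geno_validation [genotype_matrix()] for the individuals to
#'   predict.
#' @return Named numeric vector of GEBVs.
#' @export
gebv_from_effects <- function(effects, geno_validation) {
  miss <- setdiff(effects$markers, geno_validation$markers)
  extra <- setdiff(geno_validation$markers, effects$markers)
  if (length(miss)) {
    stop(paste0("marker mismatch; missing from validation genotypes: ",
                paste(utils::head(miss, 5), collapse = ", "),
                if (length(extra)) paste0(" (and ", length(extra),
                                          " extra)") else ""),
         call. = FALSE)
  }
  X <- code_indicator(geno_validation, effects$markers)
  drop(X %*% effects$effects)
}

#' Geweke-style convergence diagnostics for MCMC chains
#'
#' Compares the mean of the first 10% of each chain with the mean of the
#' last 50% using spectral-density variance estimates (AR fit), flagging
#' `|z| > 3`. Constant chains are flagged degenerate. Optionally writes
#' trace plots.
#'
#' @param chains numeric vector, matrix (iterations x chains) or named
#'   list of vectors.
#' @param plot_dir if non-`NULL`, a directory where one PNG trace plot per
#'   chain is written.
#' @return Data frame: chain, z, flagged, degenerate.
#' @export
convergence_check <- function(chains, plot_dir = NULL) {
  if (is.numeric(chains) && is.null(dim(chains))) {
    chains <- list(chain = chains)
  }
  if (is.matrix(chains)) {
    nm <- colnames(chains) %||% paste0("chain", seq_len(ncol(chains)))
    chains <- setNames(lapply(seq_len(ncol(chains)), function(j) chains[, j]),
                       nm)
  }
  spec0 <- function(x) {
    if (length(x) < 8 || var(x) == 0) return(var(x))
    fit <- tryCatch(stats::ar(x, aic = TRUE,
                              order.max = min(10, length(x) %/% 4)),
                    error = function(e) NULL)
    if (is.null(fit) || length(fit$ar) == 0) return(var(x))
    fit$var.pred / (1 - sum(fit$ar))^2
  }
  out <- do.call(rbind, lapply(names(chains), function(nm) {
    x <- as.numeric(chains[[nm]])
    if (var(x) == 0) {
      return(data.frame(chain = nm, z = NA_real_, flagged = TRUE,
                        degenerate = TRUE))
    }
    n <- length(x)
    a <- x[seq_len(max(2, floor(0.1 * n)))]
    b <- x[seq.int(ceiling(0.5 * n) + 1, n)]
    z <- (mean(a) - mean(b)) /
      sqrt(spec0(a) / length(a) + spec0(b) / length(b))
    data.frame(chain = nm, z = z, flagged = abs(z) > 3, degenerate = FALSE)
  }))
  if (!is.null(plot_dir)) {
    dir.create(plot_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(chains)) {
      grDevices::png(file.path(plot_dir, paste0("trace_", nm, ".png")),
                     width = 700, height = 350)
      plot(as.numeric(chains[[nm]]), type = "l", xlab = "retained sample",
           ylab = nm, main = paste("trace:", nm))
      grDevices::dev.off()
    }
  }
  out
}
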