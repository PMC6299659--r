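#' Specify a single-trait animal model
#'
#' Fixed effects are a grand mean and (for joint-site fits) a site effect;
#' random effects are post-block-within-site, additive genetic (pedigree or
#' genomic kinship), and -- under the homogeneous joint covariance -- a
#' site-by-additive interaction. The unstructured joint covariance instead
#' estimates per-site additive variances and their covariance, from which
#' the type-B genetic correlation follows.
#'
#' @param trait trait column name in the phenotype table.
#' @param kinship `"A"` (pedigree) or `"G"` (genomic); informational tag --
#'   the kinship actually used is the matrix passed to [fit_reml()].
#' @param scope `"site1"`, `"site2"` or `"joint"`.
#' @param joint_cov `"unstructured"` or `"homogeneous_plus_sa"`; only
#'   meaningful for joint scope.
#' @return A `model_spec` list.
#' @export
model_spec <- function(trait, kinship = c("A", "G"),
                       scope = c("joint", "site1", "site2"),
                       joint_cov = c("unstructured", "homogeneous_plus_sa")) {
  joint_cov_given <- !missing(joint_cov)
  kinship <- match.arg(kinship)
  scope <- match.arg(scope)
  joint_cov <- match.arg(joint_cov)
  if (scope != "joint" && joint_cov_given && joint_cov == "unstructured") {
    stop("unstructured covariance is only valid for joint scope", call. = FALSE)
  }
  structure(list(trait = trait, kinship = kinship, scope = scope,
                 joint_cov = joint_cov),
            class = "model_spec")
}

# 2x2 (or 1x1) lower Cholesky tolerant of rank deficiency.
chol_lower_small <- function(S) {
  s <- nrow(S)
  L <- matrix(0, s, s)
  L[1, 1] <- sqrt(max(S[1, 1], 0))
  if (s == 2) {
    L[2, 1] <- if (L[1, 1] > 0) S[2, 1] / L[1, 1] else 0
    L[2, 2] <- sqrt(max(S[2, 2] - L[2, 1]^2, 0))
  }
  L
}

# Parameterisations: th (unconstrained) -> variance components.
# All variances on log scale; the additive cross-site correlation on atanh.
reml_param <- function(model, vy) {
  switch(model,
    single = list(
      npar = 3,
      init = log(c(0.3, 0.05, 0.65) * vy),
      unpack = function(th) {
        list(Sg = matrix(exp(th[1]), 1, 1), sig2_b = exp(th[2]),
             sig2_e = exp(th[3]))
      }),
    joint_us = list(
      npar = 6,
      init = c(log(0.3 * vy), log(0.3 * vy), atanh(0.5),
               log(0.05 * vy), log(0.65 * vy), log(0.65 * vy)),
      unpack = function(th) {
        v1 <- exp(th[1]); v2 <- exp(th[2]); r <- tanh(th[3])
        list(Sg = matrix(c(v1, r * sqrt(v1 * v2), r * sqrt(v1 * v2), v2), 2, 2),
             sig2_b = exp(th[4]), sig2_e = exp(th[5:6]))
      }),
    joint_us_r1 = list(
      npar = 5,
      init = c(log(0.3 * vy), log(0.3 * vy),
               log(0.05 * vy), log(0.65 * vy), log(0.65 * vy)),
      unpack = function(th) {
        v1 <- exp(th[1]); v2 <- exp(th[2])
        list(Sg = matrix(c(v1, sqrt(v1 * v2), sqrt(v1 * v2), v2), 2, 2),
             sig2_b = exp(th[3]), sig2_e = exp(th[4:5]))
      }),
    joint_hom = list(
      npar = 4,
      init = log(c(0.2 * vy, 0.1 * vy, 0.05 * vy, 0.65 * vy)),
      unpack = function(th) {
        a <- exp(th[1]); sa <- exp(th[2])
        list(Sg = matrix(c(a + sa, a, a, a + sa), 2, 2),
             sig2_b = exp(th[3]), sig2_e = rep(exp(th[4]), 2),
             sigma2_a = a, sigma2_sa = sa)
      }),
    stop("unknown model: ", model))
}

#' REML fit of the animal model
#'
#' Variance components are estimated by direct maximisation of the
#' restricted log-likelihood (Nelder-Mead on the log-variance /
#' atanh-correlation scale, with restarts), and breeding values for every
#' individual in the kinship matrix -- phenotyped or not -- follow at the
#' converged components. When the kinship carries a low-rank-plus-diagonal
#' factorisation (pedigree A of a two-generation diallel, or a G matrix
#' with modest marker count) the likelihood is evaluated through the
#' Woodbury identity on precomputed crossproducts, making joint-site fits
#' at thousands of trees run in well under a second; otherwise a dense
#' Cholesky path is used.
#'
#' @param pheno phenotype table (`tree`, `site`, `block`, trait column).
#' @param K relationship matrix over at least all phenotyped ids (see
#'   [a_matrix()], [g_matrix()]).
#' @param spec a [model_spec()].
#' @param init optional numeric vector of starting values on the internal
#'   transformed scale.
#' @param se logical: compute a numerical-Hessian covariance of the
#'   variance-component estimates (used for heritability and type-B
#'   standard errors).
#' @param constrain_type_b if `1`, fixes the additive cross-site
#'   correlation at 1 (the constrained model of the one-tailed boundary
#'   LRT); only with unstructured joint scope.
#' @param control list: `restarts` (default 2), `maxit`, `reltol`.
#' @return A `gs_fit` list: `spec`, `vc` (variance components with REML
#'   log-likelihood and convergence flag), `beta`, `ebv` (ids x sites
#'   matrix), `ebv_joint` (per-site average for joint unstructured fits),
#'   `block_blup`, `alpha`, `vcov_theta`, `n`.
#' @export
fit_reml <- function(pheno, K, spec, init = NULL, se = TRUE,
                     constrain_type_b = NULL, control = list()) {
  ctrl <- utils::modifyList(list(restarts = 2, maxit = 2000, reltol = 1e-10),
                            control)
  assert_that(inherits(spec, "model_spec"), "spec must be a model_spec")
  assert_that(spec$trait %in% names(pheno),
              paste0("trait not in phenotype table: ", spec$trait))
  sites <- sort(unique(pheno$site))
  sub <- if (spec$scope == "joint") {
    pheno
  } else if (length(sites) == 1) {
    pheno  # single-site table: the requested site is the one present
  } else {
    k <- if (spec$scope == "site1") 1 else 2
    pheno[pheno$site == sites[k], ]
  }
  sub <- sub[!is.na(sub[[spec$trait]]), ]
  y <- sub[[spec$trait]]
  ids <- sub$tree
  assert_that(all(ids %in% rownames(K)), "phenotyped ids missing from K")
  assert_that(length(y) >= 4, "need at least a handful of observations")
  site_lev <- sort(unique(sub$site))
  S <- length(site_lev)
  site_i <- match(sub$site, site_lev)
  model <- if (spec$scope != "joint") "single" else {
    if (spec$joint_cov == "homogeneous_plus_sa") "joint_hom"
    else if (identical(constrain_type_b, 1) || identical(constrain_type_b, 1L))
      "joint_us_r1" else "joint_us"
  }
  if (model == "single" && S != 1) stop("single-site scope with mixed sites")
  if (startsWith(model, "joint") && S != 2) {
    stop("joint models require exactly two sites", call. = FALSE)
  }

  blk <- factor(sub$block)
  X <- if (S == 1) matrix(1, length(y), 1) else
    cbind(1, as.numeric(site_i == 2))
  colnames(X) <- c("(Intercept)", if (S == 2) "site2")

  par <- reml_param(model, var(y))
  lr <- attr(K, "lowrank")
  use_struct <- FALSE
  if (!is.null(lr) && all(ids %in% rownames(lr$F))) {
    r <- ncol(lr$F)
    ncomp <- if (S == 2) 2 else 1
    k_tot <- nlevels(blk) + ncomp * r
    use_struct <- k_tot <= max(500, 0.75 * length(y))
  }
  ctx <- if (use_struct) {
    reml_ctx_struct(y, X, ids, site_i, blk, lr, S)
  } else if (model == "single") {
    reml_ctx_eigen_single(y, X, ids, blk, K)
  } else {
    reml_ctx_dense(y, X, ids, site_i, blk, K, S)
  }
  negll <- function(th) {
    vcpar <- par$unpack(th)
    -ctx$loglik(vcpar)
  }
  th0 <- init %||% par$init
  best <- NULL
  for (rs in seq_len(ctrl$restarts)) {
    opt <- stats::optim(th0, negll, method = "Nelder-Mead",
                        control = list(maxit = ctrl$maxit,
                                       reltol = ctrl$reltol))
    if (is.null(best) || opt$value < best$value) best <- opt
    if (!is.null(best) && rs > 1 &&
        abs(opt$value - best$value) < 1e-8) break
    th0 <- best$par
  }
  th <- best$par
  vcpar <- par$unpack(th)
  converged <- best$convergence == 0

  vc <- extract_vc(model, vcpar, site_lev)
  vc$loglik <- -best$value
  vc$converged <- converged
  class(vc) <- "var_components"

  sol <- ctx$solve_at(vcpar)
  beta <- sol$beta
  vr <- sol$vinv_resid
  # EBVs for every id in K: a_hat[t] = Sg[t, site(obs)] * K[all, obs] %*% vr
  Sg_full <- vcpar$Sg
  ebv <- matrix(0, nrow(K), S, dimnames = list(rownames(K), site_lev))
  Kao <- K[, ids, drop = FALSE]
  for (t in seq_len(S)) {
    w <- Sg_full[t, site_i] * vr
    ebv[, t] <- Kao %*% w
  }
  blk_blup <- tapply(vr, blk, sum) * vcpar$sig2_b
  alpha <- mean(vcpar$sig2_e) / mean(diag(Sg_full))

  vcov_th <- NULL
  if (isTRUE(se)) {
    H <- tryCatch(stats::optimHess(th, negll), error = function(e) NULL)
    if (!is.null(H)) {
      vcov_th <- tryCatch(solve(H), error = function(e) NULL)
    }
  }
  structure(list(spec = spec, model = model, vc = vc, beta = beta,
                 ebv = ebv,
                 ebv_joint = if (S == 2) rowMeans(ebv) else ebv[, 1],
                 block_blup = blk_blup, alpha = alpha,
                 theta = th, vcov_theta = vcov_th, par = par,
                 site_levels = site_lev, n = length(y),
                 ids = ids, converged = converged),
            class = "gs_fit")
}

extract_vc <- function(model, vcpar, site_lev) {
  Sg <- vcpar$Sg
  out <- switch(model,
    single = list(sigma2_a = Sg[1, 1], sigma2_b = vcpar$sig2_b,
                  sigma2_e = vcpar$sig2_e),
    joint_us = ,
    joint_us_r1 = list(sigma2_a1 = Sg[1, 1], sigma2_a2 = Sg[2, 2],
                       sigma_a12 = Sg[1, 2], sigma2_b = vcpar$sig2_b,
                       sigma2_e1 = vcpar$sig2_e[1],
                       sigma2_e2 = vcpar$sig2_e[2]),
    joint_hom = list(sigma2_a = vcpar$sigma2_a, sigma2_sa = vcpar$sigma2_sa,
                     sigma2_b = vcpar$sig2_b, sigma2_e = vcpar$sig2_e[1]))
  out$model <- model
  out$sites <- site_lev
  out
}

#' @exportS3Method base::print
print.gs_fit <- function(x, ...) {
  cat(sprintf("gs_fit: %s | %s | %s (n = %d, %s)\n", x$spec$trait,
              x$spec$kinship, x$spec$scope, x$n,
              if (x$converged) "converged" else "NOT converged"))
  vc <- x$vc
  nm <- setdiff(names(vc), c("model", "sites", "loglik", "converged"))
  for (k in nm) cat(sprintf("  %-10s %.4g\n", k, vc[[k]]))
  cat(sprintf("  logLik(REML) %.4f\n", vc$loglik))
  invisible(x)
}

# ---- structured (Woodbury) likelihood --------------------------------------
# V = D + U U' with D per-site scalar diagonal d_s = sig2_e[s] + c * Sg[s, s]
# and U = [sigma_b * W | L[s,1] * F | L[s,2] * F] row-blocks per site.
reml_ctx_struct <- function(y, X, ids, site_i, blk, lr, S) {
  r <- ncol(lr$F)
  nb_lev <- levels(blk)
  p <- ncol(X)
  per_site <- lapply(seq_len(S), function(s) {
    rows <- which(site_i == s)
    Bs <- blk[rows, drop = TRUE]
    W <- matrix(0, length(rows), nlevels(Bs))
    W[cbind(seq_along(rows), as.integer(Bs))] <- 1
    Fm <- lr$F[ids[rows], , drop = FALSE]
    B <- cbind(W, Fm)
    list(rows = rows, n = length(rows), nb = nlevels(Bs),
         blk_global = match(levels(Bs), nb_lev),
         B = B, CBB = crossprod(B),
         CBX = crossprod(B, X[rows, , drop = FALSE]),
         CBy = crossprod(B, y[rows]),
         CXX = crossprod(X[rows, , drop = FALSE]),
         CXy = crossprod(X[rows, , drop = FALSE], y[rows]),
         yy = sum(y[rows]^2))
  })
  nb_tot <- length(nb_lev)
  ncomp <- S
  k <- nb_tot + ncomp * r

  assemble <- function(vcpar) {
    L <- chol_lower_small(vcpar$Sg)
    d <- vapply(seq_len(S), function(s) vcpar$sig2_e[s] + lr$c * vcpar$Sg[s, s],
                numeric(1))
    sb <- sqrt(vcpar$sig2_b)
    M <- diag(k)
    qy <- numeric(k)
    qX <- matrix(0, k, ncol(X))
    sc_yy <- 0; sc_XX <- matrix(0, ncol(X), ncol(X)); sc_Xy <- numeric(ncol(X))
    for (s in seq_len(S)) {
      ps <- per_site[[s]]
      ib <- ps$blk_global                      # global block columns
      iw <- seq_len(ps$nb)                     # local W columns in B
      if_ <- ps$nb + seq_len(r)                # local F columns in B
      gcomp <- lapply(seq_len(ncomp), function(m) nb_tot + (m - 1) * r + seq_len(r))
      invd <- 1 / d[s]
      CBB <- ps$CBB
      # block-block
      M[ib, ib] <- M[ib, ib] + sb * sb * invd * CBB[iw, iw, drop = FALSE]
      for (m in seq_len(ncomp)) {
        lm <- L[s, m]
        if (lm == 0) next
        M[ib, gcomp[[m]]] <- M[ib, gcomp[[m]]] +
          sb * lm * invd * CBB[iw, if_, drop = FALSE]
        M[gcomp[[m]], ib] <- M[gcomp[[m]], ib] +
          lm * sb * invd * t(CBB[iw, if_, drop = FALSE])
        for (m2 in seq_len(ncomp)) {
          lm2 <- L[s, m2]
          if (lm2 == 0) next
          M[gcomp[[m]], gcomp[[m2]]] <- M[gcomp[[m]], gcomp[[m2]]] +
            lm * lm2 * invd * CBB[if_, if_, drop = FALSE]
        }
      }
      # q vectors
      qy[ib] <- qy[ib] + sb * invd * ps$CBy[iw]
      qX[ib, ] <- qX[ib, ] + sb * invd * ps$CBX[iw, , drop = FALSE]
      for (m in seq_len(ncomp)) {
        lm <- L[s, m]
        if (lm == 0) next
        qy[gcomp[[m]]] <- qy[gcomp[[m]]] + lm * invd * ps$CBy[if_]
        qX[gcomp[[m]], ] <- qX[gcomp[[m]], ] + lm * invd * ps$CBX[if_, , drop = FALSE]
      }
      sc_yy <- sc_yy + invd * ps$yy
      sc_XX <- sc_XX + invd * ps$CXX
      sc_Xy <- sc_Xy + invd * ps$CXy
    }
    list(L = L, d = d, sb = sb, M = M, qy = qy, qX = qX,
         sc_yy = sc_yy, sc_XX = sc_XX, sc_Xy = sc_Xy)
  }

  loglik <- function(vcpar) {
    a <- assemble(vcpar)
    ch <- tryCatch(chol(a$M), error = function(e) NULL)
    if (is.null(ch)) return(-1e10)
    Minv_qy <- backsolve(ch, forwardsolve(t(ch), a$qy))
    Minv_qX <- backsolve(ch, forwardsolve(t(ch), a$qX))
    ytVy <- a$sc_yy - sum(a$qy * Minv_qy)
    XtVX <- a$sc_XX - crossprod(a$qX, Minv_qX)
    XtVy <- a$sc_Xy - crossprod(a$qX, Minv_qy)
    chx <- tryCatch(chol(XtVX), error = function(e) NULL)
    if (is.null(chx)) return(-1e10)
    beta <- backsolve(chx, forwardsolve(t(chx), XtVy))
    yPy <- ytVy - sum(XtVy * beta)
    logdetV <- sum(vapply(seq_len(S), function(s) per_site[[s]]$n * log(a$d[s]),
                          numeric(1))) + 2 * sum(log(diag(ch)))
    logdetX <- 2 * sum(log(diag(chx)))
    -0.5 * (logdetV + logdetX + yPy)
  }

  solve_at <- function(vcpar) {
    a <- assemble(vcpar)
    ch <- chol(a$M)
    Minv_qy <- backsolve(ch, forwardsolve(t(ch), a$qy))
    Minv_qX <- backsolve(ch, forwardsolve(t(ch), a$qX))
    XtVX <- a$sc_XX - crossprod(a$qX, Minv_qX)
    XtVy <- a$sc_Xy - crossprod(a$qX, Minv_qy)
    beta <- solve(XtVX, XtVy)
    n <- length(y)
    resid <- y - X %*% beta
    # V^-1 r = r/d - D^-1 U M^-1 U' D^-1 r, assembled per site
    vr <- numeric(n)
    # build U' D^-1 r from crossproducts: B' r = CBy - CBX beta
    k_ <- nrow(a$M)
    qr_ <- numeric(k_)
    nb_tot_ <- nb_tot
    for (s in seq_len(S)) {
      ps <- per_site[[s]]
      Br <- ps$CBy - ps$CBX %*% beta
      invd <- 1 / a$d[s]
      iw <- seq_len(ps$nb); if_ <- ps$nb + seq_len(r)
      qr_[ps$blk_global] <- qr_[ps$blk_global] + a$sb * invd * Br[iw]
      for (m in seq_len(ncomp)) {
        lm <- a$L[s, m]
        if (lm == 0) next
        gidx <- nb_tot_ + (m - 1) * r + seq_len(r)
        qr_[gidx] <- qr_[gidx] + lm * invd * Br[if_]
      }
    }
    Minv_qr <- backsolve(ch, forwardsolve(t(ch), qr_))
    for (s in seq_len(S)) {
      ps <- per_site[[s]]
      invd <- 1 / a$d[s]
      iw <- seq_len(ps$nb); if_ <- ps$nb + seq_len(r)
      u_coef <- numeric(ps$nb + r)  # (U M^-1 q)_rows via B_s T_s
      u_coef[iw] <- a$sb * Minv_qr[ps$blk_global]
      for (m in seq_len(ncomp)) {
        lm <- a$L[s, m]
        if (lm == 0) next
        gidx <- nb_tot_ + (m - 1) * r + seq_len(r)
        u_coef[if_] <- u_coef[if_] + lm * Minv_qr[gidx]
      }
      vr[ps$rows] <- invd * (resid[ps$rows] - ps$B %*% u_coef)
    }
    list(beta = as.numeric(beta), vinv_resid = vr)
  }
  list(loglik = loglik, solve_at = solve_at)
}

# ---- single-site eigen-rotation likelihood ---------------------------------
# For a generic dense kinship: rotate once by the eigenvectors of K among
# the phenotyped trees; V becomes diagonal plus a rank-n_blocks term, so
# each likelihood evaluation is O(n * nb^2).
reml_ctx_eigen_single <- function(y, X, ids, blk, K) {
  n <- length(y)
  eg <- eigen(K[ids, ids, drop = FALSE], symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  U <- eg$vectors
  W <- matrix(0, n, nlevels(blk))
  W[cbind(seq_len(n), as.integer(blk))] <- 1
  yt <- crossprod(U, y)
  Xt <- crossprod(U, X)
  Wt <- crossprod(U, W)
  core <- function(vcpar) {
    s2a <- vcpar$Sg[1, 1]; s2e <- vcpar$sig2_e[1]; s2b <- vcpar$sig2_b
    d <- s2a * lam + s2e
    Wd <- Wt / d
    M <- diag(ncol(Wt)) + s2b * crossprod(Wt, Wd)
    ch <- tryCatch(chol(M), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    solveV <- function(b) {
      b_d <- b / d
      b_d - s2b * Wd %*% backsolve(ch, forwardsolve(t(ch),
                                                    crossprod(Wt, b_d)))
    }
    Vi_y <- solveV(yt)
    Vi_X <- solveV(Xt)
    XtVX <- crossprod(Xt, Vi_X)
    XtVy <- crossprod(Xt, Vi_y)
    logdetV <- sum(log(d)) + 2 * sum(log(diag(ch)))
    list(ch = ch, d = d, solveV = solveV, Vi_y = Vi_y, Vi_X = Vi_X,
         XtVX = XtVX, XtVy = XtVy, logdetV = logdetV)
  }
  loglik <- function(vcpar) {
    cc <- core(vcpar)
    if (is.null(cc)) return(-1e10)
    chx <- tryCatch(chol(cc$XtVX), error = function(e) NULL)
    if (is.null(chx)) return(-1e10)
    beta <- backsolve(chx, forwardsolve(t(chx), cc$XtVy))
    yPy <- sum(yt * cc$Vi_y) - sum(cc$XtVy * beta)
    -0.5 * (cc$logdetV + 2 * sum(log(diag(chx))) + yPy)
  }
  solve_at <- function(vcpar) {
    cc <- core(vcpar)
    beta <- solve(cc$XtVX, cc$XtVy)
    rt <- yt - Xt %*% beta
    vr_rot <- cc$solveV(rt)
    list(beta = as.numeric(beta), vinv_resid = as.numeric(U %*% vr_rot))
  }
  list(loglik = loglik, solve_at = solve_at)
}

# ---- dense likelihood ------------------------------------------------------
reml_ctx_dense <- function(y, X, ids, site_i, blk, K, S) {
  n <- length(y)
  Kpp <- K[ids, ids, drop = FALSE]
  same_blk <- outer(as.integer(blk), as.integer(blk), "==") * 1
  site_pair <- list()
  for (s in seq_len(S)) for (t in seq_len(S)) {
    site_pair[[paste(s, t)]] <- outer(site_i == s, site_i == t) * 1
  }
  buildV <- function(vcpar) {
    Sg <- vcpar$Sg
    C <- matrix(0, n, n)
    for (s in seq_len(S)) for (t in seq_len(S)) {
      C <- C + Sg[s, t] * site_pair[[paste(s, t)]]
    }
    V <- Kpp * C + vcpar$sig2_b * same_blk
    diag(V) <- diag(V) + vcpar$sig2_e[site_i]
    V
  }
  loglik <- function(vcpar) {
    V <- buildV(vcpar)
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(-1e10)
    Vi_y <- backsolve(ch, forwardsolve(t(ch), y))
    Vi_X <- backsolve(ch, forwardsolve(t(ch), X))
    XtVX <- crossprod(X, Vi_X)
    XtVy <- crossprod(X, Vi_y)
    chx <- tryCatch(chol(XtVX), error = function(e) NULL)
    if (is.null(chx)) return(-1e10)
    beta <- backsolve(chx, forwardsolve(t(chx), XtVy))
    yPy <- sum(y * Vi_y) - sum(XtVy * beta)
    -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(chx))) + yPy)
  }
  solve_at <- function(vcpar) {
    V <- buildV(vcpar)
    ch <- chol(V)
    Vi_y <- backsolve(ch, forwardsolve(t(ch), y))
    Vi_X <- backsolve(ch, forwardsolve(t(ch), X))
    XtVX <- crossprod(X, Vi_X)
    XtVy <- crossprod(X, Vi_y)
    beta <- solve(XtVX, XtVy)
    resid <- y - X %*% beta
    vr <- backsolve(ch, forwardsolve(t(ch), resid))
    list(beta = as.numeric(beta), vinv_resid = as.numeric(vr))
  }
  list(loglik = loglik, solve_at = solve_at)
}
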