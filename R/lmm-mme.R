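#' Solve Henderson's mixed-model equations
#'
#' Solves the block system
#' \deqn{[X'X, X'Z; Z'X, Z'Z + K^{-1}\alpha] [b; u] = [X'y; Z'y]}
#' with `alpha = sigma2_e / sigma2_a`, returning fixed-effect solutions and
#' BLUPs jointly. Individuals present in `K` but without observations
#' (columns of `Z` that are all zero) receive BLUPs through their kinship
#' ties, which is how validation-set predictions are obtained.
#'
#' @param X fixed-effect incidence matrix (n x p).
#' @param Z random-effect incidence matrix (n x q), columns aligned with
#'   `K_inv`.
#' @param y response vector.
#' @param K_inv inverse relationship matrix (q x q), e.g. from
#'   [invert_relmatrix()].
#' @param alpha positive variance ratio `sigma2_e / sigma2_a`.
#' @return `list(beta, u)`; `u` is named by `K_inv` row names when present.
#' @export
solve_mme <- function(X, Z, y, K_inv, alpha) {
  assert_that(alpha > 0, "alpha must be positive")
  X <- as.matrix(X); Z <- as.matrix(Z)
  assert_that(nrow(X) == length(y) && nrow(Z) == length(y),
              "X, Z, y must have matching rows")
  assert_that(ncol(Z) == nrow(K_inv), "Z columns must match K_inv")
  p <- ncol(X); q <- ncol(Z)
  C <- rbind(cbind(crossprod(X), crossprod(X, Z)),
             cbind(crossprod(Z, X), crossprod(Z) + K_inv * alpha))
  rhs <- c(crossprod(X, y), crossprod(Z, y))
  sol <- tryCatch(solve(C, rhs), error = function(e) NULL)
  if (is.null(sol)) {
    qrr <- qr(C)
    stop(sprintf("singular MME coefficient matrix: rank %d of %d",
                 qrr$rank, nrow(C)), call. = FALSE)
  }
  u <- sol[p + seq_len(q)]
  names(u) <- rownames(K_inv)
  list(beta = sol[seq_len(p)], u = u)
}

#' Kinship BLUP on adjusted phenotypes (single random effect)
#'
#' Fits `y' = mu + a + e`, `a ~ N(0, K sigma2_a)`, the working model of the
#' cross-validation experiments: the variance ratio is estimated by REML
#' through the eigendecomposition of the kinship among the phenotyped
#' (training) individuals, and BLUPs for every individual in `K` --
#' including unphenotyped validation trees -- are recovered from the
#' mixed-model equations at that ratio.
#'
#' @param yprime named vector of adjusted phenotypes (training set).
#' @param K relationship matrix over training and prediction ids.
#' @param alpha optional fixed variance ratio; when `NULL` it is estimated
#'   by REML.
#' @return `list(gebv, mu, sigma2_a, sigma2_e, alpha, h2)`; `gebv` is named
#'   over all ids in `K`.
#' @export
kinship_blup <- function(yprime, K, alpha = NULL) {
  ids_t <- names(yprime)
  assert_that(!is.null(ids_t) && all(ids_t %in% rownames(K)),
              "yprime must be named and covered by K")
  y <- as.numeric(yprime)
  n <- length(y)
  Ktt <- K[ids_t, ids_t, drop = FALSE]
  if (is.null(alpha)) {
    eg <- eigen(Ktt, symmetric = TRUE)
    lam <- pmax(eg$values, 0)
    yr <- crossprod(eg$vectors, y)
    xr <- crossprod(eg$vectors, rep(1, n))
    # profile REML over delta = sigma2_e / sigma2_a
    negll <- function(ldelta) {
      delta <- exp(ldelta)
      d <- lam + delta
      xvx <- sum(xr^2 / d)
      beta <- sum(xr * yr / d) / xvx
      r2 <- sum((yr - xr * beta)^2 / d)
      s2a <- r2 / (n - 1)
      0.5 * (sum(log(d)) + log(xvx) + (n - 1) * (1 + log(s2a)))
    }
    opt <- stats::optimize(negll, c(-12, 12))
    delta <- exp(opt$minimum)
    d <- lam + delta
    xvx <- sum(xr^2 / d)
    mu <- sum(xr * yr / d) / xvx
    s2a <- sum((yr - xr * mu)^2 / d) / (n - 1)
    s2e <- s2a * delta
    alpha <- delta
    vr <- eg$vectors %*% ((yr - xr * mu) / d)
  } else {
    mu <- mean(y)
    V <- Ktt + diag(alpha, n)
    vr <- solve(V, y - mu)
    s2a <- drop(crossprod(y - mu, vr)) / (n - 1)
    s2e <- s2a * alpha
  }
  # a_hat = sigma2_a K[, t] V^-1 r = K[, t] (Ktt + alpha I)^-1 r
  gebv <- drop(K[, ids_t, drop = FALSE] %*% vr)
  names(gebv) <- rownames(K)
  list(gebv = gebv, mu = mu, sigma2_a = s2a, sigma2_e = s2e,
       alpha = alpha, h2 = s2a / (s2a + s2e))
}
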