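#' Pedigree additive (numerator) relationship matrix
#'
#' Tabular (recursive) method: founders have diagonal 1 and are assumed
#' unrelated and non-inbred; for individual `i` with parents `s`, `d`
#' preceding it, `A[i, i] = 1 + 0.5 A[s, d]` and
#' `A[i, j] = 0.5 (A[j, s] + A[j, d])`. Unknown parents contribute 0.
#'
#' For a two-generation design in which every non-founder has two founder
#' parents, `A` restricted to the progeny equals `0.5 I + 0.25 P P'` with
#' `P` the progeny-by-founder incidence matrix; that low-rank-plus-diagonal
#' structure is attached as attribute `lowrank` (`list(c, F, founders)`) and
#' is exploited by the REML fitter.
#'
#' @param ped pedigree data frame (`id`, `sire`, `dam`); reordered
#'   internally so parents precede offspring.
#' @return Dense symmetric matrix with ids as dimnames, attribute
#'   `kind = "A"`.
#' @export
a_matrix <- function(ped) {
  ped <- order_pedigree(ped)
  n <- nrow(ped)
  idx <- setNames(seq_len(n), ped$id)
  si <- ifelse(is.na(ped$sire), 0L, idx[ped$sire])
  di <- ifelse(is.na(ped$dam), 0L, idx[ped$dam])
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1) {
      j <- seq_len(i - 1)
      row_s <- if (s > 0) A[s, j] else 0
      row_d <- if (d > 0) A[d, j] else 0
      aij <- 0.5 * (row_s + row_d)
      A[i, j] <- aij
      A[j, i] <- aij
    }
    A[i, i] <- 1 + if (s > 0 && d > 0) 0.5 * A[s, d] else 0
  }
  attr(A, "kind") <- "A"
  fnd <- founder_ids(ped)
  prog <- setdiff(ped$id, fnd)
  two_gen <- length(prog) > 0 &&
    all(ped$sire[match(prog, ped$id)] %in% fnd) &&
    all(ped$dam[match(prog, ped$id)] %in% fnd)
  if (two_gen) {
    P <- matrix(0, length(prog), length(fnd), dimnames = list(prog, fnd))
    pr <- match(prog, ped$id)
    P[cbind(seq_along(prog), match(ped$sire[pr], fnd))] <-
      P[cbind(seq_along(prog), match(ped$sire[pr], fnd))] + 1
    P[cbind(seq_along(prog), match(ped$dam[pr], fnd))] <-
      P[cbind(seq_along(prog), match(ped$dam[pr], fnd))] + 1
    attr(A, "lowrank") <- list(c = 0.5, F = 0.5 * P, founders = fnd)
  }
  A
}

#' Genomic (VanRaden) relationship matrix
#'
#' `G = (M - P)(M - P)' / (2 sum p_i (1 - p_i))` with `M` the 0/1/2 dosage
#' matrix oriented to the minor allele. Under the default `vanraden`
#' convention column `i` of `P` is `2 p_i` (dosages centred at twice the
#' allele frequency). The `shifted` convention instead uses
#' `2 (p_i - 0.5)` -- the form sometimes printed alongside 0/1/2 coding,
#' which actually centres a -1/0/1 coding -- and is provided for
#' comparability only. Monomorphic markers (`p` of 0 or 1) are excluded.
#'
#' @param geno complete [genotype_matrix()] (impute first).
#' @param convention `"vanraden"` (default) or `"shifted"`.
#' @return Dense symmetric matrix with ids as dimnames, attributes
#'   `kind = "G"` and (when the marker count does not exceed the sample
#'   count) a `lowrank` factor used by the REML fitter.
#' @export
g_matrix <- function(geno, convention = c("vanraden", "shifted")) {
  convention <- match.arg(convention)
  assert_that(!anyNA(geno$dosage), "G requires a complete dosage matrix; impute first")
  geno <- orient_minor(geno)
  p <- geno$af
  keep <- p > 0 & p < 1
  assert_that(any(keep), "all markers monomorphic: zero denominator")
  M <- geno$dosage[, keep, drop = FALSE]
  p <- p[keep]
  ctr <- if (convention == "vanraden") 2 * p else 2 * (p - 0.5)
  Zc <- sweep(M, 2, ctr)
  denom <- 2 * sum(p * (1 - p))
  G <- tcrossprod(Zc) / denom
  attr(G, "kind") <- "G"
  if (ncol(Zc) <= nrow(Zc) * 4) {
    attr(G, "lowrank") <- list(c = 0, F = Zc / sqrt(denom))
  }
  G
}

#' Invert a relationship matrix with ridge fallback
#'
#' Returns `(K + ridge I)^-1` via Cholesky factorization. With the default
#' `ridge = 0`, a failed factorization triggers one automatic retry with
#' ridge `1e-6` (logged); if that also fails the error reports the
#' reciprocal condition number.
#'
#' @param K symmetric matrix.
#' @param ridge nonnegative scalar added to the diagonal.
#' @return The inverse, with attribute `ridge` recording the value used.
#' @export
invert_relmatrix <- function(K, ridge = 0) {
  assert_that(isSymmetric(unname(K), tol = 1e-8), "K must be symmetric")
  assert_that(ridge >= 0, "ridge must be nonnegative")
  try_inv <- function(r) {
    Kr <- K + diag(r, nrow(K))
    ch <- tryCatch(chol(Kr), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    chol2inv(ch)
  }
  inv <- try_inv(ridge)
  used <- ridge
  if (is.null(inv)) {
    used <- max(ridge, 1e-6)
    dgs_log("factorization failed; retrying with ridge ", used)
    inv <- try_inv(used)
  }
  if (is.null(inv)) {
    stop(sprintf("matrix singular even with ridge %g (rcond = %.3e)",
                 used, rcond(K)), call. = FALSE)
  }
  dimnames(inv) <- dimnames(K)
  attr(inv, "ridge") <- used
  attr(inv, "kind") <- paste0(attr(K, "kind") %||% "K", "_inv")
  inv
}

# Restrict a relationship matrix to ids, carrying the lowrank factor along.
subset_relmatrix <- function(K, ids) {
  out <- K[ids, ids, drop = FALSE]
  lr <- attr(K, "lowrank")
  if (!is.null(lr) && all(ids %in% rownames(lr$F))) {
    lr$F <- lr$F[ids, , drop = FALSE]
    attr(out, "lowrank") <- lr
  }
  attr(out, "kind") <- attr(K, "kind")
  out
}
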