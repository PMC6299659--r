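#' Construct a genotype dosage matrix
#'
#' @param dosage numeric matrix, samples x markers, entries in `{0, 1, 2}`
#'   (real-valued dosages are allowed after mean imputation) with `NA` for
#'   missing; must carry row and column names.
#' @return A `genotype_matrix` object: the dosage matrix plus per-marker
#'   observed alternate-allele frequency `af` (from non-missing entries) and
#'   minor-allele frequency `maf = pmin(af, 1 - af)`.
#' @export
genotype_matrix <- function(dosage) {
  assert_that(is.matrix(dosage), "dosage must be a matrix")
  assert_that(!is.null(rownames(dosage)) && !is.null(colnames(dosage)),
              "dosage needs sample rownames and marker colnames")
  af <- colMeans(dosage, na.rm = TRUE) / 2
  structure(list(dosage = dosage,
                 ids = rownames(dosage),
                 markers = colnames(dosage),
                 af = af,
                 maf = pmin(af, 1 - af)),
            class = "genotype_matrix")
}

#' @exportS3Method base::print
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d markers (%.2f%% missing)\n",
              length(x$ids), length(x$markers),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' Orient markers to the minor allele
#'
#' Flips the coding (dosage -> 2 - dosage) of markers whose alternate-allele
#' frequency exceeds 0.5 so that every column counts copies of the minor
#' allele and `af <= 0.5`.
#'
#' @param geno a [genotype_matrix()].
#' @return A reoriented `genotype_matrix`.
#' @export
orient_minor <- function(geno) {
  flip <- which(geno$af > 0.5)
  if (length(flip)) {
    geno$dosage[, flip] <- 2 - geno$dosage[, flip]
    geno <- genotype_matrix(geno$dosage)
  }
  geno
}

#' Gene-drop SNP genotypes through a pedigree
#'
#' Founders receive two alleles i.i.d. Bernoulli(p) per locus with founder
#' frequencies drawn uniformly from `cfg$maf_range`; each non-founder
#' receives one allele transmitted at random from each parent per locus.
#' Markers are unlinked. Dosage is the allele sum.
#'
#' @param ped a pedigree from [make_diallel_pedigree()] (or any pedigree in
#'   which every individual has either two known parents or none).
#' @param cfg a [sim_config()].
#' @return A [genotype_matrix()] over all pedigree individuals. The founder
#'   allele frequencies are attached as attribute `founder_af`.
#' @export
drop_genotypes <- function(ped, cfg) {
  one_parent <- xor(is.na(ped$sire), is.na(ped$dam))
  if (any(one_parent)) {
    stop(paste0("individuals with exactly one known parent are not supported: ",
                paste(utils::head(ped$id[one_parent], 5), collapse = ", ")),
         call. = FALSE)
  }
  ped <- order_pedigree(ped)
  m <- cfg$n_markers
  n <- nrow(ped)
  with_seed(stage_seed(cfg$seed, "genotypes"), {
    p <- runif(m, cfg$maf_range[1], cfg$maf_range[2])
    h1 <- matrix(0L, n, m, dimnames = list(ped$id, NULL))
    h2 <- h1
    fnd <- which(is.na(ped$sire))
    nf <- length(fnd)
    h1[fnd, ] <- matrix(rbinom(nf * m, 1L, rep(p, each = nf)), nf, m)
    h2[fnd, ] <- matrix(rbinom(nf * m, 1L, rep(p, each = nf)), nf, m)
    idx <- setNames(seq_len(n), ped$id)
    prog <- which(!is.na(ped$sire))
    # Generation by generation so parental haplotypes are always filled in.
    gen <- ped$generation %||% ifelse(is.na(ped$sire), 0L, 1L)
    for (g in sort(unique(gen[prog]))) {
      rows <- prog[gen[prog] == g]
      si <- idx[ped$sire[rows]]
      di <- idx[ped$dam[rows]]
      pick_s <- matrix(runif(length(rows) * m) < 0.5, length(rows), m)
      pick_d <- matrix(runif(length(rows) * m) < 0.5, length(rows), m)
      h1[rows, ] <- ifelse(pick_s, h1[si, , drop = FALSE], h2[si, , drop = FALSE])
      h2[rows, ] <- ifelse(pick_d, h1[di, , drop = FALSE], h2[di, , drop = FALSE])
    }
    dos <- h1 + h2
    colnames(dos) <- sprintf("M%05d", seq_len(m))
    out <- genotype_matrix(dos)
    attr(out, "founder_af") <- p
    out
  })
}
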