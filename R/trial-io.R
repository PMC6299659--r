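#' Write a trial to standard files
#'
#' Emits a VCF v4.2 (one sample per individual, `GT:GQ:DP` fields), a
#' pedigree CSV (`id,sire,dam`, `0` = unknown) and a phenotype CSV
#' (`tree,family,dam,sire,site,block,<traits>`). [read_trial()] round-trips
#' these losslessly at the dosage level.
#'
#' @param geno [genotype_matrix()]; `NA` dosages are written as `./.`.
#' @param ped pedigree data frame.
#' @param pheno phenotype table from [simulate_phenotypes()].
#' @param dir output directory (created if needed).
#' @param gq,dp optional integer matrices (same shape as the dosage matrix)
#'   of per-genotype quality and depth; defaults are GQ 99 and DP 30.
#' @return Invisibly, the named vector of file paths written.
#' @export
write_trial <- function(geno, ped, pheno, dir, gq = NULL, dp = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(vcf = file.path(dir, "genotypes.vcf"),
             ped = file.path(dir, "pedigree.csv"),
             pheno = file.path(dir, "phenotypes.csv"))
  write_vcf(geno, paths["vcf"], gq = gq, dp = dp)
  pd <- data.frame(id = ped$id,
                   sire = ifelse(is.na(ped$sire), "0", ped$sire),
                   dam = ifelse(is.na(ped$dam), "0", ped$dam),
                   stringsAsFactors = FALSE)
  write.csv(pd, paths["ped"], row.names = FALSE, quote = FALSE)
  write.csv(pheno, paths["pheno"], row.names = FALSE, quote = FALSE)
  invisible(paths)
}

# Plain-text VCF v4.2 emitter. Marker coding: dosage counts ALT alleles.
write_vcf <- function(geno, path, gq = NULL, dp = NULL) {
  dos <- geno$dosage
  n <- nrow(dos); m <- ncol(dos)
  if (is.null(gq)) gq <- matrix(99L, n, m)
  if (is.null(dp)) dp <- matrix(30L, n, m)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=diallelGS",
    "##contig=<ID=chr1>",
    '##INFO=<ID=NS,Number=1,Type=Integer,Description="Number of samples">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(dos)), collapse = "\t"))
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  body <- vapply(seq_len(m), function(j) {
    d <- dos[, j]
    gt <- ifelse(is.na(d), "./.", gt_code[as.character(round(d))])
    fld <- paste(gt, gq[, j], dp[, j], sep = ":")
    paste(c("chr1", j * 100L, colnames(dos)[j], "A", "G", ".", "PASS",
            paste0("NS=", sum(!is.na(d))), "GT:GQ:DP", fld), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a trial from a directory written by [write_trial()]
#'
#' Genotypes are parsed with `vcfR`; `./.` genotypes become `NA` dosages.
#' The pedigree is topologically reordered if offspring precede parents and
#' a cycle raises a diagnostic error. Sample ids must agree across the
#' three files.
#'
#' @param dir directory containing `genotypes.vcf`, `pedigree.csv`,
#'   `phenotypes.csv`.
#' @return A list `geno`, `ped`, `pheno`.
#' @export
read_trial <- function(dir) {
  vcf_path <- file.path(dir, "genotypes.vcf")
  assert_that(file.exists(vcf_path), paste0("missing VCF: ", vcf_path))
  geno <- read_vcf_genotypes(vcf_path)
  pd <- read.csv(file.path(dir, "pedigree.csv"), stringsAsFactors = FALSE,
                 colClasses = "character")
  ped <- data.frame(id = pd$id,
                    sire = ifelse(pd$sire == "0", NA_character_, pd$sire),
                    dam = ifelse(pd$dam == "0", NA_character_, pd$dam),
                    stringsAsFactors = FALSE)
  ped$generation <- ifelse(is.na(ped$sire) & is.na(ped$dam), 0L, 1L)
  ped <- order_pedigree(ped)
  pheno <- read.csv(file.path(dir, "phenotypes.csv"), stringsAsFactors = FALSE)
  bad <- setdiff(pheno$tree, ped$id)
  assert_that(length(bad) == 0,
              paste0("phenotyped trees absent from pedigree: ",
                     paste(utils::head(bad, 5), collapse = ", ")))
  bad <- setdiff(geno$ids, ped$id)
  assert_that(length(bad) == 0,
              paste0("VCF samples absent from pedigree: ",
                     paste(utils::head(bad, 5), collapse = ", ")))
  list(geno = geno, ped = ped, pheno = pheno)
}

# Parse a VCF into a genotype_matrix (GT only; GQ/DP retained as attributes
# when present). Thin wrapper over vcfR.
read_vcf_genotypes <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  if (!"GT" %in% strsplit(vcf@gt[1, "FORMAT"], ":")[[1]]) {
    stop("VCF lacks GT field", call. = FALSE)
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  dos <- gt_to_dosage(gt)
  ids <- colnames(gt)
  markers <- vcfR::getID(vcf)
  if (anyNA(markers)) markers <- paste0("V", seq_along(markers))
  dimnames(dos) <- list(markers, ids)
  out <- genotype_matrix(t(dos))
  fmt <- strsplit(vcf@gt[1, "FORMAT"], ":")[[1]]
  for (el in c("GQ", "DP")) {
    if (el %in% fmt) {
      v <- vcfR::extract.gt(vcf, element = el, as.numeric = TRUE)
      dimnames(v) <- list(markers, ids)
      attr(out, tolower(el)) <- t(v)
    }
  }
  attr(out, "vcf_meta") <- data.frame(
    id = markers,
    ref = vcfR::getREF(vcf), alt = vcfR::getALT(vcf),
    stringsAsFactors = FALSE)
  out
}

gt_to_dosage <- function(gt) {
  d <- matrix(NA_real_, nrow(gt), ncol(gt))
  clean <- gsub("\\|", "/", gt)
  d[clean %in% c("0/0")] <- 0
  d[clean %in% c("0/1", "1/0")] <- 1
  d[clean %in% c("1/1")] <- 2
  d
}
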