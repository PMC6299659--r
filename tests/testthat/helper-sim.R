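# Shared fixtures built in code; cached so expensive objects are made once
# per test run.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Small two-trait diallel trial (~330 trees over 2 sites).
small_sim <- function() {
  cached("small_sim", {
    cfg <- sim_config(
      n_parents = 20, n_families = 30, progeny_range = c(5L, 6L),
      n_markers = 600, n_qtl = 300, seed = 20260927,
      trait_specs = list(
        trait_spec("height", h2 = 0.15, type_b = 0.45, mean = 700, sd_p = 77),
        trait_spec("pilodyn", h2 = 0.40, type_b = 0.90, mean = 22, sd_p = 2.3)))
    sim <- simulate_trial(cfg)
    sim$cfg <- cfg
    sim$A <- a_matrix(sim$ped)
    sim
  })
}

# Deterministic toy pedigree: 2 founders, full sibs, half sibs, and a
# third generation.
toy_pedigree <- function() {
  data.frame(
    id = c("f1", "f2", "f3", "o1", "o2", "h1", "g1", "g2", "u1", "u2"),
    sire = c(NA, NA, NA, "f1", "f1", "f1", "o1", "o1", NA, NA),
    dam = c(NA, NA, NA, "f2", "f2", "f3", "h1", "h1", NA, NA),
    stringsAsFactors = FALSE)
}

# Hand-enumerated toy VCF: 10 records of which 3 are indels, 1 is
# triallelic, and 1 SNP has MAF 0.004 in n = 500 samples.
write_toy_qc_vcf <- function(path, n = 500) {
  samples <- sprintf("s%03d", seq_len(n))
  header <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="GQ">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="DP">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  gt_common <- function(n_het) {
    c(rep("0/1:99:30", n_het), rep("0/0:99:30", n - n_het))
  }
  rec <- function(pos, id, ref, alt, gts) {
    paste(c("chr1", pos, id, ref, alt, ".", "PASS", ".", "GT:GQ:DP", gts),
          collapse = "\t")
  }
  body <- c(
    rec(100, "v01", "A", "G", gt_common(200)),
    rec(200, "v02", "AT", "A", gt_common(200)),       # indel (deletion)
    rec(300, "v03", "C", "CGG", gt_common(200)),      # indel (insertion)
    rec(400, "v04", "G", "T", gt_common(150)),
    rec(500, "v05", "T", "TA", gt_common(200)),       # indel
    rec(600, "v06", "A", "C,T", gt_common(200)),      # triallelic
    rec(700, "v07", "G", "A", gt_common(4)),          # MAF 4/1000 = 0.004
    rec(800, "v08", "C", "G", gt_common(300)),
    rec(900, "v09", "T", "C", gt_common(120)),
    rec(1000, "v10", "A", "T", gt_common(80)))
  writeLines(c(header, body), path)
  path
}

# Pedigree-free phenotype table around a given set of ids, for null-model
# and boundary tests.
null_pheno <- function(ids, site = "S1", n_blocks = 5, sd_e = 1, seed = 1) {
  set.seed(seed)
  data.frame(tree = ids, site = site,
             block = paste0(site, "B", sample(seq_len(n_blocks),
                                              length(ids), replace = TRUE)),
             y = rnorm(length(ids), 0, sd_e),
             stringsAsFactors = FALSE)
}
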