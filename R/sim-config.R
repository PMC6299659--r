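#' Trait specification for the synthetic trial generator
#'
#' Describes one trait's generative targets: the per-site narrow-sense
#' heritability, the type-B additive genetic correlation between the two
#' sites (values well below 1 mean strong genotype-by-environment
#' interaction), and the phenotypic location/scale used to put the trait on
#' field-realistic units.
#'
#' @param name trait name (column name in the phenotype table).
#' @param h2 target per-site narrow-sense heritability, in (0, 1).
#' @param type_b target type-B additive correlation between sites, in [0, 1].
#' @param mean phenotypic mean at site 1 (trait units).
#' @param sd_p phenotypic standard deviation per site (trait units).
#' @return A `trait_spec` list.
#' @export
trait_spec <- function(name, h2, type_b, mean = 0, sd_p = 1) {
  assert_that(is.character(name) && length(name) == 1, "name must be a string")
  assert_that(h2 > 0 && h2 < 1, "h2 must be in (0, 1)")
  assert_that(type_b >= 0 && type_b <= 1, "type_b must be in [0, 1]")
  assert_that(sd_p > 0, "sd_p must be positive")
  structure(list(name = name, h2 = h2, type_b = type_b,
                 mean = mean, sd_p = sd_p),
            class = "trait_spec")
}

default_trait_specs <- function() {
  list(
    trait_spec("height",   h2 = 0.15, type_b = 0.45, mean = 700, sd_p = 77),
    trait_spec("pilodyn",  h2 = 0.40, type_b = 0.90, mean = 22,  sd_p = 2.3),
    trait_spec("velocity", h2 = 0.50, type_b = 0.85, mean = 3.6, sd_p = 0.27),
    trait_spec("moe",      h2 = 0.45, type_b = 0.90, mean = 10,  sd_p = 4)
  )
}

#' Configuration of a synthetic partial-diallel progeny trial
#'
#' The defaults emulate the mating and field design of a two-site Norway
#' spruce control-pollinated progeny test: 55 founder parents crossed into
#' 128 distinct full-sib families, 5-20 progeny per family per site, and 44
#' randomized post-blocks per site. Traits default to a low-heritability
#' growth trait with strong genotype-by-environment interaction (height) and
#' moderate-heritability wood quality traits with weak interaction (Pilodyn
#' penetration, acoustic velocity, modulus of elasticity).
#'
#' @param n_parents number of unrelated founder parents.
#' @param n_families number of distinct full-sib families (unordered parent
#'   pairs); must not exceed `choose(n_parents, 2)`.
#' @param progeny_range integer vector `c(min, max)`: progeny per family per
#'   site are drawn uniformly from this range.
#' @param n_sites number of test sites (the analysis assumes 2).
#' @param n_markers number of unlinked biallelic SNP markers.
#' @param n_qtl number of causal markers per trait (a subset of the
#'   genotyped markers); must not exceed `n_markers`.
#' @param maf_range founder minor-allele frequency range, in (0, 0.5].
#' @param trait_specs list of [trait_spec()] objects.
#' @param n_blocks_per_site number of post-blocks per site.
#' @param block_var_frac block variance as a fraction of the phenotypic
#'   variance.
#' @param site_offset_sd fixed site effects, expressed per site in units of
#'   the trait's phenotypic standard deviation.
#' @param seed global integer seed; all stage-level randomness is derived
#'   deterministically from it.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_parents = 55, n_families = 128,
                       progeny_range = c(5L, 20L), n_sites = 2,
                       n_markers = 5000, n_qtl = 500,
                       maf_range = c(0.05, 0.5),
                       trait_specs = default_trait_specs(),
                       n_blocks_per_site = 44,
                       block_var_frac = 0.10,
                       site_offset_sd = c(0, 0.5),
                       seed = 1L) {
  cfg <- list(n_parents = as.integer(n_parents),
              n_families = as.integer(n_families),
              progeny_range = as.integer(progeny_range),
              n_sites = as.integer(n_sites),
              n_markers = as.integer(n_markers),
              n_qtl = as.integer(n_qtl),
              maf_range = as.numeric(maf_range),
              trait_specs = trait_specs,
              n_blocks_per_site = as.integer(n_blocks_per_site),
              block_var_frac = as.numeric(block_var_frac),
              site_offset_sd = as.numeric(site_offset_sd),
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  assert_that(cfg$n_parents >= 2, "need at least 2 parents")
  max_fam <- choose(cfg$n_parents, 2)
  if (cfg$n_families > max_fam) {
    stop(sprintf(
      "configuration error: %d families requested but only %d distinct parent pairs exist",
      cfg$n_families, max_fam), call. = FALSE)
  }
  assert_that(length(cfg$progeny_range) == 2 &&
                cfg$progeny_range[1] >= 1 &&
                cfg$progeny_range[1] <= cfg$progeny_range[2],
              "progeny_range must be an increasing positive integer pair")
  assert_that(cfg$n_sites >= 1, "n_sites must be >= 1")
  assert_that(cfg$n_qtl <= cfg$n_markers,
              "configuration error: n_qtl must not exceed n_markers")
  assert_that(all(cfg$maf_range > 0) && all(cfg$maf_range <= 0.5) &&
                cfg$maf_range[1] <= cfg$maf_range[2],
              "maf_range must lie in (0, 0.5]")
  for (ts in cfg$trait_specs) {
    assert_that(inherits(ts, "trait_spec"), "trait_specs must be trait_spec objects")
  }
  assert_that(cfg$block_var_frac >= 0 && cfg$block_var_frac < 1,
              "block_var_frac must be in [0, 1)")
  assert_that(length(cfg$site_offset_sd) >= cfg$n_sites,
              "site_offset_sd must give one offset per site")
  invisible(cfg)
}
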