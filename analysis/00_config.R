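# Shared configuration for the analysis scripts. Everything runs at desk
# scale: the trial matches the study design (55 parents, 128 full-sib
# families over two sites) with ~1280 trees per site and a 3000-marker
# panel, which keeps every script interactive on one CPU.

library(diallelGS)

ANALYSIS_SEED <- 20260927L
OUT_ROOT <- file.path("results")
TRIAL_DIR <- file.path(OUT_ROOT, "trial")
dir.create(OUT_ROOT, showWarnings = FALSE, recursive = TRUE)

trial_config <- function(seed = ANALYSIS_SEED) {
  sim_config(
    n_parents = 55, n_families = 128, progeny_range = c(8L, 12L),
    n_sites = 2, n_markers = 3000, n_qtl = 1000,
    trait_specs = list(
      trait_spec("height",   h2 = 0.15, type_b = 0.45, mean = 700, sd_p = 77),
      trait_spec("pilodyn",  h2 = 0.40, type_b = 0.90, mean = 22,  sd_p = 2.3),
      trait_spec("velocity", h2 = 0.50, type_b = 0.85, mean = 3.6, sd_p = 0.27),
      trait_spec("moe",      h2 = 0.45, type_b = 0.90, mean = 10,  sd_p = 4)),
    seed = seed)
}

load_trial <- function() {
  stopifnot(dir.exists(TRIAL_DIR))
  read_trial(TRIAL_DIR)
}
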