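#!/usr/bin/env Rscript
# The cross-validation experiment grid: statistical methods across
# training/validation ratios, site scenarios (within, cross, joint),
# relatedness structures, family and trees-per-family subsampling, and
# marker subsets (random vs largest positive single-marker effects).
# Replicate counts and grid resolutions are desk-scale; each cell appends
# its replicate rows to results/cv_records.csv as it completes, and a
# rerun skips cells already on file, so an interrupted grid resumes where
# it stopped.

source(file.path("analysis", "00_config.R"))

trial <- load_trial()
geno <- readRDS(file.path(OUT_ROOT, "geno_qc.rds"))
traits <- c("height", "pilodyn")
data <- gs_data(trial$ped, geno, trial$pheno, traits = traits)
seed <- ANALYSIS_SEED + 4

records_file <- file.path(OUT_ROOT, "cv_records.csv")
prior_recs <- if (file.exists(records_file)) read.csv(records_file) else NULL
cell_key <- function(df) {
  paste(df$model, df$trait, df$scope, df$split, df$split_param,
        df$subset, df$m_markers, sep = "|")
}
done_cells <- if (!is.null(prior_recs)) unique(cell_key(prior_recs)) else
  character(0)
push <- function(scn, data) {
  probe <- data.frame(model = scn$model, trait = scn$trait,
                      scope = scn$scope, split = scn$split$type,
                      split_param = diallelGS:::split_param_of(scn$split),
                      subset = scn$marker_subset$type,
                      m_markers = scn$marker_subset$m %||% NA_integer_)
  if (cell_key(probe) %in% done_cells) {
    cat("cached:", cell_key(probe), "\n")
    return(invisible(NULL))
  }
  r <- run_scenario(scn, data)
  write.table(r, records_file, sep = ",", row.names = FALSE,
              col.names = !file.exists(records_file), append =
                file.exists(records_file))
  invisible(NULL)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

## BLUP methods x TS/VS ratio; the Bayesian samplers and RKHS join at the
## 9:1 ratio on a 600-marker panel (their per-fit cost scales with
## markers x trees x iterations, so the ratio sweep uses the BLUPs)
for (tr in traits) {
  for (model in c("ablup", "gblup")) {
    for (ratio in c(1, 3, 5, 7, 9)) {
      scn <- cv_scenario(model, tr, scope = "joint",
                         split = list(type = "ratio", ratio = ratio),
                         n_replicates = 3, seed = seed)
      push(scn, data)
      cat(sprintf("done: %s %s ratio %d:1\n", tr, model, ratio))
    }
  }
  for (model in c("brr", "blasso", "rkhs")) {
    # RKHS samples one coefficient per kernel eigenvector (~ per tree) each
    # sweep, so it runs within one site and with a single replicate; the
    # marker regressions run on the pooled sites
    scope <- if (model == "rkhs") "within_site1" else "joint"
    scn <- cv_scenario(model, tr, scope = scope,
                       split = list(type = "ratio", ratio = 9),
                       marker_subset = list(type = "random", m = 600),
                       n_replicates = if (model == "rkhs") 1 else 2,
                       seed = seed)
    push(scn, data)
    cat(sprintf("done: %s %s ratio 9:1\n", tr, model))
  }
}

## site scenarios (within, cross, joint) for ABLUP/GBLUP
for (tr in traits) {
  for (model in c("ablup", "gblup")) {
    for (scope in c("within_site1", "within_site2", "cross_1to2",
                    "cross_2to1", "joint")) {
      scn <- cv_scenario(model, tr, scope = scope,
                         split = list(type = "kfold", k = 10),
                         n_replicates = if (startsWith(scope, "cross")) 1 else 2,
                         seed = seed)
      push(scn, data)
    }
    cat(sprintf("done: site scenarios %s %s\n", tr, model))
  }
}

## relatedness structures
for (tr in traits) {
  for (model in c("ablup", "gblup")) {
    for (mode in c("full_sib", "half_sib", "unrelated")) {
      scn <- cv_scenario(model, tr, scope = "joint",
                         split = list(type = "relatedness", mode = mode),
                         n_replicates = 5, seed = seed)
      push(scn, data)
    }
  }
  cat(sprintf("done: relatedness %s\n", tr))
}

## number of families and trees per family (GBLUP + ABLUP)
for (model in c("ablup", "gblup")) {
  for (nf in c(10, 30, 60, 90, 120)) {
    scn <- cv_scenario(model, "height", scope = "joint",
                       split = list(type = "families", n_families = nf),
                       n_replicates = 3, seed = seed)
    push(scn, data)
  }
  for (npf in c(1, 2, 4, 8, 12, 16, 20)) {
    scn <- cv_scenario(model, "height", scope = "joint",
                       split = list(type = "trees", n_per_family = npf),
                       n_replicates = 3, seed = seed)
    push(scn, data)
  }
  cat(sprintf("done: family/tree subsampling %s\n", model))
}

## marker subsets: random vs largest positive effects
for (m in c(50, 100, 250, 500, 1000, 2000)) {
  for (mode in c("random", "largest_positive")) {
    scn <- cv_scenario("gblup", "height", scope = "joint",
                       split = list(type = "ratio", ratio = 9),
                       marker_subset = list(type = mode, m = m),
                       n_replicates = 3, seed = seed)
    push(scn, data)
  }
  cat(sprintf("done: marker subsets m = %d\n", m))
}

all_recs <- read.csv(records_file)
summ <- summarize_metrics(all_recs)
write.csv(summ, file.path(OUT_ROOT, "cv_summary.csv"), row.names = FALSE)
cat(sprintf("grid complete: %d replicate records over %d cells\n",
            nrow(all_recs), nrow(summ)))
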