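#' Declare one cross-validation experiment cell
#'
#' @param model `"ablup"`, `"gblup"`, `"brr"`, `"blasso"` or `"rkhs"`.
#' @param trait trait name.
#' @param scope `"within_site1"`, `"within_site2"`, `"cross_1to2"`,
#'   `"cross_2to1"` or `"joint"`.
#' @param split a list with `type` in `"kfold"`, `"ratio"`, `"relatedness"`,
#'   `"families"`, `"trees"` plus its parameter (`k`, `ratio`, `mode`,
#'   `n_families`, `n_per_family`); ignored for cross-site scopes (the
#'   whole training site trains).
#' @param marker_subset `list(type = "all")`, `list(type = "random", m = )`
#'   or `list(type = "largest_positive", m = )`.
#' @param n_replicates number of replicate runs (default 10).
#' @param seed base seed; replicate `i` uses `seed + i`.
#' @return A `cv_scenario` list.
#' @export
cv_scenario <- function(model, trait, scope = "joint",
                        split = list(type = "kfold", k = 10),
                        marker_subset = list(type = "all"),
                        n_replicates = 10, seed = 1L) {
  model <- match.arg(model, c("ablup", "gblup", "brr", "blasso", "rkhs"))
  scope <- match.arg(scope, c("within_site1", "within_site2",
                              "cross_1to2", "cross_2to1", "joint"))
  assert_that(is.list(split) && !is.null(split$type) && length(split$type) == 1,
              "split must be a list with exactly one type")
  assert_that(n_replicates >= 1, "n_replicates must be >= 1")
  structure(list(model = model, trait = trait, scope = scope, split = split,
                 marker_subset = marker_subset,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "cv_scenario")
}

#' Single-marker regression marker selection
#'
#' `random` draws a uniform subset; `largest_positive` regresses the
#' adjusted phenotype on each marker separately in the training set only,
#' ranks by the signed estimate in descending order, and takes the top
#' `m` (so negating a marker's coding flips its eligibility). Markers
#' monomorphic in the training set are excluded from ranking.
#'
#' @param yprime named adjusted phenotypes (training trees only).
#' @param geno [genotype_matrix()].
#' @param mode `"random"` or `"largest_positive"`.
#' @param m subset size.
#' @param seed RNG seed (random mode).
#' @return Character vector of selected marker ids.
#' @export
select_markers <- function(yprime, geno, mode = c("random", "largest_positive"),
                           m, seed = 1L) {
  mode <- match.arg(mode)
  ids <- names(yprime)
  X <- geno$dosage[ids, , drop = FALSE]
  v <- apply(X, 2, var)
  usable <- colnames(X)[v > 0]
  assert_that(m <= length(usable),
              sprintf("m = %d exceeds %d usable markers", m, length(usable)))
  if (mode == "random") {
    return(with_seed(seed, sample(usable, m)))
  }
  y <- as.numeric(yprime)
  yc <- y - mean(y)
  Xu <- X[, usable, drop = FALSE]
  beta <- as.numeric(crossprod(Xu, yc)) / (v[usable] * (length(y) - 1))
  usable[order(beta, decreasing = TRUE)[seq_len(m)]]
}

#' Bundle trial data and reference breeding values for cross-validation
#'
#' Builds the pedigree and genomic relationship matrices, fits the
#' joint-site unstructured pedigree model per trait to obtain the
#' reference ("true") EBVs -- per-site EBVs for within/cross-site
#' scenarios and their average for joint scenarios -- and the adjusted
#' phenotypes `y'` (block-corrected, per-site standardized).
#'
#' @param ped,geno,pheno trial components ([simulate_trial()] or
#'   [read_trial()]); `geno` must be complete (impute first).
#' @param traits trait columns to prepare (default: all numeric trait
#'   columns present).
#' @param K_A,K_G optional precomputed relationship matrices.
#' @return A `gs_data` list used by [run_scenario()].
#' @export
gs_data <- function(ped, geno, pheno, traits = NULL, K_A = NULL, K_G = NULL) {
  if (is.null(traits)) {
    traits <- setdiff(names(pheno)[vapply(pheno, is.numeric, logical(1))],
                      c("tree", "site", "block"))
  }
  K_A <- K_A %||% a_matrix(ped)
  K_G <- K_G %||% g_matrix(geno)
  fam_of <- {
    asg <- tryCatch(pedigree_assignment(ped), error = function(e) NULL)
    if (!is.null(asg)) setNames(asg$family, asg$id)
    else setNames(pheno$family, pheno$tree)
  }
  sites <- sort(unique(pheno$site))
  trait_info <- list()
  for (tr in traits) {
    fit <- fit_reml(pheno, K_A, model_spec(tr, kinship = "A", scope = "joint",
                                           joint_cov = "unstructured"),
                    se = FALSE)
    yprime <- adjust_phenotypes(pheno, fit, trait = tr)
    trait_info[[tr]] <- list(ref_ebv = fit$ebv, ref_joint = fit$ebv_joint,
                             yprime = yprime, fit = fit)
  }
  structure(list(ped = ped, geno = geno, pheno = pheno,
                 K_A = K_A, K_G = K_G, fam_of = fam_of,
                 sites = sites, traits = trait_info),
            class = "gs_data")
}

scope_ids <- function(data, scope) {
  ph <- data$pheno
  s <- data$sites
  switch(scope,
         within_site1 = list(pool = ph$tree[ph$site == s[1]], cross = NULL),
         within_site2 = list(pool = ph$tree[ph$site == s[2]], cross = NULL),
         cross_1to2 = list(pool = NULL,
                           cross = list(train = ph$tree[ph$site == s[1]],
                                        validate = ph$tree[ph$site == s[2]])),
         cross_2to1 = list(pool = NULL,
                           cross = list(train = ph$tree[ph$site == s[2]],
                                        validate = ph$tree[ph$site == s[1]])),
         joint = list(pool = ph$tree, cross = NULL))
}

# Training-set-only phenotype adjustment: block effects and site
# standardisation estimated on the training trees, applied to them.
adjust_on_train <- function(data, trait, train_ids) {
  ph <- data$pheno[data$pheno$tree %in% train_ids, , drop = FALSE]
  scope <- if (length(unique(ph$site)) == 2) "joint" else
    if (unique(ph$site) == data$sites[1]) "site1" else "site2"
  spec <- if (scope == "joint") {
    model_spec(trait, kinship = "A", scope = "joint",
               joint_cov = "unstructured")
  } else {
    model_spec(trait, kinship = "A", scope = scope)
  }
  fit <- fit_reml(ph, data$K_A, spec, se = FALSE)
  adjust_phenotypes(ph, fit, trait = trait)
}

# The split's one defining parameter, as a reportable string.
split_param_of <- function(sp) {
  as.character(switch(sp$type,
                      kfold = sp$k %||% 10,
                      ratio = sp$ratio,
                      relatedness = sp$mode,
                      families = sp$n_families,
                      trees = sp$n_per_family,
                      NA_character_))
}

make_split_for <- function(scn, data, pool, rep_seed) {
  sp <- scn$split
  switch(sp$type,
    kfold = make_kfold(pool, k = sp$k %||% 10, seed = rep_seed),
    ratio = list(make_ratio_split(pool, ratio = sp$ratio, seed = rep_seed)),
    relatedness = list(make_relatedness_split(
      data$ped, pool, mode = sp$mode, seed = rep_seed,
      vs_fraction = sp$vs_fraction %||% 0.1, fam_of = data$fam_of)),
    families = list(subsample_families(
      pool, data$ped, n_families = sp$n_families, seed = rep_seed,
      fam_of = data$fam_of)),
    trees = list(subsample_trees(
      pool, data$ped, n_per_family = sp$n_per_family, seed = rep_seed,
      fam_of = data$fam_of)),
    stop("unknown split type: ", sp$type))
}

fit_predict <- function(scn, data, yprime_tr, split, markers, rep_seed) {
  tr <- split$train
  vs <- split$validate
  all_ids <- c(tr, vs)
  if (scn$model %in% c("ablup", "gblup")) {
    K <- if (scn$model == "ablup") data$K_A else {
      if (is.null(markers)) data$K_G else {
        g_matrix(subset_geno(data$geno, all_ids, markers))
      }
    }
    K <- subset_relmatrix(K, intersect(rownames(K), all_ids))
    fit <- kinship_blup(yprime_tr[tr], K)
    return(fit$gebv[vs])
  }
  if (scn$model == "rkhs") {
    gsub <- subset_geno(data$geno, all_ids, markers)
    K <- gaussian_kernel(gsub)
    fit <- fit_rkhs(yprime_tr[tr], K,
                    mcmc = mcmc_settings(seed = rep_seed))
    return(fit$gvalues[vs])
  }
  gtr <- subset_geno(data$geno, tr, markers)
  fitfun <- if (scn$model == "brr") fit_brr else fit_blasso
  eff <- fitfun(yprime_tr[tr], gtr, mcmc = mcmc_settings(seed = rep_seed))
  gvs <- subset_geno(data$geno, vs, markers)
  gebv_from_effects(eff, gvs)
}

subset_geno <- function(geno, ids, markers = NULL) {
  d <- geno$dosage[ids, , drop = FALSE]
  if (!is.null(markers)) d <- d[, markers, drop = FALSE]
  genotype_matrix(d)
}

#' Run one cross-validation scenario
#'
#' Executes the scenario's splits over its replicates, fits the model on
#' the training set, predicts the validation set, and records accuracy
#' (Pearson correlation with the reference EBVs) and predictive ability
#' (correlation with the adjusted phenotypes) per replicate. Cross-site
#' scopes train on one entire site and validate on the other; phenotype
#' adjustment is refit within the training set only to avoid leakage.
#' Replicate failures are caught and flagged; more than 20% failures
#' raises an error at the end.
#'
#' @param scn a [cv_scenario()].
#' @param data a [gs_data()] bundle.
#' @return Data frame of `MetricsRecord` rows (one per replicate).
#' @export
run_scenario <- function(scn, data) {
  info <- data$traits[[scn$trait]]
  assert_that(!is.null(info), paste0("trait not prepared: ", scn$trait))
  sc <- scope_ids(data, scn$scope)
  site_of_val <- switch(scn$scope,
                        within_site1 = 1, within_site2 = 2,
                        cross_1to2 = 2, cross_2to1 = 1, joint = NULL)
  records <- list()
  for (rp in seq_len(scn$n_replicates)) {
    rep_seed <- scn$seed + rp
    rec <- tryCatch({
      splits <- if (!is.null(sc$cross)) {
        list(split_assignment(sc$cross$train, sc$cross$validate, rp))
      } else {
        make_split_for(scn, data, sc$pool, rep_seed)
      }
      pred <- numeric(0)
      for (sp in splits) {
        ytr <- adjust_on_train(data, scn$trait, sp$train)
        markers <- if (scn$marker_subset$type == "all") NULL else {
          select_markers(ytr, data$geno,
                         mode = scn$marker_subset$type,
                         m = scn$marker_subset$m, seed = rep_seed)
        }
        pred <- c(pred, fit_predict(scn, data, ytr, sp, markers, rep_seed))
      }
      vs_ids <- names(pred)
      ref <- if (is.null(site_of_val)) info$ref_joint[vs_ids] else
        info$ref_ebv[vs_ids, site_of_val]
      acc <- accuracy(pred, ref)
      pa <- predictive_ability(pred, info$yprime[vs_ids])
      degen <- isTRUE(attr(acc, "undefined"))
      if (degen && all(abs(pred) < 1e-12)) acc <- 0  # no information: zero
      data.frame(model = scn$model, scope = scn$scope,
                 split = scn$split$type,
                 split_param = split_param_of(scn$split),
                 subset = scn$marker_subset$type,
                 m_markers = scn$marker_subset$m %||% NA_integer_,
                 trait = scn$trait, replicate = rp,
                 accuracy = as.numeric(acc), pa = as.numeric(pa),
                 n_val = length(vs_ids), seed = rep_seed,
                 degenerate = degen, failed = FALSE,
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(model = scn$model, scope = scn$scope, split = scn$split$type,
                 split_param = split_param_of(scn$split),
                 subset = scn$marker_subset$type,
                 m_markers = scn$marker_subset$m %||% NA_integer_,
                 trait = scn$trait, replicate = rp,
                 accuracy = NA_real_, pa = NA_real_, n_val = NA_integer_,
                 seed = rep_seed, degenerate = FALSE, failed = TRUE,
                 stringsAsFactors = FALSE)
    })
    records[[rp]] <- rec
  }
  out <- do.call(rbind, records)
  if (mean(out$failed) > 0.2) {
    stop(sprintf("scenario failed in %d of %d replicates",
                 sum(out$failed), nrow(out)), call. = FALSE)
  }
  out
}
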