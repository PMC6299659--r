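split_assignment <- function(train, validate, replicate = 1L) {
  assert_that(length(intersect(train, validate)) == 0,
              "training and validation sets overlap")
  structure(list(replicate = replicate, train = train, validate = validate),
            class = "split_assignment")
}

#' k-fold partition of ids
#'
#' @param ids character vector.
#' @param k number of folds (>= 2).
#' @param seed RNG seed.
#' @return List of `split_assignment`s, one per fold; fold sizes differ by
#'   at most one and every id validates exactly once.
#' @export
make_kfold <- function(ids, k = 10, seed = 1L) {
  assert_that(k >= 2, "k must be >= 2")
  assert_that(length(ids) >= k, "need at least k ids")
  with_seed(seed, {
    fold <- sample(rep_len(seq_len(k), length(ids)))
    lapply(seq_len(k), function(f) {
      split_assignment(train = ids[fold != f], validate = ids[fold == f],
                       replicate = f)
    })
  })
}

#' Training/validation split at a fixed ratio
#'
#' Training size is `round(n r / (r + 1))` with ties rounded up; sampling
#' is uniform without replacement.
#'
#' @param ids character vector.
#' @param ratio training:validation ratio `r` (e.g. 1, 3, 5, 7, 9 for the
#'   1:1 ... 9:1 designs).
#' @param seed RNG seed.
#' @return A `split_assignment`.
#' @export
make_ratio_split <- function(ids, ratio, seed = 1L) {
  n <- length(ids)
  assert_that(n >= 2, "need at least 2 ids")
  n_train <- min(n - 1, max(1, floor(n * ratio / (ratio + 1) + 0.5)))
  with_seed(seed, {
    tr <- sample(ids, n_train)
    split_assignment(train = tr, validate = setdiff(ids, tr))
  })
}

#' Relatedness-structured training/validation splits
#'
#' Three family-structure scenarios for a partial diallel:
#' * `full_sib`: random split stratified within family, so every family
#'   with at least two trees contributes to both sets (training and
#'   validation share full sibs).
#' * `half_sib`: whole families are assigned to one side only; every
#'   validation family shares its designated dam (the first parent of the
#'   pair) with at least one training family, and training families that
#'   contain a validation family's sire are discarded, so cross-set
#'   relatives are half sibs (through dams) at most.
#' * `unrelated`: the parents are partitioned into two disjoint groups;
#'   families with both parents in group 1 train, both in group 2
#'   validate, and straddling families are discarded -- no parent appears
#'   on both sides.
#'
#' @param ped pedigree with family attributes (from
#'   [make_diallel_pedigree()] or [read_trial()] plus assignment columns in
#'   `pheno`); alternatively supply `fam_of` directly.
#' @param ids candidate tree ids.
#' @param mode `"full_sib"`, `"half_sib"` or `"unrelated"`.
#' @param seed RNG seed.
#' @param vs_fraction target validation fraction (default 0.1).
#' @param fam_of optional named vector mapping tree id to family id,
#'   overriding the pedigree attribute.
#' @return A `split_assignment`; for `unrelated` it carries attributes
#'   `train_parents` / `validate_parents`.
#' @export
make_relatedness_split <- function(ped, ids, mode = c("full_sib", "half_sib",
                                                      "unrelated"),
                                   seed = 1L, vs_fraction = 0.1,
                                   fam_of = NULL) {
  mode <- match.arg(mode)
  if (is.null(fam_of)) {
    asg <- pedigree_assignment(ped)
    fam_of <- setNames(asg$family, asg$id)
  }
  fams <- attr(ped, "families")
  if (is.null(fams)) {
    # reconstruct the family/parent table from the pedigree records
    idx <- match(names(fam_of), ped$id)
    ok <- !is.na(idx) & !is.na(ped$sire[idx]) & !is.na(ped$dam[idx])
    fams <- unique(data.frame(family = unname(fam_of)[ok],
                              parent1 = ped$sire[idx][ok],
                              parent2 = ped$dam[idx][ok],
                              stringsAsFactors = FALSE))
  }
  assert_that(nrow(fams) > 0 || mode == "full_sib",
              "pedigree lacks the family/parent table")
  ids <- ids[ids %in% names(fam_of)]
  fid <- fam_of[ids]

  with_seed(seed, {
    if (mode == "full_sib") {
      vs <- unlist(lapply(split(ids, fid), function(tr) {
        if (length(tr) < 2) return(character(0))
        sample(tr, max(1, round(length(tr) * vs_fraction)))
      }), use.names = FALSE)
      return(split_assignment(train = setdiff(ids, vs), validate = vs))
    }

    present <- unique(fid)
    fams <- fams[fams$family %in% present, , drop = FALSE]
    if (mode == "half_sib") {
      # families grouped by designated dam (first parent); one family per
      # multi-family dam group may validate, guaranteeing a shared dam in
      # the training set. Training families sharing a validation family's
      # sire are discarded so cross-set relatives are half sibs at most.
      by_dam <- split(fams$family, fams$parent1)
      eligible <- by_dam[lengths(by_dam) >= 2]
      assert_that(length(eligible) > 0,
                  "no dam has two families: half-sib split impossible")
      target <- max(1, round(length(present) * vs_fraction))
      sire_of <- setNames(fams$parent2, fams$family)
      dam_of <- setNames(fams$parent1, fams$family)
      ok <- FALSE
      for (try in 1:25) {
        pool <- vapply(eligible, function(f) sample(f, 1), character(1))
        vs_fams <- sample(pool, min(target, length(pool)))
        vs_sires <- unique(sire_of[vs_fams])
        ts_fams <- setdiff(fams$family, vs_fams)
        drop <- ts_fams[dam_of[ts_fams] %in% vs_sires |
                          sire_of[ts_fams] %in% vs_sires]
        ts_fams <- setdiff(ts_fams, drop)
        # keep only validation families whose dam link survived the
        # sire exclusion
        vs_fams <- vs_fams[dam_of[vs_fams] %in% dam_of[ts_fams]]
        if (length(vs_fams) >= 1) { ok <- TRUE; break }
      }
      assert_that(ok, "half-sib split infeasible: validation sires cannot be excluded from training while keeping a shared dam")
      return(split_assignment(train = ids[fid %in% ts_fams],
                              validate = ids[fid %in% vs_fams]))
    }

    # unrelated: partition parents, keep families wholly owned by a side;
    # retry the random parent partition a few times before giving up
    parents <- unique(c(fams$parent1, fams$parent2))
    q <- max(2 / length(parents), sqrt(vs_fraction))
    own <- function(pp) fams$parent1 %in% pp & fams$parent2 %in% pp
    ts_fams <- vs_fams <- character(0)
    for (try in 1:25) {
      vs_par <- sample(parents, max(2, round(length(parents) * q)))
      ts_par <- setdiff(parents, vs_par)
      ts_fams <- fams$family[own(ts_par)]
      vs_fams <- fams$family[own(vs_par)]
      if (length(ts_fams) && length(vs_fams)) break
    }
    if (!length(ts_fams) || !length(vs_fams)) {
      stop(sprintf(
        "unrelated split infeasible: %d training and %d validation families achievable with this parent partition",
        length(ts_fams), length(vs_fams)), call. = FALSE)
    }
    out <- split_assignment(train = ids[fid %in% ts_fams],
                            validate = ids[fid %in% vs_fams])
    attr(out, "train_parents") <- ts_par
    attr(out, "validate_parents") <- vs_par
    out
  })
}

#' Subsample the number of families used for training
#'
#' Selects `n_families` families at random; within their trees a 10%
#' holdout validates (k-fold semantics at the default fraction) and the
#' rest train.
#'
#' @param ids candidate tree ids.
#' @param ped pedigree with assignment attribute (or `fam_of`).
#' @param n_families number of families to keep.
#' @param seed RNG seed.
#' @param vs_fraction holdout fraction within the selected families.
#' @param fam_of optional id-to-family map.
#' @return A `split_assignment` with attribute `families`.
#' @export
subsample_families <- function(ids, ped, n_families, seed = 1L,
                               vs_fraction = 0.1, fam_of = NULL) {
  if (is.null(fam_of)) {
    asg <- pedigree_assignment(ped)
    fam_of <- setNames(asg$family, asg$id)
  }
  ids <- ids[ids %in% names(fam_of)]
  fid <- fam_of[ids]
  avail <- unique(fid)
  assert_that(n_families <= length(avail),
              sprintf("requested %d families but only %d available",
                      n_families, length(avail)))
  with_seed(seed, {
    sel <- sample(avail, n_families)
    pool <- ids[fid %in% sel]
    vs <- unlist(lapply(split(pool, fam_of[pool]), function(tr) {
      if (length(tr) < 2) return(character(0))
      sample(tr, max(1, round(length(tr) * vs_fraction)))
    }), use.names = FALSE)
    out <- split_assignment(train = setdiff(pool, vs), validate = vs)
    attr(out, "families") <- sel
    out
  })
}

#' Subsample the number of trees per family used for training
#'
#' Training takes `n_per_family` randomly chosen trees from each family
#' (families with fewer trees contribute all of them, with a log note);
#' all remaining trees validate.
#'
#' @param ids candidate tree ids.
#' @param ped pedigree with assignment attribute (or `fam_of`).
#' @param n_per_family trees per family in the training set.
#' @param seed RNG seed.
#' @param fam_of optional id-to-family map.
#' @return A `split_assignment`.
#' @export
subsample_trees <- function(ids, ped, n_per_family, seed = 1L, fam_of = NULL) {
  if (is.null(fam_of)) {
    asg <- pedigree_assignment(ped)
    fam_of <- setNames(asg$family, asg$id)
  }
  ids <- ids[ids %in% names(fam_of)]
  fid <- fam_of[ids]
  with_seed(seed, {
    short <- 0L
    tr <- unlist(lapply(split(ids, fid), function(x) {
      if (length(x) <= n_per_family) {
        if (length(x) < n_per_family) short <<- short + 1L
        return(x)
      }
      sample(x, n_per_family)
    }), use.names = FALSE)
    if (short > 0) {
      dgs_log(short, " families smaller than ", n_per_family,
              " contribute all their trees")
    }
    split_assignment(train = tr, validate = setdiff(ids, tr))
  })
}
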