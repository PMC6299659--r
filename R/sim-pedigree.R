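#' Generate a partial-diallel pedigree
#'
#' Draws `n_families` distinct unordered parent pairs among the founders and
#' one progeny cohort per family per site, with family sizes drawn uniformly
#' from the configured range. Founders have both parents unknown; every
#' progeny has two known founder parents (the design has no open-pollinated
#' material).
#'
#' @param cfg a [sim_config()] object.
#' @return A `data.frame` with class `gs_pedigree` and columns `id`, `sire`,
#'   `dam` (`NA` for unknown) and `generation`, carrying two attributes:
#'   `families` (family id and its parent pair) and `assignment` (progeny id,
#'   family, site).
#' @export
make_diallel_pedigree <- function(cfg) {
  validate_sim_config(cfg)
  with_seed(stage_seed(cfg$seed, "pedigree"), {
    parents <- sprintf("P%03d", seq_len(cfg$n_parents))
    pairs <- t(utils::combn(cfg$n_parents, 2))
    take <- sample.int(nrow(pairs), cfg$n_families)
    fam <- data.frame(
      family = sprintf("F%03d", seq_len(cfg$n_families)),
      parent1 = parents[pairs[take, 1]],
      parent2 = parents[pairs[take, 2]],
      stringsAsFactors = FALSE)
    sizes <- matrix(
      sample(seq(cfg$progeny_range[1], cfg$progeny_range[2]),
             cfg$n_families * cfg$n_sites, replace = TRUE),
      nrow = cfg$n_families, ncol = cfg$n_sites)
    n_prog <- sum(sizes)
    fam_idx <- rep(rep(seq_len(cfg$n_families), cfg$n_sites), as.vector(sizes))
    site_idx <- rep(rep(seq_len(cfg$n_sites), each = cfg$n_families),
                    as.vector(sizes))
    prog_id <- sprintf("T%05d", seq_len(n_prog))
    ped <- data.frame(
      id = c(parents, prog_id),
      sire = c(rep(NA_character_, cfg$n_parents), fam$parent1[fam_idx]),
      dam = c(rep(NA_character_, cfg$n_parents), fam$parent2[fam_idx]),
      generation = c(rep(0L, cfg$n_parents), rep(1L, n_prog)),
      stringsAsFactors = FALSE)
    attr(ped, "families") <- fam
    attr(ped, "assignment") <- data.frame(
      id = prog_id, family = fam$family[fam_idx],
      site = paste0("S", site_idx), stringsAsFactors = FALSE)
    class(ped) <- c("gs_pedigree", "data.frame")
    ped
  })
}

#' Validate and topologically order a pedigree
#'
#' Checks that ids are unique, that every named parent exists, and that no
#' individual is its own ancestor; reorders records so parents precede
#' offspring (Kahn's algorithm). A cycle raises an error naming the ids
#' involved.
#'
#' @param ped data frame with columns `id`, `sire`, `dam` (`NA` = unknown).
#' @return The pedigree reordered parents-first.
#' @export
order_pedigree <- function(ped) {
  assert_that(all(c("id", "sire", "dam") %in% names(ped)),
              "pedigree needs id, sire, dam columns")
  assert_that(!anyDuplicated(ped$id), "pedigree ids must be unique")
  known <- c(ped$sire, ped$dam)
  known <- known[!is.na(known)]
  missing <- setdiff(known, ped$id)
  assert_that(length(missing) == 0,
              paste0("parents absent from pedigree: ",
                     paste(utils::head(missing, 5), collapse = ", ")))
  n <- nrow(ped)
  idx <- setNames(seq_len(n), ped$id)
  si <- ifelse(is.na(ped$sire), 0L, idx[ped$sire])
  di <- ifelse(is.na(ped$dam), 0L, idx[ped$dam])
  indeg <- (si > 0) + (di > 0)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    if (si[i] > 0) children[[si[i]]] <- c(children[[si[i]]], i)
    if (di[i] > 0) children[[di[i]]] <- c(children[[di[i]]], i)
  }
  queue <- which(indeg == 0)
  ord <- integer(0)
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]
    ord <- c(ord, i)
    for (ch in children[[i]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0) queue <- c(queue, ch)
    }
  }
  if (length(ord) < n) {
    stop(paste0("pedigree cycle involving: ",
                paste(utils::head(ped$id[setdiff(seq_len(n), ord)], 5),
                      collapse = ", ")), call. = FALSE)
  }
  out <- ped[ord, , drop = FALSE]
  rownames(out) <- NULL
  for (a in c("families", "assignment")) attr(out, a) <- attr(ped, a)
  class(out) <- class(ped)
  out
}

founder_ids <- function(ped) ped$id[is.na(ped$sire) & is.na(ped$dam)]

# Progeny-to-(family, site) assignment table, present on generated pedigrees.
pedigree_assignment <- function(ped) {
  a <- attr(ped, "assignment")
  assert_that(!is.null(a), "pedigree carries no trial assignment table")
  a
}
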