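#' End-to-end pipeline: simulate, QC, relationships, fits, cross-validation
#'
#' Runs the stages in dependency order, writing every artifact plus a
#' manifest (config hash, seeds, file checksums) under `out_dir`. A rerun
#' with an identical configuration is a no-op unless `force = TRUE`:
#' stages whose manifest entry matches the current config hash and whose
#' output files still match their recorded checksums are skipped.
#'
#' @param config list with elements `out_dir`; `sim` (a [sim_config()]) or
#'   `data_dir` (a directory readable by [read_trial()]); optional `qc`
#'   ([qc_thresholds()]), `impute` ("mean"/"random"), `traits` (character),
#'   `scenarios` (list of [cv_scenario()]), `t_tbs`, `t_gs`.
#' @param force rerun all stages even when up to date.
#' @return The manifest (invisibly), with elements per stage.
#' @export
run_pipeline <- function(config, force = FALSE) {
  assert_that(!is.null(config$out_dir), "config$out_dir is required")
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(out, "manifest.json")
  manifest <- if (file.exists(manifest_path) && !force) {
    jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  } else list()
  cfg_hash <- config_hash(config)
  # resolved configuration with all defaults made explicit
  resolved <- config
  resolved$qc <- config$qc %||% qc_thresholds()
  resolved$impute <- config$impute %||% "mean"
  resolved$t_tbs <- config$t_tbs %||% 25
  resolved$t_gs <- config$t_gs %||% 12.5
  jsonlite::write_json(resolved, file.path(out, "resolved_config.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)

  stage_fresh <- function(name, files) {
    ent <- manifest[[name]]
    if (force || is.null(ent) || !identical(ent$config_hash, cfg_hash)) {
      return(FALSE)
    }
    all(file.exists(files)) &&
      identical(unname(tools::md5sum(files)), unname(unlist(ent$md5)))
  }
  record_stage <- function(name, files, extra = list()) {
    manifest[[name]] <<- c(list(config_hash = cfg_hash,
                                files = files,
                                md5 = as.list(tools::md5sum(files)),
                                time = format(Sys.time())), extra)
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE)
  }

  trial_dir <- file.path(out, "trial")
  trial_files <- file.path(trial_dir,
                           c("genotypes.vcf", "pedigree.csv", "phenotypes.csv"))
  if (!is.null(config$sim)) {
    if (stage_fresh("simulate", trial_files)) {
      dgs_log("simulate: up to date")
    } else {
      sim <- simulate_trial(config$sim)
      write_trial(sim$geno, sim$ped, sim$pheno, trial_dir)
      record_stage("simulate", trial_files,
                   list(seed = config$sim$seed))
    }
  } else {
    assert_that(!is.null(config$data_dir), "config needs sim or data_dir")
    trial_dir <- config$data_dir
  }
  trial <- read_trial(trial_dir)

  qc_file <- file.path(out, "qc_report.json")
  res <- filter_variants(trial$geno, config$qc %||% qc_thresholds())
  geno <- impute_missing(res$geno, method = config$impute %||% "mean")
  jsonlite::write_json(unclass(res$report)[!vapply(res$report, is.null,
                                                   logical(1))],
                       qc_file, auto_unbox = TRUE, pretty = TRUE)
  record_stage("qc", qc_file)

  K_A <- a_matrix(trial$ped)
  K_G <- g_matrix(geno)
  relmat_files <- file.path(out, c("A_matrix.tsv", "G_matrix.tsv"))
  write_relmatrix(K_A, relmat_files[1])
  write_relmatrix(K_G, relmat_files[2])
  record_stage("relmat", relmat_files)

  traits <- config$traits %||%
    setdiff(names(trial$pheno)[vapply(trial$pheno, is.numeric, logical(1))],
            c("tree", "site", "block"))
  fits_file <- file.path(out, "variance_components.json")
  vc_out <- list()
  for (tr in traits) {
    for (kin in c("A", "G")) {
      K <- if (kin == "A") K_A else K_G
      tb <- type_b_test(trial$pheno, K, tr, kinship = kin, se = TRUE)
      f <- tb$full
      vc_out[[paste(tr, kin, sep = "_")]] <- list(
        trait = tr, kinship = kin,
        components = f$vc[setdiff(names(f$vc), c("model", "sites"))],
        h2_site1 = as.numeric(heritability(f, site = 1)),
        h2_site2 = as.numeric(heritability(f, site = 2)),
        type_b = as.numeric(type_b_correlation(f)),
        lrt_vs_one = list(statistic = tb$statistic, p = tb$p_value))
    }
  }
  jsonlite::write_json(vc_out, fits_file, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  record_stage("fits", fits_file)

  cv_file <- file.path(out, "cv_records.csv")
  summary_file <- file.path(out, "cv_summary.csv")
  if (!is.null(config$scenarios) && length(config$scenarios)) {
    data <- gs_data(trial$ped, geno, trial$pheno, traits = traits,
                    K_A = K_A, K_G = K_G)
    recs <- do.call(rbind, lapply(config$scenarios, run_scenario,
                                  data = data))
    write.csv(recs, cv_file, row.names = FALSE)
    summ <- summarize_metrics(recs, t_tbs = config$t_tbs %||% 25,
                              t_gs = config$t_gs %||% 12.5)
    write.csv(summ, summary_file, row.names = FALSE)
    record_stage("cv", c(cv_file, summary_file))
  }
  invisible(manifest)
}

config_hash <- function(config) {
  s <- jsonlite::toJSON(config[setdiff(names(config), "out_dir")],
                        auto_unbox = TRUE, force = TRUE, digits = 12)
  # small rolling hash; stable across sessions, no extra dependency
  v <- utf8ToInt(as.character(s))
  sprintf("%08x", Reduce(function(h, c) (h * 31 + c) %% 2147483647, v, 7L))
}

write_relmatrix <- function(K, path) {
  df <- data.frame(id = rownames(K), as.data.frame(unclass(K)[, ,
                                                              drop = FALSE]))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Render summary tables and figures from a pipeline output directory
#'
#' Writes a markdown report with the variance-component/heritability table
#' (one row per trait and kinship), the cross-validation accuracy /
#' predictive ability / relative-efficiency table, and PNG figures of
#' accuracy against the experiment factor for each split family present.
#'
#' @param out_dir directory produced by [run_pipeline()].
#' @return Path to the markdown report (invisibly).
#' @export
report_tables <- function(out_dir) {
  rp <- file.path(out_dir, "report.md")
  lines <- c("# Genomic selection analysis report", "")
  vc_file <- file.path(out_dir, "variance_components.json")
  if (file.exists(vc_file)) {
    vc <- jsonlite::read_json(vc_file, simplifyVector = FALSE)
    lines <- c(lines, "## Variance components, heritability, type-B", "",
               "| Trait | Kinship | h2 site1 | h2 site2 | Type-B | LRT p |",
               "|---|---|---|---|---|---|")
    for (e in vc) {
      lines <- c(lines, sprintf("| %s | %s | %.2f | %.2f | %.2f | %.3g |",
                                e$trait, e$kinship, e$h2_site1, e$h2_site2,
                                e$type_b, e$lrt_vs_one$p))
    }
    lines <- c(lines, "")
  }
  cv_file <- file.path(out_dir, "cv_summary.csv")
  if (file.exists(cv_file)) {
    s <- read.csv(cv_file)
    lines <- c(lines, "## Cross-validation summary", "",
               "| Model | Scope | Split | Subset | Trait | Accuracy (SE) | PA (SE) | RE | RE/yr |",
               "|---|---|---|---|---|---|---|---|---|")
    for (i in seq_len(nrow(s))) {
      fmt2 <- function(v) ifelse(is.na(v), "NA",
                                 sprintf("%.2f", round_half_up(v, 2)))
      lines <- c(lines, sprintf(
        "| %s | %s | %s | %s | %s | %s (%s) | %s (%s) | %s | %s |",
        s$model[i], s$scope[i], s$split[i], s$subset[i], s$trait[i],
        fmt2(s$accuracy[i]), fmt2(s$accuracy_se[i]),
        fmt2(s$pa[i]), fmt2(s$pa_se[i]), fmt2(s$re[i]),
        fmt2(s$re_per_year[i])))
    }
    lines <- c(lines, "")
    recs_file <- file.path(out_dir, "cv_records.csv")
    if (file.exists(recs_file)) {
      recs <- read.csv(recs_file)
      for (spl in unique(recs$split)) {
        sub <- recs[recs$split == spl & !recs$failed, ]
        if (!nrow(sub)) next
        fig <- file.path(out_dir, paste0("accuracy_", spl, ".png"))
        grDevices::png(fig, width = 800, height = 500)
        boxplot(accuracy ~ model, data = sub,
                main = paste("Accuracy by model:", spl, "split"),
                ylab = "accuracy")
        grDevices::dev.off()
        lines <- c(lines, sprintf("![accuracy by model (%s)](%s)", spl,
                                  basename(fig)), "")
      }
    }
  }
  writeLines(lines, rp)
  invisible(rp)
}
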