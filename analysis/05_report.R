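#!/usr/bin/env Rscript
# Assemble the summary tables and figures: the heritability/type-B table,
# the accuracy/PA/RE tables, and accuracy curves against TS/VS ratio,
# family count, trees per family, marker-subset size, and relatedness.

source(file.path("analysis", "00_config.R"))

summ <- read.csv(file.path(OUT_ROOT, "cv_summary.csv"))
recs <- read.csv(file.path(OUT_ROOT, "cv_records.csv"))
vc <- read.csv(file.path(OUT_ROOT, "variance_components.csv"))
recs <- recs[!recs$failed, ]

fig <- function(name, code) {
  path <- file.path(OUT_ROOT, paste0(name, ".png"))
  grDevices::png(path, width = 900, height = 550)
  on.exit(grDevices::dev.off())
  code()
  cat("figure:", path, "\n")
}

# mean accuracy against a numeric experiment factor, one line per model
curve_plot <- function(sub, xval, main, xlab, log = "") {
  sub$x <- xval
  agg <- aggregate(accuracy ~ x + model, data = sub, FUN = mean)
  models <- sort(unique(agg$model))
  plot(range(agg$x), range(agg$accuracy), type = "n", main = main,
       xlab = xlab, ylab = "accuracy", log = log)
  for (m in models) {
    s <- agg[agg$model == m, ]
    s <- s[order(s$x), ]
    lines(s$x, s$accuracy, type = "b", pch = 19,
          lty = which(models == m))
  }
  legend("bottomright", legend = models, lty = seq_along(models), pch = 19)
}

ratio_recs <- recs[recs$split == "ratio" & recs$subset == "all" &
                     recs$trait == "height", ]
if (nrow(ratio_recs)) {
  fig("accuracy_vs_ratio", function()
    curve_plot(ratio_recs, as.numeric(ratio_recs$split_param),
               "Accuracy vs TS/VS ratio (height)",
               "training:validation ratio"))
}

fam_recs <- recs[recs$split == "families", ]
if (nrow(fam_recs)) {
  fig("accuracy_vs_families", function()
    curve_plot(fam_recs, as.numeric(fam_recs$split_param),
               "Accuracy vs number of families (height)", "families"))
}

tree_recs <- recs[recs$split == "trees", ]
if (nrow(tree_recs)) {
  fig("accuracy_vs_trees_per_family", function()
    curve_plot(tree_recs, as.numeric(tree_recs$split_param),
               "Accuracy vs trees per family in training (height)",
               "trees per family"))
}

mark_recs <- recs[recs$subset %in% c("random", "largest_positive") &
                    !is.na(recs$m_markers) & recs$split == "ratio" &
                    recs$m_markers < 3000, ]
if (nrow(mark_recs)) {
  fig("accuracy_vs_markers", function() {
    mark_recs$model <- mark_recs$subset  # one line per selection strategy
    curve_plot(mark_recs, mark_recs$m_markers,
               "Accuracy vs marker-subset size (height, GBLUP)",
               "markers", log = "x")
  })
}

rel_recs <- recs[recs$split == "relatedness", ]
if (nrow(rel_recs)) {
  fig("accuracy_vs_relatedness", function()
    boxplot(accuracy ~ split_param + model, data = rel_recs,
            main = "Accuracy by relatedness structure",
            ylab = "accuracy", las = 2, xlab = ""))
}

# markdown report with the headline tables
rp <- file.path(OUT_ROOT, "report.md")
lines <- c("# Genomic selection in a two-site progeny trial: results",
           "", "## Heritability and type-B genetic correlation", "",
           "| Trait | Kinship | Site | h2 (SE) | Type-B | LRT p |",
           "|---|---|---|---|---|---|")
for (i in seq_len(nrow(vc))) {
  lines <- c(lines, sprintf(
    "| %s | %s | %s | %.2f (%.2f) | %s | %s |",
    vc$trait[i], vc$kinship[i], vc$site[i], vc$h2[i],
    ifelse(is.na(vc$h2_se[i]), NA, vc$h2_se[i]),
    ifelse(is.na(vc$type_b[i]), "", sprintf("%.2f", vc$type_b[i])),
    ifelse(is.na(vc$lrt_p[i]), "", sprintf("%.3g", vc$lrt_p[i]))))
}
lines <- c(lines, "", "## Cross-validation cells (mean over replicates)", "",
           "| Model | Scope | Split | Param | Subset | m | Trait | Accuracy | PA | RE | RE/yr |",
           "|---|---|---|---|---|---|---|---|---|---|---|")
fmt <- function(v) ifelse(is.na(v), "", sprintf("%.2f", v))
for (i in seq_len(nrow(summ))) {
  lines <- c(lines, sprintf(
    "| %s | %s | %s | %s | %s | %s | %s | %s | %s | %s | %s |",
    summ$model[i], summ$scope[i], summ$split[i], summ$split_param[i],
    summ$subset[i],
    ifelse(is.na(summ$m_markers[i]), "all", summ$m_markers[i]),
    summ$trait[i], fmt(summ$accuracy[i]), fmt(summ$pa[i]),
    fmt(summ$re[i]), fmt(summ$re_per_year[i])))
}
writeLines(lines, rp)
cat("report:", rp, "\n")
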