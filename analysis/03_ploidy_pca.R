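#!/usr/bin/env Rscript
# Stage 3 — correlation PCA, component labelling and SD-score selection.
#
# Fits the full-rank correlation PCA on condition profiles for both
# designs, labels components from their loading sign patterns (shared /
# tissue / species / ploidy), reports variance fractions and kurtosis
# diagnostics, and selects ploidy-induced / -suppressed genes beyond 2 SD
# (3 SD written alongside as the stricter nested cut).

suppressPackageStartupMessages(library(ploidysig))

data_dir <- "results/data"
out <- "results/pca"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

analyse <- function(expr, sheet, tag) {
  model <- label_components(fit_pca(condition_profiles(expr, sheet)))
  shares <- sprintf("%.1f%%", 100 * model$var_fraction)
  cat(sprintf("[%s] components: %s\n", tag,
              paste(sprintf("%s=%s (%s)", names(model$labels), model$labels,
                            shares), collapse = ", ")))
  ploidy_pc <- names(model$labels)[model$labels == "ploidy"]
  if (length(ploidy_pc)) {
    diag <- score_diagnostics(model, ploidy_pc[[1]])
    cat(sprintf("[%s] %s kurtosis %.2f (Gaussian reference 3); 99%% |score| %.2f SD\n",
                tag, ploidy_pc[[1]], diag$kurtosis, diag$percentile_99_abs))
  }
  write.table(data.frame(variable = rownames(model$loadings), model$loadings),
              file.path(out, paste0(tag, "_loadings.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(gene = rownames(model$scores),
                         round(model$scores, 6)),
              file.path(out, paste0(tag, "_scores.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  for (thr in c(2, 3)) {
    sel <- select_by_score(model, thr)
    write_gene_list(sel$induced,
                    file.path(out, sprintf("%s_induced_%dsd.txt", tag, thr)))
    write_gene_list(sel$suppressed,
                    file.path(out, sprintf("%s_suppressed_%dsd.txt", tag, thr)))
    cat(sprintf("[%s] |score| > %d SD: %d induced, %d suppressed\n",
                tag, thr, length(sel$induced), length(sel$suppressed)))
  }
  model
}

expr <- read_expression(file.path(data_dir, "cross_species_expression.tsv"))
sheet <- read_sample_sheet(file.path(data_dir, "cross_species_samples.tsv"))
for (sp in unique(sheet$species)) {
  cols <- sheet$sample_id[sheet$species == sp]
  expr[, cols] <- quantile_normalize(expr[, cols, drop = FALSE])
}
m1 <- analyse(expr, sheet, "cross_species")

dec_expr <- quantile_normalize(
  read_expression(file.path(data_dir, "decidua_expression.tsv")))
dec_sheet <- read_sample_sheet(file.path(data_dir, "decidua_samples.tsv"))
m2 <- analyse(dec_expr, dec_sheet, "decidua")

truth <- read_truth(file.path(data_dir, "truth.json"))
sel <- select_by_score(m1, 2)
prec <- length(intersect(sel$induced, truth$ploidy_up)) /
  max(1, length(sel$induced))
cat(sprintf("cross-species 2SD induced-set precision vs truth: %.3f\n", prec))
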