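#!/usr/bin/env Rscript
# Stage 2 — quantile normalization, moderated t-tests and tiered lists.
#
# Normalizes each species' samples together, runs the reciprocal
# moderated-t contrasts (human heart polyploid vs mouse heart diploid;
# mouse liver polyploid vs human liver diploid; decidua 4n vs 2n) and
# intersects them into the direction-concordant tiers:
#   tier A — concordant in heart, liver and decidua
#   tier B — concordant in heart and liver
#   tier C — decidua alone.

suppressPackageStartupMessages(library(ploidysig))

data_dir <- "results/data"
out <- "results/de"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

expr <- read_expression(file.path(data_dir, "cross_species_expression.tsv"))
sheet <- read_sample_sheet(file.path(data_dir, "cross_species_samples.tsv"))
orth <- read_orthologs(file.path(data_dir, "orthologs.tsv"))
dec_expr <- read_expression(file.path(data_dir, "decidua_expression.tsv"))
dec_sheet <- read_sample_sheet(file.path(data_dir, "decidua_samples.tsv"))

for (sp in unique(sheet$species)) {
  cols <- sheet$sample_id[sheet$species == sp]
  expr[, cols] <- quantile_normalize(expr[, cols, drop = FALSE])
}
dec_expr <- quantile_normalize(dec_expr)

de <- list(
  heart = moderated_t_test(expr, sheet,
                           c("human_heart_polyploid", "mouse_heart_diploid")),
  liver = moderated_t_test(expr, sheet,
                           c("mouse_liver_polyploid", "human_liver_diploid")),
  decidua = moderated_t_test(dec_expr, dec_sheet,
                             c("mouse_decidua_polyploid",
                               "mouse_decidua_diploid")))
for (nm in names(de)) {
  write.table(de[[nm]], file.path(out, paste0("de_", nm, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%s: %d genes, %d with p < 0.01 and >15%% change\n",
              nm, nrow(de[[nm]]),
              sum(de[[nm]]$p < 0.01 & change_filter(de[[nm]])$pass)))
}

tiers <- build_tiered_lists(de$heart, de$liver, de$decidua, orth)
for (nm in names(tiers))
  write_gene_list(tiers[[nm]], file.path(out, paste0(nm, ".txt")))
cat(sprintf("tier A: %d up / %d down; tier B: %d / %d; tier C: %d / %d\n",
            length(tiers$tier_A_up), length(tiers$tier_A_down),
            length(tiers$tier_B_up), length(tiers$tier_B_down),
            length(tiers$tier_C_up), length(tiers$tier_C_down)))

truth <- read_truth(file.path(data_dir, "truth.json"))
planted <- c(truth$ploidy_up, truth$ploidy_down)
hits <- length(intersect(tiers$tier_B_up, truth$ploidy_up)) +
  length(intersect(tiers$tier_B_down, truth$ploidy_down))
tb <- c(tiers$tier_B_up, tiers$tier_B_down)
cat(sprintf("tier-B recovery: sensitivity %.3f, false-discovery proportion %.3f\n",
            hits / length(planted),
            length(setdiff(tb, planted)) / max(1, length(tb))))
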