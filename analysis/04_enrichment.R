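#!/usr/bin/env Rscript
# Stage 4 — interactome and module enrichment.
#
# Tests each ploidy-associated gene list (tier B up/down from stage 2 and
# the 2-SD PCA selections from stage 3) for (a) binomial enrichment of
# interactome members against the universe rate and (b) module
# over-representation with the double-background rule: hypergeometric
# p < 0.01 and Storey q < 0.15 simultaneously against all orthologs and
# against all interactome members. Group summaries report geometric-mean
# q per module class. The published decidua contingencies are recomputed
# alongside as fixed-input worked examples.

suppressPackageStartupMessages(library(ploidysig))

out <- "results/enrichment"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

truth <- read_truth("results/data/truth.json")
universe <- truth$universe
interactome <- read_gene_list("results/data/interactome.txt")
modules <- read_gene_sets("results/data/modules.gmt")
orth <- read_orthologs("results/data/orthologs.tsv")
map_b <- setNames(orth$group_id, orth$gene_b)

selections <- list(
  tier_B_up = read_gene_list("results/de/tier_B_up.txt"),
  tier_B_down = read_gene_list("results/de/tier_B_down.txt"),
  pca_induced = read_gene_list("results/pca/cross_species_induced_2sd.txt"),
  pca_suppressed = read_gene_list("results/pca/cross_species_suppressed_2sd.txt"))

binomials <- list()
for (nm in names(selections)) {
  sel <- selections[[nm]]
  if (!length(sel)) next
  b <- binomial_enrichment(sel, interactome, universe)
  binomials[[nm]] <- unclass(b)
  cat(sprintf("%s: %d/%d interactants (%.3f vs background %.3f), binomial p = %.3g\n",
              nm, b$k, b$n, b$proportion, b$p0, b$p_value))
}
jsonlite::write_json(binomials, file.path(out, "binomial.json"),
                     auto_unbox = TRUE, digits = NA)

group_map <- setNames(attr(modules, "descriptions"), names(modules))
for (nm in names(selections)) {
  sel <- selections[[nm]]
  if (!length(sel)) next
  rec <- double_background_ora(sel, modules, universe, interactome)
  write.table(rec, file.path(out, paste0("ora_", nm, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  sig <- attr(rec, "significant_terms")
  cat(sprintf("%s: %d module(s) significant in both backgrounds%s\n",
              nm, length(sig),
              if (length(sig)) paste0(": ", paste(sig, collapse = ", "))
              else ""))
  gm <- group_map[unique(rec$term_id)]
  summ <- group_summary(rec, gm)
  write.table(summ, file.path(out, paste0("groups_", nm, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}

cat("\npublished decidua contingencies (fixed inputs):\n")
inh <- binomial_enrichment(k = 242, n = 828, p0 = 0.19)
ind <- binomial_enrichment(k = 152, n = 436, p0 = 0.19)
cat(sprintf("  ploidy-inhibited: 242/828 = %.3f vs 0.19, exact upper-tail p = %.6g\n",
            inh$proportion, inh$p_value))
cat(sprintf("  ploidy-induced:   152/436 = %.3f vs 0.19, exact upper-tail p = %.6g\n",
            ind$proportion, ind$p_value))
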