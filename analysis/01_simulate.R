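#!/usr/bin/env Rscript
# Stage 1 — simulate the study inputs.
#
# Generates the reference synthetic datasets at the default study
# conditions: a reciprocal human/mouse heart-liver design (5000 ortholog
# groups, 4 replicates per condition, 5% of genes carrying a 1-log2 ploidy
# effect) plus a companion 2n/4n decidua-like design sharing the same
# planted genes, an interactome enriched 4-fold (odds) among planted
# genes, 50 annotation modules (5 planted), and a weighted interaction
# edge list with two planted 5-cliques. Everything is written as plain
# text under results/data/ together with the ground truth.

suppressPackageStartupMessages(library(ploidysig))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 2 && args[1] == "--seed") as.integer(args[2]) else 1L

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- synth_config(seed = seed)
xs <- generate_cross_species_dataset(cfg)
dec <- generate_two_condition_dataset(
  cfg, gene_ids = xs$orthologs$gene_b,
  planted = list(
    up = xs$orthologs$gene_b[xs$orthologs$group_id %in% xs$truth$ploidy_up],
    down = xs$orthologs$gene_b[xs$orthologs$group_id %in%
                                 xs$truth$ploidy_down]))
ann <- generate_annotations_and_network(cfg, xs$truth)

write_expression(xs$expr, file.path(out, "cross_species_expression.tsv"))
write_sample_sheet(xs$sheet, file.path(out, "cross_species_samples.tsv"))
write_orthologs(xs$orthologs, file.path(out, "orthologs.tsv"))
write_expression(dec$expr, file.path(out, "decidua_expression.tsv"))
write_sample_sheet(dec$sheet, file.path(out, "decidua_samples.tsv"))
write_gene_list(ann$truth$interactome, file.path(out, "interactome.txt"))
write_gene_sets(ann$gene_sets, file.path(out, "modules.gmt"))
write_edge_list(ann$edges, file.path(out, "interactions.tsv"))
write_truth(ann$truth, file.path(out, "truth.json"))

cat(sprintf(
  "simulated %d ortholog groups x %d samples (+ decidua %d x %d), seed %d\n",
  nrow(xs$expr), ncol(xs$expr), nrow(dec$expr), ncol(dec$expr), seed))
cat(sprintf("planted: %d up, %d down; interactome %d genes (%.3f of universe)\n",
            length(ann$truth$ploidy_up), length(ann$truth$ploidy_down),
            length(ann$truth$interactome),
            length(ann$truth$interactome) / length(ann$truth$universe)))
cat(sprintf("annotations: %d modules (%d planted); %d interaction edges\n",
            length(ann$gene_sets), length(ann$truth$planted_terms),
            nrow(ann$edges)))
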