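small_cfg <- function(...) {
  synth_config(n_genes = 400, reps_per_condition = 3, n_terms = 10,
               term_size = 15, planted_term_count = 2, edge_noise = 30, ...)
}

test_that("invalid configurations are rejected naming the offending field", {
  expect_error(small_cfg(noise_sd = -1), "noise_sd")
  expect_error(small_cfg(frac_ploidy_up = 0.6, frac_ploidy_down = 0.6),
               "frac_ploidy_up")
  expect_error(small_cfg(interactome_odds = 0), "interactome_odds")
  expect_error(synth_config(n_genes = 10, term_size = 50), "term_size")
})

test_that("no planted effect yields empty truth sets", {
  d <- generate_cross_species_dataset(
    small_cfg(frac_ploidy_up = 0, frac_ploidy_down = 0))
  expect_length(d$truth$ploidy_up, 0)
  expect_length(d$truth$ploidy_down, 0)
})

test_that("identical seeds give bit-identical outputs, distinct seeds differ", {
  cfg <- small_cfg(seed = 11)
  a <- generate_cross_species_dataset(cfg)
  b <- generate_cross_species_dataset(cfg)
  expect_identical(a$expr, b$expr)
  expect_identical(a$truth, b$truth)
  ann_a <- generate_annotations_and_network(cfg, a$truth)
  ann_b <- generate_annotations_and_network(cfg, b$truth)
  expect_identical(ann_a$edges, ann_b$edges)
  expect_identical(unclass(ann_a$gene_sets), unclass(ann_b$gene_sets))
  c2 <- generate_cross_species_dataset(small_cfg(seed = 12))
  expect_false(identical(a$expr, c2$expr))
})

test_that("cross-species design is reciprocal and effects have planted sign", {
  cfg <- small_cfg(seed = 3)
  d <- generate_cross_species_dataset(cfg)
  sh <- d$sheet
  expect_identical(dim(d$expr), c(400L, 12L))
  ploidy_of <- function(sp, ts)
    unique(sh$ploidy_class[sh$species == sp & sh$tissue == ts])
  expect_identical(ploidy_of("human", "heart"), "polyploid")
  expect_identical(ploidy_of("human", "liver"), "diploid")
  expect_identical(ploidy_of("mouse", "heart"), "diploid")
  expect_identical(ploidy_of("mouse", "liver"), "polyploid")

  # per-gene polyploid-minus-diploid difference approximates 2*ploidy_delta
  poly <- sh$sample_id[sh$ploidy_class == "polyploid"]
  dip <- sh$sample_id[sh$ploidy_class == "diploid"]
  diff <- rowMeans(d$expr[, poly]) - rowMeans(d$expr[, dip])
  expect_gt(mean(diff[d$truth$ploidy_up]), 2 * cfg$ploidy_delta - 0.5)
  expect_lt(mean(diff[d$truth$ploidy_down]), -2 * cfg$ploidy_delta + 0.5)
  expect_lt(abs(mean(diff[setdiff(rownames(d$expr),
                                  c(d$truth$ploidy_up,
                                    d$truth$ploidy_down))])), 0.2)
  expect_true(all(d$truth$interactome %in% rownames(d$expr)))
  expect_length(intersect(d$truth$ploidy_up, d$truth$ploidy_down), 0)
})

test_that("condition means converge to the generative means", {
  cfg <- synth_config(n_genes = 2000, reps_per_condition = 4, seed = 5)
  d <- generate_cross_species_dataset(cfg)
  sh <- d$sheet
  # reconstruct the noiseless condition mean from a second draw at zero noise
  d0 <- generate_cross_species_dataset(
    synth_config(n_genes = 2000, reps_per_condition = 4, seed = 5,
                 noise_sd = 0))
  tol <- 3 * cfg$noise_sd / sqrt(cfg$reps_per_condition)
  ok <- 0; total <- 0
  for (cond in unique(paste(sh$species, sh$tissue))) {
    cols <- sh$sample_id[paste(sh$species, sh$tissue) == cond]
    err <- abs(rowMeans(d$expr[, cols]) - rowMeans(d0$expr[, cols]))
    ok <- ok + sum(err < tol); total <- total + length(err)
  }
  expect_gt(ok / total, 0.99)
})

test_that("interactome rate among non-planted genes matches the background", {
  cfg <- synth_config(n_genes = 5000, seed = 9)
  d <- generate_cross_species_dataset(cfg)
  non_planted <- setdiff(d$truth$universe,
                         c(d$truth$ploidy_up, d$truth$ploidy_down))
  rate <- mean(non_planted %in% d$truth$interactome)
  ci <- cfg$interactome_frac + c(-1, 1) * 2.576 *
    sqrt(cfg$interactome_frac * (1 - cfg$interactome_frac) /
           length(non_planted))
  expect_gt(rate, ci[1]); expect_lt(rate, ci[2])
  # enrichment among planted genes at the configured odds
  planted_rate <- mean(c(d$truth$ploidy_up, d$truth$ploidy_down) %in%
                         d$truth$interactome)
  expect_gt(planted_rate, rate)
})

test_that("two-condition generator follows x = mu + delta*P + noise", {
  cfg <- small_cfg(seed = 21, noise_sd = 0)
  d <- generate_two_condition_dataset(cfg)
  diff <- rowMeans(d$expr[, d$sheet$ploidy_class == "polyploid"]) -
    rowMeans(d$expr[, d$sheet$ploidy_class == "diploid"])
  expect_equal(unname(diff[d$truth$ploidy_up]),
               rep(2 * cfg$ploidy_delta, length(d$truth$ploidy_up)))
  expect_equal(unname(diff[d$truth$ploidy_down]),
               rep(-2 * cfg$ploidy_delta, length(d$truth$ploidy_down)))
  null_genes <- setdiff(rownames(d$expr),
                        c(d$truth$ploidy_up, d$truth$ploidy_down))
  expect_equal(max(abs(diff[null_genes])), 0)
  # reuse of a supplied universe and planted sets
  d2 <- generate_two_condition_dataset(cfg, gene_ids = rownames(d$expr),
                                       planted = list(up = d$truth$ploidy_up,
                                                      down = d$truth$ploidy_down))
  expect_identical(d2$truth$ploidy_up, d$truth$ploidy_up)
})

test_that("annotations plant >=80%-pure terms and the edge weights obey bounds", {
  cfg <- small_cfg(seed = 13)
  d <- generate_cross_species_dataset(cfg)
  ann <- generate_annotations_and_network(cfg, d$truth)
  planted <- c(d$truth$ploidy_up, d$truth$ploidy_down)
  expect_length(ann$truth$planted_terms, cfg$planted_term_count)
  for (id in ann$truth$planted_terms) {
    expect_gte(mean(ann$gene_sets[[id]] %in% planted), 0.8)
  }
  expect_true(all(lengths(ann$gene_sets) == cfg$term_size))
  clique_pairs <- unlist(lapply(ann$truth$planted_cliques, function(cl)
    apply(combn(sort(cl), 2), 2, paste, collapse = "|")))
  key <- paste(ann$edges$node_a, ann$edges$node_b, sep = "|")
  expect_true(all(clique_pairs %in% key))
  expect_true(all(ann$edges$weight[key %in% clique_pairs] == 0.95))
  expect_true(all(ann$edges$weight[!key %in% clique_pairs] <= 0.9))
})
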