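# Synthetic-data generator. Emulates the statistical structure the
# analysis assumes: log2-additive expression with a dominant shared
# (baseline) component, tissue and species components, and a small ploidy
# component carried by a planted gene subset; an interactome enriched
# among the planted genes; annotated gene modules; and a clique-structured
# weighted interaction graph. Ground truth is returned for recovery tests.

#' Synthetic-data configuration
#'
#' Defaults describe the reference conditions used throughout the test
#' suite: 5000 ortholog groups, four replicates per condition, a planted
#' log2 ploidy effect of 1 (two-fold between classes) on 5% of genes, and
#' residual noise of 0.5 log2 units. The variance hierarchy
#' `mu_sd > tissue_sd > species_sd > effective ploidy` mirrors the ordering
#' shared > tissue > species > ploidy expected of reciprocal cross-species
#' designs.
#'
#' @param n_genes Number of ortholog groups (genes).
#' @param reps_per_condition Replicates per (species, tissue) condition.
#' @param mu_sd Spread of per-gene baselines (log2 units).
#' @param tissue_sd SD of per-gene tissue effects (log2 units).
#' @param species_sd SD of per-gene species effects (log2 units).
#' @param ploidy_delta Planted ploidy effect magnitude (log2 units).
#' @param frac_ploidy_up,frac_ploidy_down Fractions of genes planted as
#'   ploidy-induced / ploidy-suppressed; their sum must be below 1.
#' @param noise_sd Residual noise SD (log2 units).
#' @param interactome_frac Background interactome membership rate.
#' @param interactome_odds Odds ratio of interactome membership for planted
#'   versus non-planted genes (1 = no enrichment).
#' @param n_terms,term_size Number and size of annotation gene sets.
#' @param planted_term_count How many terms are drawn predominantly
#'   (>= 80% of members) from the planted genes.
#' @param edge_cliques,clique_size Number and size of complete subgraphs
#'   planted in the interaction edge list at weight 0.95.
#' @param edge_noise Number of random edges at weights uniform on
#'   \[0.4, 0.9\].
#' @param seed Master seed; every output artifact draws from its own RNG
#'   stream derived from it, so adding an artifact never perturbs others.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(n_genes = 5000L,
                         reps_per_condition = 4L,
                         mu_sd = 0.563,
                         tissue_sd = 0.455,
                         species_sd = 0.306,
                         ploidy_delta = 1,
                         frac_ploidy_up = 0.025,
                         frac_ploidy_down = 0.025,
                         noise_sd = 0.5,
                         interactome_frac = 0.2,
                         interactome_odds = 4,
                         n_terms = 50L,
                         term_size = 40L,
                         planted_term_count = 5L,
                         edge_cliques = 2L,
                         clique_size = 5L,
                         edge_noise = 100L,
                         seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              reps_per_condition = as.integer(reps_per_condition),
              mu_sd = mu_sd, tissue_sd = tissue_sd, species_sd = species_sd,
              ploidy_delta = ploidy_delta,
              frac_ploidy_up = frac_ploidy_up,
              frac_ploidy_down = frac_ploidy_down,
              noise_sd = noise_sd,
              interactome_frac = interactome_frac,
              interactome_odds = interactome_odds,
              n_terms = as.integer(n_terms), term_size = as.integer(term_size),
              planted_term_count = as.integer(planted_term_count),
              edge_cliques = as.integer(edge_cliques),
              clique_size = as.integer(clique_size),
              edge_noise = as.integer(edge_noise),
              seed = as.integer(seed))
  validate_synth_config(cfg)
}

validate_synth_config <- function(cfg) {
  chk <- function(ok, field, rule) {
    if (!ok) abort("invalid synth_config field '%s': %s", field, rule)
  }
  chk(cfg$n_genes >= 1, "n_genes", "must be >= 1")
  chk(cfg$reps_per_condition >= 1, "reps_per_condition", "must be >= 1")
  for (f in c("mu_sd", "tissue_sd", "species_sd", "ploidy_delta", "noise_sd"))
    chk(is.numeric(cfg[[f]]) && cfg[[f]] >= 0, f, "must be >= 0")
  for (f in c("frac_ploidy_up", "frac_ploidy_down"))
    chk(cfg[[f]] >= 0 && cfg[[f]] < 1, f, "must be in [0, 1)")
  chk(cfg$frac_ploidy_up + cfg$frac_ploidy_down < 1,
      "frac_ploidy_up", "frac_ploidy_up + frac_ploidy_down must be < 1")
  chk(cfg$interactome_frac > 0 && cfg$interactome_frac < 1,
      "interactome_frac", "must be in (0, 1)")
  chk(cfg$interactome_odds > 0, "interactome_odds", "must be > 0")
  chk(cfg$n_terms >= 0, "n_terms", "must be >= 0")
  chk(cfg$term_size >= 1, "term_size", "must be >= 1")
  chk(cfg$term_size <= cfg$n_genes, "term_size", "must be <= n_genes")
  chk(cfg$planted_term_count >= 0 && cfg$planted_term_count <= cfg$n_terms,
      "planted_term_count", "must be in [0, n_terms]")
  chk(cfg$edge_cliques >= 0, "edge_cliques", "must be >= 0")
  chk(cfg$clique_size >= 2, "clique_size", "must be >= 2")
  chk(cfg$edge_noise >= 0, "edge_noise", "must be >= 0")
  chk(is.finite(cfg$seed), "seed", "must be a finite integer")
  structure(cfg, class = "synth_config")
}

# One RNG sub-stream per output artifact, derived from the master seed.
artifact_seeds <- function(seed, streams) {
  withr::with_seed(seed,
    setNames(sample.int(2147483646L, length(streams)), streams))
}

# Interactome membership probability for planted genes, given a background
# rate and an odds ratio.
planted_interactome_prob <- function(base, odds) {
  o <- odds * base / (1 - base)
  o / (1 + o)
}

new_synth_truth <- function(universe, up, down, interactome,
                            planted_terms = character(),
                            planted_cliques = list()) {
  structure(list(universe = universe,
                 ploidy_up = up, ploidy_down = down,
                 interactome = interactome,
                 planted_terms = planted_terms,
                 planted_cliques = planted_cliques),
            class = "synth_truth")
}

draw_planted <- function(cfg, ids) {
  n_up <- round(cfg$frac_ploidy_up * cfg$n_genes)
  n_down <- round(cfg$frac_ploidy_down * cfg$n_genes)
  planted <- if (n_up + n_down > 0) sample(ids, n_up + n_down) else character()
  list(up = planted[seq_len(n_up)],
       down = planted[n_up + seq_len(n_down)])
}

draw_interactome <- function(cfg, ids, planted) {
  p <- rep(cfg$interactome_frac, length(ids))
  p[ids %in% planted] <-
    planted_interactome_prob(cfg$interactome_frac, cfg$interactome_odds)
  ids[rbinom(length(ids), 1L, p) == 1L]
}

#' Generate a reciprocal cross-species expression dataset
#'
#' Four conditions — human/mouse x heart/liver — with the reciprocal ploidy
#' design (human heart and mouse liver polyploid; mouse heart and human
#' liver diploid). Per gene g and condition c the log2 expression is
#' `mu_g + tau_g T(c) + sigma_g S(c) + delta_g P(c) + noise`, with
#' `T, S, P` in \{-1, +1\} coding tissue, species and ploidy class and
#' `delta_g = +/- ploidy_delta` on the planted genes, 0 elsewhere. Rows of
#' the matrix are ortholog group ids (the cross-species gene identity);
#' the ortholog table maps each group to a species-specific gene id pair.
#'
#' @param config A [synth_config()].
#' @return A list with `expr` (matrix), `sheet` (sample sheet),
#'   `orthologs` (group_id/gene_a/gene_b), and `truth` (`synth_truth`:
#'   `universe`, `ploidy_up`, `ploidy_down`, `interactome`, ...).
#' @export
generate_cross_species_dataset <- function(config) {
  cfg <- validate_synth_config(config)
  seeds <- artifact_seeds(cfg$seed, c("effects", "noise", "interactome"))
  n <- cfg$n_genes
  groups <- sprintf("OG%05d", seq_len(n))
  orthologs <- data.frame(group_id = groups,
                          gene_a = sprintf("hsa_g%05d", seq_len(n)),
                          gene_b = sprintf("mmu_g%05d", seq_len(n)),
                          stringsAsFactors = FALSE)

  conds <- data.frame(
    species = c("human", "human", "mouse", "mouse"),
    tissue = c("heart", "liver", "heart", "liver"),
    ploidy_class = c("polyploid", "diploid", "diploid", "polyploid"),
    stringsAsFactors = FALSE)
  conds$T <- ifelse(conds$tissue == "heart", 1, -1)
  conds$S <- ifelse(conds$species == "human", 1, -1)
  conds$P <- ifelse(conds$ploidy_class == "polyploid", 1, -1)

  eff <- withr::with_seed(seeds[["effects"]], {
    planted <- draw_planted(cfg, groups)
    list(mu = rnorm(n, mean = 8, sd = cfg$mu_sd),
         tau = rnorm(n, 0, cfg$tissue_sd),
         sig = rnorm(n, 0, cfg$species_sd),
         planted = planted)
  })
  delta <- numeric(n)
  delta[groups %in% eff$planted$up] <- cfg$ploidy_delta
  delta[groups %in% eff$planted$down] <- -cfg$ploidy_delta

  reps <- cfg$reps_per_condition
  n_samp <- nrow(conds) * reps
  sheet <- data.frame(
    sample_id = paste0(rep(paste(conds$species, conds$tissue, sep = "_"),
                           each = reps), "_r", seq_len(reps)),
    species = rep(conds$species, each = reps),
    tissue = rep(conds$tissue, each = reps),
    ploidy_class = rep(conds$ploidy_class, each = reps),
    replicate = rep(seq_len(reps), times = nrow(conds)),
    stringsAsFactors = FALSE)

  expr <- withr::with_seed(seeds[["noise"]], {
    m <- matrix(0, n, n_samp, dimnames = list(groups, sheet$sample_id))
    for (j in seq_len(n_samp)) {
      ci <- (j - 1L) %/% reps + 1L
      m[, j] <- eff$mu + eff$tau * conds$T[ci] + eff$sig * conds$S[ci] +
        delta * conds$P[ci] + rnorm(n, 0, cfg$noise_sd)
    }
    m
  })

  interactome <- withr::with_seed(seeds[["interactome"]],
    draw_interactome(cfg, groups, c(eff$planted$up, eff$planted$down)))

  list(expr = expr, sheet = sheet, orthologs = orthologs,
       truth = new_synth_truth(groups, eff$planted$up, eff$planted$down,
                               interactome))
}

#' Generate a two-condition (diploid vs tetraploid) dataset
#'
#' A single-tissue, single-species design with conditions 2n and 4n:
#' `x = mu_g + delta_g P(c) + noise` with `P(2n) = -1`, `P(4n) = +1`.
#' Intended to emulate sorted decidua-like cell populations.
#'
#' @param config A [synth_config()].
#' @param gene_ids Optional gene ids to use (defaults to `g00001...`);
#'   lets a pipeline reuse a species' gene universe.
#' @param planted Optional list with `up`/`down` id vectors to plant
#'   (defaults to a fresh draw), enabling truth shared with a companion
#'   cross-species dataset.
#' @return List with `expr`, `sheet`, `truth`.
#' @export
generate_two_condition_dataset <- function(config, gene_ids = NULL,
                                           planted = NULL) {
  cfg <- validate_synth_config(config)
  seeds <- artifact_seeds(cfg$seed, c("effects2", "noise2", "interactome2"))
  n <- cfg$n_genes
  ids <- if (is.null(gene_ids)) sprintf("g%05d", seq_len(n)) else gene_ids
  if (length(ids) != n)
    abort("invalid synth_config field 'n_genes': %d gene_ids supplied for n_genes = %d",
          length(ids), n)

  eff <- withr::with_seed(seeds[["effects2"]], {
    pl <- if (is.null(planted)) draw_planted(cfg, ids) else
      list(up = intersect(planted$up, ids), down = intersect(planted$down, ids))
    list(mu = rnorm(n, mean = 8, sd = cfg$mu_sd), planted = pl)
  })
  delta <- numeric(n)
  delta[ids %in% eff$planted$up] <- cfg$ploidy_delta
  delta[ids %in% eff$planted$down] <- -cfg$ploidy_delta

  reps <- cfg$reps_per_condition
  P <- c(rep(-1, reps), rep(1, reps))
  sheet <- data.frame(
    sample_id = c(paste0("decidua_2n_r", seq_len(reps)),
                  paste0("decidua_4n_r", seq_len(reps))),
    species = "mouse", tissue = "decidua",
    ploidy_class = rep(c("diploid", "polyploid"), each = reps),
    replicate = rep(seq_len(reps), 2),
    stringsAsFactors = FALSE)

  expr <- withr::with_seed(seeds[["noise2"]], {
    m <- matrix(0, n, length(P), dimnames = list(ids, sheet$sample_id))
    for (j in seq_along(P))
      m[, j] <- eff$mu + delta * P[j] + rnorm(n, 0, cfg$noise_sd)
    m
  })

  interactome <- withr::with_seed(seeds[["interactome2"]],
    draw_interactome(cfg, ids, c(eff$planted$up, eff$planted$down)))

  list(expr = expr, sheet = sheet,
       truth = new_synth_truth(ids, eff$planted$up, eff$planted$down,
                               interactome))
}

#' Generate annotation gene sets and a weighted interaction edge list
#'
#' `n_terms` gene sets of `term_size` members each; `planted_term_count`
#' of them draw at least 80% of members from the planted (ploidy-up or
#' -down) genes. The edge list contains `edge_cliques` complete subgraphs
#' of `clique_size` planted genes at weight 0.95 plus `edge_noise` random
#' edges at weights uniform on \[0.4, 0.9\], so a stringency-0.9 filter
#' keeps exactly the clique edges.
#'
#' @param config A [synth_config()].
#' @param truth A `synth_truth` from the same gene universe.
#' @return List with `gene_sets` (a `gene_set_collection`), `edges`
#'   (canonical edge-list data frame) and `truth` updated with
#'   `planted_terms` and `planted_cliques`.
#' @export
generate_annotations_and_network <- function(config, truth) {
  cfg <- validate_synth_config(config)
  universe <- truth$universe
  if (cfg$term_size > length(universe))
    abort("invalid synth_config field 'term_size': exceeds universe size %d",
          length(universe))
  seeds <- artifact_seeds(cfg$seed, c("terms", "edges"))
  planted <- c(truth$ploidy_up, truth$ploidy_down)

  res <- withr::with_seed(seeds[["terms"]], {
    sets <- list()
    planted_ids <- character()
    for (i in seq_len(cfg$n_terms)) {
      id <- sprintf("T%03d", i)
      if (i <= cfg$planted_term_count && length(planted)) {
        n_pl <- min(ceiling(0.8 * cfg$term_size), length(planted))
        members <- c(sample(planted, n_pl),
                     sample(setdiff(universe, planted), cfg$term_size - n_pl))
        planted_ids <- c(planted_ids, id)
      } else {
        members <- sample(universe, cfg$term_size)
      }
      sets[[id]] <- members
    }
    list(sets = sets, planted_ids = planted_ids)
  })

  edges <- withr::with_seed(seeds[["edges"]], {
    pool <- if (length(planted) >= cfg$edge_cliques * cfg$clique_size)
      planted else universe
    clique_nodes <- if (cfg$edge_cliques > 0)
      sample(pool, cfg$edge_cliques * cfg$clique_size) else character()
    cliques <- split(clique_nodes,
                     rep(seq_len(max(cfg$edge_cliques, 1L)),
                         each = cfg$clique_size)[seq_along(clique_nodes)])
    rows <- list()
    for (cl in cliques) {
      pairs <- utils::combn(sort(cl), 2)
      rows[[length(rows) + 1L]] <-
        data.frame(node_a = pairs[1, ], node_b = pairs[2, ], weight = 0.95,
                   stringsAsFactors = FALSE)
    }
    if (cfg$edge_noise > 0) {
      a <- sample(universe, cfg$edge_noise, replace = TRUE)
      b <- sample(universe, cfg$edge_noise, replace = TRUE)
      keep <- a != b
      rows[[length(rows) + 1L]] <-
        data.frame(node_a = a[keep], node_b = b[keep],
                   weight = runif(sum(keep), 0.4, 0.9),
                   stringsAsFactors = FALSE)
    }
    if (!length(rows))
      rows <- list(data.frame(node_a = character(), node_b = character(),
                              weight = numeric(), stringsAsFactors = FALSE))
    list(df = do.call(rbind, rows), cliques = unname(cliques))
  })

  edge_df <- canonical_edge_list(edges$df)
  truth$planted_terms <- res$planted_ids
  truth$planted_cliques <- edges$cliques
  descriptions <- setNames(
    ifelse(names(res$sets) %in% res$planted_ids,
           "planted module", "background module"),
    names(res$sets))
  list(gene_sets = gene_set_collection(res$sets, descriptions),
       edges = edge_df, truth = truth)
}
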