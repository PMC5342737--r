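# End-to-end orchestration: config validation, stage sequencing
# (synthesize/load -> normalize/DE -> tiers -> PCA -> enrichment ->
# network), report bundling and the per-gene panel summary.

#' Default pipeline configuration
#'
#' Thresholds default to the conventional settings of this analysis:
#' 15% change filter, per-comparison p < 0.01, 2-SD score selection,
#' enrichment gates p < 0.01 and q < 0.15, and interaction stringency
#' > 0.9.
#'
#' @param seed Master seed.
#' @param output_dir Where `run_pipeline()` writes its bundle (`NULL` for
#'   no file output).
#' @return Nested configuration list.
#' @export
default_pipeline_config <- function(seed = 1L, output_dir = NULL) {
  list(
    synthetic = list(seed = seed),
    inputs = NULL,
    de = list(p_threshold = 0.01, change_threshold = 0.15, use_p_gate = TRUE),
    pca = list(sd_threshold = 2),
    enrichment = list(p_gate = 0.01, q_gate = 0.15, p0_override = NULL),
    network = list(stringency = 0.9, inflation = 2),
    output_dir = output_dir,
    seed = seed,
    log_level = "info"
  )
}

known_config_keys <- list(
  top = c("synthetic", "inputs", "de", "pca", "enrichment", "network",
          "output_dir", "seed", "log_level"),
  de = c("p_threshold", "change_threshold", "use_p_gate"),
  pca = c("sd_threshold"),
  enrichment = c("p_gate", "q_gate", "p0_override"),
  network = c("stringency", "inflation"),
  inputs = c("expression", "sample_sheet", "orthologs", "decidua_expression",
             "decidua_sample_sheet", "interactome", "gene_sets", "edges"),
  synthetic = c("n_genes", "reps_per_condition", "mu_sd", "tissue_sd",
                "species_sd", "ploidy_delta", "frac_ploidy_up",
                "frac_ploidy_down", "noise_sd", "interactome_frac",
                "interactome_odds", "n_terms", "term_size",
                "planted_term_count", "edge_cliques", "clique_size",
                "edge_noise", "seed")
)

#' Validate a pipeline configuration
#'
#' Accepts a config list or a YAML file path. All problems are collected
#' and reported together; unknown keys are errors (no silent typo
#' tolerance). Exactly one of `inputs` (file paths) or `synthetic`
#' (generator settings) must be present. Defaults are filled for absent
#' threshold blocks.
#'
#' @param config A list or a path to a YAML file.
#' @return The validated config with defaults filled.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) abort("config must be a list or a YAML file path")
  errors <- character()
  note <- function(fmt, ...) errors[[length(errors) + 1L]] <<- sprintf(fmt, ...)

  unknown <- setdiff(names(config), known_config_keys$top)
  if (length(unknown))
    note("unknown config key(s): %s", paste(unknown, collapse = ", "))
  for (sec in c("de", "pca", "enrichment", "network", "inputs", "synthetic")) {
    if (!is.null(config[[sec]])) {
      bad <- setdiff(names(config[[sec]]), known_config_keys[[sec]])
      if (length(bad))
        note("unknown key(s) in '%s': %s", sec, paste(bad, collapse = ", "))
    }
  }

  has_inputs <- !is.null(config$inputs)
  has_synth <- !is.null(config$synthetic)
  if (has_inputs && has_synth)
    note("exactly one of 'inputs' and 'synthetic' may be present, not both")
  if (!has_inputs && !has_synth)
    note("one of 'inputs' or 'synthetic' is required")

  defaults <- default_pipeline_config(seed = config$seed %||% 1L)
  for (sec in c("de", "pca", "enrichment", "network")) {
    merged <- defaults[[sec]]
    merged[names(config[[sec]])] <- config[[sec]]
    config[[sec]] <- merged
  }
  config$seed <- config$seed %||% 1L
  config$log_level <- config$log_level %||% "info"

  chk_range <- function(val, lo, hi, field, lo_open = FALSE) {
    if (!is.numeric(val) || is.na(val) ||
        (if (lo_open) val <= lo else val < lo) || val > hi)
      note("config field '%s' out of range: %s", field, format(val))
  }
  chk_range(config$de$p_threshold, 0, 1, "de.p_threshold", lo_open = TRUE)
  chk_range(config$de$change_threshold, 0, 10, "de.change_threshold")
  chk_range(config$pca$sd_threshold, 0, 100, "pca.sd_threshold", lo_open = TRUE)
  chk_range(config$enrichment$p_gate, 0, 1, "enrichment.p_gate", lo_open = TRUE)
  chk_range(config$enrichment$q_gate, 0, 1, "enrichment.q_gate", lo_open = TRUE)
  if (!is.null(config$enrichment$p0_override))
    chk_range(config$enrichment$p0_override, 0, 1, "enrichment.p0_override",
              lo_open = TRUE)
  chk_range(config$network$stringency, 0, 1, "network.stringency")
  chk_range(config$network$inflation, 1, 100, "network.inflation")

  if (has_synth && !has_inputs && !length(errors)) {
    synth_args <- config$synthetic
    synth_args$seed <- synth_args$seed %||% config$seed
    config$synthetic <- tryCatch(
      unclass(do.call(synth_config, synth_args)),
      error = function(e) { note("%s", conditionMessage(e)); NULL })
  }
  if (length(errors))
    abort("invalid pipeline config:\n  - %s", paste(errors, collapse = "\n  - "))
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

log_info <- function(config, fmt, ...) {
  if (identical(config$log_level, "quiet")) return(invisible())
  message(sprintf(paste0("[ploidysig] ", fmt), ...))
}

#' Run the full analysis pipeline
#'
#' Stages: (synthesize | load) the cross-species and two-condition
#' datasets, quantile-normalize each species' samples together,
#' moderated-t differential expression for the heart, liver and decidua
#' contrasts, direction-concordant tier building, correlation PCA with
#' component labelling and SD-score selection for both designs, binomial
#' interactome enrichment plus double-background over-representation on
#' the tiered lists and the PCA selections, and a stringency-filtered MCL
#' network over the union of significant genes. All tables are written
#' under `output_dir` (when set) together with a manifest sufficient to
#' reproduce the run.
#'
#' @param config A config list or YAML path accepted by
#'   [validate_config()].
#' @return A `report_bundle` list (invisibly returns file paths when
#'   writing): `tiers`, `de`, `pca`, `enrichment`, `network`, `manifest`.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  stage <- "load inputs"
  res <- tryCatch({
    if (!is.null(config$synthetic)) {
      stage <- "synthesize"
      cfg <- validate_synth_config(config$synthetic)
      xs <- generate_cross_species_dataset(cfg)
      dec <- generate_two_condition_dataset(cfg,
        gene_ids = xs$orthologs$gene_b,
        planted = list(
          up = xs$orthologs$gene_b[xs$orthologs$group_id %in%
                                     xs$truth$ploidy_up],
          down = xs$orthologs$gene_b[xs$orthologs$group_id %in%
                                       xs$truth$ploidy_down]))
      ann <- generate_annotations_and_network(cfg, xs$truth)
      inputs <- list(expr = xs$expr, sheet = xs$sheet,
                     orthologs = xs$orthologs,
                     dec_expr = dec$expr, dec_sheet = dec$sheet,
                     interactome = xs$truth$interactome,
                     gene_sets = ann$gene_sets, edges = ann$edges,
                     truth = ann$truth)
    } else {
      inp <- config$inputs
      inputs <- list(
        expr = read_expression(inp$expression),
        sheet = read_sample_sheet(inp$sample_sheet),
        orthologs = read_orthologs(inp$orthologs),
        dec_expr = if (!is.null(inp$decidua_expression))
          read_expression(inp$decidua_expression),
        dec_sheet = if (!is.null(inp$decidua_sample_sheet))
          read_sample_sheet(inp$decidua_sample_sheet),
        interactome = if (!is.null(inp$interactome))
          read_gene_list(inp$interactome),
        gene_sets = if (!is.null(inp$gene_sets))
          read_gene_sets(inp$gene_sets),
        edges = if (!is.null(inp$edges)) read_edge_list(inp$edges),
        truth = NULL)
    }
    log_info(config, "inputs: %d genes x %d samples",
             nrow(inputs$expr), ncol(inputs$expr))

    stage <- "normalize"
    expr_n <- inputs$expr
    for (sp in unique(inputs$sheet$species)) {
      cols <- inputs$sheet$sample_id[inputs$sheet$species == sp]
      expr_n[, cols] <- quantile_normalize(inputs$expr[, cols, drop = FALSE])
    }
    dec_n <- if (!is.null(inputs$dec_expr))
      quantile_normalize(inputs$dec_expr)

    stage <- "differential expression"
    de <- list(
      heart = moderated_t_test(expr_n, inputs$sheet,
        c("human_heart_polyploid", "mouse_heart_diploid")),
      liver = moderated_t_test(expr_n, inputs$sheet,
        c("mouse_liver_polyploid", "human_liver_diploid")))
    if (!is.null(dec_n))
      de$decidua <- moderated_t_test(dec_n, inputs$dec_sheet,
        c("mouse_decidua_polyploid", "mouse_decidua_diploid"))

    stage <- "tiered lists"
    tiers <- build_tiered_lists(de$heart, de$liver, de$decidua,
                                inputs$orthologs,
                                p_threshold = config$de$p_threshold,
                                change_threshold = config$de$change_threshold,
                                use_p_gate = config$de$use_p_gate)
    log_info(config, "tiers: A %d/%d, B %d/%d, C %d/%d",
             length(tiers$tier_A_up), length(tiers$tier_A_down),
             length(tiers$tier_B_up), length(tiers$tier_B_down),
             length(tiers$tier_C_up), length(tiers$tier_C_down))

    stage <- "PCA"
    pca <- list()
    pca$cross_species <- label_components(
      fit_pca(condition_profiles(expr_n, inputs$sheet)))
    pca_sel <- list()
    if (any(pca$cross_species$labels == "ploidy")) {
      pca_sel$cross_species <-
        select_by_score(pca$cross_species, config$pca$sd_threshold)
    } else {
      warnf("no ploidy-labelled component in the cross-species PCA")
    }
    if (!is.null(dec_n)) {
      pca$decidua <- label_components(
        fit_pca(condition_profiles(dec_n, inputs$dec_sheet)))
      if (any(pca$decidua$labels == "ploidy")) {
        pca_sel$decidua <- select_by_score(pca$decidua,
                                           config$pca$sd_threshold)
      } else warnf("no ploidy-labelled component in the decidua PCA")
    }

    stage <- "enrichment"
    groups <- inputs$orthologs$group_id
    map_b <- setNames(inputs$orthologs$group_id, inputs$orthologs$gene_b)
    enr <- list(binomial = list(), ora = list())
    if (!is.null(inputs$interactome)) {
      selections <- list(tier_B_up = tiers$tier_B_up,
                         tier_B_down = tiers$tier_B_down)
      if (!is.null(pca_sel$cross_species)) {
        selections$pca_induced <- pca_sel$cross_species$induced
        selections$pca_suppressed <- pca_sel$cross_species$suppressed
      }
      if (!is.null(pca_sel$decidua)) {
        selections$pca_decidua_induced <-
          unname(na.omit(map_b[pca_sel$decidua$induced]))
        selections$pca_decidua_suppressed <-
          unname(na.omit(map_b[pca_sel$decidua$suppressed]))
      }
      for (nm in names(selections)) {
        sel <- selections[[nm]]
        if (!length(sel)) next
        enr$binomial[[nm]] <- binomial_enrichment(
          sel, inputs$interactome, groups,
          p0 = config$enrichment$p0_override)
      }
      if (!is.null(inputs$gene_sets)) {
        for (nm in names(selections)) {
          sel <- selections[[nm]]
          if (!length(sel)) next
          enr$ora[[nm]] <- double_background_ora(
            sel, inputs$gene_sets, groups, inputs$interactome,
            p_gate = config$enrichment$p_gate,
            q_gate = config$enrichment$q_gate)
        }
      }
    }

    stage <- "network"
    network <- NULL
    sig_union <- unique(c(tiers$tier_B_up, tiers$tier_B_down,
                          if (!is.null(pca_sel$cross_species))
                            c(pca_sel$cross_species$induced,
                              pca_sel$cross_species$suppressed)))
    if (!is.null(inputs$edges) && length(sig_union)) {
      graph <- build_graph(inputs$edges, sig_union,
                           stringency = config$network$stringency)
      clusters <- if (length(graph$nodes))
        mcl_cluster(graph, inflation = config$network$inflation)
      network <- list(graph = graph, clusters = clusters,
                      summary = network_summary(graph, clusters))
      log_info(config, "network: %d nodes, %d edges, %d cluster(s)",
               network$summary$n_nodes, network$summary$n_edges,
               length(network$summary$cluster_sizes))
    }

    bundle <- structure(
      list(config = config, de = de, tiers = tiers, pca = pca,
           pca_selection = pca_sel, enrichment = enr, network = network,
           truth = inputs$truth),
      class = "report_bundle")
    if (!is.null(config$output_dir)) write_bundle(bundle, config$output_dir)
    bundle
  }, error = function(e) {
    abort("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
  })
  res
}

write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(bundle$de)) {
    write.table(bundle$de[[nm]], file.path(dir, paste0("de_", nm, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  for (nm in names(bundle$tiers)) {
    write_gene_list(bundle$tiers[[nm]], file.path(dir, paste0(nm, ".txt")))
  }
  for (nm in names(bundle$pca)) {
    m <- bundle$pca[[nm]]
    write.table(data.frame(variable = rownames(m$loadings), m$loadings),
                file.path(dir, paste0("pca_", nm, "_loadings.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(data.frame(gene = rownames(m$scores), round(m$scores, 6)),
                file.path(dir, paste0("pca_", nm, "_scores.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(var_fraction = as.list(m$var_fraction),
           labels = as.list(m$labels),
           orientation = as.list(m$orientation),
           kurtosis = as.list(m$kurtosis)),
      file.path(dir, paste0("pca_", nm, "_report.json")),
      auto_unbox = TRUE, digits = NA)
  }
  if (length(bundle$enrichment$binomial)) {
    jsonlite::write_json(lapply(bundle$enrichment$binomial, unclass),
                         file.path(dir, "binomial_enrichment.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  for (nm in names(bundle$enrichment$ora)) {
    write.table(bundle$enrichment$ora[[nm]],
                file.path(dir, paste0("ora_", nm, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(bundle$network)) {
    write_edge_list(bundle$network$graph$edges,
                    file.path(dir, "network_edges.tsv"))
    if (!is.null(bundle$network$clusters)) {
      mem <- bundle$network$clusters$membership
      write.table(data.frame(gene = names(mem), cluster = as.integer(mem)),
                  file.path(dir, "network_clusters.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  if (!is.null(bundle$truth)) write_truth(bundle$truth,
                                          file.path(dir, "truth.json"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("ploidysig")),
    r_version = R.version.string,
    seed = bundle$config$seed,
    config = bundle$config[setdiff(names(bundle$config), "output_dir")])
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Summarize polyploid-vs-diploid differences for a gene panel
#'
#' For each requested gene, the mean and standard error of the log2
#' polyploid-minus-diploid difference across all comparisons present in
#' the design (each tissue's polyploid condition against its diploid
#' counterpart), with significance marks following the reporting
#' convention: `**` when the least significant comparison has p < 0.0001,
#' `*` when p < 0.01.
#'
#' @param mat Gene-by-sample matrix (log2, normalized).
#' @param sheet Sample sheet.
#' @param gene_ids Genes to report; unknown ids are collected in the
#'   `skipped_ids` attribute rather than failing.
#' @return Data frame `gene`, `mean_delta`, `se`, `n_comparisons`,
#'   `max_p`, `stars`.
#' @export
summarize_gene_panel <- function(mat, sheet, gene_ids) {
  validate_sample_sheet(sheet, mat)
  known <- intersect(gene_ids, rownames(mat))
  skipped <- setdiff(gene_ids, known)
  conds <- unique(data.frame(species = sheet$species, tissue = sheet$tissue,
                             ploidy_class = sheet$ploidy_class,
                             stringsAsFactors = FALSE))
  contrasts <- list()
  for (ts in unique(conds$tissue)) {
    poly <- conds[conds$tissue == ts & conds$ploidy_class == "polyploid", ]
    dip <- conds[conds$tissue == ts & conds$ploidy_class == "diploid", ]
    for (i in seq_len(nrow(poly))) for (j in seq_len(nrow(dip))) {
      contrasts[[length(contrasts) + 1L]] <- c(
        paste(poly$species[i], ts, "polyploid", sep = "_"),
        paste(dip$species[j], ts, "diploid", sep = "_"))
    }
  }
  if (!length(contrasts)) abort("no polyploid-vs-diploid contrast in design")

  de <- lapply(contrasts, function(cc) moderated_t_test(mat, sheet, cc))
  deltas <- vapply(de, function(d) d$delta[match(known, d$gene)],
                   numeric(length(known)))
  ps <- vapply(de, function(d) d$p[match(known, d$gene)],
               numeric(length(known)))
  deltas <- matrix(deltas, nrow = length(known))
  ps <- matrix(ps, nrow = length(known))
  k <- ncol(deltas)
  mean_delta <- rowMeans(deltas)
  se <- if (k > 1) apply(deltas, 1, sd) / sqrt(k) else rep(NA_real_,
                                                           length(known))
  max_p <- apply(ps, 1, max)
  stars <- ifelse(max_p < 1e-4, "**", ifelse(max_p < 0.01, "*", ""))
  out <- data.frame(gene = known, mean_delta = mean_delta, se = se,
                    n_comparisons = k, max_p = max_p, stars = stars,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "skipped_ids") <- skipped
  out
}
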