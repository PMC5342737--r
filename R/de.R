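# Quantile normalization, empirical-Bayes moderated t-test, 15%-change
# filtering and the direction-concordance tiering of reciprocal
# polyploid-vs-diploid comparisons.

#' Quantile-normalize an expression matrix
#'
#' After normalization every column's sorted values equal the across-column
#' mean of order statistics; ties within a column receive the mean of the
#' reference values at their tied ranks (delegated to
#' `limma::normalizeQuantiles(ties = TRUE)`).
#'
#' @param mat Numeric gene-by-sample matrix (log2 scale).
#' @return Matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(mat) {
  if (!is.matrix(mat)) abort("quantile_normalize expects a matrix")
  if (ncol(mat) < 2L)
    abort("quantile normalization needs >= 2 samples; got %d", ncol(mat))
  out <- limma::normalizeQuantiles(mat, ties = TRUE)
  dimnames(out) <- dimnames(mat)
  out
}

#' Fit empirical-Bayes variance-prior hyperparameters
#'
#' Estimates the prior degrees of freedom `d0` and prior variance `s0_sq`
#' of a scaled-F model for per-gene sample variances by moment matching on
#' log variances (trigamma inversion, via `limma::fitFDist`). When the
#' observed dispersion of log variances does not exceed the theoretical
#' chi-square dispersion, `d0 = Inf` is returned and the moderated test
#' degenerates to a z-like statistic at `s0_sq`.
#'
#' @param sample_variances Per-gene pooled sample variances.
#' @param df Residual degrees of freedom (scalar or per-gene vector).
#' @return List with `d0` and `s0_sq`, class `ebayes_params`.
#' @export
fit_ebayes <- function(sample_variances, df) {
  s2 <- sample_variances
  keep <- is.finite(s2) & rep_len(df, length(s2)) >= 1
  if (sum(keep) < 10L)
    abort("fit_ebayes needs >= 10 genes with df >= 1; got %d", sum(keep))
  if (all(s2[keep] == 0))
    abort("all sample variances are zero; degenerate data")
  fit <- limma::fitFDist(s2[keep], df1 = rep_len(df, length(s2))[keep])
  if (!is.finite(fit$scale) || fit$scale <= 0)
    abort("empirical-Bayes prior variance estimate is not positive")
  structure(list(d0 = fit$df2, s0_sq = fit$scale), class = "ebayes_params")
}

#' Moderated two-group t-test (polyploid vs diploid)
#'
#' Per gene, the posterior variance is
#' `s_tilde^2 = (d0 s0^2 + d_g s_g^2) / (d0 + d_g)` and
#' `t = delta / (s_tilde sqrt(1/n1 + 1/n2))` with `delta` the log2 mean
#' difference (polyploid minus diploid); two-sided p-values come from a t
#' distribution on `d0 + d_g` degrees of freedom (normal when `d0 = Inf`).
#' With `d0 = 0` this is the ordinary pooled two-sample t-test.
#'
#' @param mat Gene-by-sample matrix (log2 scale).
#' @param sheet Sample sheet covering `colnames(mat)`.
#' @param contrast Length-2 character vector of condition labels (see
#'   [condition_labels()]): `c(polyploid_condition, diploid_condition)`.
#' @param params Optional [fit_ebayes()] result; fitted from this
#'   comparison's pooled variances when `NULL`. Pass `list(d0 = 0)` for the
#'   ordinary t-test.
#' @return Data frame with columns `gene`, `delta`, `ratio` (`2^delta`),
#'   `t_mod`, `p`, `df_total`, `s2` and `df_resid`.
#' @export
moderated_t_test <- function(mat, sheet, contrast, params = NULL) {
  validate_sample_sheet(sheet, mat)
  labels <- condition_labels(sheet)
  if (length(contrast) != 2L)
    abort("contrast must name exactly two conditions")
  for (cc in contrast) {
    if (!cc %in% labels)
      abort("condition '%s' absent from the sample sheet (have: %s)",
            cc, paste(unique(labels), collapse = ", "))
  }
  idx1 <- sheet$sample_id[labels == contrast[[1]]]
  idx2 <- sheet$sample_id[labels == contrast[[2]]]
  n1 <- length(idx1); n2 <- length(idx2)
  x1 <- mat[, idx1, drop = FALSE]
  x2 <- mat[, idx2, drop = FALSE]

  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  ss <- rowSums((x1 - m1)^2) + rowSums((x2 - m2)^2)
  df_resid <- n1 + n2 - 2L
  if (df_resid < 1L && is.null(params))
    abort("both conditions need >= 2 samples unless ebayes params are supplied")
  s2 <- if (df_resid >= 1L) ss / df_resid else rep(0, nrow(mat))

  if (is.null(params)) params <- fit_ebayes(s2, df_resid)
  d0 <- params$d0
  if (is.null(d0) || is.na(d0) || d0 < 0)
    abort("ebayes params: d0 must be >= 0 (possibly Inf)")
  if (df_resid < 1L && d0 == 0)
    abort("single-replicate conditions need a prior (d0 > 0)")
  s0_sq <- if (d0 > 0) params$s0_sq else 0
  if (d0 > 0 && (is.null(s0_sq) || s0_sq <= 0))
    abort("ebayes params: s0_sq must be > 0 when d0 > 0")

  s2_tilde <- if (is.finite(d0)) {
    if (d0 + df_resid == 0) rep(NA_real_, nrow(mat))
    else (d0 * s0_sq + df_resid * s2) / (d0 + df_resid)
  } else rep(s0_sq, nrow(mat))
  if (anyNA(s2_tilde) || any(s2_tilde <= 0))
    abort("posterior variances are not all positive; degenerate comparison")

  delta <- m1 - m2
  se <- sqrt(s2_tilde) * sqrt(1 / n1 + 1 / n2)
  t_mod <- delta / se
  df_total <- d0 + df_resid           # Inf + k == Inf; pt handles Inf df
  p <- 2 * pt(-abs(t_mod), df = df_total)
  p <- pmin(pmax(p, .Machine$double.xmin), 1)

  data.frame(gene = rownames(mat), delta = delta, ratio = 2^delta,
             t_mod = t_mod, p = p, df_total = df_total,
             s2 = s2, df_resid = df_resid,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Fold-change filter at a linear-ratio threshold
#'
#' A gene passes upward if `ratio >= 1 + threshold` and downward if
#' `ratio <= 1 / (1 + threshold)` (boundaries inclusive; the reciprocal
#' keeps the rule symmetric in direction). Default threshold 0.15, i.e.
#' differential expression above 15%.
#'
#' @param de A [moderated_t_test()] result (needs `gene` and `ratio`).
#' @param threshold Fractional change threshold.
#' @return Data frame `gene`, `pass`, `direction` (`"up"`, `"down"` or
#'   `NA` for non-passing genes).
#' @export
change_filter <- function(de, threshold = 0.15) {
  stopifnot(threshold >= 0)
  up <- de$ratio >= 1 + threshold
  down <- de$ratio <= 1 / (1 + threshold)
  data.frame(gene = de$gene, pass = up | down,
             direction = ifelse(up, "up", ifelse(down, "down", NA_character_)),
             row.names = NULL, stringsAsFactors = FALSE)
}

passing_genes <- function(de, direction, p_threshold, change_threshold,
                          use_p_gate) {
  cf <- change_filter(de, change_threshold)
  keep <- cf$pass & !is.na(cf$direction) & cf$direction == direction
  if (use_p_gate) keep <- keep & de$p < p_threshold
  de$gene[keep]
}

#' Intersect reciprocal comparisons into tiered concordant gene lists
#'
#' Tier B: genes passing the change filter (and, by default, `p <
#' p_threshold`) in the same direction in *both* the heart and the liver
#' reciprocal comparisons (ortholog-group ids). Tier A: tier-B genes whose
#' decidua comparison agrees in direction, filter and significance. Tier C:
#' the decidua-only result (native gene ids; genes without orthologs are
#' retained, as tier C is intra-species).
#'
#' @param heart_de,liver_de [moderated_t_test()] results keyed to ortholog
#'   group ids (polyploid minus diploid in each).
#' @param decidua_de Optional decidua comparison keyed to species-B gene
#'   ids (mapped to groups via `orthologs` for tier A).
#' @param orthologs Ortholog table (`group_id`, `gene_a`, `gene_b`);
#'   required when `decidua_de` is given.
#' @param p_threshold Per-comparison significance gate (default 0.01).
#' @param change_threshold Fractional change threshold (default 0.15).
#' @param use_p_gate Apply the significance gate (default `TRUE`); with
#'   `FALSE` membership is by fold change alone.
#' @return List of class `tiered_lists` with `tier_A_up`, `tier_A_down`,
#'   `tier_B_up`, `tier_B_down`, `tier_C_up`, `tier_C_down`.
#' @export
build_tiered_lists <- function(heart_de, liver_de, decidua_de = NULL,
                               orthologs = NULL, p_threshold = 0.01,
                               change_threshold = 0.15, use_p_gate = TRUE) {
  common <- intersect(heart_de$gene, liver_de$gene)
  if (!length(common))
    abort("heart and liver comparisons share no ortholog groups")

  tier <- function(direction) {
    intersect(passing_genes(heart_de, direction, p_threshold,
                            change_threshold, use_p_gate),
              passing_genes(liver_de, direction, p_threshold,
                            change_threshold, use_p_gate))
  }
  b_up <- tier("up"); b_down <- tier("down")

  a_up <- a_down <- character()
  c_up <- c_down <- character()
  if (!is.null(decidua_de)) {
    c_up <- passing_genes(decidua_de, "up", p_threshold,
                          change_threshold, use_p_gate)
    c_down <- passing_genes(decidua_de, "down", p_threshold,
                            change_threshold, use_p_gate)
    if (is.null(orthologs))
      abort("orthologs are required to map the decidua comparison to groups")
    map <- setNames(orthologs$group_id, orthologs$gene_b)
    a_up <- intersect(b_up, na.omit(map[c_up]))
    a_down <- intersect(b_down, na.omit(map[c_down]))
  }

  structure(list(tier_A_up = unname(a_up), tier_A_down = unname(a_down),
                 tier_B_up = b_up, tier_B_down = b_down,
                 tier_C_up = c_up, tier_C_down = c_down),
            class = "tiered_lists")
}
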