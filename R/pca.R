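# Correlation-matrix PCA over condition profiles. The decomposition is a
# pure rotation of the (standardized) profiles: as many components as
# variables, no information loss. Loadings are on the correlation scale
# (loading = correlation between a condition profile and a component), so
# the mean of squared loadings per component equals that component's
# variance fraction and each variable's squared loadings sum to 1. Gene
# scores are standardized to zero mean and unit SD per component, so SD
# thresholds read directly as score cutoffs.

#' Average replicate columns into condition profiles
#'
#' One profile per (species, tissue) condition: the mean of its replicate
#' columns. The returned matrix carries a `conditions` attribute (a data
#' frame with species/tissue/ploidy_class per profile) used by
#' [label_components()].
#'
#' @param mat Gene-by-sample matrix.
#' @param sheet Sample sheet covering the columns of `mat`.
#' @return Genes x conditions matrix.
#' @export
condition_profiles <- function(mat, sheet) {
  validate_sample_sheet(sheet, mat)
  cond <- paste(sheet$species, sheet$tissue, sep = "_")
  # sorted-cell designs separate ploidy classes within one organ
  if (anyDuplicated(unique(data.frame(cond, sheet$ploidy_class))$cond))
    cond <- condition_labels(sheet)
  levels <- unique(cond)
  prof <- vapply(levels, function(cc) {
    cols <- sheet$sample_id[cond == cc]
    if (!length(cols)) abort("condition '%s' has zero samples", cc)
    rowMeans(mat[, cols, drop = FALSE])
  }, numeric(nrow(mat)))
  dimnames(prof) <- list(rownames(mat), levels)
  meta <- unique(data.frame(condition = cond, species = sheet$species,
                            tissue = sheet$tissue,
                            ploidy_class = sheet$ploidy_class,
                            stringsAsFactors = FALSE))
  attr(prof, "conditions") <- meta[match(levels, meta$condition), , drop = FALSE]
  prof
}

#' Full-rank correlation PCA of condition profiles
#'
#' Eigendecomposition of the conditions' correlation matrix computed
#' across genes. Loadings are `eigenvector * sqrt(eigenvalue)`; variance
#' fractions are `eigenvalue / n_variables`; scores are projections of the
#' standardized gene rows, re-standardized per component to zero mean and
#' unit SD. Components are ordered by decreasing eigenvalue and initially
#' oriented so the first variable loads positively (eigenvector sign is
#' arbitrary); [label_components()] applies the ploidy sign convention.
#'
#' @param profiles Genes x conditions matrix, e.g. [condition_profiles()].
#' @return List of class `ploidy_pca`: `variables`, `loadings`, `scores`,
#'   `var_fraction`, `eigenvalues`, `rotation`, `score_scale`, `labels`,
#'   `orientation`, `kurtosis`, `conditions`.
#' @export
fit_pca <- function(profiles) {
  if (ncol(profiles) < 2L) abort("PCA needs >= 2 condition variables")
  sds <- apply(profiles, 2, sd)
  if (any(sds == 0))
    abort("constant (zero-variance) variable: %s",
          paste(colnames(profiles)[sds == 0], collapse = ", "))
  k <- ncol(profiles)
  R <- cor(profiles)
  e <- eigen(R, symmetric = TRUE)
  V <- e$vectors
  # canonical pre-orientation: first variable positive in each component
  flip <- ifelse(V[1, ] < 0, -1, 1)
  V <- sweep(V, 2, flip, `*`)
  lam <- pmax(e$values, 0)

  Z <- scale(profiles)                     # genes standardized per variable
  raw <- Z %*% V
  score_scale <- apply(raw, 2, sd)
  if (any(score_scale == 0))
    abort("degenerate component with zero score variance")
  scores <- sweep(raw, 2, colMeans(raw), `-`)
  scores <- sweep(scores, 2, score_scale, `/`)

  comp <- paste0("PC", seq_len(k))
  loadings <- sweep(V, 2, sqrt(lam), `*`)
  dimnames(loadings) <- list(colnames(profiles), comp)
  dimnames(V) <- list(colnames(profiles), comp)
  dimnames(scores) <- list(rownames(profiles), comp)

  structure(list(variables = colnames(profiles),
                 loadings = loadings,
                 scores = scores,
                 var_fraction = setNames(lam / k, comp),
                 eigenvalues = setNames(lam, comp),
                 rotation = V,
                 score_scale = setNames(score_scale, comp),
                 labels = setNames(rep("unassigned", k), comp),
                 orientation = setNames(rep(1, k), comp),
                 kurtosis = apply(scores, 2, pearson_kurtosis),
                 conditions = attr(profiles, "conditions")),
            class = "ploidy_pca")
}

# Pearson (non-excess) kurtosis m4 / m2^2; equals 3 for a Gaussian.
pearson_kurtosis <- function(x) {
  d <- x - mean(x)
  mean(d^4) / mean(d^2)^2
}

#' Variance fractions implied by a loading matrix
#'
#' On the correlation scale the mean over variables of squared loadings of
#' a component equals its variance fraction; this helper makes the
#' identity available for externally printed loading tables too.
#'
#' @param loadings Variables x components loading matrix.
#' @return Per-component variance fractions.
#' @export
variance_from_loadings <- function(loadings) {
  colMeans(loadings^2)
}

factor_codings <- function(conditions) {
  codings <- list()
  for (f in c("tissue", "species", "ploidy_class")) {
    lev <- unique(conditions[[f]])
    if (length(lev) == 2L) {
      name <- if (f == "ploidy_class") "ploidy" else f
      codings[[name]] <- ifelse(conditions[[f]] == lev[[1]], 1, -1)
    } else if (length(lev) > 2L) {
      abort("factor '%s' has more than two levels; sign coding undefined", f)
    }
  }
  nm <- names(codings)
  for (i in seq_along(codings)) for (j in seq_len(i - 1L)) {
    if (all(codings[[i]] == codings[[j]]) ||
        all(codings[[i]] == -codings[[j]]))
      abort("confounded design: factors '%s' and '%s' have identical coding",
            nm[j], nm[i])
  }
  codings
}

#' Label components by loading sign pattern and canonicalize orientation
#'
#' A component is labelled `shared` when all loadings have one sign;
#' `tissue`, `species` or `ploidy` when its loading sign pattern matches
#' that factor's +/-1 coding up to a global flip; otherwise `unassigned`.
#' A ploidy component is re-oriented so the polyploid-class variables load
#' negatively — low (negative) scores then mark ploidy-induced genes, high
#' scores ploidy-suppressed ones. Other labelled components are oriented
#' with the first variable positive.
#'
#' @param model A [fit_pca()] result whose `conditions` metadata is set.
#' @return The model with `labels` and `orientation` filled in (loadings,
#'   rotation and scores flipped accordingly).
#' @export
label_components <- function(model) {
  cond <- model$conditions
  if (is.null(cond))
    abort("model carries no condition metadata; fit from condition_profiles()")
  codings <- factor_codings(cond)
  ploidy_sign <- ifelse(cond$ploidy_class == "polyploid", -1, 1)

  for (kk in seq_along(model$var_fraction)) {
    s <- sign(model$loadings[, kk])
    if (any(s == 0)) next                       # ambiguous: leave unassigned
    label <- "unassigned"
    if (all(s == s[[1]])) {
      label <- "shared"
    } else {
      for (f in names(codings)) {
        cd <- codings[[f]]
        if (all(s == cd) || all(s == -cd)) { label <- f; break }
      }
    }
    model$labels[[kk]] <- label
    if (label == "ploidy") {
      # polyploid variables negative: scores low => induced by polyploidy
      if (!all(s == ploidy_sign)) model <- flip_component(model, kk)
    } else if (label != "unassigned") {
      if (model$loadings[1, kk] < 0) model <- flip_component(model, kk)
    }
  }
  model
}

flip_component <- function(model, kk) {
  model$loadings[, kk] <- -model$loadings[, kk]
  model$rotation[, kk] <- -model$rotation[, kk]
  model$scores[, kk] <- -model$scores[, kk]
  model$orientation[[kk]] <- -model$orientation[[kk]]
  model
}

#' Select genes by standardized score on the ploidy component
#'
#' Under the canonical orientation, induced genes have `score <
#' -sd_threshold` and suppressed genes `score > +sd_threshold` (strict
#' inequalities). A 2-SD cut reads as exceeding the 95% band of a
#' unit-variance score; 3 SD is the stricter nested cut.
#'
#' @param model A labelled [label_components()] model.
#' @param sd_threshold Score threshold in SD units (commonly 2 or 3).
#' @return List with `induced`, `suppressed`, `component`, `sd_threshold`.
#' @export
select_by_score <- function(model, sd_threshold = 2) {
  kk <- which(model$labels == "ploidy")
  if (!length(kk))
    abort("no component is labelled 'ploidy'; run label_components()")
  kk <- kk[[1]]
  sc <- model$scores[, kk]
  list(induced = names(sc)[sc < -sd_threshold],
       suppressed = names(sc)[sc > sd_threshold],
       component = colnames(model$scores)[kk],
       sd_threshold = sd_threshold)
}

#' Score-distribution diagnostics for a component
#'
#' Pearson (non-excess) kurtosis `m4/m2^2` — 3 for a Gaussian, far larger
#' when a sparse planted signal dominates the tails — and the 99th
#' percentile of absolute scores.
#'
#' @param model A `ploidy_pca` model.
#' @param component Component name (e.g. `"PC4"`) or index.
#' @return List with `kurtosis` and `percentile_99_abs`.
#' @export
score_diagnostics <- function(model, component) {
  sc <- model$scores[, component]
  if (length(sc) < 4L) abort("need >= 4 genes for kurtosis")
  list(kurtosis = pearson_kurtosis(sc),
       percentile_99_abs = unname(quantile(abs(sc), 0.99)))
}
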