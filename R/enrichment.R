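# Interactome binomial enrichment, hypergeometric over-representation,
# Storey-Tibshirani q-values, the double-background significance rule and
# geometric-mean module-group summaries.

# Log-space sum of exp(terms): max-shifted to avoid underflow at tail
# probabilities around 1e-300.
log_sum_exp <- function(lx) {
  m <- max(lx)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(lx - m)))
}

#' Exact one-sided binomial enrichment of an interactome in a selection
#'
#' Tests whether the proportion of interactome members in a gene selection
#' exceeds a background proportion `p0`. The p-value is the exact upper
#' tail `P(X >= k) = sum_{j=k}^{n} C(n,j) p0^j (1-p0)^{n-j}`, accumulated
#' in log space. Either supply gene sets (with `p0` defaulting to the
#' interactome rate in the universe) or explicit counts `k`, `n`, `p0` —
#' the latter reproduces published contingencies at their printed
#' precision.
#'
#' @param selection Gene ids tested for enrichment (must be a subset of
#'   `universe`).
#' @param interactome Interactome gene ids.
#' @param universe Background gene universe.
#' @param k,n Explicit counts: interactants in the selection, selection
#'   size (alternative to the three sets).
#' @param p0 Background proportion; overrides the universe-derived rate.
#' @return List of class `binomial_enrichment`: `k`, `n`, `p0`,
#'   `proportion` (`k/n`) and `p_value`.
#' @export
binomial_enrichment <- function(selection = NULL, interactome = NULL,
                                universe = NULL, k = NULL, n = NULL,
                                p0 = NULL) {
  if (is.null(k) != is.null(n))
    abort("supply both k and n, or neither")
  if (is.null(k)) {
    if (is.null(selection) || is.null(interactome) || is.null(universe))
      abort("supply selection, interactome and universe (or explicit k, n)")
    if (!length(selection)) abort("empty selection")
    outside <- setdiff(selection, universe)
    if (length(outside))
      abort("selection contains %d gene(s) outside the universe (e.g. %s)",
            length(outside), outside[[1]])
    n <- length(unique(selection))
    k <- length(intersect(selection, interactome))
    if (is.null(p0)) {
      p0 <- length(intersect(interactome, universe)) / length(unique(universe))
    }
  } else {
    if (n < 1) abort("empty selection")
    if (k < 0 || k > n) abort("k must satisfy 0 <= k <= n")
  }
  if (is.null(p0) || p0 <= 0 || p0 >= 1)
    abort("background proportion p0 must be in (0, 1)")
  p_value <- if (k == 0) 1 else
    min(exp(log_sum_exp(dbinom(k:n, n, p0, log = TRUE))), 1)
  structure(list(k = k, n = n, p0 = p0, proportion = k / n,
                 p_value = p_value),
            class = "binomial_enrichment")
}

#' Hypergeometric over-representation of a term in a selection
#'
#' Upper-tail probability that at least `k` of the `n` selected genes fall
#' in the `K`-member term when drawing from an `N`-gene background;
#' selection and term are intersected with the background first.
#'
#' @param term Term member gene ids.
#' @param selection Selected gene ids.
#' @param background Background gene universe.
#' @return List: `k`, `n`, `K`, `N`, `p`.
#' @export
hypergeom_ora <- function(term, selection, background) {
  background <- unique(background)
  N <- length(background)
  if (N < 2) abort("background must contain at least 2 genes")
  term_b <- intersect(term, background)
  sel_b <- intersect(selection, background)
  K <- length(term_b); n <- length(sel_b)
  k <- length(intersect(sel_b, term_b))
  p <- if (k == 0) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  list(k = k, n = n, K = K, N = N, p = min(p, 1))
}

#' Storey-Tibshirani q-values
#'
#' Estimates the null proportion `pi0` on a lambda grid with a cubic
#' smoothing-spline extrapolation to `lambda -> 1` (falling back to the
#' fixed `lambda = 0.5` estimate below 100 p-values), then converts sorted
#' p-values with the step-up minimum `q_(i) = min_(j>=i) pi0 m p_(j) / j`,
#' clipped at 1.
#'
#' @param p_values P-values in (0, 1].
#' @param lambda Tuning grid for the `pi0` estimate.
#' @param pi0 Optional fixed `pi0` (bypasses estimation; `pi0 = 1` yields
#'   Benjamini-Hochberg values).
#' @param method `"auto"` (spline, or fixed for small m), `"spline"`, or
#'   `"fixed"` (single `lambda = 0.5`).
#' @return List with `q_values` (input order) and `model` (`pi0`,
#'   `lambda_grid`, `method`).
#' @export
storey_qvalues <- function(p_values, lambda = seq(0.05, 0.95, by = 0.05),
                           pi0 = NULL, method = c("auto", "spline", "fixed")) {
  method <- match.arg(method)
  p <- p_values
  m <- length(p)
  if (!m) abort("no p-values supplied")
  if (any(!is.finite(p) | p <= 0 | p > 1))
    abort("p-values must lie in (0, 1]")

  used <- method
  if (is.null(pi0)) {
    if (method == "auto") used <- if (m < 100) "fixed" else "spline"
    if (used == "fixed") {
      pi0 <- mean(p > 0.5) / 0.5
    } else {
      pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), 0)
      fit <- smooth.spline(lambda, pi0_l, df = 3)
      pi0 <- predict(fit, x = max(lambda))$y
    }
    if (pi0 <= 0) {
      warnf("pi0 estimate %.3g <= 0; falling back to 1/m floor", pi0)
      pi0 <- 1 / m
    }
    pi0 <- min(pi0, 1)
    used <- if (used == "spline") "spline" else "fixed"
  } else {
    if (pi0 <= 0 || pi0 > 1) abort("pi0 must be in (0, 1]")
    used <- "fixed"
  }

  o <- order(p)
  q_sorted <- pi0 * m * p[o] / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[o] <- q_sorted
  list(q_values = q,
       model = list(pi0 = pi0, lambda_grid = lambda, method = used))
}

# Merge terms with identical member sets (redundancy removal); the record
# keeps the lexicographically first id and lists the merged ids.
merge_identical_terms <- function(collection) {
  keys <- vapply(collection, function(g) paste(sort(unique(g)), collapse = "\r"),
                 character(1))
  groups <- split(names(collection), keys)
  ids <- vapply(groups, function(g) sort(g)[[1]], character(1))
  sets <- collection[ids]
  merged <- setNames(lapply(groups, sort), ids)
  attr(sets, "merged_ids") <- merged
  sets
}

#' Double-background over-representation analysis
#'
#' Every term is tested by [hypergeom_ora()] against two backgrounds — the
#' full ortholog universe and the interactome universe — with Storey
#' q-values computed within each background's family. A term counts as
#' significant only when `p < p_gate` and `q < q_gate` in *both*
#' backgrounds. Terms with identical member sets are united beforehand.
#'
#' @param selection Selected gene ids.
#' @param collection A `gene_set_collection` (or named list of id vectors).
#' @param ortholog_universe All ortholog gene ids.
#' @param interactome_universe All interactome gene ids.
#' @param p_gate,q_gate Significance gates (defaults 0.01 and 0.15).
#' @param qvalue_method Passed to [storey_qvalues()].
#' @return Data frame with one row per term per background (`term_id`,
#'   `background`, `k`, `n`, `K`, `N`, `p`, `q`, `pass`) plus attributes
#'   `significant_terms` (both gates in both backgrounds) and
#'   `merged_ids`.
#' @export
double_background_ora <- function(selection, collection,
                                  ortholog_universe, interactome_universe,
                                  p_gate = 0.01, q_gate = 0.15,
                                  qvalue_method = "auto") {
  if (!length(collection)) {
    out <- data.frame(term_id = character(), background = character(),
                      k = integer(), n = integer(), K = integer(),
                      N = integer(), p = numeric(), q = numeric(),
                      pass = logical(), stringsAsFactors = FALSE)
    attr(out, "significant_terms") <- character()
    return(out)
  }
  sets <- merge_identical_terms(collection)
  backgrounds <- list(orthologs = ortholog_universe,
                      interactants = interactome_universe)
  rows <- list()
  for (bg in names(backgrounds)) {
    recs <- lapply(names(sets), function(id) {
      r <- hypergeom_ora(sets[[id]], selection, backgrounds[[bg]])
      data.frame(term_id = id, background = bg, k = r$k, n = r$n,
                 K = r$K, N = r$N, p = r$p, stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, recs)
    df$q <- storey_qvalues(df$p, method = qvalue_method)$q_values
    df$pass <- df$p < p_gate & df$q < q_gate
    rows[[bg]] <- df
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  both <- tapply(out$pass, out$term_id, all)
  attr(out, "significant_terms") <- sort(names(both)[both])
  attr(out, "merged_ids") <- attr(sets, "merged_ids")
  out
}

#' Geometric-mean q-value summaries per module group
#'
#' Aggregates enrichment records into per-group (and per-background)
#' geometric means of q-values, the convention used to report module
#' functional groups. Zero q-values are floored at 1e-300 with a warning;
#' empty groups are omitted with a warning.
#'
#' @param records A [double_background_ora()] result (needs `term_id`,
#'   `background`, `q`).
#' @param group_map Named character vector mapping term id to group name;
#'   unmapped terms are an error unless mapped to `NA` (explicitly
#'   ungrouped, dropped).
#' @return Data frame `group`, `background`, `n_terms`, `geo_mean_q`.
#' @export
group_summary <- function(records, group_map) {
  unmapped <- setdiff(unique(records$term_id), names(group_map))
  if (length(unmapped))
    abort("term(s) missing from group_map: %s",
          paste(head(unmapped, 5), collapse = ", "))
  grp <- group_map[records$term_id]
  keep <- !is.na(grp)
  if (!all(keep)) warnf("%d explicitly ungrouped record(s) dropped",
                        sum(!keep))
  records <- records[keep, , drop = FALSE]
  grp <- grp[keep]
  if (!nrow(records)) {
    warnf("no grouped records; empty summary")
    return(data.frame(group = character(), background = character(),
                      n_terms = integer(), geo_mean_q = numeric(),
                      stringsAsFactors = FALSE))
  }
  q <- records$q
  if (any(q == 0)) {
    warnf("%d zero q-value(s) floored at 1e-300", sum(q == 0))
    q[q == 0] <- 1e-300
  }
  key <- paste(grp, records$background, sep = "\r")
  agg <- tapply(q, key, function(v) exp(mean(log(v))))
  cnt <- tapply(q, key, length)
  parts <- strsplit(names(agg), "\r", fixed = TRUE)
  data.frame(group = vapply(parts, `[`, "", 1L),
             background = vapply(parts, `[`, "", 2L),
             n_terms = as.integer(cnt),
             geo_mean_q = as.numeric(agg),
             row.names = NULL, stringsAsFactors = FALSE)
}
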