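# Readers and writers for every file format the pipeline touches.
# All loaders validate eagerly and fail with messages naming the file,
# the offending line/field and the rule violated; nothing is silently
# coerced. Expression values are exchanged on log2 scale throughout.

#' Read a gene-by-sample expression matrix
#'
#' Tab-separated file with a header row of sample identifiers and gene
#' identifiers in the first column. Values are interpreted as log2-scale
#' expression unless `scale = "linear"`, in which case `log2(x + 1)` is
#' applied on load so that a single declared scale is used everywhere
#' downstream.
#'
#' @param path Path to a TSV file.
#' @param scale Either `"log2"` (default, values taken as-is) or
#'   `"linear"` (values transformed with `log2(x + 1)`).
#' @return A numeric matrix with gene ids as row names and sample ids as
#'   column names.
#' @export
read_expression <- function(path, scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    abort("%s: expected gene id column plus at least one sample column", path)
  gene_ids <- df[[1L]]
  sample_ids <- colnames(df)[-1L]
  dup_g <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup_g))
    abort("%s: duplicate gene id(s): %s", path, paste(dup_g, collapse = ", "))
  dup_s <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup_s))
    abort("%s: duplicate sample id(s): %s", path, paste(dup_s, collapse = ", "))
  vals <- suppressWarnings(
    vapply(df[-1L], as.numeric, numeric(nrow(df)))
  )
  vals <- matrix(vals, nrow = nrow(df),
                 dimnames = list(gene_ids, sample_ids))
  bad <- which(is.na(vals) | !is.finite(vals), arr.ind = TRUE)
  if (nrow(bad)) {
    abort("%s: non-numeric or non-finite value at row %d (gene %s), column %s",
          path, bad[1, 1] + 1L, gene_ids[bad[1, 1]], sample_ids[bad[1, 2]])
  }
  if (scale == "linear") vals <- log2(vals + 1)
  vals
}

#' Write an expression matrix
#'
#' Inverse of [read_expression()]; values are written with 15 significant
#' digits so a write/read round trip is an identity for practical purposes.
#'
#' @param mat Numeric matrix with gene row names and sample column names.
#' @param path Output path.
#' @export
write_expression <- function(mat, path) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  df <- data.frame(gene_id = rownames(mat),
                   format(mat, digits = 15, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("gene_id", colnames(mat))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet
#'
#' TSV with columns `sample_id`, `species`, `tissue`, `ploidy_class`
#' (`diploid` or `polyploid`) and `replicate`.
#'
#' @param path Path to a TSV file.
#' @return A data frame with those five columns.
#' @export
read_sample_sheet <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  validate_sample_sheet(df, file = path)
}

#' @rdname read_sample_sheet
#' @param sheet A candidate sample-sheet data frame.
#' @param mat Optional expression matrix; if given, the sheet must cover its
#'   sample columns exactly once each.
#' @param file Label used in error messages.
#' @export
validate_sample_sheet <- function(sheet, mat = NULL, file = "sample sheet") {
  need <- c("sample_id", "species", "tissue", "ploidy_class", "replicate")
  miss <- setdiff(need, colnames(sheet))
  if (length(miss))
    abort("%s: missing column(s): %s", file, paste(miss, collapse = ", "))
  dup <- unique(sheet$sample_id[duplicated(sheet$sample_id)])
  if (length(dup))
    abort("%s: duplicate sample id(s): %s", file, paste(dup, collapse = ", "))
  bad <- setdiff(unique(sheet$ploidy_class), c("diploid", "polyploid"))
  if (length(bad))
    abort("%s: ploidy_class must be diploid/polyploid, got: %s",
          file, paste(bad, collapse = ", "))
  # a (species, tissue, ploidy_class) triple defines a comparison group; the
  # same organ may legitimately appear in both classes (sorted-cell designs)
  if (!is.null(mat)) {
    if (!setequal(sheet$sample_id, colnames(mat)))
      abort("%s: sample ids do not match the expression matrix columns", file)
  }
  sheet
}

#' @rdname read_sample_sheet
#' @export
write_sample_sheet <- function(sheet, path) {
  write.table(sheet, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Condition labels for a sample sheet
#'
#' A condition is a `(species, tissue, ploidy_class)` triple; these labels
#' are the contrast vocabulary of [moderated_t_test()].
#'
#' @param sheet A sample sheet.
#' @return Character vector, one label per sample.
#' @export
condition_labels <- function(sheet) {
  paste(sheet$species, sheet$tissue, sheet$ploidy_class, sep = "_")
}

#' Read a one-to-one ortholog table
#'
#' TSV with columns `group_id`, `gene_a`, `gene_b`. The mapping must be
#' strictly one-to-one: no gene identifier may appear in two rows.
#'
#' @param path Path to a TSV file.
#' @return Data frame with the three columns.
#' @export
read_orthologs <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("group_id", "gene_a", "gene_b")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    abort("%s: missing column(s): %s", path, paste(miss, collapse = ", "))
  validate_orthologs(df, file = path)
}

validate_orthologs <- function(df, file = "ortholog table") {
  for (col in c("group_id", "gene_a", "gene_b")) {
    dup <- unique(df[[col]][duplicated(df[[col]])])
    if (length(dup))
      abort("%s: %s not one-to-one, repeated id(s): %s",
            file, col, paste(head(dup, 5), collapse = ", "))
  }
  both <- intersect(df$gene_a, df$gene_b)
  if (length(both))
    abort("%s: id(s) appear as both gene_a and gene_b: %s",
          file, paste(head(both, 5), collapse = ", "))
  df
}

#' @rdname read_orthologs
#' @export
write_orthologs <- function(orthologs, path) {
  write.table(orthologs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' Each line: term id, description, then member gene ids, tab-separated.
#' Duplicate members within a term are removed with a warning; empty terms
#' are rejected.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors with a `descriptions`
#'   attribute (named character vector), class `gene_set_collection`.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  desc <- character()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L)
      abort("%s: line %d has %d field(s); GMT needs term, description, members",
            path, i, length(fields))
    members <- fields[-(1:2)]
    if (anyDuplicated(members)) {
      warnf("%s: line %d (term %s): duplicated member id(s) removed",
            path, i, fields[[1]])
      members <- unique(members)
    }
    if (fields[[1]] %in% names(sets))
      abort("%s: line %d: duplicate term id %s", path, i, fields[[1]])
    sets[[fields[[1]]]] <- members
    desc[[fields[[1]]]] <- fields[[2]]
  }
  gene_set_collection(sets, desc)
}

#' @rdname read_gene_sets
#' @param sets Named list of member-id character vectors.
#' @param descriptions Optional named character vector of term descriptions.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (length(sets)) {
    empty <- names(sets)[lengths(sets) == 0L]
    if (length(empty))
      abort("empty gene set(s): %s", paste(empty, collapse = ", "))
  }
  if (is.null(descriptions))
    descriptions <- setNames(rep("", length(sets)), names(sets))
  structure(sets, descriptions = descriptions, class = "gene_set_collection")
}

#' @rdname read_gene_sets
#' @export
write_gene_sets <- function(sets, path) {
  desc <- attr(sets, "descriptions")
  if (is.null(desc)) desc <- setNames(rep("", length(sets)), names(sets))
  lines <- vapply(names(sets), function(id) {
    paste(c(id, desc[[id]], sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a weighted interaction edge list
#'
#' Three tab-separated columns: two node ids and a confidence weight.
#' Weights may be floats in \[0, 1\] or integers in \[0, 1000\] (combined
#' score dialect); if any weight exceeds 1 the whole column is divided by
#' 1000. Self-edges are dropped with a warning; duplicate undirected edges
#' are collapsed keeping the maximum weight.
#'
#' @param path Path to a TSV file (no header required; a header row whose
#'   third field is non-numeric is skipped).
#' @return Data frame `node_a`, `node_b`, `weight`, canonically ordered.
#' @export
read_edge_list <- function(path) {
  df <- read.delim(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) != 3L)
    abort("%s: expected 3 columns (node_a, node_b, weight), got %d",
          path, ncol(df))
  if (is.character(df[[3]]) && is.na(suppressWarnings(as.numeric(df[1, 3])))) {
    df <- df[-1, , drop = FALSE]  # header row
  }
  w <- suppressWarnings(as.numeric(df[[3]]))
  if (anyNA(w)) {
    bad <- which(is.na(w))[1]
    abort("%s: line %d: non-numeric weight '%s'", path, bad, df[bad, 3])
  }
  if (any(w < 0))
    abort("%s: line %d: negative weight", path, which(w < 0)[1])
  if (any(w > 1)) {
    # integer combined-score dialect: every value must be a whole number
    nonint <- which(w != round(w) | w > 1000)
    if (length(nonint))
      abort("%s: mixed weight dialects: line %d has '%s' alongside scores above 1",
            path, nonint[1], format(w[nonint[1]]))
    w <- w / 1000
  }
  canonical_edge_list(data.frame(node_a = as.character(df[[1]]),
                                 node_b = as.character(df[[2]]),
                                 weight = w, stringsAsFactors = FALSE),
                      file = path)
}

canonical_edge_list <- function(edges, file = "edge list") {
  if (!nrow(edges)) {
    return(data.frame(node_a = character(), node_b = character(),
                      weight = numeric(), stringsAsFactors = FALSE))
  }
  self <- edges$node_a == edges$node_b
  if (any(self)) {
    warnf("%s: %d self-edge(s) dropped", file, sum(self))
    edges <- edges[!self, , drop = FALSE]
  }
  a <- pmin(edges$node_a, edges$node_b)
  b <- pmax(edges$node_a, edges$node_b)
  key <- paste(a, b, sep = "\r")
  w <- tapply(edges$weight, key, max)
  parts <- strsplit(names(w), "\r", fixed = TRUE)
  out <- data.frame(node_a = vapply(parts, `[`, "", 1L),
                    node_b = vapply(parts, `[`, "", 2L),
                    weight = as.numeric(w), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$node_a, out$node_b), , drop = FALSE]
}

#' @rdname read_edge_list
#' @param edges Edge-list data frame.
#' @export
write_edge_list <- function(edges, path) {
  write.table(edges, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read/write a plain gene list (one id per line)
#'
#' @param path File path.
#' @export
read_gene_list <- function(path) {
  ids <- readLines(path)
  ids[nzchar(ids)]
}

#' @rdname read_gene_list
#' @param ids Character vector of gene ids.
#' @export
write_gene_list <- function(ids, path) {
  writeLines(as.character(ids), path)
  invisible(path)
}

#' Read/write planted ground truth as JSON
#'
#' @param truth A `synth_truth` list (see [generate_cross_species_dataset()]).
#' @param path File path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  chr <- function(v) as.character(unlist(v))
  structure(list(universe = chr(x$universe),
                 ploidy_up = chr(x$ploidy_up),
                 ploidy_down = chr(x$ploidy_down),
                 interactome = chr(x$interactome),
                 planted_terms = chr(x$planted_terms),
                 planted_cliques = lapply(x$planted_cliques, chr)),
            class = "synth_truth")
}
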