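# Shared fixture builders: everything is generated in code at test time.

# Brute-force tail oracles, independent of the implementation paths.
brute_binom_tail <- function(k, n, p0) {
  if (k == 0) return(1)
  # enumerate all 2^n outcome vectors
  outcomes <- as.matrix(expand.grid(rep(list(0:1), n)))
  hits <- rowSums(outcomes)
  probs <- p0^hits * (1 - p0)^(n - hits)
  sum(probs[hits >= k])
}

brute_hyper_tail <- function(k, K, N, n) {
  if (k == 0) return(1)
  draws <- combn(N, n)
  hits <- colSums(draws <= K)   # items 1..K are the "successes"
  mean(hits >= k)
}

tiny_sheet <- function(n_rep = 3) {
  data.frame(
    sample_id = c(paste0("d", seq_len(n_rep)), paste0("p", seq_len(n_rep))),
    species = "mouse", tissue = "decidua",
    ploidy_class = rep(c("diploid", "polyploid"), each = n_rep),
    replicate = rep(seq_len(n_rep), 2),
    stringsAsFactors = FALSE)
}

tiny_two_group_matrix <- function(n_genes = 50, n_rep = 3, shift_genes = 10,
                                  shift = 1, noise = 0.4, seed = 7) {
  withr::with_seed(seed, {
    m <- matrix(rnorm(n_genes * 2 * n_rep, mean = 6, sd = 1),
                n_genes, 2 * n_rep,
                dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                c(paste0("d", seq_len(n_rep)),
                                  paste0("p", seq_len(n_rep)))))
    m[seq_len(shift_genes), n_rep + seq_len(n_rep)] <-
      m[seq_len(shift_genes), n_rep + seq_len(n_rep)] + shift
    m + rnorm(length(m), 0, noise)
  })
}

# A minimal DE-result data frame for tier tests.
fake_de <- function(genes, delta, p) {
  data.frame(gene = genes, delta = delta, ratio = 2^delta,
             t_mod = sign(delta), p = p, df_total = 10,
             stringsAsFactors = FALSE)
}

# Edge list containing two disjoint cliques at weight 0.95 plus optional
# noise edges at or below 0.9.
two_clique_edges <- function(clique1, clique2, noise = NULL) {
  mk <- function(nodes) {
    pairs <- t(combn(nodes, 2))
    data.frame(node_a = pairs[, 1], node_b = pairs[, 2], weight = 0.95,
               stringsAsFactors = FALSE)
  }
  out <- rbind(mk(clique1), mk(clique2))
  if (!is.null(noise)) out <- rbind(out, noise)
  out
}
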