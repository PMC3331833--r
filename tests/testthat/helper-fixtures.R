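# Shared fixtures: tiny graphs, record builders, and the brute-force
# hypergeometric oracle used to cross-check the analytic tail.

# exhaustive enumeration of P[overlap >= k] over all n-subsets of 1..N,
# with the gene set taken as 1..K
hyper_enum <- function(k, n, K, N) {
  if (n == 0) return(if (k == 0) 1 else 0)
  subs <- utils::combn(N, n)
  overlaps <- colSums(subs <= K)
  mean(overlaps >= k)
}

# independent closed-form route: explicit combinatorial sum (for universes
# too large to enumerate subsets)
hyper_exact <- function(k, n, K, N) {
  i <- k:min(n, K)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

k2_network <- function(w = 1) {
  gene_network(data.frame(gene_a = "a", gene_b = "b", weight = w))
}

k3_network <- function() {
  gene_network(data.frame(
    gene_a = c("a", "a", "b"), gene_b = c("b", "c", "c"), weight = 1
  ))
}

path_network <- function(genes) {
  n <- length(genes)
  gene_network(data.frame(
    gene_a = genes[-n], gene_b = genes[-1], weight = 1
  ))
}

clique_edges <- function(genes, weight = 1) {
  p <- utils::combn(genes, 2)
  data.frame(gene_a = p[1, ], gene_b = p[2, ], weight = weight,
    stringsAsFactors = FALSE)
}

# one screen record; responses given as a vector of per-animal counts
make_record <- function(clone_id, gene_id, responses, batch = "m01",
                        touches = 5L, flags = "") {
  data.frame(
    clone_id = clone_id, gene_id = gene_id, batch = batch, touches = touches,
    responses = paste(responses, collapse = ";"), flags = flags,
    stringsAsFactors = FALSE
  )
}

cumulated_baseline <- function(mean_percent = 20.6, sd_percent = 3.0) {
  data.frame(
    batch = "cumulated", mean_percent = mean_percent, sd_percent = sd_percent,
    stringsAsFactors = FALSE
  )
}

# an S-score table row without going through score_screen (for bookkeeping
# tests where only gene_id / hit_class / excluded matter)
make_sscore_table <- function(gene_id, hit_class, excluded = FALSE) {
  n <- length(gene_id)
  out <- data.frame(
    clone_id = sprintf("cl%05d", seq_len(n)), gene_id = gene_id,
    batch = rep("m01", n), n_animals = rep(80L, n),
    percent_response = rep(NA_real_, n), sd_percent = rep(NA_real_, n),
    s = rep(NA_real_, n), s_sd = rep(NA_real_, n),
    hit_class = hit_class,
    excluded = rep_len(excluded, max(n, 0)),
    exclude_reason = rep(NA_character_, n), stringsAsFactors = FALSE
  )
  class(out) <- c("sscore_table", "data.frame")
  out
}

# random weighted G(n, p) graph over named genes, guaranteed non-empty edges
random_network <- function(n, p = 0.05) {
  genes <- sprintf("r%03d", seq_len(n))
  pairs <- utils::combn(genes, 2)
  keep <- stats::runif(ncol(pairs)) < p
  if (!any(keep)) keep[1] <- TRUE
  gene_network(
    data.frame(
      gene_a = pairs[1, keep], gene_b = pairs[2, keep],
      weight = stats::runif(sum(keep), 0.1, 1), stringsAsFactors = FALSE
    ),
    nodes = genes
  )
}

random_signal <- function(network) {
  genes <- igraph::V(network)$name
  stats::setNames(stats::rnorm(length(genes)), genes)
}
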