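# Shared fixture builders; everything is generated in code.

make_table <- function(m, samples = NULL, otus = NULL) {
  if (is.null(samples)) samples <- sprintf("S%02d", seq_len(nrow(m)))
  if (is.null(otus)) otus <- sprintf("OTU%03d", seq_len(ncol(m)))
  dimnames(m) <- list(samples, otus)
  otu_table(m)
}

random_table <- function(n_samples, n_otus, seed = 1, lambda = 50) {
  set.seed(seed)
  make_table(matrix(rpois(n_samples * n_otus, lambda), n_samples))
}

# A network from bare from/to pairs; rho/q chosen to satisfy the thresholds.
toy_net <- function(from, to, rho = 0.5, label = "toy") {
  nodes <- sort(unique(c(from, to)))
  cooccurrence_network(
    nodes,
    data.frame(from = from, to = to, rho = rep_len(rho, length(from)),
               q = 0.01, stringsAsFactors = FALSE),
    network_params(), label)
}

# Graph with exactly n_nodes and n_edges (first n_edges pairs of combn).
graph_with <- function(n_nodes, n_edges) {
  nodes <- sprintf("N%03d", seq_len(n_nodes))
  pairs <- combn(nodes, 2)[, seq_len(n_edges), drop = FALSE]
  toy_net(pairs[1, ], pairs[2, ], label = "counted")
}

# Two-condition cohort with three planted guilds; small enough for fast tests.
small_sim <- function(seed = 1, n = 80, shift = 0) {
  guilds <- guild_spec(c(6, 5), rho_intra_case = 0.7, rho_inter = 0,
                       abundance_log_shift = shift)
  cohort <- cohort_spec(n_case = n, n_control = n, n_noise_otus = 20,
                        depth_mean = 20000, seed = seed)
  generate_cohort(guilds, cohort)
}

# Independent rank-correlation oracle: average ranks, then the explicit
# Pearson product-moment formula on the ranks.
spearman_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}
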