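# Dense logical adjacency of a network, in node order.
adjacency_logical <- function(net) {
  nodes <- net_nodes(net)
  a <- matrix(FALSE, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  e <- net_edges(net)
  if (nrow(e) > 0) {
    i <- match(e$from, nodes); j <- match(e$to, nodes)
    a[cbind(i, j)] <- TRUE; a[cbind(j, i)] <- TRUE
  }
  a
}

null_metric_names <- c("density", "mean_clustering", "mean_degree_centrality",
                       "max_degree_centrality", "n_edges")

# Metrics of an induced subgraph given its logical adjacency submatrix.
# Degree centralities are normalized by the subgraph size (k - 1).
submatrix_metrics <- function(s, metrics) {
  k <- nrow(s)
  deg <- rowSums(s)
  out <- numeric(length(metrics))
  names(out) <- metrics
  for (m in metrics) {
    out[m] <- switch(m,
      n_edges = sum(deg) / 2,
      density = sum(deg) / (k * (k - 1)),
      mean_degree_centrality = mean(deg) / (k - 1),
      max_degree_centrality = max(deg) / (k - 1),
      mean_clustering = {
        ss <- s * 1
        tri <- rowSums((ss %*% ss) * ss)  # 2 x triangles through each node
        denom <- deg * (deg - 1)
        mean(ifelse(deg >= 2, tri / denom, 0))
      })
  }
  out
}

#' Node-subset permutation test of sub-network topology
#'
#' Compares the topology of the sub-network induced by `target_nodes`
#' against a null distribution obtained by repeatedly drawing equally sized
#' node subsets uniformly (without replacement) from the background network
#' and taking their induced subgraphs — the "random node subset
#' permutations" null. For each metric, `z = (obs - mean_null) / sd_null`
#' and a smoothed two-sided permutation p-value
#' `(1 + 2 min(#null >= obs, #null <= obs)) / (n_perm + 1)`, capped at 1,
#' which is never 0. A zero null sd is flagged degenerate (z = NA).
#'
#' @param background a `cooccurrence_network` (the combined background).
#' @param target_nodes subset of its nodes, at least 3.
#' @param metrics any of `"density"`, `"mean_clustering"`,
#'   `"mean_degree_centrality"`, `"max_degree_centrality"`, `"n_edges"`.
#' @param n_perm number of permutations (1000 by convention).
#' @param seed RNG seed.
#' @return a `null_result`: data frame (metric, observed, null_mean,
#'   null_sd, z, p_perm, degenerate) plus `n_perm`, `seed`, `n_target`.
#' @export
subset_permutation_test <- function(background, target_nodes,
                                    metrics = null_metric_names,
                                    n_perm = 1000, seed = 1) {
  metrics <- match.arg(metrics, null_metric_names, several.ok = TRUE)
  nodes <- net_nodes(background)
  if (!all(target_nodes %in% nodes))
    abort("target_nodes must be a subset of the background nodes")
  k <- length(target_nodes)
  if (k < 3) abort("need at least 3 target nodes")
  a <- adjacency_logical(background)
  idx <- match(target_nodes, nodes)
  obs <- submatrix_metrics(a[idx, idx, drop = FALSE], metrics)
  raw <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      s <- sample.int(length(nodes), k)
      submatrix_metrics(a[s, s, drop = FALSE], metrics)
    }, numeric(length(metrics)))
  })
  null_mat <- if (length(metrics) == 1L) matrix(raw, ncol = 1L) else t(raw)
  colnames(null_mat) <- metrics
  res <- do.call(rbind, lapply(metrics, function(m) {
    nl <- null_mat[, m]
    mu <- mean(nl); s <- sd(nl)
    degenerate <- !is.finite(s) || s == 0
    z <- if (degenerate) NA_real_ else (obs[[m]] - mu) / s
    p <- min(1, (1 + 2 * min(sum(nl >= obs[[m]]), sum(nl <= obs[[m]]))) /
               (n_perm + 1))
    data.frame(metric = m, observed = obs[[m]], null_mean = mu, null_sd = s,
               z = z, p_perm = p, degenerate = degenerate,
               stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  structure(list(table = res, n_perm = n_perm, seed = seed, n_target = k),
            class = "null_result")
}

#' @export
print.null_result <- function(x, ...) {
  cat("node-subset permutation test (", x$n_target, " targets, ",
      x$n_perm, " permutations)\n", sep = "")
  print(x$table, digits = 4)
  invisible(x)
}

#' Attack-robustness curve of the largest connected component
#'
#' Removes nodes one at a time and tracks the size of the largest connected
#' component relative to its initial size. `targeted_degree` removes in
#' descending initial degree (node id as tie-break; static order unless
#' `adaptive`); `random` averages over `n_random_reps` seeded shuffles.
#' The curve starts at 1 and reaches 0 when all nodes are removed; `auc` is
#' the trapezoidal area under LCC fraction vs fraction removed (lower =
#' more vulnerable).
#'
#' @param net a network with >= 1 node.
#' @param strategy `"targeted_degree"` or `"random"`.
#' @param n_random_reps shuffles averaged for the random strategy.
#' @param seed RNG seed.
#' @param adaptive recompute degrees after every removal (targeted only).
#' @return a `robustness_curve`: `removal_fractions`, `lcc_fractions`,
#'   `strategy`, `auc`, `n_nodes`.
#' @export
robustness_curve <- function(net, strategy = c("targeted_degree", "random"),
                             n_random_reps = 20, seed = 1, adaptive = FALSE) {
  strategy <- match.arg(strategy)
  nodes <- net_nodes(net)
  n <- length(nodes)
  if (n == 0) abort("empty network")
  e <- net_edges(net)
  ei <- cbind(match(e$from, nodes), match(e$to, nodes))
  deg <- tabulate(ei, nbins = n)
  l0 <- max(lcc_sizes_prefix(integer(0), n, ei))  # initial LCC size

  curve_for_order <- function(ord) {
    # sizes[j] = LCC size with ord[1..j-1] removed; computed by adding nodes
    # in reverse with union-find, so the whole sweep is near-linear.
    sizes <- lcc_sizes_prefix(ord, n, ei)
    sizes / l0
  }

  if (strategy == "targeted_degree") {
    if (adaptive) {
      lcc <- adaptive_targeted_curve(nodes, ei, deg, l0)
    } else {
      ord <- order(-deg, nodes)
      lcc <- curve_for_order(ord)
    }
  } else {
    lcc <- with_seed(seed, {
      reps <- vapply(seq_len(n_random_reps),
                     function(r) curve_for_order(sample.int(n)),
                     numeric(n + 1))
      rowMeans(reps)
    })
  }
  frac <- (0:n) / n
  auc <- sum(diff(frac) * (head(lcc, -1) + lcc[-1]) / 2)
  structure(list(removal_fractions = frac, lcc_fractions = lcc,
                 strategy = strategy, auc = auc, n_nodes = n),
            class = "robustness_curve")
}

# LCC size after removing each prefix of `ord` (length n+1 vector, k = 0..n
# removals). Union-find over nodes added in reverse removal order.
lcc_sizes_prefix <- function(ord, n, ei) {
  if (length(ord) < n) ord <- c(ord, setdiff(seq_len(n), ord))
  parent <- seq_len(n)
  size <- rep(1L, n)
  present <- rep(FALSE, n)
  find <- function(v) {
    while (parent[v] != v) {
      parent[v] <<- parent[parent[v]]
      v <- parent[v]
    }
    v
  }
  # neighbors list
  nb <- vector("list", n)
  if (nrow(ei) > 0) {
    nb_from <- split(ei[, 2], ei[, 1])
    nb_to <- split(ei[, 1], ei[, 2])
    for (v in names(nb_from)) nb[[as.integer(v)]] <- nb_from[[v]]
    for (v in names(nb_to))
      nb[[as.integer(v)]] <- c(nb[[as.integer(v)]], nb_to[[v]])
  }
  best <- 0L
  out <- numeric(n + 1)  # out[j+1] = LCC after adding j nodes (reverse order)
  out[1] <- 0
  add_order <- rev(ord)
  for (j in seq_len(n)) {
    v <- add_order[j]
    present[v] <- TRUE
    best <- max(best, 1L)
    for (u in nb[[v]]) {
      if (present[u]) {
        ru <- find(u); rv <- find(v)
        if (ru != rv) {
          if (size[ru] < size[rv]) { tmp <- ru; ru <- rv; rv <- tmp }
          parent[rv] <- ru
          size[ru] <- size[ru] + size[rv]
        }
      }
    }
    best <- max(best, size[find(v)])
    out[j + 1] <- best
  }
  # out[j+1] corresponds to n-j removals: reverse to prefix-removal order
  rev(out)
}

adaptive_targeted_curve <- function(nodes, ei, deg, l0) {
  n <- length(nodes)
  g <- igraph::graph_from_data_frame(
    data.frame(from = nodes[ei[, 1]], to = nodes[ei[, 2]]),
    directed = FALSE, vertices = data.frame(name = nodes))
  lcc <- numeric(n + 1)
  lcc[1] <- max(igraph::components(g)$csize) / l0
  for (k in seq_len(n)) {
    d <- igraph::degree(g)
    victim <- sort(names(d)[d == max(d)])[1L]
    g <- igraph::delete_vertices(g, victim)
    lcc[k + 1] <- if (igraph::vcount(g) > 0)
      max(igraph::components(g)$csize) / l0 else 0
  }
  lcc
}

#' @export
print.robustness_curve <- function(x, ...) {
  cat("robustness_curve (", x$strategy, "): ", x$n_nodes,
      " nodes, AUC = ", round(x$auc, 4), "\n", sep = "")
  invisible(x)
}

#' Write a robustness curve as TSV
#' @param curve a `robustness_curve`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_robustness <- function(curve, path) {
  write.table(data.frame(fraction_removed = curve$removal_fractions,
                         lcc_fraction = curve$lcc_fractions,
                         strategy = curve$strategy),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
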