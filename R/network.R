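#' Thresholds for co-occurrence network construction
#'
#' An OTU pair becomes an edge iff its BH-adjusted Spearman p-value is
#' strictly below `fdr_alpha` and `|rho| >= rho_min` (inclusive), the usual
#' "FDR-adjusted P < 0.05 and |rho| >= 0.3" rule.
#'
#' @param rho_min minimum absolute Spearman correlation (inclusive).
#' @param fdr_alpha BH-adjusted significance level (exclusive).
#' @return a `network_params` object.
#' @export
network_params <- function(rho_min = 0.3, fdr_alpha = 0.05) {
  stopifnot(rho_min > 0, rho_min < 1, fdr_alpha > 0, fdr_alpha < 1)
  structure(list(correlation = "spearman", rho_min = rho_min,
                 fdr_alpha = fdr_alpha), class = "network_params")
}

#' Spearman correlation and p-value matrices
#'
#' Rank correlation (average ranks for ties) between all OTU columns, with
#' p-values from the t-distribution approximation on `n - 2` degrees of
#' freedom. Pairs involving a constant column are undefined and reported as
#' `NA` (never coerced to 0). p-values at `rho = +/-1` are floored at
#' machine epsilon so downstream BH adjustment stays finite.
#'
#' @param clr numeric matrix, samples x OTUs (>= 4 samples).
#' @return list with symmetric `rho` and `p` matrices (`diag(rho) = 1`,
#'   `diag(p) = NA`) and the sample count `n`.
#' @export
spearman_matrix <- function(clr) {
  stopifnot(is.matrix(clr), is.numeric(clr))
  n <- nrow(clr)
  if (n < 4) abort("need at least 4 samples for correlation testing")
  rho <- suppressWarnings(cor(clr, method = "spearman"))
  diag(rho) <- 1
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, 0))
  p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p[abs(rho) >= 1 - 1e-15] <- .Machine$double.eps
  p[is.na(rho)] <- NA_real_
  diag(p) <- NA_real_
  list(rho = rho, p = p, n = n)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Classic FDR step-up: sort p ascending, multiply by `n / rank`, enforce
#' monotonicity from the largest down, cap at 1. Output order matches the
#' input order; adjusted values are never below the raw ones.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1))
    abort("p-values must lie in [0, 1] with no NA")
  n <- length(pvalues)
  o <- order(pvalues, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * pvalues[o]))[ro]
}

# Low-level constructor; edges are canonicalized so from < to by string order.
new_network <- function(nodes, edges, params, label, n_samples = NA_integer_) {
  if (nrow(edges) > 0) {
    a <- pmin(edges$from, edges$to)
    b <- pmax(edges$from, edges$to)
    edges$from <- a; edges$to <- b
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(nodes = nodes, edges = edges, params = params, label = label,
                 n_samples = n_samples), class = "cooccurrence_network")
}

#' Assemble a co-occurrence network from an explicit edge list
#'
#' Low-level constructor used by readers, sub-setting operations and tests.
#' Validates the type invariants: no self-edges, undirected canonical order,
#' every edge satisfying the thresholds in `params`.
#'
#' @param nodes character vector of node (OTU) ids.
#' @param edges data frame with columns `from`, `to`, `rho`, `q` (and
#'   optionally `sign`, recomputed from `rho` when absent).
#' @param params a [network_params()].
#' @param label free-text provenance label.
#' @return a `cooccurrence_network`.
#' @export
cooccurrence_network <- function(nodes, edges, params = network_params(),
                                 label = "") {
  stopifnot(is.character(nodes), !anyDuplicated(nodes))
  need <- c("from", "to", "rho", "q")
  if (!all(need %in% names(edges)))
    abort("edges must have columns: ", paste(need, collapse = ", "))
  if (nrow(edges) > 0) {
    if (any(edges$from == edges$to)) abort("self-edges are not allowed")
    if (!all(c(edges$from, edges$to) %in% nodes))
      abort("edge endpoints must be listed in `nodes`")
    if (any(abs(edges$rho) < params$rho_min) || any(edges$q >= params$fdr_alpha))
      abort("edges violate the network thresholds (|rho| >= rho_min, q < fdr_alpha)")
    edges$sign <- ifelse(edges$rho > 0, "+", "-")
    key <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to))
    if (anyDuplicated(key)) abort("duplicate edges")
  }
  new_network(nodes, edges, params, label)
}

#' Build a signed co-occurrence network from CLR data
#'
#' Spearman correlations over all OTU pairs, a single BH adjustment across
#' the full upper triangle (undefined pairs excluded), then the edge rule
#' `q < fdr_alpha` and `|rho| >= rho_min`. Isolated OTUs are dropped by
#' default so node counts reflect connected OTUs.
#'
#' @param clr samples x OTUs matrix, typically from [clr_transform()].
#' @param params a [network_params()].
#' @param label provenance label (e.g. the group the samples came from).
#' @param retain_isolates keep OTUs with no significant edge as nodes.
#' @return a `cooccurrence_network`.
#' @export
build_network <- function(clr, params = network_params(), label = "",
                          retain_isolates = FALSE) {
  stopifnot(inherits(params, "network_params"))
  if (ncol(clr) < 2) abort("need at least 2 OTUs")
  sm <- spearman_matrix(clr)
  otus <- colnames(clr)
  if (is.null(otus)) abort("`clr` must have OTU ids as colnames")
  ut <- which(upper.tri(sm$rho), arr.ind = TRUE)
  rho <- sm$rho[ut]
  p <- sm$p[ut]
  ok <- !is.na(rho)
  q <- rep(NA_real_, length(p))
  if (any(ok)) q[ok] <- bh_adjust(p[ok])
  keep <- ok & q < params$fdr_alpha & abs(rho) >= params$rho_min
  edges <- data.frame(from = otus[ut[keep, 1L]], to = otus[ut[keep, 2L]],
                      rho = rho[keep], q = q[keep],
                      sign = ifelse(rho[keep] > 0, "+", "-"),
                      stringsAsFactors = FALSE)
  nodes <- if (retain_isolates) otus else
    otus[otus %in% c(edges$from, edges$to)]
  new_network(nodes, edges, params, label, n_samples = sm$n)
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat("cooccurrence_network", if (nzchar(x$label)) paste0("'", x$label, "'"),
      ":", length(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  cat("  thresholds: |rho| >=", x$params$rho_min, ", BH q <",
      x$params$fdr_alpha, "\n")
  if (nrow(x$edges) > 0)
    cat("  negative edges:", sum(x$edges$sign == "-"), "\n")
  invisible(x)
}

# Edge data frame of any network-like object.
net_edges <- function(net) {
  if (inherits(net, c("cooccurrence_network", "stable_network"))) net$edges
  else abort("not a network object")
}

net_nodes <- function(net) net$nodes

# igraph view; weight = |rho| (stable networks: mean of the two magnitudes).
#' Convert a network to an igraph object
#'
#' Edge attribute `weight` is `|rho|` (for stable networks, the mean of the
#' two source magnitudes); `rho`, `q` and `sign` are carried when present.
#'
#' @param net a `cooccurrence_network` or `stable_network`.
#' @param sort_nodes add vertices in lexicographic id order (used for
#'   deterministic community detection).
#' @return an igraph graph.
#' @export
as_igraph <- function(net, sort_nodes = FALSE) {
  e <- net_edges(net)
  nodes <- net_nodes(net)
  if (sort_nodes) nodes <- sort(nodes)
  w <- if ("rho" %in% names(e)) abs(e$rho) else (abs(e$rho_a) + abs(e$rho_b)) / 2
  g <- igraph::graph_from_data_frame(
    cbind(e[, c("from", "to")], weight = w,
          e[, setdiff(names(e), c("from", "to")), drop = FALSE]),
    directed = FALSE, vertices = data.frame(name = nodes))
  g
}

#' Topology metrics of a co-occurrence network
#'
#' Density `2E / (N (N - 1))`, mean degree, degree centralities
#' (`degree / (N - 1)`), mean local clustering (nodes of degree < 2
#' contribute 0), average shortest path length on the largest connected
#' component, and the fraction of negative edges.
#'
#' @param net a `cooccurrence_network` (>= 2 nodes).
#' @return a `topology_metrics` list.
#' @export
topology <- function(net) {
  nodes <- net_nodes(net); e <- net_edges(net)
  n <- length(nodes)
  if (n < 2) abort("topology needs at least 2 nodes")
  m <- nrow(e)
  deg <- tabulate(match(c(e$from, e$to), nodes), nbins = n)
  density <- 2 * m / (n * (n - 1))
  if (m > 0) {
    g <- as_igraph(net)
    lc <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
    comp <- igraph::components(g)
    big <- which.max(comp$csize)
    sub <- igraph::induced_subgraph(g, which(comp$membership == big))
    apl <- if (igraph::vcount(sub) > 1)
      igraph::mean_distance(sub, directed = FALSE, weights = NA) else NA_real_
    negf <- mean(e$sign == "-")
  } else {
    lc <- rep(0, n); apl <- NA_real_; negf <- NA_real_
  }
  structure(list(n_nodes = n, n_edges = m, density = density,
                 mean_degree = 2 * m / n,
                 mean_degree_centrality = mean(deg) / (n - 1),
                 max_degree_centrality = max(deg) / (n - 1),
                 mean_clustering = mean(lc),
                 avg_path_length = apl,
                 negative_edge_fraction = negf),
            class = "topology_metrics")
}

#' @export
print.topology_metrics <- function(x, ...) {
  cat(sprintf("topology: %d nodes, %d edges, density %.4f\n",
              x$n_nodes, x$n_edges, x$density))
  cat(sprintf("  mean degree %.2f | mean clustering %.4f | APL %.3f | neg. edges %.3f\n",
              x$mean_degree, x$mean_clustering, x$avg_path_length,
              x$negative_edge_fraction))
  invisible(x)
}

#' Fraction of negative edges
#'
#' @param net a network with at least one edge.
#' @return fraction in `[0, 1]`.
#' @export
negative_edge_fraction <- function(net) {
  e <- net_edges(net)
  if (nrow(e) == 0) abort("network has no edges")
  mean(e$sign == "-")
}

neighbor_sets <- function(net) {
  e <- net_edges(net)
  nb <- lapply(setNames(vector("list", length(net_nodes(net))), net_nodes(net)),
               function(x) character(0))
  if (nrow(e) > 0) {
    for (i in seq_len(nrow(e))) {
      nb[[e$from[i]]] <- c(nb[[e$from[i]]], e$to[i])
      nb[[e$to[i]]] <- c(nb[[e$to[i]]], e$from[i])
    }
  }
  nb
}

#' Per-node neighborhood Jaccard between two networks
#'
#' For every node shared by both networks, the Jaccard index of its
#' neighbor sets: `|N_A intersect N_B| / |N_A union N_B|` (0 when both
#' neighborhoods are empty). A histogram of these values is the node
#' "sociality" profile of the two conditions.
#'
#' @param net_a,net_b networks with overlapping node sets.
#' @return named numeric vector over shared nodes.
#' @export
neighbor_jaccard <- function(net_a, net_b) {
  shared <- intersect(net_nodes(net_a), net_nodes(net_b))
  if (length(shared) == 0) abort("node sets are disjoint")
  nb_a <- neighbor_sets(net_a); nb_b <- neighbor_sets(net_b)
  vapply(setNames(shared, shared), function(v) {
    u <- union(nb_a[[v]], nb_b[[v]])
    if (length(u) == 0) return(0)
    length(intersect(nb_a[[v]], nb_b[[v]])) / length(u)
  }, numeric(1))
}

#' OTU-by-OTU Jaccard of sample-presence profiles
#'
#' Alternative "sociality" measure on raw tables rather than networks: for
#' each OTU pair, the Jaccard index of the sets of samples in which they
#' are present. Exposed as a variant; not interchangeable with
#' [neighbor_jaccard()].
#'
#' @param x an [otu_table()].
#' @return symmetric OTUs x OTUs matrix in `[0, 1]`.
#' @export
presence_jaccard_matrix <- function(x) {
  stopifnot(inherits(x, "otu_table"))
  pres <- x$counts > 0
  inter <- crossprod(pres)
  tot <- colSums(pres)
  uni <- outer(tot, tot, "+") - inter
  j <- ifelse(uni == 0, 0, inter / uni)
  dimnames(j) <- list(otu_ids(x), otu_ids(x))
  j
}

#' Write / read a network as edge-list and node-list TSV
#'
#' Edge columns: source, target, rho, q, sign. Deterministic order.
#'
#' @param net a `cooccurrence_network`.
#' @param edges_path,nodes_path output paths (`nodes_path` optional).
#' @return `edges_path`, invisibly.
#' @export
write_network <- function(net, edges_path, nodes_path = NULL) {
  e <- net_edges(net)
  out <- data.frame(source = e$from, target = e$to, rho = e$rho, q = e$q,
                    sign = e$sign, stringsAsFactors = FALSE)
  write.table(out, edges_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(nodes_path))
    write.table(data.frame(node = net_nodes(net)), nodes_path, sep = "\t",
                quote = FALSE, row.names = FALSE)
  invisible(edges_path)
}

#' @rdname write_network
#' @param params thresholds the edges were built with.
#' @param label provenance label.
#' @export
read_network <- function(edges_path, nodes_path = NULL,
                         params = network_params(), label = "") {
  e <- read.delim(edges_path, stringsAsFactors = FALSE)
  edges <- data.frame(from = as.character(e$source), to = as.character(e$target),
                      rho = e$rho, q = e$q, stringsAsFactors = FALSE)
  nodes <- if (!is.null(nodes_path))
    as.character(read.delim(nodes_path, stringsAsFactors = FALSE)$node)
  else sort(unique(c(edges$from, edges$to)))
  cooccurrence_network(nodes, edges, params, label)
}

#' Export a network to GraphML
#'
#' @param net a network object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(path)
}
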