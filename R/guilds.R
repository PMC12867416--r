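#' Cross-condition stable network
#'
#' Intersects two co-occurrence networks built with identical thresholds:
#' an edge is kept iff it is significant in both networks and (by default)
#' carries the same sign, the "consistently present and correlated in both"
#' criterion. Nodes are kept iff incident to a kept edge.
#'
#' @param net_a,net_b `cooccurrence_network`s with equal `params`.
#' @param require_sign require sign agreement (default). `FALSE` gives the
#'   laxer "both significant, any sign" variant.
#' @return a `stable_network` with per-edge `rho_a`, `rho_b`.
#' @export
stable_network <- function(net_a, net_b, require_sign = TRUE) {
  if (!isTRUE(all.equal(net_a$params, net_b$params)))
    abort("the two networks were built with different params")
  ea <- net_edges(net_a); eb <- net_edges(net_b)
  key_a <- paste(ea$from, ea$to); key_b <- paste(eb$from, eb$to)
  hit <- match(key_a, key_b)
  keep <- !is.na(hit)
  if (require_sign) keep <- keep & ea$sign == eb$sign[hit]
  if (!any(keep)) abort("no stable edges: the networks share no consistent edge")
  edges <- data.frame(from = ea$from[keep], to = ea$to[keep],
                      rho_a = ea$rho[keep], rho_b = eb$rho[hit[keep]],
                      sign = ea$sign[keep], stringsAsFactors = FALSE)
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- sort(unique(c(edges$from, edges$to)))
  structure(list(nodes = nodes, edges = edges,
                 labels = c(net_a$label, net_b$label), params = net_a$params),
            class = "stable_network")
}

#' @export
print.stable_network <- function(x, ...) {
  cat("stable_network (", paste(x$labels, collapse = " & "), "): ",
      length(x$nodes), " nodes, ", nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

new_guild_partition <- function(assignment, algorithm, seed, resolution,
                                modularity, min_size = NA_integer_) {
  structure(list(assignment = assignment,
                 n_guilds = length(unique(assignment)),
                 modularity = modularity, algorithm = algorithm,
                 seed = seed, resolution = resolution, min_size = min_size),
            class = "guild_partition")
}

#' @export
print.guild_partition <- function(x, ...) {
  cat("guild_partition:", x$n_guilds, "guilds over", length(x$assignment),
      "nodes (", x$algorithm, ")\n")
  if (is.finite(x$modularity)) cat(sprintf("  modularity Q = %.4f\n", x$modularity))
  print(table(guild = x$assignment))
  invisible(x)
}

#' Detect guilds by modularity maximization
#'
#' Multilevel (Louvain) community detection on absolute edge weights,
#' seeded for reproducibility, with vertices inserted in lexicographic id
#' order as a tie-break. Guilds smaller than `min_size` are merged into the
#' neighboring guild with the largest total connecting weight (largest
#' remaining guild when unconnected), so abundance additivity holds. The
#' number of guilds is an outcome, never a parameter.
#'
#' @param net a `stable_network` or `cooccurrence_network` with >= 1 edge.
#' @param resolution Louvain resolution (1 = classic modularity).
#' @param seed RNG seed for the heuristic.
#' @param min_size smallest allowed guild.
#' @return a `guild_partition`; guild ids are contiguous from 0, ordered by
#'   decreasing size.
#' @export
detect_guilds <- function(net, resolution = 1, seed = 1, min_size = 3) {
  e <- net_edges(net)
  if (nrow(e) == 0) abort("network has no edges")
  stopifnot(resolution > 0, min_size >= 1)
  g <- as_igraph(net, sort_nodes = TRUE)
  cl <- with_seed(seed, igraph::cluster_louvain(g, resolution = resolution))
  mem <- igraph::membership(cl)
  nodes <- igraph::V(g)$name
  w <- igraph::E(g)$weight
  ends <- igraph::ends(g, igraph::E(g))

  # merge undersized guilds into their strongest-connected neighbor guild
  repeat {
    sizes <- table(mem)
    small <- names(sizes)[sizes < min_size]
    if (length(small) == 0 || length(sizes) == 1) break
    sm <- small[order(sizes[small], small)][1L]
    inside <- nodes[mem == sm]
    link_w <- tapply(
      c(w[ends[, 1] %in% inside & !(ends[, 2] %in% inside)],
        w[ends[, 2] %in% inside & !(ends[, 1] %in% inside)]),
      c(mem[ends[, 2][ends[, 1] %in% inside & !(ends[, 2] %in% inside)]],
        mem[ends[, 1][ends[, 2] %in% inside & !(ends[, 1] %in% inside)]]),
      sum)
    target <- if (length(link_w) > 0) {
      cand <- names(link_w)[link_w == max(link_w)]
      sort(cand)[1L]
    } else {
      rest <- sizes[names(sizes) != sm]
      names(rest)[order(-rest, names(rest))][1L]
    }
    mem[mem == sm] <- as.integer(target)
  }

  # contiguous ids from 0, by decreasing size then smallest member id
  sizes <- table(mem)
  first_node <- tapply(nodes, mem, min)
  lev <- names(sizes)[order(-sizes, first_node[names(sizes)])]
  assignment <- setNames(match(as.character(mem), lev) - 1L, nodes)
  q <- modularity_q(net, assignment)
  new_guild_partition(assignment, algorithm = "louvain", seed = seed,
                      resolution = resolution, modularity = q,
                      min_size = min_size)
}

#' Newman-Girvan modularity of a partition
#'
#' `Q = sum_g [ e_g / m - (d_g / 2m)^2 ]` with unweighted edges by default
#' (`weighted = TRUE` uses |rho| weights). Always lies in `[-0.5, 1]`.
#'
#' @param net a network object with >= 1 edge.
#' @param membership named vector (node -> community) covering all nodes,
#'   or a `guild_partition`.
#' @param weighted use edge weights instead of counts.
#' @return a single number.
#' @export
modularity_q <- function(net, membership, weighted = FALSE) {
  if (inherits(membership, "guild_partition")) membership <- membership$assignment
  e <- net_edges(net)
  nodes <- net_nodes(net)
  if (nrow(e) == 0) abort("modularity undefined: no edges")
  if (!all(nodes %in% names(membership)))
    abort("partition does not cover all nodes")
  w <- if (weighted) {
    if ("rho" %in% names(e)) abs(e$rho) else (abs(e$rho_a) + abs(e$rho_b)) / 2
  } else rep(1, nrow(e))
  m <- sum(w)
  cf <- membership[e$from]; ct <- membership[e$to]
  e_in <- tapply(w[cf == ct], cf[cf == ct], sum)
  deg <- tapply(c(w, w), c(cf, ct), sum)  # weighted degree per community
  groups <- unique(membership[nodes])
  q <- 0
  for (g in groups) {
    eg <- if (as.character(g) %in% names(e_in)) e_in[[as.character(g)]] else 0
    dg <- if (as.character(g) %in% names(deg)) deg[[as.character(g)]] else 0
    q <- q + eg / m - (dg / (2 * m))^2
  }
  unname(q)
}

#' Within-module degree (Zi) and participation coefficient (Pi)
#'
#' Guimera-Amaral role metrics on the unweighted graph:
#' `zi = (k_own - mean(k_own within module)) / sd(k_own within module)`
#' (population sd; 0 when the sd is 0 or the module has one member) and
#' `pi = 1 - sum_g (k_g / k)^2` (0 for isolated nodes). Low Pi means a
#' node's links stay inside its own guild.
#'
#' @param net a network object.
#' @param partition a `guild_partition` or named membership vector.
#' @return data frame: otu_id, guild, degree, zi, pi.
#' @export
zipi <- function(net, partition) {
  if (inherits(partition, "guild_partition")) partition <- partition$assignment
  nodes <- net_nodes(net)
  if (!all(nodes %in% names(partition)))
    abort("partition does not cover all nodes")
  e <- net_edges(net)
  mem <- partition[nodes]
  k_total <- setNames(numeric(length(nodes)), nodes)
  k_by_mod <- matrix(0, length(nodes), length(unique(mem)),
                     dimnames = list(nodes, sort(unique(as.character(mem)))))
  for (i in seq_len(nrow(e))) {
    f <- e$from[i]; t <- e$to[i]
    k_total[f] <- k_total[f] + 1; k_total[t] <- k_total[t] + 1
    k_by_mod[f, as.character(mem[t])] <- k_by_mod[f, as.character(mem[t])] + 1
    k_by_mod[t, as.character(mem[f])] <- k_by_mod[t, as.character(mem[f])] + 1
  }
  k_own <- k_by_mod[cbind(nodes, as.character(mem))]
  zi <- numeric(length(nodes))
  for (g in unique(as.character(mem))) {
    in_g <- as.character(mem) == g
    mu <- mean(k_own[in_g])
    s <- sqrt(mean((k_own[in_g] - mu)^2))
    zi[in_g] <- if (s > 0) (k_own[in_g] - mu) / s else 0
  }
  pi <- ifelse(k_total > 0, 1 - rowSums((k_by_mod / pmax(k_total, 1))^2), 0)
  data.frame(otu_id = nodes, guild = unname(mem), degree = unname(k_total),
             zi = unname(zi), pi = unname(pi), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Per-sample guild abundance
#'
#' Sum (default) or mean of the relative abundances of a guild's member
#' OTUs in each sample. Members absent from the table are skipped with a
#' warning; a guild with no member present is an error. Summed abundances
#' are additive: over all guilds they equal the total relative abundance of
#' the partitioned OTUs.
#'
#' @param table an [otu_table()].
#' @param partition a `guild_partition` or named membership vector.
#' @param guild a guild id; `NULL` returns a samples x guilds matrix.
#' @param method `"sum"` (default) or `"mean"`.
#' @return named numeric vector over samples (or a matrix when
#'   `guild = NULL`).
#' @export
guild_abundance <- function(table, partition, guild = NULL,
                            method = c("sum", "mean")) {
  method <- match.arg(method)
  if (inherits(partition, "guild_partition")) partition <- partition$assignment
  rel <- relative_abundance(table)
  one <- function(gid) {
    members <- names(partition)[partition == gid]
    if (length(members) == 0) abort("guild not found: ", gid)
    present <- intersect(members, otu_ids(table))
    if (length(present) == 0)
      abort("no member of guild ", gid, " is present in the table")
    if (length(present) < length(members))
      warning("guild ", gid, ": ", length(members) - length(present),
              " member(s) missing from the table", call. = FALSE)
    v <- rel[, present, drop = FALSE]
    if (method == "sum") rowSums(v) else rowMeans(v)
  }
  if (!is.null(guild)) return(one(guild))
  gids <- sort(unique(partition))
  out <- vapply(gids, one, numeric(nrow(rel)))
  colnames(out) <- paste0("guild_", gids)
  out
}

#' Sub-network of cross-group bridging edges
#'
#' Keeps only edges with one endpoint in `set_a` and the other in `set_b`
#' (e.g. the connections between a core guild and grey-zone OTUs). An empty
#' result is flagged, not an error. The induced two-block membership for
#' downstream modularity is attached as attribute `"sets"`; see
#' [two_block_partition()].
#'
#' @param net a `cooccurrence_network`.
#' @param set_a,set_b disjoint node sets.
#' @return a `cooccurrence_network` containing only bridging edges.
#' @export
bridging_subgraph <- function(net, set_a, set_b) {
  if (length(intersect(set_a, set_b)) > 0) abort("node sets overlap")
  e <- net_edges(net)
  keep <- (e$from %in% set_a & e$to %in% set_b) |
          (e$from %in% set_b & e$to %in% set_a)
  edges <- e[keep, , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- sort(unique(c(edges$from, edges$to)))
  out <- new_network(nodes, edges, net$params,
                     paste0(net$label, "_bridging"), net$n_samples)
  if (nrow(edges) == 0) {
    message("bridging subgraph is empty (no cross-group edges)")
    out$nodes <- character(0)
  }
  attr(out, "sets") <- list(a = intersect(set_a, nodes),
                            b = intersect(set_b, nodes))
  out
}

#' Two-block membership induced by a bridging split
#'
#' @param net a bridging subgraph from [bridging_subgraph()] (or any
#'   network) whose nodes fall into the two sets.
#' @param set_a,set_b the node sets; default taken from the `"sets"`
#'   attribute left by [bridging_subgraph()].
#' @return named membership vector (0 for `set_a`, 1 for `set_b`).
#' @export
two_block_partition <- function(net, set_a = NULL, set_b = NULL) {
  if (is.null(set_a) || is.null(set_b)) {
    s <- attr(net, "sets")
    if (is.null(s)) abort("no sets recorded; pass set_a and set_b")
    set_a <- s$a; set_b <- s$b
  }
  nodes <- net_nodes(net)
  if (!all(nodes %in% c(set_a, set_b)))
    abort("every node must belong to one of the two sets")
  setNames(ifelse(nodes %in% set_a, 0L, 1L), nodes)
}

#' Write a guild partition / Zi-Pi table / guild abundances as TSV
#'
#' @param partition a `guild_partition`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_partition <- function(partition, path) {
  df <- data.frame(otu_id = names(partition$assignment),
                   guild_id = unname(partition$assignment))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
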