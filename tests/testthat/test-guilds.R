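test_that("stable_network intersects edges with sign agreement", {
  a <- toy_net(c("x", "x", "y"), c("y", "z", "z"), rho = c(0.5, 0.6, -0.4))
  # identity: stable network of a net with itself is the net
  s <- stable_network(a, a)
  expect_identical(sort(s$nodes), sort(a$nodes))
  expect_equal(nrow(s$edges), nrow(a$edges))
  # sign conflict excluded
  b <- toy_net(c("x", "x", "y"), c("y", "z", "z"), rho = c(0.5, 0.6, 0.4))
  s2 <- stable_network(a, b)
  expect_equal(nrow(s2$edges), 2)
  expect_false(any(s2$edges$from == "y" & s2$edges$to == "z"))
  # laxer variant keeps it
  s3 <- stable_network(a, b, require_sign = FALSE)
  expect_equal(nrow(s3$edges), 3)
  # no overlap at all
  c1 <- toy_net("p", "q")
  expect_error(stable_network(a, c1), "no stable edges")
  # differing params refuse to intersect
  d <- toy_net("x", "y")
  d$params <- network_params(rho_min = 0.4)
  expect_error(stable_network(a, d), "params")
})

test_that("stable_network is symmetric and matches a set oracle", {
  set.seed(21)
  nodes <- letters[1:10]
  mk <- function() {
    pairs <- t(combn(nodes, 2))
    pick <- pairs[runif(nrow(pairs)) < 0.4, , drop = FALSE]
    toy_net(pick[, 1], pick[, 2],
            rho = sample(c(-0.5, 0.5), nrow(pick), replace = TRUE))
  }
  na <- mk(); nb <- mk()
  key <- function(e) paste(e$from, e$to, e$sign)
  want <- intersect(key(na$edges), key(nb$edges))
  s_ab <- stable_network(na, nb)
  s_ba <- stable_network(nb, na)
  expect_setequal(key(s_ab$edges), want)
  expect_identical(s_ab$edges[, c("from", "to", "sign")],
                   s_ba$edges[, c("from", "to", "sign")])
  expect_equal(s_ab$edges$rho_a, s_ba$edges$rho_b)
})

test_that("detect_guilds separates disconnected cliques and merges tiny guilds", {
  cl1 <- t(combn(c("a1", "a2", "a3", "a4"), 2))
  cl2 <- t(combn(c("b1", "b2", "b3"), 2))
  net <- toy_net(c(cl1[, 1], cl2[, 1]), c(cl1[, 2], cl2[, 2]))
  part <- detect_guilds(net, seed = 1, min_size = 1)
  expect_equal(part$n_guilds, 2)
  expect_equal(length(unique(part$assignment[c("a1", "a2", "a3", "a4")])), 1)
  expect_equal(length(unique(part$assignment[c("b1", "b2", "b3")])), 1)
  expect_setequal(unique(part$assignment), c(0L, 1L))
  # min_size forces the 3-clique to merge somewhere when bridged
  net2 <- toy_net(c(cl1[, 1], cl2[, 1], "a1"), c(cl1[, 2], cl2[, 2], "b1"))
  part2 <- detect_guilds(net2, seed = 1, min_size = 4)
  expect_equal(part2$n_guilds, 1)
  # single edge degenerates to one guild
  single <- toy_net("u", "v")
  p1 <- detect_guilds(single, seed = 1, min_size = 1)
  expect_lte(p1$n_guilds, 2)
  expect_true(all(c("u", "v") %in% names(p1$assignment)))
  # determinism under seed
  part3 <- detect_guilds(net, seed = 1, min_size = 1)
  expect_identical(part$assignment, part3$assignment)
})

test_that("detect_guilds recovers planted blocks on a stable network", {
  guilds <- guild_spec(c(8, 7, 6), rho_intra_case = 0.7, rho_inter = 0)
  cohort <- cohort_spec(150, 150, n_noise_otus = 30, seed = 22)
  sim <- generate_cohort(guilds, cohort)
  clr <- clr_transform(filter_otus(sim$table))
  st <- sim$truth$sample_state
  na <- build_network(clr[names(st)[st == "case"], ], label = "case")
  nb <- build_network(clr[names(st)[st == "control"], ], label = "control")
  sn <- stable_network(na, nb)
  part <- detect_guilds(sn, seed = 3)
  ari <- adjusted_rand_index(part$assignment,
                             sim$truth$membership[names(part$assignment)])
  expect_gte(ari, 0.8)
})

test_that("modularity_q matches hand values and the igraph reference", {
  # two 3-cliques, no cross edges, clique partition: Q = 0.5
  cl1 <- t(combn(c("a1", "a2", "a3"), 2))
  cl2 <- t(combn(c("b1", "b2", "b3"), 2))
  net <- toy_net(c(cl1[, 1], cl2[, 1]), c(cl1[, 2], cl2[, 2]))
  mem <- setNames(c(0, 0, 0, 1, 1, 1), c("a1", "a2", "a3", "b1", "b2", "b3"))
  expect_equal(modularity_q(net, mem), 0.5)
  # all nodes in one community: Q = 0
  expect_equal(modularity_q(net, setNames(rep(0, 6), names(mem))), 0)
  # random partition equals igraph's modularity to 1e-12
  set.seed(23)
  g <- graph_with(15, 30)
  mem2 <- setNames(sample(0:2, 15, replace = TRUE), g$nodes)
  ig <- igraph::graph_from_data_frame(g$edges[, 1:2], directed = FALSE,
                                      vertices = g$nodes)
  expect_equal(modularity_q(g, mem2),
               igraph::modularity(ig, mem2[igraph::V(ig)$name] + 1),
               tolerance = 1e-12)
  # bounds
  expect_gte(modularity_q(g, mem2), -0.5)
  expect_lte(modularity_q(g, mem2), 1)
})

test_that("zipi matches the per-node arithmetic oracle", {
  # hub h: 2 links into its own module (a1, a2), 2 links outside (b1, b2)
  net <- toy_net(c("h", "h", "h", "h", "a1", "b1"),
                 c("a1", "a2", "b1", "b2", "a2", "b2"))
  mem <- setNames(c(0, 0, 0, 1, 1), c("h", "a1", "a2", "b1", "b2"))
  zp <- zipi(net, mem)
  rownames(zp) <- zp$otu_id
  # pi: h has degree 4, split 2/2 -> 1 - (0.5^2 + 0.5^2) = 0.5
  expect_equal(zp["h", "pi"], 0.5)
  # a1: both links inside own module -> pi 0
  expect_equal(zp["a1", "pi"], 0)
  # zi within module 0: k_own = (2, 2, 2) -> sd 0 -> all zi 0
  expect_equal(zp[c("h", "a1", "a2"), "zi"], c(0, 0, 0))
  # hand-check a module with unequal internal degrees
  net2 <- toy_net(c("u", "u", "v"), c("v", "w", "w"))
  mem2 <- setNames(c(0, 0, 0), c("u", "v", "w"))
  zp2 <- zipi(net2, mem2)
  expect_equal(zp2$zi, c(0, 0, 0))  # triangle: all k_own equal
  expect_equal(zp2$pi, c(0, 0, 0))
  # cohesive partitions keep pi < 0.62 (planted cliques with one bridge)
  cl1 <- t(combn(paste0("a", 1:5), 2)); cl2 <- t(combn(paste0("b", 1:5), 2))
  net3 <- toy_net(c(cl1[, 1], cl2[, 1], "a1"), c(cl1[, 2], cl2[, 2], "b1"))
  mem3 <- setNames(rep(c(0, 1), each = 5), c(paste0("a", 1:5), paste0("b", 1:5)))
  expect_true(all(zipi(net3, mem3)$pi < 0.62))
})

test_that("guild_abundance sums member relative abundances additively", {
  sim <- small_sim(seed = 24, n = 30)
  part <- partition_from_membership(sim$truth$membership)
  # single-OTU guild equals that OTU's relative abundance
  one <- setNames(0L, otu_ids(sim$table)[1])
  ab1 <- guild_abundance(sim$table, one, guild = 0)
  expect_equal(unname(ab1),
               unname(relative_abundance(sim$table)[, 1]))
  # all OTUs in one guild: closure to 1
  allg <- setNames(rep(0L, ncol(otu_counts(sim$table))), otu_ids(sim$table))
  expect_true(all(abs(guild_abundance(sim$table, allg, guild = 0) - 1) < 1e-12))
  # additivity over guilds
  mat <- guild_abundance(sim$table, part)
  members <- names(part$assignment)
  expect_equal(rowSums(mat),
               rowSums(relative_abundance(sim$table)[, members]),
               tolerance = 1e-12)
  # missing members warn; fully absent guild errors
  part_plus <- c(part$assignment, setNames(0L, "OTU_9999"))
  expect_warning(guild_abundance(sim$table, part_plus, guild = 0), "missing")
  expect_error(guild_abundance(sim$table, setNames(5L, "OTU_9999"), guild = 5),
               "no member")
  # mean variant
  m0 <- guild_abundance(sim$table, part, guild = 0, method = "mean")
  s0 <- guild_abundance(sim$table, part, guild = 0)
  k0 <- sum(part$assignment == 0)
  expect_equal(s0 / k0, m0, tolerance = 1e-12)
})

test_that("bridging_subgraph keeps exactly the cross-group edges", {
  # complete bipartite K2,2
  net <- toy_net(c("a1", "a1", "a2", "a2"), c("b1", "b2", "b1", "b2"))
  sub <- bridging_subgraph(net, c("a1", "a2"), c("b1", "b2"))
  expect_equal(nrow(sub$edges), 4)
  expect_equal(topology(sub)$mean_degree, 2)
  # two-block modularity of a purely bridging graph is low
  q <- modularity_q(sub, two_block_partition(sub))
  expect_lt(q, 0)
  # no cross edges: flagged empty, not an error
  net2 <- toy_net(c("a1", "b1"), c("a2", "b2"))
  expect_message(sub2 <- bridging_subgraph(net2, c("a1", "a2"), c("b1", "b2")),
                 "empty")
  expect_equal(nrow(sub2$edges), 0)
  expect_error(bridging_subgraph(net, c("a1"), c("a1", "b1")), "overlap")
  # random graph + random split equals a brute-force filter
  set.seed(25)
  g <- graph_with(12, 25)
  half <- sample(g$nodes, 6)
  other <- setdiff(g$nodes, half)
  sub3 <- bridging_subgraph(g, half, other)
  want <- xor(g$edges$from %in% half, g$edges$to %in% half)
  expect_equal(nrow(sub3$edges), sum(want))
})
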