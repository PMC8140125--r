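test_that("lev_split separates two bridged cliques exactly", {
  g <- two_clique_bridge(5, 5)
  sp <- lev_split(g)
  expect_true(sp$divisible)
  parts <- lapply(sp$parts, sort)
  expect_setequal(parts, list(sprintf("a%02d", 1:5), sprintf("b%02d", 1:5)))
  # and the split is the exhaustive modularity optimum
  bb <- oracle_best_bipartition(g)
  expect_equal(sp$dq, bb$q, tolerance = 1e-9)
})

test_that("lev_split declares cliques and tiny modules indivisible", {
  k6 <- make_network(t(utils::combn(letters[1:6], 2)))
  expect_false(lev_split(k6)$divisible)
  pair <- make_network(cbind("a", "b"))
  tree <- decompose_network(pair)
  expect_true(tree$modules[["m"]]$terminal)
  expect_equal(tree$modules[["m"]]$terminal_reason, "too_small")
})

test_that("disconnected modules split into components before LEV", {
  g <- make_network(rbind(t(utils::combn(c("a", "b", "c"), 2)),
                          t(utils::combn(c("x", "y", "z"), 2))))
  sp <- lev_split(g)
  expect_true(sp$divisible)
  expect_setequal(lapply(sp$parts, sort),
                  list(c("a", "b", "c"), c("x", "y", "z")))
})

test_that("lev_split matches the exhaustive optimum on structured fixtures", {
  for (sizes in list(c(4, 4), c(5, 3), c(6, 5), c(4, 7))) {
    g <- two_clique_bridge(sizes[1], sizes[2])
    sp <- lev_split(g)
    bb <- oracle_best_bipartition(g)
    expect_true(sp$divisible)
    expect_setequal(lapply(sp$parts, sort), lapply(bb$parts, sort))
  }
  # on arbitrary graphs the spectral step is a relaxation; its gain is
  # positive and never beats the exhaustive optimum
  for (s in 1:10) {
    g <- random_connected_graph(8, 0.4, seed = 300 + s)
    sp <- lev_split(g)
    if (sp$divisible) {
      expect_gt(sp$dq, 0)
      expect_lte(sp$dq, oracle_best_bipartition(g)$q + 1e-9)
    }
  }
})

test_that("decomposition of disjoint cliques yields terminal motif modules", {
  g <- make_network(rbind(t(utils::combn(paste0("a", 1:4), 2)),
                          t(utils::combn(paste0("b", 1:4), 2))))
  tree <- decompose_network(g)
  root <- tree$modules[["m"]]
  expect_length(root$children, 2)
  kids <- lapply(root$children, function(id) tree$modules[[id]])
  for (kid in kids) {
    expect_true(kid$terminal)
    expect_equal(kid$terminal_reason, "indivisible")
    expect_true(kid$motif)
    expect_equal(kid$level, 1)
  }
})

test_that("triangle-free trees never carry the motif flag", {
  tree_net <- make_network(cbind(paste0("n", 2:8), paste0("n", c(1, 1, 2, 2, 3, 3, 4))))
  tr <- decompose_network(tree_net)
  expect_false(any(vapply(tr$modules, `[[`, logical(1), "motif")))
})

test_that("decomposition is deterministic and partitions every level", {
  pl <- gen_hierarchical_planted(2, 2, 8, c(0.9, 0.2, 0.02), seed = 12)
  t1 <- decompose_network(pl$network)
  t2 <- decompose_network(pl$network)
  expect_identical(t1, t2)
  nodes <- sort(igraph::V(pl$network)$name)
  counts <- integer()
  for (l in 0:t1$max_level) {
    part <- partition_at_level(t1, l)
    expect_identical(sort(unlist(part, use.names = FALSE)), nodes)
    counts <- c(counts, length(part))
  }
  expect_true(all(diff(counts) >= 0))
})

test_that("modularity matches the closed formula and igraph", {
  g <- two_clique_bridge(5, 5)
  nodes <- igraph::V(g)$name
  expect_equal(partition_modularity(g, list(nodes)), 0)
  split <- list(sprintf("a%02d", 1:5), sprintf("b%02d", 1:5))
  expect_equal(partition_modularity(g, split), 2 * (10 / 21 - (21 / 42)^2),
               tolerance = 1e-12)
  # singleton partition closed form
  k <- igraph::degree(g); m <- igraph::ecount(g)
  expect_equal(partition_modularity(g, as.list(nodes)),
               -sum((k / (2 * m))^2), tolerance = 1e-12)
  # independent cross-check against igraph on a random partition
  gg <- random_connected_graph(10, 0.4, seed = 88)
  mem <- rep(1:3, length.out = 10)
  part <- split(igraph::V(gg)$name, mem)
  expect_equal(partition_modularity(gg, part),
               igraph::modularity(gg, mem), tolerance = 1e-12)
  edgeless <- make_network(nodes = c("a", "b"))
  expect_error(partition_modularity(edgeless, list(c("a", "b"))), "undefined")
})

test_that("Hamiltonian energy reproduces direct formula evaluations", {
  tri <- make_network(t(utils::combn(c("a", "b", "c"), 2)))
  expect_equal(hamiltonian_energy(tri, list(c("a", "b", "c"))), 1.5)
  k4 <- make_network(t(utils::combn(letters[1:4], 2)))
  expect_equal(hamiltonian_energy(k4, list(letters[1:4])), 2)
  twopair <- make_network(rbind(c("a", "b"), c("c", "d")))
  expect_equal(hamiltonian_energy(twopair, list(c("a", "b"), c("c", "d"))), 2)
  # level-0 closed form: gamma * N^2 - E
  g <- gen_gnm(40, 120, seed = 7)
  expect_equal(hamiltonian_energy(g, list(igraph::V(g)$name)),
               0.5 * 40^2 - 120)
  expect_error(hamiltonian_energy(g, list(igraph::V(g)$name[-1])), "disjoint")
})

test_that("level summaries: Q starts at zero, H decreases, counts grow", {
  pl <- gen_hierarchical_planted(2, 2, 16, c(0.9, 0.15, 0.01), seed = 3)
  tree <- decompose_network(pl$network)
  lv <- level_summaries(tree, pl$network)
  expect_equal(lv$modularity[1], 0)
  expect_equal(lv$hamiltonian[1],
               0.5 * igraph::vcount(pl$network)^2 - igraph::ecount(pl$network))
  expect_true(all(diff(lv$hamiltonian) <= 1e-9))
  expect_true(all(diff(lv$n_modules) >= 0))
  # planted structure: 1, branching, branching^2 modules at levels 0..2
  expect_equal(lv$n_modules[1:3], c(1, 2, 4))
})

test_that("seed traces follow nested modules with module-local probabilities", {
  # two K5 cliques bridged: seed in clique a
  g <- two_clique_bridge(5, 5)
  tree <- decompose_network(g)
  tr <- trace_seed_genes(tree, g, "a02")
  expect_equal(tr$level, 0:1)
  # level 0: P_x = degree / E ; a02 has degree 4, E = 21
  expect_equal(tr$p_x[1], 4 / 21)
  # level 1: inside its K5, 4 of 10 edges touch it
  expect_equal(tr$p_x[2], 4 / 10)
  expect_true(all(tr$p_x >= 0 & tr$p_x <= 1))
  expect_true(all(diff(tr$p_x) >= 0))

  # unknown seeds are skipped with a warning
  expect_warning(tr2 <- trace_seed_genes(tree, g, c("a02", "ghost")), "absent")
  expect_identical(unique(tr2$gene), "a02")
})

test_that("P_x rises with depth on the planted hierarchical fixture", {
  pl <- gen_hierarchical_planted(2, 2, 16, c(0.9, 0.15, 0.01), seed = 6)
  tree <- decompose_network(pl$network)
  tr <- trace_seed_genes(tree, pl$network, pl$seed_genes)
  for (gene in unique(tr$gene)) {
    p <- tr$p_x[tr$gene == gene]
    expect_true(all(diff(p) >= -1e-12), info = gene)
  }
})

test_that("key regulators require depth, indivisibility and a triangle", {
  # K5 clique plus a separate 2-node component; both seeds reach depth 1
  e5 <- t(utils::combn(paste0("c", 1:5), 2))
  g <- make_network(rbind(e5, c("x", "y")))
  tree <- decompose_network(g)
  krs <- key_regulators(tree, g, c("c1", "x"))
  expect_identical(krs, "c1") # x's terminal module has no triangle

  # seed genes only in shallow branches are excluded by the depth rule
  pl <- gen_hierarchical_planted(2, 2, 16, c(0.9, 0.15, 0.01), seed = 4)
  tree2 <- decompose_network(pl$network)
  krs2 <- key_regulators(tree2, pl$network, pl$seed_genes)
  expect_true(all(krs2 %in% pl$seed_genes))
  expect_identical(key_regulators(tree2, pl$network, character()), character())
})

test_that("adjusted Rand index is 1 on identical partitions and penalizes noise", {
  labs <- stats::setNames(rep(c("x", "y"), each = 10), paste0("n", 1:20))
  expect_equal(adjusted_rand(labs, labs), 1)
  shuffled <- stats::setNames(labs, paste0("n", 1:20)) # same
  shuffled[1:5] <- "y"
  expect_lt(adjusted_rand(labs, shuffled), 1)
  expect_error(adjusted_rand(labs, labs[-1]), "same nodes")
})
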