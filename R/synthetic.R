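#' Erdős–Rényi G(n, M) random graph
#'
#' Uniformly samples a simple graph with exactly `n` nodes and `m` edges —
#' the size-matched random null model used to judge whether an observed
#' interaction network carries non-random structure.
#'
#' @param n number of nodes (>= 1).
#' @param m number of edges, between 0 and `n(n-1)/2`.
#' @param seed integer seed; the same seed always yields the same graph.
#' @return a network with nodes `n0001, n0002, ...`.
#' @examples
#' g <- gen_gnm(10, 15, seed = 1)
#' igraph::ecount(g) # 15
#' @export
gen_gnm <- function(n, m, seed) {
  n <- as.integer(n)
  if (n < 1L) stop("`n` must be >= 1", call. = FALSE)
  max_m <- n * (n - 1) / 2
  if (m < 0 || m > max_m) {
    stop("`m` must lie in [0, ", max_m, "]", call. = FALSE)
  }
  with_seed(seed, {
    g <- igraph::sample_gnm(n, m, directed = FALSE)
    igraph::V(g)$name <- sprintf("n%04d", seq_len(n))
    g
  })
}

#' Degree-preserving randomization by double-edge swaps
#'
#' Randomizes a network while keeping every node's degree fixed, using the
#' standard Markov-chain double-edge-swap procedure: repeatedly pick two
#' edges and exchange endpoints, rejecting any swap that would create a
#' self-loop or duplicate edge. This is the degree-preserved null model:
#' a node keeps the same number of neighbours, but which neighbours is random.
#'
#' @param net network with at least 2 edges.
#' @param swaps_per_edge attempted swaps per edge (default 10).
#' @param seed integer seed.
#' @return a network on the same node set with the identical degree sequence.
#'   If the graph admits no degree-preserving change (e.g. a star or a
#'   complete graph) the input is returned with a warning.
#' @export
rewire_preserving_degree <- function(net, swaps_per_edge = 10, seed) {
  validate_network(net)
  if (igraph::ecount(net) < 2L) {
    stop("degree-preserving rewiring needs at least 2 edges", call. = FALSE)
  }
  if (swaps_per_edge <= 0) stop("`swaps_per_edge` must be positive", call. = FALSE)
  niter <- ceiling(swaps_per_edge * igraph::ecount(net))
  out <- with_seed(seed, {
    igraph::rewire(net, igraph::keeping_degseq(loops = FALSE, niter = niter))
  })
  if (same_network(out, net)) {
    warning("rewiring left the edge set unchanged (no legal swap moved)",
            call. = FALSE)
  }
  out
}

#' Deterministic hierarchical (Ravasz-style) network
#'
#' Builds the classic deterministic hierarchical construction that combines
#' high clustering with hub structure: level 1 is a clique on `base_size`
#' nodes with the first node as hub; each further level clones the current
#' graph `base_size - 1` times and connects every non-hub clone node to the
#' root hub. The result has `base_size^levels` nodes and a clustering-versus-
#' degree curve that falls off with degree, the fingerprint of hierarchical
#' modularity.
#'
#' @param base_size clique size (>= 3).
#' @param levels number of hierarchy levels (>= 1).
#' @return a network with nodes `h0001, ...`; node `h0001` is the root hub.
#' @export
gen_hierarchical_deterministic <- function(base_size, levels) {
  base_size <- as.integer(base_size)
  levels <- as.integer(levels)
  if (base_size < 3L) stop("`base_size` must be >= 3", call. = FALSE)
  if (levels < 1L) stop("`levels` must be >= 1", call. = FALSE)

  # integer edge list; hub is node 1
  edges <- t(utils::combn(base_size, 2L))
  n <- base_size
  if (levels > 1L) {
    for (l in seq(2L, levels)) {
      blocks <- list(edges)
      periph <- integer()
      for (c_i in seq_len(base_size - 1L)) {
        off <- c_i * n
        blocks[[c_i + 1L]] <- edges + off
        periph <- c(periph, setdiff(seq_len(n) + off, 1L + off))
      }
      edges <- rbind(do.call(rbind, blocks), cbind(1L, periph))
      n <- n * base_size
    }
  }
  nm <- sprintf("h%04d", seq_len(n))
  make_network(cbind(nm[edges[, 1L]], nm[edges[, 2L]]), nodes = nm)
}

#' Planted hierarchical stochastic block model
#'
#' Samples a network with known multi-level community structure: a balanced
#' tree with `branching` children per internal node and `levels` levels sits
#' above `branching^levels` leaf blocks of `leaf_size` nodes each. A pair of
#' nodes is joined with probability `p_by_level[d + 1]`, where `d` is the
#' depth (counted from the leaves) of the pair's lowest common ancestor:
#' `d = 0` within a leaf block, `d = levels` across the top split. Because
#' the probabilities are strictly decreasing, communities are densest at the
#' bottom — the ground truth against which hierarchical community detection
#' is scored.
#'
#' @param levels depth of the hierarchy (>= 1).
#' @param branching children per internal tree node (>= 2).
#' @param leaf_size nodes per leaf block (>= 3).
#' @param p_by_level edge probabilities, length `levels + 1`, strictly
#'   decreasing from within-leaf to cross-tree.
#' @param seed integer seed.
#' @param n_seed_genes how many nodes to mark as designated seed genes
#'   (default one per leaf block, sampled uniformly within the block).
#' @return an object of class `planted_network`: a list with `network`, the
#'   leaf partition `community_labels` (named vector), `level_labels` (one
#'   named label vector per tree level, coarsest first; level `l` labels are
#'   the length-`l` tree-path prefixes, so each level refines the previous),
#'   and `seed_genes`.
#' @export
gen_hierarchical_planted <- function(levels, branching, leaf_size, p_by_level,
                                     seed, n_seed_genes = NULL) {
  levels <- as.integer(levels)
  branching <- as.integer(branching)
  leaf_size <- as.integer(leaf_size)
  if (levels < 1L) stop("`levels` must be >= 1", call. = FALSE)
  if (branching < 2L) stop("`branching` must be >= 2", call. = FALSE)
  if (leaf_size < 3L) stop("`leaf_size` must be >= 3", call. = FALSE)
  if (length(p_by_level) != levels + 1L) {
    stop("`p_by_level` must have length levels + 1", call. = FALSE)
  }
  if (any(diff(p_by_level) >= 0) || any(p_by_level < 0) || any(p_by_level > 1)) {
    stop("`p_by_level` must be strictly decreasing probabilities", call. = FALSE)
  }

  n_leaves <- branching^levels
  n <- n_leaves * leaf_size
  leaf_of <- rep(seq_len(n_leaves), each = leaf_size)
  nm <- sprintf("g%04d", seq_len(n))

  # tree path of each leaf: digit at tree level l (1 = top split)
  path <- matrix(0L, nrow = n_leaves, ncol = levels)
  for (l in seq_len(levels)) {
    block <- branching^(levels - l)
    path[, l] <- ((seq_len(n_leaves) - 1L) %/% block) %% branching
  }

  # depth (from the leaves) of the lowest common ancestor of two nodes
  # = levels - (shared path-prefix length); 0 within a leaf block
  prefix <- matrix(levels, n, n) # shared prefix length, start at max
  sameprefix <- matrix(TRUE, n, n)
  for (l in seq_len(levels)) {
    lab_l <- path[leaf_of, l]
    eq <- outer(lab_l, lab_l, "==")
    sameprefix <- sameprefix & eq
    prefix <- pmin(prefix, ifelse(sameprefix, levels, l - 1L))
  }
  same_leaf <- outer(leaf_of, leaf_of, "==")
  d <- ifelse(same_leaf, 0L, levels - prefix)
  p_mat <- matrix(p_by_level[d + 1L], n, n)

  upper <- upper.tri(p_mat)
  truth_seeds <- with_seed(seed, {
    u <- matrix(0, n, n)
    u[upper] <- runif(sum(upper))
    sel <- upper & (u < p_mat)
    ij <- which(sel, arr.ind = TRUE)
    net <- make_network(cbind(nm[ij[, 1L]], nm[ij[, 2L]]), nodes = nm)
    k <- if (is.null(n_seed_genes)) n_leaves else as.integer(n_seed_genes)
    sg <- if (is.null(n_seed_genes)) {
      vapply(seq_len(n_leaves),
             function(i) sample(nm[leaf_of == i], 1L), character(1L))
    } else {
      sample(nm, k)
    }
    list(net = net, seeds = sort(sg))
  })

  level_labels <- lapply(seq_len(levels), function(l) {
    lab <- apply(path[, seq_len(l), drop = FALSE], 1L, paste, collapse = ".")
    stats::setNames(lab[leaf_of], nm)
  })
  structure(
    list(network = truth_seeds$net,
         community_labels = stats::setNames(sprintf("leaf%03d", leaf_of), nm),
         level_labels = level_labels,
         seed_genes = truth_seeds$seeds),
    class = "planted_network"
  )
}

#' @export
print.planted_network <- function(x, ...) {
  cat("Planted hierarchical network:",
      igraph::vcount(x$network), "nodes,",
      igraph::ecount(x$network), "edges,",
      length(unique(x$community_labels)), "leaf blocks,",
      length(x$level_labels), "levels,",
      length(x$seed_genes), "seed genes\n")
  invisible(x)
}

#' Sample degrees from a discrete power law
#'
#' Draws `n` i.i.d. degrees from \eqn{P(k) \propto k^{-\gamma}}, `k >= k_min`.
#'
#' @param n sample size.
#' @param gamma exponent (> 2, so the mean is finite).
#' @param k_min minimum degree (>= 1).
#' @param seed integer seed.
#' @return integer vector of length `n`.
#' @export
sample_power_law_degrees <- function(n, gamma, k_min = 1L, seed) {
  if (gamma <= 2) stop("`gamma` must exceed 2", call. = FALSE)
  k_min <- as.integer(k_min)
  if (k_min < 1L) stop("`k_min` must be >= 1", call. = FALSE)
  # inverse-CDF table, truncated where the tail mass is negligible
  kmax <- max(1e6, k_min * 1000)
  ks <- seq(k_min, kmax)
  w <- ks^(-gamma)
  cdf <- cumsum(w) / sum(w)
  with_seed(seed, {
    u <- runif(n)
    ks[findInterval(u, cdf) + 1L]
  })
}

#' Scale-free network via the configuration model
#'
#' Samples node degrees from a discrete power law (see
#' [sample_power_law_degrees()]; one degree is redrawn if needed to make the
#' degree sum even), wires them with the configuration model and removes
#' self-loops and multi-edges. The realized degrees therefore sit at or just
#' below the sampled ones.
#'
#' @inheritParams sample_power_law_degrees
#' @return a list with `network` and the raw `degrees` sample.
#' @export
sample_power_law_network <- function(n, gamma, k_min = 1L, seed) {
  degs <- sample_power_law_degrees(n, gamma, k_min, seed)
  net <- with_seed(seed + 1L, {
    while (sum(degs) %% 2L == 1L) {
      i <- sample.int(n, 1L)
      degs[i] <- sample_power_law_degrees(1L, gamma, k_min,
                                          seed = sample.int(2^30, 1L))
    }
    g <- igraph::sample_degseq(degs, method = "configuration")
    g <- igraph::simplify(g)
    igraph::V(g)$name <- sprintf("p%05d", seq_len(n))
    g
  })
  list(network = net, degrees = degs)
}

#' Paired synthetic expression series with planted differential expression
#'
#' Emulates two independent microarray series measuring the same case/control
#' contrast: per-gene baseline log2 intensities are drawn once (uniform on
#' [4, 12], the usual microarray range) and shared by both series; a fraction
#' `frac_de` of genes is planted as differentially expressed with a signed
#' log2 fold change of magnitude uniform in `[lfc_low, lfc_high]` and random
#' sign, identical in both series; i.i.d. Gaussian noise of standard
#' deviation `noise_sd` is added on the log2 scale.
#'
#' @param n_genes number of genes.
#' @param n_ctrl,n_case samples per group (each >= 2).
#' @param frac_de fraction of genes differentially expressed.
#' @param lfc_low,lfc_high bounds on the planted |log2 fold change|
#'   (`0 < lfc_low < lfc_high`).
#' @param noise_sd Gaussian noise standard deviation (> 0) on log2 scale.
#' @param seed integer seed.
#' @return list with `series` (two [expression_dataset()] objects) and
#'   `truth` (`de_genes`, and `lfc`: named vector of planted log2 fold
#'   changes, zero for non-DE genes).
#' @export
gen_expression_pair <- function(n_genes, n_ctrl, n_case, frac_de,
                                lfc_low, lfc_high, noise_sd, seed) {
  if (n_ctrl < 2L || n_case < 2L) stop("need >= 2 samples per group", call. = FALSE)
  if (frac_de < 0 || frac_de > 1) stop("`frac_de` must be in [0, 1]", call. = FALSE)
  if (!(lfc_low > 0 && lfc_low < lfc_high)) {
    stop("need 0 < lfc_low < lfc_high", call. = FALSE)
  }
  if (noise_sd <= 0) stop("`noise_sd` must be positive", call. = FALSE)
  genes <- sprintf("g%05d", seq_len(n_genes))
  n_de <- ceiling(frac_de * n_genes)
  with_seed(seed, {
    base <- runif(n_genes, 4, 12)
    de_genes <- if (n_de > 0) sort(sample(genes, n_de)) else character()
    lfc <- stats::setNames(numeric(n_genes), genes)
    if (n_de > 0) {
      lfc[de_genes] <- sample(c(-1, 1), n_de, replace = TRUE) *
        runif(n_de, lfc_low, lfc_high)
    }
    mk_series <- function(tag) {
      mu <- cbind(matrix(base, n_genes, n_ctrl),
                  matrix(base + lfc, n_genes, n_case))
      mat <- mu + matrix(rnorm(n_genes * (n_ctrl + n_case), sd = noise_sd),
                         n_genes)
      rownames(mat) <- genes
      colnames(mat) <- c(sprintf("%s_ctrl%02d", tag, seq_len(n_ctrl)),
                         sprintf("%s_case%02d", tag, seq_len(n_case)))
      group <- stats::setNames(rep(c("control", "disease"), c(n_ctrl, n_case)),
                               colnames(mat))
      expression_dataset(mat, group)
    }
    list(series = list(mk_series("s1"), mk_series("s2")),
         truth = list(de_genes = de_genes, lfc = lfc))
  })
}
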