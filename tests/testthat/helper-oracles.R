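# Brute-force oracles, independent of the package's computation paths:
# everything here works from the raw adjacency matrix with hand-rolled
# BFS / path enumeration / dense eigensolves.

adj_matrix <- function(net) {
  nm <- sort(igraph::V(net)$name)
  A <- matrix(0L, length(nm), length(nm), dimnames = list(nm, nm))
  el <- igraph::as_edgelist(net, names = TRUE)
  for (i in seq_len(nrow(el))) {
    A[el[i, 1L], el[i, 2L]] <- 1L
    A[el[i, 2L], el[i, 1L]] <- 1L
  }
  A
}

# BFS distances from one source over an adjacency matrix.
bfs_dist <- function(A, s) {
  n <- nrow(A)
  d <- rep(Inf, n); d[s] <- 0
  frontier <- s
  while (length(frontier) > 0L) {
    nxt <- integer()
    for (v in frontier) {
      nb <- which(A[v, ] > 0 & is.infinite(d))
      d[nb] <- d[v] + 1
      nxt <- c(nxt, nb)
    }
    frontier <- unique(nxt)
  }
  d
}

# All shortest paths between i and j by depth-first enumeration.
enumerate_shortest_paths <- function(A, i, j) {
  d <- bfs_dist(A, i)
  if (is.infinite(d[j])) return(list())
  paths <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (v == j) { paths[[length(paths) + 1L]] <<- path; return() }
    for (w in which(A[v, ] > 0)) {
      if (d[w] == d[v] + 1 && d[w] <= d[j]) walk(c(path, w))
    }
  }
  walk(i)
  paths
}

# Exhaustive centralities: clustering / betweenness / closeness from first
# principles, eigenvector from a dense eigensolve on the largest component.
oracle_centralities <- function(net) {
  A <- adj_matrix(net)
  n <- nrow(A)
  nm <- rownames(A)
  deg <- rowSums(A)

  clust <- vapply(seq_len(n), function(i) {
    k <- deg[i]
    if (k < 2) return(0)
    nb <- which(A[i, ] > 0)
    2 * sum(A[nb, nb]) / 2 / (k * (k - 1))
  }, 0)

  btw <- numeric(n)
  clo <- numeric(n)
  if (n > 1L) {
    D <- t(vapply(seq_len(n), function(s) bfs_dist(A, s), numeric(n)))
    for (i in seq_len(n)) {
      fin <- is.finite(D[i, ]) & seq_len(n) != i
      clo[i] <- if (any(fin)) sum(fin) / sum(D[i, fin]) else 0
    }
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      paths <- enumerate_shortest_paths(A, i, j)
      if (length(paths) == 0L) next
      inner <- unlist(lapply(paths, function(p) p[-c(1L, length(p))]))
      if (length(inner) > 0L) {
        tab <- table(inner)
        v_idx <- as.integer(names(tab))
        btw[v_idx] <- btw[v_idx] + as.numeric(tab) / length(paths)
      }
    }
  }

  ev <- numeric(n)
  comp_lab <- rep(NA_integer_, n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp_lab[s])) next
    cid <- cid + 1L
    comp_lab[is.finite(bfs_dist(A, s))] <- cid
  }
  sizes <- table(comp_lab)
  big <- as.integer(names(sizes)[which.max(sizes)])
  idx <- which(comp_lab == big)
  if (length(idx) > 1L) {
    v <- eigen(A[idx, idx], symmetric = TRUE)$vectors[, 1L]
    v <- abs(v)
    ev[idx] <- v / sqrt(sum(v^2))
  }
  data.frame(node = nm, degree = as.numeric(deg), clustering = clust,
             betweenness = btw, closeness = clo, eigenvector = ev,
             row.names = NULL, stringsAsFactors = FALSE)
}

# CN / LCL of a pair from adjacency-matrix arithmetic.
oracle_cn_lcl <- function(net, x, y) {
  A <- adj_matrix(net)
  common <- which(A[x, ] > 0 & A[y, ] > 0)
  common <- setdiff(common, match(c(x, y), rownames(A)))
  list(cn = length(common),
       lcl = if (length(common) >= 2L) sum(A[common, common]) / 2L else 0L)
}

# Pearson LCP correlation recomputed by full pairwise enumeration over edges.
oracle_lcp_corr <- function(net) {
  el <- igraph::as_edgelist(net, names = TRUE)
  recs <- t(vapply(seq_len(nrow(el)), function(i) {
    r <- oracle_cn_lcl(net, el[i, 1L], el[i, 2L])
    c(r$cn, r$lcl)
  }, numeric(2L)))
  use <- recs[recs[, 1L] > 1, , drop = FALSE]
  if (nrow(use) < 2L || var(use[, 1L]) == 0 || var(use[, 2L]) == 0) {
    return(NA_real_)
  }
  cor(use[, 1L], use[, 2L])
}

# Exhaustive modularity-maximizing bipartition (2^(n-1) subsets).
oracle_best_bipartition <- function(net) {
  nm <- sort(igraph::V(net)$name)
  n <- length(nm)
  best_q <- -Inf; best <- NULL; unique_best <- TRUE
  for (mask in 1:(2^(n - 1) - 1)) {
    s <- as.logical(bitwAnd(mask, 2^(0:(n - 1))))
    q <- partition_modularity(net, list(nm[s], nm[!s]))
    if (q > best_q + 1e-12) {
      best_q <- q; best <- s; unique_best <- TRUE
    } else if (abs(q - best_q) <= 1e-12) {
      unique_best <- FALSE
    }
  }
  list(q = best_q, parts = list(nm[best], nm[!best]), unique = unique_best)
}

# Random connected G(n, p) graph with letter names (for oracle sweeps).
random_connected_graph <- function(n, p, seed) {
  stopifnot(n <= 26)
  with_seed_test(seed, {
    repeat {
      g <- igraph::sample_gnp(n, p)
      if (igraph::is_connected(g)) break
    }
    igraph::V(g)$name <- letters[seq_len(n)]
    g
  })
}

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(expr)
}

# Two cliques of sizes a and b joined by a single bridge edge.
two_clique_bridge <- function(a, b) {
  nm_a <- sprintf("a%02d", seq_len(a))
  nm_b <- sprintf("b%02d", seq_len(b))
  ea <- t(utils::combn(nm_a, 2L))
  eb <- t(utils::combn(nm_b, 2L))
  make_network(rbind(ea, eb, c(nm_a[1L], nm_b[1L])))
}

# Canonical sorted edge matrix (min endpoint, max endpoint), for comparisons.
canonical_edges_for_test <- function(net) {
  el <- igraph::as_edgelist(net, names = TRUE)
  if (nrow(el) == 0L) return(matrix(character(), ncol = 2L))
  a <- pmin(el[, 1L], el[, 2L]); b <- pmax(el[, 1L], el[, 2L])
  unname(cbind(a, b)[order(a, b), , drop = FALSE])
}
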