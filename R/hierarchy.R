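#' One leading-eigenvector split
#'
#' Newman's spectral bipartition step: on a connected (sub)network, form the
#' modularity matrix \eqn{B_{ij} = A_{ij} - k_i k_j / (2m)} and split nodes
#' by the sign of the leading eigenvector's entries. The module is declared
#' indivisible when the leading eigenvalue is non-positive (within
#' tolerance), when all entries fall on one side, or when the split does not
#' increase modularity. A disconnected input is split into its connected
#' components instead (sign-splitting can never merge components, so the
#' component partition always comes first).
#'
#' Determinism: the eigenvector is oriented so that the first node in
#' lexicographic order with a non-negligible entry has a positive entry, and
#' zero entries are assigned to the non-negative side.
#'
#' @param subnet network with >= 2 nodes.
#' @param tol numerical tolerance on the leading eigenvalue / modularity
#'   gain (default 1e-12; eigensolve itself is a full symmetric
#'   decomposition).
#' @return list with `divisible` (logical) and, when divisible, `parts`
#'   (list of character node vectors) and `dq` (modularity gain; `NA` for a
#'   pure component split).
#' @export
lev_split <- function(subnet, tol = 1e-12) {
  validate_network(subnet)
  n <- igraph::vcount(subnet)
  if (n < 2L) return(list(divisible = FALSE))
  comp <- igraph::components(subnet)
  if (comp$no > 1L) {
    parts <- split(node_names(subnet), comp$membership)
    names(parts) <- NULL
    return(list(divisible = TRUE, parts = parts, dq = NA_real_))
  }
  m <- igraph::ecount(subnet)
  if (m == 0L) return(list(divisible = FALSE))
  A <- as.matrix(igraph::as_adjacency_matrix(subnet, sparse = FALSE))
  k <- igraph::degree(subnet)
  B <- A - outer(k, k) / (2 * m)
  es <- eigen(B, symmetric = TRUE)
  lead <- es$values[1L]
  if (lead <= tol) return(list(divisible = FALSE))
  v <- es$vectors[, 1L]
  nm <- node_names(subnet)
  ord <- order(nm)
  anchor <- ord[which(abs(v[ord]) > 1e-10)[1L]]
  if (!is.na(anchor) && v[anchor] < 0) v <- -v
  s <- ifelse(v >= -1e-10, 1, -1)
  if (all(s == 1) || all(s == -1)) return(list(divisible = FALSE))
  dq <- as.numeric(t(s) %*% B %*% s) / (4 * m)
  if (dq <= tol) return(list(divisible = FALSE))
  list(divisible = TRUE,
       parts = list(nm[s == 1], nm[s == -1]),
       dq = dq)
}

#' Recursive community decomposition
#'
#' Applies [lev_split()] breadth-first: communities are found in the whole
#' network, then inside each module, then inside each sub-module, down to
#' terminal modules. Each module's induced subgraph is treated as a
#' standalone network for its own split. A module becomes terminal when it
#' is indivisible, has fewer than 3 nodes, or sits at `max_levels`. Terminal
#' modules whose induced subgraph contains at least one triangle carry the
#' motif flag. The procedure is fully deterministic (fixed eigenvector
#' orientation, lexicographic tie-breaks).
#'
#' @param net network to decompose.
#' @param max_levels maximum depth (default 10).
#' @return an object of class `community_tree`: list with `modules` (named
#'   list of records: `id`, `level`, `nodes`, `n_edges`, `parent`,
#'   `children`, `terminal`, `terminal_reason` in
#'   `{"indivisible","too_small","max_level"}` or `NA`, `motif`) and
#'   `max_level` (deepest level present).
#' @export
decompose_network <- function(net, max_levels = 10L) {
  validate_network(net)
  modules <- list()
  queue <- list(list(id = "m", level = 0L, nodes = node_names(net),
                     parent = NA_character_))
  max_seen <- 0L
  while (length(queue) > 0L) {
    cur <- queue[[1L]]
    queue <- queue[-1L]
    sub <- igraph::induced_subgraph(net, cur$nodes)
    rec <- list(id = cur$id, level = cur$level, nodes = sort(cur$nodes),
                n_edges = igraph::ecount(sub), parent = cur$parent,
                children = character(), terminal = FALSE,
                terminal_reason = NA_character_, motif = FALSE)
    if (length(cur$nodes) < 3L) {
      rec$terminal <- TRUE
      rec$terminal_reason <- "too_small"
    } else if (cur$level >= max_levels) {
      rec$terminal <- TRUE
      rec$terminal_reason <- "max_level"
    } else {
      sp <- lev_split(sub)
      if (!sp$divisible) {
        rec$terminal <- TRUE
        rec$terminal_reason <- "indivisible"
      } else {
        # deterministic child order: by lexicographically smallest member
        parts <- sp$parts[order(vapply(sp$parts, min, character(1L)))]
        for (i in seq_along(parts)) {
          cid <- paste0(cur$id, ".", i)
          rec$children <- c(rec$children, cid)
          queue[[length(queue) + 1L]] <-
            list(id = cid, level = cur$level + 1L, nodes = parts[[i]],
                 parent = cur$id)
        }
      }
    }
    if (rec$terminal) {
      rec$motif <- length(igraph::triangles(sub)) > 0L
    }
    max_seen <- max(max_seen, rec$level)
    modules[[rec$id]] <- rec
  }
  structure(list(modules = modules, max_level = max_seen),
            class = "community_tree")
}

#' @export
print.community_tree <- function(x, ...) {
  term <- vapply(x$modules, `[[`, logical(1L), "terminal")
  motif <- vapply(x$modules, `[[`, logical(1L), "motif")
  cat(sprintf("Community tree: %d modules over levels 0..%d; %d terminal (%d with a triangle motif)\n",
              length(x$modules), x$max_level, sum(term), sum(motif)))
  invisible(x)
}

#' Partition induced by cutting the community tree at a level
#'
#' Each node belongs to its deepest ancestor module at depth <= `level`:
#' modules exactly at `level`, plus terminal modules shallower than it.
#'
#' @param tree a `community_tree`.
#' @param level cut level (0 = whole network).
#' @return named list of character node vectors (module id -> members).
#' @export
partition_at_level <- function(tree, level) {
  stopifnot(inherits(tree, "community_tree"))
  sel <- Filter(function(mod) {
    mod$level == level || (mod$terminal && mod$level < level)
  }, tree$modules)
  lapply(sel, `[[`, "nodes")
}

#' Newman–Girvan modularity of a partition
#'
#' \eqn{Q = \sum_c [e_c/m - (d_c/2m)^2]} where \eqn{e_c} is the number of
#' edges inside community c, \eqn{d_c} its total degree and m the network's
#' edge count.
#'
#' @param net the full network (m and degrees are taken from it).
#' @param partition list of character node vectors covering the node set
#'   disjointly.
#' @return the modularity Q.
#' @export
partition_modularity <- function(net, partition) {
  validate_network(net)
  check_partition(net, partition)
  m <- igraph::ecount(net)
  if (m == 0L) stop("modularity undefined for an edgeless network", call. = FALSE)
  q <- 0
  for (nodes in partition) {
    e_c <- igraph::ecount(igraph::induced_subgraph(net, nodes))
    d_c <- sum(igraph::degree(net, nodes))
    q <- q + e_c / m - (d_c / (2 * m))^2
  }
  q
}

check_partition <- function(net, partition) {
  all_nodes <- sort(unlist(partition, use.names = FALSE))
  if (anyDuplicated(all_nodes) || !identical(all_nodes, sort(node_names(net)))) {
    stop("`partition` must cover the node set disjointly", call. = FALSE)
  }
  invisible(TRUE)
}

#' Constant-Potts-Model Hamiltonian energy of a partition
#'
#' \eqn{H = -\sum_c [e_c - \gamma n_c^2]} with \eqn{e_c} and \eqn{n_c} the
#' intra-community edge and node counts (edges between communities do not
#' contribute) and resolution \eqn{\gamma} acting as an edge-density
#' threshold. At the default \eqn{\gamma = 0.5}, refining a partition can
#' never increase H (cutting a community of sizes \eqn{n_1, n_2} changes H
#' by cut \eqn{- n_1 n_2 \le 0}), so H decreases monotonically down the
#' hierarchy.
#'
#' @param net the network.
#' @param partition list of character node vectors covering the node set.
#' @param gamma resolution parameter, default 0.5.
#' @return the Hamiltonian energy H.
#' @export
hamiltonian_energy <- function(net, partition, gamma = 0.5) {
  validate_network(net)
  check_partition(net, partition)
  h <- 0
  for (nodes in partition) {
    e_c <- igraph::ecount(igraph::induced_subgraph(net, nodes))
    h <- h - (e_c - gamma * length(nodes)^2)
  }
  h
}

#' Per-level summaries of a community tree
#'
#' For every level of the decomposition, the module count, the modularity of
#' the level's partition with respect to the full network, and its
#' Hamiltonian energy.
#'
#' @param tree a `community_tree` from [decompose_network()].
#' @param net the network it decomposed.
#' @param gamma resolution for the Hamiltonian energy, default 0.5.
#' @return data frame with columns `level`, `n_modules`, `modularity`,
#'   `hamiltonian`.
#' @export
level_summaries <- function(tree, net, gamma = 0.5) {
  stopifnot(inherits(tree, "community_tree"))
  levels <- 0:tree$max_level
  rows <- lapply(levels, function(l) {
    part <- partition_at_level(tree, l)
    data.frame(level = l, n_modules = length(part),
               modularity = partition_modularity(net, part),
               hamiltonian = hamiltonian_energy(net, part, gamma))
  })
  do.call(rbind, rows)
}

# Chain of module ids from the root to the deepest module containing `node`.
module_path <- function(tree, node) {
  path <- "m"
  repeat {
    mod <- tree$modules[[path[length(path)]]]
    if (length(mod$children) == 0L) return(path)
    nxt <- NULL
    for (cid in mod$children) {
      if (node %in% tree$modules[[cid]]$nodes) { nxt <- cid; break }
    }
    path <- c(path, nxt)
  }
}

#' Trace seed genes through the community hierarchy
#'
#' Follows each seed gene from the whole network down to its terminal
#' module, recording at every level the module it sits in and its regulating
#' probability \eqn{P_x(y^{[l]}) = y^{[l]} / E^{[l]}}: the gene's edges
#' inside its level-l module divided by that module's total edge count
#' (module-local reading; at level 0 this is degree / E of the full
#' network). A module with zero edges yields \eqn{P_x = 0}, flagged in
#' `zero_edges`.
#'
#' @param tree a `community_tree`.
#' @param net the decomposed network.
#' @param seeds character vector of seed-gene identifiers; seeds absent from
#'   the network are skipped with a warning.
#' @return data frame with columns `gene`, `level`, `module`, `y_l` (edges
#'   incident to the gene in the module), `e_l` (module edge count), `p_x`,
#'   `terminal`, `motif`, `zero_edges`.
#' @export
trace_seed_genes <- function(tree, net, seeds) {
  stopifnot(inherits(tree, "community_tree"))
  validate_network(net)
  known <- intersect(seeds, node_names(net))
  missing <- setdiff(seeds, known)
  if (length(missing) > 0L) {
    warning(length(missing), " seed(s) absent from the network, skipped: ",
            paste(head(missing, 5L), collapse = ", "), call. = FALSE)
  }
  rows <- list()
  for (g in sort(known)) {
    for (mid in module_path(tree, g)) {
      mod <- tree$modules[[mid]]
      sub <- igraph::induced_subgraph(net, mod$nodes)
      y_l <- as.numeric(igraph::degree(sub, g))
      e_l <- igraph::ecount(sub)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, level = mod$level, module = mid, y_l = y_l, e_l = e_l,
        p_x = if (e_l > 0) y_l / e_l else 0,
        terminal = mod$terminal, motif = mod$motif, zero_edges = e_l == 0,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(gene = character(), level = integer(),
                      module = character(), y_l = numeric(), e_l = numeric(),
                      p_x = numeric(), terminal = logical(), motif = logical(),
                      zero_edges = logical(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Key regulators of the network
#'
#' A seed gene qualifies as a key regulator when its branch persists to the
#' deepest level reached by any seed-containing branch, ends there in an
#' indivisible terminal module, and that module contains a triangle motif in
#' which the gene itself participates. Seeds that reach the last level
#' without forming a motif are not key regulators.
#'
#' @inheritParams trace_seed_genes
#' @return sorted character vector of key-regulator gene identifiers
#'   (possibly empty).
#' @export
key_regulators <- function(tree, net, seeds) {
  stopifnot(inherits(tree, "community_tree"))
  validate_network(net)
  known <- intersect(seeds, node_names(net))
  if (length(known) == 0L) return(character())
  term <- lapply(known, function(g) {
    path <- module_path(tree, g)
    tree$modules[[path[length(path)]]]
  })
  depth <- vapply(term, `[[`, integer(1L), "level")
  max_depth <- max(depth)
  krs <- character()
  for (i in seq_along(known)) {
    mod <- term[[i]]
    if (depth[i] < max_depth) next
    if (!identical(mod$terminal_reason, "indivisible")) next
    if (!mod$motif) next
    if (in_triangle(igraph::induced_subgraph(net, mod$nodes), known[i])) {
      krs <- c(krs, known[i])
    }
  }
  sort(krs)
}

# TRUE when `node` participates in at least one triangle of `sub`.
in_triangle <- function(sub, node) {
  nb <- igraph::neighbors(sub, node)$name
  if (length(nb) < 2L) return(FALSE)
  igraph::ecount(igraph::induced_subgraph(sub, nb)) > 0L
}

#' Adjusted Rand index between a decomposition and reference labels
#'
#' Chance-corrected agreement between the terminal-module partition of a
#' community tree (or any partition) and a reference labelling such as the
#' planted leaf blocks of [gen_hierarchical_planted()].
#'
#' @param labels_a,labels_b named label vectors over the same node set, or a
#'   `community_tree` (its terminal-module partition is used).
#' @return the adjusted Rand index.
#' @export
adjusted_rand <- function(labels_a, labels_b) {
  to_labels <- function(x) {
    if (inherits(x, "community_tree")) {
      part <- partition_at_level(x, x$max_level)
      x <- stats::setNames(rep(names(part), lengths(part)),
                           unlist(part, use.names = FALSE))
    }
    x
  }
  a <- to_labels(labels_a)
  b <- to_labels(labels_b)
  if (!setequal(names(a), names(b))) {
    stop("label vectors must cover the same nodes", call. = FALSE)
  }
  b <- b[names(a)]
  igraph::compare(as.integer(factor(a)), as.integer(factor(b)),
                  method = "adjusted.rand")
}
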