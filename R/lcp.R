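#' Common neighbours and local community links of a node pair
#'
#' `CN` is the number of common first neighbours of `x` and `y` (excluding
#' `x` and `y` themselves); `LCL` counts the edges whose both endpoints are
#' common neighbours — the internal links of the pair's local community.
#' The bound \eqn{LCL \le CN(CN-1)/2} always holds.
#'
#' @param net a network.
#' @param x,y distinct node identifiers.
#' @return list with `cn` and `lcl` (integers).
#' @export
cn_lcl <- function(net, x, y) {
  validate_network(net)
  if (identical(x, y)) stop("`x` and `y` must differ", call. = FALSE)
  nb <- function(v) setdiff(igraph::neighbors(net, v)$name, c(x, y))
  common <- intersect(nb(x), nb(y))
  lcl <- if (length(common) >= 2L) {
    igraph::ecount(igraph::induced_subgraph(net, common))
  } else 0L
  list(cn = length(common), lcl = as.integer(lcl))
}

# CN/LCL for every edge of the network, vectorized via the sparse adjacency.
lcp_records <- function(net) {
  ce <- canonical_edges(net)
  if (nrow(ce) == 0L) {
    return(data.frame(node_a = character(), node_b = character(),
                      cn = integer(), lcl = integer(), stringsAsFactors = FALSE))
  }
  A <- igraph::as_adjacency_matrix(net, sparse = TRUE)
  nm <- rownames(A)
  neigh <- lapply(seq_len(nrow(A)), function(i) nm[A[i, ] > 0])
  names(neigh) <- nm
  cn <- integer(nrow(ce)); lcl <- integer(nrow(ce))
  for (i in seq_len(nrow(ce))) {
    a <- ce[i, 1L]; b <- ce[i, 2L]
    common <- setdiff(intersect(neigh[[a]], neigh[[b]]), c(a, b))
    cn[i] <- length(common)
    lcl[i] <- if (cn[i] >= 2L) sum(A[common, common]) / 2L else 0L
  }
  data.frame(node_a = ce[, 1L], node_b = ce[, 2L], cn = cn, lcl = lcl,
             stringsAsFactors = FALSE)
}

#' LCP correlation of a network
#'
#' Computes the (CN, LCL) record of every edge (each pair of interacting
#' nodes) and the local-community-paradigm correlation: the Pearson
#' correlation between CN and LCL over edges with CN > 1. A value near 1
#' indicates a strong LCP — links concentrated inside compact local
#' communities. The correlation is undefined (status `"undefined"`, value
#' `NA`) when fewer than 2 edges have CN > 1 or either variable has zero
#' variance (e.g. in a complete graph).
#'
#' @param net a network.
#' @return an object of class `lcp_summary`: list with `lcp_corr`,
#'   `n_pairs_used`, `status` (`"ok"`/`"undefined"`), and `records` (the
#'   per-edge data frame `node_a`, `node_b`, `cn`, `lcl`).
#' @export
lcp_corr <- function(net) {
  validate_network(net)
  rec <- lcp_records(net)
  use <- rec[rec$cn > 1L, , drop = FALSE]
  undef <- nrow(use) < 2L || var(use$cn) == 0 || var(use$lcl) == 0
  structure(
    list(lcp_corr = if (undef) NA_real_ else cor(use$cn, use$lcl),
         n_pairs_used = nrow(use),
         status = if (undef) "undefined" else "ok",
         records = rec),
    class = "lcp_summary"
  )
}

#' @export
print.lcp_summary <- function(x, ...) {
  cat("LCP summary:", nrow(x$records), "edges,", x$n_pairs_used,
      "with CN > 1; LCP-corr =",
      if (x$status == "ok") sprintf("%.4f", x$lcp_corr) else "undefined", "\n")
  invisible(x)
}

#' LCP decomposition-plot points
#'
#' One `(CN, sqrt(LCL))` point per edge with CN >= 1 — the scatter whose
#' linear trend characterizes local-community compactness.
#'
#' @param net a network.
#' @return data frame with columns `cn` and `sqrt_lcl`.
#' @export
lcp_dp <- function(net) {
  rec <- lcp_records(net)
  rec <- rec[rec$cn >= 1L, , drop = FALSE]
  data.frame(cn = rec$cn, sqrt_lcl = sqrt(rec$lcl), row.names = NULL)
}

#' Mean LCP correlation per hierarchy level
#'
#' For each level of a community tree, computes the LCP correlation of every
#' module's induced subgraph; modules whose correlation is undefined or
#' exactly zero are excluded, and the unweighted mean of the rest is
#' reported (`NA` when all modules are excluded).
#'
#' @param net the decomposed network.
#' @param tree its `community_tree`.
#' @return data frame with columns `level`, `mean_lcp_corr`,
#'   `n_modules_used`, `n_modules`.
#' @export
per_level_lcp <- function(net, tree) {
  stopifnot(inherits(tree, "community_tree"))
  rows <- lapply(0:tree$max_level, function(l) {
    part <- partition_at_level(tree, l)
    vals <- vapply(part, function(nodes) {
      lcp_corr(igraph::induced_subgraph(net, nodes))$lcp_corr
    }, 0)
    ok <- !is.na(vals) & vals != 0
    data.frame(level = l,
               mean_lcp_corr = if (any(ok)) mean(vals[ok]) else NA_real_,
               n_modules_used = sum(ok), n_modules = length(part))
  })
  do.call(rbind, rows)
}
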