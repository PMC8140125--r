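#' Node centralities
#'
#' Computes, per node: degree \eqn{k_i}; local clustering coefficient
#' \eqn{C(k_i) = 2 e_i / (k_i (k_i - 1))} with `C = 0` for degree < 2;
#' unnormalized betweenness \eqn{C_B(v) = \sum_{i<j} \sigma_{ij}(v)/\sigma_{ij}}
#' over unordered pairs with all shortest paths counted (Freeman/Brandes);
#' closeness \eqn{C_C(i) = n_i / \sum_j d_{ij}} where \eqn{n_i} is the number
#' of other nodes reachable from `i` (0 for isolated nodes); and eigenvector
#' centrality, the non-negative principal eigenvector of the adjacency
#' matrix computed on the largest connected component, scaled to unit
#' Euclidean norm, with nodes outside that component scored 0.
#'
#' @param net a network.
#' @return data frame with columns `node`, `degree`, `clustering`,
#'   `betweenness`, `closeness`, `eigenvector`, one row per node in the
#'   network's node order.
#' @export
compute_centralities <- function(net) {
  validate_network(net)
  n <- igraph::vcount(net)
  nm <- node_names(net)
  deg <- igraph::degree(net)
  if (n == 1L) {
    return(data.frame(node = nm, degree = 0, clustering = 0, betweenness = 0,
                      closeness = 0, eigenvector = 0, stringsAsFactors = FALSE))
  }
  cl <- igraph::transitivity(net, type = "local", isolates = "zero")
  btw <- igraph::betweenness(net, directed = FALSE, normalized = FALSE)

  d <- igraph::distances(net)
  diag(d) <- Inf
  reach <- rowSums(is.finite(d))
  sumd <- rowSums(ifelse(is.finite(d), d, 0))
  clo <- ifelse(reach > 0, reach / sumd, 0)

  comp <- igraph::components(net)
  big <- which.max(comp$csize)
  ev <- numeric(n)
  in_big <- comp$membership == big
  if (sum(in_big) > 1L && comp$csize[big] > 1L) {
    # dense symmetric eigensolve: deterministic, exact Perron vector
    sub <- igraph::induced_subgraph(net, which(in_big))
    A <- as.matrix(igraph::as_adjacency_matrix(sub, sparse = FALSE))
    v <- abs(eigen(A, symmetric = TRUE)$vectors[, 1L])
    ev[in_big][match(igraph::V(sub)$name, nm[in_big])] <- v / sqrt(sum(v^2))
  }
  data.frame(node = nm, degree = as.numeric(deg), clustering = cl,
             betweenness = btw, closeness = clo, eigenvector = ev,
             row.names = NULL, stringsAsFactors = FALSE)
}

degree_curve <- function(k, value, semantics) {
  structure(data.frame(k = k, value = value, row.names = NULL),
            class = c("degree_curve", "data.frame"), semantics = semantics)
}

#' Degree distribution P(k)
#'
#' \eqn{P(k) = n_k / N}: the fraction of nodes with each observed degree.
#'
#' @param net a network.
#' @return a `degree_curve` data frame (`k`, `value`) whose values sum to 1.
#' @export
degree_distribution <- function(net) {
  validate_network(net)
  tab <- table(igraph::degree(net))
  k <- as.integer(names(tab))
  ord <- order(k)
  degree_curve(k[ord], as.numeric(tab)[ord] / igraph::vcount(net), "P(k)")
}

#' Topology measures as functions of degree
#'
#' For each observed degree `k`, the mean over degree-`k` nodes of: local
#' clustering `C(k)`; neighbourhood connectivity `C_N(k)` (the mean degree of
#' a node's neighbours, averaged over degree-`k` nodes — the standard
#' estimator of the conditional neighbour-degree expectation); betweenness
#' `C_B(k)`; closeness `C_C(k)`; and eigenvector centrality `C_E(k)`. A
#' rising `C_N(k)` indicates assortative mixing.
#'
#' @param net a network with at least 2 nodes.
#' @return named list of `degree_curve` data frames: `"C(k)"`, `"C_N(k)"`,
#'   `"C_B(k)"`, `"C_C(k)"`, `"C_E(k)"` (degree-0 nodes are omitted from
#'   `C_N(k)`, whose value they do not define).
#' @export
topology_curves <- function(net) {
  validate_network(net)
  if (igraph::vcount(net) < 2L) stop("need at least 2 nodes", call. = FALSE)
  cent <- compute_centralities(net)
  knn <- suppressWarnings(igraph::knn(net)$knn) # NaN for isolated nodes
  by_k <- function(vals, keep = rep(TRUE, nrow(cent))) {
    k <- cent$degree[keep]
    v <- tapply(vals[keep], k, mean)
    kk <- as.integer(names(v))
    ord <- order(kk)
    degree_curve(kk[ord], as.numeric(v)[ord], NULL)
  }
  out <- list(
    "C(k)"   = by_k(cent$clustering),
    "C_N(k)" = by_k(knn, keep = cent$degree > 0 & !is.nan(knn)),
    "C_B(k)" = by_k(cent$betweenness),
    "C_C(k)" = by_k(cent$closeness),
    "C_E(k)" = by_k(cent$eigenvector)
  )
  for (nm in names(out)) attr(out[[nm]], "semantics") <- nm
  out
}

# Hurwitz zeta sum_{j=0}^inf (q + j)^(-a), a > 1, via direct summation plus
# an Euler-Maclaurin tail correction.
hurwitz_zeta <- function(a, q, nterms = 1000L) {
  j <- seq_len(nterms) - 1L
  s <- sum((q + j)^(-a))
  N <- q + nterms
  s + N^(1 - a) / (a - 1) + 0.5 * N^(-a) + a / 12 * N^(-a - 1)
}

# Discrete power-law log-likelihood for tail sample x >= xmin.
plaw_loglik <- function(alpha, x, xmin) {
  -length(x) * log(hurwitz_zeta(alpha, xmin)) - alpha * sum(log(x))
}

#' Fit a power law to degrees or a degree curve
#'
#' Two fitting routes are provided, mirroring how interaction-network
#' topology papers report exponents.
#'
#' `"mle-ks"` applies the Clauset–Shalizi–Newman procedure to a raw sample of
#' discrete degrees: for every candidate lower cut-off `x_min` the exponent
#' is estimated by maximizing the discrete power-law likelihood (Hurwitz-zeta
#' normalization), and the `x_min` minimizing the Kolmogorov–Smirnov distance
#' between the empirical and fitted tail CDFs is selected. An optional
#' semi-parametric bootstrap yields a goodness-of-fit p-value. The MLE route
#' is only valid for exponents > 1; shallower fits are flagged.
#'
#' `"loglog-ols"` fits a least-squares line through `(log k, log value)` over
#' the strictly positive points of any degree curve, reporting the signed
#' slope. This is the route that can produce the shallow sub-1 exponents
#' commonly printed for clustering/centrality-versus-degree curves, which lie
#' outside the MLE regime.
#'
#' @param x for `"mle-ks"`: an integer vector of degrees, or a network (its
#'   degree sequence is used); for `"loglog-ols"`: a `degree_curve` data
#'   frame with columns `k` and `value` (>= 3 strictly positive points).
#' @param method `"mle-ks"` or `"loglog-ols"`.
#' @param xmin fix the MLE lower cut-off instead of scanning (optional).
#' @param bootstrap number of bootstrap replicates for the MLE
#'   goodness-of-fit p-value; 0 (default) skips it.
#' @param seed seed for the bootstrap.
#' @return an object of class `power_law_fit`: list with `exponent` (signed
#'   for OLS, > 0 for MLE), `sign` (`"rising"`/`"falling"`), `method`, and
#'   per-method diagnostics (`x_min`, `ks_statistic`, `n_tail`, `valid`,
#'   `bootstrap_p` for MLE; `r_squared`, `n_points` for OLS).
#' @export
fit_power_law <- function(x, method = c("mle-ks", "loglog-ols"),
                          xmin = NULL, bootstrap = 0L, seed = 1L) {
  method <- match.arg(method)
  if (method == "loglog-ols") {
    if (!is.data.frame(x) || !all(c("k", "value") %in% names(x))) {
      stop("OLS fitting needs a degree curve with columns k and value",
           call. = FALSE)
    }
    pts <- x[x$k > 0 & x$value > 0, , drop = FALSE]
    if (nrow(pts) < 3L) stop("need >= 3 strictly positive points", call. = FALSE)
    fit <- lm(log(value) ~ log(k), data = pts)
    slope <- unname(coef(fit)[2L])
    out <- list(exponent = slope,
                sign = if (slope >= 0) "rising" else "falling",
                method = "loglog-ols",
                r_squared = suppressWarnings(summary(fit)$r.squared),
                n_points = nrow(pts))
  } else {
    if (igraph::is_igraph(x)) x <- igraph::degree(x)
    x <- as.integer(round(x))
    x <- x[x >= 1L]
    if (length(x) < 3L) stop("need >= 3 positive degrees", call. = FALSE)
    fit <- plaw_fit_mle(x, xmin)
    out <- c(fit, list(method = "mle-ks", sign = "falling"))
    if (bootstrap > 0L) {
      out$bootstrap_p <- plaw_bootstrap_p(x, fit, nrep = bootstrap, seed = seed)
    }
  }
  structure(out, class = "power_law_fit")
}

plaw_fit_mle <- function(x, xmin = NULL) {
  cand <- if (is.null(xmin)) sort(unique(x)) else as.integer(xmin)
  cand <- cand[cand >= 1L]
  # cap the scan so at least a handful of points remain in the tail
  cand <- cand[vapply(cand, function(xm) sum(x >= xm), 0L) >= 5L]
  if (length(cand) == 0L) cand <- min(x)
  best <- NULL
  for (xm in cand) {
    tail_x <- x[x >= xm]
    opt <- optimize(plaw_loglik, c(1 + 1e-6, 25), x = tail_x, xmin = xm,
                    maximum = TRUE, tol = 1e-8)
    alpha <- opt$maximum
    ks <- plaw_ks(tail_x, alpha, xm)
    if (is.null(best) || ks < best$ks_statistic) {
      best <- list(exponent = alpha, x_min = xm, ks_statistic = ks,
                   n_tail = length(tail_x))
    }
  }
  best$valid <- best$exponent > 1 + 1e-4
  best
}

# KS distance between empirical and fitted discrete power-law tail CDFs.
plaw_ks <- function(tail_x, alpha, xmin) {
  ks_vals <- sort(unique(tail_x))
  Z <- hurwitz_zeta(alpha, xmin)
  # theoretical CDF at k: 1 - zeta(alpha, k + 1)/zeta(alpha, xmin)
  th <- 1 - vapply(ks_vals + 1L, function(q) hurwitz_zeta(alpha, q), 0) / Z
  emp <- cumsum(tabulate(factor(tail_x, levels = ks_vals))) / length(tail_x)
  max(abs(emp - th))
}

plaw_sample <- function(n, alpha, xmin, kmax = 1e6) {
  ks <- seq(xmin, max(kmax, xmin * 100))
  w <- ks^(-alpha)
  cdf <- cumsum(w) / sum(w)
  ks[findInterval(runif(n), cdf) + 1L]
}

# Clauset-style semi-parametric bootstrap goodness-of-fit p-value.
plaw_bootstrap_p <- function(x, fit, nrep = 100L, seed = 1L) {
  n <- length(x)
  body_x <- x[x < fit$x_min]
  with_seed(seed, {
    exceed <- 0L
    for (r in seq_len(nrep)) {
      ntail <- stats::rbinom(1L, n, fit$n_tail / n)
      sim <- c(sample(body_x, n - ntail, replace = TRUE),
               plaw_sample(ntail, fit$exponent, fit$x_min))
      simfit <- plaw_fit_mle(sim)
      if (simfit$ks_statistic >= fit$ks_statistic) exceed <- exceed + 1L
    }
    exceed / nrep
  })
}

#' @export
print.power_law_fit <- function(x, ...) {
  if (x$method == "mle-ks") {
    cat(sprintf("Discrete power-law MLE fit: exponent %.4f (x_min = %d, KS = %.4f, n_tail = %d)%s\n",
                x$exponent, x$x_min, x$ks_statistic, x$n_tail,
                if (!x$valid) " [invalid regime: exponent <= 1]" else ""))
    if (!is.null(x$bootstrap_p)) cat(sprintf("  bootstrap GoF p = %.3f\n", x$bootstrap_p))
  } else {
    cat(sprintf("Log-log OLS fit: slope %.4f (%s, R^2 = %.3f, %d points)\n",
                x$exponent, x$sign, x$r_squared, x$n_points))
  }
  invisible(x)
}

# Summary statistics + OLS curve exponents for one network (one table row).
network_summary_row <- function(net, label) {
  cent <- compute_centralities(net)
  curves <- topology_curves(net)
  comp <- igraph::components(net)
  big <- igraph::induced_subgraph(net, which(comp$membership == which.max(comp$csize)))
  ols <- function(curve) {
    res <- try(fit_power_law(curve, method = "loglog-ols")$exponent, silent = TRUE)
    if (inherits(res, "try-error")) NA_real_ else res
  }
  data.frame(
    model = label,
    nodes = igraph::vcount(net),
    edges = igraph::ecount(net),
    mean_clustering = mean(cent$clustering),
    diameter = igraph::diameter(big, directed = FALSE),
    radius = igraph::radius(big),
    exp_clustering = ols(curves[["C(k)"]]),
    exp_degree_dist = ols(degree_distribution(net)),
    exp_neighborhood = ols(curves[["C_N(k)"]]),
    exp_betweenness = ols(curves[["C_B(k)"]]),
    exp_closeness = ols(curves[["C_C(k)"]]),
    exp_eigenvector = ols(curves[["C_E(k)"]]),
    stringsAsFactors = FALSE
  )
}

#' Null-model comparison table
#'
#' Compares an observed network against two size-matched null models — its
#' degree-preserving rewiring and an Erdős–Rényi G(n, M) graph — on node and
#' edge counts, mean clustering, diameter and radius (of the largest
#' connected component) and the log-log OLS exponents of the six topology
#' curves. Null rows are averaged over the supplied seeds.
#'
#' @param net observed network.
#' @param seeds integer seeds for the null replicates (default 1:5).
#' @return data frame with rows `observed`, `degree_preserved`, `gnm`.
#' @export
null_comparison <- function(net, seeds = 1:5) {
  validate_network(net)
  n <- igraph::vcount(net); m <- igraph::ecount(net)
  avg_rows <- function(gen, label) {
    rows <- lapply(seeds, function(s) network_summary_row(gen(s), label))
    out <- rows[[1L]]
    num <- vapply(out, is.numeric, logical(1L))
    out[num] <- lapply(names(out)[num], function(cn) {
      mean(vapply(rows, function(r) r[[cn]], 0), na.rm = TRUE)
    })
    out
  }
  rbind(
    network_summary_row(net, "observed"),
    avg_rows(function(s) suppressWarnings(
      rewire_preserving_degree(net, seed = s)), "degree_preserved"),
    avg_rows(function(s) gen_gnm(n, m, seed = s), "gnm")
  )
}

#' Essential candidate genes by centrality consensus
#'
#' Ranks all nodes by degree, betweenness, closeness and eigenvector
#' centrality, takes the top `top_n` of each ranking (ties broken
#' lexicographically by node identifier), intersects the four lists, and
#' keeps only nodes that interact with (are adjacent to) at least one seed
#' gene.
#'
#' @param net a network.
#' @param seed_genes character vector of seed-gene node identifiers.
#' @param top_n list length per category, default 100 (must not exceed the
#'   node count).
#' @return sorted character vector of candidate node identifiers.
#' @export
essential_candidates <- function(net, seed_genes, top_n = 100L) {
  validate_network(net)
  if (top_n > igraph::vcount(net)) stop("`top_n` exceeds node count", call. = FALSE)
  if (length(seed_genes) == 0L) return(character())
  cent <- compute_centralities(net)
  top <- function(v) cent$node[order(-v, cent$node)][seq_len(top_n)]
  common <- Reduce(intersect, list(top(cent$degree), top(cent$betweenness),
                                   top(cent$closeness), top(cent$eigenvector)))
  seeds_in <- intersect(seed_genes, cent$node)
  if (length(seeds_in) == 0L) return(character())
  partners <- unique(unlist(lapply(
    igraph::adjacent_vertices(net, seeds_in),
    function(vs) vs$name
  )))
  sort(intersect(common, partners))
}
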