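#' Construct a simple undirected network
#'
#' Networks throughout this package are simple undirected \pkg{igraph} graphs
#' with character node identifiers (gene symbols): no self-loops, no duplicate
#' edges, no weights. `make_network()` builds one from an edge table and an
#' optional set of isolated nodes, collapsing duplicate and reversed-duplicate
#' edges and dropping self-loops with a warning.
#'
#' @param edges two-column character matrix or data frame of endpoints; may
#'   have zero rows.
#' @param nodes optional character vector of node identifiers to include even
#'   when they touch no edge.
#' @return an undirected simple `igraph` graph with a `name` vertex attribute.
#' @examples
#' net <- make_network(cbind(c("a", "b"), c("b", "a")), nodes = "c")
#' igraph::vcount(net) # 3
#' igraph::ecount(net) # 1
#' @export
make_network <- function(edges = NULL, nodes = NULL) {
  if (is.null(edges)) {
    em <- matrix(character(), ncol = 2L)
  } else {
    em <- as.matrix(edges)
    if (length(em) == 0L) em <- matrix(character(), ncol = 2L)
    if (ncol(em) < 2L) stop("`edges` must have two columns", call. = FALSE)
    em <- em[, 1:2, drop = FALSE]
    storage.mode(em) <- "character"
  }
  loops <- em[, 1L] == em[, 2L]
  if (any(loops)) {
    warning(sum(loops), " self-loop(s) dropped", call. = FALSE)
    em <- em[!loops, , drop = FALSE]
  }
  all_nodes <- sort(unique(c(as.character(em), as.character(nodes))))
  if (length(all_nodes) == 0L) {
    stop("a network needs at least one node", call. = FALSE)
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = em[, 1L], to = em[, 2L], stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = all_nodes, stringsAsFactors = FALSE)
  )
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

# Validate that `net` is a usable network object; returns it invisibly.
validate_network <- function(net) {
  if (!igraph::is_igraph(net)) stop("not an igraph network", call. = FALSE)
  if (igraph::is_directed(net)) stop("network must be undirected", call. = FALSE)
  if (igraph::vcount(net) < 1L) stop("network has no nodes", call. = FALSE)
  if (is.null(igraph::V(net)$name)) {
    stop("network nodes must be named", call. = FALSE)
  }
  invisible(net)
}

node_names <- function(net) igraph::V(net)$name

# Canonical edge table: columns a <= b, rows sorted lexicographically.
canonical_edges <- function(net) {
  el <- igraph::as_edgelist(net, names = TRUE)
  if (nrow(el) == 0L) {
    return(matrix(character(), ncol = 2L, dimnames = list(NULL, c("a", "b"))))
  }
  a <- pmin(el[, 1L], el[, 2L])
  b <- pmax(el[, 1L], el[, 2L])
  ord <- order(a, b)
  cbind(a = a[ord], b = b[ord])
}

#' Read a network from an edge-list TSV or SIF file
#'
#' The edge-list dialect has two tab-separated columns (an optional third
#' column, e.g. a STRING confidence score, is parsed and ignored); a line with
#' a single column declares an isolated node; `#`-prefixed lines are comments.
#' The SIF dialect is `node relation node [node ...]` with the relation token
#' ignored and one edge fanned out per trailing node; a line with only a
#' source token declares an isolated node. In both dialects duplicate and
#' reversed-duplicate lines collapse to a single edge and self-loops are
#' dropped with a warning.
#'
#' @param path file to read.
#' @param format `"edgelist"`, `"sif"`, or `"auto"` (by file extension,
#'   default edge list).
#' @return a simple undirected network (see [make_network()]).
#' @seealso [write_network()]
#' @export
read_network <- function(path, format = c("auto", "edgelist", "sif")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.sif$", path, ignore.case = TRUE)) "sif" else "edgelist"
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) stop("empty network file: ", path, call. = FALSE)

  edges <- vector("list", length(idx))
  singles <- character()
  for (i in seq_along(idx)) {
    ln <- lines[idx[i]]
    if (format == "edgelist") {
      tok <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
      tok <- tok[nzchar(tok)]
      if (length(tok) == 1L) {
        singles <- c(singles, tok)
      } else if (length(tok) %in% c(2L, 3L)) {
        edges[[i]] <- matrix(tok[1:2], ncol = 2L)
      } else {
        stop("malformed edge-list line ", idx[i], " (", length(tok),
             " columns): ", ln, call. = FALSE)
      }
    } else {
      tok <- strsplit(trimws(ln), "[ \t]+")[[1L]]
      tok <- tok[nzchar(tok)]
      if (length(tok) == 1L) {
        singles <- c(singles, tok)
      } else if (length(tok) >= 3L) {
        tgt <- tok[-(1:2)] # token 2 is the relation type, ignored
        edges[[i]] <- cbind(rep(tok[1L], length(tgt)), tgt)
      } else {
        stop("malformed SIF line ", idx[i], ": ", ln, call. = FALSE)
      }
    }
  }
  em <- do.call(rbind, edges[!vapply(edges, is.null, logical(1L))])
  make_network(em, nodes = singles)
}

#' Write a network to an edge-list TSV or SIF file
#'
#' Output is deterministic: one line per edge, endpoints ordered so the
#' lexicographically smaller node comes first, lines sorted by (min endpoint,
#' max endpoint); isolated nodes are written as single-column (edge list) or
#' single-token (SIF) records so that `read_network(write_network(net))`
#' reproduces the node and edge sets exactly.
#'
#' @param net network to write.
#' @param path destination file.
#' @param format `"edgelist"` or `"sif"`.
#' @return the path, invisibly.
#' @export
write_network <- function(net, path, format = c("edgelist", "sif")) {
  validate_network(net)
  format <- match.arg(format)
  ce <- canonical_edges(net)
  isolated <- sort(setdiff(node_names(net), unique(as.character(ce))))
  lines <- if (format == "edgelist") {
    c(paste(ce[, 1L], ce[, 2L], sep = "\t"), isolated)
  } else {
    c(paste(ce[, 1L], "pp", ce[, 2L], sep = "\t"), isolated)
  }
  writeLines(lines, path)
  invisible(path)
}

# TRUE when two networks have identical node and edge sets.
same_network <- function(a, b) {
  identical(sort(node_names(a)), sort(node_names(b))) &&
    identical(canonical_edges(a), canonical_edges(b))
}
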