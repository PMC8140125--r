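#' Read per-species ortholog maps
#'
#' The TSV has columns `species`, `source_gene`, `target_gene`, one row per
#' ortholog pair; many-to-many mappings are allowed.
#'
#' @param path TSV file.
#' @return named list (by species) of ortholog maps: each a named list
#'   source gene -> character vector of target-species genes.
#' @export
read_ortholog_maps <- function(path) {
  df <- read_tsv_file(path)
  stopifnot(all(c("species", "source_gene", "target_gene") %in% names(df)))
  lapply(split(df, df$species), function(sp) {
    lapply(split(as.character(sp$target_gene), sp$source_gene), unique)
  })
}

orthologs_of <- function(map, gene) {
  tg <- map[[gene]]
  if (is.null(tg)) character() else tg
}

#' Check whether one interaction is conserved across species
#'
#' An edge (a, b) of the source network is conserved in a species when some
#' ortholog of a and some ortholog of b interact in that species' network
#' (one witnessing pair suffices); an interolog is an edge conserved in
#' every species. A gene lacking an ortholog in a species makes the edge
#' non-conserved there.
#'
#' @param edge character vector of two node identifiers.
#' @param maps named list (by species) of ortholog maps, as from
#'   [read_ortholog_maps()].
#' @param nets named list (by species) of that species' interaction network;
#'   every species in `maps` must be present.
#' @return an object of class `interolog_record`: list with `edge`,
#'   `species` (per species: `conserved` flag and the lexicographically
#'   first `witness` ortholog pair or `NULL`), and `conserved_in_all`.
#' @export
check_interolog <- function(edge, maps, nets) {
  stopifnot(length(edge) == 2L)
  if (!all(names(maps) %in% names(nets))) {
    stop("every species in `maps` needs a network in `nets`", call. = FALSE)
  }
  a <- edge[[1L]]; b <- edge[[2L]]
  species <- lapply(names(maps), function(sp) {
    net <- nets[[sp]]
    oa <- sort(intersect(orthologs_of(maps[[sp]], a), node_names(net)))
    ob <- sort(intersect(orthologs_of(maps[[sp]], b), node_names(net)))
    witness <- NULL
    for (x in oa) {
      nb <- igraph::neighbors(net, x)$name
      hit <- sort(intersect(ob, setdiff(nb, x)))
      if (length(hit) > 0L) { witness <- c(x, hit[1L]); break }
    }
    list(conserved = !is.null(witness), witness = witness)
  })
  names(species) <- names(maps)
  structure(
    list(edge = c(a, b), species = species,
         conserved_in_all = all(vapply(species, `[[`, logical(1L), "conserved"))),
    class = "interolog_record"
  )
}

#' @export
print.interolog_record <- function(x, ...) {
  cat("Interaction ", x$edge[1L], "-", x$edge[2L], ": conserved in ",
      sum(vapply(x$species, `[[`, logical(1L), "conserved")), "/",
      length(x$species), " species",
      if (x$conserved_in_all) " (interolog)" else "", "\n", sep = "")
  invisible(x)
}

#' Interologs: interactions conserved in every species
#'
#' @param edges two-column character matrix/data frame of candidate edges.
#' @param maps,nets as in [check_interolog()].
#' @return data frame of the conserved edges (`node_a`, `node_b`, endpoints
#'   in canonical order, sorted); zero rows when none is conserved.
#' @export
find_interologs <- function(edges, maps, nets) {
  edges <- as.matrix(edges)
  if (nrow(edges) == 0L) {
    return(data.frame(node_a = character(), node_b = character(),
                      stringsAsFactors = FALSE))
  }
  keep <- vapply(seq_len(nrow(edges)), function(i) {
    check_interolog(edges[i, 1:2], maps, nets)$conserved_in_all
  }, logical(1L))
  kept <- edges[keep, , drop = FALSE]
  out <- data.frame(node_a = pmin(kept[, 1L], kept[, 2L]),
                    node_b = pmax(kept[, 1L], kept[, 2L]),
                    stringsAsFactors = FALSE)
  out <- unique(out[order(out$node_a, out$node_b), , drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Conserved triangle motifs
#'
#' All triangles of the graph spanned by a set of conserved edges — the
#' 3-gene motifs that survive in every species.
#'
#' @param conserved_edges two-column matrix/data frame of edges (e.g. from
#'   [find_interologs()]).
#' @return list of sorted character triples (possibly empty).
#' @export
conserved_motifs <- function(conserved_edges) {
  conserved_edges <- as.matrix(conserved_edges)
  if (nrow(conserved_edges) < 3L) return(list())
  g <- make_network(conserved_edges)
  tri <- igraph::triangles(g)
  if (length(tri) == 0L) return(list())
  mat <- matrix(tri$name, ncol = 3L, byrow = TRUE)
  trips <- lapply(seq_len(nrow(mat)), function(i) sort(mat[i, ]))
  trips[order(vapply(trips, paste, character(1L), collapse = "|"))]
}
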