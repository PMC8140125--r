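# A 7-species interolog fixture with a planted conserved subgraph: three
# disjoint triangles plus a conserved path survive in every species; every
# other candidate edge is broken in at least one species.
planted_seven_species <- function() {
  tri <- rbind(c("t1", "t2"), c("t2", "t3"), c("t1", "t3"),
               c("u1", "u2"), c("u2", "u3"), c("u1", "u3"),
               c("v1", "v2"), c("v2", "v3"), c("v1", "v3"))
  path <- rbind(c("p1", "p2"), c("p2", "p3"))
  # exactly one broken edge per species, so each is absent somewhere
  broken <- rbind(c("x1", "x2"), c("x3", "x4"), c("x5", "x6"),
                  c("t1", "u1"), c("v1", "p1"), c("x2", "x3"),
                  c("x6", "x7"))
  all_edges <- rbind(tri, path, broken)
  src <- make_network(all_edges)
  species <- sprintf("sp%d", 1:7)
  maps <- list(); nets <- list()
  nodes <- igraph::V(src)$name
  for (i in seq_along(species)) {
    tgt <- stats::setNames(paste0(species[i], "_", nodes), nodes)
    drop_i <- (i - 1) %% nrow(broken) + 1 # a different broken edge per species
    sp_edges <- rbind(tri, path, broken[-drop_i, , drop = FALSE])
    nets[[species[i]]] <- make_network(cbind(tgt[sp_edges[, 1]],
                                             tgt[sp_edges[, 2]]),
                                       nodes = unname(tgt))
    maps[[species[i]]] <- lapply(stats::setNames(nodes, nodes),
                                 function(g) unname(tgt[g]))
  }
  list(src = src, candidate = all_edges, planted = rbind(tri, path),
       maps = maps, nets = nets)
}
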