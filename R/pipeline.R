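#' Write a complete synthetic input bundle
#'
#' Generates everything [run_pipeline()] consumes, with planted ground
#' truth: two paired expression series for an index disease and for a
#' comorbidity (sharing part of their differentially expressed genes), a
#' planted hierarchical network whose designated seed genes anchor the
#' decomposition stages, a gene-to-chromosome annotation, and per-species
#' ortholog maps/networks for the interolog stage. All files are plain TSV;
#' the ground truth is written as JSON.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed driving every stochastic choice.
#' @param n_genes genes per expression series (default 2000).
#' @param n_ctrl,n_case samples per group (default 10 each).
#' @param frac_de fraction of planted DEGs (default 0.1).
#' @param lfc_low,lfc_high planted |log2 fold change| range (default [1, 2]).
#' @param noise_sd expression noise SD on log2 scale (default 0.5).
#' @param levels,branching,leaf_size,p_by_level planted-network shape
#'   (defaults: 2 levels, branching 2, leaf size 16, p = 0.9/0.15/0.01).
#' @param n_species species count for the interolog fixture (default 3).
#' @return named list of the written file paths, invisibly.
#' @export
simulate_bundle <- function(dir, seed,
                            n_genes = 2000L, n_ctrl = 10L, n_case = 10L,
                            frac_de = 0.1, lfc_low = 1, lfc_high = 2,
                            noise_sd = 0.5,
                            levels = 2L, branching = 2L, leaf_size = 16L,
                            p_by_level = c(0.9, 0.15, 0.01),
                            n_species = 3L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, paste0(...))
  files <- list()

  disease <- gen_expression_pair(n_genes, n_ctrl, n_case, frac_de,
                                 lfc_low, lfc_high, noise_sd, seed = seed)
  comorb <- gen_expression_pair(n_genes, n_ctrl, n_case, frac_de,
                                lfc_low, lfc_high, noise_sd, seed = seed + 1L)
  sets <- list(disease = disease, comorbidity = comorb)
  for (nm in names(sets)) {
    for (i in 1:2) {
      ds <- sets[[nm]]$series[[i]]
      ds$label <- sprintf("%s_series%d", nm, i)
      files[[sprintf("%s_expr%d", nm, i)]] <- p(nm, "_expr", i, ".tsv")
      files[[sprintf("%s_group%d", nm, i)]] <- p(nm, "_group", i, ".tsv")
      write_expression(ds, files[[sprintf("%s_expr%d", nm, i)]],
                       files[[sprintf("%s_group%d", nm, i)]])
    }
  }

  planted <- gen_hierarchical_planted(levels, branching, leaf_size,
                                      p_by_level, seed = seed + 2L)
  # relabel network nodes with gene identifiers so that consensus DEGs occur
  # in the network: planted seed nodes take planted-DE gene names, the rest
  # take non-DE names
  old_names <- node_names(planted$network)
  relabel <- with_seed(seed + 4L, {
    de <- disease$truth$de_genes
    n_seed <- length(planted$seed_genes)
    seed_names <- sample(de, min(n_seed, length(de)))
    rest <- sample(setdiff(sprintf("g%05d", seq_len(n_genes)), de),
                   length(old_names) - length(seed_names))
    map <- stats::setNames(character(length(old_names)), old_names)
    map[planted$seed_genes] <- seed_names
    map[setdiff(old_names, planted$seed_genes)] <- rest
    map
  })
  igraph::V(planted$network)$name <- unname(relabel[old_names])
  planted$community_labels <- stats::setNames(planted$community_labels,
                                              relabel[names(planted$community_labels)])
  planted$level_labels <- lapply(planted$level_labels, function(ll) {
    stats::setNames(ll, relabel[names(ll)])
  })
  planted$seed_genes <- sort(unname(relabel[planted$seed_genes]))
  files$network <- p("network.tsv")
  write_network(planted$network, files$network)

  genes <- sprintf("g%05d", seq_len(n_genes))
  chrom <- with_seed(seed + 3L, {
    sample(c(as.character(1:22), "X"), n_genes, replace = TRUE,
           prob = c(22:1, 8) / sum(c(22:1, 8)))
  })
  files$annotation <- p("annotation.tsv")
  write_tsv_file(data.frame(gene = genes, chromosome = paste0("chr", chrom)),
                 files$annotation)

  # interolog fixture: each species' network is an ortholog-relabelled copy
  # of the planted network with a seeded fraction of edges knocked out
  species <- sprintf("species%02d", seq_len(n_species))
  net_nodes <- node_names(planted$network)
  maps_df <- list(); net_paths <- character()
  for (si in seq_along(species)) {
    sp <- species[si]
    tgt <- stats::setNames(paste0(sp, "_", net_nodes), net_nodes)
    ce <- canonical_edges(planted$network)
    keep <- with_seed(seed + 10L + si, runif(nrow(ce)) < 0.9)
    spnet <- make_network(cbind(tgt[ce[keep, 1L]], tgt[ce[keep, 2L]]),
                          nodes = tgt)
    net_paths[sp] <- p("net_", sp, ".tsv")
    write_network(spnet, net_paths[sp])
    maps_df[[sp]] <- data.frame(species = sp, source_gene = net_nodes,
                                target_gene = unname(tgt))
  }
  files$ortholog_maps <- p("orthologs.tsv")
  write_tsv_file(do.call(rbind, maps_df), files$ortholog_maps)
  files$species_networks <- net_paths

  files$truth <- p("truth.json")
  jsonlite::write_json(
    list(seed = seed,
         de_genes_disease = disease$truth$de_genes,
         de_genes_comorbidity = comorb$truth$de_genes,
         lfc_disease = as.list(disease$truth$lfc[disease$truth$de_genes]),
         community_labels = as.list(planted$community_labels),
         seed_genes = planted$seed_genes),
    files$truth, auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(files)
}

#' Pipeline configuration
#'
#' Bundles the thresholds and file paths consumed by [run_pipeline()].
#' Defaults follow the conventional screening parameters: primary DEG
#' cut-off p < 0.05 and |logFC| >= 0.5, opposite-direction screen at
#' |logFC| >= 1, Constant-Potts resolution 0.5, top-100 centrality lists.
#'
#' @param disease_expr,disease_group length-2 character vectors: the index
#'   disease's two expression TSVs and group TSVs.
#' @param comorbidity_expr,comorbidity_group optional, same shape, for one
#'   comorbidity.
#' @param network_path edge-list TSV of the interaction network.
#' @param annotation_path optional gene-to-chromosome TSV.
#' @param ortholog_path,species_network_paths optional interolog inputs:
#'   ortholog-map TSV and a named character vector of per-species edge-list
#'   TSVs.
#' @param p_max,lfc_min primary DEG thresholds (0.05, 0.5).
#' @param opposite_lfc_min |logFC| threshold of the opposite-direction
#'   screen (1.0).
#' @param gamma Constant-Potts resolution (0.5).
#' @param max_levels decomposition depth cap (10).
#' @param top_n centrality list length (100, capped at the node count).
#' @param null_seeds seeds for the null-model replicates.
#' @param out_dir where [run_pipeline()] writes its artifacts.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(disease_expr, disease_group, network_path,
                            comorbidity_expr = NULL, comorbidity_group = NULL,
                            annotation_path = NULL,
                            ortholog_path = NULL, species_network_paths = NULL,
                            p_max = 0.05, lfc_min = 0.5,
                            opposite_lfc_min = 1.0, gamma = 0.5,
                            max_levels = 10L, top_n = 100L,
                            null_seeds = 1:3, out_dir = tempfile("keyregnet_")) {
  stopifnot(length(disease_expr) == 2L, length(disease_group) == 2L,
            p_max > 0, lfc_min > 0, opposite_lfc_min > 0, gamma > 0,
            max_levels >= 1L, top_n >= 1L)
  all_paths <- c(disease_expr, disease_group, network_path, comorbidity_expr,
                 comorbidity_group, annotation_path, ortholog_path,
                 species_network_paths)
  missing <- all_paths[!file.exists(all_paths)]
  if (length(missing) > 0L) {
    stop("input file not found: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(disease_expr = disease_expr, disease_group = disease_group,
         network_path = network_path, comorbidity_expr = comorbidity_expr,
         comorbidity_group = comorbidity_group,
         annotation_path = annotation_path, ortholog_path = ortholog_path,
         species_network_paths = species_network_paths,
         p_max = p_max, lfc_min = lfc_min, opposite_lfc_min = opposite_lfc_min,
         gamma = gamma, max_levels = max_levels, top_n = top_n,
         null_seeds = null_seeds, out_dir = out_dir),
    class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Chains the stages: per-series differential expression and filtering →
#' two-series consensus (per disease) → signature-gene overlap and
#' chromosome contribution → opposite-direction screen across the two index
#' series → network topology, power-law fits and null-model comparison →
#' recursive community decomposition with level summaries, seed-gene traces
#' and key regulators → per-level LCP profile → (when ortholog inputs are
#' configured) interolog mapping and conserved motifs. Seed genes are the
#' consensus DEGs present in the network; when none is, the network's
#' designated seed list (if any) is used and otherwise the regulator stages
#' emit empty results without failing.
#'
#' Every stage writes plain TSV/JSON under `config$out_dir` and a
#' `manifest.json` records each artifact together with the configuration;
#' re-running the same configuration reproduces identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return the manifest, invisibly (list with `config`, `outputs`,
#'   `summary`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$out_dir, paste0(...))
  outputs <- list()
  summary <- list()

  screen_pair <- function(expr, group, tag) {
    tabs <- lapply(1:2, function(i) {
      differential_expression(
        read_expression(expr[i], group[i], label = sprintf("%s_%d", tag, i)))
    })
    filt <- lapply(tabs, filter_degs, p_max = config$p_max,
                   lfc_min = config$lfc_min)
    cons <- consensus_degs(filt[[1L]], filt[[2L]])
    for (i in 1:2) {
      outputs[[sprintf("deg_%s_%d", tag, i)]] <<- out("deg_", tag, "_", i, ".tsv")
      write_tsv_file(as.data.frame(filt[[i]]), outputs[[sprintf("deg_%s_%d", tag, i)]])
    }
    outputs[[paste0("consensus_", tag)]] <<- out("consensus_", tag, ".tsv")
    write_tsv_file(cons, outputs[[paste0("consensus_", tag)]])
    list(tables = tabs, consensus = cons)
  }

  dis <- screen_pair(config$disease_expr, config$disease_group, "disease")
  summary$n_consensus_disease <- nrow(dis$consensus)

  if (!is.null(config$comorbidity_expr)) {
    com <- screen_pair(config$comorbidity_expr, config$comorbidity_group,
                       "comorbidity")
    sig <- overlap_signature(dis$consensus, com$consensus)
    outputs$signature <- out("signature_genes.tsv")
    write_tsv_file(sig, outputs$signature)
    summary$n_signature <- nrow(sig)
  }

  if (!is.null(config$annotation_path) && nrow(dis$consensus) > 0L) {
    ann <- read_tsv_file(config$annotation_path)
    pct <- suppressWarnings(chromosome_contribution(dis$consensus$gene, ann))
    outputs$chromosome <- out("chromosome_contribution.tsv")
    write_tsv_file(data.frame(chromosome = names(pct), percent = as.numeric(pct)),
                   outputs$chromosome)
  }

  opp <- opposite_direction_genes(dis$tables[[1L]], dis$tables[[2L]],
                                  p_max = config$p_max,
                                  lfc_min = config$opposite_lfc_min)
  outputs$opposite <- out("opposite_direction.tsv")
  write_tsv_file(
    data.frame(gene = c(opp$up_in_a_down_in_b, opp$down_in_a_up_in_b),
               orientation = rep(c("up_in_a_down_in_b", "down_in_a_up_in_b"),
                                 c(length(opp$up_in_a_down_in_b),
                                   length(opp$down_in_a_up_in_b)))),
    outputs$opposite)

  net <- read_network(config$network_path)
  cent <- compute_centralities(net)
  outputs$centralities <- out("centralities.tsv")
  write_tsv_file(cent, outputs$centralities)

  curves <- topology_curves(net)
  pk <- degree_distribution(net)
  fits <- list(
    degree_mle = tryCatch(
      unclass(fit_power_law(net, method = "mle-ks")),
      error = function(e) list(error = conditionMessage(e)))
  )
  for (nm in names(curves)) {
    fits[[nm]] <- tryCatch(unclass(fit_power_law(curves[[nm]], "loglog-ols")),
                           error = function(e) list(error = conditionMessage(e)))
  }
  fits[["P(k)_ols"]] <- tryCatch(unclass(fit_power_law(pk, "loglog-ols")),
                                 error = function(e) list(error = conditionMessage(e)))
  outputs$power_law_fits <- out("power_law_fits.json")
  jsonlite::write_json(fits, outputs$power_law_fits, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  nullcmp <- suppressWarnings(null_comparison(net, seeds = config$null_seeds))
  outputs$null_comparison <- out("null_comparison.tsv")
  write_tsv_file(nullcmp, outputs$null_comparison)
  summary$mean_clustering_observed <- nullcmp$mean_clustering[1L]

  seeds_in_net <- intersect(dis$consensus$gene, node_names(net))
  if (length(seeds_in_net) == 0L) {
    truth_seeds <- igraph::V(net)$is_seed
    seeds_in_net <- if (!is.null(truth_seeds)) {
      node_names(net)[as.logical(truth_seeds)]
    } else character()
  }
  summary$n_seed_genes <- length(seeds_in_net)

  ess <- essential_candidates(net, seeds_in_net,
                              top_n = min(config$top_n, igraph::vcount(net)))
  outputs$essential <- out("essential_candidates.tsv")
  write_tsv_file(data.frame(gene = ess), outputs$essential)

  tree <- decompose_network(net, max_levels = config$max_levels)
  lev <- level_summaries(tree, net, gamma = config$gamma)
  outputs$levels <- out("level_summaries.tsv")
  lcp_prof <- per_level_lcp(net, tree)
  lev$mean_lcp_corr <- lcp_prof$mean_lcp_corr[match(lev$level, lcp_prof$level)]
  write_tsv_file(lev, outputs$levels)
  summary$n_levels <- tree$max_level

  tree_json <- lapply(tree$modules, function(m) {
    m[c("id", "level", "parent", "children", "terminal", "terminal_reason",
        "motif", "n_edges", "nodes")]
  })
  outputs$tree <- out("community_tree.json")
  jsonlite::write_json(tree_json, outputs$tree, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")

  trace <- suppressWarnings(trace_seed_genes(tree, net, seeds_in_net))
  outputs$trace <- out("seed_trace.tsv")
  write_tsv_file(trace, outputs$trace)
  krs <- suppressWarnings(key_regulators(tree, net, seeds_in_net))
  outputs$key_regulators <- out("key_regulators.tsv")
  write_tsv_file(data.frame(gene = krs), outputs$key_regulators)
  summary$n_key_regulators <- length(krs)

  lcp_sum <- lcp_corr(net)
  outputs$lcp_records <- out("lcp_records.tsv")
  write_tsv_file(lcp_sum$records, outputs$lcp_records)
  outputs$lcp_summary <- out("lcp_summary.json")
  jsonlite::write_json(
    list(lcp_corr = lcp_sum$lcp_corr, n_pairs_used = lcp_sum$n_pairs_used,
         status = lcp_sum$status),
    outputs$lcp_summary, auto_unbox = TRUE, digits = NA, pretty = TRUE)

  if (!is.null(config$ortholog_path)) {
    maps <- read_ortholog_maps(config$ortholog_path)
    nets <- lapply(config$species_network_paths, read_network)
    names(nets) <- names(config$species_network_paths)
    cand <- canonical_edges(net)
    il <- find_interologs(cand, maps, nets)
    outputs$interologs <- out("interologs.tsv")
    write_tsv_file(il, outputs$interologs)
    motifs <- conserved_motifs(il)
    outputs$conserved_motifs <- out("conserved_motifs.tsv")
    write_tsv_file(
      data.frame(gene_a = vapply(motifs, `[`, character(1L), 1L),
                 gene_b = vapply(motifs, `[`, character(1L), 2L),
                 gene_c = vapply(motifs, `[`, character(1L), 3L)),
      outputs$conserved_motifs)
    summary$n_interologs <- nrow(il)
    summary$n_conserved_motifs <- length(motifs)
  }

  cfg <- unclass(config)
  cfg <- cfg[!vapply(cfg, is.null, logical(1L))]
  manifest <- list(config = cfg, outputs = outputs, summary = summary)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
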