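make_ds <- function(ctrl, case, genes = paste0("g", seq_len(nrow(ctrl)))) {
  mat <- cbind(ctrl, case)
  rownames(mat) <- genes
  colnames(mat) <- c(paste0("c", seq_len(ncol(ctrl))),
                     paste0("d", seq_len(ncol(case))))
  expression_dataset(mat, rep(c("control", "disease"),
                              c(ncol(ctrl), ncol(case))))
}

test_that("differential expression matches the Welch t-test oracle", {
  ds <- make_ds(matrix(c(1, 2, 3), 1), matrix(c(3, 4, 5), 1))
  tab <- differential_expression(ds)
  expect_equal(tab$logFC, 2)
  oracle <- stats::t.test(c(3, 4, 5), c(1, 2, 3), var.equal = FALSE)
  expect_equal(tab$p_value, oracle$p.value)

  # parameterized sweep against stats::t.test per gene
  set.seed(20)
  ctrl <- matrix(rnorm(50 * 4, mean = 7), 50)
  case <- matrix(rnorm(50 * 6, mean = 7.3, sd = 1.4), 50)
  tab <- differential_expression(make_ds(ctrl, case))
  for (i in c(1, 10, 25, 50)) {
    o <- stats::t.test(case[i, ], ctrl[i, ], var.equal = FALSE)
    expect_equal(tab$p_value[i], o$p.value, tolerance = 1e-12)
    expect_equal(tab$logFC[i], unname(o$estimate[1] - o$estimate[2]),
                 tolerance = 1e-12)
  }
})

test_that("degenerate zero-variance genes are flagged, not mis-scored", {
  ds <- make_ds(matrix(c(5, 5, 5, 2, 2, 2), 2, byrow = TRUE),
                matrix(c(5, 5, 5, 4, 4, 4), 2, byrow = TRUE),
                genes = c("same", "shifted"))
  tab <- differential_expression(ds)
  expect_equal(tab$p_value[tab$gene == "same"], 1)
  expect_equal(tab$logFC[tab$gene == "same"], 0)
  expect_equal(tab$p_value[tab$gene == "shifted"], .Machine$double.xmin)
  expect_true(tab$degenerate[tab$gene == "shifted"])
  expect_true(all(tab$p_value > 0 & tab$p_value <= 1))
})

test_that("filter boundary: strict on p, inclusive on |logFC|", {
  tab <- structure(
    data.frame(gene = c("a", "b", "c", "d"),
               logFC = c(0.5, 3, -0.5, 0.49),
               p_value = c(0.049, 0.05, 0.01, 0.001),
               direction = "flat", degenerate = FALSE,
               stringsAsFactors = FALSE),
    class = c("deg_table", "data.frame"),
    provenance = "x", p_max = NA_real_, lfc_min = NA_real_)
  f <- filter_degs(tab)
  expect_setequal(f$gene, c("a", "c")) # b fails strict p, d fails |logFC|
  expect_equal(f$direction[f$gene == "a"], "up")
  expect_equal(f$direction[f$gene == "c"], "down")
  expect_equal(attr(f, "p_max"), 0.05)
})

test_that("filtering is idempotent, monotone, and refuses loosening", {
  pair <- gen_expression_pair(300, 4, 4, 0.2, 1, 2, 0.5, seed = 31)
  tab <- differential_expression(pair$series[[1]])
  f1 <- filter_degs(tab, 0.05, 0.5)
  expect_identical(as.data.frame(filter_degs(f1, 0.05, 0.5)),
                   as.data.frame(f1))
  f2 <- filter_degs(tab, 0.01, 1.0)
  expect_true(all(f2$gene %in% f1$gene))
  expect_error(filter_degs(f2, 0.05, 0.5), "strictly")
})

test_that("consensus keeps genes passing both series with the same direction", {
  mk <- function(genes, lfc, p) {
    filter_degs(structure(
      data.frame(gene = genes, logFC = lfc, p_value = p, direction = "flat",
                 degenerate = FALSE, stringsAsFactors = FALSE),
      class = c("deg_table", "data.frame"),
      provenance = "x", p_max = NA_real_, lfc_min = NA_real_))
  }
  tA <- mk(c("up_both", "flip", "only_a"), c(1, 1, 1), c(0.01, 0.01, 0.01))
  tB <- mk(c("up_both", "flip"), c(2, -1), c(0.01, 0.01))
  cons <- consensus_degs(tA, tB)
  expect_identical(cons$gene, "up_both")
  expect_identical(cons$direction, "up")

  # self-consensus identity
  self <- consensus_degs(tA, tA)
  expect_setequal(self$gene, tA$gene)

  tC <- mk("up_both", 1, 0.001)
  attr(tC, "p_max") <- 0.01
  expect_error(consensus_degs(tA, tC), "different thresholds")
})

test_that("consensus recovers a planted DE set with high recall and precision", {
  pair <- gen_expression_pair(2000, 10, 10, 0.1, 1, 2, 0.5, seed = 17)
  cons <- consensus_degs(
    filter_degs(differential_expression(pair$series[[1]])),
    filter_degs(differential_expression(pair$series[[2]]))
  )
  tp <- length(intersect(cons$gene, pair$truth$de_genes))
  expect_gte(tp / length(pair$truth$de_genes), 0.9)
  expect_gte(tp / nrow(cons), 0.9)
  # recovered directions match the planted fold-change signs
  dir_truth <- ifelse(pair$truth$lfc[cons$gene] > 0, "up", "down")
  hits <- cons$gene %in% pair$truth$de_genes
  expect_identical(cons$direction[hits], unname(dir_truth[hits]))
})

test_that("signature overlap intersects disease sets and keeps both directions", {
  a <- data.frame(gene = c("g1", "g2", "g3"), direction = c("up", "down", "up"))
  b <- data.frame(gene = c("g2", "g3", "g4"), direction = c("down", "down", "up"))
  sig <- overlap_signature(a, b)
  expect_identical(sig$gene, c("g2", "g3"))
  expect_identical(sig$direction_disease, c("down", "up"))
  expect_identical(sig$direction_comorbidity, c("down", "down"))
  expect_equal(nrow(overlap_signature(a, data.frame(gene = "zz", direction = "up"))), 0)
})

test_that("two simulated diseases sharing planted genes overlap exactly there", {
  # same seed for the shared block, disjoint gene universes otherwise
  shared <- sprintf("s%02d", 1:5)
  mk_cons <- function(extra, seed) {
    pair <- gen_expression_pair(300, 8, 8, 0.1, 1.5, 2, 0.3, seed = seed)
    cons <- consensus_degs(
      filter_degs(differential_expression(pair$series[[1]])),
      filter_degs(differential_expression(pair$series[[2]])))
    cons$gene <- paste0(extra, cons$gene) # disjoint namespaces
    rbind(cons, data.frame(gene = shared, direction = "up"))
  }
  sig <- overlap_signature(mk_cons("A_", 1), mk_cons("B_", 2))
  expect_setequal(sig$gene, shared)
})

test_that("chromosome contribution percentages are correct and sum to 100", {
  ann <- c(g1 = "chr1", g2 = "chr1", g3 = "chr1", g4 = "chr1", g5 = "chrX")
  pct <- chromosome_contribution(names(ann), ann)
  expect_equal(pct[["chr1"]], 80)
  expect_equal(pct[["chrX"]], 20)

  expect_equal(as.numeric(chromosome_contribution("g1", ann)), 100)

  set.seed(5)
  genes <- paste0("r", 1:200)
  ann2 <- stats::setNames(sample(paste0("chr", 1:22), 200, TRUE), genes)
  expect_equal(sum(chromosome_contribution(genes, ann2)), 100, tolerance = 1e-9)

  expect_warning(p3 <- chromosome_contribution(c("g1", "nope"), ann), "unmapped")
  expect_equal(attr(p3, "unmapped"), 1)
  expect_error(chromosome_contribution(character(), ann), "empty")
})

test_that("opposite-direction screen partitions sign-flipping genes", {
  mkraw <- function(genes, lfc, p) {
    structure(
      data.frame(gene = genes, logFC = lfc, p_value = p, direction = "flat",
                 degenerate = FALSE, stringsAsFactors = FALSE),
      class = c("deg_table", "data.frame"),
      provenance = "x", p_max = NA_real_, lfc_min = NA_real_)
  }
  tA <- mkraw(c("flip1", "flip2", "same", "weak"), c(1.2, -1.5, 2, 1.2),
              c(0.01, 0.02, 0.01, 0.5))
  tB <- mkraw(c("flip1", "flip2", "same", "weak"), c(-1.5, 1.1, 2, -1.2),
              c(0.02, 0.01, 0.01, 0.01))
  opp <- opposite_direction_genes(tA, tB)
  expect_identical(opp$up_in_a_down_in_b, "flip1")
  expect_identical(opp$down_in_a_up_in_b, "flip2") # 'weak' fails p in A
})

test_that("a planted 24/48 sign-flip design is recovered exactly", {
  n_genes <- 1000
  genes <- sprintf("g%04d", seq_len(n_genes))
  set.seed(77)
  up_a <- genes[1:24]    # up in A, down in B
  down_a <- genes[25:72] # down in A, up in B
  lfc_mag <- function(n) runif(n, 1.5, 2)
  base <- runif(n_genes, 4, 12)
  build <- function(sign_map) {
    mu <- base + sign_map
    mat <- cbind(matrix(rep(base, 10), n_genes) + rnorm(n_genes * 10, sd = 0.3),
                 matrix(rep(mu, 10), n_genes) + rnorm(n_genes * 10, sd = 0.3))
    rownames(mat) <- genes
    colnames(mat) <- paste0("s", 1:20)
    expression_dataset(mat, rep(c("control", "disease"), each = 10))
  }
  shift_a <- shift_b <- numeric(n_genes)
  names(shift_a) <- names(shift_b) <- genes
  shift_a[up_a] <- lfc_mag(24);  shift_b[up_a] <- -lfc_mag(24)
  shift_a[down_a] <- -lfc_mag(48); shift_b[down_a] <- lfc_mag(48)
  opp <- opposite_direction_genes(differential_expression(build(shift_a)),
                                  differential_expression(build(shift_b)))
  expect_setequal(opp$up_in_a_down_in_b, up_a)
  expect_setequal(opp$down_in_a_up_in_b, down_a)
})

test_that("expression TSV round-trips through read/write", {
  pair <- gen_expression_pair(50, 3, 3, 0.1, 1, 2, 0.5, seed = 21)
  ds <- pair$series[[1]]
  e <- withr::local_tempfile(); g <- withr::local_tempfile()
  write_expression(ds, e, g)
  back <- read_expression(e, g)
  expect_equal(back$matrix, ds$matrix, tolerance = 1e-12)
  expect_identical(back$group, ds$group)
})
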