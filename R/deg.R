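#' Expression dataset
#'
#' A log2 expression matrix (genes in rows, samples in columns) together with
#' a control/disease group assignment.
#'
#' @param matrix numeric matrix of log2 intensities with gene row names.
#' @param group character vector, one of `"control"`/`"disease"` per sample,
#'   named by (or aligned with) the matrix columns.
#' @param label optional provenance label carried into downstream tables.
#' @return an object of class `expression_dataset`.
#' @export
expression_dataset <- function(matrix, group, label = "dataset") {
  matrix <- as.matrix(matrix)
  if (is.null(rownames(matrix)) || anyNA(rownames(matrix)) ||
      any(!nzchar(rownames(matrix)))) {
    stop("matrix must have complete gene row names", call. = FALSE)
  }
  if (anyDuplicated(rownames(matrix))) {
    stop("duplicate gene identifiers", call. = FALSE)
  }
  if (!all(is.finite(matrix))) stop("expression matrix must be finite", call. = FALSE)
  group <- as.character(group)
  if (!is.null(names(group))) {
    if (!setequal(names(group), colnames(matrix))) {
      stop("group names do not match sample names", call. = FALSE)
    }
    group <- group[colnames(matrix)]
  } else if (length(group) != ncol(matrix)) {
    stop("one group label per sample required", call. = FALSE)
  }
  if (!all(group %in% c("control", "disease"))) {
    stop('groups must be "control" or "disease"', call. = FALSE)
  }
  if (sum(group == "control") < 2L || sum(group == "disease") < 2L) {
    stop("need at least 2 samples per group", call. = FALSE)
  }
  structure(list(matrix = matrix, group = group, label = label),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat("Expression dataset '", x$label, "': ", nrow(x$matrix), " genes, ",
      sum(x$group == "control"), " control / ",
      sum(x$group == "disease"), " disease samples\n", sep = "")
  invisible(x)
}

#' Read an expression TSV and its sample-group file
#'
#' The expression TSV has the gene identifier in the first column and one
#' column per sample; the group TSV has columns `sample` and `group`
#' (`control`/`disease`).
#'
#' @param expr_path expression TSV.
#' @param group_path group TSV.
#' @param label provenance label.
#' @return an [expression_dataset()].
#' @export
read_expression <- function(expr_path, group_path, label = expr_path) {
  ex <- read_tsv_file(expr_path)
  mat <- as.matrix(ex[, -1L, drop = FALSE])
  rownames(mat) <- as.character(ex[[1L]])
  gr <- read_tsv_file(group_path)
  expression_dataset(mat, stats::setNames(gr$group, gr$sample), label = label)
}

#' Write an expression dataset to TSV (plus group file)
#' @param ds an [expression_dataset()].
#' @param expr_path,group_path destination files.
#' @return `expr_path`, invisibly.
#' @export
write_expression <- function(ds, expr_path, group_path) {
  df <- data.frame(gene = rownames(ds$matrix), ds$matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_file(df, expr_path)
  write_tsv_file(data.frame(sample = colnames(ds$matrix), group = ds$group),
                 group_path)
  invisible(expr_path)
}

#' Per-gene differential expression (Welch's t-test)
#'
#' For every gene, the log2 fold change is mean(disease) - mean(control) and
#' the p-value comes from a two-sided Welch (unequal-variance) two-sample
#' t-test. All genes are returned unfiltered and no multiple-testing
#' adjustment is applied; thresholding is a separate step ([filter_degs()]).
#' Degenerate genes (zero variance in both groups) get p = 1 when the group
#' means agree and the smallest representable positive p when they differ,
#' and are flagged in the `degenerate` column.
#'
#' @param ds an [expression_dataset()].
#' @return a `deg_table`: data frame with columns `gene`, `logFC`, `p_value`,
#'   `direction` (all `"flat"` until filtered) and `degenerate`, plus
#'   attributes `provenance`, `p_max`, `lfc_min` (the latter two `NA` while
#'   unfiltered).
#' @export
differential_expression <- function(ds) {
  stopifnot(inherits(ds, "expression_dataset"))
  ctrl <- ds$matrix[, ds$group == "control", drop = FALSE]
  case <- ds$matrix[, ds$group == "disease", drop = FALSE]
  n1 <- ncol(ctrl); n2 <- ncol(case)
  m1 <- rowMeans(ctrl); m2 <- rowMeans(case)
  v1 <- apply(ctrl, 1L, var); v2 <- apply(case, 1L, var)
  lfc <- m2 - m1
  se2 <- v1 / n1 + v2 / n2
  tstat <- ifelse(se2 > 0, lfc / sqrt(se2), 0)
  df <- ifelse(se2 > 0,
               se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)),
               1)
  p <- 2 * pt(-abs(tstat), df)
  degen <- se2 == 0
  p[degen & lfc == 0] <- 1
  p[degen & lfc != 0] <- .Machine$double.xmin
  lfc[degen & lfc == 0] <- 0
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  out <- data.frame(gene = rownames(ds$matrix), logFC = lfc, p_value = p,
                    direction = "flat", degenerate = degen,
                    row.names = NULL, stringsAsFactors = FALSE)
  deg_table(out, provenance = ds$label, p_max = NA_real_, lfc_min = NA_real_)
}

deg_table <- function(df, provenance, p_max, lfc_min) {
  structure(df, class = c("deg_table", "data.frame"),
            provenance = provenance, p_max = p_max, lfc_min = lfc_min)
}

#' @export
print.deg_table <- function(x, ...) {
  filt <- !is.na(attr(x, "p_max"))
  cat("DEG table '", attr(x, "provenance"), "': ", nrow(x), " genes",
      if (filt) sprintf(" (filtered at p < %g, |logFC| >= %g)",
                        attr(x, "p_max"), attr(x, "lfc_min")) else " (unfiltered)",
      "\n", sep = "")
  print.data.frame(head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat("...", nrow(x) - 10L, "more rows\n")
  invisible(x)
}

#' Threshold a DEG table
#'
#' Keeps genes with `p_value < p_max` (strict) and `|logFC| >= lfc_min`
#' (inclusive) — the conventional primary cut-off criteria — and assigns the
#' `up`/`down` direction from the sign of the log2 fold change. Idempotent
#' and monotone: re-filtering at equal or stricter thresholds yields a
#' subset.
#'
#' @param t a `deg_table` (unfiltered, or filtered less strictly).
#' @param p_max p-value cut-off (exclusive), default 0.05.
#' @param lfc_min |logFC| cut-off (inclusive), default 0.5.
#' @return the filtered `deg_table` with the thresholds recorded.
#' @export
filter_degs <- function(t, p_max = 0.05, lfc_min = 0.5) {
  stopifnot(inherits(t, "deg_table"))
  old_p <- attr(t, "p_max"); old_l <- attr(t, "lfc_min")
  if (!is.na(old_p) && (old_p < p_max || old_l > lfc_min)) {
    stop("table already filtered more strictly than requested", call. = FALSE)
  }
  keep <- t$p_value < p_max & abs(t$logFC) >= lfc_min
  out <- as.data.frame(t)[keep, , drop = FALSE]
  out$direction <- ifelse(out$logFC > 0, "up", "down")
  rownames(out) <- NULL
  deg_table(out, provenance = attr(t, "provenance"),
            p_max = p_max, lfc_min = lfc_min)
}

#' Consensus DEGs across two series of the same disease
#'
#' A gene counts as a significant DEG of a disease only when it passes the
#' cut-off criteria in both of the disease's series with the same direction
#' of change.
#'
#' @param tA,tB `deg_table`s filtered with identical thresholds.
#' @return data frame with columns `gene` and `direction`, sorted by gene.
#' @export
consensus_degs <- function(tA, tB) {
  stopifnot(inherits(tA, "deg_table"), inherits(tB, "deg_table"))
  thA <- c(attr(tA, "p_max"), attr(tA, "lfc_min"))
  thB <- c(attr(tB, "p_max"), attr(tB, "lfc_min"))
  if (anyNA(c(thA, thB))) {
    stop("both tables must be filtered (see filter_degs)", call. = FALSE)
  }
  if (!isTRUE(all.equal(thA, thB))) {
    stop("tables filtered with different thresholds", call. = FALSE)
  }
  m <- merge(as.data.frame(tA)[, c("gene", "direction")],
             as.data.frame(tB)[, c("gene", "direction")],
             by = "gene", suffixes = c("_a", "_b"))
  m <- m[m$direction_a == m$direction_b, , drop = FALSE]
  out <- data.frame(gene = m$gene, direction = m$direction_a,
                    stringsAsFactors = FALSE)
  out[order(out$gene), , drop = FALSE]
}

#' Signature genes: overlap of two diseases' consensus DEG sets
#'
#' Gene-level intersection of two consensus sets (e.g. the index disease and
#' a comorbidity); each signature gene carries both diseases' directions.
#'
#' @param disease_set,comorbidity_set outputs of [consensus_degs()].
#' @return data frame `gene`, `direction_disease`, `direction_comorbidity`.
#' @export
overlap_signature <- function(disease_set, comorbidity_set) {
  m <- merge(disease_set, comorbidity_set, by = "gene",
             suffixes = c("_disease", "_comorbidity"))
  m <- m[order(m$gene), , drop = FALSE]
  rownames(m) <- NULL
  m
}

#' Chromosome contribution of a gene set
#'
#' Percentage of a gene set on each chromosome. Genes missing from the
#' annotation are counted as unmapped (with a warning) and excluded from the
#' percentages, which sum to 100 over mapped genes.
#'
#' @param genes character vector of gene identifiers (non-empty).
#' @param annotation named character vector gene -> chromosome, or a data
#'   frame with columns `gene` and `chromosome`.
#' @return named numeric vector of percentages, with attribute `unmapped`
#'   (count of unannotated genes).
#' @export
chromosome_contribution <- function(genes, annotation) {
  genes <- unique(as.character(genes))
  if (length(genes) == 0L) stop("empty gene set", call. = FALSE)
  if (is.data.frame(annotation)) {
    annotation <- stats::setNames(as.character(annotation$chromosome),
                                  annotation$gene)
  }
  chr <- annotation[genes]
  unmapped <- sum(is.na(chr))
  if (unmapped > 0L) {
    warning(unmapped, " gene(s) missing from annotation, counted as unmapped",
            call. = FALSE)
  }
  chr <- chr[!is.na(chr)]
  if (length(chr) == 0L) stop("no gene could be mapped", call. = FALSE)
  tab <- table(chr)
  pct <- 100 * as.numeric(tab) / sum(tab)
  structure(stats::setNames(pct, names(tab)), unmapped = unmapped)
}

#' Genes reversing direction between two conditions
#'
#' Screens two unfiltered DEG tables (e.g. fetal and adult case/control
#' contrasts) for genes significant in both at `p < p_max`,
#' `|logFC| >= lfc_min` but with opposite signs of change.
#'
#' @param tA,tB unfiltered `deg_table`s.
#' @param p_max p-value cut-off, default 0.05.
#' @param lfc_min |logFC| cut-off, default 1.0 (stricter than the primary
#'   screen).
#' @return list with `up_in_a_down_in_b` and `down_in_a_up_in_b`, sorted
#'   character vectors.
#' @export
opposite_direction_genes <- function(tA, tB, p_max = 0.05, lfc_min = 1.0) {
  fA <- filter_degs(tA, p_max, lfc_min)
  fB <- filter_degs(tB, p_max, lfc_min)
  m <- merge(as.data.frame(fA)[, c("gene", "direction")],
             as.data.frame(fB)[, c("gene", "direction")],
             by = "gene", suffixes = c("_a", "_b"))
  list(
    up_in_a_down_in_b = sort(m$gene[m$direction_a == "up" & m$direction_b == "down"]),
    down_in_a_up_in_b = sort(m$gene[m$direction_a == "down" & m$direction_b == "up"])
  )
}
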