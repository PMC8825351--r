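# Expression-side pipeline: QC filtering with the study thresholds,
# library-size normalization, per-gene Wilcoxon differential expression
# between MLR+ and MLR- cells, and signed gene-signature scoring.

#' QC thresholds for expression filtering
#'
#' Defaults are the study thresholds: genes present in fewer than 5 cells
#' removed; cells retained with 500 to 6,000 genes detected (closed
#' interval), 1,800 to 40,000 transcripts detected (closed interval), and
#' strictly less than 5% mitochondrial counts.
#'
#' @param min_cells_per_gene,min_genes,max_genes,min_counts,max_counts,max_mito
#'   Individual thresholds.
#' @return list of class `QCThresholds`.
#' @export
qc_thresholds <- function(min_cells_per_gene = 5, min_genes = 500,
                          max_genes = 6000, min_counts = 1800,
                          max_counts = 40000, max_mito = 0.05) {
  stopifnot(min_genes <= max_genes, min_counts <= max_counts,
            min_cells_per_gene >= 0, max_mito >= 0)
  structure(list(min_cells_per_gene = min_cells_per_gene,
                 min_genes = min_genes, max_genes = max_genes,
                 min_counts = min_counts, max_counts = max_counts,
                 max_mito = max_mito),
            class = "QCThresholds")
}

#' QC-filter an expression matrix
#'
#' Applies the gene filter first (genes detected in fewer than
#' `min_cells_per_gene` cells are removed), then the cell filters on the
#' recomputed per-cell metadata: genes detected and total counts within
#' their closed intervals, mitochondrial fraction strictly below
#' `max_mito`. The per-criterion removal tally is attached as the
#' `qc_log` attribute.
#'
#' @param gex A `GEXMatrix`.
#' @param thr A `QCThresholds` object.
#' @return The filtered `GEXMatrix`, with attribute `qc_log`: a list with
#'   `genes_removed`, a named per-criterion cell tally `cells_removed`
#'   (cells violating several criteria count in each), and
#'   `cells_removed_total`.
#' @export
qc_filter <- function(gex, thr = qc_thresholds()) {
  stopifnot(inherits(gex, "GEXMatrix"), inherits(thr, "QCThresholds"))
  detected_in <- Matrix::colSums(gex$counts > 0)
  gene_keep <- detected_in >= thr$min_cells_per_gene
  counts <- gex$counts[, gene_keep, drop = FALSE]
  mito_prefix <- if (is.null(gex$mito_prefix)) .DEFAULT_MITO_PREFIX else
    gex$mito_prefix
  sub <- gex_matrix(counts, gex$barcodes, gex$genes[gene_keep],
                    mito_prefix = mito_prefix)

  meta <- sub$meta
  fail <- list(
    low_genes = meta$n_genes < thr$min_genes,
    high_genes = meta$n_genes > thr$max_genes,
    low_counts = meta$total_counts < thr$min_counts,
    high_counts = meta$total_counts > thr$max_counts,
    high_mito = meta$mito_frac >= thr$max_mito
  )
  cell_keep <- !Reduce(`|`, fail)
  tally <- vapply(fail, sum, numeric(1))
  if (!any(cell_keep)) {
    stop("QC removed every cell; per-criterion tally: ",
         paste(sprintf("%s=%d", names(tally), tally), collapse = ", "),
         call. = FALSE)
  }
  out <- gex_matrix(sub$counts[cell_keep, , drop = FALSE],
                    sub$barcodes[cell_keep], sub$genes,
                    mito_prefix = mito_prefix)
  attr(out, "qc_log") <- list(genes_removed = sum(!gene_keep),
                              cells_removed = tally,
                              cells_removed_total = sum(!cell_keep))
  out
}

#' Normalize an expression matrix
#'
#' Default normalization is log counts-per-10k: each cell is scaled to
#' 10,000 total counts, then `log(1 + x)` is applied. The alternative is
#' per-gene Pearson residuals under a negative-binomial null with fixed
#' dispersion (`mu + mu^2 / theta` variance), which produces a dense
#' matrix. The variant used is recorded in the result's `method` field.
#'
#' @param gex A (QC-filtered) `GEXMatrix`.
#' @param method `"logcp10k"` (default) or `"pearson"`.
#' @param scale_factor Per-cell target total for `"logcp10k"`.
#' @param theta Fixed NB dispersion for `"pearson"`.
#' @return A `NormalizedGEX`: list with `mat` (cells x genes), `barcodes`,
#'   `genes`, `method`.
#' @export
normalize_gex <- function(gex, method = c("logcp10k", "pearson"),
                          scale_factor = 1e4, theta = 100) {
  stopifnot(inherits(gex, "GEXMatrix"))
  method <- match.arg(method)
  tot <- Matrix::rowSums(gex$counts)
  if (any(tot == 0)) {
    stop("matrix contains zero-count cells; QC-filter first", call. = FALSE)
  }
  if (method == "logcp10k") {
    mat <- Matrix::Diagonal(x = scale_factor / tot) %*% gex$counts
    mat@x <- log1p(mat@x)   # log1p(0) = 0, sparsity preserved
    dimnames(mat) <- dimnames(gex$counts)
  } else {
    dense <- as.matrix(gex$counts)
    gene_frac <- colSums(dense) / sum(dense)
    mu <- outer(tot, gene_frac)
    mat <- (dense - mu) / sqrt(mu + mu^2 / theta)
    mat[is.nan(mat)] <- 0
  }
  structure(list(mat = mat, barcodes = gex$barcodes, genes = gex$genes,
                 method = method),
            class = "NormalizedGEX")
}

.resolve_labels <- function(labels, barcodes) {
  if (!is.null(names(labels))) {
    labels <- labels[barcodes]
  } else if (length(labels) != length(barcodes)) {
    stop("labels must be named by barcode or aligned with the matrix",
         call. = FALSE)
  }
  as.character(labels)
}

#' Per-gene Wilcoxon rank-sum differential expression
#'
#' Tests every gene for a shift in normalized expression between two cell
#' groups with a two-sided Wilcoxon rank-sum test (normal approximation
#' with tie correction). The fold change is computed on de-logged means,
#' `log2((mean(expm1(A)) + eps) / (mean(expm1(B)) + eps))` with
#' `eps = 1e-9`. P-values are Bonferroni-adjusted by default
#' (Benjamini-Hochberg available); a gene is `significant` iff its
#' adjusted p is below `alpha`.
#'
#' @param norm A `NormalizedGEX` (log-scale normalization assumed for the
#'   fold change).
#' @param labels Cell group labels, named by barcode or aligned with the
#'   matrix rows.
#' @param group_a,group_b The two label values to compare (A vs B;
#'   positive fold change means higher in A). Defaults are the MLR
#'   tags.
#' @param adjust `"bonferroni"` (default) or `"BH"`.
#' @param alpha Significance level on the adjusted p-value.
#' @return data.frame, one row per gene: `gene`, `pct_a`, `pct_b`
#'   (detection fractions), `log2_fc`, `p`, `p_adj`, `significant`.
#' @export
wilcoxon_de <- function(norm, labels, group_a = "MLR_plus",
                        group_b = "MLR_minus",
                        adjust = c("bonferroni", "BH"), alpha = 0.05) {
  stopifnot(inherits(norm, "NormalizedGEX"))
  adjust <- match.arg(adjust)
  labels <- .resolve_labels(labels, norm$barcodes)
  ia <- which(labels == group_a)
  ib <- which(labels == group_b)
  if (length(ia) < 3 || length(ib) < 3) {
    stop(sprintf("need >= 3 cells per group (found %d vs %d)",
                 length(ia), length(ib)), call. = FALSE)
  }
  mat <- as.matrix(norm$mat)
  eps <- 1e-9
  res <- lapply(seq_along(norm$genes), function(g) {
    va <- mat[ia, g]
    vb <- mat[ib, g]
    p <- if (all(va == va[1]) && all(vb == vb[1]) && va[1] == vb[1]) 1 else
      stats::wilcox.test(va, vb, exact = FALSE, correct = FALSE)$p.value
    data.frame(gene = norm$genes[g],
               pct_a = mean(va > 0), pct_b = mean(vb > 0),
               log2_fc = log2((mean(expm1(va)) + eps) /
                                (mean(expm1(vb)) + eps)),
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- stats::p.adjust(out$p, method = adjust)
  out$significant <- out$p_adj < alpha
  out
}

#' Read gene signatures from a GMT file
#'
#' Standard GMT: one signature per line, tab-delimited name, description,
#' then genes. Signed signatures encode down-regulated members with a
#' leading `-` on the gene symbol; everything else is an up-regulated
#' (positive) member.
#'
#' @param path GMT file path.
#' @return Named list of signatures, each a list with `name`,
#'   `description`, `pos`, `neg`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sigs <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("malformed GMT line: ", l, call. = FALSE)
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    neg <- grepl("^-", genes)
    list(name = f[1], description = f[2],
         pos = genes[!neg], neg = sub("^-", "", genes[neg]))
  })
  names(sigs) <- vapply(sigs, `[[`, character(1), "name")
  sigs
}

#' Score cells with a signed gene signature
#'
#' Per cell, the score is the mean z-scored normalized expression of the
#' signature's positive genes minus that of its negative genes:
#' `(sum(z_pos) - sum(z_neg)) / n_present`, where z-scoring is per gene
#' across all cells in the compared set and `n_present` counts the
#' signature genes found in the matrix. Genes with zero variance
#' contribute 0; signature genes absent from the matrix are dropped
#' (their number is reported in the `missing_genes` attribute).
#'
#' @param norm A `NormalizedGEX`.
#' @param signature One signature from [read_gmt()] (a list with `pos`
#'   and `neg`), or a character vector (all positive).
#' @param labels Optional per-cell group labels (named by barcode or
#'   aligned), carried into the output.
#' @return data.frame `barcode`, `signature`, `score` (and `label` if
#'   given), with attribute `missing_genes`.
#' @export
signature_score <- function(norm, signature, labels = NULL) {
  stopifnot(inherits(norm, "NormalizedGEX"))
  if (is.character(signature)) {
    signature <- list(name = "signature", pos = signature, neg = character())
  }
  pos <- intersect(unique(signature$pos), norm$genes)
  neg <- intersect(unique(signature$neg), norm$genes)
  missing <- length(setdiff(unique(signature$pos), pos)) +
    length(setdiff(unique(signature$neg), neg))
  n_present <- length(pos) + length(neg)
  if (n_present == 0) {
    stop("no signature gene present in the matrix", call. = FALSE)
  }
  sub <- as.matrix(norm$mat[, c(pos, neg), drop = FALSE])
  mu <- colMeans(sub)
  sd <- apply(sub, 2, stats::sd)
  z <- sweep(sub, 2, mu, "-")
  z <- sweep(z, 2, ifelse(sd > 0, sd, 1), "/")
  z[, sd == 0] <- 0
  sign_vec <- c(rep(1, length(pos)), rep(-1, length(neg)))
  score <- as.numeric(z %*% sign_vec) / n_present
  out <- data.frame(barcode = norm$barcodes,
                    signature = if (!is.null(signature$name))
                      signature$name else "signature",
                    score = score, stringsAsFactors = FALSE)
  if (!is.null(labels)) out$label <- .resolve_labels(labels, norm$barcodes)
  attr(out, "missing_genes") <- missing
  out
}

#' Compare signature scores between two cell groups
#'
#' Two-sided Wilcoxon rank-sum test on per-cell signature scores between
#' two groups (e.g. MLR+ vs MLR- within an organ).
#'
#' @param scores Output of [signature_score()], or a numeric score
#'   vector.
#' @param labels Group labels (named by barcode, aligned, or already in
#'   the `label` column of `scores`).
#' @param group_a,group_b Label values to compare.
#' @return An `htest` (Wilcoxon rank-sum) object.
#' @export
compare_scores <- function(scores, labels = NULL, group_a = "MLR_plus",
                           group_b = "MLR_minus") {
  if (is.data.frame(scores)) {
    values <- scores$score
    if (is.null(labels)) labels <- scores$label
    if (!is.null(names(labels))) labels <- labels[scores$barcode]
  } else {
    values <- scores
  }
  if (is.null(labels) || length(labels) != length(values)) {
    stop("labels must be provided and aligned with scores", call. = FALSE)
  }
  a <- values[labels == group_a]
  b <- values[labels == group_b]
  if (length(a) == 0 || length(b) == 0) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  stats::wilcox.test(a, b, exact = FALSE)
}
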