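# Readers for the two single-cell dialects the pipeline consumes: the
# filtered contig annotation CSV emitted by VDJ assembly, and the
# MatrixMarket + TSV triplet used for expression counts.

.parse_10x_logical <- function(x) {
  x <- tolower(as.character(x))
  out <- rep(NA, length(x))
  out[x %in% c("true", "t", "1")] <- TRUE
  out[x %in% c("false", "f", "0", "none", "")] <- FALSE
  out
}

.none_to_na <- function(x) {
  x <- as.character(x)
  x[x %in% c("None", "none", "")] <- NA_character_
  x
}

#' Read a 10x-style filtered contig annotation table
#'
#' Parses the `filtered_contig_annotations.csv` dialect: one row per
#' assembled contig (chain) with its cell barcode, chain, V/D/J/C calls,
#' CDR3 nucleotide and amino-acid sequences, full-length / productive
#' flags and UMI support. Cells are the groups of rows sharing a barcode.
#'
#' Boolean columns accept `True`/`False`/`true`/`false`/`None`; the string
#' `None` in sequence and gene-call columns maps to `NA`.
#'
#' @param path CSV path (or anything `read.csv` accepts).
#' @param sample_id Sample label attached to the result as an attribute
#'   and used downstream; defaults to the file name.
#' @return data.frame with one row per contig and (at least) columns
#'   `barcode`, `contig_id`, `chain`, `v_gene`, `d_gene`, `j_gene`,
#'   `c_gene`, `cdr3`, `cdr3_nt`, `full_length`, `productive`, `umis`,
#'   `reads`, plus attribute `sample_id`.
#' @export
read_contig_annotations <- function(path, sample_id = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  required <- c("barcode", "chain", "cdr3_nt", "full_length", "productive",
                "umis")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("contig table is missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  optional <- c(contig_id = NA_character_, v_gene = NA_character_,
                d_gene = NA_character_, j_gene = NA_character_,
                c_gene = NA_character_, cdr3 = NA_character_,
                reads = "0")
  for (col in names(optional)) {
    if (!col %in% names(df)) df[[col]] <- rep(optional[[col]], nrow(df))
  }
  if (all(is.na(df$contig_id)) && nrow(df) > 0) {
    df$contig_id <- sprintf("%s_contig_%d", df$barcode,
                            stats::ave(seq_len(nrow(df)), df$barcode,
                                       FUN = seq_along))
  }
  for (col in c("cdr3_nt", "cdr3", "v_gene", "d_gene", "j_gene", "c_gene")) {
    df[[col]] <- .none_to_na(df[[col]])
  }
  df$cdr3_nt <- toupper(df$cdr3_nt)
  df$full_length <- .parse_10x_logical(df$full_length)
  df$productive <- .parse_10x_logical(df$productive)
  df$umis <- as.integer(df$umis)
  df$reads <- as.integer(df$reads)
  if (is.null(sample_id)) {
    sample_id <- if (is.character(path)) basename(path) else "sample"
  }
  attr(df, "sample_id") <- sample_id
  df
}

#' Per-sample chain reconstruction summary
#'
#' Summarizes how well TCR chains were reconstructed in a sample: the
#' percentage of cells with a CDR3-annotated alpha chain contig, with a
#' CDR3-annotated beta chain contig, and with a productive full-length
#' alpha + beta pair. Denominator is every distinct barcode in the table
#' (cells with only non-alpha/beta chains count in the denominator).
#'
#' @param contigs Contig table from [read_contig_annotations()] (or the
#'   synthetic generator).
#' @param sample_id Sample label; defaults to the table's attribute.
#' @return One-row data.frame: `sample_id`, `n_cells`, `pct_cdr3_alpha`,
#'   `pct_cdr3_beta`, `pct_productive_pair` (percentages in \[0, 100\]).
#' @export
chain_summary <- function(contigs, sample_id = attr(contigs, "sample_id")) {
  cells <- unique(contigs$barcode)
  if (length(cells) == 0) stop("no cells in contig table", call. = FALSE)

  has_cdr3 <- !is.na(contigs$cdr3_nt)
  alpha_cells <- unique(contigs$barcode[contigs$chain == "TRA" & has_cdr3])
  beta_cells <- unique(contigs$barcode[contigs$chain == "TRB" & has_cdr3])
  good <- contigs$productive %in% TRUE & contigs$full_length %in% TRUE
  pair_cells <- intersect(
    unique(contigs$barcode[contigs$chain == "TRA" & good]),
    unique(contigs$barcode[contigs$chain == "TRB" & good])
  )
  pct <- function(x) 100 * length(x) / length(cells)
  data.frame(sample_id = if (is.null(sample_id)) NA_character_ else sample_id,
             n_cells = length(cells),
             pct_cdr3_alpha = pct(alpha_cells),
             pct_cdr3_beta = pct(beta_cells),
             pct_productive_pair = pct(pair_cells),
             stringsAsFactors = FALSE)
}

.DEFAULT_MITO_PREFIX <- c("MT-", "MT_", "mt-")

#' Construct a gene-expression matrix container
#'
#' @param counts Sparse (or dense) nonnegative integer matrix, cells in
#'   rows and genes in columns.
#' @param barcodes,genes Row / column identifiers.
#' @param mito_prefix Character vector of gene-name prefixes identifying
#'   mitochondrial genes (annotation conventions vary, so this is a
#'   configurable list).
#' @return A `GEXMatrix`: list with `counts` (dgCMatrix, cells x genes),
#'   `barcodes`, `genes`, `mito_genes`, and `meta` (data.frame with
#'   per-cell `barcode`, `total_counts`, `n_genes`, `mito_frac`).
#' @export
gex_matrix <- function(counts, barcodes, genes,
                       mito_prefix = .DEFAULT_MITO_PREFIX) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  if (nrow(counts) != length(barcodes) || ncol(counts) != length(genes)) {
    stop(sprintf(
      "dimension mismatch: counts is %d x %d but %d barcodes / %d genes given",
      nrow(counts), ncol(counts), length(barcodes), length(genes)),
      call. = FALSE)
  }
  if (any(counts@x < 0)) stop("negative counts", call. = FALSE)
  dimnames(counts) <- list(barcodes, genes)
  mito <- genes[Reduce(`|`, lapply(mito_prefix, startsWith, x = genes))]
  tot <- Matrix::rowSums(counts)
  mito_tot <- if (length(mito) > 0) {
    Matrix::rowSums(counts[, mito, drop = FALSE])
  } else rep(0, length(barcodes))
  meta <- data.frame(
    barcode = barcodes,
    total_counts = as.numeric(tot),
    n_genes = as.numeric(Matrix::rowSums(counts > 0)),
    mito_frac = ifelse(tot > 0, mito_tot / tot, 0),
    stringsAsFactors = FALSE)
  structure(list(counts = counts, barcodes = barcodes, genes = genes,
                 mito_genes = mito, mito_prefix = mito_prefix, meta = meta),
            class = "GEXMatrix")
}

#' @export
print.GEXMatrix <- function(x, ...) {
  cat(sprintf("GEXMatrix: %d cells x %d genes (%d mitochondrial)\n",
              length(x$barcodes), length(x$genes), length(x$mito_genes)))
  invisible(x)
}

.open_maybe_gz <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path) else path
}

#' Read a MatrixMarket expression matrix with barcode / feature TSVs
#'
#' Reads the standard triplet (`matrix.mtx`, `barcodes.tsv`,
#' `features.tsv`, each optionally gzipped) in the usual orientation of
#' features x barcodes, and returns a cells x genes [gex_matrix()] with
#' per-cell metadata populated. Feature names are taken from the second
#' TSV column when present (id, name, type), else the first.
#'
#' @param matrix_path,barcodes_path,features_path File paths.
#' @inheritParams gex_matrix
#' @return A `GEXMatrix`.
#' @export
read_mtx <- function(matrix_path, barcodes_path, features_path,
                     mito_prefix = .DEFAULT_MITO_PREFIX) {
  m <- Matrix::readMM(.open_maybe_gz(matrix_path))
  barcodes <- readLines(.open_maybe_gz(barcodes_path))
  feat <- utils::read.delim(.open_maybe_gz(features_path), header = FALSE,
                            stringsAsFactors = FALSE)
  genes <- if (ncol(feat) >= 2) feat[[2]] else feat[[1]]
  if (nrow(m) != length(genes) || ncol(m) != length(barcodes)) {
    stop(sprintf(
      "dimension mismatch: matrix is %d x %d but %d features / %d barcodes",
      nrow(m), ncol(m), length(genes), length(barcodes)), call. = FALSE)
  }
  gex_matrix(Matrix::t(m), barcodes, genes, mito_prefix = mito_prefix)
}

#' Write a GEXMatrix as MatrixMarket + TSVs
#'
#' Inverse of [read_mtx()]: writes `matrix.mtx` (features x barcodes),
#' `barcodes.tsv` and `features.tsv` into `dir`.
#'
#' @param gex A `GEXMatrix`.
#' @param dir Output directory (created if needed).
#' @return Named list of the three file paths, invisibly.
#' @export
write_mtx <- function(gex, dir) {
  stopifnot(inherits(gex, "GEXMatrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(matrix = file.path(dir, "matrix.mtx"),
                barcodes = file.path(dir, "barcodes.tsv"),
                features = file.path(dir, "features.tsv"))
  Matrix::writeMM(Matrix::t(gex$counts), paths$matrix)
  writeLines(gex$barcodes, paths$barcodes)
  utils::write.table(
    data.frame(id = gex$genes, name = gex$genes, type = "Gene Expression"),
    paths$features, sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  invisible(paths)
}

#' Match VDJ cell barcodes to expression barcodes
#'
#' Computes the fraction of VDJ-assayed cells that also have expression
#' data: `|VDJ barcodes intersect GEX barcodes| / |VDJ barcodes|`, after
#' optional GEM-well suffix normalization (a trailing `-<digits>` is
#' stripped from both sides, since aggregation pipelines append well
#' suffixes).
#'
#' @param contigs Contig table (or a character vector of VDJ barcodes).
#' @param gex A `GEXMatrix` (or a character vector of GEX barcodes).
#' @param strip_suffix Strip a single trailing `-<digits>` suffix before
#'   matching (default `TRUE`).
#' @return list with `fraction` (in \[0, 1\]) and `matched` (the matched
#'   VDJ barcodes, in their original spelling).
#' @export
match_vdj_to_gex <- function(contigs, gex, strip_suffix = TRUE) {
  vdj_bc <- if (is.data.frame(contigs)) unique(contigs$barcode) else unique(contigs)
  gex_bc <- if (inherits(gex, "GEXMatrix")) gex$barcodes else gex
  if (length(vdj_bc) == 0) stop("no VDJ barcodes", call. = FALSE)
  norm <- function(x) if (strip_suffix) sub("-[0-9]+$", "", x) else x
  hit <- norm(vdj_bc) %in% norm(gex_bc)
  list(fraction = mean(hit), matched = vdj_bc[hit])
}
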