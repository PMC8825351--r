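# Clonotype assignment groups cells by the exact nucleotide sequence of
# the CDR3 region -- of the alpha chain, the beta chain, or both chains
# paired. Single-chain modes deliberately allow a clonotype key to be
# shared across donors, which is what makes cross-donor overlap a
# meaningful specificity control.

.CLONO_MODES <- c("alpha_nt", "beta_nt", "paired_nt")

.best_chain_contig <- function(contigs, chain) {
  sel <- contigs$chain == chain & !is.na(contigs$cdr3_nt)
  sub <- contigs[sel, , drop = FALSE]
  if (nrow(sub) == 0) {
    return(data.frame(barcode = character(), cdr3_nt = character(),
                      stringsAsFactors = FALSE))
  }
  # highest UMI count wins; ties broken by lexicographically smallest
  # contig_id so assignment is invariant to input row order
  ord <- order(sub$barcode, -sub$umis, sub$contig_id)
  sub <- sub[ord, , drop = FALSE]
  sub <- sub[!duplicated(sub$barcode), c("barcode", "cdr3_nt"), drop = FALSE]
  rownames(sub) <- NULL
  sub
}

#' Assign cells to CDR3 clonotypes
#'
#' Groups the cells of one sample into clonotypes by CDR3 nucleotide
#' identity. A cell is assigned iff it has the chain(s) the mode requires
#' (with a CDR3 call); when a cell carries multiple contigs of a chain,
#' the highest-UMI contig is used, ties broken by contig id. Assigned
#' cells partition across clonotype keys; the rest are unassigned.
#'
#' @param contigs Contig table ([read_contig_annotations()]).
#' @param mode `"alpha_nt"`, `"beta_nt"`, or `"paired_nt"` (both CDR3s).
#' @param sample_id Sample label; defaults to the table's attribute.
#' @return A `ClonotypeTable`: list with
#'   \describe{
#'     \item{mode}{the clonotyping mode.}
#'     \item{keys}{data.frame `key`, `alpha_cdr3_nt`, `beta_cdr3_nt`.}
#'     \item{counts}{integer matrix, clonotypes x samples.}
#'     \item{assignments}{data.frame `barcode`, `sample_id`, `key`
#'       (`NA` = unassigned).}
#'   }
#'   Attribute `multi_chain_cells` counts cells carrying more than one
#'   CDR3-bearing contig of the same chain (doublet-like).
#' @export
assign_clonotypes <- function(contigs, mode = c("alpha_nt", "beta_nt", "paired_nt"),
                              sample_id = attr(contigs, "sample_id")) {
  mode <- match.arg(mode)
  if (is.null(sample_id)) sample_id <- "sample"

  cells <- sort(unique(contigs$barcode))
  alpha <- .best_chain_contig(contigs, "TRA")
  beta <- .best_chain_contig(contigs, "TRB")
  a <- alpha$cdr3_nt[match(cells, alpha$barcode)]
  b <- beta$cdr3_nt[match(cells, beta$barcode)]

  key <- switch(mode,
    alpha_nt = a,
    beta_nt = b,
    paired_nt = ifelse(is.na(a) | is.na(b), NA_character_, paste(a, b, sep = "|")))

  assignments <- data.frame(barcode = cells, sample_id = sample_id,
                            key = key, stringsAsFactors = FALSE)
  assigned <- assignments[!is.na(assignments$key), , drop = FALSE]
  ukeys <- sort(unique(assigned$key))
  counts <- matrix(0L, nrow = length(ukeys), ncol = 1,
                   dimnames = list(ukeys, sample_id))
  if (nrow(assigned) > 0) {
    tab <- table(assigned$key)
    counts[names(tab), 1] <- as.integer(tab)
  }
  keys <- data.frame(
    key = ukeys,
    alpha_cdr3_nt = switch(mode,
      alpha_nt = ukeys,
      beta_nt = rep(NA_character_, length(ukeys)),
      paired_nt = sub("\\|.*$", "", ukeys)),
    beta_cdr3_nt = switch(mode,
      alpha_nt = rep(NA_character_, length(ukeys)),
      beta_nt = ukeys,
      paired_nt = sub("^.*\\|", "", ukeys)),
    stringsAsFactors = FALSE)

  multi <- sum(vapply(c("TRA", "TRB"), function(ch) {
    sel <- contigs$chain == ch & !is.na(contigs$cdr3_nt)
    sum(table(contigs$barcode[sel]) > 1)
  }, numeric(1)))

  structure(list(mode = mode, keys = keys, counts = counts,
                 assignments = assignments),
            class = "ClonotypeTable", multi_chain_cells = multi)
}

#' @export
print.ClonotypeTable <- function(x, ...) {
  cat(sprintf("ClonotypeTable (%s): %d clonotypes x %d sample(s), %d/%d cells assigned\n",
              x$mode, nrow(x$keys), ncol(x$counts),
              sum(!is.na(x$assignments$key)), nrow(x$assignments)))
  invisible(x)
}

#' Merge per-sample clonotype tables into a cross-sample occurrence matrix
#'
#' Takes clonotype tables from multiple samples (all in the same mode) and
#' returns one table over the union of clonotype keys, with one count
#' column per sample; a key absent from a sample has count 0.
#'
#' @param tables A list of `ClonotypeTable` objects (or several passed as
#'   `...`).
#' @param ... Additional tables.
#' @return A merged `ClonotypeTable`.
#' @export
occurrence_matrix <- function(tables, ...) {
  if (inherits(tables, "ClonotypeTable")) tables <- list(tables)
  tables <- c(tables, list(...))
  stopifnot(length(tables) >= 1)
  modes <- unique(vapply(tables, `[[`, character(1), "mode"))
  if (length(modes) != 1) {
    stop("clonotyping mode mismatch across samples: ",
         paste(modes, collapse = ", "), call. = FALSE)
  }
  keys <- unique(do.call(rbind, lapply(tables, `[[`, "keys")))
  keys <- keys[order(keys$key), , drop = FALSE]
  rownames(keys) <- NULL
  samples <- unlist(lapply(tables, function(t) colnames(t$counts)))
  if (anyDuplicated(samples)) {
    stop("duplicate sample ids across tables", call. = FALSE)
  }
  counts <- matrix(0L, nrow = nrow(keys), ncol = length(samples),
                   dimnames = list(keys$key, samples))
  for (t in tables) {
    counts[rownames(t$counts), colnames(t$counts)] <- t$counts
  }
  assignments <- do.call(rbind, lapply(tables, `[[`, "assignments"))
  rownames(assignments) <- NULL
  structure(list(mode = modes, keys = keys, counts = counts,
                 assignments = assignments),
            class = "ClonotypeTable")
}

#' Track a sample's top clonotypes across every other sample
#'
#' Ranks the clonotypes of a focal sample by their cell count there and
#' reports each of the top `k` with its counts in every sample of the
#' table (zero counts included) -- the tabular form of a clone-tracking
#' plot across sorted MLR fractions.
#'
#' @param ct A multi-sample `ClonotypeTable` ([occurrence_matrix()]).
#' @param focal_sample Sample id to rank by.
#' @param top_k Number of clonotypes to report (ties broken by key order;
#'   a `top_k` larger than the table returns everything).
#' @return data.frame: `rank`, `key`, then one count column per sample.
#' @export
track_clonotypes <- function(ct, focal_sample, top_k = 10L) {
  stopifnot(inherits(ct, "ClonotypeTable"))
  if (top_k < 1) stop("top_k must be >= 1", call. = FALSE)
  if (!focal_sample %in% colnames(ct$counts)) {
    stop("focal sample not present: ", focal_sample, call. = FALSE)
  }
  focal <- ct$counts[, focal_sample]
  ord <- order(-focal, rownames(ct$counts))
  take <- ord[seq_len(min(top_k, length(ord)))]
  out <- data.frame(rank = seq_along(take), key = rownames(ct$counts)[take],
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(ct$counts[take, , drop = FALSE],
                           stringsAsFactors = FALSE), row.names = NULL)
}

#' Extract the allo-proliferating clonotype set from a sorted fraction
#'
#' The allo-proliferating set is defined as every clonotype observed in
#' the highly-proliferated (CTV-Low) fraction with at least `min_cells`
#' cells. The threshold is a configuration knob (default 2) since a
#' singleton observation is weak evidence of proliferation.
#'
#' @param ct A `ClonotypeTable` containing the fraction.
#' @param sample Sample id of the proliferated fraction.
#' @param min_cells Minimum cell count for a clonotype to qualify.
#' @return Character vector of clonotype keys.
#' @export
alloreactive_keys <- function(ct, sample, min_cells = 2L) {
  stopifnot(inherits(ct, "ClonotypeTable"))
  if (!sample %in% colnames(ct$counts)) {
    stop("sample not present: ", sample, call. = FALSE)
  }
  rownames(ct$counts)[ct$counts[, sample] >= min_cells]
}

#' Tag tissue cells as MLR+ / MLR- against an allo-proliferating set
#'
#' Labels each tissue cell by whether its clonotype matches an
#' allo-proliferating clonotype identified in vitro: `MLR_plus` if its
#' assigned key is in `allo_keys`, `MLR_minus` if it is assigned to any
#' other key, `unassigned` if the cell lacks the chain(s) the mode
#' requires. The three labels always partition the cells.
#'
#' @param tissue Contig table for the tissue sample, or an already
#'   assigned `ClonotypeTable`.
#' @param allo_keys Character vector of allo-proliferating clonotype keys
#'   ([alloreactive_keys()]).
#' @param mode Clonotyping mode (must match how `allo_keys` were built).
#' @return data.frame `barcode`, `key`, `label`
#'   (`MLR_plus`/`MLR_minus`/`unassigned`), with attribute `label_counts`
#'   (named count vector, the per-label cell tally).
#' @export
tag_alloreactive <- function(tissue, allo_keys,
                             mode = c("paired_nt", "alpha_nt", "beta_nt")) {
  mode <- match.arg(mode)
  if (length(allo_keys) == 0) stop("allo_keys is empty", call. = FALSE)
  ct <- if (inherits(tissue, "ClonotypeTable")) tissue else
    assign_clonotypes(tissue, mode = mode)
  if (!identical(ct$mode, mode)) {
    stop(sprintf("mode mismatch: table is %s, requested %s", ct$mode, mode),
         call. = FALSE)
  }
  asg <- ct$assignments
  label <- ifelse(is.na(asg$key), "unassigned",
                  ifelse(asg$key %in% allo_keys, "MLR_plus", "MLR_minus"))
  out <- data.frame(barcode = asg$barcode, key = asg$key, label = label,
                    stringsAsFactors = FALSE)
  counts <- c(MLR_plus = sum(label == "MLR_plus"),
              MLR_minus = sum(label == "MLR_minus"),
              unassigned = sum(label == "unassigned"))
  attr(out, "label_counts") <- counts
  out
}
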