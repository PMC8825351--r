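# Enrichment-primer audits against reference segments. Coordinates are
# 0-based, half-open, always on the segment's sense strand; a primer that
# anneals as a reverse primer is reported with strand = "antisense".

#' Find primer annealing sites on a reference segment
#'
#' Reports every position where the primer matches the segment's sense
#' strand (`strand = "sense"`, a forward primer) and every position where
#' the reverse complement of the primer matches the sense strand
#' (`strand = "antisense"`, the primer anneals as a reverse primer), with
#' at most `max_mismatch` mismatches. Matching is Hamming-only (no
#' indels); an `N` in the segment counts as a mismatch.
#'
#' @param primer Primer sequence, 5'->3', over A/C/G/T, length >= 10.
#' @param record One reference segment: a single row of
#'   `ReferenceSet$records`, or a list with `sequence` and `allele`.
#' @param max_mismatch Maximum Hamming distance (default 0).
#' @return data.frame of sites sorted by `start`: `segment_allele`,
#'   `start`, `end` (0-based half-open on the sense strand), `strand`,
#'   `mismatches`.
#' @export
find_primer_sites <- function(primer, record, max_mismatch = 0L) {
  primer <- toupper(primer)
  if (!grepl("^[ACGT]+$", primer)) {
    stop("primer must contain only A, C, G, T", call. = FALSE)
  }
  if (nchar(primer) < 10) {
    stop("primer length must be >= 10", call. = FALSE)
  }
  allele <- if (!is.null(record$allele)) record$allele else NA_character_
  subject <- Biostrings::DNAString(toupper(record$sequence))

  scan_one <- function(pattern, strand) {
    hits <- Biostrings::matchPattern(pattern, subject,
                                     max.mismatch = max_mismatch,
                                     with.indels = FALSE)
    if (length(hits) == 0) return(NULL)
    mm <- vapply(seq_along(hits), function(i) {
      sum(strsplit(as.character(hits[[i]]), "")[[1]] !=
            strsplit(pattern, "")[[1]])
    }, integer(1))
    data.frame(segment_allele = allele,
               start = Biostrings::start(hits) - 1L,
               end = Biostrings::end(hits),
               strand = strand, mismatches = mm,
               stringsAsFactors = FALSE)
  }

  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(primer)))
  out <- rbind(scan_one(primer, "sense"), scan_one(rc, "antisense"))
  if (is.null(out)) {
    out <- data.frame(segment_allele = character(), start = integer(),
                      end = integer(), strand = character(),
                      mismatches = integer(), stringsAsFactors = FALSE)
  }
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Distance between the 3' ends of two nested primer sites
#'
#' For a nested PCR pair, reports the distance (bp) between the template
#' positions of the two primers' 3' ends. On the sense strand a primer's
#' 3' end is its last base (`end - 1`); for an antisense site (a reverse
#' primer) the 3' end maps to the `start` coordinate. The sign is
#' positive when the outer primer's 3' end lies 3' of the inner's on the
#' sense strand.
#'
#' @param outer,inner Single-row data.frames as returned by
#'   [find_primer_sites()] (one site each). Both sites must be on the
#'   same segment and the same strand.
#' @return Integer distance in bp.
#' @export
nested_distance <- function(outer, inner) {
  if (nrow(outer) != 1 || nrow(inner) != 1) {
    stop("outer and inner must each be a single primer site", call. = FALSE)
  }
  if (!identical(outer$segment_allele, inner$segment_allele)) {
    stop("primer sites are on different segments", call. = FALSE)
  }
  if (!identical(outer$strand, inner$strand)) {
    stop("primer sites are on different strands", call. = FALSE)
  }
  p3 <- function(site) {
    if (site$strand == "antisense") site$start else site$end - 1L
  }
  as.integer(p3(outer) - p3(inner))
}

#' GC fraction and Wallace-rule melting temperature of a primer
#'
#' The Wallace rule estimates Tm as `2*(A+T) + 4*(G+C)` degrees C; GC
#' fraction is `(G+C)/length`. Both are the standard quick screens used
#' when matching custom enrichment primers to a kit's forward primers.
#'
#' @param primer Primer sequence over A/C/G/T.
#' @return list with `gc_fraction` and `wallace_tm`.
#' @examples
#' primer_properties("CCGGCCACTTTCAGGAGGAGG")
#' @export
primer_properties <- function(primer) {
  primer <- toupper(primer)
  if (nchar(primer) == 0) stop("primer is empty", call. = FALSE)
  if (!grepl("^[ACGT]+$", primer)) {
    stop("primer must contain only A, C, G, T", call. = FALSE)
  }
  bases <- strsplit(primer, "")[[1]]
  gc <- sum(bases %in% c("G", "C"))
  at <- length(bases) - gc
  list(gc_fraction = gc / length(bases), wallace_tm = 2 * at + 4 * gc)
}
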