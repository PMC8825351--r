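#' Parse a pipe-delimited V(D)J segment reference FASTA
#'
#' Reads a custom V(D)J reference in the 8-field pipe-delimited header
#' dialect used by cellranger-style references, e.g.
#' `>340|TRAC*01 IMGT|TRAC|C-REGION|TR|TRA|None|01`.
#' Fields are, in order: record id, allele (plus an optional
#' space-separated source note), gene, region type, chain type (e.g. `TR`),
#' chain (e.g. `TRA`), isotype, and allele number. Sequence lines are
#' concatenated and uppercased.
#'
#' Records whose header does not have exactly 8 `|`-separated fields, or
#' whose sequence is empty, are rejected (not parsed); rejected headers and
#' the reason are reported in the `rejected` element of the result.
#'
#' @param input Path to a FASTA file, or a character vector of FASTA text
#'   lines (a single string with embedded newlines also works).
#' @param provenance Free-text provenance note stored on the result.
#'
#' @return A `ReferenceSet`: a list with elements
#'   \describe{
#'     \item{records}{data.frame with one row per segment: `record_id`,
#'       `allele`, `source_note`, `gene`, `region` (one of `V-REGION`,
#'       `D-REGION`, `J-REGION`, `C-REGION`, `L-REGION`, or `other`),
#'       `region_raw`, `chain` (`TRA`, `TRB`, or `other`), `chain_raw`,
#'       `chain_type`, `isotype`, `allele_number`, `sequence`.}
#'     \item{provenance}{the provenance string.}
#'     \item{rejected}{data.frame of rejected headers with a `reason`.}
#'   }
#'
#' Unknown region / chain strings are preserved verbatim in the `*_raw`
#' columns and mapped to `"other"` in the typed columns.
#'
#' @examples
#' fa <- c(">1|TRAC*01 IMGT|TRAC|C-REGION|TR|TRA|None|01", "ATGAAA")
#' ref <- parse_imgt_fasta(fa)
#' ref$records$allele
#' @export
parse_imgt_fasta <- function(input, provenance = "") {
  known_regions <- c("V-REGION", "D-REGION", "J-REGION", "C-REGION", "L-REGION")

  if (length(input) == 1 && !grepl("\n", input) && file.exists(input)) {
    seqs <- Biostrings::readBStringSet(input)
  } else {
    tf <- tempfile(fileext = ".fasta")
    on.exit(unlink(tf), add = TRUE)
    writeLines(unlist(strsplit(input, "\n", fixed = TRUE)), tf)
    seqs <- Biostrings::readBStringSet(tf)
  }

  empty_records <- data.frame(
    record_id = integer(), allele = character(), source_note = character(),
    gene = character(), region = character(), region_raw = character(),
    chain = character(), chain_raw = character(), chain_type = character(),
    isotype = character(), allele_number = character(),
    sequence = character(), stringsAsFactors = FALSE
  )
  rejected <- data.frame(header = character(), reason = character(),
                         stringsAsFactors = FALSE)
  records <- empty_records

  if (length(seqs) > 0) {
    headers <- names(seqs)
    sequences <- toupper(as.character(seqs))
    for (i in seq_along(headers)) {
      fields <- strsplit(headers[i], "|", fixed = TRUE)[[1]]
      if (length(fields) != 8) {
        rejected <- rbind(rejected, data.frame(
          header = headers[i],
          reason = sprintf("expected 8 pipe-delimited header fields, found %d",
                           length(fields)),
          stringsAsFactors = FALSE))
        next
      }
      if (nchar(sequences[i]) == 0) {
        rejected <- rbind(rejected, data.frame(
          header = headers[i], reason = "empty sequence",
          stringsAsFactors = FALSE))
        next
      }
      # field 2 splits on the first space into allele and source note
      allele_note <- sub(" .*$", "", fields[2])
      note <- if (grepl(" ", fields[2])) sub("^[^ ]+ ", "", fields[2]) else NA_character_
      region_raw <- fields[4]
      chain_raw <- fields[6]
      records <- rbind(records, data.frame(
        record_id = as.integer(fields[1]),
        allele = allele_note,
        source_note = note,
        gene = fields[3],
        region = if (region_raw %in% known_regions) region_raw else "other",
        region_raw = region_raw,
        chain = if (chain_raw %in% c("TRA", "TRB")) chain_raw else "other",
        chain_raw = chain_raw,
        chain_type = fields[5],
        isotype = fields[7],
        allele_number = fields[8],
        sequence = sequences[i],
        stringsAsFactors = FALSE))
    }
  }
  rownames(records) <- NULL
  structure(list(records = records, provenance = provenance,
                 rejected = rejected),
            class = "ReferenceSet")
}

#' @export
print.ReferenceSet <- function(x, ...) {
  cat(sprintf("ReferenceSet: %d segment(s)", nrow(x$records)))
  if (nrow(x$rejected) > 0) cat(sprintf(", %d rejected", nrow(x$rejected)))
  cat("\n")
  if (nrow(x$records) > 0) {
    tab <- table(x$records$chain, x$records$region)
    print(tab)
  }
  invisible(x)
}

#' Write a ReferenceSet back to pipe-delimited FASTA
#'
#' Emits the same 8-field header dialect consumed by [parse_imgt_fasta()],
#' so that parse -> write -> parse round-trips losslessly.
#'
#' @param ref A `ReferenceSet`.
#' @param path Output file path.
#' @param width Sequence line-wrap width.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(ref, path, width = 60L) {
  stopifnot(inherits(ref, "ReferenceSet"))
  r <- ref$records
  field2 <- ifelse(is.na(r$source_note), r$allele,
                   paste(r$allele, r$source_note))
  headers <- sprintf("%d|%s|%s|%s|%s|%s|%s|%s", r$record_id, field2, r$gene,
                     r$region_raw, r$chain_type, r$chain_raw, r$isotype,
                     r$allele_number)
  seqs <- Biostrings::BStringSet(r$sequence)
  names(seqs) <- headers
  Biostrings::writeXStringSet(seqs, path, width = width)
  invisible(path)
}

.STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Quality-control one reference segment
#'
#' Scans a segment for premature stop codons in a given reading frame, a
#' frame-incompatible length (constant regions only), ambiguous bases, and
#' a too-short sequence. An empty flag table means the segment is clean.
#'
#' Flag codes:
#' \describe{
#'   \item{PREMATURE_STOP}{an in-frame TAA/TAG/TGA codon before the last
#'     complete codon of the frame (a terminal stop is normal for a
#'     constant region and is not flagged). `position` is the 0-based
#'     codon start.}
#'   \item{FRAME_LENGTH}{for C-REGION records, `(length - frame_offset)`
#'     is not a multiple of 3 (a frameshift relative to the annotated
#'     length), unless the record is declared `partial`.}
#'   \item{AMBIGUOUS_BASE}{an `N` base; one flag per position.}
#'   \item{TOO_SHORT}{sequence shorter than `min_length`.}
#' }
#'
#' @param record A single-row data.frame (one row of
#'   `ReferenceSet$records`) or a list with elements `sequence` and
#'   optionally `region` and `allele`.
#' @param frame_offset Reading-frame offset, 0, 1 or 2. For a constant
#'   region this is the frame implied by the upstream J junction; 0 by
#'   default.
#' @param min_length Minimum acceptable segment length in nt (default 30).
#' @param partial Logical; if `TRUE` the record is treated as a partial
#'   segment and the FRAME_LENGTH check is skipped.
#' @return data.frame with columns `code`, `position` (0-based, `NA` where
#'   not applicable) and `detail`.
#' @examples
#' qc_segment(list(sequence = "ATGTAAGGGCCC", region = "C-REGION"), 0)
#' @export
qc_segment <- function(record, frame_offset = 0L, min_length = 30L,
                       partial = FALSE) {
  if (!frame_offset %in% 0:2) {
    stop("frame_offset must be 0, 1 or 2", call. = FALSE)
  }
  s <- toupper(record$sequence)
  if (is.null(s) || length(s) != 1 || is.na(s) || nchar(s) == 0) {
    stop("record has no sequence", call. = FALSE)
  }
  region <- if (!is.null(record$region)) record$region else "other"
  n <- nchar(s)
  flags <- data.frame(code = character(), position = integer(),
                      detail = character(), stringsAsFactors = FALSE)
  add <- function(code, position, detail) {
    rbind(flags, data.frame(code = code, position = as.integer(position),
                            detail = detail, stringsAsFactors = FALSE))
  }

  # premature stops: walk complete codons from frame_offset; the last
  # complete codon is the terminal one and a stop there is not premature
  starts <- seq.int(frame_offset + 1L, by = 3L,
                    length.out = max(0L, (n - frame_offset) %/% 3L))
  if (length(starts) > 0) {
    codons <- substring(s, starts, starts + 2L)
    is_stop <- codons %in% .STOP_CODONS
    is_stop[length(is_stop)] <- FALSE   # terminal codon
    for (k in which(is_stop)) {
      flags <- add("PREMATURE_STOP", starts[k] - 1L,
                   sprintf("stop codon %s at codon %d", codons[k], k))
    }
  }

  if (identical(region, "C-REGION") && !partial &&
      (n - frame_offset) %% 3L != 0L) {
    flags <- add("FRAME_LENGTH", NA_integer_,
                 sprintf("(length %d - frame %d) %%%% 3 = %d",
                         n, frame_offset, (n - frame_offset) %% 3L))
  }

  npos <- gregexpr("N", s, fixed = TRUE)[[1]]
  if (npos[1] != -1) {
    for (p in npos) flags <- add("AMBIGUOUS_BASE", p - 1L, "ambiguous base N")
  }

  if (n < min_length) {
    flags <- add("TOO_SHORT", NA_integer_,
                 sprintf("length %d < minimum %d", n, min_length))
  }
  flags
}

#' QC every segment of a ReferenceSet
#'
#' @param ref A `ReferenceSet`.
#' @param frame_offset Either a single frame offset applied to every
#'   record, or a named vector keyed by region type (e.g.
#'   `c("C-REGION" = 0)`); regions not named default to 0.
#' @param min_length Minimum segment length (see [qc_segment()]).
#' @return data.frame with one row per flag: `record_id`, `allele`,
#'   `code`, `position`, `detail`. Suitable for writing as a TSV QC
#'   report. Zero rows means the whole set is clean.
#' @export
qc_reference <- function(ref, frame_offset = 0L, min_length = 30L) {
  stopifnot(inherits(ref, "ReferenceSet"))
  out <- lapply(seq_len(nrow(ref$records)), function(i) {
    rec <- ref$records[i, ]
    fo <- .frame_for(rec$region, frame_offset)
    fl <- qc_segment(rec, frame_offset = fo, min_length = min_length)
    if (nrow(fl) == 0) return(NULL)
    cbind(data.frame(record_id = rec$record_id, allele = rec$allele,
                     stringsAsFactors = FALSE), fl)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(record_id = integer(), allele = character(),
                      code = character(), position = integer(),
                      detail = character(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

.frame_for <- function(region, frame_offset) {
  if (length(frame_offset) == 1 && is.null(names(frame_offset))) {
    return(as.integer(frame_offset))
  }
  if (region %in% names(frame_offset)) {
    return(as.integer(frame_offset[[region]]))
  }
  0L
}

#' Filter a ReferenceSet on QC flags
#'
#' Partitions the set into kept and removed segments. A segment is removed
#' iff it carries at least one flag whose code is in `removal_codes`;
#' order is preserved and `kept` plus `removed` is always the input.
#'
#' @param ref A `ReferenceSet`.
#' @param removal_codes Flag codes that trigger removal. The default
#'   removes segments with premature stop codons or frameshift-length
#'   problems; ambiguous bases and short segments warn only.
#' @inheritParams qc_reference
#' @return list with `kept` (a `ReferenceSet`), `removed` (data.frame of
#'   removed records), and `removed_flags` (the flags of removed records).
#' @export
filter_reference <- function(ref,
                             removal_codes = c("PREMATURE_STOP", "FRAME_LENGTH"),
                             frame_offset = 0L, min_length = 30L) {
  stopifnot(inherits(ref, "ReferenceSet"))
  flags <- qc_reference(ref, frame_offset = frame_offset,
                        min_length = min_length)
  bad_ids <- unique(flags$record_id[flags$code %in% removal_codes])
  keep <- !(ref$records$record_id %in% bad_ids)
  kept <- ref
  kept$records <- ref$records[keep, , drop = FALSE]
  rownames(kept$records) <- NULL
  removed <- ref$records[!keep, , drop = FALSE]
  rownames(removed) <- NULL
  list(kept = kept, removed = removed,
       removed_flags = flags[flags$record_id %in% bad_ids, , drop = FALSE])
}
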