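# Independent brute-force oracles. These deliberately use plain loops and
# direct formula transcription, and never call the package functions they
# are used to check.

oracle_shannon <- function(x) {
  x <- x[x > 0]
  N <- sum(x)
  S <- length(x)
  H <- 0
  plogp2 <- 0
  for (xi in x) {
    p <- xi / N
    H <- H - p * log(p)
    plogp2 <- plogp2 + p * log(p)^2
  }
  list(H = H, varH = (plogp2 - H^2) / N + (S - 1) / (2 * N^2), N = N, S = S)
}

oracle_hutcheson <- function(x1, x2) {
  a <- oracle_shannon(x1)
  b <- oracle_shannon(x2)
  t <- (a$H - b$H) / sqrt(a$varH + b$varH)
  df <- max((a$varH + b$varH)^2 / (a$varH^2 / a$N + b$varH^2 / b$N), 1)
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

oracle_morisita <- function(x, y) {
  nx <- sum(x)
  ny <- sum(y)
  cross <- 0
  lx <- 0
  ly <- 0
  for (i in seq_along(x)) {
    cross <- cross + x[i] * y[i]
    lx <- lx + x[i] * (x[i] - 1)
    ly <- ly + y[i] * (y[i] - 1)
  }
  lx <- lx / (nx * (nx - 1))
  ly <- ly / (ny * (ny - 1))
  2 * cross / ((lx + ly) * nx * ny)
}

revcomp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# naive O(n*m) sliding-window Hamming scan on both strands
oracle_primer_sites <- function(primer, sequence, max_mismatch = 0) {
  out <- NULL
  for (strand in c("sense", "antisense")) {
    pat <- if (strand == "sense") primer else revcomp(primer)
    pv <- strsplit(pat, "")[[1]]
    sv <- strsplit(sequence, "")[[1]]
    m <- length(pv)
    if (length(sv) >= m) {
      for (i in seq_len(length(sv) - m + 1)) {
        mm <- sum(sv[i:(i + m - 1)] != pv)
        if (mm <= max_mismatch) {
          out <- rbind(out, data.frame(start = i - 1L, end = i + m - 1L,
                                       strand = strand, mismatches = mm,
                                       stringsAsFactors = FALSE))
        }
      }
    }
  }
  if (is.null(out)) {
    out <- data.frame(start = integer(), end = integer(),
                      strand = character(), mismatches = integer(),
                      stringsAsFactors = FALSE)
  }
  out[order(out$start, out$strand), , drop = FALSE]
}

random_count_pair <- function(n_labels = 30, max_count = 40) {
  list(x = rpois(n_labels, runif(1, 0.5, max_count / 2)) +
         rbinom(n_labels, 1, 0.5),
       y = rpois(n_labels, runif(1, 0.5, max_count / 2)) +
         rbinom(n_labels, 1, 0.5))
}

# small in-memory contig table builder for hand-constructed cases
make_contigs <- function(barcode, chain, cdr3_nt, umis = 1,
                         productive = TRUE, full_length = TRUE,
                         contig_id = NULL, sample_id = "s1") {
  n <- length(barcode)
  if (is.null(contig_id)) contig_id <- sprintf("ctg%03d", seq_len(n))
  df <- data.frame(barcode = barcode, contig_id = contig_id, chain = chain,
                   v_gene = NA_character_, d_gene = NA_character_,
                   j_gene = NA_character_, c_gene = NA_character_,
                   cdr3 = NA_character_, cdr3_nt = cdr3_nt,
                   full_length = rep_len(full_length, n),
                   productive = rep_len(productive, n),
                   umis = rep_len(as.integer(umis), n),
                   reads = rep_len(10L, n), stringsAsFactors = FALSE)
  attr(df, "sample_id") <- sample_id
  df
}

cregion_fixture_path <- function() {
  system.file("extdata", "rhesus_cregion_segments.fasta",
              package = "clonotrack")
}
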