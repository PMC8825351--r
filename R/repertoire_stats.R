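# Repertoire diversity and overlap statistics on clonotype count vectors.
# All logs are natural (H in nats): with thousands of clonotypes that is
# the scale on which observed single-sample diversities land in the 7-9
# range, and it is the convention of the R ecology packages.

#' Clonotype count vector for one sample
#'
#' @param ct A `ClonotypeTable`.
#' @param sample Sample id.
#' @return Named integer vector of clonotype cell counts.
#' @export
clonotype_counts <- function(ct, sample) {
  stopifnot(inherits(ct, "ClonotypeTable"))
  if (!sample %in% colnames(ct$counts)) {
    stop("sample not present: ", sample, call. = FALSE)
  }
  x <- ct$counts[, sample]
  names(x) <- rownames(ct$counts)
  x
}

#' Shannon diversity of a clonotype count vector
#'
#' With proportions `p_i = x_i / N` over the observed clonotypes,
#' `H = -sum(p_i log p_i)` (nats) and the large-sample variance estimate
#' `varH = (sum(p_i log(p_i)^2) - H^2) / N + (S - 1) / (2 N^2)`, where
#' `N` is the number of cells and `S` the number of observed clonotypes.
#' This is the variance the Hutcheson t-test is built on.
#'
#' @param x Nonnegative count vector (zeros are dropped).
#' @return list of class `diversity`: `H`, `varH`, `N`, `S`.
#' @examples
#' shannon_index(c(2, 1, 1))
#' @export
shannon_index <- function(x) {
  if (any(x < 0) || any(x != floor(x))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  x <- x[x > 0]
  N <- sum(x)
  if (N < 1) stop("count vector has no observations", call. = FALSE)
  p <- x / N
  S <- length(x)
  H <- -sum(p * log(p))
  varH <- (sum(p * log(p)^2) - H^2) / N + (S - 1) / (2 * N^2)
  structure(list(H = H, varH = max(varH, 0), N = N, S = S),
            class = "diversity")
}

#' @export
print.diversity <- function(x, ...) {
  cat(sprintf("Shannon H = %.4f nats (var %.3g), N = %d cells, S = %d clonotypes\n",
              x$H, x$varH, x$N, x$S))
  invisible(x)
}

#' Hutcheson t-test comparing two Shannon diversities
#'
#' Two-sided t-test of `H1 = H2` using the analytic variance estimates of
#' [shannon_index()]: `t = (H1 - H2) / sqrt(varH1 + varH2)` with
#' Welch-style effective degrees of freedom
#' `df = (varH1 + varH2)^2 / (varH1^2 / N1 + varH2^2 / N2)`, floored at 1.
#' The degenerate case of two identical diversities with zero variance
#' is defined as `t = 0, p = 1`.
#'
#' @param x1,x2 Nonnegative count vectors (each with `N >= 2` cells).
#' @return An `htest` object: statistic `t`, parameter `df`, `p.value`,
#'   and the two H estimates.
#' @examples
#' hutcheson_test(c(60, 10, 10, 10, 10), c(20, 20, 20, 20, 20))
#' @export
hutcheson_test <- function(x1, x2) {
  d1 <- shannon_index(x1)
  d2 <- shannon_index(x2)
  if (d1$N < 2 || d2$N < 2) {
    stop("each sample needs at least 2 cells", call. = FALSE)
  }
  v <- d1$varH + d2$varH
  if (v == 0) {
    t <- 0
    df <- Inf
    p <- 1
  } else {
    t <- (d1$H - d2$H) / sqrt(v)
    df <- v^2 / (d1$varH^2 / d1$N + d2$varH^2 / d2$N)
    df <- max(df, 1)
    p <- 2 * stats::pt(-abs(t), df)
  }
  structure(list(
    statistic = c(t = t), parameter = c(df = df), p.value = p,
    estimate = c(H1 = d1$H, H2 = d2$H),
    method = "Hutcheson t-test for two Shannon diversity indices",
    data.name = paste(deparse1(substitute(x1)), "vs",
                      deparse1(substitute(x2)))),
    class = "htest")
}

#' Morisita overlap index of two repertoires
#'
#' Classical Morisita similarity of two integer count vectors over a
#' shared clonotype label set:
#' `mi = 2 sum(x_i y_i) / ((lambda_x + lambda_y) Nx Ny)` with
#' `lambda_x = sum(x_i (x_i - 1)) / (Nx (Nx - 1))`. It is ~0 for disjoint
#' repertoires and ~1 (it can slightly exceed 1) for identical ones. When
#' both samples are all singletons the classical denominator vanishes and
#' the Horn variant (`lambda = sum((x_i / Nx)^2)`) is used instead,
#' flagged via the `variant` attribute. The Horn variant can also be
#' requested directly.
#'
#' If both vectors are named they are aligned on the union of their
#' names (missing labels count 0); unnamed vectors must be equal-length
#' and position-aligned.
#'
#' @param x,y Nonnegative integer count vectors, each with `N >= 2`.
#' @param variant `"classical"` (default) or `"horn"`.
#' @return Numeric overlap index with attribute `variant`.
#' @examples
#' morisita(c(a = 2, b = 2), c(a = 2, b = 2))  # 1.5
#' @export
morisita <- function(x, y, variant = c("classical", "horn")) {
  variant <- match.arg(variant)
  if (!is.null(names(x)) && !is.null(names(y))) {
    labels <- union(names(x), names(y))
    xx <- ifelse(is.na(match(labels, names(x))), 0, x[match(labels, names(x))])
    yy <- ifelse(is.na(match(labels, names(y))), 0, y[match(labels, names(y))])
    x <- xx
    y <- yy
  } else if (length(x) != length(y)) {
    stop("unnamed count vectors must have equal length", call. = FALSE)
  }
  if (any(x < 0) || any(y < 0)) stop("negative counts", call. = FALSE)
  nx <- sum(x)
  ny <- sum(y)
  if (nx < 2 || ny < 2) {
    stop("each sample needs at least 2 cells", call. = FALSE)
  }
  cross <- sum(x * y)
  if (variant == "classical") {
    lx <- sum(x * (x - 1)) / (nx * (nx - 1))
    ly <- sum(y * (y - 1)) / (ny * (ny - 1))
    if (lx + ly > 0) {
      return(structure(2 * cross / ((lx + ly) * nx * ny),
                       variant = "classical"))
    }
    # all-singleton samples: fall through to the Horn estimator
  }
  lx <- sum((x / nx)^2)
  ly <- sum((y / ny)^2)
  structure(2 * cross / ((lx + ly) * nx * ny), variant = "horn")
}

#' Pairwise Morisita overlap matrix
#'
#' Computes the symmetric sample-by-sample overlap matrix (the heatmap
#' matrix), aligning all samples on the union of clonotype keys. The
#' diagonal is each sample against itself.
#'
#' @param samples A multi-sample `ClonotypeTable`, or a named list of
#'   named count vectors.
#' @param variant Passed to [morisita()].
#' @return Symmetric numeric matrix with sample ids as dimnames.
#' @export
pairwise_overlap <- function(samples, variant = c("classical", "horn")) {
  variant <- match.arg(variant)
  if (inherits(samples, "ClonotypeTable")) {
    m <- samples$counts
  } else {
    labels <- sort(unique(unlist(lapply(samples, names))))
    m <- vapply(samples, function(x) {
      v <- numeric(length(labels))
      v[match(names(x), labels)] <- x
      v
    }, numeric(length(labels)))
    rownames(m) <- labels
  }
  ns <- ncol(m)
  if (ns < 2) stop("need at least 2 samples", call. = FALSE)
  out <- matrix(NA_real_, ns, ns, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(ns)) {
    for (j in i:ns) {
      mi <- as.numeric(morisita(m[, i], m[, j], variant = variant))
      out[i, j] <- mi
      out[j, i] <- mi
    }
  }
  out
}
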