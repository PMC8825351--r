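toy_gex <- function(m, genes = NULL, barcodes = NULL) {
  if (is.null(genes)) genes <- sprintf("G%d", seq_len(ncol(m)))
  if (is.null(barcodes)) barcodes <- sprintf("BC%d", seq_len(nrow(m)))
  gex_matrix(m, barcodes, genes)
}

test_that("cell thresholds are closed intervals except the strict mito bound", {
  # 20 base cells comfortably inside every threshold; gene filter disabled
  set.seed(1)
  base <- matrix(rpois(20 * 600, 5), nrow = 20)
  thr <- qc_thresholds(min_cells_per_gene = 0)
  genes <- c("MT-1", sprintf("G%d", 1:599))

  # a cell with 400 genes detected is removed (below 500)
  low <- rep(0, 600); low[1:400] <- 5
  g <- toy_gex(rbind(base, low), genes = genes)
  f <- qc_filter(g, thr)
  expect_false("BC21" %in% f$barcodes)
  expect_equal(attr(f, "qc_log")$cells_removed[["low_genes"]], 1)

  # mito fraction exactly at the bound is removed ("less than 5%" strict);
  # exact integer construction: 1 mito of 20 counts = 0.05
  thr2 <- qc_thresholds(min_cells_per_gene = 0, min_genes = 1,
                        min_counts = 1)
  m <- rbind(c(0, 19), c(1, 19), c(0, 20))
  g2 <- toy_gex(m, genes = c("MT-1", "G1"))
  expect_equal(g2$meta$mito_frac[2], 0.05)
  f2 <- qc_filter(g2, thr2)
  expect_identical(f2$barcodes, c("BC1", "BC3"))
  expect_equal(attr(f2, "qc_log")$cells_removed[["high_mito"]], 1)
})

test_that("the gene filter runs first and all-removed is an informative error", {
  m <- rbind(matrix(5, 6, 4), matrix(c(1, 0, 0, 0), 1))
  g <- toy_gex(m)
  f <- qc_filter(g, qc_thresholds(min_cells_per_gene = 2, min_genes = 1,
                                  min_counts = 1))
  expect_equal(attr(f, "qc_log")$genes_removed, 0)
  m2 <- matrix(c(5, 5, 0, 5, 5, 0, 1, 1, 1), 3, byrow = TRUE)
  f2 <- qc_filter(toy_gex(m2), qc_thresholds(min_cells_per_gene = 3,
                                             min_genes = 1, min_counts = 1))
  expect_equal(attr(f2, "qc_log")$genes_removed, 1)
  expect_equal(f2$genes, c("G1", "G2"))
  expect_error(qc_filter(toy_gex(matrix(1, 2, 2))),
               "per-criterion tally")
})

test_that("QC removes exactly the planted outliers and is idempotent", {
  cfg <- sim_config(seed = 5, n_outliers = 100)
  labels <- data.frame(barcode = sprintf("BC%04d-1", 1:900),
                       label = rep(c("MLR_plus", "MLR_minus"),
                                   length.out = 900))
  sim <- simulate_gex(labels, cfg)
  f <- qc_filter(sim$gex)
  removed <- setdiff(sim$gex$barcodes, f$barcodes)
  expect_setequal(removed, sim$truth$outliers$barcode)
  expect_equal(attr(f, "qc_log")$cells_removed_total, 100)
  # independent boolean-mask recomputation of the survivor count
  dense <- as.matrix(sim$gex$counts)
  keep_gene <- colSums(dense > 0) >= 5
  d2 <- dense[, keep_gene]
  mito <- grepl("^MT-", colnames(d2))
  tot <- rowSums(d2)
  mask <- rowSums(d2 > 0) >= 500 & rowSums(d2 > 0) <= 6000 &
    tot >= 1800 & tot <= 40000 & rowSums(d2[, mito]) / tot < 0.05
  expect_equal(length(f$barcodes), sum(mask))
  # idempotence on the cell dimension after the gene filter settles
  f2 <- qc_filter(f)
  f3 <- qc_filter(f2)
  expect_identical(f3$barcodes, f2$barcodes)
  expect_identical(f3$genes, f2$genes)
  expect_equal(attr(f2, "qc_log")$cells_removed_total, 0)
})

test_that("log-CP10K normalization matches its formula and invariances", {
  m <- matrix(c(0, 10, 0, 0,
                5, 5, 5, 5), nrow = 2, byrow = TRUE)
  g <- toy_gex(m)
  norm <- normalize_gex(g)
  expect_equal(norm$mat[1, 2], log(1 + 10000))
  # doubling a cell's counts leaves its normalized vector unchanged
  g2 <- toy_gex(rbind(m[1, ] * 2, m[2, ]))
  expect_equal(as.matrix(normalize_gex(g2)$mat)[1, ],
               as.matrix(norm$mat)[1, ])
  expect_error(normalize_gex(toy_gex(rbind(c(0, 0), c(1, 1)))),
               "zero-count")
  expect_equal(norm$method, "logcp10k")
})

test_that("normalization equals a dense recomputation", {
  cfg <- sim_config(seed = 44, n_genes = 80, signature_genes = character(0))
  sim <- simulate_gex(data.frame(barcode = sprintf("B%d", 1:60),
                                 label = "MLR_minus"), cfg)
  norm <- normalize_gex(sim$gex)
  dense <- as.matrix(sim$gex$counts)
  want <- log1p(dense / rowSums(dense) * 1e4)
  expect_equal(as.matrix(norm$mat), want, tolerance = 1e-10,
               ignore_attr = TRUE)
  # Pearson variant is recorded and has zero row-correlation with totals
  pr <- normalize_gex(sim$gex, method = "pearson")
  expect_equal(pr$method, "pearson")
  expect_equal(dim(pr$mat), dim(dense))
})

test_that("Wilcoxon DE is null on duplicated groups and honors adjustments", {
  cfg <- sim_config(seed = 3, n_genes = 50, signature_genes = character(0))
  sim <- simulate_gex(data.frame(barcode = sprintf("B%d", 1:40),
                                 label = "MLR_minus"), cfg)
  norm <- normalize_gex(sim$gex)
  # same cells in both groups -> all fold changes exactly 0
  labels <- rep(c("MLR_plus", "MLR_minus"), each = 20)
  norm_dup <- norm
  norm_dup$mat <- rbind(norm$mat[1:20, ], norm$mat[1:20, ])
  norm_dup$barcodes <- sprintf("B%d", 1:40)
  de <- wilcoxon_de(norm_dup, labels)
  expect_true(all(de$log2_fc == 0))
  expect_true(all(de$p_adj >= de$p))
  expect_equal(de$p_adj, pmin(1, de$p * nrow(de)))
  de_bh <- wilcoxon_de(norm_dup, labels, adjust = "BH")
  expect_true(all(de_bh$p_adj >= de_bh$p))
  expect_error(wilcoxon_de(norm, rep(c("MLR_plus", "MLR_minus"),
                                     c(2, 38))), ">= 3 cells")
})

test_that("a planted up-regulated gene is recovered and top-ranked", {
  cfg <- sim_config(seed = 23, n_genes = 300, planted_effect = 2.5)
  labels <- data.frame(barcode = sprintf("B%04d", 1:1000),
                       label = rep(c("MLR_plus", "MLR_minus"), each = 500))
  sim <- simulate_gex(labels, cfg)
  de <- wilcoxon_de(normalize_gex(sim$gex),
                    stats::setNames(labels$label, labels$barcode))
  top <- de$gene[order(de$p)][1]
  expect_equal(top, "GZMB")
  expect_true(de$significant[de$gene == "GZMB"])
  expect_gt(de$log2_fc[de$gene == "GZMB"], 0)
})

test_that("GMT files round-trip with signed gene sets", {
  sigs <- list(
    up_down = list(name = "up_down", description = "signed",
                   pos = c("A", "B"), neg = c("C")),
    plain = list(name = "plain", description = "", pos = c("D", "E"),
                 neg = character()))
  tf <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sigs, tf)
  back <- read_gmt(tf)
  expect_equal(back$up_down$pos, c("A", "B"))
  expect_equal(back$up_down$neg, "C")
  expect_equal(back$plain$pos, c("D", "E"))
  expect_error(read_gmt(withr::local_tempfile(lines = "just_a_name")),
               "malformed GMT")
})

test_that("signature scores vanish on constant data and flip with sign swap", {
  g <- toy_gex(matrix(3, 10, 4))
  norm <- normalize_gex(g)
  sc <- signature_score(norm, c("G1", "G2"))
  expect_true(all(sc$score == 0))

  set.seed(10)
  g2 <- toy_gex(matrix(rpois(200, 5) + 1, 20, 10))
  n2 <- normalize_gex(g2)
  sig <- list(name = "s", pos = c("G1", "G3"), neg = c("G5"))
  swapped <- list(name = "s", pos = c("G5"), neg = c("G1", "G3"))
  expect_equal(signature_score(n2, sig)$score,
               -signature_score(n2, swapped)$score)
  # gene order permutation and absent genes change nothing
  perm <- list(name = "s", pos = c("G3", "G1"), neg = c("G5"))
  with_absent <- list(name = "s", pos = c("G1", "G3", "NOT_A_GENE"),
                      neg = c("G5"))
  expect_equal(signature_score(n2, perm)$score,
               signature_score(n2, sig)$score)
  expect_equal(signature_score(n2, with_absent)$score,
               signature_score(n2, sig)$score)
  expect_equal(attr(signature_score(n2, with_absent), "missing_genes"), 1)
  expect_error(signature_score(n2, c("NOPE1", "NOPE2")), "no signature gene")
})

test_that("score comparisons behave at the null and at extreme separation", {
  set.seed(8)
  # identical score sets in both groups: the rank statistic is central
  s <- rep(rnorm(30), 2)
  labels <- rep(c("MLR_plus", "MLR_minus"), each = 30)
  expect_gt(compare_scores(s, labels)$p.value, 0.5)
  sep <- c(rnorm(30, 10), rnorm(30, 0))
  expect_lt(compare_scores(sep, rep(c("MLR_plus", "MLR_minus"),
                                    each = 30))$p.value, 1e-9)
  expect_error(compare_scores(s, rep("MLR_plus", 60)), "non-empty")
})

test_that("planted signature shifts are detected between MLR groups", {
  cfg <- sim_config(seed = 61)
  labels <- data.frame(barcode = sprintf("B%04d", 1:600),
                       label = rep(c("MLR_plus", "MLR_minus"), each = 300))
  sim <- simulate_gex(labels, cfg)
  norm <- normalize_gex(sim$gex)
  sig <- list(name = "planted", pos = sim$truth$signature_genes,
              neg = character())
  sc <- signature_score(norm, sig,
                        labels = stats::setNames(labels$label,
                                                 labels$barcode))
  expect_gt(mean(sc$score[sc$label == "MLR_plus"]),
            mean(sc$score[sc$label == "MLR_minus"]))
  expect_lt(compare_scores(sc)$p.value, 0.05)
})
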