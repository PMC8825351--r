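test_that("config validation rejects impossible study designs", {
  expect_error(sim_config(expansion = c(ctv_high = 2, ctv_mid = 1,
                                        ctv_low = 50)), "ordered")
  expect_error(sim_config(expansion = c(ctv_high = 0.5, ctv_mid = 1,
                                        ctv_low = 2)), ">= 1")
  expect_error(sim_config(nb_dispersion = 0), "nb_dispersion")
  rep0 <- sample_repertoire(sim_config(allo_fraction = 0, n_clones = 50,
                                       n_cells = 50))
  expect_error(simulate_mlr(rep0, sim_config(allo_fraction = 0,
                                             n_clones = 50, n_cells = 50)),
               "nothing to expand")
})

test_that("the generator is deterministic given its seed", {
  cfg <- sim_config(seed = 99, n_clones = 150, n_cells = 300)
  r1 <- sample_repertoire(cfg)
  r2 <- sample_repertoire(cfg)
  expect_identical(r1, r2)
  m1 <- simulate_mlr(r1, cfg)
  m2 <- simulate_mlr(r2, cfg)
  expect_identical(m1$samples, m2$samples)
  # byte-identical emitted files
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  emit_contig_csv(m1$samples$blood, r1, cfg, "blood", path = f1)
  emit_contig_csv(m2$samples$blood, r2, cfg, "blood", path = f2)
  expect_identical(readLines(f1), readLines(f2))
  g1 <- simulate_gex(data.frame(barcode = m1$samples$blood$barcode[1:50],
                                label = "MLR_minus"), cfg)
  g2 <- simulate_gex(data.frame(barcode = m2$samples$blood$barcode[1:50],
                                label = "MLR_minus"), cfg)
  expect_identical(as.matrix(g1$gex$counts), as.matrix(g2$gex$counts))
})

test_that("repertoire frequencies are normalized with unique CDR3s", {
  cfg <- sim_config(seed = 2, n_clones = 500)
  rep <- sample_repertoire(cfg)
  expect_equal(sum(rep$freq), 1)
  expect_false(anyDuplicated(rep$alpha_cdr3_nt) > 0)
  expect_false(anyDuplicated(rep$beta_cdr3_nt) > 0)
  expect_true(all(nchar(rep$alpha_cdr3_nt) %% 3 == 0))
  # translations start with the canonical cysteine
  expect_true(all(startsWith(rep$alpha_cdr3_aa, "C")))
})

test_that("a near-flat Dirichlet concentrates to uniform frequencies", {
  cfg <- sim_config(seed = 3, n_clones = 100, clone_dist = "dirichlet",
                    dirichlet_alpha = 1e6)
  rep <- sample_repertoire(cfg)
  expect_lt(max(rep$freq) / min(rep$freq), 1.2)
})

test_that("sampled diversity underestimates analytic H and converges", {
  cfg <- sim_config(seed = 4, n_clones = 5000, lognormal_sigma = 1.5)
  rep <- sample_repertoire(cfg)
  H_analytic <- -sum(rep$freq * log(rep$freq))
  set.seed(5)
  small <- as.vector(stats::rmultinom(1, 5000, rep$freq))
  big <- as.vector(stats::rmultinom(1, 100000, rep$freq))
  expect_lt(shannon_index(small[small > 0])$H, H_analytic)
  expect_lt(abs(shannon_index(big[big > 0])$H - H_analytic), 0.1)
})

test_that("without expansion the fractions are exchangeable blood draws", {
  ok <- 0
  for (s in 1:5) {
    cfg <- sim_config(seed = s, n_clones = 1000, n_cells = 3000,
                      expansion = c(ctv_high = 1, ctv_mid = 1, ctv_low = 1))
    mlr <- simulate_mlr(sample_repertoire(cfg), cfg)
    sizes_high <- as.integer(table(mlr$samples$ctv_high$clone_id))
    sizes_low <- as.integer(table(mlr$samples$ctv_low$clone_id))
    p <- suppressWarnings(stats::ks.test(sizes_high, sizes_low)$p.value)
    ok <- ok + (p > 0.01)
  }
  expect_gte(ok, 4)
})

test_that("sample sizes are conserved and dropout keeps cells", {
  cfg <- sim_config(seed = 6, n_clones = 300, n_cells = 1234,
                    p_alpha = 0.3, p_beta = 0.4)
  rep <- sample_repertoire(cfg)
  mlr <- simulate_mlr(rep, cfg)
  for (s in mlr$samples) expect_equal(nrow(s), 1234)
  contigs <- emit_contig_csv(mlr$samples$blood, rep, cfg, "blood")
  # every emitted barcode belongs to the sample; the sample table itself
  # never loses cells to dropout
  expect_true(all(contigs$barcode %in% mlr$samples$blood$barcode))
  expect_equal(nrow(mlr$samples$blood), cfg$n_cells)
})

test_that("extreme dropout settings hit their closed-form rates", {
  cfg1 <- sim_config(seed = 7, n_clones = 100, n_cells = 500,
                     p_alpha = 1, p_beta = 1, corrupt_frac = 0)
  rep <- sample_repertoire(cfg1)
  mlr <- simulate_mlr(rep, cfg1)
  cs <- chain_summary(emit_contig_csv(mlr$samples$blood, rep, cfg1, "b"))
  expect_equal(cs$pct_cdr3_alpha, 100)
  expect_equal(cs$pct_cdr3_beta, 100)
  expect_equal(cs$pct_productive_pair, 100)

  cfg2 <- sim_config(seed = 7, n_clones = 100, n_cells = 500,
                     p_alpha = 0, p_beta = 1)
  mlr2 <- simulate_mlr(rep, cfg2)
  cs2 <- chain_summary(emit_contig_csv(mlr2$samples$blood, rep, cfg2, "b"))
  expect_equal(cs2$pct_cdr3_alpha, 0)
  expect_equal(cs2$pct_productive_pair, 0)
})

test_that("corrupt contigs lose their productive and full-length flags", {
  cfg <- sim_config(seed = 13, n_clones = 100, n_cells = 2000,
                    p_alpha = 1, p_beta = 1, corrupt_frac = 0.3)
  rep <- sample_repertoire(cfg)
  mlr <- simulate_mlr(rep, cfg)
  contigs <- emit_contig_csv(mlr$samples$blood, rep, cfg, "b")
  frac_bad <- mean(!contigs$productive)
  expect_lt(abs(frac_bad - 0.3), 0.03)
  expect_identical(contigs$productive, contigs$full_length)
})

test_that("tissue samples seed a subset of the alloreactive clones", {
  cfg <- sim_config(seed = 9, n_clones = 1000, n_cells = 1000,
                    allo_fraction = 0.02)
  rep <- sample_repertoire(cfg)
  mlr <- simulate_mlr(rep, cfg)
  tis <- simulate_tissue(rep, mlr$truth$allo_clones, n_cells = 800,
                         n_allo_cells = 60, allo_subset = 0.5, seed = 10)
  expect_equal(nrow(tis), 800)
  expect_equal(sum(tis$is_allo), 60)
  seeded <- attr(tis, "seeded_clones")
  expect_true(all(seeded %in% mlr$truth$allo_clones))
  expect_equal(length(seeded), 10)
  expect_true(all(tis$clone_id[tis$is_allo] %in% seeded))
})

test_that("null expression simulations stay null through the DE pipeline", {
  cfg <- sim_config(seed = 15, n_genes = 200, planted_effect = 1,
                    signature_effect = 1)
  labels <- data.frame(barcode = sprintf("B%03d", 1:200),
                       label = rep(c("MLR_plus", "MLR_minus"), each = 100))
  sim <- simulate_gex(labels, cfg)
  de <- wilcoxon_de(normalize_gex(sim$gex),
                    stats::setNames(labels$label, labels$barcode))
  expect_lte(mean(de$significant), 0.05)
})

test_that("the full pipeline recovers every planted truth end to end", {
  cfg <- sim_config(seed = 17, n_clones = 800, n_cells = 2000,
                    allo_fraction = 0.01, p_alpha = 0.8, p_beta = 0.95)
  rep <- sample_repertoire(cfg)
  mlr <- simulate_mlr(rep, cfg)

  # contigs -> clonotypes: planted allo clones among CTV-Low expansions
  low <- assign_clonotypes(
    emit_contig_csv(mlr$samples$ctv_low, rep, cfg, "ctv_low"),
    mode = "paired_nt")
  truth_keys <- clone_keys(rep, mlr$truth$allo_clones, mode = "paired_nt")

  # tissue tagging recovers the planted set exactly
  tis <- simulate_tissue(rep, mlr$truth$allo_clones, n_cells = 900,
                         n_allo_cells = 120, seed = 18)
  tis_contigs <- emit_contig_csv(tis, rep,
                                 sim_config(seed = 17, p_alpha = 1,
                                            p_beta = 1), "liver")
  tags <- tag_alloreactive(tis_contigs, truth_keys, mode = "paired_nt")
  truth_lab <- tis$is_allo[match(tags$barcode, tis$barcode)]
  expect_identical(tags$label == "MLR_plus", truth_lab)

  # QC -> DE -> scores on the tagged cells
  glabels <- data.frame(barcode = tags$barcode,
                        label = tags$label, stringsAsFactors = FALSE)
  sim <- simulate_gex(glabels, cfg)
  norm <- normalize_gex(qc_filter(sim$gex))
  de <- wilcoxon_de(norm, stats::setNames(glabels$label, glabels$barcode))
  expect_true(de$significant[de$gene == "GZMB"])
  sc <- signature_score(norm, list(name = "ctl",
                                   pos = sim$truth$signature_genes,
                                   neg = character()),
                        labels = stats::setNames(glabels$label,
                                                 glabels$barcode))
  expect_lt(compare_scores(sc)$p.value, 0.05)
})
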