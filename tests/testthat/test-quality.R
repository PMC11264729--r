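test_that("screen ROC reproduces pairwise-concordance examples", {
  sets <- gene_sets(essential = c("e1", "e2"),
                    nonessential = c("n1", "n2", "n3"))
  perfect <- c(e1 = -3, e2 = -2, n1 = 0, n2 = 1, n3 = 2)
  expect_equal(screen_roc(perfect, sets)$auroc, 1.0)
  expect_equal(screen_roc(-perfect, sets)$auroc, 0.0)
  mixed <- c(e1 = -3, e2 = -1, n1 = -2, n2 = 0, n3 = 1)
  expect_equal(screen_roc(mixed, sets)$auroc, 5 / 6, tolerance = 1e-12)
  expect_equal(screen_roc(perfect, sets)$auprc, 1.0, tolerance = 1e-12)
})

test_that("AUROC equals brute-force concordance on tie-free inputs", {
  set.seed(71)
  for (i in 1:20) {
    nE <- sample(5:80, 1); nN <- sample(5:120, 1)
    genes <- sprintf("g%03d", seq_len(nE + nN))
    lfc <- setNames(rnorm(nE + nN), genes)
    sets <- gene_sets(essential = genes[1:nE],
                      nonessential = genes[(nE + 1):(nE + nN)])
    expect_equal(screen_roc(lfc, sets)$auroc,
                 auroc_brute(lfc[1:nE], lfc[(nE + 1):(nE + nN)]),
                 tolerance = 1e-12)
  }
})

test_that("NNMD matches direct evaluation and is shift-equivariant", {
  expect_equal(nnmd(c(-2.2, -2.0, -1.8), c(0.1, -0.1, 0.0)), -20,
               tolerance = 1e-12)
  x <- rnorm(50); y <- rnorm(80)
  expect_equal(nnmd(x, x), 0)
  base <- nnmd(x, y)
  expect_equal(nnmd(x + 3, y + 3), base, tolerance = 1e-12)
  # moving essentials down by delta changes NNMD by -delta / MAD(N) exactly
  delta <- 0.7
  expect_equal(nnmd(x - delta, y) - base, -delta / mad(y, constant = 1),
               tolerance = 1e-12)
  expect_error(nnmd(x, rep(1, 10)), "MAD")
  # scaled variant differs by the consistency constant
  expect_equal(nnmd(x, y, scaled_mad = TRUE) * 1.4826, base, tolerance = 1e-9)
})

test_that("recall at fixed FDR finds the deepest rank meeting the precision bar", {
  # ranked labels E,E,N,E,N,E,N,N: PPV drops below 0.95 after k = 2
  lfc <- setNames(1:8, c("e1", "e2", "n1", "e3", "n2", "e4", "n3", "n4"))
  sets <- gene_sets(essential = paste0("e", 1:4),
                    nonessential = paste0("n", 1:4))
  res <- recall_at_fdr(lfc, sets)
  expect_identical(res$k_star, 2L)
  expect_equal(res$lfc_star, 2)
  expect_equal(unname(res$recalls["essential"]), 0.5)
  expect_equal(unname(res$recalls["nonessential"]), 0)
  # perfect separation recovers everything at 5% FDR
  perfect <- setNames(c(-4, -3, -2, -1, 1, 2, 3, 4), names(lfc)[c(1, 2, 4, 6, 3, 5, 7, 8)])
  resp <- recall_at_fdr(perfect, sets)
  expect_equal(unname(resp$recalls["essential"]), 1.0)
  expect_equal(unname(resp$recalls["nonessential"]), 0.0)
  # a target set disjoint from the sub-threshold genes recalls 0
  res2 <- recall_at_fdr(lfc, sets, target_sets = list(other = c("n3", "n4")))
  expect_equal(unname(res2$recalls["other"]), 0)
})

test_that("relaxing the precision threshold never decreases recall", {
  set.seed(73)
  genes <- sprintf("g%03d", 1:200)
  lfc <- setNames(c(rnorm(80, -1.5, 0.7), rnorm(120, 0, 0.7)), genes)
  sets <- gene_sets(essential = genes[1:80], nonessential = genes[81:200])
  thresholds <- c(0.99, 0.95, 0.9, 0.8)
  recs <- sapply(thresholds, function(t)
    recall_at_fdr(lfc, sets, ppv_threshold = t)$recalls["essential"])
  expect_true(all(diff(recs) >= 0))
})

test_that("oncogene-addiction ROC pools instances and counts concordance", {
  models <- sprintf("M%d", 1:5)
  scaled <- screen_matrix(
    matrix(c(-1.5, -0.1, -0.2, 0.0, 0.1), 1, 5,
           dimnames = list("ONC1", models)), scale_tag = "scaled")
  tpm <- matrix(c(10, 10, 0.2, 0.5, 0.1), 1, 5, dimnames = list("ONC1", models))
  om <- omics_profiles(cn = (tpm * 0) + 2, tpm = tpm)
  calls <- matrix(c(1, 1, 0, 0, 0), 1, 5, dimnames = list("ONC1", models))
  res <- oncogene_addiction_auroc(scaled, om, "ONC1", calls)
  expect_equal(res$auroc, 5 / 6, tolerance = 1e-12)
  expect_identical(res$n_positives, 2L + 0L)
  expect_identical(res$n_negatives, 3L)
  # refuses unscaled input
  raw <- screen_matrix(unclass(scaled))
  expect_error(oncogene_addiction_auroc(raw, om, "ONC1", calls), "scaled")
  # oncogene with no negative control is dropped -> empty pool errors
  calls2 <- calls; calls2[1, ] <- 1
  expect_error(oncogene_addiction_auroc(scaled, om, "ONC1", calls2), "empty")
})

test_that("randomly labelled addiction instances score near 0.5", {
  set.seed(79)
  vals <- replicate(20, {
    pos <- rnorm(300); neg <- rnorm(500)
    auroc_brute(pos, neg)
  })
  expect_equal(mean(vals), 0.5, tolerance = 0.03)
})

test_that("the vectorized t-scan matches stats::t.test and flags the clear hit", {
  models <- sprintf("M%d", 1:6)
  vals <- rbind(SSD1 = c(-1.0, -1.1, -0.9, 0.0, 0.1, -0.1),
                SSD2 = c(0.2, -0.1, 0.0, 0.1, -0.2, 0.05))
  colnames(vals) <- models
  lfc <- screen_matrix(vals, level = "gene")
  cfe <- cfe_catalog(matrix(c(1, 1, 1, 0, 0, 0), 1, 6,
                            dimnames = list("CFE1", models)),
                     setNames(rep("lung", 6), models),
                     setNames(rep("wild_type", 6), models))
  res <- biomarker_scan(lfc, cfe, c("SSD1", "SSD2"))
  hit <- res[res$gene == "SSD1", ]
  expect_equal(hit$t, -12.24745, tolerance = 1e-4)
  ref <- t.test(c(-1.0, -1.1, -0.9), c(0.0, 0.1, -0.1), var.equal = TRUE)
  expect_equal(hit$p, ref$p.value, tolerance = 1e-10)
  expect_true(hit$significant)
  expect_false(res$significant[res$gene == "SSD2"])
  expect_identical(attr(res, "n_tests"), 2L)
  # groups below the minimum size yield no tests
  cfe2 <- cfe
  cfe2$events[1, ] <- c(1, 0, 0, 0, 0, 0)
  expect_warning(res2 <- biomarker_scan(lfc, cfe2, c("SSD1", "SSD2")),
                 "no testable")
  expect_identical(nrow(res2), 0L)
})

test_that("Welch and pooled scans agree with their t.test counterparts", {
  set.seed(83)
  x1 <- matrix(rnorm(40, 0, 2), 4); x0 <- matrix(rnorm(60), 4)
  for (ve in c(TRUE, FALSE)) {
    ours <- screenbias:::row_t_tests(x1, x0, var_equal = ve)
    for (i in 1:4) {
      ref <- t.test(x1[i, ], x0[i, ], var.equal = ve)
      expect_equal(unname(ours$t[i]), unname(ref$statistic), tolerance = 1e-10)
      expect_equal(ours$p[i], ref$p.value, tolerance = 1e-10)
    }
  }
})

test_that("the per-screen quality summary stitches the metrics together", {
  b <- null_bundle(89, n_chromosomes = 2, genes_per_arm = 50, n_models = 6)
  q <- screen_quality_summary(b$lfc, b$sets)
  expect_identical(q$model, colnames(b$lfc))
  expect_true(all(q$auroc > 0.9))          # effect -1 vs noise 0.2 separates
  expect_true(all(q$nnmd < -3))
  expect_true(all(q$recall_essential >= 0.9))
  expect_true(all(q$recall_nonessential <= 0.1))
  expect_true("recall_msigdb_essential" %in% names(q))
})
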