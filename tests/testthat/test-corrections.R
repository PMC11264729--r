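test_that("arm-median alignment reproduces the hand-computed two-screen shift", {
  ann <- one_chrom_annotation(6, 0)
  genes <- sprintf("g%02d", 1:6)
  v <- cbind(A = c(0.1, 0.2, 0.3, 0.5, 0.6, 0.7),
             B = c(-0.5, -0.3, -0.2, -0.2, -0.1, 0.1))
  rownames(v) <- genes
  m <- screen_matrix(v)
  res <- ac_chronos_correct(m, ann)
  # medians 0.4 and -0.2, med over screens 0.1 -> shifts -0.3 / +0.3
  expect_equal(sort(res$state$shift), c(-0.3, 0.3))
  expect_equal(unclass(res$corrected)[, "A"], v[, "A"] - 0.3)
  expect_equal(unclass(res$corrected)[, "B"], v[, "B"] + 0.3)
  expect_equal(unname(apply(unclass(res$corrected), 2, median)), c(0.1, 0.1))
})

test_that("arms at or below the gene-count guard are untouched", {
  ann <- one_chrom_annotation(5, 0)
  v <- matrix(rnorm(10), 5, 2, dimnames = list(sprintf("g%02d", 1:5),
                                               c("A", "B")))
  res <- ac_chronos_correct(screen_matrix(v), ann)
  expect_equal(unclass(res$corrected)[, ], v)
  expect_identical(nrow(res$state), 0L)
})

test_that("single-screen arm alignment is the identity", {
  ann <- one_chrom_annotation(10, 10)
  v <- matrix(rnorm(20), 20, 1, dimnames = list(sprintf("g%02d", 1:20), "A"))
  res <- ac_chronos_correct(screen_matrix(v), ann)
  expect_equal(unclass(res$corrected)[, ], v[, ], tolerance = 1e-15)
})

test_that("arm alignment is idempotent and rank-preserving within (screen, arm)", {
  set.seed(5)
  ann <- one_chrom_annotation(12, 8)
  genes <- sprintf("g%02d", 1:20)
  v <- matrix(rnorm(20 * 6), 20, 6, dimnames = list(genes, sprintf("S%d", 1:6)))
  m <- screen_matrix(v)
  once <- ac_chronos_correct(m, ann)$corrected
  twice <- ac_chronos_correct(once, ann)$corrected
  expect_equal(unclass(twice)[, ], unclass(once)[, ], tolerance = 1e-12)
  for (arm_rows in list(1:12, 13:20)) {
    for (s in 1:6) {
      expect_identical(order(unclass(once)[arm_rows, s]),
                       order(v[arm_rows, s]))
    }
  }
})

test_that("arm alignment recovers a common base up to a per-arm constant", {
  set.seed(9)
  ann <- one_chrom_annotation(15, 15)
  genes <- sprintf("g%02d", 1:30)
  screens <- sprintf("S%d", 1:8)
  base <- matrix(rnorm(30), 30, 1)[, rep(1, 8)]
  dimnames(base) <- list(genes, screens)
  offsets <- matrix(rnorm(2 * 8, 0, 0.5), 2, 8)  # per (arm, screen)
  v <- base
  v[1:15, ] <- v[1:15, ] + rep(offsets[1, ], each = 15)
  v[16:30, ] <- v[16:30, ] + rep(offsets[2, ], each = 15)
  corr <- ac_chronos_correct(screen_matrix(v), ann)$corrected
  resid <- unclass(corr) - base
  for (arm_rows in list(1:15, 16:30)) {
    vals <- resid[arm_rows, ]
    expect_lt(max(vals) - min(vals), 1e-12)  # constant within arm, all screens
  }
})

geo_fixture <- function(lfc_vals, tpm_vals, n_p = 4, n_q = 0) {
  genes <- sprintf("g%02d", seq_len(n_p + n_q))
  ann <- one_chrom_annotation(n_p, n_q)
  m <- screen_matrix(matrix(lfc_vals, ncol = 1, dimnames = list(genes, "M1")))
  om <- omics_profiles(
    cn = matrix(2L, length(genes), 1, dimnames = list(genes, "M1")),
    tpm = matrix(tpm_vals, ncol = 1, dimnames = list(genes, "M1")))
  list(m = m, om = om, ann = ann, genes = genes)
}

test_that("geometric correction centers the arm by its unexpressed mean", {
  # unexpressed genes at -0.4 and -0.6 -> every arm gene shifted by +0.5
  f <- geo_fixture(c(-0.4, -0.6, 1.0, 0.2), c(0.1, 0.5, 10, 10))
  out <- geometric_correct(f$m, f$om, f$ann)
  expect_equal(unname(unclass(out)[, "M1"]), c(0.1, -0.1, 1.5, 0.7))
  expect_equal(mean(unclass(out)[c("g01", "g02"), "M1"]), 0, tolerance = 1e-14)
  # idempotence
  again <- geometric_correct(out, f$om, f$ann)
  expect_equal(unclass(again)[, ], unclass(out)[, ], tolerance = 1e-14)
})

test_that("arms without unexpressed genes are skipped with a warning", {
  f <- geo_fixture(c(-0.4, -0.6, 1.0, 0.2), c(5, 5, 10, 10))
  expect_warning(out <- geometric_correct(f$m, f$om, f$ann), "no unexpressed")
  expect_equal(unclass(out)[, ], unclass(f$m)[, ])
  expect_identical(nrow(attr(out, "skipped")), 1L)
})

test_that("geometric correction zeroes unexpressed means on a full bundle", {
  b <- biased_bundle(31, tau = 0.3)
  out <- geometric_correct(b$lfc, b$omics, b$annotation)
  labs <- b$truth$gene_arm[rownames(out)]
  for (mod in colnames(out)[1:5]) {
    unexpr <- rownames(out)[b$omics$tpm[rownames(out), mod] < 1]
    for (arm in unique(labs)[1:4]) {
      u <- intersect(unexpr, names(labs)[labs == arm])
      if (length(u))
        expect_lt(abs(mean(unclass(out)[u, mod])), 1e-10)
    }
  }
  # rank order preserved within (model, arm)
  arm1 <- names(labs)[labs == unique(labs)[1]]
  expect_identical(order(unclass(out)[arm1, 1]),
                   order(unclass(b$lfc)[arm1, 1]))
})

test_that("external corrections are validated against the reference axes", {
  b <- null_bundle(7, n_chromosomes = 1, genes_per_arm = 10, n_models = 4)
  tagged <- register_external_correction("CRISPRcleanR", unclass(b$lfc), b$lfc)
  expect_identical(attr(tagged, "method"), "CRISPRcleanR")
  short <- unclass(b$lfc)[, -(1:3)]
  expect_error(register_external_correction("x", short, b$lfc), "MODEL001")
  base <- register_external_correction("uncorrected", unclass(b$lfc), b$lfc)
  expect_identical(attr(base, "scale_tag"), "raw")
})
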