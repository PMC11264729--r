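make_gm <- function(flags) {
  guide_map(data.frame(guide_id = sprintf("s%d", seq_along(flags)),
                       gene = sprintf("G%d", seq_along(flags)),
                       chromosome = "1", position = seq_along(flags) * 100,
                       qc_flags = flags, stringsAsFactors = FALSE))
}

test_that("guide QC removes exactly the flagged guides", {
  gm <- make_gm(c("", "no_alignment", "sole_passing_guide",
                  "multi_align_multi_gene;intergenic_only", ""))
  res <- filter_guides(gm)
  expect_setequal(res$guidemap$guide_id, c("s1", "s5"))
  expect_setequal(res$report$guide_id, c("s2", "s3", "s4"))
  expect_true(all(nzchar(res$report$reasons)))
  expect_error(filter_guides(make_gm(c("no_alignment", "no_alignment"))),
               "no guides survive")
})

counts_fixture <- function(values, models_per_rep) {
  reps <- colnames(values)[-1]
  count_matrix(values,
               setNames(c("plasmid", rep("replicate", length(reps))),
                        colnames(values)),
               setNames(models_per_rep, reps))
}

test_that("LFC formula matches direct evaluation of the stated form", {
  # equal totals, sample count equal to plasmid count -> LFC 0
  v <- matrix(c(100, 900, 100, 900), 2,
              dimnames = list(c("sA", "sB"), c("plasmid", "r1")))
  cm <- counts_fixture(v, "M1")
  lfc <- compute_lfc(cm)
  expect_equal(unname(unclass(lfc)["sA", "M1"]), 0)
  # totals both 1e6, plasmid 100 vs sample 25 -> log2(26/101)
  v2 <- matrix(c(100, 1e6 - 100, 25, 1e6 - 25), 2,
               dimnames = list(c("sA", "sB"), c("plasmid", "r1")))
  lfc2 <- compute_lfc(counts_fixture(v2, "M1"))
  expect_equal(unname(unclass(lfc2)["sA", "M1"]), log2(26 / 101),
               tolerance = 1e-12)
  expect_equal(log2(26 / 101), -1.958, tolerance = 1e-3)
})

test_that("replicate LFCs are averaged per model", {
  # equal totals (1000) in every sample; guide sA: plasmid 99 -> LFC exactly
  # -1 in r1 (count 49) and -2 in r2 (count 24); model value is the mean
  v <- matrix(c(99, 901, 49, 951, 24, 976), 2,
              dimnames = list(c("sA", "sB"), c("plasmid", "r1", "r2")))
  lfc <- compute_lfc(counts_fixture(v, c("M1", "M1")))
  expect_equal(unname(unclass(lfc)["sA", "M1"]), -1.5)
})

test_that("with no pseudocount the LFC is invariant to uniform count rescaling", {
  set.seed(7)
  v <- matrix(rpois(40, 200) + 1, 10,
              dimnames = list(sprintf("s%d", 1:10),
                              c("plasmid", "r1", "r2", "r3")))
  cm1 <- counts_fixture(v, c("M1", "M1", "M2"))
  v2 <- v; v2[, "r1"] <- v[, "r1"] * 7L  # uniform rescale of one sample
  cm2 <- counts_fixture(v2, c("M1", "M1", "M2"))
  expect_equal(unclass(compute_lfc(cm1, pseudocount = 0))[, ],
               unclass(compute_lfc(cm2, pseudocount = 0))[, ],
               tolerance = 1e-12)
})

test_that("zero-total samples are rejected by name", {
  v <- matrix(c(1, 1, 0, 0), 2,
              dimnames = list(c("sA", "sB"), c("plasmid", "r1")))
  expect_error(compute_lfc(counts_fixture(v, "M1")), "r1")
})

test_that("gene collapse takes the per-gene median of guide LFCs", {
  gl <- screen_matrix(matrix(c(-1, -2, -4, -1, -3, 0.5), 6, 1,
                             dimnames = list(sprintf("s%d", 1:6), "M1")),
                      level = "guide")
  gm <- guide_map(data.frame(
    guide_id = sprintf("s%d", 1:6),
    gene = c("G1", "G1", "G1", "G2", "G2", "G3"),
    chromosome = "1", position = 1:6 * 100, qc_flags = ""))
  gene <- collapse_to_genes(gl, gm)
  expect_equal(unname(unclass(gene)[c("G1", "G2", "G3"), "M1"]),
               c(-2, -2, 0.5))  # odd median, even midpoint, single guide
})

test_that("collapse commutes with per-model monotone relabeling of guides", {
  set.seed(11)
  v <- matrix(rnorm(40), 20, 2,
              dimnames = list(sprintf("s%02d", 1:20), c("M1", "M2")))
  gm <- guide_map(data.frame(guide_id = rownames(v),
                             gene = rep(sprintf("G%d", 1:5), each = 4),
                             chromosome = "1", position = 1:20 * 50,
                             qc_flags = ""))
  gl <- screen_matrix(v, level = "guide")
  perm <- sample(rownames(v))
  gl2 <- screen_matrix(v[perm, ], level = "guide")
  g1 <- collapse_to_genes(gl, gm)
  g2 <- collapse_to_genes(gl2, gm)
  expect_equal(unclass(g1)[rownames(g1), ], unclass(g2)[rownames(g1), ])
})

test_that("profile scaling pins control medians at exactly -1 and 0", {
  set.seed(3)
  genes <- sprintf("G%02d", 1:40)
  m <- screen_matrix(matrix(rnorm(80, -0.5, 1), 40, 2,
                            dimnames = list(genes, c("M1", "M2"))))
  sets <- gene_sets(essential = genes[1:10], nonessential = genes[11:25])
  sc <- scale_profiles(m, sets)
  for (mod in colnames(sc)) {
    expect_equal(median(unclass(sc)[genes[1:10], mod]), -1, tolerance = 1e-12)
    expect_equal(median(unclass(sc)[genes[11:25], mod]), 0, tolerance = 1e-12)
  }
  # idempotence
  sc2 <- scale_profiles(sc, sets)
  expect_equal(unclass(sc2)[, ], unclass(sc)[, ], tolerance = 1e-12)
  # degenerate screen: identical control medians
  flat <- screen_matrix(matrix(0, 40, 1, dimnames = list(genes, "M1")))
  expect_error(scale_profiles(flat, sets), "degenerate")
})

test_that("replicate QC applies the three criteria and drops lost models", {
  set.seed(21)
  n_genes <- 60; gpg <- 2
  guides <- sprintf("G%02d_sg%d", rep(1:n_genes, each = gpg), 1:gpg)
  genes <- sprintf("G%02d", rep(1:n_genes, each = gpg))
  ess <- sprintf("G%02d", 1:15); non <- sprintf("G%02d", 16:40)
  plasmid <- rpois(length(guides), 1000) + 1
  good_rep <- function() {
    depleted <- genes %in% ess
    mu <- ifelse(depleted, plasmid * 0.1, plasmid)
    rpois(length(guides), mu)
  }
  v <- cbind(plasmid = plasmid,
             a1 = good_rep(), a2 = good_rep(),   # model A: two good replicates
             b1 = round(good_rep() * 0.15),      # model B: low mean reads
             c1 = rpois(length(guides), plasmid))# model C: no separation (NNMD)
  rownames(v) <- guides
  cm <- counts_fixture(v, c("A", "A", "B", "C"))
  gm <- guide_map(data.frame(guide_id = guides, gene = genes,
                             chromosome = "1", position = seq_along(guides),
                             qc_flags = ""))
  sets <- gene_sets(essential = ess, nonessential = non)
  expect_warning(res <- filter_replicates(cm, gm, sets), "lost all replicates")
  rep_report <- res$report
  expect_false(any(rep_report$removed[rep_report$model == "A"]))
  expect_true(rep_report$fail_mean_reads[rep_report$sample == "b1"])
  expect_true(rep_report$fail_nnmd[rep_report$sample == "c1"])
  expect_true(all(rep_report$single_replicate[rep_report$model %in% c("B", "C")]))
  expect_setequal(unname(res$counts$replicate_to_model), "A")
  expect_identical(attr(rep_report, "correlation_level"), "gene")
  # deterministic: rerun gives the identical report
  expect_warning(res2 <- filter_replicates(cm, gm, sets), "lost all")
  expect_identical(res$report, res2$report)
})
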