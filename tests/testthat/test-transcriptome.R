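# Normalization, stringent DEG calling, signatures, clustering,
# differentiation axis and gene-set scoring.

test_that("normalization follows the log2(1 + 1e4 * count / total) rule", {
  counts <- Matrix::Matrix(matrix(c(0L, 7L, 0L, 0L, 3L, 2L), 3, 2,
                                  dimnames = list(paste0("g", 1:3),
                                                  c("c1", "c2"))),
                           sparse = TRUE)
  norm <- normalize_expression(counts, min_total = 0)
  expect_equal(norm$mat["g1", "c1"], 0)
  # single expressed gene: whole library collapses onto it
  expect_equal(norm$mat["g2", "c1"], log2(1 + 1e4))
  expect_equal(norm$mat["g2", "c2"], log2(1 + 3 / 5 * 1e4))
  # zero-total cells are dropped, not divided by zero
  counts2 <- counts
  counts2[, 1] <- 0L
  expect_message(norm2 <- normalize_expression(counts2, min_total = 1),
                 "dropping 1")
  expect_equal(colnames(norm2$mat), "c2")
})

test_that("DEG caller is antisymmetric under group swap", {
  co <- small_cohort()
  norm <- normalize_expression(co$rna)
  meta <- co$meta
  a <- intersect(meta[tissue_class == "cancer" & patient == "P1", cell_id],
                 colnames(norm$mat))
  b <- intersect(meta[tissue_class == "normal_epi_stomach", cell_id],
                 colnames(norm$mat))
  r1 <- call_degs(norm, a, b)
  r2 <- call_degs(norm, b, a)
  expect_equal(r1$p, r2$p)
  expect_equal(r1$lfc, -r2$lfc)
  both <- r1$called & r2$called
  expect_true(all(r1$direction[both] != r2$direction[both]))
  # order invariance
  r3 <- call_degs(norm, sample(a), sample(b))
  expect_equal(r3[order(feature)], r1[order(feature)])
})

test_that("maximal DEG case: gene exclusive to one group is called up", {
  set.seed(21)
  m <- matrix(rpois(200 * 60, 3), 200, 60,
              dimnames = list(sprintf("g%03d", 1:200), paste0("c", 1:60)))
  m["g001", 1:30] <- 50L
  m["g001", 31:60] <- 0L
  norm <- normalize_expression(Matrix::Matrix(m, sparse = TRUE), min_total = 0)
  res <- call_degs(norm, paste0("c", 1:30), paste0("c", 31:60))
  g1 <- res[feature == "g001"]
  expect_true(g1$called)
  expect_equal(g1$direction, "up")
  expect_equal(g1$frac_b, 0)
})

test_that("signature derivation recovers planted tissue programs exactly", {
  co <- small_cohort()
  norm <- normalize_expression(co$rna)
  meta <- co$meta
  stomach <- intersect(meta[tissue_class == "normal_epi_stomach", cell_id],
                       colnames(norm$mat))
  colon <- intersect(meta[tissue_class == "normal_epi_colon", cell_id],
                     colnames(norm$mat))
  sigs <- derive_signatures(norm, stomach, colon)
  truth <- co$truth$signatures
  expect_setequal(sigs$stomach_high, truth[signature == "stomach_high", gene])
  expect_setequal(sigs$colon_high, truth[signature == "colon_high", gene])
  expect_length(intersect(sigs$stomach_high, sigs$colon_high), 0)
  # swapping the tissue groups swaps the two sets exactly
  sw <- derive_signatures(norm, colon, stomach)
  expect_setequal(sw$stomach_high, sigs$colon_high)
  expect_setequal(sw$colon_high, sigs$stomach_high)
  expect_error(derive_signatures(norm, stomach, colon[1:3]), "at least")
})

test_that("signature overlap fractions are simple set arithmetic", {
  sig <- paste0("g", 1:111)
  degs <- c(paste0("g", 1:26), paste0("x", 1:40))
  ov <- signature_overlap_fraction(degs, sig)
  expect_equal(ov$overlap_count, 26L)
  expect_equal(round(ov$fraction, 3), 0.234)
  sig158 <- paste0("s", 1:158)
  ov2 <- signature_overlap_fraction(paste0("s", 1:81), sig158)
  expect_equal(round(ov2$fraction, 3), 0.513)
  expect_equal(signature_overlap_fraction("a", "b")$fraction, 0)
  expect_error(signature_overlap_fraction("a", character()), "empty signature")
})

test_that("transcriptome clustering: degenerate cases", {
  co <- small_cohort()
  norm <- normalize_expression(co$rna)
  cells <- colnames(norm$mat)[1:20]
  cl1 <- cluster_transcriptome(norm, k = 1, cells = cells)
  expect_equal(length(unique(cl1$labels)), 1L)
  expect_error(cluster_transcriptome(norm, k = 50, cells = cells), "exceeds")
  # duplicated cell profile lands in the same cluster
  m <- norm$mat[, 1:20]
  m <- cbind(m, dup = m[, 1])
  cl2 <- cluster_transcriptome(m, k = 3)
  expect_equal(unname(cl2$labels["dup"]), unname(cl2$labels[1]))
})

test_that("differentiation axis requires at least two cancer clusters", {
  co <- small_cohort()
  norm <- normalize_expression(co$rna)
  meta <- co$meta
  cancer <- intersect(meta[tissue_class == "cancer", cell_id],
                      colnames(norm$mat))
  normal <- intersect(meta[tissue_class == "normal_epi_stomach", cell_id],
                      colnames(norm$mat))
  one_cluster <- setNames(rep("k1", length(cancer)), cancer)
  expect_error(differentiation_axis(norm, cancer, normal, one_cluster),
               "at least two")
})

test_that("gene-set score closed forms: maximal and zero scores", {
  n <- 40
  s <- 8
  vals <- seq_len(n)  # set genes occupy the top s ranks
  m <- matrix(vals, n, 2, dimnames = list(sprintf("g%02d", 1:n), c("c1", "c2")))
  sets <- list(top = sprintf("g%02d", (n - s + 1):n))
  sc <- gene_set_scores(m, sets, min_set_size = 2)
  expect_equal(unname(sc["top", "c1"]), (n - s) / (2 * n))
  # uniform expression -> average ranks -> score 0
  m0 <- matrix(1, n, 2, dimnames = dimnames(m))
  sc0 <- gene_set_scores(m0, sets, min_set_size = 2)
  expect_equal(unname(sc0["top", ]), c(0, 0))
  # bottom ranks give the mirrored minimal score
  sets_bot <- list(bot = sprintf("g%02d", 1:s))
  scb <- gene_set_scores(m, sets_bot, min_set_size = 2)
  expect_equal(unname(scb["bot", "c1"]), -(n - s) / (2 * n))
})

test_that("random-set scores center on zero (permutation oracle)", {
  set.seed(31)
  n <- 200
  m <- matrix(rnorm(n * 3), n, 3,
              dimnames = list(sprintf("g%03d", 1:n), c("c1", "c2", "c3")))
  s <- 15
  # brute-force oracle: mean score over many random same-size sets
  ranks <- apply(m, 2, rank)
  oracle <- replicate(1000, {
    idx <- sample.int(n, s)
    (colMeans(ranks[idx, ]) - (n + 1) / 2) / n
  })
  expect_true(all(abs(rowMeans(oracle)) < 3 * apply(oracle, 1, sd) / sqrt(1000)))
  # the package's standardized variant agrees with the oracle's null moments
  sets <- list(rand = sprintf("g%03d", sample.int(n, s)))
  raw <- gene_set_scores(m, sets)
  z <- gene_set_scores(m, sets, standardize = TRUE, n_perm = 1000, seed = 5)
  mu <- rowMeans(oracle)
  sdv <- apply(oracle, 1, sd)
  expect_equal(unname(z["rand", ]),
               unname((raw["rand", ] - mu) / sdv), tolerance = 0.15)
})

test_that("per-patient DEG consistency keeps only cross-patient calls", {
  co <- small_cohort()
  norm <- normalize_expression(co$rna)
  meta <- co$meta
  cancer <- intersect(meta[tissue_class == "cancer", cell_id],
                      colnames(norm$mat))
  stomach <- intersect(meta[tissue_class == "normal_epi_stomach", cell_id],
                       colnames(norm$mat))
  degs <- call_degs(norm, cancer, stomach, per_patient = TRUE, meta = meta)
  shared <- attr(degs, "shared")
  expect_true(all(shared$n_patients_called == 2L))
  expect_true(all(c("P1", "P2") %in% degs$patient))
})
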