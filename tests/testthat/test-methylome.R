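# Context classification, level quantification and the differential
# promoter caller.

test_that("context classification matches the figure-legend examples", {
  expect_equal(classify_cytosine_context("AACGT", 2, "+"), "WCG")
  expect_equal(classify_cytosine_context("AGCAT", 2, "+"), "GCH")
  expect_equal(classify_cytosine_context("AGCGT", 2, "+"), "EXCLUDED")
  # edges lack a flank
  expect_equal(classify_cytosine_context("CAT", 0, "+"), "EXCLUDED")
  expect_equal(classify_cytosine_context("ATC", 2, "+"), "EXCLUDED")
  expect_error(classify_cytosine_context("AACGT", 1, "+"), "not a cytosine")
})

test_that("classification equals the brute-force enumerator on random sequence", {
  set.seed(101)
  s <- paste(sample(c("A", "C", "G", "T"), 10000, replace = TRUE),
             collapse = "")
  chars <- strsplit(s, "")[[1]]
  pos_plus <- which(chars == "C") - 1L
  pos_minus <- which(chars == "G") - 1L
  got_plus <- classify_cytosine_context(s, pos_plus, "+")
  got_minus <- classify_cytosine_context(s, pos_minus, "-")
  expect_equal(got_plus, oracle_context(s, pos_plus, rep("+", length(pos_plus))))
  expect_equal(got_minus, oracle_context(s, pos_minus, rep("-", length(pos_minus))))
  # partition: every C is classified, exactly one label each
  expect_true(all(got_plus %in% c("WCG", "GCH", "EXCLUDED")))
  # mirror consistency: classifying on the reverse complement gives the same
  # answer for the same physical cytosine
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rc <- paste(rev(comp[chars]), collapse = "")
  n <- nchar(s)
  rc_pos <- n - 1L - pos_minus  # minus-strand C maps to a plus-strand C on the RC
  got_rc <- classify_cytosine_context(rc, rc_pos, "+")
  expect_equal(got_rc, got_minus)
})

make_call_table <- function(rows) {
  ctx <- if (is.null(rows$context)) "WCG" else rows$context
  data.table(cell_id = rows$cell_id, chrom = rows$chrom, pos = rows$pos,
             strand = "+", context = ctx,
             meth_count = rows$meth, total_count = rows$total)
}

test_that("region levels are coverage-weighted fractions with thresholds", {
  regions <- data.table(chrom = "chr1", start = 0L, end = 1000L, name = "r1")
  calls <- make_call_table(list(cell_id = "c1", chrom = "chr1",
                                pos = c(10L, 20L), meth = c(3L, 1L),
                                total = c(4L, 4L)))
  out <- region_levels(calls, regions, min_sites = 1, min_reads = 1)
  expect_equal(out$level, 0.5)  # (3+1)/(4+4)
  expect_equal(out$n_sites, 2L)
  expect_equal(out$n_reads, 8L)
  # below thresholds -> NA level
  out2 <- region_levels(calls, regions, min_sites = 3, min_reads = 1)
  expect_true(is.na(out2$level))
  # no covered sites -> row absent, not zero
  far <- data.table(chrom = "chr1", start = 5000L, end = 6000L, name = "r2")
  expect_equal(nrow(region_levels(calls, far)), 0L)
})

test_that("region levels equal an independent summation oracle", {
  set.seed(55)
  regions <- data.table(chrom = "chr1",
                        start = seq(0L, 9000L, by = 1000L),
                        end = seq(1000L, 10000L, by = 1000L),
                        name = paste0("r", 1:10))
  n <- 50
  tot <- sample(1:6, n, replace = TRUE)
  calls <- data.table(cell_id = sample(c("c1", "c2"), n, replace = TRUE),
                      chrom = "chr1", pos = sample.int(10000, n) - 1L,
                      strand = "+", context = "WCG",
                      meth_count = vapply(tot, function(t) sample(0:t, 1), 0L),
                      total_count = tot)
  out <- region_levels(calls, regions, min_sites = 1, min_reads = 1)
  # brute force: loop over every (region, cell) and sum
  for (i in seq_len(nrow(out))) {
    r <- regions[name == out$region[i]]
    sub <- calls[cell_id == out$cell_id[i] & pos >= r$start & pos < r$end]
    expect_identical(out$level[i], sum(sub$meth_count) / sum(sub$total_count))
  }
})

test_that("merging disjoint regions gives the coverage-weighted combination", {
  regions <- data.table(chrom = "chr1", start = c(0L, 1000L),
                        end = c(1000L, 2000L), name = c("a", "b"))
  merged <- data.table(chrom = "chr1", start = 0L, end = 2000L, name = "ab")
  calls <- make_call_table(list(cell_id = "c1", chrom = "chr1",
                                pos = c(10L, 1500L), meth = c(2L, 5L),
                                total = c(10L, 5L)))
  sep <- region_levels(calls, regions, min_sites = 1, min_reads = 1)
  comb <- region_levels(calls, merged, min_sites = 1, min_reads = 1)
  w <- sep$n_reads
  expect_equal(comb$level, sum(sep$level * w) / sum(w))
})

test_that("global level: degenerate and order-invariance cases", {
  calls <- make_call_table(list(cell_id = rep("c1", 5), chrom = "chr1",
                                pos = c(1L, 5L, 9L, 13L, 17L),
                                meth = rep(0L, 5), total = rep(3L, 5)))
  g <- global_level(calls, min_sites_qc = 3)
  expect_equal(g$level, 0)
  expect_false(g$low_qc)
  g2 <- global_level(calls[sample(5)], min_sites_qc = 3)
  expect_equal(g2, g)
  g3 <- global_level(calls, min_sites_qc = 100)
  expect_true(g3$low_qc)
})

test_that("repeat-class pooling is consistent with region levels", {
  rep_bed <- data.table(chrom = "chr3", start = 0L, end = 1000L,
                        name = "rep1", class_label = "L1")
  calls <- make_call_table(list(cell_id = "c1", chrom = "chr3",
                                pos = c(5L, 500L), meth = c(1L, 3L),
                                total = c(2L, 4L)))
  by_class <- repeat_class_levels(calls, rep_bed)
  by_region <- region_levels(calls, rep_bed, min_sites = 1, min_reads = 1)
  expect_equal(by_class$level, by_region$level)
  expect_equal(by_class$class_label, "L1")
  # unknown class labels pass through
  rep_bed2 <- copy(rep_bed)[, class_label := "weird_class"]
  expect_equal(repeat_class_levels(calls, rep_bed2)$class_label, "weird_class")
})

test_that("DMP caller: maximal separation, null input and guards", {
  lv <- rbind(p1 = c(rep(1, 10), rep(0, 10)))
  colnames(lv) <- paste0("c", 1:20)
  res <- call_dmps(lv, paste0("c", 1:10), paste0("c", 11:20), min_cells = 5)
  expect_equal(res$delta, 1)
  expect_equal(res$direction, "hyper")
  expect_true(res$called)
  expect_lt(res$q, 1e-4)

  set.seed(77)
  lv2 <- matrix(runif(100 * 40), 100, 40,
                dimnames = list(paste0("p", 1:100), paste0("c", 1:40)))
  res2 <- call_dmps(lv2, paste0("c", 1:20), paste0("c", 21:40))
  expect_equal(sum(res2$called), 0L)

  expect_error(call_dmps(lv, paste0("c", 1:10), paste0("c", 5:20)), "overlap")
  expect_error(call_dmps(lv, character(), paste0("c", 1:10)), "non-empty|at least")
})

test_that("features with too few covered cells are skipped", {
  lv <- matrix(runif(2 * 20), 2, 20,
               dimnames = list(c("p1", "p2"), paste0("c", 1:20)))
  lv["p2", 1:8] <- NA
  res <- call_dmps(lv, paste0("c", 1:10), paste0("c", 11:20), min_cells = 5)
  expect_equal(res$feature, "p1")
})

test_that("shared features: per-direction counting across patients", {
  mk <- function(feature, direction, called = TRUE) {
    data.table(feature = feature, direction = direction, called = called)
  }
  # hyper in 11/14 patients at min_fraction 0.5 -> included
  res14 <- c(replicate(11, mk("TMEM240", "hyper"), simplify = FALSE),
             replicate(3, mk("TMEM240", "hyper", called = FALSE),
                       simplify = FALSE))
  out <- shared_features(res14, min_fraction = 0.5)
  expect_true(out[feature == "TMEM240" & direction == "hyper", shared])
  expect_equal(out[feature == "TMEM240", n_patients_called], 11L)

  # hyper in 6/14 and hypo in 8/14 -> included as hypo only
  res_mixed <- c(replicate(6, mk("X", "hyper"), simplify = FALSE),
                 replicate(8, mk("X", "hypo"), simplify = FALSE))
  out2 <- shared_features(res_mixed, min_fraction = 0.5)
  expect_true(out2[direction == "hypo", shared])
  expect_false(out2[direction == "hyper", shared])

  # min_fraction 1 with one discordant patient -> excluded
  res_alm <- c(replicate(13, mk("Y", "hyper"), simplify = FALSE),
               list(mk("Y", "hypo")))
  out3 <- shared_features(res_alm, min_fraction = 1)
  expect_false(any(out3[feature == "Y", shared] & out3[feature == "Y", n_patients_called] == 14L))
  expect_false(out3[feature == "Y" & direction == "hyper", shared])
})
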