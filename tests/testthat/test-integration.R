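# Cross-omics integration: lineage methylation summaries with the PT/LN
# shift rule, contingency structure, state ordering and trio concordance.

make_levels <- function(cells, levels) {
  data.table(cell_id = cells, level = levels, n_sites = 5000L,
             n_reads = 10000L, low_qc = FALSE)
}

test_that("PT-vs-LN shift flag follows the >5% median rule", {
  cells <- paste0("c", 1:40)
  lineages <- setNames(rep("A", 40), cells)
  meta <- data.table(cell_id = cells, patient = "P1",
                     site = rep(c("PT", "LN"), each = 20),
                     site_position = "x", tissue_class = "cancer")
  # PT median 0.50, LN median 0.44 -> delta 0.06 -> flagged
  gl <- make_levels(cells, rep(c(0.50, 0.44), each = 20))
  s <- lineage_methylation(lineages, gl, meta)$summaries
  expect_equal(s$pt_ln_delta, 0.06)
  expect_true(s$apparent_shift)
  # PT 0.50 vs LN 0.48 -> not flagged
  gl2 <- make_levels(cells, rep(c(0.50, 0.48), each = 20))
  s2 <- lineage_methylation(lineages, gl2, meta)$summaries
  expect_false(s2$apparent_shift)
  # oracle recomputation from raw per-cell levels
  dt <- merge(gl, meta, by = "cell_id")
  expect_equal(s$pt_ln_delta,
               median(dt[site == "PT", level]) - median(dt[site == "LN", level]))
})

test_that("between-lineage tests separate planted levels", {
  set.seed(41)
  cells <- paste0("c", 1:90)
  lineages <- setNames(rep(c("A", "B", "C"), each = 30), cells)
  meta <- data.table(cell_id = cells, patient = "P1", site = "PT",
                     site_position = "PT1", tissue_class = "cancer")
  gl <- make_levels(cells, rep(c(0.55, 0.65, 0.75), each = 30) +
                      rnorm(90, 0, 0.01))
  lm <- lineage_methylation(lineages, gl, meta)
  expect_true(all(lm$tests$q < 0.05))
  expect_equal(lm$summaries[order(lineage), round(median, 1)], c(0.6, 0.7, 0.8),
               tolerance = 0.1)
})

test_that("contingency: perfect map, split lineage, degenerate input", {
  cells <- paste0("c", 1:100)
  lin <- setNames(rep(c("A", "B"), each = 50), cells)
  cl <- setNames(rep(c(1L, 2L), each = 50), cells)
  res <- lineage_cluster_contingency(lin, cl)
  expect_equal(res$cramers_v, 1)
  expect_equal(unname(res$entropy), c(0, 0))
  expect_equal(sum(res$table), 100)
  expect_equal(as.vector(rowSums(res$table)),
               as.vector(table(lin)[rownames(res$table)]))

  # one lineage split 25/25 over two clusters -> entropy 1 bit
  cl2 <- cl
  cl2[1:25] <- 2L
  res2 <- lineage_cluster_contingency(lin, cl2)
  expect_equal(unname(res2$entropy["A"]), 1)
  expect_lt(res2$cramers_v, 1)

  # single lineage -> V undefined, entropy still reported
  res3 <- lineage_cluster_contingency(setNames(rep("A", 100), cells), cl)
  expect_true(is.na(res3$cramers_v))
  expect_equal(unname(res3$entropy), 1)

  expect_error(lineage_cluster_contingency(lin[1:50], cl), "same cells")
})

test_that("planted many-to-many map is recovered exactly on the cohort", {
  co <- small_cohort()
  tc <- co$truth$cells
  lin <- setNames(tc$clone, tc$cell_id)
  cl <- setNames(paste0(tc$patient, ":", tc$cluster), tc$cell_id)
  res <- lineage_cluster_contingency(lin[tc$patient == "P1"],
                                     cl[tc$patient == "P1"])
  n <- co$params$cells_per_clone
  # clone A -> cluster 1, clone B -> clusters 1+2 (half/half), clone C -> 3
  expect_equal(unname(res$table["P1_A", "P1:1"]), n)
  expect_equal(unname(res$table["P1_B", "P1:1"]), n %/% 2)
  expect_equal(unname(res$table["P1_B", "P1:2"]), n - n %/% 2)
  expect_equal(unname(res$table["P1_C", "P1:3"]), n)
  expect_equal(unname(res$entropy["P1_A"]), 0)
  expect_equal(unname(res$entropy["P1_B"]), 1)
})

test_that("state methylation ordering check behaves at planted and null levels", {
  cells <- paste0("c", 1:70)
  meta <- data.table(cell_id = cells,
                     patient = "P1",
                     site = c(rep("PT", 50), rep("NAT", 20)),
                     site_position = "x",
                     tissue_class = c(rep("cancer", 50),
                                      rep("normal_epi_stomach", 20)))
  states <- setNames(c(rep("poorer_diff", 25), rep("better_diff", 25)),
                     cells[1:50])
  set.seed(51)
  gl <- make_levels(cells, c(rnorm(25, 0.65, 0.01), rnorm(25, 0.55, 0.01),
                             rnorm(20, 0.80, 0.01)))
  res <- state_methylation_compare(states, gl, meta)
  expect_true(res$ordering_ok)
  expect_lt(res$p, 1e-6)

  # equal planted levels: ordering fails
  gl0 <- make_levels(cells, rnorm(70, 0.6, 0.01))
  res0 <- state_methylation_compare(states, gl0, meta)
  expect_false(res0$ordering_ok)

  # singleton state group is skipped with a reason
  states1 <- states
  states1[1:24] <- "better_diff"  # one poorer cell left
  res1 <- state_methylation_compare(states1, gl, meta)
  expect_true(res1$skipped)
  expect_match(res1$reason, "min_cells")
})

test_that("trio concordance classes follow the direction triples", {
  mk <- function(feature, direction, called) {
    data.table(feature = feature, direction = direction, called = called)
  }
  deg <- mk(c("a", "b", "c", "d", "e"), c("up", "down", "up", "up", "down"),
            c(TRUE, TRUE, TRUE, FALSE, TRUE))
  dmp <- mk(c("a", "b", "c", "d", "e"), c("hypo", "hyper", "hyper", "hyper", "hypo"),
            c(TRUE, TRUE, TRUE, TRUE, FALSE))
  acc <- mk(c("a", "b", "c", "d", "e"), c("hyper", "hyper", "hypo", "hyper", "hyper"),
            c(TRUE, FALSE, TRUE, FALSE, FALSE))
  tri <- trio_concordance(deg, dmp, acc)
  cls <- setNames(tri$concordance_class, tri$gene)
  expect_equal(unname(cls["a"]), "concordant_activated")   # up, hypo, open
  expect_equal(unname(cls["b"]), "concordant_repressed")   # down, hyper, ns
  expect_equal(unname(cls["c"]), "discordant")             # up, hyper, closed
  expect_equal(unname(cls["d"]), "epigenetics_only")       # ns, hyper, ns
  expect_equal(unname(cls["e"]), "expression_only")        # down, ns, ns
})

test_that("trio classification is total over all direction triples", {
  dirs_e <- c("up", "down", "ns")
  dirs_m <- c("hyper", "hypo", "ns")
  dirs_a <- c("hyper", "hypo", "ns")  # acc 'hyper' = open
  grid <- expand.grid(e = dirs_e, m = dirs_m, a = dirs_a,
                      stringsAsFactors = FALSE)
  genes <- sprintf("g%02d", seq_len(nrow(grid)))
  deg <- data.table(feature = genes, direction = ifelse(grid$e == "ns", "up", grid$e),
                    called = grid$e != "ns")
  dmp <- data.table(feature = genes, direction = ifelse(grid$m == "ns", "hyper", grid$m),
                    called = grid$m != "ns")
  acc <- data.table(feature = genes, direction = ifelse(grid$a == "ns", "hyper", grid$a),
                    called = grid$a != "ns")
  tri <- trio_concordance(deg, dmp, acc)
  expect_equal(nrow(tri), nrow(grid))
  expect_false(anyNA(tri$concordance_class))
  expect_true(all(tri$concordance_class %in%
                    c("concordant_activated", "concordant_repressed",
                      "discordant", "expression_only", "epigenetics_only",
                      "ns")))
})

test_that("contrast mismatch between result tables errors", {
  deg <- data.table(feature = "a", direction = "up", called = TRUE)
  dmp <- copy(deg)[, direction := "hypo"]
  acc <- copy(deg)[, direction := "hypo"]
  setattr(deg, "contrast", list(a = "cancer", b = "normal"))
  setattr(dmp, "contrast", list(a = "cancer", b = "normal"))
  setattr(acc, "contrast", list(a = "cancer", b = "other"))
  expect_error(trio_concordance(deg, dmp, acc), "different group contrasts")
})
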