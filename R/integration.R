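# Cross-omics integration: lineage-resolved global methylation (including
# the PT-vs-LN shift flag), lineage-by-transcriptomic-cluster contingency
# structure, differentiation-state methylation ordering, and promoter trio
# (expression / methylation / accessibility) concordance classes.

#' Lineage-resolved global methylation summaries
#'
#' Per lineage: per-cell global WCG levels, median and IQR, PT/LN medians
#' where both compartments are present, and the shift flag
#' `apparent_shift = |median_PT - median_LN| > shift_threshold`. Lineages
#' with fewer than `min_cells` cells are summarized but flagged untested.
#' Pairwise between-lineage rank-sum tests (BH adjusted) are returned
#' alongside.
#'
#' @param lineages named vector cell -> lineage label (cancer cells).
#' @param global_levels [global_level()] table (`cell_id`, `level`).
#' @param meta cell metadata (for PT/LN sites).
#' @param shift_threshold absolute median difference flagged as an apparent
#'   PT-vs-LN change (default 0.05, i.e. a >5% shift in methylation).
#' @param min_cells minimum lineage size entering the pairwise tests.
#' @return list with `summaries` and `tests` data.tables.
#' @export
lineage_methylation <- function(lineages, global_levels, meta,
                                shift_threshold = 0.05, min_cells = 5L) {
  gl <- as.data.table(global_levels)
  meta <- as.data.table(meta)
  dt <- data.table(cell_id = names(lineages), lineage = unname(lineages))
  dt <- merge(dt, gl[, .(cell_id, level)], by = "cell_id")
  dt <- merge(dt, meta[, .(cell_id, site)], by = "cell_id")
  summaries <- dt[, {
    pt <- level[site == "PT"]
    ln <- level[site == "LN"]
    pt_med <- if (length(pt)) median(pt) else NA_real_
    ln_med <- if (length(ln)) median(ln) else NA_real_
    delta <- if (!is.na(pt_med) && !is.na(ln_med)) pt_med - ln_med else NA_real_
    .(n_cells = .N, median = median(level),
      iqr = quantile(level, 0.75) - quantile(level, 0.25),
      median_pt = pt_med, median_ln = ln_med, pt_ln_delta = delta,
      apparent_shift = if (is.na(delta)) NA else abs(delta) > shift_threshold,
      tested = .N >= min_cells)
  }, by = lineage]
  setorder(summaries, lineage)
  lins <- summaries[tested == TRUE, lineage]
  tests <- if (length(lins) >= 2L) {
    pairs <- utils::combn(lins, 2L)
    tt <- rbindlist(lapply(seq_len(ncol(pairs)), function(i) {
      a <- dt[lineage == pairs[1, i], level]
      b <- dt[lineage == pairs[2, i], level]
      ts <- rank_sum_test(a, b)
      data.table(lineage_a = pairs[1, i], lineage_b = pairs[2, i],
                 delta = median(a) - median(b), statistic = ts$statistic,
                 p = ts$p)
    }))
    tt[, q := p.adjust(p, method = "BH")]
    tt[]
  } else {
    data.table(lineage_a = character(), lineage_b = character(),
               delta = double(), statistic = double(), p = double(),
               q = double())
  }
  list(summaries = summaries, tests = tests)
}

#' Lineage-by-cluster contingency structure
#'
#' Counts cancer cells per (genetic lineage, transcriptomic cluster) and
#' summarizes the association: chi-square statistic (no continuity
#' correction), Cramer's V = sqrt(chisq / (n * (min(r, c) - 1))), and the
#' Shannon entropy (bits) of each lineage's cluster composition — nonzero
#' entropy for a lineage spanning several clusters, V < 1 when different
#' lineages share a cluster.
#'
#' @param lineages named vector cell -> lineage.
#' @param clusters named vector cell -> cluster (same cells).
#' @return list with `table` (lineage x cluster counts), `chisq`, `cramers_v`
#'   (`NA` for a single row or column), `entropy` (per lineage, bits),
#'   `n`.
#' @export
lineage_cluster_contingency <- function(lineages, clusters) {
  cells <- intersect(names(lineages), names(clusters))
  if (!setequal(names(lineages), names(clusters))) {
    stop("lineage and cluster labelings must cover the same cells")
  }
  tab <- table(lineage = lineages[cells], cluster = clusters[cells])
  if (nrow(tab) >= 2L && ncol(tab) >= 2L) {
    chi <- suppressWarnings(chisq.test(tab, correct = FALSE))
    chisq <- unname(chi$statistic)
    v <- sqrt(chisq / (length(cells) * (min(dim(tab)) - 1L)))
  } else {
    chisq <- NA_real_
    v <- NA_real_
  }
  entropy <- apply(tab, 1, shannon_entropy)
  list(table = tab, chisq = chisq, cramers_v = v, entropy = entropy,
       n = length(cells))
}

#' Differentiation-state global methylation comparison per patient
#'
#' For each patient, compares global WCG levels of primary-tumor (PT) cancer
#' cells between the two differentiation states (rank-sum test) and checks
#' the three-way ordering: poorer_diff median > better_diff median, with
#' both below the normal-epithelium median. Patients missing a state (or
#' with fewer than `min_cells` cells in one) are reported as skipped.
#'
#' @param states named vector cell -> state (`better_diff` / `poorer_diff`
#'   for cancer cells).
#' @param global_levels [global_level()] table.
#' @param meta cell metadata.
#' @param site_filter sampling compartment of cancer cells compared
#'   (default `"PT"`; `NULL` keeps all).
#' @param min_cells minimum cells per state group.
#' @return `data.table` per patient: state medians, normal median, rank-sum
#'   `p`, `ordering_ok`, `skipped`, `reason`.
#' @export
state_methylation_compare <- function(states, global_levels, meta,
                                      site_filter = "PT", min_cells = 3L) {
  gl <- as.data.table(global_levels)
  meta <- as.data.table(meta)
  dt <- merge(meta, gl[, .(cell_id, level)], by = "cell_id")
  dt[, state := states[cell_id]]
  pats <- sort(unique(dt[tissue_class == "cancer", patient]))
  rbindlist(lapply(pats, function(pp) {
    canc <- dt[patient == pp & tissue_class == "cancer"]
    if (!is.null(site_filter)) canc <- canc[site %in% site_filter]
    nor <- dt[patient == pp & tissue_class == "normal_epi_stomach", level]
    po <- canc[state == "poorer_diff", level]
    be <- canc[state == "better_diff", level]
    if (length(po) < min_cells || length(be) < min_cells) {
      return(data.table(patient = pp, n_poorer = length(po),
                        n_better = length(be),
                        median_poorer = NA_real_, median_better = NA_real_,
                        median_normal = if (length(nor)) median(nor) else NA_real_,
                        p = NA_real_, ordering_ok = NA, skipped = TRUE,
                        reason = "state group below min_cells"))
    }
    ts <- rank_sum_test(po, be)
    mp <- median(po); mb <- median(be)
    mn <- if (length(nor)) median(nor) else NA_real_
    data.table(patient = pp, n_poorer = length(po), n_better = length(be),
               median_poorer = mp, median_better = mb, median_normal = mn,
               p = ts$p,
               ordering_ok = !is.na(mn) && mp > mb && mp < mn && mb < mn,
               skipped = FALSE, reason = NA_character_)
  }))
}

#' Classify promoter trio concordance per gene
#'
#' Joins differential expression, promoter methylation and promoter
#' accessibility results sharing the same group contrast, and classifies
#' each gene present in all three by its direction triple:
#' `concordant_activated` (up with hypomethylated and/or open promoter),
#' `concordant_repressed` (down with hypermethylated and/or closed
#' promoter; a single epigenetic arm suffices), `discordant` (any
#' epigenetic arm opposing the expression change), `expression_only`,
#' `epigenetics_only`, `ns`. The class is a pure function of the three
#' directions.
#'
#' @param deg_results [call_degs()] table (`feature`, `direction`, `called`).
#' @param dmp_results [call_dmps()] table on promoter WCG levels.
#' @param acc_results [call_dmps()] table on promoter GCH levels (direction
#'   `hyper` is read as `open`, `hypo` as `closed`).
#' @param contrast optional list with `group_a`, `group_b` recorded for
#'   mismatch checking; when all three result tables carry a `contrast`
#'   attribute they must be identical.
#' @return `data.table(gene, expr_direction, meth_direction, acc_direction,
#'   concordance_class)`.
#' @export
trio_concordance <- function(deg_results, dmp_results, acc_results,
                             contrast = NULL) {
  cons <- lapply(list(deg_results, dmp_results, acc_results),
                 attr, "contrast")
  cons <- cons[!vapply(cons, is.null, TRUE)]
  if (length(cons) > 1L) {
    for (i in seq_along(cons)[-1]) {
      if (!identical(cons[[1]], cons[[i]])) {
        stop("result tables come from different group contrasts")
      }
    }
  }
  deg <- as.data.table(deg_results)[, .(gene = feature,
    expr_direction = ifelse(called, direction, "ns"))]
  dmp <- as.data.table(dmp_results)[, .(gene = feature,
    meth_direction = ifelse(called, direction, "ns"))]
  acc <- as.data.table(acc_results)[, .(gene = feature,
    acc_direction = ifelse(called, ifelse(direction == "hyper", "open",
                                          "closed"), "ns"))]
  tri <- merge(merge(deg, dmp, by = "gene"), acc, by = "gene")
  classify <- function(e, m, a) {
    if (e == "ns" && m == "ns" && a == "ns") return("ns")
    if (e == "ns") return("epigenetics_only")
    support <- if (e == "up") (m == "hypo") + (a == "open")
               else (m == "hyper") + (a == "closed")
    oppose <- if (e == "up") (m == "hyper") + (a == "closed")
              else (m == "hypo") + (a == "open")
    if (oppose > 0L) return("discordant")
    if (support > 0L) return(if (e == "up") "concordant_activated"
                             else "concordant_repressed")
    "expression_only"
  }
  tri[, concordance_class := mapply(classify, expr_direction, meth_direction,
                                    acc_direction)]
  tri[]
}
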