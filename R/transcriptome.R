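# Expression normalization, stringent DEG calling, tissue-signature
# derivation and overlap, transcriptomic clustering, differentiation-state
# assignment along a principal-component axis, and per-cell rank-based
# gene-set scoring.

#' Library-size normalize a UMI count matrix
#'
#' `log2(1 + count * scale_factor / cell_total)`; cells with total counts
#' below `min_total` are dropped (reported via message).
#'
#' @param counts genes-by-cells integer matrix (sparse or dense) with
#'   dimnames.
#' @param scale_factor target library size (default 10,000).
#' @param min_total minimum per-cell total.
#' @return object of class `normalized_matrix`: list with `mat` (dense
#'   genes-by-cells), `cell_totals`, `dropped_cells`.
#' @export
normalize_expression <- function(counts, scale_factor = 1e4, min_total = 200L) {
  totals <- Matrix::colSums(counts)
  dropped <- colnames(counts)[totals < min_total]
  if (length(dropped)) {
    message("dropping ", length(dropped), " cell(s) with total < ", min_total)
    counts <- counts[, totals >= min_total, drop = FALSE]
    totals <- totals[totals >= min_total]
  }
  if (ncol(counts) == 0L) stop("no cells left after total-count filtering")
  mat <- log2(1 + sweep(as.matrix(counts), 2, totals, "/") * scale_factor)
  structure(list(mat = mat, cell_totals = totals, dropped_cells = dropped),
            class = "normalized_matrix")
}

.norm_mat <- function(norm) {
  if (inherits(norm, "normalized_matrix")) norm$mat else as.matrix(norm)
}

#' Call differentially expressed genes between two cell groups
#'
#' Per gene: Wilcoxon rank-sum p ([rank_sum_test()]) on normalized values,
#' BH-adjusted across genes; log2 fold change of de-logged group means with
#' pseudo-count 1; fraction of cells with nonzero expression per group. A
#' gene is called when `q <= q_max`, `|lfc| >= lfc_min` and the expressing
#' fraction in the up-regulated group is `>= min_frac`. With
#' `per_patient = TRUE` tests run within each patient and a gene is called
#' only when the per-patient calls agree (same direction) in at least
#' `patient_fraction` of patients ([shared_features()]).
#'
#' @param norm `normalized_matrix` or genes-by-cells matrix of log2 values.
#' @param group_a,group_b disjoint cell-id vectors (lfc > 0 means up in A).
#' @param lfc_min,q_max,min_frac stringent call thresholds.
#' @param per_patient run within patients and keep consistent calls only.
#' @param meta cell metadata (needed when `per_patient = TRUE`).
#' @param patient_fraction consistency fraction across patients.
#' @param min_cells minimum group size per test.
#' @return `data.table(feature, n_a, n_b, mean_a, mean_b, lfc, frac_a,
#'   frac_b, statistic, p, q, direction, called, patient)`; with
#'   `per_patient`, one row per (patient, gene) plus attribute `"shared"`
#'   (the combined table whose `called` reflects cross-patient consistency).
#' @export
call_degs <- function(norm, group_a, group_b, lfc_min = 1, q_max = 0.01,
                      min_frac = 0.5, per_patient = FALSE, meta = NULL,
                      patient_fraction = 0.8, min_cells = 5L,
                      patient = NA_character_) {
  .check_groups(group_a, group_b)
  mat <- .norm_mat(norm)
  if (per_patient) {
    stopifnot(!is.null(meta))
    meta <- as.data.table(meta)
    pats <- sort(unique(meta[cell_id %in% c(group_a, group_b), patient]))
    per_pat <- lapply(pats, function(p) {
      cells_p <- meta[patient == p, cell_id]
      ga <- intersect(group_a, cells_p)
      gb <- intersect(group_b, cells_p)
      if (length(ga) < min_cells || length(gb) < min_cells) return(NULL)
      call_degs(mat, ga, gb, lfc_min = lfc_min, q_max = q_max,
                min_frac = min_frac, per_patient = FALSE, patient = p,
                min_cells = min_cells)
    })
    per_pat <- per_pat[!vapply(per_pat, is.null, TRUE)]
    if (length(per_pat) == 0L) stop("no patient had enough cells in both groups")
    shared <- shared_features(per_pat, min_fraction = patient_fraction)
    out <- rbindlist(per_pat)
    res <- shared[shared == TRUE]
    combined <- out[, .(lfc = mean(lfc), mean_p = mean(p)), by = .(feature, direction)]
    combined <- merge(res[, .(feature, direction, n_patients_called)],
                      combined, by = c("feature", "direction"))
    setorder(combined, -n_patients_called, feature)
    data.table::setattr(out, "shared", combined)
    return(out[])
  }
  ga <- intersect(group_a, colnames(mat))
  gb <- intersect(group_b, colnames(mat))
  if (length(ga) < min_cells || length(gb) < min_cells) {
    stop("fewer than min_cells cells present in a group")
  }
  a_lin <- 2^mat[, ga, drop = FALSE] - 1
  b_lin <- 2^mat[, gb, drop = FALSE] - 1
  mean_a <- rowMeans(a_lin)
  mean_b <- rowMeans(b_lin)
  lfc <- log2((mean_a + 1) / (mean_b + 1))
  frac_a <- rowMeans(mat[, ga, drop = FALSE] > 0)
  frac_b <- rowMeans(mat[, gb, drop = FALSE] > 0)
  stat_p <- vapply(rownames(mat), function(g) {
    ts <- rank_sum_test(mat[g, ga], mat[g, gb])
    c(ts$statistic, ts$p)
  }, c(0, 0))
  out <- data.table(feature = rownames(mat), n_a = length(ga), n_b = length(gb),
                    mean_a = mean_a, mean_b = mean_b, lfc = lfc,
                    frac_a = frac_a, frac_b = frac_b,
                    statistic = stat_p[1, ], p = stat_p[2, ])
  out[, q := p.adjust(p, method = "BH")]
  out[, direction := ifelse(lfc > 0, "up", "down")]
  out[, called := q <= q_max & abs(lfc) >= lfc_min &
        ifelse(lfc > 0, frac_a, frac_b) >= min_frac]
  pat <- patient
  out[, patient := pat]
  out[]
}

#' Derive stomach-high and colon-high tissue signatures
#'
#' Runs the stringent DEG caller between the two normal epithelium groups;
#' genes up in stomach form `stomach_high`, genes up in colon form
#' `colon_high` (disjoint by construction).
#' @param norm normalized matrix.
#' @param stomach_cells,colon_cells cell ids of the two normal tissues.
#' @param lfc_min,q_max,min_frac thresholds passed to [call_degs()].
#' @param min_cells minimum cells per tissue.
#' @return list with `stomach_high`, `colon_high` (character vectors),
#'   `thresholds`, `deg_table`.
#' @export
derive_signatures <- function(norm, stomach_cells, colon_cells, lfc_min = 1,
                              q_max = 0.01, min_frac = 0.5, min_cells = 10L) {
  if (length(stomach_cells) < min_cells || length(colon_cells) < min_cells) {
    stop("need at least ", min_cells, " cells in each normal tissue group")
  }
  degs <- call_degs(norm, stomach_cells, colon_cells, lfc_min = lfc_min,
                    q_max = q_max, min_frac = min_frac)
  list(stomach_high = degs[called == TRUE & direction == "up", feature],
       colon_high = degs[called == TRUE & direction == "down", feature],
       thresholds = list(lfc_min = lfc_min, q_max = q_max, min_frac = min_frac),
       deg_table = degs)
}

#' Overlap of cancer DEGs with a tissue signature
#'
#' @param cancer_degs character vector of called cancer DEGs (one direction).
#' @param signature character vector of signature genes.
#' @return list with `overlap_count`, `fraction`
#'   (`|signature intersect cancer_degs| / |signature|`), `genes`.
#' @export
signature_overlap_fraction <- function(cancer_degs, signature) {
  if (length(signature) == 0L) stop("empty signature: fraction undefined")
  ov <- intersect(signature, cancer_degs)
  list(overlap_count = length(ov),
       fraction = length(ov) / length(signature),
       genes = ov)
}

# Top-variance gene selection + PCA in cell space, shared by clustering and
# the differentiation axis.
.expr_pca <- function(mat, cells, n_hvg, n_comp) {
  sub <- mat[, cells, drop = FALSE]
  v <- apply(sub, 1, var)
  hvg <- names(sort(v, decreasing = TRUE))[seq_len(min(n_hvg, sum(v > 0)))]
  x <- t(sub[hvg, , drop = FALSE])
  n_comp <- min(n_comp, nrow(x) - 1L, ncol(x))
  pc <- prcomp(x, center = TRUE, scale. = FALSE, rank. = n_comp)
  flip <- vapply(seq_len(ncol(pc$rotation)), function(j) {
    l <- pc$rotation[, j]
    s <- sign(l[which.max(abs(l))])
    if (s == 0) 1 else s
  }, 0)
  list(coords = sweep(pc$x, 2, flip, "*"),
       loadings = sweep(pc$rotation, 2, flip, "*"),
       sdev = pc$sdev[seq_len(n_comp)], hvg = hvg)
}

#' Cluster cells in expression PCA space
#'
#' Top-variance genes, PCA, then Ward agglomerative clustering on Euclidean
#' distance in component space; when `k = "auto"` the number of clusters
#' maximizes the mean silhouette width over `2:k_max`.
#' @param norm normalized matrix.
#' @param k cluster count or `"auto"`.
#' @param cells optional subset of cells to cluster (default all).
#' @param n_hvg number of top-variance genes.
#' @param n_comp number of principal components.
#' @param k_max maximum k tried under `"auto"`.
#' @return list with `labels` (named integer vector), `k`, `silhouette`,
#'   `pca`.
#' @export
cluster_transcriptome <- function(norm, k = "auto", cells = NULL,
                                  n_hvg = 1000L, n_comp = 10L, k_max = 8L) {
  mat <- .norm_mat(norm)
  cells <- cells %||% colnames(mat)
  if (is.numeric(k) && k > length(cells)) stop("k exceeds number of cells")
  pca <- .expr_pca(mat, cells, n_hvg, n_comp)
  d <- dist(pca$coords)
  tree <- hclust(d, method = "ward.D2")
  sil <- NULL
  if (identical(k, "auto")) {
    ks <- seq(2L, min(k_max, length(cells) - 1L))
    sil <- vapply(ks, function(kk) {
      mean(cluster::silhouette(cutree(tree, k = kk), d)[, "sil_width"])
    }, 0)
    names(sil) <- ks
    k <- ks[which.max(sil)]
  }
  labels <- if (k == 1L) setNames(rep(1L, length(cells)), cells) else cutree(tree, k = k)
  list(labels = labels, k = as.integer(k), silhouette = sil, pca = pca)
}

# Best split of a set of per-cluster medians into two groups (1-D two-means
# by exhaustive cut over the sorted medians); returns the between-group sum
# of squares and the midpoint between group means.
.two_means_split <- function(medians) {
  o <- order(medians)
  m <- medians[o]
  n <- length(m)
  best <- list(bss = -Inf)
  for (cut in seq_len(n - 1L)) {
    lo <- m[seq_len(cut)]
    hi <- m[(cut + 1L):n]
    bss <- length(lo) * (mean(lo) - mean(m))^2 + length(hi) * (mean(hi) - mean(m))^2
    if (bss > best$bss) {
      best <- list(bss = bss, midpoint = (mean(lo) + mean(hi)) / 2,
                   low_group = names(m)[seq_len(cut)],
                   high_group = names(m)[(cut + 1L):n])
    }
  }
  best
}

#' Differentiation axis and state assignment
#'
#' PCA over normal and cancer cells jointly on top-variance genes. The
#' component best separating normal from cancer cells (maximal
#' `|AUROC - 0.5|`) is identified first; among the remaining components the
#' differentiation axis is the one maximizing the between-group sum of
#' squares of the optimal two-way split of per-cluster median coordinates
#' (two-means criterion on cancer transcriptomic clusters). Cancer cells are
#' assigned `better_diff` / `poorer_diff` by thresholding their coordinate
#' at the midpoint between the two cluster-median groups; normal cells get
#' state `normal`. When per-cell histopathology labels are supplied the axis
#' is oriented so that `better_diff` has the higher coordinate, otherwise
#' the orientation is recorded as arbitrary.
#'
#' @param norm normalized matrix.
#' @param cancer_cells,normal_cells cell-id vectors.
#' @param clusters named vector of transcriptomic cluster labels for the
#'   cancer cells (patient-qualified labels recommended).
#' @param histopath optional named vector (`better_diff` / `poorer_diff`)
#'   for at least some cancer cells, used only for orientation.
#' @param n_hvg,n_comp PCA parameters.
#' @return list with `coords`, `loadings`, `separating_component`,
#'   `axis_component`, `axis_score`, `separating_auroc`, `threshold`,
#'   `states` (named vector over all cells), `orientation`.
#' @export
differentiation_axis <- function(norm, cancer_cells, normal_cells, clusters,
                                 histopath = NULL, n_hvg = 1000L,
                                 n_comp = 10L) {
  mat <- .norm_mat(norm)
  cancer_cells <- intersect(cancer_cells, colnames(mat))
  normal_cells <- intersect(normal_cells, colnames(mat))
  clusters <- clusters[intersect(names(clusters), cancer_cells)]
  if (length(unique(clusters)) < 2L) {
    stop("need at least two cancer transcriptomic clusters to define states")
  }
  cells <- c(normal_cells, cancer_cells)
  pca <- .expr_pca(mat, cells, n_hvg, n_comp)
  is_cancer <- cells %in% cancer_cells
  # orientation along a PC is arbitrary, so separation is |AUROC - 0.5|
  aurocs <- apply(pca$coords, 2, function(co) auroc(co, is_cancer))
  aurocs <- pmax(aurocs, 1 - aurocs)
  sep <- which.max(aurocs)
  candidates <- setdiff(seq_len(ncol(pca$coords)), sep)
  cl_cells <- names(clusters)
  splits <- lapply(candidates, function(j) {
    co <- pca$coords[cl_cells, j]
    med <- tapply(co, clusters[cl_cells], median)
    .two_means_split(med)
  })
  scores <- vapply(splits, function(s) s$bss, 0)
  axis <- candidates[which.max(scores)]
  split <- splits[[which.max(scores)]]
  coord <- pca$coords[, axis]
  high <- names(coord)[coord > split$midpoint]
  orientation <- "arbitrary"
  hi_state <- "state_high"
  lo_state <- "state_low"
  if (!is.null(histopath)) {
    hp <- histopath[intersect(names(histopath), cancer_cells)]
    if (length(hp)) {
      med_better <- median(coord[names(hp)[hp == "better_diff"]])
      med_poorer <- median(coord[names(hp)[hp == "poorer_diff"]])
      orientation <- "better_diff_high"
      if (!is.na(med_better) && !is.na(med_poorer) && med_better < med_poorer) {
        coord <- -coord
        pca$coords[, axis] <- -pca$coords[, axis]
        split$midpoint <- -split$midpoint
        high <- names(coord)[coord > split$midpoint]
      }
      hi_state <- "better_diff"
      lo_state <- "poorer_diff"
    }
  }
  states <- setNames(rep(lo_state, length(cells)), cells)
  states[intersect(high, cells)] <- hi_state
  states[normal_cells] <- "normal"
  list(coords = pca$coords, loadings = pca$loadings,
       separating_component = sep, axis_component = axis,
       axis_score = max(scores), separating_auroc = aurocs[sep],
       threshold = split$midpoint, states = states, orientation = orientation)
}

#' Per-cell rank-based gene-set scores
#'
#' Within each cell, genes are ranked by normalized expression (average rank
#' for ties); a set's score is `(mean rank of set genes - mean rank of all
#' genes) / n_genes`, bounded by +/-(n - |S|) / (2n): positive when set
#' genes sit high in the cell's expression ranking. With
#' `standardize = TRUE`, each score is z-standardized against `n_perm`
#' random same-size gene sets.
#'
#' @param norm normalized matrix.
#' @param gene_sets named list of gene-id vectors (e.g. [read_gmt()]).
#' @param min_set_size sets with fewer matrix genes are skipped (`NA` row,
#'   reported via message).
#' @param standardize permutation-standardize the scores.
#' @param n_perm number of random sets when standardizing.
#' @param seed RNG seed for the permutations.
#' @return sets-by-cells numeric matrix.
#' @export
gene_set_scores <- function(norm, gene_sets, min_set_size = 5L,
                            standardize = FALSE, n_perm = 1000L, seed = 1L) {
  mat <- .norm_mat(norm)
  n_genes <- nrow(mat)
  ranks <- apply(mat, 2, rank)
  mean_all <- (n_genes + 1) / 2
  out <- matrix(NA_real_, length(gene_sets), ncol(mat),
                dimnames = list(names(gene_sets), colnames(mat)))
  present <- lapply(gene_sets, function(g) intersect(unique(g), rownames(mat)))
  for (i in seq_along(gene_sets)) {
    g <- present[[i]]
    if (length(g) < min_set_size) {
      message("gene set '", names(gene_sets)[i], "' has ", length(g),
              " genes in the matrix (< ", min_set_size, "); skipped")
      next
    }
    out[i, ] <- (colMeans(ranks[g, , drop = FALSE]) - mean_all) / n_genes
  }
  if (standardize) {
    out <- with_seed(seed, {
      z <- out
      for (i in seq_along(gene_sets)) {
        s <- length(present[[i]])
        if (s < min_set_size) next
        # cells x n_perm null score matrix from random same-size sets
        null_scores <- vapply(seq_len(n_perm), function(b) {
          gs <- sample.int(n_genes, s)
          (colMeans(ranks[gs, , drop = FALSE]) - mean_all) / n_genes
        }, numeric(ncol(mat)))
        null_scores <- matrix(null_scores, nrow = ncol(mat))
        mu <- rowMeans(null_scores)
        sdv <- apply(null_scores, 1, sd)
        z[i, ] <- (out[i, ] - mu) / sdv
      }
      z
    })
  }
  out
}
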