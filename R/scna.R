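# Somatic copy-number profiles from binned single-cell DNA coverage, and
# genetic-lineage inference by hierarchical clustering of Spearman
# correlations between profiles.

#' Per-cell relative copy-number profiles from binned read counts
#'
#' Each cell's bin counts are converted to within-cell coverage shares, then
#' divided by the median share of a diploid normal-cell panel, so 1.0 is the
#' diploid expectation. Profiles are smoothed with a running median of width
#' `w` over usable bins in genomic order. Bins where the normal-panel median
#' share is zero, or where fewer than `min_normal_frac` of normal cells have
#' any coverage, are masked (`NA`), never silently dropped.
#'
#' @param bin_counts bins-by-cells integer matrix (cells to profile).
#' @param normal_panel bins-by-cells integer matrix of diploid reference
#'   cells (same bins, same order).
#' @param bins optional BED table describing the bins (carried through).
#' @param w running-median width (odd; `w = 1` disables smoothing).
#' @param min_normal_frac minimum fraction of normal cells with nonzero
#'   count for a bin to be usable.
#' @return an object of class `scna_profiles`: list with `ratio`
#'   (bins-by-cells matrix, masked bins `NA`), `masked` (logical per bin),
#'   `qc` (`data.table(cell_id, total_reads, n_usable_bins)`), `bins`,
#'   `excluded_cells`.
#' @export
compute_scna_profiles <- function(bin_counts, normal_panel, bins = NULL,
                                  w = 3L, min_normal_frac = 0.8) {
  stopifnot(nrow(bin_counts) == nrow(normal_panel))
  if (ncol(normal_panel) < 1L) stop("need at least one normal cell")
  if (w %% 2L == 0L) stop("running-median width `w` must be odd")
  totals <- colSums(bin_counts)
  excluded <- colnames(bin_counts)[totals == 0]
  if (length(excluded)) {
    warning("excluding ", length(excluded), " cell(s) with zero total reads: ",
            paste(head(excluded, 5), collapse = ", "))
    bin_counts <- bin_counts[, totals > 0, drop = FALSE]
    totals <- totals[totals > 0]
  }
  norm_totals <- colSums(normal_panel)
  if (any(norm_totals == 0)) {
    normal_panel <- normal_panel[, norm_totals > 0, drop = FALSE]
    norm_totals <- norm_totals[norm_totals > 0]
  }
  norm_shares <- sweep(normal_panel, 2, norm_totals, "/")
  ref <- apply(norm_shares, 1, median)
  nonzero_frac <- rowMeans(normal_panel > 0)
  masked <- ref == 0 | nonzero_frac < min_normal_frac
  shares <- sweep(bin_counts, 2, totals, "/")
  ratio <- shares / ref
  ratio[masked, ] <- NA_real_
  if (w > 1L && sum(!masked) >= w) {
    usable <- which(!masked)
    for (j in seq_len(ncol(ratio))) {
      ratio[usable, j] <- stats::runmed(ratio[usable, j], w, endrule = "median")
    }
  }
  structure(list(
    ratio = ratio,
    masked = masked,
    qc = data.table(cell_id = colnames(bin_counts),
                    total_reads = as.numeric(totals),
                    n_usable_bins = sum(!masked)),
    bins = bins,
    excluded_cells = excluded
  ), class = "scna_profiles")
}

#' @export
print.scna_profiles <- function(x, ...) {
  cat(sprintf("scna_profiles: %d cells x %d bins (%d masked)\n",
              ncol(x$ratio), nrow(x$ratio), sum(x$masked)))
  invisible(x)
}

#' Pairwise Spearman correlations of SCNA profiles
#'
#' Masked bins are excluded pairwise; pairs sharing fewer than `min_bins`
#' usable bins get `NA`. The diagonal is 1.
#' @param profiles an `scna_profiles` object or a bins-by-cells ratio matrix.
#' @param min_bins minimum shared usable bins per pair.
#' @return symmetric cell-by-cell correlation matrix.
#' @export
scna_correlations <- function(profiles, min_bins = 3L) {
  ratio <- if (inherits(profiles, "scna_profiles")) profiles$ratio else profiles
  if (ncol(ratio) < 2L) stop("need at least two profiles")
  rho <- suppressWarnings(
    stats::cor(ratio, method = "spearman", use = "pairwise.complete.obs"))
  shared <- crossprod(!is.na(ratio))
  rho[shared < min_bins] <- NA_real_
  diag(rho) <- 1
  rho
}

#' Group cells into genetic lineages
#'
#' Agglomerative clustering (average linkage) on distance `1 - rho`. When
#' `k = "auto"`, k is chosen to maximize the mean silhouette width over
#' `2:k_max`. Lineage labels are `A, B, C, ...` ordered by decreasing size.
#'
#' @param correlations Spearman correlation matrix ([scna_correlations()]).
#' @param k number of lineages, or `"auto"`.
#' @param k_max largest k tried when `k = "auto"`.
#' @return object of class `lineage_assignment`: list with `labels` (named
#'   character vector cell -> lineage), `tree` (`hclust`), `k`,
#'   `silhouette` (mean widths per candidate k, auto only), `correlations`.
#' @export
cluster_lineages <- function(correlations, k = "auto", k_max = 8L) {
  stopifnot(is.matrix(correlations), nrow(correlations) == ncol(correlations))
  rho <- correlations
  if (anyNA(rho)) {
    if (all(is.na(rho[upper.tri(rho)]))) stop("all correlations missing")
    warning("imputing ", sum(is.na(rho)), " missing correlation entries by column mean")
    col_mean <- colMeans(rho, na.rm = TRUE)
    idx <- which(is.na(rho), arr.ind = TRUE)
    rho[idx] <- col_mean[idx[, 2]]
    rho <- (rho + t(rho)) / 2
  }
  d <- as.dist(1 - rho)
  tree <- hclust(d, method = "average")
  sil <- NULL
  if (identical(k, "auto")) {
    ks <- seq(2L, min(k_max, nrow(rho) - 1L))
    sil <- vapply(ks, function(kk) {
      cl <- cutree(tree, k = kk)
      mean(cluster::silhouette(cl, d)[, "sil_width"])
    }, 0)
    names(sil) <- ks
    k <- ks[which.max(sil)]
  }
  stopifnot(is.numeric(k), k >= 1L, k <= nrow(rho))
  raw <- if (k == 1L) setNames(rep(1L, nrow(rho)), rownames(rho)) else cutree(tree, k = k)
  labels <- setNames(relabel_by_size(raw), names(raw))
  structure(list(labels = labels, tree = tree, k = as.integer(k),
                 silhouette = sil, correlations = correlations),
            class = "lineage_assignment")
}

#' @export
print.lineage_assignment <- function(x, ...) {
  cat(sprintf("lineage_assignment: %d cells in %d lineage(s)\n",
              length(x$labels), x$k))
  print(table(x$labels))
  invisible(x)
}

#' PCA of SCNA profiles
#'
#' Bins masked in any cell are dropped listwise; profiles are centered per
#' bin. The sign of each component is fixed so its largest-magnitude loading
#' is positive, making the projection invariant to cell input order.
#'
#' @param profiles `scna_profiles` object or bins-by-cells ratio matrix.
#' @param n_comp number of components to keep.
#' @return list with `coords` (cells-by-components), `loadings`, `sdev`.
#' @export
scna_pca <- function(profiles, n_comp = 10L) {
  ratio <- if (inherits(profiles, "scna_profiles")) profiles$ratio else profiles
  keep <- rowSums(is.na(ratio)) == 0L
  x <- t(ratio[keep, , drop = FALSE])
  max_comp <- min(nrow(x) - 1L, ncol(x))
  if (n_comp > max_comp) {
    warning("reducing components from ", n_comp, " to ", max_comp)
    n_comp <- max_comp
  }
  pc <- prcomp(x, center = TRUE, scale. = FALSE, rank. = n_comp)
  flip <- vapply(seq_len(ncol(pc$rotation)), function(j) {
    l <- pc$rotation[, j]
    sign(l[which.max(abs(l))])
  }, 0)
  flip[flip == 0] <- 1
  list(coords = sweep(pc$x, 2, flip, "*"),
       loadings = sweep(pc$rotation, 2, flip, "*"),
       sdev = pc$sdev[seq_len(n_comp)])
}
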