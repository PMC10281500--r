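# Synthetic trio-omics cohort generator. Plants clonal copy-number profiles,
# lineage-specific global methylation, repeat-class demethylation, promoter
# DMPs with inversely coupled accessibility, stringent DEG programs including
# a colon-signature program aberrantly activated in cancer cells, cluster
# marker programs with a many-to-many clone-to-cluster map, and two
# differentiation-state programs with immune gene-set activity higher in
# better-differentiated cells. The planted truth tables are the oracle for
# every downstream recovery check.

#' Simulate clone-level copy-number profiles
#'
#' Baseline copy number 2 everywhere; each clone receives
#' `events_per_clone` non-overlapping gain/loss events with lengths drawn
#' between `max_event_len %/% 2` and `max_event_len` bins and copy numbers in
#' {0, 1, 3, 4}. Any two clones are guaranteed to differ in at least one bin.
#'
#' @param n_clones number of clones (>= 1).
#' @param n_bins number of genome bins.
#' @param events_per_clone CNV events per clone (0 allowed).
#' @param max_event_len maximum event length in bins.
#' @param seed RNG seed.
#' @param clone_ids optional clone names (default "clone1", ...).
#' @param max_clone_cor clones are redrawn until the Pearson correlation of
#'   their copy-number vectors with every earlier clone is below this bound
#'   (emulates the low between-lineage SCNA correlations of distinct genetic
#'   lineages); set to 1 to disable.
#' @return object of class `clonal_cn_map`: list with `n_bins`, `clones`
#'   (named list of integer copy-number vectors), `event_log`
#'   (`data.table(clone_id, start_bin, end_bin, cn)`, 1-based inclusive).
#' @export
simulate_clones <- function(n_clones, n_bins, events_per_clone = 8L,
                            max_event_len = 50L, seed = 1L, clone_ids = NULL,
                            max_clone_cor = 0.2) {
  stopifnot(n_clones >= 1L, n_bins >= 1L, events_per_clone >= 0L)
  if (events_per_clone * max_event_len > n_bins) {
    stop("events_per_clone * max_event_len exceeds n_bins; events cannot fit")
  }
  if (n_clones > 1L && events_per_clone == 0L) {
    stop("clones cannot differ with events_per_clone = 0")
  }
  clone_ids <- clone_ids %||% paste0("clone", seq_len(n_clones))
  stopifnot(length(clone_ids) == n_clones)
  min_len <- max(1L, max_event_len %/% 2L)
  with_seed(seed, {
    # all starts where a `len`-bin event fits in free space
    feasible_starts <- function(occupied, len) {
      runs <- rle(!occupied)
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1L
      out <- integer()
      for (r in which(runs$values & runs$lengths >= len)) {
        out <- c(out, starts[r]:(ends[r] - len + 1L))
      }
      out
    }
    draw_clone <- function() {
      cn <- rep(2L, n_bins)
      log <- list()
      occupied <- rep(FALSE, n_bins)
      for (e in seq_len(events_per_clone)) {
        len <- if (min_len >= max_event_len) max_event_len
               else sample(min_len:max_event_len, 1L)
        cand <- feasible_starts(occupied, len)
        if (!length(cand)) {
          # shrink to the largest free window still >= 1 bin
          len <- max(rle(!occupied)$lengths[rle(!occupied)$values], 0L)
          if (len == 0L) {
            stop("could not place non-overlapping events; reduce events or lengths")
          }
          cand <- feasible_starts(occupied, len)
        }
        s <- cand[sample.int(length(cand), 1L)]
        idx <- s:(s + len - 1L)
        occupied[idx] <- TRUE
        ev_cn <- sample(c(0L, 1L, 3L, 4L), 1L, prob = c(0.1, 0.4, 0.4, 0.1))
        cn[idx] <- ev_cn
        log[[e]] <- data.table(start_bin = s, end_bin = s + len - 1L, cn = ev_cn)
      }
      list(cn = cn, log = rbindlist(log))
    }
    clones <- vector("list", n_clones)
    logs <- vector("list", n_clones)
    for (i in seq_len(n_clones)) {
      for (try in seq_len(100L)) {
        cand <- draw_clone()
        distinct <- all(vapply(seq_len(i - 1L), function(j) {
          if (all(cand$cn == clones[[j]])) return(FALSE)
          r <- suppressWarnings(stats::cor(cand$cn, clones[[j]]))
          is.na(r) || r <= max_clone_cor
        }, TRUE))
        if (distinct) break
      }
      if (!distinct && i > 1L) stop("failed to draw sufficiently distinct clone profiles")
      clones[[i]] <- cand$cn
      logs[[i]] <- if (nrow(cand$log)) cand$log[, .(clone_id = clone_ids[i],
                                                    start_bin, end_bin, cn)]
                   else NULL
    }
    names(clones) <- clone_ids
    structure(list(n_bins = n_bins, clones = clones,
                   event_log = rbindlist(logs)),
              class = "clonal_cn_map")
  })
}

#' Simulate per-cell binned DNA read counts
#'
#' Counts are negative-binomial with expectation proportional to the clone's
#' copy number in the bin (`mean_reads_per_bin * cn / 2`); a diploid normal
#' panel is always emitted alongside the cancer cells.
#'
#' @param cn_map a [simulate_clones()] result.
#' @param cells_per_clone scalar or per-clone vector (0 drops a clone from
#'   the output while it stays in the map).
#' @param mean_reads_per_bin expected reads per diploid bin.
#' @param overdispersion NB dispersion (variance = mu + mu^2 * overdispersion);
#'   0 gives Poisson counts.
#' @param n_normal number of diploid normal panel cells.
#' @param seed RNG seed.
#' @param cell_prefix prefix for generated cell ids.
#' @return list with `counts` (bins x cancer cells), `normal_counts`
#'   (bins x normals), `cell_clone` (`data.table(cell_id, clone)`).
#' @export
simulate_dna <- function(cn_map, cells_per_clone, mean_reads_per_bin = 50,
                         overdispersion = 0.1, n_normal = 30L, seed = 1L,
                         cell_prefix = "cell") {
  stopifnot(inherits(cn_map, "clonal_cn_map"))
  if (mean_reads_per_bin <= 0) stop("mean_reads_per_bin must be positive")
  clone_ids <- names(cn_map$clones)
  if (length(cells_per_clone) == 1L) {
    cells_per_clone <- rep(cells_per_clone, length(clone_ids))
  }
  stopifnot(length(cells_per_clone) == length(clone_ids))
  n_bins <- cn_map$n_bins
  draw <- function(mu, n) {
    if (overdispersion <= 0) rpois(n, mu)
    else rnbinom(n, size = 1 / overdispersion, mu = mu)
  }
  with_seed(seed, {
    mats <- list()
    clones_of <- character()
    for (i in seq_along(clone_ids)) {
      nc <- cells_per_clone[i]
      if (nc == 0L) next
      mu <- mean_reads_per_bin * cn_map$clones[[i]] / 2
      m <- matrix(draw(rep(mu, nc), n_bins * nc), nrow = n_bins)
      mats[[length(mats) + 1L]] <- m
      clones_of <- c(clones_of, rep(clone_ids[i], nc))
    }
    counts <- if (length(mats)) do.call(cbind, mats)
              else matrix(0L, n_bins, 0L)
    if (ncol(counts)) {
      within_clone <- unlist(lapply(rle(clones_of)$lengths, seq_len))
      colnames(counts) <- sprintf("%s_c%03d", clones_of, within_clone)
    }
    normal_counts <- matrix(draw(rep(mean_reads_per_bin, n_normal), n_bins * n_normal),
                            nrow = n_bins)
    colnames(normal_counts) <- sprintf("%s_normal_%03d", cell_prefix, seq_len(n_normal))
    list(counts = counts, normal_counts = normal_counts,
         cell_clone = data.table(cell_id = colnames(counts), clone = clones_of))
  })
}

#' Draw a cytosine call table from expected region levels
#'
#' Low-level generator: for each region, `n_sites` evenly spaced cytosines
#' are placed and each receives `reads_per_site` reads with methylated counts
#' binomial at the (region, cell) expected level.
#'
#' @param level_mat regions-by-cells matrix of expected levels in `[0, 1]`
#'   (rownames = region names, colnames = cell ids).
#' @param regions table with `chrom, start, end, name, n_sites,
#'   reads_per_site` (rows matching `rownames(level_mat)`).
#' @param context context label written on every record.
#' @param seed RNG seed.
#' @return a cytosine call table ([read_meth_calls()] schema).
#' @export
simulate_meth_calls <- function(level_mat, regions, context = "WCG", seed = 1L) {
  regions <- as.data.table(regions)
  stopifnot(all(rownames(level_mat) == regions$name))
  if (anyNA(level_mat) || any(level_mat < 0 | level_mat > 1)) {
    stop("expected levels must lie in [0, 1]")
  }
  n_sites <- regions$n_sites
  reads <- regions$reads_per_site
  reg_idx <- rep(seq_len(nrow(regions)), n_sites)
  site_no <- sequence(n_sites)
  width <- regions$end - regions$start
  pos <- regions$start[reg_idx] +
    floor(width[reg_idx] * (site_no - 0.5) / n_sites[reg_idx])
  cells <- colnames(level_mat)
  n_site_rows <- length(reg_idx)
  cell_idx <- rep(seq_along(cells), each = n_site_rows)
  reg_all <- rep(reg_idx, times = length(cells))
  lvl <- level_mat[cbind(reg_all, cell_idx)]
  tot <- reads[reg_all]
  with_seed(seed, {
    meth <- rbinom(length(lvl), tot, lvl)
    data.table(cell_id = cells[cell_idx],
               chrom = regions$chrom[reg_all],
               pos = rep(pos, times = length(cells)),
               strand = "+",
               context = context,
               meth_count = meth,
               total_count = tot)
  })
}

.clip01 <- function(x, eps = 0.02) pmin(1 - eps, pmax(eps, x))

#' Simulate WCG methylation and GCH accessibility call tables
#'
#' Plants (i) per-clone global WCG levels (the expected genome-wide
#' coverage-weighted level of each cancer cell, with an optional PT-vs-LN
#' offset subtracted for LN cells), (ii) repeat-class demethylation in cancer
#' cells (class level = `repeat_factors[class] * global`), (iii) promoter
#' baselines shared by all cells with planted DMP deltas added for cancer
#' cells, and (iv) a flat GCH accessibility background with
#' logit-linear inverse coupling to the planted promoter methylation change.
#' Genome-bin levels are solved per cell so that the coverage-weighted
#' expectation over all sites equals the planted global level exactly.
#'
#' @param cells `data.table(cell_id, tissue_class, clone, site)`; `clone` is
#'   `NA` for normal cells.
#' @param regions region table with `chrom, start, end, name, role` (one of
#'   `bin`, `promoter`, `repeat`), `class_label`, `n_sites`, `reads_per_site`.
#' @param clone_levels named vector of planted global WCG levels per clone.
#' @param planted_dmps `data.table(name, delta)` of promoter names and the
#'   level change in cancer cells (positive = hyper).
#' @param normal_level global WCG level of normal cells.
#' @param repeat_factors named vector, cancer repeat level as a fraction of
#'   the cell's global level (normals keep `normal_level` on repeats).
#' @param pt_ln_offsets named per-clone vector; LN cells of a clone sit at
#'   `clone level - offset`.
#' @param promoter_baseline optional named vector of promoter baselines;
#'   drawn `runif(0.15, 0.85)` when `NULL` (DMP promoters are drawn so that
#'   the delta survives clipping).
#' @param acc_background GCH accessibility background level.
#' @param acc_coupling strength of the logit-linear inverse coupling between
#'   a planted promoter methylation change and its accessibility.
#' @param seed RNG seed.
#' @return list with `wcg`, `gch` (call tables), `expected` (list with
#'   `wcg_levels`, `gch_levels` matrices, `global` named per-cell expected
#'   global WCG level, `promoter_baseline`).
#' @export
simulate_methylome <- function(cells, regions, clone_levels,
                               planted_dmps = NULL, normal_level = 0.8,
                               repeat_factors = c(L1 = 0.80, LTR = 0.85,
                                                  satellite = 0.67),
                               pt_ln_offsets = NULL,
                               promoter_baseline = NULL,
                               acc_background = 0.25, acc_coupling = 1,
                               seed = 1L) {
  cells <- as.data.table(cells)
  regions <- as.data.table(regions)
  stopifnot(all(c("role", "n_sites", "reads_per_site") %in% names(regions)))
  if (any(clone_levels < 0 | clone_levels > 1) || normal_level < 0 || normal_level > 1) {
    stop("planted levels must lie in [0, 1]")
  }
  n_cell <- nrow(cells)
  is_cancer <- cells$tissue_class == "cancer"
  # expected genome-wide level per cell
  g <- ifelse(is_cancer, clone_levels[cells$clone], normal_level)
  if (!is.null(pt_ln_offsets)) {
    ln <- is_cancer & cells$site == "LN"
    g[ln] <- g[ln] - pt_ln_offsets[cells$clone[ln]]
  }
  if (any(g < 0 | g > 1)) stop("per-cell global levels fall outside [0, 1]")
  names(g) <- cells$cell_id
  w <- regions$n_sites * regions$reads_per_site
  lvl <- matrix(NA_real_, nrow(regions), n_cell,
                dimnames = list(regions$name, cells$cell_id))
  prom <- which(regions$role == "promoter")
  reps <- which(regions$role == "repeat")
  bins <- which(regions$role == "bin")
  if (length(prom)) {
    if (is.null(promoter_baseline)) {
      promoter_baseline <- with_seed(seed + 101L, {
        base <- runif(length(prom), 0.15, 0.85)
        names(base) <- regions$name[prom]
        if (!is.null(planted_dmps)) {
          pd <- as.data.table(planted_dmps)
          hyper <- pd[delta > 0, name]
          hypo <- pd[delta < 0, name]
          base[intersect(hyper, names(base))] <-
            runif(length(intersect(hyper, names(base))), 0.15,
                  0.98 - max(pd$delta) - 0.02)
          base[intersect(hypo, names(base))] <-
            runif(length(intersect(hypo, names(base))),
                  0.02 - min(pd$delta) + 0.02, 0.85)
        }
        base
      })
    }
    pb <- promoter_baseline[regions$name[prom]]
    lvl[prom, ] <- matrix(pb, length(prom), n_cell)
    if (!is.null(planted_dmps) && any(is_cancer)) {
      pd <- as.data.table(planted_dmps)
      ridx <- match(pd$name, regions$name)
      stopifnot(!anyNA(ridx))
      lvl[ridx, is_cancer] <- .clip01(
        matrix(promoter_baseline[pd$name] + pd$delta, length(ridx),
               sum(is_cancer)))
    }
  }
  if (length(reps)) {
    fac <- repeat_factors[regions$class_label[reps]]
    if (anyNA(fac)) stop("repeat class without a repeat_factors entry")
    lvl[reps, ] <- outer(fac, g)
    lvl[reps, !is_cancer] <- normal_level
  }
  if (length(bins)) {
    w_tot <- sum(w)
    w_bin <- sum(w[bins])
    other <- c(prom, reps)
    nonbin <- if (length(other)) colSums(lvl[other, , drop = FALSE] * w[other]) else 0
    l_bin <- (g * w_tot - nonbin) / w_bin
    if (any(l_bin < 0 | l_bin > 1)) {
      stop("solved genome-bin levels fall outside [0, 1]; ",
           "planted global levels are inconsistent with the promoter/repeat compartments")
    }
    lvl[bins, ] <- matrix(l_bin, length(bins), n_cell, byrow = TRUE)
  }
  # GCH accessibility: flat background, inversely coupled at DMP promoters
  acc <- matrix(acc_background, nrow(regions), n_cell,
                dimnames = dimnames(lvl))
  if (!is.null(planted_dmps) && length(prom) && any(is_cancer)) {
    pd <- as.data.table(planted_dmps)
    ridx <- match(pd$name, regions$name)
    m_norm <- .clip01(promoter_baseline[pd$name])
    m_canc <- .clip01(promoter_baseline[pd$name] + pd$delta)
    shift <- acc_coupling * (stats::qlogis(m_canc) - stats::qlogis(m_norm))
    acc_c <- stats::plogis(stats::qlogis(acc_background) - shift)
    acc[ridx, is_cancer] <- matrix(acc_c, length(ridx), sum(is_cancer))
  }
  wcg <- simulate_meth_calls(lvl, regions, context = "WCG", seed = seed + 1L)
  gch <- simulate_meth_calls(acc, regions, context = "GCH", seed = seed + 2L)
  list(wcg = wcg, gch = gch,
       expected = list(wcg_levels = lvl, gch_levels = acc, global = g,
                       promoter_baseline = promoter_baseline))
}

#' Simulate a UMI count matrix with planted programs
#'
#' Per-gene baseline means times multiplicative planted effects (log2 scale)
#' times a lognormal per-cell size factor, drawn negative-binomial. Effects
#' select cells by tissue class, by cancer status, by transcriptomic cluster
#' or by differentiation state; two effects on the same gene whose selectors
#' can match the same cell with conflicting signs raise an error.
#'
#' @param cells `data.table(cell_id, tissue_class, cluster, state)`
#'   (`cluster`/`state` may be `NA` for normals).
#' @param n_genes number of genes.
#' @param effects `data.table(gene, type, value, log2fc)` with `type` in
#'   `tissue`, `cancer`, `cluster`, `state` (`value` ignored for `cancer`).
#' @param baseline optional per-gene baseline mean vector (named); drawn
#'   lognormal when `NULL`, with genes named in `effects` drawn from the
#'   higher `effect_baseline_*` distribution so planted programs are
#'   detectable.
#' @param dispersion NB dispersion (0 = Poisson).
#' @param size_factor_sd sd of log-normal per-cell size factors.
#' @param gene_ids optional gene names (default `g0001`, ...).
#' @param baseline_meanlog,baseline_sdlog lognormal parameters for null genes.
#' @param effect_baseline_meanlog,effect_baseline_sdlog lognormal parameters
#'   for planted-effect genes.
#' @param seed RNG seed.
#' @return list with `counts` (sparse genes-by-cells `dgCMatrix`),
#'   `baseline`, `size_factors`.
#' @export
simulate_expression <- function(cells, n_genes, effects = NULL,
                                baseline = NULL, dispersion = 0.3,
                                size_factor_sd = 0.3, gene_ids = NULL,
                                baseline_meanlog = log(0.2),
                                baseline_sdlog = 1.2,
                                effect_baseline_meanlog = log(4),
                                effect_baseline_sdlog = 0.3,
                                seed = 1L) {
  cells <- as.data.table(cells)
  gene_ids <- gene_ids %||% sprintf("g%04d", seq_len(n_genes))
  stopifnot(length(gene_ids) == n_genes)
  match_cells <- function(type, value) {
    switch(type,
      tissue = cells$tissue_class == value,
      cancer = cells$tissue_class == "cancer",
      cluster = cells$tissue_class == "cancer" & !is.na(cells$cluster) &
        as.character(cells$cluster) == as.character(value),
      state = cells$tissue_class == "cancer" & !is.na(cells$state) &
        cells$state == value,
      stop("unknown effect type: ", type))
  }
  if (!is.null(effects)) {
    effects <- as.data.table(effects)
    stopifnot(all(effects$gene %in% gene_ids))
    for (gn in unique(effects$gene[duplicated(effects$gene)])) {
      sub <- effects[gene == gn]
      masks <- lapply(seq_len(nrow(sub)), function(i) match_cells(sub$type[i], sub$value[i]))
      for (i in seq_len(nrow(sub) - 1L)) for (j in (i + 1L):nrow(sub)) {
        if (any(masks[[i]] & masks[[j]]) &&
            sign(sub$log2fc[i]) != sign(sub$log2fc[j])) {
          stop("conflicting planted effects on gene ", gn,
               ": overlapping cell selectors with opposite signs")
        }
      }
    }
  }
  with_seed(seed, {
    if (is.null(baseline)) {
      baseline <- rlnorm(n_genes, baseline_meanlog, baseline_sdlog)
      names(baseline) <- gene_ids
      if (!is.null(effects)) {
        eg <- unique(effects$gene)
        baseline[eg] <- rlnorm(length(eg), effect_baseline_meanlog,
                               effect_baseline_sdlog)
      }
    }
    sf <- rlnorm(nrow(cells), 0, size_factor_sd)
    lfc <- matrix(0, n_genes, nrow(cells))
    if (!is.null(effects)) {
      for (i in seq_len(nrow(effects))) {
        mask <- match_cells(effects$type[i], effects$value[i])
        gi <- match(effects$gene[i], gene_ids)
        lfc[gi, mask] <- lfc[gi, mask] + effects$log2fc[i]
      }
    }
    mu <- sweep(baseline * 2^lfc, 2, sf, "*")
    counts <- if (dispersion <= 0) rpois(length(mu), mu)
              else rnbinom(length(mu), size = 1 / dispersion, mu = mu)
    m <- Matrix::Matrix(matrix(counts, n_genes, nrow(cells),
                               dimnames = list(gene_ids, cells$cell_id)),
                        sparse = TRUE)
    list(counts = m, baseline = baseline, size_factors = sf)
  })
}
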