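# End-to-end orchestration: simulate (or load) a cohort, run the SCNA,
# methylome, transcriptome and integration stages, compute planted-truth
# recovery metrics, and emit a deterministic report.

#' Map partition labels onto a reference partition by majority vote
#'
#' Each label of `labels` is renamed to the reference label holding the
#' majority of its cells (greedy, largest classes first, without reuse).
#' Useful for comparing an inferred clustering with a planted truth up to
#' label permutation.
#' @param labels named vector (cell -> label).
#' @param reference named vector (cell -> reference label), same cells.
#' @return named vector with `labels` renamed into reference labels (classes
#'   left over keep their original name prefixed `unmatched_`).
#' @export
match_partition_labels <- function(labels, reference) {
  cells <- intersect(names(labels), names(reference))
  tab <- table(labels[cells], reference[cells])
  map <- character(nrow(tab))
  names(map) <- rownames(tab)
  used <- character()
  for (lb in rownames(tab)[order(-rowSums(tab))]) {
    cand <- colnames(tab)[order(-tab[lb, ])]
    cand <- setdiff(cand, used)
    if (length(cand)) {
      map[lb] <- cand[1]
      used <- c(used, cand[1])
    } else {
      map[lb] <- paste0("unmatched_", lb)
    }
  }
  out <- map[as.character(labels)]
  names(out) <- names(labels)
  out
}

#' Adjusted Rand index between two labelings
#' @param a,b named label vectors (intersecting cells compared).
#' @return ARI in [-1, 1].
#' @export
ari <- function(a, b) {
  cells <- intersect(names(a), names(b))
  mclust::adjustedRandIndex(as.character(a[cells]), as.character(b[cells]))
}

.stage <- function(name, code) {
  tryCatch(code, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full trio-omics analysis pipeline
#'
#' Executes simulate (optional) -> SCNA lineages -> methylome ->
#' transcriptome -> integration on one cohort and returns a result bundle.
#' When the cohort carries planted truth, recovery metrics (lineage/cluster
#' ARI, clone methylation recovery, DMP/DEG sensitivity and FDR, state
#' accuracy, signature overlap fractions) are computed as part of the
#' integration stage. With `out_dir`, all result tables plus a plain-text
#' report, the configuration echo and the seed are written; reruns at a
#' fixed seed are bit-identical.
#'
#' @param config list (or path to a YAML file) with optional entries:
#'   `seed` (default 1), `simulate` (list of [cohort_params()] overrides;
#'   default empty = default cohort), `input_dir` (load a written cohort
#'   instead of simulating), `k_lineages`/`k_clusters` (`"auto"`),
#'   `n_hvg`, `dmp` / `deg` threshold lists.
#' @param out_dir optional output directory (created; overwritten files).
#' @return invisible list with components `cohort`, `scna`, `methylome`,
#'   `rna`, `integration`, `recovery`, `config`.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- config$seed %||% 1L
  k_lineages <- config$k_lineages %||% "auto"
  k_clusters <- config$k_clusters %||% "auto"
  n_hvg <- config$n_hvg %||% 1000L
  dmp_opt <- config$dmp %||% list()
  deg_opt <- config$deg %||% list()

  cohort <- .stage("simulate", {
    if (!is.null(config$input_dir)) {
      read_cohort(config$input_dir)
    } else if (is.null(config$simulate) || is.list(config$simulate)) {
      simulate_cohort(do.call(cohort_params, config$simulate %||% list()),
                      seed = seed)
    } else {
      stop("config must provide either `input_dir` or a `simulate` block")
    }
  })
  meta <- cohort$meta
  patients <- setdiff(unique(meta[tissue_class == "cancer", patient]), NA)

  scna <- .stage("scna", {
    res <- list()
    for (pp in patients) {
      canc <- meta[patient == pp & tissue_class == "cancer", cell_id]
      nor <- meta[patient == pp & tissue_class == "normal_epi_stomach", cell_id]
      canc <- intersect(canc, colnames(cohort$dna))
      nor <- intersect(nor, colnames(cohort$dna))
      prof <- compute_scna_profiles(cohort$dna[, canc, drop = FALSE],
                                    cohort$dna[, nor, drop = FALSE],
                                    bins = cohort$regions[role == "bin"])
      rho <- scna_correlations(prof)
      lin <- cluster_lineages(rho, k = k_lineages)
      pca <- scna_pca(prof)
      res[[pp]] <- list(profiles = prof, correlations = rho, lineages = lin,
                        pca = pca)
    }
    labels <- unlist(lapply(patients, function(pp) {
      lb <- res[[pp]]$lineages$labels
      setNames(paste0(pp, ":", lb), names(lb))
    }))
    list(per_patient = res, labels = labels)
  })

  methylome <- .stage("methylome", {
    glob <- global_level(cohort$wcg, "WCG")
    rep_lvl <- repeat_class_levels(cohort$wcg,
                                   cohort$regions[role == "repeat"])
    promoters <- cohort$regions[role == "promoter"]
    prom_wcg <- region_levels(cohort$wcg, promoters, "WCG")
    prom_gch <- region_levels(cohort$gch, promoters, "GCH")
    wcg_mat <- level_matrix(prom_wcg, regions = promoters$name)
    gch_mat <- level_matrix(prom_gch, regions = promoters$name)
    cancer_cells <- meta[tissue_class == "cancer", cell_id]
    normal_cells <- meta[tissue_class == "normal_epi_stomach", cell_id]
    dmp_args <- function(mat, ga, gb, pat = NA_character_) {
      do.call(call_dmps, c(list(mat, ga, gb, patient = pat), dmp_opt))
    }
    dmps_pooled <- dmp_args(wcg_mat, cancer_cells, normal_cells)
    acc_pooled <- dmp_args(gch_mat, cancer_cells, normal_cells)
    dmps_per_pat <- lapply(patients, function(pp) {
      dmp_args(wcg_mat, meta[patient == pp & tissue_class == "cancer", cell_id],
               meta[patient == pp & tissue_class == "normal_epi_stomach", cell_id],
               pat = pp)
    })
    names(dmps_per_pat) <- patients
    dmps_shared <- shared_features(dmps_per_pat, min_fraction = 0.5)
    list(global = glob, repeat_levels = rep_lvl, promoter_wcg = wcg_mat,
         promoter_gch = gch_mat, dmps_pooled = dmps_pooled,
         acc_pooled = acc_pooled, dmps_per_patient = dmps_per_pat,
         dmps_shared = dmps_shared)
  })

  rna <- .stage("rna", {
    norm <- normalize_expression(cohort$rna)
    kept <- colnames(norm$mat)
    cancer_cells <- intersect(meta[tissue_class == "cancer", cell_id], kept)
    stomach_cells <- intersect(meta[tissue_class == "normal_epi_stomach", cell_id], kept)
    colon_cells <- intersect(meta[tissue_class == "normal_epi_colon", cell_id], kept)
    clusters_pp <- lapply(patients, function(pp) {
      cells <- intersect(meta[patient == pp & tissue_class == "cancer", cell_id], kept)
      cluster_transcriptome(norm, k = k_clusters, cells = cells, n_hvg = n_hvg)
    })
    names(clusters_pp) <- patients
    cluster_labels <- unlist(lapply(patients, function(pp) {
      lb <- clusters_pp[[pp]]$labels
      setNames(paste0(pp, ":", lb), names(lb))
    }))
    degs <- do.call(call_degs,
                    c(list(norm, cancer_cells, stomach_cells,
                           per_patient = TRUE, meta = meta), deg_opt))
    degs_shared <- attr(degs, "shared")
    degs_pooled <- do.call(call_degs,
                           c(list(norm, cancer_cells, stomach_cells), deg_opt))
    sigs <- derive_signatures(norm, stomach_cells, colon_cells)
    up_shared <- degs_shared[direction == "up", feature]
    down_shared <- degs_shared[direction == "down", feature]
    colon_overlap <- if (length(sigs$colon_high))
      signature_overlap_fraction(up_shared, sigs$colon_high) else NULL
    stomach_overlap <- if (length(sigs$stomach_high))
      signature_overlap_fraction(down_shared, sigs$stomach_high) else NULL
    histopath <- NULL
    if (!is.null(cohort$truth)) {
      tc <- cohort$truth$cells
      histopath <- setNames(tc$state, tc$cell_id)
    }
    axis <- differentiation_axis(norm, cancer_cells, stomach_cells,
                                 clusters = cluster_labels,
                                 histopath = histopath, n_hvg = n_hvg)
    scores <- gene_set_scores(norm, cohort$gene_sets)
    list(norm = norm, clusters = clusters_pp, cluster_labels = cluster_labels,
         degs = degs, degs_shared = degs_shared, degs_pooled = degs_pooled,
         signatures = sigs,
         colon_overlap = colon_overlap, stomach_overlap = stomach_overlap,
         axis = axis, scores = scores)
  })

  integration <- .stage("integration", {
    lin_meth <- lapply(patients, function(pp) {
      lab <- scna$per_patient[[pp]]$lineages$labels
      lineage_methylation(lab, methylome$global, meta)
    })
    names(lin_meth) <- patients
    contingency <- lapply(patients, function(pp) {
      lab <- scna$per_patient[[pp]]$lineages$labels
      cl <- rna$clusters[[pp]]$labels
      lineage_cluster_contingency(lab, cl[names(lab)])
    })
    names(contingency) <- patients
    states <- rna$axis$states
    state_meth <- state_methylation_compare(states, methylome$global, meta)
    trio <- trio_concordance(rna$degs_pooled, methylome$dmps_pooled,
                             methylome$acc_pooled)
    list(lineage_methylation = lin_meth, contingency = contingency,
         state_methylation = state_meth, trio = trio)
  })

  recovery <- if (!is.null(cohort$truth)) {
    .stage("recovery", .recovery_metrics(cohort, scna, methylome, rna,
                                         integration))
  } else NULL

  result <- list(cohort = cohort, scna = scna, methylome = methylome,
                 rna = rna, integration = integration, recovery = recovery,
                 config = c(list(seed = seed), config[setdiff(names(config), "seed")]))
  if (!is.null(out_dir)) .write_report(result, out_dir)
  invisible(result)
}

# Planted-truth recovery metrics; every quantity here is recomputed from the
# pipeline outputs against the generator's truth tables.
.recovery_metrics <- function(cohort, scna, methylome, rna, integration) {
  truth <- cohort$truth
  tc <- truth$cells
  truth_clone <- setNames(tc$clone, tc$cell_id)
  truth_cluster <- setNames(paste0(tc$patient, ":", tc$cluster), tc$cell_id)
  truth_state <- setNames(tc$state, tc$cell_id)
  patients <- names(scna$per_patient)

  lineage_ari <- vapply(patients, function(pp) {
    ari(scna$per_patient[[pp]]$lineages$labels, truth_clone)
  }, 0)
  cluster_ari <- vapply(patients, function(pp) {
    ari(rna$clusters[[pp]]$labels, truth_cluster)
  }, 0)

  glob <- methylome$global
  clone_err <- truth$clones[, {
    cells <- tc[clone == .BY$clone, cell_id]
    est <- glob[cell_id %in% cells, median(level)]
    .(planted = meth_level[1], estimated = est, error = est - meth_level[1])
  }, by = clone]

  shared <- rna$degs_shared
  up <- shared[direction == "up", feature]
  down <- shared[direction == "down", feature]
  tg <- truth$genes
  deg_up_truth <- tg[block == "deg_up", gene]
  deg_down_truth <- tg[block == "deg_down", gene]
  universe <- truth_deg_universe(cohort)
  called <- union(up, down)
  deg_sensitivity <- (sum(deg_up_truth %in% up) + sum(deg_down_truth %in% down)) /
    (length(deg_up_truth) + length(deg_down_truth))
  deg_fdr <- if (length(called)) mean(!called %in% universe) else 0

  dmp <- methylome$dmps_pooled
  dmp_called <- dmp[called == TRUE]
  truth_dmps <- truth$dmps
  dmp_sensitivity <- mean(truth_dmps$name %in% dmp_called$feature)
  dmp_fd <- sum(!dmp_called$feature %in% truth_dmps$name)

  states_inf <- rna$axis$states
  cancer_cells <- tc$cell_id
  state_accuracy <- mean(states_inf[cancer_cells] == truth_state[cancer_cells],
                         na.rm = TRUE)

  contingency_exact <- vapply(patients, function(pp) {
    lab <- scna$per_patient[[pp]]$lineages$labels
    cl <- rna$clusters[[pp]]$labels
    mapped_lin <- match_partition_labels(lab, truth_clone)
    mapped_cl <- match_partition_labels(
      setNames(paste0(pp, ":", cl), names(cl)), truth_cluster)
    t_inf <- table(mapped_lin[names(lab)], mapped_cl[names(lab)])
    tt <- tc[patient == pp]
    t_true <- table(tt$clone, paste0(pp, ":", tt$cluster))
    identical(as.vector(t_inf[sort(rownames(t_inf)), sort(colnames(t_inf))]),
              as.vector(t_true[sort(rownames(t_true)), sort(colnames(t_true))])) &&
      setequal(rownames(t_inf), rownames(t_true)) &&
      setequal(colnames(t_inf), colnames(t_true))
  }, TRUE)

  overlap <- list(
    colon_fraction = rna$colon_overlap$fraction %||% NA_real_,
    stomach_fraction = rna$stomach_overlap$fraction %||% NA_real_)

  # planted PT-LN shifts: lineage summaries joined to truth offsets by
  # majority clone
  shift_flags <- rbindlist(lapply(patients, function(pp) {
    lab <- scna$per_patient[[pp]]$lineages$labels
    mapped <- match_partition_labels(lab, truth_clone)
    summ <- integration$lineage_methylation[[pp]]$summaries
    lin2clone <- unique(data.table(lineage = unname(lab), clone = unname(mapped)))
    m <- merge(summ, lin2clone, by = "lineage")
    merge(m, cohort$truth$clones[, .(clone, pt_ln_offset)], by = "clone")
  }))

  imm <- rna$scores
  better <- names(truth_state)[truth_state == "better_diff"]
  poorer <- names(truth_state)[truth_state == "poorer_diff"]
  better <- intersect(better, colnames(imm))
  poorer <- intersect(poorer, colnames(imm))
  immune_direction_ok <- all(apply(imm, 1, function(s) {
    median(s[better], na.rm = TRUE) > median(s[poorer], na.rm = TRUE)
  }))

  list(lineage_ari = lineage_ari, cluster_ari = cluster_ari,
       clone_meth = clone_err, deg_sensitivity = deg_sensitivity,
       deg_fdr = deg_fdr, dmp_sensitivity = dmp_sensitivity,
       dmp_false_discoveries = dmp_fd, state_accuracy = state_accuracy,
       separating_auroc = unname(rna$axis$separating_auroc),
       contingency_exact = contingency_exact, overlap = overlap,
       shift_flags = shift_flags, immune_direction_ok = immune_direction_ok,
       state_ordering = integration$state_methylation)
}

# Deterministic plain-text + TSV report (no timestamps).
.write_report <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, f) fwrite(x, file.path(out_dir, f), sep = "\t")
  lab <- result$scna$labels
  w(data.table(cell_id = names(lab), lineage = unname(lab)), "lineages.tsv")
  w(result$methylome$global, "global_wcg.tsv")
  w(result$methylome$repeat_levels, "repeat_levels.tsv")
  w(result$methylome$dmps_pooled, "dmps_pooled.tsv")
  w(result$methylome$dmps_shared, "dmps_shared.tsv")
  cl <- result$rna$cluster_labels
  w(data.table(cell_id = names(cl), cluster = unname(cl)), "clusters.tsv")
  w(result$rna$degs, "degs_per_patient.tsv")
  w(result$rna$degs_shared, "degs_shared.tsv")
  w(data.table(gene = result$rna$signatures$stomach_high, signature = "stomach_high"),
    "signature_stomach.tsv")
  w(data.table(gene = result$rna$signatures$colon_high, signature = "colon_high"),
    "signature_colon.tsv")
  st <- result$rna$axis$states
  w(data.table(cell_id = names(st), state = unname(st),
               coord = result$rna$axis$coords[names(st), result$rna$axis$axis_component]),
    "states.tsv")
  sc <- result$rna$scores
  w(data.table(set = rownames(sc), sc), "gene_set_scores.tsv")
  w(result$integration$state_methylation, "state_methylation.tsv")
  w(result$integration$trio, "trio_concordance.tsv")
  for (pp in names(result$integration$contingency)) {
    tab <- as.data.table(result$integration$contingency[[pp]]$table)
    w(tab, paste0("contingency_", pp, ".tsv"))
  }
  rbl <- rbindlist(lapply(names(result$integration$lineage_methylation), function(pp) {
    s <- copy(result$integration$lineage_methylation[[pp]]$summaries)
    s[, patient := pp][]
  }))
  w(rbl, "lineage_methylation.tsv")
  yaml::write_yaml(result$config, file.path(out_dir, "config_echo.yaml"))

  rec <- result$recovery
  lines <- c("# trio-omics pipeline report",
             "",
             sprintf("seed: %d", result$config$seed),
             sprintf("cells: %d (%d cancer)", nrow(result$cohort$meta),
                     sum(result$cohort$meta$tissue_class == "cancer")),
             sprintf("patients: %s",
                     paste(names(result$scna$per_patient), collapse = ", ")),
             "")
  if (!is.null(rec)) {
    lines <- c(lines, "## planted-truth recovery", "",
      sprintf("lineage ARI: %s",
              paste(sprintf("%s=%.3f", names(rec$lineage_ari), rec$lineage_ari),
                    collapse = " ")),
      sprintf("cluster ARI: %s",
              paste(sprintf("%s=%.3f", names(rec$cluster_ari), rec$cluster_ari),
                    collapse = " ")),
      sprintf("max clone methylation error: %.4f",
              rec$clone_meth[, max(abs(error))]),
      sprintf("DEG sensitivity: %.3f, empirical FDR: %.3f",
              rec$deg_sensitivity, rec$deg_fdr),
      sprintf("DMP sensitivity: %.3f, false discoveries: %d",
              rec$dmp_sensitivity, rec$dmp_false_discoveries),
      sprintf("state accuracy: %.3f (normal/cancer AUROC %.3f)",
              rec$state_accuracy, rec$separating_auroc),
      sprintf("contingency recovered exactly: %s",
              paste(sprintf("%s=%s", names(rec$contingency_exact),
                            rec$contingency_exact), collapse = " ")),
      sprintf("colon-signature overlap fraction: %.3f",
              rec$overlap$colon_fraction),
      sprintf("stomach-signature overlap fraction: %.3f",
              rec$overlap$stomach_fraction),
      sprintf("immune sets higher in better_diff: %s", rec$immune_direction_ok),
      sprintf("state ordering ok in %d/%d patients",
              rec$state_ordering[skipped == FALSE, sum(ordering_ok)],
              nrow(rec$state_ordering)))
    w(rec$clone_meth, "recovery_clone_meth.tsv")
    w(rec$shift_flags, "recovery_shift_flags.tsv")
  }
  writeLines(lines, file.path(out_dir, "report.md"))
  invisible(out_dir)
}
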