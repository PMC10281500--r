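# Assembly of the default synthetic trio-omics cohort: the study conditions
# (patients, clones, planted levels and effect sizes) live in
# cohort_params(); simulate_cohort() wires the per-omic generators together
# and records the planted truth tables used as oracles downstream.

#' Default synthetic-cohort parameters
#'
#' Desk-scale conditions: 2 patients x 3 clones x 50 cancer cells, 30 normal
#' stomach cells per patient plus one 30-cell normal colon reference, 1,000
#' genome bins, 2,000 promoters, 200 repeat regions in 3 classes, 5,000
#' genes. Planted structure: clone global WCG levels 0.55/0.65/0.75 against
#' 0.80 in normal stomach; repeat-class demethylation factors L1 0.80 /
#' LTR 0.85 / satellite 0.67 of the cell's global level; a PT-vs-LN global
#' methylation offset of 0.06 for the middle lineage of each patient and
#' 0.02 for the others; 120 hyper- and 30 hypomethylated promoters at
#' |delta| = 0.3; 500 cancer-vs-stomach DEGs at |log2FC| = 2 (10% of genes);
#' a 60-gene colon signature of which 25% is aberrantly activated in cancer
#' cells and an 80-gene stomach signature of which 50% is lost in cancer
#' cells; per-cluster marker programs wired many-to-many onto the clones
#' (clone A -> cluster 1, clone B -> clusters 1+2, clone C -> cluster 3);
#' clusters 1-2 form the better differentiated state and cluster 3 the
#' poorer one, with a poorer-state program and three immune gene sets more
#' active in better-differentiated cells.
#'
#' @param ... overrides for individual entries.
#' @return named list of parameters.
#' @export
cohort_params <- function(...) {
  p <- list(
    patients = c("P1", "P2"),
    clones_per_patient = 3L,
    cells_per_clone = 50L,
    n_normal_stomach = 30L,
    n_colon = 30L,
    pt_fraction = 0.6,
    # DNA / SCNA
    n_bins = 1000L,
    bin_width = 10000L,
    events_per_clone = 8L,
    max_event_len = 50L,
    mean_reads_per_bin = 50,
    dna_overdispersion = 0.1,
    # methylome
    n_promoters = 2000L,
    n_repeats = 200L,
    repeat_classes = c("L1", "LTR", "satellite"),
    clone_meth_levels = c(0.55, 0.65, 0.75),
    normal_meth_level = 0.80,
    repeat_meth_factors = c(L1 = 0.80, LTR = 0.85, satellite = 0.67),
    pt_ln_offsets = c(0.02, 0.06, 0.02),
    dmp_delta = 0.3,
    n_hyper_dmps = 120L,
    n_hypo_dmps = 30L,
    bin_sites = 4L, bin_reads = 5L,
    promoter_sites = 3L, promoter_reads = 2L,
    repeat_sites = 3L, repeat_reads = 4L,
    acc_background = 0.25,
    acc_coupling = 1,
    # transcriptome
    n_genes = 5000L,
    deg_log2fc = 2,
    n_deg_up = 250L,
    n_deg_down = 250L,
    sig_log2fc = 3,
    n_colon_sig = 60L,
    colon_sig_cancer_frac = 0.25,
    n_stomach_sig = 80L,
    stomach_sig_retained_frac = 0.5,
    n_clusters = 3L,
    cluster_marker_log2fc = 3,
    n_cluster_markers = 60L,
    poorer_log2fc = log2(5),
    n_poorer_genes = 80L,
    immune_log2fc = log2(3),
    immune_set_sizes = c(30L, 30L, 30L),
    expr_dispersion = 0.3,
    size_factor_sd = 0.3,
    # gene-index layout of the planted blocks (1-based starts)
    deg_block_start = 141L,
    marker_block_start = 701L,
    dmp_hyper_start = 1500L,
    dmp_hypo_start = 1800L
  )
  over <- list(...)
  stopifnot(all(names(over) %in% names(p)))
  p[names(over)] <- over
  p
}

# Genome layout: bins on chr1, promoters (TSS +/- 1 kb of genes g0001...)
# on chr2, repeat regions on chr3 with cycling class labels.
cohort_regions <- function(p) {
  bins <- data.table(
    chrom = "chr1",
    start = (seq_len(p$n_bins) - 1L) * p$bin_width,
    end = seq_len(p$n_bins) * p$bin_width,
    name = sprintf("bin%04d", seq_len(p$n_bins)),
    role = "bin", class_label = NA_character_,
    n_sites = p$bin_sites, reads_per_site = p$bin_reads)
  tss <- seq_len(p$n_promoters) * 10000L
  proms <- data.table(
    chrom = "chr2", start = tss - 1000L, end = tss + 1000L,
    name = sprintf("g%04d", seq_len(p$n_promoters)),
    role = "promoter", class_label = NA_character_,
    n_sites = p$promoter_sites, reads_per_site = p$promoter_reads)
  reps <- data.table(
    chrom = "chr3",
    start = (seq_len(p$n_repeats) - 1L) * 5000L,
    end = (seq_len(p$n_repeats) - 1L) * 5000L + 1000L,
    name = sprintf("rep%03d", seq_len(p$n_repeats)),
    role = "repeat",
    class_label = rep(p$repeat_classes, length.out = p$n_repeats),
    n_sites = p$repeat_sites, reads_per_site = p$repeat_reads)
  rbindlist(list(bins, proms, reps))
}

# Gene block layout over g0001..gNNNN; blocks are disjoint except that the
# colon/stomach signature genes carry an additional cancer-cell effect for
# their aberrant subsets. All promoter-coupled blocks sit below n_promoters.
cohort_gene_blocks <- function(p) {
  g <- function(from, n) sprintf("g%04d", seq(from, length.out = n))
  n_colon_cancer <- round(p$n_colon_sig * p$colon_sig_cancer_frac)
  n_stomach_ret <- round(p$n_stomach_sig * p$stomach_sig_retained_frac)
  blocks <- list(
    colon_sig = g(1L, p$n_colon_sig),
    colon_sig_cancer = g(1L, n_colon_cancer),
    stomach_sig = g(1L + p$n_colon_sig, p$n_stomach_sig),
    stomach_retained = g(1L + p$n_colon_sig, n_stomach_ret),
    deg_up = g(p$deg_block_start, p$n_deg_up),
    deg_down = g(p$deg_block_start + p$n_deg_up, p$n_deg_down)
  )
  # cluster marker programs are patient-specific (strong inter-patient
  # transcriptomic heterogeneity); the differentiation-state and immune
  # programs are shared across patients
  at <- p$marker_block_start
  for (pat in p$patients) for (k in seq_len(p$n_clusters)) {
    blocks[[paste0("markers_", pat, ":", k)]] <- g(at, p$n_cluster_markers)
    at <- at + p$n_cluster_markers
  }
  blocks$poorer_program <- g(at, p$n_poorer_genes)
  at <- at + p$n_poorer_genes
  blocks$immune_a <- g(at, p$immune_set_sizes[1])
  blocks$immune_b <- g(at + p$immune_set_sizes[1], p$immune_set_sizes[2])
  blocks$immune_c <- g(at + sum(p$immune_set_sizes[1:2]), p$immune_set_sizes[3])
  last <- at + sum(p$immune_set_sizes)
  stopifnot(last <= p$dmp_hyper_start,
            p$deg_block_start + p$n_deg_up + p$n_deg_down <= p$marker_block_start,
            1L + p$n_colon_sig + p$n_stomach_sig <= p$deg_block_start,
            p$dmp_hypo_start + p$n_hypo_dmps <= p$n_promoters + 1L)
  # stomach genes NOT retained in cancer are the planted "lost" signature
  blocks$stomach_lost <- setdiff(blocks$stomach_sig, blocks$stomach_retained)
  blocks
}

#' Simulate the full trio-omics cohort
#'
#' Runs the clone, DNA-coverage, methylome/accessibility and expression
#' generators under one master seed and assembles the planted truth tables.
#'
#' @param params a [cohort_params()] list.
#' @param seed master seed; stage seeds are derived as small offsets.
#' @return object of class `trio_cohort`: list with `params`, `seed`, `meta`
#'   (cell metadata), `regions` (bins/promoters/repeats), `cn_maps` (per
#'   patient), `dna` (bins-by-cells count matrix incl. normals), `wcg`,
#'   `gch` (call tables), `rna` (sparse counts), `gene_sets` (immune sets),
#'   `truth` (list of data.tables: `cells`, `genes`, `dmps`, `clones`,
#'   `signatures`).
#' @export
simulate_cohort <- function(params = cohort_params(), seed = 1L) {
  p <- params
  stopifnot(length(p$clone_meth_levels) == p$clones_per_patient,
            length(p$pt_ln_offsets) == p$clones_per_patient)
  regions <- cohort_regions(p)
  blocks <- cohort_gene_blocks(p)
  clone_letters <- LETTERS[seq_len(p$clones_per_patient)]

  meta_list <- list()
  dna_list <- list()
  cn_maps <- list()
  truth_cells <- list()
  for (pi in seq_along(p$patients)) {
    pat <- p$patients[pi]
    clone_ids <- paste0(pat, "_", clone_letters)
    cn_map <- simulate_clones(p$clones_per_patient, p$n_bins,
                              p$events_per_clone, p$max_event_len,
                              seed = seed + 10L * pi, clone_ids = clone_ids)
    cn_maps[[pat]] <- cn_map
    dna <- simulate_dna(cn_map, p$cells_per_clone, p$mean_reads_per_bin,
                        p$dna_overdispersion, n_normal = p$n_normal_stomach,
                        seed = seed + 10L * pi + 1L, cell_prefix = pat)
    colnames(dna$normal_counts) <- sprintf("%s_N_%03d", pat,
                                           seq_len(p$n_normal_stomach))
    dna_list[[pat]] <- cbind(dna$counts, dna$normal_counts)
    cc <- dna$cell_clone
    # within-clone layout: first pt_fraction of cells PT, rest LN;
    # clusters: clone A -> 1, clone B -> 1/2 split, clone C -> 3 (letters
    # generalize as A -> 1, mid clones split with the next cluster, last ->
    # n_clusters)
    cc[, patient := pat]
    cc[, idx := seq_len(.N), by = clone]
    n_pt <- ceiling(p$cells_per_clone * p$pt_fraction)
    cc[, site := ifelse(idx <= n_pt, "PT", "LN")]
    cc[, site_position := ifelse(site == "PT",
                                 paste0("PT", 1L + idx %% 2L),
                                 paste0("LN1-", 1L + idx %% 2L))]
    clone_no <- match(cc$clone, clone_ids)
    cl <- integer(nrow(cc))
    cl[clone_no == 1L] <- 1L
    cl[clone_no == p$clones_per_patient] <- p$n_clusters
    mid <- clone_no > 1L & clone_no < p$clones_per_patient
    cl[mid] <- ifelse(cc$idx[mid] <= p$cells_per_clone / 2, 1L, 2L)
    cc[, cluster := cl]
    cc[, state := ifelse(cluster == p$n_clusters, "poorer_diff", "better_diff")]
    truth_cells[[pat]] <- cc[, .(cell_id, patient, clone, cluster, state,
                                 site, site_position)]
    meta_list[[pat]] <- rbindlist(list(
      cc[, .(cell_id, patient, site, site_position, tissue_class = "cancer")],
      data.table(cell_id = colnames(dna$normal_counts), patient = pat,
                 site = "NAT", site_position = "NAT1",
                 tissue_class = "normal_epi_stomach")))
  }
  colon_meta <- data.table(
    cell_id = sprintf("CREF_C_%03d", seq_len(p$n_colon)),
    patient = "CREF", site = "NAT", site_position = "NAT1",
    tissue_class = "normal_epi_colon")
  meta <- rbindlist(c(meta_list, list(colon_meta)))
  truth_cells <- rbindlist(truth_cells)
  dna_counts <- do.call(cbind, dna_list)
  rownames(dna_counts) <- regions[role == "bin", name]

  # --- methylome (no colon reference cells; methylome covers the trio cells)
  meth_cells <- merge(meta[tissue_class != "normal_epi_colon"],
                      truth_cells[, .(cell_id, clone)], by = "cell_id",
                      all.x = TRUE, sort = FALSE)
  clone_levels <- setNames(
    rep(p$clone_meth_levels, times = length(p$patients)),
    as.vector(vapply(p$patients, function(pat) paste0(pat, "_", clone_letters),
                     character(p$clones_per_patient))))
  pt_ln <- setNames(rep(p$pt_ln_offsets, times = length(p$patients)),
                    names(clone_levels))
  dmps <- rbindlist(list(
    # promoters of aberrantly activated colon-signature genes: hypomethylated
    data.table(name = blocks$colon_sig_cancer, delta = -p$dmp_delta),
    # promoters of lost stomach-signature genes: hypermethylated
    data.table(name = blocks$stomach_lost, delta = p$dmp_delta),
    # additional pure DMPs on promoters without expression programs
    data.table(name = sprintf("g%04d", seq(p$dmp_hyper_start,
                                           length.out = p$n_hyper_dmps -
                                             length(blocks$stomach_lost))),
               delta = p$dmp_delta),
    data.table(name = sprintf("g%04d", seq(p$dmp_hypo_start,
                                           length.out = p$n_hypo_dmps -
                                             length(blocks$colon_sig_cancer))),
               delta = -p$dmp_delta)))
  meth <- simulate_methylome(
    meth_cells[, .(cell_id, tissue_class, clone, site)], regions,
    clone_levels = clone_levels, planted_dmps = dmps,
    normal_level = p$normal_meth_level,
    repeat_factors = p$repeat_meth_factors, pt_ln_offsets = pt_ln,
    acc_background = p$acc_background, acc_coupling = p$acc_coupling,
    seed = seed + 40L)

  # --- transcriptome
  expr_cells <- merge(meta, truth_cells[, .(cell_id, cluster, state)],
                      by = "cell_id", all.x = TRUE, sort = FALSE)
  expr_cells[, cluster := ifelse(is.na(cluster), NA_character_,
                                 paste0(patient, ":", cluster))]
  marker_effects <- rbindlist(lapply(
    grep("^markers_", names(blocks), value = TRUE), function(b) {
      data.table(gene = blocks[[b]], type = "cluster",
                 value = sub("^markers_", "", b),
                 log2fc = p$cluster_marker_log2fc)
    }))
  effects <- rbindlist(list(
    data.table(gene = blocks$colon_sig, type = "tissue",
               value = "normal_epi_colon", log2fc = p$sig_log2fc),
    data.table(gene = blocks$colon_sig_cancer, type = "cancer", value = NA,
               log2fc = p$deg_log2fc),
    data.table(gene = blocks$stomach_sig, type = "tissue",
               value = "normal_epi_stomach", log2fc = p$sig_log2fc),
    data.table(gene = blocks$stomach_retained, type = "cancer", value = NA,
               log2fc = p$sig_log2fc),
    data.table(gene = blocks$deg_up, type = "cancer", value = NA,
               log2fc = p$deg_log2fc),
    data.table(gene = blocks$deg_down, type = "cancer", value = NA,
               log2fc = -p$deg_log2fc),
    marker_effects,
    data.table(gene = blocks$poorer_program, type = "state",
               value = "poorer_diff", log2fc = p$poorer_log2fc),
    data.table(gene = c(blocks$immune_a, blocks$immune_b, blocks$immune_c),
               type = "state", value = "better_diff", log2fc = p$immune_log2fc)
  ))
  expr <- simulate_expression(
    expr_cells[, .(cell_id, tissue_class, cluster, state)], p$n_genes,
    effects = effects, dispersion = p$expr_dispersion,
    size_factor_sd = p$size_factor_sd, seed = seed + 50L)

  gene_sets <- list(immune_response_a = blocks$immune_a,
                    immune_response_b = blocks$immune_b,
                    immune_response_c = blocks$immune_c)

  truth_genes <- rbindlist(lapply(names(blocks), function(b) {
    if (length(blocks[[b]]) == 0L) return(NULL)
    data.table(gene = blocks[[b]], block = b)
  }))
  truth_clones <- data.table(
    clone = names(clone_levels),
    patient = rep(p$patients, each = p$clones_per_patient),
    meth_level = as.numeric(clone_levels),
    pt_ln_offset = as.numeric(pt_ln))
  truth_dmps <- copy(dmps)[, direction := ifelse(delta > 0, "hyper", "hypo")]
  truth_sig <- data.table(
    gene = c(blocks$colon_sig, blocks$stomach_sig),
    signature = c(rep("colon_high", length(blocks$colon_sig)),
                  rep("stomach_high", length(blocks$stomach_sig))),
    aberrant_in_cancer = c(blocks$colon_sig %in% blocks$colon_sig_cancer,
                           blocks$stomach_sig %in% blocks$stomach_lost))

  structure(list(
    params = p, seed = as.integer(seed), meta = meta, regions = regions,
    cn_maps = cn_maps, dna = dna_counts, wcg = meth$wcg, gch = meth$gch,
    rna = expr$counts, gene_sets = gene_sets,
    expected = meth$expected,
    truth = list(cells = truth_cells, genes = truth_genes, dmps = truth_dmps,
                 clones = truth_clones, signatures = truth_sig)
  ), class = "trio_cohort")
}

#' @export
print.trio_cohort <- function(x, ...) {
  cat(sprintf(paste0("trio_cohort: %d cells (%d cancer), %d patients, ",
                     "%d bins, %d genes, seed %d\n"),
              nrow(x$meta), sum(x$meta$tissue_class == "cancer"),
              length(x$params$patients), x$params$n_bins, x$params$n_genes,
              x$seed))
  invisible(x)
}

#' Genes planted with any expression difference between cancer and normal
#' stomach cells (the truth universe for DEG false-discovery accounting:
#' blocks affecting all cancer cells or any cancer subpopulation).
#' @param cohort a `trio_cohort`.
#' @return character vector of gene ids.
#' @export
truth_deg_universe <- function(cohort) {
  tg <- cohort$truth$genes
  unique(tg[block %in% c("deg_up", "deg_down", "colon_sig_cancer",
                         "stomach_lost", "poorer_program", "immune_a",
                         "immune_b", "immune_c") | startsWith(block, "markers_"),
            gene])
}

#' Write a cohort to disk
#'
#' Emits every external representation (BED annotations, call tables, MTX
#' counts, metadata, gene sets, truth tables, a YAML parameter echo) plus a
#' `manifest.tsv` of MD5 hashes.
#' @param cohort a `trio_cohort`.
#' @param out_dir output directory.
#' @param force overwrite an existing non-empty directory.
#' @return `out_dir`, invisibly.
#' @export
write_cohort <- function(cohort, out_dir, force = FALSE) {
  if (dir.exists(out_dir) && length(dir(out_dir)) && !force) {
    stop("output directory ", out_dir, " is not empty (use force = TRUE)")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  r <- cohort$regions
  write_bed(r[role == "bin"], file.path(out_dir, "bins.bed"))
  write_bed(r[role == "promoter"], file.path(out_dir, "promoters.bed"))
  write_bed(r[role == "repeat"], file.path(out_dir, "repeats.bed"), class_col = 7L)
  fwrite(r, file.path(out_dir, "regions_full.tsv"), sep = "\t")
  dna <- data.table(bin = rownames(cohort$dna) %||%
                      r[role == "bin", name], cohort$dna)
  fwrite(dna, file.path(out_dir, "dna_counts.tsv.gz"), sep = "\t",
         compress = "gzip")
  write_meth_calls(cohort$wcg, file.path(out_dir, "wcg_calls.tsv.gz"))
  write_meth_calls(cohort$gch, file.path(out_dir, "gch_calls.tsv.gz"))
  write_counts_mtx(cohort$rna, file.path(out_dir, "rna.mtx"),
                   file.path(out_dir, "features.tsv"),
                   file.path(out_dir, "barcodes.tsv"))
  write_cell_meta(cohort$meta, file.path(out_dir, "meta.tsv"))
  write_gmt(cohort$gene_sets, file.path(out_dir, "immune_sets.gmt"))
  for (nm in names(cohort$truth)) {
    fwrite(cohort$truth[[nm]], file.path(out_dir, paste0("truth_", nm, ".tsv")),
           sep = "\t")
  }
  yaml::write_yaml(c(list(seed = cohort$seed), cohort$params),
                   file.path(out_dir, "params.yaml"))
  files <- setdiff(dir(out_dir), "manifest.tsv")
  manifest <- data.table(file = files,
                         md5 = unname(tools::md5sum(file.path(out_dir, files))))
  fwrite(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t")
  invisible(out_dir)
}

#' Read a cohort written by [write_cohort()]
#' @param dir cohort directory.
#' @return a `trio_cohort` (without the `expected` level matrices, which are
#'   generator internals).
#' @export
read_cohort <- function(dir) {
  if (!file.exists(file.path(dir, "params.yaml"))) {
    stop("not a cohort directory (missing params.yaml): ", dir)
  }
  pars <- yaml::read_yaml(file.path(dir, "params.yaml"))
  seed <- pars$seed
  pars$seed <- NULL
  for (nm in c("repeat_meth_factors", "clone_meth_levels", "pt_ln_offsets",
               "immune_set_sizes")) {
    if (!is.null(pars[[nm]])) pars[[nm]] <- unlist(pars[[nm]])
  }
  regions <- fread(file.path(dir, "regions_full.tsv"), sep = "\t")
  dna <- fread_auto(file.path(dir, "dna_counts.tsv.gz"), sep = "\t")
  dna_mat <- as.matrix(dna[, -1])
  rownames(dna_mat) <- dna[[1]]
  truth <- lapply(c(cells = "cells", genes = "genes", dmps = "dmps",
                    clones = "clones", signatures = "signatures"),
                  function(nm) fread(file.path(dir, paste0("truth_", nm, ".tsv")),
                                     sep = "\t"))
  structure(list(
    params = pars, seed = as.integer(seed),
    meta = read_cell_meta(file.path(dir, "meta.tsv")),
    regions = regions,
    cn_maps = NULL,
    dna = dna_mat,
    wcg = read_meth_calls(file.path(dir, "wcg_calls.tsv.gz")),
    gch = read_meth_calls(file.path(dir, "gch_calls.tsv.gz")),
    rna = read_counts_mtx(file.path(dir, "rna.mtx"),
                          file.path(dir, "features.tsv"),
                          file.path(dir, "barcodes.tsv")),
    gene_sets = read_gmt(file.path(dir, "immune_sets.gmt")),
    expected = NULL,
    truth = truth
  ), class = "trio_cohort")
}
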