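# Cytosine-context classification and coverage-weighted quantification of WCG
# methylation / GCH accessibility, plus the differential promoter caller.
#
# Context model (GpC-methyltransferase-treated libraries): a cytosine in
# W-C-G (W = A/T) reports endogenous CpG methylation; a cytosine in G-C-H
# (H = A/C/T) reports exogenous GpC methylation, i.e. chromatin
# accessibility; G-C-G is ambiguous (both CpG and GpC) and is excluded, as is
# every other trinucleotide.

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Classify cytosine trinucleotide contexts
#'
#' @param sequence a single character string of forward-strand genomic
#'   sequence (A/C/G/T/N).
#' @param pos integer vector of 0-based positions. On the `+` strand the
#'   forward base at `pos` must be `C`; on the `-` strand it must be `G`
#'   (i.e. a cytosine on the reverse complement), and classification is done
#'   on the reverse-complement flanks.
#' @param strand `"+"` or `"-"`, length 1 or `length(pos)`.
#' @return character vector in `{WCG, GCH, EXCLUDED}`. Positions lacking a
#'   flank (sequence edges) are `EXCLUDED`.
#' @export
classify_cytosine_context <- function(sequence, pos, strand = "+") {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  s <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  n <- length(s)
  if (length(strand) == 1L) strand <- rep(strand, length(pos))
  stopifnot(length(strand) == length(pos), all(strand %in% c("+", "-")))
  if (any(pos < 0L | pos >= n)) stop("pos out of sequence range")
  base <- s[pos + 1L]
  need <- ifelse(strand == "+", "C", "G")
  if (any(base != need)) {
    i <- which(base != need)[1]
    stop(sprintf("position %d is '%s', not a cytosine on strand '%s'",
                 pos[i], base[i], strand[i]))
  }
  up <- character(length(pos))
  down <- character(length(pos))
  plus <- strand == "+"
  # + strand: upstream base precedes the C, downstream follows it
  up[plus] <- ifelse(pos[plus] >= 1L, s[pmax(pos[plus], 1L)], NA_character_)
  down[plus] <- ifelse(pos[plus] + 2L <= n, s[pmin(pos[plus] + 2L, n)], NA_character_)
  # - strand: flanks are the complements of the forward neighbours, swapped
  mins <- !plus
  up[mins] <- ifelse(pos[mins] + 2L <= n,
                     COMPLEMENT[s[pmin(pos[mins] + 2L, n)]], NA_character_)
  down[mins] <- ifelse(pos[mins] >= 1L,
                       COMPLEMENT[s[pmax(pos[mins], 1L)]], NA_character_)
  ctx <- rep("EXCLUDED", length(pos))
  ok <- !is.na(up) & !is.na(down)
  ctx[ok & up %in% c("A", "T") & down == "G"] <- "WCG"
  ctx[ok & up == "G" & down %in% c("A", "C", "T")] <- "GCH"
  ctx
}

.overlap_calls <- function(calls, regions, context) {
  ctx_want <- context
  cc <- as.data.table(calls)[context == ctx_want & total_count > 0L]
  reg <- as.data.table(regions)[, .(chrom, start, end, region = name)]
  if (nrow(cc) == 0L || nrow(reg) == 0L) {
    return(data.table(region = character(), cell_id = character(),
                      chrom = character(), pos = integer(),
                      meth_count = integer(), total_count = integer()))
  }
  cc[, `:=`(istart = pos, iend = pos + 1L)]
  data.table::setkey(reg, chrom, start, end)
  ov <- data.table::foverlaps(cc, reg, by.x = c("chrom", "istart", "iend"),
                              type = "within", nomatch = NULL)
  ov[, .(region, cell_id, chrom, pos, meth_count, total_count)]
}

#' Per-cell region-level methylation or accessibility
#'
#' The level of a region in a cell is the coverage-weighted fraction
#' `sum(meth_count) / sum(total_count)` over all context sites falling in the
#' region. Levels are set to `NA` (not 0) when the site or read thresholds
#' are unmet; (region, cell) pairs with no coverage are absent from the
#' output. A site overlapping several regions contributes to each.
#'
#' @param calls cytosine call table (`read_meth_calls()` schema).
#' @param regions BED-style table with `chrom, start, end, name`.
#' @param context `"WCG"` or `"GCH"`.
#' @param min_sites,min_reads minimum covered sites / total reads per
#'   (region, cell) for the level to be defined.
#' @return `data.table(region, cell_id, level, n_sites, n_reads)`.
#' @export
region_levels <- function(calls, regions, context = "WCG",
                          min_sites = 3L, min_reads = 5L) {
  ov <- .overlap_calls(calls, regions, context)
  out <- ov[, .(level = sum(meth_count) / sum(total_count),
                n_sites = .N, n_reads = sum(total_count)),
            by = .(region, cell_id)]
  out[n_sites < min_sites | n_reads < min_reads, level := NA_real_]
  out[]
}

#' Pivot region levels to a regions-by-cells matrix
#' @param levels output of [region_levels()].
#' @param regions,cells optional row/column universes (rows/columns with no
#'   data become `NA`).
#' @return numeric matrix.
#' @export
level_matrix <- function(levels, regions = NULL, cells = NULL) {
  levels <- as.data.table(levels)
  regions <- regions %||% sort(unique(levels$region))
  cells <- cells %||% sort(unique(levels$cell_id))
  m <- matrix(NA_real_, length(regions), length(cells),
              dimnames = list(regions, cells))
  sub <- levels[region %in% regions & cell_id %in% cells]
  m[cbind(match(sub$region, regions), match(sub$cell_id, cells))] <- sub$level
  m
}

#' Per-cell genome-wide methylation or accessibility level
#'
#' Coverage-weighted fraction over all sites of the context; cells below
#' `min_sites_qc` covered sites are flagged `low_qc` (kept, not dropped).
#' @param calls cytosine call table.
#' @param context `"WCG"` or `"GCH"`.
#' @param min_sites_qc QC threshold on covered sites per cell.
#' @return `data.table(cell_id, level, n_sites, n_reads, low_qc)`.
#' @export
global_level <- function(calls, context = "WCG", min_sites_qc = 1000L) {
  ctx_want <- context
  cc <- as.data.table(calls)[context == ctx_want & total_count > 0L]
  out <- cc[, .(level = sum(meth_count) / sum(total_count),
                n_sites = .N, n_reads = sum(total_count)), by = cell_id]
  out[, low_qc := n_sites < min_sites_qc]
  out[]
}

#' Per-cell repeat-class methylation levels
#'
#' Pools all repeat regions of a class (long interspersed elements, long
#' terminal repeats, satellites, ...) into one coverage-weighted level per
#' (cell, class). Unknown class labels pass through verbatim.
#' @param calls cytosine call table.
#' @param repeat_bed BED table with a `class_label` column.
#' @param context `"WCG"` or `"GCH"`.
#' @return `data.table(cell_id, class_label, level, n_sites, n_reads)`.
#' @export
repeat_class_levels <- function(calls, repeat_bed, context = "WCG") {
  rep_bed <- as.data.table(repeat_bed)
  stopifnot("class_label" %in% names(rep_bed))
  ov <- .overlap_calls(calls, rep_bed, context)
  ov <- merge(ov, rep_bed[, .(region = name, class_label)], by = "region",
              allow.cartesian = TRUE)
  ov[, .(level = sum(meth_count) / sum(total_count),
         n_sites = .N, n_reads = sum(total_count)),
     by = .(cell_id, class_label)]
}

.check_groups <- function(group_a, group_b) {
  if (length(group_a) == 0L || length(group_b) == 0L) {
    stop("both groups must contain at least one cell")
  }
  if (length(intersect(group_a, group_b))) {
    stop("groups overlap: ", paste(head(intersect(group_a, group_b), 3), collapse = ", "))
  }
}

#' Call differentially methylated promoters (or regions)
#'
#' Per feature, compares per-cell levels between two cell groups with the
#' shared Wilcoxon rank-sum engine ([rank_sum_test()]); p-values are BH
#' adjusted across tested features. A feature is called when `q <= q_max` and
#' `|delta| >= delta_min`, with `delta = mean(groupA) - mean(groupB)` and
#' direction `hyper` (delta > 0, higher in group A) or `hypo`.
#'
#' @param levels features-by-cells numeric matrix (e.g. [level_matrix()]), or
#'   a [region_levels()] table.
#' @param group_a,group_b disjoint cell-id vectors (convention: group A =
#'   cancer, group B = reference).
#' @param delta_min minimum absolute level difference.
#' @param q_max BH-adjusted p-value cut-off.
#' @param min_cells features with fewer covered cells than this in either
#'   group are skipped.
#' @param patient optional patient label recorded in the result.
#' @return `data.table` with one row per tested feature: `feature, n_a, n_b,
#'   mean_a, mean_b, delta, statistic, p, q, direction, called, patient`.
#' @export
call_dmps <- function(levels, group_a, group_b, delta_min = 0.2,
                      q_max = 0.05, min_cells = 5L, patient = NA_character_) {
  .check_groups(group_a, group_b)
  if (!is.matrix(levels)) levels <- level_matrix(levels)
  ga <- intersect(group_a, colnames(levels))
  gb <- intersect(group_b, colnames(levels))
  rows <- lapply(rownames(levels), function(f) {
    a <- levels[f, ga]; a <- a[!is.na(a)]
    b <- levels[f, gb]; b <- b[!is.na(b)]
    if (length(a) < min_cells || length(b) < min_cells) return(NULL)
    ts <- rank_sum_test(a, b)
    data.table(feature = f, n_a = length(a), n_b = length(b),
               mean_a = mean(a), mean_b = mean(b),
               delta = mean(a) - mean(b),
               statistic = ts$statistic, p = ts$p)
  })
  out <- rbindlist(rows)
  if (nrow(out) == 0L) {
    return(data.table(feature = character(), n_a = integer(), n_b = integer(),
                      mean_a = double(), mean_b = double(), delta = double(),
                      statistic = double(), p = double(), q = double(),
                      direction = character(), called = logical(),
                      patient = character()))
  }
  out[, q := p.adjust(p, method = "BH")]
  out[, direction := ifelse(delta > 0, "hyper", "hypo")]
  out[, called := q <= q_max & abs(delta) >= delta_min]
  pat <- patient
  out[, patient := pat]
  out[]
}

#' Features recurrently called across patients
#'
#' Counts, per (feature, direction), in how many patients the feature was
#' called with that direction; directions are never merged, so a feature
#' called hyper in some patients and hypo in others is assessed separately
#' per direction. Inclusion requires calls in at least
#' `ceiling(min_fraction * n_patients)` patients.
#'
#' @param per_patient_results list of per-patient [call_dmps()] /
#'   [call_degs()] result tables (must contain `feature`, `direction`,
#'   `called`).
#' @param min_fraction minimum fraction of patients.
#' @return `data.table(feature, direction, n_patients_called, n_patients,
#'   shared)` for every (feature, direction) called at least once.
#' @export
shared_features <- function(per_patient_results, min_fraction = 0.5) {
  stopifnot(length(per_patient_results) >= 1L)
  n_pat <- length(per_patient_results)
  called <- rbindlist(lapply(per_patient_results, function(r) {
    as.data.table(r)[called == TRUE, .(feature, direction)]
  }))
  if (nrow(called) == 0L) {
    return(data.table(feature = character(), direction = character(),
                      n_patients_called = integer(), n_patients = integer(),
                      shared = logical()))
  }
  out <- called[, .(n_patients_called = .N), by = .(feature, direction)]
  out[, n_patients := n_pat]
  out[, shared := n_patients_called >= ceiling(min_fraction * n_pat)]
  setorder(out, -n_patients_called, feature)
  out[]
}
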