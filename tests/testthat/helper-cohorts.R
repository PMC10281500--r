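library(data.table)

# Session-level cache so the default cohort / pipeline run is simulated once
# and reused across test files.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# scaled-down cohort for unit tests (fast, structure intact)
small_params <- function(...) {
  cohort_params(
    cells_per_clone = 12L, n_normal_stomach = 10L, n_colon = 10L,
    n_bins = 300L, max_event_len = 30L, n_promoters = 400L, n_repeats = 30L,
    n_genes = 800L, n_deg_up = 40L, n_deg_down = 40L,
    n_colon_sig = 12L, n_stomach_sig = 16L,
    n_hyper_dmps = 20L, n_hypo_dmps = 6L,
    n_cluster_markers = 10L, n_poorer_genes = 20L,
    immune_set_sizes = c(8L, 8L, 8L),
    deg_block_start = 41L, marker_block_start = 121L,
    dmp_hyper_start = 301L, dmp_hypo_start = 351L, ...)
}

small_cohort <- function() cached("small_cohort", simulate_cohort(small_params(), seed = 7))

# the default study-scale cohort and its full pipeline run (shared by the
# acceptance tests)
default_cohort <- function() cached("default_cohort", simulate_cohort(seed = 1))

default_pipeline <- function() {
  cached("default_pipeline", run_pipeline(list(seed = 1)))
}

# independent brute-force trinucleotide classifier used as the context oracle:
# enumerates the trinucleotide around each cytosine and applies the WCG / GCH
# / GCG rules on the literal strings (minus strand via reverse complement).
oracle_context <- function(sequence, pos, strand) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  s <- strsplit(toupper(sequence), "")[[1]]
  n <- length(s)
  vapply(seq_along(pos), function(i) {
    p <- pos[i] + 1L  # 1-based
    if (p == 1L || p == n) return("EXCLUDED")
    tri <- s[(p - 1L):(p + 1L)]
    if (strand[i] == "-") tri <- rev(comp[tri])
    if (tri[2] != "C") stop("oracle: not a C")
    if (tri[1] == "G" && tri[3] == "G") return("EXCLUDED")
    if (tri[1] %in% c("A", "T") && tri[3] == "G") return("WCG")
    if (tri[1] == "G" && tri[3] %in% c("A", "C", "T")) return("GCH")
    "EXCLUDED"
  }, "")
}

# brute-force two-sided rank-sum p by enumerating every split of the pooled
# ranks (tie-free data only)
enumerate_ranksum_p <- function(x, y) {
  nx <- length(x)
  r <- rank(c(x, y))
  obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  n <- nx + length(y)
  splits <- utils::combn(n, nx)
  us <- apply(splits, 2, function(idx) sum(seq_len(n)[idx]) - nx * (nx + 1) / 2)
  mu <- nx * length(y) / 2
  # two-sided: double the smaller tail (matching the exact Wilcoxon rule)
  if (obs > mu) min(1, 2 * mean(us >= obs)) else min(1, 2 * mean(us <= obs))
}
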