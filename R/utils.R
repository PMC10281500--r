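#' @importFrom data.table data.table as.data.table setnames setorder := .N .SD fwrite fread rbindlist setDT copy
#' @importFrom stats median quantile rank prcomp hclust cutree as.dist dist rbinom rpois rnbinom rlnorm runif p.adjust pnorm pwilcox setNames sd var chisq.test
#' @importFrom utils head
#' @importFrom methods as
NULL

# data.table NSE columns
utils::globalVariables(c(
  ".", "cell_id", "chrom", "pos", "strand", "context", "meth_count",
  "total_count", "level", "n_sites", "n_reads", "region", "class_label",
  "name", "start", "end", "clone", "patient", "site", "tissue_class",
  "gene", "delta", "q", "called", "direction", "feature", "lineage",
  "cluster", "state", "istart", "iend", "meth", "total", "i.name",
  "i.class_label", "n_patients_called", "p", "V1", "site_position", "lfc"
))

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that simulation functions are
#' deterministic given `seed` without disturbing the caller's RNG stream.
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number")
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Two-sample Wilcoxon rank-sum test
#'
#' The single rank-sum engine shared by the differential methylation,
#' differential expression and integration modules. The statistic is the
#' Mann-Whitney U computed from the rank formula. The p-value is two-sided:
#' exact (via the null Wilcoxon distribution) when both samples have at most
#' `exact_max` observations and there are no ties, otherwise a normal
#' approximation with tie correction and continuity correction.
#'
#' @param x,y numeric vectors (the two groups).
#' @param exact_max use the exact null distribution when both group sizes are
#'   <= `exact_max` and the pooled sample is tie-free.
#' @return list with `statistic` (U for the first sample), `p` (two-sided),
#'   `method` ("exact" or "normal").
#' @export
rank_sum_test <- function(x, y, exact_max = 25L) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  nx <- length(x)
  ny <- length(y)
  if (nx == 0L || ny == 0L) stop("both groups must be non-empty")
  r <- rank(c(x, y))
  n <- nx + ny
  W <- sum(r[seq_len(nx)])
  U <- W - nx * (nx + 1) / 2
  tie_tab <- table(r)
  has_ties <- any(tie_tab > 1L)
  if (!has_ties && nx <= exact_max && ny <= exact_max) {
    p <- if (U > nx * ny / 2) {
      2 * pwilcox(U - 1, nx, ny, lower.tail = FALSE)
    } else {
      2 * pwilcox(U, nx, ny)
    }
    return(list(statistic = U, p = min(1, p), method = "exact"))
  }
  mu <- nx * ny / 2
  tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
  sigma2 <- (nx * ny / 12) * ((n + 1) - tie_term)
  if (sigma2 <= 0) return(list(statistic = U, p = 1, method = "normal"))
  z <- U - mu
  z <- z - sign(z) * 0.5  # continuity correction
  z <- z / sqrt(sigma2)
  p <- 2 * pnorm(-abs(z))
  list(statistic = U, p = min(1, p), method = "normal")
}

# Rank-based AUROC of `score` for the binary labels `positive` (logical).
# Identical to U / (n1 * n0); used as the normal-vs-cancer axis selection
# statistic.
auroc <- function(score, positive) {
  stopifnot(length(score) == length(positive))
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) stop("both classes required for AUROC")
  r <- rank(score)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Shannon entropy (bits) of a count vector.
shannon_entropy <- function(counts) {
  p <- counts[counts > 0]
  p <- p / sum(p)
  -sum(p * log2(p))
}

# Relabel integer cluster ids to A, B, C... by decreasing cluster size
# (ties broken by first occurrence) for deterministic lineage naming.
relabel_by_size <- function(labels) {
  tab <- sort(table(labels), decreasing = TRUE)
  new <- setNames(LETTERS[seq_along(tab)], names(tab))
  unname(new[as.character(labels)])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# fread with transparent gzip support (data.table's own gz path needs an
# optional dependency; a gzfile connection does not)
fread_auto <- function(path, ...) {
  if (grepl("\\.gz$", path)) {
    con <- gzfile(path, "rt")
    on.exit(close(con))
    lines <- readLines(con)
    if (length(lines) <= 1L) {
      return(fread(text = paste0(lines, "\n"), ...))
    }
    fread(text = lines, ...)
  } else {
    fread(path, ...)
  }
}
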