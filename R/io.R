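# Readers and writers for every external representation the pipeline touches.
# All tables are tab-separated with a header; gzip is handled transparently
# (gzfile connection on read, by extension on write). Coordinates are 0-based
# half-open (BED convention) everywhere inside the package.

METH_CALL_COLUMNS <- c("cell_id", "chrom", "pos", "strand", "context",
                       "meth_count", "total_count")
METH_CONTEXTS <- c("WCG", "GCH", "EXCLUDED")
META_COLUMNS <- c("cell_id", "patient", "site", "site_position", "tissue_class")
SITE_LEVELS <- c("PT", "LN", "NAT")
TISSUE_CLASSES <- c("cancer", "normal_epi_stomach", "normal_epi_colon", "other")

.check_integerish <- function(x, col, path, header_offset = 1L) {
  xi <- suppressWarnings(as.integer(x))
  bad <- which(is.na(xi) & !is.na(x))
  if (length(bad)) {
    stop(sprintf("%s: non-integer value '%s' in column '%s' at line %d",
                 path, x[bad[1]], col, bad[1] + header_offset))
  }
  xi
}

#' Read a per-cell cytosine call table
#'
#' Expects a tab-separated file (optionally gzipped) with header columns
#' `cell_id, chrom, pos, strand, context, meth_count, total_count`. `pos` is
#' the 0-based position of the cytosine on the annotated strand; `context` is
#' one of `WCG` (endogenous methylation), `GCH` (GpC accessibility) or
#' `EXCLUDED` (GCG and other non-informative trinucleotides).
#'
#' @param path file path.
#' @return a `data.table` with the seven schema columns (zero rows allowed).
#' @export
read_meth_calls <- function(path) {
  tbl <- fread_auto(path, sep = "\t", header = TRUE, colClasses = "character")
  if (!identical(names(tbl), METH_CALL_COLUMNS)) {
    stop(sprintf("%s: expected columns [%s], found [%s]", path,
                 paste(METH_CALL_COLUMNS, collapse = ", "),
                 paste(names(tbl), collapse = ", ")))
  }
  if (nrow(tbl) == 0L) {
    return(data.table(cell_id = character(), chrom = character(),
                      pos = integer(), strand = character(),
                      context = character(), meth_count = integer(),
                      total_count = integer()))
  }
  tbl[, pos := .check_integerish(pos, "pos", path)]
  tbl[, meth_count := .check_integerish(meth_count, "meth_count", path)]
  tbl[, total_count := .check_integerish(total_count, "total_count", path)]
  bad_ctx <- which(!tbl$context %in% METH_CONTEXTS)
  if (length(bad_ctx)) {
    stop(sprintf("%s: invalid context '%s' at line %d (allowed: %s)",
                 path, tbl$context[bad_ctx[1]], bad_ctx[1] + 1L,
                 paste(METH_CONTEXTS, collapse = ", ")))
  }
  bad_strand <- which(!tbl$strand %in% c("+", "-"))
  if (length(bad_strand)) {
    stop(sprintf("%s: invalid strand '%s' at line %d", path,
                 tbl$strand[bad_strand[1]], bad_strand[1] + 1L))
  }
  over <- which(tbl$meth_count > tbl$total_count)
  if (length(over)) {
    stop(sprintf("%s: meth_count > total_count at line %d", path,
                 over[1] + 1L))
  }
  neg <- which(tbl$meth_count < 0L | tbl$total_count < 0L)
  if (length(neg)) {
    stop(sprintf("%s: negative count at line %d", path, neg[1] + 1L))
  }
  tbl[]
}

#' Write a cytosine call table
#'
#' Canonical form: schema column order, tab-separated, `\n` line endings;
#' gzip-compressed when `path` ends in `.gz`.
#' @param calls a table with the `read_meth_calls()` schema.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_meth_calls <- function(calls, path) {
  calls <- as.data.table(calls)
  stopifnot(all(METH_CALL_COLUMNS %in% names(calls)))
  fwrite(calls[, METH_CALL_COLUMNS, with = FALSE], path, sep = "\t",
         compress = if (endsWith(path, ".gz")) "gzip" else "none")
  invisible(path)
}

#' Read a sparse genes-by-cells count matrix (MatrixMarket)
#'
#' @param mtx_path MatrixMarket coordinate file.
#' @param features_path one feature (gene) id per line, tab-separated extra
#'   columns ignored.
#' @param barcodes_path one cell id per line.
#' @return a `dgCMatrix` with feature/barcode dimnames.
#' @export
read_counts_mtx <- function(mtx_path, features_path, barcodes_path) {
  m <- Matrix::readMM(mtx_path)
  features <- fread(features_path, header = FALSE, sep = "\t")[[1]]
  barcodes <- fread(barcodes_path, header = FALSE, sep = "\t")[[1]]
  if (nrow(m) != length(features)) {
    stop(sprintf("feature dimension mismatch: matrix has %d rows, %d features listed",
                 nrow(m), length(features)))
  }
  if (ncol(m) != length(barcodes)) {
    stop(sprintf("barcode dimension mismatch: matrix has %d columns, %d barcodes listed",
                 ncol(m), length(barcodes)))
  }
  m <- methods::as(m, "CsparseMatrix")
  dimnames(m) <- list(features, barcodes)
  m
}

#' Write a sparse count matrix as MTX + feature/barcode lists
#' @param m genes-by-cells matrix with dimnames.
#' @param mtx_path,features_path,barcodes_path output paths.
#' @return `mtx_path`, invisibly.
#' @export
write_counts_mtx <- function(m, mtx_path, features_path, barcodes_path) {
  stopifnot(!is.null(rownames(m)), !is.null(colnames(m)))
  Matrix::writeMM(methods::as(methods::as(m, "generalMatrix"), "TsparseMatrix"),
                  mtx_path)
  fwrite(data.table(rownames(m)), features_path, col.names = FALSE, sep = "\t")
  fwrite(data.table(colnames(m)), barcodes_path, col.names = FALSE, sep = "\t")
  invisible(mtx_path)
}

#' Read a BED annotation (bins, promoters or repeat elements)
#'
#' Standard BED 4-6 columns; coordinates stay 0-based half-open. A repeat
#' class label may live in the `name` column (`class_col = 4`) or in an extra
#' seventh column (`class_col = 7`).
#'
#' @param path BED file.
#' @param class_col `NULL` (no class labels), `4` or `7`.
#' @return `data.table(chrom, start, end, name, strand, class_label)`.
#' @export
read_bed <- function(path, class_col = NULL) {
  tbl <- fread_auto(path, header = FALSE, sep = "\t", colClasses = "character")
  if (ncol(tbl) < 3L) stop(sprintf("%s: BED needs >= 3 columns", path))
  out <- data.table(
    chrom = tbl[[1]],
    start = .check_integerish(tbl[[2]], "start", path, header_offset = 0L),
    end = .check_integerish(tbl[[3]], "end", path, header_offset = 0L)
  )
  out[, name := if (ncol(tbl) >= 4L) tbl[[4]] else paste0(chrom, ":", start, "-", end)]
  out[, strand := if (ncol(tbl) >= 6L) tbl[[6]] else NA_character_]
  out[, class_label := NA_character_]
  if (!is.null(class_col)) {
    if (class_col == 4L) out[, class_label := name]
    else if (class_col == 7L) {
      if (ncol(tbl) < 7L) stop(sprintf("%s: class_col = 7 but only %d columns", path, ncol(tbl)))
      out[, class_label := tbl[[7]]]
    } else stop("class_col must be NULL, 4 or 7")
  }
  bad <- out[start >= end | chrom == "", which = TRUE]
  if (length(bad)) {
    stop(sprintf("%s: invalid interval at line %d (start must be < end, chrom non-empty)",
                 path, bad[1]))
  }
  out[]
}

#' Write BED records
#' @param records table with `chrom, start, end, name` (optionally `strand`,
#'   `class_label`).
#' @param path output path.
#' @param class_col `NULL`, or `7` to append `class_label` as a seventh column
#'   (score and strand columns are then always emitted).
#' @return `path`, invisibly.
#' @export
write_bed <- function(records, path, class_col = NULL) {
  records <- as.data.table(records)
  out <- records[, .(chrom, start, end,
                     name = if ("name" %in% names(records)) name
                            else paste0(chrom, ":", start, "-", end))]
  if (!is.null(class_col) && class_col == 7L) {
    out[, c("score", "strand2") := .(0L, records$strand %||% "+")]
    out[is.na(strand2), strand2 := "+"]
    out[, class7 := records$class_label]
  }
  fwrite(out, path, sep = "\t", col.names = FALSE,
         compress = if (endsWith(path, ".gz")) "gzip" else "none")
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Lines are `name<TAB>description<TAB>gene1<TAB>gene2...`; duplicate genes
#' within a set are dropped (first kept).
#' @param path GMT file.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 2L) stop(sprintf("%s: malformed GMT line: %s", path, l))
    unique(parts[-c(1, 2)])
  })
  names(sets) <- vapply(lines, function(l) strsplit(l, "\t", fixed = TRUE)[[1]][1], "")
  sets
}

#' Write gene sets to a GMT file
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional character vector of set descriptions.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  stopifnot(!is.null(names(sets)))
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], unique(sets[[i]])), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read per-cell metadata
#'
#' Tab-separated with header `cell_id, patient, site, site_position,
#' tissue_class`. `site` is the sampling compartment (PT primary tumor, LN
#' lymph-node metastasis, NAT normal adjacent tissue); `site_position` the
#' multi-regional label (e.g. "PT3", "LN1-2").
#' @param path file path.
#' @return `data.table`, one row per cell.
#' @export
read_cell_meta <- function(path) {
  tbl <- fread_auto(path, sep = "\t", header = TRUE, colClasses = "character")
  miss <- setdiff(META_COLUMNS, names(tbl))
  if (length(miss)) stop(sprintf("%s: missing metadata columns: %s", path,
                                 paste(miss, collapse = ", ")))
  if (anyDuplicated(tbl$cell_id)) {
    stop(sprintf("%s: duplicated cell_id '%s'", path,
                 tbl$cell_id[anyDuplicated(tbl$cell_id)]))
  }
  bad <- which(!tbl$site %in% SITE_LEVELS)
  if (length(bad)) stop(sprintf("%s: invalid site '%s' at line %d", path,
                                tbl$site[bad[1]], bad[1] + 1L))
  bad <- which(!tbl$tissue_class %in% TISSUE_CLASSES)
  if (length(bad)) stop(sprintf("%s: invalid tissue_class '%s' at line %d",
                                path, tbl$tissue_class[bad[1]], bad[1] + 1L))
  tbl[, META_COLUMNS, with = FALSE]
}

#' Write per-cell metadata
#' @param meta table with the `read_cell_meta()` columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cell_meta <- function(meta, path) {
  meta <- as.data.table(meta)
  stopifnot(all(META_COLUMNS %in% names(meta)))
  fwrite(meta[, META_COLUMNS, with = FALSE], path, sep = "\t",
         compress = if (endsWith(path, ".gz")) "gzip" else "none")
  invisible(path)
}
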