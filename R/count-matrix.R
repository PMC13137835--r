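#' Construct and validate a count matrix
#'
#' A count matrix is the universal input of the pipeline: an integer matrix
#' of raw (un-normalized) counts with genes as rows and samples as columns.
#' Row and column names are mandatory and must be unique.
#'
#' @param counts numeric matrix of non-negative integers with unique,
#'   non-empty rownames (gene ids) and colnames (sample ids).
#' @return the validated matrix with class `"count_matrix"` prepended.
#' @export
count_matrix <- function(counts) {
  if (!is.matrix(counts)) stop_txc("counts must be a matrix")
  validate_count_matrix(counts)
  storage.mode(counts) <- "double"  # keeps > .Machine$integer.max safe
  class(counts) <- c("count_matrix", class(unclass(counts)))
  counts
}

validate_count_matrix <- function(counts) {
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop_txc("count matrix must have gene rownames and sample colnames")
  if (nrow(counts) < 1L || ncol(counts) < 2L)
    stop_txc("count matrix needs at least 1 gene and 2 samples")
  if (anyNA(counts)) stop_txc("count matrix contains missing values")
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1L, ]
    stop_txc("negative count for gene '", rownames(counts)[bad[1L]],
             "', sample '", colnames(counts)[bad[2L]], "'")
  }
  if (any(counts != round(counts))) {
    bad <- which(counts != round(counts), arr.ind = TRUE)[1L, ]
    stop_txc("non-integer count ", counts[bad[1L], bad[2L]], " for gene '",
             rownames(counts)[bad[1L]], "', sample '",
             colnames(counts)[bad[2L]], "'")
  }
  dup <- unique(rownames(counts)[duplicated(rownames(counts))])
  if (length(dup))
    stop_txc("duplicate gene ids: ", paste(dup, collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop_txc("duplicate sample ids")
  if (any(!nzchar(rownames(counts))) || any(!nzchar(colnames(counts))))
    stop_txc("empty gene or sample id")
  invisible(TRUE)
}

#' Read a gene-by-sample count table
#'
#' Supported dialects: `tsv`/`csv` (header row of sample ids, first column
#' gene ids, `#` comment lines ignored) and `mtx-triplet` (MatrixMarket
#' coordinate file with sidecar `<path>.rownames` / `<path>.colnames`
#' files, one id per line).
#'
#' @param path file to read.
#' @param dialect one of `"tsv"`, `"csv"`, `"mtx-triplet"`.
#' @return a [count_matrix()] preserving the file's row and column order.
#' @export
read_count_matrix <- function(path, dialect = c("tsv", "csv", "mtx-triplet")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_txc("no such file: ", path)
  if (dialect == "mtx-triplet") return(read_count_mtx(path))
  sep <- if (dialect == "tsv") "\t" else ","
  df <- utils::read.delim(path, sep = sep, header = TRUE, comment.char = "#",
                          check.names = FALSE, colClasses = "character",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop_txc("count table needs >= 1 gene id column and 2 samples")
  gene_ids <- trimws(df[[1L]])
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup)) stop_txc("duplicate gene ids: ", paste(dup, collapse = ", "))
  samples <- colnames(df)[-1L]
  m <- matrix(NA_real_, nrow(df), length(samples),
              dimnames = list(gene_ids, samples))
  for (j in seq_along(samples)) {
    v <- suppressWarnings(as.numeric(df[[j + 1L]]))
    bad <- which(is.na(v) | v < 0 | v != round(v))
    if (length(bad))
      stop_txc("invalid count '", df[[j + 1L]][bad[1L]], "' for gene '",
               gene_ids[bad[1L]], "', sample '", samples[j], "'")
    m[, j] <- v
  }
  count_matrix(m)
}

read_count_mtx <- function(path) {
  rn <- readLines(paste0(path, ".rownames"))
  cn <- readLines(paste0(path, ".colnames"))
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "%") & nzchar(trimws(lines))]
  hdr <- as.numeric(strsplit(trimws(lines[1L]), "\\s+")[[1L]])
  if (length(hdr) != 3L) stop_txc("malformed MatrixMarket size header")
  if (hdr[1L] != length(rn) || hdr[2L] != length(cn))
    stop_txc("MatrixMarket dimensions disagree with sidecar name files")
  m <- matrix(0, hdr[1L], hdr[2L], dimnames = list(rn, cn))
  if (length(lines) > 1L) {
    trip <- do.call(rbind, lapply(strsplit(trimws(lines[-1L]), "\\s+"), as.numeric))
    bad <- which(trip[, 3L] < 0 | trip[, 3L] != round(trip[, 3L]))
    if (length(bad))
      stop_txc("invalid count ", trip[bad[1L], 3L], " for gene '",
               rn[trip[bad[1L], 1L]], "', sample '", cn[trip[bad[1L], 2L]], "'")
    m[trip[, 1:2, drop = FALSE]] <- trip[, 3L]
  }
  count_matrix(m)
}

#' Write a count matrix
#'
#' @param m a [count_matrix()].
#' @param path destination file.
#' @param dialect `"tsv"`, `"csv"`, or `"mtx-triplet"` (writes sidecar
#'   `.rownames`/`.colnames` files).
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(m, path, dialect = c("tsv", "csv", "mtx-triplet")) {
  dialect <- match.arg(dialect)
  validate_count_matrix(m)
  if (dialect == "mtx-triplet") {
    nz <- which(m != 0, arr.ind = TRUE)
    nz <- nz[order(nz[, 2L], nz[, 1L]), , drop = FALSE]
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("%%MatrixMarket matrix coordinate integer general", con)
    writeLines(sprintf("%d %d %d", nrow(m), ncol(m), nrow(nz)), con)
    if (nrow(nz))
      writeLines(sprintf("%d %d %d", nz[, 1L], nz[, 2L], m[nz]), con)
    writeLines(rownames(m), paste0(path, ".rownames"))
    writeLines(colnames(m), paste0(path, ".colnames"))
  } else {
    sep <- if (dialect == "tsv") "\t" else ","
    df <- data.frame(gene = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read or validate a sample sheet
#'
#' A sample sheet maps sample ids to condition labels; extra covariate
#' columns are carried through untouched.
#'
#' @param path TSV with columns `sample` and `condition` (extra columns kept).
#' @return data.frame with class `"sample_sheet"`.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  sample_sheet(df)
}

#' @param df data.frame with columns `sample` and `condition`.
#' @rdname read_sample_sheet
#' @export
sample_sheet <- function(df) {
  if (!all(c("sample", "condition") %in% colnames(df)))
    stop_txc("sample sheet needs 'sample' and 'condition' columns")
  df$sample <- as.character(df$sample)
  df$condition <- as.character(df$condition)
  if (anyDuplicated(df$sample)) stop_txc("duplicate sample ids in sheet")
  if (anyNA(df$sample) || anyNA(df$condition))
    stop_txc("missing sample or condition entries")
  class(df) <- c("sample_sheet", "data.frame")
  df
}

#' @rdname read_sample_sheet
#' @param sheet a sample sheet.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.table(sheet, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# samples of `sheet` restricted to a count matrix, with >= 2 per condition
# enforced for the conditions in `conditions`
sheet_samples <- function(sheet, condition, m = NULL) {
  s <- sheet$sample[sheet$condition == condition]
  if (!is.null(m)) s <- intersect(s, colnames(m))
  if (length(s) < 2L)
    stop_txc("condition '", condition, "' has fewer than 2 samples")
  s
}
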