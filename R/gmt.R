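#' Gene-set collections and the GMT format
#'
#' A collection is a named list of sets, each a list with `description`
#' (character scalar) and `genes` (unique character vector).  The on-disk
#' carrier is the Broad GMT dialect: one set per line,
#' `name<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param sets named list of `list(description =, genes =)` entries.
#' @return object of class `"gene_set_collection"`.
#' @export
gene_set_collection <- function(sets) {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop_txc("set names must be present and unique")
  sets <- lapply(sets, function(s) {
    g <- unique(trimws(as.character(s$genes)))
    g <- g[nzchar(g)]
    if (!length(g)) stop_txc("empty gene set after load")
    list(description = as.character(s$description %||% ""), genes = g)
  })
  structure(sets, class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("gene_set_collection with", length(x), "sets; sizes",
      paste(range(lengths(lapply(x, `[[`, "genes"))), collapse = "-"), "\n")
  invisible(x)
}

#' @param path GMT file.
#' @rdname gene_set_collection
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    txc_log("warn", "empty GMT file: ", path)
    return(structure(list(), class = "gene_set_collection"))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop_txc("GMT line ", short[1L], " has fewer than 3 fields")
  sets <- lapply(fields, function(f)
    list(description = f[2L], genes = unique(f[-(1:2)])))
  names(sets) <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(names(sets)))
    stop_txc("duplicate set names in GMT: ",
             paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  gene_set_collection(sets)
}

#' @param collection a gene-set collection.
#' @rdname gene_set_collection
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection), function(nm) {
    s <- collection[[nm]]
    paste(c(nm, s$description, s$genes), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

# plain named list of character vectors, used internally
collection_genes <- function(collection) lapply(collection, `[[`, "genes")
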