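#' Read a two-column identifier mapping table
#'
#' Rows of (source_id, target_symbol), e.g. Ensembl gene ids to HGNC
#' symbols.  Duplicate source ids are permitted in the file; how they are
#' resolved is decided at mapping time by [map_gene_ids()].
#'
#' @param path TSV with two columns; a header line is auto-detected when the
#'   first line's fields match `source` / `target` (case-insensitive).
#' @return data.frame with columns `source_id`, `target_symbol`.
#' @export
read_id_map <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (!length(lines)) stop_txc("empty id map: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 2L))
    stop_txc("id map line without two tab-separated fields")
  df <- data.frame(source_id = trimws(vapply(fields, `[[`, "", 1L)),
                   target_symbol = trimws(vapply(fields, `[[`, "", 2L)),
                   stringsAsFactors = FALSE)
  if (grepl("^source", df$source_id[1L], ignore.case = TRUE))
    df <- df[-1L, , drop = FALSE]
  id_map(df)
}

#' @param df data.frame with columns `source_id` and `target_symbol`.
#' @rdname read_id_map
#' @export
id_map <- function(df) {
  if (!all(c("source_id", "target_symbol") %in% colnames(df)))
    stop_txc("id map needs 'source_id' and 'target_symbol' columns")
  df$source_id <- trimws(as.character(df$source_id))
  df$target_symbol <- trimws(as.character(df$target_symbol))
  if (!nrow(df)) stop_txc("empty id map")
  if (any(!nzchar(df$source_id)) || any(!nzchar(df$target_symbol)))
    stop_txc("id map contains empty fields")
  df <- unique(df[, c("source_id", "target_symbol")])
  class(df) <- c("id_map", "data.frame")
  df
}

#' Map count-matrix gene identifiers to symbols
#'
#' Translates row identifiers through an [id_map()].  Source ids mapping to
#' several symbols are resolved by `policy`; several source ids landing on
#' the same symbol are resolved by `collision`.  Unmapped genes are dropped
#' and enumerated in the attached report.
#'
#' @param m a [count_matrix()].
#' @param map an [id_map()].
#' @param policy `"drop_ambiguous"` (default: a source id with more than one
#'   target is removed) or `"first"` (first target in map order wins).
#' @param collision `"sum"` (default: counts of source ids sharing a symbol
#'   are added element-wise) or `"drop"` (the colliding symbol is removed).
#' @return a [count_matrix()] keyed by symbol, with attribute `"report"`:
#'   a list with `n_input`, `n_mapped_input` (input genes that mapped,
#'   before collision merging), `n_mapped` (output rows), `unmapped`,
#'   `ambiguous`, `collided`.
#' @export
map_gene_ids <- function(m, map,
                         policy = c("drop_ambiguous", "first"),
                         collision = c("sum", "drop")) {
  policy <- match.arg(policy)
  collision <- match.arg(collision)
  validate_count_matrix(m)
  if (!inherits(map, "id_map")) map <- id_map(map)

  ambiguous <- character(0)
  if (policy == "drop_ambiguous") {
    multi <- unique(map$source_id[duplicated(map$source_id)])
    ambiguous <- intersect(rownames(m), multi)
    map <- map[!map$source_id %in% multi, , drop = FALSE]
  } else {
    map <- map[!duplicated(map$source_id), , drop = FALSE]
  }
  sym <- map$target_symbol[match(rownames(m), map$source_id)]
  unmapped <- rownames(m)[is.na(sym)]
  unmapped <- setdiff(unmapped, ambiguous)
  keep <- !is.na(sym)
  out <- m[keep, , drop = FALSE]
  sym <- sym[keep]

  collided <- unique(sym[duplicated(sym)])
  if (length(collided)) {
    if (collision == "sum") {
      out <- rowsum(unclass(out), group = sym, reorder = FALSE)
    } else {
      drop_rows <- sym %in% collided
      out <- out[!drop_rows, , drop = FALSE]
      sym <- sym[!drop_rows]
      rownames(out) <- sym
    }
  } else {
    rownames(out) <- sym
  }
  if (!nrow(out)) stop_txc("no genes left after identifier mapping")
  out <- count_matrix(as.matrix(out))
  attr(out, "report") <- list(
    n_input = nrow(m), n_mapped_input = sum(keep), n_mapped = nrow(out),
    unmapped = unmapped, ambiguous = ambiguous, collided = collided)
  txc_log("info", "mapped ", nrow(out), "/", nrow(m), " genes (",
          length(unmapped), " unmapped, ", length(ambiguous), " ambiguous)")
  out
}

#' Merge per-source gene lists into a gene-set collection
#'
#' Combines several curated disease gene lists (e.g. one file per database)
#' into a [gene_set_collection()]: one set per source plus a union set whose
#' description records each member's provenance.
#'
#' @param sources named character vector of file paths, or a named list of
#'   character vectors of symbols.  File format: one symbol per line, `#`
#'   comments ignored.
#' @param union_name name of the union set (default `"union"`).
#' @return a [gene_set_collection()].
#' @export
merge_gene_sources <- function(sources, union_name = "union") {
  if (is.null(names(sources)) || any(!nzchar(names(sources))))
    stop_txc("sources must be named")
  lists <- lapply(sources, function(s) {
    if (is.character(s) && length(s) == 1L && file.exists(s)) {
      v <- readLines(s)
      v <- trimws(v[!startsWith(trimws(v), "#")])
      v <- v[nzchar(v)]
    } else v <- trimws(as.character(s))
    unique(v[nzchar(v)])
  })
  if (all(lengths(lists) == 0L)) stop_txc("all gene-list sources are empty")
  lists <- lists[lengths(lists) > 0L]
  members <- sort(unique(unlist(lists, use.names = FALSE)))
  prov <- vapply(members, function(g) {
    paste(names(lists)[vapply(lists, function(l) g %in% l, logical(1))],
          collapse = "|")
  }, "")
  sets <- c(
    lapply(seq_along(lists), function(i)
      list(description = paste0("source:", names(lists)[i]),
           genes = sort(lists[[i]]))),
    list(list(description = paste0("union of ", paste(names(lists), collapse = ","),
                                   "; provenance ",
                                   paste(members, prov, sep = "=", collapse = ";")),
              genes = members)))
  names(sets) <- c(names(lists), union_name)
  gene_set_collection(sets)
}
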