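#' Classify reference DEGs as convergent or divergent in a model contrast
#'
#' For every gene in the reference DEG set, the model contrast is examined:
#' * `absent` — the gene was not tested in the model contrast (or its
#'   p-value is missing);
#' * `unresolved` — tested, but failing the significance or fold-change
#'   gate;
#' * `convergent` — passing both gates with the same fold-change sign as
#'   the reference effect;
#' * `divergent` — passing both gates with the opposite sign.
#'
#' Both contrasts carry an orientation stamp (`semantic` tag set in
#' [fit_contrast()]).  When the stamps differ, or either is missing, the
#' caller must state explicitly whether the model sign is to be flipped;
#' this prevents silently comparing, say, treated-vs-untreated against
#' control-vs-disease.
#'
#' @param ref a `deg_set` from the reference contrast ([select_degs()]).
#' @param model a `contrast_result` for one model contrast.
#' @param p_adj_max,abs_log2fc_min model-side gates (defaults 0.05, 0.2).
#' @param flip `NULL` (allowed only when both semantic stamps are present
#'   and equal), `FALSE` (orientations aligned), or `TRUE` (negate the
#'   model sign before comparison).
#' @return data.frame of class `"concordance_table"` with one row per
#'   reference DEG: `gene`, `contrast`, `label`, `ref_sign`, `model_sign`,
#'   `model_padj`, `model_log2fc`.
#' @export
classify_genes <- function(ref, model, p_adj_max = 0.05,
                           abs_log2fc_min = 0.2, flip = NULL) {
  stopifnot(inherits(ref, "deg_set"), inherits(model, "contrast_result"))
  if (p_adj_max <= 0 || abs_log2fc_min < 0) stop_txc("thresholds must be positive")
  ref_sem <- ref$semantic
  mod_sem <- attr(model, "semantic")
  if (is.null(flip)) {
    if (is.null(ref_sem) || is.null(mod_sem) || !identical(ref_sem, mod_sem))
      stop_txc("orientation stamps differ or are missing (reference '",
               ref_sem %||% "<none>", "' vs model '", mod_sem %||% "<none>",
               "'); pass flip = TRUE or flip = FALSE explicitly")
    flip <- FALSE
  }
  idx <- match(ref$genes$gene, model$gene)
  m_lfc <- model$log2fc[idx]
  m_padj <- model$padj[idx]
  m_sign0 <- sign(m_lfc) * if (flip) -1 else 1

  tested <- !is.na(idx) & !is.na(m_padj)
  passes <- tested & m_padj < p_adj_max & abs(m_lfc) >= abs_log2fc_min &
    m_sign0 != 0
  label <- rep("unresolved", nrow(ref$genes))
  label[!tested] <- "absent"
  label[passes & m_sign0 == ref$genes$sign] <- "convergent"
  label[passes & m_sign0 == -ref$genes$sign] <- "divergent"

  out <- data.frame(
    gene = ref$genes$gene,
    contrast = paste0(attr(model, "condB"), "_vs_", attr(model, "condA")),
    label = label,
    ref_sign = ref$genes$sign,
    model_sign = ifelse(passes, as.integer(m_sign0), NA_integer_),
    model_padj = m_padj,
    model_log2fc = m_lfc,
    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("concordance_table", "data.frame")
  attr(out, "reference") <- sort(ref$genes$gene)
  attr(out, "thresholds") <- c(p_adj_max = p_adj_max,
                               abs_log2fc_min = abs_log2fc_min)
  out
}

label_set <- function(table, lab) sort(table$gene[table$label == lab])

#' Intersection exclusion sets across model contrasts
#'
#' `all_convergent` holds the genes labeled convergent in *every* supplied
#' contrast; `all_divergent` likewise for divergent.  All tables must stem
#' from the same reference DEG universe.
#'
#' @param tables list of `concordance_table` objects (one per contrast).
#' @return list of class `"exclusion_sets"` with `all_convergent` and
#'   `all_divergent` character vectors.
#' @export
build_exclusion_sets <- function(tables) {
  if (!length(tables)) stop_txc("at least one concordance table required")
  refs <- lapply(tables, attr, "reference")
  if (!all(vapply(refs, identical, logical(1), refs[[1L]])))
    stop_txc("concordance tables stem from different reference DEG sets")
  all_conv <- Reduce(intersect, lapply(tables, label_set, "convergent"))
  all_div <- Reduce(intersect, lapply(tables, label_set, "divergent"))
  structure(list(all_convergent = sort(all_conv), all_divergent = sort(all_div),
                 reference = refs[[1L]]),
            class = "exclusion_sets")
}

#' Residual DEG sets after exclusion
#'
#' Removes the cross-contrast exclusion sets from one contrast's convergent
#' and divergent gene sets, leaving the genes whose concordance is specific
#' to that contrast.
#'
#' @param table a `concordance_table`.
#' @param excl an `exclusion_sets` built from the same reference.
#' @return list with `convergent_residual` and `divergent_residual`.
#' @export
residual_degs <- function(table, excl) {
  stopifnot(inherits(table, "concordance_table"), inherits(excl, "exclusion_sets"))
  if (!identical(attr(table, "reference"), excl$reference))
    stop_txc("exclusion sets stem from a different reference DEG set")
  drop <- union(excl$all_convergent, excl$all_divergent)
  list(convergent_residual = sort(setdiff(label_set(table, "convergent"), drop)),
       divergent_residual = sort(setdiff(label_set(table, "divergent"), drop)))
}

#' Summarize a concordance table
#'
#' Counts and fractions of each label; counts always sum to the reference
#' DEG set size.  On an empty reference set the fractions are reported as
#' `NA` rather than `NaN`.  A signed concordance fraction
#' `(convergent - divergent) / n` is exposed as a convenience score.
#'
#' @param table a `concordance_table`.
#' @return one-row data.frame of counts, fractions, and `signed_concordance`.
#' @export
summarize_concordance <- function(table) {
  stopifnot(inherits(table, "concordance_table"))
  labs <- c("convergent", "divergent", "unresolved", "absent")
  n <- nrow(table)
  counts <- vapply(labs, function(l) sum(table$label == l), integer(1))
  fr <- if (n > 0) counts / n else rep(NA_real_, 4L)
  data.frame(contrast = if (n) table$contrast[1L] else NA_character_,
             n_reference_degs = n,
             t(counts),
             t(stats::setNames(fr, paste0("frac_", labs))),
             signed_concordance = if (n > 0) (counts[1L] - counts[2L]) / n else NA_real_,
             row.names = NULL, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Concordance serialization
#'
#' @param table a `concordance_table`.
#' @param path TSV destination.
#' @export
write_concordance_table <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export residual gene sets as one-symbol-per-line lists
#'
#' @param residuals list from [residual_degs()].
#' @param dir destination directory; files `<contrast>.<side>.txt`.
#' @param contrast contrast name used in file names.
#' @export
write_residual_sets <- function(residuals, dir, contrast) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (side in names(residuals)) {
    writeLines(residuals[[side]],
               file.path(dir, paste0(contrast, ".", side, ".txt")))
  }
  invisible(dir)
}
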