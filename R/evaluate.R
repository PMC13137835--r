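#' Score the analysis chain against planted ground truth
#'
#' Runs the full module chain — reference differential expression, DEG
#' selection, model contrasts, concordance classification, exclusion sets,
#' and over-representation of the convergent genes — on one simulated study
#' and scores it against the simulation's truth tables.  Used to measure
#' recovery operating characteristics over repeated seeded runs.
#'
#' @param cfg a [sim_config()].
#' @param model_contrast character pair `c(condA, condB)` of the model
#'   contrast scored against truth (default untreated vs treated,
#'   `c("NUntr", "NTr")`).
#' @param p_adj_max,abs_log2fc_min DEG and concordance gates.
#' @return named numeric vector: `sensitivity` (fraction of
#'   planted-convergent genes labeled convergent), `divergent_mislabel`
#'   (fraction labeled divergent), `n_planted_convergent`,
#'   `enriched_retained` (1 if every planted-enriched set is BH-retained at
#'   `p_adjust < 0.05` in the convergent-gene ORA, else 0).
#' @export
planted_recovery <- function(cfg, model_contrast = c("NUntr", "NTr"),
                             p_adj_max = 0.05, abs_log2fc_min = 0.2) {
  st <- simulate_study(cfg)
  ref_res <- fit_contrast(st$reference$counts, st$reference$sheet,
                          names(cfg$ref_sizes)[1L], names(cfg$ref_sizes)[2L],
                          semantic = "case_vs_control")
  degs <- select_degs(ref_res, p_adj_max, abs_log2fc_min)

  sf <- estimate_size_factors(st$model$counts)
  disp <- estimate_dispersions(st$model$counts, st$model$sheet, sf)
  base_cond <- names(cfg$model_sizes)[1L]
  active <- setdiff(names(cfg$model_sizes), base_cond)
  results <- lapply(active, function(cc)
    fit_contrast(st$model$counts, st$model$sheet, base_cond, cc,
                 sf = sf, disp = disp, semantic = "case_vs_control"))
  names(results) <- paste0(active, "_vs_", base_cond)
  tables <- lapply(results, function(r)
    classify_genes(degs, r, p_adj_max, abs_log2fc_min))

  key <- paste0(model_contrast[2L], "_vs_", model_contrast[1L])
  if (!key %in% names(tables)) stop_txc("contrast ", key, " not scored")
  tab <- tables[[key]]
  truth <- attr(st$model$truth, "contrast_truth")[[key]]
  planted_conv <- truth$gene[truth$planted_label == "convergent"]
  lab <- tab$label[match(planted_conv, tab$gene)]
  sens <- mean(lab == "convergent", na.rm = TRUE)
  mis <- mean(lab == "divergent", na.rm = TRUE)

  # ORA of the contrast's convergent genes over the simulated collection,
  # in symbol space, against the tested-gene universe
  sym <- function(g) st$reference$truth$symbol[match(g, st$reference$truth$gene)]
  universe <- sym(results[[key]]$gene[!is.na(results[[key]]$padj)])
  conv <- intersect(sym(tab$gene[tab$label == "convergent"]), universe)
  retained <- NA_real_
  planted_sets <- st$genesets$truth$set[st$genesets$truth$planted_enriched]
  if (length(conv) && length(planted_sets)) {
    o <- tryCatch(ora(conv, universe, st$genesets$collection),
                  error = function(e) NULL)
    retained <- if (is.null(o)) 0 else
      as.numeric(all(planted_sets %in% o$set[o$retained]))
  }
  c(sensitivity = sens, divergent_mislabel = mis,
    n_planted_convergent = length(planted_conv),
    enriched_retained = retained)
}
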