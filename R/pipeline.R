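.run_config_keys <- c("seed", "output_dir", "synthetic", "inputs", "contrasts",
                      "thresholds", "enrichment", "plots")

#' Read and validate a run configuration
#'
#' The YAML schema (unknown keys are rejected):
#' ```yaml
#' seed: 1                    # mandatory
#' output_dir: out/run1
#' synthetic:                 # either this or `inputs`
#'   preset: default          # default | null | strong
#'   n_genes: 1000            # any sim_config() field may be overridden
#' inputs:
#'   reference_counts: ref_counts.tsv
#'   reference_samples: ref_samples.tsv
#'   model_counts: model_counts.tsv
#'   model_samples: model_samples.tsv
#'   id_map: id_map.tsv       # optional
#'   collections:             # named GMT files
#'     curated_disease: asd_sets.gmt
#' contrasts:
#'   reference: {condA: CTL, condB: ASD, semantic: case_vs_control}
#'   model:
#'     - {condA: NUntr, condB: NTr, semantic: case_vs_control}
#'   exclusion: [NTr_vs_NUntr]   # optional, default: all model contrasts
#'   gsea: NTr_vs_NUntr          # optional, default: first model contrast
#' thresholds: {p_adj_max: 0.05, abs_log2fc_min: 0.2}
#' enrichment: {min_overlap: 1, B: 1000, perm: gene_set, weight_exponent: 1,
#'              metric: signed_stat, gsea_collection: curated_disease}
#' plots: true
#' ```
#'
#' @param path YAML file, or a list with the same structure.
#' @return validated list of class `"run_config"`.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  unknown <- setdiff(names(cfg), .run_config_keys)
  if (length(unknown))
    stop_txc("unknown config keys: ", paste(unknown, collapse = ", "))
  if (is.null(cfg$seed)) stop_txc("config section 'seed' is missing")
  if (is.null(cfg$synthetic) && is.null(cfg$inputs))
    stop_txc("config needs either a 'synthetic' or an 'inputs' section")
  if (is.null(cfg$contrasts))
    stop_txc("config section 'contrasts' is missing")
  if (is.null(cfg$contrasts$reference))
    stop_txc("config section 'contrasts.reference' is missing")
  if (!length(cfg$contrasts$model))
    stop_txc("config section 'contrasts.model' is missing or empty")
  if (is.null(cfg$output_dir)) stop_txc("config section 'output_dir' is missing")
  if (!is.null(cfg$inputs)) {
    files <- unlist(cfg$inputs[setdiff(names(cfg$inputs), "collections")],
                    use.names = FALSE)
    files <- c(files, unlist(cfg$inputs$collections, use.names = FALSE))
    missing <- files[!file.exists(files)]
    if (length(missing))
      stop_txc("referenced input files do not exist: ",
               paste(missing, collapse = ", "))
  }
  cfg$thresholds <- utils::modifyList(
    list(p_adj_max = 0.05, abs_log2fc_min = 0.2), cfg$thresholds %||% list())
  cfg$enrichment <- utils::modifyList(
    list(min_overlap = 1L, B = 1000L, perm = "gene_set", weight_exponent = 1,
         metric = "signed_stat", gsea_collection = NULL),
    cfg$enrichment %||% list())
  cfg$plots <- isTRUE(cfg$plots %||% TRUE)
  structure(cfg, class = "run_config")
}

sim_config_from_section <- function(syn, seed) {
  preset <- syn$preset %||% "default"
  over <- syn[setdiff(names(syn), "preset")]
  base <- switch(preset,
    default = list(),
    null = list(de_fraction = 0),
    strong = list(ref_lfc = 2, model_lfc = 2, dispersion = 0.05),
    trended = list(dispersion_trend = c(0.05, 5)),
    stop_txc("unknown synthetic preset '", preset, "'"))
  args <- utils::modifyList(base, over)
  args$seed <- seed
  # yaml delivers named sections as lists; sim_config wants vectors
  for (f in c("ref_sizes", "model_sizes", "concordance_plan", "lib_size_range"))
    if (!is.null(args[[f]]) && is.list(args[[f]])) args[[f]] <- unlist(args[[f]])
  do.call(sim_config, args)
}

load_pipeline_inputs <- function(cfg) {
  if (!is.null(cfg$synthetic)) {
    study <- simulate_study(sim_config_from_section(cfg$synthetic, cfg$seed))
    list(ref_counts = study$reference$counts, ref_sheet = study$reference$sheet,
         model_counts = study$model$counts, model_sheet = study$model$sheet,
         idmap = study$reference$id_map,
         collections = list(simulated = study$genesets$collection),
         study = study)
  } else {
    inp <- cfg$inputs
    collections <- lapply(inp$collections %||% list(), read_gmt)
    list(ref_counts = read_count_matrix(inp$reference_counts),
         ref_sheet = read_sample_sheet(inp$reference_samples),
         model_counts = read_count_matrix(inp$model_counts),
         model_sheet = read_sample_sheet(inp$model_samples),
         idmap = if (!is.null(inp$id_map)) read_id_map(inp$id_map),
         collections = collections, study = NULL)
  }
}

#' Run the full concordance pipeline
#'
#' Stage order: identifier mapping, reference differential expression and
#' DEG selection, serial model contrasts, concordance classification,
#' exclusion sets and residual subsetting, over-representation analysis of
#' the residual sets, GSEA, and report tables (row z-scores, lollipop).
#' All tables are written as TSV under `output_dir` together with a JSON
#' run manifest; rerunning with the same config and seed reproduces the
#' tables byte-identically.
#'
#' @param cfg a [read_run_config()] result, a YAML path, or a list.
#' @param until last stage to execute: `"de"`, `"concord"` or `"enrich"`
#'   (full run, default).
#' @return the run manifest, invisibly; all outputs on disk.
#' @export
run_pipeline <- function(cfg, until = c("enrich", "concord", "de")) {
  until <- match.arg(until)
  if (!inherits(cfg, "run_config")) cfg <- read_run_config(cfg)
  out <- cfg$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(obj, name, writer = NULL) {
    path <- file.path(out, name)
    dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
    if (is.null(writer)) {
      utils::write.table(obj, path, sep = "\t", quote = FALSE, row.names = FALSE)
    } else writer(obj, path)
    written <<- c(written, path)
    path
  }
  stage <- "setup"
  manifest <- list(seed = cfg$seed, version = as.character(utils::packageVersion("txconcord")))
  result <- tryCatch({
    set.seed(cfg$seed)

    stage <- "load_inputs"
    inputs <- load_pipeline_inputs(cfg)
    if (!is.null(inputs$study)) {
      # persist the simulated study so downstream stages are file-traceable
      write_simulation(inputs$study, file.path(out, "simulated_input"))
    }
    manifest$genes_in <- nrow(inputs$ref_counts)

    stage <- "map_ids"
    ref_counts <- inputs$ref_counts
    model_counts <- inputs$model_counts
    if (!is.null(inputs$idmap)) {
      ref_counts <- map_gene_ids(ref_counts, inputs$idmap)
      model_counts <- map_gene_ids(model_counts, inputs$idmap)
    }
    manifest$genes_mapped <- nrow(ref_counts)

    stage <- "reference_de"
    rc <- cfg$contrasts$reference
    ref_res <- fit_contrast(ref_counts, inputs$ref_sheet, rc$condA, rc$condB,
                            semantic = rc$semantic)
    emit(ref_res, "reference_contrast.tsv", write_contrast_result)
    th <- cfg$thresholds
    ref_degs <- select_degs(ref_res, th$p_adj_max, th$abs_log2fc_min)
    emit(ref_degs$genes, "reference_degs.tsv")
    manifest$genes_tested_reference <- sum(!is.na(ref_res$padj))
    manifest$n_reference_degs <- nrow(ref_degs$genes)

    stage <- "model_contrasts"
    model_sf <- estimate_size_factors(model_counts)
    model_disp <- estimate_dispersions(model_counts, inputs$model_sheet, model_sf)
    model_res <- list()
    for (mc in cfg$contrasts$model) {
      nm <- paste0(mc$condB, "_vs_", mc$condA)
      model_res[[nm]] <- fit_contrast(model_counts, inputs$model_sheet,
                                      mc$condA, mc$condB, sf = model_sf,
                                      disp = model_disp, semantic = mc$semantic)
      emit(model_res[[nm]], file.path("contrasts", paste0(nm, ".tsv")),
           write_contrast_result)
    }
    if (until == "de") {
      manifest$stages <- "through differential expression"
      return(finalize_manifest(cfg, manifest, out, written))
    }

    stage <- "concordance"
    tables <- lapply(model_res, function(r)
      classify_genes(ref_degs, r, th$p_adj_max, th$abs_log2fc_min))
    for (nm in names(tables))
      emit(tables[[nm]], file.path("concordance", paste0(nm, ".tsv")),
           write_concordance_table)
    summaries <- do.call(rbind, lapply(tables, summarize_concordance))
    emit(summaries, "concordance_summary.tsv")
    manifest$labels <- lapply(tables, function(tb) {
      counts <- table(factor(tb$label, c("convergent", "divergent",
                                         "unresolved", "absent")))
      as.list(stats::setNames(as.integer(counts), names(counts)))
    })
    for (nm in names(manifest$labels)) {
      if (sum(unlist(manifest$labels[[nm]])) != manifest$n_reference_degs)
        stop_txc("manifest inconsistency: labels of ", nm,
                 " do not sum to the reference DEG count")
    }

    stage <- "exclusion"
    excl_names <- cfg$contrasts$exclusion %||% names(tables)
    bad <- setdiff(excl_names, names(tables))
    if (length(bad)) stop_txc("unknown exclusion contrasts: ",
                              paste(bad, collapse = ", "))
    excl <- build_exclusion_sets(tables[excl_names])
    emit(data.frame(gene = c(excl$all_convergent, excl$all_divergent),
                    set = rep(c("all_convergent", "all_divergent"),
                              c(length(excl$all_convergent),
                                length(excl$all_divergent))),
                    stringsAsFactors = FALSE),
         "exclusion_sets.tsv")
    residuals <- lapply(tables, residual_degs, excl = excl)
    resid_gmt <- list()
    for (nm in names(residuals)) {
      write_residual_sets(residuals[[nm]], file.path(out, "residuals"), nm)
      for (side in names(residuals[[nm]]))
        if (length(residuals[[nm]][[side]]))
          resid_gmt[[paste0(nm, ".", side)]] <-
            list(description = "residual DEG set", genes = residuals[[nm]][[side]])
    }
    if (length(resid_gmt))
      emit(gene_set_collection(resid_gmt), "residual_sets.gmt", write_gmt)
    manifest$exclusion <- list(all_convergent = length(excl$all_convergent),
                               all_divergent = length(excl$all_divergent))
    manifest$residual_sizes <- lapply(residuals, lengths)
    for (nm in names(residuals)) {
      if (sum(lengths(residuals[[nm]])) > manifest$n_reference_degs)
        stop_txc("manifest inconsistency: residual sets of ", nm,
                 " exceed the reference DEG count")
    }
    if (until == "concord") {
      manifest$stages <- "through concordance"
      return(finalize_manifest(cfg, manifest, out, written))
    }

    stage <- "ora"
    en <- cfg$enrichment
    ora_tables <- list()
    retained_sets <- 0L
    for (nm in names(residuals)) {
      universe <- model_res[[nm]]$gene[!is.na(model_res[[nm]]$padj)]
      for (side in c("convergent", "divergent")) {
        query <- intersect(residuals[[nm]][[paste0(side, "_residual")]], universe)
        if (!length(query)) next
        for (coll_nm in names(inputs$collections)) {
          res <- tryCatch(
            ora(query, universe, inputs$collections[[coll_nm]],
                min_overlap = en$min_overlap, direction = side),
            error = function(e) NULL)
          if (is.null(res)) next
          key <- paste(nm, side, coll_nm, sep = ".")
          ora_tables[[key]] <- res
          retained_sets <- retained_sets + sum(res$retained)
          emit(res, file.path("ora", paste0(key, ".tsv")))
        }
      }
      lt <- lollipop_table(
        ora_tables[[paste(nm, "convergent", names(inputs$collections)[1L], sep = ".")]],
        ora_tables[[paste(nm, "divergent", names(inputs$collections)[1L], sep = ".")]])
      emit(lt, file.path("lollipop", paste0(nm, ".tsv")))
    }
    manifest$ora_sets_retained <- retained_sets

    stage <- "gsea"
    gsea_contrast <- cfg$contrasts$gsea %||% names(model_res)[1L]
    if (!gsea_contrast %in% names(model_res))
      stop_txc("unknown gsea contrast '", gsea_contrast, "'")
    gsea_coll_nm <- en$gsea_collection %||% names(inputs$collections)[1L]
    gs_res <- gsea(rank_genes(model_res[[gsea_contrast]], en$metric),
                   inputs$collections[[gsea_coll_nm]], B = en$B,
                   perm = "gene_set", seed = cfg$seed,
                   weight_exponent = en$weight_exponent)
    emit(gs_res, "gsea.tsv")
    manifest$gsea_sets_tested <- nrow(gs_res)

    stage <- "report"
    deg_genes <- intersect(ref_degs$genes$gene, rownames(model_counts))
    if (length(deg_genes) >= 1L) {
      norm <- normalize_counts(model_counts, model_sf)
      z <- zscore_rows(norm[deg_genes, , drop = FALSE])
      emit(data.frame(gene = rownames(z), z, check.names = FALSE,
                      stringsAsFactors = FALSE), "heatmap_zscores.tsv")
    }
    if (cfg$plots) render_plots(out)

    manifest$stages <- "complete"
    finalize_manifest(cfg, manifest, out, written)
  }, error = function(e) {
    unlink(written)
    stop_txc("pipeline stage '", stage, "' failed: ", conditionMessage(e))
  })
  invisible(result)
}

finalize_manifest <- function(cfg, manifest, out, written) {
  cfg_path <- file.path(out, "run_config.yaml")
  cfg_plain <- unclass(cfg)
  yaml::write_yaml(cfg_plain, cfg_path)
  # hash the analytic configuration only, so the same analysis written to a
  # different directory is recognizably the same run
  hash_cfg <- cfg_plain[setdiff(names(cfg_plain), "output_dir")]
  tmp <- tempfile(fileext = ".yaml")
  yaml::write_yaml(hash_cfg, tmp)
  manifest$config_hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  manifest$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  manifest$outputs <- sort(basename(written))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  manifest
}

# plots are rebuilt from the serialized tables, never from in-memory state
render_plots <- function(out) {
  lolli_files <- list.files(file.path(out, "lollipop"), full.names = TRUE,
                            pattern = "\\.tsv$")
  for (f in lolli_files) {
    tab <- utils::read.delim(f, stringsAsFactors = FALSE)
    if (!nrow(tab)) next
    tab$x <- ifelse(tab$side == "divergent", tab$neg_log10_padj,
                    -tab$neg_log10_padj)
    tab$set <- factor(tab$set, levels = unique(tab$set[order(abs(tab$x))]))
    p <- ggplot2::ggplot(tab, ggplot2::aes(x = x, y = set, color = side)) +
      ggplot2::geom_segment(ggplot2::aes(x = 0, xend = x, yend = set)) +
      ggplot2::geom_point(size = 3) +
      ggplot2::labs(x = "-log10(adjusted p)  (convergent left / divergent right)",
                    y = NULL) +
      ggplot2::theme_minimal()
    ggplot2::ggsave(sub("\\.tsv$", ".png", f), p, width = 7, height = 4, dpi = 120)
  }
  hz <- file.path(out, "heatmap_zscores.tsv")
  if (file.exists(hz)) {
    tab <- utils::read.delim(hz, check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(tab[, -1L, drop = FALSE])
    rownames(m) <- tab[[1L]]
    if (nrow(m) >= 2L) {
      grDevices::png(file.path(out, "heatmap_zscores.png"), 900, 700)
      pheatmap::pheatmap(utils::head(m, 50L), cluster_cols = FALSE,
                         show_rownames = nrow(m) <= 60L)
      grDevices::dev.off()
    }
  }
  invisible(NULL)
}
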