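#' Simulation configuration
#'
#' Defines a synthetic study with the shape of the analyses this package
#' targets: a disease-vs-control reference cohort of 12 vs 12 bulk RNA-seq
#' samples and a three-condition in vitro model (neuron-microglia co-culture
#' `NM` n=3, untreated neurons `NUntr` n=3, mitochondria-treated neurons
#' `NTr` n=4).  Counts are negative-binomial with log-normal baseline means
#' and log-uniform library sizes; a fraction of genes carries planted
#' differential expression in the reference, and reference DEGs are planted
#' as convergent, divergent or null in the model conditions.
#'
#' @param n_genes number of genes (default 2000).
#' @param ref_sizes named vector of the two reference group sizes
#'   (default `c(CTL = 12, ASD = 12)`); the second name is the case group.
#' @param model_sizes named vector of model condition sizes
#'   (default `c(NUntr = 3, NM = 3, NTr = 4)`); the first name is the
#'   untreated baseline condition.
#' @param lib_size_range library-size multipliers, log-uniform (default
#'   0.5-2).
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of gene
#'   baseline means (defaults 4 and 1.3, heavy-tailed like empirical
#'   RNA-seq means).
#' @param dispersion shared NB dispersion `alpha` (variance
#'   `mu + alpha mu^2`), default 0.1.
#' @param dispersion_trend optional `c(a0, a1)`: per-gene dispersion
#'   `a0 + a1 / baseline_mean`, overriding the shared scalar; exercises the
#'   trend-fitting path of the dispersion estimator.
#' @param de_fraction fraction `pi` of genes differentially expressed in
#'   the reference (default 0.1); signs split evenly.
#' @param ref_lfc,model_lfc planted |log2 fold change| magnitudes
#'   (defaults 1).
#' @param concordance_plan named fractions of reference DEGs planted
#'   `convergent`, `divergent`, `null` in the model (must sum to <= 1; the
#'   remainder is null).
#' @param geneset_plan list with `n_sets`, `set_size`, `n_enriched`,
#'   `enriched_overlap` (fraction of an enriched set drawn from planted
#'   model-effect genes).
#' @param seed mandatory integer seed.
#' @return validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_genes = 2000L,
                       ref_sizes = c(CTL = 12L, ASD = 12L),
                       model_sizes = c(NUntr = 3L, NM = 3L, NTr = 4L),
                       lib_size_range = c(0.5, 2),
                       baseline_meanlog = 4, baseline_sdlog = 1.3,
                       dispersion = 0.1, dispersion_trend = NULL,
                       de_fraction = 0.1,
                       ref_lfc = 1, model_lfc = 1,
                       concordance_plan = c(convergent = 0.4, divergent = 0.3,
                                            null = 0.3),
                       geneset_plan = list(n_sets = 10L, set_size = 25L,
                                           n_enriched = 1L,
                                           enriched_overlap = 1.0),
                       seed) {
  if (missing(seed) || is.null(seed)) stop_txc("seed is mandatory")
  cfg <- list(n_genes = as.integer(n_genes), ref_sizes = ref_sizes,
              model_sizes = model_sizes, lib_size_range = lib_size_range,
              baseline_meanlog = baseline_meanlog,
              baseline_sdlog = baseline_sdlog, dispersion = dispersion,
              dispersion_trend = dispersion_trend,
              de_fraction = de_fraction, ref_lfc = ref_lfc,
              model_lfc = model_lfc, concordance_plan = concordance_plan,
              geneset_plan = geneset_plan, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_genes < 1L) stop_txc("n_genes must be >= 1")
  if (length(cfg$ref_sizes) != 2L || any(cfg$ref_sizes < 2L))
    stop_txc("ref_sizes must give two groups of >= 2 samples")
  if (length(cfg$model_sizes) < 2L || any(cfg$model_sizes < 2L))
    stop_txc("model_sizes must give >= 2 conditions of >= 2 samples")
  if (is.null(names(cfg$ref_sizes)) || is.null(names(cfg$model_sizes)))
    stop_txc("ref_sizes and model_sizes must be named")
  if (cfg$dispersion < 0) stop_txc("dispersion must be >= 0")
  if (!is.null(cfg$dispersion_trend) &&
      (length(cfg$dispersion_trend) != 2L || any(cfg$dispersion_trend < 0)))
    stop_txc("dispersion_trend must be two non-negative coefficients")
  if (cfg$de_fraction < 0 || cfg$de_fraction > 1)
    stop_txc("de_fraction must lie in [0, 1]")
  if (cfg$de_fraction > 0 && round(cfg$de_fraction * cfg$n_genes) < 1)
    stop_txc("de_fraction > 0 but no DE gene results at this n_genes")
  cp <- cfg$concordance_plan
  if (any(cp < 0) || any(cp > 1) || sum(cp[c("convergent", "divergent")]) > 1)
    stop_txc("concordance_plan fractions must be coherent in [0, 1]")
  gp <- cfg$geneset_plan
  if (gp$set_size > cfg$n_genes)
    stop_txc("geneset_plan set_size exceeds n_genes")
  if (diff(cfg$lib_size_range) < 0 || any(cfg$lib_size_range <= 0))
    stop_txc("lib_size_range must be positive and increasing")
  invisible(TRUE)
}

sim_gene_ids <- function(n) sprintf("ENSG%06d", seq_len(n))
sim_symbols <- function(n) sprintf("GENE%d", seq_len(n))

# alpha may be a scalar or one value per gene (mean-dispersion trend)
draw_counts <- function(baseline, lfc_by_sample, lib, alpha) {
  g <- length(baseline); n <- length(lib)
  mu <- (baseline %o% lib) * 2^lfc_by_sample
  alpha_m <- matrix(alpha, g, n)
  out <- matrix(0, g, n)
  pois <- alpha_m <= 0
  if (any(pois)) out[pois] <- stats::rpois(sum(pois), mu[pois])
  if (any(!pois)) out[!pois] <- stats::rnbinom(sum(!pois),
                                               size = 1 / alpha_m[!pois],
                                               mu = mu[!pois])
  out
}

gene_dispersions <- function(cfg, baseline) {
  if (!is.null(cfg$dispersion_trend)) {
    pmax(cfg$dispersion_trend[1L] + cfg$dispersion_trend[2L] / baseline, 0)
  } else cfg$dispersion
}

#' Generate the reference cohort
#'
#' Draws `counts ~ NB(mean = baseline * lib_size * 2^(lfc * group),
#' dispersion alpha)` with exactly `round(de_fraction * n_genes)` DE genes,
#' signs split evenly.  Deterministic given the config (which embeds the
#' seed).
#'
#' @param cfg a [sim_config()].
#' @return list with `counts` ([count_matrix()], rows keyed by source ids),
#'   `sheet` ([sample_sheet()]), `truth` (per-gene data.frame: `gene`,
#'   `symbol`, `is_de`, `ref_lfc`, `ref_sign`), and `id_map` (source id ->
#'   symbol, see [id_map()]).
#' @export
generate_reference <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  g <- cfg$n_genes
  ids <- sim_gene_ids(g); syms <- sim_symbols(g)
  baseline <- stats::rlnorm(g, cfg$baseline_meanlog, cfg$baseline_sdlog)

  n_de <- round(cfg$de_fraction * g)
  de_idx <- sample.int(g, n_de)
  signs <- rep(c(1, -1), length.out = n_de)
  lfc <- numeric(g)
  lfc[de_idx] <- signs * cfg$ref_lfc

  sizes <- cfg$ref_sizes
  cond <- rep(names(sizes), sizes)
  n <- sum(sizes)
  lib <- exp(stats::runif(n, log(cfg$lib_size_range[1L]),
                          log(cfg$lib_size_range[2L])))
  case <- as.numeric(cond == names(sizes)[2L])
  counts <- draw_counts(baseline, outer(lfc, case), lib,
                        gene_dispersions(cfg, baseline))
  dimnames(counts) <- list(ids, sprintf("%s_%02d", cond, stats::ave(
    seq_len(n), cond, FUN = seq_along)))

  truth <- data.frame(gene = ids, symbol = syms, baseline = baseline,
                      is_de = seq_len(g) %in% de_idx, ref_lfc = lfc,
                      ref_sign = sign(lfc),
                      row.names = NULL, stringsAsFactors = FALSE)
  list(counts = count_matrix(counts),
       sheet = sample_sheet(data.frame(sample = colnames(counts),
                                       condition = cond,
                                       stringsAsFactors = FALSE)),
       truth = truth,
       id_map = id_map(data.frame(source_id = ids, target_symbol = syms,
                                  stringsAsFactors = FALSE)))
}

#' Generate the model cohorts
#'
#' Adds planted model effects on top of the reference truth: each reference
#' DE gene is assigned `convergent` (model effect with the reference sign),
#' `divergent` (opposite sign) or `null` per the config's concordance plan.
#' The effect is applied to every non-baseline model condition relative to
#' the first (untreated) condition, so both treated-vs-untreated contrasts
#' carry the planted direction while the treated-vs-treated contrast is
#' null.
#'
#' @param cfg a [sim_config()].
#' @param ref_truth the `truth` table from [generate_reference()].
#' @return list with `counts`, `sheet`, and `truth` (per-gene: `gene`,
#'   `planted_label`, `model_lfc` plus per-contrast planted labels in
#'   attribute `"contrast_truth"` keyed `"<condB>_vs_<condA>"`).
#' @export
generate_model_cohorts <- function(cfg, ref_truth) {
  validate_sim_config(cfg)
  if (!all(c("gene", "is_de", "ref_sign") %in% colnames(ref_truth)))
    stop_txc("ref_truth lacks reference truth columns")
  set.seed(cfg$seed + 1L)
  g <- cfg$n_genes
  if (nrow(ref_truth) != g) stop_txc("ref_truth does not match n_genes")

  de_idx <- which(ref_truth$is_de)
  cp <- cfg$concordance_plan
  n_conv <- round(cp[["convergent"]] * length(de_idx))
  n_div <- round(cp[["divergent"]] * length(de_idx))
  if (n_conv + n_div > length(de_idx)) n_div <- length(de_idx) - n_conv
  shuffled <- sample(de_idx)
  conv_idx <- shuffled[seq_len(n_conv)]
  div_idx <- shuffled[n_conv + seq_len(n_div)]

  label <- rep("none", g)
  label[de_idx] <- "null"
  label[conv_idx] <- "convergent"
  label[div_idx] <- "divergent"
  m_lfc <- numeric(g)
  m_lfc[conv_idx] <- ref_truth$ref_sign[conv_idx] * cfg$model_lfc
  m_lfc[div_idx] <- -ref_truth$ref_sign[div_idx] * cfg$model_lfc

  sizes <- cfg$model_sizes
  base_cond <- names(sizes)[1L]
  cond <- rep(names(sizes), sizes)
  n <- sum(sizes)
  lib <- exp(stats::runif(n, log(cfg$lib_size_range[1L]),
                          log(cfg$lib_size_range[2L])))
  active <- as.numeric(cond != base_cond)
  baseline <- ref_truth$baseline
  counts <- draw_counts(baseline, outer(m_lfc, active), lib,
                        gene_dispersions(cfg, baseline))
  dimnames(counts) <- list(ref_truth$gene, sprintf("%s_%02d", cond, stats::ave(
    seq_len(n), cond, FUN = seq_along)))

  # per-contrast planted labels derived from the condition-level effects
  conds <- names(sizes)
  cond_lfc <- function(cn) if (cn == base_cond) numeric(g) else m_lfc
  pairs <- utils::combn(conds, 2L)
  contrast_truth <- list()
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1L, j]; b <- pairs[2L, j]
    delta <- cond_lfc(b) - cond_lfc(a)
    lab <- rep("null", g)
    lab[delta != 0 & sign(delta) == ref_truth$ref_sign] <- "convergent"
    lab[delta != 0 & sign(delta) == -ref_truth$ref_sign] <- "divergent"
    lab[!ref_truth$is_de] <- "none"
    contrast_truth[[paste0(b, "_vs_", a)]] <-
      data.frame(gene = ref_truth$gene, planted_label = lab, planted_lfc = delta,
                 row.names = NULL, stringsAsFactors = FALSE)
  }

  truth <- data.frame(gene = ref_truth$gene, planted_label = label,
                      model_lfc = m_lfc,
                      row.names = NULL, stringsAsFactors = FALSE)
  attr(truth, "contrast_truth") <- contrast_truth
  attr(truth, "base_condition") <- base_cond
  list(counts = count_matrix(counts),
       sheet = sample_sheet(data.frame(sample = colnames(counts),
                                       condition = cond,
                                       stringsAsFactors = FALSE)),
       truth = truth)
}

#' Generate gene-set collections with planted enrichment
#'
#' Enriched sets draw `round(enriched_overlap * set_size)` members from the
#' planted model-effect genes (convergent or divergent) and the rest from
#' the background; background sets are uniform draws.  Symbols (not source
#' ids) are used, matching the namespace after identifier mapping.
#'
#' @param cfg a [sim_config()].
#' @param ref_truth,model_truth truth tables from the two generators.
#' @return list with `collection` (a [gene_set_collection()]) and
#'   `truth` (data.frame: `set`, `planted_enriched`).
#' @export
generate_genesets <- function(cfg, ref_truth, model_truth) {
  validate_sim_config(cfg)
  set.seed(cfg$seed + 2L)
  gp <- cfg$geneset_plan
  symbols <- ref_truth$symbol
  planted <- symbols[model_truth$planted_label %in% c("convergent", "divergent")]
  if (gp$n_enriched > 0L && !length(planted))
    stop_txc("no planted model-effect genes to build enriched sets from")
  sets <- list()
  flags <- logical(0)
  for (i in seq_len(gp$n_sets)) {
    enriched <- i <= gp$n_enriched
    if (enriched) {
      n_in <- min(round(gp$enriched_overlap * gp$set_size), length(planted))
      inside <- sample(planted, n_in)
      outside <- sample(setdiff(symbols, inside), gp$set_size - n_in)
      members <- c(inside, outside)
    } else {
      members <- sample(symbols, gp$set_size)
    }
    nm <- sprintf("SET%03d", i)
    sets[[nm]] <- list(description = if (enriched) "planted_enriched" else "background",
                       genes = sort(members))
    flags <- c(flags, enriched)
  }
  list(collection = gene_set_collection(sets),
       truth = data.frame(set = names(sets), planted_enriched = flags,
                          row.names = NULL, stringsAsFactors = FALSE))
}

#' Simulate a complete study
#'
#' Convenience wrapper chaining [generate_reference()],
#' [generate_model_cohorts()] and [generate_genesets()].
#'
#' @param cfg a [sim_config()].
#' @return list with `reference`, `model`, `genesets`, and `config`.
#' @export
simulate_study <- function(cfg) {
  ref <- generate_reference(cfg)
  mod <- generate_model_cohorts(cfg, ref$truth)
  gs <- generate_genesets(cfg, ref$truth, mod$truth)
  list(reference = ref, model = mod, genesets = gs, config = cfg)
}

#' Write a simulated study to disk
#'
#' Emits exactly the formats the pipeline ingests: count TSVs, sample-sheet
#' TSVs, an id-map TSV, a GMT collection, truth TSVs, and the config as
#' YAML.
#'
#' @param study result of [simulate_study()].
#' @param dir destination directory (created).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_count_matrix(study$reference$counts, file.path(dir, "reference_counts.tsv"))
  write_sample_sheet(study$reference$sheet, file.path(dir, "reference_samples.tsv"))
  write_count_matrix(study$model$counts, file.path(dir, "model_counts.tsv"))
  write_sample_sheet(study$model$sheet, file.path(dir, "model_samples.tsv"))
  utils::write.table(study$reference$id_map, file.path(dir, "id_map.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_gmt(study$genesets$collection, file.path(dir, "genesets.gmt"))
  utils::write.table(study$reference$truth, file.path(dir, "truth_reference.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(study$model$truth, file.path(dir, "truth_model.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(study$genesets$truth, file.path(dir, "truth_genesets.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- unclass(study$config)
  cfg$ref_sizes <- as.list(cfg$ref_sizes)
  cfg$model_sizes <- as.list(cfg$model_sizes)
  cfg$concordance_plan <- as.list(cfg$concordance_plan)
  yaml::write_yaml(cfg, file.path(dir, "sim_config.yaml"))
  invisible(dir)
}
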