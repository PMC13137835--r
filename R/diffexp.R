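#' Median-of-ratios size factors
#'
#' Per-sample scale factors: for each gene present in every sample, the
#' geometric mean across samples is the reference; a sample's factor is the
#' median over those genes of count / reference.  Genes containing any zero
#' are excluded from the reference set.
#'
#' @param m a [count_matrix()] (or plain matrix of counts).
#' @param pseudo_reference if `TRUE`, fall back to computing geometric means
#'   over positive counts only, so matrices without any all-positive gene
#'   can still be normalized.
#' @return named numeric vector of positive factors, one per sample.
#' @export
estimate_size_factors <- function(m, pseudo_reference = FALSE) {
  m <- unclass(as.matrix(m))
  if (!pseudo_reference) {
    ref <- rowSums(m > 0) == ncol(m)
    if (!any(ref))
      stop_txc("no gene has positive counts in every sample; ",
               "retry with pseudo_reference = TRUE")
    logg <- rowMeans(log(m[ref, , drop = FALSE]))
    sf <- apply(m[ref, , drop = FALSE], 2L, function(col)
      stats::median(exp(log(col) - logg)))
  } else {
    npos <- rowSums(m > 0)
    use <- npos > 0
    lm0 <- log(m[use, , drop = FALSE])
    lm0[!is.finite(lm0)] <- NA
    logg <- rowMeans(lm0, na.rm = TRUE)
    sf <- apply(m[use, , drop = FALSE], 2L, function(col) {
      r <- exp(log(col) - logg)
      stats::median(r[col > 0])
    })
  }
  if (any(!is.finite(sf)) || any(sf <= 0))
    stop_txc("size factor estimation produced a non-positive factor")
  stats::setNames(sf, colnames(m))
}

#' Normalize counts by size factors
#'
#' @param m counts, genes x samples.
#' @param sf size factors as from [estimate_size_factors()].
#' @return matrix of counts divided column-wise by their factors.
#' @export
normalize_counts <- function(m, sf) {
  m <- unclass(as.matrix(m))
  sf <- sf[colnames(m)]
  if (anyNA(sf)) stop_txc("size factors missing for some samples")
  sweep(m, 2L, sf, "/")
}

#' Negative-binomial dispersion estimation
#'
#' Per-gene method-of-moments estimates on normalized counts pooled within
#' condition (`alpha_hat = max(0, (s2 - mu)/mu^2)` with `s2` the pooled
#' within-condition variance and `mu` the grand mean), a parametric trend
#' `a0 + a1/mu` fitted across genes, and a final estimate obtained by
#' shrinking `log(alpha_hat)` toward the trend.  Genes with zero counts in
#' every sample are excluded and reported.
#'
#' @param m a [count_matrix()].
#' @param sheet a [sample_sheet()]; only its samples present in `m` are used.
#' @param sf size factors for the samples used.
#' @param shrink_weight weight in `[0, 1]` on the trend in log space
#'   (0 = raw estimate, 1 = trend); default 0.5.
#' @param dispersion_floor lower bound on the final dispersion.
#' @return data.frame (class `"dispersion_estimates"`) with columns `gene`,
#'   `base_mean`, `raw`, `trend`, `final`; attribute `"excluded"` lists
#'   all-zero genes.
#' @export
estimate_dispersions <- function(m, sheet, sf, shrink_weight = 0.5,
                                 dispersion_floor = 1e-8) {
  m <- unclass(as.matrix(m))
  samples <- intersect(sheet$sample, colnames(m))
  cond <- sheet$condition[match(samples, sheet$sample)]
  if (any(table(cond) < 2L)) stop_txc("every condition needs >= 2 samples")
  m <- m[, samples, drop = FALSE]
  excluded <- rownames(m)[rowSums(m) == 0]
  m <- m[rowSums(m) > 0, , drop = FALSE]
  if (length(excluded))
    txc_log("info", length(excluded), " all-zero genes excluded from dispersion fit")
  k <- normalize_counts(m, sf)

  mu <- rowMeans(k)
  groups <- split(seq_along(samples), cond)
  ss <- Reduce(`+`, lapply(groups, function(ix) {
    sub <- k[, ix, drop = FALSE]
    rowSums((sub - rowMeans(sub))^2)
  }))
  s2 <- ss / (length(samples) - length(groups))
  raw <- pmax(0, (s2 - mu) / mu^2)

  trend <- fit_dispersion_trend(mu, raw, dispersion_floor)
  w <- shrink_weight
  final <- ifelse(raw <= dispersion_floor, trend,
                  exp((1 - w) * log(raw) + w * log(trend)))
  final <- pmax(final, dispersion_floor)

  out <- data.frame(gene = rownames(m), base_mean = mu, raw = raw,
                    trend = trend, final = final,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("dispersion_estimates", "data.frame")
  attr(out, "excluded") <- excluded
  out
}

# parametric mean-dispersion trend a0 + a1/mu, least squares on genes with a
# positive raw estimate, one trimming pass against gross outliers
fit_dispersion_trend <- function(mu, raw, floor) {
  use <- raw > 0 & is.finite(mu) & mu > 0
  if (sum(use) < 10L) {
    const <- if (any(use)) stats::median(raw[use]) else floor
    return(pmax(rep(const, length(mu)), floor))
  }
  fit_once <- function(idx) {
    cf <- stats::coef(stats::lm(raw[idx] ~ I(1 / mu[idx])))
    c(a0 = max(cf[[1L]], floor), a1 = max(cf[[2L]], 0))
  }
  cf <- fit_once(which(use))
  fitted <- cf[["a0"]] + cf[["a1"]] / mu
  keep <- use & raw / pmax(fitted, floor) < 100 & raw / pmax(fitted, floor) > 0.01
  if (sum(keep) >= 10L) cf <- fit_once(which(keep))
  pmax(cf[["a0"]] + cf[["a1"]] / mu, floor)
}

# Vectorized scalar IRLS for a per-gene NB mean with log link and offsets
# log(sf): solves sum_i (y_gi - mu_gi) / (1 + alpha_g * mu_gi) = 0 for the
# gene-wise log mean c_g, where mu_gi = sf_i * exp(c_g).
fit_group_log_means <- function(y, sf, alpha, tol = 1e-10, maxit = 100L) {
  y <- unclass(as.matrix(y))
  g <- nrow(y); n <- ncol(y)
  sfm <- matrix(sf, g, n, byrow = TRUE)
  cc <- log(pmax(rowMeans(y / sfm), 1e-8))
  converged <- rep(FALSE, g)
  active <- rep(TRUE, g)
  for (it in seq_len(maxit)) {
    mu <- exp(cc) * sfm
    w <- mu / (1 + alpha * mu)
    step <- rowSums((y - mu) / (1 + alpha * mu)) / rowSums(w)
    step <- pmin(pmax(step, -5), 5)  # damp early wild steps
    cc[active] <- cc[active] + step[active]
    done <- abs(step) < tol
    converged <- converged | (active & done)
    active <- active & !done
    if (!any(active)) break
  }
  mu <- exp(cc) * sfm
  info <- rowSums(mu / (1 + alpha * mu))
  # all-zero groups drift to -Inf and never satisfy the tolerance
  list(log_mean = cc, info = info, converged = converged)
}

#' Two-group negative-binomial Wald contrast
#'
#' Fits, per gene, a negative-binomial log-linear model with offsets
#' `log(size factor)` and a two-group design, and tests the log2 fold
#' change (condB over condA) with a Wald statistic against the standard
#' normal.  Genes with zero counts in all used samples are dropped before
#' testing and excluded from the multiple-testing family; genes whose fit
#' does not converge are flagged with missing p-values.
#'
#' @param m a [count_matrix()].
#' @param sheet a [sample_sheet()].
#' @param condA,condB condition labels; the reported fold change is
#'   condB relative to condA.
#' @param sf size factors (estimated from the used samples when `NULL`).
#' @param disp a `dispersion_estimates` object (estimated when `NULL`).
#' @param semantic optional orientation tag describing the biological
#'   direction of the contrast, e.g. `"case_vs_control"`; consumed by
#'   [classify_genes()] to align reference and model contrasts.
#' @return data.frame (class `"contrast_result"`) with columns `gene`,
#'   `base_mean`, `log2fc`, `se`, `stat`, `pvalue`, `padj`; attributes
#'   `condA`, `condB`, `semantic`, `dropped` (all-zero genes),
#'   `nonconverged` (flagged genes).
#' @export
fit_contrast <- function(m, sheet, condA, condB, sf = NULL, disp = NULL,
                         semantic = NULL) {
  m0 <- unclass(as.matrix(m))
  sA <- sheet_samples(sheet, condA, m0)
  sB <- sheet_samples(sheet, condB, m0)
  used <- c(sA, sB)
  sub <- m0[, used, drop = FALSE]
  if (is.null(sf)) sf <- estimate_size_factors(sub)
  sf <- sf[used]
  if (anyNA(sf)) stop_txc("size factors missing for contrast samples")
  dropped <- rownames(sub)[rowSums(sub) == 0]
  sub <- sub[rowSums(sub) > 0, , drop = FALSE]
  if (!nrow(sub)) stop_txc("no non-zero genes for contrast ", condB, " vs ", condA)
  if (is.null(disp)) {
    two <- sheet[sheet$sample %in% used, , drop = FALSE]
    disp <- estimate_dispersions(count_matrix(sub), sample_sheet(two), sf)
  }
  alpha <- disp$final[match(rownames(sub), disp$gene)]
  if (anyNA(alpha)) stop_txc("dispersion estimates missing for some genes")

  fitA <- fit_group_log_means(sub[, sA, drop = FALSE], sf[sA], alpha)
  fitB <- fit_group_log_means(sub[, sB, drop = FALSE], sf[sB], alpha)
  ok <- fitA$converged & fitB$converged

  b1 <- fitB$log_mean - fitA$log_mean
  se_ln <- sqrt(1 / fitA$info + 1 / fitB$info)
  log2fc <- b1 / log(2)
  se <- se_ln / log(2)
  stat <- b1 / se_ln
  pvalue <- 2 * stats::pnorm(-abs(stat))
  pvalue[!ok] <- NA_real_
  stat[!ok] <- NA_real_
  padj <- rep(NA_real_, length(pvalue))
  padj[ok] <- bh_adjust(pvalue[ok])

  base_mean <- rowMeans(normalize_counts(sub, sf))
  out <- data.frame(gene = rownames(sub), base_mean = base_mean,
                    log2fc = log2fc, se = se, stat = stat,
                    pvalue = pvalue, padj = padj,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("contrast_result", "data.frame")
  attr(out, "condA") <- condA
  attr(out, "condB") <- condB
  attr(out, "semantic") <- semantic
  attr(out, "dropped") <- dropped
  attr(out, "nonconverged") <- out$gene[!ok]
  if (any(!ok))
    txc_log("warn", sum(!ok), " genes failed IRLS convergence in ",
            condB, " vs ", condA)
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment; output order matches input
#' order.  Backed by [stats::p.adjust()].
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop_txc("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Select differentially expressed genes
#'
#' Members must pass both gates: `padj < p_adj_max` and
#' `|log2fc| >= abs_log2fc_min`.
#'
#' @param r a `contrast_result`.
#' @param p_adj_max adjusted-p gate (strict `<`), default 0.05.
#' @param abs_log2fc_min absolute log2 fold-change gate (`>=`), default 0.2.
#' @return list of class `"deg_set"`: `contrast`, thresholds, and a
#'   data.frame `genes` with `gene`, `sign` (+1/-1), `log2fc`, `padj`.
#' @export
select_degs <- function(r, p_adj_max = 0.05, abs_log2fc_min = 0.2) {
  stopifnot(inherits(r, "contrast_result"))
  if (p_adj_max <= 0 || abs_log2fc_min < 0)
    stop_txc("thresholds must be positive")
  keep <- !is.na(r$padj) & r$padj < p_adj_max & abs(r$log2fc) >= abs_log2fc_min
  genes <- data.frame(gene = r$gene[keep],
                      sign = ifelse(r$log2fc[keep] >= 0, 1L, -1L),
                      log2fc = r$log2fc[keep], padj = r$padj[keep],
                      row.names = NULL, stringsAsFactors = FALSE)
  if (!nrow(genes)) txc_log("info", "empty DEG set at padj<", p_adj_max,
                            ", |log2fc|>=", abs_log2fc_min)
  structure(list(contrast = paste0(attr(r, "condB"), "_vs_", attr(r, "condA")),
                 p_adj_max = p_adj_max, abs_log2fc_min = abs_log2fc_min,
                 semantic = attr(r, "semantic"), genes = genes),
            class = "deg_set")
}

#' Contrast result serialization
#'
#' Fixed TSV layout `gene, base_mean, log2fc, se, stat, pvalue, padj` with
#' the orientation stamp carried in `#`-prefixed header lines.
#'
#' @param r a `contrast_result`.
#' @param path destination / source file.
#' @export
write_contrast_result <- function(r, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# condA: ", attr(r, "condA")),
               paste0("# condB: ", attr(r, "condB")),
               paste0("# semantic: ", attr(r, "semantic") %||% "")), con)
  utils::write.table(as.data.frame(r), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_contrast_result
#' @export
read_contrast_result <- function(path) {
  lines <- readLines(path, n = 10L)
  hdr <- grep("^# ", lines, value = TRUE)
  get <- function(key) {
    v <- sub(paste0("^# ", key, ": "), "", grep(paste0("^# ", key, ":"), hdr, value = TRUE))
    if (length(v) && nzchar(v)) v else NULL
  }
  df <- utils::read.delim(path, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  class(df) <- c("contrast_result", "data.frame")
  attr(df, "condA") <- get("condA")
  attr(df, "condB") <- get("condB")
  attr(df, "semantic") <- get("semantic")
  df
}
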