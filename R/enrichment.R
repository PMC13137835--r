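#' Hypergeometric over-representation analysis
#'
#' Tests each set of a collection for over-representation of a query gene
#' list within a universe (the mapped, tested genes of the originating
#' contrast).  The p-value is the upper hypergeometric tail
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)` with `N` the universe
#' size, `K` the set's overlap with the universe, `n` the query size and
#' `k` the query/set overlap.  BH adjustment runs across the sets with
#' `K >= 1` and `k >= min_overlap`; a set is *retained* when
#' `p_adjust < 0.05`.
#'
#' @param query character vector of genes, a subset of `universe`.
#' @param universe character vector of background genes.
#' @param collection a [gene_set_collection()].
#' @param min_overlap minimum `k` for a set to enter the tested family.
#' @param direction optional provenance tag (e.g. `"convergent"`) stamped
#'   into the result.
#' @return data.frame of class `"ora_result"`: `set`, `k`, `K`, `n`, `N`,
#'   `p_value`, `p_adjust`, `retained`, `direction`, `genes` (overlap,
#'   comma-separated), sorted by p-value.
#' @export
ora <- function(query, universe, collection, min_overlap = 1,
                direction = NA_character_) {
  query <- unique(query)
  universe <- unique(universe)
  extra <- setdiff(query, universe)
  if (length(extra))
    stop_txc("query genes outside the universe: ",
             paste(utils::head(extra, 5L), collapse = ", "),
             if (length(extra) > 5L) ", ...")
  sets <- collection_genes(collection)
  K <- vapply(sets, function(g) length(intersect(g, universe)), integer(1))
  if (all(K == 0))
    stop_txc("no gene set overlaps the universe; identifier namespaces ",
             "probably disagree")
  hits <- lapply(sets, function(g) intersect(g, query))
  k <- lengths(hits)
  N <- length(universe); n <- length(query)
  p <- hyper_tail_p(k, K, n, N)
  fam <- K >= 1L & k >= min_overlap
  padj <- rep(NA_real_, length(p))
  padj[fam] <- bh_adjust(p[fam])
  out <- data.frame(set = names(sets), k = k, K = K, n = n, N = N,
                    p_value = p, p_adjust = padj,
                    retained = !is.na(padj) & padj < 0.05,
                    direction = direction,
                    genes = vapply(hits, function(g) paste(sort(g), collapse = ","), ""),
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[fam, , drop = FALSE]
  out <- out[order(out$p_value, out$set), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ora_result", "data.frame")
  out
}

#' Rank genes by a contrast statistic
#'
#' Builds the strictly ordered input of GSEA.  Metrics: `signed_stat` (the
#' Wald statistic), `log2fc`, or `signed_logp`
#' (`sign(log2fc) * -log10(pvalue)`).  Genes with missing metric values are
#' dropped and reported.  Ordering is descending by metric with ties broken
#' lexicographically by gene id, so the ranking is deterministic.
#'
#' @param r a `contrast_result`.
#' @param metric one of `"signed_stat"`, `"log2fc"`, `"signed_logp"`.
#' @return data.frame of class `"ranked_list"` with `gene` and `metric`;
#'   attribute `"dropped"` lists genes removed for missing values.
#' @export
rank_genes <- function(r, metric = c("signed_stat", "log2fc", "signed_logp")) {
  metric <- match.arg(metric)
  v <- switch(metric,
              signed_stat = r$stat,
              log2fc = r$log2fc,
              signed_logp = sign(r$log2fc) * -log10(pmax(r$pvalue, 1e-300)))
  keep <- is.finite(v)
  dropped <- r$gene[!keep]
  if (length(dropped))
    txc_log("info", length(dropped), " genes dropped from ranking (missing metric)")
  genes <- r$gene[keep]; v <- v[keep]
  o <- order(-v, genes, method = "radix")
  out <- data.frame(gene = genes[o], metric = v[o],
                    row.names = NULL, stringsAsFactors = FALSE)
  if (anyDuplicated(out$gene)) stop_txc("duplicate genes in ranking")
  class(out) <- c("ranked_list", "data.frame")
  attr(out, "dropped") <- dropped
  out
}

#' GSEA running enrichment score
#'
#' Weighted Kolmogorov-Smirnov-like running sum over a ranked list: at a
#' set member ("hit") the sum rises by `|metric|^w / sum_hits |metric|^w`
#' (equal steps when that normalizer is zero), at a miss it falls by
#' `1/(N - |S|)`.  The enrichment score is the signed extremum of the
#' running sum and lies in `[-1, 1]`.
#'
#' @param rl a `ranked_list`.
#' @param set_members character vector; must hit the ranking in at least
#'   one but not all positions.
#' @param weight_exponent `w >= 0`, default 1.
#' @return list with `es`, `running_sum` (length `N`), and `hit_index`.
#' @export
gsea_es <- function(rl, set_members, weight_exponent = 1) {
  stopifnot(inherits(rl, "ranked_list"))
  hit <- rl$gene %in% set_members
  nh <- sum(hit); N <- nrow(rl)
  if (nh == 0L) stop_txc("gene set is disjoint from the ranking")
  if (nh == N) stop_txc("gene set covers the whole ranking")
  wts <- abs(rl$metric)^weight_exponent
  denom <- sum(wts[hit])
  inc <- if (denom > 0) wts / denom else rep(1 / nh, N)
  step <- ifelse(hit, inc, -1 / (N - nh))
  run <- cumsum(step)
  # signed extremum; when the positive and negative extrema tie in magnitude
  # (to within accumulation noise) the positive one is reported, so the sign
  # is deterministic rather than at the mercy of floating-point order
  hi <- max(run); lo <- min(run)
  es <- if (hi >= -lo - 1e-12) hi else lo
  es <- min(1, max(-1, es))  # the exact bound; cumsum noise can overshoot
  list(es = es, running_sum = run, hit_index = which(hit))
}

#' Permutation gene set enrichment analysis
#'
#' Computes, per gene set, the running-sum enrichment score on a ranked
#' list and a permutation p-value.  Input may be a `ranked_list` (gene-set
#' permutation only) or a count matrix plus sample sheet and contrast, in
#' which case the ranking is recomputed internally and phenotype
#' permutation (relabeling samples) becomes available.  Phenotype
#' permutation requires at least 3 samples per group; with smaller groups
#' the function falls back to gene-set permutation with a warning.
#'
#' The permutation p-value is computed relative to the same-sign portion of
#' the null, `(1 + #\{|ES_perm| >= |ES_obs|\}) / (n_same_sign + 1)`, and is
#' therefore never 0; `NES = ES / mean(|ES_perm|)` over the same-sign
#' permutations.  For gene-set permutation, when the number of distinct
#' same-size subsets is at most `B` the null is enumerated exactly instead
#' of sampled.
#'
#' @param x a `ranked_list` or a [count_matrix()].
#' @param collection a [gene_set_collection()].
#' @param B number of permutations (>= 10), default 1000.
#' @param perm `"gene_set"` or `"phenotype"`.
#' @param seed integer seed; mandatory for reproducibility.
#' @param weight_exponent passed to [gsea_es()].
#' @param sheet,condA,condB,metric used only for count-matrix input.
#' @param min_size sets smaller than this (within the ranking) are skipped.
#' @return data.frame of class `"gsea_result"`: `set`, `size`, `es`,
#'   `nes`, `p_value`, `p_adjust`, `leading_edge` (comma-separated).
#' @export
gsea <- function(x, collection, B = 1000L, perm = c("gene_set", "phenotype"),
                 seed, weight_exponent = 1, sheet = NULL, condA = NULL,
                 condB = NULL, metric = "signed_stat", min_size = 1L) {
  perm <- match.arg(perm)
  if (missing(seed)) stop_txc("seed is mandatory")
  if (B < 10L) stop_txc("B must be at least 10")
  set.seed(as.integer(seed))

  if (inherits(x, "ranked_list")) {
    if (perm == "phenotype")
      stop_txc("phenotype permutation needs count input, not a ranked list")
    rl <- x
    ranker <- NULL
  } else {
    if (is.null(sheet) || is.null(condA) || is.null(condB))
      stop_txc("count input requires sheet, condA and condB")
    ranker <- function(sh) {
      r <- fit_contrast(x, sh, condA, condB)
      rank_genes(r, metric)
    }
    rl <- ranker(sheet)
    if (perm == "phenotype") {
      sizes <- table(sheet$condition[sheet$condition %in% c(condA, condB)])
      if (any(sizes < 3L)) {
        txc_log("warn", "a group has < 3 samples; falling back to gene_set ",
                "permutation")
        perm <- "gene_set"
      }
    }
  }
  N <- nrow(rl)

  sets <- collection_genes(collection)
  sizes <- vapply(sets, function(g) sum(rl$gene %in% g), integer(1))
  usable <- sizes >= max(1L, min_size) & sizes < N
  if (!any(usable)) stop_txc("no usable gene set (empty or full overlap)")
  sets <- sets[usable]

  obs <- lapply(sets, function(g) gsea_es(rl, g, weight_exponent))
  es <- vapply(obs, `[[`, numeric(1), "es")

  null_es <- if (perm == "gene_set") {
    lapply(lengths(lapply(obs, `[[`, "hit_index")), function(k)
      null_es_gene_set(rl, k, B, weight_exponent))
  } else {
    two <- sheet[sheet$condition %in% c(condA, condB), , drop = FALSE]
    perms <- replicate(B, {
      sh <- two
      sh$condition <- sample(sh$condition)
      es_p <- tryCatch({
        rlp <- ranker(sample_sheet(sh))
        vapply(sets, function(g) gsea_es(rlp, g, weight_exponent)$es, numeric(1))
      }, error = function(e) rep(NA_real_, length(sets)))
      es_p
    })
    perms <- matrix(perms, nrow = length(sets))
    lapply(seq_along(sets), function(i) perms[i, !is.na(perms[i, ])])
  }

  stats_tab <- mapply(function(e, nulls) {
    same <- nulls[sign(nulls) == sign(e)]
    # nominal p relative to the same-sign portion of the null, as in
    # classic phenotype-permutation GSEA; +1 keeps p off zero
    p <- (1 + sum(abs(same) >= abs(e))) / (length(same) + 1)
    nes <- if (length(same)) e / mean(abs(same)) else NA_real_
    c(p = p, nes = nes)
  }, es, null_es)

  le <- vapply(seq_along(sets), function(i) {
    o <- obs[[i]]
    peak <- if (o$es >= 0) which.max(o$running_sum) else which.min(o$running_sum)
    idx <- if (o$es >= 0) o$hit_index[o$hit_index <= peak]
           else o$hit_index[o$hit_index >= peak]
    paste(rl$gene[idx], collapse = ",")
  }, "")

  out <- data.frame(set = names(sets),
                    size = lengths(lapply(obs, `[[`, "hit_index")),
                    es = es, nes = stats_tab["nes", ],
                    p_value = stats_tab["p", ],
                    p_adjust = bh_adjust(stats_tab["p", ]),
                    leading_edge = le,
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(out$p_value, out$set), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("gsea_result", "data.frame")
  attr(out, "B") <- B
  attr(out, "perm") <- perm
  out
}

#' Upper hypergeometric tail `P(X >= k)`
#'
#' The ORA test statistic: `X ~ Hypergeometric(N, K, n)` counts how many of
#' `n` query genes fall inside a set of `K` universe members out of `N`.
#' Vectorized over its arguments.
#'
#' @param k observed overlap(s).
#' @param K set size(s) within the universe.
#' @param n query size(s).
#' @param N universe size(s).
#' @return `P(X >= k)`, in `(0, 1]` for feasible `k`.
#' @export
hyper_tail_p <- function(k, K, n, N) {
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

# null ES for a set of size k under gene-set permutation; enumerates the
# full subset space exactly when it is no larger than B
null_es_gene_set <- function(rl, k, B, weight_exponent) {
  N <- nrow(rl)
  n_subsets <- suppressWarnings(choose(N, k))
  if (is.finite(n_subsets) && n_subsets <= B) {
    combos <- utils::combn(N, k)
    apply(combos, 2L, function(ix)
      gsea_es(rl, rl$gene[ix], weight_exponent)$es)
  } else {
    vapply(seq_len(B), function(b)
      gsea_es(rl, sample(rl$gene, k), weight_exponent)$es, numeric(1))
  }
}

#' Row-wise z-score standardization
#'
#' Standard preparation of normalized expression for a DEG heatmap: each
#' gene row is centered and scaled to unit variance.  Constant rows (zero
#' standard deviation) are mapped to all-zero rows with a warning.
#'
#' @param mat numeric matrix (genes x samples, >= 2 samples).
#' @return matrix of the same shape.
#' @export
zscore_rows <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2L) stop_txc("z-scoring needs at least 2 samples")
  mu <- rowMeans(mat)
  s <- apply(mat, 1L, stats::sd)
  const <- s == 0 | !is.finite(s)
  if (any(const)) {
    txc_log("warn", sum(const), " constant rows mapped to zeros in z-scoring")
    s[const] <- 1
  }
  out <- (mat - mu) / s
  out[const, ] <- 0
  out
}

#' Two-sided lollipop report table
#'
#' Assembles the retained (BH `p_adjust < 0.05`) pathways of the convergent
#' and divergent over-representation runs into one table, one row per
#' (pathway, side), with `-log10(p_adjust)` as the plotted effect, sorted
#' within side by significance.  A pathway retained on both sides appears
#' twice.  Either side may be empty.
#'
#' @param ora_convergent,ora_divergent `ora_result` objects.
#' @return data.frame with `set`, `side`, `p_adjust`, `neg_log10_padj`, `k`.
#' @export
lollipop_table <- function(ora_convergent = NULL, ora_divergent = NULL) {
  take <- function(res, side) {
    if (is.null(res) || !nrow(res)) return(NULL)
    res <- res[res$retained, , drop = FALSE]
    if (!nrow(res)) return(NULL)
    data.frame(set = res$set, side = side, p_adjust = res$p_adjust,
               neg_log10_padj = -log10(res$p_adjust), k = res$k,
               row.names = NULL, stringsAsFactors = FALSE)
  }
  out <- rbind(take(ora_convergent, "convergent"),
               take(ora_divergent, "divergent"))
  if (is.null(out))
    return(data.frame(set = character(0), side = character(0),
                      p_adjust = numeric(0), neg_log10_padj = numeric(0),
                      k = integer(0), stringsAsFactors = FALSE))
  out <- out[order(out$side, out$p_adjust, out$set), , drop = FALSE]
  rownames(out) <- NULL
  out
}
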