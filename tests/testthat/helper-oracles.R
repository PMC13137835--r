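# Brute-force oracles, deliberately naive and independent of the package's
# implementation paths.

oracle_size_factors <- function(m) {
  ref <- which(apply(m, 1L, function(r) all(r > 0)))
  geo <- vapply(ref, function(g) prod(m[g, ])^(1 / ncol(m)), numeric(1))
  vapply(seq_len(ncol(m)), function(j) {
    ratios <- vapply(seq_along(ref), function(i) m[ref[i], j] / geo[i], numeric(1))
    median(ratios)
  }, numeric(1))
}

oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    val <- min(prev, p[o[i]] * m / i)
    adj[o[i]] <- val
    prev <- val
  }
  adj
}

oracle_hyper_tail <- function(N, K, n, k) {
  js <- k:min(K, n)
  sum(vapply(js, function(j) choose(K, j) * choose(N - K, n - j), numeric(1))) /
    choose(N, n)
}

# explicit loop over ranked positions; hits is a logical vector
oracle_gsea_es <- function(metric, hits, w) {
  N <- length(metric)
  nh <- sum(hits)
  denom <- sum(abs(metric[hits])^w)
  run <- numeric(N)
  cur <- 0
  for (i in seq_len(N)) {
    cur <- cur + if (hits[i]) {
      if (denom > 0) abs(metric[i])^w / denom else 1 / nh
    } else -1 / (N - nh)
    run[i] <- cur
  }
  # ties of extremum magnitude resolve to the positive extremum
  if (max(run) >= -min(run) - 1e-12) max(run) else min(run)
}

oracle_classify_one <- function(ref_sign, m_lfc, m_padj, tested,
                                p_max = 0.05, fc_min = 0.2) {
  if (!tested) return("absent")
  if (is.na(m_padj) || m_padj >= p_max || abs(m_lfc) < fc_min ||
      sign(m_lfc) == 0) return("unresolved")
  if (sign(m_lfc) == ref_sign) "convergent" else "divergent"
}

random_count_matrix <- function(ng = 5L, ns = 4L, max_count = 50L) {
  m <- matrix(sample.int(max_count, ng * ns, replace = TRUE), ng, ns,
              dimnames = list(sprintf("g%02d", seq_len(ng)),
                              sprintf("s%02d", seq_len(ns))))
  m
}

# hand-built contrast_result for unit tests that do not need a model fit
fake_contrast <- function(gene, log2fc, pvalue = NULL, padj,
                          condA = "A", condB = "B", semantic = "case_vs_control") {
  df <- data.frame(gene = gene, base_mean = 10, log2fc = log2fc,
                   se = 0.1, stat = log2fc / 0.1,
                   pvalue = if (is.null(pvalue)) padj else pvalue,
                   padj = padj, stringsAsFactors = FALSE)
  class(df) <- c("contrast_result", "data.frame")
  attr(df, "condA") <- condA
  attr(df, "condB") <- condB
  attr(df, "semantic") <- semantic
  df
}

fake_ranked <- function(gene, metric) {
  o <- order(-metric, gene, method = "radix")
  df <- data.frame(gene = gene[o], metric = metric[o], stringsAsFactors = FALSE)
  class(df) <- c("ranked_list", "data.frame")
  df
}
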