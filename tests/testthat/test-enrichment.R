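test_that("ORA p-values equal the exact hypergeometric tail", {
  u <- sprintf("u%02d", 1:20)
  coll <- gene_set_collection(list(S = list(description = "", genes = u[1:5])))
  res <- ora(u[c(1, 2, 3, 10, 11)], u, coll)
  expect_equal(res$p_value, oracle_hyper_tail(20, 5, 5, 3), tolerance = 1e-12)

  # k = 0 with min_overlap 0 -> p = 1
  res0 <- ora(u[10:14], u, coll, min_overlap = 0)
  expect_equal(res0$p_value, 1)

  # query = universe -> k = K, p = 1
  resU <- ora(u, u, coll)
  expect_equal(resU$k, resU$K)
  expect_equal(resU$p_value, 1)

  # randomized sweep against the combinatorial oracle
  set.seed(61)
  for (rep in 1:100) {
    N <- sample(5:60, 1)
    uni <- sprintf("g%03d", seq_len(N))
    K <- sample.int(N, 1)
    n <- sample.int(N, 1)
    set_genes <- sample(uni, K)
    query <- sample(uni, n)
    k <- length(intersect(set_genes, query))
    if (k < 1) next
    coll <- gene_set_collection(list(S = list(description = "", genes = set_genes)))
    res <- ora(query, uni, coll)
    expect_equal(res$p_value, oracle_hyper_tail(N, K, n, k), tolerance = 1e-10)
    expect_lte(res$k, min(res$K, res$n))
  }

  expect_error(ora(c(u[1], "nope"), u, coll), "outside the universe")
  far <- gene_set_collection(list(S = list(description = "", genes = "zzz")))
  expect_error(ora(u[1:2], u, far), "namespace")
})

test_that("gene ranking is deterministic with lexicographic tie-breaks", {
  r <- fake_contrast(gene = c("b", "a", "c", "d"),
                     log2fc = c(1, 2, -1, 0.5), padj = rep(0.01, 4))
  rl <- rank_genes(r, "log2fc")
  expect_identical(rl$gene, c("a", "b", "d", "c"))  # brute-force sort

  # all-equal metrics -> gene-id lexicographic order
  r2 <- fake_contrast(gene = c("z", "m", "a"), log2fc = c(1, 1, 1),
                      padj = rep(0.01, 3))
  expect_identical(rank_genes(r2, "log2fc")$gene, c("a", "m", "z"))

  # negating every metric reverses a tie-free order exactly
  set.seed(62)
  r3 <- fake_contrast(gene = sprintf("g%02d", 1:15), log2fc = rnorm(15),
                      padj = rep(0.01, 15))
  fwd <- rank_genes(r3, "log2fc")$gene
  r3neg <- r3
  r3neg$log2fc <- -r3$log2fc
  expect_identical(rank_genes(r3neg, "log2fc")$gene, rev(fwd))

  # missing metrics are dropped and reported
  r4 <- fake_contrast(gene = c("a", "b"), log2fc = c(1, NA), padj = c(0.01, NA))
  rl4 <- rank_genes(r4, "log2fc")
  expect_identical(attr(rl4, "dropped"), "b")
})

test_that("enrichment scores match full running-sum enumeration", {
  # single member at rank 1 with w=0 -> ES = 1
  rl <- fake_ranked(c("a", "b", "c", "d"), c(4, 3, 2, 1))
  expect_equal(gsea_es(rl, "a", 0)$es, 1)
  # single member at the last rank of N=4 -> running sum -1/3, -2/3, -1, 0
  out <- gsea_es(rl, "d", 0)
  expect_equal(out$running_sum, c(-1, -2, -3, 0) / 3, tolerance = 1e-12)
  expect_equal(out$es, -1)
  # 6-gene ranking with hits at ranks 2 and 3
  rl6 <- fake_ranked(sprintf("g%d", 1:6), 6:1)
  expect_equal(gsea_es(rl6, c("g2", "g3"), 0)$es,
               oracle_gsea_es(6:1, c(FALSE, TRUE, TRUE, FALSE, FALSE, FALSE), 0))

  # random instances with N <= 12, both weights, vs the loop oracle
  set.seed(63)
  for (rep in 1:200) {
    N <- sample(3:12, 1)
    metric <- round(rnorm(N), 3)
    rl <- fake_ranked(sprintf("g%02d", 1:N), metric)
    k <- sample(N - 1, 1)
    hits_idx <- sort(sample(N, k))
    w <- sample(c(0, 1), 1)
    es <- gsea_es(rl, rl$gene[hits_idx], w)$es
    expect_equal(es, oracle_gsea_es(rl$metric, seq_len(N) %in% hits_idx, w),
                 tolerance = 1e-12)
    expect_gte(es, -1)
    expect_lte(es, 1)
  }

  expect_error(gsea_es(rl6, "absent"), "disjoint")
  expect_error(gsea_es(rl6, sprintf("g%d", 1:6)), "whole ranking")
})

test_that("gsea permutation p matches exhaustive subset enumeration", {
  rl <- fake_ranked(sprintf("g%d", 1:6), c(3, 2, 1, -1, -2, -3))
  coll <- gene_set_collection(list(S = list(description = "", genes = c("g1", "g2"))))
  res <- gsea(rl, coll, B = 15, seed = 1)  # choose(6,2)=15 -> exact enumeration

  combos <- combn(6, 2)
  null_es <- apply(combos, 2, function(ix)
    oracle_gsea_es(rl$metric, seq_len(6) %in% ix, 1))
  obs <- oracle_gsea_es(rl$metric, seq_len(6) %in% c(1, 2), 1)
  same <- null_es[sign(null_es) == sign(obs)]
  expect_equal(res$p_value, (1 + sum(abs(same) >= abs(obs))) / (length(same) + 1))
  expect_equal(res$es, obs)
  expect_equal(sign(res$nes), sign(res$es))
  expect_gte(res$p_value, 1 / (15 + 1))

  # determinism: same seed, same input, identical result
  res2 <- gsea(rl, coll, B = 15, seed = 1)
  expect_identical(res, res2)

  expect_error(gsea(rl, coll, B = 5, seed = 1), "at least 10")
  expect_error(gsea(rl, coll, B = 15), "seed")
})

test_that("gsea agrees with an independent ES implementation (fgsea)", {
  skip_if_not_installed("fgsea")
  set.seed(64)
  N <- 50
  stats <- sort(rnorm(N), decreasing = TRUE)
  names(stats) <- sprintf("g%02d", 1:N)
  members <- sample(names(stats), 8)
  rl <- fake_ranked(names(stats), stats)
  ours <- gsea_es(rl, members, weight_exponent = 1)$es
  theirs <- fgsea::calcGseaStat(stats, selectedStats = which(names(stats) %in% members),
                                gseaParam = 1)
  expect_equal(ours, theirs, tolerance = 1e-6)
})

test_that("gsea on counts supports phenotype permutation with a small-group fallback", {
  cfg <- sim_config(n_genes = 120, seed = 65, model_lfc = 2, dispersion = 0.05,
                    model_sizes = c(NUntr = 2, NM = 3, NTr = 4))
  st <- simulate_study(cfg)
  coll <- gene_set_collection(list(
    S = list(description = "", genes = st$model$truth$gene[1:20])))
  # a 2-sample group cannot support phenotype relabeling
  expect_message(
    res <- gsea(st$model$counts, coll, B = 20, perm = "phenotype", seed = 2,
                sheet = st$model$sheet, condA = "NUntr", condB = "NTr"),
    "gene_set")
  expect_s3_class(res, "gsea_result")
  # with >= 3 per group, phenotype permutation proper runs
  res2 <- gsea(st$model$counts, coll, B = 12, perm = "phenotype", seed = 3,
               sheet = st$model$sheet, condA = "NM", condB = "NTr")
  expect_identical(attr(res2, "perm"), "phenotype")
  expect_gte(res2$p_value, 1 / 13)
})

test_that("row z-scoring standardizes and guards constant rows", {
  set.seed(66)
  m <- matrix(rnorm(30, 10, 3), 5, 6,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:6)))
  z <- zscore_rows(m)
  expect_equal(unname(rowMeans(z)), rep(0, 5), tolerance = 1e-12)
  expect_equal(unname(apply(z, 1, sd)), rep(1, 5), tolerance = 1e-12)
  # brute force standardization
  brute <- t(apply(m, 1, function(r) (r - mean(r)) / sd(r)))
  expect_equal(z, brute, tolerance = 1e-12)

  m2 <- rbind(m, const = rep(4, 6))
  expect_message(z2 <- zscore_rows(m2), "constant")
  expect_equal(unname(z2["const", ]), rep(0, 6))
})

test_that("lollipop tables partition retained pathways by side", {
  mk_ora <- function(sets, padj, k = 3) {
    df <- data.frame(set = sets, k = k, K = 10, n = 20, N = 100,
                     p_value = padj / 2, p_adjust = padj,
                     retained = padj < 0.05, direction = NA, genes = "",
                     stringsAsFactors = FALSE)
    class(df) <- c("ora_result", "data.frame")
    df
  }
  conv <- mk_ora(c("P1", "P2"), c(0.01, 0.2))
  div <- mk_ora(c("P1", "P3"), c(0.03, 0.001))
  tab <- lollipop_table(conv, div)
  expect_identical(sort(unique(tab$side)), c("convergent", "divergent"))
  expect_equal(sum(tab$set == "P1"), 2)  # retained on both sides -> twice
  expect_false("P2" %in% tab$set)        # not retained
  # sorted within side by significance
  div_rows <- tab[tab$side == "divergent", ]
  expect_identical(div_rows$set, c("P3", "P1"))

  one_sided <- lollipop_table(NULL, div)
  expect_true(all(one_sided$side == "divergent"))
  expect_equal(nrow(lollipop_table(NULL, NULL)), 0)
})
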