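make_ref_degs <- function(genes, signs) {
  structure(list(contrast = "ASD_vs_CTL", p_adj_max = 0.05,
                 abs_log2fc_min = 0.2, semantic = "case_vs_control",
                 genes = data.frame(gene = genes, sign = signs,
                                    log2fc = signs, padj = 0.01,
                                    stringsAsFactors = FALSE)),
            class = "deg_set")
}

test_that("gene classification follows the direction/gate rules", {
  ref <- make_ref_degs(c("g1", "g2", "g3", "g4"), c(-1L, -1L, 1L, 1L))
  model <- fake_contrast(gene = c("g1", "g2", "g3"),
                         log2fc = c(-0.5, 0.5, 0.5),
                         padj = c(0.01, 0.01, 0.2))
  tab <- classify_genes(ref, model)
  expect_identical(tab$label[tab$gene == "g1"], "convergent")
  expect_identical(tab$label[tab$gene == "g2"], "divergent")
  expect_identical(tab$label[tab$gene == "g3"], "unresolved")
  expect_identical(tab$label[tab$gene == "g4"], "absent")
  # only reference DEGs appear, exactly once each
  expect_setequal(tab$gene, ref$genes$gene)
  expect_false(anyDuplicated(tab$gene) > 0)
})

test_that("classification matches the enumeration oracle on a full grid", {
  grid <- expand.grid(ref_sign = c(1L, -1L), m_sign = c(1, -1),
                      m_padj = c(0.01, 0.2), m_fc = c(0.1, 0.5),
                      tested = c(TRUE, FALSE))
  genes <- sprintf("g%02d", seq_len(nrow(grid)))
  ref <- make_ref_degs(genes, grid$ref_sign)
  model_rows <- grid$tested
  model <- fake_contrast(gene = genes[model_rows],
                         log2fc = (grid$m_sign * grid$m_fc)[model_rows],
                         padj = grid$m_padj[model_rows])
  tab <- classify_genes(ref, model)
  expected <- vapply(seq_len(nrow(grid)), function(i)
    oracle_classify_one(grid$ref_sign[i], grid$m_sign[i] * grid$m_fc[i],
                        grid$m_padj[i], grid$tested[i]), "")
  expect_identical(tab$label[match(genes, tab$gene)], expected)

  # randomized instances keep matching, and labels always partition
  set.seed(51)
  for (rep in 1:50) {
    n <- sample(5:30, 1)
    g <- sprintf("r%03d", seq_len(n))
    rs <- sample(c(1L, -1L), n, replace = TRUE)
    tested <- runif(n) < 0.8
    lfc <- round(rnorm(n), 2)
    padj <- round(runif(n), 3)
    ref <- make_ref_degs(g, rs)
    model <- fake_contrast(g[tested], lfc[tested], padj = padj[tested])
    tab <- classify_genes(ref, model)
    expected <- vapply(seq_len(n), function(i)
      oracle_classify_one(rs[i], lfc[i], padj[i], tested[i]), "")
    expect_identical(tab$label[match(g, tab$gene)], expected)
    expect_equal(nrow(tab), n)  # exactly one label per reference DEG
    expect_true(all(tab$label %in% c("convergent", "divergent",
                                     "unresolved", "absent")))
  }
})

test_that("orientation stamps are enforced and flipping swaps labels", {
  ref <- make_ref_degs(c("g1", "g2", "g3"), c(1L, -1L, 1L))
  model <- fake_contrast(gene = c("g1", "g2", "g3"),
                         log2fc = c(0.5, 0.5, 0.1),
                         padj = c(0.01, 0.01, 0.01),
                         semantic = "control_vs_case")
  expect_error(classify_genes(ref, model), "orientation")
  straight <- classify_genes(ref, model, flip = FALSE)
  flipped <- classify_genes(ref, model, flip = TRUE)
  swap <- c(convergent = "divergent", divergent = "convergent",
            unresolved = "unresolved", absent = "absent")
  expect_identical(unname(swap[straight$label]), flipped$label)
})

test_that("exclusion sets are exact intersections across contrasts", {
  ref <- make_ref_degs(c("a", "b", "c", "d"), c(1L, 1L, -1L, -1L))
  t1 <- classify_genes(ref, fake_contrast(c("a", "b", "c", "d"),
                                          c(0.5, 0.5, 0.5, -0.5),
                                          padj = rep(0.01, 4)))
  expect_identical(build_exclusion_sets(list(t1))$all_convergent,
                   sort(t1$gene[t1$label == "convergent"]))

  t2 <- classify_genes(ref, fake_contrast(c("a", "b", "c", "d"),
                                          c(0.5, -0.5, 0.5, -0.5),
                                          padj = rep(0.01, 4)))
  excl <- build_exclusion_sets(list(t1, t2))
  # b convergent in t1, divergent in t2 -> in neither set
  expect_false("b" %in% c(excl$all_convergent, excl$all_divergent))
  expect_true("a" %in% excl$all_convergent)

  # random 3-contrast instances vs brute-force set intersection
  set.seed(52)
  for (rep in 1:30) {
    n <- 20
    g <- sprintf("g%02d", 1:n)
    ref <- make_ref_degs(g, sample(c(1L, -1L), n, TRUE))
    tabs <- lapply(1:3, function(i)
      classify_genes(ref, fake_contrast(g, round(rnorm(n), 2),
                                        padj = round(runif(n), 2))))
    excl <- build_exclusion_sets(tabs)
    brute_conv <- Reduce(intersect,
                         lapply(tabs, function(tb) tb$gene[tb$label == "convergent"]))
    brute_div <- Reduce(intersect,
                        lapply(tabs, function(tb) tb$gene[tb$label == "divergent"]))
    expect_setequal(excl$all_convergent, brute_conv)
    expect_setequal(excl$all_divergent, brute_div)

    # residuals equal brute-force set algebra
    drop <- union(brute_conv, brute_div)
    res <- residual_degs(tabs[[1]], excl)
    expect_setequal(res$convergent_residual,
                    setdiff(tabs[[1]]$gene[tabs[[1]]$label == "convergent"], drop))
    expect_setequal(res$divergent_residual,
                    setdiff(tabs[[1]]$gene[tabs[[1]]$label == "divergent"], drop))
  }

  # mismatched references are refused
  ref2 <- make_ref_degs(c("a", "b"), c(1L, 1L))
  t3 <- classify_genes(ref2, fake_contrast(c("a", "b"), c(0.5, 0.5),
                                           padj = c(0.01, 0.01)))
  expect_error(build_exclusion_sets(list(t1, t3)), "different reference")
  expect_error(residual_degs(t3, excl), "different reference")
})

test_that("empty exclusion sets leave residuals untouched", {
  ref <- make_ref_degs(c("a", "b"), c(1L, -1L))
  t1 <- classify_genes(ref, fake_contrast(c("a", "b"), c(0.5, 0.5),
                                          padj = c(0.01, 0.01)))
  t2 <- classify_genes(ref, fake_contrast(c("a", "b"), c(-0.5, -0.5),
                                          padj = c(0.01, 0.01)))
  excl <- build_exclusion_sets(list(t1, t2))
  expect_length(excl$all_convergent, 0L)
  res <- residual_degs(t1, excl)
  expect_setequal(res$convergent_residual, t1$gene[t1$label == "convergent"])
  # a contrast whose convergent set is fully excluded has empty residuals
  excl_all <- build_exclusion_sets(list(t1))
  expect_length(residual_degs(t1, excl_all)$convergent_residual, 0L)
})

test_that("summaries count every label and handle empty references", {
  ref <- make_ref_degs(sprintf("g%02d", 1:10), rep(c(1L, -1L), 5))
  model <- fake_contrast(sprintf("g%02d", 1:9),
                         log2fc = c(0.5, -0.5, 0.5, -0.5, 0.5, -0.5, -0.5, 0.1, 0.1),
                         padj = c(rep(0.01, 4), 0.2, 0.2, 0.01, 0.01, 0.01))
  tab <- classify_genes(ref, model)
  s <- summarize_concordance(tab)
  expect_equal(s$n_reference_degs, 10)
  expect_equal(sum(s$convergent, s$divergent, s$unresolved, s$absent), 10)
  expect_equal(s$frac_convergent + s$frac_divergent + s$frac_unresolved +
                 s$frac_absent, 1, tolerance = 1e-12)

  empty <- tab[0, , drop = FALSE]
  class(empty) <- class(tab)
  attr(empty, "reference") <- character(0)
  s0 <- summarize_concordance(empty)
  expect_equal(s0$n_reference_degs, 0)
  expect_true(is.na(s0$frac_convergent))
  expect_false(is.nan(s0$frac_convergent))
})

test_that("planted concordance structure is recovered end to end", {
  cfg <- sim_config(n_genes = 800, ref_lfc = 2, model_lfc = 2,
                    dispersion = 0.05, seed = 42)
  st <- simulate_study(cfg)
  ref_res <- fit_contrast(st$reference$counts, st$reference$sheet, "CTL", "ASD",
                          semantic = "case_vs_control")
  degs <- select_degs(ref_res)
  sf <- estimate_size_factors(st$model$counts)
  disp <- estimate_dispersions(st$model$counts, st$model$sheet, sf)
  r <- fit_contrast(st$model$counts, st$model$sheet, "NUntr", "NTr",
                    sf = sf, disp = disp, semantic = "case_vs_control")
  tab <- classify_genes(degs, r)
  truth <- attr(st$model$truth, "contrast_truth")[["NTr_vs_NUntr"]]
  planted_conv <- truth$gene[truth$planted_label == "convergent"]
  labels <- tab$label[match(planted_conv, tab$gene)]
  expect_gte(mean(labels == "convergent", na.rm = TRUE), 0.8)
  expect_lte(mean(labels == "divergent", na.rm = TRUE), 0.01)
})
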