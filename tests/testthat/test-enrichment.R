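test_that("2x2 Fisher matches enumeration, fisher.test, and its conventions", {
  expect_equal(fisher_2x2(0, 10, 0, 10)$p_value, 1)
  expect_equal(fisher_2x2(1, 9, 9, 1)$p_value, 202 / 184756)
  f <- fisher_2x2(2, 329, 19, 928)
  expect_equal(round(f$p_value, 2), 0.13)
  # odds ratio invariant under transposition
  expect_equal(fisher_2x2(3, 7, 5, 11)$odds_ratio,
               fisher_2x2(3, 5, 7, 11)$odds_ratio)
  # random tables: enumeration oracle and stats::fisher.test cross-check
  set.seed(5)
  for (i in 1:40) {
    tab <- as.vector(stats::rmultinom(1, sample(10:100, 1), rep(0.25, 4)))
    p <- fisher_2x2(tab[1], tab[2], tab[3], tab[4])$p_value
    expect_equal(p, fisher_two_sided_oracle(tab[1], tab[2], tab[3], tab[4]),
                 tolerance = 1e-12)
    if (all(rowSums(matrix(tab, 2, byrow = TRUE)) > 0) &&
        all(colSums(matrix(tab, 2, byrow = TRUE)) > 0)) {
      ft <- stats::fisher.test(matrix(tab, 2, byrow = TRUE))
      expect_equal(p, ft$p.value, tolerance = 1e-8)
      g <- fisher_2x2(tab[1], tab[2], tab[3], tab[4], sided = "greater")$p_value
      fg <- stats::fisher.test(matrix(tab, 2, byrow = TRUE),
                               alternative = "greater")$p.value
      expect_equal(g, fg, tolerance = 1e-8)
    }
  }
})

test_that("per-time-point set enrichment handles degenerate and planted cases", {
  de <- data.frame(gene_id = rep(paste0("G", 1:10), 2),
                   time_label = rep(c("3h", "7d"), each = 10),
                   is_de = rep(c(TRUE, FALSE), c(10, 10)),
                   direction = "up", stringsAsFactors = FALSE)
  bg <- paste0("G", 1:10)
  # query equals background: no association possible
  r <- timecourse_set_enrichment(de[de$time_label == "3h", ],
                                 gene_set = paste0("G", 1:4), background = bg)
  expect_equal(r$p_value, 1)
  expect_equal(r$odds_ratio, 1)
  expect_error(timecourse_set_enrichment(de, gene_set = "ZZZ", background = bg),
               "no members")
  expect_error(timecourse_set_enrichment(de, gene_set = "G2",
                                         background = paste0("G", 2:5)),
               "absent from the background")
})

test_that("planted early-burst program enriches early, not late", {
  hits_early <- 0L; miss_late <- 0L; n_runs <- 5
  for (i in seq_len(n_runs)) {
    st <- make_study(n_genes = 250, seed = 600 + i, prop_early = 0.1,
                     prop_late = 0.1, mean_expression = rep(300, 250))
    gene_counts <- aggregate_counts(st$counts, map_from_truth(st$truth))
    de <- call_de_timecourse(gene_counts, st$design,
                             common_dispersion(gene_counts, st$design)$common)
    bg <- rownames(gene_counts)
    onco <- names(st$truth$program)[st$truth$program == "early_burst"]
    enr <- timecourse_set_enrichment(de, onco, bg)
    if (all(enr$p_value[enr$time_label %in% c("3h", "6h", "12h", "1d")] < 0.01))
      hits_early <- hits_early + 1L
    if (all(enr$p_value[enr$time_label %in% c("21d", "28d")] > 0.1))
      miss_late <- miss_late + 1L
    g <- grouped_enrichment(de, c("3h", "6h", "12h", "1d"),
                            c("3d", "5d", "7d", "10d", "14d", "21d", "28d"),
                            onco)
    expect_lt(g$p_value, 0.05)
  }
  expect_gte(hits_early, n_runs - 1)
  expect_gte(miss_late, n_runs - 1)
})

test_that("grouped enrichment guards its degenerate cases", {
  de <- data.frame(gene_id = rep(paste0("G", 1:6), 2),
                   time_label = rep(c("3h", "7d"), each = 6),
                   is_de = TRUE, direction = "up", stringsAsFactors = FALSE)
  expect_error(grouped_enrichment(de, c("3h"), c("3h", "7d"), "G1"),
               "overlap")
  # identical group queries cannot show association
  g <- grouped_enrichment(de, "3h", "7d", paste0("G", 1:3))
  expect_equal(g$p_value, 1)
  # empty late query: warning, p = 1
  de2 <- de; de2$is_de[de2$time_label == "7d"] <- FALSE
  expect_warning(g2 <- grouped_enrichment(de2, "3h", "7d", "G1"), "empty")
  expect_equal(g2$p_value, 1)
})

test_that("term-enrichment matrix filters, transforms, and honors EASE", {
  de <- data.frame(gene_id = paste0("G", 1:20), time_label = "3h",
                   is_de = rep(c(TRUE, FALSE), c(8, 12)),
                   direction = "up", stringsAsFactors = FALSE)
  bg <- paste0("G", 1:100)
  terms <- list(exact = paste0("G", 1:8),          # identical to the query
                off = paste0("G", 50:80))
  tm <- term_enrichment_table(de, terms, bg, fdr_threshold = 0.05)
  expect_equal(rownames(tm), "exact")
  expect_gt(tm["exact", "3h"], 2)                  # -log10(fdr) large
  expect_warning(
    empty <- term_enrichment_table(de, terms["off"], bg, fdr_threshold = 0.01),
    "no term")
  expect_equal(nrow(empty), 0)
  # EASE is uniformly conservative
  set.seed(7)
  for (i in 1:25) {
    a <- sample(2:10, 1); b <- sample(0:20, 1)
    cc <- sample(0:20, 1); d <- sample(5:60, 1)
    p0 <- fisher_2x2(a, b, cc, d, sided = "greater")$p_value
    p1 <- fisher_2x2(a - 1, b + 1, cc, d, sided = "greater")$p_value
    expect_gte(p1, p0 - 1e-12)
  }
})

test_that("null term tests reject at close to the nominal rate", {
  set.seed(99)
  bg <- paste0("G", 1:2000)
  ps <- replicate(2000, {
    q <- sample(bg, 400)
    s <- sample(bg, 400)
    a <- length(intersect(q, s))
    fisher_2x2(a, 400 - a, 400 - a, 2000 - 800 + a, sided = "two_sided")$p_value
  })
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.02)
})
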