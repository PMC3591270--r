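test_that("library-size equalization scales to the geometric mean and rounds", {
  m <- matrix(c(10, 90, 40, 360), 2, 2,
              dimnames = list(c("g1", "g2"), c("a", "b")))
  eq <- equalize_and_round(m)          # libs 100 and 400, gm 200
  expect_equal(unname(eq["g1", ]), c(20, 20))
  expect_equal(unname(eq["g2", ]), c(180, 180))
  # equal libraries unchanged up to rounding
  m2 <- matrix(c(3, 7, 5, 5), 2, 2, dimnames = list(c("g1", "g2"), c("a", "b")))
  expect_equal(equalize_and_round(m2), round(m2))
  # all-zero gene stays zero
  m3 <- rbind(m, g3 = c(0, 0))
  expect_equal(unname(equalize_and_round(m3)["g3", ]), c(0, 0))
  expect_error(equalize_and_round(cbind(m, z = c(0, 0))), "zero library")
  expect_error(equalize_and_round(m[, 1, drop = FALSE]), "at least 2")
})

test_that("exact NB test matches its examples and conventions", {
  expect_equal(nb_exact_test(5, 5, 0), 1)
  expect_equal(nb_exact_test(5, 5, 0.3), 1)
  expect_equal(nb_exact_test(0, 10, 0), 2 / 1024)
  expect_equal(nb_exact_test(0, 0, 0.1), 1)          # t = 0 convention
  expect_error(nb_exact_test(1, 2, -0.1), ">= 0")
  # symmetric in the two counts
  expect_equal(nb_exact_test(3, 17, 0.1), nb_exact_test(17, 3, 0.1))
  # brute-force enumeration oracle at a handful of totals
  for (phi in c(0, 0.05, 0.5)) {
    for (y in list(c(3, 17), c(0, 8), c(12, 12), c(1, 40))) {
      expect_equal(nb_exact_test(y[1], y[2], phi),
                   nb_p_oracle(y[1], y[2], phi), tolerance = 1e-12)
    }
  }
  # vectorized path agrees with the scalar path
  y1 <- c(0, 3, 5, 12, 40); y2 <- c(10, 17, 5, 12, 1)
  expect_equal(xenoexpress:::nb_exact_test_many(y1, y2, 0.05),
               mapply(nb_exact_test, y1, y2, 0.05))
})

test_that("pair dispersion recovers truth and hits the zero boundary", {
  set.seed(42)
  y <- rpois(2000, 100)
  expect_identical(as.numeric(estimate_pair_dispersion(y, y)), 0)
  a <- rpois(2000, 80); b <- rpois(2000, 80)
  expect_lt(as.numeric(estimate_pair_dispersion(a, b)), 0.01)
  phis <- vapply(1:5, function(i) {
    set.seed(100 + i)
    a <- rnbinom(2000, size = 10, mu = 100)
    b <- rnbinom(2000, size = 10, mu = 100)
    as.numeric(estimate_pair_dispersion(a, b))
  }, 0)
  expect_true(all(phis >= 0.05 & phis <= 0.2))   # true phi 0.1
  expect_warning(estimate_pair_dispersion(c(1, 2, 0), c(2, 1, 0)),
                 "unstable")
})

test_that("common dispersion is the lower median over consecutive pairs", {
  expect_equal(xenoexpress:::lower_median(c(0.03, 0.05, 0.07)), 0.05)
  expect_equal(xenoexpress:::lower_median(c(0.06, 0.04)), 0.04)
  st <- make_study(n_genes = 500, seed = 21, dispersion = 0.05,
                   prop_early = 0, prop_late = 0)
  d <- common_dispersion(st$counts, st$design)
  expect_length(d$pair_values, 11)
  expect_equal(d$common, xenoexpress:::lower_median(d$pair_values))
  expect_gt(d$common, 0.02)
  expect_lt(d$common, 0.1)
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  p <- c(0.001, 0.04, 0.2, 0.9)
  expect_true(all(bh_adjust(p) >= p))
})

test_that("time-course DE calls respect the control and the FDR gate", {
  st <- make_study(n_genes = 300, seed = 31, dispersion = 0.05,
                   mean_expression = rep(300, 300))
  de <- call_de_timecourse(st$counts, st$design, phi = 0.05)
  expect_s3_class(de, "de_result")
  expect_true(all(de$fdr >= de$p_value - 1e-12))
  expect_identical(de$is_de, de$fdr < 0.05)
  expect_setequal(unique(de$time_label), st$design$time_label[-1])
  # control against a copy of itself yields no calls
  counts2 <- st$counts[, 1:2]
  counts2[, 2] <- counts2[, 1]
  colnames(counts2) <- c("S00", "S01")
  d2 <- timecourse_design(c("S00", "S01"), c("0h", "3h"))
  de2 <- call_de_timecourse(counts2, d2, phi = 0.05)
  expect_equal(sum(de2$is_de), 0)
  # strong planted effects at deep counts are detected (lift contigs to genes)
  truth_de <- names(st$truth$program)[st$truth$program != "null"]
  hit_genes <- unique(st$truth$contig_to_gene[de_union(de)])
  expect_gt(length(intersect(hit_genes, truth_de)) / length(truth_de), 0.8)
})

test_that("null p-values are super-uniform", {
  ks_stats <- vapply(1:10, function(i) {
    st <- make_study(n_genes = 300, seed = 400 + i, dispersion = 0.05,
                     prop_early = 0, prop_late = 0)
    de <- call_de_timecourse(st$counts, st$design, phi = 0.05)
    # one-sided KS: D+ large means sub-uniform (anti-conservative)
    suppressWarnings(
      stats::ks.test(de$p_value, "punif", alternative = "greater")$p.value)
  }, 0)
  expect_true(all(ks_stats > 0.01))
})

map_identity <- function(genes) {
  structure(list(entries = data.frame(contig_id = genes, target_id = genes,
                                      gene_id = genes, e_value = 1e-10,
                                      source = "nucleotide_search",
                                      stringsAsFactors = FALSE),
                 rrna_flagged = character(), unmapped = character()),
            class = "contig_gene_map")
}

test_that("gene-vs-contig DE comparison is exact set algebra", {
  st <- make_study(n_genes = 150, seed = 51, contig_frag_rate = 1,
                   mean_expression = rep(400, 150))
  map <- make_truth_map(st$sim)
  gene_counts <- aggregate_counts(st$counts, map)
  de_g <- call_de_timecourse(gene_counts, st$design, 0.05)
  de_c <- call_de_timecourse(st$counts, st$design, 0.05)
  cmp <- compare_de_levels(de_g, de_c, map,
                           reference_genes = rownames(st$truth$de_truth)[1:30])
  g_set <- de_union(de_g)
  c_set <- unique(map$entries$gene_id[map$entries$contig_id %in% de_union(de_c)])
  expect_setequal(cmp$shared, intersect(g_set, c_set))
  expect_setequal(cmp$gene_only, setdiff(g_set, c_set))
  expect_setequal(cmp$contig_only, setdiff(c_set, g_set))
  expect_equal(sum(cmp$comparison_table), length(cmp$gene_only) + length(cmp$contig_only))
  # identical inputs leave no unique calls
  cmp2 <- compare_de_levels(de_g, de_g, map_identity(g_set))
  expect_length(cmp2$gene_only, 0)
  expect_length(cmp2$contig_only, 0)
})
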