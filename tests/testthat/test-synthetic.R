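test_that("zero-noise contigs are exact substrings and generation is deterministic", {
  sim <- simulate_anchor_and_contigs(n_genes = 5, mutation_rate = 0, seed = 1,
                                     n_orphan_contigs = 2)
  src <- sim$truth$contig_source
  for (i in seq_len(nrow(src))) {
    expect_identical(sim$contigs[[src$contig_id[i]]],
                     substring(sim$transcripts[[src$transcript_id[i]]],
                               src$start[i], src$end[i]))
    expect_true(grepl(sim$contigs[[src$contig_id[i]]],
                      sim$transcripts[[src$transcript_id[i]]], fixed = TRUE))
  }
  sim2 <- simulate_anchor_and_contigs(n_genes = 5, mutation_rate = 0, seed = 1,
                                      n_orphan_contigs = 2)
  expect_identical(sim$contigs, sim2$contigs)
  expect_identical(sim$annotation, sim2$annotation)
  f1 <- tempfile(); f2 <- tempfile()
  write_fasta(sim$contigs, f1); write_fasta(sim2$contigs, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("generator rejects bad arguments", {
  expect_error(simulate_anchor_and_contigs(n_genes = 0), "positive")
  expect_error(simulate_anchor_and_contigs(n_genes = 5, mutation_rate = 2),
               "rates")
  expect_error(simulate_read_provenance(100, p_un = 1.5), "probabilities")
})

test_that("per-contig mismatch fraction matches the mutation rate", {
  sim <- simulate_anchor_and_contigs(n_genes = 50, mutation_rate = 0.02,
                                     seed = 7, n_orphan_contigs = 0)
  src <- sim$truth$contig_source
  fr <- vapply(seq_len(nrow(src)), function(i) {
    a <- strsplit(sim$contigs[[src$contig_id[i]]], "")[[1]]
    b <- strsplit(substring(sim$transcripts[[src$transcript_id[i]]],
                            src$start[i], src$end[i]), "")[[1]]
    mean(a != b)
  }, 0)
  expect_lt(abs(mean(fr) - 0.02), 0.005)
})

test_that("phi = 0 null counts have Poisson moments", {
  st <- make_study(n_genes = 1200, seed = 3, dispersion = 0,
                   prop_early = 0, prop_late = 0,
                   mean_expression = rep(100, 1200))
  m <- rowMeans(st$counts)
  v <- apply(st$counts, 1, var)
  # variance/mean ratio near 1 over >= 1000 genes
  expect_equal(mean(v / m), 1, tolerance = 0.05)
  # determinism
  counts2 <- simulate_timecourse_counts(st$truth, st$design,
                                        mean_expression = rep(100, 1200),
                                        seed = 3 + 1000)
  expect_identical(st$counts, counts2)
})

test_that("a planted log2 fold change of 2 quadruples the sample mean", {
  st <- make_study(n_genes = 200, seed = 11, dispersion = 0.05,
                   prop_early = 0, prop_late = 0,
                   mean_expression = rep(200, 200))
  truth <- st$truth
  truth$de_truth[, "6h"] <- 2   # every gene x4 at one time point
  counts <- simulate_timecourse_counts(truth, st$design,
                                       mean_expression = rep(200, 200),
                                       seed = 99)
  ratio <- mean(counts[, st$design$sample_id[st$design$time_label == "6h"]]) /
    mean(counts[, st$design$sample_id[st$design$is_control]])
  expect_equal(ratio, 4, tolerance = 0.05)
})

test_that("simulated BLAST hits recover truth noiselessly and hit the decoy rate", {
  sim <- simulate_anchor_and_contigs(n_genes = 60, seed = 2,
                                     n_orphan_contigs = 10,
                                     contig_frag_rate = 0.5)
  rows0 <- simulate_blast_hits(sim$contigs, sim$truth, decoy_rate = 0, seed = 1)
  expect_true(all(rows0$evalue < 1e-5))
  orphans <- names(sim$contigs)[is.na(sim$truth$contig_to_gene)]
  expect_length(intersect(rows0$qseqid, orphans), 0)

  path <- tempfile()
  write_blast_tsv(rows0, path)
  best <- select_best_hits(parse_blast_tabular(path))
  map <- resolve_to_genes(best, sim$annotation, contigs = names(sim$contigs))
  got <- setNames(map$entries$gene_id, map$entries$contig_id)
  truth_map <- sim$truth$contig_to_gene[!is.na(sim$truth$contig_to_gene)]
  expect_mapequal(as.list(got), as.list(truth_map))
  expect_setequal(map$unmapped, orphans)

  big <- simulate_anchor_and_contigs(n_genes = 600, seed = 2,
                                     n_orphan_contigs = 60,
                                     contig_frag_rate = 0.5,
                                     transcript_length = c(200, 400))
  rows <- simulate_blast_hits(big$contigs, big$truth, decoy_rate = 0.1, seed = 3)
  src <- big$truth$contig_source
  true_key <- paste(src$contig_id, src$transcript_id)
  is_decoy <- !(paste(rows$qseqid, rows$sseqid) %in% true_key) | rows$evalue >= 1e-5
  expect_lt(abs(mean(is_decoy) - 0.1), 0.02)
})

test_that("read provenance honors the estimator's assumptions", {
  prov <- simulate_read_provenance(5000, p_un = 0.5, p_a_given_un = 1, seed = 4)
  expect_true(all(prov$from_organism[!prov$aligned]))
  expect_true(all(prov$from_organism[prov$aligned]))   # aligned => organism
  expect_false(any(prov$blastx_hit[!prov$from_organism]))
  prov2 <- simulate_read_provenance(5000, p_un = 0.5, p_a_given_un = 1, seed = 4)
  expect_identical(prov, prov2)
})

test_that("qPCR CTs encode the planted fold changes", {
  st <- make_study(n_genes = 30, seed = 5, prop_early = 0, prop_late = 0)
  genes <- rownames(st$truth$de_truth)[1:3]
  ct <- simulate_qpcr(st$truth, st$design, genes, noise_sd = 0, seed = 1)
  d <- delta_ct(ct)
  # null genes: delta-CT constant across samples
  for (g in genes) expect_equal(var(d$dct[d$gene_id == g]), 0)
  # planted logFC +1 at one sample: ddCT = -1 there
  truth <- st$truth
  truth$de_truth[genes[1], "12h"] <- 1
  ct2 <- simulate_qpcr(truth, st$design, genes[1], noise_sd = 0, seed = 1)
  d2 <- delta_ct(ct2)
  s12 <- st$design$sample_id[st$design$time_label == "12h"]
  s0 <- st$design$sample_id[st$design$is_control]
  ddct <- d2$dct[d2$sample_id == s12] - d2$dct[d2$sample_id == s0]
  expect_equal(ddct, -1)
  expect_error(simulate_qpcr(st$truth, st$design, "NOPE"), "absent")
})
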