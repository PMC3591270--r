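blast_line <- function(q, s, e, rank_cols = c(99, 100, 0, 0, 1, 100, 1, 100)) {
  paste(c(q, s, rank_cols[1], rank_cols[2], rank_cols[3], rank_cols[4],
          rank_cols[5], rank_cols[6], rank_cols[7], rank_cols[8], e, 180),
        collapse = "\t")
}

test_that("outfmt-6 parsing preserves order and reports malformed rows", {
  f <- tempfile()
  writeLines(character(), f)
  expect_equal(nrow(parse_blast_tabular(f)), 0)

  writeLines(c(blast_line("c1", "t1", "1e-20"),
               blast_line("c2", "t1", "1e-8"),
               blast_line("c1", "t2", "1e-9")), f)
  h <- parse_blast_tabular(f)
  expect_equal(h$file_rank, 0:2)
  expect_equal(h$contig_id, c("c1", "c2", "c1"))

  writeLines(c(blast_line("c1", "t1", "1e-20"),
               blast_line("c2", "t1", "oops")), f)
  expect_error(parse_blast_tabular(f), "line 2")

  writeLines("c1\tt1\t99", f)
  expect_error(parse_blast_tabular(f), "12 columns")
})

test_that("best-hit selection applies the threshold and the first-listed tie rule", {
  f <- tempfile()
  writeLines(c(blast_line("c1", "tA", "1e-3"),
               blast_line("c1", "tB", "1e-6"),
               blast_line("c2", "tC", "1e-10"),
               blast_line("c2", "tD", "1e-10"),
               blast_line("c3", "tE", "1e-4")), f)
  best <- select_best_hits(parse_blast_tabular(f))
  expect_setequal(best$contig_id, c("c1", "c2"))       # c3 over threshold
  expect_equal(best$target_id[best$contig_id == "c1"], "tB")
  # equal e-values: the hit listed first wins
  expect_equal(best$target_id[best$contig_id == "c2"], "tC")
  # idempotent and order-independent apart from file_rank
  expect_identical(select_best_hits(best), best)
  h <- parse_blast_tabular(f)
  perm <- h[c(5, 3, 1, 4, 2), ]
  best2 <- select_best_hits(perm)
  expect_equal(best2$target_id[best2$contig_id == "c2"], "tC")
})

test_that("gene resolution arbitrates searches and partitions the universe", {
  ann <- data.frame(transcript_id = c("tA", "tB"), gene_id = c("GA", "GB"),
                    stringsAsFactors = FALSE)
  prot <- data.frame(protein_id = c("pB"), gene_id = c("GB"),
                     stringsAsFactors = FALSE)
  mk <- function(contig, target, e, source) {
    data.frame(contig_id = contig, target_id = target, pident = 99,
               align_length = 100, mismatch = 0, gapopen = 0, qstart = 1,
               qend = 100, sstart = 1, send = 100, e_value = e,
               bit_score = 180, file_rank = 0L, source = source,
               stringsAsFactors = FALSE)
  }
  best <- rbind(mk("c1", "tA", 1e-20, "nucleotide_search"),
                mk("c1", "pB", 1e-8, "protein_search"),
                mk("c2", "tA", 1e-9, "nucleotide_search"),
                mk("c3", "tB", 1e-7, "nucleotide_search"))
  map <- resolve_to_genes(best, ann, prot, contigs = c("c1", "c2", "c3", "c4"))
  e <- setNames(map$entries$gene_id, map$entries$contig_id)
  expect_equal(unname(e["c1"]), "GA")   # lower e-value wins across searches
  expect_equal(unname(e["c2"]), "GA")
  expect_equal(unname(e["c3"]), "GB")
  expect_equal(map$unmapped, "c4")
  expect_equal(sort(c(map$entries$contig_id, map$rrna_flagged, map$unmapped)),
               c("c1", "c2", "c3", "c4"))
  # two contigs hitting transcripts of one gene both carry that gene
  expect_equal(unname(e["c1"]), unname(e["c2"]))
  # unresolvable target
  bad <- mk("c9", "tZ", 1e-20, "nucleotide_search")
  expect_error(resolve_to_genes(bad, ann, prot, contigs = "c9"),
               "not resolvable")
})

test_that("rRNA flagging moves contigs out of the mapped entries", {
  sim <- simulate_anchor_and_contigs(n_genes = 10, seed = 3,
                                     n_orphan_contigs = 2)
  map <- make_truth_map(sim)
  expect_identical(flag_and_remove_rrna(map, character()), map)
  victim_tx <- map$entries$target_id[1]
  n0 <- nrow(map$entries)
  flagged <- flag_and_remove_rrna(map, victim_tx)
  expect_equal(length(flagged$rrna_flagged),
               sum(map$entries$target_id == victim_tx))
  expect_equal(nrow(flagged$entries) + length(flagged$rrna_flagged), n0)
})
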