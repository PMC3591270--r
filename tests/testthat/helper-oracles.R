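# Independent oracles used to check the package's statistical operations.
# Each deliberately uses a different computational route than the
# implementation it checks.

# Conditional NB split test by naive enumeration: probabilities from the raw
# product pmf normalized by its sum (the implementation instead uses the NB
# convolution identity for the normalizer).
nb_p_oracle <- function(y1, y2, phi) {
  t <- y1 + y2
  if (t == 0) return(1)
  f <- if (phi > 0) {
    function(k) dnbinom(k, size = 1 / phi, mu = t / 2)
  } else {
    function(k) dpois(k, t / 2)
  }
  pr <- f(0:t) * f(t:0)
  pr <- pr / sum(pr)
  sum(pr[pr <= pr[y1 + 1] * (1 + 1e-10)])
}

# Two-sided Fisher p by explicit enumeration over all tables with the
# observed margins, using log-binomial coefficients (not dhyper).
fisher_two_sided_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  supp <- max(0, k - n):min(k, m)
  lp <- lchoose(m, supp) + lchoose(n, k - supp) - lchoose(m + n, k)
  pr <- exp(lp)
  obs <- pr[match(a, supp)]
  sum(pr[pr <= obs * (1 + 1e-7)])
}

# Brute-force six-frame longest-ORF scan: a plain per-codon loop with
# explicit state, independent of the vectorized implementation.
orf_len_oracle <- function(seq) {
  seq <- toupper(seq)
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  rc <- paste(rev(comp[strsplit(seq, "")[[1]]]), collapse = "")
  best <- 0L
  for (s in c(seq, rc)) {
    for (off in 1:3) {
      if (off > nchar(s) - 2L) next
      pos <- seq.int(off, nchar(s) - 2L, by = 3L)
      cods <- substring(s, pos, pos + 2L)
      n_cod <- length(cods)
      open_at <- NA_integer_
      for (i in seq_len(n_cod)) {
        if (is.na(open_at) && cods[i] == "ATG") open_at <- i
        if (!is.na(open_at) && cods[i] %in% c("TAA", "TAG", "TGA")) {
          best <- max(best, (i - open_at + 1L) * 3L)
          open_at <- NA_integer_
        }
      }
      if (!is.na(open_at)) best <- max(best, (n_cod - open_at + 1L) * 3L)
    }
  }
  best
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# Small synthetic study used across tests: short transcripts keep sequence
# generation cheap; counts are unaffected by transcript length.
make_study <- function(n_genes = 200, seed = 1, dispersion = 0.05,
                       prop_early = 0.05, prop_late = 0.05,
                       contig_frag_rate = 0, mutation_rate = 0,
                       n_orphan_contigs = 0, mean_expression = NULL,
                       logfc_amplitude = 3) {
  sim <- simulate_anchor_and_contigs(
    n_genes = n_genes, contig_frag_rate = contig_frag_rate,
    mutation_rate = mutation_rate, n_orphan_contigs = n_orphan_contigs,
    seed = seed, prop_early = prop_early, prop_late = prop_late,
    logfc_amplitude = logfc_amplitude, dispersion = dispersion,
    transcript_length = c(150, 400))
  design <- timecourse_design(sprintf("S%02d", 0:11))
  counts <- simulate_timecourse_counts(sim$truth, design,
                                       mean_expression = mean_expression,
                                       seed = seed + 1000)
  list(sim = sim, design = design, counts = counts, truth = sim$truth)
}

# Contig->gene map taken directly from the planted truth (no BLAST round
# trip); orphans land in unmapped.
map_from_truth <- function(truth) {
  src <- truth$contig_source
  structure(list(
    entries = data.frame(contig_id = src$contig_id,
                         target_id = src$transcript_id,
                         gene_id = src$gene_id, e_value = 1e-20,
                         source = "nucleotide_search", stringsAsFactors = FALSE),
    rrna_flagged = character(),
    unmapped = names(truth$contig_to_gene)[is.na(truth$contig_to_gene)]),
    class = "contig_gene_map")
}

# Noiseless contig->gene map recovered through the package's own path.
make_truth_map <- function(sim, seed = 1) {
  rows <- simulate_blast_hits(sim$contigs, sim$truth, decoy_rate = 0,
                              seed = seed)
  path <- tempfile(fileext = ".tsv")
  write_blast_tsv(rows, path)
  hits <- parse_blast_tabular(path, source = "nucleotide_search")
  resolve_to_genes(select_best_hits(hits), sim$annotation,
                   contigs = names(sim$contigs))
}
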