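NON_STOP_CODONS <- setdiff(
  apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"), c("A","C","G","T")),
        1, paste, collapse = ""),
  c("TAA", "TAG", "TGA"))

random_dna <- function(n) paste(sample(c("A","C","G","T"), n, replace = TRUE),
                                collapse = "")

# Transcript with a planted coding region: short 5' UTR, ATG + non-stop
# codons + stop, 3' UTR. Gives contigs realistic ORF statistics.
random_transcript <- function(len) {
  utr5 <- max(12L, round(0.12 * len))
  utr3 <- max(12L, round(0.15 * len))
  n_cod <- max(10L, ((len - utr5 - utr3) %/% 3L) - 2L)
  orf <- paste0("ATG",
                paste(sample(NON_STOP_CODONS, n_cod, replace = TRUE),
                      collapse = ""),
                sample(c("TAA", "TAG", "TGA"), 1))
  paste0(random_dna(utr5), orf, random_dna(utr3))
}

mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(list(seq = seq, n_mut = 0L))
  bases <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(bases)) < rate)
  for (i in hit) bases[i] <- sample(setdiff(c("A","C","G","T"), bases[i]), 1)
  list(seq = paste(bases, collapse = ""), n_mut = length(hit))
}

#' Simulate an anchor gene set and a contig assembly
#'
#' Generates a toy anchor annotation (genes with one or more transcript
#' isoforms carrying planted open reading frames), a contig set consisting of
#' fragmented and point-mutated substrings of those transcripts plus
#' composition-shuffled orphan contigs with no coding signal and no anchor
#' homolog, and a ground-truth object used by the other generators and by
#' tests. True per-gene-per-time log2 fold changes follow designated
#' programs: an early burst (up at 3h-1d), a late peak (up at 7d-14d), or
#' null (flat); all fold changes are relative to the zero-hour control.
#'
#' @param n_genes Number of anchor genes, `>= 1`.
#' @param isoforms_per_gene Transcript isoforms per gene.
#' @param contig_frag_rate Probability a transcript copy is fragmented into
#'   several contigs rather than one near-full-length contig.
#' @param mutation_rate Per-base substitution probability in contigs.
#' @param n_orphan_contigs Number of orphan (non-coding, unmappable) contigs.
#' @param seed Integer seed; output is byte-identical under a fixed seed.
#' @param prop_early,prop_late Fractions of genes in the early-burst and
#'   late-peak programs (defaults 0.05 each, i.e. 10% DE genes).
#' @param logfc_amplitude True log2 fold change of program genes when on.
#' @param dispersion True NB dispersion used by the count generator.
#' @param transcript_length Min/max transcript length (nt).
#' @return List: `annotation` (`data.frame` transcript_id, gene_id, length),
#'   `protein_annotation` (`data.frame` protein_id, gene_id), `contigs`
#'   (named character vector), `truth` (a `synthetic_truth`: contig_to_gene,
#'   contig_source, weights, program, de_truth, dispersion).
#' @export
simulate_anchor_and_contigs <- function(n_genes, isoforms_per_gene = 1,
                                        contig_frag_rate = 0.5,
                                        mutation_rate = 0.005,
                                        n_orphan_contigs = max(1L, round(0.1 * n_genes)),
                                        seed = 1,
                                        prop_early = 0.05, prop_late = 0.05,
                                        logfc_amplitude = 3, dispersion = 0.05,
                                        transcript_length = c(600, 2400)) {
  if (n_genes < 1 || isoforms_per_gene < 1)
    stop("n_genes and isoforms_per_gene must be positive")
  if (n_orphan_contigs < 0) stop("n_orphan_contigs must be non-negative")
  rates <- c(contig_frag_rate, mutation_rate, prop_early, prop_late)
  if (any(rates < 0 | rates > 1)) stop("rates must be in [0, 1]")
  with_seed(seed, {
    genes <- sprintf("G%04d", seq_len(n_genes))
    tx_rows <- list(); seqs_tx <- character()
    for (g in genes) {
      for (i in seq_len(isoforms_per_gene)) {
        tid <- paste0(g, ".T", i)
        len <- sample(transcript_length[1]:transcript_length[2], 1)
        s <- random_transcript(len)
        seqs_tx[tid] <- s
        tx_rows[[tid]] <- data.frame(transcript_id = tid, gene_id = g,
                                     length = nchar(s), stringsAsFactors = FALSE)
      }
    }
    annotation <- do.call(rbind, tx_rows); rownames(annotation) <- NULL

    contigs <- character(); src <- list()
    n_ctg <- 0L
    for (tid in annotation$transcript_id) {
      s <- seqs_tx[[tid]]; L <- nchar(s)
      frag <- runif(1) < contig_frag_rate
      k <- if (frag) sample(2:3, 1) else 1L
      for (j in seq_len(k)) {
        if (k == 1L) {
          a <- 1L; b <- L
        } else {
          lf <- max(90L, round(L * runif(1, 0.25, 0.55)))
          a <- sample.int(L - lf + 1L, 1); b <- a + lf - 1L
        }
        n_ctg <- n_ctg + 1L
        cid <- sprintf("CTG%05d", n_ctg)
        mut <- mutate_seq(substring(s, a, b), mutation_rate)
        contigs[cid] <- mut$seq
        src[[cid]] <- data.frame(contig_id = cid, transcript_id = tid,
                                 gene_id = annotation$gene_id[annotation$transcript_id == tid],
                                 start = a, end = b, n_mut = mut$n_mut,
                                 stringsAsFactors = FALSE)
      }
    }
    contig_source <- do.call(rbind, src); rownames(contig_source) <- NULL

    # orphans: mononucleotide-shuffled substrings of real transcripts
    orphan_ids <- if (n_orphan_contigs > 0) sprintf("ORPH%04d", seq_len(n_orphan_contigs)) else character()
    for (oid in orphan_ids) {
      tid <- sample(annotation$transcript_id, 1)
      s <- seqs_tx[[tid]]; L <- nchar(s)
      lf <- max(90L, round(L * runif(1, 0.3, 0.7)))
      a <- sample.int(L - lf + 1L, 1)
      piece <- strsplit(substring(s, a, a + lf - 1L), "", fixed = TRUE)[[1]]
      contigs[oid] <- paste(sample(piece), collapse = "")
    }

    contig_to_gene <- setNames(rep(NA_character_, length(contigs)), names(contigs))
    contig_to_gene[contig_source$contig_id] <- contig_source$gene_id

    # per-gene Dirichlet(1,...,1) weights over member contigs
    weights <- setNames(rep(NA_real_, length(contigs)), names(contigs))
    for (g in genes) {
      ids <- contig_source$contig_id[contig_source$gene_id == g]
      e <- rexp(length(ids))
      weights[ids] <- e / sum(e)
    }

    # expression programs and true log2 fold changes
    n_e <- round(prop_early * n_genes); n_l <- round(prop_late * n_genes)
    program <- setNames(rep("null", n_genes), genes)
    picked <- sample(genes, n_e + n_l)
    program[picked[seq_len(n_e)]] <- "early_burst"
    if (n_l > 0) program[picked[n_e + seq_len(n_l)]] <- "late_peak"
    labels <- tc_time_labels()
    de_truth <- matrix(0, n_genes, length(labels), dimnames = list(genes, labels))
    de_truth[program == "early_burst", c("3h", "6h", "12h", "1d")] <- logfc_amplitude
    de_truth[program == "late_peak", c("7d", "10d", "14d")] <- logfc_amplitude

    truth <- structure(list(contig_to_gene = contig_to_gene,
                            contig_source = contig_source,
                            weights = weights, program = program,
                            de_truth = de_truth, dispersion = dispersion),
                       class = "synthetic_truth")
    list(annotation = annotation,
         protein_annotation = data.frame(protein_id = paste0("P_", genes),
                                         gene_id = genes,
                                         stringsAsFactors = FALSE),
         transcripts = seqs_tx,
         contigs = contigs, truth = truth)
  })
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("synthetic_truth:", length(x$contig_to_gene), "contigs (",
      sum(is.na(x$contig_to_gene)), "orphans ),",
      nrow(x$de_truth), "genes; programs:",
      paste(names(table(x$program)), table(x$program), collapse = ", "),
      "; dispersion", x$dispersion, "\n")
  invisible(x)
}

#' Simulate NB time-course counts at the contig level
#'
#' The expected gene-level count at sample `s` is
#' `mean_expression * 2^logFC(s) * lib_size`, partitioned across the gene's
#' contigs by the fixed Dirichlet weights stored in the truth; each contig
#' count is drawn NB with the truth's dispersion (`phi = 0` gives Poisson).
#' Orphan contigs get their own flat (null) baselines.
#'
#' @param truth A `synthetic_truth`.
#' @param design Time-course design with a designated control.
#' @param mean_expression Named per-gene positive baseline means; default
#'   log-normal around 100.
#' @param lib_sizes Per-sample relative library-size factors (default 1).
#' @param seed Integer seed.
#' @return Numeric count matrix, contigs x samples.
#' @export
simulate_timecourse_counts <- function(truth, design, mean_expression = NULL,
                                       lib_sizes = NULL, seed = 1) {
  validate_design(design)
  genes <- rownames(truth$de_truth)
  labels <- design$time_label
  if (!all(labels %in% colnames(truth$de_truth)))
    stop("design time labels absent from the truth fold-change matrix")
  contigs <- names(truth$contig_to_gene)
  orphans <- contigs[is.na(truth$contig_to_gene)]
  phi <- truth$dispersion
  with_seed(seed, {
    if (is.null(mean_expression)) {
      mean_expression <- setNames(rlnorm(length(genes), log(100), 1), genes)
    } else if (is.null(names(mean_expression))) {
      mean_expression <- setNames(rep_len(mean_expression, length(genes)), genes)
    }
    orphan_mean <- setNames(rlnorm(length(orphans), log(50), 1), orphans)
    if (is.null(lib_sizes)) lib_sizes <- rep(1, nrow(design))
    draw <- function(mu) {
      if (phi > 0) rnbinom(length(mu), size = 1 / phi, mu = mu) else rpois(length(mu), mu)
    }
    counts <- matrix(0, length(contigs), nrow(design),
                     dimnames = list(contigs, design$sample_id))
    for (s in seq_len(nrow(design))) {
      lab <- labels[s]
      mu_gene <- mean_expression[genes] * 2^truth$de_truth[genes, lab] * lib_sizes[s]
      mapped <- !is.na(truth$contig_to_gene)
      mu_ctg <- numeric(length(contigs))
      mu_ctg[mapped] <- truth$weights[contigs[mapped]] *
        mu_gene[truth$contig_to_gene[contigs[mapped]]]
      mu_ctg[!mapped] <- orphan_mean[contigs[!mapped]] * lib_sizes[s]
      counts[, s] <- draw(mu_ctg)
    }
    counts
  })
}

#' Simulate BLAST tabular hits for the contigs
#'
#' Every mapped contig gets one true hit to its source transcript (or its
#' gene's protein for the protein search) with a sub-threshold e-value drawn
#' log-uniform in `[1e-50, 1e-6]`. Decoy rows hit a wrong target with
#' above-threshold e-values log-uniform in `[1e-4, 1]`, at a rate making the
#' expected decoy fraction of all rows equal `decoy_rate`; orphan contigs can
#' only ever receive decoy rows, so they never have a sub-threshold hit.
#'
#' @param contigs Named character vector of contig sequences.
#' @param truth A `synthetic_truth`.
#' @param decoy_rate Target fraction of rows that are decoys.
#' @param seed Integer seed.
#' @param search `"nucleotide"` (targets = transcripts) or `"protein"`.
#' @return `data.frame` with the 12 standard BLAST tabular columns.
#' @export
simulate_blast_hits <- function(contigs, truth, decoy_rate = 0, seed = 1,
                                search = c("nucleotide", "protein")) {
  search <- match.arg(search)
  if (decoy_rate < 0 || decoy_rate >= 1) stop("decoy_rate must be in [0, 1)")
  src <- truth$contig_source
  all_ids <- names(contigs)
  with_seed(seed, {
    target <- if (search == "nucleotide") src$transcript_id else paste0("P_", src$gene_id)
    len <- nchar(contigs[src$contig_id])
    true_rows <- data.frame(
      qseqid = src$contig_id, sseqid = target,
      pident = round(100 * (1 - src$n_mut / len), 2),
      length = len, mismatch = src$n_mut, gapopen = 0L,
      qstart = 1L, qend = len, sstart = src$start, send = src$end,
      evalue = 10^runif(nrow(src), -50, -6),
      bitscore = round(1.8 * len), stringsAsFactors = FALSE)
    rows <- true_rows
    if (decoy_rate > 0) {
      q <- nrow(src) * decoy_rate / (1 - decoy_rate) / length(all_ids)
      decoy_for <- all_ids[runif(length(all_ids)) < q]
      if (length(decoy_for)) {
        pool <- unique(target)
        dl <- nchar(contigs[decoy_for])
        decoys <- data.frame(
          qseqid = decoy_for, sseqid = sample(pool, length(decoy_for), replace = TRUE),
          pident = round(runif(length(decoy_for), 60, 80), 2),
          length = pmin(dl, 120L), mismatch = round(runif(length(decoy_for), 10, 30)),
          gapopen = 0L, qstart = 1L, qend = pmin(dl, 120L),
          sstart = 1L, send = pmin(dl, 120L),
          evalue = 10^runif(length(decoy_for), -4, 0),
          bitscore = round(runif(length(decoy_for), 20, 40)),
          stringsAsFactors = FALSE)
        rows <- rbind(rows, decoys)
      }
    }
    rows <- rows[order(rows$qseqid, rows$evalue), , drop = FALSE]
    rownames(rows) <- NULL
    rows
  })
}

#' Write simulated BLAST rows as outfmt-6 TSV
#' @param rows `data.frame` from [simulate_blast_hits()].
#' @param path File path.
#' @export
write_blast_tsv <- function(rows, path) {
  rows$evalue <- format(rows$evalue, scientific = TRUE, trim = TRUE)
  write.table(rows, path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Simulate per-read provenance for completeness estimation
#'
#' Generates reads satisfying the estimator's assumptions: aligned reads are
#' always truly from the organism, non-organism reads never have a
#' protein-search hit, and the hit probability given organism and
#' high-quality is the same for aligned and unaligned reads. Read quality is
#' independent of everything else.
#'
#' @param n_reads Number of reads.
#' @param p_un Probability a read is unaligned.
#' @param p_a_given_un Probability an unaligned read is truly from the
#'   organism.
#' @param p_b_given_a_hq Hit probability for organism high-quality reads.
#' @param seed Integer seed.
#' @param p_hq Probability a read is high quality (mean phred >= 38).
#' @param n_proteins Size of the anchor protein pool hits are drawn from.
#' @return `data.frame`: `read_id`, `aligned`, `from_organism`,
#'   `mean_quality`, `blastx_hit`, `protein_id`.
#' @export
simulate_read_provenance <- function(n_reads, p_un = 0.49, p_a_given_un = 0.23,
                                     p_b_given_a_hq = 0.17, seed = 1,
                                     p_hq = 0.3, n_proteins = 200) {
  probs <- c(p_un, p_a_given_un, p_b_given_a_hq, p_hq)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  if (n_reads < 1) stop("n_reads must be positive")
  with_seed(seed, {
    aligned <- runif(n_reads) >= p_un
    from_org <- aligned | (runif(n_reads) < p_a_given_un)
    hq <- runif(n_reads) < p_hq
    quality <- ifelse(hq, runif(n_reads, 38, 40), runif(n_reads, 25, 37.9))
    p_hit <- ifelse(from_org & hq, p_b_given_a_hq,
                    ifelse(from_org, 0.6 * p_b_given_a_hq, 0))
    hit <- runif(n_reads) < p_hit
    protein <- rep(NA_character_, n_reads)
    protein[hit] <- paste0("P", sample.int(n_proteins, sum(hit), replace = TRUE))
    data.frame(read_id = sprintf("R%07d", seq_len(n_reads)),
               aligned = aligned, from_organism = from_org,
               mean_quality = round(quality, 1), blastx_hit = hit,
               protein_id = protein, stringsAsFactors = FALSE)
  })
}

#' Simulate qPCR CT tables from the planted fold changes
#'
#' Delta-CT (target CT minus reference-gene CT) encodes the true log2 fold
#' change under the comparative-CT convention:
#' `dCT(s) = dCT(control) - logFC(s)` plus Gaussian noise. The reference-gene
#' CT is constant at 18; target CTs above 40 are set to 40 (the undetected
#' convention).
#'
#' @param truth A `synthetic_truth`.
#' @param design Time-course design.
#' @param genes Genes to assay (must exist in the truth).
#' @param noise_sd Gaussian CT noise standard deviation.
#' @param seed Integer seed.
#' @return CT table `data.frame`: `gene_id`, `sample_id`, `replicate`,
#'   `ct_target`, `ct_reference`.
#' @export
simulate_qpcr <- function(truth, design, genes, noise_sd = 0.3, seed = 1) {
  validate_design(design)
  if (!all(genes %in% rownames(truth$de_truth)))
    stop("genes absent from truth: ",
         paste(setdiff(genes, rownames(truth$de_truth)), collapse = ", "))
  ct_ref <- 18
  with_seed(seed, {
    base_dct <- setNames(runif(length(genes), 5, 10), genes)
    rows <- expand.grid(gene_id = genes, sample_id = design$sample_id,
                        stringsAsFactors = FALSE)
    lab <- design$time_label[match(rows$sample_id, design$sample_id)]
    dct <- base_dct[rows$gene_id] -
      truth$de_truth[cbind(rows$gene_id, lab)] +
      rnorm(nrow(rows), 0, noise_sd)
    ct_t <- pmin(ct_ref + dct, 40)
    data.frame(gene_id = rows$gene_id, sample_id = rows$sample_id,
               replicate = 1L, ct_target = as.numeric(ct_t),
               ct_reference = ct_ref, stringsAsFactors = FALSE)
  })
}
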