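STOP_CODONS <- c("TAA", "TAG", "TGA")

frame_codons <- function(seq, offset) {
  L <- nchar(seq)
  starts <- seq.int(offset, L - 2L, by = 3L)
  if (offset > L - 2L) return(character())
  substring(seq, starts, starts + 2L)
}

# Longest qualifying run in one frame. In "atg" mode an ORF starts at an ATG
# and ends at the first in-frame stop (stop included); an ATG-initiated run
# reaching the end of the sequence with no stop also qualifies. In
# "stop2stop" mode an ORF is any maximal stop-free codon run (terminal stop
# included when present). Codons containing N match neither ATG nor a stop,
# so N never opens or closes an ORF.
frame_longest <- function(codons, mode) {
  n <- length(codons)
  if (n == 0L) return(c(len = 0L, start = NA_integer_))
  stops <- which(codons %in% STOP_CODONS)
  if (mode == "atg") {
    starts <- which(codons == "ATG")
    if (length(starts) == 0L) return(c(len = 0L, start = NA_integer_))
    # index of first stop at or after each start
    nxt <- stops[findInterval(starts - 0.5, stops) + 1L]
    ends <- ifelse(is.na(nxt), n, nxt)
  } else {
    bounds <- c(0L, stops, if (length(stops) == 0L || stops[length(stops)] < n) n + 1L)
    starts <- head(bounds, -1L) + 1L
    ends <- pmin(bounds[-1L], n)
    keep <- ends >= starts
    starts <- starts[keep]; ends <- ends[keep]
    if (length(starts) == 0L) return(c(len = 0L, start = NA_integer_))
  }
  lens <- (ends - starts + 1L)
  i <- which.max(lens)
  c(len = lens[i] * 3L, start = starts[i])
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Longest open reading frame in a sequence
#'
#' Scans all six frames of a DNA sequence (alphabet ACGTN; N never completes
#' a start or stop codon). By default an ORF is ATG-initiated and terminated
#' by the first in-frame stop codon, which is included in the length; an
#' ATG-initiated run reaching the sequence end without a stop also counts.
#' `mode = "stop2stop"` instead takes maximal stop-free runs. Coordinates are
#' 0-based half-open on the forward strand; frames are `+1..+3` (forward
#' offsets) and `-1..-3` (reverse-complement offsets).
#'
#' @param seq DNA string.
#' @param mode `"atg"` (default) or `"stop2stop"`.
#' @return List: `longest_orf_length` (nt, 0 when none), `fraction_of_contig`,
#'   `frame` (0 when none), `start`, `end` (0-based half-open, forward
#'   strand).
#' @export
longest_orf <- function(seq, mode = c("atg", "stop2stop")) {
  mode <- match.arg(mode)
  seq <- toupper(seq)
  L <- nchar(seq)
  if (L < 3L)
    return(list(longest_orf_length = 0L, fraction_of_contig = 0,
                frame = 0L, start = NA_integer_, end = NA_integer_))
  best <- list(len = 0L, frame = 0L, start = NA_integer_, end = NA_integer_)
  consider <- function(len, start0, end0, frame, best) {
    if (len > best$len) list(len = len, frame = frame, start = start0, end = end0)
    else best
  }
  for (off in 1:3) {
    r <- frame_longest(frame_codons(seq, off), mode)
    if (r["len"] > 0L) {
      s1 <- off + (r["start"] - 1L) * 3L        # 1-based forward start
      best <- consider(unname(r["len"]), unname(s1 - 1L),
                       unname(s1 - 1L + r["len"]), off, best)
    }
  }
  rc <- revcomp(seq)
  for (off in 1:3) {
    r <- frame_longest(frame_codons(rc, off), mode)
    if (r["len"] > 0L) {
      s1 <- off + (r["start"] - 1L) * 3L        # 1-based start on rc strand
      e1 <- s1 + r["len"] - 1L                  # 1-based end on rc strand
      # map back to forward strand: rc position j <-> forward L - j + 1
      f_start <- L - e1                          # 0-based forward start
      best <- consider(unname(r["len"]), unname(f_start),
                       unname(f_start + r["len"]), -off, best)
    }
  }
  list(longest_orf_length = best$len,
       fraction_of_contig = best$len / L,
       frame = best$frame, start = best$start, end = best$end)
}

#' Longest-ORF scan over many sequences
#'
#' @param seqs Named character vector of DNA sequences.
#' @param mode See [longest_orf()].
#' @return `data.frame`: `contig_id`, `length`, `longest_orf_length`,
#'   `fraction_of_contig`, `frame`.
#' @export
orf_scan <- function(seqs, mode = "atg") {
  rows <- lapply(seq_along(seqs), function(i) {
    r <- longest_orf(seqs[[i]], mode)
    data.frame(contig_id = names(seqs)[i], length = nchar(seqs[[i]]),
               longest_orf_length = r$longest_orf_length,
               fraction_of_contig = r$fraction_of_contig, frame = r$frame,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Shuffled-sequence ORF null
#'
#' Applies a uniform mononucleotide permutation to each sequence (preserving
#' base composition exactly, destroying any true coding signal) and rescans
#' for the longest ORF. This is the null against which observed ORF fractions
#' are compared.
#'
#' @param seqs Named character vector of DNA sequences.
#' @param seed Integer seed.
#' @param mode See [longest_orf()].
#' @return `data.frame` as in [orf_scan()] for the shuffled sequences.
#' @export
shuffled_null <- function(seqs, seed = 1, mode = "atg") {
  shuffled <- with_seed(seed, {
    vapply(seqs, function(s) {
      paste(sample(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
    }, "")
  })
  names(shuffled) <- names(seqs)
  out <- orf_scan(shuffled, mode)
  attr(out, "shuffled_seqs") <- shuffled
  out
}

#' Per-group ORF fraction distributions
#'
#' Computes the longest-ORF fraction vector for each named group of
#' sequences, with per-group medians (of fraction and of sequence length),
#' suitable for comparing e.g. DE contigs with and without an anchor hit and
#' their shuffled null.
#'
#' @param groups Named list of named character vectors of sequences.
#' @param mode See [longest_orf()].
#' @return List: `fractions` (named list of numeric vectors), `summary`
#'   (`data.frame` with `group`, `n`, `median_fraction`, `median_length`).
#' @export
fraction_distributions <- function(groups, mode = "atg") {
  if (length(groups) == 0L || any(lengths(groups) == 0L))
    stop("every group must be a nonempty set of sequences")
  scans <- lapply(groups, orf_scan, mode = mode)
  fr <- lapply(scans, `[[`, "fraction_of_contig")
  summ <- data.frame(group = names(groups), n = lengths(groups),
                     median_fraction = vapply(fr, median, 0),
                     median_length = vapply(scans, function(s) median(s$length), 0),
                     stringsAsFactors = FALSE, row.names = NULL)
  list(fractions = fr, summary = summ)
}
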