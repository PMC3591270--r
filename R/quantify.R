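#' Aggregate contig-level expected counts to anchor genes
#'
#' Gene count = sum of expected counts over the gene's mapped, non-rRNA
#' contigs. Counts of unmapped and rRNA-flagged contigs are excluded; genes
#' with no mapped contig are absent. Counts are kept as reals (RSEM expected
#' counts are fractional); rounding happens only at the DE test boundary.
#'
#' @param contig_counts Numeric matrix, rows = contigs, columns = samples.
#' @param map A `contig_gene_map` covering every counted contig.
#' @return Numeric matrix, rows = genes, columns = samples.
#' @export
aggregate_counts <- function(contig_counts, map) {
  universe <- c(map$entries$contig_id, map$rrna_flagged, map$unmapped)
  extra <- setdiff(rownames(contig_counts), universe)
  if (length(extra))
    stop("contigs present in counts but absent from the map universe: ",
         paste(head(extra, 10), collapse = ", "))
  e <- map$entries[map$entries$contig_id %in% rownames(contig_counts), , drop = FALSE]
  if (nrow(e) == 0L)
    return(matrix(0, 0, ncol(contig_counts),
                  dimnames = list(character(), colnames(contig_counts))))
  sub <- contig_counts[e$contig_id, , drop = FALSE]
  out <- rowsum(sub, group = e$gene_id)
  out[order(rownames(out)), , drop = FALSE]
}

#' Gene effective lengths from member contigs
#'
#' The effective length of a contig is its length minus the read length (the
#' number of distinct read start positions); a gene's effective length is the
#' sum over its mapped non-rRNA contigs. Contigs shorter than the read length
#' would yield a non-positive value and are floored at 1 (logged per contig).
#'
#' @param map A `contig_gene_map`.
#' @param contig_lengths Named numeric vector of contig lengths (nt).
#' @param read_length Read length in nt, `>= 1`.
#' @return Named numeric vector: gene id -> effective length.
#' @export
gene_effective_length <- function(map, contig_lengths, read_length) {
  if (read_length < 1) stop("read_length must be >= 1")
  e <- map$entries
  len <- contig_lengths[e$contig_id]
  if (anyNA(len))
    stop("missing contig lengths for: ",
         paste(head(e$contig_id[is.na(len)], 10), collapse = ", "))
  eff <- len - read_length
  short <- eff < 1
  if (any(short)) {
    message(sum(short), " contig(s) shorter than the read length;",
            " effective length floored at 1")
    eff[short] <- 1
  }
  v <- rowsum(eff, group = e$gene_id)[, 1]
  v[order(names(v))]
}

#' Contig effective lengths (contig-level quantification path)
#'
#' @param contig_lengths Named numeric vector of contig lengths.
#' @param read_length Read length in nt.
#' @return Named numeric vector of per-contig effective lengths, floored at 1.
#' @export
contig_effective_length <- function(contig_lengths, read_length) {
  if (read_length < 1) stop("read_length must be >= 1")
  pmax(contig_lengths - read_length, 1)
}

#' Transcripts per million with effective-length normalization
#'
#' Per sample, counts are divided by effective lengths and the resulting
#' rates rescaled to sum to one million. An all-zero column stays all-zero.
#'
#' @param counts Numeric matrix, rows = entities (genes or contigs).
#' @param eff_lengths Named numeric vector covering every row of `counts`.
#' @return Matrix of TPM values with the same dimnames as `counts`.
#' @export
compute_tpm <- function(counts, eff_lengths) {
  el <- eff_lengths[rownames(counts)]
  if (anyNA(el))
    stop("missing effective length for: ",
         paste(head(rownames(counts)[is.na(el)], 10), collapse = ", "))
  rates <- counts / el
  tots <- colSums(rates)
  tpm <- sweep(rates, 2, ifelse(tots > 0, tots, 1), "/") * 1e6
  tpm[, tots == 0] <- 0
  tpm
}
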