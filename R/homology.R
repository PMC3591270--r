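#' Parse BLAST tabular output (outfmt 6)
#'
#' Reads the standard 12-column tab-separated BLAST format
#' (qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore), preserving file order via a 0-based `file_rank`.
#'
#' @param path File path.
#' @param source Which search produced the file: hits against anchor
#'   transcripts (`"nucleotide_search"`) or anchor proteins
#'   (`"protein_search"`).
#' @return `data.frame` with columns `contig_id`, `target_id`, `pident`,
#'   `align_length`, `mismatch`, `gapopen`, `qstart`, `qend`, `sstart`,
#'   `send`, `e_value`, `bit_score`, `file_rank`, `source`.
#' @export
parse_blast_tabular <- function(path,
                                source = c("nucleotide_search", "protein_search")) {
  source <- match.arg(source)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(empty_hits(source))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols != 12L)) {
    bad <- which(ncols != 12L)[1L]
    stop(sprintf("malformed BLAST tabular row at line %d: expected 12 columns, got %d",
                 bad, ncols[bad]))
  }
  m <- do.call(rbind, fields)
  num <- function(j, what) {
    v <- suppressWarnings(as.numeric(m[, j]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1L]
      stop(sprintf("malformed BLAST tabular row at line %d: non-numeric %s '%s'",
                   bad, what, m[bad, j]))
    }
    v
  }
  data.frame(contig_id = m[, 1], target_id = m[, 2],
             pident = num(3, "pident"), align_length = num(4, "length"),
             mismatch = num(5, "mismatch"), gapopen = num(6, "gapopen"),
             qstart = num(7, "qstart"), qend = num(8, "qend"),
             sstart = num(9, "sstart"), send = num(10, "send"),
             e_value = num(11, "evalue"), bit_score = num(12, "bitscore"),
             file_rank = seq_along(lines) - 1L, source = source,
             stringsAsFactors = FALSE)
}

empty_hits <- function(source = "nucleotide_search") {
  data.frame(contig_id = character(), target_id = character(),
             pident = numeric(), align_length = numeric(), mismatch = numeric(),
             gapopen = numeric(), qstart = numeric(), qend = numeric(),
             sstart = numeric(), send = numeric(), e_value = numeric(),
             bit_score = numeric(), file_rank = integer(), source = character(),
             stringsAsFactors = FALSE)
}

#' Select the best hit per contig
#'
#' Keeps, for each contig, the minimum e-value hit with e-value strictly below
#' the threshold; ties on e-value are broken by order of appearance in the
#' file (smallest `file_rank` wins). Contigs with no qualifying hit are absent
#' from the result.
#'
#' @param hits `data.frame` from [parse_blast_tabular()].
#' @param threshold E-value threshold (default `1e-5`).
#' @return `data.frame`, one row per contig.
#' @export
select_best_hits <- function(hits, threshold = 1e-5) {
  hits <- hits[hits$e_value < threshold, , drop = FALSE]
  if (nrow(hits) == 0L) return(hits)
  o <- order(hits$contig_id, hits$e_value, hits$file_rank)
  hits <- hits[o, , drop = FALSE]
  hits <- hits[!duplicated(hits$contig_id), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Resolve best hits to anchor genes
#'
#' Combines best hits from the nucleotide and protein searches into a single
#' contig-to-gene assignment. When a contig has qualifying hits from both
#' searches to different genes, the lower e-value wins; on an exact e-value
#' tie the nucleotide search takes precedence (nucleotide identity being the
#' stronger orthology claim for transcript quantification), and the conflict
#' is reported via a message.
#'
#' @param best_hits `data.frame` of best hits (one or both searches combined,
#'   e.g. `rbind` of two [select_best_hits()] results).
#' @param transcript_to_gene `data.frame` with columns `transcript_id`,
#'   `gene_id` (anchor annotation).
#' @param protein_to_gene Optional `data.frame` with columns `protein_id`,
#'   `gene_id`.
#' @param contigs Character vector: the contig universe (all ids in the
#'   assembly FASTA).
#' @return A `contig_gene_map`: list with `entries` (`data.frame` of
#'   `contig_id`, `target_id`, `gene_id`, `e_value`, `source`),
#'   `rrna_flagged` (character) and `unmapped` (character). The three parts
#'   partition the contig universe.
#' @export
resolve_to_genes <- function(best_hits, transcript_to_gene,
                             protein_to_gene = NULL, contigs) {
  contigs <- as.character(contigs)
  if (nrow(best_hits) > 0L) {
    gene <- character(nrow(best_hits))
    is_nucl <- best_hits$source == "nucleotide_search"
    gene[is_nucl] <- transcript_to_gene$gene_id[
      match(best_hits$target_id[is_nucl], transcript_to_gene$transcript_id)]
    if (any(!is_nucl)) {
      if (is.null(protein_to_gene))
        stop("protein_search hits present but no protein_to_gene table given")
      gene[!is_nucl] <- protein_to_gene$gene_id[
        match(best_hits$target_id[!is_nucl], protein_to_gene$protein_id)]
    }
    if (anyNA(gene)) {
      bad <- unique(best_hits$target_id[is.na(gene)])
      stop("target ids not resolvable in the annotation: ",
           paste(head(bad, 10), collapse = ", "))
    }
    best_hits$gene_id <- gene
    # arbitrate across searches: lower e-value, tie -> nucleotide first
    pref <- ifelse(best_hits$source == "nucleotide_search", 0L, 1L)
    o <- order(best_hits$contig_id, best_hits$e_value, pref)
    bh <- best_hits[o, , drop = FALSE]
    dup <- duplicated(bh$contig_id)
    if (any(dup)) {
      both <- bh$contig_id[dup]
      conflict <- vapply(both, function(cid) {
        length(unique(bh$gene_id[bh$contig_id == cid])) > 1L
      }, NA)
      if (any(conflict))
        message(sum(conflict),
                " contig(s) with conflicting nucleotide/protein gene assignments;",
                " kept the lower e-value (tie -> nucleotide search)")
    }
    bh <- bh[!dup, , drop = FALSE]
    entries <- bh[, c("contig_id", "target_id", "gene_id", "e_value", "source")]
    rownames(entries) <- NULL
  } else {
    entries <- data.frame(contig_id = character(), target_id = character(),
                          gene_id = character(), e_value = numeric(),
                          source = character(), stringsAsFactors = FALSE)
  }
  missing <- setdiff(entries$contig_id, contigs)
  if (length(missing))
    stop("hits for contigs absent from the contig universe: ",
         paste(head(missing, 10), collapse = ", "))
  map <- structure(list(entries = entries,
                        rrna_flagged = character(),
                        unmapped = setdiff(contigs, entries$contig_id)),
                   class = "contig_gene_map")
  validate_map(map)
  map
}

validate_map <- function(map) {
  parts <- c(map$entries$contig_id, map$rrna_flagged, map$unmapped)
  if (anyDuplicated(parts))
    stop("contig_gene_map parts do not partition the contig universe")
  invisible(map)
}

#' @export
print.contig_gene_map <- function(x, ...) {
  cat("contig_gene_map:", nrow(x$entries), "mapped,",
      length(x$rrna_flagged), "rRNA-flagged,",
      length(x$unmapped), "unmapped contigs\n")
  cat("  genes:", length(unique(x$entries$gene_id)), "\n")
  invisible(x)
}

#' Flag and remove rRNA contigs
#'
#' Contigs whose assigned anchor target is on the rRNA accession list are
#' moved out of the mapped entries into `rrna_flagged`; downstream TPM
#' renormalization then excludes them.
#'
#' @param map A `contig_gene_map`.
#' @param rrna_ids Character vector of anchor transcript/protein ids (or
#'   gene ids) considered rRNA.
#' @return Updated `contig_gene_map`.
#' @export
flag_and_remove_rrna <- function(map, rrna_ids) {
  hit <- map$entries$target_id %in% rrna_ids | map$entries$gene_id %in% rrna_ids
  map$rrna_flagged <- c(map$rrna_flagged, map$entries$contig_id[hit])
  map$entries <- map$entries[!hit, , drop = FALSE]
  validate_map(map)
  map
}

#' Write a contig-gene map to TSV
#' @param map A `contig_gene_map`.
#' @param path File path.
#' @export
write_map_tsv <- function(map, path) {
  e <- map$entries
  e$rrna_flag <- FALSE
  extra <- function(ids, flag) {
    if (!length(ids)) return(NULL)
    data.frame(contig_id = ids, target_id = NA, gene_id = NA, e_value = NA,
               source = NA, rrna_flag = flag, stringsAsFactors = FALSE)
  }
  out <- rbind(e, extra(map$rrna_flagged, TRUE), extra(map$unmapped, FALSE))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
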