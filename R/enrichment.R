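#' Fisher's exact test on a 2x2 table
#'
#' Exact hypergeometric computation from the table
#' `[[a, b], [c, d]]` (rows: in-set / out-of-set, columns: query / rest).
#' The two-sided p-value is the sum of the probabilities of all tables with
#' the observed margins whose point probability does not exceed that of the
#' observed table; `"greater"` sums the upper tail of `a`. Degenerate tables
#' (a zero margin, where no association is possible) give `p = 1`,
#' `odds_ratio = 1`.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @param sided `"two_sided"` or `"greater"`.
#' @return List with `p_value` and `odds_ratio` (sample odds ratio `ad/bc`).
#' @export
fisher_2x2 <- function(a, b, c, d, sided = c("two_sided", "greater")) {
  sided <- match.arg(sided)
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0)
    return(list(p_value = 1, odds_ratio = 1))
  m <- a + b        # in-set total
  n <- c + d        # out-of-set total
  k <- a + c        # query size
  lo <- max(0L, k - n)
  hi <- min(k, m)
  supp <- lo:hi
  pr <- dhyper(supp, m, n, k)
  obs <- dhyper(a, m, n, k)
  p <- switch(sided,
              two_sided = sum(pr[pr <= obs * (1 + 1e-7)]),
              greater = sum(pr[supp >= a]))
  or <- (a * d) / (b * c)
  if (!is.finite(or)) or <- if (a * d > 0) Inf else 0
  list(p_value = min(1, p), odds_ratio = or)
}

de_query <- function(de, labels, direction = "up") {
  sel <- de$is_de & de$time_label %in% labels &
    (direction == "any" | de$direction == direction)
  unique(de$gene_id[sel])
}

#' Gene-set enrichment of upregulated DE genes per time point
#'
#' At each time point the query is the set of upregulated DE genes; the 2x2
#' table partitions the background by set membership and query membership.
#' The default is one-sided (greater), testing enrichment.
#'
#' @param de A `de_result` (gene level).
#' @param gene_set Character vector of member gene ids.
#' @param background Character vector: the enrichment universe (genes with a
#'   qualifying best hit and at least one mapped read).
#' @param sided Test sidedness.
#' @param direction Which DE direction forms the query (default `"up"`).
#' @return `data.frame`: one row per time point with the 2x2 cells,
#'   `odds_ratio` and `p_value`.
#' @export
timecourse_set_enrichment <- function(de, gene_set, background,
                                      sided = "greater", direction = "up") {
  background <- unique(background)
  set_bg <- intersect(unique(gene_set), background)
  if (length(set_bg) == 0L)
    stop("gene set has no members in the background")
  labels <- unique(de$time_label)
  rows <- lapply(labels, function(tl) {
    q <- de_query(de, tl, direction)
    if (length(setdiff(q, background)))
      stop("query genes absent from the background at ", tl)
    a <- length(intersect(q, set_bg))
    b <- length(set_bg) - a
    cc <- length(q) - a
    d <- length(background) - length(set_bg) - cc
    ft <- fisher_2x2(a, b, cc, d, sided = sided)
    data.frame(time_label = tl, in_set_query = a, in_set_rest = b,
               out_set_query = cc, out_set_rest = d,
               odds_ratio = ft$odds_ratio, p_value = ft$p_value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Grouped early-vs-late gene-set enrichment
#'
#' Compares the in-set fraction between the unions of upregulated DE genes
#' over an early group of time points and a late group, via a 2x2 Fisher test
#' (two-sided by default). A degenerate table (e.g. an empty group query)
#' returns `p = 1` with a warning.
#'
#' @param de A `de_result`.
#' @param early_labels,late_labels Disjoint character vectors of time labels.
#' @param gene_set Character vector of member gene ids.
#' @param background Optional universe used only to validate the queries.
#' @param sided Test sidedness (default two-sided).
#' @return List: the 2x2 `table`, `odds_ratio`, `p_value`, and the two
#'   queries.
#' @export
grouped_enrichment <- function(de, early_labels, late_labels, gene_set,
                               background = NULL, sided = "two_sided") {
  if (length(intersect(early_labels, late_labels)))
    stop("early and late label groups overlap")
  q_early <- de_query(de, early_labels)
  q_late <- de_query(de, late_labels)
  if (!is.null(background)) {
    if (length(setdiff(c(q_early, q_late), background)))
      stop("query genes absent from the background")
  }
  a <- sum(q_early %in% gene_set)
  b <- length(q_early) - a
  cc <- sum(q_late %in% gene_set)
  d <- length(q_late) - cc
  if (length(q_early) == 0L || length(q_late) == 0L)
    warning("empty group query; no association testable (p = 1)")
  ft <- fisher_2x2(a, b, cc, d, sided = sided)
  tab <- matrix(c(a, b, cc, d), nrow = 2, byrow = TRUE,
                dimnames = list(c("early", "late"), c("in_set", "out_set")))
  list(table = tab, odds_ratio = ft$odds_ratio, p_value = ft$p_value,
       query_early = q_early, query_late = q_late)
}

#' Term-enrichment matrix over the time course
#'
#' For each time point, each term set is tested for enrichment among the
#' upregulated DE genes (one-sided Fisher; the EASE variant subtracts 1 from
#' the overlap cell first, a conservative adjustment). Terms overlapping the
#' query by fewer than `min_overlap` genes get `p = 1`. BH adjustment is
#' applied across terms within each time point, the matrix is filtered to
#' terms reaching `fdr < fdr_threshold` at any time point, and `-log10(fdr)`
#' is returned (heat-map input).
#'
#' @param de A `de_result`.
#' @param term_sets Named list of character vectors (e.g. from [read_gmt()]).
#' @param background Character vector: enrichment universe.
#' @param ease_adjust Use the EASE variant (default `FALSE`).
#' @param fdr_threshold Filter threshold (default 0.01).
#' @param min_overlap Minimum query overlap for a term to be testable.
#' @return Numeric matrix, rows = passing terms, columns = time points, of
#'   `-log10(fdr)`; empty (with a warning) when no term passes.
#' @export
term_enrichment_table <- function(de, term_sets, background,
                                  ease_adjust = FALSE, fdr_threshold = 0.01,
                                  min_overlap = 2) {
  if (length(term_sets) < 1L) stop("need at least one term set")
  background <- unique(background)
  labels <- unique(de$time_label)
  fdr_mat <- matrix(NA_real_, length(term_sets), length(labels),
                    dimnames = list(names(term_sets), labels))
  for (tl in labels) {
    q <- de_query(de, tl)
    p <- vapply(term_sets, function(members) {
      set_bg <- intersect(unique(members), background)
      a <- length(intersect(q, set_bg))
      if (a < min_overlap) return(1)
      if (ease_adjust) a <- max(a - 1L, 0L)
      b <- length(set_bg) - a
      cc <- length(q) - a
      d <- length(background) - length(set_bg) - cc
      fisher_2x2(a, b, cc, d, sided = "greater")$p_value
    }, 0)
    fdr_mat[, tl] <- bh_adjust(p)
  }
  keep <- apply(fdr_mat, 1, function(v) any(v < fdr_threshold))
  if (!any(keep)) {
    warning("no term passes the FDR filter at any time point")
    return(matrix(0, 0, length(labels), dimnames = list(character(), labels)))
  }
  -log10(fdr_mat[keep, , drop = FALSE])
}
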