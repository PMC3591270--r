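#' Equalize library sizes and round to integers
#'
#' Scales each sample column to the geometric mean of the column sums
#' (library sizes) and rounds half-to-even, as required by the conditional
#' exact test, which compares two counts at a common library size.
#'
#' @param counts Numeric matrix (entities x samples), `>= 2` columns.
#' @return Integer-valued matrix with equalized library sizes.
#' @export
equalize_and_round <- function(counts) {
  if (ncol(counts) < 2L) stop("need at least 2 samples to equalize")
  libs <- colSums(counts)
  if (any(libs == 0)) {
    stop("degenerate sample with zero library size: ",
         paste(colnames(counts)[libs == 0], collapse = ", "))
  }
  gm <- exp(mean(log(libs)))
  round(sweep(counts, 2, gm / libs, "*"))
}

# Conditional null distribution of y1 given t = y1 + y2 under NB(t/2, phi)
# in both samples. Uses the NB convolution identity: the normalizer
# sum_k f(k; r, t/2) f(t-k; r, t/2) equals f(t; 2r, t), so P(k | t) is exact
# without numerical normalization. phi = 0 is the Poisson limit, a binomial
# (t, 1/2) split.
cond_null_pmf <- function(t, phi) {
  k <- 0:t
  if (phi <= 0) return(dbinom(k, t, 0.5))
  r <- 1 / phi
  lp <- dnbinom(k, size = r, mu = t / 2, log = TRUE) +
    dnbinom(t - k, size = r, mu = t / 2, log = TRUE) -
    dnbinom(t, size = 2 * r, mu = t, log = TRUE)
  exp(lp)
}

#' Exact negative-binomial test for two counts
#'
#' Conditional on the total `t = y1 + y2`, the null distribution of `y1` puts
#' probability proportional to `f(k) f(t - k)` on each split, where `f` is
#' the NB pmf with mean `t/2` and dispersion `phi`. The two-sided p-value
#' sums the probabilities of all splits at most as likely as the observed
#' one. `phi = 0` uses the Poisson limit (a binomial `(t, 1/2)` split);
#' `t = 0` gives `p = 1` by convention.
#'
#' @param y1,y2 Non-negative integer counts at a common library size.
#' @param phi Common dispersion, `>= 0` (variance `mu + phi mu^2`).
#' @return p-value in `(0, 1]`.
#' @export
nb_exact_test <- function(y1, y2, phi) {
  if (phi < 0) stop("phi must be >= 0")
  t <- y1 + y2
  if (t == 0) return(1)
  pmf <- cond_null_pmf(t, phi)
  p_obs <- pmf[y1 + 1L]
  min(1, sum(pmf[pmf <= p_obs * (1 + 1e-10)]) / sum(pmf))
}

# Vectorized exact tests, grouping genes by total so each conditional pmf is
# computed once.
nb_exact_test_many <- function(y1, y2, phi) {
  t <- y1 + y2
  p <- rep(1, length(t))
  for (tv in unique(t[t > 0])) {
    pmf <- cond_null_pmf(tv, phi)
    tot <- sum(pmf)
    idx <- which(t == tv)
    obs <- pmf[y1[idx] + 1L]
    p[idx] <- vapply(obs, function(po) {
      min(1, sum(pmf[pmf <= po * (1 + 1e-10)]) / tot)
    }, 0)
  }
  p
}

# Summed per-gene log conditional likelihood of the observed splits given
# totals, under a shared dispersion phi. Exact via the convolution identity.
pair_cond_loglik <- function(y1, y2, phi) {
  t <- y1 + y2
  keep <- t > 0
  y1 <- y1[keep]; y2 <- y2[keep]; t <- t[keep]
  if (phi <= 0) return(sum(dbinom(y1, t, 0.5, log = TRUE)))
  r <- 1 / phi
  sum(dnbinom(y1, size = r, mu = t / 2, log = TRUE) +
        dnbinom(y2, size = r, mu = t / 2, log = TRUE) -
        dnbinom(t, size = 2 * r, mu = t, log = TRUE))
}

#' Common dispersion from one consecutive-sample pair
#'
#' Treats the two samples as replicates of one condition and maximizes the
#' summed per-gene log conditional likelihood of each observed split given
#' its total, over `delta = phi / (1 + phi)` in `[0, 1)`. Genes with total 0
#' carry no information and are excluded.
#'
#' @param y_a,y_b Equalized integer count vectors for the two samples.
#' @return Dispersion estimate `phi >= 0`. If fewer than 10 genes have a
#'   positive total the estimate is returned with attribute
#'   `unstable = TRUE` and a warning.
#' @export
estimate_pair_dispersion <- function(y_a, y_b) {
  stopifnot(length(y_a) == length(y_b))
  t <- y_a + y_b
  n_pos <- sum(t > 0)
  unstable <- n_pos < 10L
  if (unstable)
    warning("fewer than 10 genes with positive totals; dispersion estimate unstable")
  if (n_pos == 0L) return(structure(0, unstable = TRUE))
  ll <- function(delta) {
    phi <- delta / (1 - delta)
    pair_cond_loglik(y_a, y_b, phi)
  }
  opt <- optimize(ll, interval = c(1e-8, 0.99), maximum = TRUE, tol = 1e-6)
  # boundary check: no-overdispersion (Poisson) fit can dominate
  if (ll(0) >= opt$objective) {
    phi <- 0
  } else {
    phi <- opt$maximum / (1 - opt$maximum)
  }
  if (unstable) structure(phi, unstable = TRUE) else phi
}

#' Median common dispersion over consecutive time-point pairs
#'
#' Each consecutive pair of samples (in design order) is equalized and its
#' common dispersion estimated; the median of the per-pair values (lower
#' median for an even count) is the single dispersion used for all DE tests.
#'
#' @param counts Numeric matrix (entities x samples), columns in design order.
#' @param design Time-course design (see [timecourse_design()]).
#' @return List of class `dispersion_estimate`: `pair_values` (named by
#'   "a|b" sample pairs) and `common`.
#' @export
common_dispersion <- function(counts, design) {
  validate_design(design)
  ids <- design$sample_id
  if (length(ids) < 3L) stop("need >= 2 consecutive pairs (>= 3 samples)")
  counts <- counts[, ids, drop = FALSE]
  pairs <- cbind(ids[-length(ids)], ids[-1])
  vals <- vapply(seq_len(nrow(pairs)), function(i) {
    eq <- equalize_and_round(counts[, pairs[i, ], drop = FALSE])
    as.numeric(estimate_pair_dispersion(eq[, 1], eq[, 2]))
  }, 0)
  names(vals) <- paste(pairs[, 1], pairs[, 2], sep = "|")
  structure(list(pair_values = vals, common = lower_median(vals)),
            class = "dispersion_estimate")
}

#' @export
print.dispersion_estimate <- function(x, ...) {
  cat("common dispersion (median of", length(x$pair_values),
      "consecutive-pair estimates):", format(x$common, digits = 3), "\n")
  invisible(x)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (delegates to [stats::p.adjust()]).
#'
#' @param p_values Numeric vector of p-values.
#' @return FDR-adjusted values.
#' @export
bh_adjust <- function(p_values) p.adjust(p_values, method = "BH")

#' Call differential expression over an unreplicated time course
#'
#' For each non-control time point, the control and that sample are equalized
#' to a common library size, every gene is tested with the exact NB test at
#' the common dispersion, and BH adjustment is applied within the time point.
#' log2 fold changes use a 0.5 offset on the equalized counts to avoid
#' infinities.
#'
#' @param counts Numeric matrix (entities x samples).
#' @param design Time-course design.
#' @param phi Common dispersion (e.g. `common_dispersion(...)$common`).
#' @param alpha FDR threshold for calling DE (default 0.05).
#' @return `data.frame` of class `de_result` with columns `gene_id`,
#'   `time_label`, `log2_fold_change`, `p_value`, `fdr`, `is_de`,
#'   `direction`; the union-over-time DE set is in `attr(, "de_union")`.
#' @export
call_de_timecourse <- function(counts, design, phi, alpha = 0.05) {
  validate_design(design)
  control <- design$sample_id[design$is_control]
  others <- design[!design$is_control, , drop = FALSE]
  out <- vector("list", nrow(others))
  for (i in seq_len(nrow(others))) {
    s <- others$sample_id[i]
    eq <- equalize_and_round(counts[, c(control, s), drop = FALSE])
    y0 <- eq[, 1]; yt <- eq[, 2]
    p <- nb_exact_test_many(y0, yt, phi)
    fdr <- bh_adjust(p)
    lfc <- log2((yt + 0.5) / (y0 + 0.5))
    out[[i]] <- data.frame(gene_id = rownames(counts),
                           time_label = others$time_label[i],
                           log2_fold_change = lfc,
                           p_value = p, fdr = fdr,
                           is_de = fdr < alpha,
                           direction = ifelse(lfc >= 0, "up", "down"),
                           stringsAsFactors = FALSE, row.names = NULL)
  }
  res <- do.call(rbind, out)
  attr(res, "de_union") <- sort(unique(res$gene_id[res$is_de]))
  attr(res, "alpha") <- alpha
  class(res) <- c("de_result", class(res))
  res
}

#' Union-over-time DE set
#' @param de A `de_result`.
#' @return Character vector of entities called DE at any time point.
#' @export
de_union <- function(de) {
  u <- attr(de, "de_union")
  if (is.null(u)) sort(unique(de$gene_id[de$is_de])) else u
}

#' Compare gene-level and contig-level DE calls
#'
#' A contig-level "DE gene" is any gene with at least one DE contig (mapped
#' through `map`). Reports the intersection and set differences of the two
#' union-over-time DE gene sets, plus counts of members of an optional
#' reference gene list (e.g. limb-development genes) in each unique set,
#' ready for a Fisher comparison.
#'
#' @param gene_results `de_result` from the gene-level path.
#' @param contig_results `de_result` from the contig-level path.
#' @param map `contig_gene_map` used to lift contigs to genes.
#' @param reference_genes Optional character vector.
#' @return List: `shared`, `gene_only`, `contig_only` (character vectors),
#'   `n_shared`, `n_gene_only`, `n_contig_only`, and when a reference list is
#'   given, `ref_gene_only`, `ref_contig_only` counts and the 2x2
#'   `comparison_table` (unique-set reference membership).
#' @export
compare_de_levels <- function(gene_results, contig_results, map,
                              reference_genes = NULL) {
  g_set <- de_union(gene_results)
  de_contigs <- de_union(contig_results)
  c_set <- sort(unique(map$entries$gene_id[map$entries$contig_id %in% de_contigs]))
  shared <- intersect(g_set, c_set)
  g_only <- setdiff(g_set, c_set)
  c_only <- setdiff(c_set, g_set)
  out <- list(shared = shared, gene_only = g_only, contig_only = c_only,
              n_shared = length(shared), n_gene_only = length(g_only),
              n_contig_only = length(c_only))
  if (!is.null(reference_genes)) {
    k_g <- sum(g_only %in% reference_genes)
    k_c <- sum(c_only %in% reference_genes)
    out$ref_gene_only <- k_g
    out$ref_contig_only <- k_c
    out$comparison_table <- matrix(
      c(k_c, length(c_only) - k_c, k_g, length(g_only) - k_g),
      nrow = 2, byrow = TRUE,
      dimnames = list(c("contig_only", "gene_only"), c("in_ref", "not_in_ref")))
  }
  out
}
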