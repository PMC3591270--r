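#' RNA-seq log2 expression ratio vs the control
#'
#' `log2((tpm_x + 1) / (tpm_0 + 1))`; the added 1 guards against division by
#' zero, log(0), and inflated ratios when both TPMs are small.
#'
#' @param tpm_x,tpm_0 Non-negative TPM values (time point x, control).
#' @return log2 ratio(s).
#' @export
rnaseq_log2_ratio <- function(tpm_x, tpm_0) {
  stopifnot(all(tpm_x >= 0), all(tpm_0 >= 0))
  log2((tpm_x + 1) / (tpm_0 + 1))
}

#' qPCR log2 expression ratio vs the control
#'
#' Two conventions. `"methods_ratio"`: `log2(dct_x / dct_0)` on the raw
#' delta-CT values, with any delta-CT of exactly 0 replaced by 0.1 before
#' division. `"ddct"`: the standard comparative-CT fold-change exponent,
#' `-(dct_x - dct_0)`. The ratio-of-delta-CT convention is the default; both
#' are kept because the two are in common use and differ numerically (they
#' agree only in direction for monotone delta-CT changes).
#'
#' @param dct_x,dct_0 Delta-CT (target CT minus reference-gene CT) at time
#'   point x and at the control.
#' @param convention `"methods_ratio"` or `"ddct"`.
#' @return log2 ratio(s).
#' @export
qpcr_log2_ratio <- function(dct_x, dct_0,
                            convention = c("methods_ratio", "ddct")) {
  convention <- match.arg(convention)
  if (convention == "ddct") return(-(dct_x - dct_0))
  dct_x <- ifelse(dct_x == 0, 0.1, dct_x)
  dct_0 <- ifelse(dct_0 == 0, 0.1, dct_0)
  log2(dct_x / dct_0)
}

#' Delta-CT per gene and sample from a CT table
#'
#' Averages replicate CT values (mean per gene/sample, computed before the
#' subtraction), then takes `ct_target - ct_reference`. Undetected samples
#' are expected to carry CT = 40 exactly (the undetected convention) and are
#' flagged.
#'
#' @param ct Long-format `data.frame` with columns `gene_id`, `sample_id`,
#'   `ct_target`, `ct_reference` (replicate rows allowed).
#' @return `data.frame`: `gene_id`, `sample_id`, `dct`, `undetected`.
#' @export
delta_ct <- function(ct) {
  key <- paste(ct$gene_id, ct$sample_id, sep = "\r")
  tgt <- tapply(ct$ct_target, key, mean)
  ref <- tapply(ct$ct_reference, key, mean)
  undet <- tapply(ct$ct_target == 40, key, any)
  parts <- do.call(rbind, strsplit(names(tgt), "\r", fixed = TRUE))
  data.frame(gene_id = parts[, 1], sample_id = parts[, 2],
             dct = as.numeric(tgt - ref), undetected = as.logical(undet),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Shift-left alignment of RNA-seq and qPCR time series
#'
#' qPCR animals lag the RNA-seq animals late in the course, so for
#' correlation the day-3 qPCR point is dropped and the remaining late qPCR
#' points are shifted one slot earlier: time points up to day 1 pair
#' label-to-label, then RNA-seq days 3-21 pair with qPCR days 5-28. The
#' control is excluded. With `shift = FALSE` pairing is straight
#' label-to-label over all non-control points.
#'
#' @param rnaseq Named numeric vector of RNA-seq log2 ratios, names = time
#'   labels (canonical 12-point labels, control excluded or present).
#' @param qpcr Named numeric vector of qPCR log2 ratios, same label scheme.
#' @param shift Apply the shift-left alignment (default `TRUE`).
#' @return `data.frame`: `time_rnaseq`, `time_qpcr`, `rnaseq`, `qpcr`.
#' @export
shift_left_align <- function(rnaseq, qpcr, shift = TRUE) {
  labels <- tc_time_labels()
  non_ctrl <- labels[-1]
  if (shift) {
    early <- c("3h", "6h", "12h", "1d")
    late_rna <- c("3d", "5d", "7d", "10d", "14d", "21d")
    late_qpcr <- c("5d", "7d", "10d", "14d", "21d", "28d")
    rna_lab <- c(early, late_rna)
    qp_lab <- c(early, late_qpcr)
  } else {
    rna_lab <- qp_lab <- non_ctrl
  }
  missing_r <- setdiff(rna_lab, names(rnaseq))
  missing_q <- setdiff(qp_lab, names(qpcr))
  if (length(missing_r) || length(missing_q))
    stop("missing required time labels: ",
         paste(unique(c(missing_r, missing_q)), collapse = ", "))
  data.frame(time_rnaseq = rna_lab, time_qpcr = qp_lab,
             rnaseq = as.numeric(rnaseq[rna_lab]),
             qpcr = as.numeric(qpcr[qp_lab]),
             stringsAsFactors = FALSE)
}

#' Pearson concordance of paired expression series
#'
#' @param pairs `data.frame` from [shift_left_align()] (or any frame with
#'   `rnaseq` and `qpcr` columns), `>= 3` rows.
#' @return List: `r`, `r_squared`, `n`, `defined` (`FALSE` when either
#'   vector has zero variance).
#' @export
concordance <- function(pairs) {
  if (nrow(pairs) < 3L) stop("need at least 3 pairs")
  if (sd(pairs$rnaseq) == 0 || sd(pairs$qpcr) == 0)
    return(list(r = NA_real_, r_squared = NA_real_, n = nrow(pairs),
                defined = FALSE))
  r <- cor(pairs$rnaseq, pairs$qpcr)
  list(r = r, r_squared = r^2, n = nrow(pairs), defined = TRUE)
}

#' qPCR vs RNA-seq concordance report
#'
#' Computes per-gene RNA-seq log2 TPM ratios and qPCR log2 ratios vs the
#' control, aligns them (optionally shift-left), and reports per-gene and
#' average Pearson correlation.
#'
#' @param tpm Gene-level TPM matrix (genes x samples).
#' @param ct CT table (see [delta_ct()]); sample ids must match the design.
#' @param design Time-course design.
#' @param convention qPCR ratio convention (see [qpcr_log2_ratio()]).
#' @param shift Apply shift-left alignment.
#' @return List: `per_gene` (`data.frame` with `gene_id`, `r`, `r_squared`),
#'   `mean_r`, `mean_r_squared`.
#' @export
qpcr_concordance <- function(tpm, ct, design,
                             convention = "methods_ratio", shift = TRUE) {
  validate_design(design)
  dct <- delta_ct(ct)
  control <- design$sample_id[design$is_control]
  lab_of <- setNames(design$time_label, design$sample_id)
  genes <- intersect(rownames(tpm), unique(dct$gene_id))
  per <- lapply(genes, function(g) {
    rna <- rnaseq_log2_ratio(tpm[g, design$sample_id], tpm[g, control])
    names(rna) <- design$time_label
    d <- dct[dct$gene_id == g, ]
    d0 <- d$dct[d$sample_id == control]
    qp <- qpcr_log2_ratio(d$dct, d0, convention)
    names(qp) <- lab_of[d$sample_id]
    cc <- concordance(shift_left_align(rna, qp, shift = shift))
    data.frame(gene_id = g, r = cc$r, r_squared = cc$r_squared,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  list(per_gene = per,
       mean_r = mean(per$r, na.rm = TRUE),
       mean_r_squared = mean(per$r_squared, na.rm = TRUE))
}
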