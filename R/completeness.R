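#' Partition reads into high-quality aligned and unaligned sets
#'
#' Selects very high quality reads (mean phred score at or above the
#' threshold; only the highest-quality reads are used so that alignability
#' is not confounded with read quality) and partitions them by alignment
#' status. The unaligned fraction is computed over ALL reads, not only the
#' high-quality ones.
#'
#' @param provenance `data.frame` with per-read columns `aligned` (logical)
#'   and `mean_quality` (numeric); optionally `blastx_hit` (logical) and
#'   `protein_id`.
#' @param hq_threshold Mean phred threshold (default 38).
#' @return List: `al_hq` and `un_hq` (row indices), `p_un` (fraction of all
#'   reads unaligned), `n_reads`.
#' @export
partition_hq_reads <- function(provenance, hq_threshold = 38) {
  hq <- provenance$mean_quality >= hq_threshold
  list(al_hq = which(hq & provenance$aligned),
       un_hq = which(hq & !provenance$aligned),
       p_un = mean(!provenance$aligned),
       n_reads = nrow(provenance))
}

#' Fraction of unaligned reads truly from the assembled organism
#'
#' Under the assumptions that (i) reads not from the organism never have a
#' protein-search hit, (ii) aligned reads are all from the organism, and
#' (iii) having a hit is independent of alignment status given that a read is
#' truly from the organism and high-quality, the fraction of unaligned reads
#' that are truly from the organism is the ratio of the hit rates:
#' `P(A | UN) = P(B | UN, HQ) / P(B | AL, HQ)`. False-positive hits among
#' non-organism reads inflate the numerator, so the estimate is conservative
#' (an over-estimate of the unalignable organism fraction).
#'
#' @param p_b_given_un_hq Hit rate among unaligned high-quality reads.
#' @param p_b_given_al_hq Hit rate among aligned high-quality reads; must be
#'   positive.
#' @return Probability, clipped to `[0, 1]` (with a warning if clipped).
#' @export
estimate_unaligned_true_fraction <- function(p_b_given_un_hq, p_b_given_al_hq) {
  if (p_b_given_al_hq <= 0)
    stop("undefined estimate: no hits among aligned high-quality reads")
  r <- p_b_given_un_hq / p_b_given_al_hq
  if (r > 1) {
    warning("hit-rate ratio above 1 (sampling noise); clipped to 1")
    r <- 1
  }
  r
}

#' Fraction of all reads that are from the organism but unalignable
#'
#' The product of the unaligned fraction of all reads and the estimated
#' truly-from-organism fraction among unaligned reads.
#'
#' @param p_un Fraction of all reads unaligned.
#' @param p_a_given_un Estimated organism fraction among unaligned reads.
#' @return Probability.
#' @export
estimate_overall_unalignable <- function(p_un, p_a_given_un) {
  stopifnot(p_un >= 0, p_un <= 1, p_a_given_un >= 0, p_a_given_un <= 1)
  p_un * p_a_given_un
}

#' Anchor-proteome representation of the assembly
#'
#' Fraction of the anchor proteins hit by either aligned or unaligned reads
#' that are hit by the aligned reads: `|AL| / |AL U UN|`.
#'
#' @param proteins_hit_al,proteins_hit_un Character vectors of protein ids.
#' @return Probability.
#' @export
protein_representation <- function(proteins_hit_al, proteins_hit_un) {
  al <- unique(proteins_hit_al)
  un <- unique(proteins_hit_un)
  denom <- length(union(al, un))
  if (denom == 0L) stop("undefined estimate: no proteins hit by either set")
  length(al) / denom
}

#' Full completeness report
#'
#' Runs the whole estimator either from a per-read provenance table or from
#' pre-computed summary fractions, reporting probabilities and their
#' whole-percent presentation (truncated toward zero).
#'
#' @param provenance Optional per-read table (see [partition_hq_reads()]).
#' @param summary Optional list with `p_b_al`, `p_b_un`, `p_un`.
#' @param hq_threshold Mean phred threshold when a table is given.
#' @return List with `p_b_given_al_hq`, `p_b_given_un_hq`, `p_un`,
#'   `p_a_given_un`, `p_unalignable_organism`, optional
#'   `protein_representation`, and `percent` (whole-percent versions).
#' @export
completeness_report <- function(provenance = NULL, summary = NULL,
                                hq_threshold = 38) {
  if (is.null(provenance) == is.null(summary))
    stop("give exactly one of provenance or summary")
  if (!is.null(provenance)) {
    part <- partition_hq_reads(provenance, hq_threshold)
    if (length(part$al_hq) == 0L || length(part$un_hq) == 0L)
      stop("no high-quality reads in one of the partitions; cannot estimate")
    p_b_al <- mean(provenance$blastx_hit[part$al_hq])
    p_b_un <- mean(provenance$blastx_hit[part$un_hq])
    p_un <- part$p_un
    prot <- NULL
    if (!is.null(provenance$protein_id)) {
      pa <- provenance$protein_id[part$al_hq][provenance$blastx_hit[part$al_hq]]
      pu <- provenance$protein_id[part$un_hq][provenance$blastx_hit[part$un_hq]]
      pa <- pa[!is.na(pa)]; pu <- pu[!is.na(pu)]
      if (length(pa) + length(pu) > 0) prot <- protein_representation(pa, pu)
    }
  } else {
    p_b_al <- summary$p_b_al
    p_b_un <- summary$p_b_un
    p_un <- summary$p_un
    prot <- NULL
  }
  p_a_un <- estimate_unaligned_true_fraction(p_b_un, p_b_al)
  p_unal <- estimate_overall_unalignable(p_un, p_a_un)
  out <- list(p_b_given_al_hq = p_b_al, p_b_given_un_hq = p_b_un, p_un = p_un,
              p_a_given_un = p_a_un, p_unalignable_organism = p_unal,
              protein_representation = prot)
  out$percent <- list(p_a_given_un = pct_whole(p_a_un),
                      p_unalignable_organism = pct_whole(p_unal),
                      protein_representation = if (!is.null(prot)) pct_whole(prot))
  out
}
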