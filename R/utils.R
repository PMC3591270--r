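#' Canonical blastemal time-course labels
#'
#' The twelve time points of the regeneration time course, in chronological
#' order, with the zero-hour control first: 0h, 3h, 6h, 12h, then 1, 3, 5, 7,
#' 10, 14, 21 and 28 days post amputation.
#'
#' @return Character vector of length 12.
#' @export
tc_time_labels <- function() {
  c("0h", "3h", "6h", "12h", "1d", "3d", "5d", "7d", "10d", "14d", "21d", "28d")
}

#' Build a time-course design table
#'
#' @param sample_ids Ordered sample identifiers.
#' @param time_labels Time label per sample, chronological; defaults to
#'   [tc_time_labels()] when there are twelve samples.
#' @param control_id Identifier of the control sample; must be the first.
#' @return A `data.frame` with columns `sample_id`, `time_label`, `is_control`.
#' @export
timecourse_design <- function(sample_ids,
                              time_labels = NULL,
                              control_id = sample_ids[1]) {
  if (is.null(time_labels)) {
    if (length(sample_ids) != 12L)
      stop("time_labels must be given unless there are exactly 12 samples")
    time_labels <- tc_time_labels()
  }
  if (length(sample_ids) != length(time_labels))
    stop("sample_ids and time_labels differ in length")
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  if (!control_id %in% sample_ids) stop("control_id not among sample_ids")
  if (match(control_id, sample_ids) != 1L)
    stop("the control sample must be the first (earliest) sample")
  data.frame(sample_id = as.character(sample_ids),
             time_label = as.character(time_labels),
             is_control = sample_ids == control_id,
             stringsAsFactors = FALSE)
}

validate_design <- function(design) {
  need <- c("sample_id", "time_label", "is_control")
  if (!all(need %in% names(design)))
    stop("design must have columns sample_id, time_label, is_control")
  if (sum(design$is_control) != 1L)
    stop("design must designate exactly one control sample")
  if (!design$is_control[1L])
    stop("the control sample must be first in the design")
  invisible(design)
}

#' Whole-percent presentation of a probability
#'
#' Truncates toward zero after scaling to percent (0.2353 -> 23,
#' 0.1127 -> 11), the presentation used by the completeness report.
#'
#' @param x Probability (or vector of probabilities).
#' @return Integer percent value(s).
#' @export
whole_percent <- function(x) trunc(x * 100 + 1e-9)

pct_whole <- whole_percent

# Evaluate code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Lower median: for an even number of values take the smaller of the two
# central order statistics; deterministic, no interpolation.
lower_median <- function(x) {
  x <- sort(x)
  x[ceiling(length(x) / 2)]
}
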