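#' Uncentered Pearson distance
#'
#' `d = 1 - sum(x*y) / sqrt(sum(x^2) * sum(y^2))`, in `[0, 2]`. The
#' uncentered (cosine-like) form suits log fold-change profiles, which are
#' expected to be centered at zero; the centered Pearson variant
#' (`1 - cor(x, y)`) is provided for all-non-negative matrices such as
#' `-log10(FDR)` term-enrichment profiles.
#'
#' @param x,y Numeric vectors of equal length `>= 2`.
#' @return Distance in `[0, 2]`.
#' @export
uncentered_pearson_distance <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L)
    stop("vectors must have equal length >= 2")
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0)
    stop("undefined distance: zero-norm vector")
  1 - sum(x * y) / (nx * ny)
}

# Pairwise distance over the COLUMNS of a matrix.
column_dist <- function(mat, distance = c("uncentered", "pearson")) {
  distance <- match.arg(distance)
  if (distance == "uncentered") {
    nrm <- sqrt(colSums(mat^2))
    if (any(nrm == 0)) stop("undefined distance: zero-norm column")
    cc <- crossprod(mat) / tcrossprod(nrm)
  } else {
    sds <- apply(mat, 2, sd)
    if (any(sds == 0)) stop("undefined distance: zero-variance column")
    cc <- cor(mat)
  }
  d <- 1 - cc
  d[d < 0] <- 0
  as.dist(d)
}

#' Average-linkage hierarchical clustering of samples
#'
#' UPGMA agglomeration of the matrix columns under the chosen correlation
#' distance. Rows are features (e.g. DE genes, log2 fold changes vs control),
#' columns are the samples being clustered.
#'
#' @param mat Numeric matrix, features x samples, `>= 2` columns.
#' @param distance `"uncentered"` (uncentered Pearson) or `"pearson"`.
#' @return An object of class `hclust`.
#' @export
average_linkage <- function(mat, distance = c("uncentered", "pearson")) {
  if (ncol(mat) < 2L) stop("need at least 2 columns to cluster")
  hclust(column_dist(mat, distance), method = "average")
}

# Leaf-label sets of all internal nodes of an hclust tree, each as a sorted,
# collapsed string key.
tree_clades <- function(hc) {
  labs <- hc$labels
  n <- length(labs)
  sets <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    get <- function(j) if (j < 0) labs[-j] else sets[[j]]
    sets[[i]] <- c(get(hc$merge[i, 1]), get(hc$merge[i, 2]))
  }
  vapply(sets, function(s) paste(sort(s), collapse = "\r"), "")
}

#' Bootstrap edge support (BP and multiscale AU)
#'
#' Resamples the feature rows and re-clusters the samples. BP for an edge of
#' the full-data tree is the fraction of ordinary (scale 1) bootstrap trees
#' containing the edge's leaf set. For the approximately unbiased (AU) value,
#' resampling is repeated at several relative data sizes `r` (default ten
#' sizes spanning 0.6 to 1.4 of the feature count); the per-scale proportions
#' `bp_r` are mapped through the probit, `z_r = qnorm(1 - bp_r)`, and fitted
#' by weighted least squares to `z = v*sqrt(r) + c/sqrt(r)` (weights from the
#' binomial variance of `bp_r` propagated through the probit), giving
#' `AU = 1 - pnorm(v - c)`. Proportions are clipped away from 0 and 1 before
#' the probit; an edge absent or present in every resample at every scale is
#' assigned AU 0 or 1 directly and flagged (`fit = FALSE`).
#'
#' @param mat Numeric matrix, features (resampled) x samples (clustered).
#' @param n_boot Total bootstrap budget; each scale, and the ordinary run,
#'   uses `n_boot / length(scales)` resamples.
#' @param scales Relative resample sizes.
#' @param seed Integer seed; results are reproducible under a fixed seed.
#' @param distance Distance kind, as in [average_linkage()].
#' @return `data.frame` of class `edge_support`: per edge `edge`, `members`,
#'   `bp`, `au`, `v`, `c`, `fit`; per-scale proportions in
#'   `attr(, "bp_scales")`, the full-data tree in `attr(, "tree")`.
#' @export
bootstrap_support <- function(mat, n_boot = 10000,
                              scales = seq(0.6, 1.4, length.out = 10),
                              seed = 1, distance = "uncentered") {
  hc <- average_linkage(mat, distance)
  clades <- tree_clades(hc)
  n_feat <- nrow(mat)
  per_scale <- max(1L, round(n_boot / length(scales)))

  count_edges <- function(size, B) {
    hits <- integer(length(clades))
    ok <- 0L
    for (b in seq_len(B)) {
      idx <- sample.int(n_feat, size, replace = TRUE)
      bt <- tryCatch(average_linkage(mat[idx, , drop = FALSE], distance),
                     error = function(e) NULL)
      if (is.null(bt)) next   # e.g. zero-norm column in a degenerate resample
      ok <- ok + 1L
      hits <- hits + (clades %in% tree_clades(bt))
    }
    c(hits, ok)
  }

  with_seed(seed, {
    # ordinary bootstrap at scale 1 for BP
    ord <- count_edges(n_feat, per_scale)
    bp <- ord[seq_along(clades)] / max(1L, ord[length(ord)])
    # multiscale runs
    sizes <- pmax(2L, round(scales * n_feat))
    bp_r <- matrix(NA_real_, length(clades), length(scales),
                   dimnames = list(NULL, paste0("r", signif(scales, 3))))
    n_r <- integer(length(scales))
    for (j in seq_along(scales)) {
      res <- count_edges(sizes[j], per_scale)
      n_r[j] <- res[length(res)]
      bp_r[, j] <- res[seq_along(clades)] / max(1L, n_r[j])
    }
    au <- v_coef <- c_coef <- rep(NA_real_, length(clades))
    fitted <- rep(FALSE, length(clades))
    r_rel <- sizes / n_feat
    for (i in seq_along(clades)) {
      props <- bp_r[i, ]
      if (all(props == 1)) { au[i] <- 1; next }
      if (all(props == 0)) { au[i] <- 0; next }
      eps <- 1 / (per_scale + 1)
      pc <- pmin(pmax(props, eps), 1 - eps)
      z <- qnorm(1 - pc)
      w <- n_r * dnorm(z)^2 / (pc * (1 - pc))
      X <- cbind(sqrt(r_rel), 1 / sqrt(r_rel))
      fit <- tryCatch(stats::lm.wfit(X, z, w), error = function(e) NULL)
      if (is.null(fit) || anyNA(fit$coefficients)) { au[i] <- bp[i]; next }
      v_coef[i] <- fit$coefficients[1]
      c_coef[i] <- fit$coefficients[2]
      au[i] <- 1 - pnorm(v_coef[i] - c_coef[i])
      fitted[i] <- TRUE
    }
    members <- gsub("\r", ",", clades, fixed = TRUE)
    out <- data.frame(edge = seq_along(clades), members = members,
                      bp = bp, au = au, v = v_coef, c = c_coef, fit = fitted,
                      stringsAsFactors = FALSE)
    attr(out, "bp_scales") <- bp_r
    attr(out, "scales") <- r_rel
    attr(out, "tree") <- hc
    class(out) <- c("edge_support", class(out))
    out
  })
}

#' Write a support-annotated Newick tree
#'
#' Exports the full-data tree with internal-node labels `"au-bp"` (rounded
#' to two decimals; a dash separates the two supports because the colon is
#' reserved syntax in Newick).
#'
#' @param support An `edge_support` result.
#' @param path File path.
#' @export
write_support_newick <- function(support, path) {
  hc <- attr(support, "tree")
  phy <- ape::as.phylo(hc)
  # ape orders internal nodes root-first; map clades by membership
  clade_key <- function(phy, node) {
    tips <- ape::extract.clade(phy, node)$tip.label
    paste(sort(tips), collapse = ",")
  }
  n_tip <- length(phy$tip.label)
  keys <- vapply((n_tip + 1):(n_tip + phy$Nnode), function(nd) clade_key(phy, nd), "")
  lab <- rep("", phy$Nnode)
  m <- match(keys, support$members)
  ok <- !is.na(m)
  lab[ok] <- sprintf("%.2f-%.2f", support$au[m[ok]], support$bp[m[ok]])
  phy$node.label <- lab
  ape::write.tree(phy, file = path)
  invisible(path)
}
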