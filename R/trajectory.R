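.log_profiles <- function(counts) log2(1 + counts)

#' Cluster cells by k-medoids on correlation distance
#'
#' Partitions cells with PAM-style k-medoids (greedy swap to a local optimum)
#' on the distance `1 - Pearson correlation` of `log2(1 + count)` profiles —
#' the documented stand-in for published rare-cell-type clusterers whose
#' partition is all the downstream pipeline needs.  If `k` is `NULL` it is
#' chosen by average silhouette width over `k = 2..10`.
#'
#' @param counts Integer genes x cells matrix at uniform depth.
#' @param k Number of clusters, or `NULL` for silhouette selection.
#' @param seed Integer seed (the algorithm itself is deterministic; the seed
#'   is consumed for interface uniformity).
#' @return An `iahc_clusters` list: `cluster` (named integer 1..k), `medoids`
#'   (cell identifiers), `k`, `metric`.
#' @export
cluster_cells <- function(counts, k = NULL, seed = 1L) {
  n <- ncol(counts)
  if (!is.null(k) && k > n) stop("k must not exceed the number of cells")
  set.seed(as.integer(seed))
  d <- stats::as.dist(1 - stats::cor(.log_profiles(counts)))
  if (is.null(k)) {
    ks <- 2:min(10, n - 1)
    sil <- vapply(ks, function(kk) {
      fit <- cluster::pam(d, kk, diss = TRUE)
      fit$silinfo$avg.width
    }, numeric(1))
    k <- ks[which.max(sil)]
  }
  if (k == 1) {
    dm <- as.matrix(d)
    med <- colnames(counts)[which.min(rowSums(dm))]
    assign <- stats::setNames(rep(1L, n), colnames(counts))
  } else {
    fit <- cluster::pam(d, k, diss = TRUE)
    assign <- stats::setNames(as.integer(fit$clustering), colnames(counts))
    med <- fit$medoids
  }
  structure(list(cluster = assign, medoids = med, k = as.integer(k),
                 metric = "1 - Pearson(log2(1 + x))"),
            class = "iahc_clusters")
}

#' @export
print.iahc_clusters <- function(x, ...) {
  cat("k-medoids partition of", length(x$cluster), "cells into", x$k,
      "clusters (", x$metric, ")\n")
  print(table(cluster = x$cluster))
  invisible(x)
}

#' Order cells along a one-dimensional developmental axis
#'
#' Projects cells to two principal components of `log2(1 + count)` profiles
#' restricted to `gene_subset`, builds a minimum spanning tree over the cells
#' in that plane, and takes graph distance along the tree's diameter path as
#' pseudotime; off-path cells are projected to their nearest path node.
#' Values are min-max scaled to `[0, 30]` and oriented so the endpoint with
#' higher mean anchor-marker (endothelial) expression is time 0.  Ties are
#' broken by cell identifier.
#'
#' @param counts Integer genes x cells matrix (>= 3 cells).
#' @param gene_subset Genes used for the embedding; defaults to
#'   [filter_genes_min_expression()] of `counts`.
#' @param anchor_markers Genes anchoring time 0 (default endothelial panel).
#' @param seed Integer seed (consumed for interface uniformity; the
#'   construction is deterministic).
#' @return An `iahc_pseudotime` list: `pt` (named values in `[0, 30]`),
#'   `order` (cell identifiers sorted by pseudotime), `pc` (scores), `genes`.
#' @export
order_cells <- function(counts, gene_subset = NULL,
                        anchor_markers = marker_panels()$endothelial,
                        seed = 1L) {
  if (ncol(counts) < 3) stop("at least 3 cells are required")
  if (is.null(gene_subset)) gene_subset <- filter_genes_min_expression(counts)
  gene_subset <- intersect(gene_subset, rownames(counts))
  if (length(gene_subset) == 0) stop("gene_subset is empty")
  sub <- counts[gene_subset, , drop = FALSE]
  if (all(sub == 0)) stop("gene_subset has all-zero expression")
  set.seed(as.integer(seed))
  x <- t(.log_profiles(sub))
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = 2)$x
  if (ncol(pc) < 2) pc <- cbind(pc, 0)

  dm <- as.matrix(stats::dist(pc))
  g <- igraph::graph_from_adjacency_matrix(dm, mode = "undirected",
                                           weighted = TRUE)
  tree <- igraph::mst(g)
  path <- igraph::get_diameter(tree)
  path_ids <- names(path)
  # cumulative weighted position of each path node
  ew <- igraph::E(tree, path = path)$weight
  pos <- c(0, cumsum(ew))
  names(pos) <- path_ids
  # project every cell to its nearest path node (tree graph distance)
  dpath <- igraph::distances(tree, v = igraph::V(tree), to = path)
  nearest <- apply(dpath, 1, which.min)
  pt <- pos[nearest]
  names(pt) <- rownames(dm)

  rng <- range(pt)
  pt <- if (rng[2] > rng[1]) (pt - rng[1]) / (rng[2] - rng[1]) * 30 else pt * 0
  # orientation: anchor (endothelial) expression must be highest at time 0
  anchors <- intersect(anchor_markers, rownames(counts))
  if (length(anchors) == 0) stop("no anchor markers present in the matrix")
  a <- colMeans(.log_profiles(counts[anchors, , drop = FALSE]))
  cc <- suppressWarnings(stats::cor(pt, a[names(pt)]))
  if (!is.na(cc) && cc > 0) pt <- 30 - pt

  ord <- names(pt)[order(pt, names(pt))]
  structure(list(pt = pt, order = ord, pc = pc, genes = gene_subset),
            class = "iahc_pseudotime")
}

#' @export
print.iahc_pseudotime <- function(x, ...) {
  cat("Pseudotime over", length(x$pt), "cells on [0, 30] (",
      length(x$genes), "genes in embedding )\n")
  print(summary(x$pt))
  invisible(x)
}

#' @export
plot.iahc_pseudotime <- function(x, ...) {
  graphics::plot(x$pc[, 1], x$pc[, 2], col = grDevices::hcl.colors(
    100, "viridis")[cut(x$pt[rownames(x$pc)], 100, labels = FALSE)],
    pch = 16, xlab = "PC1", ylab = "PC2",
    main = "Cells coloured by pseudotime", ...)
  invisible(x)
}

#' Summarize a per-cell quantity along pseudotime
#'
#' For a categorical vector (population labels) returns per-bin proportions
#' (each bin sums to 1; empty bins are emitted with total 0 and flagged).  For
#' a numeric vector (gene expression, index-sort fluorescence) returns a
#' sliding-window mean over cells ordered by pseudotime, which preserves
#' monotonicity of monotone inputs.
#'
#' @param values Named per-cell vector (names = cell identifiers) or unnamed
#'   vector aligned to `names(pt$pt)`.
#' @param pt An `iahc_pseudotime`.
#' @param bins Number of equal-width pseudotime bins (categorical summaries;
#'   default 10).
#' @param window_cells Odd window size for the rolling mean (numeric
#'   summaries; default `max(5, ~10%` of cells`)` made odd).
#' @return A data.frame: either `(bin_center, level, proportion, n)` or
#'   `(cell, pseudotime, value)`.
#' @export
summarize_along_pseudotime <- function(values, pt, bins = 10,
                                       window_cells = NULL) {
  cells <- names(pt$pt)
  if (is.null(names(values))) {
    stopifnot(length(values) == length(cells))
    names(values) <- cells
  }
  values <- values[cells]
  if (is.character(values) || is.factor(values)) {
    values <- factor(values)
    edges <- seq(0, 30, length.out = bins + 1)
    bin <- cut(pt$pt, edges, include.lowest = TRUE, labels = FALSE)
    out <- do.call(rbind, lapply(seq_len(bins), function(b) {
      inb <- values[bin == b]
      n <- length(inb)
      prop <- if (n > 0) as.numeric(table(inb) / n) else
        rep(0, nlevels(values))
      data.frame(bin_center = (edges[b] + edges[b + 1]) / 2,
                 level = levels(values), proportion = prop, n = n,
                 stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    return(out)
  }
  n <- length(cells)
  if (is.null(window_cells)) {
    window_cells <- max(5L, round(0.1 * n))
    if (window_cells %% 2 == 0) window_cells <- window_cells + 1L
  }
  ord <- pt$order
  v <- values[ord]
  sm <- .rolling_mean(v, window_cells)
  data.frame(cell = ord, pseudotime = pt$pt[ord], value = sm,
             stringsAsFactors = FALSE)
}

# truncated-window rolling mean over an ordered vector
.rolling_mean <- function(v, w) {
  n <- length(v)
  h <- (w - 1) %/% 2
  cs <- c(0, cumsum(v))
  lo <- pmax(1L, seq_len(n) - h)
  hi <- pmin(n, seq_len(n) + h)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
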