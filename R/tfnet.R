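#' Smooth expression profiles along pseudotime
#'
#' Sorts cells by pseudotime (ties broken by cell identifier) and replaces
#' each cell's value by the mean over the `window_cells` nearest cells in rank
#' order, truncating the window at the ends.  This is the drop-out rescue
#' applied before transcription-factor selection and clustering: a contraction
#' that leaves constant genes untouched and keeps every smoothed value inside
#' the per-gene input range.
#'
#' @param counts Numeric genes x cells matrix.
#' @param pt An `iahc_pseudotime` covering the cells.
#' @param window_cells Odd window size, `<=` number of cells; default
#'   `max(5, ~10%` of cells`)` made odd.
#' @return Numeric matrix, same dimensions and cell order as `counts`.
#' @export
smooth_profiles <- function(counts, pt, window_cells = NULL) {
  n <- ncol(counts)
  if (is.null(window_cells)) {
    window_cells <- max(5L, round(0.1 * n))
    if (window_cells %% 2 == 0) window_cells <- window_cells + 1L
  }
  if (window_cells > n) stop("window_cells must not exceed the number of cells")
  if (window_cells %% 2 == 0) stop("window_cells must be odd")
  ptv <- pt$pt[colnames(counts)]
  if (anyNA(ptv)) stop("all cells need a pseudotime value")
  ord <- order(ptv, colnames(counts))
  m <- counts[, ord, drop = FALSE]
  h <- (window_cells - 1) %/% 2
  cs <- cbind(0, t(apply(m, 1, cumsum)))
  lo <- pmax(1L, seq_len(n) - h)
  hi <- pmin(n, seq_len(n) + h)
  sm <- (cs[, hi + 1L, drop = FALSE] - cs[, lo, drop = FALSE]) /
    rep(hi - lo + 1L, each = nrow(m))
  dimnames(sm) <- dimnames(m)
  sm[, colnames(counts), drop = FALSE]
}

#' Select expressed transcription factors
#'
#' Keeps the TFs from `tf_list` present in the matrix whose maximum smoothed
#' value reaches at least one transcript (the inclusion rule applied after
#' smoothing along pseudotime).
#'
#' @param smoothed Smoothed genes x cells matrix from [smooth_profiles()].
#' @param tf_list Candidate TF gene identifiers.
#' @return Character vector of retained TFs (input order).
#' @export
select_tfs <- function(smoothed, tf_list) {
  if (length(tf_list) == 0) stop("tf_list must be non-empty")
  absent <- setdiff(tf_list, rownames(smoothed))
  if (length(absent) > 0) {
    warning(length(absent), " TF(s) absent from the matrix, skipped")
  }
  present <- intersect(tf_list, rownames(smoothed))
  mx <- apply(smoothed[present, , drop = FALSE], 1, max)
  present[mx >= 1]
}

#' Cluster transcription-factor temporal profiles
#'
#' Scales each smoothed TF profile to unit maximum, clusters with
#' agglomerative hierarchical clustering (complete linkage on
#' `1 - Pearson` distance) cut at `k` clusters, and labels the clusters
#' `I`, `II`, `III`, ... by ascending mean peak pseudotime of their members —
#' early, intermediate and late temporal programs.  Constant (zero-variance)
#' profiles have no defined correlation; they are assigned to the cluster with
#' the nearest mean peak time and flagged.
#'
#' @param smoothed Smoothed TF x cells matrix.
#' @param pt An `iahc_pseudotime` covering the cells.
#' @param k Number of temporal classes (default 3).
#' @return Data.frame `(tf, cluster, peak, flagged)` with `cluster` a factor
#'   with roman-numeral levels.
#' @export
cluster_tf_profiles <- function(smoothed, pt, k = 3) {
  if (nrow(smoothed) < k) stop("need at least k TF profiles")
  ptv <- pt$pt[colnames(smoothed)]
  peak <- apply(smoothed, 1, function(v) {
    cand <- which(v == max(v))
    ptv[cand[which.min(ptv[cand])]]
  })
  mx <- apply(smoothed, 1, max)
  scaled <- smoothed / ifelse(mx > 0, mx, 1)
  sdv <- apply(scaled, 1, stats::sd)
  ok <- sdv > 0
  labels <- rep(NA_integer_, nrow(smoothed))
  names(labels) <- rownames(smoothed)
  if (k == 1) {
    labels[] <- 1L
  } else {
    if (sum(ok) < k) stop("fewer than k non-constant TF profiles")
    d <- stats::as.dist(1 - stats::cor(t(scaled[ok, , drop = FALSE])))
    hc <- stats::hclust(d, method = "complete")
    labels[ok] <- stats::cutree(hc, k = k)
  }
  # order raw cluster ids by ascending mean peak pseudotime
  mean_peak <- tapply(peak[!is.na(labels)], labels[!is.na(labels)], mean)
  ordered <- integer(length(mean_peak))
  ordered[order(mean_peak)] <- seq_along(mean_peak)
  labels_ord <- ordered[labels]
  # constant profiles: nearest cluster by peak time
  if (any(!ok)) {
    centers <- sort(as.numeric(mean_peak))
    for (i in which(!ok)) {
      labels_ord[i] <- which.min(abs(centers - peak[i]))
    }
  }
  roman <- as.character(utils::as.roman(seq_len(k)))
  data.frame(tf = rownames(smoothed),
             cluster = factor(roman[labels_ord], levels = roman),
             peak = as.numeric(peak), flagged = !ok,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Build a transcription-factor correlation network
#'
#' Pairwise Pearson correlation over smoothed TF profiles; edges retained when
#' `|r| >= threshold`.  Zero-variance profiles stay as nodes with no edges
#' (warning).
#'
#' @param smoothed Smoothed TF x cells matrix (>= 2 TFs).
#' @param threshold Absolute-correlation edge cutoff (default 0.4).
#' @param labels Optional data.frame from [cluster_tf_profiles()] carried as
#'   node metadata.
#' @return A `tf_network` list: `nodes` (tf, cluster, peak), `edges`
#'   (from, to, weight), `threshold`.
#' @export
build_network <- function(smoothed, threshold = 0.4, labels = NULL) {
  if (nrow(smoothed) < 2) stop("need at least 2 TF profiles")
  sdv <- apply(smoothed, 1, stats::sd)
  if (any(sdv == 0)) {
    warning("zero-variance profile(s): ",
            paste(rownames(smoothed)[sdv == 0], collapse = ", "),
            " retained as isolated nodes")
  }
  cm <- suppressWarnings(stats::cor(t(smoothed)))
  tfs <- rownames(smoothed)
  ij <- which(upper.tri(cm) & !is.na(cm) & abs(cm) >= threshold,
              arr.ind = TRUE)
  edges <- data.frame(from = tfs[ij[, 1]], to = tfs[ij[, 2]],
                      weight = cm[ij], stringsAsFactors = FALSE)
  nodes <- data.frame(tf = tfs, stringsAsFactors = FALSE)
  if (!is.null(labels)) {
    nodes <- merge(nodes, labels[, c("tf", "cluster", "peak")], by = "tf",
                   all.x = TRUE, sort = FALSE)
  }
  structure(list(nodes = nodes, edges = edges, threshold = threshold),
            class = "tf_network")
}

#' @export
print.tf_network <- function(x, ...) {
  cat("TF correlation network:", nrow(x$nodes), "nodes,", nrow(x$edges),
      "edges at |r| >=", x$threshold, "\n")
  if ("cluster" %in% names(x$nodes)) {
    print(table(cluster = x$nodes$cluster))
  }
  invisible(x)
}

#' Convert a TF network to igraph / GraphML
#'
#' @param network A `tf_network`.
#' @return An igraph object.
#' @export
as_igraph <- function(network) {
  igraph::graph_from_data_frame(
    network$edges,
    directed = FALSE,
    vertices = data.frame(name = network$nodes$tf,
                          cluster = as.character(network$nodes$cluster %||% NA),
                          peak = network$nodes$peak %||% NA_real_)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname as_igraph
#' @param path Output GraphML path.
#' @export
write_graphml <- function(network, path) {
  igraph::write_graph(as_igraph(network), path, format = "graphml")
  invisible(path)
}

#' @export
plot.tf_network <- function(x, ...) {
  g <- as_igraph(x)
  cl <- igraph::V(g)$cluster
  pal <- c(I = "#1b9e77", II = "#d95f02", III = "#7570b3")
  igraph::plot.igraph(g, vertex.color = pal[cl], vertex.size = 8,
                      vertex.label.cex = 0.6, ...)
  invisible(x)
}

#' Cross-stage transcription-factor cluster overlap
#'
#' For each temporal cluster label, the proportion of TFs carrying that label
#' at both stages, only at stage 1, or only at stage 2, computed over the
#' union of TFs with that label in either stage.  The three proportions sum
#' to 1 per cluster.
#'
#' @param labels1,labels2 Named vectors (or [cluster_tf_profiles()] frames)
#'   mapping TFs to cluster labels at the two stages.
#' @return Data.frame `(cluster, shared, only_stage1, only_stage2, n_union)`.
#' @export
cross_stage_cluster_overlap <- function(labels1, labels2) {
  as_named <- function(x) {
    if (is.data.frame(x)) stats::setNames(as.character(x$cluster), x$tf)
    else stats::setNames(as.character(x), names(x))
  }
  l1 <- as_named(labels1); l2 <- as_named(labels2)
  labs <- sort(unique(c(l1, l2)))
  rows <- lapply(labs, function(cl) {
    s1 <- names(l1)[l1 == cl]
    s2 <- names(l2)[l2 == cl]
    u <- union(s1, s2)
    n <- length(u)
    data.frame(cluster = cl,
               shared = if (n > 0) length(intersect(s1, s2)) / n else 0,
               only_stage1 = if (n > 0) length(setdiff(s1, s2)) / n else 0,
               only_stage2 = if (n > 0) length(setdiff(s2, s1)) / n else 0,
               n_union = n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
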