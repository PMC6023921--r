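#' Two-group negative-binomial differential expression test
#'
#' Per gene, a Wald test on the difference of log group means of UMI counts at
#' uniform depth.  The negative-binomial dispersion is estimated by method of
#' moments pooled across both groups (floored at 1e-8); the statistic is
#' `(log mean A - log mean B) / SE` with the delta-method standard error
#' `sqrt((1/muA + phi)/nA + (1/muB + phi)/nB)`, and two-sided p-values come
#' from the normal approximation.  Benjamini-Hochberg correction is applied
#' over the tested genes.  Genes in `exclude_genes` (e.g. a cell-cycle list)
#' are removed before testing; genes with zero total count are reported `NA`.
#' Cells are treated as replicates (pseudo-replication, as is conventional in
#' single-cell DE).
#'
#' A half-count pseudocount per group mean (0.5 / group size) stabilises logs;
#' because it follows its group, swapping the groups negates the log2 fold
#' change exactly and leaves p-values unchanged.
#'
#' @param counts Integer genes x cells matrix at uniform depth.
#' @param group_a,group_b Disjoint cell identifier sets, each of size >= 3.
#' @param alpha FDR level for the significant-gene list (default 0.05).
#' @param exclude_genes Optional genes removed before testing.
#' @return An `iahc_de` list: `table` (per-gene means, log2FC, statistic,
#'   p-value, BH q-value), `significant` (genes with `q < alpha`), `alpha`.
#' @export
de_test <- function(counts, group_a, group_b, alpha = 0.05,
                    exclude_genes = NULL) {
  if (length(intersect(group_a, group_b)) > 0) {
    stop("groups must be disjoint")
  }
  if (length(group_a) < 3 || length(group_b) < 3) {
    stop("each group needs at least 3 cells")
  }
  missing <- setdiff(c(group_a, group_b), colnames(counts))
  if (length(missing) > 0) {
    stop("cells absent from the matrix: ", paste(missing, collapse = ", "))
  }
  if (!is.null(exclude_genes)) {
    counts <- counts[setdiff(rownames(counts), exclude_genes), , drop = FALSE]
  }
  a <- counts[, group_a, drop = FALSE]
  b <- counts[, group_b, drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- (rowSums(a * a) - na * ma^2) / (na - 1)
  vb <- (rowSums(b * b) - nb * mb^2) / (nb - 1)

  testable <- (ma + mb) > 0
  # pooled method-of-moments dispersion: per-group (var - mean)/mean^2
  da <- ifelse(ma > 0, (va - ma) / ma^2, 0)
  db <- ifelse(mb > 0, (vb - mb) / mb^2, 0)
  phi <- pmax(((na - 1) * da + (nb - 1) * db) / (na + nb - 2), 1e-8)

  pa <- ma + 0.5 / na
  pb <- mb + 0.5 / nb
  se <- sqrt((1 / pa + phi) / na + (1 / pb + phi) / nb)
  stat <- (log(pa) - log(pb)) / se
  log2fc <- log2(pa / pb)
  p <- 2 * stats::pnorm(-abs(stat))

  stat[!testable] <- NA_real_
  log2fc[!testable] <- NA_real_
  p[!testable] <- NA_real_
  q <- rep(NA_real_, length(p))
  q[testable] <- stats::p.adjust(p[testable], method = "BH")

  tab <- data.frame(gene = rownames(counts), mean_a = ma, mean_b = mb,
                    log2fc = log2fc, stat = stat, pvalue = p, qvalue = q,
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  sig <- tab$gene[!is.na(tab$qvalue) & tab$qvalue < alpha]
  structure(list(table = tab, significant = sig, alpha = alpha,
                 n_a = na, n_b = nb),
            class = "iahc_de")
}

#' @export
print.iahc_de <- function(x, ...) {
  cat("NB Wald differential expression:", nrow(x$table), "genes,",
      x$n_a, "vs", x$n_b, "cells\n")
  cat(length(x$significant), "genes significant at FDR", x$alpha, "\n")
  invisible(x)
}

#' Sliding-window geometry for pseudotime differential expression
#'
#' @param width Window width in pseudotime units (default 10).
#' @param half Width of the first half compared against the remainder
#'   (default 5).
#' @param step Step between window centers (default 1).
#' @param alpha FDR level per window (default 0.05).
#' @return A `window_spec` list.
#' @export
window_spec <- function(width = 10, half = 5, step = 1, alpha = 0.05) {
  if (half > width) stop("half must not exceed width")
  if (step <= 0) stop("step must be positive")
  structure(list(width = width, half = half, step = step, alpha = alpha),
            class = "window_spec")
}

#' Differentially expressed gene counts along pseudotime
#'
#' Slides a window of `width` pseudotime units along the axis; within each
#' window `[c - width/2, c + width/2)` the cells in the first `half` units
#' form group A and the remaining cells group B, and the number of genes
#' significant at FDR `alpha` (via [de_test()]) is recorded.  Windows whose
#' halves hold fewer than 3 cells are emitted with count `NA`.
#'
#' @param counts Integer genes x cells matrix at uniform depth.
#' @param pt An `iahc_pseudotime` covering the cells.
#' @param spec A [window_spec()].
#' @param exclude_genes Optional genes removed before testing.
#' @return Data.frame `(center, n_a, n_b, n_sig)` with centers from
#'   `min + width/2` to `max - width/2`.
#' @export
windowed_de <- function(counts, pt, spec = window_spec(),
                        exclude_genes = NULL) {
  ptv <- pt$pt[colnames(counts)]
  if (anyNA(ptv)) stop("all cells in the matrix need a pseudotime value")
  rng <- range(ptv)
  if (diff(rng) < spec$width) {
    stop("window width exceeds the pseudotime range")
  }
  centers <- seq(rng[1] + spec$width / 2, rng[2] - spec$width / 2,
                 by = spec$step)
  rows <- lapply(centers, function(ct) {
    lo <- ct - spec$width / 2
    hi <- lo + spec$width
    # windows are half-open except at the end of the axis, so the
    # maximum-pseudotime cell is not silently dropped
    last <- hi >= rng[2] - 1e-9
    ina <- names(ptv)[ptv >= lo & ptv < lo + spec$half]
    inb <- names(ptv)[ptv >= lo + spec$half &
                      (ptv < hi | (last & ptv <= hi))]
    if (length(ina) < 3 || length(inb) < 3) {
      return(data.frame(center = ct, n_a = length(ina), n_b = length(inb),
                        n_sig = NA_integer_))
    }
    de <- de_test(counts, ina, inb, alpha = spec$alpha,
                  exclude_genes = exclude_genes)
    data.frame(center = ct, n_a = length(ina), n_b = length(inb),
               n_sig = length(de$significant))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Hypergeometric gene-list overlap test
#'
#' Overlap of two gene lists drawn from a common universe: reports the overlap
#' size, the percentage of list A shared, and the upper-tail hypergeometric
#' p-value `P(X >= overlap)`.
#'
#' @param list_a,list_b Gene sets, both subsets of `universe`.
#' @param universe The tested gene universe.
#' @return List: `overlap`, `percent_a`, `pvalue`.
#' @export
overlap_test <- function(list_a, list_b, universe) {
  for (nm in c("list_a", "list_b")) {
    bad <- setdiff(get(nm), universe)
    if (length(bad) > 0) {
      stop(nm, " contains genes outside the universe: ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
  }
  list_a <- unique(list_a); list_b <- unique(list_b)
  k <- length(intersect(list_a, list_b))
  p <- stats::phyper(k - 1, length(list_b),
                     length(unique(universe)) - length(list_b),
                     length(list_a), lower.tail = FALSE)
  list(overlap = k,
       percent_a = if (length(list_a) > 0) 100 * k / length(list_a) else NA_real_,
       pvalue = p)
}
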