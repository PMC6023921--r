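#' Deconvolution search configuration
#'
#' @param n_swaps Random swap proposals per restart (default 10,000).
#' @param n_restarts Restarts from fresh random member sets (default 100).
#' @param acceptance `"greedy"` (accept only strict improvement, default) or
#'   `"metropolis"` (accept worse moves with probability `exp(dr/T)`).
#' @param temperature Metropolis temperature (> 0).
#' @param space Correlation space: `"log2cp10k"` (default, `log2(1 +`
#'   counts-per-10k`)` of both the summed member profile and the bulk) or
#'   `"raw"`.
#' @param seed Integer seed.
#' @return A `decon_config` list.
#' @export
decon_config <- function(n_swaps = 10000L, n_restarts = 100L,
                         acceptance = c("greedy", "metropolis"),
                         temperature = 0.01, space = c("log2cp10k", "raw"),
                         seed = 1L) {
  acceptance <- match.arg(acceptance)
  space <- match.arg(space)
  if (n_swaps < 1 || n_restarts < 1) {
    stop("n_swaps and n_restarts must be >= 1")
  }
  if (acceptance == "metropolis" && temperature <= 0) {
    stop("temperature must be > 0 for metropolis acceptance")
  }
  structure(list(n_swaps = as.integer(n_swaps),
                 n_restarts = as.integer(n_restarts),
                 acceptance = acceptance, temperature = temperature,
                 space = space, seed = as.integer(seed)),
            class = "decon_config")
}

#' Resolve a bulk whole-cluster profile into constituent single cells
#'
#' For a whole-IAHC bulk transcriptome of known constituent cell count `n`,
#' searches for the set of `n` reference single cells whose summed profile
#' best matches the bulk by Pearson correlation: each restart initialises with
#' `n` distinct cells chosen uniformly at random, then proposes `n_swaps`
#' random member/non-member swaps, accepting by the configured rule.  Final
#' member sets across restarts feed [contribution_probability()],
#' [cluster_contribution()] and [pseudotime_density()].
#'
#' @param bulk Named numeric gene vector (same gene index as `reference`).
#' @param reference Genes x cells matrix of single-cell UMI counts (uniform
#'   depth recommended).
#' @param n Constituent cell count of the bulk (known from imaging).
#' @param config A [decon_config()].
#' @return An `iahc_decon` list: per-restart member sets (cell identifiers),
#'   final correlations, accepted-swap counts and objective traces, plus `n`
#'   and the config.
#' @export
deconvolve <- function(bulk, reference, n, config = decon_config()) {
  if (n > ncol(reference)) {
    stop("n (", n, ") exceeds the ", ncol(reference), " reference cells")
  }
  if (n < 1) stop("n must be >= 1")
  if (!is.null(names(bulk))) {
    if (!identical(names(bulk), rownames(reference))) {
      if (!setequal(names(bulk), rownames(reference))) {
        stop("bulk and reference gene indices differ")
      }
      bulk <- bulk[rownames(reference)]
    }
  } else if (length(bulk) != nrow(reference)) {
    stop("bulk length does not match the reference gene index")
  }
  set.seed(config$seed)
  res <- decon_search_cpp(as.matrix(reference) * 1.0, as.numeric(bulk),
                          as.integer(n), config$n_swaps, config$n_restarts,
                          config$acceptance == "greedy", config$temperature,
                          config$space == "log2cp10k")
  cells <- colnames(reference)
  members <- lapply(seq_len(nrow(res$members)),
                    function(r) cells[res$members[r, ]])
  structure(list(members = members, correlation = as.numeric(res$correlation),
                 accepted = as.integer(res$accepted), traces = res$traces,
                 n = as.integer(n), reference_cells = cells,
                 config = config),
            class = "iahc_decon")
}

#' @export
print.iahc_decon <- function(x, ...) {
  cat("wIAHC deconvolution: n =", x$n, "members,",
      length(x$members), "restarts x", x$config$n_swaps, "swaps (",
      x$config$acceptance, ",", x$config$space, ")\n")
  cat(sprintf("final correlation: mean %.4f, range [%.4f, %.4f]\n",
              mean(x$correlation), min(x$correlation), max(x$correlation)))
  invisible(x)
}

#' Per-cell contribution probability
#'
#' Fraction of restarts whose final member set contains each reference cell.
#' Probabilities lie in `[0, 1]` and sum over cells to `n` exactly (each
#' restart contributes `n` memberships).
#'
#' @param result An `iahc_decon`.
#' @return Named numeric vector over all reference cells.
#' @export
contribution_probability <- function(result) {
  counts <- table(factor(unlist(result$members),
                         levels = result$reference_cells))
  stats::setNames(as.numeric(counts) / length(result$members),
                  result$reference_cells)
}

#' Per-cluster contribution fractions
#'
#' Per restart, the fraction of the `n` member cells belonging to each
#' cluster; the headline fraction is the mean over restarts.  Fractions sum
#' to 1 per restart and in the mean.
#'
#' @param result An `iahc_decon`.
#' @param clusters An `iahc_clusters` (or named cluster vector) labelling
#'   every reference cell.
#' @return List: `mean` (named fractions) and `per_restart` (restarts x
#'   clusters matrix, for box plots).
#' @export
cluster_contribution <- function(result, clusters) {
  cl <- if (inherits(clusters, "iahc_clusters")) clusters$cluster else clusters
  unlabeled <- setdiff(unique(unlist(result$members)), names(cl))
  if (length(unlabeled) > 0) {
    stop("member cells without a cluster label: ",
         paste(utils::head(unlabeled, 5), collapse = ", "))
  }
  levs <- sort(unique(cl))
  per <- t(vapply(result$members, function(m) {
    as.numeric(table(factor(cl[m], levels = levs))) / length(m)
  }, numeric(length(levs))))
  colnames(per) <- as.character(levs)
  list(mean = colMeans(per), per_restart = per)
}

#' Probability density of contribution along pseudotime
#'
#' Gaussian kernel density over member-cell pseudotimes weighted by
#' contribution probability, with Silverman's bandwidth and boundary
#' reflection at the ends of the axis so the density integrates to 1 over
#' `[0, 30]`.
#'
#' @param probabilities Named per-cell probabilities (from
#'   [contribution_probability()]).
#' @param pt An `iahc_pseudotime` covering those cells.
#' @param n_grid Grid resolution (default 512).
#' @return Data.frame `(pseudotime, density)`.
#' @export
pseudotime_density <- function(probabilities, pt, n_grid = 512) {
  w <- probabilities[probabilities > 0]
  if (length(w) == 0) stop("no contributing cells")
  x <- pt$pt[names(w)]
  if (anyNA(x)) stop("contributing cells lack pseudotime values")
  wn <- w / sum(w)
  # weighted Silverman bandwidth with effective sample size
  n_eff <- 1 / sum(wn^2)
  mu <- sum(wn * x)
  sdw <- sqrt(sum(wn * (x - mu)^2))
  qs <- .weighted_quantile(x, wn, c(0.25, 0.75))
  iqr <- qs[2] - qs[1]
  sig <- min(sdw, iqr / 1.349)
  if (sig <= 0) sig <- max(sdw, 0.1)
  bw <- 0.9 * sig * n_eff^(-1 / 5)
  if (bw <= 0) bw <- 0.1
  a <- 0; b <- 30
  grid <- seq(a, b, length.out = n_grid)
  dens <- vapply(grid, function(g) {
    sum(wn * (stats::dnorm(g, x, bw) +
              stats::dnorm(g, 2 * a - x, bw) +
              stats::dnorm(g, 2 * b - x, bw)))
  }, numeric(1))
  data.frame(pseudotime = grid, density = dens)
}

.weighted_quantile <- function(x, w, probs) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  vapply(probs, function(p) x[which(cw >= p)[1]], numeric(1))
}

#' Bulk-bulk transcriptome similarity
#'
#' Pairwise Pearson correlation of `log2(1 + counts-per-10k)` bulk profiles;
#' the similarity structure is the Euclidean distance between rows of the
#' correlation matrix, with an average-linkage dendrogram leaf order for
#' heatmap rendering.
#'
#' @param bulks Genes x bulks matrix (>= 2 bulks) or an `iahc_bulks`.
#' @return List: `correlation` (C, symmetric, unit diagonal), `distance`
#'   (D, symmetric, zero diagonal), `order` (leaf order), `hclust`.
#' @export
wiahc_similarity <- function(bulks) {
  m <- if (inherits(bulks, "iahc_bulks")) bulks$counts else bulks
  if (ncol(m) < 2) stop("need at least 2 bulks")
  tot <- colSums(m)
  keep <- apply(m, 2, function(v) stats::sd(v) > 0)
  if (!all(keep)) {
    warning("zero-variance bulk(s) excluded: ",
            paste(colnames(m)[!keep], collapse = ", "))
    m <- m[, keep, drop = FALSE]
    tot <- tot[keep]
  }
  lt <- log2(1 + sweep(m, 2, tot / 1e4, "/"))
  C <- stats::cor(lt)
  D <- as.matrix(stats::dist(C))
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  list(correlation = C, distance = D,
       order = colnames(C)[hc$order], hclust = hc)
}
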