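#' Downsample every cell to a fixed number of unique transcripts
#'
#' Per cell, draws `depth` UMIs uniformly without replacement from the cell's
#' UMI pool (the per-gene retained counts are jointly multivariate
#' hypergeometric), so every retained cell totals exactly `depth`.  Cells with
#' fewer than `depth` total transcripts are discarded and listed.
#'
#' @param counts Integer genes x cells matrix.
#' @param depth Target depth (default 5000 unique transcripts).
#' @param seed Integer seed.
#' @return List with `counts` (retained cells, each summing to `depth`) and
#'   `discarded` (identifiers of cells below depth).
#' @export
downsample_cells <- function(counts, depth = 5000L, seed = 1L) {
  if (length(depth) != 1 || depth <= 0 || depth != round(depth)) {
    stop("depth must be a positive integer")
  }
  depth <- as.integer(depth)
  set.seed(as.integer(seed))
  totals <- colSums(counts)
  keep <- totals >= depth
  out <- counts[, keep, drop = FALSE]
  for (j in seq_len(ncol(out))) {
    tot <- totals[keep][j]
    if (tot == depth) next
    v <- out[, j]
    nz <- which(v > 0L)
    pool <- rep.int(nz, v[nz])
    take <- pool[sample.int(length(pool), depth)]
    out[, j] <- tabulate(take, nbins = nrow(out))
  }
  storage.mode(out) <- "integer"
  list(counts = out, discarded = colnames(counts)[!keep])
}

#' Purification rule for in silico IAHC selection
#'
#' A cell is kept iff its inclusion-marker count is at least `include_min`
#' (default: more than one *Gpr56* transcript, i.e. >= 2) and no exclusion
#' marker exceeds `exclude_max` transcripts (default: more than two of any
#' non-IAHC gene rejects).  The default exclusion list unions the named
#' mesenchymal, EMP and sub-aortic-patch markers.
#'
#' @param include_gene Inclusion marker (default `"Gpr56"`).
#' @param include_min Minimum inclusion-marker count to keep (default 2).
#' @param exclude_genes Character vector of non-IAHC markers.
#' @param exclude_max Maximum tolerated count of any exclusion marker
#'   (default 2).
#' @return A `purification_rule` list.
#' @export
purification_rule <- function(include_gene = "Gpr56", include_min = 2L,
                              exclude_genes = c("Epha7", "Crabp1", "Cxcl12",
                                                "Pdgfrb", "Sox11", "Ptprd",
                                                "Col3a1", "Csf1r", "Fcgr3",
                                                "Gata3", "Cdkn1c"),
                              exclude_max = 2L) {
  if (include_gene %in% exclude_genes) {
    stop("include_gene must not appear in exclude_genes")
  }
  if (include_min < 0 || exclude_max < 0) stop("thresholds must be >= 0")
  structure(list(include_gene = include_gene,
                 include_min = as.integer(include_min),
                 exclude_genes = exclude_genes,
                 exclude_max = as.integer(exclude_max)),
            class = "purification_rule")
}

#' In silico purification of IAHC cells
#'
#' Applies a [purification_rule()] to raw UMI counts.  Rejected cells are
#' labelled `"low-include"` (inclusion marker below threshold) or
#' `"contaminant:<gene>"` (first offending exclusion marker).  Selection is
#' idempotent: purifying the purified set returns it unchanged.
#'
#' @param counts Integer genes x cells matrix (raw, pre-downsampling, by
#'   default usage).
#' @param rule A [purification_rule()].
#' @return List with `selected` (cell identifiers) and `rejected`
#'   (data.frame of cell, reason).
#' @export
purify <- function(counts, rule = purification_rule()) {
  if (!rule$include_gene %in% rownames(counts)) {
    stop("inclusion gene '", rule$include_gene, "' is absent from the matrix")
  }
  excl <- rule$exclude_genes
  missing <- setdiff(excl, rownames(counts))
  if (length(missing) > 0) {
    warning("exclusion gene(s) absent from the matrix (treated as zero): ",
            paste(missing, collapse = ", "))
    excl <- setdiff(excl, missing)
  }
  inc <- counts[rule$include_gene, ]
  cells <- colnames(counts)
  reason <- rep(NA_character_, length(cells))
  low <- inc < rule$include_min
  reason[low] <- "low-include"
  if (length(excl) > 0) {
    em <- counts[excl, , drop = FALSE]
    over <- em > rule$exclude_max
    hit <- !low & colSums(over) > 0
    if (any(hit)) {
      first <- apply(over[, hit, drop = FALSE], 2, function(z) excl[which(z)[1]])
      reason[hit] <- paste0("contaminant:", first)
    }
  }
  sel <- is.na(reason)
  list(selected = cells[sel],
       rejected = data.frame(cell = cells[!sel], reason = reason[!sel],
                             stringsAsFactors = FALSE))
}

#' Minimum-expression gene filter
#'
#' Keeps genes expressed in at least `min_cells` cells with at least
#' `min_count` transcripts (default: at least one cell with at least five
#' transcripts), preserving input order.
#'
#' @param counts Integer genes x cells matrix.
#' @param min_count Minimum per-cell count (default 5).
#' @param min_cells Minimum number of cells reaching it (default 1).
#' @return Character vector of retained gene identifiers.
#' @export
filter_genes_min_expression <- function(counts, min_count = 5L,
                                        min_cells = 1L) {
  if (min_count < 1 || min_cells < 1) stop("thresholds must be >= 1")
  keep <- rowSums(counts >= min_count) >= min_cells
  rownames(counts)[keep]
}
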