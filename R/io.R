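#' Read a UMI count matrix
#'
#' Reads a genes x cells matrix of non-negative integer UMI counts from either
#' the sparse Matrix Market dialect (`<stem>.mtx` plus `<stem>.genes.tsv` and
#' `<stem>.cells.tsv` index files, one identifier per line) or a dense TSV
#' (gene identifiers in the first column, cell identifiers in the header).
#'
#' @param path Path to the `.mtx` file or the dense TSV.
#' @param format `"auto"` (default, decided by the file extension), `"mtx"`, or
#'   `"tsv"`.
#' @return An integer matrix with gene rownames and cell colnames.
#' @seealso [write_count_matrix()]
#' @export
read_count_matrix <- function(path, format = c("auto", "mtx", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.mtx$", path)) "mtx" else "tsv"
  }
  if (!file.exists(path)) stop("count matrix file not found: ", path)
  if (format == "mtx") {
    stem <- sub("\\.mtx$", "", path)
    gene_file <- paste0(stem, ".genes.tsv")
    cell_file <- paste0(stem, ".cells.tsv")
    for (f in c(gene_file, cell_file)) {
      if (!file.exists(f)) stop("index file not found: ", f)
    }
    m <- as.matrix(Matrix::readMM(path))
    genes <- readLines(gene_file)
    cells <- if (file.size(cell_file) > 0) readLines(cell_file) else character(0)
    if (length(genes) != nrow(m)) {
      stop("dimension mismatch: ", gene_file, " has ", length(genes),
           " entries but matrix has ", nrow(m), " rows")
    }
    if (length(cells) != ncol(m)) {
      stop("dimension mismatch: ", cell_file, " has ", length(cells),
           " entries but matrix has ", ncol(m), " columns")
    }
    dimnames(m) <- list(genes, cells)
  } else {
    df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                            stringsAsFactors = FALSE)
    genes <- as.character(df[[1L]])
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- genes
  }
  .validate_counts(m)
  storage.mode(m) <- "integer"
  m
}

#' Write a UMI count matrix
#'
#' Inverse of [read_count_matrix()]; write-then-read reproduces the matrix
#' exactly (entries, gene and cell identifiers).
#'
#' @param counts Integer matrix, genes x cells, with dimnames.
#' @param path Output path (`.mtx` for the sparse dialect, anything else for
#'   dense TSV).
#' @param format See [read_count_matrix()].
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(counts, path, format = c("auto", "mtx", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.mtx$", path)) "mtx" else "tsv"
  }
  .validate_counts(counts)
  if (format == "mtx") {
    stem <- sub("\\.mtx$", "", path)
    Matrix::writeMM(methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                            "generalMatrix"), "CsparseMatrix"), path)
    writeLines(rownames(counts), paste0(stem, ".genes.tsv"))
    writeLines(if (is.null(colnames(counts))) character(0) else
               colnames(counts), paste0(stem, ".cells.tsv"))
  } else {
    df <- data.frame(gene = rownames(counts), counts, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

.validate_counts <- function(m) {
  if (is.null(rownames(m)) || anyDuplicated(rownames(m))) {
    stop("gene identifiers must be present and unique")
  }
  if (ncol(m) > 0 && (is.null(colnames(m)) || anyDuplicated(colnames(m)))) {
    stop("cell identifiers must be present and unique")
  }
  bad <- which(m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("negative or non-integer count at gene '", rownames(m)[bad[1, 1]],
         "', cell '", colnames(m)[bad[1, 2]], "'")
  }
  invisible(TRUE)
}

#' Read a gene list
#'
#' One identifier per line; lines starting with `#` are comments and blank
#' lines are skipped.  Duplicates are removed preserving first occurrence.
#'
#' @param path Path to the list file.
#' @return Character vector of unique gene identifiers (possibly empty, with a
#'   warning).
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop("gene list file not found: ", path)
  x <- readLines(path)
  x <- trimws(x)
  x <- x[nzchar(x) & !startsWith(x, "#")]
  x <- x[!duplicated(x)]
  if (length(x) == 0) warning("gene list '", path, "' is empty")
  x
}

#' Read / write a per-cell annotation table
#'
#' TSV with a header; first column `cell` holds the cell identifier.
#'
#' @param path File path.
#' @return A data.frame.
#' @export
read_annotation <- function(path) {
  utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' @rdname read_annotation
#' @param annotation Data frame to write.
#' @export
write_annotation <- function(annotation, path) {
  utils::write.table(annotation, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# -- run configuration ---------------------------------------------------

.config_defaults <- function() {
  list(
    seed = 1L,
    scenario = "e11",
    n_genes = 2000L,
    mean_depth = 12000,
    dispersion = 0.3,
    contaminants = c(mesenchymal = 40L, `EMP-like` = 15L, subaortic = 15L),
    n_wiahcs = 12L,
    wiahc_size_range = c(3L, 30L),
    downsample_depth = 5000L,
    purify_pool = c("preHSC-I", "preHSC-II", "progenitor",
                    "mesenchymal", "EMP-like", "subaortic"),
    n_clusters = 0L,           # 0 = choose by silhouette
    window_width = 10,
    window_half = 5,
    window_step = 1,
    de_alpha = 0.05,
    network_threshold = 0.4,
    decon_swaps = 10000L,
    decon_restarts = 100L,
    out_dir = "iahc_run"
  )
}

#' Build a run configuration
#'
#' Holds every tunable of the pipeline: simulation scenario and sizes, the
#' downsampling depth (default 5000 unique transcripts), the sliding-window
#' geometry (width 10 pseudotime units split 5/5), the FDR level, the
#' correlation threshold of the TF network, and the deconvolution search size
#' (default 10,000 swaps, 100 restarts).
#'
#' @param ... Named settings overriding the defaults; unknown names are an
#'   error.
#' @return An object of class `iahc_config` (a validated named list).
#' @export
run_config <- function(...) {
  cfg <- .config_defaults()
  dots <- list(...)
  if (length(dots) > 0 && (is.null(names(dots)) || any(!nzchar(names(dots))))) {
    stop("all configuration settings must be named")
  }
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  validate_config(cfg)
}

#' @rdname run_config
#' @param config A configuration list to validate.
#' @export
validate_config <- function(config) {
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), names(.config_defaults()))
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  missing <- setdiff(names(.config_defaults()), names(config))
  if (length(missing) > 0) {
    stop("missing configuration key(s): ", paste(missing, collapse = ", "))
  }
  int_keys <- c("seed", "n_genes", "n_wiahcs", "downsample_depth",
                "decon_swaps", "decon_restarts", "n_clusters")
  for (k in int_keys) {
    v <- config[[k]]
    if (!is.numeric(v) || length(v) != 1 || v != round(v)) {
      stop("configuration key '", k, "' must be a single integer")
    }
    config[[k]] <- as.integer(v)
  }
  if (config$seed < 0) stop("seed must be >= 0")
  for (k in c("n_genes", "n_wiahcs", "downsample_depth",
              "decon_swaps", "decon_restarts")) {
    if (config[[k]] < 1) stop("configuration key '", k, "' must be positive")
  }
  if (!config$scenario %in% c("e10", "e11")) {
    stop("scenario must be 'e10' or 'e11'")
  }
  if (config$mean_depth <= 0) stop("mean_depth must be positive")
  if (config$dispersion <= 0) stop("dispersion must be positive")
  if (config$de_alpha <= 0 || config$de_alpha >= 1) {
    stop("de_alpha must be in (0, 1)")
  }
  if (config$network_threshold < 0 || config$network_threshold > 1) {
    stop("network_threshold must be in [0, 1]")
  }
  if (config$window_half * 2 != config$window_width) {
    stop("window_half must equal window_width / 2")
  }
  if (config$window_step <= 0) stop("window_step must be positive")
  sr <- config$wiahc_size_range
  if (length(sr) != 2 || sr[1] < 2 || sr[2] < sr[1]) {
    stop("wiahc_size_range must be an increasing pair with lower bound >= 2")
  }
  config$wiahc_size_range <- as.integer(sr)
  cont <- config$contaminants
  if (is.list(cont)) cont <- unlist(cont)
  if (is.null(names(cont)) || any(cont < 0)) {
    stop("contaminants must be a named vector of non-negative counts")
  }
  config$contaminants <- vapply(cont, as.integer, integer(1))
  config$purify_pool <- as.character(unlist(config$purify_pool))
  structure(config, class = "iahc_config")
}

#' Read / write a run configuration as YAML
#'
#' Round-trips exactly: `read_config(write_config(cfg, f))` reproduces the
#' value set.  Unknown keys in the file are an error (typo protection).
#'
#' @param path YAML file path.
#' @return An `iahc_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

#' @rdname read_config
#' @param config An `iahc_config`.
#' @export
write_config <- function(config, path) {
  config <- validate_config(config)
  out <- unclass(config)
  out$contaminants <- as.list(out$contaminants)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @export
print.iahc_config <- function(x, ...) {
  cat("IAHC pipeline configuration\n")
  for (k in names(x)) {
    v <- x[[k]]
    if (!is.null(names(v)) && length(v) > 1) {
      v <- paste(names(v), v, sep = "=", collapse = ", ")
    } else {
      v <- paste(v, collapse = ", ")
    }
    cat(sprintf("  %-18s %s\n", k, v))
  }
  invisible(x)
}

#' Derive a stage-specific child seed
#'
#' All pipeline randomness flows from one root seed; each stage derives its own
#' seed from (root seed, stage name) so stages are independently reproducible.
#'
#' @param seed Root seed (non-negative integer).
#' @param stage Stage name.
#' @return An integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483647)
}
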