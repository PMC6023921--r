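#' Marker gene panels used by the simulator and the purification defaults
#'
#' Endothelial and haematopoietic panels form the opposing gradients along the
#' differentiation axis; `iahc` is the cluster-inclusion marker; the three
#' contaminant panels mark mesenchymal, erythro-myeloid-progenitor-like and
#' sub-aortic-patch cells; `tf_I/II/III` are the three temporal transcription
#' factor archetype panels (early / intermediate / late peaking).
#'
#' @return Named list of character vectors.
#' @export
marker_panels <- function() {
  list(
    endothelial = c("Vwf", "Cdh5", "Pecam1", "Gja4", "Gja5"),
    haematopoietic = c("Kit", "Runx1", "Mpo", "Mt1", "Rac2", "Ptprc"),
    iahc = "Gpr56",
    mesenchymal = c("Epha7", "Crabp1", "Cxcl12", "Pdgfrb", "Sox11",
                    "Ptprd", "Col3a1"),
    emp = c("Csf1r", "Fcgr3"),
    subaortic = c("Gata3", "Cdkn1c"),
    tf_I = c("Sox17", "Hey2", "Elk3", "Jun", "Mecom", "Epas1",
             "Id3", "Erg", "Sox7", "Hes1", "Foxc2", "Tcf15"),
    tf_II = c("Gfi1", "Ikzf2", "Dnmt3a", "Lmo2", "Tal1", "Lyl1",
              "Cbfb", "Etv6", "Meis1", "Mycn", "Myb", "Nfe2"),
    tf_III = c("Zfpm1", "Klf1", "Gata1", "Cebpa", "Irf8", "Sfpi1",
               "Hhex", "Nfia", "Bcl11a", "Ikzf1", "Stat5a", "Cited4")
  )
}

#' Describe one simulated cell population
#'
#' @param name Population label, one of `non-HE`, `HE`, `EHT`, `preHSC-I`,
#'   `preHSC-II`, `progenitor`, `YS-HSPC` (trajectory populations) or
#'   `mesenchymal`, `EMP-like`, `subaortic` (contaminants).
#' @param n_cells Number of cells (>= 1).
#' @param time_center True-pseudotime location in `[0, 1]`; `NA` for
#'   contaminants, which sit off the differentiation axis.
#' @param time_sd Spread of per-cell true times around the center.
#' @param marker_overrides Named numeric vector of per-gene mean multipliers.
#' @return A `population_spec` list.
#' @export
population_spec <- function(name, n_cells, time_center = NA_real_,
                            time_sd = 0.05, marker_overrides = NULL) {
  stopifnot(n_cells >= 1)
  if (!is.na(time_center) && (time_center < 0 || time_center > 1)) {
    stop("time_center must lie in [0, 1]")
  }
  structure(list(name = name, n_cells = as.integer(n_cells),
                 time_center = time_center, time_sd = time_sd,
                 marker_overrides = marker_overrides),
            class = "population_spec")
}

.trajectory_centers <- c(
  "non-HE" = 0.04, "HE" = 0.20, "EHT" = 0.40, "preHSC-I" = 0.60,
  "preHSC-II" = 0.75, "progenitor" = 0.80, "YS-HSPC" = 0.92
)

.contaminant_names <- c("mesenchymal", "EMP-like", "subaortic")

#' Preset population inventories
#'
#' `scenario_e11()` mirrors the embryonic-day-11 design: 27 non-HE, 45 HE and
#' 43 EHT cells, 282 purified IAHC cells (allocated 91/91/100 to preHSC-I /
#' preHSC-II / progenitor on top of the 58 + 55 sorted pre-HSCs), and 44
#' yolk-sac HSPCs — 554 cells in all.  `scenario_e10()` mirrors the E10 design
#' (39/96/116 non-HE/HE/EHT, 73 IAHC cells split 40/33, 140 YS HSPCs; 464
#' cells).  Contaminant populations are added on top when requested.
#'
#' @param contaminants Named integer vector of extra contaminant cells
#'   (`mesenchymal`, `EMP-like`, `subaortic`); default none.
#' @return List of [population_spec()]s.
#' @export
scenario_e11 <- function(contaminants = c(mesenchymal = 0L, `EMP-like` = 0L,
                                          subaortic = 0L)) {
  sizes <- c("non-HE" = 27L, "HE" = 45L, "EHT" = 43L,
             "preHSC-I" = 58L + 91L, "preHSC-II" = 55L + 91L,
             "progenitor" = 100L, "YS-HSPC" = 44L)
  .build_scenario(sizes, contaminants)
}

#' @rdname scenario_e11
#' @export
scenario_e10 <- function(contaminants = c(mesenchymal = 0L, `EMP-like` = 0L,
                                          subaortic = 0L)) {
  sizes <- c("non-HE" = 39L, "HE" = 96L, "EHT" = 116L,
             "preHSC-I" = 40L, "progenitor" = 33L, "YS-HSPC" = 140L)
  .build_scenario(sizes, contaminants)
}

.build_scenario <- function(sizes, contaminants) {
  pops <- lapply(names(sizes), function(nm) {
    population_spec(nm, sizes[[nm]], time_center = .trajectory_centers[[nm]])
  })
  contaminants <- contaminants[contaminants > 0]
  for (nm in names(contaminants)) {
    if (!nm %in% .contaminant_names) {
      stop("unknown contaminant population: ", nm)
    }
    pops <- c(pops, list(population_spec(nm, contaminants[[nm]])))
  }
  pops
}

# logistic gradients along true time t in [0, 1]
.curve_endo <- function(t) 1 / (1 + exp((t - 0.35) / 0.08))
.curve_haem <- function(t) 1 / (1 + exp(-(t - 0.45) / 0.08))
.curve_iahc <- function(t) 1 / (1 + exp(-(t - 0.30) / 0.06))
.curve_bump <- function(t, t0, sd = 0.13) exp(-(t - t0)^2 / (2 * sd^2))

.tf_peak_times <- c(I = 0.15, II = 0.50, III = 0.85)

#' Simulate single-cell UMI count matrices
#'
#' Draws negative-binomial UMI counts whose per-gene means follow population /
#' time archetypes: a decreasing endothelial gradient and an increasing
#' haematopoietic gradient along the differentiation axis, a cluster marker
#' (*Gpr56*) high from the endothelial-to-haematopoietic transition onward and
#' absent from contaminants, contaminant-specific marker panels, three
#' Gaussian-bump transcription-factor archetypes (peaks at true time 0.15,
#' 0.5, 0.85), and static log-normal background genes.  Per-cell means are
#' scaled so the expected total equals `mean_depth` (default 12,000 unique
#' transcripts, the CEL-Seq calibration).
#'
#' @param populations List of [population_spec()]s (e.g. [scenario_e11()]).
#' @param n_genes Total number of genes (must cover the marker panels).
#' @param mean_depth Expected total UMIs per cell.
#' @param dispersion Negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`).
#' @param seed Integer seed; fixed seed gives identical output.
#' @return An `iahc_sim` list: `counts` (integer genes x cells matrix),
#'   `annotation` (per-cell data.frame: population, stage, index-sort
#'   fluorescence), and `truth` (per-cell true time and population,
#'   placeholder wIAHC slots).
#' @export
simulate_cells <- function(populations, n_genes = 2000L, mean_depth = 12000,
                           dispersion = 0.3, seed = 1L) {
  if (mean_depth <= 0) stop("mean_depth must be positive")
  if (dispersion <= 0) stop("dispersion must be positive")
  panels <- marker_panels()
  special <- unlist(panels, use.names = FALSE)
  if (n_genes < length(special)) {
    stop("n_genes must be at least ", length(special),
         " to cover the marker panels")
  }
  set.seed(as.integer(seed))
  n_bg <- n_genes - length(special)
  genes <- c(special, sprintf("Gene%04d", seq_len(n_bg)))

  # static relative weights: background sums to 1, panels ride on top
  w_bg <- stats::rlnorm(n_bg, meanlog = 0, sdlog = 1.2)
  w_bg <- w_bg / sum(w_bg)

  n_cells_total <- sum(vapply(populations, `[[`, integer(1), "n_cells"))
  counts <- matrix(0L, n_genes, n_cells_total, dimnames = list(genes, NULL))
  ann <- vector("list", length(populations))
  truth_time <- numeric(0)
  truth_pop <- character(0)
  cell_names <- character(0)
  col0 <- 0L

  tf_all <- c(panels$tf_I, panels$tf_II, panels$tf_III)
  tf_peak <- rep(.tf_peak_times, each = 12L)
  names(tf_peak) <- tf_all

  for (ip in seq_along(populations)) {
    pop <- populations[[ip]]
    n <- pop$n_cells
    is_cont <- pop$name %in% .contaminant_names
    if (is_cont) {
      t <- rep(NA_real_, n)
    } else {
      ctr <- if (is.na(pop$time_center)) .trajectory_centers[[pop$name]] else pop$time_center
      t <- pmin(1, pmax(0, stats::rnorm(n, ctr, pop$time_sd)))
    }
    ids <- sprintf("%s_c%03d", gsub("[^A-Za-z0-9]", "", pop$name),
                   seq_len(n) + col0)
    mu <- matrix(0, n_genes, n, dimnames = list(genes, ids))
    if (n_bg > 0) mu[seq(length(special) + 1L, n_genes), ] <- w_bg
    if (is_cont) {
      mu[panels$endothelial, ] <- 0.0002
      mu[panels$haematopoietic, ] <- 0.0002
      mu[panels$iahc, ] <- 0.00001
      mu[tf_all, ] <- 0.0001
      key <- switch(pop$name, mesenchymal = "mesenchymal",
                    `EMP-like` = "emp", subaortic = "subaortic")
      mu[panels[[key]], ] <- 0.003
      if (pop$name == "EMP-like") mu["Kit", ] <- 0.003  # c-kit+ circulating EMPs
    } else {
      mu[panels$endothelial, ] <- rep(0.004 * .curve_endo(t) + 1e-4, each = 5)
      mu[panels$haematopoietic, ] <- rep(0.004 * .curve_haem(t) + 1e-4, each = 6)
      mu[panels$iahc, ] <- 0.004 * .curve_iahc(t) + 2e-5
      mu[panels$mesenchymal, ] <- 1e-5
      mu[panels$emp, ] <- 1e-5
      mu[panels$subaortic, ] <- 1e-5
      for (g in tf_all) {
        mu[g, ] <- 0.0015 * (0.05 + .curve_bump(t, tf_peak[[g]]))
      }
    }
    if (!is.null(pop$marker_overrides)) {
      for (g in names(pop$marker_overrides)) {
        mu[g, ] <- mu[g, ] * pop$marker_overrides[[g]]
      }
    }
    mu <- sweep(mu, 2, colSums(mu), "/") * mean_depth
    x <- stats::rnbinom(length(mu), mu = as.vector(mu), size = 1 / dispersion)
    counts[, col0 + seq_len(n)] <- matrix(as.integer(x), n_genes, n)
    cell_names <- c(cell_names, ids)

    fl_cdh5 <- if (is_cont) rep(NA_real_, n) else
      1000 * .curve_endo(t) * stats::rlnorm(n, 0, 0.25)
    fl_ptprc <- if (is_cont) rep(NA_real_, n) else
      1000 * .curve_haem(t) * stats::rlnorm(n, 0, 0.25)
    fl_kit <- if (is_cont) rep(NA_real_, n) else
      800 * stats::rlnorm(n, 0, 0.15)
    ann[[ip]] <- data.frame(cell = ids, population = pop$name,
                            true_time = t,
                            fluor_CDH5 = fl_cdh5, fluor_PTPRC = fl_ptprc,
                            fluor_KIT = fl_kit, stringsAsFactors = FALSE)
    truth_time <- c(truth_time, stats::setNames(t, ids))
    truth_pop <- c(truth_pop, stats::setNames(rep(pop$name, n), ids))
    col0 <- col0 + n
  }
  colnames(counts) <- cell_names
  annotation <- do.call(rbind, ann)
  rownames(annotation) <- NULL
  truth <- structure(list(cell_time = truth_time, cell_population = truth_pop,
                          wiahc_members = list(), wiahc_side = character(0)),
                     class = "iahc_truth")
  structure(list(counts = counts, annotation = annotation, truth = truth),
            class = "iahc_sim")
}

#' @export
print.iahc_sim <- function(x, ...) {
  cat("Simulated IAHC dataset:", nrow(x$counts), "genes x",
      ncol(x$counts), "cells\n")
  print(table(x$annotation$population))
  cat("mean depth:", round(mean(colSums(x$counts))), "UMIs/cell\n")
  if (length(x$truth$wiahc_members) > 0) {
    cat(length(x$truth$wiahc_members), "wIAHC bulks with known membership\n")
  }
  invisible(x)
}

#' Simulate whole-IAHC pseudo-bulk profiles
#'
#' Each pseudo-bulk is the exact element-wise sum of the UMI counts of `n`
#' member cells drawn without replacement from the cluster-resident
#' populations, emulating mechanically picked whole clusters of known
#' constituent cell count.  Ventral/dorsal side labels are assigned with
#' identical member composition on both sides (the study design under test);
#' an optional Poisson resampling flag adds measurement noise.
#'
#' @param sim An `iahc_sim` from [simulate_cells()] (or a list with `counts`
#'   and `truth`).
#' @param n_wiahcs Number of pseudo-bulks.
#' @param size_range Integer interval of member counts (default `c(3, 30)`).
#' @param member_pops Populations members may be drawn from.
#' @param poisson_noise If `TRUE`, resample each bulk gene count as
#'   Poisson(sum) instead of the exact sum.
#' @param seed Integer seed.
#' @return An `iahc_bulks` list: `counts` (genes x bulks integer matrix),
#'   `meta` (bulk id, n, side), and the updated `truth` carrying member sets.
#' @export
simulate_wiahcs <- function(sim, n_wiahcs = 12L, size_range = c(3L, 30L),
                            member_pops = c("EHT", "preHSC-I", "preHSC-II",
                                            "progenitor"),
                            poisson_noise = FALSE, seed = 1L) {
  counts <- sim$counts
  truth <- sim$truth
  pool <- names(truth$cell_population)[truth$cell_population %in% member_pops]
  if (length(pool) < size_range[2]) {
    stop("size_range upper bound (", size_range[2],
         ") exceeds the ", length(pool), " available member cells")
  }
  if (size_range[1] < 2) stop("size_range lower bound must be >= 2")
  set.seed(as.integer(seed))
  size_pool <- seq(size_range[1], size_range[2])
  sizes <- size_pool[sample.int(length(size_pool), n_wiahcs, replace = TRUE)]
  sides <- sample(c("ventral", "dorsal"), n_wiahcs, replace = TRUE)
  ids <- sprintf("wIAHC%02d", seq_len(n_wiahcs))
  bulk <- matrix(0L, nrow(counts), n_wiahcs,
                 dimnames = list(rownames(counts), ids))
  members <- vector("list", n_wiahcs)
  names(members) <- ids
  for (i in seq_len(n_wiahcs)) {
    mem <- sample(pool, sizes[i])
    v <- as.integer(rowSums(counts[, mem, drop = FALSE]))
    if (poisson_noise) v <- as.integer(stats::rpois(length(v), v))
    bulk[, i] <- v
    members[[i]] <- mem
  }
  truth$wiahc_members <- members
  truth$wiahc_side <- stats::setNames(sides, ids)
  meta <- data.frame(wiahc = ids, n = sizes, side = sides,
                     stringsAsFactors = FALSE)
  structure(list(counts = bulk, meta = meta, truth = truth),
            class = "iahc_bulks")
}

#' @export
print.iahc_bulks <- function(x, ...) {
  cat("Simulated wIAHC bulks:", ncol(x$counts), "bulks,",
      nrow(x$counts), "genes\n")
  cat("member counts:", paste(x$meta$n, collapse = ", "), "\n")
  cat("sides:", paste(sprintf("%s=%d", names(table(x$meta$side)),
                              table(x$meta$side)), collapse = ", "), "\n")
  invisible(x)
}
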