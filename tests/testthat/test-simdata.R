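test_that("scenario presets reproduce the published population inventories", {
  e11 <- simulate_cells(scenario_e11(), seed = 1)
  expect_equal(ncol(e11$counts), 554)
  tab <- table(e11$annotation$population)
  expect_equal(unname(tab[c("non-HE", "HE", "EHT", "YS-HSPC")]),
               c(27, 45, 43, 44), ignore_attr = TRUE)

  e10 <- simulate_cells(scenario_e10(), seed = 1)
  expect_equal(ncol(e10$counts), 464)
  tab10 <- table(e10$annotation$population)
  expect_equal(unname(tab10[c("non-HE", "HE", "EHT", "YS-HSPC")]),
               c(39, 96, 116, 140), ignore_attr = TRUE)
})

test_that("simulation is deterministic under a fixed seed", {
  a <- simulate_cells(scenario_e10(), seed = 11)
  b <- simulate_cells(scenario_e10(), seed = 11)
  expect_identical(a$counts, b$counts)
  expect_identical(a$annotation, b$annotation)
  c2 <- simulate_cells(scenario_e10(), seed = 12)
  expect_false(identical(a$counts, c2$counts))
})

test_that("mean simulated depth matches the calibration within 2%", {
  sim <- simulate_cells(scenario_e11(), seed = 3)
  expect_gt(ncol(sim$counts), 500)
  m <- mean(colSums(sim$counts))
  expect_lt(abs(m - 12000) / 12000, 0.02)
})

test_that("marker gradients oppose each other across population time", {
  sim <- simulate_cells(scenario_e11(contaminants = c(mesenchymal = 30L)),
                        seed = 5)
  panels <- marker_panels()
  ann <- sim$annotation
  traj <- c("non-HE", "HE", "EHT", "preHSC-I", "preHSC-II", "progenitor")
  endo <- sapply(traj, function(p) {
    mean(sim$counts[panels$endothelial, ann$cell[ann$population == p]])
  })
  haem <- sapply(traj, function(p) {
    mean(sim$counts[panels$haematopoietic, ann$cell[ann$population == p]])
  })
  # allow tiny sampling jitter on the plateaus of the logistic curves
  expect_true(all(diff(endo) <= endo[-length(endo)] * 0.1))
  expect_true(all(diff(haem) >= -haem[-1] * 0.1))
  expect_gt(endo[1], endo[length(endo)])
  expect_gt(haem[length(haem)], haem[1])

  # cluster marker high from EHT onward, absent from contaminants
  gpr_iahc <- mean(sim$counts["Gpr56",
                              ann$cell[ann$population %in%
                                       c("EHT", "preHSC-I", "preHSC-II",
                                         "progenitor")]])
  gpr_cont <- mean(sim$counts["Gpr56",
                              ann$cell[ann$population == "mesenchymal"]])
  expect_gt(gpr_iahc, 10)
  expect_lt(gpr_cont, 1)
})

test_that("near-zero dispersion approaches the Poisson limit", {
  pop <- list(population_spec("preHSC-I", 2000, time_sd = 0))
  sim <- simulate_cells(pop, n_genes = 120, mean_depth = 12000,
                        dispersion = 1e-4, seed = 8)
  m <- rowMeans(sim$counts)
  v <- apply(sim$counts, 1, var)
  keep <- m > 5
  # Fano factor -> 1; 3-standard-error band for var/mean of Poisson at n=2000
  fano <- v[keep] / m[keep]
  se <- sqrt(2 / 2000)
  expect_true(mean(abs(fano - 1) < 3 * se) > 0.9)
  expect_lt(abs(mean(colSums(sim$counts)) - 12000) / 12000, 0.02)
})

test_that("parameter errors are raised", {
  expect_error(simulate_cells(scenario_e10(), mean_depth = -1), "mean_depth")
  expect_error(simulate_cells(scenario_e10(), dispersion = 0), "dispersion")
  expect_error(simulate_cells(scenario_e10(), n_genes = 10), "n_genes")
})

test_that("wIAHC bulks are exact sums of their member cells", {
  counts <- matrix(c(1L, 0L, 2L, 0L, 3L, 1L), 3, 2,
                   dimnames = list(c("gA", "gB", "gC"), c("c1", "c2")))
  sim <- fake_sim(counts, c("EHT", "preHSC-I"))
  b <- simulate_wiahcs(sim, n_wiahcs = 1, size_range = c(2, 2), seed = 1)
  expect_equal(unname(b$counts[, 1]), c(1, 3, 3))
  expect_setequal(b$truth$wiahc_members[[1]], c("c1", "c2"))
  expect_equal(b$meta$n, 2)

  sim2 <- simulate_cells(scenario_e10(), seed = 4)
  b2 <- simulate_wiahcs(sim2, n_wiahcs = 20, size_range = c(3, 30), seed = 2)
  for (i in seq_len(5)) {
    mem <- b2$truth$wiahc_members[[i]]
    expect_equal(b2$counts[, i],
                 rowSums(sim2$counts[, mem, drop = FALSE]),
                 ignore_attr = TRUE)
    expect_length(mem, b2$meta$n[i])
  }
  # reproducible member multisets
  b3 <- simulate_wiahcs(sim2, n_wiahcs = 20, size_range = c(3, 30), seed = 2)
  expect_identical(b2$truth$wiahc_members, b3$truth$wiahc_members)
})

test_that("ventral and dorsal bulks share the same member composition", {
  sim <- simulate_cells(scenario_e11(), seed = 14)
  b <- simulate_wiahcs(sim, n_wiahcs = 40, size_range = c(5, 25), seed = 15)
  pop <- sim$truth$cell_population
  # true pre-HSC fraction among members, grouped by assigned side
  frac <- vapply(b$truth$wiahc_members, function(mem) {
    mean(pop[mem] %in% c("preHSC-I", "preHSC-II"))
  }, numeric(1))
  side <- b$truth$wiahc_side[names(frac)]
  d <- abs(mean(frac[side == "ventral"]) - mean(frac[side == "dorsal"]))
  se <- sqrt(var(frac[side == "ventral"]) / sum(side == "ventral") +
             var(frac[side == "dorsal"]) / sum(side == "dorsal"))
  expect_lt(d, 3 * se)
})

test_that("wIAHC size_range beyond the available cells is an error", {
  counts <- matrix(1L, 3, 4, dimnames = list(c("a", "b", "c"),
                                             sprintf("c%d", 1:4)))
  sim <- fake_sim(counts, rep("EHT", 4))
  expect_error(simulate_wiahcs(sim, n_wiahcs = 1, size_range = c(3, 10)),
               "size_range")
})
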