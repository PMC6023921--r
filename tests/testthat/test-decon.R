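test_that("closed-world deconvolution recovers the full set exactly", {
  fx <- decon_fixture(10, seed = 2)
  bulk <- rowSums(fx$counts)
  dc <- deconvolve(bulk, fx$counts, 10,
                   decon_config(n_swaps = 50, n_restarts = 5, seed = 3))
  expect_true(all(abs(dc$correlation - 1) < 1e-12))
  for (mem in dc$members) expect_setequal(mem, colnames(fx$counts))
})

test_that("accepted objective sequences increase strictly under greedy", {
  fx <- decon_fixture(60, seed = 4)
  bulk <- rowSums(fx$counts[, 1:8])
  dc <- deconvolve(bulk, fx$counts, 8,
                   decon_config(n_swaps = 500, n_restarts = 10, seed = 5))
  for (tr in dc$traces) {
    expect_true(all(diff(tr) > 0))
    expect_gte(tr[length(tr)], tr[1])
  }
  expect_true(all(lengths(dc$traces) == dc$accepted + 1))
  # member sets keep exactly n distinct cells
  expect_true(all(vapply(dc$members,
                         function(m) length(unique(m)) == 8, logical(1))))
})

test_that("deconvolution is reproducible from config and seed", {
  fx <- decon_fixture(40, seed = 6)
  bulk <- rowSums(fx$counts[, 1:6])
  cfg <- decon_config(n_swaps = 300, n_restarts = 5, seed = 9)
  d1 <- deconvolve(bulk, fx$counts, 6, cfg)
  d2 <- deconvolve(bulk, fx$counts, 6, cfg)
  expect_identical(d1$members, d2$members)
  expect_identical(d1$correlation, d2$correlation)
})

test_that("a 70/30 cluster mixture is recovered within 15 points", {
  fx <- decon_fixture(200, seed = 7)
  members <- c(colnames(fx$counts)[1:7],     # 7 cluster-1 cells
               colnames(fx$counts)[101:103]) # 3 cluster-2 cells
  bulk <- rowSums(fx$counts[, members])
  dc <- deconvolve(bulk, fx$counts, 10,
                   decon_config(n_swaps = 2000, n_restarts = 30, seed = 8))
  cc <- cluster_contribution(dc, fx$cluster)
  expect_lt(abs(cc$mean[["1"]] - 0.7), 0.15)
  expect_true(all(abs(rowSums(cc$per_restart) - 1) < 1e-12))
  expect_equal(sum(cc$mean), 1, tolerance = 1e-12)
})

test_that("contribution probabilities count restarts and sum to n", {
  fx <- decon_fixture(40, seed = 10)
  bulk <- rowSums(fx$counts[, 1:5])
  dc <- deconvolve(bulk, fx$counts, 5,
                   decon_config(n_swaps = 400, n_restarts = 20, seed = 11))
  pr <- contribution_probability(dc)
  expect_true(all(pr >= 0 & pr <= 1))
  expect_equal(sum(pr), 5, tolerance = 1e-9)
  never <- setdiff(names(pr), unique(unlist(dc$members)))
  expect_true(all(pr[never] == 0))
})

test_that("cluster contribution arithmetic averages per-restart fractions", {
  res <- structure(list(
    members = list(c("a1", "a2", "a3", "b1", "b2"),
                   c("a1", "a2", "a3", "a4", "b1")),
    reference_cells = c(paste0("a", 1:4), paste0("b", 1:2)),
    n = 5L), class = "iahc_decon")
  cl <- setNames(c(rep("A", 4), rep("B", 2)), res$reference_cells)
  cc <- cluster_contribution(res, cl)
  expect_equal(unname(cc$mean), c(0.7, 0.3))
  expect_error(cluster_contribution(res, cl[-1]), "without a cluster label")
})

test_that("pseudotime density is a proper boundary-corrected density", {
  ptv <- setNames(seq(0.5, 29.5, length.out = 100), sprintf("c%03d", 1:100))
  pt <- fake_pt(ptv)

  # point mass: all probability on cells at pseudotime ~20
  pr <- setNames(rep(0, 100), names(ptv))
  pr[abs(ptv - 20) < 0.5] <- 1
  d <- pseudotime_density(pr, pt)
  expect_lt(abs(d$pseudotime[which.max(d$density)] - 20), 1)

  # uniform probabilities over a uniform spread: flat away from the edges
  pru <- setNames(rep(0.5, 100), names(ptv))
  du <- pseudotime_density(pru, pt)
  mid <- du$density[du$pseudotime > 3 & du$pseudotime < 27]
  expect_lt(max(mid) / min(mid), 1.5)

  # integral over the axis is 1 (trapezoid rule on the returned grid)
  for (dd in list(d, du)) {
    step <- diff(dd$pseudotime[1:2])
    f <- dd$density
    integral <- step * (sum(f) - (f[1] + f[length(f)]) / 2)
    expect_lt(abs(integral - 1), 1e-3)
  }

  # zero-probability cells contribute nothing: moving them changes nothing
  pr2 <- pr
  ptv2 <- ptv
  ptv2[pr2 == 0] <- 5  # relocate only zero-weight cells
  d2 <- pseudotime_density(pr2, fake_pt(ptv2))
  expect_equal(d2$density, d$density)

  expect_error(pseudotime_density(setNames(rep(0, 100), names(ptv)), pt),
               "no contributing cells")
})

test_that("bulk similarity matrices satisfy their structural contracts", {
  fx <- decon_fixture(30, seed = 12)
  b1 <- rowSums(fx$counts[, 1:5])
  b2 <- rowSums(fx$counts[, 16:20])
  b3 <- rowSums(fx$counts[, c(1:3, 16:17)])
  bulks <- cbind(w1 = b1, w2 = b2, w3 = b3, w1dup = b1)
  sim <- wiahc_similarity(bulks)
  expect_equal(sim$correlation["w1", "w1dup"], 1)
  expect_equal(sim$distance["w1", "w1dup"], 0)
  expect_true(all(diag(sim$correlation) == 1))
  expect_true(all(diag(sim$distance) == 0))
  expect_equal(sim$correlation, t(sim$correlation))
  expect_equal(sim$distance, t(sim$distance))
  # duplicates sit on adjacent leaves
  ord <- match(c("w1", "w1dup"), sim$order)
  expect_equal(abs(diff(ord)), 1)
  # hand-computed row distance
  C <- sim$correlation
  expect_equal(sim$distance["w1", "w2"],
               sqrt(sum((C["w1", ] - C["w2", ])^2)))
})
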