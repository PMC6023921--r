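# clean archetype profiles over an explicit pseudotime grid
archetype_profiles <- function(n_cells = 90, per_class = 12, noise = 0,
                               seed = 1) {
  set.seed(seed)
  ptv <- setNames(seq(0, 30, length.out = n_cells),
                  sprintf("cell%03d", seq_len(n_cells)))
  peaks <- c(I = 4.5, II = 15, III = 25.5)
  m <- do.call(rbind, lapply(names(peaks), function(cl) {
    t(sapply(seq_len(per_class), function(i) {
      5 * exp(-(ptv - peaks[[cl]])^2 / (2 * 4^2)) +
        noise * runif(n_cells)
    }))
  }))
  rownames(m) <- paste0("TF", rep(names(peaks), each = per_class),
                        rep(seq_len(per_class), 3))
  colnames(m) <- names(ptv)
  list(m = m, pt = fake_pt(ptv),
       truth = rep(c("I", "II", "III"), each = per_class))
}

test_that("smoothing equals a truncated rolling-mean oracle", {
  set.seed(3)
  m <- matrix(rpois(5 * 30, 4), 5, 30,
              dimnames = list(sprintf("g%d", 1:5), sprintf("c%02d", 1:30)))
  ptv <- setNames(sample(seq(0, 30, length.out = 30)), colnames(m))
  pt <- fake_pt(ptv)
  sm <- smooth_profiles(m, pt, window_cells = 5)
  ord <- names(ptv)[order(ptv, names(ptv))]
  for (g in rownames(m)) {
    v <- m[g, ord]
    oracle <- sapply(seq_along(v), function(i) {
      mean(v[max(1, i - 2):min(length(v), i + 2)])
    })
    expect_equal(unname(sm[g, ord]), unname(oracle))
  }
})

test_that("smoothing fixes constants and spreads impulses arithmetically", {
  n <- 11
  ptv <- setNames(seq_len(n), sprintf("c%02d", seq_len(n)))
  pt <- fake_pt(ptv)
  m <- rbind(const = rep(3, n), impulse = c(rep(0, 5), 9, rep(0, 5)))
  colnames(m) <- names(ptv)
  sm <- smooth_profiles(m, pt, window_cells = 3)
  expect_true(all(sm["const", ] == 3))
  expect_equal(unname(sm["impulse", sprintf("c%02d", 5:7)]), c(3, 3, 3))
  expect_true(all(sm["impulse", sprintf("c%02d", c(1:3, 9:11))] == 0))
})

test_that("smoothing is a variance contraction within the input range", {
  set.seed(4)
  m <- matrix(rpois(20 * 60, 6), 20, 60,
              dimnames = list(sprintf("g%d", 1:20), sprintf("c%02d", 1:60)))
  pt <- fake_pt(setNames(runif(60, 0, 30), colnames(m)))
  sm <- smooth_profiles(m, pt, window_cells = 7)
  expect_true(all(apply(sm, 1, var) <= apply(m, 1, var) + 1e-12))
  expect_true(all(sm >= apply(m, 1, min)))
  expect_true(all(sm <= apply(m, 1, max)))
  expect_error(smooth_profiles(m, pt, window_cells = 61), "window_cells")
  expect_error(smooth_profiles(m, pt, window_cells = 4), "odd")
})

test_that("TF selection applies the smoothed one-transcript rule", {
  ptv <- setNames(1:10, sprintf("c%02d", 1:10))
  pt <- fake_pt(ptv)
  m <- rbind(at1 = c(rep(1, 10)), under = rep(0.4, 10), zero = rep(0, 10))
  colnames(m) <- names(ptv)
  expect_warning(kept <- select_tfs(m, c("at1", "under", "zero", "absent")),
                 "absent")
  expect_identical(kept, "at1")

  set.seed(6)
  big <- matrix(runif(40 * 20, 0, 2), 40, 20,
                dimnames = list(sprintf("tf%02d", 1:40),
                                sprintf("c%02d", 1:20)))
  kept2 <- select_tfs(big, rownames(big))
  brute <- rownames(big)[apply(big, 1, max) >= 1]
  expect_identical(kept2, brute)
})

test_that("temporal archetypes recover their three classes exactly", {
  fx <- archetype_profiles(noise = 0.15, seed = 11)
  lab <- cluster_tf_profiles(fx$m, fx$pt, k = 3)
  expect_equal(ari(lab$cluster, fx$truth), 1.0)
  # labels I/II/III ordered by ascending mean peak time
  mp <- tapply(lab$peak, lab$cluster, mean)
  expect_true(all(diff(mp[c("I", "II", "III")]) > 0))
  # class labels line up with the generating archetypes
  expect_true(all(lab$cluster == fx$truth))
})

test_that("TF clustering is invariant to input order and handles k = 1", {
  fx <- archetype_profiles(noise = 0.15, seed = 12)
  lab1 <- cluster_tf_profiles(fx$m, fx$pt, k = 3)
  perm <- sample(nrow(fx$m))
  lab2 <- cluster_tf_profiles(fx$m[perm, ], fx$pt, k = 3)
  merged <- merge(lab1, lab2, by = "tf")
  expect_true(all(merged$cluster.x == merged$cluster.y))

  lab3 <- cluster_tf_profiles(fx$m, fx$pt, k = 1)
  expect_true(all(lab3$cluster == "I"))
})

test_that("constant TF profiles are placed by peak time and flagged", {
  fx <- archetype_profiles(noise = 0, seed = 13)
  m <- rbind(fx$m, FlatTF = rep(2, ncol(fx$m)))
  lab <- cluster_tf_profiles(m, fx$pt, k = 3)
  flat <- lab[lab$tf == "FlatTF", ]
  expect_true(flat$flagged)
  expect_true(flat$cluster %in% c("I", "II", "III"))
  expect_false(any(lab$flagged[lab$tf != "FlatTF"]))
})

test_that("network edges equal a brute-force correlation filter", {
  set.seed(14)
  m <- matrix(rnorm(20 * 50), 20, 50,
              dimnames = list(sprintf("tf%02d", 1:20), sprintf("c%02d", 1:50)))
  net <- build_network(m, threshold = 0.2)
  cm <- cor(t(m))
  brute <- which(upper.tri(cm) & abs(cm) >= 0.2, arr.ind = TRUE)
  expect_equal(nrow(net$edges), nrow(brute))
  for (i in seq_len(nrow(net$edges))) {
    expect_equal(net$edges$weight[i],
                 cm[net$edges$from[i], net$edges$to[i]])
  }
  expect_true(all(abs(net$edges$weight) <= 1))
  expect_true(all(net$edges$from != net$edges$to))

  # duplicates correlate at exactly 1; unattainable threshold empties the set
  dup <- rbind(a = m[1, ], b = m[1, ])
  net2 <- build_network(dup, threshold = 0.9)
  expect_equal(net2$edges$weight, 1)
  net3 <- build_network(m, threshold = 1.01)
  expect_equal(nrow(net3$edges), 0)

  flat <- rbind(m[1:3, ], flat = rep(1, 50))
  expect_warning(net4 <- build_network(flat, threshold = 0.1),
                 "zero-variance")
  expect_false("flat" %in% c(net4$edges$from, net4$edges$to))
  expect_true("flat" %in% net4$nodes$tf)
})

test_that("cross-stage overlap proportions are exact set computations", {
  l1 <- setNames(rep(c("I", "II"), each = 5), sprintf("tf%02d", 1:10))
  ident <- cross_stage_cluster_overlap(l1, l1)
  expect_true(all(ident$shared == 1))
  expect_true(all(abs(ident$shared + ident$only_stage1 +
                      ident$only_stage2 - 1) < 1e-12))

  l2 <- setNames(rep("I", 4), sprintf("x%02d", 1:4))
  l3 <- setNames(rep("I", 6), sprintf("y%02d", 1:6))
  disj <- cross_stage_cluster_overlap(l2, l3)
  expect_equal(disj$shared, 0)
  expect_equal(disj$only_stage1, 0.4)
  expect_equal(disj$only_stage2, 0.6)

  set.seed(15)
  r1 <- setNames(sample(c("I", "II", "III"), 100, TRUE),
                 sprintf("tf%03d", 1:100))
  r2 <- setNames(sample(c("I", "II", "III"), 80, TRUE),
                 sprintf("tf%03d", 11:90))
  out <- cross_stage_cluster_overlap(r1, r2)
  for (cl in out$cluster) {
    s1 <- names(r1)[r1 == cl]; s2 <- names(r2)[r2 == cl]
    u <- union(s1, s2)
    row <- out[out$cluster == cl, ]
    expect_equal(row$shared, length(intersect(s1, s2)) / length(u))
    expect_equal(row$only_stage1, length(setdiff(s1, s2)) / length(u))
    expect_equal(row$only_stage2, length(setdiff(s2, s1)) / length(u))
  }
})
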