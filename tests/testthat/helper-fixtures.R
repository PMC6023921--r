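# shared fixtures and small independent oracles, built in code

random_count_matrix <- function(n_genes, n_cells, seed = 1, max_count = 20) {
  set.seed(seed)
  m <- matrix(sample.int(max_count + 1, n_genes * n_cells, replace = TRUE) - 1L,
              n_genes, n_cells,
              dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                              sprintf("c%04d", seq_len(n_cells))))
  storage.mode(m) <- "integer"
  m
}

# two populations with disjoint marker panels over a shared background
two_pop_counts <- function(n_per_pop = 25, seed = 1) {
  set.seed(seed)
  n_genes <- 40
  genes <- sprintf("g%02d", seq_len(n_genes))
  mu_a <- c(rep(50, 10), rep(0.5, 10), rep(5, 20))
  mu_b <- c(rep(0.5, 10), rep(50, 10), rep(5, 20))
  draw <- function(mu, n) {
    matrix(rnbinom(n_genes * n, mu = mu, size = 5), n_genes, n)
  }
  m <- cbind(draw(mu_a, n_per_pop), draw(mu_b, n_per_pop))
  dimnames(m) <- list(genes, sprintf("cell%02d", seq_len(2 * n_per_pop)))
  storage.mode(m) <- "integer"
  list(counts = m,
       labels = rep(c("A", "B"), each = n_per_pop))
}

# adjusted Rand index, computed from the contingency-table definition
ari <- function(a, b) {
  ct <- table(a, b)
  n <- sum(ct)
  sij <- sum(choose(ct, 2))
  si <- sum(choose(rowSums(ct), 2))
  sj <- sum(choose(colSums(ct), 2))
  e <- si * sj / choose(n, 2)
  (sij - e) / ((si + sj) / 2 - e)
}

# partitions equal up to relabelling
same_partition <- function(a, b) {
  isTRUE(all.equal(ari(a, b), 1))
}

# pseudotime object over explicit values (for tests that control the axis)
fake_pt <- function(values) {
  structure(list(pt = values,
                 order = names(values)[order(values, names(values))]),
            class = "iahc_pseudotime")
}

# NB null matrix with lognormal gene means scaled to a common depth
null_nb_counts <- function(n_genes, n_cells, seed, depth = 5000,
                           dispersion = 0.3) {
  set.seed(seed)
  w <- rlnorm(n_genes, 0, 1)
  mu <- w / sum(w) * depth
  m <- matrix(rnbinom(n_genes * n_cells, mu = mu, size = 1 / dispersion),
              n_genes, n_cells,
              dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                              sprintf("c%04d", seq_len(n_cells))))
  storage.mode(m) <- "integer"
  m
}

# small reference panel at uniform depth with two planted clusters
decon_fixture <- function(n_cells = 60, depth = 2000, seed = 1) {
  set.seed(seed)
  n_genes <- 300
  wA <- rlnorm(n_genes, 0, 1); wA[1:30] <- wA[1:30] * 8
  wB <- rlnorm(n_genes, 0, 1); wB[31:60] <- wB[31:60] * 8
  half <- n_cells / 2
  draw <- function(w, n) {
    vapply(seq_len(n), function(i) {
      as.integer(rmultinom(1, depth, w))
    }, integer(n_genes))
  }
  m <- cbind(draw(wA, half), draw(wB, half))
  dimnames(m) <- list(sprintf("g%03d", seq_len(n_genes)),
                      sprintf("cell%03d", seq_len(n_cells)))
  list(counts = m,
       cluster = setNames(rep(1:2, each = half), colnames(m)))
}

# minimal simulated dataset wrapper for wIAHC construction
fake_sim <- function(counts, populations) {
  truth <- structure(list(
    cell_time = stats::setNames(rep(0.5, ncol(counts)), colnames(counts)),
    cell_population = stats::setNames(populations, colnames(counts)),
    wiahc_members = list(), wiahc_side = character(0)),
    class = "iahc_truth")
  structure(list(counts = counts, truth = truth), class = "iahc_sim")
}
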