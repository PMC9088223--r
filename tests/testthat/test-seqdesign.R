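test_that("energy tables round-trip through text and reject bad input", {
  set.seed(5)
  path <- tempfile()
  tab20 <- random_energy_table(3, AA20, p_pair = 1)
  write_energy_table(tab20, path)
  back <- read_energy_table(path)
  expect_equal(back$self, tab20$self, tolerance = 1e-9)
  for (k in names(tab20$pair))
    expect_equal(back$pair[[k]], tab20$pair[[k]], tolerance = 1e-9)
  # a self-only table returns zero for every pair lookup
  solo <- energy_table(3, AA20, self = matrix(1, 3, 20))
  expect_equal(sequence_energy(solo, "ACD"), 3)
  expect_error(read_energy_table(c("ETAB 2", "SELF 1 A 1.0", "SELF 1 A 2.0")),
               "duplicate")
  expect_error(read_energy_table(c("ETAB 2", "SELF 1 Z 1.0")), "unknown")
  expect_error(read_energy_table(c("ETAB 2", "WAT 1")), "unknown record")
})

test_that("sequence energy equals the naive double-loop evaluation", {
  expect_equal(sequence_energy(energy_table(5), "ACDEF"), 0)
  single <- energy_table(1, AA20,
                         self = matrix(seq(0.1, 2, 0.1), 1, 20))
  expect_equal(sequence_energy(single, "C"), 0.2)
  set.seed(8)
  for (rep in 1:5) {
    tab <- random_energy_table(6, AA20[1:10])
    s <- sample(AA20[1:10], 6, replace = TRUE)
    idx <- match(s, tab$alphabet)
    naive <- sum(vapply(1:6, function(i) tab$self[i, idx[i]], 1))
    for (i in 1:5) for (j in (i + 1):6) {
      k <- sprintf("%d:%d", i, j)
      if (!is.null(tab$pair[[k]])) naive <- naive + tab$pair[[k]][idx[i], idx[j]]
    }
    expect_equal(sequence_energy(tab, s), naive, tolerance = 1e-12)
  }
})

test_that("annealed sampling matches symmetry, Boltzmann weights and
           dominance limits", {
  # flat table: uniform per-position frequencies
  flat <- energy_table(3)
  ens <- sample_sequences(flat, anneal_params(n_samples = 5000, thin = 10,
                                              n_sigma_est = 2000,
                                              rng_seed = 2))
  expect_true(all(abs(ens$freqs - 0.05) < 0.02))
  expect_true(all(abs(colSums(ens$freqs) - 1) < 1e-9))
  # 2-position table: sampled joint frequencies near the exact Boltzmann
  # distribution at the selected temperature
  set.seed(13)
  tab2 <- random_energy_table(2, AA20, p_pair = 1, scale = 0.6)
  ens2 <- sample_sequences(tab2, anneal_params(n_samples = 40000, thin = 5,
                                               rng_seed = 4))
  combos <- expand.grid(a = seq_len(20), b = seq_len(20))
  e_all <- vapply(seq_len(400), function(r)
    sequence_energy(tab2, AA20[c(combos$a[r], combos$b[r])]), 1)
  w <- exp(-(e_all - min(e_all)) / ens2$t_final)
  p_exact <- w / sum(w)
  p_obs <- vapply(seq_len(400), function(r)
    mean(ens2$seqs[, 1] == combos$a[r] & ens2$seqs[, 2] == combos$b[r]), 1)
  expect_lte(sum(abs(p_exact - p_obs)) / 2, 0.05)   # total variation
  # a dominant amino acid takes over at low temperature
  dom_self <- matrix(0, 2, 20, dimnames = list(NULL, AA20))
  dom_self[1, "W"] <- -10
  dom <- energy_table(2, AA20, self = dom_self)
  ens3 <- sample_sequences(dom, anneal_params(t_grid = 0.05,
                                              n_samples = 2000,
                                              n_sigma_est = 2000,
                                              rng_seed = 6))
  expect_gt(ens3$freqs["W", 1], 0.99)
  # reproducibility
  ens3b <- sample_sequences(dom, anneal_params(t_grid = 0.05,
                                               n_samples = 2000,
                                               n_sigma_est = 2000,
                                               rng_seed = 6))
  expect_identical(ens3$seqs, ens3b$seqs)
})

test_that("conservation bits and consensus follow their closed forms", {
  inv <- matrix(0, 20, 3, dimnames = list(AA20, NULL))
  inv["G", 1] <- 1              # invariant column
  inv[, 2] <- 1 / 20            # uniform column
  inv[c("A", "G"), 3] <- 0.5    # two-state column, tie broken alphabetically
  cc <- conservation_and_consensus(inv)
  expect_equal(cc$bits[1], log2(20))
  expect_equal(cc$bits[2], 0)
  expect_equal(cc$bits[3], log2(20) - 1)
  expect_equal(cc$consensus, "GAA")
  # permutation invariance over sequences and bounds
  seqs <- c("AAG", "ACG", "AAG", "GCG")
  c1 <- conservation_and_consensus(seqs)
  c2 <- conservation_and_consensus(sample(seqs))
  expect_equal(c1$bits, c2$bits)
  expect_true(all(c1$bits >= 0 & c1$bits <= log2(20)))
})

test_that("exact optimisation matches exhaustive enumeration with and
           without the charge constraint", {
  ab6 <- c("A", "D", "G", "K", "S", "V")   # two charged letters (D, K)
  set.seed(17)
  for (rep in 1:3) {
    tab <- random_energy_table(4, ab6, p_pair = 1)
    expect_equal(optimal_sequence(tab)$energy,
                 enumerate_optimum(tab)$energy, tolerance = 1e-10)
    for (nc in 0:4) {
      got <- optimal_sequence(tab, n_charged = nc)
      want <- enumerate_optimum(tab, n_charged = nc)
      expect_equal(got$energy, want$energy, tolerance = 1e-10)
      expect_equal(sum(strsplit(got$sequence, "")[[1]] %in% c("D", "K")), nc)
    }
  }
  # no pair terms, no constraint: the per-position argmin sequence
  self <- matrix(rnorm(5 * 20), 5, 20, dimnames = list(NULL, AA20))
  solo <- energy_table(5, AA20, self = self)
  expect_equal(optimal_sequence(solo)$sequence,
               paste(AA20[apply(self, 1, which.min)], collapse = ""))
  # n_charged = 0 excludes all of R, D, E, K
  z <- optimal_sequence(random_energy_table(6, AA20, p_pair = 0.3),
                        n_charged = 0)
  expect_false(any(strsplit(z$sequence, "")[[1]] %in% c("R", "D", "E", "K")))
})

test_that("the optimum bounds sampled ensembles and shifts cancel", {
  set.seed(23)
  tab <- random_energy_table(5, AA20[1:6], p_pair = 0.6)
  opt <- optimal_sequence(tab)
  ens <- sample_sequences(tab, anneal_params(n_samples = 1000, thin = 5,
                                             n_sigma_est = 2000,
                                             rng_seed = 3))
  expect_lte(opt$energy, min(ens$energies) + 1e-9)
  # adding a constant to one position's self energies shifts every energy by
  # that constant and leaves the optimiser's choice unchanged
  tab2 <- tab
  tab2$self[2, ] <- tab2$self[2, ] + 7.5
  expect_equal(optimal_sequence(tab2)$sequence, opt$sequence)
  expect_equal(optimal_sequence(tab2)$energy, opt$energy + 7.5,
               tolerance = 1e-10)
  s <- paste(sample(AA20[1:6], 5, replace = TRUE), collapse = "")
  expect_equal(sequence_energy(tab2, s), sequence_energy(tab, s) + 7.5,
               tolerance = 1e-12)
})

test_that("sequence recovery is a masked percent identity", {
  expect_equal(recovery_metrics("ACDEF", "ACDEF"), 100)
  expect_equal(recovery_metrics("AAAA", "GGGG"), 0)
  expect_equal(recovery_metrics("ACDEFGHI", "ACAAFGAA", mask = c(1, 2, 5, 7)),
               75)
  expect_error(recovery_metrics("ACD", "AC"), "equal length")
})
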