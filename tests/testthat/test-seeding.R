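test_that("substructure search equals the brute-force window scan", {
  cx <- sheet_complex()
  db <- sheet_db()
  chains <- cx$chains["R"]
  for (central in list(c(1, 5), c(1, 15))) {
    frag <- define_fragment(chains, central, db,
                            fragment_params(n_min_matches = 3))
    got <- search_matches(frag, db, 1.0)
    want <- brute_force_matches(frag, db, 1.0)
    expect_equal(length(got), length(want))
    key <- function(src, starts) paste(src, paste(starts, collapse = ","))
    got_keys <- sort(vapply(got, function(m)
      key(m$source, vapply(m$windows, min, 1L)), ""))
    want_keys <- sort(vapply(want, function(m) key(m$source, m$starts), ""))
    expect_identical(got_keys, want_keys)
  }
})

test_that("search handles planted exact copies and incompatible geometry", {
  strand <- build_ideal_chain("strand", 8, source_id = "q")
  frag <- termseed:::new_fragment(list(strand), c(1, 4),
                                  list(termseed:::res_set(1, 3:5)))
  db_hit <- structure_db(list(strand,
                              build_ideal_chain("helix", 12, source_id = "h")))
  hits <- search_matches(frag, db_hit, 1.0)
  expect_gt(length(hits), 0)
  expect_equal(hits[[1]]$rmsd, 0, tolerance = 1e-6)
  # a pure helix database offers no matches to a strand window at 0.5 A
  db_hel <- structure_db(lapply(1:3, function(i)
    build_ideal_chain("helix", 10, source_id = paste0("h", i))))
  expect_length(search_matches(frag, db_hel, 0.5), 0)
  expect_length(search_matches(frag, structure_db(list()), 1.0), 0)
})

test_that("fragments grow greedily and shrink with stricter match demands", {
  cx <- sheet_complex()
  db <- sheet_db()
  chains <- cx$chains["R"]
  # impossible demand: only the minimal 3-residue fragment is returned
  f_min <- define_fragment(chains, c(1, 5), db,
                           fragment_params(n_min_matches = 1e6))
  expect_equal(sum(f_min$seg_len), 3)
  # a database stuffed with copies of the target lets growth reach 7
  copies <- structure_db(lapply(1:6, function(i) {
    ch <- cx$chains$R
    ch$source_id <- paste0("copy", i)
    ch
  }))
  f_max <- define_fragment(chains, c(1, 5), copies,
                           fragment_params(n_min_matches = 3))
  expect_equal(sum(f_max$seg_len), 7)
  # fragment size is monotone non-increasing in the match demand
  sizes <- vapply(c(1, 4, 1e6), function(N)
    sum(define_fragment(chains, c(1, 5), db,
                        fragment_params(n_min_matches = N))$seg_len), 1)
  expect_true(all(diff(sizes) <= 0))
})

test_that("seed extraction maps source coordinates through the match
           transform and skips isolated matches", {
  cx <- sheet_complex()
  db <- sheet_db()
  frag <- define_fragment(cx$chains["R"], c(1, 15), db,
                          fragment_params(n_min_matches = 3))
  m <- search_matches(frag, db, 1.0)[[1]]
  seeds <- extract_seeds(m, db, flank = 2, target = cx$chains["R"])
  expect_gt(length(seeds), 0)
  for (s in seeds) {
    expect_gte(nres(s$chain), 3)
    # inverse transform returns the seed exactly onto its source residues
    src <- db$chains[[m$source]]
    back <- apply_transform(s$chain, invert_transform(m$transform))
    expect_lt(max(abs(back$xyz - src$xyz[s$source_res, , , drop = FALSE])),
              1e-8)
  }
  # an entry holding nothing but the matched segment itself yields no seeds
  lone <- build_ideal_chain("strand", 3, source_id = "lone")
  db1 <- structure_db(list(lone))
  frag1 <- termseed:::new_fragment(list(lone), c(1, 2),
                                   list(termseed:::res_set(1, 1:3)))
  m1 <- search_matches(frag1, db1, 0.5)[[1]]
  expect_length(extract_seeds(m1, db1, flank = 2), 0)
})

test_that("generated seeds recover the planted peptide and never clash", {
  cx <- sheet_complex()
  seeds <- sheet_seeds()
  expect_gt(length(seeds), 0)
  pep <- cx$chains$P
  # at least one seed 3-window overlays the planted peptide almost exactly
  best <- Inf
  for (s in seeds) {
    for (st in termseed:::window_starts(s$chain, 3)) {
      w <- bb_coords(s$chain, st:(st + 2))
      for (pt in termseed:::window_starts(pep, 3)) {
        best <- min(best, window_rmsd_fixed(w, bb_coords(pep, pt:(pt + 2))))
      }
    }
  }
  expect_lte(best, 0.1)
  # no seed clashes with the target (element-aware radii, as in the pipeline)
  tgt <- bb_coords(cx$chains$R)
  tgt_el <- termseed:::bb_elements(nres(cx$chains$R))
  for (s in seeds)
    expect_false(clash_check(bb_coords(s$chain), tgt,
                             elements_a = termseed:::bb_elements(nres(s$chain)),
                             elements_b = tgt_el))
  # empty site yields no seeds
  expect_length(generate_seeds(cx$chains["R"],
                               termseed:::res_set(integer(0), integer(0)),
                               sheet_db()), 0)
})

test_that("decoys preserve counts, match the distance distribution, and are
           reproducible", {
  cx <- sheet_complex()
  seeds <- sheet_seeds()
  pool <- rep(seeds, length.out = 400)
  d1 <- generate_decoys(pool, cx$chains["R"], rng_seed = 42)
  expect_equal(length(d1), length(pool))
  expect_identical(vapply(d1, function(s) nres(s$chain), 1L),
                   vapply(pool, function(s) nres(s$chain), 1L))
  # two-sample KS statistic between real and decoy distances, by definition
  dr <- sort(vapply(pool, `[[`, 1, "distance_to_protein"))
  dd <- sort(vapply(d1, `[[`, 1, "distance_to_protein"))
  grid <- sort(c(dr, dd))
  ks <- max(abs(vapply(grid, function(x) mean(dr <= x) - mean(dd <= x), 1)))
  expect_lte(ks, 0.1)
  # decoys never clash with the target
  tgt <- bb_coords(cx$chains$R)
  tgt_el <- termseed:::bb_elements(nres(cx$chains$R))
  for (s in d1[seq(1, length(d1), by = 20)])
    expect_false(clash_check(bb_coords(s$chain), tgt,
                             elements_a = termseed:::bb_elements(nres(s$chain)),
                             elements_b = tgt_el))
  d2 <- generate_decoys(pool, cx$chains["R"], rng_seed = 42)
  expect_equal(lapply(d2, function(s) s$chain$xyz),
               lapply(d1, function(s) s$chain$xyz))
})

test_that("greedy set cover clusters seed windows in degree order", {
  base <- build_ideal_chain("strand", 5)
  identical_seeds <- lapply(1:30, function(i) as_seed(base, paste0("s", i)))
  cl <- cluster_seed_windows(identical_seeds, k = 4, stop_fraction = 0.10)
  expect_length(cl, 1)                      # one cluster covers everything
  expect_gte(nrow(cl[[1]]$members), 0.10 * 30 * 2)
  # disjoint windows: singleton clusters accumulate until 10% is reached
  apart <- lapply(1:20, function(i)
    as_seed(apply_transform(base, rigid_transform(diag(3), c(40 * i, 0, 0))),
            paste0("a", i)))
  cl2 <- cluster_seed_windows(apart, k = 4, stop_fraction = 0.10)
  expect_true(all(vapply(cl2, function(x) nrow(x$members), 1L) == 1))
  # the first representative has maximal alignment degree (brute force)
  set.seed(9)
  mixed <- c(lapply(1:6, function(i) as_seed(base, paste0("m", i))),
             apart[1:6])
  cl3 <- cluster_seed_windows(mixed, k = 4, stop_fraction = 0.05)
  ov <- brute_force_overlaps(mixed, overlap_params(window_len = 4))
  degs <- table(c(paste(ov$seed_i, ov$win_i), paste(ov$seed_j, ov$win_j)))
  rep1 <- cl3[[1]]$representative
  expect_equal(unname(degs[paste(rep1$seed, rep1$start)]), max(degs))
})
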