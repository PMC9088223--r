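test_that("overlap detection finds exact copies and nothing at long range", {
  ch <- build_ideal_chain("strand", 8)
  s1 <- as_seed(ch, "a")
  s2 <- as_seed(ch, "b")
  ov <- find_overlaps(list(s1, s2), overlap_params())
  expect_equal(nrow(ov), 8 - 4 + 1)     # every aligned 4-window
  far <- as_seed(apply_transform(ch, rigid_transform(diag(3), c(100, 0, 0))),
                 "c")
  expect_equal(nrow(find_overlaps(list(s1, far), overlap_params())), 0)
})

test_that("hash-found overlaps equal brute-force verification", {
  set.seed(21)
  seeds <- c(
    lapply(1:10, function(i) as_seed(random_backbone(7), paste0("r", i))),
    # planted near-duplicates that do overlap
    lapply(1:8, function(i) {
      ch <- build_ideal_chain("strand", 6)
      ch$xyz <- ch$xyz + array(rnorm(length(ch$xyz), 0, 0.1), dim = dim(ch$xyz))
      as_seed(ch, paste0("p", i))
    }))
  params <- overlap_params()
  expect_identical(edge_key_set(find_overlaps(seeds, params)),
                   edge_key_set(brute_force_overlaps(seeds, params)))
})

test_that("clash detection applies the scaled-radius rule strictly", {
  two <- function(d) list(matrix(c(0, 0, 0), 1), matrix(c(d, 0, 0), 1))
  p <- clash_params()                      # scale 0.7, carbon 1.7
  expect_false(clash_check(two(5)[[1]], two(5)[[2]], p))
  expect_true(clash_check(two(1)[[1]], two(1)[[2]], p))
  thr <- 0.7 * (1.7 + 1.7)
  expect_false(clash_check(two(thr)[[1]], two(thr)[[2]], p))   # strict <
  expect_true(clash_check(two(thr - 1e-6)[[1]], two(thr - 1e-6)[[2]], p))
  # unknown elements fall back to the default radius
  expect_true(clash_check(matrix(0, 1, 3), matrix(c(2.3, 0, 0), 1), p,
                          elements_a = "Zz", elements_b = "Zz"))
  expect_error(clash_check(matrix(0, 0, 3), matrix(0, 1, 3), p), "non-empty")
})

test_that("path sampling enforces the four rejection rules and tallies them", {
  # lone long seed with no overlap edges: everything rejected as no-alignment
  lone <- as_seed(build_ideal_chain("helix", 20), "lone")
  g1 <- seed_graph(list(lone), find_overlaps(list(lone), overlap_params()))
  r1 <- sample_paths(g1, n_accept = 3, rng_seed = 5, max_samples = 40)
  expect_length(r1$paths, 0)
  expect_equal(unname(r1$tally["no_alignment"]), 40L)
  expect_equal(sum(r1$tally), r1$n_sampled)
  # two short overlapping seeds can never reach 15 residues
  ch <- build_ideal_chain("strand", 6)
  short <- list(as_seed(ch, "a"), as_seed(ch, "b"))
  g2 <- seed_graph(short, find_overlaps(short, overlap_params()))
  r2 <- sample_paths(g2, n_accept = 3, rng_seed = 5, max_samples = 40)
  expect_length(r2$paths, 0)
  expect_gt(unname(r2$tally["too_short"]), 0)
  # identical accepted paths are rejected as redundant: one long seed with a
  # single short overlap partner admits very few distinct full-length walks
  long <- build_ideal_chain("helix", 15)
  dup <- list(as_seed(long, "a"), as_seed(long[1:4], "b"))
  g3 <- seed_graph(dup, find_overlaps(dup, overlap_params()))
  r3 <- sample_paths(g3, n_accept = 50, min_length = 15, rng_seed = 5,
                     max_samples = 400)
  expect_gt(unname(r3$tally["redundant"]), 0)
  # a path fused on top of the target is rejected as a clash
  tgt <- list(build_ideal_chain("strand", 16))
  ontop <- list(as_seed(tgt[[1]], "a"), as_seed(tgt[[1]], "b"))
  g4 <- seed_graph(ontop, find_overlaps(ontop, overlap_params()))
  r4 <- sample_paths(g4, n_accept = 3, min_length = 15, target = tgt,
                     rng_seed = 5, max_samples = 60)
  expect_length(r4$paths, 0)
  expect_gt(unname(r4$tally["clash"]), 0)
})

test_that("path sampling is reproducible and its accepted paths are legal", {
  seeds <- sheet_seeds()
  params <- overlap_params()
  g <- seed_graph(seeds, find_overlaps(seeds, params), params)
  r1 <- sample_paths(g, n_accept = 5, min_length = 15,
                     target = sheet_target(), rng_seed = 11)
  r2 <- sample_paths(g, n_accept = 5, min_length = 15,
                     target = sheet_target(), rng_seed = 11)
  expect_equal(lapply(r1$paths, `[[`, "nodes"),
               lapply(r2$paths, `[[`, "nodes"))
  expect_equal(sum(r1$tally) + length(r1$paths), r1$n_sampled)
  for (p in r1$paths) {
    expect_gte(p$length, 15)
    expect_true(length(p$seeds_used) >= 2 ||
                  g$seed_has_overlap[p$seeds_used])
    # junction peptide bonds are chemically plausible after fusion
    fb <- p$backbone
    cn <- vapply(seq_len(nres(fb) - 1), function(i)
      sqrt(sum((fb$xyz[i, "C", ] - fb$xyz[i + 1, "N", ])^2)), 1)
    expect_true(all(cn >= 1.25 & cn <= 1.40))
  }
})

test_that("fusion reproduces consistent fragments and averages noisy ones", {
  ch <- build_ideal_chain("helix", 10)
  topo1 <- fusion_topology(10, list(list(frag = 1, frag_res = 1:10,
                                         out_pos = 1:10)))
  f1 <- fuse(topo1, list(ch))
  expect_lt(superpose(bb_coords(f1), bb_coords(ch))$rmsd, 0.05)
  # two fragments sharing an exact 4-residue overlap
  a <- ch[1:7]; b <- ch[4:10]
  topo2 <- fusion_topology(10, list(
    list(frag = 1, frag_res = 1:7, out_pos = 1:7),
    list(frag = 2, frag_res = 1:7, out_pos = 4:10)))
  f2 <- fuse(topo2, list(a, b))
  expect_lt(superpose(bb_coords(f2), bb_coords(ch))$rmsd, 0.05)
  # noisy overlap: fused coordinates stay near the per-position mean
  set.seed(3)
  bn <- b
  bn$xyz <- bn$xyz + array(rnorm(length(bn$xyz), 0, 0.5), dim = dim(bn$xyz))
  f3 <- fuse(topo2, list(a, bn))
  for (pos in 4:7) {
    mean_xyz <- (a$xyz[pos, , ] + bn$xyz[pos - 3, , ]) / 2
    expect_lt(sqrt(mean(rowSums((f3$xyz[pos, , ] - mean_xyz)^2))), 0.6)
  }
  # uncovered non-omitted positions are a topology error
  bad <- fusion_topology(10, list(list(frag = 1, frag_res = 1:7,
                                       out_pos = 1:7)))
  expect_error(fuse(bad, list(a)), "uncovered")
  # explicitly omitted positions are dropped and flagged as a break
  omit_topo <- fusion_topology(10, list(
    list(frag = 1, frag_res = 1:4, out_pos = 1:4),
    list(frag = 1, frag_res = 7:10, out_pos = 7:10)), omit = 5:6)
  fo <- fuse(omit_topo, list(ch))
  expect_equal(nres(fo), 8)
  expect_equal(chain_breaks(fo), 4L)
})
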