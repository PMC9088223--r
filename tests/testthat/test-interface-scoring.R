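test_that("contacts per residue counts posed-backbone contacts", {
  cx <- sheet_complex()
  target <- sheet_target()
  pep <- cx$chains$P
  far <- apply_transform(pep, rigid_transform(diag(3), c(50, 0, 0)))
  expect_equal(contacts_per_residue(far, target), 0)
  cpr <- contacts_per_residue(pep, target)
  # matches the hand-assembled contact map on the same pose
  chains <- c(list(pep), target)
  cmap <- potential_contact_map(chains, termseed:::res_set(1, 1:nres(pep)),
                                all_residues(chains, 2), native_only = "b")
  expect_equal(cpr, sum(cmap$pairs$contact) / nres(pep))
  # appending a residue with no contacts strictly lowers the mean
  ext <- termseed:::concat_chains(
    list(pep, apply_transform(pep[1], rigid_transform(diag(3), c(0, 0, 60)))),
    chain_id = "P")
  expect_lt(contacts_per_residue(ext, target), cpr)
})

test_that("the TERM interface score follows its match-abundance formula", {
  cx <- sheet_complex()
  db <- sheet_db()
  target <- sheet_target()
  pep <- cx$chains$P
  sc <- term_interface_score(pep, target, db, ref_size = 40)
  # independent recomputation: contact pairs, per-pair match counts by brute
  # force, reference median from the cached reference
  chains <- c(list(pep), target)
  cmap <- potential_contact_map(chains, termseed:::res_set(1, 1:nres(pep)),
                                all_residues(chains, 2), native_only = "b")
  cp <- cmap$pairs[cmap$pairs$contact, , drop = FALSE]
  m_ref <- termseed:::pair_term_reference(db, default_rotamer_library(),
                                          1.0, 40)
  scores <- vapply(seq_len(nrow(cp)), function(r) {
    frag <- termseed:::pair_term_fragment(
      chains, c(cp$chain_a[r], cp$res_a[r]), c(cp$chain_b[r], cp$res_b[r]))
    if (is.null(frag)) return(NA_real_)
    m <- length(brute_force_matches(frag, db, 1.0))
    -log10((m + 1) / (m_ref + 1))
  }, 1)
  expect_equal(sc, mean(scores, na.rm = TRUE), tolerance = 1e-9)
  # the planted (database-supported) pose scores better than the same
  # backbone shifted off its support: shifted pair-TERMs find no matches
  n_dir <- colMeans(pep$xyz[, "CA", ]) -
    colMeans(target$R$xyz[11:20, "CA", ])
  n_dir <- 2.0 * n_dir / sqrt(sum(n_dir^2))
  shifted <- apply_transform(pep, rigid_transform(diag(3), n_dir))
  expect_gt(contacts_per_residue(shifted, target), 0)
  expect_lt(sc, term_interface_score(shifted, target, db, ref_size = 40))
  # the pair score is strictly decreasing in the match count
  f <- function(m, m_ref) -log10((m + 1) / (m_ref + 1))
  expect_true(all(diff(f(0:50, 3)) < 0))
  expect_equal(f(3, 3), 0)
  # a backbone with no contact at all is unscorable
  far <- apply_transform(pep, rigid_transform(diag(3), c(80, 0, 0)))
  expect_error(term_interface_score(far, target, db), "unscorable")
})

test_that("complete-linkage clustering matches the textbook agglomeration", {
  ch <- build_ideal_chain("helix", 8)
  same <- lapply(1:5, function(i) ch)
  cl <- cluster_backbones(same, threshold = 1.0)
  expect_equal(length(unique(cl$assignment)), 1)
  # two rigid groups far apart split at a 20 A cut
  groupB <- lapply(1:4, function(i)
    apply_transform(ch, rigid_transform(diag(3), c(50, 0, 0))))
  cl2 <- cluster_backbones(c(same, groupB), threshold = 20)
  expect_equal(length(unique(cl2$assignment)), 2)
  expect_equal(length(unique(cl2$assignment[1:5])), 1)
  # random backbones against an O(n^3) textbook oracle
  set.seed(31)
  bbs <- lapply(1:12, function(i) random_backbone(8, sigma = 0.5))
  thr <- 6
  got <- cluster_backbones(bbs, thr)
  D <- got$dist
  # naive agglomeration: merge the closest pair of clusters (complete
  # linkage) while the merge height is at most the threshold
  clusters <- as.list(seq_len(12))
  repeat {
    best <- c(NA, NA); bestd <- Inf
    if (length(clusters) < 2) break
    for (i in seq_len(length(clusters) - 1)) for (j in (i + 1):length(clusters)) {
      d <- max(D[clusters[[i]], clusters[[j]]])
      if (d < bestd) { bestd <- d; best <- c(i, j) }
    }
    if (bestd > thr) break
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  oracle <- integer(12)
  for (k in seq_along(clusters)) oracle[clusters[[k]]] <- k
  # partitions must agree up to label permutation
  expect_equal(length(unique(oracle)), length(unique(got$assignment)))
  expect_true(all(tapply(got$assignment, oracle,
                         function(v) length(unique(v))) == 1))
  # representative minimises the mean intra-cluster distance
  for (cl_id in unique(got$assignment)) {
    members <- which(got$assignment == cl_id)
    rep_ <- got$representatives[cl_id]
    means <- rowMeans(D[members, members, drop = FALSE])
    expect_equal(mean(D[rep_, members]), min(means), tolerance = 1e-12)
  }
})

test_that("design filtering applies both cutoffs and the per-cluster cap", {
  rec <- data.frame(
    design_id = sprintf("d%02d", 1:10),
    contacts_per_res = c(3.0, 2.4, 4.2, 2.6, 5.0, 2.5, 3.1, 2.45, 3.3, 2.8),
    term_score = c(0.05, -0.1, 0.1, 0.25, -0.2, 0.0, 0.15, -0.3, 0.21, 0.19),
    cluster = c(1, 1, 1, 1, 1, 1, 2, 2, 2, 2))
  out <- filter_and_select(rec)
  # survivors by hand: contacts >= 2.5 drops d02, d08; score <= 0.2 drops
  # d04 (0.25), d09 (0.21); cluster 1 passing: d01, d03, d05, d06 -> top 3 by
  # score: d05 (-0.2), d06 (0.0), d01 (0.05); cluster 2 passing: d07, d10
  expect_identical(out$design_id[out$selected],
                   c("d01", "d05", "d06", "d07", "d10"))
  expect_false(out$selected[out$design_id == "d02"])   # 2.4 < 2.5
  expect_false(out$selected[out$design_id == "d03"])   # 4th best in cluster 1
  # exactly three selected from a cluster of five passing records
  rec2 <- data.frame(design_id = sprintf("e%d", 1:5),
                     contacts_per_res = 3, term_score = seq(0.01, 0.05, 0.01),
                     cluster = 1)
  expect_equal(sum(filter_and_select(rec2)$selected), 3)
  # selection is invariant to input order
  perm <- sample(nrow(rec))
  out_p <- filter_and_select(rec[perm, ])
  expect_identical(sort(out_p$design_id[out_p$selected]),
                   sort(out$design_id[out$selected]))
})
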