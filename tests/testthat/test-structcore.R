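test_that("PDB writing and parsing round-trips coordinates", {
  ch <- build_ideal_chain("helix", 3, chain_id = "A",
                          aa = c("A", "G", "L"))
  txt <- write_pdb(ch)
  expect_equal(sum(grepl("^ATOM", strsplit(txt, "\n")[[1]])), 12)
  back <- parse_pdb(txt)
  expect_length(back, 1)
  expect_equal(nres(back[[1]]), 3)
  expect_equal(back[[1]]$aa, ch$aa)
  expect_lt(max(abs(back[[1]]$xyz - ch$xyz)), 1e-3)
  expect_error(write_pdb(list()), "non-empty")
  # residue ordering survives double-digit residue numbers
  long <- build_ideal_chain("helix", 12)
  back12 <- parse_pdb(write_pdb(long))[[1]]
  expect_identical(back12$resno, 1:12)
  expect_lt(max(abs(back12$xyz - long$xyz)), 1e-3)
  expect_length(chain_breaks(back12), 0)
})

test_that("parsing resolves altlocs by occupancy and rejects bad input", {
  ch <- build_ideal_chain("strand", 1 + 2)[1]
  base <- strsplit(write_pdb(ch), "\n")[[1]]
  atoms <- grep("^ATOM", base, value = TRUE)
  # duplicate the N atom as altlocs A (occ 0.60) and B (occ 0.40), B shifted
  altA <- sub("^(ATOM  .{10}) ", "\\1A", atoms[1])
  altA <- sub("  1\\.00", "  0.60", altA)
  altB <- sub("^(ATOM  .{10}) ", "\\1B", atoms[1])
  altB <- sub("  1\\.00", "  0.40", altB)
  old_x <- as.numeric(substr(atoms[1], 31, 38))
  altB <- paste0(substr(altB, 1, 30), sprintf("%8.3f", old_x + 5),
                 substr(altB, 39, nchar(altB)))
  txt <- paste(c(altA, altB, atoms[-1], "END"), collapse = "\n")
  parsed <- parse_pdb(txt)[[1]]
  expect_equal(parsed$xyz[1, "N", 1], old_x, tolerance = 1e-3)  # A retained
  expect_error(parse_pdb("REMARK nothing here"), "ATOM")
  # duplicate atom for the same residue/altloc
  dup <- paste(c(atoms[1], atoms, "END"), collapse = "\n")
  expect_error(parse_pdb(dup), "duplicate")
})

test_that("residues missing backbone atoms are dropped, missing O rebuilt", {
  ch <- build_ideal_chain("helix", 4)
  lines <- strsplit(write_pdb(ch), "\n")[[1]]
  # drop residue 2's CA entirely, and residue 3's O
  lines <- lines[!(grepl("^ATOM", lines) &
                     substr(lines, 14, 15) == "CA" &
                     substr(lines, 23, 26) == "   2")]
  o3 <- grepl("^ATOM", lines) & substr(lines, 14, 14) == "O" &
    substr(lines, 23, 26) == "   3"
  lines <- lines[!o3]
  expect_warning(parse_pdb(paste(lines, collapse = "\n")), "dropped")
  parsed <- suppressWarnings(parse_pdb(paste(lines, collapse = "\n")))
  expect_equal(nres(parsed[[1]]), 3)
  expect_true(all(is.finite(parsed[[1]]$xyz)))   # O rebuilt, not NA
  # rebuilt O close to the ideal position
  expect_lt(sqrt(sum((parsed[[1]]$xyz[2, "O", ] - ch$xyz[3, "O", ])^2)), 0.3)
})

test_that("superposition recovers exact transforms and never reflects", {
  set.seed(1)
  pts <- matrix(rnorm(15), 5, 3)
  id <- superpose(pts, pts)
  expect_equal(id$rmsd, 0, tolerance = 1e-10)
  expect_equal(id$transform$R, diag(3), tolerance = 1e-8)
  th <- pi / 2
  R90 <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  moved <- pts %*% t(R90) + rep(c(3, -2, 7), each = 5)
  sp <- superpose(moved, pts)
  expect_equal(sp$rmsd, 0, tolerance = 1e-8)
  expect_equal(apply_transform(moved, sp$transform), pts, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(det(sp$transform$R), 1, tolerance = 1e-9)
  expect_error(superpose(pts, pts[1:4, ]), "equal cardinality")
})

test_that("superposed RMSD is invariant to rigid pre-transformation", {
  set.seed(7)
  for (rep in 1:5) {
    a <- matrix(rnorm(24), 8, 3)
    b <- matrix(rnorm(24), 8, 3)
    r0 <- superpose(a, b)$rmsd
    R <- random_rotation_test()
    a2 <- a %*% t(R) + rep(runif(3, -9, 9), each = 8)
    expect_equal(superpose(a2, b)$rmsd, r0, tolerance = 1e-8)
  }
})

test_that("fixed-frame window RMSD matches its definition", {
  ch <- build_ideal_chain("strand", 4)
  w <- bb_coords(ch)
  expect_equal(window_rmsd_fixed(w, w), 0)
  expect_equal(window_rmsd_fixed(w, w + rep(c(1, 0, 0), each = nrow(w))), 1.0)
  set.seed(2)
  a <- matrix(rnorm(36), 12, 3); b <- matrix(rnorm(36), 12, 3)
  naive <- sqrt(sum(vapply(seq_len(12), function(k)
    sum((a[k, ] - b[k, ])^2), 1)) / 12)
  expect_equal(window_rmsd_fixed(a, b), naive, tolerance = 1e-10)
  expect_equal(window_rmsd_fixed(a, b), window_rmsd_fixed(b, a))
  # fixed-frame RMSD always bounds the superposed RMSD from above
  expect_gte(window_rmsd_fixed(a, b), superpose(a, b)$rmsd - 1e-12)
  expect_error(window_rmsd_fixed(a, b[1:6, ]), "equal size")
})

test_that("secondary structure labels helix, strand pairing and coil", {
  h <- build_ideal_chain("helix", 12)
  ss <- assign_ss(h)
  expect_length(ss, 12)
  expect_true(all(ss[3:10] == "H"))
  one <- build_ideal_chain("strand", 3)[1]
  expect_equal(assign_ss(one), "C")
  s <- build_ideal_chain("strand", 10)
  ss_iso <- assign_ss(s)
  expect_false(any(ss_iso == "E"))   # no partner, no bridges
  cx <- sheet_complex()
  ss_pair <- assign_ss(list(cx$chains$R, cx$chains$P))
  expect_true(all(ss_pair[[2]][3:8] == "E"))
})

test_that("secondary structure is invariant to rigid-body motion", {
  cx <- sheet_complex()
  chains <- list(cx$chains$R, cx$chains$P)
  ss0 <- assign_ss(chains)
  tf <- rigid_transform(random_rotation_test(), c(11, -4, 23))
  ss1 <- assign_ss(lapply(chains, apply_transform, tf = tf))
  expect_identical(ss0, ss1)
})

test_that("relative solvent accessibility separates exposed from buried", {
  single <- build_ideal_chain("strand", 3)[2]
  rs <- relative_sasa(single)
  expect_gte(rs$rel_sasa[1], 0.95)
  expect_true(rs$surface[1])
  base <- build_ideal_chain("strand", 3)[1]
  lattice <- list()
  for (ix in -1:1) for (iy in -1:1) for (iz in -1:1)
    lattice[[length(lattice) + 1]] <-
      apply_transform(base, rigid_transform(diag(3), c(ix, iy, iz) * 4.6))
  rs2 <- relative_sasa(lattice)
  expect_lt(rs2$rel_sasa[14], 0.05)   # the (0,0,0) copy is residue 14
  expect_false(rs2$surface[14])
  # the surface set is exactly the > cutoff rule
  expect_identical(rs2$surface, rs2$rel_sasa > 0.05)
})
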