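# Synthetic structure generators: ideal secondary structures, toy
# peptide-protein complexes with known contact geometry, and planted
# miniature databases. These are first-class test substrate for the whole
# pipeline: a known binding geometry is inserted into the search database so
# that seed generation, coverage and reconstruction are fully checkable.

# place atom D given A, B, C with bond length |C-D|, angle B-C-D and dihedral
# A-B-C-D (natural extension reference frame)
nerf_place <- function(a, b, c, r, theta_deg, chi_deg) {
  theta <- theta_deg * pi / 180
  chi <- chi_deg * pi / 180
  bc <- normalize(c - b)
  n <- normalize(pracma_cross(b - a, bc))
  m <- pracma_cross(n, bc)
  d2 <- r * c(-cos(theta), sin(theta) * cos(chi), sin(theta) * sin(chi))
  c + cbind(bc, m, n) %*% d2
}

# proper rotation taking unit vector u onto unit vector v (Rodrigues)
rotation_between <- function(u, v) {
  u <- normalize(u); v <- normalize(v)
  w <- pracma_cross(u, v)
  s <- sqrt(sum(w^2)); cth <- sum(u * v)
  if (s < 1e-10) {
    if (cth > 0) return(diag(3))
    # antiparallel: rotate pi about any perpendicular axis
    perp <- normalize(pracma_cross(u, if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)))
    return(2 * outer(perp, perp) - diag(3))
  }
  K <- rbind(c(0, -w[3], w[2]), c(w[3], 0, -w[1]), c(-w[2], w[1], 0))
  diag(3) + K + K %*% K * ((1 - cth) / s^2)
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Build an ideal backbone chain
#'
#' Constructs a poly-backbone with ideal bond lengths and angles and repeating
#' dihedrals: alpha helix (phi = -57, psi = -47) or extended strand
#' (phi = -139, psi = 135), omega = 180 (trans).
#'
#' @param kind `"helix"` or `"strand"`.
#' @param n number of residues, at least 3.
#' @param chain_id,source_id identifiers for the resulting chain.
#' @param aa amino-acid sequence (default poly-alanine).
#' @return a `backbone_chain`.
#' @export
build_ideal_chain <- function(kind = c("helix", "strand"), n,
                              chain_id = "A", source_id = "ideal", aa = NULL) {
  kind <- match.arg(kind)
  if (n < 3) stop("need at least 3 residues")
  tors <- switch(kind,
                 helix = c(phi = -57, psi = -47),
                 strand = c(phi = -139, psi = 135))
  g <- IDEAL_GEOM
  xyz <- array(NA_real_, dim = c(n, 4, 3))
  # first residue seeded in a canonical pose
  xyz[1, 1, ] <- c(0, 0, 0)                                   # N
  xyz[1, 2, ] <- c(g$n_ca, 0, 0)                              # CA
  ang <- g$ang_n_ca_c * pi / 180
  xyz[1, 3, ] <- xyz[1, 2, ] + g$ca_c * c(-cos(ang), sin(ang), 0)  # C
  for (i in seq_len(n - 1)) {
    xyz[i + 1, 1, ] <- nerf_place(xyz[i, 1, ], xyz[i, 2, ], xyz[i, 3, ],
                                  g$c_n, g$ang_ca_c_n, tors["psi"])
    xyz[i + 1, 2, ] <- nerf_place(xyz[i, 2, ], xyz[i, 3, ], xyz[i + 1, 1, ],
                                  g$n_ca, g$ang_c_n_ca, 180)
    xyz[i + 1, 3, ] <- nerf_place(xyz[i, 3, ], xyz[i + 1, 1, ], xyz[i + 1, 2, ],
                                  g$ca_c, g$ang_n_ca_c, tors["phi"])
    xyz[i, 4, ] <- place_carbonyl_o(xyz[i, 1, ], xyz[i, 2, ], xyz[i, 3, ],
                                    xyz[i + 1, 1, ])
  }
  xyz[n, 4, ] <- place_carbonyl_o(xyz[n, 1, ], xyz[n, 2, ], xyz[n, 3, ])
  if (is.null(aa)) aa <- rep("A", n)
  backbone_chain(xyz, aa = aa, chain_id = chain_id, source_id = source_id)
}

# Pose a copy of `strand` next to itself so the copy forms backbone hydrogen
# bonds with the original: grid search over pairing direction side, axial
# shift and separation, maximising Kabsch-Sander H-bond count (deterministic).
# flip = TRUE gives an antiparallel partner.
pair_strand <- function(strand, flip = TRUE, chain_id = "P") {
  n <- nres(strand)
  ca <- strand$xyz[, "CA", ]
  axis <- normalize(ca[n, ] - ca[1, ])
  # carbonyl directions are roughly in-plane, alternating sides
  o_dir <- strand$xyz[, "O", ] - strand$xyz[, "C", ]
  side <- normalize(o_dir[2, ] - sum(o_dir[2, ] * axis) * axis)
  centroid <- colMeans(ca)
  best <- NULL
  for (sgn in c(1, -1)) {
    u <- sgn * side
    for (d in seq(4.0, 5.6, by = 0.2)) {
      for (s in seq(-3.5, 3.5, by = 0.5)) {
        cand <- strand
        if (flip) {
          # 180 degree rotation about u through the centroid reverses the
          # chain direction while keeping the pairing face toward the original
          R <- 2 * outer(u, u) - diag(3)
          tf <- rigid_transform(R, centroid - as.numeric(R %*% centroid))
          cand <- apply_transform(cand, tf)
        }
        tf2 <- rigid_transform(diag(3), u * d + axis * s)
        cand <- apply_transform(cand, tf2)
        cand$chain_id <- chain_id
        # steric floor: closest backbone approach must stay in the
        # hydrogen-bond range, never collapse into the partner
        dmin_all <- min(cross_dist(bb_coords(cand), bb_coords(strand)))
        if (dmin_all < 2.6) next
        hb <- backbone_hbonds(list(strand, cand))$hb
        inter <- sum(hb[seq_len(n), n + seq_len(n)]) +
          sum(hb[n + seq_len(n), seq_len(n)])
        # residues of the partner with a backbone-backbone contact
        ncontact <- sum(vapply(seq_len(n), function(i) {
          di <- min(sqrt(outer(rowSums(bb_coords(cand, i)^2), rep(1, 4 * n)) +
                           outer(rep(1, 4), rowSums(bb_coords(strand)^2)) -
                           2 * bb_coords(cand, i) %*% t(bb_coords(strand))))
          di <= 3.25
        }, TRUE))
        score <- inter + 0.5 * ncontact
        if (is.null(best) || score > best$score)
          best <- list(score = score, chain = cand, hbonds = inter,
                       n_bb_contact = ncontact)
      }
    }
  }
  best
}

#' Build a toy peptide-protein complex with known contact geometry
#'
#' Two kinds are provided. `"sheet-pair"`: the receptor is a two-strand
#' beta sheet (one chain with a flagged break) and the peptide is a third
#' strand hydrogen-bonded to the edge strand, so every peptide residue has a
#' backbone-backbone contact. `"helix-on-sheet"`: the receptor sheet carries
#' an alpha-helical peptide packed over its face at roughly 10 Angstrom axis
#' distance, so contacts are sidechain-mediated.
#'
#' @param kind complex kind.
#' @param peptide_len peptide length (receptor strands are sized to match).
#' @param noise_sigma Gaussian coordinate noise, Angstrom.
#' @param rng_seed seed used for the noise (construction itself is
#'   deterministic).
#' @return list with `chains` (receptor chain "R" then peptide chain "P"),
#'   `peptide_chain`, and `ground_truth` (the constructed inter-chain residue
#'   pairings, peptide residue vs receptor residue).
#' @export
make_toy_complex <- function(kind = c("sheet-pair", "helix-on-sheet"),
                             peptide_len = 10, noise_sigma = 0, rng_seed = 1) {
  kind <- match.arg(kind)
  n <- peptide_len
  s1 <- build_ideal_chain("strand", n, chain_id = "R", source_id = "toy")
  p1 <- pair_strand(s1, flip = TRUE, chain_id = "R")
  s2 <- p1$chain                                # second receptor strand
  if (kind == "sheet-pair") {
    # peptide pairs with the edge strand (s1) on its free side
    pep <- pair_strand(s2, flip = TRUE, chain_id = "P")$chain
    # make sure the peptide sits on the side away from s1
    if (mean_dist(pep, s1) < mean_dist(pep, s2)) {
      pep <- pair_strand(s2, flip = FALSE, chain_id = "P")$chain
    }
    pep$source_id <- "toy"
  } else {
    hel <- build_ideal_chain("helix", n, chain_id = "P", source_id = "toy")
    # place the helix axis parallel to the strands, above the sheet plane
    ca1 <- s1$xyz[, "CA", ]; ca2 <- s2$xyz[, "CA", ]
    axis <- normalize(ca1[n, ] - ca1[1, ])
    normal <- normalize(pracma_cross(axis, colMeans(ca2) - colMeans(ca1)))
    hca <- hel$xyz[, "CA", ]
    haxis <- normalize(hca[n, ] - hca[1, ])
    R <- rotation_between(haxis, axis)
    hel <- apply_transform(hel, rigid_transform(R, -as.numeric(R %*% colMeans(hca))))
    hel <- apply_transform(hel, rigid_transform(diag(3), colMeans(ca1)))
    # push along the sheet normal until the closest CA-CA distance is ~6 A
    sheet_ca <- rbind(ca1, ca2)
    for (step in 1:200) {
      d <- min(cross_dist(hel$xyz[, "CA", ], sheet_ca))
      if (d >= 6.0) break
      hel <- apply_transform(hel, rigid_transform(diag(3), normal * 0.25))
    }
    pep <- hel
    pep$chain_id <- "P"; pep$source_id <- "toy"
  }
  receptor <- concat_chains(list(s1, s2), chain_id = "R", source_id = "toy")
  if (noise_sigma > 0) {
    set.seed(rng_seed %% .Machine$integer.max)
    receptor$xyz <- receptor$xyz + array(stats::rnorm(length(receptor$xyz),
                                                      0, noise_sigma),
                                         dim = dim(receptor$xyz))
    pep$xyz <- pep$xyz + array(stats::rnorm(length(pep$xyz), 0, noise_sigma),
                               dim = dim(pep$xyz))
  }
  gt <- ground_truth_pairs(pep, receptor)
  list(chains = list(R = receptor, P = pep), peptide_chain = "P",
       ground_truth = gt)
}

mean_dist <- function(a, b) mean(cross_dist(a$xyz[, "CA", ], b$xyz[, "CA", ]))

cross_dist <- function(a, b) {
  a <- rbind(a); b <- rbind(b)
  m <- outer(rowSums(a^2), rep(1, nrow(b))) +
    outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * a %*% t(b)
  m[m < 0] <- 0
  sqrt(m)
}

# constructed inter-chain pairings: backbone-backbone pairs (<= 3.25 A) plus
# nearest-CA pairings within 7.5 A (the sidechain-mediated regime)
ground_truth_pairs <- function(pep, receptor) {
  out <- NULL
  for (i in seq_len(nres(pep))) {
    bbp <- bb_coords(pep, i)
    dmin <- vapply(seq_len(nres(receptor)), function(j)
      min(cross_dist(bbp, bb_coords(receptor, j))), 1)
    dca <- cross_dist(pep$xyz[i, "CA", , drop = TRUE],
                      receptor$xyz[, "CA", ])[1, ]
    j_bb <- which(dmin <= 3.25)
    j_near <- which(dca <= 7.5)
    js <- union(j_bb, j_near)
    if (length(js))
      out <- rbind(out, data.frame(pep_res = i, rec_res = js,
                                   backbone_backbone = js %in% j_bb))
  }
  out
}

# join chains end to end into one chain (renumbered; the junction shows up as
# a flagged chain break, which is intended)
concat_chains <- function(chains, chain_id = "A", source_id = "") {
  xyz <- do.call(abind3, lapply(chains, `[[`, "xyz"))
  backbone_chain(xyz, aa = unlist(lapply(chains, `[[`, "aa")),
                 chain_id = chain_id, source_id = source_id)
}

abind3 <- function(...) {
  parts <- list(...)
  n <- sum(vapply(parts, function(p) dim(p)[1], 1L))
  out <- array(NA_real_, dim = c(n, dim(parts[[1]])[2], dim(parts[[1]])[3]))
  at <- 0L
  for (p in parts) {
    out[at + seq_len(dim(p)[1]), , ] <- p
    at <- at + dim(p)[1]
  }
  out
}

#' Build a planted miniature structure database
#'
#' For each toy complex, a single-chain database entry is emitted that
#' concatenates the receptor and the peptide (renumbered into one chain), so
#' the binding geometry is present in the database as a genuinely
#' *tertiary* (sequence-distant) motif within a monomer. `n_copies` noisy
#' clones (Gaussian coordinate noise) and ideal-helix distractor chains are
#' added.
#'
#' @param complexes list of complexes from [make_toy_complex()].
#' @param n_copies noisy clones per complex.
#' @param noise_sigma clone coordinate noise, Angstrom.
#' @param rng_seed reproducibility seed.
#' @param n_distractors ideal-helix distractor chains.
#' @return a `structure_db`.
#' @export
make_planted_db <- function(complexes, n_copies = 3, noise_sigma = 0,
                            rng_seed = 1, n_distractors = 4) {
  set.seed(rng_seed %% .Machine$integer.max)
  entries <- list()
  for (ci in seq_along(complexes)) {
    cx <- complexes[[ci]]
    pc <- cx$peptide_chain
    parts <- c(cx$chains[setdiff(names(cx$chains), pc)], cx$chains[pc])
    planted <- concat_chains(unname(parts), chain_id = "A",
                             source_id = sprintf("planted%d", ci))
    entries[[length(entries) + 1]] <- planted
    for (k in seq_len(n_copies)) {
      clone <- planted
      if (noise_sigma > 0)
        clone$xyz <- clone$xyz + array(stats::rnorm(length(clone$xyz), 0,
                                                    noise_sigma),
                                       dim = dim(clone$xyz))
      # pose clones elsewhere so identical coordinates are not duplicated
      th <- stats::runif(1, 0, 2 * pi)
      R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
      clone <- apply_transform(clone, rigid_transform(R, stats::runif(3, 50, 150)))
      clone$source_id <- sprintf("planted%d_clone%d", ci, k)
      entries[[length(entries) + 1]] <- clone
    }
  }
  for (k in seq_len(n_distractors)) {
    h <- build_ideal_chain("helix", 14 + (k %% 4),
                           source_id = sprintf("distractor%d", k))
    h <- apply_transform(h, rigid_transform(diag(3), c(200 + 30 * k, 0, 0)))
    entries[[length(entries) + 1]] <- h
  }
  structure_db(entries)
}
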