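# Structure I/O and backbone geometry: chains of N/CA/C/O residues, rigid
# superposition, fixed-frame RMSD, secondary structure, solvent accessibility.

BB_ATOMS <- c("N", "CA", "C", "O")

# ideal backbone geometry (Engh & Huber averages), Angstrom / degrees
IDEAL_GEOM <- list(
  n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
  ang_n_ca_c = 111.0, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
  ang_ca_c_o = 120.8, ang_o_c_n = 123.0
)

#' Construct a backbone chain
#'
#' A backbone chain is the universal currency of substructure search, overlap
#' detection and fusion: an ordered run of residues, each carrying the four
#' backbone heavy atoms N, CA, C, O.
#'
#' @param xyz numeric array `n x 4 x 3`; second dimension ordered N, CA, C, O.
#' @param aa character vector of one-letter amino-acid codes (`"X"` allowed).
#' @param chain_id single chain identifier.
#' @param source_id identifier of the originating structure.
#' @param resno original residue numbers (metadata only; internal indexing is
#'   1..n and contiguous).
#' @param ins insertion codes, `""` if none.
#' @param bfac per-residue mean B-factor over backbone atoms.
#' @return An object of class `backbone_chain`.
#' @export
backbone_chain <- function(xyz, aa = NULL, chain_id = "A", source_id = "",
                           resno = NULL, ins = NULL, bfac = NULL) {
  stopifnot(length(dim(xyz)) == 3L, dim(xyz)[2] == 4L, dim(xyz)[3] == 3L)
  n <- dim(xyz)[1]
  if (is.null(aa)) aa <- rep("X", n)
  if (is.null(resno)) resno <- seq_len(n)
  if (is.null(ins)) ins <- rep("", n)
  if (is.null(bfac)) bfac <- rep(0, n)
  stopifnot(length(aa) == n, length(resno) == n, length(bfac) == n)
  dimnames(xyz) <- list(NULL, BB_ATOMS, c("x", "y", "z"))
  structure(list(xyz = xyz, aa = aa, chain_id = chain_id,
                 source_id = source_id, resno = as.integer(resno),
                 ins = ins, bfac = bfac),
            class = "backbone_chain")
}

#' Number of residues in a chain
#' @param chain a `backbone_chain`.
#' @export
nres <- function(chain) dim(chain$xyz)[1]

#' @export
print.backbone_chain <- function(x, ...) {
  brk <- chain_breaks(x)
  cat(sprintf("<backbone_chain> %s/%s: %d residues%s\n",
              x$source_id, x$chain_id, nres(x),
              if (length(brk)) sprintf(" (%d chain breaks)", length(brk)) else ""))
  invisible(x)
}

#' @export
`[.backbone_chain` <- function(x, i) {
  backbone_chain(x$xyz[i, , , drop = FALSE], aa = x$aa[i],
                 chain_id = x$chain_id, source_id = x$source_id,
                 resno = x$resno[i], ins = x$ins[i], bfac = x$bfac[i])
}

#' Flatten residue windows to an atom coordinate matrix
#'
#' @param chain a `backbone_chain`.
#' @param idx residue indices (default all).
#' @param atoms which backbone atoms, in order.
#' @return numeric matrix with `length(atoms) * length(idx)` rows, grouped by
#'   residue.
#' @export
bb_coords <- function(chain, idx = seq_len(nres(chain)), atoms = BB_ATOMS) {
  sub <- chain$xyz[idx, atoms, , drop = FALSE]
  # rows: residue-major, atom within residue
  m <- matrix(aperm(sub, c(2, 1, 3)), ncol = 3)
  colnames(m) <- c("x", "y", "z")
  m
}

#' Indices after which the chain is broken
#'
#' A break is flagged between residue i and i+1 when the C(i)-N(i+1) distance
#' exceeds 2.0 Angstrom.
#' @param chain a `backbone_chain`.
#' @export
chain_breaks <- function(chain) {
  n <- nres(chain)
  if (n < 2) return(integer(0))
  c_xyz <- chain$xyz[-n, "C", , drop = TRUE]
  n_xyz <- chain$xyz[-1, "N", , drop = TRUE]
  if (n == 2) { c_xyz <- rbind(c_xyz); n_xyz <- rbind(n_xyz) }
  d <- sqrt(rowSums((c_xyz - n_xyz)^2))
  which(d > 2.0)
}

# ---- rigid transforms -------------------------------------------------------

#' Rigid-body transform (rotation + translation)
#' @param R 3x3 rotation matrix, det +1.
#' @param t length-3 translation, Angstrom.
#' @export
rigid_transform <- function(R = diag(3), t = c(0, 0, 0)) {
  stopifnot(all(dim(R) == c(3, 3)), length(t) == 3)
  if (abs(det(R) - 1) > 1e-6)
    stop("rotation must be proper (det = +1)")
  structure(list(R = R, t = as.numeric(t)), class = "rigid_transform")
}

#' Apply a rigid transform to coordinates
#' @param xyz n x 3 matrix (or a `backbone_chain`).
#' @param tf a `rigid_transform`.
#' @export
apply_transform <- function(xyz, tf) {
  if (inherits(xyz, "backbone_chain")) {
    flat <- matrix(xyz$xyz, ncol = 3)
    out <- xyz
    out$xyz <- array(flat %*% t(tf$R) + rep(tf$t, each = nrow(flat)),
                     dim = dim(xyz$xyz), dimnames = dimnames(xyz$xyz))
    return(out)
  }
  xyz %*% t(tf$R) + rep(tf$t, each = nrow(xyz))
}

#' Invert a rigid transform
#' @param tf a `rigid_transform`.
#' @export
invert_transform <- function(tf) {
  rigid_transform(t(tf$R), -as.numeric(t(tf$R) %*% tf$t))
}

#' Optimal rigid superposition (Kabsch)
#'
#' Finds the proper rotation + translation minimising the RMSD between two
#' paired point sets; reflections are never returned.
#'
#' @param mobile,fixed n x 3 matrices, n >= 3, same n.
#' @return list with `transform` (maps mobile onto fixed) and `rmsd`.
#' @export
superpose <- function(mobile, fixed) {
  mobile <- as.matrix(mobile); fixed <- as.matrix(fixed)
  if (nrow(mobile) != nrow(fixed))
    stop("point sets must have equal cardinality")
  if (nrow(mobile) < 3) stop("need at least 3 points")
  cm <- colMeans(mobile); cf <- colMeans(fixed)
  A <- sweep(mobile, 2, cm); B <- sweep(fixed, 2, cf)
  H <- crossprod(A, B)              # 3x3 covariance
  s <- svd(H)
  if (s$d[1] < 1e-12 || s$d[2] < 1e-10)
    warning("degenerate (near-collinear) point set in superposition")
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  t_vec <- cf - as.numeric(R %*% cm)
  moved <- A %*% t(R)
  rmsd <- sqrt(max(0, mean(rowSums((moved - B)^2))))
  list(transform = rigid_transform(R, t_vec), rmsd = rmsd)
}

#' Fixed-frame RMSD between two residue windows
#'
#' Root mean squared deviation over paired atoms with no superposition: both
#' windows are taken where they sit in the laboratory frame. This is the
#' coverage criterion's distance.
#'
#' @param a,b equal-size coordinate matrices (rows paired).
#' @export
window_rmsd_fixed <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b))) stop("windows must have equal size")
  sqrt(mean(rowSums((a - b)^2)))
}

# ---- PDB I/O ----------------------------------------------------------------

AA_321 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
            GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
            MET = "M", MSE = "M", PHE = "F", PRO = "P", SER = "S", THR = "T",
            TRP = "W", TYR = "Y", VAL = "V")
AA_123 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
            E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
            M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
            Y = "TYR", V = "VAL", X = "UNK")

#' Parse PDB-format text into backbone chains
#'
#' Reads ATOM records (plus selenomethionine HETATMs, mapped to MET), resolves
#' alternate locations by highest occupancy (ties alphabetical), drops
#' residues missing N, CA or C with a warning, and rebuilds a missing O from
#' ideal geometry so every accepted residue carries all four backbone atoms.
#'
#' @param text PDB-format content (single string or character vector of lines),
#'   or a path to a PDB file.
#' @param source_id identifier stored on the returned chains.
#' @return list of `backbone_chain`, one per chain identifier.
#' @export
parse_pdb <- function(text, source_id = "") {
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text)) {
    path <- text
    if (source_id == "") source_id <- tools::file_path_sans_ext(basename(path))
  } else {
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path), add = TRUE)
    writeLines(paste(text, collapse = "\n"), path)
  }
  pdb <- try(suppressWarnings(bio3d::read.pdb(path, multi = FALSE,
                                              rm.alt = FALSE, verbose = FALSE)),
             silent = TRUE)
  if (inherits(pdb, "try-error") || is.null(pdb$atom) || nrow(pdb$atom) == 0)
    stop("no parsable ATOM records")
  at <- pdb$atom
  keep <- at$type == "ATOM" | (at$type == "HETATM" & at$resid == "MSE")
  at <- at[keep, , drop = FALSE]
  if (nrow(at) == 0) stop("no parsable ATOM records")
  at$resid[at$resid == "MSE"] <- "MET"
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  rid <- paste(at$chain, at$resno, at$insert, sep = "|")
  dup <- duplicated(paste(rid, at$elety, at$alt))
  if (any(dup)) stop("duplicate atom record for the same residue/altloc")

  # altloc: per (residue, atom name), keep highest occupancy, ties
  # alphabetical; file order is restored afterwards so residue ordering is
  # untouched
  key <- paste(rid, at$elety)
  ord <- order(key, -at$o, at$alt)
  keep <- ord[!duplicated(key[ord])]
  at <- at[sort(keep), , drop = FALSE]

  chains <- list()
  for (ch in unique(at$chain)) {
    ca <- at[at$chain == ch, , drop = FALSE]
    rkey <- paste(ca$resno, ca$insert)
    ures <- unique(rkey)
    n <- length(ures)
    xyz <- array(NA_real_, dim = c(n, 4, 3))
    aa <- character(n); resno <- integer(n); ins <- character(n); bf <- numeric(n)
    ok <- logical(n)
    for (k in seq_len(n)) {
      rr <- ca[rkey == ures[k], , drop = FALSE]
      for (j in seq_along(BB_ATOMS)) {
        hit <- which(rr$elety == BB_ATOMS[j])
        if (length(hit)) xyz[k, j, ] <- as.numeric(rr[hit[1], c("x", "y", "z")])
      }
      aa[k] <- if (rr$resid[1] %in% names(AA_321)) AA_321[[rr$resid[1]]] else "X"
      resno[k] <- rr$resno[1]; ins[k] <- rr$insert[1]
      got <- !is.na(xyz[k, , 1])
      bf[k] <- mean(rr$b[rr$elety %in% BB_ATOMS[got]], na.rm = TRUE)
      if (!is.finite(bf[k])) bf[k] <- 0
      ok[k] <- all(!is.na(xyz[k, 1:3, 1]))  # N, CA, C required
    }
    if (any(!ok))
      warning(sprintf("chain %s: dropped %d residue(s) missing backbone atoms",
                      ch, sum(!ok)))
    if (!any(ok)) next
    xyz <- xyz[ok, , , drop = FALSE]
    aa <- aa[ok]; resno <- resno[ok]; ins <- ins[ok]; bf <- bf[ok]
    # rebuild missing O from N/CA/C ideal geometry
    for (k in seq_len(dim(xyz)[1])) {
      if (is.na(xyz[k, 4, 1])) {
        n_next <- if (k < dim(xyz)[1]) xyz[k + 1, 1, ] else NULL
        xyz[k, 4, ] <- place_carbonyl_o(xyz[k, 1, ], xyz[k, 2, ], xyz[k, 3, ],
                                        n_next)
      }
    }
    chains[[ch]] <- backbone_chain(xyz, aa = aa, chain_id = ch,
                                   source_id = source_id, resno = resno,
                                   ins = ins, bfac = bf)
  }
  if (!length(chains)) stop("no chain with usable backbone residues")
  chains
}

# carbonyl O from N, CA, C (and next N when available): O in the peptide plane,
# CA-C-O angle 120.8 deg, trans to the next N.
place_carbonyl_o <- function(n, ca, c, n_next = NULL) {
  if (!is.null(n_next)) {
    u1 <- normalize(c - ca); u2 <- normalize(c - n_next)
    return(c + IDEAL_GEOM$c_o * normalize(u1 + u2))
  }
  v <- normalize(ca - c)
  w <- normalize(n - ca)
  perp <- normalize(w - sum(w * v) * v)      # in-plane, orthogonal to v
  ang <- IDEAL_GEOM$ang_ca_c_o * pi / 180
  c + IDEAL_GEOM$c_o * (cos(ang) * v - sin(ang) * perp)
}

normalize <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalize zero vector")
  v / n
}

#' Write backbone chains as PDB-format text
#'
#' @param chains a `backbone_chain` or list thereof.
#' @param path optional file path; when given, text is also written there.
#' @return PDB-format text, invisibly when `path` is given.
#' @export
write_pdb <- function(chains, path = NULL) {
  if (inherits(chains, "backbone_chain")) chains <- list(chains)
  if (!length(chains) || !all(vapply(chains, inherits, TRUE, "backbone_chain")))
    stop("need a non-empty list of backbone chains")
  lines <- character(0)
  serial <- 0L
  for (chain in chains) {
    for (k in seq_len(nres(chain))) {
      res3 <- if (chain$aa[k] %in% names(AA_123)) AA_123[[chain$aa[k]]] else "UNK"
      for (j in seq_along(BB_ATOMS)) {
        serial <- serial + 1L
        el <- substr(BB_ATOMS[j], 1, 1)
        lines <- c(lines, sprintf(
          "ATOM  %5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial %% 100000L, paste0(" ", BB_ATOMS[j]), " ", res3,
          substr(chain$chain_id, 1, 1), chain$resno[k] %% 10000L,
          substr(paste0(chain$ins[k], " "), 1, 1),
          chain$xyz[k, j, 1], chain$xyz[k, j, 2], chain$xyz[k, j, 3],
          1.00, chain$bfac[k], el))
      }
    }
    lines <- c(lines, "TER")
  }
  lines <- c(lines, "END")
  txt <- paste(lines, collapse = "\n")
  if (!is.null(path)) { writeLines(txt, path); return(invisible(txt)) }
  txt
}

# ---- secondary structure ----------------------------------------------------

# Kabsch-Sander style backbone H-bond detection over one or more chains.
# Returns an n_total x n_total logical matrix: hb[i, j] = CO(i) ... HN(j).
backbone_hbonds <- function(chains) {
  if (inherits(chains, "backbone_chain")) chains <- list(chains)
  ns <- vapply(chains, nres, 1L)
  off <- c(0L, cumsum(ns))
  n <- sum(ns)
  Nx <- matrix(NA_real_, n, 3); CAx <- Nx; Cx <- Nx; Ox <- Nx; Hx <- Nx
  chain_of <- integer(n); pos_of <- integer(n)
  for (ci in seq_along(chains)) {
    ch <- chains[[ci]]
    idx <- off[ci] + seq_len(ns[ci])
    Nx[idx, ] <- ch$xyz[, "N", ]; CAx[idx, ] <- ch$xyz[, "CA", ]
    Cx[idx, ] <- ch$xyz[, "C", ]; Ox[idx, ] <- ch$xyz[, "O", ]
    chain_of[idx] <- ci; pos_of[idx] <- seq_len(ns[ci])
    brk <- chain_breaks(ch)
    for (k in seq_len(ns[ci])) {
      if (k == 1 || (k - 1) %in% brk) next  # no amide H without preceding C
      i <- off[ci] + k
      d1 <- normalize(Nx[i, ] - Cx[i - 1, ])
      d2 <- normalize(Nx[i, ] - CAx[i, ])
      Hx[i, ] <- Nx[i, ] + 1.0 * normalize(d1 + d2)
    }
  }
  hb <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    dca <- sqrt(rowSums((CAx - rep(CAx[i, ], each = n))^2))
    cand <- which(dca < 9 & seq_len(n) != i)
    for (j in cand) {
      if (chain_of[i] == chain_of[j] && abs(pos_of[i] - pos_of[j]) < 2) next
      if (any(is.na(Hx[j, ]))) next
      d_on <- sqrt(sum((Ox[i, ] - Nx[j, ])^2))
      d_ch <- sqrt(sum((Cx[i, ] - Hx[j, ])^2))
      d_oh <- sqrt(sum((Ox[i, ] - Hx[j, ])^2))
      d_cn <- sqrt(sum((Cx[i, ] - Nx[j, ])^2))
      e <- 0.084 * 332 * (1 / d_on + 1 / d_ch - 1 / d_oh - 1 / d_cn)
      if (e < -0.5) hb[i, j] <- TRUE
    }
  }
  list(hb = hb, chain_of = chain_of, pos_of = pos_of, ns = ns, off = off)
}

#' Assign secondary-structure labels
#'
#' Labels every residue with one of H (alpha helix), G (3-10 helix), E
#' (extended strand), B (isolated bridge), T (turn) or C (coil), using a
#' hydrogen-bond rule set in the Kabsch-Sander style (amide H rebuilt from
#' backbone geometry, electrostatic bond energy < -0.5 kcal/mol, helix turns
#' and strand bridges). Residues that cannot be classified inherit the shared
#' label of their two flanking residues, else coil.
#'
#' Pass a list of chains to let inter-chain hydrogen bonds (sheet pairing)
#' count; a single chain is labelled in isolation.
#'
#' @param chains a `backbone_chain` or list of them.
#' @return character vector of labels (list input: list of vectors, one per
#'   chain).
#' @export
assign_ss <- function(chains) {
  single <- inherits(chains, "backbone_chain")
  if (single) chains <- list(chains)
  hbi <- backbone_hbonds(chains)
  hb <- hbi$hb; n <- nrow(hb)
  lab <- rep(NA_character_, n)
  same_run <- function(i, j) {            # contiguous same-chain, no break
    if (hbi$chain_of[i] != hbi$chain_of[j]) return(FALSE)
    ch <- chains[[hbi$chain_of[i]]]
    a <- min(hbi$pos_of[i], hbi$pos_of[j]); b <- max(hbi$pos_of[i], hbi$pos_of[j])
    !any(chain_breaks(ch) %in% a:(b - 1))
  }
  turn <- function(nt) {
    out <- rep(FALSE, n)
    for (i in seq_len(n)) {
      j <- i + nt
      if (j <= n && hbi$chain_of[i] == hbi$chain_of[j] &&
          hbi$pos_of[j] == hbi$pos_of[i] + nt && same_run(i, j) && hb[i, j])
        out[i] <- TRUE
    }
    out
  }
  t3 <- turn(3); t4 <- turn(4); t5 <- turn(5)
  is_H <- rep(FALSE, n); is_G <- rep(FALSE, n)
  for (i in seq_len(n - 1)) {
    if (t4[i] && i > 1 && t4[i - 1]) is_H[i:min(n, i + 3)] <- TRUE
    if (t3[i] && i > 1 && t3[i - 1]) is_G[i:min(n, i + 2)] <- TRUE
  }
  # pi-helix folded into H (alphabet has no I)
  for (i in seq_len(n - 1)) if (t5[i] && i > 1 && t5[i - 1]) is_H[i:min(n, i + 4)] <- TRUE

  # bridges
  bridge <- rep(FALSE, n)
  nonadj <- function(i, j) {
    hbi$chain_of[i] != hbi$chain_of[j] || abs(hbi$pos_of[i] - hbi$pos_of[j]) > 2
  }
  hbs <- function(i, j) i >= 1 && j >= 1 && i <= n && j <= n && hb[i, j]
  for (i in 2:max(2, n - 1)) {
    if (n < 3) break
    for (j in seq_len(n)) {
      if (!nonadj(i, j)) next
      par <- (hbs(i - 1, j) && hbs(j, i + 1)) || (hbs(j - 1, i) && hbs(i, j + 1))
      anti <- (hbs(i, j) && hbs(j, i)) || (hbs(i - 1, j + 1) && hbs(j - 1, i + 1))
      if (par || anti) { bridge[i] <- TRUE; bridge[j] <- TRUE }
    }
  }
  is_E <- rep(FALSE, n)
  # consecutive bridge residues form strands; isolated ones stay B
  r <- rle(bridge)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  for (k in seq_along(r$values)) {
    if (r$values[k] && r$lengths[k] >= 2) is_E[starts[k]:ends[k]] <- TRUE
  }
  is_T <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (t3[i]) is_T[pmin(n, i + 1):pmin(n, i + 2)] <- TRUE
    if (t4[i]) is_T[pmin(n, i + 1):pmin(n, i + 3)] <- TRUE
    if (t5[i]) is_T[pmin(n, i + 1):pmin(n, i + 4)] <- TRUE
  }
  lab[is_T] <- "T"
  lab[bridge & !is_E] <- "B"
  lab[is_G & !is_H] <- "G"
  lab[is_E] <- "E"
  lab[is_H] <- "H"
  # propagation rule for unclassified residues
  for (i in seq_len(n)) {
    if (!is.na(lab[i])) next
    l <- if (i > 1 && hbi$chain_of[i - 1] == hbi$chain_of[i]) lab[i - 1] else NA
    r2 <- if (i < n && hbi$chain_of[i + 1] == hbi$chain_of[i]) lab[i + 1] else NA
    lab[i] <- if (!is.na(l) && !is.na(r2) && l == r2) l else "C"
  }
  out <- split(lab, hbi$chain_of)
  out <- lapply(seq_along(chains), function(ci) unname(out[[as.character(ci)]]))
  if (single) out[[1]] else out
}

# ---- solvent accessibility --------------------------------------------------

# van der Waals radii by element for SASA and clash checks
ELEMENT_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20)

bb_elements <- function(n_res) rep(c("N", "C", "C", "O"), n_res)

# deterministic quasi-uniform sphere points (golden spiral)
sphere_points <- function(n) {
  k <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * k / n)
  theta <- pi * (1 + sqrt(5)) * k
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# Shrake-Rupley SASA per atom. xyz: m x 3; radii: length m.
shrake_rupley <- function(xyz, radii, probe = 1.4, n_points = 200) {
  pts <- sphere_points(n_points)
  m <- nrow(xyz)
  r_ext <- radii + probe
  area <- numeric(m)
  for (i in seq_len(m)) {
    d <- sqrt(rowSums((xyz - rep(xyz[i, ], each = m))^2))
    nb <- which(d < r_ext[i] + r_ext & seq_len(m) != i)
    p <- pts * r_ext[i]
    p <- p + rep(xyz[i, ], each = n_points)
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      dj <- rowSums((p - rep(xyz[j, ], each = n_points))^2)
      acc <- acc & dj > r_ext[j]^2
    }
    area[i] <- 4 * pi * r_ext[i]^2 * mean(acc)
  }
  area
}

.termseed_cache <- new.env(parent = emptyenv())

# reference SASA per amino acid: the backbone atoms of the central residue of
# an ideal extended Gly-X-Gly tripeptide (self-consistent for backbone-only
# structures)
sasa_reference <- function(probe = 1.4, n_points = 200) {
  key <- sprintf("sasa_ref_%g_%d", probe, n_points)
  if (!is.null(.termseed_cache[[key]])) return(.termseed_cache[[key]])
  tri <- build_ideal_chain("strand", 3)
  xyz <- bb_coords(tri)
  area <- shrake_rupley(xyz, ELEMENT_RADII[bb_elements(3)], probe, n_points)
  ref_val <- sum(area[5:8])             # central residue's four atoms
  ref <- rep(ref_val, 21)
  names(ref) <- c(names(AA_123))
  .termseed_cache[[key]] <- ref
  ref
}

#' Per-residue relative solvent accessibility
#'
#' Shrake-Rupley accessible surface area over all atoms of the supplied
#' chains, normalised per residue by a Gly-X-Gly extended-tripeptide
#' reference, clamped to [0, 1]. Residues with relative accessibility above
#' `surface_cutoff` are classified as surface.
#'
#' @param chains a `backbone_chain` or list of them (scored jointly).
#' @param probe probe radius, Angstrom.
#' @param n_points sphere sample points per atom.
#' @param surface_cutoff relative-accessibility threshold for the surface set.
#' @return data.frame with chain, residue index, `rel_sasa` and `surface`.
#' @export
relative_sasa <- function(chains, probe = 1.4, n_points = 200,
                          surface_cutoff = 0.05) {
  if (inherits(chains, "backbone_chain")) chains <- list(chains)
  ns <- vapply(chains, nres, 1L)
  xyz <- do.call(rbind, lapply(chains, bb_coords))
  radii <- ELEMENT_RADII[bb_elements(sum(ns))]
  area <- shrake_rupley(xyz, radii, probe, n_points)
  ref <- sasa_reference(probe, n_points)
  res_area <- colSums(matrix(area, nrow = 4))
  aa <- unlist(lapply(chains, `[[`, "aa"))
  ref_i <- ifelse(aa %in% names(ref), ref[aa], stats::median(ref))
  rel <- pmin(1, res_area / ref_i)
  data.frame(
    chain = rep(vapply(chains, `[[`, "", "chain_id"), ns),
    res = unlist(lapply(ns, seq_len)),
    rel_sasa = rel,
    surface = rel > surface_cutoff,
    row.names = NULL, stringsAsFactors = FALSE)
}
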