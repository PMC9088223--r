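# Backbone-only "potential contact" relations: contact degree
# (sidechain-sidechain), interference (sidechain-backbone) and
# backbone-backbone distance. These capture the potential for two residues to
# interact given only backbone coordinates, and are binarized at a single
# threshold (0.01) everywhere in the package.

CONTACT_THRESHOLD <- 0.01   # the single binarization point
BB_BB_CUTOFF <- 3.25        # backbone-backbone contact distance, Angstrom
CONTACT_DIST <- 4.5         # heavy-atom approach distance, Angstrom

CHARGED_AA <- c("R", "D", "E", "K")   # His excluded (uncharged at neutral pH)

# ---- rotamer library --------------------------------------------------------

# linear sidechain lengths (heavy atoms beyond CB) of the coarse synthetic
# library; rings are represented by reach-equivalent linear chains
SIDECHAIN_LEN <- c(A = 0, C = 1, D = 2, E = 3, F = 4, G = -1, H = 3, I = 3,
                   K = 4, L = 3, M = 3, N = 2, P = 2, Q = 3, R = 5, S = 1,
                   T = 2, V = 2, W = 5, Y = 5)

# canonical residue frame: N at the origin, CA on +x, C in the xy-plane (y>0)
canonical_backbone <- function() {
  g <- IDEAL_GEOM
  ang <- g$ang_n_ca_c * pi / 180
  list(N = c(0, 0, 0), CA = c(g$n_ca, 0, 0),
       C = c(g$n_ca, 0, 0) + g$ca_c * c(-cos(ang), sin(ang), 0))
}

#' Build the coarse synthetic rotamer library
#'
#' A deliberately coarse, backbone-independent rotamer library constructed
#' from ideal sidechain geometry: CB placed from the backbone frame, then a
#' linear chain of pseudo heavy atoms (bond 1.52 Angstrom, angle 114 degrees)
#' at common chi1/chi2 dihedral values. It is synthetic - built by this
#' generator, not derived from any published rotamer survey - and exists so
#' the contact-degree and interference definitions are computable offline;
#' [read_rotamer_library()] lets users substitute a richer library.
#'
#' @return a `rotamer_library`: per amino acid, a list of conformers
#'   (`prob`, `atoms` matrix with rownames) in the canonical frame.
#' @export
rotamer_library_synthetic <- function() {
  bb <- canonical_backbone()
  chi1_set <- c(-60, 180, 60); chi1_p <- c(0.50, 0.32, 0.18)
  chi2_set <- c(180, -60); chi2_p <- c(0.65, 0.35)
  lib <- list()
  for (aa in names(SIDECHAIN_LEN)) {
    nsc <- SIDECHAIN_LEN[[aa]]
    if (nsc < 0) {   # glycine: no sidechain
      lib[[aa]] <- list(list(prob = 1, atoms = matrix(0, 0, 3)))
      next
    }
    cb <- nerf_place(bb$C, bb$N, bb$CA, 1.53, 110.5, -122.6)
    if (nsc == 0) {
      lib[[aa]] <- list(list(prob = 1,
                             atoms = matrix(cb, 1, 3, dimnames = list("CB", NULL))))
      next
    }
    confs <- list()
    for (i1 in seq_along(chi1_set)) {
      chi2s <- if (nsc >= 2) seq_along(chi2_set) else 1L
      for (i2 in chi2s) {
        atoms <- matrix(NA_real_, nsc + 1, 3)
        rownames(atoms) <- c("CB", paste0("G", seq_len(nsc)))
        atoms[1, ] <- cb
        prev <- list(bb$N, bb$CA, cb)
        for (k in seq_len(nsc)) {
          chi <- if (k == 1) chi1_set[i1] else if (k == 2 && nsc >= 2)
            chi2_set[i2] else 180
          nxt <- nerf_place(prev[[1]], prev[[2]], prev[[3]], 1.52, 114, chi)
          atoms[k + 1, ] <- nxt
          prev <- list(prev[[2]], prev[[3]], nxt)
        }
        p <- chi1_p[i1] * (if (nsc >= 2) chi2_p[i2] else 1)
        confs[[length(confs) + 1]] <- list(prob = p, atoms = atoms)
      }
    }
    lib[[aa]] <- confs
  }
  structure(lib, class = "rotamer_library")
}

#' Write a rotamer library as a text table
#'
#' Format: tab-separated `AA conformer_id prob atom_name x y z`, coordinates
#' in the canonical frame (N at origin, CA on +x, C in the xy-plane).
#' Glycine is recorded with a single `-` atom row (empty sidechain).
#'
#' @param lib a `rotamer_library`.
#' @param path output path.
#' @export
write_rotamer_library <- function(lib, path) {
  rows <- character(0)
  for (aa in names(lib)) {
    for (ci in seq_along(lib[[aa]])) {
      conf <- lib[[aa]][[ci]]
      if (nrow(conf$atoms) == 0) {
        rows <- c(rows, sprintf("%s\t%d\t%.6f\t-\t0\t0\t0", aa, ci, conf$prob))
      } else {
        for (k in seq_len(nrow(conf$atoms))) {
          rows <- c(rows, sprintf("%s\t%d\t%.6f\t%s\t%.4f\t%.4f\t%.4f",
                                  aa, ci, conf$prob, rownames(conf$atoms)[k],
                                  conf$atoms[k, 1], conf$atoms[k, 2],
                                  conf$atoms[k, 3]))
        }
      }
    }
  }
  writeLines(rows, path)
  invisible(path)
}

#' Read a rotamer library text table
#' @param path library file (see [write_rotamer_library()] for the format).
#' @return a `rotamer_library`.
#' @export
read_rotamer_library <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                          col.names = c("aa", "conf", "prob", "atom",
                                        "x", "y", "z"))
  lib <- list()
  for (aa in unique(df$aa)) {
    sub <- df[df$aa == aa, , drop = FALSE]
    confs <- list()
    for (ci in sort(unique(sub$conf))) {
      cs <- sub[sub$conf == ci, , drop = FALSE]
      if (nrow(cs) == 1 && cs$atom[1] == "-") {
        atoms <- matrix(0, 0, 3)
      } else {
        atoms <- as.matrix(cs[, c("x", "y", "z")])
        rownames(atoms) <- cs$atom
      }
      confs[[length(confs) + 1]] <- list(prob = cs$prob[1], atoms = atoms)
    }
    tot <- sum(vapply(confs, `[[`, 1, "prob"))
    if (abs(tot - 1) > 1e-6)
      stop(sprintf("conformer probabilities for %s sum to %g, not 1", aa, tot))
    lib[[aa]] <- confs
  }
  structure(lib, class = "rotamer_library")
}

#' Default packaged rotamer library
#' @return the coarse synthetic `rotamer_library` shipped with the package.
#' @export
default_rotamer_library <- function() {
  if (!is.null(.termseed_cache$default_lib)) return(.termseed_cache$default_lib)
  path <- system.file("extdata", "rotamers_synthetic.tsv", package = "termseed")
  lib <- if (nzchar(path)) read_rotamer_library(path) else rotamer_library_synthetic()
  .termseed_cache$default_lib <- lib
  lib
}

# ---- residue references -----------------------------------------------------

# residues within a multi-chain structure are addressed as (chain index,
# residue index) pairs; sets are 2-column matrices
res_set <- function(chain, res) cbind(chain = as.integer(chain),
                                      res = as.integer(res))

all_residues <- function(chains, which_chains = seq_along(chains)) {
  do.call(rbind, lapply(which_chains, function(ci)
    res_set(ci, seq_len(nres(chains[[ci]])))))
}

res_xyz <- function(chains, ref, atom) chains[[ref[1]]]$xyz[ref[2], atom, ]
res_aa <- function(chains, ref) chains[[ref[1]]]$aa[ref[2]]

# local frame of a residue (rotation from the canonical frame + N position)
residue_frame <- function(chains, ref) {
  N <- res_xyz(chains, ref, "N"); CA <- res_xyz(chains, ref, "CA")
  C <- res_xyz(chains, ref, "C")
  e1 <- normalize(CA - N)
  v <- C - N
  e2 <- normalize(v - sum(v * e1) * e1)
  e3 <- pracma_cross(e1, e2)
  list(R = cbind(e1, e2, e3), origin = N)
}

# all sidechain atoms of the rotamer set at a residue, placed on its backbone
# frame; native restricts to the residue's own amino acid
placed_rotamers <- function(chains, ref, lib, native = FALSE) {
  fr <- residue_frame(chains, ref)
  aas <- if (native) {
    aa <- res_aa(chains, ref)
    if (!aa %in% names(lib))
      stop(sprintf("unknown amino acid '%s' with native-only rotamers", aa))
    aa
  } else names(lib)
  p_aa <- 1 / length(aas)
  atoms <- NULL; conf_id <- integer(0); probs <- numeric(0)
  id <- 0L
  for (aa in aas) {
    for (conf in lib[[aa]]) {
      id <- id + 1L
      probs[id] <- p_aa * conf$prob
      if (nrow(conf$atoms)) {
        placed <- conf$atoms %*% t(fr$R) + rep(fr$origin, each = nrow(conf$atoms))
        atoms <- rbind(atoms, placed)
        conf_id <- c(conf_id, rep(id, nrow(conf$atoms)))
      }
    }
  }
  list(atoms = atoms, conf = conf_id, probs = probs, n_conf = id,
       reach = if (is.null(atoms)) 0 else
         max(cross_dist(res_xyz(chains, ref, "CA"), atoms)))
}

# ---- contact operations -----------------------------------------------------

#' Contact degree between two residues
#'
#' Probability-weighted fraction of rotamer pairs, placed on the two backbone
#' frames, whose sidechain heavy atoms approach within the contact distance.
#' This measures the potential for a sidechain-sidechain interaction given
#' only backbone coordinates.
#'
#' @param chains structure (list of `backbone_chain`).
#' @param i,j residue references `c(chain_index, residue_index)`.
#' @param lib a `rotamer_library`.
#' @param native_only use only each residue's native amino acid.
#' @param contact_dist heavy-atom approach distance, Angstrom.
#' @return score in `[0, 1]`.
#' @export
contact_degree <- function(chains, i, j, lib = default_rotamer_library(),
                           native_only = FALSE, contact_dist = CONTACT_DIST) {
  if (all(i == j)) stop("i and j must differ")
  ri <- placed_rotamers(chains, i, lib, native_only)
  rj <- placed_rotamers(chains, j, lib, native_only)
  if (is.null(ri$atoms) || is.null(rj$atoms)) return(0)
  dca <- cross_dist(res_xyz(chains, i, "CA"), res_xyz(chains, j, "CA"))[1, 1]
  if (dca > ri$reach + rj$reach + contact_dist) return(0)
  pair_contact_degree(ri, rj, contact_dist)
}

#' Interference of residue i's sidechain with residue j's backbone
#'
#' Probability-weighted fraction of rotamers at `i` whose sidechain heavy
#' atoms approach the backbone atoms of `j` within the contact distance.
#' Directional (i to j).
#'
#' @inheritParams contact_degree
#' @return score in `[0, 1]`.
#' @export
interference <- function(chains, i, j, lib = default_rotamer_library(),
                         native_only = FALSE, contact_dist = CONTACT_DIST) {
  if (all(i == j)) stop("i and j must differ")
  ri <- placed_rotamers(chains, i, lib, native_only)
  if (is.null(ri$atoms)) return(0)
  bbj <- bb_coords(chains[[j[1]]], j[2])
  dca <- cross_dist(res_xyz(chains, i, "CA"), res_xyz(chains, j, "CA"))[1, 1]
  if (dca > ri$reach + 2.5 + contact_dist) return(0)
  close <- cross_dist(ri$atoms, bbj) <= contact_dist
  hit <- rowsum(close + 0, ri$conf)
  sum(ri$probs[as.integer(rownames(hit))] * (rowSums(hit) > 0))
}

#' Backbone-backbone contact flag
#'
#' TRUE iff any of the 16 inter-residue backbone atom pairs is within the
#' cutoff (3.25 Angstrom). Sequence-adjacent residues of the same chain
#' (separation < 2) are never flagged.
#'
#' @inheritParams contact_degree
#' @export
backbone_backbone_contact <- function(chains, i, j, cutoff = BB_BB_CUTOFF) {
  if (i[1] == j[1] && abs(i[2] - j[2]) < 2) return(FALSE)
  min(cross_dist(bb_coords(chains[[i[1]]], i[2]),
                 bb_coords(chains[[j[1]]], j[2]))) <= cutoff
}

#' Potential-contact map between two residue groups
#'
#' A pair is in contact iff contact degree >= 0.01, or interference (in
#' either direction) >= 0.01, or the backbone-backbone criterion holds.
#'
#' @param chains structure (list of `backbone_chain`).
#' @param group_a,group_b residue sets (2-column matrices `chain, res`),
#'   disjoint or identical.
#' @param lib a `rotamer_library`.
#' @param native_only `FALSE` (all amino acids everywhere), `TRUE` (native
#'   both sides), `"a"` or `"b"` (native on one side - "a" is the usual
#'   fixed-sequence protein side).
#' @param contact_dist heavy-atom approach distance.
#' @return object of class `contact_map`: data.frame `pairs` with flags and
#'   raw scores, plus `per_residue` (contacting partners in `group_b` per
#'   residue of `group_a`) and its mean `contacts_per_residue`.
#' @export
potential_contact_map <- function(chains, group_a, group_b,
                                  lib = default_rotamer_library(),
                                  native_only = FALSE,
                                  contact_dist = CONTACT_DIST,
                                  rot_cache = NULL) {
  empty <- data.frame(chain_a = integer(0), res_a = integer(0),
                      chain_b = integer(0), res_b = integer(0),
                      cd = numeric(0), intf_ab = numeric(0),
                      intf_ba = numeric(0), bb = logical(0),
                      contact = logical(0))
  if (is.null(group_a) || is.null(group_b) ||
      nrow(group_a) == 0 || nrow(group_b) == 0)
    return(new_contact_map(empty, group_a))
  nat_a <- isTRUE(native_only) || identical(native_only, "a")
  nat_b <- isTRUE(native_only) || identical(native_only, "b")
  if (is.null(rot_cache)) rot_cache <- new.env(parent = emptyenv())
  get_rot <- function(ref, native) {
    key <- sprintf("%d.%d.%d", ref[1], ref[2], native)
    if (is.null(rot_cache[[key]]))
      rot_cache[[key]] <- placed_rotamers(chains, ref, lib, native)
    rot_cache[[key]]
  }
  ca_a <- t(vapply(seq_len(nrow(group_a)), function(k)
    res_xyz(chains, group_a[k, ], "CA"), numeric(3)))
  ca_b <- t(vapply(seq_len(nrow(group_b)), function(k)
    res_xyz(chains, group_b[k, ], "CA"), numeric(3)))
  dca <- cross_dist(ca_a, ca_b)
  max_reach <- 2 * max(3 + 1.52 * max(SIDECHAIN_LEN)) + contact_dist  # generous
  rows <- list()
  for (ai in seq_len(nrow(group_a))) {
    for (bi in seq_len(nrow(group_b))) {
      a <- group_a[ai, ]; b <- group_b[bi, ]
      if (a[1] == b[1] && a[2] == b[2]) next
      if (dca[ai, bi] > max_reach) next
      bb <- backbone_backbone_contact(chains, a, b)
      cd <- pair_contact_degree(get_rot(a, nat_a), get_rot(b, nat_b),
                                contact_dist)
      iab <- rot_interference(get_rot(a, nat_a), bb_coords(chains[[b[1]]], b[2]),
                              contact_dist)
      iba <- rot_interference(get_rot(b, nat_b), bb_coords(chains[[a[1]]], a[2]),
                              contact_dist)
      contact <- bb || cd >= CONTACT_THRESHOLD || iab >= CONTACT_THRESHOLD ||
        iba >= CONTACT_THRESHOLD
      if (contact || cd > 0 || iab > 0 || iba > 0)
        rows[[length(rows) + 1]] <- data.frame(
          chain_a = a[1], res_a = a[2], chain_b = b[1], res_b = b[2],
          cd = cd, intf_ab = iab, intf_ba = iba, bb = bb, contact = contact)
    }
  }
  pairs <- if (length(rows)) do.call(rbind, rows) else empty
  rownames(pairs) <- NULL
  new_contact_map(pairs, group_a)
}

new_contact_map <- function(pairs, group_a) {
  per <- if (!is.null(group_a) && nrow(group_a)) {
    key_a <- paste(pairs$chain_a[pairs$contact], pairs$res_a[pairs$contact])
    cnt <- table(key_a)
    all_keys <- paste(group_a[, 1], group_a[, 2])
    out <- integer(length(all_keys)); names(out) <- all_keys
    out[names(cnt)] <- as.integer(cnt)
    out
  } else integer(0)
  structure(list(pairs = pairs, per_residue = per,
                 contacts_per_residue = if (length(per)) mean(per) else 0),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("<contact_map> %d contacting pairs, %.2f contacts/residue\n",
              sum(x$pairs$contact), x$contacts_per_residue))
  invisible(x)
}

# contact degree from two pre-placed rotamer sets
pair_contact_degree <- function(ri, rj, contact_dist) {
  if (is.null(ri$atoms) || is.null(rj$atoms)) return(0)
  close <- cross_dist(ri$atoms, rj$atoms) <= contact_dist
  if (!any(close)) return(0)
  m1 <- rowsum(close + 0, ri$conf)
  m2 <- t(rowsum(t(m1), rj$conf))
  pi_ <- ri$probs[as.integer(rownames(m1))]
  pj_ <- rj$probs[as.integer(colnames(m2))]
  sum(outer(pi_, pj_) * (m2 > 0))
}

rot_interference <- function(ri, bbj, contact_dist) {
  if (is.null(ri$atoms)) return(0)
  close <- cross_dist(ri$atoms, bbj) <= contact_dist
  if (!any(close)) return(0)
  hit <- rowsum(close + 0, ri$conf)
  sum(ri$probs[as.integer(rownames(hit))] * (rowSums(hit) > 0))
}
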