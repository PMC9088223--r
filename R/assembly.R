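# Seed assembly: 4-residue geometric overlap detection via spatial hashing,
# seed-graph construction, stochastic path sampling with the four rejection
# rules, and fusion of aligned fragments into one backbone.

#' Overlap criterion parameters
#'
#' Two seed windows overlap when every aligned CA pair is within
#' `max_ca_dist` and the relative rotation between every pair of aligned
#' residue frames is at most `max_frame_angle`.
#'
#' @param window_len aligned window length, residues.
#' @param max_ca_dist per-residue CA distance bound, Angstrom.
#' @param max_frame_angle per-residue frame rotation bound, degrees.
#' @param cell_size spatial-hash cell size (defaults to `max_ca_dist`, which
#'   makes the hash lossless: aligned CAs within the bound can differ by at
#'   most one cell per axis).
#' @export
overlap_params <- function(window_len = 4, max_ca_dist = 0.75,
                           max_frame_angle = 30, cell_size = max_ca_dist) {
  stopifnot(window_len >= 2, max_ca_dist > 0, max_frame_angle > 0)
  structure(list(window_len = window_len, max_ca_dist = max_ca_dist,
                 max_frame_angle = max_frame_angle, cell_size = cell_size),
            class = "overlap_params")
}

# per-residue orthonormal frame (x: CA->N, z: x cross CA->C); returns list of
# 3x3 matrices for the residues of a chain
residue_frames <- function(chain, idx) {
  lapply(idx, function(k) {
    x <- normalize(chain$xyz[k, "N", ] - chain$xyz[k, "CA", ])
    v <- chain$xyz[k, "C", ] - chain$xyz[k, "CA", ]
    z <- normalize(pracma_cross(x, v))
    y <- pracma_cross(z, x)
    cbind(x, y, z)
  })
}

rotation_angle_deg <- function(R1, R2) {
  tr <- sum(diag(crossprod(R1, R2)))
  acos(pmin(1, pmax(-1, (tr - 1) / 2))) * 180 / pi
}

#' Find geometric overlaps between seed windows
#'
#' All pairs of `window_len`-residue windows from different seeds satisfying
#' the CA-distance and frame-angle criteria, found with a spatial hash of
#' quantized window CA coordinates and then verified exactly (the hash has no
#' false negatives at `cell_size >= max_ca_dist`).
#'
#' @param seeds list of `seed`.
#' @param params an `overlap_params`.
#' @param allow_same_seed also report overlaps between windows of one seed
#'   (used by seed-binding-mode clustering; the seed graph never uses them).
#' @return data.frame with columns `seed_i, win_i, seed_j, win_j, ca_dist,
#'   angle` (one row per unordered pair, `seed_i < seed_j` or `win_i < win_j`).
#' @export
find_overlaps <- function(seeds, params = overlap_params(),
                          allow_same_seed = FALSE) {
  L <- params$window_len
  wins <- seed_windows(seeds, L)
  empty <- data.frame(seed_i = integer(0), win_i = integer(0),
                      seed_j = integer(0), win_j = integer(0),
                      ca_dist = numeric(0), angle = numeric(0))
  nW <- nrow(wins$index)
  if (nW < 2) return(empty)
  ca <- array(NA_real_, dim = c(nW, L, 3))
  for (w in seq_len(nW)) {
    ch <- seeds[[wins$index$seed[w]]]$chain
    ca[w, , ] <- ch$xyz[wins$index$start[w] + 0:(L - 1), "CA", ]
  }
  cell <- params$cell_size
  keys <- floor(ca / cell)              # nW x L x 3 integer cells
  # hash on the first aligned CA's cell; query the 27-neighbourhood
  key_str <- function(v) paste(v, collapse = ",")
  buckets <- new.env(parent = emptyenv())
  for (w in seq_len(nW)) {
    k <- key_str(keys[w, 1, ])
    buckets[[k]] <- c(buckets[[k]], w)
  }
  neigh <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  rows <- list()
  for (w in seq_len(nW)) {
    base <- keys[w, 1, ]
    cands <- integer(0)
    for (r in seq_len(nrow(neigh))) {
      hit <- buckets[[key_str(base + neigh[r, ])]]
      if (!is.null(hit)) cands <- c(cands, hit)
    }
    cands <- cands[cands > w]
    if (!length(cands)) next
    for (v in cands) {
      if (!allow_same_seed && wins$index$seed[v] == wins$index$seed[w]) next
      if (allow_same_seed && wins$index$seed[v] == wins$index$seed[w] &&
          wins$index$start[v] == wins$index$start[w]) next
      # remaining aligned cells must also be within one cell per axis
      if (any(abs(keys[v, , ] - keys[w, , ]) > 1)) next
      d <- sqrt(rowSums((ca[w, , ] - ca[v, , ])^2))
      if (any(d > params$max_ca_dist)) next
      fr_w <- residue_frames(seeds[[wins$index$seed[w]]]$chain,
                             wins$index$start[w] + 0:(L - 1))
      fr_v <- residue_frames(seeds[[wins$index$seed[v]]]$chain,
                             wins$index$start[v] + 0:(L - 1))
      angs <- vapply(seq_len(L), function(t)
        rotation_angle_deg(fr_w[[t]], fr_v[[t]]), 1)
      if (any(angs > params$max_frame_angle)) next
      rows[[length(rows) + 1]] <- data.frame(
        seed_i = wins$index$seed[w], win_i = wins$index$start[w],
        seed_j = wins$index$seed[v], win_j = wins$index$start[v],
        ca_dist = max(d), angle = max(angs))
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build the seed graph
#'
#' Nodes are seed residues; edges are chain succession within a seed and the
#' 4-residue overlap alignments between seeds.
#'
#' @param seeds list of `seed`.
#' @param overlaps edge table from [find_overlaps()].
#' @param params the `overlap_params` used.
#' @return a `seed_graph`.
#' @export
seed_graph <- function(seeds, overlaps, params = overlap_params()) {
  structure(list(seeds = seeds, overlaps = overlaps, params = params,
                 seed_has_overlap = seq_along(seeds) %in%
                   c(overlaps$seed_i, overlaps$seed_j)),
            class = "seed_graph")
}

#' @export
print.seed_graph <- function(x, ...) {
  cat(sprintf("<seed_graph> %d seeds, %d overlap edges (%.0f%% of seeds with none)\n",
              length(x$seeds), nrow(x$overlaps),
              100 * mean(!x$seed_has_overlap)))
  invisible(x)
}

#' Van der Waals clash parameters
#' @param scale radius scale factor in (0, 1].
#' @param radii per-element radii table, Angstrom.
#' @param default_radius radius for unknown elements.
#' @export
clash_params <- function(scale = 0.7, radii = ELEMENT_RADII,
                         default_radius = 1.7) {
  stopifnot(scale > 0, scale <= 1)
  structure(list(scale = scale, radii = radii,
                 default_radius = default_radius), class = "clash_params")
}

#' Check for a van der Waals clash between two atom sets
#'
#' TRUE iff any inter-set heavy-atom pair is strictly closer than
#' `scale * (r_a + r_b)`.
#'
#' @param atoms_a,atoms_b coordinate matrices.
#' @param clash a `clash_params`.
#' @param elements_a,elements_b element symbols per atom (default carbon).
#' @export
clash_check <- function(atoms_a, atoms_b, clash = clash_params(),
                        elements_a = NULL, elements_b = NULL) {
  if (!nrow(atoms_a) || !nrow(atoms_b)) stop("both atom sets must be non-empty")
  ra <- lookup_radii(elements_a %||% rep("C", nrow(atoms_a)), clash)
  rb <- lookup_radii(elements_b %||% rep("C", nrow(atoms_b)), clash)
  d <- cross_dist(atoms_a, atoms_b)
  thr <- clash$scale * outer(ra, rb, `+`)
  any(d < thr)
}

lookup_radii <- function(elements, clash) {
  r <- clash$radii[elements]
  miss <- is.na(r)
  if (any(miss)) r[miss] <- clash$default_radius
  unname(r)
}

#' Sample paths through the seed graph
#'
#' Random walks over seed residues (uniform choice among extensions, grown in
#' both directions, with stochastic stopping) are accepted iff they use at
#' least two seeds or a seed with at least one overlap edge, have at least
#' `min_length` residues, fuse without a van der Waals clash against the
#' target, and are not identical (same ordered node list) to an already
#' accepted path. Reproducible from `rng_seed`.
#'
#' @param graph a `seed_graph`.
#' @param n_accept stop after this many accepted paths.
#' @param min_length minimum residues per accepted path.
#' @param target target chains (fixed context for the clash test), or NULL.
#' @param clash a `clash_params`.
#' @param rng_seed reproducibility seed.
#' @param max_samples sampling budget.
#' @return list with `paths` (each: node list, seeds used, fused
#'   `backbone_chain`) and `tally` of rejections by cause.
#' @export
sample_paths <- function(graph, n_accept, min_length = 15, target = NULL,
                         clash = clash_params(), rng_seed = 1,
                         max_samples = 200 * n_accept) {
  set.seed(rng_seed %% .Machine$integer.max)
  seeds <- graph$seeds
  ov <- graph$overlaps
  L <- graph$params$window_len
  # jump table: at the last residue of an overlap window in one seed, the walk
  # may continue after the aligned window of the partner seed
  jump_fwd <- new.env(parent = emptyenv())   # "seed.pos" -> list of c(seed, pos)
  jump_bwd <- new.env(parent = emptyenv())
  add_jump <- function(env, s1, p1, s2, p2) {
    key <- sprintf("%d.%d", s1, p1)
    env[[key]] <- c(env[[key]], list(c(s2, p2)))
  }
  for (r in seq_len(nrow(ov))) {
    si <- ov$seed_i[r]; wi <- ov$win_i[r]
    sj <- ov$seed_j[r]; wj <- ov$win_j[r]
    add_jump(jump_fwd, si, wi + L - 1, sj, wj + L - 1)
    add_jump(jump_fwd, sj, wj + L - 1, si, wi + L - 1)
    add_jump(jump_bwd, si, wi, sj, wj)
    add_jump(jump_bwd, sj, wj, si, wi)
  }
  tally <- c(no_alignment = 0L, too_short = 0L, clash = 0L, redundant = 0L)
  accepted <- list()
  seen <- new.env(parent = emptyenv())
  target_atoms <- if (!is.null(target)) do.call(rbind, lapply(target, bb_coords))
  target_elem <- if (!is.null(target))
    unlist(lapply(target, function(ch) bb_elements(nres(ch))))
  n_sampled <- 0L
  while (length(accepted) < n_accept && n_sampled < max_samples) {
    n_sampled <- n_sampled + 1L
    s0 <- sample.int(length(seeds), 1)
    p0 <- sample.int(nres(seeds[[s0]]$chain), 1)
    nodes <- matrix(c(s0, p0), 1, 2)
    segs <- list(c(seed = s0, from = p0, to = p0))
    # forward extension
    repeat {
      cur <- nodes[nrow(nodes), ]
      moves <- list()
      if (cur[2] < nres(seeds[[cur[1]]]$chain))
        moves[[length(moves) + 1]] <- c(cur[1], cur[2] + 1, 0)
      for (j in jump_fwd[[sprintf("%d.%d", cur[1], cur[2])]] %||% list())
        if (j[2] < nres(seeds[[j[1]]]$chain))
          moves[[length(moves) + 1]] <- c(j[1], j[2] + 1, 1)
      if (!length(moves) || stats::runif(1) < 0.08) break
      mv <- moves[[sample.int(length(moves), 1)]]
      nodes <- rbind(nodes, mv[1:2])
      lastseg <- segs[[length(segs)]]
      if (mv[3] == 0 && mv[1] == lastseg["seed"]) {
        segs[[length(segs)]]["to"] <- mv[2]
      } else {
        segs[[length(segs) + 1]] <- c(seed = mv[1], from = mv[2], to = mv[2])
      }
    }
    # backward extension from the start
    repeat {
      cur <- nodes[1, ]
      moves <- list()
      if (cur[2] > 1)
        moves[[length(moves) + 1]] <- c(cur[1], cur[2] - 1, 0)
      for (j in jump_bwd[[sprintf("%d.%d", cur[1], cur[2])]] %||% list())
        if (j[2] > 1)
          moves[[length(moves) + 1]] <- c(j[1], j[2] - 1, 1)
      if (!length(moves) || stats::runif(1) < 0.08) break
      mv <- moves[[sample.int(length(moves), 1)]]
      nodes <- rbind(mv[1:2], nodes)
      firstseg <- segs[[1]]
      if (mv[3] == 0 && mv[1] == firstseg["seed"]) {
        segs[[1]]["from"] <- mv[2]
      } else {
        segs <- c(list(c(seed = mv[1], from = mv[2], to = mv[2])), segs)
      }
    }
    used <- unique(nodes[, 1])
    if (length(used) == 1 && !graph$seed_has_overlap[used]) {
      tally["no_alignment"] <- tally["no_alignment"] + 1L
      next
    }
    if (nrow(nodes) < min_length) {
      tally["too_short"] <- tally["too_short"] + 1L
      next
    }
    key <- paste(nodes[, 1], nodes[, 2], sep = ".", collapse = "|")
    if (!is.null(seen[[key]])) {
      tally["redundant"] <- tally["redundant"] + 1L
      next
    }
    topo <- path_topology(nodes, seeds, L)
    fused <- try(fuse(topo, lapply(seeds, `[[`, "chain")), silent = TRUE)
    if (inherits(fused, "try-error")) {
      tally["clash"] <- tally["clash"] + 1L   # counted as a fusion failure
      next
    }
    if (!is.null(target_atoms) &&
        clash_check(bb_coords(fused), target_atoms, clash,
                    elements_a = bb_elements(nres(fused)),
                    elements_b = target_elem)) {
      tally["clash"] <- tally["clash"] + 1L
      next
    }
    seen[[key]] <- TRUE
    accepted[[length(accepted) + 1]] <- structure(
      list(nodes = nodes, seeds_used = used, length = nrow(nodes),
           backbone = fused), class = "seed_path")
  }
  list(paths = accepted, tally = tally, n_sampled = n_sampled)
}

# fusion topology from a path's ordered node list: every output position is
# covered by the seed residue occupying it; overlap regions around jumps are
# covered by both partners (the aligned windows share output positions)
path_topology <- function(nodes, seeds, L) {
  n_pos <- nrow(nodes)
  cov <- list()
  # primary coverage
  by_seed <- split(seq_len(n_pos), nodes[, 1])
  for (s in names(by_seed)) {
    pos <- by_seed[[s]]
    cov[[length(cov) + 1]] <- list(frag = as.integer(s),
                                   frag_res = nodes[pos, 2],
                                   out_pos = pos)
  }
  # at each seed switch the L aligned residues are shared between the two
  # seeds; add the incoming/outgoing partner's aligned window as co-coverage
  # (verified geometrically, since the walk may have crossed in either
  # direction)
  add_cocov <- function(s2, res_end, out_end) {
    span_out <- (out_end - L + 1):out_end
    span_res <- (res_end - L + 1):res_end
    keep <- span_out >= 1 & span_out <= n_pos & span_res >= 1 &
      span_res <= nres(seeds[[s2]]$chain)
    if (!any(keep)) return(NULL)
    # only residues genuinely close to the primary coverage are co-averaged
    prim <- nodes[span_out[keep], , drop = FALSE]
    d <- vapply(seq_len(sum(keep)), function(q)
      sqrt(sum((seeds[[s2]]$chain$xyz[span_res[keep][q], "CA", ] -
                  seeds[[prim[q, 1]]]$chain$xyz[prim[q, 2], "CA", ])^2)), 1)
    ok <- d <= 1.0
    if (!any(ok)) return(NULL)
    list(frag = s2, frag_res = span_res[keep][ok], out_pos = span_out[keep][ok])
  }
  if (n_pos > 1) {
    for (t in seq_len(n_pos - 1)) {
      if (nodes[t, 1] != nodes[t + 1, 1]) {
        cc1 <- add_cocov(nodes[t + 1, 1], nodes[t + 1, 2] - 1, t)
        cc2 <- add_cocov(nodes[t, 1], nodes[t, 2] + L, t + L)
        if (!is.null(cc1)) cov[[length(cov) + 1]] <- cc1
        if (!is.null(cc2)) cov[[length(cov) + 1]] <- cc2
      }
    }
  }
  fusion_topology(n_pos, cov)
}

#' Fusion topology
#'
#' @param n_pos number of output positions.
#' @param coverage list of fragment alignments: each `list(frag, frag_res,
#'   out_pos)` maps residues of fragment `frag` onto output positions.
#' @param omit output positions deliberately left uncovered (these are
#'   dropped from the fused chain).
#' @export
fusion_topology <- function(n_pos, coverage, omit = integer(0)) {
  structure(list(n_pos = n_pos, coverage = coverage, omit = as.integer(omit)),
            class = "fusion_topology")
}

# equilibrium distances for the harmonic network, derived from ideal geometry
fuse_targets <- function() {
  if (!is.null(.termseed_cache$fuse_targets)) return(.termseed_cache$fuse_targets)
  g <- IDEAL_GEOM
  d13 <- function(r1, r2, ang) sqrt(r1^2 + r2^2 - 2 * r1 * r2 * cos(ang * pi / 180))
  # omega-dependent 1-4 distances measured on an ideal trans dipeptide
  dip <- build_ideal_chain("strand", 3)
  ca_ca <- sqrt(sum((dip$xyz[1, "CA", ] - dip$xyz[2, "CA", ])^2))
  o_ca <- sqrt(sum((dip$xyz[1, "O", ] - dip$xyz[2, "CA", ])^2))
  out <- list(
    intra = list(c("N", "CA", g$n_ca), c("CA", "C", g$ca_c),
                 c("C", "O", g$c_o),
                 c("N", "C", d13(g$n_ca, g$ca_c, g$ang_n_ca_c)),
                 c("CA", "O", d13(g$ca_c, g$c_o, g$ang_ca_c_o))),
    inter = list(c("C", "N", g$c_n),
                 c("CA", "N", d13(g$ca_c, g$c_n, g$ang_ca_c_n)),
                 c("O", "N", d13(g$c_o, g$c_n, g$ang_o_c_n)),
                 c("C", "CA", d13(g$c_n, g$n_ca, g$ang_c_n_ca)),
                 c("CA", "CA", ca_ca),       # trans-omega surrogates
                 c("O", "CA", o_ca)))
  .termseed_cache$fuse_targets <- out
  out
}

#' Fuse aligned fragments into one backbone
#'
#' Initial coordinates are the per-atom unweighted mean over the fragments
#' covering each output position; the chain is then refined by minimising a
#' harmonic network (bond lengths, bond angles and trans-omega planarity
#' encoded as their equivalent 1-3 / 1-4 atom distances) plus a restraint to
#' the initial coordinates, using L-BFGS with closed-form gradients.
#'
#' @param topology a `fusion_topology`.
#' @param fragments list of `backbone_chain` indexed by the topology.
#' @param restraint_weight weight of the initial-coordinate restraint.
#' @param maxit optimiser iteration cap.
#' @return fused `backbone_chain` (omitted positions dropped; junctions at
#'   omissions appear as flagged chain breaks).
#' @export
fuse <- function(topology, fragments, restraint_weight = 0.05, maxit = 500) {
  n_pos <- topology$n_pos
  keep <- setdiff(seq_len(n_pos), topology$omit)
  acc <- array(0, dim = c(n_pos, 4, 3))
  cnt <- matrix(0L, n_pos, 4)
  for (cv in topology$coverage) {
    fr <- fragments[[cv$frag]]
    for (t in seq_along(cv$out_pos)) {
      acc[cv$out_pos[t], , ] <- acc[cv$out_pos[t], , ] + fr$xyz[cv$frag_res[t], , ]
      cnt[cv$out_pos[t], ] <- cnt[cv$out_pos[t], ] + 1L
    }
  }
  uncovered <- setdiff(which(cnt[, 1] == 0L), topology$omit)
  if (length(uncovered))
    stop(sprintf("output position(s) %s uncovered and not omitted",
                 paste(uncovered, collapse = ",")))
  init <- acc[keep, , , drop = FALSE] / array(cnt[keep, ], dim = c(length(keep), 4, 3))
  n <- length(keep)
  # adjacency in output numbering: consecutive kept positions only
  adj <- which(diff(keep) == 1)
  tg <- fuse_targets()
  a_idx <- function(res, atom) (res - 1L) * 4L + match(atom, BB_ATOMS)
  ii <- integer(0); jj <- integer(0); d0 <- numeric(0)
  for (tm in tg$intra) for (r in seq_len(n)) {
    ii <- c(ii, a_idx(r, tm[1])); jj <- c(jj, a_idx(r, tm[2]))
    d0 <- c(d0, as.numeric(tm[3]))
  }
  for (tm in tg$inter) for (r in adj) {
    ii <- c(ii, a_idx(r, tm[1])); jj <- c(jj, a_idx(r + 1, tm[2]))
    d0 <- c(d0, as.numeric(tm[3]))
  }
  x0 <- matrix(aperm(init, c(2, 1, 3)), ncol = 3)   # 4n x 3, residue-major
  obj <- function(x) {
    xm <- matrix(x, ncol = 3)
    dv <- xm[ii, , drop = FALSE] - xm[jj, , drop = FALSE]
    d <- sqrt(rowSums(dv^2))
    sum((d - d0)^2) + restraint_weight * sum((xm - x0)^2)
  }
  grd <- function(x) {
    xm <- matrix(x, ncol = 3)
    dv <- xm[ii, , drop = FALSE] - xm[jj, , drop = FALSE]
    d <- sqrt(rowSums(dv^2))
    coef <- 2 * (d - d0) / pmax(d, 1e-9)
    g <- 2 * restraint_weight * (xm - x0)
    gi <- dv * coef
    add <- rowsum(rbind(gi, -gi), c(ii, jj))
    rows <- as.integer(rownames(add))
    g[rows, ] <- g[rows, ] + add
    as.numeric(g)
  }
  fit <- stats::optim(as.numeric(x0), obj, grd, method = "L-BFGS-B",
                      control = list(maxit = maxit, factr = 1e4))
  if (fit$convergence != 0 && fit$convergence != 1)
    stop(sprintf("fusion refinement failed to converge (code %d: %s)",
                 fit$convergence, fit$message))
  xf <- matrix(fit$par, ncol = 3)
  out <- array(NA_real_, dim = c(n, 4, 3))
  for (r in seq_len(n)) out[r, , ] <- xf[(r - 1) * 4 + 1:4, ]
  backbone_chain(out, chain_id = "F", source_id = "fused")
}
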