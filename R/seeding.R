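# Binding-site definition, substructure search against a structure database,
# seed extraction and placement in the target frame, decoy seeds, and greedy
# set-cover clustering of seed binding modes.

#' Structure database
#'
#' Wraps a list of chains for substructure search; per-chain coordinate
#' caches and CA end-to-end window signatures (used for lossless pruning) are
#' precomputed lazily per window length.
#'
#' @param chains list of `backbone_chain` (single-chain database entries).
#' @return a `structure_db`.
#' @export
structure_db <- function(chains) {
  stopifnot(length(chains) >= 0,
            all(vapply(chains, inherits, TRUE, "backbone_chain")))
  .termseed_cache$db_counter <- (.termseed_cache$db_counter %||% 0L) + 1L
  structure(list(chains = chains,
                 db_id = sprintf("db%d", .termseed_cache$db_counter),
                 cache = new.env(parent = emptyenv())),
            class = "structure_db")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.structure_db <- function(x, ...) {
  cat(sprintf("<structure_db> %d chains, %d residues total\n",
              length(x$chains), sum(vapply(x$chains, nres, 1L))))
  invisible(x)
}

#' @export
length.structure_db <- function(x) length(x$chains)

# all contiguous windows of length L in a chain that do not cross a chain
# break; returns start indices
window_starts <- function(chain, L) {
  n <- nres(chain)
  if (n < L) return(integer(0))
  starts <- seq_len(n - L + 1)
  brk <- chain_breaks(chain)
  if (length(brk))
    starts <- starts[vapply(starts, function(s) !any(brk %in% s:(s + L - 2)), TRUE)]
  starts
}

# per-chain window coordinate cache: starts, per-window coordinate matrices,
# centered stacks + squared norms (for batch Kabsch), and CA end-to-end
# signature distances
db_windows <- function(db, ci, L) {
  key <- sprintf("w_%d_%d", ci, L)
  if (!is.null(db$cache[[key]])) return(db$cache[[key]])
  chain <- db$chains[[ci]]
  starts <- window_starts(chain, L)
  if (!length(starts)) {
    out <- list(starts = integer(0))
  } else {
    coords <- lapply(starts, function(s) bb_coords(chain, s:(s + L - 1)))
    centered <- lapply(coords, function(m) sweep(m, 2, colMeans(m)))
    # stacked per-axis matrices: nwin x (4L), for fast cross-covariances
    W <- lapply(1:3, function(ax)
      t(vapply(centered, function(m) m[, ax], numeric(4 * L))))
    ssq <- vapply(centered, function(m) sum(m^2), 1)
    ca1 <- t(vapply(starts, function(s) chain$xyz[s, "CA", ], numeric(3)))
    caL <- t(vapply(starts, function(s) chain$xyz[s + L - 1, "CA", ], numeric(3)))
    d_end <- sqrt(rowSums((ca1 - caL)^2))
    out <- list(starts = starts, coords = coords, d_end = d_end,
                W = W, ssq = ssq)
  }
  db$cache[[key]] <- out
  out
}

# Kabsch RMSD of query coords q against a subset of a window cache, batched:
# cross-covariances by matrix products, then a 3x3 SVD per window
batch_kabsch_rmsd <- function(dw, idx, q) {
  qc <- sweep(q, 2, colMeans(q))
  q_ssq <- sum(qc^2)
  nat <- nrow(q)
  H <- array(0, dim = c(length(idx), 3, 3))
  for (a in 1:3) {
    Wa <- dw$W[[a]][idx, , drop = FALSE]
    H[, a, ] <- Wa %*% qc
  }
  vapply(seq_along(idx), function(k) {
    s <- svd(H[k, , ])
    sig <- s$d
    if (det(s$u %*% t(s$v)) < 0) sig[3] <- -sig[3]
    sqrt(max(0, (dw$ssq[idx[k]] + q_ssq - 2 * sum(sig)) / nat))
  }, 1)
}

#' Binding-site fragment parameters
#'
#' @param n_min_matches minimum structural matches a fragment must retain
#'   while being grown.
#' @param size_range allowed single-segment sizes (odd, centered).
#' @param rmsd_cutoff backbone RMSD cutoff for matches, Angstrom.
#' @param multi_segment allow spatially proximal extra segments.
#' @export
fragment_params <- function(n_min_matches = 10, size_range = c(3, 7),
                            rmsd_cutoff = 1.0, multi_segment = FALSE) {
  stopifnot(n_min_matches >= 1, rmsd_cutoff > 0)
  structure(list(n_min_matches = n_min_matches, size_range = size_range,
                 rmsd_cutoff = rmsd_cutoff, multi_segment = multi_segment),
            class = "fragment_params")
}

#' Define binding-site and interface residue sets for a complex
#'
#' The binding site is the set of protein residues making at least one
#' potential contact of any type with the peptide (protein positions use only
#' native-amino-acid rotamers). Peptide interface residues are peptide
#' residues with at least one such contact whose B-factor lies within three
#' standard deviations of the complex mean.
#'
#' @param chains named list of `backbone_chain` (the complex).
#' @param peptide_chain name of the peptide chain.
#' @param lib rotamer library.
#' @return list with `binding_site` and `interface` residue sets (2-column
#'   matrices indexing into `chains`) and the underlying `contact_map`.
#' @export
define_binding_site <- function(chains, peptide_chain,
                                lib = default_rotamer_library()) {
  if (length(chains) < 2) stop("complex must have at least 2 chains")
  pidx <- which(names(chains) == peptide_chain)
  if (!length(pidx)) stop("peptide chain not found")
  prot_idx <- setdiff(seq_along(chains), pidx)
  prot <- all_residues(chains, prot_idx)
  pep <- all_residues(chains, pidx)
  cmap <- potential_contact_map(chains, prot, pep, lib, native_only = "a")
  cpairs <- cmap$pairs[cmap$pairs$contact, , drop = FALSE]
  bs_keys <- unique(paste(cpairs$chain_a, cpairs$res_a))
  site <- prot[paste(prot[, 1], prot[, 2]) %in% bs_keys, , drop = FALSE]
  pep_keys <- unique(paste(cpairs$chain_b, cpairs$res_b))
  contacting_pep <- pep[paste(pep[, 1], pep[, 2]) %in% pep_keys, , drop = FALSE]
  # B-factor rule over all residues of the complex
  all_b <- unlist(lapply(chains, `[[`, "bfac"))
  mu <- mean(all_b); sd_b <- stats::sd(all_b)
  if (!is.finite(sd_b) || sd_b == 0) {
    keep <- rep(TRUE, nrow(contacting_pep))
  } else {
    bvals <- vapply(seq_len(nrow(contacting_pep)), function(k)
      chains[[contacting_pep[k, 1]]]$bfac[contacting_pep[k, 2]], 1)
    keep <- abs(bvals - mu) <= 3 * sd_b
  }
  list(binding_site = site,
       interface = contacting_pep[keep, , drop = FALSE],
       contact_map = cmap)
}

#' Define the binding-site fragment around a central residue
#'
#' Greedy growth: start from the 3-residue window centered on the residue and
#' expand the flanks one step at a time (up to the size bound), keeping an
#' expansion only while the database still returns at least `n_min_matches`
#' matches at the RMSD cutoff; with `multi_segment`, up to two spatially
#' proximal 3-residue segments (around residues with a potential contact to
#' the central residue) are then added under the same rule. The minimum
#' returned fragment is the 3-residue window regardless of its match count.
#'
#' @param chains target structure (list of `backbone_chain`).
#' @param central residue reference `c(chain_index, residue_index)`.
#' @param db a `structure_db`.
#' @param params a `fragment_params`.
#' @param lib rotamer library (used for proximal-segment discovery).
#' @return a `binding_site_fragment`: central reference plus a list of
#'   segments (residue-index vectors per chain reference).
#' @export
define_fragment <- function(chains, central, db, params = fragment_params(),
                            lib = default_rotamer_library()) {
  chain <- chains[[central[1]]]
  n <- nres(chain)
  brk <- chain_breaks(chain)
  run_lo <- max(c(1, brk[brk < central[2]] + 1))
  run_hi <- min(c(n, brk[brk >= central[2]]))
  clip <- function(a, b) c(max(run_lo, a), min(run_hi, b))
  # minimal 3-residue span containing the central residue
  w <- clip(central[2] - 1, central[2] + 1)
  while (w[2] - w[1] < 2 && (w[1] > run_lo || w[2] < run_hi))
    w <- clip(w[1] - 1, w[2] + 1)
  if (w[2] - w[1] < 2) stop("no 3-residue span around the central residue")
  frag <- new_fragment(chains, central, list(res_set(central[1], w[1]:w[2])))
  count <- function(f) length(search_matches(f, db, params$rmsd_cutoff,
                                             limit = params$n_min_matches,
                                             transforms = FALSE))
  grow <- frag
  repeat {
    sz <- nrow(do.call(rbind, grow$segments))
    if (sz + 2 > params$size_range[2]) break
    w2 <- clip(grow$segments[[1]][1, 2] - 1,
               grow$segments[[1]][nrow(grow$segments[[1]]), 2] + 1)
    if (diff(w2) + 1 == nrow(grow$segments[[1]])) break  # cannot grow further
    segs <- grow$segments
    segs[[1]] <- res_set(central[1], w2[1]:w2[2])
    cand <- new_fragment(chains, central, segs)
    if (count(cand) >= params$n_min_matches) grow <- cand else break
  }
  if (isTRUE(params$multi_segment)) {
    others <- all_residues(chains)
    in_seg <- paste(grow$segments[[1]][, 1], grow$segments[[1]][, 2])
    others <- others[!paste(others[, 1], others[, 2]) %in% in_seg, , drop = FALSE]
    cmap <- potential_contact_map(chains, others, rbind(central), lib)
    cp <- cmap$pairs[cmap$pairs$contact, , drop = FALSE]
    added <- 0L
    for (k in seq_len(nrow(cp))) {
      if (added >= 2) break
      ci2 <- cp$chain_a[k]; r2 <- cp$res_a[k]
      ch2 <- chains[[ci2]]
      brk2 <- chain_breaks(ch2)
      lo2 <- max(c(1, brk2[brk2 < r2] + 1)); hi2 <- min(c(nres(ch2), brk2[brk2 >= r2]))
      seg <- max(lo2, r2 - 1):min(hi2, r2 + 1)
      if (length(seg) < 3) next
      covered <- do.call(rbind, grow$segments)
      if (any(paste(ci2, seg) %in% paste(covered[, 1], covered[, 2]))) next
      segs <- grow$segments
      segs[[length(segs) + 1]] <- res_set(ci2, seg)
      cand <- new_fragment(chains, central, segs)
      if (count(cand) >= params$n_min_matches) { grow <- cand; added <- added + 1L }
    }
  }
  grow
}

new_fragment <- function(chains, central, segments) {
  coords <- do.call(rbind, lapply(segments, function(seg)
    do.call(rbind, lapply(seq_len(nrow(seg)), function(k)
      bb_coords(chains[[seg[k, 1]]], seg[k, 2])))))
  structure(list(central = central, segments = segments, coords = coords,
                 seg_len = vapply(segments, nrow, 1L)),
            class = "binding_site_fragment")
}

#' @export
print.binding_site_fragment <- function(x, ...) {
  cat(sprintf("<binding_site_fragment> %d segment(s), %d residues\n",
              length(x$segments), sum(x$seg_len)))
  invisible(x)
}

# Kabsch RMSD of a candidate window (coords matrix) against query coords,
# returning rmsd only (cheap path)
kabsch_rmsd <- function(a, b) {
  cm <- colMeans(a); cf <- colMeans(b)
  A <- sweep(a, 2, cm); B <- sweep(b, 2, cf)
  H <- crossprod(A, B)
  s <- svd(H)
  d <- det(s$v %*% t(s$u))
  sig <- s$d; sig[3] <- sig[3] * sign(d)
  msd <- (sum(A^2) + sum(B^2) - 2 * sum(sig)) / nrow(a)
  sqrt(max(0, msd))
}

#' Search the database for matches to a binding-site fragment
#'
#' Scans all same-length windows of every database chain (for multi-segment
#' fragments, all compatible window tuples within one chain, preserving the
#' inter-segment geometry) and returns those whose optimally superposed
#' backbone RMSD is at or below the cutoff, sorted by ascending RMSD.
#'
#' A lossless CA end-to-end distance signature prunes candidate windows: a
#' window whose end-to-end CA distance differs from the query's by more than
#' `2 * sqrt(2L) * cutoff` cannot superpose within the cutoff.
#'
#' @param fragment a `binding_site_fragment`.
#' @param db a `structure_db`.
#' @param rmsd_cutoff Angstrom.
#' @param limit maximum matches returned (ascending RMSD).
#' @param transforms also compute each match's transform (skipped for pure
#'   counting, where only RMSDs are needed).
#' @return list of `term_match` (source chain index/id, windows, transform
#'   mapping source onto the target frame, rmsd).
#' @export
search_matches <- function(fragment, db, rmsd_cutoff = 1.0, limit = Inf,
                           transforms = TRUE) {
  if (!length(db$chains)) return(list())
  nseg <- length(fragment$segments)
  seg_lens <- fragment$seg_len
  n_atoms_tot <- 4 * sum(seg_lens)
  q_coords <- fragment$coords
  # per-segment query coords and relaxed per-segment cutoff (lossless bound:
  # n_seg * rmsd_seg^2 <= n_tot * rmsd_tot^2)
  seg_off <- c(0, cumsum(4 * seg_lens))
  seg_q <- lapply(seq_len(nseg), function(s)
    q_coords[(seg_off[s] + 1):seg_off[s + 1], , drop = FALSE])
  seg_cut <- rmsd_cutoff * sqrt(n_atoms_tot / (4 * seg_lens))
  hits <- list()
  for (ci in seq_along(db$chains)) {
    chain <- db$chains[[ci]]
    # candidate windows per segment
    seg_cand <- vector("list", nseg)
    ok <- TRUE
    for (s in seq_len(nseg)) {
      L <- seg_lens[s]
      dw <- db_windows(db, ci, L)
      if (!length(dw$starts)) { ok <- FALSE; break }
      q_end <- sqrt(sum((seg_q[[s]][2, ] - seg_q[[s]][4 * L - 2, ])^2))
      keep <- abs(dw$d_end - q_end) <= 2 * sqrt(2 * L) * seg_cut[s]
      idx <- which(keep)
      if (!length(idx)) { ok <- FALSE; break }
      rs <- batch_kabsch_rmsd(dw, idx, seg_q[[s]])
      sel <- rs <= seg_cut[s] + 1e-9
      if (!any(sel)) { ok <- FALSE; break }
      seg_cand[[s]] <- list(starts = dw$starts[idx[sel]],
                            coords = dw$coords[idx[sel]])
    }
    if (!ok) next
    combos <- combo_grid(lapply(seg_cand, function(x) seq_along(x$starts)))
    # lossless inter-segment centroid prune: after a joint superposition at
    # rmsd <= cutoff, each segment centroid moves at most
    # sqrt(n_atoms_tot / n_seg_atoms) * cutoff
    if (nseg > 1) {
      cent_q <- lapply(seg_q, colMeans)
      cent_c <- lapply(seq_len(nseg), function(s)
        t(vapply(seg_cand[[s]]$coords, colMeans, numeric(3))))
      keep_combo <- rep(TRUE, nrow(combos))
      for (s1 in seq_len(nseg - 1)) for (s2 in (s1 + 1):nseg) {
        dq <- sqrt(sum((cent_q[[s1]] - cent_q[[s2]])^2))
        tol <- rmsd_cutoff * (sqrt(n_atoms_tot / (4 * seg_lens[s1])) +
                                sqrt(n_atoms_tot / (4 * seg_lens[s2])))
        dc <- sqrt(rowSums((cent_c[[s1]][combos[, s1], , drop = FALSE] -
                              cent_c[[s2]][combos[, s2], , drop = FALSE])^2))
        keep_combo <- keep_combo & abs(dc - dq) <= tol + 1e-9
      }
      combos <- combos[keep_combo, , drop = FALSE]
    }
    for (ri in seq_len(nrow(combos))) {
      starts <- vapply(seq_len(nseg), function(s)
        seg_cand[[s]]$starts[combos[ri, s]], 1L)
      # segments must not overlap within the source chain
      spans <- lapply(seq_len(nseg), function(s) starts[s]:(starts[s] + seg_lens[s] - 1))
      if (nseg > 1 && length(unique(unlist(spans))) != sum(seg_lens)) next
      w_coords <- do.call(rbind, lapply(seq_len(nseg), function(s)
        seg_cand[[s]]$coords[[combos[ri, s]]]))
      r <- kabsch_rmsd(w_coords, q_coords)
      if (r <= rmsd_cutoff + 1e-9) {
        tf <- if (transforms) superpose(w_coords, q_coords)$transform
        hits[[length(hits) + 1]] <- structure(
          list(source = ci, source_id = chain$source_id,
               windows = spans, transform = tf, rmsd = r),
          class = "term_match")
      }
    }
  }
  if (!length(hits)) return(list())
  ord <- order(vapply(hits, `[[`, 1, "rmsd"))
  hits <- hits[ord]
  if (is.finite(limit) && length(hits) > limit) hits <- hits[seq_len(limit)]
  hits
}

combo_grid <- function(idx_list) {
  as.matrix(do.call(expand.grid, idx_list))
}

#' Extract seeds from a structural match
#'
#' Searches the match's source structure for residues with the potential to
#' contact the central residue of the match (any contact type, excluding the
#' match window itself and its two sequence neighbours on each side), expands
#' each by `flank` residues, merges overlapping expansions, and places the
#' resulting fragments in the target frame with the match transform.
#'
#' @param match a `term_match`.
#' @param db the `structure_db` the match came from.
#' @param flank flanking residues on each side.
#' @param lib rotamer library.
#' @param target target chains (used for `distance_to_protein`), or NULL.
#' @return list of `seed`.
#' @export
extract_seeds <- function(match, db, flank = 2,
                          lib = default_rotamer_library(), target = NULL) {
  chain <- db$chains[[match$source]]
  win <- match$windows[[1]]
  central <- win[ceiling(length(win) / 2)]
  excl <- unique(unlist(lapply(match$windows, function(w)
    (min(w) - 2):(max(w) + 2))))
  cand <- setdiff(seq_len(nres(chain)), excl)
  if (!length(cand)) return(list())
  rc_key <- sprintf("rotcache_%d", match$source)
  if (is.null(db$cache[[rc_key]]))
    db$cache[[rc_key]] <- new.env(parent = emptyenv())
  cmap <- potential_contact_map(list(chain), res_set(1, cand),
                                res_set(1, central), lib,
                                rot_cache = db$cache[[rc_key]])
  cres <- sort(cmap$pairs$res_a[cmap$pairs$contact])
  if (!length(cres)) return(list())
  brk <- chain_breaks(chain)
  expand <- lapply(cres, function(r) {
    lo <- max(c(1, brk[brk < r] + 1, r - flank))
    hi <- min(c(nres(chain), brk[brk >= r], r + flank))
    lo:hi
  })
  # merge overlapping/adjacent expansions
  merged <- list()
  for (iv in expand) {
    if (length(merged) && iv[1] <= merged[[length(merged)]][length(merged[[length(merged)]])] + 1 &&
        !any(brk %in% (merged[[length(merged)]][length(merged[[length(merged)]])]):(iv[1]))) {
      merged[[length(merged)]] <- min(merged[[length(merged)]]):max(iv[length(iv)], max(merged[[length(merged)]]))
    } else merged[[length(merged) + 1]] <- iv
  }
  ss_all <- db_entry_ss(db, match$source)
  seeds <- list()
  for (iv in merged) {
    if (length(iv) < 3) next
    sub <- chain[iv]
    placed <- apply_transform(sub, match$transform)
    placed$source_id <- chain$source_id
    dtp <- if (!is.null(target))
      min(cross_dist(placed$xyz[, "CA", ], do.call(rbind, lapply(target, bb_coords))))
    else NA_real_
    seeds[[length(seeds) + 1]] <- structure(
      list(chain = placed, source_id = chain$source_id,
           source_res = iv, match_rmsd = match$rmsd,
           ss = ss_all[iv], distance_to_protein = dtp),
      class = "seed")
  }
  seeds
}

# secondary structure of a database entry, cached (labels are assigned in the
# original structural context and inherited by seeds)
db_entry_ss <- function(db, ci) {
  key <- sprintf("ss_%d", ci)
  if (is.null(db$cache[[key]]))
    db$cache[[key]] <- assign_ss(db$chains[[ci]])
  db$cache[[key]]
}

#' @export
print.seed <- function(x, ...) {
  cat(sprintf("<seed> %d residues from %s, match rmsd %.2f, d(protein) %.2f\n",
              nres(x$chain), x$source_id, x$match_rmsd,
              x$distance_to_protein))
  invisible(x)
}

#' Generate interface seeds around a binding site
#'
#' For every binding-site residue: define its fragment, search the database,
#' and extract seeds from every match; seeds clashing with the target are
#' discarded. Deterministic given the database ordering.
#'
#' @param chains target structure (list of `backbone_chain`).
#' @param site binding-site residue set (2-column matrix into `chains`).
#' @param db a `structure_db`.
#' @param params a `fragment_params`.
#' @param flank seed flank width.
#' @param lib rotamer library.
#' @param clash a `clash_params`.
#' @return list of `seed` with unique `seed_id`s.
#' @export
generate_seeds <- function(chains, site, db, params = fragment_params(),
                           flank = 2, lib = default_rotamer_library(),
                           clash = clash_params()) {
  if (is.null(site) || nrow(site) == 0) return(list())
  target_atoms <- do.call(rbind, lapply(chains, bb_coords))
  target_elem <- unlist(lapply(chains, function(ch) bb_elements(nres(ch))))
  seeds <- list()
  for (k in seq_len(nrow(site))) {
    frag <- define_fragment(chains, site[k, ], db, params, lib)
    matches <- search_matches(frag, db, params$rmsd_cutoff,
                              limit = params$n_min_matches)
    for (m in matches) {
      for (s in extract_seeds(m, db, flank, lib, target = chains)) {
        s_atoms <- bb_coords(s$chain)
        if (clash_check(s_atoms, target_atoms, clash,
                        elements_a = bb_elements(nres(s$chain)),
                        elements_b = target_elem)) next
        s$site_residue <- site[k, ]
        seeds[[length(seeds) + 1]] <- s
      }
    }
  }
  for (i in seq_along(seeds)) seeds[[i]]$seed_id <- sprintf("seed%04d", i)
  seeds
}

#' Generate decoy seeds matched in size and distance-to-protein
#'
#' One decoy per input seed, with the same residue count, a random rigid
#' pose, and a distance-to-protein drawn from the real seeds' empirical
#' distribution (matched within 0.25 Angstrom by construction), with no
#' clash against the target. Decoys carry no database provenance.
#'
#' @param seeds real seeds.
#' @param chains target structure.
#' @param rng_seed reproducibility seed.
#' @param clash a `clash_params`.
#' @param max_attempts pose attempts per decoy before skipping with a warning.
#' @return list of `seed`.
#' @export
generate_decoys <- function(seeds, chains, rng_seed = 1,
                            clash = clash_params(), max_attempts = 200) {
  if (!length(seeds)) stop("need at least one real seed")
  set.seed(rng_seed %% .Machine$integer.max)
  dists <- vapply(seeds, `[[`, 1, "distance_to_protein")
  target_atoms <- do.call(rbind, lapply(chains, bb_coords))
  target_elem <- unlist(lapply(chains, function(ch) bb_elements(nres(ch))))
  target_ca <- do.call(rbind, lapply(chains, function(ch) ch$xyz[, "CA", ]))
  decoys <- list()
  skipped <- 0L
  for (si in seq_along(seeds)) {
    sd0 <- seeds[[si]]
    done <- FALSE
    # one distance target per decoy, drawn from the real seeds' empirical
    # distance distribution; fixed before pose attempts so rejections cannot
    # bias the distribution
    d_star <- sample(dists, 1)
    for (attempt in seq_len(max_attempts)) {
      R <- random_rotation()
      ch <- sd0$chain
      ctr <- colMeans(bb_coords(ch))
      ch <- apply_transform(ch, rigid_transform(R, -as.numeric(R %*% ctr)))
      anchor <- target_ca[sample(nrow(target_ca), 1), ]
      u <- normalize(stats::rnorm(3))
      # bisection on the offset so min CA-to-target distance hits d_star
      f <- function(t) {
        pos <- apply_transform(ch, rigid_transform(diag(3), anchor + u * t))
        min(cross_dist(pos$xyz[, "CA", ], target_atoms)) - d_star
      }
      lo <- 0; hi <- 40
      if (f(hi) < 0) next
      for (it in 1:70) {            # below double resolution: d hits d_star
        mid <- (lo + hi) / 2
        if (mid <= lo || mid >= hi) break
        if (f(mid) < 0) lo <- mid else hi <- mid
      }
      pos <- apply_transform(ch, rigid_transform(diag(3), anchor + u * hi))
      d_actual <- min(cross_dist(pos$xyz[, "CA", ], target_atoms))
      if (abs(d_actual - d_star) > 0.25) next
      if (clash_check(bb_coords(pos), target_atoms, clash,
                      elements_a = bb_elements(nres(pos)),
                      elements_b = target_elem)) next
      decoys[[length(decoys) + 1]] <- structure(
        list(chain = pos, source_id = "decoy", source_res = sd0$source_res,
             match_rmsd = NA_real_, ss = rep("C", nres(pos)),
             distance_to_protein = d_actual,
             seed_id = sprintf("decoy%04d", si)),
        class = "seed")
      done <- TRUE
      break
    }
    if (!done) skipped <- skipped + 1L
  }
  if (skipped) warning(sprintf("skipped %d decoy(s): pose rejection failed",
                               skipped))
  decoys
}

# uniform random rotation via QR of a Gaussian matrix, sign-fixed
random_rotation <- function() {
  M <- matrix(stats::rnorm(9), 3, 3)
  qr_ <- qr(M)
  Q <- qr.Q(qr_)
  d <- diag(qr.R(qr_))
  Q <- Q %*% diag(sign(d))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' Cluster seed binding modes by greedy set cover
#'
#' U is the set of all k-residue seed windows. Repeatedly the window aligned
#' (by the geometric overlap criterion) with the most other windows still in
#' U is picked as a representative, its aligned windows joining its cluster
#' and leaving U, until at least `stop_fraction` of the windows are
#' clustered.
#'
#' @param seeds list of `seed`.
#' @param k window length for alignment.
#' @param stop_fraction stop once this fraction of windows is clustered.
#' @param params an `overlap_params` (its `window_len` is overridden by `k`).
#' @return list of clusters (`representative` window, `members`), in pick
#'   order.
#' @export
cluster_seed_windows <- function(seeds, k = 4, stop_fraction = 0.10,
                                 params = overlap_params()) {
  params$window_len <- k
  wins <- seed_windows(seeds, k)
  nU <- nrow(wins$index)
  if (!nU) return(list())
  edges <- find_overlaps(seeds, params, allow_same_seed = TRUE)
  adj <- vector("list", nU)
  if (nrow(edges)) {
    ij <- cbind(wins$lookup[paste(edges$seed_i, edges$win_i)],
                wins$lookup[paste(edges$seed_j, edges$win_j)])
    for (r in seq_len(nrow(ij))) {
      adj[[ij[r, 1]]] <- c(adj[[ij[r, 1]]], ij[r, 2])
      adj[[ij[r, 2]]] <- c(adj[[ij[r, 2]]], ij[r, 1])
    }
  }
  in_u <- rep(TRUE, nU)
  clustered <- 0L
  clusters <- list()
  while (clustered < stop_fraction * nU) {
    deg <- vapply(seq_len(nU), function(i)
      if (in_u[i]) sum(in_u[adj[[i]]]) else -1L, 1L)
    best <- which.max(deg)
    members <- c(best, adj[[best]][in_u[adj[[best]]]])
    in_u[members] <- FALSE
    clustered <- clustered + length(members)
    clusters[[length(clusters) + 1]] <-
      list(representative = wins$index[best, , drop = FALSE],
           members = wins$index[members, , drop = FALSE])
  }
  clusters
}

# enumerate k-windows over seeds: index data.frame (seed, start) + lookup
seed_windows <- function(seeds, k) {
  rows <- list()
  for (si in seq_along(seeds)) {
    st <- window_starts(seeds[[si]]$chain, k)
    if (length(st)) rows[[length(rows) + 1]] <- data.frame(seed = si, start = st)
  }
  index <- if (length(rows)) do.call(rbind, rows) else
    data.frame(seed = integer(0), start = integer(0))
  lookup <- seq_len(nrow(index))
  names(lookup) <- paste(index$seed, index$start)
  list(index = index, lookup = lookup)
}
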