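# Coverage and reconstruction benchmarks: strip the peptide from a complex,
# regenerate seeds around its binding site, and measure how well the seeds
# cover - and can rebuild - the native peptide.

#' Coverage parameters
#' @param k alignment window length (1, 3, 4, 5 or 7 in the benchmarks).
#' @param r_c fixed-frame backbone RMSD cutoff, Angstrom, in [0, 3].
#' @export
coverage_params <- function(k = 3, r_c = 1.0) {
  stopifnot(k >= 1, r_c >= 0)
  structure(list(k = k, r_c = r_c), class = "coverage_params")
}

# fixed-frame k-window alignment: minimum window RMSD of each peptide window
# against every seed window (no superposition; atoms fixed in space)
peptide_window_cover <- function(pep, seeds, k, r_c) {
  p_starts <- window_starts(pep, k)
  if (!length(p_starts))
    return(list(starts = integer(0), covered = logical(0),
                best = data.frame()))
  s_wins <- list()
  for (si in seq_along(seeds)) {
    for (st in window_starts(seeds[[si]]$chain, k))
      s_wins[[length(s_wins) + 1]] <-
        list(seed = si, start = st,
             coords = bb_coords(seeds[[si]]$chain, st:(st + k - 1)),
             ca = seeds[[si]]$chain$xyz[st, "CA", ])
  }
  covered <- rep(FALSE, length(p_starts))
  best <- vector("list", length(p_starts))
  for (pi in seq_along(p_starts)) {
    pw <- bb_coords(pep, p_starts[pi]:(p_starts[pi] + k - 1))
    ca0 <- pep$xyz[p_starts[pi], "CA", ]
    for (sw in s_wins) {
      if (sqrt(sum((sw$ca - ca0)^2)) > r_c + 4 * k) next  # cheap triage
      r <- window_rmsd_fixed(pw, sw$coords)
      if (r <= r_c) {
        covered[pi] <- TRUE
        if (is.null(best[[pi]]) || r < best[[pi]]$rmsd)
          best[[pi]] <- list(seed = sw$seed, start = sw$start, rmsd = r)
      }
    }
  }
  list(starts = p_starts, covered = covered, best = best)
}

#' Run the native-peptide coverage benchmark
#'
#' For each complex: the peptide is removed, the binding site is defined on
#' the remaining protein, seeds are generated from the database, and a
#' peptide residue counts as covered iff it lies in some k-residue peptide
#' window whose fixed-frame backbone RMSD to some seed k-window is at most
#' `r_c`. Coverage is aggregated over peptide interface residues only, with
#' a by-secondary-structure breakdown, and optionally a match-count sweep
#' (coverage using only seeds from the top-M matches by RMSD) or decoy seeds
#' in place of real ones.
#'
#' @param complexes list of complexes (`chains` + `peptide_chain`, as from
#'   [make_toy_complex()]).
#' @param db a `structure_db`.
#' @param params a `coverage_params`.
#' @param fragment_params a `fragment_params`.
#' @param lib rotamer library.
#' @param flank seed flank width.
#' @param decoys use distance-matched decoy seeds instead of real seeds.
#' @param rng_seed seed for decoy generation.
#' @param match_sweep optional vector of match-count caps M for the sweep.
#' @return a `coverage_result`.
#' @export
run_coverage <- function(complexes, db, params = coverage_params(),
                         fragment_params = fragment_params(),
                         lib = default_rotamer_library(), flank = 2,
                         decoys = FALSE, rng_seed = 1, match_sweep = NULL) {
  per_complex <- list()
  for (cxi in seq_along(complexes)) {
    cx <- complexes[[cxi]]
    if (length(cx$chains) < 2) stop("complex must have at least 2 chains")
    pc <- cx$peptide_chain
    pidx <- which(names(cx$chains) == pc)
    site_info <- define_binding_site(cx$chains, pc, lib)
    target <- cx$chains[-pidx]
    pep <- cx$chains[[pidx]]
    # binding-site references are into the full complex; re-index to target
    site <- site_info$binding_site
    site[, 1] <- match(site[, 1], setdiff(seq_along(cx$chains), pidx))
    seeds <- generate_seeds(target, site, db, fragment_params, flank, lib)
    if (decoys && length(seeds))
      seeds <- generate_decoys(seeds, target, rng_seed = rng_seed)
    interface_res <- site_info$interface[, 2]
    ss <- assign_ss(cx$chains)[[pidx]]
    cover_with <- function(seed_subset) {
      cov <- peptide_window_cover(pep, seed_subset, params$k, params$r_c)
      res_cov <- rep(FALSE, nres(pep))
      for (pi in seq_along(cov$starts))
        if (cov$covered[pi])
          res_cov[cov$starts[pi]:(cov$starts[pi] + params$k - 1)] <- TRUE
      res_cov
    }
    res_cov <- cover_with(seeds)
    sweep <- NULL
    if (!is.null(match_sweep) && length(seeds)) {
      rms <- vapply(seeds, `[[`, 1, "match_rmsd")
      ord <- order(rms)
      sweep <- vapply(match_sweep, function(M) {
        sub <- seeds[utils::head(ord, M)]
        100 * mean(cover_with(sub)[interface_res])
      }, 1)
      names(sweep) <- match_sweep
    }
    per_complex[[cxi]] <- list(
      covered = res_cov, interface = interface_res, ss = ss,
      n_seeds = length(seeds), sweep = sweep)
  }
  all_cov <- unlist(lapply(per_complex, function(p) p$covered[p$interface]))
  all_ss <- unlist(lapply(per_complex, function(p) p$ss[p$interface]))
  by_ss <- tapply(all_cov, all_ss, function(v) 100 * mean(v))
  structure(list(
    per_complex = per_complex,
    pct_covered = if (length(all_cov)) 100 * mean(all_cov) else 0,
    n_interface = length(all_cov),
    by_ss = by_ss,
    sweep = if (!is.null(match_sweep))
      Reduce(`+`, lapply(per_complex, `[[`, "sweep")) / length(per_complex)),
    class = "coverage_result")
}

#' @export
print.coverage_result <- function(x, ...) {
  cat(sprintf("<coverage_result> %.1f%% of %d interface residues covered\n",
              x$pct_covered, x$n_interface))
  invisible(x)
}

#' Run the native-peptide reconstruction benchmark
#'
#' Seeds covering 3-residue peptide windows at a 2.0 Angstrom fixed-frame
#' cutoff are assigned to windows greedily in ascending RMSD with seed reuse
#' forbidden (every window must be covered by a different seed); positions in
#' no assigned window are omitted from the topology; the selected windows are
#' fused against the protein context and compared with the native peptide.
#'
#' @param complexes list of complexes.
#' @param db a `structure_db`.
#' @param fragment_params a `fragment_params`.
#' @param lib rotamer library.
#' @param flank seed flank width.
#' @param window_rc fixed-frame cutoff for candidate windows, Angstrom.
#' @return list of `reconstruction_result`, one per complex (NULL where no
#'   window was covered).
#' @export
run_reconstruction <- function(complexes, db,
                               fragment_params = fragment_params(),
                               lib = default_rotamer_library(), flank = 2,
                               window_rc = 2.0) {
  out <- list()
  for (cxi in seq_along(complexes)) {
    cx <- complexes[[cxi]]
    pc <- cx$peptide_chain
    pidx <- which(names(cx$chains) == pc)
    site_info <- define_binding_site(cx$chains, pc, lib)
    target <- cx$chains[-pidx]
    pep <- cx$chains[[pidx]]
    site <- site_info$binding_site
    site[, 1] <- match(site[, 1], setdiff(seq_along(cx$chains), pidx))
    seeds <- generate_seeds(target, site, db, fragment_params, flank, lib)
    out[[cxi]] <- reconstruct_peptide(pep, seeds, target, lib,
                                      window_rc = window_rc,
                                      native_complex = cx)
  }
  out
}

#' Reconstruct a peptide backbone from a seed set
#'
#' @param pep native peptide `backbone_chain` (defines the topology length).
#' @param seeds list of `seed` posed in the target frame.
#' @param target protein context chains.
#' @param lib rotamer library (contact conservation).
#' @param window_rc candidate-window cutoff, Angstrom.
#' @param native_complex optional full complex for contact conservation.
#' @return a `reconstruction_result` or NULL when nothing is covered.
#' @export
reconstruct_peptide <- function(pep, seeds, target, lib =
                                  default_rotamer_library(), window_rc = 2.0,
                                  native_complex = NULL) {
  k <- 3
  p_starts <- window_starts(pep, k)
  cands <- list()
  for (si in seq_along(seeds)) {
    ch <- seeds[[si]]$chain
    for (st in window_starts(ch, k)) {
      w <- bb_coords(ch, st:(st + k - 1))
      for (pi in seq_along(p_starts)) {
        pw <- bb_coords(pep, p_starts[pi]:(p_starts[pi] + k - 1))
        r <- window_rmsd_fixed(pw, w)
        if (r <= window_rc)
          cands[[length(cands) + 1]] <- data.frame(win = pi, seed = si,
                                                   start = st, rmsd = r)
      }
    }
  }
  if (!length(cands)) return(NULL)
  cands <- do.call(rbind, cands)
  cands <- cands[order(cands$rmsd), , drop = FALSE]
  assigned <- list(); used_seed <- logical(length(seeds))
  win_done <- logical(length(p_starts))
  for (r in seq_len(nrow(cands))) {
    w <- cands$win[r]; s <- cands$seed[r]
    if (win_done[w] || used_seed[s]) next
    win_done[w] <- TRUE; used_seed[s] <- TRUE
    assigned[[length(assigned) + 1]] <- cands[r, ]
  }
  coverage <- lapply(assigned, function(a)
    list(frag = a$seed, frag_res = a$start:(a$start + k - 1),
         out_pos = p_starts[a$win]:(p_starts[a$win] + k - 1)))
  covered_pos <- sort(unique(unlist(lapply(coverage, `[[`, "out_pos"))))
  omit <- setdiff(seq_len(nres(pep)), covered_pos)
  topo <- fusion_topology(nres(pep), coverage, omit = omit)
  fused <- fuse(topo, lapply(seeds, `[[`, "chain"))
  # per-residue RMSD to the native over non-omitted positions
  per_res <- vapply(seq_along(covered_pos), function(t)
    window_rmsd_fixed(bb_coords(fused, t), bb_coords(pep, covered_pos[t])), 1)
  conserved <- if (!is.null(native_complex)) {
    conserved_contact_fraction(native_complex, fused,
                               reconstructed_positions = covered_pos,
                               lib = lib)
  } else NA_real_
  structure(list(backbone = fused, positions = covered_pos, omitted = omit,
                 per_residue_rmsd = per_res, mean_rmsd = mean(per_res),
                 pct_contacts_conserved = conserved,
                 n_windows = sum(win_done)),
            class = "reconstruction_result")
}

#' @export
print.reconstruction_result <- function(x, ...) {
  cat(sprintf("<reconstruction_result> %d positions (%d omitted), mean RMSD %.2f A, %.1f%% contacts conserved\n",
              length(x$positions), length(x$omitted), x$mean_rmsd,
              x$pct_contacts_conserved))
  invisible(x)
}

#' Fraction of native potential contacts conserved by a reconstruction
#'
#' Native peptide-protein potential contacts are computed backbone-only on
#' the native complex; a contact is conserved iff the same (peptide position,
#' protein residue) pair is a potential contact with the reconstructed
#' backbone in place of the peptide.
#'
#' @param native_complex complex (`chains` + `peptide_chain`).
#' @param reconstructed a `backbone_chain` posed in the native frame.
#' @param reconstructed_positions native peptide positions the reconstruction
#'   covers, in order (default: first `nres(reconstructed)` positions).
#' @param lib rotamer library.
#' @return percent in [0, 100].
#' @export
conserved_contact_fraction <- function(native_complex, reconstructed,
                                       reconstructed_positions = NULL,
                                       lib = default_rotamer_library()) {
  pc <- native_complex$peptide_chain
  pidx <- which(names(native_complex$chains) == pc)
  chains <- native_complex$chains
  pep <- chains[[pidx]]
  prot_idx <- setdiff(seq_along(chains), pidx)
  if (is.null(reconstructed_positions))
    reconstructed_positions <- seq_len(nres(reconstructed))
  nat_map <- potential_contact_map(chains, all_residues(chains, pidx),
                                   all_residues(chains, prot_idx), lib,
                                   native_only = "b")
  nat <- nat_map$pairs[nat_map$pairs$contact, , drop = FALSE]
  if (!nrow(nat)) stop("no native potential contacts")
  rec_chains <- c(chains[prot_idx], list(REC = reconstructed))
  ri <- length(rec_chains)
  rec_map <- potential_contact_map(rec_chains, all_residues(rec_chains, ri),
                                   all_residues(rec_chains, seq_len(ri - 1)),
                                   lib, native_only = "b")
  rec <- rec_map$pairs[rec_map$pairs$contact, , drop = FALSE]
  # translate reconstruction residue index -> native peptide position, and
  # protein chain index back to the complex numbering
  rec_keys <- if (nrow(rec)) paste(reconstructed_positions[rec$res_a],
                                   prot_idx[rec$chain_b], rec$res_b) else character(0)
  nat_keys <- paste(nat$res_a, nat$chain_b, nat$res_b)
  100 * mean(nat_keys %in% rec_keys)
}

#' Select one representative complex per cluster by peptide B-factor
#'
#' Generic curation over any complex list: within each cluster, the complex
#' whose peptide has the lowest mean B-factor is retained.
#'
#' @param complexes list of complexes (`chains` + `peptide_chain`).
#' @param cluster_ids cluster label per complex.
#' @return indices of the retained complexes, one per cluster (cluster order
#'   by decreasing cluster size, ties by first appearance).
#' @export
curate_complexes <- function(complexes, cluster_ids) {
  stopifnot(length(complexes) == length(cluster_ids))
  mean_b <- vapply(complexes, function(cx)
    mean(cx$chains[[cx$peptide_chain]]$bfac), 1)
  sizes <- table(cluster_ids)
  cl_order <- names(sort(sizes, decreasing = TRUE))
  vapply(cl_order, function(cl) {
    members <- which(cluster_ids == cl)
    members[which.min(mean_b[members])]
  }, 1L)
}
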