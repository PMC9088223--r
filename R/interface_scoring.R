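# Contact-based and TERM-statistics filters over candidate peptide backbones,
# backbone clustering, and final design selection.

#' Mean potential contacts per residue of a posed backbone
#'
#' Total potential contacts (any type) between the backbone's residues and
#' the target, divided by the backbone length. The target's residues use
#' native-amino-acid rotamers (its sequence is fixed); the designed backbone,
#' having no sequence yet, uses the full amino-acid alphabet.
#'
#' @param backbone a `backbone_chain` posed against the target.
#' @param target list of `backbone_chain`.
#' @param lib rotamer library.
#' @return non-negative mean count.
#' @export
contacts_per_residue <- function(backbone, target,
                                 lib = default_rotamer_library()) {
  chains <- c(list(backbone), target)
  cmap <- potential_contact_map(chains,
                                res_set(1, seq_len(nres(backbone))),
                                all_residues(chains, 1 + seq_along(target)),
                                lib, native_only = "b")
  cmap$contacts_per_residue
}

# reference median match count over pair-TERMs sampled from the database's
# own contacts; cached per (db, cutoff)
pair_term_reference <- function(db, lib, rmsd_cutoff = 1.0, ref_size = 500,
                                rng_seed = 42) {
  key <- sprintf("ref_%s_%g_%d", db$db_id, rmsd_cutoff, ref_size)
  if (!is.null(db$cache[[key]])) return(db$cache[[key]])
  set.seed(rng_seed)
  # candidate contacts within database entries: backbone-backbone pairs plus
  # nearby (CA <= 7.5 A) sequence-distant pairs, a cheap but representative
  # pool of intra-molecular potential contacts
  pool <- list()
  for (ci in seq_along(db$chains)) {
    ch <- db$chains[[ci]]
    n <- nres(ch)
    if (n < 7) next
    ca <- ch$xyz[, "CA", ]
    d <- cross_dist(ca, ca)
    cand <- which(d <= 7.5 & upper.tri(d), arr.ind = TRUE)
    cand <- cand[abs(cand[, 1] - cand[, 2]) >= 3, , drop = FALSE]
    if (nrow(cand))
      pool[[length(pool) + 1]] <- cbind(chain = ci, cand)
  }
  if (!length(pool)) {
    db$cache[[key]] <- 1
    return(1)
  }
  pool <- do.call(rbind, pool)
  take <- sample(nrow(pool), min(ref_size, nrow(pool)))
  counts <- vapply(take, function(r) {
    ch <- db$chains[[pool[r, 1]]]
    frag <- pair_term_fragment(list(ch), c(1, pool[r, 2]), c(1, pool[r, 3]))
    if (is.null(frag)) return(NA_real_)
    length(search_matches(frag, db, rmsd_cutoff, transforms = FALSE))
  }, 1)
  med <- stats::median(counts, na.rm = TRUE)
  if (!is.finite(med)) med <- 1
  db$cache[[key]] <- med
  med
}

# two-segment pair-TERM around a contacting residue pair (each residue +/- 1)
pair_term_fragment <- function(chains, a, b) {
  seg_of <- function(ref) {
    ch <- chains[[ref[1]]]
    brk <- chain_breaks(ch)
    lo <- max(c(1, brk[brk < ref[2]] + 1, ref[2] - 1))
    hi <- min(c(nres(ch), brk[brk >= ref[2]], ref[2] + 1))
    if (hi - lo < 1) return(NULL)
    res_set(ref[1], lo:hi)
  }
  s1 <- seg_of(a); s2 <- seg_of(b)
  if (is.null(s1) || is.null(s2)) return(NULL)
  # overlapping segments (sequence-local pair) collapse to one segment
  if (a[1] == b[1] && length(intersect(s1[, 2], s2[, 2])))
    return(new_fragment(chains, a, list(res_set(a[1], union(s1[, 2], s2[, 2])))))
  new_fragment(chains, a, list(s1, s2))
}

#' TERM interface score of a backbone against a target
#'
#' For every contacting (backbone residue, target residue) pair, a
#' two-segment pair-TERM (each residue with its +/- 1 flanks) is searched
#' against the database; the pair score is `-log10((m + 1) / (m_ref + 1))`
#' where `m` is its match count and `m_ref` the median match count of a
#' reference sample of pair-TERMs drawn from the database itself. The score
#' is the mean over contacting pairs: negative means the interface geometry
#' is better supported by known structure than typical.
#'
#' The formula matches the sign convention and database-relative
#' normalisation of the statistic it emulates, but its absolute values are
#' specific to this package and to the database supplied.
#'
#' @param backbone a `backbone_chain` posed against the target.
#' @param target list of `backbone_chain`.
#' @param db a `structure_db`.
#' @param lib rotamer library.
#' @param rmsd_cutoff pair-TERM match cutoff, Angstrom.
#' @param ref_size reference sample size.
#' @return mean pair score (dimensionless; negative favourable).
#' @export
term_interface_score <- function(backbone, target, db,
                                 lib = default_rotamer_library(),
                                 rmsd_cutoff = 1.0, ref_size = 500) {
  chains <- c(list(backbone), target)
  cmap <- potential_contact_map(chains,
                                res_set(1, seq_len(nres(backbone))),
                                all_residues(chains, 1 + seq_along(target)),
                                lib, native_only = "b")
  cp <- cmap$pairs[cmap$pairs$contact, , drop = FALSE]
  if (!nrow(cp)) stop("unscorable backbone: no potential contact with target")
  m_ref <- pair_term_reference(db, lib, rmsd_cutoff, ref_size)
  scores <- vapply(seq_len(nrow(cp)), function(r) {
    frag <- pair_term_fragment(chains, c(cp$chain_a[r], cp$res_a[r]),
                               c(cp$chain_b[r], cp$res_b[r]))
    if (is.null(frag)) return(NA_real_)
    m <- length(search_matches(frag, db, rmsd_cutoff, transforms = FALSE))
    -log10((m + 1) / (m_ref + 1))
  }, 1)
  mean(scores, na.rm = TRUE)
}

# best-alignment RMSD between two backbones, in the common (target) frame:
# equal lengths compare directly; otherwise the shorter slides over every
# window of the longer and the minimum is taken. No superposition is applied
# - designs live around one target, so the distance separates binding sites
# as well as shapes (which is what the 5 / 20 Angstrom thresholds assume)
backbone_pair_rmsd <- function(a, b) {
  if (nres(a) > nres(b)) { tmp <- a; a <- b; b <- tmp }
  la <- nres(a); lb <- nres(b)
  qa <- bb_coords(a)
  best <- Inf
  for (s in seq_len(lb - la + 1)) {
    r <- window_rmsd_fixed(bb_coords(b, s:(s + la - 1)), qa)
    if (r < best) best <- r
  }
  best
}

#' Cluster backbones by complete-linkage hierarchical clustering
#'
#' All-vs-all distance is the best sliding-window backbone RMSD in the
#' common target frame (no superposition); the complete-linkage dendrogram
#' is cut at `threshold`. Each cluster's representative is the member with
#' the lowest mean distance to the others.
#'
#' @param backbones list of `backbone_chain`.
#' @param threshold RMSD cut height, Angstrom.
#' @return list with `assignment` (integer vector), `representatives`
#'   (indices into `backbones`) and the distance matrix.
#' @export
cluster_backbones <- function(backbones, threshold) {
  n <- length(backbones)
  if (!n) stop("need at least one backbone")
  if (n == 1)
    return(list(assignment = 1L, representatives = 1L,
                dist = matrix(0, 1, 1)))
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    D[i, j] <- D[j, i] <- backbone_pair_rmsd(backbones[[i]], backbones[[j]])
  hc <- stats::hclust(stats::as.dist(D), method = "complete")
  assignment <- stats::cutree(hc, h = threshold)
  reps <- vapply(sort(unique(assignment)), function(cl) {
    members <- which(assignment == cl)
    if (length(members) == 1) return(members)
    members[which.min(rowMeans(D[members, members, drop = FALSE]))]
  }, 1L)
  list(assignment = assignment, representatives = reps, dist = D)
}

#' Filter scored designs and select the best per cluster
#'
#' Keeps designs with at least `contacts_cutoff` potential contacts per
#' residue, then TERM interface score at most `score_cutoff`, then at most
#' `per_cluster` best-scoring designs (ascending score, ties broken by
#' design id) from each cluster.
#'
#' @param records data.frame with columns `design_id`, `contacts_per_res`,
#'   `term_score` and `cluster` (cluster id at the selection threshold).
#' @param contacts_cutoff minimum contacts per residue.
#' @param score_cutoff maximum TERM interface score.
#' @param per_cluster designs kept per cluster.
#' @return `records` with a logical `selected` column added, original row
#'   order preserved.
#' @export
filter_and_select <- function(records, contacts_cutoff = 2.5,
                              score_cutoff = 0.2, per_cluster = 3) {
  stopifnot(all(c("design_id", "contacts_per_res", "term_score", "cluster")
                %in% names(records)))
  pass <- records$contacts_per_res >= contacts_cutoff &
    records$term_score <= score_cutoff
  selected <- rep(FALSE, nrow(records))
  for (cl in unique(records$cluster[pass])) {
    members <- which(pass & records$cluster == cl)
    ord <- members[order(records$term_score[members],
                         records$design_id[members])]
    selected[utils::head(ord, per_cluster)] <- TRUE
  }
  records$selected <- selected
  records
}
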