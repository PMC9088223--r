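# Shared fixtures, built once per test run and cached. Everything is
# generated in code from fixed seeds; nothing is read from disk.

.fix <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fix[[key]])) .fix[[key]] <- builder()
  .fix[[key]]
}

sheet_complex <- function() memo("sheet", function()
  make_toy_complex("sheet-pair", peptide_len = 10))

helix_complex <- function() memo("helix", function()
  make_toy_complex("helix-on-sheet", peptide_len = 10))

sheet_db <- function() memo("sheet_db", function()
  make_planted_db(list(sheet_complex()), n_copies = 2, rng_seed = 7))

# seeds generated around the sheet complex's binding site
sheet_seeds <- function() memo("sheet_seeds", function() {
  cx <- sheet_complex()
  bs <- define_binding_site(cx$chains, "P")
  site <- bs$binding_site
  site[, 1] <- 1L
  generate_seeds(cx$chains["R"], site, sheet_db(),
                 fragment_params(n_min_matches = 3))
})

# target-only view of the sheet complex (peptide stripped)
sheet_target <- function() sheet_complex()$chains["R"]

# a small random backbone: an ideal chain with Gaussian coordinate noise,
# randomly posed
random_backbone <- function(n = 8, sigma = 0.3,
                            kind = c("helix", "strand")) {
  kind <- sample(kind, 1)
  ch <- build_ideal_chain(kind, n)
  ch$xyz <- ch$xyz + array(stats::rnorm(length(ch$xyz), 0, sigma),
                           dim = dim(ch$xyz))
  R <- random_rotation_test()
  apply_transform(ch, rigid_transform(R, stats::runif(3, -30, 30)))
}

random_rotation_test <- function() {
  M <- matrix(stats::rnorm(9), 3, 3)
  q <- qr(M)
  Q <- qr.Q(q) %*% diag(sign(diag(qr.R(q))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

as_seed <- function(chain, id = "s") {
  structure(list(chain = chain, source_id = id, source_res = seq_len(nres(chain)),
                 match_rmsd = 0, ss = rep("C", nres(chain)),
                 distance_to_protein = NA_real_, seed_id = id),
            class = "seed")
}

# Horn's closed-form quaternion superposition: the independent oracle for
# Kabsch (maximum eigenvalue of the 4x4 quaternion matrix; quaternions
# parameterise proper rotations only, so no reflection can be returned)
horn_rmsd <- function(mobile, fixed) {
  A <- sweep(mobile, 2, colMeans(mobile))
  B <- sweep(fixed, 2, colMeans(fixed))
  S <- crossprod(A, B)
  K <- rbind(
    c(S[1, 1] + S[2, 2] + S[3, 3], S[2, 3] - S[3, 2], S[3, 1] - S[1, 3], S[1, 2] - S[2, 1]),
    c(S[2, 3] - S[3, 2], S[1, 1] - S[2, 2] - S[3, 3], S[1, 2] + S[2, 1], S[3, 1] + S[1, 3]),
    c(S[3, 1] - S[1, 3], S[1, 2] + S[2, 1], -S[1, 1] + S[2, 2] - S[3, 3], S[2, 3] + S[3, 2]),
    c(S[1, 2] - S[2, 1], S[3, 1] + S[1, 3], S[2, 3] + S[3, 2], -S[1, 1] - S[2, 2] + S[3, 3]))
  lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  sqrt(max(0, (sum(A^2) + sum(B^2) - 2 * lam) / nrow(A)))
}

# brute-force substructure scan: every same-length window tuple of every
# chain, optimal superposition, no pruning
brute_force_matches <- function(fragment, db, rmsd_cutoff) {
  nseg <- length(fragment$segments)
  lens <- fragment$seg_len
  out <- list()
  for (ci in seq_along(db$chains)) {
    ch <- db$chains[[ci]]
    starts_by_seg <- lapply(lens, function(L) {
      n <- nres(ch)
      if (n < L) return(integer(0))
      st <- seq_len(n - L + 1)
      brk <- chain_breaks(ch)
      if (length(brk))
        st <- st[vapply(st, function(s) !any(brk %in% s:(s + L - 2)), TRUE)]
      st
    })
    if (any(!vapply(starts_by_seg, length, 1L))) next
    combos <- as.matrix(do.call(expand.grid, starts_by_seg))
    for (ri in seq_len(nrow(combos))) {
      spans <- lapply(seq_len(nseg), function(s)
        combos[ri, s]:(combos[ri, s] + lens[s] - 1))
      if (nseg > 1 && length(unique(unlist(spans))) != sum(lens)) next
      w <- do.call(rbind, lapply(spans, function(sp) bb_coords(ch, sp)))
      r <- suppressWarnings(superpose(w, fragment$coords)$rmsd)
      if (r <= rmsd_cutoff + 1e-9)
        out[[length(out) + 1]] <- list(source = ci, starts = combos[ri, ],
                                       rmsd = r)
    }
  }
  out
}

# brute-force overlap detection: every window pair, full criterion
brute_force_overlaps <- function(seeds, params) {
  L <- params$window_len
  wins <- list()
  for (si in seq_along(seeds)) {
    ch <- seeds[[si]]$chain
    n <- nres(ch)
    if (n < L) next
    for (st in seq_len(n - L + 1)) {
      brk <- chain_breaks(ch)
      if (length(brk) && any(brk %in% st:(st + L - 2))) next
      wins[[length(wins) + 1]] <- list(seed = si, start = st)
    }
  }
  rows <- list()
  frame_of <- function(si, k) {
    ch <- seeds[[si]]$chain
    x <- ch$xyz[k, "N", ] - ch$xyz[k, "CA", ]
    x <- x / sqrt(sum(x^2))
    v <- ch$xyz[k, "C", ] - ch$xyz[k, "CA", ]
    z <- c(x[2] * v[3] - x[3] * v[2], x[3] * v[1] - x[1] * v[3],
           x[1] * v[2] - x[2] * v[1])
    z <- z / sqrt(sum(z^2))
    cbind(x, c(z[2] * x[3] - z[3] * x[2], z[3] * x[1] - z[1] * x[3],
               z[1] * x[2] - z[2] * x[1]), z)
  }
  for (a in seq_along(wins)) for (b in seq_along(wins)) {
    if (b <= a) next
    wa <- wins[[a]]; wb <- wins[[b]]
    if (wa$seed == wb$seed) next
    ok <- TRUE
    for (t in 0:(L - 1)) {
      ca_a <- seeds[[wa$seed]]$chain$xyz[wa$start + t, "CA", ]
      ca_b <- seeds[[wb$seed]]$chain$xyz[wb$start + t, "CA", ]
      if (sqrt(sum((ca_a - ca_b)^2)) > params$max_ca_dist) { ok <- FALSE; break }
      Ra <- frame_of(wa$seed, wa$start + t); Rb <- frame_of(wb$seed, wb$start + t)
      tr <- sum(diag(crossprod(Ra, Rb)))
      ang <- acos(min(1, max(-1, (tr - 1) / 2))) * 180 / pi
      if (ang > params$max_frame_angle) { ok <- FALSE; break }
    }
    if (ok) rows[[length(rows) + 1]] <-
        data.frame(seed_i = wa$seed, win_i = wa$start,
                   seed_j = wb$seed, win_j = wb$start)
  }
  if (!length(rows)) return(data.frame(seed_i = integer(0), win_i = integer(0),
                                       seed_j = integer(0), win_j = integer(0)))
  do.call(rbind, rows)
}

edge_key_set <- function(df) {
  if (!nrow(df)) return(character(0))
  a <- pmin(paste(df$seed_i, df$win_i), paste(df$seed_j, df$win_j))
  b <- pmax(paste(df$seed_i, df$win_i), paste(df$seed_j, df$win_j))
  sort(paste(a, b, sep = "|"))
}

# random energy table over a reduced alphabet
random_energy_table <- function(n_pos, alphabet, p_pair = 1, scale = 1) {
  self <- matrix(stats::rnorm(n_pos * length(alphabet), sd = scale),
                 n_pos, length(alphabet))
  pair <- list()
  for (i in seq_len(n_pos - 1)) for (j in (i + 1):n_pos) {
    if (stats::runif(1) <= p_pair) {
      pair[[sprintf("%d:%d", i, j)]] <-
        matrix(stats::rnorm(length(alphabet)^2, sd = scale),
               length(alphabet), length(alphabet))
    }
  }
  energy_table(n_pos, alphabet, self, pair)
}

# exhaustive optimum over every sequence (tiny alphabets only)
enumerate_optimum <- function(tab, n_charged = NULL) {
  A <- length(tab$alphabet)
  combos <- as.matrix(do.call(expand.grid, rep(list(seq_len(A)), tab$n)))
  charged <- tab$alphabet %in% c("R", "D", "E", "K")
  best <- Inf; best_s <- NULL
  for (r in seq_len(nrow(combos))) {
    idx <- combos[r, ]
    if (!is.null(n_charged) && sum(charged[idx]) != n_charged) next
    e <- sequence_energy(tab, tab$alphabet[idx])
    if (e < best) { best <- e; best_s <- idx }
  }
  list(sequence = paste(tab$alphabet[best_s], collapse = ""), energy = best)
}
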