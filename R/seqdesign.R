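# Sequence-space analyses over linear energy tables: Metropolis Monte-Carlo
# simulated annealing with temperature selection by a target mean energy,
# conservation/consensus statistics, and exact optimisation under a
# charged-residue constraint.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Linear sequence energy table
#'
#' The energy of a sequence is linear in per-position self terms and
#' position-pair terms: `E(s) = sum_i self(i, s_i) + sum_{i<j} pair(i, j,
#' s_i, s_j)`; absent pairs contribute 0.
#'
#' @param n_positions number of positions.
#' @param alphabet amino-acid alphabet.
#' @param self `n x |alphabet|` self-energy matrix (default all zero).
#' @param pair named list `"i:j"` of `|alphabet| x |alphabet|` matrices,
#'   i < j.
#' @export
energy_table <- function(n_positions, alphabet = AA20, self = NULL,
                         pair = list()) {
  if (is.null(self)) self <- matrix(0, n_positions, length(alphabet))
  stopifnot(nrow(self) == n_positions, ncol(self) == length(alphabet),
            all(is.finite(self)))
  colnames(self) <- alphabet
  for (k in names(pair)) {
    ij <- as.integer(strsplit(k, ":")[[1]])
    stopifnot(length(ij) == 2, ij[1] < ij[2], ij[2] <= n_positions,
              all(dim(pair[[k]]) == length(alphabet)),
              all(is.finite(pair[[k]])))
    dimnames(pair[[k]]) <- list(alphabet, alphabet)
  }
  structure(list(n = n_positions, alphabet = alphabet, self = self,
                 pair = pair), class = "energy_table")
}

#' @export
print.energy_table <- function(x, ...) {
  cat(sprintf("<energy_table> %d positions, %d-letter alphabet, %d pair term(s)\n",
              x$n, length(x$alphabet), length(x$pair)))
  invisible(x)
}

#' Read an energy table from text
#'
#' Format: header `ETAB n_positions`, then lines `SELF pos aa value` and
#' `PAIR pos_i pos_j aa_i aa_j value` (1-based positions, one-letter codes).
#'
#' @param path file path (or a character vector of lines).
#' @return an `energy_table`.
#' @export
read_energy_table <- function(path) {
  lines <- if (length(path) == 1 && file.exists(path)) readLines(path) else path
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  hdr <- strsplit(lines[1], "\\s+")[[1]]
  if (length(hdr) != 2 || hdr[1] != "ETAB")
    stop("line 1: expected header 'ETAB n_positions'")
  n <- as.integer(hdr[2])
  tab <- energy_table(n)
  seen_self <- new.env(parent = emptyenv())
  for (ln in seq_along(lines)[-1]) {
    f <- strsplit(lines[ln], "\\s+")[[1]]
    if (f[1] == "SELF") {
      if (length(f) != 4) stop(sprintf("line %d: malformed SELF line", ln))
      pos <- as.integer(f[2]); aa <- f[3]; val <- as.numeric(f[4])
      if (is.na(pos) || pos < 1 || pos > n || is.na(val))
        stop(sprintf("line %d: bad SELF entry", ln))
      if (!aa %in% tab$alphabet)
        stop(sprintf("line %d: unknown amino acid '%s'", ln, aa))
      key <- paste(pos, aa)
      if (!is.null(seen_self[[key]]))
        stop(sprintf("line %d: duplicate SELF entry for (%d, %s)", ln, pos, aa))
      seen_self[[key]] <- TRUE
      tab$self[pos, aa] <- val
    } else if (f[1] == "PAIR") {
      if (length(f) != 6) stop(sprintf("line %d: malformed PAIR line", ln))
      i <- as.integer(f[2]); j <- as.integer(f[3])
      ai <- f[4]; aj <- f[5]; val <- as.numeric(f[6])
      if (is.na(i) || is.na(j) || i >= j || j > n || is.na(val))
        stop(sprintf("line %d: bad PAIR entry", ln))
      if (!ai %in% tab$alphabet || !aj %in% tab$alphabet)
        stop(sprintf("line %d: unknown amino acid", ln))
      key <- sprintf("%d:%d", i, j)
      if (is.null(tab$pair[[key]]))
        tab$pair[[key]] <- matrix(0, length(tab$alphabet), length(tab$alphabet),
                                  dimnames = list(tab$alphabet, tab$alphabet))
      tab$pair[[key]][ai, aj] <- val
    } else stop(sprintf("line %d: unknown record '%s'", ln, f[1]))
  }
  tab
}

#' Write an energy table as text
#' @param tab an `energy_table`.
#' @param path output path (omit to return the lines).
#' @export
write_energy_table <- function(tab, path = NULL) {
  lines <- sprintf("ETAB %d", tab$n)
  nz <- which(tab$self != 0, arr.ind = TRUE)
  for (r in seq_len(nrow(nz)))
    lines <- c(lines, sprintf("SELF %d %s %.10g", nz[r, 1],
                              tab$alphabet[nz[r, 2]], tab$self[nz[r, 1], nz[r, 2]]))
  for (k in names(tab$pair)) {
    ij <- as.integer(strsplit(k, ":")[[1]])
    nzp <- which(tab$pair[[k]] != 0, arr.ind = TRUE)
    for (r in seq_len(nrow(nzp)))
      lines <- c(lines, sprintf("PAIR %d %d %s %s %.10g", ij[1], ij[2],
                                tab$alphabet[nzp[r, 1]], tab$alphabet[nzp[r, 2]],
                                tab$pair[[k]][nzp[r, 1], nzp[r, 2]]))
  }
  if (!is.null(path)) { writeLines(lines, path); return(invisible(lines)) }
  lines
}

as_seq_idx <- function(tab, sequence) {
  s <- if (length(sequence) == 1) strsplit(sequence, "")[[1]] else sequence
  if (length(s) != tab$n) stop("sequence length does not match table")
  idx <- match(s, tab$alphabet)
  if (anyNA(idx)) stop("sequence contains letters outside the alphabet")
  idx
}

#' Energy of a sequence under a table
#' @param tab an `energy_table`.
#' @param sequence string or character vector of length `tab$n`.
#' @export
sequence_energy <- function(tab, sequence) {
  idx <- as_seq_idx(tab, sequence)
  e <- sum(tab$self[cbind(seq_len(tab$n), idx)])
  for (k in names(tab$pair)) {
    ij <- as.integer(strsplit(k, ":")[[1]])
    e <- e + tab$pair[[k]][idx[ij[1]], idx[ij[2]]]
  }
  unname(e)
}

# vectorised energies for a matrix of sequences (rows = sequences, integer
# alphabet indices)
batch_energy <- function(tab, S) {
  n <- tab$n
  e <- rowSums(matrix(tab$self[cbind(rep(seq_len(n), each = nrow(S)),
                                     as.vector(S))], nrow(S), n))
  for (k in names(tab$pair)) {
    ij <- as.integer(strsplit(k, ":")[[1]])
    e <- e + tab$pair[[k]][cbind(S[, ij[1]], S[, ij[2]])]
  }
  e
}

#' Annealing parameters for sequence sampling
#'
#' @param t_grid final temperatures to scan, in units of the table's energy
#'   standard deviation (NULL: a default geometric grid).
#' @param n_samples Metropolis samples collected per final temperature.
#' @param n_sigma_est uniform-random sequences used to estimate the table's
#'   energy standard deviation.
#' @param burn_frac burn-in fraction at the final temperature.
#' @param thin thinning stride.
#' @param rng_seed reproducibility seed.
#' @export
anneal_params <- function(t_grid = NULL, n_samples = 2000,
                          n_sigma_est = 10000, burn_frac = 0.1, thin = 10,
                          rng_seed = 1) {
  structure(list(t_grid = t_grid, n_samples = n_samples,
                 n_sigma_est = n_sigma_est, burn_frac = burn_frac,
                 thin = thin, rng_seed = rng_seed), class = "anneal_params")
}

#' Sample a sequence ensemble by Metropolis simulated annealing
#'
#' The table's energy scale is estimated as the standard deviation `s` of
#' uniform-random sequence energies; the minimum energy `E_min` is computed
#' exactly; and the target mean energy is `E = E_min + s/2`. For each final
#' temperature in the grid the sampler anneals geometrically from a hot
#' start, then collects Metropolis samples (single-position mutations) at the
#' fixed final temperature. The ensemble whose mean energy is closest to `E`
#' is returned.
#'
#' @param tab an `energy_table`.
#' @param params an `anneal_params`.
#' @return a `sequence_ensemble`: sampled sequences and energies, the
#'   per-position frequency profile, conservation in bits, consensus
#'   sequence, and the selected temperature.
#' @export
sample_sequences <- function(tab, params = anneal_params()) {
  set.seed(params$rng_seed %% .Machine$integer.max)
  n <- tab$n; A <- length(tab$alphabet)
  S0 <- matrix(sample.int(A, params$n_sigma_est * n, replace = TRUE),
               params$n_sigma_est, n)
  sigma <- stats::sd(batch_energy(tab, S0))
  if (!is.finite(sigma) || sigma == 0) sigma <- 1e-9
  e_min <- optimal_sequence(tab)$energy
  e_target <- e_min + sigma / 2
  t_grid <- params$t_grid %||% (sigma * c(0.05, 0.1, 0.2, 0.35, 0.6, 1, 1.8, 3))
  t_grid <- pmax(t_grid, 1e-12)
  best <- NULL
  for (t_final in t_grid) {
    ens <- metropolis_run(tab, t_final, params)
    gap <- abs(mean(ens$energies) - e_target)
    if (is.null(best) || gap < best$gap) best <- c(ens, list(gap = gap,
                                                             t_final = t_final))
  }
  freqs <- apply(best$seqs, 2, function(col)
    tabulate(col, nbins = A) / length(col))
  rownames(freqs) <- tab$alphabet
  cons <- conservation_bits(freqs)
  consensus <- consensus_from_freqs(freqs, tab$alphabet)
  structure(list(seqs = best$seqs, energies = best$energies,
                 sequences = apply(best$seqs, 1, function(r)
                   paste(tab$alphabet[r], collapse = "")),
                 freqs = freqs, conservation = cons, consensus = consensus,
                 t_final = best$t_final, sigma = sigma, e_min = e_min,
                 e_target = e_target, alphabet = tab$alphabet),
            class = "sequence_ensemble")
}

#' @export
print.sequence_ensemble <- function(x, ...) {
  cat(sprintf("<sequence_ensemble> %d sequences x %d positions, mean E %.3f (target %.3f)\nconsensus: %s\n",
              nrow(x$seqs), ncol(x$seqs), mean(x$energies), x$e_target,
              x$consensus))
  invisible(x)
}

# anneal geometrically from 5*sigma-ish hot start to t_final, then sample
metropolis_run <- function(tab, t_final, params) {
  n <- tab$n; A <- length(tab$alphabet)
  # per-position pair partner lists for O(1) single-site deltas
  partners <- vector("list", n)
  for (k in names(tab$pair)) {
    ij <- as.integer(strsplit(k, ":")[[1]])
    partners[[ij[1]]] <- c(partners[[ij[1]]], list(list(j = ij[2], M = tab$pair[[k]], row = TRUE)))
    partners[[ij[2]]] <- c(partners[[ij[2]]], list(list(j = ij[1], M = tab$pair[[k]], row = FALSE)))
  }
  site_energy <- function(s, i, a) {
    e <- tab$self[i, a]
    for (p in partners[[i]]) {
      e <- e + if (p$row) p$M[a, s[p$j]] else p$M[s[p$j], a]
    }
    e
  }
  s <- sample.int(A, n, replace = TRUE)
  t_hi <- max(t_final * 50, t_final)
  stages <- t_hi * (t_final / t_hi)^(seq(0, 1, length.out = 15))
  for (tt in stages) {
    for (step in seq_len(20 * n)) {
      i <- sample.int(n, 1); a <- sample.int(A, 1)
      de <- site_energy(s, i, a) - site_energy(s, i, s[i])
      if (de <= 0 || stats::runif(1) < exp(-de / tt)) s[i] <- a
    }
  }
  total <- params$n_samples * params$thin
  burn <- ceiling(params$burn_frac * total)
  out <- matrix(0L, params$n_samples, n)
  energies <- numeric(params$n_samples)
  cur_e <- sequence_energy(tab, tab$alphabet[s])
  kept <- 0L
  for (step in seq_len(total + burn)) {
    i <- sample.int(n, 1); a <- sample.int(A, 1)
    de <- site_energy(s, i, a) - site_energy(s, i, s[i])
    if (de <= 0 || stats::runif(1) < exp(-de / t_final)) {
      s[i] <- a; cur_e <- cur_e + de
    }
    if (step > burn && (step - burn) %% params$thin == 0) {
      kept <- kept + 1L
      out[kept, ] <- s
      energies[kept] <- cur_e
    }
  }
  list(seqs = out[seq_len(kept), , drop = FALSE],
       energies = energies[seq_len(kept)])
}

#' Per-position conservation in bits and consensus sequence
#'
#' Conservation is the maximum possible entropy minus the plug-in entropy of
#' the observed amino-acid frequencies, in bits: an invariant column scores
#' `log2(20)`, a uniform column 0. The consensus takes the most frequent
#' amino acid per position, ties broken alphabetically.
#'
#' @param x a `sequence_ensemble`, a frequency matrix (alphabet x positions),
#'   or a character vector of equal-length sequences.
#' @return list with `bits` and `consensus`.
#' @export
conservation_and_consensus <- function(x) {
  if (inherits(x, "sequence_ensemble")) {
    freqs <- x$freqs; alphabet <- x$alphabet
  } else if (is.matrix(x)) {
    freqs <- x; alphabet <- rownames(x) %||% AA20
  } else {
    if (!length(x)) stop("empty ensemble")
    chars <- do.call(rbind, strsplit(x, ""))
    alphabet <- AA20
    freqs <- apply(chars, 2, function(col)
      vapply(alphabet, function(a) mean(col == a), 1))
  }
  list(bits = conservation_bits(freqs),
       consensus = consensus_from_freqs(freqs, alphabet))
}

conservation_bits <- function(freqs) {
  apply(freqs, 2, function(p) {
    p <- p[p > 0]
    log2(nrow(freqs)) + sum(p * log2(p))
  })
}

consensus_from_freqs <- function(freqs, alphabet) {
  paste(alphabet[apply(freqs, 2, which.max)], collapse = "")
}

#' Exact minimum-energy sequence, optionally with a charge constraint
#'
#' Finds the global minimum of the linear sequence energy, optionally subject
#' to the total number of charged residues (Arg, Asp, Glu, Lys; His is
#' excluded as uncharged at neutral pH) being exactly (or at most)
#' `n_charged`. The optimum is certified by branch-and-bound with an
#' admissible lower bound (per-position minima given assigned interactions,
#' plus global pair minima among unassigned positions, plus a sorted-delta
#' bound for the remaining charge budget), so the returned sequence attains
#' the true optimum.
#'
#' @param tab an `energy_table`.
#' @param n_charged required number of charged residues (NULL: unconstrained).
#' @param mode `"eq"` (exactly `n_charged`) or `"le"` (at most).
#' @return list with `sequence` (string) and `energy`.
#' @export
optimal_sequence <- function(tab, n_charged = NULL, mode = c("eq", "le")) {
  mode <- match.arg(mode)
  n <- tab$n; A <- length(tab$alphabet)
  charged <- tab$alphabet %in% CHARGED_AA
  if (!is.null(n_charged)) {
    stopifnot(n_charged >= 0, n_charged <= n)
    if (mode == "eq" && n_charged > 0 && !any(charged))
      stop("infeasible: alphabet has no charged residues")
  }
  # pair matrices keyed both ways for fast access
  P <- vector("list", n)
  for (i in seq_len(n)) P[[i]] <- list()
  pair_min <- matrix(0, n, n)
  for (k in names(tab$pair)) {
    ij <- as.integer(strsplit(k, ":")[[1]])
    P[[ij[1]]][[as.character(ij[2])]] <- tab$pair[[k]]
    P[[ij[2]]][[as.character(ij[1])]] <- t(tab$pair[[k]])
    pair_min[ij[1], ij[2]] <- pair_min[ij[2], ij[1]] <- min(tab$pair[[k]])
  }
  # incumbent via greedy sequential assignment
  greedy <- integer(n)
  for (i in seq_len(n)) {
    cost <- tab$self[i, ]
    for (j in as.integer(names(P[[i]]))) if (j < i)
      cost <- cost + P[[i]][[as.character(j)]][, greedy[j]]
    greedy[i] <- which.min(cost)
  }
  if (!is.null(n_charged)) {
    # repair the greedy incumbent to satisfy the charge constraint
    rep_seq <- greedy
    nc <- sum(charged[rep_seq])
    while (nc != n_charged && (mode == "eq" || nc > n_charged)) {
      target_class <- nc < n_charged
      cand_pos <- which(charged[rep_seq] != target_class)
      bestd <- Inf; besti <- NA; besta <- NA
      for (i in cand_pos) {
        opts <- which(charged == target_class)
        cost <- tab$self[i, opts]
        for (j in as.integer(names(P[[i]])))
          cost <- cost + P[[i]][[as.character(j)]][opts, rep_seq[j]]
        k2 <- which.min(cost)
        d <- cost[k2] - site_cost(tab, P, rep_seq, i, rep_seq[i])
        if (d < bestd) { bestd <- d; besti <- i; besta <- opts[k2] }
      }
      rep_seq[besti] <- besta
      nc <- sum(charged[rep_seq])
    }
    incumbent <- rep_seq
  } else incumbent <- greedy
  best_e <- seq_energy_idx(tab, incumbent)
  best_s <- incumbent
  # branch and bound over positions 1..n
  assign <- integer(n)
  recurse <- function(d, e_assigned, n_charged_used) {
    if (d > n) {
      ok <- is.null(n_charged) ||
        (mode == "eq" && n_charged_used == n_charged) ||
        (mode == "le" && n_charged_used <= n_charged)
      if (ok && e_assigned < best_e - 1e-12) {
        best_e <<- e_assigned; best_s <<- assign
      }
      return(invisible(NULL))
    }
    rest <- d:n
    # per-position class minima given assigned interactions
    mins_u <- numeric(length(rest)); mins_c <- numeric(length(rest))
    ord_cost <- vector("list", length(rest))
    for (t in seq_along(rest)) {
      i <- rest[t]
      cost <- tab$self[i, ]
      for (j in as.integer(names(P[[i]]))) if (j < d)
        cost <- cost + P[[i]][[as.character(j)]][, assign[j]]
      ord_cost[[t]] <- cost
      mins_u[t] <- min(cost[!charged])
      mins_c[t] <- if (any(charged)) min(cost[charged]) else Inf
    }
    pair_lb <- 0
    if (length(rest) > 1) {
      sub <- pair_min[rest, rest, drop = FALSE]
      pair_lb <- sum(sub[upper.tri(sub)][sub[upper.tri(sub)] < 0])
    }
    lb_uncon <- sum(pmin(mins_u, mins_c)) + pair_lb
    if (is.null(n_charged)) {
      lb <- lb_uncon
    } else {
      c_rem_min <- if (mode == "eq") n_charged - n_charged_used else 0
      c_rem_max <- n_charged - n_charged_used
      if (c_rem_max < 0 || (mode == "eq" && c_rem_min > length(rest)))
        return(invisible(NULL))
      delta <- sort(mins_c - mins_u)
      base <- sum(mins_u) + pair_lb
      csum <- c(0, cumsum(delta))
      cc_range <- max(0, c_rem_min):min(length(rest), c_rem_max)
      lb <- min(base + csum[cc_range + 1])
    }
    if (e_assigned + lb >= best_e - 1e-12) return(invisible(NULL))
    cost_d <- ord_cost[[1]]
    for (a in order(cost_d)) {
      assign[d] <<- a
      recurse(d + 1, e_assigned + cost_d[a],
              n_charged_used + as.integer(charged[a]))
    }
    assign[d] <<- 0L
    invisible(NULL)
  }
  recurse(1L, 0, 0L)
  list(sequence = paste(tab$alphabet[best_s], collapse = ""),
       energy = unname(best_e))
}

site_cost <- function(tab, P, s, i, a) {
  e <- tab$self[i, a]
  for (j in as.integer(names(P[[i]])))
    e <- e + P[[i]][[as.character(j)]][a, s[j]]
  e
}

seq_energy_idx <- function(tab, idx) sequence_energy(tab, tab$alphabet[idx])

#' Percent sequence identity, optionally over a masked position set
#'
#' @param seq_a,seq_b equal-length sequences (strings or vectors).
#' @param mask positions to score (default: all positions).
#' @return percent identity in `[0, 100]`.
#' @export
recovery_metrics <- function(seq_a, seq_b, mask = NULL) {
  a <- if (length(seq_a) == 1) strsplit(seq_a, "")[[1]] else seq_a
  b <- if (length(seq_b) == 1) strsplit(seq_b, "")[[1]] else seq_b
  if (length(a) != length(b)) stop("sequences must have equal length")
  if (is.null(mask) || !length(mask)) mask <- seq_along(a)
  stopifnot(all(mask >= 1), all(mask <= length(a)))
  100 * mean(a[mask] == b[mask])
}
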