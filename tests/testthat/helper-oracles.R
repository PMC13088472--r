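# Independent oracles used to cross-check the implementation. These are
# deliberately naive (enumeration, brute force, off-the-shelf hierarchical
# clustering) and share no code with the package internals.

# single-linkage clone partition via stats::hclust on the full distance
# matrix, cut at the threshold
oracle_single_linkage <- function(junctions, threshold = 0.1) {
  n <- length(junctions)
  if (n == 1L) return(1L)
  chars <- strsplit(junctions, "")
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d[i, j] <- d[j, i] <- mean(chars[[i]] != chars[[j]])
  }
  hc <- stats::hclust(stats::as.dist(d), method = "single")
  stats::cutree(hc, h = threshold)
}

# exact two-sided signed-rank p by enumeration of all 2^n sign patterns
oracle_signed_rank_p <- function(a, b) {
  d <- (a - b)[a != b]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  mu <- n * (n + 1) / 4
  min(1, mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9))
}

# exact two-sided Mann-Whitney p by enumeration of all group assignments
oracle_mann_whitney_p <- function(a, b) {
  x <- c(a, b); na <- length(a)
  u_of <- function(idx) {
    g1 <- x[idx]; g2 <- x[-idx]
    sum(outer(g1, g2, ">")) + 0.5 * sum(outer(g1, g2, "=="))
  }
  u_obs <- u_of(seq_len(na))
  combs <- utils::combn(length(x), na)
  mu <- na * length(b) / 2
  u_all <- apply(combs, 2, u_of)
  min(1, mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9))
}

# union length of 0-based half-open integer intervals clipped to [lo, hi)
oracle_interval_union <- function(starts, ends, lo, hi) {
  pos <- rep(FALSE, hi - lo)
  for (i in seq_along(starts)) {
    a <- max(starts[i], lo); b <- min(ends[i], hi)
    if (b > a) pos[(a - lo + 1):(b - lo)] <- TRUE
  }
  sum(pos)
}

# adjusted Rand index between two labelings (contingency-table formula)
oracle_ari <- function(x, y) {
  tab <- table(x, y)
  a <- sum(choose(tab, 2))
  b <- sum(choose(rowSums(tab), 2))
  c2 <- sum(choose(colSums(tab), 2))
  n <- sum(tab)
  expected <- b * c2 / choose(n, 2)
  mx <- (b + c2) / 2
  if (mx == expected) return(1)
  (a - expected) / (mx - expected)
}

# small simulation config shared across tests: four subsets, modest clone
# counts, 5x error-free coverage unless overridden
small_sim_config <- function(seed = 1, n_clones = 15L, shm = NULL,
                             error = 0, q15 = 0, reads = 5) {
  subs <- vhrep::subset_defaults()
  for (s in names(subs)) {
    subs[[s]]$n_clones <- n_clones
    if (!is.null(shm)) subs[[s]]$shm_rate <- shm
  }
  vhrep::sim_config(seed = seed, subsets = subs, per_base_read_error = error,
                    reads_per_molecule_law = list(name = "constant", value = reads),
                    q15_fraction = q15)
}

# match recovered unique sequences back to truth rows (by subset + sequence)
truth_index <- function(rearrangements, molecules) {
  tr <- molecules[!duplicated(paste(molecules$timepoint, molecules$subset,
                                    molecules$nt_sequence)), ]
  mi <- match(paste(rearrangements$timepoint, rearrangements$cell_subset,
                    rearrangements$sequence),
              paste(tr$timepoint, tr$subset, tr$nt_sequence))
  list(truth = tr, idx = mi)
}
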