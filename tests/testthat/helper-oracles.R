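# Independent brute-force oracles used to cross-check the package's
# statistics. These deliberately use direct formula enumeration rather than
# the implementation's algorithms.

# Exact HWE p by direct enumeration of heterozygote counts with the
# conditional probability formula P(h | nA, n) = n! / (nAA! h! naa!) * 2^h
# * nA! na! / (2n)!.
oracle_hwe <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  hets <- seq(min(nA, na) %% 2, min(nA, na), by = 2)
  logp <- vapply(hets, function(h) {
    naa <- (na - h) / 2; nAA <- (nA - h) / 2
    lfactorial(n) - lfactorial(nAA) - lfactorial(h) - lfactorial(naa) +
      h * log(2) + lfactorial(nA) + lfactorial(na) - lfactorial(2 * n)
  }, 0)
  p <- exp(logp)
  p_obs <- p[match(n_Aa, hets)]
  min(1, sum(p[p <= p_obs * (1 + 1e-7)]))
}

# One-sided (enrichment) Fisher p for [[a,b],[c,d]]: hypergeometric upper
# tail of the top-left cell.
oracle_fisher_greater <- function(a, b, c_, d) {
  m <- a + b; n <- c_ + d; k <- a + c_
  xs <- max(0, k - n):min(m, k)
  p <- exp(lchoose(m, xs) + lchoose(n, k - xs) - lchoose(m + n, k))
  sum(p[xs >= a])
}

# Two-sided Fisher p for an r x c table by full enumeration of tables with
# the observed margins (probability-mass definition with the standard
# relative tie tolerance).
oracle_fisher_rxc <- function(tab, eps = 1e-7) {
  rs <- rowSums(tab); cs <- colSums(tab)
  logK <- sum(lfactorial(rs)) + sum(lfactorial(cs)) - lfactorial(sum(tab))
  logp_obs <- logK - sum(lfactorial(tab))
  total <- 0
  nr <- length(rs); nc <- length(cs)
  rec <- function(row, cols_left, logacc) {
    if (row == nr) {
      logp <- logK + logacc - sum(lfactorial(cols_left))
      if (logp <= logp_obs + log1p(eps)) total <<- total + exp(logp)
      return(invisible())
    }
    cells <- integer(nc)
    fill <- function(cidx, rem) {
      if (cidx == nc) {
        cells[nc] <<- rem
        if (rem <= cols_left[nc]) {
          rec(row + 1, cols_left - cells,
              logacc - sum(lfactorial(cells)))
        }
        return(invisible())
      }
      for (v in 0:min(rem, cols_left[cidx])) {
        cells[cidx] <<- v
        fill(cidx + 1, rem - v)
      }
    }
    fill(1, rs[row])
    invisible()
  }
  rec(1, cs, 0)
  min(1, total)
}

# Maximal cliques by exhaustive subset enumeration (<= 12 nodes). Edges as a
# 2-column character matrix; returns sorted list of sorted gene vectors.
oracle_cliques <- function(nodes, edges, min_size = 2) {
  adj <- matrix(FALSE, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(edges))) {
    adj[edges[i, 1], edges[i, 2]] <- TRUE
    adj[edges[i, 2], edges[i, 1]] <- TRUE
  }
  n <- length(nodes)
  subsets <- list()
  for (mask in seq_len(2^n - 1)) {
    mem <- nodes[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
    if (length(mem) < min_size) next
    sub <- adj[mem, mem, drop = FALSE]
    if (all(sub[upper.tri(sub)])) subsets[[length(subsets) + 1]] <- mem
  }
  # keep maximal only
  keep <- vapply(seq_along(subsets), function(i) {
    !any(vapply(seq_along(subsets), function(j)
      j != i && all(subsets[[i]] %in% subsets[[j]]), TRUE))
  }, TRUE)
  cl <- lapply(subsets[keep], sort)
  cl[order(vapply(cl, paste, "", collapse = "|"))]
}

# Transitive closure of the r^2 >= threshold relation by repeated expansion.
oracle_ld_partition <- function(r2, thr) {
  n <- nrow(r2)
  adj <- (!is.na(r2) & r2 >= thr - 1e-12) | diag(n) > 0
  repeat {
    nxt <- (adj %*% adj) > 0
    if (identical(nxt, adj)) break
    adj <- nxt
  }
  grp <- integer(n)
  g <- 0
  for (i in seq_len(n)) {
    if (grp[i] == 0) { g <- g + 1; grp[adj[i, ]] <- g }
  }
  grp
}

# normalise a partition (group labels by first appearance) for comparison
canon_partition <- function(grp) match(grp, unique(grp))
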