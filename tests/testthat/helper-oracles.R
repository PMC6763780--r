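# Independent oracles (brute force / enumeration / closed form) used to
# check the package's statistics. These never call the code paths they test.

# Step-up BH by the definition: sort, p * m / rank, cumulative min from the
# largest, cap at 1, restore order.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  scaled <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(scaled)))
  pmin(adj, 1)[order(ord)]
}

# Exact two-sided Wilcoxon p by full enumeration of all C(n+m, n) group
# assignments (no ties assumed).
wilcox_enum_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  ranks <- rank(pooled)
  w_obs <- sum(ranks[seq_len(nx)])
  combos <- utils::combn(nx + ny, nx)
  w_all <- apply(combos, 2, function(idx) sum(ranks[idx]))
  p_lo <- mean(w_all <= w_obs)
  p_hi <- mean(w_all >= w_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# Two-sided 2x2 Fisher p by direct hypergeometric summation over all tables
# with the observed margins (tables as improbable as the observed one).
fisher22_oracle <- function(tab) {
  stopifnot(all(dim(tab) == c(2, 2)))
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  dens <- stats::dhyper(support, m, n, k)
  d_obs <- stats::dhyper(tab[1, 1], m, n, k)
  sum(dens[dens <= d_obs * (1 + 1e-7)])
}

# Upper-tail hypergeometric p by summation (ORA oracle).
hyper_tail_oracle <- function(overlap, set_size, universe, list_size) {
  kk <- overlap:min(set_size, list_size)
  sum(stats::dhyper(kk, set_size, universe - set_size, list_size))
}

# Brute-force UPGMA returning the cophenetic distance matrix.
upgma_cophenetic_oracle <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  members <- as.list(seq_len(n))
  act <- seq_len(n)
  coph <- matrix(0, n, n)
  dd <- d
  while (length(act) > 1) {
    best <- c(NA, NA); bd <- Inf
    for (i in seq_along(act)) for (j in seq_len(i - 1)) {
      if (dd[act[i], act[j]] < bd) { bd <- dd[act[i], act[j]]; best <- c(act[i], act[j]) }
    }
    a <- best[1]; b <- best[2]
    for (p in members[[a]]) for (q in members[[b]])
      coph[p, q] <- coph[q, p] <- bd
    na <- length(members[[a]]); nb <- length(members[[b]])
    for (k in setdiff(act, c(a, b)))
      dd[a, k] <- dd[k, a] <- (na * dd[a, k] + nb * dd[b, k]) / (na + nb)
    members[[a]] <- c(members[[a]], members[[b]])
    act <- setdiff(act, b)
  }
  coph
}
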