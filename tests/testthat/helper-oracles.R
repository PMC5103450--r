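# Independent brute-force oracles. These deliberately avoid the code paths
# (and where possible the library routines) used by the package itself.

# two-sided Fisher exact p by explicit hypergeometric enumeration over the
# support of the first cell, probabilities from choose() products
oracle_fisher <- function(a, b, c_, d) {
  r1 <- a + b; r2 <- c_ + d; k <- a + c_; n <- a + b + c_ + d
  lo <- max(0L, k - r2); hi <- min(r1, k)
  xs <- lo:hi
  probs <- choose(r1, xs) * choose(r2, k - xs) / choose(n, k)
  p_obs <- probs[xs == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Benjamini-Hochberg by the definition: sort, p * m / rank, cummin from the
# largest p, cap at 1, restore order
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# exact two-sided rank-sum p by enumeration of all C(n, n_a) group
# assignments of the observed (tie-free) values
oracle_wilcox_exact <- function(a, i) {
  vals <- c(a, i)
  n_a <- length(a)
  r <- rank(vals)
  u_obs <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  subsets <- utils::combn(length(vals), n_a)
  u_all <- apply(subsets, 2L, function(s) sum(r[s]) - n_a * (n_a + 1) / 2)
  p <- 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs))
  min(p, 1)
}

# exhaustive permutation p for the Welch z: all subsets of size n_a
oracle_perm_exact <- function(values, active) {
  n_a <- sum(active)
  z_obs <- welch_z(values[active], values[!active])
  subsets <- utils::combn(length(values), n_a)
  z_all <- apply(subsets, 2L, function(s) {
    z <- welch_z(values[s], values[-s])
    if (!is.finite(z)) 0 else z
  })
  tol <- 1e-8 * (1 + abs(z_obs))
  mean(abs(z_all) >= abs(z_obs) - tol)
}

# Rand index between two label vectors (pair-counting definition)
rand_index <- function(x, y) {
  stopifnot(length(x) == length(y))
  x <- unname(x); y <- unname(y)
  n <- length(x)
  agree <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      same_x <- x[i] == x[j]
      same_y <- y[i] == y[j]
      agree <- agree + (same_x == same_y)
    }
  }
  agree / choose(n, 2)
}

link_key <- function(d) paste(d$probe_id, d$gene_id)
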