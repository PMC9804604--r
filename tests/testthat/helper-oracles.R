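# Independent oracles: literal-definition implementations, kept free of the
# package's own code paths.

# NODF by exhaustive pair enumeration with the decreasing-fill rule
nodf_oracle <- function(m) {
  m <- (m > 0) * 1
  paired <- function(u, v) {        # ordered: fill(u) > fill(v)
    fu <- sum(u); fv <- sum(v)
    if (fu <= fv || fv == 0) return(0)
    sum(u & v) / fv
  }
  s <- 0; np <- 0
  for (i in seq_len(nrow(m) - 1)) for (j in (i + 1):nrow(m)) {
    fi <- sum(m[i, ]); fj <- sum(m[j, ])
    s <- s + if (fi > fj) paired(m[i, ], m[j, ]) else paired(m[j, ], m[i, ])
    np <- np + 1
  }
  for (i in seq_len(ncol(m) - 1)) for (j in (i + 1):ncol(m)) {
    fi <- sum(m[, i]); fj <- sum(m[, j])
    s <- s + if (fi > fj) paired(m[, i], m[, j]) else paired(m[, j], m[, i])
    np <- np + 1
  }
  100 * s / np
}

# weighted Newman-Girvan Q by direct double sum over the full adjacency
modularity_oracle <- function(adj, membership) {
  m2 <- sum(adj)                    # 2m for a symmetric adjacency
  k <- rowSums(adj)
  q <- 0
  for (i in seq_len(nrow(adj))) for (j in seq_len(ncol(adj))) {
    if (membership[i] == membership[j]) {
      q <- q + adj[i, j] - k[i] * k[j] / m2
    }
  }
  q / m2
}

# symmetric adjacency of a bipartite count matrix
bip_adjacency <- function(counts) {
  np <- nrow(counts); na <- ncol(counts)
  adj <- matrix(0, np + na, np + na)
  adj[seq_len(np), np + seq_len(na)] <- counts
  adj[np + seq_len(na), seq_len(np)] <- t(counts)
  adj
}

# all set partitions of 1..n, enumerated iteratively as restricted growth
# strings (a[1] = 1; a[i] <= 1 + max(a[1..i-1]))
all_partitions <- function(n) {
  bell <- c(1, 2, 5, 15, 52, 203, 877, 4140, 21147, 115975)
  stopifnot(n >= 1, n <= 10)
  out <- vector("list", bell[n])
  a <- rep(1L, n)
  idx <- 0L
  repeat {
    idx <- idx + 1L
    out[[idx]] <- a
    # successor: rightmost position that can be incremented
    i <- n
    while (i > 1) {
      if (a[i] <= max(a[seq_len(i - 1)])) break
      i <- i - 1
    }
    if (i == 1) break
    a[i] <- a[i] + 1L
    if (i < n) a[(i + 1):n] <- 1L
  }
  out[seq_len(idx)]
}

# exhaustive modularity optimum over every partition (feasible to ~10 nodes);
# evaluates the same double-sum formula as modularity_oracle, expressed with
# matrix operations so the full enumeration stays fast
best_partition_oracle <- function(adj) {
  m2 <- sum(adj)
  k <- rowSums(adj)
  b <- (adj - outer(k, k) / m2) / m2
  best <- -Inf; best_p <- NULL
  for (p in all_partitions(nrow(adj))) {
    q <- sum(b[outer(p, p, "==")])
    if (q > best) { best <- q; best_p <- p }
  }
  list(q = best, partition = best_p)
}

# all-pairs shortest paths by Floyd-Warshall on lengths 1/count
distance_oracle <- function(counts) {
  adj <- bip_adjacency(counts)
  n <- nrow(adj)
  d <- matrix(Inf, n, n); diag(d) <- 0
  d[adj > 0] <- 1 / adj[adj > 0]
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  d
}

closeness_oracle <- function(counts) {
  d <- distance_oracle(counts)
  n <- nrow(d)
  vapply(seq_len(n), function(i) {
    reach <- which(is.finite(d[i, ]) & seq_len(n) != i)
    if (length(reach) == 0) return(0)
    length(reach) / sum(d[i, reach])
  }, numeric(1))
}

# d' by re-derivation: KL divergence standardised between the
# largest-remainder minimum and ln(m/A_i)
dprime_oracle <- function(counts) {
  one_margin <- function(m) {
    total <- sum(m)
    q <- colSums(m) / total
    sapply(seq_len(nrow(m)), function(i) {
      ai <- sum(m[i, ])
      p <- m[i, ] / ai
      d <- sum(ifelse(p > 0, p * log(p / q), 0))
      dmax <- log(total / ai)
      ideal <- ai * q
      alloc <- floor(ideal)
      left <- ai - sum(alloc)
      if (left > 0) {
        ord <- order(ideal - alloc, decreasing = TRUE)
        alloc[ord[seq_len(left)]] <- alloc[ord[seq_len(left)]] + 1
      }
      pm <- alloc / ai
      dmin <- sum(ifelse(pm > 0, pm * log(pm / q), 0))
      if (dmax - dmin < 1e-15) 0 else min(1, max(0, (d - dmin) / (dmax - dmin)))
    })
  }
  list(plants = one_margin(counts), pollinators = one_margin(t(counts)))
}

# connected components by reachability over boolean adjacency powers
components_oracle <- function(counts) {
  adj <- bip_adjacency(counts) > 0
  n <- nrow(adj)
  reach <- adj | diag(TRUE, n)
  for (k in seq_len(n)) reach <- reach | (reach %*% reach) > 0
  memb <- integer(n); lab <- 0
  for (i in seq_len(n)) {
    if (memb[i] == 0) {
      lab <- lab + 1
      memb[reach[i, ]] <- lab
    }
  }
  memb
}

# 2D Newton root-finder with numerical Jacobian (for fixed-point oracles)
newton2d <- function(f, x0, tol = 1e-12, max_iter = 200) {
  x <- x0
  for (it in seq_len(max_iter)) {
    fx <- f(x)
    if (max(abs(fx)) < tol) return(x)
    eps <- 1e-7
    jac <- matrix(0, 2, 2)
    for (j in 1:2) {
      xp <- x; xp[j] <- xp[j] + eps
      jac[, j] <- (f(xp) - fx) / eps
    }
    x <- x - solve(jac, fx)
  }
  stop("Newton did not converge")
}
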