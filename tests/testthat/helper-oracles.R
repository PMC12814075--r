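# Independent brute-force oracles. These re-derive each quantity from its
# definition with naive loops, deliberately sharing no code with the
# package implementation.

# direct DFT band-power: explicit double loop over bins and time
oracle_band_power <- function(series, tr, band) {
  n <- length(series)
  total <- 0
  for (k in 1:floor(n / 2)) { # k cycles over the run; bin index k+1
    f <- k / (n * tr)
    if (f < band[1] - 1e-12 || f > band[2] + 1e-12) next
    re <- sum(series * cos(-2 * pi * k * (0:(n - 1)) / n))
    im <- sum(series * sin(-2 * pi * k * (0:(n - 1)) / n))
    total <- total + 2 * (re^2 + im^2) / n^2
  }
  total
}

# Kendall's W from first principles: rank each series over time, sum
# ranks per time point, normalize the rank-sum variance
oracle_kendall_w <- function(series_matrix) {
  k <- nrow(series_matrix)
  n <- ncol(series_matrix)
  rks <- matrix(0, k, n)
  for (i in 1:k) rks[i, ] <- rank(series_matrix[i, ])
  r_sum <- colSums(rks)
  s <- sum((r_sum - mean(r_sum))^2)
  12 * s / (k^2 * (n^3 - n))
}

# all-pairs BFS distances on a binary adjacency matrix
oracle_bfs_dist <- function(adj, s) {
  n <- nrow(adj)
  d <- rep(Inf, n)
  d[s] <- 0
  frontier <- s
  while (length(frontier)) {
    nxt <- integer(0)
    for (u in frontier) {
      for (v in which(adj[u, ] == 1)) {
        if (is.infinite(d[v])) {
          d[v] <- d[u] + 1
          nxt <- c(nxt, v)
        }
      }
    }
    frontier <- nxt
  }
  d
}

# shortest-path counts via layered DP
oracle_path_counts <- function(adj, s) {
  n <- nrow(adj)
  d <- oracle_bfs_dist(adj, s)
  sigma <- rep(0, n)
  sigma[s] <- 1
  for (dist in sort(unique(d[is.finite(d) & d > 0]))) {
    for (v in which(d == dist)) {
      preds <- which(adj[v, ] == 1 & d == dist - 1)
      sigma[v] <- sum(sigma[preds])
    }
  }
  list(d = d, sigma = sigma)
}

# normalized betweenness by explicit pair enumeration
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  btw <- rep(0, n)
  for (s in 1:(n - 1)) {
    ps <- oracle_path_counts(adj, s)
    for (t in (s + 1):n) {
      if (!is.finite(ps$d[t]) || ps$d[t] == 0) next
      pt <- oracle_path_counts(adj, t)
      for (v in 1:n) {
        if (v == s || v == t) next
        if (is.finite(ps$d[v]) && is.finite(pt$d[v]) &&
            ps$d[v] + pt$d[v] == ps$d[t]) {
          btw[v] <- btw[v] + ps$sigma[v] * pt$sigma[v] / ps$sigma[t]
        }
      }
    }
  }
  btw / ((n - 1) * (n - 2) / 2)
}

# Wasserman-Faust component-scaled closeness
oracle_closeness <- function(adj) {
  n <- nrow(adj)
  vapply(1:n, function(u) {
    d <- oracle_bfs_dist(adj, u)
    reach <- which(is.finite(d) & seq_len(n) != u)
    if (!length(reach)) return(0)
    nr <- length(reach)
    (nr / (n - 1)) * (nr / sum(d[reach]))
  }, numeric(1))
}

# local clustering by triangle enumeration
oracle_clustering <- function(adj) {
  n <- nrow(adj)
  vapply(1:n, function(u) {
    nb <- which(adj[u, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    tri <- 0
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      tri <- tri + adj[nb[i], nb[j]]
    }
    tri / (k * (k - 1) / 2)
  }, numeric(1))
}

oracle_degree <- function(adj) rowSums(adj) / (nrow(adj) - 1)

# literal re-evaluation of the Power FD formula
oracle_fd <- function(motion, radius = 50) {
  out <- numeric(nrow(motion) - 1)
  for (t in 2:nrow(motion)) {
    s <- 0
    for (j in 1:3) s <- s + abs(motion[t, j] - motion[t - 1, j])
    for (j in 4:6) s <- s + radius * abs(motion[t, j] - motion[t - 1, j])
    out[t - 1] <- s
  }
  out
}

# voxel-loop DVARS
oracle_dvars <- function(arr4d, mask) {
  idx <- which(mask)
  t_len <- dim(arr4d)[4]
  out <- numeric(t_len - 1)
  flat <- matrix(arr4d, prod(dim(arr4d)[1:3]), t_len)
  for (t in 2:t_len) {
    out[t - 1] <- sqrt(mean((flat[idx, t] - flat[idx, t - 1])^2))
  }
  out
}

# hand-stepped BH adjustment
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  prev <- Inf
  for (i in n:1) {
    val <- min(prev, p[o[i]] * n / i)
    q[o[i]] <- val
    prev <- val
  }
  pmin(q, 1)
}

# random connected-ish binary graph on n nodes
random_small_graph <- function(n, p_edge = 0.5) {
  adj <- matrix(0L, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (runif(1) < p_edge) adj[i, j] <- adj[j, i] <- 1L
  }
  adj
}

make_functional_graph <- function(adj) {
  structure(list(adjacency = adj, sparsity = NA_real_,
                 weights = adj, n_nodes = nrow(adj)),
            class = "functional_graph")
}
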