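# Independent oracles used across the suite. These deliberately avoid
# the code paths they check: brute-force enumeration, naive loops, and
# numerical quadrature.

# Naive O(m^2) Benjamini-Hochberg step-up: for each p, q = min over all
# thresholds m*p_(j)/j with p_(j) >= p, clipped at 1.
naive_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(m * ps[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# All simple paths between s and t in an adjacency matrix, as a list of
# vertex index vectors (plain DFS).
.all_paths <- function(adj, s, t) {
  paths <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (v == t) {
      paths[[length(paths) + 1L]] <<- path
      return(invisible())
    }
    for (u in which(adj[v, ] == 1)) {
      if (!u %in% path) walk(c(path, u))
    }
  }
  walk(s)
  paths
}

# Brute-force node and edge betweenness by exhaustive shortest-path
# enumeration. Endpoints excluded for nodes; unordered pairs counted
# once. Returns list(node = vector, edge = matrix-keyed list).
brute_betweenness <- function(adj) {
  n <- nrow(adj)
  node_b <- numeric(n)
  edge_b <- list()
  ekey <- function(a, b) paste(min(a, b), max(a, b), sep = "-")
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      paths <- .all_paths(adj, s, t)
      if (length(paths) == 0) next
      lens <- vapply(paths, length, 1L)
      shortest <- paths[lens == min(lens)]
      sigma <- length(shortest)
      for (p in shortest) {
        inner <- p[-c(1, length(p))]
        for (v in inner) node_b[v] <- node_b[v] + 1 / sigma
        for (i in seq_len(length(p) - 1)) {
          k <- ekey(p[i], p[i + 1])
          edge_b[[k]] <- (if (is.null(edge_b[[k]])) 0 else edge_b[[k]]) + 1 / sigma
        }
      }
    }
  }
  list(node = node_b, edge = edge_b)
}

# Exhaustive upper-tail hypergeometric: over all C(N, n) draws from a
# universe containing K marked items, the fraction with >= k marked.
enum_hypergeom_upper <- function(k, K, n, N) {
  draws <- utils::combn(N, n)
  marked <- colSums(draws <= K)
  mean(marked >= k)
}

# Exhaustive two-sided Fisher p for a 2x2 table: sum of probabilities of
# all tables with the same margins whose probability does not exceed the
# observed one (within a relative tolerance, as in fisher.test).
enum_fisher_two_sided <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  prob <- function(a) stats::dhyper(a, r1, r2, c1)
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(support, prob, 1)
  obs <- prob(tab[1, 1])
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Posterior mean of the exponential signal under the
# normal-plus-exponential model, by numerical quadrature.
quadrature_normexp <- function(x, mu, sigma, alpha) {
  f <- function(s) stats::dexp(s, rate = 1 / alpha) * stats::dnorm(x - s, mu, sigma)
  # integrate over the window where the Gaussian factor has support, so
  # the quadrature cannot miss the narrow spike near s = x - mu
  lo <- max(0, x - mu - 15 * sigma)
  hi <- max(0, x - mu) + 15 * sigma
  num <- stats::integrate(function(s) s * f(s), lo, hi, rel.tol = 1e-10)$value
  den <- stats::integrate(f, lo, hi, rel.tol = 1e-10)$value
  num / den
}

# Random undirected simple graph as an adjacency matrix.
random_adjacency <- function(n, p) {
  adj <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (stats::runif(1) < p) adj[i, j] <- adj[j, i] <- 1L
    }
  }
  adj
}

adjacency_to_igraph <- function(adj) {
  rownames(adj) <- colnames(adj) <- paste0("n", seq_len(nrow(adj)))
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
}
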