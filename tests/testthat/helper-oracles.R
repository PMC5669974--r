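# Independent oracles kept free of the implementation paths they check.

# brute-force all-pairs shortest paths by breadth-first search on an
# adjacency list (undirected, unweighted)
bfs_distances <- function(n, edges) {
  adj <- vector("list", n)
  if (nrow(edges) > 0) {
    for (i in seq_len(nrow(edges))) {
      a <- edges[i, 1]
      b <- edges[i, 2]
      if (a != b) {
        adj[[a]] <- c(adj[[a]], b)
        adj[[b]] <- c(adj[[b]], a)
      }
    }
  }
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (s in seq_len(n)) {
    queue <- s
    while (length(queue) > 0) {
      v <- queue[1]
      queue <- queue[-1]
      for (w in adj[[v]]) {
        if (!is.finite(d[s, w])) {
          d[s, w] <- d[s, v] + 1
          queue <- c(queue, w)
        }
      }
    }
  }
  d
}

# closeness centrality and eccentricity from a distance matrix, component-wise
bfs_metrics <- function(d) {
  n <- nrow(d)
  cc <- numeric(n)
  ecc <- numeric(n)
  for (i in seq_len(n)) {
    di <- d[i, is.finite(d[i, ])]
    di <- di[di > 0]
    cc[i] <- if (length(di) == 0) 0 else length(di) / sum(di)
    ecc[i] <- if (length(di) == 0) 0 else max(di)
  }
  list(CC = cc, E = ecc)
}

# total-variation distance between N(mu1, 1) and N(mu2, 1)
tv_normal <- function(mu1, mu2) 2 * stats::pnorm(abs(mu1 - mu2) / 2) - 1

# algebraic steady state of the receptor -> A Michaelis-Menten cascade,
# solved by root finding on the balance equation
two_node_steady_state <- function(stim, kdec_R, k, K, kdec_A) {
  aR <- stim / (stim + kdec_R)
  f <- function(a) k * aR * (1 - a) / (K + (1 - a)) - kdec_A * a
  aA <- stats::uniroot(f, c(0, 1 - 1e-12), tol = 1e-12)$root
  c(R = aR, A = aA)
}

# one-at-a-time dense-grid sensitivity: range of the AUC of `node` as one
# parameter sweeps its bounds with all others at nominal
grid_sensitivity <- function(model, space, node, n_grid = 25) {
  vapply(seq_len(nrow(space)), function(j) {
    if (space$fixed[j]) return(0)
    grid <- exp(seq(log(space$lower[j]), log(space$upper[j]),
                    length.out = n_grid))
    auc <- vapply(grid, function(v) {
      theta <- stats::setNames(space$nominal, space$name)
      theta[j] <- v
      evaluation_auc(simulate_pathway(model, theta), node)
    }, numeric(1))
    diff(range(auc))
  }, numeric(1))
}
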