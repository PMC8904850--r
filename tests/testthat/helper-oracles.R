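# Shared fixtures and independent brute-force oracles. Everything here is
# deliberately naive (enumeration, path search, closed forms) so it cannot
# share a code path with the implementation it checks.

toy_net <- function(w, theta = 1) brain_network(as.matrix(w), theta = theta)

# chain 1-2-...-n with uniform weight
chain_net <- function(n, w = 0.5) {
  m <- matrix(0, n, n)
  for (i in seq_len(n - 1)) m[i, i + 1] <- m[i + 1, i] <- w
  toy_net(m)
}

# random connected weighted network on n nodes (weights in (0, 1))
rand_toy <- function(n, seed) {
  set.seed(seed)
  repeat {
    m <- matrix(0, n, n)
    ut <- upper.tri(m)
    on <- runif(sum(ut)) < 0.5
    vals <- runif(sum(ut))
    m[ut] <- ifelse(on, round(vals, 3), 0)
    m <- m + t(m)
    g <- igraph::graph_from_adjacency_matrix(m > 0, mode = "undirected")
    if (igraph::is_connected(g)) return(toy_net(m))
  }
}

# exhaustive enumeration of all slow-propagation infection sequences:
# expected activation step and reach probability per node
enum_slow_expected <- function(W, seed) {
  n <- nrow(W)
  exp_step <- numeric(n)
  reach_prob <- numeric(n)
  recurse <- function(infected, prob, step) {
    sus <- setdiff(seq_len(n), infected)
    if (length(sus) == 0) return()
    press <- vapply(sus, function(j) sum(W[infected, j]), numeric(1))
    tot <- sum(press)
    if (tot <= 0) return()
    for (k in seq_along(sus)) {
      if (press[k] <= 0) next
      pj <- prob * press[k] / tot
      j <- sus[k]
      exp_step[j] <<- exp_step[j] + pj * step
      reach_prob[j] <<- reach_prob[j] + pj
      recurse(c(infected, j), pj, step + 1)
    }
  }
  recurse(seed, 1, 1)
  exp_step[seed] <- 0
  reach_prob[seed] <- 1
  list(expected = ifelse(reach_prob > 0, exp_step / reach_prob, NA_real_),
       reach = reach_prob)
}

# rank-pattern correlation straight from the covariance formula with
# population moments
brute_eq1 <- function(a, b) {
  ca <- a - mean(a)
  cb <- b - mean(b)
  mean(ca * cb) / (sqrt(mean(ca^2)) * sqrt(mean(cb^2)))
}

# effective distance by exhaustive enumeration of simple paths over the
# d_ij = 1 - log(w_ij / strength_i) lengths, multi-source over the seed
path_effdist_oracle <- function(W, seed) {
  n <- nrow(W)
  s <- rowSums(W)
  dmat <- matrix(Inf, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && W[i, j] > 0 && s[i] > 0) {
      dmat[i, j] <- 1 - log(W[i, j] / s[i])
    }
  }
  best <- rep(Inf, n)
  best[seed] <- 0
  dfs <- function(node, len, visited) {
    for (j in seq_len(n)) {
      if (!is.finite(dmat[node, j]) || j %in% visited) next
      l2 <- len + dmat[node, j]
      if (l2 < best[j]) best[j] <<- l2
      dfs(j, l2, c(visited, j))
    }
  }
  for (sd0 in seed) dfs(sd0, 0, seed)
  best
}

# exhaustive best size-S resection by surrogate objective
exhaustive_best_surrogate <- function(net, seed, S, pool, cap) {
  combos <- combn(pool, S, simplify = FALSE)
  vals <- vapply(combos, function(s)
    surrogate_objective(net, seed, s, cap = cap), numeric(1))
  list(value = max(vals), sets = combos[vals == max(vals)])
}
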