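# Independent brute-force oracles used to verify the graph machinery.
# These deliberately avoid igraph and the package's own code paths.

# all simple paths between s and t over the nonzero edges of W
.all_simple_paths <- function(W, s, t) {
  p <- nrow(W)
  paths <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (v == t) {
      paths[[length(paths) + 1]] <<- path
      return(invisible())
    }
    for (u in seq_len(p)) {
      if (W[v, u] != 0 && !(u %in% path)) walk(c(path, u))
    }
  }
  walk(s)
  paths
}

.path_length <- function(W, path) {
  sum(vapply(seq_len(length(path) - 1),
             function(k) 1 / abs(W[path[k], path[k + 1]]), numeric(1)))
}

# exhaustive all-pairs shortest-path distances with edge length 1/|w|
oracle_distances <- function(W) {
  p <- nrow(W)
  d <- matrix(Inf, p, p)
  diag(d) <- 0
  for (s in seq_len(p - 1)) {
    for (t in (s + 1):p) {
      paths <- .all_simple_paths(W, s, t)
      if (length(paths)) {
        len <- vapply(paths, .path_length, numeric(1), W = W)
        d[s, t] <- d[t, s] <- min(len)
      }
    }
  }
  d
}

# exhaustive betweenness with fractional credit among tied shortest paths
oracle_betweenness <- function(W, tol = 1e-9) {
  p <- nrow(W)
  b <- numeric(p)
  for (s in seq_len(p - 1)) {
    for (t in (s + 1):p) {
      paths <- .all_simple_paths(W, s, t)
      if (!length(paths)) next
      len <- vapply(paths, .path_length, numeric(1), W = W)
      shortest <- paths[len <= min(len) + tol]
      for (v in seq_len(p)) {
        if (v == s || v == t) next
        through <- sum(vapply(shortest, function(pa) v %in% pa, logical(1)))
        b[v] <- b[v] + through / length(shortest)
      }
    }
  }
  b
}

oracle_closeness <- function(W) {
  d <- oracle_distances(W)
  p <- nrow(W)
  vapply(seq_len(p), function(i) {
    di <- d[i, -i]
    if (any(is.infinite(di))) 0 else (p - 1) / sum(di)
  }, numeric(1))
}

# direct-formula moment oracle (population central moments)
oracle_moments <- function(x) {
  mu <- mean(x)
  m2 <- mean((x - mu)^2); m3 <- mean((x - mu)^3); m4 <- mean((x - mu)^4)
  list(mean = mu, sd = sqrt(sum((x - mu)^2) / (length(x) - 1)),
       skew = m3 / m2^1.5, kurt = m4 / m2^2 - 3)
}

# partial correlations straight from a matrix inverse
oracle_pcor <- function(S) {
  K <- solve(S)
  pc <- -K / sqrt(diag(K) %o% diag(K))
  diag(pc) <- 0
  pc
}

# symptom network from an explicit weights matrix
net_from_weights <- function(W, labels = paste0("V", seq_len(nrow(W)))) {
  new_symptom_network(W, labels)
}

# precision spec wrapping an explicit matrix (bypasses the random generator)
truth_from_precision <- function(K) {
  structure(list(p = nrow(K), precision = K, seed = NA_integer_,
                 params = list()), class = "precision_spec")
}
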