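#' Node strength
#'
#' Sum of absolute incident edge weights, `s_i = sum_j |w_ij|`.
#'
#' @param network a `symptom_network`.
#' @return named numeric vector.
#' @export
node_strength <- function(network) {
  rowSums(abs(network$weights))
}

#' Node expected influence
#'
#' Signed sum of incident edge weights, `ei_i = sum_j w_ij`. Equals strength
#' when no incident edge is negative.
#'
#' @param network a `symptom_network`.
#' @return named numeric vector.
#' @export
node_expected_influence <- function(network) {
  rowSums(network$weights)
}

# weighted graph with edge length 1/|w|
.distance_graph <- function(network) {
  A <- abs(network$weights)
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  if (igraph::ecount(g) > 0)
    igraph::E(g)$weight <- 1 / igraph::E(g)$weight
  g
}

#' All-pairs shortest-path distances
#'
#' Edge length is the reciprocal absolute weight `1/|w_ij|` (the convention
#' of the symptom-network literature: strong edges are short). Unreachable
#' pairs get `Inf`.
#'
#' @param network a `symptom_network`.
#' @return p x p matrix of distances, zero diagonal.
#' @export
node_distances <- function(network) {
  d <- igraph::distances(.distance_graph(network))
  dimnames(d) <- list(network$labels, network$labels)
  d
}

#' Closeness centrality
#'
#' `c_i = (p - 1) / sum_j d(i, j)` over the shortest-path distances of
#' [node_distances()]. A node with any unreachable peer (including isolated
#' nodes) gets closeness 0, keeping the index bounded. Set
#' `harmonic = TRUE` for the harmonic variant
#' `c_i = mean_j 1/d(i, j)`, which degrades gracefully under disconnection.
#'
#' @param network a `symptom_network`.
#' @param harmonic use the harmonic closeness variant.
#' @return named numeric vector.
#' @export
node_closeness <- function(network, harmonic = FALSE) {
  d <- node_distances(network)
  p <- nrow(d)
  out <- vapply(seq_len(p), function(i) {
    di <- d[i, -i]
    if (harmonic) return(mean(1 / di))
    if (any(is.infinite(di))) return(0)
    (p - 1) / sum(di)
  }, numeric(1))
  names(out) <- network$labels
  out
}

#' Betweenness centrality
#'
#' Count-based betweenness over weighted shortest paths (edge length
#' `1/|w|`), with fractional credit shared among tied shortest paths.
#'
#' @param network a `symptom_network`.
#' @return named numeric vector.
#' @export
node_betweenness <- function(network) {
  g <- .distance_graph(network)
  b <- igraph::betweenness(g, directed = FALSE)
  names(b) <- network$labels
  b
}

#' Z-score centrality columns
#'
#' Standardizes each centrality index across the nodes using the population
#' (n-denominator) SD. A constant index yields all zeros with a warning.
#'
#' @param raw data frame of raw per-node indices (plus optional `node`
#'   column, carried through).
#' @return data frame with each numeric column replaced by its z-scores.
#' @export
zscore_centralities <- function(raw) {
  out <- raw
  for (nm in names(raw)) {
    x <- raw[[nm]]
    if (!is.numeric(x)) next
    s <- sqrt(mean((x - mean(x))^2))
    if (s == 0) {
      warning("constant centrality index '", nm, "'; z-scores set to 0")
      out[[nm]] <- rep(0, length(x))
    } else {
      out[[nm]] <- (x - mean(x)) / s
    }
  }
  out
}

#' Node predictability
#'
#' For each node, the R-squared of an ordinary least-squares regression of
#' that node's scores on all remaining nodes: the share of its variance
#' explained by its neighbours.
#'
#' @param scores `mht_scores` data frame or numeric matrix of node columns.
#' @return data frame `node`, `r2`.
#' @export
predictability <- function(scores) {
  X <- if (is.matrix(scores)) scores else score_matrix(scores)
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop("need n > p observations for nodewise regression")
  labs <- colnames(X)
  if (is.null(labs)) labs <- paste0("V", seq_len(p))
  r2 <- vapply(seq_len(p), function(j) {
    y <- X[, j]
    Z <- cbind(1, X[, -j, drop = FALSE])
    if (qr(Z)$rank < ncol(Z))
      stop("degenerate input: singular design when predicting ", labs[j])
    tss <- sum((y - mean(y))^2)
    if (tss == 0)
      stop("degenerate input: constant node ", labs[j])
    fit <- lm.fit(Z, y)
    1 - sum(fit$residuals^2) / tss
  }, numeric(1))
  data.frame(node = labs, r2 = r2, stringsAsFactors = FALSE)
}

#' Centrality (and predictability) table
#'
#' Assembles the per-node indices — strength, expected influence, closeness,
#' betweenness — raw and z-scored, plus predictability when scores are
#' supplied.
#'
#' @param network a `symptom_network`.
#' @param scores optional `mht_scores` for the predictability column.
#' @return data frame of class `centrality_table`: `node`, raw columns
#'   `strength`, `expected_influence`, `closeness`, `betweenness`, their
#'   `*_z` counterparts, and optionally `predictability`.
#' @export
centrality_table <- function(network, scores = NULL) {
  raw <- data.frame(node = network$labels,
                    strength = node_strength(network),
                    expected_influence = node_expected_influence(network),
                    closeness = node_closeness(network),
                    betweenness = node_betweenness(network),
                    stringsAsFactors = FALSE, row.names = NULL)
  z <- suppressWarnings(zscore_centralities(raw[-1]))
  names(z) <- paste0(names(z), "_z")
  out <- cbind(raw, z)
  if (!is.null(scores)) {
    pr <- predictability(scores)
    out$predictability <- pr$r2[match(out$node, pr$node)]
  }
  class(out) <- c("centrality_table", "data.frame")
  out
}
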