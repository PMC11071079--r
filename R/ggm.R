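#' Construct a symptom network object
#'
#' Low-level constructor used by [estimate_network()] and
#' [true_network_of()]. Validates symmetry, zero diagonal and weight bounds.
#'
#' @param weights p x p symmetric partial-correlation matrix, zero diagonal.
#' @param labels node labels.
#' @param lambda,gamma,method,n selection metadata.
#' @return object of class `symptom_network`.
#' @export
new_symptom_network <- function(weights, labels, lambda = NA_real_,
                                gamma = NA_real_, method = NA_character_,
                                n = NA_integer_) {
  weights <- as.matrix(weights)
  p <- nrow(weights)
  stopifnot(ncol(weights) == p, length(labels) == p)
  if (max(abs(weights - t(weights))) > 1e-8)
    stop("weights matrix must be symmetric")
  if (any(diag(weights) != 0)) stop("weights diagonal must be zero")
  if (any(abs(weights) >= 1)) stop("edge weights must have magnitude < 1")
  dimnames(weights) <- list(labels, labels)
  structure(list(labels = as.character(labels), weights = weights,
                 lambda = lambda, gamma = gamma, method = method, n = n,
                 n_edges = sum(weights[upper.tri(weights)] != 0)),
            class = "symptom_network")
}

#' @export
print.symptom_network <- function(x, ...) {
  p <- length(x$labels)
  cat(sprintf("symptom network: %d nodes, %d/%d edges", p, x$n_edges,
              p * (p - 1) / 2))
  if (!is.na(x$lambda))
    cat(sprintf(" (glasso lambda=%.4g, EBIC gamma=%.2g, %s, n=%d)",
                x$lambda, x$gamma, x$method, x$n))
  cat("\n")
  w <- x$weights[upper.tri(x$weights)]
  if (any(w != 0))
    cat(sprintf("  weight range [%.3f, %.3f], %d negative\n",
                min(w[w != 0]), max(w), sum(w < 0)))
  invisible(x)
}

#' Edge list of a network
#'
#' @param x a `symptom_network`.
#' @param ... unused.
#' @param all include zero-weight pairs.
#' @return data frame `node_i`, `node_j`, `weight` (unordered pairs, i < j).
#' @export
as.data.frame.symptom_network <- function(x, ..., all = FALSE) {
  p <- length(x$labels)
  ij <- which(upper.tri(x$weights), arr.ind = TRUE)
  out <- data.frame(node_i = x$labels[ij[, 1]], node_j = x$labels[ij[, 2]],
                    weight = x$weights[ij], stringsAsFactors = FALSE)
  if (!all) out <- out[out$weight != 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Correlation matrix of subscale scores
#'
#' Pearson (default) or Spearman correlations of the eight content subscale
#' scores. Rank-based correlation matrices can be indefinite; if the smallest
#' eigenvalue is negative the matrix is projected to the nearest positive
#' semi-definite correlation matrix (eigenvalue clipping plus re-scaling to
#' unit diagonal) and the smoothing is recorded.
#'
#' @param scores `mht_scores` data frame or numeric matrix of node columns.
#' @param method `"pearson"` or `"spearman"`.
#' @return object of class `mht_cor`: list with `mat`, `method`,
#'   `n_effective`, `smoothed`.
#' @export
correlation_matrix <- function(scores, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  X <- if (is.matrix(scores)) scores else score_matrix(scores)
  if (nrow(X) < ncol(X) + 1)
    stop("need n >= p + 1 observations for correlation estimation")
  if (anyNA(X)) stop("missing values in scores; apply exclusions first")
  sds <- apply(X, 2, sd)
  if (any(sds == 0))
    stop("degenerate input: constant column ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  S <- cor(X, method = method)
  smoothed <- FALSE
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) < 0) {
    v <- pmax(e$values, 0)
    S <- e$vectors %*% diag(v) %*% t(e$vectors)
    d <- 1 / sqrt(diag(S))
    S <- S * tcrossprod(d)
    S <- (S + t(S)) / 2
    smoothed <- TRUE
  }
  structure(list(mat = S, method = method, n_effective = nrow(X),
                 smoothed = smoothed), class = "mht_cor")
}

#' Penalty grid for the graphical lasso
#'
#' Log-spaced grid of `n_lambda` penalties from `lambda_max` (the largest
#' absolute off-diagonal correlation, at which the estimated network is
#' empty) down to `lambda_max * ratio`.
#'
#' @param S an `mht_cor` or plain correlation matrix.
#' @param n_lambda grid size (>= 2).
#' @param ratio ratio of smallest to largest penalty, in (0,1).
#' @return decreasing numeric vector of penalties.
#' @export
lambda_grid <- function(S, n_lambda = 100, ratio = 0.01) {
  stopifnot(n_lambda >= 2, ratio > 0, ratio < 1)
  m <- if (inherits(S, "mht_cor")) S$mat else S
  lmax <- max(abs(m[upper.tri(m)]))
  if (lmax == 0) {
    warning("all off-diagonal correlations are zero; single-point grid at 0")
    return(0)
  }
  g <- exp(seq(log(lmax), log(lmax * ratio), length.out = n_lambda))
  g[1] <- lmax  # guard against one-ulp undershoot of exp(log(lmax))
  g[n_lambda] <- lmax * ratio
  g
}

.loglik_gauss <- function(K, S, n) {
  n / 2 * (determinant(K, logarithm = TRUE)$modulus[1] - sum(S * K))
}

#' Fit the graphical lasso at one penalty
#'
#' Maximizes the L1-penalized Gaussian log-likelihood
#' `log det K - tr(SK) - lambda * sum_(i!=j) |k_ij|` by block coordinate
#' descent (diagonal unpenalized). Partial correlations are recovered from
#' the precision estimate by the sign-flip normalization
#' `pcor_ij = -k_ij / sqrt(k_ii k_jj)`.
#'
#' @param S an `mht_cor` (or correlation matrix; then pass `n`).
#' @param lambda penalty >= 0.
#' @param n sample size (for the log-likelihood).
#' @param tol convergence tolerance on the maximum parameter change.
#' @param maxit maximum coordinate-descent sweeps.
#' @return object of class `glasso_fit`: `lambda`, `precision_estimate`,
#'   `pcor_estimate`, `loglik`, `n_edges`.
#' @export
glasso_fit <- function(S, lambda, n = NULL, tol = 1e-6, maxit = 10000) {
  if (inherits(S, "mht_cor")) {
    if (is.null(n)) n <- S$n_effective
    S <- S$mat
  }
  if (is.null(n)) stop("sample size n is required")
  stopifnot(lambda >= 0)
  res <- .glasso_path_cpp(S, lambda, tol = tol, maxit = maxit)
  if (!res$converged[1])
    stop(sprintf("glasso did not converge in %d sweeps (duality gap %.3e)",
                 maxit, res$gap[1]))
  K <- res$precision[[1]]
  structure(list(lambda = lambda, precision_estimate = K,
                 pcor_estimate = .pcor_from_precision(K),
                 loglik = .loglik_gauss(K, S, n),
                 n_edges = res$n_edges[1]),
            class = "glasso_fit")
}

#' Extended Bayesian Information Criterion of a glasso fit
#'
#' `EBIC = -2 loglik + E log n + 4 E gamma log p`, with E the number of
#' nonzero off-diagonal pairs. `gamma = 0` reduces to the ordinary BIC.
#'
#' @param fit a `glasso_fit`.
#' @param n sample size.
#' @param p node count.
#' @param gamma EBIC hyperparameter (>= 0).
#' @return numeric score (smaller is better).
#' @export
ebic_score <- function(fit, n, p, gamma = 0.5) {
  stopifnot(gamma >= 0)
  E <- fit$n_edges
  -2 * fit$loglik + E * log(n) + 4 * E * gamma * log(p)
}

#' Estimate a regularized partial-correlation network
#'
#' The full pipeline stage: correlation matrix of the subscale scores,
#' graphical-lasso path over a log-spaced penalty grid (warm starts from
#' sparse to dense), EBIC computed for every fit, and the minimum-EBIC
#' penalty selected (ties broken toward the larger penalty, i.e. the sparser
#' network). Edge weights are the partial correlations of the selected
#' precision estimate; absent edges are exact zeros produced by the penalty,
#' with no post-hoc thresholding.
#'
#' @param scores `mht_scores` data frame or numeric matrix of node columns.
#' @param gamma EBIC hyperparameter (default 0.5).
#' @param method correlation method.
#' @param n_lambda,ratio penalty-grid parameters (see [lambda_grid()]).
#' @param labels node labels (default the score column names).
#' @return a `symptom_network` with attributes `path` (data frame of lambda,
#'   EBIC, edge count per grid point) and `correlation` (the `mht_cor` used).
#' @export
#' @examples
#' tr <- make_precision_matrix(8, 0.6, c(0.05, 0.35), 0.06, seed = 3)
#' sim <- simulate_subscale_scores(tr, n = 400, seed = 3)
#' estimate_network(sim$scores)
estimate_network <- function(scores, gamma = 0.5,
                             method = c("pearson", "spearman"),
                             n_lambda = 100, ratio = 0.01, labels = NULL) {
  method <- match.arg(method)
  X <- if (is.matrix(scores)) scores else score_matrix(scores)
  if (is.null(labels))
    labels <- if (!is.null(colnames(X))) colnames(X) else
      paste0("V", seq_len(ncol(X)))
  S <- correlation_matrix(X, method)
  n <- S$n_effective
  p <- ncol(X)
  grid <- lambda_grid(S, n_lambda, ratio)
  res <- .glasso_path_cpp(S$mat, grid)
  if (!all(res$converged))
    stop("glasso failed to converge at lambda = ",
         paste(signif(grid[!res$converged], 4), collapse = ", "))
  ebic <- vapply(seq_along(grid), function(i) {
    ll <- .loglik_gauss(res$precision[[i]], S$mat, n)
    -2 * ll + res$n_edges[i] * log(n) + 4 * res$n_edges[i] * gamma * log(p)
  }, numeric(1))
  # minimum EBIC; on ties prefer the larger penalty (sparser model). The
  # grid is stored in decreasing order, so the first minimizer wins.
  best <- which(ebic <= min(ebic) + 1e-9)[1]
  K <- res$precision[[best]]
  net <- new_symptom_network(.pcor_from_precision(K), labels,
                             lambda = grid[best], gamma = gamma,
                             method = method, n = n)
  attr(net, "path") <- data.frame(lambda = grid, ebic = ebic,
                                  n_edges = res$n_edges)
  attr(net, "correlation") <- S
  attr(net, "precision") <- K
  net
}

#' Write a network to disk
#'
#' Three serializations: a TSV weighted edge list (`node_i node_j weight`),
#' a full adjacency CSV, and a JSON file carrying the weights plus selection
#' metadata (lambda, gamma, correlation method, n).
#'
#' @param network a `symptom_network`.
#' @param stem output path stem (writes `<stem>_edges.tsv`,
#'   `<stem>_adjacency.csv`, `<stem>.json`).
#' @return invisibly, the file paths.
#' @export
write_network <- function(network, stem) {
  edges <- paste0(stem, "_edges.tsv")
  adj <- paste0(stem, "_adjacency.csv")
  js <- paste0(stem, ".json")
  utils::write.table(as.data.frame(network), edges, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  write.csv(as.data.frame(network$weights), adj, row.names = TRUE, quote = FALSE)
  jsonlite::write_json(
    list(labels = network$labels, weights = network$weights,
         lambda = network$lambda, gamma = network$gamma,
         method = network$method, n = network$n, n_edges = network$n_edges),
    js, auto_unbox = TRUE, digits = NA)
  invisible(c(edges = edges, adjacency = adj, json = js))
}

#' Read a network edge list written by [write_network()]
#'
#' @param path TSV edge-list path.
#' @param labels full node label set (edge lists omit isolated nodes).
#' @return a `symptom_network`.
#' @export
read_network_tsv <- function(path, labels) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  p <- length(labels)
  W <- matrix(0, p, p, dimnames = list(labels, labels))
  for (k in seq_len(nrow(df)))
    W[df$node_i[k], df$node_j[k]] <- W[df$node_j[k], df$node_i[k]] <- df$weight[k]
  new_symptom_network(W, labels)
}
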