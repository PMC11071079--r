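#' Generate a ground-truth precision matrix
#'
#' Builds a sparse symmetric positive-definite precision matrix whose implied
#' partial-correlation network has a requested edge density, weight range and
#' fraction of negative edges. Off-diagonal entries are set to minus the
#' desired partial correlation (so positive weights yield positive partial
#' correlations); if the raw matrix is not positive definite with margin, the
#' diagonal is inflated and the matrix rescaled back to unit diagonal.
#'
#' @param p node count.
#' @param edge_density fraction of the p(p-1)/2 node pairs that carry an edge.
#' @param weight_range interval (within (0,1)) from which absolute edge
#'   weights are drawn uniformly.
#' @param negative_fraction fraction of edges given a negative sign. The
#'   default density/weights/negative-fraction describe the package's
#'   standard 8-node fixture: about 17 edges with weights 0.05-0.35, one of
#'   them negative.
#' @param seed integer seed; the construction is deterministic given it.
#' @return object of class `precision_spec`: list with `p`, `precision`
#'   (unit-diagonal SPD matrix), `seed` and the generation parameters.
#' @export
#' @examples
#' tr <- make_precision_matrix(8, 0.6, c(0.05, 0.35), 0.06, seed = 1)
#' min(eigen(tr$precision)$values) > 0
make_precision_matrix <- function(p, edge_density = 0.6,
                                  weight_range = c(0.05, 0.35),
                                  negative_fraction = 0.06, seed = 1) {
  stopifnot(p >= 2, edge_density >= 0, edge_density <= 1,
            negative_fraction >= 0, negative_fraction <= 1)
  if (weight_range[1] < 0 || weight_range[2] >= 1 ||
      weight_range[1] > weight_range[2])
    stop("weight_range must lie within (0,1)")
  set.seed(seed)
  npairs <- p * (p - 1) / 2
  n_edges <- round(edge_density * npairs)
  K <- diag(p)
  if (n_edges > 0) {
    sel <- sort(sample.int(npairs, n_edges))
    w <- runif(n_edges, weight_range[1], weight_range[2])
    n_neg <- round(negative_fraction * n_edges)
    if (n_neg > 0) {
      neg <- sample.int(n_edges, n_neg)
      w[neg] <- -w[neg]
    }
    pair_idx <- which(upper.tri(K))
    K[pair_idx[sel]] <- -w   # sign flip: k_ij = -pcor_ij for unit diagonal
    K[lower.tri(K)] <- t(K)[lower.tri(K)]
  }
  ev_min <- min(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < 0.05) {
    K <- K + diag(0.05 - ev_min, p)      # diagonal dominance adjustment
    d <- 1 / sqrt(diag(K))
    K <- K * tcrossprod(d)               # rescale to unit diagonal
  }
  pc <- .pcor_from_precision(K)
  if (any(abs(pc[upper.tri(pc)]) >= 1))
    stop("generation error: requested density/weights imply |pcor| >= 1")
  structure(list(p = as.integer(p), precision = K, seed = as.integer(seed),
                 params = list(edge_density = edge_density,
                               weight_range = weight_range,
                               negative_fraction = negative_fraction)),
            class = "precision_spec")
}

# partial correlations from a precision matrix: -k_ij / sqrt(k_ii k_jj)
.pcor_from_precision <- function(K) {
  d <- 1 / sqrt(diag(K))
  pc <- -K * tcrossprod(d)
  diag(pc) <- 0
  pc
}

#' Ground-truth partial-correlation network of a precision spec
#'
#' @param truth a `precision_spec`.
#' @param labels node labels (default MHT1..MHTp).
#' @return a `symptom_network` whose weights are the implied partial
#'   correlations, zero diagonal, with no regularization metadata.
#' @export
true_network_of <- function(truth, labels = paste0("MHT", seq_len(truth$p))) {
  new_symptom_network(.pcor_from_precision(truth$precision), labels,
                      lambda = NA_real_, gamma = NA_real_,
                      method = "truth", n = NA_integer_)
}

#' Default marginal targets for the eight MHT subscales
#'
#' Bounded-integer score marginals (support 0..max, target mean and SD)
#' typical of senior-high-school MHT samples: learning anxiety highest and
#' strongly endorsed, horror/loneliness tendencies low with right skew.
#' These are the generator's standard conditions.
#'
#' @return data frame with columns `node`, `max`, `mean`, `sd`.
#' @export
default_marginals <- function() {
  data.frame(
    node = paste0("MHT", 1:8),
    max  = c(15, 10, 10, 10, 10, 15, 10, 10),
    mean = c(8.87, 5.15, 3.63, 5.37, 6.34, 6.68, 3.34, 3.96),
    sd   = c(3.60, 2.73, 2.95, 2.97, 2.44, 3.57, 2.74, 2.89),
    stringsAsFactors = FALSE
  )
}

# beta-binomial CDF on 0..m matching a target mean and sd; collapses to the
# plain binomial when the target variance is at or below binomial variance
.bounded_cdf <- function(m, mu, sd) {
  stopifnot(mu > 0, mu < m, sd > 0)
  pi <- mu / m
  base <- m * pi * (1 - pi)
  rho <- (sd^2 / base - 1) / (m - 1)
  k <- 0:m
  if (rho <= 1e-8) {
    pmf <- stats::dbinom(k, m, pi)
  } else {
    rho <- min(rho, 0.98)
    a <- pi * (1 - rho) / rho
    b <- (1 - pi) * (1 - rho) / rho
    pmf <- exp(lchoose(m, k) + lbeta(k + a, m - k + b) - lbeta(a, b))
  }
  cumsum(pmf / sum(pmf))
}

# monotone quantile map of uniforms onto the bounded integer support
.quantile_map <- function(u, cdf) {
  findInterval(u, cdf, left.open = TRUE)
}

#' Simulate subscale scores from a known network
#'
#' Gaussian-copula generator: draws latent multivariate normal scores with
#' correlation structure implied by the ground-truth precision matrix, then
#' maps each node monotonically through a bounded-integer quantile transform
#' (beta-binomial shape) matching that node's target mean and SD. An
#' independent lie score (binomial on 0..10) is attached so exclusion logic
#' can be exercised orthogonally to the network structure.
#'
#' @param truth a `precision_spec`.
#' @param marginals data frame as [default_marginals()].
#' @param n number of participants.
#' @param seed integer seed; output is bit-identical given (truth, marginals,
#'   n, seed).
#' @return object of class `mht_synth`: list with `scores` (an `mht_scores`
#'   data frame), `latent` (the underlying normal draws), `truth` and
#'   `generator_params`.
#' @export
simulate_subscale_scores <- function(truth, marginals = default_marginals(),
                                     n, seed = 1) {
  stopifnot(n >= 1, nrow(marginals) == truth$p)
  ev <- eigen(truth$precision, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("generation error: precision matrix not positive definite")
  set.seed(seed)
  R <- stats::cov2cor(solve(truth$precision))
  Z <- MASS::mvrnorm(n, mu = rep(0, truth$p), Sigma = R)
  Z <- matrix(Z, nrow = n)
  X <- matrix(0L, n, truth$p)
  for (j in seq_len(truth$p)) {
    cdf <- .bounded_cdf(marginals$max[j], marginals$mean[j], marginals$sd[j])
    X[, j] <- .quantile_map(stats::pnorm(Z[, j]), cdf)
  }
  lie <- rbinom(n, 10, 0.25)
  colnames(X) <- marginals$node
  out <- data.frame(id = seq_len(n), X, lie = lie,
                    total = as.integer(rowSums(X)),
                    stringsAsFactors = FALSE, check.names = FALSE)
  out$grade <- classify_total(out$total)
  class(out) <- c("mht_scores", "data.frame")
  structure(list(scores = out, latent = Z, truth = truth,
                 generator_params = list(n = n, seed = seed,
                                         marginals = marginals)),
            class = "mht_synth")
}

#' Simulate item-level MHT responses from a known network
#'
#' Each participant gets a latent propensity per subscale from the
#' ground-truth multivariate normal; items within a subscale are independent
#' Bernoulli draws whose probability increases with that propensity, so
#' subscale sums depend monotonically (stochastically) on the latent scores.
#' A configurable number of rows receives injected missing answers, and a
#' disjoint set receives lie scores in the invalid 7..10 band, for testing
#' the exclusion path; remaining rows are clamped to valid lie scores so the
#' injected counts are exact.
#'
#' @param truth a `precision_spec` with p = 8.
#' @param spec instrument key.
#' @param n number of participants.
#' @param seed integer seed.
#' @param marginals marginal targets, used for per-subscale base endorsement
#'   rates (mean/max).
#' @param slope logistic slope linking the latent score to item endorsement.
#' @param n_missing rows given 1-3 missing answers.
#' @param n_lie_invalid further rows given a lie score in 7..10.
#' @return an `mht_responses` object with the latent matrix in attribute
#'   `latent`.
#' @export
simulate_item_responses <- function(truth, spec = mht_default_spec(), n,
                                    seed = 1, marginals = default_marginals(),
                                    slope = 1.7, n_missing = 0,
                                    n_lie_invalid = 0) {
  stopifnot(truth$p == length(spec$subscale_names),
            n_missing + n_lie_invalid <= n)
  set.seed(seed)
  R <- stats::cov2cor(solve(truth$precision))
  Z <- matrix(MASS::mvrnorm(n, mu = rep(0, truth$p), Sigma = R), nrow = n)
  m <- matrix(0L, n, spec$total_items)
  for (j in seq_len(truth$p)) {
    items <- spec$items_per_subscale[[j]]
    p0 <- qlogis(marginals$mean[j] / marginals$max[j])
    pr <- plogis(p0 + slope * Z[, j])
    m[, items] <- rbinom(n * length(items), 1L, rep(pr, length(items)))
  }
  m[, spec$lie_items] <- rbinom(n * length(spec$lie_items), 1L, 0.25)
  lie_sum <- rowSums(m[, spec$lie_items, drop = FALSE])

  rows <- sample.int(n, n_missing + n_lie_invalid)
  miss_rows <- rows[seq_len(n_missing)]
  lie_rows <- setdiff(rows, miss_rows)
  # clamp natural lie scores out of the invalid band on non-injected rows
  clamp <- setdiff(which(lie_sum >= 7), lie_rows)
  for (i in clamp) {
    on <- spec$lie_items[m[i, spec$lie_items] == 1L]
    m[i, on[seq_len(lie_sum[i] - 6L)]] <- 0L
  }
  for (i in lie_rows) {
    target <- sample(7:10, 1)
    m[i, spec$lie_items] <- 0L
    m[i, spec$lie_items[seq_len(target)]] <- 1L
  }
  for (i in miss_rows) {
    m[i, sample.int(spec$total_items, sample(1:3, 1))] <- NA_integer_
  }
  out <- mht_responses(m, spec = spec)
  attr(out, "latent") <- Z
  out
}

#' Write a synthetic dataset and its ground truth to disk
#'
#' Scores go to `<stem>.csv` (the dialect [read_scores_csv()] reads); the
#' generating truth (precision matrix, seed, parameters) to `<stem>_truth.json`.
#'
#' @param synth an `mht_synth` object.
#' @param stem output path stem.
#' @return invisibly, the two file paths.
#' @export
write_synthetic <- function(synth, stem) {
  csv <- paste0(stem, ".csv")
  js <- paste0(stem, "_truth.json")
  write_scores_csv(synth$scores, csv)
  jsonlite::write_json(
    list(p = synth$truth$p,
         precision = synth$truth$precision,
         seed = synth$truth$seed,
         params = synth$truth$params,
         generator_params = synth$generator_params[c("n", "seed")]),
    js, auto_unbox = TRUE, digits = NA)
  invisible(c(scores = csv, truth = js))
}
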