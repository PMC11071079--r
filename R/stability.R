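#' Estimation settings reused across bootstrap replicates
#'
#' Bundles the network-estimation hyperparameters so every bootstrap
#' replicate runs the identical pipeline as the sample estimate.
#'
#' @param gamma EBIC hyperparameter.
#' @param method correlation method.
#' @param n_lambda,ratio penalty-grid parameters.
#' @return list of class `estimation_config`.
#' @export
estimation_config <- function(gamma = 0.5, method = "pearson",
                              n_lambda = 100, ratio = 0.01) {
  structure(list(gamma = gamma, method = method, n_lambda = n_lambda,
                 ratio = ratio), class = "estimation_config")
}

.estimate_with <- function(X, config, labels = colnames(X)) {
  estimate_network(X, gamma = config$gamma, method = config$method,
                   n_lambda = config$n_lambda, ratio = config$ratio,
                   labels = labels)
}

# unordered pair bookkeeping: labels "A--B" for i < j
.edge_pairs <- function(labels) {
  p <- length(labels)
  ij <- which(upper.tri(diag(p)), arr.ind = TRUE)
  data.frame(i = ij[, 1], j = ij[, 2],
             edge = paste(labels[ij[, 1]], labels[ij[, 2]], sep = "--"),
             stringsAsFactors = FALSE)
}

.upper_vec <- function(W) W[upper.tri(W)]

.centrality_indices <- c("strength", "expected_influence", "closeness",
                         "betweenness")

.replicate_stats <- function(net) {
  list(edges = .upper_vec(net$weights),
       strength = node_strength(net),
       expected_influence = node_expected_influence(net),
       closeness = node_closeness(net),
       betweenness = node_betweenness(net))
}

.collect_replicates <- function(X, index_list, config, labels, what) {
  B <- length(index_list)
  p <- length(labels)
  npair <- p * (p - 1) / 2
  edges <- matrix(NA_real_, B, npair)
  cent <- lapply(.centrality_indices, function(i) matrix(NA_real_, B, p))
  names(cent) <- .centrality_indices
  failed <- 0L
  for (b in seq_len(B)) {
    st <- tryCatch(
      .replicate_stats(.estimate_with(X[index_list[[b]], , drop = FALSE],
                                      config, labels)),
      error = function(e) NULL)
    if (is.null(st)) { failed <- failed + 1L; next }
    edges[b, ] <- st$edges
    for (nm in .centrality_indices) cent[[nm]][b, ] <- st[[nm]]
  }
  if (failed > 0.05 * B)
    stop(sprintf("%d of %d %s replicates failed estimation", failed, B, what))
  ok <- !is.na(edges[, 1])
  list(edges = edges[ok, , drop = FALSE],
       centralities = lapply(cent, function(m) m[ok, , drop = FALSE]),
       n_failed = failed)
}

#' Nonparametric bootstrap of the network
#'
#' Resamples participants with replacement at the original sample size and
#' re-runs the full estimation pipeline (correlation, glasso path, EBIC
#' selection) plus all centrality indices on every replicate. Replicates
#' whose estimation fails are recorded and skipped; more than 5% failures
#' aborts.
#'
#' @param scores `mht_scores` data frame or numeric matrix.
#' @param B replicate count (2000 recommended for edge CIs).
#' @param seed integer seed; ensembles are identical given (scores, B, seed,
#'   config).
#' @param config an [estimation_config()].
#' @return object of class `bootstrap_ensemble` with the sample network and
#'   centralities, per-replicate edge-weight rows and centrality matrices.
#' @export
nonparametric_bootstrap <- function(scores, B = 2000, seed = 1,
                                    config = estimation_config()) {
  stopifnot(B >= 1)
  X <- if (is.matrix(scores)) scores else score_matrix(scores)
  labels <- colnames(X)
  n <- nrow(X)
  sample_net <- .estimate_with(X, config, labels)
  set.seed(seed)
  idx <- replicate(B, sample.int(n, n, replace = TRUE), simplify = FALSE)
  reps <- .collect_replicates(X, idx, config, labels, "bootstrap")
  structure(c(list(kind = "nonparametric", B = B, seed = seed,
                   labels = labels, pairs = .edge_pairs(labels),
                   sample_network = sample_net,
                   sample_stats = .replicate_stats(sample_net),
                   config = config),
              reps),
            class = "bootstrap_ensemble")
}

#' @export
print.bootstrap_ensemble <- function(x, ...) {
  cat(sprintf("%s bootstrap ensemble: B=%d (%d failed), %d nodes, seed %d\n",
              x$kind, x$B, x$n_failed, length(x$labels), x$seed))
  invisible(x)
}

#' Bootstrap confidence intervals for edge weights
#'
#' Empirical per-edge quantile intervals at level `1 - alpha` (type-7
#' quantiles), alongside the sample estimate and the bootstrap mean.
#'
#' @param ensemble a nonparametric `bootstrap_ensemble`.
#' @param alpha significance level (default 0.05 for 95% CIs).
#' @return data frame: `edge`, `estimate`, `boot_mean`, `lower`, `upper`,
#'   `alpha`.
#' @export
edge_ci <- function(ensemble, alpha = 0.05) {
  stopifnot(inherits(ensemble, "bootstrap_ensemble"),
            ensemble$kind == "nonparametric")
  Bok <- nrow(ensemble$edges)
  if (Bok < 1 / alpha)
    stop(sprintf("need at least %.0f replicates for alpha = %g, have %d",
                 1 / alpha, alpha, Bok))
  lo <- apply(ensemble$edges, 2, quantile, probs = alpha / 2)
  hi <- apply(ensemble$edges, 2, quantile, probs = 1 - alpha / 2)
  data.frame(edge = ensemble$pairs$edge,
             estimate = ensemble$sample_stats$edges,
             boot_mean = colMeans(ensemble$edges),
             lower = lo, upper = hi, alpha = alpha,
             stringsAsFactors = FALSE, row.names = NULL)
}

.resolve_edge <- function(ensemble, edge) {
  if (is.numeric(edge) && length(edge) == 2) {
    i <- min(edge); j <- max(edge)
    k <- which(ensemble$pairs$i == i & ensemble$pairs$j == j)
  } else {
    if (length(edge) == 2) edge <- paste(edge, collapse = "--")
    k <- which(ensemble$pairs$edge == edge |
                 ensemble$pairs$edge == paste(rev(strsplit(edge, "--")[[1]]),
                                              collapse = "--"))
  }
  if (length(k) != 1) stop("unknown edge: ", paste(edge, collapse = ","))
  k
}

#' Bootstrapped difference test for two edge weights
#'
#' The edges differ detectably (`"distinct"`) iff the empirical `1 - alpha`
#' bootstrap interval of their weight difference excludes zero.
#'
#' @param ensemble a nonparametric `bootstrap_ensemble`.
#' @param edge_a,edge_b edges, as `"MHT1--MHT2"` labels, label pairs, or
#'   index pairs `c(i, j)`.
#' @param alpha significance level.
#' @return `"distinct"` or `"indistinct"`.
#' @export
edge_difference_test <- function(ensemble, edge_a, edge_b, alpha = 0.05) {
  a <- .resolve_edge(ensemble, edge_a)
  b <- .resolve_edge(ensemble, edge_b)
  if (a == b) {
    warning("identical edge supplied twice; difference is zero by definition")
    return("indistinct")
  }
  d <- ensemble$edges[, a] - ensemble$edges[, b]
  ci <- quantile(d, c(alpha / 2, 1 - alpha / 2))
  if (ci[1] > 0 || ci[2] < 0) "distinct" else "indistinct"
}

#' Bootstrapped difference test for two nodes' centrality
#'
#' @param ensemble a nonparametric `bootstrap_ensemble`.
#' @param node_a,node_b node labels or indices.
#' @param index centrality index name.
#' @param alpha significance level.
#' @return `"distinct"` or `"indistinct"`.
#' @export
centrality_difference_test <- function(ensemble, node_a, node_b,
                                       index = "strength", alpha = 0.05) {
  index <- match.arg(index, .centrality_indices)
  a <- if (is.numeric(node_a)) node_a else match(node_a, ensemble$labels)
  b <- if (is.numeric(node_b)) node_b else match(node_b, ensemble$labels)
  if (is.na(a) || is.na(b)) stop("unknown node label")
  if (a == b) {
    warning("identical node supplied twice; difference is zero by definition")
    return("indistinct")
  }
  m <- ensemble$centralities[[index]]
  d <- m[, a] - m[, b]
  ci <- quantile(d, c(alpha / 2, 1 - alpha / 2))
  if (ci[1] > 0 || ci[2] < 0) "distinct" else "indistinct"
}

#' Case-dropping bootstrap
#'
#' For each drop proportion, draws `B` subsamples without replacement
#' retaining `(1 - proportion) * n` participants and re-runs the full
#' estimation pipeline on each. Proportions whose retained sample is too
#' small for estimation are skipped with a warning.
#'
#' @param scores `mht_scores` data frame or numeric matrix.
#' @param proportions increasing grid of drop fractions in (0,1).
#' @param B subsamples per proportion (1000 recommended).
#' @param seed integer seed.
#' @param config an [estimation_config()].
#' @return object of class `casedrop_ensemble`: sample statistics plus, per
#'   proportion, replicate edge and centrality matrices.
#' @export
case_dropping_bootstrap <- function(scores,
                                    proportions = seq(0.05, 0.75, by = 0.05),
                                    B = 1000, seed = 1,
                                    config = estimation_config()) {
  stopifnot(all(proportions > 0), all(proportions < 1), B >= 1)
  X <- if (is.matrix(scores)) scores else score_matrix(scores)
  labels <- colnames(X)
  n <- nrow(X); p <- ncol(X)
  sample_net <- .estimate_with(X, config, labels)
  set.seed(seed)
  per_prop <- list()
  used <- numeric(0)
  for (prop in proportions) {
    keep <- round((1 - prop) * n)
    if (keep <= p + 1) {
      warning(sprintf("proportion %.2f retains only %d rows; skipped",
                      prop, keep))
      next
    }
    idx <- replicate(B, sample.int(n, keep, replace = FALSE), simplify = FALSE)
    reps <- .collect_replicates(X, idx, config, labels,
                                sprintf("case-dropping (%.2f)", prop))
    reps$n_retained <- keep
    per_prop[[sprintf("%.2f", prop)]] <- reps
    used <- c(used, prop)
  }
  structure(list(kind = "case_dropping", B = B, seed = seed, labels = labels,
                 pairs = .edge_pairs(labels), proportions = used,
                 sample_network = sample_net,
                 sample_stats = .replicate_stats(sample_net),
                 per_proportion = per_prop, config = config),
            class = "casedrop_ensemble")
}

#' @export
print.casedrop_ensemble <- function(x, ...) {
  cat(sprintf(
    "case-dropping ensemble: %d proportions (%.2f-%.2f), B=%d, seed %d\n",
    length(x$proportions), min(x$proportions), max(x$proportions), x$B,
    x$seed))
  invisible(x)
}

# Pearson correlation between the original statistic vector and one
# replicate; degenerate (zero-variance) vectors count as correlation 0
.stat_cor <- function(orig, rep_vec) {
  if (sd(orig) == 0 || sd(rep_vec) == 0) return(0)
  cor(orig, rep_vec)
}

#' Correlation-stability (CS) coefficient
#'
#' For each drop proportion, correlates the statistic (a centrality index
#' over nodes, or the edge weights over node pairs) of every subsample with
#' the full-sample value, and takes the `1 - certainty` quantile of those
#' correlations. The CS coefficient is the largest tested proportion at
#' which that quantile still reaches the correlation threshold (0 if none
#' does). Values below 0.25 are labelled `unstable`, 0.25-0.5 `acceptable`,
#' 0.5 and above `good`.
#'
#' @param ensemble a `casedrop_ensemble` covering at least two proportions.
#' @param statistic one of `"strength"`, `"expected_influence"`,
#'   `"closeness"`, `"betweenness"`, `"edge_weights"`.
#' @param threshold correlation threshold (default 0.7).
#' @param certainty required certainty level (default 0.95: the 5th
#'   percentile of correlations must clear the threshold).
#' @return object of class `cs_result`: `statistic`, `cs_value`,
#'   `correlation_threshold`, `certainty_level`, `label`, and a per-
#'   proportion table of correlation quantiles.
#' @export
cs_coefficient <- function(ensemble,
                           statistic = c("strength", "expected_influence",
                                         "closeness", "betweenness",
                                         "edge_weights"),
                           threshold = 0.7, certainty = 0.95) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(ensemble, "casedrop_ensemble"))
  if (length(ensemble$proportions) < 2)
    stop("need at least 2 drop proportions to locate a CS coefficient")
  orig <- if (statistic == "edge_weights") ensemble$sample_stats$edges
          else ensemble$sample_stats[[statistic]]
  tab <- lapply(ensemble$proportions, function(prop) {
    reps <- ensemble$per_proportion[[sprintf("%.2f", prop)]]
    m <- if (statistic == "edge_weights") reps$edges
         else reps$centralities[[statistic]]
    cors <- apply(m, 1, .stat_cor, orig = orig)
    data.frame(proportion = prop,
               cor_quantile = quantile(cors, 1 - certainty, names = FALSE),
               cor_median = stats::median(cors))
  })
  tab <- do.call(rbind, tab)
  ok <- tab$proportion[tab$cor_quantile >= threshold]
  cs <- if (length(ok)) max(ok) else 0
  label <- if (cs < 0.25) "unstable" else if (cs < 0.5) "acceptable" else "good"
  structure(list(statistic = statistic, cs_value = cs,
                 correlation_threshold = threshold,
                 certainty_level = certainty, label = label, table = tab),
            class = "cs_result")
}

#' @export
print.cs_result <- function(x, ...) {
  cat(sprintf("CS(%s) = %.2f (%s; threshold %.2f at %.0f%% certainty)\n",
              x$statistic, x$cs_value, x$label, x$correlation_threshold,
              100 * x$certainty_level))
  invisible(x)
}

#' All-pairs bootstrapped difference matrix
#'
#' Upper-triangular logical matrix of [edge_difference_test()] (for
#' `what = "edges"`) or [centrality_difference_test()] outcomes over all
#' unordered pairs: `TRUE` where the pair is distinct.
#'
#' @param ensemble a nonparametric `bootstrap_ensemble`.
#' @param what `"edges"` or a centrality index name.
#' @param alpha significance level.
#' @return logical matrix with `NA` on and below the diagonal.
#' @export
difference_matrix <- function(ensemble, what = "edges", alpha = 0.05) {
  if (what == "edges") {
    m <- ensemble$edges
    nm <- ensemble$pairs$edge
  } else {
    what <- match.arg(what, .centrality_indices)
    m <- ensemble$centralities[[what]]
    nm <- ensemble$labels
  }
  k <- ncol(m)
  out <- matrix(NA, k, k, dimnames = list(nm, nm))
  for (a in seq_len(k - 1)) {
    for (b in (a + 1):k) {
      ci <- quantile(m[, a] - m[, b], c(alpha / 2, 1 - alpha / 2))
      out[a, b] <- (ci[1] > 0 || ci[2] < 0)
    }
  }
  out
}
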