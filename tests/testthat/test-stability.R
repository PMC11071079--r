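# shared medium-sized fixture: clear structure, quick to re-estimate
fix_truth <- make_precision_matrix(8, 0.6, c(0.05, 0.35), 0.06, seed = 1)
fix_sim <- simulate_subscale_scores(fix_truth, n = 5000, seed = 1)
fix_X <- as.matrix(fix_sim$scores[, paste0("MHT", 1:8)])
fix_cfg <- estimation_config()

test_that("an identity resample reproduces the sample network exactly", {
  reps <- mhtnet:::.collect_replicates(fix_X, list(seq_len(nrow(fix_X))),
                                       fix_cfg, colnames(fix_X), "identity")
  net <- estimate_network(fix_X)
  expect_equal(reps$edges[1, ], net$weights[upper.tri(net$weights)])
})

test_that("bootstrap ensembles are reproducible and recover true edges on average", {
  bs <- nonparametric_bootstrap(fix_sim$scores, B = 200, seed = 7)
  bs2 <- nonparametric_bootstrap(fix_sim$scores, B = 200, seed = 7)
  expect_identical(bs$edges, bs2$edges)
  expect_equal(bs$n_failed, 0)

  truth_w <- true_network_of(fix_truth)$weights
  tvec <- truth_w[upper.tri(truth_w)]
  bmean <- colMeans(bs$edges)
  expect_true(all(abs(bmean[tvec != 0] - tvec[tvec != 0]) < 0.05))

  # sample estimate lies inside the replicate range, edge by edge
  expect_true(all(bs$sample_stats$edges >= apply(bs$edges, 2, min) - 1e-12))
  expect_true(all(bs$sample_stats$edges <= apply(bs$edges, 2, max) + 1e-12))

  # CIs: bootstrap median inside every interval, estimate column coherent
  ci <- edge_ci(bs)
  med <- apply(bs$edges, 2, median)
  expect_true(all(ci$lower <= med & med <= ci$upper))
  expect_true(all(ci$lower <= ci$upper))
  expect_error(edge_ci(bs, alpha = 0.001), "replicates")

  # clearly separated edges are flagged distinct
  w <- abs(tvec)
  a <- which.max(w)
  zero_edges <- which(tvec == 0)
  expect_equal(edge_difference_test(bs, c(bs$pairs$i[a], bs$pairs$j[a]),
                                    c(bs$pairs$i[zero_edges[1]],
                                      bs$pairs$j[zero_edges[1]])),
               "distinct")
  expect_warning(same <- edge_difference_test(bs, c(1, 2), c(2, 1)),
                 "identical")
  expect_equal(same, "indistinct")
  # difference tests are symmetric in their arguments
  e1 <- bs$pairs$edge[1]; e2 <- bs$pairs$edge[5]
  expect_equal(edge_difference_test(bs, e1, e2),
               edge_difference_test(bs, e2, e1))
})

test_that("hand-computed quantiles back the edge CI rule", {
  fake <- structure(list(kind = "nonparametric",
                         edges = matrix(seq(0.1, 1, 0.1), ncol = 1),
                         sample_stats = list(edges = 0.5),
                         pairs = data.frame(edge = "A--B")),
                    class = "bootstrap_ensemble")
  ci <- edge_ci(fake, alpha = 0.2)
  expect_equal(ci$lower, 0.19)   # type-7 10th percentile of 0.1..1.0
  expect_equal(ci$upper, 0.91)
  fake$edges <- matrix(0.3, 25, 1)
  ci0 <- edge_ci(fake, alpha = 0.1)
  expect_equal(ci0$lower, 0.3)
  expect_equal(ci0$upper, 0.3)
})

test_that("centrality difference tests separate hubs from isolated nodes", {
  K <- diag(8)
  K[1, 2:5] <- K[2:5, 1] <- -0.25   # hub with four spokes; nodes 6-8 isolated
  hub_truth <- truth_from_precision(K)
  sim <- simulate_subscale_scores(hub_truth, n = 2000, seed = 8)
  bs <- nonparametric_bootstrap(sim$scores, B = 100, seed = 8)
  expect_equal(centrality_difference_test(bs, "MHT1", "MHT7", "strength"),
               "distinct")
  expect_warning(r <- centrality_difference_test(bs, "MHT3", "MHT3"),
                 "identical")
  expect_equal(r, "indistinct")
})

test_that("permutation-symmetric nodes are rarely flagged distinct", {
  K <- diag(8)
  K[1, 2] <- K[2, 1] <- -0.3        # nodes 3..8 exchangeable
  sym_truth <- truth_from_precision(K)
  hits <- 0
  for (s in 1:10) {
    sim <- simulate_subscale_scores(sym_truth, n = 500, seed = s)
    bs <- nonparametric_bootstrap(sim$scores, B = 60, seed = s)
    if (centrality_difference_test(bs, "MHT3", "MHT4", "strength") ==
        "indistinct") hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("case-dropping subsamples degrade gracefully and reproducibly", {
  cd <- case_dropping_bootstrap(fix_sim$scores,
                                proportions = seq(0.1, 0.7, 0.2),
                                B = 30, seed = 9)
  cd2 <- case_dropping_bootstrap(fix_sim$scores,
                                 proportions = seq(0.1, 0.7, 0.2),
                                 B = 30, seed = 9)
  expect_identical(cd$per_proportion, cd2$per_proportion)
  # zero-drop analogue: a full-index subsample equals the sample estimate
  reps <- mhtnet:::.collect_replicates(fix_X, list(seq_len(nrow(fix_X))),
                                       fix_cfg, colnames(fix_X), "full")
  expect_equal(reps$centralities$strength[1, ],
               unname(cd$sample_stats$strength))
  # median correlation with the original declines (weakly) with the drop
  med <- vapply(cd$proportions, function(pr) {
    m <- cd$per_proportion[[sprintf("%.2f", pr)]]$centralities$strength
    median(apply(m, 1, cor, y = cd$sample_stats$strength))
  }, numeric(1))
  expect_lt(cor(cd$proportions, med, method = "spearman"), 0.5)
  expect_lte(med[length(med)], med[1] + 0.02)
  # a proportion that leaves too few rows is skipped with a warning
  tiny <- fix_sim$scores[1:40, ]
  expect_warning(case_dropping_bootstrap(tiny, proportions = c(0.5, 0.9),
                                         B = 5, seed = 9), "skipped")
})

test_that("CS coefficient follows its definition on constructed ensembles", {
  props <- c(0.1, 0.3, 0.5, 0.7)
  orig <- c(3, 1, 4, 1, 5, 9, 2, 6)
  stable <- structure(list(
    kind = "case_dropping", proportions = props,
    sample_stats = list(strength = orig),
    per_proportion = setNames(lapply(props, function(p) list(
      centralities = list(strength = matrix(rep(orig, 20), 20, byrow = TRUE)))),
      sprintf("%.2f", props))), class = "casedrop_ensemble")
  cs <- cs_coefficient(stable, "strength")
  expect_equal(cs$cs_value, 0.7)       # perfect correlation everywhere
  expect_equal(cs$label, "good")

  one_prop <- stable; one_prop$proportions <- 0.1
  expect_error(cs_coefficient(one_prop, "strength"), "at least 2")
})

test_that("CS is monotone in threshold and certainty on a real ensemble", {
  cd <- case_dropping_bootstrap(fix_sim$scores,
                                proportions = seq(0.15, 0.75, 0.2),
                                B = 30, seed = 10)
  cs_by_thr <- vapply(c(0.5, 0.7, 0.9), function(th)
    cs_coefficient(cd, "strength", threshold = th)$cs_value, numeric(1))
  expect_true(all(diff(cs_by_thr) <= 0))
  cs_by_cert <- vapply(c(0.8, 0.9, 0.95), function(ce)
    cs_coefficient(cd, "strength", certainty = ce)$cs_value, numeric(1))
  expect_true(all(diff(cs_by_cert) <= 0))
  # edge-weight variant runs over the 28 pairs
  cs_e <- cs_coefficient(cd, "edge_weights")
  expect_true(cs_e$cs_value %in% c(0, cd$proportions))
})
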