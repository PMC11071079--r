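spec <- mht_default_spec()

test_that("instrument key validates its invariants", {
  expect_s3_class(spec, "mht_instrument")
  expect_equal(sum(spec$subscale_sizes) + length(spec$lie_items), 100L)
  all_items <- c(unlist(spec$items_per_subscale), spec$lie_items)
  expect_setequal(all_items, 1:100)
  # overlapping or incomplete keys are rejected
  bad <- spec$items_per_subscale
  bad$MHT1[1] <- bad$MHT2[1]
  expect_error(mht_instrument_spec(spec$subscale_names, bad, spec$lie_items),
               "disjoint")
  expect_error(mht_instrument_spec(spec$subscale_names[-1],
                                   spec$items_per_subscale[-1],
                                   spec$lie_items), "8 content")
})

test_that("scoring sums items per subscale, lie kept out of the total", {
  zero <- mht_responses(matrix(0L, 1, 100), spec = spec)
  sc0 <- score_responses(zero)
  expect_true(all(as.matrix(sc0[, paste0("MHT", 1:8)]) == 0))
  expect_equal(sc0$lie, 0L)
  expect_equal(sc0$total, 0L)

  one <- mht_responses(matrix(1L, 1, 100), spec = spec)
  sc1 <- score_responses(one)
  expect_equal(unname(unlist(sc1[, paste0("MHT", 1:8)])),
               unname(spec$subscale_sizes))
  expect_equal(sc1$total, 100L - length(spec$lie_items))
  expect_equal(sc1$lie, length(spec$lie_items))
})

test_that("scoring equals a per-item accumulation oracle on random data", {
  set.seed(71)
  m <- matrix(rbinom(50 * 100, 1, 0.4), 50, 100)
  sc <- score_responses(mht_responses(m, spec = spec))
  for (k in 1:8) {
    oracle <- apply(m, 1, function(row) {
      acc <- 0L
      for (it in spec$items_per_subscale[[k]]) acc <- acc + row[it]
      acc
    })
    expect_equal(sc[[paste0("MHT", k)]], oracle)
  }
  expect_equal(sc$total, as.integer(rowSums(m[, 1:90])))
  expect_equal(sc$lie, as.integer(rowSums(m[, 91:100])))
})

test_that("scoring is participant-permutation equivariant and item-order invariant", {
  set.seed(72)
  m <- matrix(rbinom(20 * 100, 1, 0.5), 20, 100)
  sc <- score_responses(mht_responses(m, spec = spec))
  perm <- sample(20)
  sc_p <- score_responses(mht_responses(m[perm, ], spec = spec))
  expect_equal(sc_p$total, sc$total[perm])
  # shuffling items within a subscale leaves every score unchanged
  spec2 <- spec
  spec2$items_per_subscale$MHT3 <- rev(spec2$items_per_subscale$MHT3)
  sc_r <- score_responses(mht_responses(m, spec = spec), spec = spec2)
  expect_equal(sc_r[, -1], sc[, -1])
})

test_that("invalid entries and schema mismatches are rejected with location", {
  m <- matrix(0L, 3, 100)
  m[2, 17] <- 2L
  expect_error(mht_responses(m, spec = spec), "row 2, item 17")
  expect_error(mht_responses(matrix(0L, 3, 99), spec = spec), "schema")
  m2 <- matrix(0L, 2, 100); m2[1, 5] <- NA_integer_
  expect_error(score_responses(mht_responses(m2, spec = spec)), "missing")
})

test_that("exclusion removes incomplete rows first, then lie scores 7-10", {
  base <- matrix(0L, 6, 100)
  base[1, 3] <- NA_integer_             # incomplete
  base[2, 91:97] <- 1L                  # lie = 7: excluded
  base[3, 91:96] <- 1L                  # lie = 6: retained
  base[4, 91:100] <- 1L                 # lie = 10: excluded
  base[5, c(1, 91:99)] <- c(1L, rep(NA_integer_, 9))  # incomplete, not lie
  res <- apply_exclusions(mht_responses(base, spec = spec))
  expect_equal(res$report$n_received, 6)
  expect_equal(res$report$n_incomplete, 2)
  expect_equal(res$report$n_lie_invalid, 2)
  expect_equal(res$report$n_retained, 2)
  expect_equal(res$responses$ids, c(3, 6))
  # conservation and idempotence
  with(res$report, expect_equal(n_received,
                                n_retained + n_incomplete + n_lie_invalid))
  again <- apply_exclusions(res$responses)
  expect_equal(again$report$n_incomplete, 0)
  expect_equal(again$report$n_lie_invalid, 0)
  expect_equal(again$responses$responses, res$responses$responses)
})

test_that("a clean roster passes through unchanged at 100% effective rate", {
  m <- matrix(rbinom(10 * 100, 1, 0.2), 10, 100)
  m[, 91:100] <- 0L
  res <- apply_exclusions(mht_responses(m, spec = spec))
  expect_equal(res$report$effective_rate, 100)
  expect_equal(res$responses$responses,
               mht_responses(m, spec = spec)$responses)
  # empty input yields empty output and zero counts
  e <- apply_exclusions(mht_responses(m[0, , drop = FALSE], spec = spec))
  expect_equal(e$report$n_received, 0)
  expect_equal(nrow(e$responses$responses), 0)
})

test_that("severity grades partition totals at 55/56 and 64/65", {
  expect_equal(as.character(classify_total(c(0, 47, 55))),
               rep("normal", 3))
  expect_equal(as.character(classify_total(c(56, 60, 64))), rep("poor", 3))
  expect_equal(as.character(classify_total(c(65, 90))), rep("severe", 2))
  expect_error(classify_total(-1), "domain")
  # exactly one label per input over the whole range
  g <- classify_total(0:92)
  expect_false(anyNA(g))
  expect_equal(nlevels(g), 3)
})

test_that("subscale flags partition at 3/4 and 7/8", {
  expect_equal(as.character(flag_subscale(8)), "clear_tendency")
  expect_equal(as.character(flag_subscale(3)), "no_tendency")
  expect_equal(as.character(flag_subscale(5)), "intermediate")
  expect_error(flag_subscale(-2), "domain")
  f <- flag_subscale(0:15)
  expect_false(anyNA(f))
})

test_that("descriptives match a direct moment oracle and flag counts", {
  df <- data.frame(matrix(0, 4, 8)); names(df) <- paste0("MHT", 1:8)
  df$MHT1 <- c(0, 0, 10, 10)
  df[paste0("MHT", 2:8)] <- replicate(7, sample(0:5, 4, TRUE))
  d <- descriptive_stats(df)
  expect_equal(d$mean[1], 5)
  expect_equal(d$skew[1], 0)
  expect_equal(d$n_flagged[1], 2)

  set.seed(73)
  df2 <- as.data.frame(matrix(rbinom(8 * 200, 12, 0.4), 200, 8))
  names(df2) <- paste0("MHT", 1:8)
  d2 <- descriptive_stats(df2)
  for (k in 1:8) {
    o <- oracle_moments(df2[[k]])
    expect_equal(d2$mean[k], o$mean, tolerance = 1e-12)
    expect_equal(d2$sd[k], o$sd, tolerance = 1e-12)
    expect_equal(d2$skew[k], o$skew, tolerance = 1e-12)
    expect_equal(d2$kurt[k], o$kurt, tolerance = 1e-12)
    expect_equal(d2$n_flagged[k], sum(df2[[k]] >= 8))
  }
})

test_that("constant columns get NA skew/kurtosis, not NaN", {
  df <- as.data.frame(matrix(5, 10, 8)); names(df) <- paste0("MHT", 1:8)
  d <- descriptive_stats(df)
  expect_true(all(is.na(d$skew)))
  expect_false(any(is.nan(d$skew)))
})

test_that("item responses and scores survive a CSV round trip", {
  set.seed(74)
  m <- matrix(rbinom(12 * 100, 1, 0.3), 12, 100)
  m[2, 7] <- NA_integer_
  resp <- mht_responses(m, spec = spec,
                        metadata = data.frame(age = 15:26))
  tmp <- tempfile(fileext = ".csv")
  df <- data.frame(id = resp$ids, resp$responses, age = 15:26)
  write.csv(df, tmp, row.names = FALSE, na = "")
  back <- read_responses_csv(tmp, spec)
  expect_equal(back$responses, resp$responses)
  expect_equal(back$metadata$age, 15:26)

  sc <- score_responses(apply_exclusions(resp)$responses)
  tmp2 <- tempfile(fileext = ".csv")
  write_scores_csv(sc, tmp2)
  sc2 <- read_scores_csv(tmp2)
  expect_equal(sc2$total, sc$total)
  expect_equal(sc2$MHT4, sc$MHT4)
})
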