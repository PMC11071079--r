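#' Define an MHT instrument key
#'
#' The MHT (Middle School Student Mental Health Test) has 100 yes/no items
#' scored 0/1, organised into eight content subscales plus a lie (validity)
#' scale. The authentic item key is proprietary and not distributed here;
#' [mht_default_spec()] ships a documented default layout that users should
#' override with the real key via this constructor when they have it.
#'
#' @param subscale_names character vector of the 8 content subscale labels,
#'   in order.
#' @param items_per_subscale named list mapping each subscale label to the
#'   integer item indices (1-based, within 1..`total_items`) it comprises.
#' @param lie_items integer item indices of the lie scale.
#' @param total_items total item count of the instrument (default 100).
#' @return An object of class `mht_instrument`: a list with fields
#'   `subscale_names`, `items_per_subscale`, `lie_items`, `total_items`,
#'   and `subscale_sizes`.
#' @export
#' @examples
#' spec <- mht_default_spec()
#' spec$subscale_sizes
mht_instrument_spec <- function(subscale_names, items_per_subscale, lie_items,
                                total_items = 100L) {
  if (length(subscale_names) != 8L)
    stop("exactly 8 content subscales are required, got ", length(subscale_names))
  if (!setequal(names(items_per_subscale), subscale_names))
    stop("items_per_subscale must be named by the subscale labels")
  items_per_subscale <- items_per_subscale[subscale_names]
  all_items <- c(unlist(items_per_subscale, use.names = FALSE), lie_items)
  if (anyDuplicated(all_items))
    stop("item index sets must be disjoint; duplicated item(s): ",
         paste(unique(all_items[duplicated(all_items)]), collapse = ", "))
  if (!setequal(all_items, seq_len(total_items)))
    stop("item indices must jointly cover 1..", total_items)
  structure(list(
    subscale_names = as.character(subscale_names),
    items_per_subscale = lapply(items_per_subscale, as.integer),
    lie_items = as.integer(lie_items),
    total_items = as.integer(total_items),
    subscale_sizes = vapply(items_per_subscale, length, integer(1))
  ), class = "mht_instrument")
}

#' Default MHT instrument layout
#'
#' A documented stand-in key: 90 content items in eight contiguous blocks
#' (15, 10, 10, 10, 10, 15, 10, 10 items for MHT1..MHT8) followed by 10 lie
#' items (91..100). Subscale sizes follow the usual MHT convention in which
#' learning anxiety (MHT1) and physical symptoms (MHT6) are the long scales.
#' Override with [mht_instrument_spec()] for the authentic key.
#'
#' @return An `mht_instrument` object.
#' @export
mht_default_spec <- function() {
  sizes <- c(15L, 10L, 10L, 10L, 10L, 15L, 10L, 10L)
  labels <- paste0("MHT", 1:8)
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  items <- Map(function(a, b) seq.int(a, b), starts, ends)
  names(items) <- labels
  mht_instrument_spec(labels, items, lie_items = 91:100, total_items = 100L)
}

#' @export
print.mht_instrument <- function(x, ...) {
  cat("MHT instrument:", x$total_items, "items;",
      length(x$subscale_names), "content subscales +",
      length(x$lie_items), "lie items\n")
  cat("  sizes:", paste(sprintf("%s=%d", x$subscale_names, x$subscale_sizes),
                        collapse = " "), "\n")
  invisible(x)
}

#' Construct an item-response matrix
#'
#' @param responses n x 100 matrix or data frame of 0/1 item answers
#'   (NA marks a missing answer).
#' @param ids participant identifiers (default 1..n).
#' @param metadata optional data frame of per-participant covariates
#'   (e.g. age, sex).
#' @param spec instrument key, used to validate the column count.
#' @return An object of class `mht_responses` wrapping the integer matrix.
#' @export
mht_responses <- function(responses, ids = NULL, metadata = NULL,
                          spec = mht_default_spec()) {
  m <- as.matrix(responses)
  if (ncol(m) != spec$total_items)
    stop("schema error: expected ", spec$total_items, " item columns, got ",
         ncol(m))
  storage.mode(m) <- "integer"
  bad <- which(!is.na(m) & !(m %in% c(0L, 1L)), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("invalid response %s at row %d, item %d (must be 0/1)",
                 m[bad[1, 1], bad[1, 2]], bad[1, 1], bad[1, 2]))
  if (is.null(ids)) ids <- seq_len(nrow(m))
  if (length(ids) != nrow(m)) stop("ids length must match row count")
  colnames(m) <- sprintf("item_%03d", seq_len(ncol(m)))
  structure(list(ids = ids, responses = m, metadata = metadata, spec = spec),
            class = "mht_responses")
}

#' @export
print.mht_responses <- function(x, ...) {
  cat("MHT item responses:", nrow(x$responses), "participants x",
      ncol(x$responses), "items;",
      sum(!stats::complete.cases(x$responses)), "incomplete row(s)\n")
  invisible(x)
}

#' Score MHT item responses into subscale totals
#'
#' Sums each participant's 0/1 answers within each content subscale and the
#' lie scale. The total score is the sum of the eight content subscales; the
#' lie score never enters the total. Apply [apply_exclusions()] first:
#' scoring requires complete, binary responses.
#'
#' @param responses an `mht_responses` object (complete rows only).
#' @param spec instrument key (defaults to the one carried by `responses`).
#' @return A data frame of class `mht_scores` with columns `id`, the eight
#'   subscale labels, `lie`, `total` and `grade` (see [classify_total()]).
#' @export
#' @examples
#' spec <- mht_default_spec()
#' resp <- mht_responses(matrix(0L, 2, 100), spec = spec)
#' score_responses(resp)$total  # all-zero rows score 0
score_responses <- function(responses, spec = responses$spec) {
  m <- responses$responses
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)
    stop(sprintf("missing response at row %d, item %d: apply_exclusions() first",
                 bad[1, 1], bad[1, 2]))
  }
  sc <- vapply(spec$items_per_subscale,
               function(it) as.integer(rowSums(m[, it, drop = FALSE])),
               integer(nrow(m)))
  if (nrow(m) == 1L) sc <- matrix(sc, nrow = 1,
                                  dimnames = list(NULL, spec$subscale_names))
  lie <- as.integer(rowSums(m[, spec$lie_items, drop = FALSE]))
  total <- as.integer(rowSums(sc))
  out <- data.frame(id = responses$ids, sc, lie = lie, total = total,
                    grade = classify_total(total),
                    stringsAsFactors = FALSE, check.names = FALSE)
  class(out) <- c("mht_scores", "data.frame")
  attr(out, "spec") <- spec
  out
}

#' Exclude incomplete and lie-invalid protocols
#'
#' Applies the MHT validity rules in a fixed order: first remove every row
#' with any missing answer (listwise deletion), then remove rows whose lie
#' score falls in 7..10 (protocol deemed unreliable). Each row is counted
#' under exactly one exclusion cause.
#'
#' @param responses an `mht_responses` object.
#' @param spec instrument key.
#' @return A list with `responses` (the retained `mht_responses`) and
#'   `report`, a list of class `mht_exclusion` with counts `n_received`,
#'   `n_incomplete`, `n_lie_invalid`, `n_retained` and `effective_rate`
#'   (percent retained).
#' @export
apply_exclusions <- function(responses, spec = responses$spec) {
  m <- responses$responses
  n_received <- nrow(m)
  complete <- stats::complete.cases(m)
  n_incomplete <- sum(!complete)
  m2 <- m[complete, , drop = FALSE]
  ids2 <- responses$ids[complete]
  meta2 <- if (!is.null(responses$metadata))
    responses$metadata[complete, , drop = FALSE] else NULL
  lie <- rowSums(m2[, spec$lie_items, drop = FALSE])
  lie_ok <- !(lie >= 7 & lie <= 10)
  n_lie_invalid <- sum(!lie_ok)
  kept <- mht_responses(m2[lie_ok, , drop = FALSE], ids = ids2[lie_ok],
                        metadata = if (!is.null(meta2))
                          meta2[lie_ok, , drop = FALSE] else NULL,
                        spec = spec)
  n_retained <- n_received - n_incomplete - n_lie_invalid
  report <- structure(list(
    n_received = n_received,
    n_incomplete = n_incomplete,
    n_lie_invalid = n_lie_invalid,
    n_retained = n_retained,
    effective_rate = if (n_received > 0) 100 * n_retained / n_received else NA_real_
  ), class = "mht_exclusion")
  list(responses = kept, report = report)
}

#' @export
print.mht_exclusion <- function(x, ...) {
  cat(sprintf(
    "received %d; excluded %d incomplete, %d lie-invalid; retained %d (%.2f%%)\n",
    x$n_received, x$n_incomplete, x$n_lie_invalid, x$n_retained,
    x$effective_rate))
  invisible(x)
}

#' Classify an MHT total score into a severity grade
#'
#' Totals 0-55 are graded `normal`, 56-64 `poor` (moderate tendency to
#' psychological problems) and 65 or more `severe`.
#'
#' @param total_score integer vector of MHT totals (content subscales only).
#' @return factor with levels `normal`, `poor`, `severe`.
#' @export
#' @examples
#' classify_total(c(47, 55, 56, 64, 65))
classify_total <- function(total_score) {
  if (any(total_score < 0, na.rm = TRUE))
    stop("domain error: total score must be non-negative")
  cut(total_score, breaks = c(-0.5, 55.5, 64.5, Inf),
      labels = c("normal", "poor", "severe"))
}

#' Flag a subscale score for psychological-problem tendency
#'
#' Subscale scores of 8 or above mark a clear tendency towards psychological
#' problems on that symptom; 3 or below marks no tendency; scores in between
#' are intermediate.
#'
#' @param score integer vector of subscale scores.
#' @return factor with levels `no_tendency`, `intermediate`, `clear_tendency`.
#' @export
flag_subscale <- function(score) {
  if (any(score < 0, na.rm = TRUE))
    stop("domain error: subscale score must be non-negative")
  cut(score, breaks = c(-0.5, 3.5, 7.5, Inf),
      labels = c("no_tendency", "intermediate", "clear_tendency"))
}

# population central moments; returns skew g1 and excess kurtosis g2
.moments_g <- function(x) {
  n <- length(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  if (m2 == 0) return(c(skew = NA_real_, kurt = NA_real_))
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)
  c(skew = m3 / m2^1.5, kurt = m4 / m2^2 - 3)
}

#' Descriptive statistics per subscale
#'
#' Per-subscale mean, sample standard deviation (n-1 denominator), Fisher
#' skewness g1 = m3/m2^1.5 and excess kurtosis g2 = m4/m2^2 - 3 (population
#' central moments), and the count/percentage of participants flagged with a
#' clear tendency (score >= 8) by [flag_subscale()]. A constant column gets
#' `NA` skew/kurtosis rather than propagating NaN.
#'
#' @param scores an `mht_scores` data frame (or any data frame whose content
#'   subscale columns are named in `subscale_names`).
#' @param subscale_names columns to summarise; defaults to MHT1..MHT8.
#' @return data frame with one row per subscale: `node`, `mean`, `sd`,
#'   `skew`, `kurt`, `n_flagged`, `pct_flagged`.
#' @export
descriptive_stats <- function(scores, subscale_names = paste0("MHT", 1:8)) {
  n <- nrow(scores)
  if (n < 2) stop("need at least 2 participants for descriptives")
  rows <- lapply(subscale_names, function(nm) {
    x <- scores[[nm]]
    g <- .moments_g(x)
    nf <- sum(flag_subscale(x) == "clear_tendency")
    data.frame(node = nm, mean = mean(x), sd = sd(x),
               skew = g[["skew"]], kurt = g[["kurt"]],
               n_flagged = nf, pct_flagged = 100 * nf / n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Read MHT item responses from CSV
#'
#' Expects one row per participant with header
#' `id,item_001..item_100[,age,sex]`; an empty cell marks a missing answer.
#'
#' @param path CSV file path.
#' @param spec instrument key.
#' @return An `mht_responses` object (extra columns go into `metadata`).
#' @export
read_responses_csv <- function(path, spec = mht_default_spec()) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  item_cols <- grep("^item_[0-9]+$", names(df), value = TRUE)
  if (length(item_cols) != spec$total_items)
    stop("schema error: expected ", spec$total_items, " item_* columns, found ",
         length(item_cols))
  item_cols <- item_cols[order(as.integer(sub("item_", "", item_cols)))]
  meta_cols <- setdiff(names(df), c("id", item_cols))
  mht_responses(df[, item_cols],
                ids = if ("id" %in% names(df)) df$id else NULL,
                metadata = if (length(meta_cols))
                  df[, meta_cols, drop = FALSE] else NULL,
                spec = spec)
}

#' Write subscale scores to CSV
#'
#' @param scores an `mht_scores` data frame.
#' @param path output CSV path (`id,MHT1..MHT8,lie,total,grade`).
#' @export
write_scores_csv <- function(scores, path) {
  write.csv(as.data.frame(scores), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read subscale scores from CSV
#'
#' @param path CSV written by [write_scores_csv()] (grade column optional;
#'   recomputed if absent).
#' @return an `mht_scores` data frame.
#' @export
read_scores_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", paste0("MHT", 1:8), "lie", "total")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("scores CSV missing column(s): ",
                         paste(miss, collapse = ", "))
  if (!"grade" %in% names(df)) df$grade <- classify_total(df$total)
  class(df) <- c("mht_scores", "data.frame")
  df
}

# 8-column numeric matrix of content subscale scores
score_matrix <- function(scores, subscale_names = paste0("MHT", 1:8)) {
  as.matrix(as.data.frame(scores)[, subscale_names])
}
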