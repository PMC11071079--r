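#' Build a pipeline configuration
#'
#' Collects every setting the end-to-end pipeline needs; all stochastic
#' stages are driven by the single mandatory `seed`. Supply either `input`
#' (a CSV path: item-level responses with `item_*` columns, or a subscale
#' scores table) or `synthetic` (parameters for the built-in generator).
#'
#' @param input CSV path, or `NULL` to simulate.
#' @param synthetic list of generator settings: `n`, and optionally `p`,
#'   `edge_density`, `weight_range`, `negative_fraction`, `level`
#'   (`"scores"` or `"items"`), `n_missing`, `n_lie_invalid`.
#' @param method,gamma,n_lambda,ratio estimation settings
#'   (see [estimate_network()]).
#' @param alpha significance level for CIs and difference tests.
#' @param boot_B nonparametric bootstrap replicates (2000 recommended).
#' @param casedrop_B subsamples per drop proportion (1000 recommended).
#' @param proportions case-dropping proportion grid.
#' @param cs_threshold,cs_certainty CS-coefficient parameters.
#' @param seed integer seed (mandatory).
#' @param outdir optional output directory; when set, [run_pipeline()]
#'   writes the full report there.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, synthetic = NULL,
                            method = "pearson", gamma = 0.5, n_lambda = 100,
                            ratio = 0.01, alpha = 0.05, boot_B = 2000,
                            casedrop_B = 1000,
                            proportions = seq(0.05, 0.75, by = 0.05),
                            cs_threshold = 0.7, cs_certainty = 0.95,
                            seed, outdir = NULL) {
  if (missing(seed) || is.null(seed))
    stop("seed is mandatory: every stochastic stage derives from it")
  if (is.null(input) && is.null(synthetic))
    stop("provide either an input CSV path or synthetic generator settings")
  structure(list(input = input, synthetic = synthetic, method = method,
                 gamma = gamma, n_lambda = n_lambda, ratio = ratio,
                 alpha = alpha, boot_B = boot_B, casedrop_B = casedrop_B,
                 proportions = proportions, cs_threshold = cs_threshold,
                 cs_certainty = cs_certainty, seed = as.integer(seed),
                 outdir = outdir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path config file; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`). Note that YAML 1.1 parses a bare `n` key as a boolean; quote
#'   it (`"n": 625`) inside the `synthetic` block.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required for YAML configs")
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else stop("unsupported config format: .", ext)
  if (!is.null(raw$input) && !file.exists(raw$input))
    stop("config input path does not exist: ", raw$input)
  do.call(pipeline_config, raw)
}

# scores-level exclusions: listwise deletion, then lie in 7..10
.exclude_scores <- function(scores) {
  cols <- c(paste0("MHT", 1:8), "lie")
  n_received <- nrow(scores)
  complete <- stats::complete.cases(scores[, cols])
  s2 <- scores[complete, , drop = FALSE]
  lie_ok <- !(s2$lie >= 7 & s2$lie <= 10)
  kept <- s2[lie_ok, , drop = FALSE]
  report <- structure(list(
    n_received = n_received,
    n_incomplete = sum(!complete),
    n_lie_invalid = sum(!lie_ok),
    n_retained = nrow(kept),
    effective_rate = if (n_received > 0) 100 * nrow(kept) / n_received
                     else NA_real_), class = "mht_exclusion")
  list(scores = kept, report = report)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full symptom-network pipeline
#'
#' Executes, in order: input loading (or synthesis), exclusion, scoring,
#' descriptive statistics, network estimation, centrality and
#' predictability, bootstrap accuracy (edge CIs, difference matrices) and
#' case-dropping stability (CS coefficients), then a deterministic
#' force-directed layout for plotting. Any stage error aborts with the stage
#' name. Given the same input, configuration and seed the bundle is
#' reproduced exactly.
#'
#' @param config a `pipeline_config` (or path readable by
#'   [read_pipeline_config()]).
#' @return object of class `mht_report` with fields `exclusion`,
#'   `descriptives`, `network`, `centrality`, `predictability`, `stability`
#'   (edge CIs, difference matrices, CS results), `layout`, `truth` (for
#'   synthetic runs) and `config`. Written to `config$outdir` when set.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  spec <- mht_default_spec()

  truth <- NULL
  if (!is.null(config$synthetic)) {
    syn <- config$synthetic
    p <- syn$p %||% 8
    truth <- .stage("synthesis", make_precision_matrix(
      p, syn$edge_density %||% 0.6,
      syn$weight_range %||% c(0.05, 0.35),
      syn$negative_fraction %||% 0.06, seed = config$seed))
    level <- syn$level %||% "scores"
    if (level == "items") {
      resp <- .stage("synthesis", simulate_item_responses(
        truth, spec, n = syn$n, seed = config$seed,
        n_missing = syn$n_missing %||% 0,
        n_lie_invalid = syn$n_lie_invalid %||% 0))
      excl <- .stage("exclusion", apply_exclusions(resp, spec))
      scores <- .stage("scoring", score_responses(excl$responses, spec))
      report <- excl$report
    } else {
      sim <- .stage("synthesis", simulate_subscale_scores(
        truth, n = syn$n, seed = config$seed))
      ex <- .stage("exclusion", .exclude_scores(sim$scores))
      scores <- ex$scores
      report <- ex$report
    }
  } else {
    header <- names(read.csv(config$input, nrows = 1))
    if (any(grepl("^item_", header))) {
      resp <- .stage("input", read_responses_csv(config$input, spec))
      excl <- .stage("exclusion", apply_exclusions(resp, spec))
      scores <- .stage("scoring", score_responses(excl$responses, spec))
      report <- excl$report
    } else {
      raw <- .stage("input", read_scores_csv(config$input))
      ex <- .stage("exclusion", .exclude_scores(raw))
      scores <- ex$scores
      report <- ex$report
    }
  }

  desc <- .stage("descriptives", descriptive_stats(scores))
  est_cfg <- estimation_config(config$gamma, config$method,
                               config$n_lambda, config$ratio)
  network <- .stage("network", .estimate_with(score_matrix(scores), est_cfg))
  centrality <- .stage("centrality", centrality_table(network, scores))
  pred <- .stage("predictability", predictability(scores))
  desc$expected_influence_z <-
    centrality$expected_influence_z[match(desc$node, centrality$node)]
  desc$predictability <- pred$r2[match(desc$node, pred$node)]

  boot <- .stage("bootstrap", nonparametric_bootstrap(
    scores, B = config$boot_B, seed = config$seed, config = est_cfg))
  cis <- .stage("bootstrap", edge_ci(boot, config$alpha))
  diff_edges <- .stage("bootstrap", difference_matrix(boot, "edges",
                                                      config$alpha))
  diff_strength <- .stage("bootstrap", difference_matrix(boot, "strength",
                                                         config$alpha))
  diff_ei <- .stage("bootstrap", difference_matrix(
    boot, "expected_influence", config$alpha))
  drop <- .stage("stability", case_dropping_bootstrap(
    scores, proportions = config$proportions, B = config$casedrop_B,
    seed = config$seed, config = est_cfg))
  cs <- lapply(c("strength", "expected_influence"), function(st)
    .stage("stability", cs_coefficient(drop, st, config$cs_threshold,
                                       config$cs_certainty)))
  names(cs) <- c("strength", "expected_influence")

  layout <- .stage("layout", network_layout(network, seed = config$seed))

  bundle <- structure(list(
    exclusion = report, scores = scores, descriptives = desc,
    network = network, centrality = centrality, predictability = pred,
    stability = list(edge_ci = cis, difference_edges = diff_edges,
                     difference_strength = diff_strength,
                     difference_expected_influence = diff_ei,
                     cs = cs, boot_failures = boot$n_failed),
    layout = layout, truth = truth, config = config,
    version = as.character(utils::packageVersion("mhtnet")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    class = "mht_report")
  if (!is.null(config$outdir)) write_report(bundle, config$outdir)
  bundle
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Deterministic force-directed node layout
#'
#' Machine-readable figure data: Fruchterman-Reingold coordinates computed
#' with a fixed seed, plus per-edge sign and a width proportional to |w|.
#'
#' @param network a `symptom_network`.
#' @param seed layout seed.
#' @return list with `nodes` (node, x, y) and `edges` (node_i, node_j,
#'   weight, sign, width).
#' @export
network_layout <- function(network, seed = 1) {
  g <- igraph::graph_from_adjacency_matrix(abs(network$weights),
                                           mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  set.seed(seed)
  xy <- igraph::layout_with_fr(g)
  el <- as.data.frame(network)
  el$sign <- ifelse(el$weight >= 0, "positive", "negative")
  wmax <- max(abs(el$weight), 1e-12)
  el$width <- abs(el$weight) / wmax
  list(nodes = data.frame(node = network$labels, x = xy[, 1], y = xy[, 2],
                          stringsAsFactors = FALSE),
       edges = el)
}

#' @export
print.mht_report <- function(x, ...) {
  cat("MHT symptom-network report\n")
  print(x$exclusion)
  print(x$network)
  ei <- x$centrality$expected_influence_z
  ord <- order(ei, decreasing = TRUE)
  cat("  top expected influence:",
      paste(sprintf("%s (%.2f)", x$centrality$node[ord[1:3]], ei[ord[1:3]]),
            collapse = ", "), "\n")
  for (cs in x$stability$cs) print(cs)
  invisible(x)
}

# percentages to 1 decimal for written tables
.round_pct <- function(x) round(x, 1)

#' Write a report bundle to disk
#'
#' Deterministically named CSV/TSV/JSON files plus a manifest listing every
#' file with its MD5 checksum. Percentages are written to one decimal.
#'
#' @param bundle an `mht_report`.
#' @param outdir output directory (created if needed).
#' @return invisibly, the manifest data frame.
#' @export
write_report <- function(bundle, outdir) {
  ok <- dir.exists(outdir) || dir.create(outdir, recursive = TRUE)
  if (!ok || file.access(outdir, 2) != 0)
    stop("cannot write to output directory: ", outdir)
  path <- function(f) file.path(outdir, f)

  excl <- bundle$exclusion
  excl$effective_rate <- .round_pct(excl$effective_rate)
  jsonlite::write_json(unclass(excl), path("exclusion.json"),
                       auto_unbox = TRUE, digits = NA)
  desc <- bundle$descriptives
  desc$pct_flagged <- .round_pct(desc$pct_flagged)
  write.csv(desc, path("descriptives.csv"), row.names = FALSE, quote = FALSE)
  write_scores_csv(bundle$scores, path("scores.csv"))
  write_network(bundle$network, path("network"))
  utils::write.table(bundle$centrality, path("centrality.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(bundle$predictability, path("predictability.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(bundle$stability$edge_ci, path("edge_ci.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(cs = lapply(bundle$stability$cs, unclass),
         difference_edges = bundle$stability$difference_edges,
         difference_strength = bundle$stability$difference_strength,
         difference_expected_influence =
           bundle$stability$difference_expected_influence,
         boot_failures = bundle$stability$boot_failures),
    path("stability.json"), auto_unbox = TRUE, digits = NA)
  write.csv(bundle$layout$nodes, path("layout_nodes.csv"), row.names = FALSE,
            quote = FALSE)
  write.csv(bundle$layout$edges, path("layout_edges.csv"), row.names = FALSE,
            quote = FALSE)
  if (!is.null(bundle$truth))
    jsonlite::write_json(list(p = bundle$truth$p,
                              precision = bundle$truth$precision,
                              seed = bundle$truth$seed,
                              params = bundle$truth$params),
                         path("truth.json"), auto_unbox = TRUE, digits = NA)

  files <- setdiff(list.files(outdir), "manifest.json")
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(outdir, files))),
    stringsAsFactors = FALSE)
  jsonlite::write_json(
    list(files = manifest,
         config_hash = .config_hash(bundle$config),
         version = bundle$version,
         timestamp = bundle$timestamp,
         seed = bundle$config$seed),
    path("manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

.config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              digits = NA, null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

#' Verify a written report against its manifest
#'
#' @param outdir report directory containing `manifest.json`.
#' @return `TRUE` if every listed file exists with a matching checksum.
#' @export
verify_manifest <- function(outdir) {
  man <- jsonlite::read_json(file.path(outdir, "manifest.json"),
                             simplifyVector = TRUE)
  files <- file.path(outdir, man$files$file)
  all(file.exists(files)) &&
    all(unname(tools::md5sum(files)) == man$files$md5)
}
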