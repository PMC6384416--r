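#' @title Pipeline orchestration
#' @description File-level front ends over the package functions: each run
#'   reads inputs, executes one stage (describe / score / simulate), writes
#'   machine-readable outputs and a run manifest sufficient to reproduce the
#'   run bit-for-bit. A thin command-line wrapper over these functions ships
#'   in \code{inst/cli/npa.R}.
#' @name pipeline
NULL

.pkg_version <- function() {
  as.character(utils::packageVersion("cbnpa"))
}

.write_manifest <- function(out_dir, command, inputs, config, seed) {
  hashes <- vapply(inputs, function(p)
    if (file.exists(p)) unname(tools::md5sum(p)) else NA_character_,
    character(1))
  manifest <- list(command = command,
                   inputs = as.list(inputs),
                   input_md5 = as.list(hashes),
                   config = config,
                   seed = seed,
                   tool = "cbnpa", version = .pkg_version(),
                   timestamp = format(Sys.time(), tz = "UTC",
                                      "%Y-%m-%dT%H:%M:%SZ"),
                   schema = 1L)
  path <- file.path(out_dir, paste0(command, "_manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

.load_model <- function(path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.json$", path)) "node-link-json"
              else if (grepl("\\.(tsv|txt)$", path)) "edge-tsv"
              else "bel"
  net <- read_network(path, format)
  if (any(net$nodes$kind == "rna")) split_layers(net, name = basename(path))
  else two_layer_model(net, name = basename(path))
}

#' Describe a model file
#'
#' Prints (and returns) node/edge counts before and after the layer split,
#' component diagnostics, and the top-k degree table. Both pre- and
#' post-split counts are reported because published summaries do not always
#' say whether transcript nodes are included.
#'
#' @param model_path Path to a model file (BEL, node-link JSON or edge TSV).
#' @param k Rows of the degree table.
#' @param format Force the input format (default: inferred from extension).
#' @param out_dir If non-NULL, writes the degree table (TSV) and a manifest.
#' @return List with \code{counts}, \code{degree}, \code{diagnostics},
#'   invisibly.
#' @export
run_describe <- function(model_path, k = 10, format = NULL, out_dir = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.json$", model_path)) "node-link-json"
              else if (grepl("\\.(tsv|txt)$", model_path)) "edge-tsv"
              else "bel"
  net <- read_network(model_path, format)
  model <- if (any(net$nodes$kind == "rna"))
    split_layers(net, name = basename(model_path))
  else two_layer_model(net, name = basename(model_path))
  counts <- list(
    nodes_total = nrow(net$nodes), edges_total = nrow(net$edges),
    backbone_nodes = nrow(model$backbone$nodes),
    backbone_edges = nrow(model$backbone$edges),
    downstream_edges = nrow(model$downstream),
    downstream_genes = length(unique(model$downstream$gene)))
  deg <- degree_table(model$backbone, k = k)
  diag <- validate_model(model)
  cat(sprintf("model: %s\n", model_path))
  cat(sprintf("  nodes (with transcripts): %d   edges: %d\n",
              counts$nodes_total, counts$edges_total))
  cat(sprintf("  backbone nodes: %d   backbone edges: %d\n",
              counts$backbone_nodes, counts$backbone_edges))
  cat(sprintf("  downstream edges: %d (%d genes)\n",
              counts$downstream_edges, counts$downstream_genes))
  cat(sprintf("  components: %d   flags: %d\n", nrow(diag$components),
              length(diag$flags)))
  cat("top connected backbone nodes:\n")
  utils::write.table(deg, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(deg, file.path(out_dir, "degree_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    .write_manifest(out_dir, "describe", c(model = model_path),
                    list(k = k, format = format), NULL)
  }
  invisible(list(counts = counts, degree = deg, diagnostics = diag))
}

#' Score an expression contrast onto a model, writing result files
#'
#' Full pipeline: read, split, optional trim, match, assemble, infer, score,
#' confidence interval, O/K permutation statistics, leading nodes, leading
#' subnetwork export. Outputs: \code{npa_result.json},
#' \code{node_values.tsv}, \code{contributions.tsv},
#' \code{leading_nodes.tsv}, \code{leading_subnetwork.json}, and a manifest.
#'
#' @param model_path,expression_path Input files.
#' @param out_dir Output directory (created).
#' @param trim Trim hanging nodes first.
#' @param format Model format override.
#' @param ... Passed to \code{\link{npa}} (mode, n_perm, seed, alphas, ...).
#' @return The \code{"npa"} fit, invisibly.
#' @export
run_score <- function(model_path, expression_path, out_dir, trim = FALSE,
                      format = NULL, ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  model <- .load_model(model_path, format)
  expr <- read_expression(expression_path)
  fit <- npa(model, expr, trim = trim, ...)
  dots <- list(...)
  result <- list(
    schema = 1L,
    model = model$name, mode = fit$mode,
    score = fit$score, ci_low = fit$ci_low, ci_high = fit$ci_high,
    level = fit$level, ci_method = fit$ci_method,
    p_O = fit$p_O, p_K = fit$p_K,
    flags = fit$flags, coverage = fit$coverage,
    n_perm = fit$n_perm, seed = fit$seed,
    permutation_scheme = as.list(fit$permutation_scheme),
    n_leading = sum(fit$leading$leading))
  jsonlite::write_json(result, file.path(out_dir, "npa_result.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", na = "null")
  utils::write.table(
    data.frame(node = names(fit$f), value = fit$f,
               direction = fit$directions[names(fit$f)]),
    file.path(out_dir, "node_values.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(node = names(fit$contributions),
               contribution = fit$contributions),
    file.path(out_dir, "contributions.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(fit$leading, file.path(out_dir, "leading_nodes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  sub <- leading_subnetwork(fit$model, fit$leading, f = fit$f,
                            contributions = fit$contributions)
  write_network(sub, file.path(out_dir, "leading_subnetwork.json"),
                "node-link-json")
  .write_manifest(out_dir, "score",
                  c(model = model_path, expression = expression_path),
                  c(list(trim = trim), dots),
                  if (!is.null(dots$seed)) dots$seed else NULL)
  invisible(fit)
}

#' Generate and write a synthetic dataset
#'
#' Writes the model (node-link JSON), downstream layer (TSV), simulated
#' expression table (TSV), ground truth (TSV), and a manifest.
#'
#' @param config A \code{"synth_config"}.
#' @param out_dir Output directory.
#' @param seed Seed (overrides \code{config$seed}).
#' @return The \code{"synth_truth"}, invisibly.
#' @export
run_simulate <- function(config = synth_config(), out_dir, seed = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(seed)) config$seed <- seed
  truth <- generate_model(config)
  expr <- simulate_expression(truth, seed = .child_seed(config$seed, 7L))
  write_network(truth$model$backbone, file.path(out_dir, "backbone.json"),
                "node-link-json")
  utils::write.table(truth$model$downstream,
                     file.path(out_dir, "downstream.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_expression(expr, file.path(out_dir, "expression.tsv"))
  utils::write.table(data.frame(node = names(truth$f_true),
                                f_true = truth$f_true),
                     file.path(out_dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  .write_manifest(out_dir, "simulate", character(0),
                  unclass(config), config$seed)
  invisible(truth)
}

#' Run the calibration, power and recovery suites
#'
#' The synthetic benchmark behind the package's statistical guarantees:
#' \itemize{
#'   \item \strong{calibration} — fraction of null datasets with
#'     \code{p_O < 0.05} (should be near 0.05);
#'   \item \strong{power} — fraction of on-model signal datasets with
#'     \code{p_O} and \code{p_K} below 0.05;
#'   \item \strong{specificity} — fraction of decoy-model scorings (signal
#'     from a different, gene-disjoint model relabelled onto this one) with
#'     \code{p_O >= 0.05};
#'   \item \strong{recovery} — mean Pearson correlation between true and
#'     inferred backbone values.
#' }
#'
#' @param seed Master seed.
#' @param n_calibration,n_power,n_recovery Replicate counts.
#' @param n_perm Permutations per p-value.
#' @param config Model configuration for the suites.
#' @param quiet Suppress the progress summary.
#' @return data.frame summary, one row per suite.
#' @export
run_benchmark <- function(seed = 1, n_calibration = 100, n_power = 50,
                          n_recovery = 20, n_perm = 200,
                          config = synth_config(), quiet = FALSE) {
  cal <- calibration_suite(seed = .child_seed(seed, 11L),
                           n_datasets = n_calibration, n_perm = n_perm,
                           config = config)
  pow <- power_suite(seed = .child_seed(seed, 12L), n_runs = n_power,
                     n_perm = n_perm, config = config)
  rec <- recovery_suite(seed = .child_seed(seed, 13L), n_replicates = n_recovery,
                        config = config)
  out <- data.frame(
    suite = c("calibration", "power_O", "power_K", "specificity", "recovery"),
    metric = c("fraction p_O < 0.05 under null",
               "fraction p_O < 0.05 with signal",
               "fraction p_K < 0.05 with signal",
               "fraction p_O >= 0.05 on decoy model",
               "mean pearson_r(f_true, f_hat)"),
    value = c(cal$fraction_significant, pow$power_O, pow$power_K,
              pow$specificity, rec$mean_pearson_r),
    n = c(n_calibration, n_power, n_power, n_power, n_recovery))
  if (!quiet) print(out, row.names = FALSE)
  invisible(out)
}

#' Calibration of the O statistic under the global null
#'
#' Simulates pure-noise datasets on a fixed synthetic model and reports the
#' fraction of runs with \code{p_O < alpha}; for a well-calibrated test this
#' approaches alpha.
#'
#' @param seed Master seed.
#' @param n_datasets Simulated null datasets.
#' @param n_perm Permutations per p-value.
#' @param noise_sd Null noise sd.
#' @param alpha Nominal level.
#' @param config Model configuration.
#' @return List with \code{fraction_significant}, \code{p_values},
#'   \code{alpha}.
#' @export
calibration_suite <- function(seed = 1, n_datasets = 500, n_perm = 200,
                              noise_sd = 1, alpha = 0.05,
                              config = synth_config()) {
  truth <- generate_model(config, seed = .child_seed(seed, 1L))
  p <- vapply(seq_len(n_datasets), function(i) {
    expr <- null_expression(truth, noise_sd = noise_sd,
                            seed = .child_seed(seed, 100L + i))
    permutation_pvalue(truth$model, expr, "O", n_perm = n_perm,
                       seed = .child_seed(seed, 10000L + i))$p
  }, numeric(1))
  list(fraction_significant = mean(p < alpha), p_values = p, alpha = alpha)
}

#' Power and decoy specificity of the O/K statistics
#'
#' Each run simulates signal data from a generating model and computes p_O
#' and p_K on it (power), then relabels the same signal onto an
#' independently generated, gene-disjoint decoy model and computes p_O there
#' (specificity: the decoy should NOT look specific).
#'
#' @param seed Master seed.
#' @param n_runs Replicates.
#' @param n_perm Permutations per p-value.
#' @param effect_sd,noise_sd Signal strength and noise.
#' @param alpha Nominal level.
#' @param config Model configuration (effect/noise overridden).
#' @param coherent Use network-coherent true effects (default). A coherent
#'   truth — a root effect propagated through the edge signs — is the signal
#'   the model's wiring actually predicts; it gives the K statistic something
#'   to detect, whereas i.i.d. node effects are uninformative about wiring
#'   by construction.
#' @return List with \code{power_O}, \code{power_K}, \code{specificity} and
#'   per-run p-values.
#' @export
power_suite <- function(seed = 1, n_runs = 100, n_perm = 200,
                        effect_sd = 1, noise_sd = 0.1, alpha = 0.05,
                        config = synth_config(), coherent = TRUE) {
  config$effect_sd <- effect_sd
  config$noise_sd <- noise_sd
  p_O <- p_K <- p_decoy <- numeric(n_runs)
  for (i in seq_len(n_runs)) {
    tA <- generate_model(config, seed = .child_seed(seed, 1000L + i),
                         gene_prefix = "SGA", coherent = coherent)
    exprA <- simulate_expression(tA, seed = .child_seed(seed, 2000L + i))
    p_O[i] <- permutation_pvalue(tA$model, exprA, "O", n_perm = n_perm,
                                 seed = .child_seed(seed, 3000L + i))$p
    p_K[i] <- permutation_pvalue(tA$model, exprA, "K", n_perm = n_perm,
                                 seed = .child_seed(seed, 4000L + i))$p
    # decoy: an independent model; A's fold-changes re-labelled with B's
    # gene symbols in a random order, so the data carry no information
    # about B's wiring
    tB <- generate_model(config, seed = .child_seed(seed, 5000L + i),
                         gene_prefix = "SGB")
    genesB <- unique(tB$model$downstream$gene)
    exprB <- exprA
    stopifnot(length(genesB) >= nrow(exprB))
    exprB$gene <- .with_seed(.child_seed(seed, 6000L + i),
                             sample(genesB, nrow(exprB)))
    p_decoy[i] <- permutation_pvalue(tB$model, exprB, "O", n_perm = n_perm,
                                     seed = .child_seed(seed, 7000L + i))$p
  }
  list(power_O = mean(p_O < alpha), power_K = mean(p_K < alpha),
       specificity = mean(p_decoy >= alpha),
       p_O = p_O, p_K = p_K, p_decoy = p_decoy)
}

#' Parameter recovery of backbone values
#'
#' Simulates signal data and compares the inferred backbone state with the
#' generating truth across replicates.
#'
#' @param seed Master seed.
#' @param n_replicates Replicates (new model and data each time).
#' @param config Model configuration.
#' @return List with \code{mean_pearson_r}, \code{mean_rmse} and per-run
#'   values.
#' @export
recovery_suite <- function(seed = 1, n_replicates = 20,
                           config = synth_config()) {
  r <- rmse <- numeric(n_replicates)
  for (i in seq_len(n_replicates)) {
    truth <- generate_model(config, seed = .child_seed(seed, 100L + i))
    expr <- simulate_expression(truth, seed = .child_seed(seed, 200L + i))
    sc <- .pipeline_score(truth$model, expr)
    m <- recovery_metrics(truth$f_true[names(sc$f)], sc$f)
    r[i] <- m$pearson_r; rmse[i] <- m$rmse
  }
  list(mean_pearson_r = mean(r), mean_rmse = mean(rmse),
       pearson_r = r, rmse = rmse)
}

#' Benchmark published model files
#'
#' Parses locally available published model files (e.g. downloaded from the
#' causal biological network database) and reports node/edge counts and the
#' top hub per model, for comparison against their published descriptions.
#' The files are third-party data and are not shipped with the package.
#'
#' @param dir Directory containing the model files.
#' @param pattern File pattern.
#' @return data.frame with one row per model file.
#' @export
benchmark_published <- function(dir, pattern = "\\.(bel|json|tsv)$") {
  if (!dir.exists(dir))
    stop("published model directory not found: ", dir,
         "\nDownload the models (causalbionet.com / NPAModels) into it first.")
  files <- list.files(dir, pattern = pattern, full.names = TRUE)
  if (!length(files)) stop("no model files in ", dir)
  rows <- lapply(files, function(f) {
    d <- run_describe(f)
    top <- if (nrow(d$degree)) d$degree[1, ] else
      data.frame(node = NA, indegree = NA, outdegree = NA, total = NA)
    data.frame(file = basename(f),
               nodes_total = d$counts$nodes_total,
               edges_total = d$counts$edges_total,
               backbone_nodes = d$counts$backbone_nodes,
               backbone_edges = d$counts$backbone_edges,
               top_node = top$node, top_indegree = top$indegree,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
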