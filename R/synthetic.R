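#' @title Synthetic two-layer models and expression data
#' @description Generates random two-layer models and fold-change tables with
#'   known ground truth, so that every pipeline stage — inference, scoring,
#'   permutation statistics — can be tested against the truth that generated
#'   the data. The generator emulates the statistical structure the scoring
#'   assumes: a connected signed backbone, per-node downstream transcripts
#'   with signed expected responses, and Gaussian measurement noise on the
#'   fold-changes.
#' @name synthetic-data
NULL

#' Synthetic generator configuration
#'
#' @param n_backbone Number of backbone nodes (>= 2).
#' @param n_edges Number of backbone edges (between \code{n_backbone - 1} and
#'   the simple-graph maximum).
#' @param p_negative Probability an edge sign is -1.
#' @param genes_per_node Downstream transcripts per backbone node.
#' @param effect_sd Spread of the true node effects (log2 scale).
#' @param noise_sd Measurement noise sd on fold-changes.
#' @param seed RNG seed.
#' @return List of class \code{"synth_config"}.
#' @export
synth_config <- function(n_backbone = 30, n_edges = 60, p_negative = 0.3,
                         genes_per_node = 10, effect_sd = 1, noise_sd = 0.2,
                         seed = NULL) {
  stopifnot(n_backbone >= 2, n_edges >= n_backbone - 1,
            p_negative >= 0, p_negative <= 1, genes_per_node >= 1,
            effect_sd >= 0, noise_sd >= 0)
  if (n_edges > n_backbone * (n_backbone - 1) / 2)
    stop("n_edges exceeds the simple-graph maximum for ", n_backbone, " nodes")
  structure(list(n_backbone = n_backbone, n_edges = n_edges,
                 p_negative = p_negative, genes_per_node = genes_per_node,
                 effect_sd = effect_sd, noise_sd = noise_sd, seed = seed),
            class = "synth_config")
}

# uniform random labelled tree on n nodes via a random Pruefer sequence
.random_tree_edges <- function(n) {
  if (n == 2) return(cbind(1L, 2L))
  pruefer <- sample.int(n, n - 2, replace = TRUE)
  degree <- rep(1L, n)
  for (p in pruefer) degree[p] <- degree[p] + 1L
  edges <- matrix(0L, n - 1, 2)
  for (k in seq_along(pruefer)) {
    leaf <- which(degree == 1L)[1]
    edges[k, ] <- c(leaf, pruefer[k])
    degree[leaf] <- 0L
    degree[pruefer[k]] <- degree[pruefer[k]] - 1L
  }
  edges[n - 1, ] <- which(degree == 1L)
  edges
}

#' Generate a random two-layer model with ground truth
#'
#' The backbone is a uniform random spanning tree plus extra distinct edges
#' (connected by construction), each edge signed -1 with probability
#' \code{p_negative} and given a random direction. One node is designated a
#' bioprocess so that trimming is exercisable; the rest are proteins. Each
#' node gets \code{genes_per_node} unique synthetic transcripts with
#' equiprobable downstream signs. True node effects are drawn i.i.d.
#' \eqn{N(0, effect\_sd^2)} (or propagated coherently from a root, see
#' \code{coherent}).
#'
#' @param config A \code{"synth_config"}.
#' @param seed Optional seed (overrides \code{config$seed}).
#' @param coherent If \code{TRUE}, the truth is maximally
#'   network-consistent: a root value of magnitude \code{effect_sd}
#'   propagated through edge signs, instead of i.i.d. effects.
#' @param gene_prefix Prefix for synthetic gene symbols; vary it to obtain
#'   gene-disjoint models.
#' @return Object of class \code{"synth_truth"}: \code{model}
#'   (a \code{"two_layer_model"}), \code{f_true} (named), \code{config}.
#' @export
generate_model <- function(config = synth_config(), seed = NULL,
                           coherent = FALSE, gene_prefix = "SG") {
  stopifnot(inherits(config, "synth_config"))
  seed <- if (!is.null(seed)) seed else config$seed
  .with_seed(seed, {
    n <- config$n_backbone
    ids <- sprintf("p(SYN:N%03d)", seq_len(n))
    tree <- .random_tree_edges(n)
    key <- function(e) paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    have <- key(tree)
    extra <- config$n_edges - (n - 1)
    edges <- tree
    if (extra > 0) {
      all_pairs <- t(utils::combn(n, 2))
      pool <- all_pairs[!(key(all_pairs) %in% have), , drop = FALSE]
      pick <- pool[sample.int(nrow(pool), extra), , drop = FALSE]
      edges <- rbind(edges, pick)
    }
    # random orientation; signs -1 with probability p_negative
    flip <- stats::runif(nrow(edges)) < 0.5
    src <- ifelse(flip, edges[, 2], edges[, 1])
    tgt <- ifelse(flip, edges[, 1], edges[, 2])
    sgn <- ifelse(stats::runif(nrow(edges)) < config$p_negative, -1L, 1L)
    bp <- sample.int(n, 1)
    kinds <- rep("protein", n)
    kinds[bp] <- "bioprocess"
    ids[bp] <- sub("^p\\(", "bp(", ids[bp])
    nodes <- data.frame(id = ids, kind = kinds, namespace = "SYN",
                        name = sprintf("N%03d", seq_len(n)),
                        stringsAsFactors = FALSE)
    edge_df <- data.frame(source = ids[src], target = ids[tgt], sign = sgn,
                          direct = FALSE, weight = 1,
                          evidence_count = 1L, via_activity = FALSE,
                          stringsAsFactors = FALSE)
    backbone <- causal_network(nodes, edge_df)
    down <- data.frame(
      backbone_node = rep(ids, each = config$genes_per_node),
      gene = sprintf("%s%04d", gene_prefix,
                     seq_len(n * config$genes_per_node)),
      sign = ifelse(stats::runif(n * config$genes_per_node) < 0.5, -1L, 1L),
      weight = 1, stringsAsFactors = FALSE)
    model <- two_layer_model(backbone, down, name = "synthetic")
    f_true <- if (coherent) {
      # propagate a root value through edge signs along a spanning tree
      g <- igraph::graph_from_edgelist(cbind(src, tgt), directed = FALSE)
      root <- 1L
      val <- rep(NA_real_, n)
      val[root] <- config$effect_sd
      sgn_of <- new.env(parent = emptyenv())
      for (e in seq_len(nrow(edges)))
        assign(paste(src[e], tgt[e]), sgn[e], envir = sgn_of)
      bfs <- igraph::bfs(g, root, father = TRUE)
      ord <- as.integer(bfs$order)
      fa <- as.integer(bfs$father)
      for (v in ord[-1]) {
        p <- fa[v]
        s <- get0(paste(p, v), envir = sgn_of,
                  ifnotfound = get0(paste(v, p), envir = sgn_of))
        val[v] <- val[p] * s
      }
      val
    } else stats::rnorm(n, 0, config$effect_sd)
    names(f_true) <- ids
    structure(list(model = model, f_true = f_true, config = config),
              class = "synth_truth")
  })
}

#' @export
print.synth_truth <- function(x, ...) {
  cat("<synth_truth> ", sep = "")
  print(x$model)
  invisible(x)
}

#' Simulate an expression table from a ground truth
#'
#' For each downstream edge (x, g, s):
#' \eqn{\beta_g = s f_{true}(x) + \epsilon_g},
#' \eqn{\epsilon_g \sim N(0, noise\_sd^2)} independent; the variance field is
#' \code{noise_sd^2}.
#'
#' @param truth A \code{"synth_truth"} (or a \code{"two_layer_model"} with
#'   \code{f_true} given separately).
#' @param noise_sd Noise sd (defaults to the generating config's value).
#' @param seed Optional seed.
#' @param f_true Named truth vector when \code{truth} is a plain model.
#' @return An \code{"expression_table"}.
#' @export
simulate_expression <- function(truth, noise_sd = NULL, seed = NULL,
                                f_true = NULL) {
  if (inherits(truth, "synth_truth")) {
    model <- truth$model
    if (is.null(f_true)) f_true <- truth$f_true
    if (is.null(noise_sd)) noise_sd <- truth$config$noise_sd
  } else {
    model <- truth
    if (is.null(f_true)) stop("give f_true when truth is a plain model")
    if (is.null(noise_sd)) stop("give noise_sd")
  }
  stopifnot(noise_sd >= 0)
  down <- model$downstream
  .with_seed(seed, {
    beta <- down$sign * as.numeric(f_true[down$backbone_node]) +
      stats::rnorm(nrow(down), 0, noise_sd)
    expression_table(down$gene, beta, variance = rep(noise_sd^2, nrow(down)))
  })
}

#' Null expression table (no signal)
#'
#' As \code{\link{simulate_expression}} with all true effects zero: pure
#' noise on the model's own downstream genes.
#'
#' @param model A \code{"two_layer_model"} or \code{"synth_truth"}.
#' @param noise_sd Noise sd.
#' @param seed Optional seed.
#' @return An \code{"expression_table"}.
#' @export
null_expression <- function(model, noise_sd = 1, seed = NULL) {
  if (inherits(model, "synth_truth")) model <- model$model
  f0 <- rep(0, nrow(model$backbone$nodes))
  names(f0) <- model$backbone$nodes$id
  simulate_expression(model, noise_sd = noise_sd, seed = seed, f_true = f0)
}

#' Recovery metrics between truth and estimate
#'
#' @param f_true,f_hat Named vectors over the same node set (order-free).
#' @return List with \code{pearson_r} and \code{rmse}. Correlation is
#'   \code{NA} with a warning when either vector has zero variance.
#' @export
recovery_metrics <- function(f_true, f_hat) {
  if (length(f_true) != length(f_hat))
    stop("f_true and f_hat must have the same length")
  if (!is.null(names(f_true)) && !is.null(names(f_hat))) {
    if (!setequal(names(f_true), names(f_hat)))
      stop("f_true and f_hat must cover the same node set")
    f_hat <- f_hat[names(f_true)]
  }
  rmse <- sqrt(mean((f_true - f_hat)^2))
  r <- if (stats::sd(f_true) == 0 || stats::sd(f_hat) == 0) {
    warning("zero variance; correlation undefined", call. = FALSE)
    NA_real_
  } else stats::cor(f_true, f_hat)
  list(pearson_r = r, rmse = rmse)
}
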