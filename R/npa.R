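#' @title Network perturbation amplitude engine
#' @description Translates gene-expression fold-changes into differential
#'   values on the model backbone by signed harmonic extension, then
#'   summarizes them into a single network perturbation amplitude (NPA).
#'
#'   The backbone values f minimize the quadratic objective
#'   \deqn{\sum_{(x,y)\in backbone} w (f_x - \sigma_{xy} f_y)^2 +
#'         \sum_{(x,g)\in downstream} w (f_x - s_{xg}\beta_g)^2 +
#'         \epsilon \sum_x f_x^2,}
#'   whose unique minimizer is \eqn{f = -L_{bb}^{-1} L_{bg} \beta} with the
#'   signed-Laplacian blocks assembled by \code{\link{assemble_system}}.
#'   Backbone edges act as undirected signed smoothness constraints;
#'   direction is kept for trimming and display only.
#' @name npa-engine
NULL

# undirected connected components by union-find; i,j are integer endpoint
# indices in 1..n
.components <- function(n, i, j) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (k in seq_along(i)) {
    a <- find(i[k]); b <- find(j[k])
    if (a != b) parent[a] <- b
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' Match an expression table to a model's downstream genes
#'
#' Keeps rows whose gene occurs in the downstream layer. Matching is
#' case-insensitive; symbols are canonicalized to upper case in the result.
#'
#' @param model A \code{"two_layer_model"}.
#' @param table An \code{"expression_table"}.
#' @return List with \code{table} (matched rows, upper-case symbols) and
#'   \code{coverage} (matched distinct downstream genes / all distinct
#'   downstream genes). Coverage below 0.5 warns; zero coverage is an error.
#' @export
match_expression <- function(model, table) {
  stopifnot(inherits(model, "two_layer_model"))
  down_genes <- unique(toupper(model$downstream$gene))
  if (!length(down_genes)) stop("model has no downstream genes")
  tg <- toupper(table$gene)
  keep <- tg %in% down_genes
  matched_genes <- unique(tg[keep])
  coverage <- length(matched_genes) / length(down_genes)
  if (coverage == 0)
    stop("no measurable overlap between expression table and model downstream genes")
  if (coverage <= 0.5)
    warning(sprintf("only %.0f%% of downstream genes are measured", 100 * coverage),
            call. = FALSE)
  out <- table[keep, , drop = FALSE]
  out$gene <- tg[keep]
  # case-collision after canonicalization would duplicate symbols
  if (anyDuplicated(out$gene))
    stop("gene symbols collide after upper-casing: ",
         paste(unique(out$gene[duplicated(out$gene)]), collapse = ", "))
  rownames(out) <- NULL
  class(out) <- c("expression_table", "data.frame")
  list(table = out, coverage = coverage)
}

#' Assemble the signed-Laplacian system
#'
#' Builds the blocks of the inference system over the scoreable backbone:
#' \itemize{
#'   \item \code{L_bb[x,x]} = total absolute incident weight (backbone edges
#'     plus matched downstream edges) + ridge;
#'   \item \code{L_bb[x,y]} = \eqn{-\sum sign \cdot weight} over backbone
#'     edges between x and y (both directions);
#'   \item \code{L_bg[x,g]} = \eqn{-s(x,g) \cdot weight} for matched
#'     downstream edges.
#' }
#' Connected components with no matched downstream edge carry no information
#' and are removed with a warning before assembly; \code{L_bb} is positive
#' definite on what remains.
#'
#' @param model A \code{"two_layer_model"}.
#' @param matched Matched \code{"expression_table"}
#'   (from \code{\link{match_expression}}).
#' @param ridge Non-negative diagonal regularizer (numerical safety).
#' @return Object of class \code{"laplacian_system"}: \code{backbone_index},
#'   \code{gene_index}, \code{L_bb}, \code{L_bg}, \code{L_backbone} (the
#'   backbone-only signed Laplacian, for the alternative score mode),
#'   \code{ridge}, plus the downstream slot bookkeeping used for
#'   permutations.
#' @export
assemble_system <- function(model, matched, ridge = 1e-10) {
  stopifnot(inherits(model, "two_layer_model"))
  ids <- model$backbone$nodes$id
  n <- length(ids)
  if (!n) stop("backbone is empty")
  ed <- model$backbone$edges
  ei <- match(ed$source, ids); ej <- match(ed$target, ids)
  down <- model$downstream
  di <- match(down$backbone_node, ids)
  dgene <- toupper(down$gene)
  dmatch <- dgene %in% matched$gene

  comp <- .components(n, ei, ej)
  has_gene <- unique(comp[di[dmatch]])
  keep <- comp %in% has_gene
  if (!any(keep)) stop("empty backbone after dropping components without matched genes")
  if (!all(keep))
    warning(sprintf("%d backbone node(s) in %d component(s) without matched downstream genes dropped before assembly",
                    sum(!keep), length(unique(comp[!keep]))), call. = FALSE)

  old2new <- cumsum(keep); old2new[!keep] <- NA_integer_
  ids2 <- ids[keep]; n2 <- sum(keep)
  ekeep <- keep[ei] & keep[ej]
  ei2 <- old2new[ei[ekeep]]; ej2 <- old2new[ej[ekeep]]
  es2 <- ed$sign[ekeep]; ew2 <- ed$weight[ekeep]

  L_backbone <- matrix(0, n2, n2, dimnames = list(ids2, ids2))
  for (k in seq_along(ei2)) {
    a <- ei2[k]; b <- ej2[k]
    L_backbone[a, b] <- L_backbone[a, b] - es2[k] * ew2[k]
    L_backbone[b, a] <- L_backbone[b, a] - es2[k] * ew2[k]
    L_backbone[a, a] <- L_backbone[a, a] + ew2[k]
    L_backbone[b, b] <- L_backbone[b, b] + ew2[k]
  }

  dkeep <- dmatch & keep[di]
  di2 <- old2new[di[dkeep]]
  ds2 <- down$sign[dkeep]; dw2 <- down$weight[dkeep]
  dg2 <- dgene[dkeep]
  gene_index <- sort(unique(dg2))
  gj <- match(dg2, gene_index)
  L_bg <- matrix(0, n2, length(gene_index),
                 dimnames = list(ids2, gene_index))
  L_bg[cbind(di2, gj)] <- L_bg[cbind(di2, gj)] - ds2 * dw2
  diag_down <- numeric(n2)
  agg <- rowsum(dw2, di2)
  diag_down[as.integer(rownames(agg))] <- agg[, 1]

  L_bb <- L_backbone
  diag(L_bb) <- diag(L_bb) + diag_down + ridge

  structure(list(backbone_index = ids2, gene_index = gene_index,
                 L_bb = L_bb, L_bg = L_bg, L_backbone = L_backbone,
                 ridge = ridge,
                 slots = data.frame(node = di2, gene = dg2, sign = ds2,
                                    weight = dw2, stringsAsFactors = FALSE)),
            class = "laplacian_system")
}

#' @export
print.laplacian_system <- function(x, ...) {
  cat("<laplacian_system> ", length(x$backbone_index), " backbone nodes x ",
      length(x$gene_index), " matched genes (ridge ", format(x$ridge), ")\n",
      sep = "")
  invisible(x)
}

#' Infer backbone differential values
#'
#' Solves \eqn{f = -L_{bb}^{-1} L_{bg} \beta}, the closed form of the signed
#' harmonic-extension objective (see \code{\link{npa-engine}}).
#'
#' @param system A \code{"laplacian_system"}.
#' @param beta Numeric vector of fold-changes. Either aligned with
#'   \code{system$gene_index}, or named by gene symbol (reordered
#'   internally).
#' @return Named numeric vector of differential values over
#'   \code{system$backbone_index}.
#' @export
infer_backbone <- function(system, beta) {
  beta <- .align_beta(system, beta)
  ch <- tryCatch(chol(system$L_bb), error = function(e) NULL)
  if (is.null(ch) || kappa(system$L_bb, exact = FALSE) > 1e12)
    stop("L_bb is singular or ill-conditioned (condition number > 1e12); ",
         "run validate_model() and check for components without matched genes")
  rhs <- -as.vector(system$L_bg %*% beta)
  f <- backsolve(ch, forwardsolve(t(ch), rhs))
  names(f) <- system$backbone_index
  f
}

.align_beta <- function(system, beta) {
  if (!is.null(names(beta))) {
    idx <- match(system$gene_index, toupper(names(beta)))
    if (anyNA(idx))
      stop("beta lacks value(s) for matched gene(s): ",
           paste(system$gene_index[is.na(idx)], collapse = ", "))
    beta <- beta[idx]
  } else if (length(beta) != length(system$gene_index)) {
    stop("beta must align with system$gene_index")
  }
  as.numeric(beta)
}

#' Compute the NPA score and per-node contributions
#'
#' Mean-square mode (default): \eqn{score = |V_b|^{-1} \sum_x f_x^2} with
#' non-negative contributions \eqn{f_x^2/|V_b|}. Backbone-laplacian mode:
#' \eqn{score = |V_b|^{-1} f^T \tilde L f} with contributions
#' \eqn{f_x (\tilde L f)_x / |V_b|}, which may be negative (flagged).
#' Directions are \eqn{sign(f_x)}, zero below 1e-12.
#'
#' @param f Named backbone state from \code{\link{infer_backbone}}.
#' @param system The \code{"laplacian_system"} (needed for the
#'   backbone-laplacian mode; optional for mean-square).
#' @param mode \code{"mean-square"} or \code{"backbone-laplacian"}.
#' @return List with \code{score}, \code{contributions} (named),
#'   \code{directions} (named, in -1/0/1), \code{mode},
#'   \code{negative_contributions} (logical flag).
#' @export
npa_score <- function(f, system = NULL,
                      mode = c("mean-square", "backbone-laplacian")) {
  mode <- match.arg(mode)
  n <- length(f)
  if (!n) stop("empty backbone state")
  if (mode == "mean-square") {
    contrib <- f^2 / n
  } else {
    if (is.null(system)) stop("backbone-laplacian mode needs the system")
    Lf <- as.vector(system$L_backbone %*% f)
    contrib <- f * Lf / n
  }
  names(contrib) <- names(f)
  dirs <- ifelse(abs(f) < 1e-12, 0, sign(f))
  names(dirs) <- names(f)
  list(score = sum(contrib), contributions = contrib, directions = dirs,
       mode = mode, negative_contributions = any(contrib < 0))
}

#' Delta-method confidence interval for the NPA score
#'
#' First-order propagation of per-gene variances through the pipeline: with
#' \eqn{M = -L_{bb}^{-1} L_{bg}} and \eqn{score = q(M\beta)},
#' \eqn{Var(score) \approx \sum_g (\partial score/\partial \beta_g)^2 Var(\beta_g)}
#' evaluated at beta. The interval is
#' \eqn{score \pm z_{(1+level)/2} \sqrt{Var}}.
#'
#' @param system A \code{"laplacian_system"}.
#' @param beta Fold-changes (aligned or named; see
#'   \code{\link{infer_backbone}}).
#' @param variances Per-gene variances aligned the same way as beta.
#' @param level Confidence level.
#' @param mode Score mode.
#' @return List with \code{ci_low}, \code{ci_high}, \code{score},
#'   \code{var_score}, \code{gradient}.
#' @export
confidence_interval <- function(system, beta, variances, level = 0.95,
                                mode = c("mean-square", "backbone-laplacian")) {
  mode <- match.arg(mode)
  if (!is.null(names(variances)) && !is.null(names(beta)))
    variances <- variances[match(names(beta), names(variances))]
  beta_al <- .align_beta(system, beta)
  var_al <- if (!is.null(names(beta))) {
    v <- variances
    names(v) <- toupper(names(beta))
    as.numeric(v[match(system$gene_index, names(v))])
  } else as.numeric(variances)
  if (length(var_al) != length(beta_al)) stop("variances must align with beta")
  if (anyNA(var_al) || any(var_al < 0)) stop("variances must be non-negative")
  f <- infer_backbone(system, beta_al)
  sc <- npa_score(f, system, mode)
  n <- length(f)
  g_f <- if (mode == "mean-square") 2 * f / n
         else 2 * as.vector(system$L_backbone %*% f) / n
  # d score / d beta = M' g_f  with M = -L_bb^{-1} L_bg (L_bb symmetric)
  grad <- -as.vector(t(system$L_bg) %*% solve(system$L_bb, g_f))
  var_score <- sum(grad^2 * var_al)
  z <- stats::qnorm((1 + level) / 2)
  half <- z * sqrt(var_score)
  list(ci_low = sc$score - half, ci_high = sc$score + half,
       score = sc$score, var_score = var_score, gradient = grad)
}

#' Monte-Carlo confidence interval
#'
#' Resamples \eqn{\beta^* \sim N(\beta, Var(\beta))} gene-wise, re-scores,
#' and returns empirical quantiles — a sampling-based alternative to the
#' delta method.
#'
#' @inheritParams confidence_interval
#' @param n_draws Number of resampled datasets.
#' @param seed Optional RNG seed (restored on exit).
#' @return List with \code{ci_low}, \code{ci_high}, \code{score},
#'   \code{draws}.
#' @export
mc_confidence_interval <- function(system, beta, variances, level = 0.95,
                                   mode = c("mean-square", "backbone-laplacian"),
                                   n_draws = 1000, seed = NULL) {
  mode <- match.arg(mode)
  beta_al <- .align_beta(system, beta)
  var_al <- if (!is.null(names(beta))) {
    v <- variances; names(v) <- toupper(names(beta))
    as.numeric(v[match(system$gene_index, names(v))])
  } else as.numeric(variances)
  sc <- npa_score(infer_backbone(system, beta_al), system, mode)
  draws <- .with_seed(seed, {
    vapply(seq_len(n_draws), function(i) {
      b <- stats::rnorm(length(beta_al), beta_al, sqrt(var_al))
      npa_score(infer_backbone(system, b), system, mode)$score
    }, numeric(1))
  })
  qs <- stats::quantile(draws, c((1 - level) / 2, (1 + level) / 2),
                        names = FALSE)
  list(ci_low = qs[1], ci_high = qs[2], score = sc$score, draws = draws)
}

#' Extract leading nodes
#'
#' Nodes sorted by absolute contribution (ties by node id); the leading set
#' is the shortest prefix whose cumulative share of total absolute
#' contribution reaches the threshold (80% by default).
#'
#' @param contributions Named numeric contributions.
#' @param threshold Cumulative share in (0, 1].
#' @param directions Optional named direction vector carried onto the rows.
#' @return data.frame with columns node, contribution, pct, cum_pct, rank,
#'   direction, leading (logical), ordered by rank; attribute
#'   \code{"leading"} holds the leading node ids.
#' @export
leading_nodes <- function(contributions, threshold = 0.8, directions = NULL) {
  stopifnot(threshold > 0, threshold <= 1)
  tot <- sum(abs(contributions))
  if (tot == 0) {
    warning("all contributions are zero; no leading nodes", call. = FALSE)
    out <- data.frame(node = character(0), contribution = numeric(0),
                      pct = numeric(0), cum_pct = numeric(0),
                      rank = integer(0), direction = numeric(0),
                      leading = logical(0))
    attr(out, "leading") <- character(0)
    return(out)
  }
  ord <- order(-abs(contributions), names(contributions))
  cc <- contributions[ord]
  pct <- 100 * abs(cc) / tot
  cum <- cumsum(pct)
  n_lead <- which(cum >= 100 * threshold - 1e-9)[1]
  out <- data.frame(node = names(cc), contribution = as.numeric(cc),
                    pct = pct, cum_pct = cum, rank = seq_along(cc),
                    direction = if (!is.null(directions))
                      as.numeric(directions[names(cc)]) else sign(cc),
                    leading = seq_along(cc) <= n_lead,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "leading") <- out$node[out$leading]
  out
}

#' Induced subnetwork on the leading nodes
#'
#' @param model A \code{"two_layer_model"}.
#' @param leading Character vector of leading node ids, or the data.frame
#'   from \code{\link{leading_nodes}}.
#' @param f Optional named backbone state; stored on nodes as
#'   \code{npa_value}.
#' @param contributions Optional named contributions; stored as
#'   \code{contribution}.
#' @return A \code{"causal_network"}: the induced backbone subgraph on the
#'   leading set, nodes annotated with inferred direction and contribution.
#' @export
leading_subnetwork <- function(model, leading, f = NULL, contributions = NULL) {
  if (is.data.frame(leading)) leading <- attr(leading, "leading")
  stopifnot(inherits(model, "two_layer_model"))
  bb <- model$backbone
  missing <- setdiff(leading, bb$nodes$id)
  if (length(missing))
    stop("leading node(s) not in backbone: ", paste(missing, collapse = ", "))
  nodes <- bb$nodes[bb$nodes$id %in% leading, , drop = FALSE]
  edges <- bb$edges[bb$edges$source %in% leading &
                    bb$edges$target %in% leading, , drop = FALSE]
  if (!is.null(f)) {
    nodes$npa_value <- as.numeric(f[nodes$id])
    nodes$direction <- ifelse(abs(nodes$npa_value) < 1e-12, 0,
                              sign(nodes$npa_value))
  }
  if (!is.null(contributions))
    nodes$contribution <- as.numeric(contributions[nodes$id])
  net <- causal_network(nodes[, c("id", "kind", "namespace", "name")],
                        edges, bb$provenance)
  net$nodes <- nodes  # keep annotation columns
  net
}
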