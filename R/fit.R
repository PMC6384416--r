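#' Fit the network perturbation amplitude
#'
#' The main entry point: scores a differential gene-expression contrast onto
#' a two-layer causal network model. Runs the full pipeline — gene matching,
#' signed-Laplacian assembly, backbone inference, scoring, confidence
#' interval, O/K permutation statistics, leading-node decomposition — and
#' returns a fitted object with the usual methods (\code{print},
#' \code{summary}, \code{coef}, \code{fitted}, \code{residuals},
#' \code{predict}, \code{plot}, \code{simulate}).
#'
#' @param model A \code{"two_layer_model"} (see \code{\link{split_layers}}),
#'   or a \code{"causal_network"} (split automatically).
#' @param expression An \code{"expression_table"} (gene, beta, variance).
#' @param mode Score quadratic form: \code{"mean-square"} (default) or
#'   \code{"backbone-laplacian"}.
#' @param level Confidence level for the score interval.
#' @param leading_threshold Cumulative contribution share defining the
#'   leading nodes (default 0.8).
#' @param permutations Which companion statistics to compute: any of
#'   \code{"O"}, \code{"K"} (default both); \code{character(0)} for none.
#' @param n_perm Permutations per statistic.
#' @param seed Master seed; per-statistic child streams are derived from it,
#'   so a fit is bit-reproducible given the seed.
#' @param alpha_strong,alpha_weak Significance levels for the strong/weak
#'   flags.
#' @param exhaustive Enumerate all permutations when there are at most
#'   10,000.
#' @param trim Trim hanging backbone nodes before scoring.
#' @param ridge Diagonal regularizer for the Laplacian system.
#' @param ci_method \code{"delta"} (first-order propagation, default) or
#'   \code{"montecarlo"} (resampling beta).
#' @param mc_draws Draws for the Monte-Carlo interval.
#' @return Object of class \code{"npa"}.
#' @examples
#' net <- compile_network(parse_script(c(
#'   'p(HGNC:A) increases p(HGNC:B)',
#'   'p(HGNC:A) increases r(HGNC:G1)',
#'   'p(HGNC:B) decreases r(HGNC:G2)')))
#' model <- split_layers(net)
#' expr <- expression_table(c("G1", "G2"), c(2, -2), c(0.1, 0.1))
#' fit <- npa(model, expr, permutations = character(0))
#' coef(fit)
#' @export
npa <- function(model, expression,
                mode = c("mean-square", "backbone-laplacian"),
                level = 0.95, leading_threshold = 0.8,
                permutations = c("O", "K"), n_perm = 500, seed = NULL,
                alpha_strong = 0.05, alpha_weak = 0.1, exhaustive = FALSE,
                trim = FALSE, ridge = 1e-10,
                ci_method = c("delta", "montecarlo"), mc_draws = 1000) {
  mode <- match.arg(mode)
  ci_method <- match.arg(ci_method)
  cl <- match.call()
  if (inherits(model, "causal_network")) model <- split_layers(model)
  stopifnot(inherits(model, "two_layer_model"))
  if (trim) model <- trim_dangling(model)$model

  m <- match_expression(model, expression)
  sys <- assemble_system(model, m$table, ridge = ridge)
  beta <- m$table$beta; names(beta) <- m$table$gene
  variances <- m$table$variance; names(variances) <- m$table$gene
  f <- infer_backbone(sys, beta)
  sc <- npa_score(f, sys, mode)
  ci <- if (ci_method == "delta")
    confidence_interval(sys, beta, variances, level = level, mode = mode)
  else
    mc_confidence_interval(sys, beta, variances, level = level, mode = mode,
                           n_draws = mc_draws, seed = .child_seed(seed, 3L))

  lead <- leading_nodes(sc$contributions, threshold = leading_threshold,
                        directions = sc$directions)

  res <- structure(list(
    score = sc$score, ci_low = ci$ci_low, ci_high = ci$ci_high,
    var_score = ci$var_score, f = f,
    contributions = sc$contributions, directions = sc$directions,
    leading = lead, leading_threshold = leading_threshold,
    mode = mode, level = level, ci_method = ci_method,
    negative_contributions = sc$negative_contributions,
    p_O = NA_real_, p_K = NA_real_, null_O = NULL, null_K = NULL,
    flags = list(star = isTRUE(ci$ci_low > 0), O_strong = NA, O_weak = NA,
                 K_strong = NA, K_weak = NA),
    coverage = m$coverage, matched = m$table, model = model, system = sys,
    n_perm = n_perm, seed = seed, ridge = ridge,
    permutation_scheme = c(O = "downstream gene-label shuffle",
                           K = "backbone edge-head permutation (tail-degree preserving)"),
    call = cl), class = "npa")

  o <- k <- NULL
  if ("O" %in% permutations)
    o <- permutation_pvalue(model, m$table, "O", n_perm = n_perm,
                            seed = .child_seed(seed, 1L),
                            exhaustive = exhaustive, mode = mode, ridge = ridge)
  if ("K" %in% permutations && nrow(model$backbone$edges) >= 2)
    k <- permutation_pvalue(model, m$table, "K", n_perm = n_perm,
                            seed = .child_seed(seed, 2L),
                            exhaustive = exhaustive, mode = mode, ridge = ridge)
  annotate_significance(res, o, k, alpha_strong = alpha_strong,
                        alpha_weak = alpha_weak)
}

.flag_string <- function(x) {
  fl <- x$flags
  tag <- function(ok, strong, weak, lab) {
    if (isTRUE(strong)) paste0("*", lab, "*")
    else if (isTRUE(weak)) lab
    else if (isTRUE(!strong && !weak)) paste0("(", lab, " n.s.)")
    else ""
  }
  paste(c(if (isTRUE(fl$star)) "*star*" else NULL,
          tag(TRUE, fl$O_strong, fl$O_weak, "O"),
          tag(TRUE, fl$K_strong, fl$K_weak, "K")), collapse = " ")
}

#' @export
print.npa <- function(x, digits = 4, ...) {
  cat("Network perturbation amplitude (", x$mode, ")\n", sep = "")
  cat("  model: '", x$model$name, "' (", length(x$f), " backbone nodes, ",
      nrow(x$model$downstream), " downstream edges, coverage ",
      sprintf("%.0f%%", 100 * x$coverage), ")\n", sep = "")
  cat("  NPA = ", format(x$score, digits = digits), "  [",
      format(x$ci_low, digits = digits), ", ",
      format(x$ci_high, digits = digits), "] (",
      sprintf("%.0f%%", 100 * x$level), " CI, ", x$ci_method, ")  ",
      .flag_string(x), "\n", sep = "")
  if (!is.na(x$p_O)) cat("  O statistic p = ", format(x$p_O, digits = digits),
                         "\n", sep = "")
  if (!is.na(x$p_K)) cat("  K statistic p = ", format(x$p_K, digits = digits),
                         "\n", sep = "")
  nl <- sum(x$leading$leading)
  cat("  leading nodes: ", nl, " of ", nrow(x$leading), " (",
      sprintf("%.0f%%", 100 * x$leading_threshold),
      " cumulative contribution)\n", sep = "")
  invisible(x)
}

#' @export
summary.npa <- function(object, n_top = 10, ...) {
  structure(list(fit = object, n_top = n_top), class = "summary.npa")
}

#' @export
print.summary.npa <- function(x, ...) {
  print(x$fit)
  lead <- x$fit$leading
  cat("\nTop contributing nodes:\n")
  top <- utils::head(lead, x$n_top)
  top$contribution <- signif(top$contribution, 4)
  top$pct <- round(top$pct, 1)
  top$cum_pct <- round(top$cum_pct, 1)
  print(top, row.names = FALSE)
  invisible(x)
}

#' @export
coef.npa <- function(object, ...) object$f

#' Fitted downstream fold-changes
#'
#' The model's prediction for each matched downstream edge:
#' \eqn{\hat\beta_g = s(x,g) f(x)} (inverting the downstream sign
#' convention), named by gene.
#'
#' @param object An \code{"npa"} fit.
#' @param ... Unused.
#' @export
fitted.npa <- function(object, ...) {
  sl <- object$system$slots
  out <- sl$sign * object$f[sl$node]
  names(out) <- sl$gene
  out
}

#' @export
residuals.npa <- function(object, ...) {
  fit <- fitted(object)
  beta <- object$matched$beta
  names(beta) <- object$matched$gene
  beta[names(fit)] - fit
}

#' Predict downstream responses or re-score new data
#'
#' Without \code{newdata}, returns the per-downstream-edge predicted
#' fold-changes (as \code{\link{fitted.npa}}, with bookkeeping columns).
#' With \code{newdata} (an \code{"expression_table"}), re-runs the fit on
#' the same model and returns the new \code{"npa"} object.
#'
#' @param object An \code{"npa"} fit.
#' @param newdata Optional \code{"expression_table"}.
#' @param ... Passed on to \code{\link{npa}} when re-fitting.
#' @export
predict.npa <- function(object, newdata = NULL, ...) {
  if (!is.null(newdata)) {
    args <- list(model = object$model, expression = newdata, mode = object$mode,
                 level = object$level, ridge = object$ridge, ...)
    return(do.call(npa, args))
  }
  sl <- object$system$slots
  data.frame(backbone_node = object$system$backbone_index[sl$node],
             gene = sl$gene, sign = sl$sign,
             predicted = sl$sign * object$f[sl$node],
             stringsAsFactors = FALSE)
}

#' Plot per-node contributions
#'
#' Horizontal bars of the top contributing backbone nodes, signed by the
#' inferred direction (positive = inferred activation); leading nodes are
#' marked with an asterisk.
#'
#' @param x An \code{"npa"} fit.
#' @param n_top Number of nodes shown.
#' @param ... Passed to \code{barplot}.
#' @export
plot.npa <- function(x, n_top = 10, ...) {
  lead <- utils::head(x$leading, n_top)
  vals <- lead$direction * abs(lead$contribution)
  labs <- ifelse(lead$leading, paste0(lead$node, " *"), lead$node)
  op <- graphics::par(mar = c(4, 12, 2, 1))
  on.exit(graphics::par(op))
  graphics::barplot(rev(vals), names.arg = rev(labs), horiz = TRUE,
                    las = 1, col = ifelse(rev(vals) >= 0, "firebrick",
                                          "steelblue"),
                    xlab = "signed contribution to NPA",
                    main = sprintf("NPA = %.3g %s", x$score, .flag_string(x)),
                    ...)
  invisible(x)
}

#' Simulate scores under the estimated sampling distribution of beta
#'
#' Draws \eqn{\beta^* \sim N(\hat\beta, Var(\hat\beta))} gene-wise and
#' re-scores each draw, giving the sampling distribution behind the
#' Monte-Carlo confidence interval.
#'
#' @param object An \code{"npa"} fit.
#' @param nsim Number of draws.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return Numeric vector of simulated scores, class-free.
#' @export
simulate.npa <- function(object, nsim = 100, seed = NULL, ...) {
  beta <- object$matched$beta; names(beta) <- object$matched$gene
  vars <- object$matched$variance; names(vars) <- object$matched$gene
  mc <- mc_confidence_interval(object$system, beta, vars,
                               level = object$level, mode = object$mode,
                               n_draws = nsim, seed = seed)
  mc$draws
}
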