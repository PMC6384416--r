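#' @title O and K permutation companion statistics
#' @description The NPA score alone does not say whether a perturbation is
#'   specific to the biology encoded in the model. Two permutation nulls
#'   probe this: the \emph{O} statistic shuffles which gene sits in which
#'   downstream slot (destroying the gene-to-backbone biology while keeping
#'   graph scale), and the \emph{K} statistic rewires backbone edge heads
#'   (destroying the backbone wiring). The observed score is compared against
#'   each null with the add-one estimator
#'   \eqn{p = (1 + \#\{score_{perm} \ge score_{obs}\}) / (n_{perm} + 1)}.
#' @name ok-statistics
NULL

#' Permute the downstream layer (O null)
#'
#' Gene labels are randomly permuted across downstream edge slots; signs and
#' weights stay with the slot, the backbone is untouched, and the downstream
#' size is preserved.
#'
#' @param model A \code{"two_layer_model"} with non-empty downstream layer.
#' @return A permuted \code{"two_layer_model"}.
#' @export
permute_downstream <- function(model) {
  stopifnot(inherits(model, "two_layer_model"))
  m <- nrow(model$downstream)
  if (!m) stop("downstream layer is empty")
  model$downstream$gene <- model$downstream$gene[sample.int(m)]
  model
}

#' Permute the backbone wiring (K null)
#'
#' Edge head endpoints are randomly permuted across backbone edges; tails,
#' signs and weights stay with their edge, so the node set, edge count and
#' sign multiset are preserved (a tail-degree-preserving rewiring). Draws
#' producing self-loops are re-drawn up to 100 times, then accepted.
#'
#' @param model A \code{"two_layer_model"} whose backbone has >= 2 edges.
#' @return A permuted \code{"two_layer_model"}.
#' @export
permute_backbone <- function(model) {
  stopifnot(inherits(model, "two_layer_model"))
  ed <- model$backbone$edges
  if (nrow(ed) < 2) stop("backbone needs >= 2 edges for the K permutation")
  for (attempt in seq_len(100)) {
    perm <- sample.int(nrow(ed))
    heads <- ed$target[perm]
    if (!any(heads == ed$source)) break
  }
  model$backbone$edges$target <- heads
  model
}

# one full scoring pass: match -> assemble -> infer -> score; warnings about
# coverage/component dropping are silenced inside permutation loops
.pipeline_score <- function(model, table, mode = "mean-square",
                            ridge = 1e-10, quiet = FALSE) {
  run <- function() {
    m <- match_expression(model, table)
    sys <- assemble_system(model, m$table, ridge = ridge)
    beta <- m$table$beta
    names(beta) <- m$table$gene
    f <- infer_backbone(sys, beta)
    sc <- npa_score(f, sys, mode)
    list(score = sc$score, f = f, system = sys, matched = m, npa = sc)
  }
  if (quiet) suppressWarnings(run()) else run()
}

#' Permutation p-value for the NPA score
#'
#' Re-runs the full assemble/infer/score pipeline on permuted copies of the
#' model (same expression table) and compares with the observed score.
#' Permutations whose model cannot be scored (e.g. a permuted component left
#' without matched genes) are re-drawn, up to \code{10 * n_perm} redraws.
#' With \code{exhaustive = TRUE} and at most 10,000 distinct permutations,
#' all of them are enumerated for an exact null.
#'
#' @param model A \code{"two_layer_model"}.
#' @param table An \code{"expression_table"}.
#' @param kind \code{"O"} (downstream shuffle) or \code{"K"} (backbone
#'   rewiring).
#' @param n_perm Number of permutations (ignored in exhaustive mode).
#' @param seed Optional seed; results are reproducible given the seed.
#' @param exhaustive Enumerate all permutations when feasible.
#' @param mode,ridge Passed to the scoring pipeline.
#' @return Object of class \code{"permutation_null"}: \code{values},
#'   \code{observed}, \code{p}, \code{kind}, \code{n_perm},
#'   \code{exhaustive}, \code{redraws}.
#' @export
permutation_pvalue <- function(model, table, kind = c("O", "K"),
                               n_perm = 500, seed = NULL, exhaustive = FALSE,
                               mode = "mean-square", ridge = 1e-10) {
  kind <- match.arg(kind)
  stopifnot(n_perm >= 1)
  observed <- .pipeline_score(model, table, mode, ridge)$score
  n_slots <- if (kind == "O") nrow(model$downstream)
             else nrow(model$backbone$edges)
  if (kind == "K" && n_slots < 2)
    stop("backbone needs >= 2 edges for the K permutation")

  apply_perm <- function(model, perm) {
    if (kind == "O") model$downstream$gene <- model$downstream$gene[perm]
    else model$backbone$edges$target <- model$backbone$edges$target[perm]
    model
  }

  if (exhaustive && factorial(n_slots) <= 10000) {
    perms <- .all_permutations(n_slots)
    values <- vapply(perms, function(p) {
      tryCatch(.pipeline_score(apply_perm(model, p), table, mode, ridge,
                               quiet = TRUE)$score,
               error = function(e) NA_real_)
    }, numeric(1))
    values <- values[!is.na(values)]
    n_used <- length(values)
  } else {
    if (exhaustive)
      warning("more than 10,000 permutations; falling back to sampling",
              call. = FALSE)
    values <- numeric(n_perm)
    redraws <- 0L
    .with_seed(seed, {
      for (i in seq_len(n_perm)) {
        repeat {
          mp <- if (kind == "O") permute_downstream(model)
                else permute_backbone(model)
          sc <- tryCatch(.pipeline_score(mp, table, mode, ridge,
                                         quiet = TRUE)$score,
                         error = function(e) NA_real_)
          if (!is.na(sc)) break
          redraws <- redraws + 1L
          if (redraws > 10L * n_perm)
            stop("too many unscoreable permuted models (", redraws,
                 " redraws); check validate_model()")
        }
        values[i] <- sc
      }
    })
    n_used <- n_perm
  }
  p <- (1 + sum(values >= observed - 1e-12)) / (n_used + 1)
  structure(list(values = values, observed = observed, p = p, kind = kind,
                 n_perm = n_used, exhaustive = exhaustive,
                 redraws = if (exists("redraws")) redraws else 0L),
            class = "permutation_null")
}

#' @export
print.permutation_null <- function(x, ...) {
  cat("<permutation_null> ", x$kind, " statistic: observed ",
      format(x$observed, digits = 4), ", p = ", format(x$p, digits = 4),
      " (", x$n_perm, " permutations",
      if (x$exhaustive) ", exhaustive" else "", ")\n", sep = "")
  invisible(x)
}

#' Attach significance flags to an NPA result
#'
#' Sets \code{star} (confidence interval excludes zero), and strong/weak
#' flags per statistic: strong when \eqn{p < \alpha_{strong}} (0.05 by
#' default), weak when \eqn{\alpha_{strong} \le p < \alpha_{weak}} (0.1).
#'
#' @param result An \code{"npa"} fit.
#' @param o,k \code{"permutation_null"} objects (either may be NULL).
#' @param alpha_strong,alpha_weak Significance levels,
#'   \code{0 < alpha_strong < alpha_weak < 1}.
#' @return The result with \code{p_O}, \code{p_K}, \code{null_O},
#'   \code{null_K} and \code{flags} filled in.
#' @export
annotate_significance <- function(result, o = NULL, k = NULL,
                                  alpha_strong = 0.05, alpha_weak = 0.1) {
  stopifnot(alpha_strong > 0, alpha_strong < alpha_weak, alpha_weak < 1)
  flags <- list(star = isTRUE(result$ci_low > 0),
                O_strong = NA, O_weak = NA, K_strong = NA, K_weak = NA)
  if (!is.null(o)) {
    result$p_O <- o$p; result$null_O <- o
    flags$O_strong <- o$p < alpha_strong
    flags$O_weak <- o$p >= alpha_strong && o$p < alpha_weak
  }
  if (!is.null(k)) {
    result$p_K <- k$p; result$null_K <- k
    flags$K_strong <- k$p < alpha_strong
    flags$K_weak <- k$p >= alpha_strong && k$p < alpha_weak
  }
  result$flags <- flags
  result
}
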