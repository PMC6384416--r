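#' Split a compiled network into backbone and downstream layers
#'
#' RNA nodes are removed from the model backbone and used in the downstream
#' layer: every edge from a backbone node to an RNA node becomes a downstream
#' edge whose sign is the edge sign and whose gene symbol is the RNA node's
#' identifier. Edges between two RNA nodes, or from an RNA node into the
#' backbone, carry no meaning in the two-layer scoring model and are dropped
#' with a warning. All non-RNA nodes and their mutual edges form the backbone.
#'
#' @param network A \code{"causal_network"}.
#' @param name Model name recorded on the result.
#' @return A \code{"two_layer_model"}: list with \code{backbone}
#'   (\code{"causal_network"} without RNA nodes), \code{downstream}
#'   (data.frame: backbone_node, gene, sign, weight) and \code{name}.
#' @export
split_layers <- function(network, name = "model") {
  stopifnot(inherits(network, "causal_network"))
  is_rna <- network$nodes$kind == "rna"
  rna_ids <- network$nodes$id[is_rna]
  ed <- network$edges
  src_rna <- ed$source %in% rna_ids
  tgt_rna <- ed$target %in% rna_ids
  down <- ed[!src_rna & tgt_rna, , drop = FALSE]
  dropped <- ed[src_rna, , drop = FALSE]
  if (nrow(dropped))
    warning(sprintf(
      "%d edge(s) out of RNA nodes dropped during layer split (first: %s -> %s)",
      nrow(dropped), dropped$source[1], dropped$target[1]), call. = FALSE)
  backbone <- causal_network(
    nodes = network$nodes[!is_rna, , drop = FALSE],
    edges = ed[!src_rna & !tgt_rna, , drop = FALSE],
    provenance = network$provenance)
  gene_of <- network$nodes$name[match(down$target, network$nodes$id)]
  downstream <- data.frame(backbone_node = down$source,
                           gene = gene_of,
                           sign = down$sign,
                           weight = down$weight,
                           stringsAsFactors = FALSE)
  dup <- duplicated(downstream[, c("backbone_node", "gene")])
  if (any(dup)) downstream <- downstream[!dup, , drop = FALSE]
  rownames(downstream) <- NULL
  two_layer_model(backbone, downstream, name = name)
}

#' Construct a two-layer model
#'
#' @param backbone \code{"causal_network"} with no RNA-kind nodes.
#' @param downstream data.frame with columns \code{backbone_node},
#'   \code{gene}, \code{sign}, optionally \code{weight}.
#' @param name Model name.
#' @return Object of class \code{"two_layer_model"}.
#' @export
two_layer_model <- function(backbone, downstream = NULL, name = "model") {
  stopifnot(inherits(backbone, "causal_network"))
  if (any(backbone$nodes$kind == "rna"))
    stop("backbone must not contain RNA-kind nodes; use split_layers()")
  if (is.null(downstream) || !nrow(as.data.frame(downstream)))
    downstream <- data.frame(backbone_node = character(0), gene = character(0),
                             sign = integer(0), weight = numeric(0),
                             stringsAsFactors = FALSE)
  downstream <- as.data.frame(downstream, stringsAsFactors = FALSE)
  if (is.null(downstream$weight)) downstream$weight <- rep(1, nrow(downstream))
  need <- c("backbone_node", "gene", "sign", "weight")
  if (!all(need %in% names(downstream)))
    stop("downstream must have columns: ", paste(need, collapse = ", "))
  bad <- setdiff(unique(downstream$backbone_node), backbone$nodes$id)
  if (length(bad))
    stop("downstream edges reference unknown backbone node(s): ",
         paste(bad, collapse = ", "))
  if (nrow(downstream) && !all(downstream$sign %in% c(-1, 1)))
    stop("downstream signs must be +1 or -1")
  rownames(downstream) <- NULL
  structure(list(backbone = backbone,
                 downstream = downstream[, need, drop = FALSE],
                 name = as.character(name)),
            class = "two_layer_model")
}

#' @export
print.two_layer_model <- function(x, ...) {
  cat("<two_layer_model> '", x$name, "': ", nrow(x$backbone$nodes),
      " backbone nodes, ", nrow(x$backbone$edges), " backbone edges, ",
      nrow(x$downstream), " downstream edges (",
      length(unique(x$downstream$gene)), " genes)\n", sep = "")
  invisible(x)
}

#' Trim hanging backbone nodes
#'
#' Iteratively removes backbone nodes with no directed path to any
#' biological-process node ("hanging" nodes that do not lead to a process
#' described in the model). Process nodes always survive. Downstream edges of
#' removed nodes are removed with them. With \code{undirected = TRUE}
#' reachability ignores edge direction.
#'
#' @param model A \code{"two_layer_model"}.
#' @param undirected Use undirected reachability.
#' @param allow_no_bioprocess If \code{TRUE}, a model without any bioprocess
#'   node is returned untrimmed instead of raising an error.
#' @return List with elements \code{model} (trimmed) and \code{report}
#'   (class \code{"trim_report"}: removed_nodes, removed_edges, iterations).
#' @export
trim_dangling <- function(model, undirected = FALSE,
                          allow_no_bioprocess = FALSE) {
  stopifnot(inherits(model, "two_layer_model"))
  bb <- model$backbone
  bp <- bb$nodes$id[bb$nodes$kind == "bioprocess"]
  if (!length(bp)) {
    if (allow_no_bioprocess)
      return(list(model = model,
                  report = structure(list(removed_nodes = character(0),
                                          removed_edges = 0L, iterations = 0L),
                                     class = "trim_report")))
    stop("model has no bioprocess node; nothing can anchor trimming ",
         "(set allow_no_bioprocess = TRUE to skip)")
  }
  g <- .as_igraph(bb)
  mode <- if (undirected) "all" else "out"
  # nodes from which some bioprocess is reachable (fixpoint of iterated
  # removal equals one reachability pass on the full graph)
  d <- igraph::distances(g, to = bp, mode = mode)
  reach <- apply(is.finite(d), 1, any)
  keep <- bb$nodes$id[reach[bb$nodes$id]]
  removed <- setdiff(bb$nodes$id, keep)
  # iteration count reported as the longest chain peeled off, for
  # compatibility with the iterative description
  iters <- if (length(removed)) {
    sub <- igraph::induced_subgraph(g, removed)
    comp_d <- igraph::distances(sub, mode = "all")
    max(1L, as.integer(max(comp_d[is.finite(comp_d)])) + 1L)
  } else 0L
  edges <- bb$edges
  keep_e <- edges$source %in% keep & edges$target %in% keep
  new_bb <- causal_network(bb$nodes[bb$nodes$id %in% keep, , drop = FALSE],
                           edges[keep_e, , drop = FALSE], bb$provenance)
  down <- model$downstream
  down <- down[down$backbone_node %in% keep, , drop = FALSE]
  list(model = two_layer_model(new_bb, down, name = model$name),
       report = structure(list(removed_nodes = sort(removed),
                               removed_edges = sum(!keep_e),
                               iterations = iters),
                          class = "trim_report"))
}

#' @export
print.trim_report <- function(x, ...) {
  cat("<trim_report> removed ", length(x$removed_nodes), " node(s), ",
      x$removed_edges, " edge(s) in ", x$iterations, " iteration(s)\n",
      sep = "")
  invisible(x)
}

#' Degree table of the most connected nodes
#'
#' Computes in/out/total degree per node on the network as distributed:
#' parallel opposite-sign edges each count once. Rows are sorted by total
#' degree descending, ties broken by indegree then node id.
#'
#' @param network A \code{"causal_network"} (typically a model backbone).
#' @param k Number of top rows to return (\code{Inf} for all).
#' @return data.frame with columns node, indegree, outdegree, total.
#' @export
degree_table <- function(network, k = 10) {
  stopifnot(inherits(network, "causal_network"), k >= 1)
  ids <- network$nodes$id
  if (!length(ids))
    return(data.frame(node = character(0), indegree = integer(0),
                      outdegree = integer(0), total = integer(0)))
  indeg <- table(factor(network$edges$target, levels = ids))
  outdeg <- table(factor(network$edges$source, levels = ids))
  out <- data.frame(node = ids, indegree = as.integer(indeg),
                    outdegree = as.integer(outdeg),
                    stringsAsFactors = FALSE)
  out$total <- out$indegree + out$outdegree
  out <- out[order(-out$total, -out$indegree, out$node), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, n = if (is.finite(k)) k else nrow(out))
}

#' Diagnose a two-layer model before scoring
#'
#' Reports, per connected component of the backbone (undirected sense), the
#' node count and downstream-edge count; components with zero downstream
#' edges cannot be scored and are flagged, as are duplicate
#' (backbone_node, gene) downstream pairs.
#'
#' @param model A \code{"two_layer_model"}.
#' @return List of class \code{"model_diagnostics"}: \code{components}
#'   (data.frame: component, n_nodes, n_downstream), \code{flags}
#'   (character vector of problems), \code{component_of} (named membership).
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "two_layer_model"))
  bb <- model$backbone
  flags <- character(0)
  if (!nrow(bb$nodes)) {
    return(structure(list(components = data.frame(component = integer(0),
                                                  n_nodes = integer(0),
                                                  n_downstream = integer(0)),
                          flags = "backbone is empty",
                          component_of = integer(0)),
                     class = "model_diagnostics"))
  }
  g <- .as_igraph(bb)
  comp <- igraph::components(g, mode = "weak")$membership
  down_comp <- comp[model$downstream$backbone_node]
  tab <- data.frame(component = seq_len(max(comp)),
                    n_nodes = as.integer(table(factor(comp, seq_len(max(comp))))),
                    n_downstream = as.integer(table(factor(down_comp,
                                                           seq_len(max(comp))))))
  for (ci in tab$component[tab$n_downstream == 0]) {
    members <- names(comp)[comp == ci]
    flags <- c(flags, sprintf(
      "component %d (%d node(s), e.g. %s) has no downstream edges and cannot be scored",
      ci, length(members), members[1]))
  }
  dup <- duplicated(model$downstream[, c("backbone_node", "gene")])
  if (any(dup))
    flags <- c(flags, sprintf("duplicate downstream pair(s): %s",
                              paste(unique(paste0(
                                model$downstream$backbone_node[dup], "/",
                                model$downstream$gene[dup])), collapse = ", ")))
  structure(list(components = tab, flags = flags, component_of = comp),
            class = "model_diagnostics")
}

#' @export
print.model_diagnostics <- function(x, ...) {
  cat("<model_diagnostics> ", nrow(x$components), " component(s)\n", sep = "")
  print(x$components, row.names = FALSE)
  if (length(x$flags)) cat("flags:\n", paste0("  - ", x$flags, "\n"), sep = "")
  else cat("no flags\n")
  invisible(x)
}
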