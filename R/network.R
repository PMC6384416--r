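#' Construct a causal network
#'
#' A causal network holds a node table and a signed edge table. Used both for
#' full compiled knowledge assemblies and for model backbones.
#'
#' @param nodes data.frame with columns \code{id}, \code{kind},
#'   \code{namespace}, \code{name}.
#' @param edges data.frame with columns \code{source}, \code{target},
#'   \code{sign} (+1/-1), \code{direct} (logical), \code{weight} (> 0),
#'   \code{evidence_count} (>= 1), \code{via_activity} (logical).
#' @param provenance Free-text metadata.
#' @return Object of class \code{"causal_network"}.
#' @export
causal_network <- function(nodes = empty_nodes(), edges = empty_edges(),
                           provenance = character(0)) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  need_n <- c("id", "kind", "namespace", "name")
  if (!all(need_n %in% names(nodes)))
    stop("nodes must have columns: ", paste(need_n, collapse = ", "))
  need_e <- c("source", "target", "sign")
  if (!all(need_e %in% names(edges)))
    stop("edges must have columns: ", paste(need_e, collapse = ", "))
  if (is.null(edges$direct)) edges$direct <- FALSE
  if (is.null(edges$weight)) edges$weight <- 1
  if (is.null(edges$evidence_count)) edges$evidence_count <- 1L
  if (is.null(edges$via_activity)) edges$via_activity <- FALSE
  if (anyDuplicated(nodes$id))
    stop("duplicate node ids: ",
         paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", "))
  missing <- setdiff(unique(c(edges$source, edges$target)), nodes$id)
  if (length(missing))
    stop("edge endpoint(s) not declared as nodes: ",
         paste(missing, collapse = ", "))
  if (nrow(edges)) {
    if (!all(edges$sign %in% c(-1, 1))) stop("edge signs must be +1 or -1")
    if (any(edges$weight <= 0)) stop("edge weights must be positive")
    if (any(edges$evidence_count < 1)) stop("evidence_count must be >= 1")
  }
  rownames(nodes) <- NULL; rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges,
                 provenance = as.character(provenance)),
            class = "causal_network")
}

#' @rdname causal_network
#' @export
empty_nodes <- function() {
  data.frame(id = character(0), kind = character(0),
             namespace = character(0), name = character(0),
             stringsAsFactors = FALSE)
}

#' @rdname causal_network
#' @export
empty_edges <- function() {
  data.frame(source = character(0), target = character(0),
             sign = integer(0), direct = logical(0), weight = numeric(0),
             evidence_count = integer(0), via_activity = logical(0),
             stringsAsFactors = FALSE)
}

#' @export
print.causal_network <- function(x, ...) {
  cat("<causal_network> ", nrow(x$nodes), " nodes, ", nrow(x$edges),
      " edges\n", sep = "")
  kinds <- table(x$nodes$kind)
  if (length(kinds))
    cat("  kinds: ", paste(names(kinds), kinds, sep = "=", collapse = ", "),
        "\n", sep = "")
  invisible(x)
}

#' @export
format.causal_network <- function(x, ...) {
  sprintf("causal_network(%d nodes, %d edges)", nrow(x$nodes), nrow(x$edges))
}

#' Compile BEL statements into a causal network
#'
#' Statements with \code{relation = "unsupported"} are skipped. Activity
#' wrappers are collapsed onto the wrapped entity for node identity (recorded
#' per edge as \code{via_activity}). Parallel statements with the same
#' (source, target, sign) merge into one edge with \code{evidence_count}
#' incremented; opposite-sign edges between the same pair are retained, so
#' contradictory findings coexist in the model without preferential
#' treatment.
#'
#' @param statements List of \code{"bel_statement"} objects.
#' @param weight_by_evidence If \code{TRUE}, edge weight is set to the merged
#'   evidence count; default keeps weight 1 regardless of evidence volume.
#' @return A \code{"causal_network"}.
#' @export
compile_network <- function(statements, weight_by_evidence = FALSE) {
  keep <- vapply(statements, function(s) s$relation != "unsupported", logical(1))
  statements <- statements[keep]
  if (!length(statements)) return(causal_network())

  node_tab <- new.env(parent = emptyenv())
  add_node <- function(e) {
    id <- entity_id(e)
    if (is.null(node_tab[[id]])) {
      b <- entity_base(e)
      node_tab[[id]] <- c(id = id, kind = b$kind,
                          namespace = b$namespace, name = b$identifier)
    }
    id
  }
  src <- tgt <- character(length(statements))
  sgn <- integer(length(statements))
  dir <- act <- logical(length(statements))
  for (i in seq_along(statements)) {
    s <- statements[[i]]
    src[i] <- add_node(s$subject)
    tgt[i] <- add_node(s$object)
    sgn[i] <- if (s$relation %in% c("increases", "directlyIncreases")) 1L else -1L
    dir[i] <- s$relation %in% c("directlyIncreases", "directlyDecreases")
    act[i] <- s$subject$kind == "activity-wrapped" ||
      s$object$kind == "activity-wrapped"
  }
  key <- paste(src, tgt, sgn, sep = "\r")
  agg <- data.frame(source = src, target = tgt, sign = sgn, direct = dir,
                    via_activity = act, stringsAsFactors = FALSE)
  ev <- as.vector(table(key)[unique(key)])
  first <- !duplicated(key)
  merged <- agg[first, , drop = FALSE]
  merged$direct <- as.logical(tapply(dir, key, any)[unique(key)])
  merged$via_activity <- as.logical(tapply(act, key, any)[unique(key)])
  merged$evidence_count <- as.integer(ev)
  merged$weight <- if (weight_by_evidence) as.numeric(ev) else 1
  ids <- ls(node_tab)
  nodes <- do.call(rbind, lapply(ids, function(id)
    as.data.frame(as.list(node_tab[[id]]), stringsAsFactors = FALSE)))
  causal_network(nodes = nodes[order(nodes$id), , drop = FALSE],
                 edges = merged[order(merged$source, merged$target, merged$sign),
                                c("source", "target", "sign", "direct",
                                  "weight", "evidence_count", "via_activity")])
}

# causal_network -> igraph (directed); used for reachability and components
.as_igraph <- function(network) {
  igraph::graph_from_data_frame(
    d = network$edges[, c("source", "target"), drop = FALSE],
    directed = TRUE,
    vertices = network$nodes[, "id", drop = FALSE])
}

#' Test two networks for equality up to ordering
#'
#' @param a,b \code{"causal_network"} objects.
#' @return \code{TRUE} or \code{FALSE}.
#' @export
network_equal <- function(a, b) {
  norm <- function(n) {
    nd <- n$nodes[order(n$nodes$id),
                  c("id", "kind", "namespace", "name"), drop = FALSE]
    ed <- n$edges[order(n$edges$source, n$edges$target, n$edges$sign),
                  c("source", "target", "sign", "direct", "weight",
                    "evidence_count", "via_activity"), drop = FALSE]
    rownames(nd) <- NULL; rownames(ed) <- NULL
    list(nd, ed)
  }
  isTRUE(all.equal(norm(a), norm(b), check.attributes = FALSE))
}
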