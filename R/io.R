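#' Read a causal network from a file
#'
#' Supported formats: \code{"bel"} (restricted BEL script, read-only),
#' \code{"node-link-json"} (nodes with id/kind/namespace/name, links with
#' source/target/sign/direct/weight/evidence_count), and \code{"edge-tsv"}
#' (columns source, relation, target, optionally weight and evidence_count).
#' For edge tables the node kinds are re-derived by parsing canonical BEL
#' term ids where possible, falling back to \code{kind = "other"}.
#'
#' @param path Input file.
#' @param format One of \code{"bel"}, \code{"node-link-json"},
#'   \code{"edge-tsv"}.
#' @return A \code{"causal_network"}.
#' @export
read_network <- function(path, format = c("bel", "node-link-json", "edge-tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
    "bel" = compile_network(parse_script(readLines(path, warn = FALSE))),
    "node-link-json" = .read_node_link(path),
    "edge-tsv" = .read_edge_tsv(path))
}

.SIGN_RELATION <- function(sign, direct) {
  ifelse(direct,
         ifelse(sign > 0, "directlyIncreases", "directlyDecreases"),
         ifelse(sign > 0, "increases", "decreases"))
}

.relation_sign <- function(rel) {
  ok <- rel %in% c("increases", "decreases", "directlyIncreases",
                   "directlyDecreases")
  if (!all(ok))
    stop("unknown relation(s) in edge table: ",
         paste(unique(rel[!ok]), collapse = ", "))
  ifelse(rel %in% c("increases", "directlyIncreases"), 1L, -1L)
}

# parse a canonical term id back to (kind, namespace, name); kind=other when
# the id is not a canonical BEL term
.node_fields_from_id <- function(ids) {
  out <- data.frame(id = ids, kind = "other", namespace = "",
                    name = ids, stringsAsFactors = FALSE)
  for (i in seq_along(ids)) {
    e <- tryCatch(.parse_term(.new_cursor(ids[i], 0L)), error = function(e) NULL)
    if (!is.null(e) && identical(entity_id(e), ids[i])) {
      b <- entity_base(e)
      out$kind[i] <- b$kind; out$namespace[i] <- b$namespace
      out$name[i] <- b$identifier
    }
  }
  out
}

.read_node_link <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (is.null(j$nodes)) stop("node-link file lacks a 'nodes' array: ", path)
  nodes <- as.data.frame(j$nodes, stringsAsFactors = FALSE)
  if (!nrow(nodes)) nodes <- empty_nodes()
  if (is.null(nodes$id)) stop("node records must carry 'id'")
  for (f in c("kind", "namespace", "name"))
    if (is.null(nodes[[f]]))
      nodes[[f]] <- if (f == "kind") "other" else ""
  links <- if (!is.null(j$links) && length(j$links)) {
    as.data.frame(j$links, stringsAsFactors = FALSE)
  } else empty_edges()
  if (nrow(links)) {
    for (f in c("source", "target"))
      if (is.null(links[[f]])) stop("link records must carry '", f, "'")
    bad <- setdiff(unique(c(links$source, links$target)), nodes$id)
    if (length(bad))
      stop("link references undeclared node id(s): ",
           paste(bad, collapse = ", "))
    if (is.null(links$sign)) links$sign <- 1L
    links$sign <- as.integer(links$sign)
  }
  causal_network(nodes = nodes[, c("id", "kind", "namespace", "name")],
                 edges = links,
                 provenance = if (!is.null(j$provenance))
                   as.character(j$provenance) else character(0))
}

.read_edge_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE, quote = "")
  need <- c("source", "relation", "target")
  if (!all(need %in% names(tab)))
    stop("edge-tsv must have header columns: ", paste(need, collapse = ", "),
         " (got: ", paste(names(tab), collapse = ", "), ")")
  if (!nrow(tab)) return(causal_network())
  sign <- .relation_sign(tab$relation)
  direct <- tab$relation %in% c("directlyIncreases", "directlyDecreases")
  edges <- data.frame(source = tab$source, target = tab$target, sign = sign,
                      direct = direct,
                      weight = if (!is.null(tab$weight)) tab$weight else 1,
                      evidence_count = if (!is.null(tab$evidence_count))
                        as.integer(tab$evidence_count) else 1L,
                      via_activity = FALSE, stringsAsFactors = FALSE)
  nodes <- .node_fields_from_id(sort(unique(c(edges$source, edges$target))))
  causal_network(nodes = nodes, edges = edges)
}

#' Write a causal network to a file
#'
#' Output is deterministic (nodes and edges sorted) so identical networks
#' produce byte-identical files. \code{read_network(write_network(n))}
#' preserves nodes, edges, signs, weights and evidence counts for both
#' formats.
#'
#' @param network A \code{"causal_network"}.
#' @param path Output file.
#' @param format \code{"node-link-json"} or \code{"edge-tsv"}.
#' @return \code{path}, invisibly.
#' @export
write_network <- function(network, path,
                          format = c("node-link-json", "edge-tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(network, "causal_network"))
  nodes <- network$nodes[order(network$nodes$id), , drop = FALSE]
  edges <- network$edges[order(network$edges$source, network$edges$target,
                               network$edges$sign), , drop = FALSE]
  rownames(nodes) <- NULL; rownames(edges) <- NULL
  if (format == "node-link-json") {
    obj <- list(
      directed = TRUE,
      provenance = network$provenance,
      nodes = nodes[, c("id", "kind", "namespace", "name"), drop = FALSE],
      links = edges[, c("source", "target", "sign", "direct", "weight",
                        "evidence_count", "via_activity"), drop = FALSE])
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    out <- data.frame(source = edges$source,
                      relation = .SIGN_RELATION(edges$sign, edges$direct),
                      target = edges$target,
                      weight = edges$weight,
                      evidence_count = edges$evidence_count,
                      stringsAsFactors = FALSE)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
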