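#' @title Restricted BEL 1.0 statement parsing
#' @description Parsers for the entity-level subset of the Biological
#'   Expression Language used by causal network models: terms
#'   \code{p(NS:ID)}, \code{r(NS:ID)}, \code{a(NS:ID)}, \code{bp(NS:ID)},
#'   \code{complex(NS:ID)} and \code{act(term)}, joined by one of the four
#'   causal relations (\code{increases}, \code{decreases},
#'   \code{directlyIncreases}, \code{directlyDecreases}; the arrow forms
#'   \code{->}, \code{-|}, \code{=>}, \code{=|} are accepted as synonyms).
#'   Any other relation token yields a statement with
#'   \code{relation = "unsupported"}, which never produces an edge. All other
#'   BEL constructs (\code{tloc}, \code{deg}, \code{pep}, modification
#'   arguments, list-form complexes) are rejected with a parse error.
#' @name bel-parsing
NULL

.BEL_FUNS <- c(p = "protein", r = "rna", a = "abundance",
               bp = "bioprocess", complex = "complex")

.BEL_RELATIONS <- c(
  "increases" = "increases", "->" = "increases",
  "decreases" = "decreases", "-|" = "decreases",
  "directlyIncreases" = "directlyIncreases", "=>" = "directlyIncreases",
  "directlyDecreases" = "directlyDecreases", "=|" = "directlyDecreases")

#' Construct an entity reference
#'
#' @param kind One of \code{"protein"}, \code{"rna"}, \code{"abundance"},
#'   \code{"bioprocess"}, \code{"complex"}, \code{"activity-wrapped"},
#'   \code{"other"}.
#' @param namespace Short namespace string (e.g. \code{"HGNC"}, \code{"GO"}).
#' @param identifier Non-empty identifier; may contain spaces.
#' @param wrapped Inner entity for \code{kind = "activity-wrapped"}.
#' @return An object of class \code{"entity_ref"}.
#' @export
entity_ref <- function(kind, namespace = "", identifier = "", wrapped = NULL) {
  kinds <- c("protein", "rna", "abundance", "bioprocess", "complex",
             "activity-wrapped", "other")
  kind <- match.arg(kind, kinds)
  if (kind == "activity-wrapped") {
    stopifnot(inherits(wrapped, "entity_ref"))
    if (identical(wrapped$kind, "activity-wrapped"))
      stop("activity terms cannot be nested")
  } else {
    if (!nzchar(identifier)) stop("identifier must be non-empty")
    if (!nzchar(namespace) && kind != "complex")
      stop("namespace must be non-empty for kind '", kind, "'")
  }
  structure(list(kind = kind, namespace = namespace,
                 identifier = identifier, wrapped = wrapped),
            class = "entity_ref")
}

# canonical serialization; activity wrappers collapse onto the inner entity
# so that act(p(X)) and p(X) share one backbone node
entity_id <- function(e) {
  if (e$kind == "activity-wrapped") return(entity_id(e$wrapped))
  fn <- names(.BEL_FUNS)[match(e$kind, .BEL_FUNS)]
  if (is.na(fn)) fn <- "x"
  id <- e$identifier
  if (grepl("[^A-Za-z0-9_.-]", id)) id <- paste0('"', id, '"')
  paste0(fn, "(", e$namespace, ":", id, ")")
}

# the entity a node id stands for, past any activity wrapper
entity_base <- function(e) if (e$kind == "activity-wrapped") e$wrapped else e

#' @export
print.entity_ref <- function(x, ...) {
  cat("<entity_ref> ", entity_id(x),
      if (x$kind == "activity-wrapped") " (activity)" else "", "\n", sep = "")
  invisible(x)
}

parse_error <- function(msg, line = NA_integer_, col = NA_integer_) {
  stop(structure(class = c("cbnpa_parse_error", "error", "condition"),
                 list(message = sprintf("parse error at line %s, column %s: %s",
                                        line, col, msg),
                      call = NULL, line = line, col = col)))
}

# single-pass cursor over one statement line
.new_cursor <- function(text, line) {
  env <- new.env(parent = emptyenv())
  env$text <- text; env$pos <- 1L; env$line <- line
  env
}
.peek <- function(cur) {
  if (cur$pos > nchar(cur$text)) return("")
  substr(cur$text, cur$pos, cur$pos)
}
.skip_ws <- function(cur) {
  while (.peek(cur) %in% c(" ", "\t")) cur$pos <- cur$pos + 1L
}
.expect <- function(cur, ch) {
  if (.peek(cur) != ch)
    parse_error(sprintf("expected '%s', found '%s'", ch,
                        if (nzchar(.peek(cur))) .peek(cur) else "end of line"),
                cur$line, cur$pos)
  cur$pos <- cur$pos + 1L
}
.read_token <- function(cur) {
  rest <- substring(cur$text, cur$pos)
  m <- regmatches(rest, regexpr("^[A-Za-z0-9_.-]+", rest))
  if (length(m) == 0 || !nzchar(m))
    parse_error("expected an identifier", cur$line, cur$pos)
  cur$pos <- cur$pos + nchar(m)
  m
}
.read_identifier <- function(cur) {
  if (.peek(cur) == '"') {
    start <- cur$pos
    cur$pos <- cur$pos + 1L
    out <- character(0)
    repeat {
      ch <- .peek(cur)
      if (ch == "") parse_error("unterminated quoted identifier",
                                cur$line, start)
      if (ch == '"') { cur$pos <- cur$pos + 1L; break }
      if (ch == "\\") cur$pos <- cur$pos + 1L
      out <- c(out, .peek(cur))
      cur$pos <- cur$pos + 1L
    }
    id <- paste(out, collapse = "")
    if (!nzchar(id)) parse_error("empty quoted identifier", cur$line, start)
    id
  } else .read_token(cur)
}

.parse_term <- function(cur, depth = 0L) {
  .skip_ws(cur)
  start <- cur$pos
  fn <- .read_token(cur)
  .skip_ws(cur)
  .expect(cur, "(")
  if (fn == "act") {
    if (depth > 0L)
      parse_error("activity terms cannot be nested", cur$line, start)
    inner <- .parse_term(cur, depth + 1L)
    .skip_ws(cur)
    .expect(cur, ")")
    return(entity_ref("activity-wrapped", wrapped = inner))
  }
  if (!fn %in% names(.BEL_FUNS))
    parse_error(sprintf(
      paste0("unknown term function '%s' (supported: ",
             "p, r, a, bp, complex, act)"), fn), cur$line, start)
  .skip_ws(cur)
  ns <- .read_token(cur)
  .skip_ws(cur)
  .expect(cur, ":")
  .skip_ws(cur)
  id <- .read_identifier(cur)
  .skip_ws(cur)
  .expect(cur, ")")
  entity_ref(.BEL_FUNS[[fn]], namespace = ns, identifier = id)
}

#' Parse one BEL statement
#'
#' Parses a single-line subject--relation--object statement in the restricted
#' grammar. Unknown relation tokens give \code{relation = "unsupported"} with
#' a warning (such statements are skipped at compile time); malformed terms
#' raise a parse error carrying line and column.
#'
#' @param text One statement line.
#' @param line Line number recorded on the statement (for scripts).
#' @param annotations Named character vector of annotations in force.
#' @return An object of class \code{"bel_statement"} with fields
#'   \code{subject}, \code{relation}, \code{object}, \code{annotations},
#'   \code{evidence}, \code{source_line}.
#' @examples
#' parse_statement('p(HGNC:FOXJ1) increases bp(GO:"cilium assembly")')
#' @export
parse_statement <- function(text, line = 1L, annotations = character(0)) {
  cur <- .new_cursor(text, line)
  subject <- .parse_term(cur)
  .skip_ws(cur)
  rel_start <- cur$pos
  rest <- substring(cur$text, cur$pos)
  m <- regmatches(rest, regexpr("^[A-Za-z]+|^[-=][>|]", rest))
  if (length(m) == 0 || !nzchar(m))
    parse_error("expected a relation token", cur$line, rel_start)
  cur$pos <- cur$pos + nchar(m)
  relation <- if (m %in% names(.BEL_RELATIONS)) .BEL_RELATIONS[[m]] else {
    warning(sprintf("line %d: relation '%s' is not causal; statement kept as unsupported",
                    line, m), call. = FALSE)
    "unsupported"
  }
  object <- .parse_term(cur)
  .skip_ws(cur)
  if (nzchar(.peek(cur)))
    parse_error("trailing text after statement", cur$line, cur$pos)
  structure(list(subject = subject, relation = relation, object = object,
                 annotations = annotations, evidence = NULL,
                 source_line = as.integer(line)),
            class = "bel_statement")
}

#' @export
print.bel_statement <- function(x, ...) {
  cat("<bel_statement> ", entity_id(x$subject), " ", x$relation, " ",
      entity_id(x$object), "\n", sep = "")
  if (length(x$annotations))
    cat("  annotations: ",
        paste(names(x$annotations), unname(x$annotations),
              sep = "=", collapse = "; "), "\n", sep = "")
  invisible(x)
}

#' Parse a BEL script
#'
#' Processes a script in the BEL script dialect: \code{#} comment lines,
#' blank lines, \code{SET Annotation = "value"} / \code{UNSET Annotation}
#' directives (an open annotation set, preserved verbatim), and statements.
#' \code{DEFINE} header lines are ignored. Each returned statement carries the
#' annotation mapping in force at its line, and its line number.
#'
#' @param lines Character vector of script lines (or a single string with
#'   embedded newlines).
#' @return List of \code{"bel_statement"} objects.
#' @export
parse_script <- function(lines) {
  if (length(lines) == 1L && grepl("\n", lines))
    lines <- strsplit(lines, "\n", fixed = TRUE)[[1]]
  anns <- character(0)
  out <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (!nzchar(ln) || startsWith(ln, "#")) next
    if (grepl("^DEFINE\\b", ln)) next
    if (grepl("^SET\\b", ln)) {
      m <- regmatches(ln, regexec('^SET\\s+([A-Za-z0-9_]+)\\s*=\\s*"?([^"]*)"?\\s*$', ln))[[1]]
      if (length(m) < 3 || !nzchar(trimws(m[3])))
        parse_error("SET requires 'SET Key = \"value\"'", i, 1L)
      anns[[m[2]]] <- trimws(m[3])
      next
    }
    if (grepl("^UNSET\\b", ln)) {
      key <- trimws(sub("^UNSET\\s+", "", ln))
      if (!key %in% names(anns))
        warning(sprintf("line %d: UNSET of annotation '%s' which is not set",
                        i, key), call. = FALSE)
      anns <- anns[setdiff(names(anns), key)]
      next
    }
    out[[length(out) + 1L]] <- parse_statement(ln, line = i, annotations = anns)
  }
  out
}
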