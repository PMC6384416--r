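test_that("statements in the restricted grammar parse to their structure", {
  s <- parse_statement('p(HGNC:FOXJ1) increases bp(GO:"cilium assembly")')
  expect_identical(s$subject$kind, "protein")
  expect_identical(s$subject$namespace, "HGNC")
  expect_identical(s$subject$identifier, "FOXJ1")
  expect_identical(s$relation, "increases")
  expect_identical(s$object$kind, "bioprocess")
  expect_identical(s$object$identifier, "cilium assembly")

  s2 <- parse_statement("act(p(HGNC:EGFR)) directlyIncreases r(HGNC:MUC5AC)")
  expect_identical(s2$subject$kind, "activity-wrapped")
  expect_identical(s2$subject$wrapped$identifier, "EGFR")
  expect_identical(s2$relation, "directlyIncreases")
  expect_identical(s2$object$kind, "rna")

  # activity wrappers collapse onto the inner entity for node identity
  expect_identical(entity_id(s2$subject), "p(HGNC:EGFR)")

  # arrow synonyms
  expect_identical(parse_statement("p(HGNC:A) -> p(HGNC:B)")$relation,
                   "increases")
  expect_identical(parse_statement("p(HGNC:A) =| p(HGNC:B)")$relation,
                   "directlyDecreases")
})

test_that("non-causal relations are kept as unsupported with a warning", {
  expect_warning(
    s <- parse_statement("p(HGNC:FOXA2) association r(HGNC:MUC5AC)"),
    "not causal")
  expect_identical(s$relation, "unsupported")
})

test_that("malformed terms raise parse errors carrying line and column", {
  err <- tryCatch(parse_statement("tloc(HGNC:A) increases p(HGNC:B)", line = 7),
                  cbnpa_parse_error = identity)
  expect_s3_class(err, "cbnpa_parse_error")
  expect_match(conditionMessage(err), "line 7")
  expect_match(conditionMessage(err), "unknown term function 'tloc'")

  expect_error(parse_statement("p(HGNC) increases p(HGNC:B)"),
               class = "cbnpa_parse_error")
  expect_error(parse_statement('p(HGNC:"unterminated increases p(HGNC:B)'),
               class = "cbnpa_parse_error")
  expect_error(parse_statement("act(act(p(HGNC:A))) increases p(HGNC:B)"),
               class = "cbnpa_parse_error")
  expect_error(parse_statement("p(HGNC:A) increases p(HGNC:B) trailing"),
               class = "cbnpa_parse_error")
})

test_that("scripts carry SET/UNSET annotation state onto statements", {
  lines <- c('SET Species = "human"',
             "p(HGNC:A) increases p(HGNC:B)",
             "UNSET Species",
             "p(HGNC:B) increases p(HGNC:C)")
  st <- parse_script(lines)
  expect_length(st, 2)
  expect_identical(st[[1]]$annotations, c(Species = "human"))
  expect_length(st[[2]]$annotations, 0)
  expect_identical(st[[1]]$source_line, 2L)

  expect_identical(parse_script(character(0)), list())
  expect_error(parse_script('SET Species = '), class = "cbnpa_parse_error")
  expect_warning(parse_script("UNSET Tissue"), "not set")

  mixed <- suppressWarnings(parse_script(c(
    "# a comment",
    "p(HGNC:A) increases p(HGNC:B)",
    "p(HGNC:A) decreases p(HGNC:C)",
    "p(HGNC:C) association p(HGNC:B)",
    "p(HGNC:B) directlyIncreases r(HGNC:G1)")))
  expect_length(mixed, 4)
  expect_identical(sum(vapply(mixed, function(s) s$relation == "unsupported",
                              logical(1))), 1L)
})

test_that("parsing round-trips statements assembled from grammar productions", {
  set.seed(41)
  kinds <- c("protein", "rna", "abundance", "bioprocess", "complex")
  rels <- c("increases", "decreases", "directlyIncreases", "directlyDecreases")
  rand_entity <- function() {
    e <- entity_ref(sample(kinds, 1), namespace = sample(c("HGNC", "GO", "CHEBI"), 1),
                    identifier = paste(sample(c(LETTERS, "x", "9", " "),
                                              sample(3:8, 1), replace = TRUE),
                                       collapse = ""))
    if (stats::runif(1) < 0.3 && e$kind != "bioprocess")
      e <- entity_ref("activity-wrapped", wrapped = e)
    e
  }
  term_text <- function(e) {
    if (e$kind == "activity-wrapped") paste0("act(", term_text(e$wrapped), ")")
    else entity_id(e)
  }
  for (i in 1:50) {
    sub <- rand_entity(); obj <- rand_entity(); rel <- sample(rels, 1)
    txt <- paste(term_text(sub), rel, term_text(obj))
    s <- parse_statement(txt)
    expect_identical(s$relation, rel)
    expect_identical(entity_id(s$subject), entity_id(sub))
    expect_identical(entity_id(s$object), entity_id(obj))
    expect_identical(s$subject$kind, sub$kind)
    expect_identical(s$object$kind, obj$kind)
  }
})

test_that("compilation merges same-sign duplicates and keeps contradictions", {
  st <- parse_script(c("p(HGNC:A) increases p(HGNC:B)",
                       "p(HGNC:A) increases p(HGNC:B)"))
  net <- compile_network(st)
  expect_identical(nrow(net$edges), 1L)
  expect_identical(net$edges$evidence_count, 2L)
  expect_identical(net$edges$weight, 1)

  contra <- compile_network(parse_script(c("p(HGNC:A) increases p(HGNC:B)",
                                           "p(HGNC:A) decreases p(HGNC:B)")))
  expect_identical(nrow(contra$edges), 2L)
  expect_setequal(contra$edges$sign, c(1L, -1L))

  expect_identical(nrow(compile_network(list())$nodes), 0L)
  expect_identical(nrow(compile_network(list())$edges), 0L)
})

test_that("compile is idempotent on the statements a network induces", {
  net <- compile_network(suppressWarnings(parse_script(c(
    "p(HGNC:A) increases p(HGNC:B)",
    "p(HGNC:A) increases p(HGNC:B)",
    "p(HGNC:A) decreases p(HGNC:B)",
    "act(p(HGNC:B)) directlyIncreases r(HGNC:G1)",
    'bp(GO:"mucus secretion") decreases p(HGNC:A)'))))
  induce <- function(net) {
    rows <- rep(seq_len(nrow(net$edges)), net$edges$evidence_count)
    ed <- net$edges[rows, ]
    rel <- ifelse(ed$direct,
                  ifelse(ed$sign > 0, "directlyIncreases", "directlyDecreases"),
                  ifelse(ed$sign > 0, "increases", "decreases"))
    paste(ed$source, rel, ed$target)
  }
  net2 <- compile_network(parse_script(induce(net)))
  expect_identical(net2$nodes[order(net2$nodes$id), c("id", "kind")],
                   net$nodes[order(net$nodes$id), c("id", "kind")])
  key <- function(n) {
    e <- n$edges[order(n$edges$source, n$edges$target, n$edges$sign), ]
    e[, c("source", "target", "sign", "weight", "evidence_count")]
  }
  expect_equal(key(net2), key(net), ignore_attr = TRUE)
})
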