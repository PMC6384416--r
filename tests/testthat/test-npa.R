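test_that("expression matching is case-insensitive with coverage accounting", {
  m <- model_e1()
  expect_warning(res <- match_expression(m, expression_table("G1", 2, 1)),
                 "50%")
  expect_equal(res$coverage, 0.5)

  res2 <- match_expression(m, expression_table(c("g1", "g2"), c(2, -2), c(1, 1)))
  expect_equal(res2$coverage, 1)
  expect_setequal(res2$table$gene, c("G1", "G2"))

  expect_error(match_expression(m, expression_table("OTHER", 1, 1)),
               "no measurable overlap")
})

test_that("the Laplacian system matches its defining entries on E1", {
  m <- model_e1()
  matched <- match_expression(m, expr_e1())$table
  sys <- assemble_system(m, matched, ridge = 0)
  expect_equal(unname(sys$L_bb), rbind(c(2, -1), c(-1, 2)))
  expect_equal(unname(sys$L_bg), rbind(c(-1, 0), c(0, 1)))
  expect_identical(sys$gene_index, c("G1", "G2"))

  # single node, one downstream gene, no backbone edges
  lone <- split_layers(compile_network(parse_script(
    "p(HGNC:A) increases r(HGNC:G1)")))
  s1 <- assemble_system(lone, match_expression(lone,
                        expression_table("G1", 1, 0))$table, ridge = 0)
  expect_equal(unname(s1$L_bb), rbind(1))

  # unmatched gene's column is absent
  m2 <- model_e1()
  expect_warning(part <- match_expression(m2, expression_table("G1", 2, 1)))
  s2 <- assemble_system(m2, part$table)
  expect_identical(s2$gene_index, "G1")
  expect_identical(ncol(s2$L_bg), 1L)
})

test_that("components without matched genes are dropped before assembly", {
  e1 <- model_e1()
  bb <- e1$backbone
  bb$nodes <- rbind(bb$nodes,
                    data.frame(id = "p(HGNC:LONE)", kind = "protein",
                               namespace = "HGNC", name = "LONE"))
  m <- two_layer_model(causal_network(bb$nodes, bb$edges), e1$downstream)
  matched <- match_expression(m, expr_e1())$table
  expect_warning(sys <- assemble_system(m, matched), "dropped")
  expect_setequal(sys$backbone_index, c("p(HGNC:X)", "p(HGNC:Y)"))
})

test_that("closed-form inference solves the quadratic objective (E1 oracle)", {
  m <- model_e1()
  matched <- match_expression(m, expr_e1())$table
  sys <- assemble_system(m, matched)
  beta <- matched$beta; names(beta) <- matched$gene
  f <- infer_backbone(sys, beta)
  expect_equal(unname(f), c(2, 2), tolerance = 1e-8)
  expect_equal(unname(oracle_infer(m, matched)), c(2, 2), tolerance = 1e-6)

  # linearity
  expect_equal(unname(infer_backbone(sys, beta * 0)), c(0, 0))
  expect_equal(unname(infer_backbone(sys, beta * 3)), unname(f) * 3)
})

test_that("inference agrees with direct numerical minimization on random models", {
  for (seed in 1:20) {
    case <- random_small_case(seed)
    sc <- suppressWarnings(cbnpa:::.pipeline_score(case$model, case$expr))
    f_oracle <- oracle_infer(case$model, case$expr)
    rel <- sqrt(sum((sc$f - f_oracle[names(sc$f)])^2)) /
      max(sqrt(sum(f_oracle^2)), 1e-12)
    expect_lt(rel, 1e-8)
  }
})

test_that("scores, contributions and directions follow the quadratic form", {
  m <- model_e1()
  fit <- npa(m, expr_e1(), permutations = character(0))
  expect_equal(fit$score, 4, tolerance = 1e-9)
  expect_equal(unname(fit$contributions), c(2, 2), tolerance = 1e-9)
  expect_equal(sum(fit$contributions), fit$score, tolerance = 1e-9)
  expect_identical(unname(fit$directions), c(1, 1))

  # zero data: zero everything
  fit0 <- suppressWarnings(
    npa(m, expression_table(c("G1", "G2"), c(0, 0), c(0, 0)),
        permutations = character(0)))
  expect_equal(fit0$score, 0)
  expect_identical(unname(fit0$directions), c(0, 0))

  # gauge-flipped model: f flips on the flipped node, score unchanged
  fit2 <- npa(model_e2(), expr_e1(), permutations = character(0))
  expect_equal(unname(coef(fit2)), c(2, -2), tolerance = 1e-8)
  expect_equal(fit2$score, 4, tolerance = 1e-9)
})

test_that("gauge transformations flip f on the flipped set, score invariant", {
  for (seed in 1:8) {
    case <- random_small_case(seed)
    sc <- suppressWarnings(cbnpa:::.pipeline_score(case$model, case$expr))
    set.seed(seed)
    ids <- case$model$backbone$nodes$id
    S <- sample(ids, sample(seq_along(ids), 1))
    flipped <- gauge_flip(case$model, S)
    sc2 <- suppressWarnings(cbnpa:::.pipeline_score(flipped, case$expr))
    expected <- ifelse(names(sc$f) %in% S, -sc$f, sc$f)
    expect_equal(unname(sc2$f), unname(expected), tolerance = 1e-8)
    expect_equal(sc2$score, sc$score, tolerance = 1e-10)
  }
})

test_that("the score is homogeneous of degree two in the data", {
  case <- random_small_case(3)
  base <- suppressWarnings(cbnpa:::.pipeline_score(case$model, case$expr))
  for (c_mult in c(-2, 0.5, 3)) {
    scaled <- case$expr
    scaled$beta <- scaled$beta * c_mult
    sc <- suppressWarnings(cbnpa:::.pipeline_score(case$model, scaled))
    expect_equal(sc$score, c_mult^2 * base$score, tolerance = 1e-9)
  }
})

test_that("score is invariant to isolated components dropped at assembly", {
  case <- random_small_case(5)
  base <- suppressWarnings(cbnpa:::.pipeline_score(case$model, case$expr))
  aug <- case$model
  bb <- aug$backbone
  bb$nodes <- rbind(bb$nodes,
                    data.frame(id = c("p(SYN:ZZ1)", "p(SYN:ZZ2)"),
                               kind = "protein", namespace = "SYN",
                               name = c("ZZ1", "ZZ2")))
  bb$edges <- rbind(bb$edges,
                    data.frame(source = "p(SYN:ZZ1)", target = "p(SYN:ZZ2)",
                               sign = 1L, direct = FALSE, weight = 1,
                               evidence_count = 1L, via_activity = FALSE))
  aug$backbone <- causal_network(bb$nodes, bb$edges)
  sc <- suppressWarnings(cbnpa:::.pipeline_score(aug, case$expr))
  expect_equal(sc$score, base$score, tolerance = 1e-10)
})

test_that("backbone-laplacian mode conserves contributions and flags negatives", {
  case <- random_small_case(7)
  m <- suppressWarnings(match_expression(case$model, case$expr))
  sys <- assemble_system(case$model, m$table)
  beta <- m$table$beta; names(beta) <- m$table$gene
  f <- infer_backbone(sys, beta)
  sc <- npa_score(f, sys, "backbone-laplacian")
  expect_equal(sum(sc$contributions), sc$score, tolerance = 1e-9)
  expect_identical(sc$negative_contributions, any(sc$contributions < 0))
  # quadratic form agrees with explicit f' L f / n
  expect_equal(sc$score,
               as.numeric(t(f) %*% sys$L_backbone %*% f) / length(f),
               tolerance = 1e-12)
})

test_that("delta-method intervals behave like the formula says", {
  m <- model_e1()
  matched <- match_expression(m, expr_e1())$table
  sys <- assemble_system(m, matched)
  beta <- matched$beta; names(beta) <- matched$gene

  ci0 <- confidence_interval(sys, beta, c(G1 = 0, G2 = 0))
  expect_equal(ci0$ci_low, ci0$score)
  expect_equal(ci0$ci_high, ci0$score)

  ci1 <- confidence_interval(sys, beta, c(G1 = 1, G2 = 1))
  ci2 <- confidence_interval(sys, beta, c(G1 = 2, G2 = 2))
  expect_equal(ci2$ci_high - ci2$ci_low,
               sqrt(2) * (ci1$ci_high - ci1$ci_low), tolerance = 1e-10)
  expect_true(ci1$ci_low <= ci1$score && ci1$score <= ci1$ci_high)
  expect_error(confidence_interval(sys, beta, c(G1 = -1, G2 = 1)),
               "non-negative")
})

test_that("the delta-method gradient matches finite differences of the pipeline", {
  for (seed in c(2, 9)) {
    case <- random_small_case(seed)
    m <- suppressWarnings(match_expression(case$model, case$expr))
    sys <- assemble_system(case$model, m$table)
    beta <- m$table$beta; names(beta) <- m$table$gene
    vars <- m$table$variance
    ci <- confidence_interval(sys, beta, vars)
    h <- 1e-6
    fd <- vapply(seq_along(sys$gene_index), function(g) {
      bp <- bm <- beta
      bp[sys$gene_index[g]] <- bp[sys$gene_index[g]] + h
      bm[sys$gene_index[g]] <- bm[sys$gene_index[g]] - h
      (npa_score(infer_backbone(sys, bp), sys)$score -
         npa_score(infer_backbone(sys, bm), sys)$score) / (2 * h)
    }, numeric(1))
    expect_equal(ci$gradient, fd, tolerance = 1e-6)
  }
})

test_that("Monte-Carlo intervals are reproducible and bracket the score for small noise", {
  m <- model_e1()
  matched <- match_expression(m, expr_e1(variance = 0.01))$table
  sys <- assemble_system(m, matched)
  beta <- matched$beta; names(beta) <- matched$gene
  mc1 <- mc_confidence_interval(sys, beta, matched$variance, n_draws = 200,
                                seed = 11)
  mc2 <- mc_confidence_interval(sys, beta, matched$variance, n_draws = 200,
                                seed = 11)
  expect_identical(mc1$draws, mc2$draws)
  expect_true(mc1$ci_low <= mc1$score && mc1$score <= mc1$ci_high)
})

test_that("leading sets are the shortest prefixes reaching the threshold", {
  contrib <- c(a = 0.6, b = 0.3, c = 0.1)
  lead <- leading_nodes(contrib)
  expect_identical(attr(lead, "leading"), c("a", "b"))
  expect_equal(lead$cum_pct[2], 90)

  one <- leading_nodes(c(solo = 5))
  expect_identical(attr(one, "leading"), "solo")

  half <- leading_nodes(c(a = 0.5, b = 0.5))
  expect_identical(attr(half, "leading"), c("a", "b"))

  expect_warning(z <- leading_nodes(c(a = 0, b = 0)), "zero")
  expect_identical(nrow(z), 0L)

  # threshold 1 takes everything; tiny threshold takes one node
  expect_length(attr(leading_nodes(contrib, threshold = 1), "leading"), 3)
  expect_length(attr(leading_nodes(contrib, threshold = 0.1), "leading"), 1)
})

test_that("leading subnetworks are induced subgraphs with annotations", {
  m <- model_e1()
  fit <- npa(m, expr_e1(), permutations = character(0))
  all_nodes <- m$backbone$nodes$id
  sub_all <- leading_subnetwork(m, all_nodes, f = fit$f,
                                contributions = fit$contributions)
  expect_setequal(sub_all$nodes$id, all_nodes)
  expect_identical(nrow(sub_all$edges), nrow(m$backbone$edges))
  expect_equal(sub_all$nodes$npa_value,
               unname(fit$f[sub_all$nodes$id]), tolerance = 1e-9)

  sub_x <- leading_subnetwork(m, "p(HGNC:X)")
  expect_identical(nrow(sub_x$nodes), 1L)
  expect_identical(nrow(sub_x$edges), 0L)

  expect_error(leading_subnetwork(m, "p(HGNC:NOPE)"), "NOPE")
})
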