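test_that("the fitted object supports the standard modelling methods", {
  # coherent truth + zero noise: the data are exactly network-consistent,
  # so inference reproduces them and residuals vanish
  truth <- generate_model(synth_config(n_backbone = 8, n_edges = 12,
                                       genes_per_node = 3, noise_sd = 0,
                                       p_negative = 0),
                          seed = 14, coherent = TRUE)
  expr <- simulate_expression(truth, seed = 15)
  fit <- npa(truth$model, expr, n_perm = 20, seed = 16)

  expect_s3_class(fit, "npa")
  expect_named(coef(fit), truth$model$backbone$nodes$id, ignore.order = TRUE)
  expect_length(fitted(fit), nrow(truth$model$downstream))
  expect_lt(max(abs(residuals(fit))), 1e-4)
  expect_equal(sum(fit$contributions), fit$score, tolerance = 1e-9)

  pred <- predict(fit)
  expect_identical(nrow(pred), nrow(truth$model$downstream))
  expect_equal(pred$predicted, unname(fitted(fit)))

  refit <- predict(fit, newdata = expr, permutations = character(0))
  expect_s3_class(refit, "npa")
  expect_equal(refit$score, fit$score, tolerance = 1e-12)

  sims <- simulate(fit, nsim = 25, seed = 17)
  expect_length(sims, 25)
  expect_true(all(sims >= 0))

  expect_output(print(fit), "NPA")
  expect_output(print(summary(fit)), "Top contributing nodes")

  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("fits are reproducible given the master seed", {
  case <- random_small_case(18)
  f1 <- npa(case$model, case$expr, n_perm = 30, seed = 77)
  f2 <- npa(case$model, case$expr, n_perm = 30, seed = 77)
  expect_identical(f1$p_O, f2$p_O)
  expect_identical(f1$p_K, f2$p_K)
  expect_identical(f1$null_O$values, f2$null_O$values)
})

test_that("score runs write a complete, re-runnable set of result files", {
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  truth <- generate_model(synth_config(n_backbone = 8, n_edges = 12,
                                       genes_per_node = 3), seed = 19)
  model_path <- file.path(out1, "model_in.json")
  # serialize the full two-layer model as one network (rna nodes re-attached)
  bb <- truth$model$backbone
  down <- truth$model$downstream
  rna_nodes <- data.frame(id = paste0("r(SYN:", down$gene, ")"), kind = "rna",
                          namespace = "SYN", name = down$gene)
  full <- causal_network(rbind(bb$nodes, rna_nodes),
                         rbind(bb$edges,
                               data.frame(source = down$backbone_node,
                                          target = rna_nodes$id,
                                          sign = down$sign, direct = FALSE,
                                          weight = down$weight,
                                          evidence_count = 1L,
                                          via_activity = FALSE)))
  write_network(full, model_path, "node-link-json")
  expr <- simulate_expression(truth, seed = 20)
  expr_path <- file.path(out1, "expr.tsv")
  write_expression(expr, expr_path)

  fit <- run_score(model_path, expr_path, file.path(out1, "res"),
                   n_perm = 20, seed = 5)
  files <- c("npa_result.json", "node_values.tsv", "contributions.tsv",
             "leading_nodes.tsv", "leading_subnetwork.json",
             "score_manifest.json")
  expect_true(all(file.exists(file.path(out1, "res", files))))

  manifest <- jsonlite::fromJSON(file.path(out1, "res", "score_manifest.json"))
  expect_identical(manifest$command, "score")
  expect_identical(manifest$seed, 5L)

  # same inputs and seed: bit-identical stochastic outputs
  run_score(model_path, expr_path, file.path(out2, "res"),
            n_perm = 20, seed = 5)
  for (f in setdiff(files, "score_manifest.json"))
    expect_identical(readLines(file.path(out1, "res", f)),
                     readLines(file.path(out2, "res", f)),
                     info = f)

  res <- jsonlite::fromJSON(file.path(out1, "res", "npa_result.json"))
  expect_equal(res$score, fit$score, tolerance = 1e-12)
  expect_true(res$p_O > 0 && res$p_O <= 1)
})

test_that("describe reports pre- and post-split counts and hubs", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "toy.bel")
  writeLines(c("p(HGNC:X) increases p(HGNC:Y)",
               "p(HGNC:X) increases r(HGNC:G1)",
               "p(HGNC:Y) decreases r(HGNC:G2)"), p)
  out <- NULL
  expect_output(out <- run_describe(p, out_dir = file.path(dir, "d")),
                "backbone nodes: 2")
  expect_identical(out$counts$nodes_total, 4L)
  expect_identical(out$counts$edges_total, 3L)
  expect_identical(out$counts$backbone_edges, 1L)
  expect_identical(out$counts$downstream_edges, 2L)
  expect_true(file.exists(file.path(dir, "d", "degree_table.tsv")))

  empty <- file.path(dir, "empty.tsv")
  writeLines("source\trelation\ttarget", empty)
  out0 <- suppressWarnings(run_describe(empty))
  expect_identical(out0$counts$nodes_total, 0L)
})

test_that("simulate runs write model, data and truth with a manifest", {
  dir <- withr::local_tempdir()
  truth <- run_simulate(synth_config(n_backbone = 6, n_edges = 8,
                                     genes_per_node = 2), dir, seed = 33)
  expect_true(all(file.exists(file.path(
    dir, c("backbone.json", "downstream.tsv", "expression.tsv",
           "truth.tsv", "simulate_manifest.json")))))
  tt <- utils::read.delim(file.path(dir, "truth.tsv"))
  expect_identical(nrow(tt), 6L)
  # truth file matches the in-memory truth
  expect_equal(tt$f_true, unname(truth$f_true), tolerance = 1e-12)

  dir2 <- withr::local_tempdir()
  run_simulate(synth_config(n_backbone = 6, n_edges = 8,
                            genes_per_node = 2), dir2, seed = 33)
  expect_identical(readLines(file.path(dir, "expression.tsv")),
                   readLines(file.path(dir2, "expression.tsv")))
})

test_that("the command-line wrapper runs and signals parse errors", {
  cli <- system.file("cli", "npa.R", package = "cbnpa")
  expect_true(nzchar(cli))
  dir <- withr::local_tempdir()
  p <- file.path(dir, "toy.bel")
  writeLines(c("p(HGNC:X) increases p(HGNC:Y)",
               "p(HGNC:X) increases r(HGNC:G1)"), p)
  rscript <- file.path(R.home("bin"), "Rscript")
  out <- system2(rscript, c(cli, "describe", "--model", shQuote(p)),
                 stdout = TRUE, stderr = TRUE)
  expect_identical(attr(out, "status"), NULL)  # exit 0
  expect_true(any(grepl("backbone nodes", out)))

  bad <- file.path(dir, "bad.bel")
  writeLines("p(HGNC:X increases p(HGNC:Y)", bad)
  r2 <- suppressWarnings(system2(rscript, c(cli, "describe", "--model",
                                            shQuote(bad)),
                                 stdout = TRUE, stderr = TRUE))
  expect_identical(attr(r2, "status"), 3L)
})
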