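# Shared fixtures: toy models built in code, and an independent numerical
# oracle for backbone inference.

# E1: backbone x --(+1)--> y, downstream (x, G1, +1), (y, G2, -1)
model_e1 <- function() {
  net <- compile_network(parse_script(c(
    "p(HGNC:X) increases p(HGNC:Y)",
    "p(HGNC:X) increases r(HGNC:G1)",
    "p(HGNC:Y) decreases r(HGNC:G2)")))
  split_layers(net, name = "E1")
}

# E2: gauge flip of E1 at node y — edge sign -1, downstream (y, G2, +1)
model_e2 <- function() {
  net <- compile_network(parse_script(c(
    "p(HGNC:X) decreases p(HGNC:Y)",
    "p(HGNC:X) increases r(HGNC:G1)",
    "p(HGNC:Y) increases r(HGNC:G2)")))
  split_layers(net, name = "E2")
}

expr_e1 <- function(variance = 1) {
  expression_table(c("G1", "G2"), c(2, -2), rep(variance, 2))
}

# independent oracle: minimize the stated quadratic objective
#   sum_bb w (f_x - sigma f_y)^2 + sum_down w (f_x - s beta_g)^2
#   + ridge sum f^2
# by BFGS with a gradient written directly from the objective terms, never
# touching the closed-form Laplacian assembly
oracle_infer <- function(model, table, ridge = 1e-10) {
  ids <- model$backbone$nodes$id
  n <- length(ids)
  ed <- model$backbone$edges
  ei <- match(ed$source, ids); ej <- match(ed$target, ids)
  es <- ed$sign; ew <- ed$weight
  tg <- toupper(table$gene)
  down <- model$downstream
  dg <- toupper(down$gene)
  keep <- dg %in% tg
  di <- match(down$backbone_node[keep], ids)
  ds <- down$sign[keep]; dw <- down$weight[keep]
  beta <- table$beta[match(dg[keep], tg)]
  obj <- function(f) {
    v <- 0
    for (k in seq_along(ei))
      v <- v + ew[k] * (f[ei[k]] - es[k] * f[ej[k]])^2
    for (k in seq_along(di))
      v <- v + dw[k] * (f[di[k]] - ds[k] * beta[k])^2
    v + ridge * sum(f^2)
  }
  grad <- function(f) {
    g <- 2 * ridge * f
    for (k in seq_along(ei)) {
      d <- 2 * ew[k] * (f[ei[k]] - es[k] * f[ej[k]])
      g[ei[k]] <- g[ei[k]] + d
      g[ej[k]] <- g[ej[k]] - es[k] * d
    }
    for (k in seq_along(di))
      g[di[k]] <- g[di[k]] + 2 * dw[k] * (f[di[k]] - ds[k] * beta[k])
    g
  }
  # conjugate-gradient descent driven purely by the term-wise gradient; the
  # objective is quadratic, so grad(f + d) - grad(f) is linear in d and
  # yields an exact line search. Converges to machine precision in at most
  # n steps per restart.
  f <- rep(0, n)
  g <- grad(f)
  d <- -g
  for (iter in seq_len(3L * n + 10L)) {
    if (sqrt(sum(g^2)) < 1e-13) break
    hd <- grad(f + d) - g
    step <- -sum(g * d) / sum(d * hd)
    f <- f + step * d
    g_new <- grad(f)
    d <- -g_new + (sum(g_new^2) / sum(g^2)) * d
    g <- g_new
  }
  names(f) <- ids
  f
}

# small connected random model with full expression coverage, for
# property-style checks
random_small_case <- function(seed, n_backbone = 6, genes_per_node = 2,
                              noise_sd = 0.3) {
  n_edges <- min(n_backbone + 2, n_backbone * (n_backbone - 1) / 2)
  cfg <- synth_config(n_backbone = n_backbone, n_edges = n_edges,
                      p_negative = 0.4, genes_per_node = genes_per_node,
                      effect_sd = 1, noise_sd = noise_sd)
  truth <- generate_model(cfg, seed = seed)
  expr <- simulate_expression(truth, seed = seed + 10000)
  list(truth = truth, model = truth$model, expr = expr)
}

# gauge (switching) transform: negate all signs incident to node set S
gauge_flip <- function(model, S) {
  ed <- model$backbone$edges
  flip_e <- xor(ed$source %in% S, ed$target %in% S)
  ed$sign[flip_e] <- -ed$sign[flip_e]
  model$backbone$edges <- ed
  dn <- model$downstream
  flip_d <- dn$backbone_node %in% S
  dn$sign[flip_d] <- -dn$sign[flip_d]
  model$downstream <- dn
  model
}
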