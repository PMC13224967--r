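# Joint training loop: determinism, ablation equivalences, gradient flow.

tiny_setup <- function(seed = 3) {
  spec <- synthetic_spec(n_compounds = 50, n_proteins = 40, n_pairs = 500,
                         seed = seed)
  d <- generate_cpi_data(spec)
  sp <- inductive_cluster_split(d$compound_features, d$protein_features,
                                d$interactions, k_split = 5, seed = 2)
  list(data = d, split = sp)
}

tiny_config <- function(...) {
  args <- utils::modifyList(
    list(d_model = 16, embed_dim = 16, token_dim = 16, k1 = 3, k2 = 2,
         max_epochs = 3, patience = 3, lr = 5e-3, seed = 1),
    list(...))
  do.call(train_config, args)
}

test_that("training is deterministic: same seed reproduces the trajectory", {
  s <- tiny_setup()
  f1 <- train_cpi(s$data, s$split, tiny_config())
  f2 <- train_cpi(s$data, s$split, tiny_config())
  expect_identical(f1$history, f2$history)
  expect_identical(f1$params, f2$params)
  expect_identical(score_pairs(f1, s$split$test$pairs),
                   score_pairs(f2, s$split$test$pairs))
})

test_that("lambda = 0 and hkd_on = FALSE produce identical trajectories", {
  s <- tiny_setup()
  f_off <- train_cpi(s$data, s$split, tiny_config(hkd_on = FALSE))
  f_l0 <- train_cpi(s$data, s$split, tiny_config(lambda = 0))
  expect_identical(f_off$history$loss, f_l0$history$loss)
  expect_identical(f_off$history$bce, f_l0$history$bce)
  expect_identical(f_off$history$val_auroc, f_l0$history$val_auroc)
  expect_identical(score_pairs(f_off, s$split$test$pairs),
                   score_pairs(f_l0, s$split$test$pairs))
})

test_that("teacher weights receive gradient iff the distillation loss is active", {
  s <- tiny_setup()
  for (lam in c(1, 0)) {
    cfg <- tiny_config(lambda = lam)
    ctx <- cpidistill:::build_context(s$data, s$split, cfg)
    params <- init_model_state(cfg, ncol(ctx$xc_in), ncol(ctx$xp_in), ctx$d_atom)
    m_hg <- cpidistill:::build_teacher_operator(params, ctx, cfg)$m
    tr <- s$split$train$pairs
    fw <- cpidistill:::forward_pass(params, ctx, cfg, tr, tr$label,
                                    training = TRUE, epoch = 1, m_hg = m_hg)
    g <- cpidistill:::collect_param_grads(fw)
    if (lam > 0) {
      expect_gt(sqrt(sum(g$tea1_theta^2)), 0)
      # distillation also reaches the student path
      expect_gt(sqrt(sum(g$stu1_gcn_W^2)), 0)
    } else {
      expect_null(g$tea1_theta)
    }
  }
})

test_that("stop-gradient flags cut one side of the distillation loss", {
  s <- tiny_setup()
  cfg <- tiny_config(distill_stopgrad = "teacher")
  ctx <- cpidistill:::build_context(s$data, s$split, cfg)
  params <- init_model_state(cfg, ncol(ctx$xc_in), ncol(ctx$xp_in), ctx$d_atom)
  m_hg <- cpidistill:::build_teacher_operator(params, ctx, cfg)$m
  tr <- s$split$train$pairs
  fw <- cpidistill:::forward_pass(params, ctx, cfg, tr, tr$label,
                                  training = TRUE, epoch = 1, m_hg = m_hg)
  g <- cpidistill:::collect_param_grads(fw)
  expect_null(g$tea1_theta)
  expect_gt(sqrt(sum(g$stu1_gcn_W^2)), 0)
})

test_that("ablation flags reroute the compound feature path", {
  s <- tiny_setup()
  # sequence-only: no molecular graph parameters in the gradient
  cfg <- tiny_config(mol_graph_on = FALSE, lambda = 0)
  ctx <- cpidistill:::build_context(s$data, s$split, cfg)
  expect_null(ctx$mol)
  params <- init_model_state(cfg, ncol(ctx$xc_in), ncol(ctx$xp_in), ctx$d_atom)
  tr <- s$split$train$pairs
  fw <- cpidistill:::forward_pass(params, ctx, cfg, tr, tr$label, training = TRUE)
  g <- cpidistill:::collect_param_grads(fw)
  expect_null(g$enc1_gcn_W)
  expect_null(g$tok_mlp_W1)

  # graph without tokenizer: encoder trains, tokenizer does not
  cfg2 <- tiny_config(tokenizer_on = FALSE, lambda = 0)
  ctx2 <- cpidistill:::build_context(s$data, s$split, cfg2)
  params2 <- init_model_state(cfg2, ncol(ctx2$xc_in), ncol(ctx2$xp_in), ctx2$d_atom)
  fw2 <- cpidistill:::forward_pass(params2, ctx2, cfg2, tr, tr$label, training = TRUE)
  g2 <- cpidistill:::collect_param_grads(fw2)
  expect_gt(sqrt(sum(g2$enc1_gcn_W^2)), 0)
  expect_null(g2$tok_mlp_W1)

  # tokenizer feeding forward trains the tokenizer MLP
  cfg3 <- tiny_config(lambda = 0)
  params3 <- init_model_state(cfg3, ncol(ctx$xc_in), ncol(ctx$xp_in), 12)
  ctx3 <- cpidistill:::build_context(s$data, s$split, cfg3)
  fw3 <- cpidistill:::forward_pass(params3, ctx3, cfg3, tr, tr$label, training = TRUE)
  g3 <- cpidistill:::collect_param_grads(fw3)
  expect_gt(sqrt(sum(g3$tok_mlp_W1^2)), 0)
})

test_that("distillation is restricted to train-visible nodes", {
  s <- tiny_setup()
  cfg <- tiny_config()
  ctx <- cpidistill:::build_context(s$data, s$split, cfg)
  nvis <- length(ctx$vis_idx)
  expect_lt(nvis, ctx$n_compounds + ctx$n_proteins)
  params <- init_model_state(cfg, ncol(ctx$xc_in), ncol(ctx$xp_in), ctx$d_atom)
  tb <- cpidistill:::build_teacher_operator(params, ctx, cfg)
  expect_equal(dim(tb$m), c(nvis, nvis))
  # no test entity index appears among the distilled nodes
  test_nodes <- c(s$split$test$pairs$compound + 1L,
                  ctx$n_compounds + s$split$test$pairs$protein + 1L)
  expect_length(intersect(test_nodes, ctx$vis_idx), 0)
})

test_that("test-pair scores are untouched by train-entity features (inductive path)", {
  s <- tiny_setup()
  cfg <- tiny_config(lambda = 0, max_epochs = 2)
  fit <- train_cpi(s$data, s$split, cfg)
  te <- s$split$test$pairs
  base <- score_pairs(fit, te)

  # zero every train-visible entity's raw features and rescore
  fit2 <- fit
  fit2$ctx$xc_in[s$split$visible_compounds + 1, ] <- 0
  fit2$ctx$xp_in[s$split$visible_proteins + 1, ] <- 0
  expect_equal(score_pairs(fit2, te), base, tolerance = 1e-12)
})

test_that("scoring is invariant to pair batch order", {
  s <- tiny_setup()
  fit <- train_cpi(s$data, s$split, tiny_config(max_epochs = 2))
  te <- s$split$test$pairs
  ord <- sample(nrow(te))
  expect_equal(score_pairs(fit, te[ord, ]), score_pairs(fit, te)[ord],
               tolerance = 1e-12)
})
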