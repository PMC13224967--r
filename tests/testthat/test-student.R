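# Bipartite GCN student and the pair predictor head.

stu_params <- function(d, n_layers = 1, identity = FALSE, seed = 1) {
  set.seed(seed)
  mk <- function(nr, nc, id) if (identity && id) diag(nr) else rand_mat(nr, nc)
  p <- list()
  for (l in seq_len(n_layers)) {
    p[[paste0("stu", l, "_gcn_W")]] <- mk(d, d, TRUE)
    p[[paste0("stu", l, "_mlp_W1")]] <- mk(d, d, TRUE)
    p[[paste0("stu", l, "_mlp_b1")]] <- matrix(0, 1, d)
    p[[paste0("stu", l, "_mlp_W2")]] <- mk(d, d, TRUE)
    p[[paste0("stu", l, "_mlp_b2")]] <- matrix(0, 1, d)
    p[[paste0("stu", l, "_ln_g")]] <- matrix(1, 1, d)
    p[[paste0("stu", l, "_ln_b")]] <- matrix(0, 1, d)
  }
  p
}

pred_params <- function(d, zero = FALSE, seed = 2) {
  set.seed(seed)
  mk <- function(nr, nc) if (zero) matrix(0, nr, nc) else rand_mat(nr, nc)
  list(pred_ln_c_g = matrix(1, 1, d), pred_ln_c_b = matrix(0, 1, d),
       pred_ln_p_g = matrix(1, 1, d), pred_ln_p_b = matrix(0, 1, d),
       pred_W1 = mk(2 * d, d), pred_b1 = matrix(0, 1, d),
       pred_W2 = mk(d, 1), pred_b2 = matrix(0, 1, 1))
}

empty_train <- function(nc, np) {
  interaction_table(0, 0, 0, nc, np, role = "train")  # single negative: no edges
}

test_that("edgeless graph with identity weights doubles nonnegative features", {
  d <- 4
  g <- bipartite_cpi_graph(empty_train(3, 2), 3, 2)
  expect_equal(g$A, diag(5))   # self-loops only
  X <- matrix(abs(rnorm(5 * d)), 5)
  out <- student_layer(X, g, stu_params(d, identity = TRUE), bypass_ln = TRUE)
  expect_equal(out, 2 * X, tolerance = 1e-12)
})

test_that("zero weights reduce the layer to LN(X)", {
  d <- 5
  g <- bipartite_cpi_graph(empty_train(2, 2), 2, 2)
  p <- stu_params(d)
  for (nm in grep("_(gcn_W|mlp_W1|mlp_W2)$", names(p), value = TRUE)) p[[nm]][] <- 0
  X <- rand_mat(4, d, seed = 6)
  ln_oracle <- t(apply(X, 1, function(r) {
    (r - mean(r)) / sqrt(mean((r - mean(r))^2) + 1e-5)
  }))
  expect_equal(student_layer(X, g, p), ln_oracle, tolerance = 1e-10)
})

test_that("student layer matches a dense normalized-adjacency oracle", {
  set.seed(14)
  nc <- 6; np <- 5; d <- 4
  tr <- interaction_table(c(0, 1, 2, 3, 0), c(0, 1, 2, 3, 4),
                          c(1, 1, 1, 0, 1), nc, np, role = "train")
  g <- bipartite_cpi_graph(tr, nc, np)
  pos <- tr$pairs[tr$pairs$label == 1, ]
  A <- gcn_norm_adj_oracle(nc + np, cbind(pos$compound + 1, nc + pos$protein + 1))
  expect_equal(g$A, A, tolerance = 1e-12)

  p <- stu_params(d, seed = 3)
  X <- rand_mat(nc + np, d, seed = 4)
  h <- A %*% X %*% p$stu1_gcn_W
  h <- pmax(h %*% p$stu1_mlp_W1, 0) %*% p$stu1_mlp_W2 + X
  ln <- t(apply(h, 1, function(r) (r - mean(r)) / sqrt(mean((r - mean(r))^2) + 1e-5)))
  expect_equal(student_layer(X, g, p), ln, tolerance = 1e-5)
})

test_that("isolated nodes depend on their own features only", {
  nc <- 5; np <- 4; d <- 6
  # train edges touch compounds 0-2 and proteins 0-1; compound 4/protein 3 isolated
  tr <- interaction_table(c(0, 1, 2), c(0, 1, 0), c(1, 1, 1), nc, np, role = "train")
  g <- bipartite_cpi_graph(tr, nc, np)
  p <- stu_params(d, n_layers = 3, seed = 5)
  X <- rand_mat(nc + np, d, seed = 7)
  base <- student_forward(X, g, p, n_layers = 3)
  X2 <- X
  X2[1:3, ] <- 0   # zero the connected train compounds
  pert <- student_forward(X2, g, p, n_layers = 3)
  expect_equal(pert[5, ], base[5, ], tolerance = 1e-12)      # isolated compound
  expect_equal(pert[nc + 4, ], base[nc + 4, ], tolerance = 1e-12) # isolated protein
  expect_false(isTRUE(all.equal(pert[1, ], base[1, ])))
})

test_that("student forward is permutation consistent within node blocks", {
  nc <- 4; np <- 3; d <- 5
  tr <- interaction_table(c(0, 1, 2), c(0, 1, 2), c(1, 1, 1), nc, np, role = "train")
  g <- bipartite_cpi_graph(tr, nc, np)
  p <- stu_params(d, n_layers = 2, seed = 11)
  X <- rand_mat(nc + np, d, seed = 12)
  out <- student_forward(X, g, p, n_layers = 2)

  perm <- c(sample(nc), nc + sample(np))  # permute compounds and proteins
  inv <- order(perm)
  pos <- tr$pairs
  tr2 <- interaction_table(inv[pos$compound + 1] - 1L,
                           inv[nc + pos$protein + 1] - nc - 1L,
                           pos$label, nc, np, role = "train")
  g2 <- bipartite_cpi_graph(tr2, nc, np)
  out2 <- student_forward(X[perm, ], g2, p, n_layers = 2)
  expect_equal(out2, out[perm, ], tolerance = 1e-10)
})

test_that("predictor anchors: zero weights give 0.5, outputs stay in (0,1)", {
  d <- 4
  p0 <- pred_params(d, zero = TRUE)
  pr <- predict_pair(rand_mat(3, d, seed = 1), rand_mat(3, d, seed = 2),
                     rand_mat(3, d, seed = 3), rand_mat(3, d, seed = 4), p0)
  expect_equal(pr, rep(0.5, 3))

  p <- pred_params(d)
  set.seed(20)
  pr2 <- predict_pair(rand_mat(1000, d), rand_mat(1000, d),
                      rand_mat(1000, d), rand_mat(1000, d), p)
  expect_true(all(pr2 > 0 & pr2 < 1))
})

test_that("predictor equals the step-by-step oracle and is order equivariant", {
  set.seed(33)
  d <- 5; n <- 8
  p <- pred_params(d, seed = 9)
  xcs <- rand_mat(n, d); xcp <- rand_mat(n, d)
  xps <- rand_mat(n, d); xpp <- rand_mat(n, d)
  got <- predict_pair(xcs, xcp, xps, xpp, p)

  lnv <- function(r) (r - mean(r)) / sqrt(mean((r - mean(r))^2) + 1e-5)
  oracle <- vapply(seq_len(n), function(i) {
    z <- c(lnv(xcs[i, ] + xcp[i, ]), lnv(xps[i, ] + xpp[i, ]))
    h <- pmax(z %*% p$pred_W1, 0) %*% p$pred_W2
    stats::plogis(as.numeric(h))
  }, numeric(1))
  expect_equal(got, oracle, tolerance = 1e-6)

  ord <- sample(n)
  expect_equal(predict_pair(xcs[ord, ], xcp[ord, ], xps[ord, ], xpp[ord, ], p),
               got[ord], tolerance = 1e-12)
  expect_error(predict_pair(xcs, xcp[, 1:3], xps, xpp, p), "width")
})
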