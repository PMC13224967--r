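# Molecular graphs, the residual graph encoder, readout, tokenizer,
# feature transforms, and the offline k-mer hash embedder.

# identity-shaped parameter sets used by the exactness checks below
enc_identity_params <- function(d, n_layers = 1) {
  p <- list(enc_in_W = diag(d), enc_in_b = matrix(0, 1, d),
            read_W = diag(d), read_b = matrix(0, 1, d))
  for (l in seq_len(n_layers)) {
    p[[paste0("enc", l, "_gcn_W")]] <- diag(d)
    p[[paste0("enc", l, "_ln_g")]] <- matrix(1, 1, d)
    p[[paste0("enc", l, "_ln_b")]] <- matrix(0, 1, d)
    p[[paste0("enc", l, "_mlp_W1")]] <- diag(d)
    p[[paste0("enc", l, "_mlp_b1")]] <- matrix(0, 1, d)
    p[[paste0("enc", l, "_mlp_W2")]] <- diag(d)
    p[[paste0("enc", l, "_mlp_b2")]] <- matrix(0, 1, d)
  }
  p
}

rand_enc_params <- function(d_in, d, n_layers = 1, seed = 1) {
  set.seed(seed)
  p <- list(enc_in_W = rand_mat(d_in, d), enc_in_b = rand_mat(1, d),
            read_W = rand_mat(d, d), read_b = rand_mat(1, d))
  for (l in seq_len(n_layers)) {
    p[[paste0("enc", l, "_gcn_W")]] <- rand_mat(d, d)
    p[[paste0("enc", l, "_ln_g")]] <- rand_mat(1, d)
    p[[paste0("enc", l, "_ln_b")]] <- rand_mat(1, d)
    p[[paste0("enc", l, "_mlp_W1")]] <- rand_mat(d, d)
    p[[paste0("enc", l, "_mlp_b1")]] <- rand_mat(1, d)
    p[[paste0("enc", l, "_mlp_W2")]] <- rand_mat(d, d)
    p[[paste0("enc", l, "_mlp_b2")]] <- rand_mat(1, d)
  }
  p
}

test_that("SMILES parse to the expected heavy-atom topology", {
  g <- mol_graph_from_smiles("CCO")
  expect_equal(g$m, 3)
  expect_equal(nrow(g$bonds), 2)
  expect_setequal(g$elements, c("C", "C", "O"))
  expect_equal(sum(g$atom_features[, "ring"]), 0)

  b <- mol_graph_from_smiles("c1ccccc1")
  expect_equal(b$m, 6)
  expect_equal(nrow(b$bonds), 6)   # ring closure
  expect_equal(sum(b$atom_features[, "ring"]), 6)
  expect_equal(unname(b$atom_features[, "degree"]), rep(2, 6))
})

test_that("an unparseable SMILES raises an error naming the string", {
  # the printed case-study macrocycle is invalid once whitespace is
  # stripped (stereo markers outside brackets); the documented error path
  bad <- "CC(C)C[C@@H]1NC(=O)CC@HC@HNC(=O)C@@HCCC(=O)NCc2cccc (c2)CNC1 = O"
  expect_error(mol_graph_from_smiles(bad), "cannot parse SMILES")
  expect_error(mol_graph_from_smiles("not_a_smiles(("), "cannot parse SMILES")
})

test_that("a singleton atom with identity weights reduces to MLP(LN(x))", {
  d <- 12
  g <- list(atom_features = matrix(rnorm(d), 1), bonds = matrix(integer(0), 0, 2))
  p <- enc_identity_params(d)
  # singleton with self-loop: GCN(x) = x; sigma=identity; residual doubles
  out <- encode_mol_graph(g, p, n_layers = 1, sigma = "identity", bypass_ln = TRUE)
  # identity-MLP is Linear-ReLU-Linear, so the image is relu(2x)
  expect_equal(out, pmax(2 * g$atom_features, 0), tolerance = 1e-12)
  # with zero input and zero biases the LN-epsilon guard keeps output finite
  g0 <- list(atom_features = matrix(0, 1, d), bonds = matrix(integer(0), 0, 2))
  out0 <- encode_mol_graph(g0, p, n_layers = 1, sigma = "identity")
  expect_true(all(is.finite(out0)))
})

test_that("encoder matches a dense normalized-adjacency oracle on a path graph", {
  d_in <- 12; d <- 6
  m <- 5
  set.seed(4)
  g <- list(atom_features = rand_mat(m, d_in),
            bonds = cbind(1:4, 2:5))
  p <- rand_enc_params(d_in, d, n_layers = 2, seed = 9)
  out <- encode_mol_graph(g, p, n_layers = 2)

  # independent dense recomputation
  A <- gcn_norm_adj_oracle(m, g$bonds)
  ln <- function(X, gam, bet, eps = 1e-5) {
    t(apply(X, 1, function(r) (r - mean(r)) / sqrt(mean((r - mean(r))^2) + eps))) *
      rep(as.numeric(gam), each = nrow(X)) + rep(as.numeric(bet), each = nrow(X))
  }
  mlp <- function(X, W1, b1, W2, b2) {
    pmax(X %*% W1 + rep(as.numeric(b1), each = nrow(X)), 0) %*% W2 +
      rep(as.numeric(b2), each = nrow(X))
  }
  X <- g$atom_features %*% p$enc_in_W + rep(as.numeric(p$enc_in_b), each = m)
  for (l in 1:2) {
    H <- pmax(A %*% X %*% p[[paste0("enc", l, "_gcn_W")]], 0) + X
    H <- ln(H, p[[paste0("enc", l, "_ln_g")]], p[[paste0("enc", l, "_ln_b")]])
    X <- mlp(H, p[[paste0("enc", l, "_mlp_W1")]], p[[paste0("enc", l, "_mlp_b1")]],
             p[[paste0("enc", l, "_mlp_W2")]], p[[paste0("enc", l, "_mlp_b2")]])
  }
  expect_equal(out, X, tolerance = 1e-5)
})

test_that("encoder is equivariant to atom relabeling and readout invariant", {
  d_in <- 12; d <- 8
  g <- mol_graph_from_smiles("CC(=O)O")
  p <- rand_enc_params(d_in, d, n_layers = 2, seed = 3)
  out <- encode_mol_graph(g, p, n_layers = 2)

  perm <- c(3L, 1L, 4L, 2L)
  inv <- order(perm)
  gp <- list(atom_features = g$atom_features[perm, ],
             bonds = matrix(inv[g$bonds], ncol = 2))
  outp <- encode_mol_graph(gp, p, n_layers = 2)
  expect_equal(outp, out[perm, ], tolerance = 1e-10)
  expect_equal(readout(outp, p), readout(out, p), tolerance = 1e-10)
})

test_that("readout is mean-then-affine", {
  d <- 4
  p <- list(read_W = diag(d), read_b = matrix(0, 1, d))
  v <- matrix(rep(c(1, 2, 3, 4), each = 3), 3)
  expect_equal(as.numeric(readout(v, p)), c(1, 2, 3, 4))

  p2 <- list(read_W = diag(2), read_b = matrix(c(1, 1), 1))
  expect_equal(as.numeric(readout(rbind(c(1, 0), c(0, 1)), p2)), c(1.5, 1.5))

  set.seed(8)
  M <- rand_mat(7, 4); W <- rand_mat(4, 5); b <- rand_mat(1, 5)
  expect_equal(readout(M, list(read_W = W, read_b = b)),
               matrix(colMeans(M), 1) %*% W + b, tolerance = 1e-6)
  expect_error(readout(M[0, , drop = FALSE], p), "at least one atom")
})

test_that("tokenizer equals the concat+MLP oracle and rejects empty tokens", {
  set.seed(12)
  d <- 5; dt <- 3
  xg <- rand_mat(1, d); toks <- rand_mat(6, dt)
  p <- list(tok_mlp_W1 = rand_mat(d + dt, d), tok_mlp_b1 = rand_mat(1, d),
            tok_mlp_W2 = rand_mat(d, d), tok_mlp_b2 = rand_mat(1, d))
  out <- tokenize(xg, toks, p)
  z <- cbind(xg, matrix(colMeans(toks), 1))
  oracle <- pmax(z %*% p$tok_mlp_W1 + p$tok_mlp_b1, 0) %*% p$tok_mlp_W2 + p$tok_mlp_b2
  expect_equal(out, oracle, tolerance = 1e-6)

  # zero inputs with zero biases give MLP(0) = 0
  p0 <- p; p0$tok_mlp_b1[] <- 0; p0$tok_mlp_b2[] <- 0
  expect_equal(tokenize(matrix(0, 1, d), matrix(0, 2, dt), p0),
               matrix(0, 1, d))
  expect_error(tokenize(xg, toks[0, , drop = FALSE], p), "empty")
  expect_error(tokenize(xg, rand_mat(4, dt + 1), p), "width")
})

trans_identity_params <- function(d) {
  list(fuse_W1 = rbind(diag(d), diag(d)) * 0.5, fuse_b1 = matrix(0, 1, d),
       fuse_W2 = diag(d), fuse_b2 = matrix(0, 1, d),
       ct_W = diag(d), ct_b = matrix(0, 1, d),
       ct_ln_g = matrix(1, 1, d), ct_ln_b = matrix(0, 1, d),
       ct_mlp_W1 = diag(d), ct_mlp_b1 = matrix(0, 1, d),
       ct_mlp_W2 = diag(d), ct_mlp_b2 = matrix(0, 1, d),
       pt_W = diag(d), pt_b = matrix(0, 1, d),
       pt_ln_g = matrix(1, 1, d), pt_ln_b = matrix(0, 1, d),
       pt_mlp_W1 = diag(d), pt_mlp_b1 = matrix(0, 1, d),
       pt_mlp_W2 = diag(d), pt_mlp_b2 = matrix(0, 1, d))
}

test_that("residual transforms double nonnegative input under identity weights", {
  d <- 6
  p <- trans_identity_params(d)
  v <- matrix(abs(rnorm(2 * d)), 2)
  # fusing v with itself averages back to v; W=I doubles through the residual
  expect_equal(transform_compound(v, v, p, bypass_ln = TRUE), 2 * v,
               tolerance = 1e-12)
  expect_equal(transform_protein(v, p, bypass_ln = TRUE), 2 * v,
               tolerance = 1e-12)
})

test_that("transforms match a step-by-step oracle on random inputs", {
  set.seed(77)
  d <- 5; n <- 4
  p <- trans_identity_params(d)
  for (nm in names(p)) p[[nm]] <- rand_mat(nrow(p[[nm]]), ncol(p[[nm]]))
  xs <- rand_mat(n, d); xg <- rand_mat(n, d)

  lnr <- function(X, gam, bet, eps = 1e-5) {
    t(apply(X, 1, function(r) (r - mean(r)) / sqrt(mean((r - mean(r))^2) + eps))) *
      rep(as.numeric(gam), each = nrow(X)) + rep(as.numeric(bet), each = nrow(X))
  }
  mlp <- function(X, W1, b1, W2, b2) {
    pmax(X %*% W1 + rep(as.numeric(b1), each = nrow(X)), 0) %*% W2 +
      rep(as.numeric(b2), each = nrow(X))
  }
  xc <- mlp(cbind(xs, xg), p$fuse_W1, p$fuse_b1, p$fuse_W2, p$fuse_b2)
  h <- lnr((xc %*% p$ct_W + rep(as.numeric(p$ct_b), each = n)) + xc,
           p$ct_ln_g, p$ct_ln_b)
  expect_equal(transform_compound(xs, xg, p),
               mlp(h, p$ct_mlp_W1, p$ct_mlp_b1, p$ct_mlp_W2, p$ct_mlp_b2),
               tolerance = 1e-6)

  hp <- lnr((xs %*% p$pt_W + rep(as.numeric(p$pt_b), each = n)) + xs,
            p$pt_ln_g, p$pt_ln_b)
  expect_equal(transform_protein(xs, p),
               mlp(hp, p$pt_mlp_W1, p$pt_mlp_b1, p$pt_mlp_W2, p$pt_mlp_b2),
               tolerance = 1e-6)
})

test_that("transform outputs stay finite across random draws and zeroed weights", {
  d <- 6
  set.seed(5)
  p <- trans_identity_params(d)
  for (i in 1:200) {
    x <- rand_mat(1, d) * 10^runif(1, -3, 3)
    expect_true(all(is.finite(transform_compound(x, rand_mat(1, d), p))))
  }
  p0 <- lapply(p, function(m) m * 0)
  out <- transform_compound(matrix(0, 1, d), matrix(0, 1, d), p0)
  expect_true(all(is.finite(out)))  # LN epsilon guards the all-zero branch
})

test_that("hash embedder is deterministic, unit-norm, and locality-sensitive", {
  expect_identical(hash_embed("CCON", 32), hash_embed("CCON", 32))
  for (s in c("A", "CCO", "MKTAYIAKQRQISFVKSHFSRQ")) {
    expect_equal(sqrt(sum(hash_embed(s, 16, k = 2)^2)), 1, tolerance = 1e-12)
  }
  expect_error(hash_embed_tokens("CCO", 4), ">= 8")

  cos <- function(a, b) sum(a * b)
  set.seed(42)
  alpha <- c("A", "C", "G", "T")
  wins <- 0
  for (i in 1:100) {
    base <- paste(sample(alpha, 12, TRUE), collapse = "")
    near <- paste0(substr(base, 1, 11), sample(setdiff(alpha, substr(base, 12, 12)), 1))
    far <- paste(sample(c("W", "X", "Y", "Z"), 12, TRUE), collapse = "")
    d16 <- function(s) hash_embed(s, 64, k = 3)
    wins <- wins + (cos(d16(base), d16(near)) > cos(d16(base), d16(far)))
  }
  expect_gte(wins, 95)
})

test_that("embedding caches round-trip with their sidecar", {
  et <- entity_table(c("a", "b"), c("CCO", "CCN"), "compound")
  m <- embed_entities(et, 16)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_embedding_cache(m, f, name = "hash_embed")
  back <- read_embedding_cache(f)
  expect_equal(back, m, tolerance = 1e-12)
  side <- jsonlite::read_json(paste0(f, ".json"))
  expect_equal(side$dim, 16)
})
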