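# Per-entity featurization: offline k-mer hash embeddings (a deterministic
# sequence embedder), SMILES -> molecular graphs, the residual GCN molecular
# graph encoder, mean-pool readout, the graph tokenizer, and the residual
# feature transforms that map every modality into a common model dimension.

ELEMENT_VOCAB <- c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I")

# polynomial rolling hashes kept below 2^31; (mult, mod) pairs differ so the
# bucket and sign hashes are independent
.string_hash <- function(s, mult, mod) {
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * mult + ch) %% mod
  h
}

#' Deterministic k-mer hash embedding of a sequence payload
#'
#' Feature-hashes the payload's overlapping k-mers into `dim` signed buckets
#' and L2-normalizes, giving a cheap, fully offline sequence embedder:
#' identical payloads map to identical vectors and payloads sharing k-mers
#' map to nearby vectors. Intended as the default stand-in for pretrained
#' sequence language-model embeddings (use `k = 2` for SMILES, `k = 3` for
#' amino-acid sequences).
#'
#' @param payload nonempty string.
#' @param dim embedding dimension (>= 8).
#' @param k k-mer length.
#' @return numeric vector of length `dim` with unit L2 norm.
#' @export
#' @examples
#' v <- hash_embed("MKTAYIAKQR", dim = 32, k = 3)
#' sqrt(sum(v^2))
hash_embed <- function(payload, dim, k = 2) {
  toks <- hash_tokens(payload, k)
  v <- numeric(dim)
  for (tok in toks) {
    b <- .string_hash(tok, 131, 2147483647) %% dim + 1
    s <- if (.string_hash(tok, 137, 2147483629) %% 2 == 0) 1 else -1
    v[b] <- v[b] + s
  }
  nrm <- sqrt(sum(v^2))
  if (nrm == 0) {
    # all k-mer signs cancelled; fall back to a single whole-string bucket
    b <- .string_hash(payload, 131, 2147483647) %% dim + 1
    v[b] <- 1
    nrm <- 1
  }
  v / nrm
}

hash_tokens <- function(payload, k) {
  payload <- as.character(payload)
  if (length(payload) != 1 || is.na(payload) || !nzchar(payload)) {
    stopf("payload must be a nonempty string")
  }
  n <- nchar(payload)
  if (n < k) return(payload)
  substring(payload, seq_len(n - k + 1), seq_len(n - k + 1) + k - 1)
}

#' Per-position token embeddings of a payload
#'
#' One row per overlapping k-mer, each row the unit-norm hash embedding of
#' that k-mer. Mean-pooling these rows is the offline analogue of pooling a
#' language model's token embedding matrix.
#'
#' @inheritParams hash_embed
#' @return a `tokens x dim` matrix.
#' @export
hash_embed_tokens <- function(payload, dim, k = 2) {
  if (dim < 8) stopf("embedding dim must be >= 8, got %d", dim)
  toks <- hash_tokens(payload, k)
  out <- matrix(0, length(toks), dim)
  for (i in seq_along(toks)) {
    b <- .string_hash(toks[i], 131, 2147483647) %% dim + 1
    s <- if (.string_hash(toks[i], 137, 2147483629) %% 2 == 0) 1 else -1
    out[i, b] <- s
  }
  out
}

#' Embed all entities of a table
#'
#' Applies [hash_embed()] to every payload (k = 2 for compounds, k = 3 for
#' proteins), returning a feature matrix with ids as row names.
#'
#' @param entities an [entity_table()].
#' @param dim embedding dimension (>= 8).
#' @return an `n x dim` numeric matrix.
#' @export
embed_entities <- function(entities, dim = 64) {
  if (dim < 8) stopf("embedding dim must be >= 8, got %d", dim)
  k <- if (entities$kind == "compound") 2 else 3
  out <- t(vapply(entities$payloads, hash_embed, numeric(dim), dim = dim, k = k))
  rownames(out) <- entities$ids
  out
}

#' Save / load an embedding cache
#'
#' Stores a per-entity embedding matrix as a TSV keyed by entity id, with a
#' JSON sidecar recording the embedder name and dimension.
#'
#' @param mat matrix with entity ids as row names.
#' @param path output TSV path (sidecar written to `<path>.json`).
#' @param name embedder name recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_embedding_cache <- function(mat, path, name = "hash_embed") {
  df <- data.frame(id = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(name = name, dim = ncol(mat), n = nrow(mat)),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_embedding_cache
#' @export
read_embedding_cache <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  dimnames(m) <- list(df$id, NULL)
  m
}

# session-level molecule parse cache (SMILES string -> molecule_graph)
.mol_cache <- new.env(parent = emptyenv())

#' Parse a SMILES string into a molecular graph
#'
#' Uses the OpenBabel-backed parser from ChemmineR. Heavy atoms become nodes
#' carrying a fixed-length feature vector: one-hot element over the common
#' organic set (C, N, O, S, P, F, Cl, Br, I, other), degree, and a
#' ring-membership flag. Bonds become simple undirected edges.
#'
#' @param smiles SMILES string.
#' @return an object of class `molecule_graph`: `atom_features` (`m x 12`
#'   matrix), `bonds` (2-column 1-based edge matrix), `elements`, `m`.
#' @export
#' @examples
#' g <- mol_graph_from_smiles("CCO")
#' g$m           # 3 heavy atoms
#' nrow(g$bonds) # 2 bonds
mol_graph_from_smiles <- function(smiles) {
  smiles <- gsub("[[:space:]]", "", as.character(smiles))
  if (!nzchar(smiles)) stopf("empty SMILES string")
  if (!is.null(.mol_cache[[smiles]])) return(.mol_cache[[smiles]])
  sdf <- tryCatch(suppressWarnings(ChemmineR::smiles2sdf(smiles)),
                  error = function(e) NULL)
  if (is.null(sdf) || length(sdf) == 0) {
    stopf("cannot parse SMILES '%s'", smiles)
  }
  ab <- ChemmineR::atomblock(sdf[[1]])
  m <- nrow(ab)
  if (is.null(m) || m == 0) stopf("cannot parse SMILES '%s' (no atoms)", smiles)
  elements <- sub("_.*$", "", rownames(ab))

  bb <- ChemmineR::bondblock(sdf[[1]])
  if (is.null(bb) || nrow(bb) == 0) {
    bonds <- matrix(integer(0), 0, 2)
  } else {
    bonds <- cbind(as.integer(bb[, 1]), as.integer(bb[, 2]))
    bonds <- bonds[bonds[, 1] != bonds[, 2], , drop = FALSE]
    bonds <- unique(t(apply(bonds, 1, sort)))
    bonds <- matrix(as.integer(bonds), ncol = 2)
  }
  if (nrow(bonds) > 0 && max(bonds) > m) {
    stopf("cannot parse SMILES '%s' (bond references missing atom)", smiles)
  }

  deg <- tabulate(c(bonds[, 1], bonds[, 2]), nbins = m)
  in_ring <- rep(FALSE, m)
  if (nrow(bonds) > 1) {
    g <- igraph::graph_from_edgelist(bonds, directed = FALSE)
    br <- igraph::bridges(g)
    cyc_edges <- setdiff(seq_len(nrow(bonds)), as.integer(br))
    in_ring[unique(as.vector(bonds[cyc_edges, , drop = FALSE]))] <- TRUE
  }

  onehot <- matrix(0, m, length(ELEMENT_VOCAB) + 1)
  colnames(onehot) <- c(ELEMENT_VOCAB, "other")
  pos <- match(elements, ELEMENT_VOCAB)
  pos[is.na(pos)] <- length(ELEMENT_VOCAB) + 1
  onehot[cbind(seq_len(m), pos)] <- 1

  out <- structure(list(
    atom_features = cbind(onehot, degree = deg, ring = as.numeric(in_ring)),
    bonds = bonds, elements = elements, m = m, smiles = smiles
  ), class = "molecule_graph")
  .mol_cache[[smiles]] <- out
  out
}

#' @export
print.molecule_graph <- function(x, ...) {
  cat(sprintf("<molecule_graph> %s: %d atoms, %d bonds\n",
              x$smiles, x$m, nrow(x$bonds)))
  invisible(x)
}

# Symmetric-normalized adjacency with self-loops for a simple graph.
normalized_adjacency <- function(n, edges) {
  A <- diag(n)
  if (nrow(edges) > 0) {
    A[edges] <- 1
    A[edges[, c(2, 1), drop = FALSE]] <- 1
  }
  dinv <- 1 / sqrt(rowSums(A))
  A * tcrossprod(dinv)
}

# --- tape-level builders shared by the exported ops and the trainer -------

act_fn <- function(sigma) {
  switch(sigma,
         relu = ad_relu,
         identity = function(x) x,
         stopf("unknown activation '%s'", sigma))
}

tb_layernorm <- function(x, gamma, beta, bypass) {
  if (bypass) x else ad_layernorm(x, gamma, beta)
}

# residual molecular-graph encoder stack:
# X(l+1) = MLP(LN(sigma(A X(l) W) + X(l)))
# `a` is the fixed normalized adjacency (base or sparse Matrix), not a node
tb_encode_mol <- function(tape, xnode, a, pn, n_layers, sigma = "relu",
                          bypass_ln = FALSE) {
  act <- act_fn(sigma)
  x <- ad_linear(xnode, pn$enc_in_W, pn$enc_in_b)
  for (l in seq_len(n_layers)) {
    h <- act(ad_spmm(a, ad_matmul(x, pn[[paste0("enc", l, "_gcn_W")]])))
    h <- tb_layernorm(ad_add(h, x), pn[[paste0("enc", l, "_ln_g")]],
                      pn[[paste0("enc", l, "_ln_b")]], bypass_ln)
    x <- ad_mlp(h, pn[[paste0("enc", l, "_mlp_W1")]], pn[[paste0("enc", l, "_mlp_b1")]],
                pn[[paste0("enc", l, "_mlp_W2")]], pn[[paste0("enc", l, "_mlp_b2")]])
  }
  x
}

tb_readout <- function(x, pn) ad_linear(ad_colmean(x), pn$read_W, pn$read_b)

tb_tokenize <- function(xgraph, tokmean, pn) {
  ad_mlp(ad_cbind(xgraph, tokmean), pn$tok_mlp_W1, pn$tok_mlp_b1,
         pn$tok_mlp_W2, pn$tok_mlp_b2)
}

# fuse two compound modalities, then the affine-residual transform:
# x_c = MLP(x_smiles || x_second);  x_c' = MLP(LN((W x_c + b) + x_c))
tb_transform_compound <- function(xsmiles, xsecond, pn, bypass_ln = FALSE) {
  xc <- ad_mlp(ad_cbind(xsmiles, xsecond), pn$fuse_W1, pn$fuse_b1,
               pn$fuse_W2, pn$fuse_b2)
  h <- ad_add(ad_linear(xc, pn$ct_W, pn$ct_b), xc)
  h <- tb_layernorm(h, pn$ct_ln_g, pn$ct_ln_b, bypass_ln)
  list(fused = xc,
       prime = ad_mlp(h, pn$ct_mlp_W1, pn$ct_mlp_b1, pn$ct_mlp_W2, pn$ct_mlp_b2))
}

tb_transform_protein <- function(xp, pn, bypass_ln = FALSE) {
  h <- ad_add(ad_linear(xp, pn$pt_W, pn$pt_b), xp)
  h <- tb_layernorm(h, pn$pt_ln_g, pn$pt_ln_b, bypass_ln)
  ad_mlp(h, pn$pt_mlp_W1, pn$pt_mlp_b1, pn$pt_mlp_W2, pn$pt_mlp_b2)
}

params_to_nodes <- function(tape, params) {
  lapply(params, function(p) ad_param(tape, p))
}

# --- exported plain-matrix ops -------------------------------------------

#' Encode a molecular graph with the residual GCN stack
#'
#' Each layer applies, in order: a symmetric-normalized graph convolution
#' with self-loops, the activation, a residual addition of the previous
#' layer's atom matrix, LayerNorm, and a 2-layer MLP. Atom features are first
#' projected to the working width by `params$enc_in_W` / `enc_in_b`.
#'
#' @param graph a [mol_graph_from_smiles()] result, or any list with
#'   `atom_features` and `bonds`.
#' @param params named list of encoder weights (see [init_model_state()]).
#' @param n_layers number of residual layers (default 2).
#' @param sigma `"relu"` or `"identity"`.
#' @param bypass_ln skip LayerNorm (diagnostic mode used in exactness tests).
#' @return the final `m x d` atom-feature matrix.
#' @export
encode_mol_graph <- function(graph, params, n_layers = 2, sigma = "relu",
                             bypass_ln = FALSE) {
  m <- nrow(graph$atom_features)
  if (ncol(graph$atom_features) != nrow(params$enc_in_W)) {
    stopf("atom feature width %d does not match enc_in_W rows %d",
          ncol(graph$atom_features), nrow(params$enc_in_W))
  }
  tape <- ad_tape()
  x <- ad_const(tape, graph$atom_features)
  pn <- params_to_nodes(tape, params)
  ad_value(tb_encode_mol(tape, x, normalized_adjacency(m, graph$bonds), pn,
                         n_layers, sigma, bypass_ln))
}

#' Mean-pool readout of an atom-feature matrix
#'
#' `x = W (mean over atom rows) + b`.
#'
#' @param atom_matrix `m x d` matrix, `m >= 1`.
#' @param params list with `read_W` (`d x d_out`) and `read_b` (`1 x d_out`).
#' @return a `1 x d_out` row vector.
#' @export
readout <- function(atom_matrix, params) {
  if (is.null(nrow(atom_matrix)) || nrow(atom_matrix) == 0) {
    stopf("readout requires at least one atom row")
  }
  tape <- ad_tape()
  pn <- params_to_nodes(tape, params)
  ad_value(tb_readout(ad_const(tape, atom_matrix), pn))
}

#' Graph tokenizer: fuse a graph vector with pooled sequence tokens
#'
#' Mean-pools the token embedding matrix, concatenates with the graph-level
#' vector, and applies a 2-layer MLP.
#'
#' @param x_c_graph `1 x d` graph readout vector (or `n x d` matrix).
#' @param token_matrix `tokens x d_token` token embedding matrix (nonempty),
#'   or an `n x d_token` matrix of already-pooled means when `x_c_graph` has
#'   `n` rows.
#' @param params list with `tok_mlp_W1/b1/W2/b2`.
#' @param pooled set `TRUE` if `token_matrix` rows are already pooled means.
#' @return matrix with the same number of rows as `x_c_graph`.
#' @export
tokenize <- function(x_c_graph, token_matrix, params, pooled = FALSE) {
  x_c_graph <- if (is.matrix(x_c_graph)) x_c_graph else matrix(x_c_graph, 1)
  if (nrow(token_matrix) == 0) stopf("token matrix is empty")
  tokmean <- if (pooled) token_matrix else matrix(colMeans(token_matrix), 1)
  if (nrow(tokmean) != nrow(x_c_graph)) {
    stopf("pooled token rows (%d) do not match graph rows (%d)",
          nrow(tokmean), nrow(x_c_graph))
  }
  if (ncol(x_c_graph) + ncol(tokmean) != nrow(params$tok_mlp_W1)) {
    stopf("tokenizer input width %d does not match tok_mlp_W1 rows %d",
          ncol(x_c_graph) + ncol(tokmean), nrow(params$tok_mlp_W1))
  }
  tape <- ad_tape()
  pn <- params_to_nodes(tape, params)
  ad_value(tb_tokenize(ad_const(tape, x_c_graph), ad_const(tape, tokmean), pn))
}

#' Compound feature transform
#'
#' Fuses the sequence-derived compound vector with a second modality (the
#' tokenized or plain graph readout; the sequence vector itself in the
#' sequence-only ablation) by concatenation + MLP, then applies the
#' affine-residual transform `MLP(LN((W x + b) + x))`.
#'
#' @param x_c_smiles,x_second `n x d` matrices of the two modalities.
#' @param params list with `fuse_*`, `ct_*` weights (see [init_model_state()]).
#' @param bypass_ln skip LayerNorm (diagnostic mode).
#' @return the transformed `n x d` compound matrix.
#' @export
transform_compound <- function(x_c_smiles, x_second, params, bypass_ln = FALSE) {
  assert_finite_matrix(as.matrix(x_c_smiles), "x_c_smiles")
  assert_finite_matrix(as.matrix(x_second), "x_second")
  tape <- ad_tape()
  pn <- params_to_nodes(tape, params)
  ad_value(tb_transform_compound(ad_const(tape, x_c_smiles),
                                 ad_const(tape, x_second), pn, bypass_ln)$prime)
}

#' Protein feature transform
#'
#' The affine-residual transform `MLP(LN((W x + b) + x))` applied to the
#' protein sequence embedding, without fusion.
#'
#' @param x_p `n x d` protein feature matrix.
#' @param params list with `pt_*` weights.
#' @param bypass_ln skip LayerNorm (diagnostic mode).
#' @return the transformed `n x d` protein matrix.
#' @export
transform_protein <- function(x_p, params, bypass_ln = FALSE) {
  assert_finite_matrix(as.matrix(x_p), "x_p")
  tape <- ad_tape()
  pn <- params_to_nodes(tape, params)
  ad_value(tb_transform_protein(ad_const(tape, as.matrix(x_p)), pn, bypass_ln))
}
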