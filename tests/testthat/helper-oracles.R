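# Shared test helpers: numeric differentiation and small brute-force oracles.

# Central-difference gradient of scalar-valued f at matrix x.
num_grad <- function(f, x, eps = 1e-5) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

rand_mat <- function(n, d, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(rnorm(n * d), n, d)
}

# O(n^2) pair-counting AUROC oracle (ties count 1/2).
auroc_pair_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Direct double-loop InfoNCE oracle.
infonce_oracle <- function(xt, xs, tau) {
  n <- nrow(xt)
  tot <- 0
  for (i in seq_len(n)) {
    num <- exp(sum(xt[i, ] * xs[i, ]) / tau)
    den <- 0
    for (j in seq_len(n)) den <- den + exp(sum(xt[i, ] * xs[j, ]) / tau)
    tot <- tot - log(num / den)
  }
  tot / n
}

# Dense hypergraph convolution oracle: sigma(Dv^-1/2 H W De^-1 H' Dv^-1/2 X Theta)
hgnn_dense_oracle <- function(X, H, theta, w = NULL, sigma = function(z) pmax(z, 0)) {
  if (is.null(w)) w <- diag(ncol(H))
  dv <- rowSums(H %*% w)
  de <- colSums(H)
  dvm <- diag(1 / sqrt(dv))
  dem <- diag(1 / de, nrow = length(de))
  sigma(dvm %*% H %*% w %*% dem %*% t(H) %*% dvm %*% X %*% theta)
}

# Symmetric-normalized adjacency with self-loops (dense GCN oracle).
gcn_norm_adj_oracle <- function(n, edges) {
  A <- diag(n)
  if (nrow(edges) > 0) {
    for (r in seq_len(nrow(edges))) {
      A[edges[r, 1], edges[r, 2]] <- 1
      A[edges[r, 2], edges[r, 1]] <- 1
    }
  }
  d <- rowSums(A)
  diag(1 / sqrt(d)) %*% A %*% diag(1 / sqrt(d))
}

# exhaustive-search oracle for cluster-guided hyperedge construction:
# same clustering, O(n^2) distance sort, lowest-index tie rule
sub_hypergraph_oracle <- function(xq, xr, k2, clustering) {
  lapply(seq_len(nrow(xq)), function(i) {
    dc <- apply(clustering$centers, 1, function(cen) cosine_distance(xq[i, ], cen))
    best <- which(dc == min(dc))[1]
    members <- which(clustering$cluster == best)
    dm <- vapply(members, function(j) cosine_distance(xq[i, ], xr[j, ]), numeric(1))
    ord <- order(dm, members)
    list(center = i, members = as.integer(members[ord[seq_len(min(k2, length(members)))]]))
  })
}

# small random hypergraph: every node in its own edge plus random extras
rand_hypergraph <- function(n_nodes, n_extra, seed) {
  set.seed(seed)
  edges <- c(as.list(seq_len(n_nodes)),
             lapply(seq_len(n_extra), function(j) {
               sort(sample.int(n_nodes, sample(2:min(4, n_nodes), 1)))
             }))
  H <- matrix(0, n_nodes, length(edges))
  for (j in seq_along(edges)) H[edges[[j]], j] <- 1
  structure(list(n_nodes = n_nodes, n_compounds = n_nodes, n_proteins = 0,
                 edges = lapply(edges, as.integer), H = H,
                 Dv = rowSums(H), De = colSums(H)),
            class = "hypergraph")
}
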