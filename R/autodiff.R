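# Minimal reverse-mode automatic differentiation over dense matrices.
#
# Every model forward pass is recorded on a tape; ad_backward() walks the
# tape in reverse and accumulates gradients into leaf nodes marked as
# parameters. Backward rules are supplied per parent as lazy closures, so a
# gradient with respect to a constant (an adjacency operator, an input
# feature matrix) is never materialized. All values are base-R matrices.

ad_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$n <- 0L
  t$val <- list()
  t$parents <- list()
  t$bw <- list()
  t$ng <- logical(0)
  t
}

# backward: list of closures, one per parent, each mapping the upstream
# gradient to that parent's gradient contribution
ad_push <- function(tape, value, parents = list(), backward = NULL) {
  i <- tape$n + 1L
  tape$n <- i
  tape$val[[i]] <- value
  pid <- vapply(parents, function(p) p$id, integer(1))
  tape$parents[[i]] <- pid
  tape$bw[[i]] <- backward
  tape$ng[i] <- length(pid) > 0 && any(tape$ng[pid])
  structure(list(tape = tape, id = i), class = "ad_node")
}

ad_const <- function(tape, x) {
  if (!is.matrix(x)) x <- as.matrix(x)
  ad_push(tape, x)
}

# a leaf that accumulates gradients (a trainable parameter)
ad_param <- function(tape, x) {
  n <- ad_const(tape, x)
  n$tape$ng[n$id] <- TRUE
  n
}

ad_value <- function(node) node$tape$val[[node$id]]

ad_backward <- function(loss) {
  tape <- loss$tape
  grads <- vector("list", tape$n)
  v <- ad_value(loss)
  grads[[loss$id]] <- matrix(1, nrow(v), ncol(v))
  for (i in seq.int(loss$id, 1L)) {
    g <- grads[[i]]
    if (is.null(g) || is.null(tape$bw[[i]]) || !tape$ng[i]) next
    ps <- tape$parents[[i]]
    bw <- tape$bw[[i]]
    for (k in seq_along(ps)) {
      p <- ps[k]
      if (!tape$ng[p]) next
      pg <- bw[[k]](g)
      if (is.null(pg)) next
      grads[[p]] <- if (is.null(grads[[p]])) pg else grads[[p]] + pg
    }
  }
  grads
}

ad_matmul <- function(a, b) {
  av <- ad_value(a); bv <- ad_value(b)
  ad_push(a$tape, av %*% bv, list(a, b),
          list(function(g) tcrossprod(g, bv),
               function(g) crossprod(av, g)))
}

ad_add <- function(a, b) {
  ad_push(a$tape, ad_value(a) + ad_value(b), list(a, b),
          list(function(g) g, function(g) g))
}

# X + bias, bias a 1 x d row vector broadcast over rows
ad_bias <- function(x, b) {
  xv <- ad_value(x); bv <- as.numeric(ad_value(b))
  ad_push(x$tape, xv + rep(bv, each = nrow(xv)), list(x, b),
          list(function(g) g,
               function(g) matrix(.colSums(g, nrow(g), ncol(g)), 1)))
}

ad_relu <- function(x) {
  xv <- ad_value(x)
  mask <- xv > 0
  ad_push(x$tape, xv * mask, list(x), list(function(g) g * mask))
}

ad_cbind <- function(a, b) {
  av <- ad_value(a); bv <- ad_value(b)
  da <- ncol(av)
  ad_push(a$tape, cbind(av, bv), list(a, b),
          list(function(g) g[, seq_len(da), drop = FALSE],
               function(g) g[, -seq_len(da), drop = FALSE]))
}

ad_rbind2 <- function(a, b) {
  av <- ad_value(a); bv <- ad_value(b)
  na <- nrow(av)
  ad_push(a$tape, rbind(av, bv), list(a, b),
          list(function(g) g[seq_len(na), , drop = FALSE],
               function(g) g[-seq_len(na), , drop = FALSE]))
}

# Row selection; backward scatter-adds (duplicated indices accumulate).
ad_gather <- function(x, idx) {
  xv <- ad_value(x)
  idx <- as.integer(idx)
  ad_push(x$tape, xv[idx, , drop = FALSE], list(x),
          list(function(g) {
            gz <- rowsum(g, group = idx)
            out <- matrix(0, nrow(xv), ncol(xv))
            out[as.integer(rownames(gz)), ] <- gz
            out
          }))
}

# Per-group row means: rows of x are grouped by `group` (1..n_groups),
# output row k is the mean of group k's rows. Used to read out a batch of
# disjoint molecular graphs in one pass.
ad_groupmean <- function(x, group, n_groups) {
  xv <- ad_value(x)
  group <- as.integer(group)
  cnt <- tabulate(group, nbins = n_groups)
  if (any(cnt == 0)) stopf("empty group in segmented mean")
  gm <- rowsum(xv, group = group) / cnt
  dimnames(gm) <- NULL
  ad_push(x$tape, gm, list(x),
          list(function(g) (g / cnt)[group, , drop = FALSE]))
}

# Column means as a 1 x d row (mean over rows).
ad_colmean <- function(x) {
  xv <- ad_value(x)
  m <- nrow(xv)
  ad_push(x$tape, matrix(.colMeans(xv, m, ncol(xv)), 1), list(x),
          list(function(g) matrix(1, m, 1) %*% g / m))
}

# Row-wise LayerNorm with learnable gain/offset (1 x d each).
ad_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  xv <- ad_value(x); gv <- as.numeric(ad_value(gamma)); bv <- as.numeric(ad_value(beta))
  d <- ncol(xv)
  n <- nrow(xv)
  mu <- .rowMeans(xv, n, d)
  xc <- xv - mu
  va <- .rowMeans(xc * xc, n, d)
  inv <- 1 / sqrt(va + eps)
  xhat <- xc * inv
  y <- xhat * rep(gv, each = n) + rep(bv, each = n)
  ad_push(x$tape, y, list(x, gamma, beta),
          list(function(g) {
            gy <- g * rep(gv, each = n)
            m1 <- .rowMeans(gy, n, d)
            m2 <- .rowMeans(gy * xhat, n, d)
            inv * (gy - m1 - xhat * m2)
          },
          function(g) matrix(.colSums(g * xhat, n, d), 1),
          function(g) matrix(.colSums(g, n, d), 1)))
}

# Inverted dropout with a caller-supplied binary keep mask.
ad_dropout <- function(x, mask, rate) {
  scale <- 1 / (1 - rate)
  ad_push(x$tape, ad_value(x) * mask * scale, list(x),
          list(function(g) g * mask * scale))
}

ad_stopgrad <- function(x) {
  n <- ad_push(x$tape, ad_value(x), list(x), list(function(g) NULL))
  n$tape$ng[n$id] <- FALSE
  n
}

# InfoNCE over matched rows: anchor teacher row i against all student rows.
# value = -1/N sum_i log softmax_j(T_i . S_j / tau)[j = i]
ad_infonce <- function(xt, xs, tau) {
  tv <- ad_value(xt); sv <- ad_value(xs)
  n <- nrow(tv)
  s <- tcrossprod(tv, sv) / tau
  mx <- apply(s, 1, max)
  lse <- mx + log(rowSums(exp(s - mx)))
  val <- mean(lse - diag(s))
  p <- exp(s - lse)  # row softmax
  ad_push(xt$tape, matrix(val, 1, 1), list(xt, xs),
          list(function(g) ((p - diag(n)) * (as.numeric(g) / (n * tau))) %*% sv,
               function(g) crossprod((p - diag(n)) * (as.numeric(g) / (n * tau)), tv)))
}

# Mean binary cross-entropy on logits (numerically stable closed form);
# matches bce_loss(plogis(z), y) away from the clipping region.
ad_bce_logits <- function(z, y) {
  zv <- as.numeric(ad_value(z))
  n <- length(zv)
  val <- mean(pmax(zv, 0) - zv * y + log1p(exp(-abs(zv))))
  p <- stats::plogis(zv)
  ad_push(z$tape, matrix(val, 1, 1), list(z),
          list(function(g) matrix((p - y) * (as.numeric(g) / n), ncol = 1)))
}

# a + lambda * b for scalar nodes
ad_axpy <- function(a, b, lambda) {
  ad_push(a$tape, ad_value(a) + lambda * ad_value(b), list(a, b),
          list(function(g) g, function(g) g * lambda))
}

# Convenience layers -------------------------------------------------------

ad_linear <- function(x, w, b) ad_bias(ad_matmul(x, w), b)

# 2-layer perceptron: Linear -> ReLU -> Linear
ad_mlp <- function(x, w1, b1, w2, b2) {
  ad_linear(ad_relu(ad_linear(x, w1, b1)), w2, b2)
}

# Fixed-operator multiply A %*% X where A is a constant (possibly sparse
# Matrix) propagation operator; gradient flows only into X.
ad_spmm <- function(A, x) {
  xv <- ad_value(x)
  ad_push(x$tape, as.matrix(A %*% xv), list(x),
          list(function(g) as.matrix(Matrix::crossprod(A, g))))
}
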