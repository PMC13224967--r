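# Hypergraph convolutional teacher (HGNN). One layer computes
#   X(l+1) = sigma(Dv^-1/2 H W De^-1 H' Dv^-1/2 X(l) Theta(l))
# where H is the incidence matrix, Dv/De the node/hyperedge degree matrices
# and W a diagonal matrix of hyperedge weights (identity by default).

#' One hypergraph convolution layer
#'
#' Evaluates the degree-normalized hypergraph convolution by sparse
#' edge-wise aggregation over the incidence list (gather to hyperedges,
#' weight by `w / De`, scatter back to nodes), which matches the dense
#' matrix product exactly.
#'
#' @param x `n_nodes x d` node feature matrix.
#' @param hg a `hypergraph` (see [build_cpi_hypergraph()]).
#' @param theta `d x d_out` layer weight.
#' @param w optional hyperedge weight vector (nonnegative; default all 1).
#' @param sigma `"relu"` or `"identity"`.
#' @return `n_nodes x d_out` matrix.
#' @export
hgnn_layer <- function(x, hg, theta, w = NULL, sigma = "relu") {
  x <- as.matrix(x)
  if (nrow(x) != hg$n_nodes) {
    stopf("x has %d rows but hypergraph has %d nodes", nrow(x), hg$n_nodes)
  }
  if (ncol(x) != nrow(theta)) {
    stopf("x width %d does not match theta rows %d", ncol(x), nrow(theta))
  }
  if (is.null(w)) w <- rep(1, length(hg$edges))
  if (any(w < 0)) stopf("hyperedge weights must be nonnegative")
  dv <- as.numeric(hg$H %*% w)
  de <- colSums(hg$H)
  if (any(dv <= 0)) stopf("node with zero hypergraph degree; cannot normalize")

  inc_e <- rep(seq_along(hg$edges), vapply(hg$edges, function(e) length(unique(e)), integer(1)))
  inc_v <- unlist(lapply(hg$edges, unique))

  xs <- x / sqrt(dv)
  ef <- rowsum(xs[inc_v, , drop = FALSE], group = inc_e)       # H' Dv^-1/2 X
  ef <- ef[order(as.integer(rownames(ef))), , drop = FALSE]
  ef <- ef * (w / de)                                          # W De^-1 ...
  nf <- rowsum(ef[inc_e, , drop = FALSE], group = inc_v)       # H ...
  out <- matrix(0, hg$n_nodes, ncol(x))
  out[as.integer(rownames(nf)), ] <- nf
  out <- (out / sqrt(dv)) %*% theta
  if (sigma == "relu") pmax(out, 0) else out
}

#' Teacher forward pass
#'
#' Stacks [hgnn_layer()] applications over the node feature matrix obtained
#' by concatenating compound and protein features (compounds first, matching
#' the merged hypergraph's index offset).
#'
#' @param x0 `n_nodes x d` initial node features.
#' @param hg a `hypergraph`.
#' @param state list with `layers` (list of `theta` matrices), optional `w`
#'   (hyperedge weights) and `sigma` (default `"relu"`).
#' @return the high-order node representation matrix.
#' @export
teacher_forward <- function(x0, hg, state) {
  x <- as.matrix(x0)
  sigma <- state$sigma %||% "relu"
  for (theta in state$layers) {
    x <- hgnn_layer(x, hg, theta, w = state$w, sigma = sigma)
  }
  x
}
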