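# Low-order student: residual GCN over the bipartite CPI graph, plus the
# pair predictor head. Message-passing edges come from TRAIN-role positive
# interactions only; unseen (inductive) entities are isolated nodes that
# update through their self-loops alone, which is what makes inference on
# unseen compound-protein pairs well-defined.

#' Build the bipartite CPI message-passing graph
#'
#' Returns the symmetric-normalized adjacency (with self-loops on every
#' node) of the unified compound+protein node set, with edges from positive
#' training interactions only. Proteins occupy rows
#' `n_compounds+1 .. n_compounds+n_proteins`.
#'
#' @param train an [interaction_table()] of training pairs (only rows with
#'   `label == 1` become edges).
#' @param n_compounds,n_proteins entity counts.
#' @return list with `A` (normalized dense adjacency) and `edges`
#'   (2-column 1-based unified edge matrix).
#' @export
bipartite_cpi_graph <- function(train, n_compounds, n_proteins) {
  pos <- train$pairs[train$pairs$label == 1, , drop = FALSE]
  edges <- cbind(pos$compound + 1L, n_compounds + pos$protein + 1L)
  edges <- matrix(as.integer(edges), ncol = 2)
  n <- n_compounds + n_proteins
  list(A = normalized_adjacency(n, edges), edges = edges,
       n_compounds = n_compounds, n_proteins = n_proteins)
}

# `a` is the fixed normalized bipartite operator (base or sparse Matrix)
tb_student_layer <- function(x, a, pn, l, bypass_ln = FALSE) {
  h <- ad_spmm(a, ad_matmul(x, pn[[paste0("stu", l, "_gcn_W")]]))
  h <- ad_mlp(h, pn[[paste0("stu", l, "_mlp_W1")]], pn[[paste0("stu", l, "_mlp_b1")]],
              pn[[paste0("stu", l, "_mlp_W2")]], pn[[paste0("stu", l, "_mlp_b2")]])
  tb_layernorm(ad_add(h, x), pn[[paste0("stu", l, "_ln_g")]],
               pn[[paste0("stu", l, "_ln_b")]], bypass_ln)
}

#' One student layer
#'
#' `X(l+1) = LN(MLP(GCN(X(l), G)) + X(l))`: graph convolution, 2-layer MLP,
#' residual addition of the previous layer, LayerNorm outermost. Note the
#' operator order intentionally differs from the molecular graph encoder
#' (there the MLP is outside the residual; here it is inside).
#'
#' @param x `n_nodes x d` node features.
#' @param g a [bipartite_cpi_graph()] (or any list with normalized adjacency
#'   `A`).
#' @param params named weight list holding `stu<l>_gcn_W`, `stu<l>_mlp_*`,
#'   `stu<l>_ln_*`.
#' @param l layer index into `params` (default 1).
#' @param bypass_ln skip LayerNorm (diagnostic mode).
#' @return updated `n_nodes x d` matrix.
#' @export
student_layer <- function(x, g, params, l = 1, bypass_ln = FALSE) {
  x <- as.matrix(x)
  if (nrow(x) != nrow(g$A)) stopf("x has %d rows but graph has %d nodes",
                                  nrow(x), nrow(g$A))
  if (ncol(x) != nrow(params[[paste0("stu", l, "_gcn_W")]])) {
    stopf("x width does not match student layer %d weights", l)
  }
  tape <- ad_tape()
  pn <- params_to_nodes(tape, params)
  ad_value(tb_student_layer(ad_const(tape, x), g$A, pn, l, bypass_ln))
}

#' Student forward pass
#'
#' Stacks `n_layers` student layers over the initial node features (the
#' transformed compound features followed by the transformed protein
#' features). Isolated nodes receive well-defined outputs through their
#' self-loops.
#'
#' @param x0 `n_nodes x d` initial node features.
#' @param g a [bipartite_cpi_graph()].
#' @param params weight list covering layers `1..n_layers`.
#' @param n_layers number of layers (default 4).
#' @return `n_nodes x d` student representation matrix.
#' @export
student_forward <- function(x0, g, params, n_layers = 4) {
  tape <- ad_tape()
  pn <- params_to_nodes(tape, params)
  x <- ad_const(tape, as.matrix(x0))
  for (l in seq_len(n_layers)) x <- tb_student_layer(x, g$A, pn, l)
  ad_value(x)
}

tb_predict_pairs <- function(xstu, xc_prime, xp_prime, c_idx, p_idx,
                             n_compounds, pn, bypass_ln = FALSE) {
  cs <- ad_gather(xstu, c_idx + 1L)
  ps <- ad_gather(xstu, n_compounds + p_idx + 1L)
  cp <- ad_gather(xc_prime, c_idx + 1L)
  pp <- ad_gather(xp_prime, p_idx + 1L)
  cside <- tb_layernorm(ad_add(cs, cp), pn$pred_ln_c_g, pn$pred_ln_c_b, bypass_ln)
  pside <- tb_layernorm(ad_add(ps, pp), pn$pred_ln_p_g, pn$pred_ln_p_b, bypass_ln)
  ad_mlp(ad_cbind(cside, pside), pn$pred_W1, pn$pred_b1, pn$pred_W2, pn$pred_b2)
}

#' Score compound-protein pairs
#'
#' `y = MLP(LN(x_c_s + x_c') || LN(x_p_s + x_p'))`: the raw transformed
#' features re-enter as residuals on top of the student outputs, each side
#' is LayerNormed, the sides are concatenated and a 2-layer MLP produces a
#' logit mapped through a sigmoid to an interaction probability.
#'
#' @param x_c_s,x_c_prime `n x d` compound-side student output and
#'   transformed features, row-aligned with the pairs.
#' @param x_p_s,x_p_prime protein-side analogues.
#' @param params weight list holding `pred_*`.
#' @param bypass_ln skip LayerNorm (diagnostic mode).
#' @return numeric vector of probabilities in (0, 1).
#' @export
predict_pair <- function(x_c_s, x_c_prime, x_p_s, x_p_prime, params,
                         bypass_ln = FALSE) {
  mats <- lapply(list(x_c_s, x_c_prime, x_p_s, x_p_prime), as.matrix)
  d <- unique(vapply(mats, ncol, integer(1)))
  if (length(d) != 1) stopf("all four inputs must share one feature width")
  n <- unique(vapply(mats, nrow, integer(1)))
  if (length(n) != 1) stopf("all four inputs must share one row count")
  tape <- ad_tape()
  pn <- params_to_nodes(tape, params)
  xstu <- ad_const(tape, rbind(mats[[1]], mats[[3]]))
  logits <- tb_predict_pairs(xstu, ad_const(tape, mats[[2]]),
                             ad_const(tape, mats[[4]]),
                             seq_len(n) - 1L, seq_len(n) - 1L, n, pn, bypass_ln)
  as.numeric(stats::plogis(ad_value(logits)))
}
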