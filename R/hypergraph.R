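# Feature-similarity hypergraph over compounds and proteins.
#
# Construction is cluster-guided: the reference side is k-means clustered
# (k1 clusters); each query entity opens a hyperedge containing itself,
# locates its single nearest cluster center by cosine distance, and inserts
# the k2 reference members of that cluster closest to it in cosine distance.
# Compound-centered and protein-centered sub-hypergraphs are then merged on
# a unified node index (proteins offset by the number of compounds).

#' Cosine distance between two vectors
#'
#' `1 - u.v / (||u|| ||v||)`, in `[0, 2]`.
#'
#' @param u,v numeric vectors with positive norm.
#' @return scalar distance.
#' @export
cosine_distance <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stopf("cosine distance undefined for zero vector")
  1 - sum(u * v) / (nu * nv)
}

# rows of a vs rows of b -> distance matrix; rows with zero norm are an error
cosine_distance_rows <- function(a, b) {
  na <- sqrt(rowSums(a^2)); nb <- sqrt(rowSums(b^2))
  if (any(na == 0) || any(nb == 0)) {
    stopf("cosine distance undefined for all-zero feature row")
  }
  1 - tcrossprod(a / na, b / nb)
}

#' Seeded k-means clustering of reference features
#'
#' @param x feature matrix.
#' @param k number of clusters (`k <= nrow(x)`).
#' @param seed integer seed.
#' @return list with `cluster` (assignment vector) and `centers`.
#' @export
hg_cluster <- function(x, k, seed) {
  if (!is_count(k) || k < 1) stopf("k1 must be a positive integer")
  if (k > nrow(x)) stopf("k1=%d exceeds number of reference rows (%d)", k, nrow(x))
  if (k == nrow(x)) {
    # trivial partition (kmeans requires k < n when restarting)
    return(list(cluster = seq_len(nrow(x)), centers = as.matrix(x)))
  }
  km <- with_seed(seed, stats::kmeans(x, centers = k, nstart = 10, iter.max = 50))
  list(cluster = km$cluster, centers = km$centers)
}

#' Build one entity-centered sub-hypergraph
#'
#' For each query row: start a hyperedge with the query itself, pick the
#' nearest reference cluster center by cosine distance (ties to the lowest
#' cluster index), and insert the `k2` members of that cluster with the
#' smallest cosine distance to the query (ties to the lowest node index;
#' clusters smaller than `k2` contribute all their members).
#'
#' @param x_query query-side feature matrix (one hyperedge per row).
#' @param x_ref reference-side feature matrix.
#' @param k1 number of reference clusters (`k1 <= nrow(x_ref)`).
#' @param k2 neighbors sampled per hyperedge (>= 1).
#' @param seed integer seed for the clustering.
#' @param clustering optional precomputed [hg_cluster()] result.
#' @return list of hyperedge records `list(center = i, members = ref ids)`,
#'   in query-row order.
#' @export
construct_sub_hypergraph <- function(x_query, x_ref, k1, k2, seed = 1,
                                     clustering = NULL) {
  x_query <- as.matrix(x_query); x_ref <- as.matrix(x_ref)
  assert_finite_matrix(x_query, "x_query")
  assert_finite_matrix(x_ref, "x_ref")
  if (!is_count(k2) || k2 < 1) stopf("k2 must be a positive integer")
  if (is.null(clustering)) clustering <- hg_cluster(x_ref, k1, seed)
  centers <- as.matrix(clustering$centers)
  cnorm <- sqrt(rowSums(centers^2))
  if (any(cnorm == 0)) stopf("cluster center with zero norm; features degenerate")
  d_center <- cosine_distance_rows(x_query, centers)
  d_all <- cosine_distance_rows(x_query, x_ref)

  lapply(seq_len(nrow(x_query)), function(i) {
    nearest <- which.min(d_center[i, ])  # ties -> lowest cluster index
    members <- which(clustering$cluster == nearest)
    ord <- order(d_all[i, members], members)  # ties -> lowest node index
    take <- members[ord[seq_len(min(k2, length(members)))]]
    list(center = i, members = as.integer(take))
  })
}

#' Merge compound- and protein-centered sub-hypergraphs
#'
#' Protein node indices are offset by `n_compounds` so both sides share one
#' index space; the merged edge list is the compound-centered edges followed
#' by the protein-centered edges. Duplicate hyperedges are kept: each
#' occurrence contributes to the degree matrices.
#'
#' @param hc compound-centered hyperedges from [construct_sub_hypergraph()]
#'   (centers are compound indices, members protein indices).
#' @param hp protein-centered hyperedges (centers are protein indices,
#'   members compound indices); may be an empty list.
#' @param n_compounds,n_proteins entity counts.
#' @return an object of class `hypergraph`: `n_nodes`, `edges` (list of
#'   1-based unified node-index vectors), incidence matrix `H`
#'   (`n_nodes x n_edges`), node/hyperedge degree vectors `Dv`, `De`.
#' @export
merge_hypergraphs <- function(hc, hp, n_compounds, n_proteins) {
  n_nodes <- n_compounds + n_proteins
  ec <- lapply(hc, function(e) c(e$center, e$members + n_compounds))
  ep <- lapply(hp, function(e) c(e$center + n_compounds, e$members))
  edges <- c(ec, ep)
  if (length(edges) == 0) stopf("cannot merge two empty sub-hypergraphs")
  if (max(unlist(edges)) > n_nodes || min(unlist(edges)) < 1) {
    stopf("hyperedge references node outside 1..%d", n_nodes)
  }
  H <- matrix(0, n_nodes, length(edges))
  for (j in seq_along(edges)) H[unique(edges[[j]]), j] <- 1
  structure(list(n_nodes = n_nodes, n_compounds = n_compounds,
                 n_proteins = n_proteins, edges = edges, H = H,
                 Dv = rowSums(H), De = colSums(H)),
            class = "hypergraph")
}

#' @export
print.hypergraph <- function(x, ...) {
  cat(sprintf("<hypergraph> %d nodes (%d compounds + %d proteins), %d hyperedges\n",
              x$n_nodes, x$n_compounds, x$n_proteins, length(x$edges)))
  invisible(x)
}

#' Construct the merged compound-protein hypergraph
#'
#' Runs [construct_sub_hypergraph()] in both directions (compounds querying
#' protein clusters and vice versa) and merges the results.
#'
#' @param x_c,x_p compound and protein feature matrices.
#' @param k1 clusters per reference side (default 25).
#' @param k2 neighbors per hyperedge (default 3).
#' @param seed integer seed.
#' @return a `hypergraph` with `nrow(x_c) + nrow(x_p)` hyperedges.
#' @export
build_cpi_hypergraph <- function(x_c, x_p, k1 = 25, k2 = 3, seed = 1) {
  hc <- construct_sub_hypergraph(x_c, x_p, k1, k2, derive_seed(seed, "hg-c"))
  hp <- construct_sub_hypergraph(x_p, x_c, k1, k2, derive_seed(seed, "hg-p"))
  hg <- merge_hypergraphs(hc, hp, nrow(x_c), nrow(x_p))
  hg$k1 <- k1; hg$k2 <- k2; hg$seed <- seed
  hg
}

#' Export / import a hypergraph as text
#'
#' Writes a two-column TSV of `(edge_id, node_id)` incidences plus a JSON
#' header `<path>.json` with `n_nodes`, `n_compounds`, `n_proteins`,
#' `n_edges`, `k1`, `k2`, `seed`.
#'
#' @param hg a `hypergraph`.
#' @param path output TSV path.
#' @return `path` (write) or the reconstructed `hypergraph` (read).
#' @export
write_hypergraph <- function(hg, path) {
  df <- data.frame(
    edge_id = rep(seq_along(hg$edges), lengths(hg$edges)),
    node_id = unlist(hg$edges))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(n_nodes = hg$n_nodes, n_compounds = hg$n_compounds,
                            n_proteins = hg$n_proteins,
                            n_edges = length(hg$edges),
                            k1 = hg$k1 %||% NA, k2 = hg$k2 %||% NA,
                            seed = hg$seed %||% NA),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_hypergraph
#' @export
read_hypergraph <- function(path) {
  hdr <- jsonlite::read_json(paste0(path, ".json"))
  df <- utils::read.delim(path)
  edges <- split(as.integer(df$node_id), df$edge_id)
  edges <- edges[order(as.integer(names(edges)))]
  names(edges) <- NULL
  H <- matrix(0, hdr$n_nodes, length(edges))
  for (j in seq_along(edges)) H[unique(edges[[j]]), j] <- 1
  structure(list(n_nodes = hdr$n_nodes, n_compounds = hdr$n_compounds,
                 n_proteins = hdr$n_proteins, edges = edges, H = H,
                 Dv = rowSums(H), De = colSums(H),
                 k1 = hdr$k1, k2 = hdr$k2, seed = hdr$seed),
            class = "hypergraph")
}

# Dense hypergraph convolution operator Dv^-1/2 H W De^-1 H' Dv^-1/2 used by
# the trainer (the structure is fixed during training, so the operator is
# precomputed once).
hypergraph_operator <- function(hg, w = NULL) {
  if (is.null(w)) w <- rep(1, length(hg$edges))
  dv <- as.numeric(hg$H %*% w)
  de <- colSums(hg$H)
  if (any(dv <= 0)) stopf("node with zero hypergraph degree; cannot normalize")
  if (any(de <= 0)) stopf("empty hyperedge; cannot normalize")
  hv <- hg$H / sqrt(dv)          # Dv^-1/2 H (row scaling)
  hv %*% (t(hv) * (w / de))      # ... W De^-1 H' Dv^-1/2
}
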