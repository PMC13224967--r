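# Synthetic CPI datasets with planted archetype (cluster) structure.
#
# Each side of the bipartite system has a small number of latent archetypes;
# entity feature vectors are drawn around unit-norm archetype centroids, and
# interaction labels follow an archetype-compatibility matrix. Feature-similar
# entity groups therefore genuinely share binding partners -- the high-order
# signal the hypergraph teacher is designed to exploit -- while every entity
# also carries a text payload (SMILES / amino-acid sequence) so readers and
# featurizers can be exercised end to end.

# curated short valid SMILES, grouped by chemotype so archetypes can be
# tagged with structurally coherent molecules
SYNTH_SMILES <- c(
  "CCO", "CCN", "CCC", "CC(C)O", "CCCl",
  "c1ccccc1", "Cc1ccccc1", "c1ccncc1", "c1ccsc1", "c1ccoc1",
  "CC(=O)O", "CC(=O)N", "CCOC(C)=O", "CC(=O)C", "OCC(=O)O",
  "C1CCCCC1", "C1CCNCC1", "C1CCOC1", "C1CCCC1", "C1CCNC1")

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Specification of a synthetic CPI dataset
#'
#' @param n_compounds,n_proteins entity counts.
#' @param a_c,a_p archetype counts per side.
#' @param feat_dim feature dimensionality.
#' @param noise_sd per-coordinate Gaussian spread around the archetype
#'   centroid (centroids have unit norm).
#' @param compat `a_c x a_p` matrix of interaction probabilities in `[0, 1]`;
#'   default is block-diagonal-dominant (0.97 within matched archetypes,
#'   0.01 elsewhere).
#' @param n_pairs number of labeled pairs to sample (without replacement
#'   over the compound-protein grid).
#' @param pos_neg_balance target fraction of positive pairs.
#' @param seed integer seed.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_compounds = 200, n_proteins = 100,
                           a_c = 4, a_p = 4, feat_dim = 32, noise_sd = 0.3,
                           compat = NULL, n_pairs = 2000,
                           pos_neg_balance = 0.5, seed = 1) {
  if (is.null(compat)) {
    # contrast chosen so that label noise keeps the Bayes-oracle AUROC
    # ceiling above 0.95 even on small per-role pair subsets
    compat <- matrix(0.01, a_c, a_p)
    for (i in seq_len(min(a_c, a_p))) compat[i, i] <- 0.97
  }
  compat <- as.matrix(compat)
  if (nrow(compat) != a_c || ncol(compat) != a_p) {
    stopf("compat must be %d x %d", a_c, a_p)
  }
  if (any(compat < 0 | compat > 1)) stopf("compat entries must lie in [0,1]")
  if (noise_sd < 0) stopf("noise_sd must be nonnegative")
  for (v in c(n_compounds, n_proteins, a_c, a_p, feat_dim, n_pairs)) {
    if (!is_count(v)) stopf("counts in a synthetic spec must be positive integers")
  }
  if (pos_neg_balance < 0 || pos_neg_balance > 1) {
    stopf("pos_neg_balance must lie in [0,1]")
  }
  if (all(compat == 0) && pos_neg_balance > 0) {
    stopf("compat is all-zero: cannot reach a positive pair balance")
  }
  structure(list(n_compounds = n_compounds, n_proteins = n_proteins,
                 a_c = a_c, a_p = a_p, feat_dim = feat_dim,
                 noise_sd = noise_sd, compat = compat, n_pairs = n_pairs,
                 pos_neg_balance = pos_neg_balance, seed = seed),
            class = "synthetic_spec")
}

unit_rows <- function(n, d) {
  m <- matrix(stats::rnorm(n * d), n, d)
  m / sqrt(rowSums(m^2))
}

#' Generate a synthetic CPI dataset
#'
#' Draws unit-norm archetype centroids once per side, assigns entities to
#' archetypes round-robin, sets each entity's features to its centroid plus
#' `N(0, noise_sd^2)` noise, and samples labeled pairs without replacement:
#' a candidate pair is labeled 1 with probability
#' `compat[arch(c), arch(p)]` and accepted into the positive or negative
#' pool until the `pos_neg_balance` quotas are met. Compound payloads are
#' short valid SMILES drawn from a curated archetype-tagged list; protein
#' payloads are random 50-mers. Fully reproducible from `spec$seed`.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `compounds`, `proteins` ([entity_table()]s),
#'   `interactions` ([interaction_table()], role `"all"`),
#'   `compound_features`, `protein_features`, `compound_arch`,
#'   `protein_arch` (1-based archetype labels), `centroids`, `spec`.
#' @export
generate_cpi_data <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  seed <- spec$seed

  cen_c <- with_seed(derive_seed(seed, "cen-c"), unit_rows(spec$a_c, spec$feat_dim))
  cen_p <- with_seed(derive_seed(seed, "cen-p"), unit_rows(spec$a_p, spec$feat_dim))

  arch_c <- rep_len(seq_len(spec$a_c), spec$n_compounds)
  arch_p <- rep_len(seq_len(spec$a_p), spec$n_proteins)

  xc <- cen_c[arch_c, , drop = FALSE] +
    with_seed(derive_seed(seed, "noise-c"),
              matrix(stats::rnorm(spec$n_compounds * spec$feat_dim, sd = spec$noise_sd),
                     spec$n_compounds))
  xp <- cen_p[arch_p, , drop = FALSE] +
    with_seed(derive_seed(seed, "noise-p"),
              matrix(stats::rnorm(spec$n_proteins * spec$feat_dim, sd = spec$noise_sd),
                     spec$n_proteins))

  # archetype-tagged payloads: each compound archetype owns a slice of the
  # curated SMILES list; proteins get random 50-mers
  groups <- split(SYNTH_SMILES, rep_len(seq_len(spec$a_c), length(SYNTH_SMILES)))
  pay_c <- with_seed(derive_seed(seed, "pay-c"), vapply(arch_c, function(a) {
    g <- groups[[((a - 1) %% length(groups)) + 1]]
    g[sample.int(length(g), 1)]
  }, character(1)))
  pay_p <- with_seed(derive_seed(seed, "pay-p"), vapply(seq_len(spec$n_proteins), function(i) {
    paste(sample(AA_ALPHABET, 50, replace = TRUE), collapse = "")
  }, character(1)))

  compounds <- entity_table(sprintf("c%04d", seq_len(spec$n_compounds)), pay_c, "compound")
  proteins <- entity_table(sprintf("p%04d", seq_len(spec$n_proteins)), pay_p, "protein")

  n_grid <- spec$n_compounds * spec$n_proteins
  n_pairs <- min(spec$n_pairs, n_grid)
  want_pos <- round(spec$pos_neg_balance * n_pairs)
  want_neg <- n_pairs - want_pos

  pairs <- with_seed(derive_seed(seed, "pairs"), {
    perm <- sample.int(n_grid)
    ci <- integer(0); pi_ <- integer(0); lab <- numeric(0)
    got_pos <- 0L; got_neg <- 0L
    for (cell in perm) {
      if (got_pos >= want_pos && got_neg >= want_neg) break
      c_i <- ((cell - 1L) %% spec$n_compounds) + 1L
      p_i <- ((cell - 1L) %/% spec$n_compounds) + 1L
      y <- stats::rbinom(1, 1, spec$compat[arch_c[c_i], arch_p[p_i]])
      if (y == 1 && got_pos < want_pos) {
        got_pos <- got_pos + 1L
      } else if (y == 0 && got_neg < want_neg) {
        got_neg <- got_neg + 1L
      } else {
        next
      }
      ci <- c(ci, c_i); pi_ <- c(pi_, p_i); lab <- c(lab, y)
    }
    list(ci = ci, pi = pi_, lab = lab)
  })

  interactions <- interaction_table(pairs$ci - 1L, pairs$pi - 1L, pairs$lab,
                                    spec$n_compounds, spec$n_proteins, role = "all")
  list(compounds = compounds, proteins = proteins, interactions = interactions,
       compound_features = xc, protein_features = xp,
       compound_arch = arch_c, protein_arch = arch_p,
       centroids = list(compound = cen_c, protein = cen_p), spec = spec)
}

#' Fixed planted acceptance benchmark
#'
#' A reproducible planted-archetype dataset (400 compounds x 200 proteins,
#' 4 x 4 block-diagonal-dominant compatibility, 32-dimensional features,
#' `noise_sd = 0.3`, 6000 balanced pairs) together with its cluster-disjoint
#' inductive split (split on the raw synthetic features, `k_split = 10`).
#'
#' @param seed integer seed.
#' @return list with `data` (see [generate_cpi_data()]) and `split`
#'   (an [inductive_cluster_split()] result).
#' @export
planted_benchmark <- function(seed = 7) {
  spec <- synthetic_spec(n_compounds = 400, n_proteins = 200,
                         a_c = 4, a_p = 4, feat_dim = 32, noise_sd = 0.3,
                         n_pairs = 6000, pos_neg_balance = 0.5, seed = seed)
  data <- generate_cpi_data(spec)
  split <- inductive_cluster_split(data$compound_features, data$protein_features,
                                   data$interactions, k_split = 10,
                                   seed = derive_seed(seed, "bench-split"))
  list(data = data, split = split)
}

#' Bayes-oracle scores for sampled pairs
#'
#' Looks up the true archetype-compatibility probability of each pair -- the
#' best score any model could assign -- providing a sanity ceiling for
#' learned models on planted data.
#'
#' @param data a [generate_cpi_data()] result.
#' @param interactions an [interaction_table()] (e.g. a split role).
#' @return numeric vector of true interaction probabilities.
#' @export
bayes_oracle_scores <- function(data, interactions) {
  pr <- interactions$pairs
  data$spec$compat[cbind(data$compound_arch[pr$compound + 1L],
                         data$protein_arch[pr$protein + 1L])]
}

#' Write / read a dense feature matrix as plain text
#'
#' Whitespace-delimited numeric rows preceded by a one-line header
#' `n dim`.
#'
#' @param mat numeric matrix.
#' @param path file path.
#' @return `path` (write) or the matrix (read).
#' @export
write_feature_matrix <- function(mat, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(nrow(mat), ncol(mat)), con)
  utils::write.table(mat, con, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  hdr <- as.integer(strsplit(trimws(readLines(path, n = 1)), "[[:space:]]+")[[1]])
  m <- as.matrix(utils::read.table(path, skip = 1))
  if (nrow(m) != hdr[1] || ncol(m) != hdr[2]) {
    stopf("%s: header says %d x %d but body is %d x %d", path,
          hdr[1], hdr[2], nrow(m), ncol(m))
  }
  dimnames(m) <- NULL
  m
}
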