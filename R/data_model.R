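# Entity and interaction tables, TSV readers/writers, and the
# cluster-disjoint inductive splitter.

#' Construct an entity table
#'
#' An entity table holds one side of a CPI dataset: compounds (with SMILES
#' payloads) or proteins (with amino-acid sequence payloads), each entity
#' assigned a dense 0-based integer index in input order.
#'
#' @param ids character vector of unique entity identifiers.
#' @param payloads character vector of payload strings (SMILES or sequences),
#'   one per id.
#' @param kind `"compound"` or `"protein"`.
#' @return an object of class `entity_table` with fields `kind`, `ids`,
#'   `payloads`, `index` (named integer vector, 0-based) and `n`.
#' @export
#' @examples
#' entity_table(c("c1", "c2"), c("CCO", "c1ccccc1"), "compound")
entity_table <- function(ids, payloads, kind = c("compound", "protein")) {
  kind <- match.arg(kind)
  ids <- as.character(ids)
  payloads <- as.character(payloads)
  if (length(ids) == 0) stopf("entity table must contain at least one %s", kind)
  if (length(ids) != length(payloads)) {
    stopf("ids and payloads differ in length (%d vs %d)", length(ids), length(payloads))
  }
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) stopf("duplicate id %s", dup[1])
  if (any(!nzchar(payloads))) {
    stopf("empty payload for id %s", ids[which(!nzchar(payloads))[1]])
  }
  idx <- seq_along(ids) - 1L
  names(idx) <- ids
  structure(list(kind = kind, ids = ids, payloads = payloads,
                 index = idx, n = length(ids)),
            class = "entity_table")
}

#' @export
print.entity_table <- function(x, ...) {
  cat(sprintf("<entity_table> %d %ss (e.g. %s)\n", x$n, x$kind,
              paste(utils::head(x$ids, 3), collapse = ", ")))
  invisible(x)
}

#' Read an entity table from a TSV file
#'
#' The file must be tab-separated with header columns `id` and `payload`.
#' SMILES validity is not checked here; it is deferred to featurization.
#'
#' @param path file path.
#' @param kind `"compound"` or `"protein"`.
#' @return an [entity_table()].
#' @export
read_entities <- function(path, kind = c("compound", "protein")) {
  kind <- match.arg(kind)
  df <- utils::read.delim(path, colClasses = "character", quote = "")
  if (!all(c("id", "payload") %in% names(df))) {
    stopf("%s: expected TSV header columns 'id' and 'payload'", path)
  }
  if (nrow(df) == 0) stopf("%s: empty entity file", path)
  entity_table(df$id, df$payload, kind)
}

#' Write an entity table as TSV
#'
#' @param entities an [entity_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_entities <- function(entities, path) {
  df <- data.frame(id = entities$ids, payload = entities$payloads)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct an interaction table
#'
#' Pairs are stored as 0-based entity indices with binary activity labels.
#'
#' @param compound_idx,protein_idx integer vectors of 0-based entity indices.
#' @param label numeric vector of labels in `{0, 1}`.
#' @param n_compounds,n_proteins entity counts used for bounds checking.
#' @param role one of `"all"`, `"train"`, `"val"`, `"test"`.
#' @return an object of class `interaction_table` with a data frame `pairs`
#'   (columns `compound`, `protein`, `label`) and fields `role`, `n`.
#' @export
interaction_table <- function(compound_idx, protein_idx, label,
                              n_compounds, n_proteins,
                              role = c("all", "train", "val", "test")) {
  role <- match.arg(role)
  ci <- as.integer(compound_idx)
  pi_ <- as.integer(protein_idx)
  lb <- as.numeric(label)
  if (length(ci) != length(pi_) || length(ci) != length(lb)) {
    stopf("pair columns differ in length")
  }
  if (any(ci < 0 | ci >= n_compounds)) stopf("compound index out of bounds")
  if (any(pi_ < 0 | pi_ >= n_proteins)) stopf("protein index out of bounds")
  if (!all(lb %in% c(0, 1))) {
    stopf("label outside {0,1}: %s", format(lb[!(lb %in% c(0, 1))][1]))
  }
  key <- paste(ci, pi_)
  if (anyDuplicated(key)) {
    k <- strsplit(key[duplicated(key)][1], " ")[[1]]
    stopf("duplicate pair (compound %s, protein %s) within role '%s'", k[1], k[2], role)
  }
  structure(list(pairs = data.frame(compound = ci, protein = pi_, label = lb),
                 role = role, n = length(ci),
                 n_compounds = n_compounds, n_proteins = n_proteins),
            class = "interaction_table")
}

#' @export
print.interaction_table <- function(x, ...) {
  cat(sprintf("<interaction_table> role=%s, %d pairs (%d active)\n",
              x$role, x$n, sum(x$pairs$label == 1)))
  invisible(x)
}

#' Read interaction triples from TSV
#'
#' The file must have header columns `compound_id`, `protein_id`, `label`;
#' ids are resolved against the entity tables.
#'
#' @param path file path.
#' @param compounds,proteins [entity_table()]s used to resolve ids.
#' @param role role tag for the resulting table.
#' @return an [interaction_table()].
#' @export
read_interactions <- function(path, compounds, proteins, role = "all") {
  df <- utils::read.delim(path, colClasses = "character", quote = "")
  need <- c("compound_id", "protein_id", "label")
  if (!all(need %in% names(df))) {
    stopf("%s: expected TSV header columns %s", path, paste(need, collapse = ", "))
  }
  unknown_c <- setdiff(df$compound_id, compounds$ids)
  if (length(unknown_c) > 0) stopf("unknown compound id %s", unknown_c[1])
  unknown_p <- setdiff(df$protein_id, proteins$ids)
  if (length(unknown_p) > 0) stopf("unknown protein id %s", unknown_p[1])
  lab <- suppressWarnings(as.numeric(df$label))
  if (any(is.na(lab))) stopf("non-numeric label '%s'", df$label[which(is.na(lab))[1]])
  interaction_table(compounds$index[df$compound_id],
                    proteins$index[df$protein_id],
                    lab, compounds$n, proteins$n, role = role)
}

#' Write interaction triples as TSV
#'
#' @param interactions an [interaction_table()].
#' @param compounds,proteins [entity_table()]s used to restore string ids.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_interactions <- function(interactions, compounds, proteins, path) {
  df <- data.frame(compound_id = compounds$ids[interactions$pairs$compound + 1L],
                   protein_id = proteins$ids[interactions$pairs$protein + 1L],
                   label = interactions$pairs$label)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Internal: seeded k-means with k-means++-style robustness via restarts.
cluster_assign <- function(features, k, seed) {
  if (k > nrow(features)) stopf("cannot form %d clusters from %d rows", k, nrow(features))
  if (k == nrow(features)) return(seq_len(k))
  with_seed(seed, stats::kmeans(features, centers = k, nstart = 10,
                                iter.max = 50)$cluster)
}

#' Cluster-disjoint inductive split
#'
#' Implements the cold-pair split protocol used for inductive CPI
#' evaluation: compounds and proteins are independently k-means clustered on
#' their feature vectors, whole clusters (not entities) are assigned to
#' train/validation/test roles, and an interaction pair inherits a role only
#' when both of its entities' clusters share that role. Cross-role pairs are
#' dropped, which guarantees that every compound and protein occurring in
#' the test pairs is absent from the training pairs.
#'
#' Cluster-to-role assignment shuffles cluster ids with `seed` and takes the
#' first `ceiling(train_frac * k_split)` clusters for training; the rest are
#' divided between validation and test in `val_test_ratio` proportion
#' (default 4 parts validation : 1 part test).
#'
#' @param compound_features,protein_features numeric matrices, one row per
#'   entity (same order as the entity tables).
#' @param interactions an [interaction_table()] with role `"all"`.
#' @param k_split number of clusters per entity type (>= 3).
#' @param train_frac fraction of clusters assigned to training.
#' @param val_test_ratio length-2 numeric, validation:test cluster ratio.
#' @param seed integer seed controlling clustering and role assignment.
#' @return an object of class `inductive_split`: fields `train`, `val`,
#'   `test` ([interaction_table()]s), `visible_compounds`/`visible_proteins`
#'   (0-based index sets of train entities), `dropped` (number of cross-role
#'   pairs discarded) and `roles` (per-entity role data frames).
#' @export
inductive_cluster_split <- function(compound_features, protein_features,
                                    interactions, k_split = 10,
                                    train_frac = 0.6,
                                    val_test_ratio = c(4, 1),
                                    seed = 1) {
  assert_finite_matrix(compound_features, "compound_features")
  assert_finite_matrix(protein_features, "protein_features")
  if (!is_count(k_split) || k_split < 3) {
    stopf("k_split must be an integer >= 3 (cannot form three roles with k_split=%s)",
          format(k_split))
  }
  if (nrow(compound_features) != interactions$n_compounds ||
      nrow(protein_features) != interactions$n_proteins) {
    stopf("feature row counts do not match interaction table entity counts")
  }

  cl_c <- cluster_assign(compound_features, k_split, derive_seed(seed, "split-c"))
  cl_p <- cluster_assign(protein_features, k_split, derive_seed(seed, "split-p"))

  assign_roles <- function(k, frac, ratio, s) {
    ord <- with_seed(s, sample.int(k))
    n_train <- ceiling(frac * k)
    rest <- ord[-seq_len(n_train)]
    if (length(rest) < 2) stopf("k_split=%d leaves too few clusters for val/test", k)
    n_val <- max(1L, round(length(rest) * ratio[1] / sum(ratio)))
    n_val <- min(n_val, length(rest) - 1L)
    roles <- character(k)
    roles[ord[seq_len(n_train)]] <- "train"
    roles[rest[seq_len(n_val)]] <- "val"
    roles[rest[-seq_len(n_val)]] <- "test"
    roles
  }
  roles_c <- assign_roles(k_split, train_frac, val_test_ratio, derive_seed(seed, "roles-c"))
  roles_p <- assign_roles(k_split, train_frac, val_test_ratio, derive_seed(seed, "roles-p"))

  ent_role_c <- roles_c[cl_c]
  ent_role_p <- roles_p[cl_p]

  pr <- interactions$pairs
  role_c <- ent_role_c[pr$compound + 1L]
  role_p <- ent_role_p[pr$protein + 1L]
  pair_role <- ifelse(role_c == role_p, role_c, "dropped")

  take <- function(role) {
    sel <- pair_role == role
    if (!any(sel)) {
      stopf("role '%s' ended with zero pairs; try a smaller k_split or another seed", role)
    }
    interaction_table(pr$compound[sel], pr$protein[sel], pr$label[sel],
                      interactions$n_compounds, interactions$n_proteins,
                      role = role)
  }
  train <- take("train"); val <- take("val"); test <- take("test")

  split <- structure(list(
    train = train, val = val, test = test,
    visible_compounds = sort(unique(train$pairs$compound)),
    visible_proteins = sort(unique(train$pairs$protein)),
    dropped = sum(pair_role == "dropped"),
    roles = list(compound = ent_role_c, protein = ent_role_p),
    k_split = k_split, seed = seed
  ), class = "inductive_split")
  validate_inductive_split(split)
  split
}

# The hard inductive condition: test entities never occur in train pairs.
validate_inductive_split <- function(split) {
  if (length(intersect(split$test$pairs$compound, split$train$pairs$compound)) > 0) {
    stopf("inductive violation: compound shared between train and test")
  }
  if (length(intersect(split$test$pairs$protein, split$train$pairs$protein)) > 0) {
    stopf("inductive violation: protein shared between train and test")
  }
  invisible(split)
}

#' @export
print.inductive_split <- function(x, ...) {
  cat(sprintf(
    "<inductive_split> train=%d val=%d test=%d dropped=%d (k_split=%d, seed=%d)\n",
    x$train$n, x$val$n, x$test$n, x$dropped, x$k_split, x$seed))
  invisible(x)
}

#' Write a split manifest as JSON
#'
#' The manifest maps each role to its list of `(compound_id, protein_id,
#' label)` triples, using string ids.
#'
#' @param split an [inductive_cluster_split()] result.
#' @param compounds,proteins [entity_table()]s used to restore string ids.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_split_manifest <- function(split, compounds, proteins, path) {
  one <- function(tab) {
    data.frame(compound_id = compounds$ids[tab$pairs$compound + 1L],
               protein_id = proteins$ids[tab$pairs$protein + 1L],
               label = tab$pairs$label)
  }
  jsonlite::write_json(list(train = one(split$train), val = one(split$val),
                            test = one(split$test)),
                       path, dataframe = "rows", auto_unbox = TRUE)
  invisible(path)
}
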