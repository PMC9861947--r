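# Independent oracles, written from first principles and kept free of the
# package's internal helpers.

# naive-Bayes score recomputed from scratch by explicit loops
oracle_score <- function(features, active_ids, query, c0 = 1) {
  ids <- sort(unique(names(features)))
  N <- length(ids)
  n_a <- sum(ids %in% active_ids)
  p_a <- n_a / N
  vocab <- sort(unique(unlist(features)))
  terms <- c()
  for (d in query) {
    if (!d %in% vocab) next
    n_d <- sum(vapply(ids, function(i) d %in% features[[i]], logical(1)))
    n_da <- sum(vapply(intersect(ids, active_ids),
                       function(i) d %in% features[[i]], logical(1)))
    terms <- c(terms, asin(2 * (n_da + c0 * p_a) / (n_d + c0) - 1))
  }
  if (!length(terms)) return(asin(2 * p_a - 1))
  mean(terms)
}

# ROC AUC by brute-force pair counting with half credit for ties
brute_force_auc <- function(act, inact) {
  wins <- 0
  for (a in act) for (b in inact)
    wins <- wins + if (a > b) 1 else if (a == b) 0.5 else 0
  wins / (length(act) * length(inact))
}

# independent MNA recursion over an adjacency list
oracle_mna <- function(elements, adj, i, level) {
  if (level == 0) return(elements[i])
  subs <- sort(vapply(adj[[i]], function(j)
    oracle_mna(elements, adj, j, level - 1), character(1)))
  paste0(elements[i], "(", paste(subs, collapse = ""), ")")
}

# random small molecule_graph for property tests (connected not required)
random_graph <- function(n_atoms, seed) {
  set.seed(seed)
  elems <- sample(c("C", "N", "O", "H"), n_atoms, replace = TRUE)
  pairs <- t(combn(n_atoms, 2))
  keep <- runif(nrow(pairs)) < 0.4
  edges <- pairs[keep, , drop = FALSE]
  if (!nrow(edges)) edges <- pairs[1, , drop = FALSE]
  molecule_graph(elems, integer(n_atoms), edges, paste0("rg", seed))
}

# apply an atom permutation to a molecule_graph
permute_graph <- function(mol, perm) {
  inv <- order(perm)   # new index of old atom i is inv[i]... careful below
  # perm[k] = old index placed at new position k
  new_elems <- mol$atoms$element[perm]
  new_chg <- mol$atoms$charge[perm]
  remap <- integer(n_atoms(mol))
  remap[perm] <- seq_along(perm)
  e <- mol$edges
  new_edges <- cbind(remap[e[, 1]], remap[e[, 2]])
  molecule_graph(new_elems, new_chg, new_edges, mol$source_id)
}

# small random descriptor-level training fixture
toy_fixture <- function(n = 10, vocab = 8, seed = 1, n_active = NULL) {
  set.seed(seed)
  voc <- paste0("V", seq_len(vocab))
  ids <- paste0("t", seq_len(n))
  feats <- lapply(ids, function(i)
    sort(sample(voc, sample(2:min(5, vocab), 1))))
  names(feats) <- ids
  if (is.null(n_active)) n_active <- max(2, n %/% 3)
  label <- c(rep("active", n_active), rep("inactive", n - n_active))
  list(features = feats,
       labeled = labeled_set("toy", ids, label))
}
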