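# Shared fixtures and independent oracles, built in code at test time.

# Brute-force pairwise AUC: enumerate every (positive, negative) pair and
# average full/half credit.  Independent of the rank-based implementation.
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# A random but structurally valid molecular graph (random tree plus an
# optional extra edge), bypassing SMILES so GNN tests control size and seed.
random_graph <- function(n_atoms, seed) {
  n_atoms <- as.integer(n_atoms)
  set.seed(seed)
  elements <- sample(c("C", "N", "O", "F"), n_atoms, replace = TRUE,
                     prob = c(0.7, 0.1, 0.15, 0.05))
  hyb <- sample(c("sp", "sp2", "sp3", "other"), n_atoms, replace = TRUE)
  arom <- sample(c(TRUE, FALSE), n_atoms, replace = TRUE, prob = c(0.2, 0.8))
  hcount <- sample(0:3, n_atoms, replace = TRUE)
  edges <- if (n_atoms > 1)
    cbind(2:n_atoms, vapply(2:n_atoms, function(i) sample.int(i - 1L, 1L), 1L))
  else matrix(integer(0), 0, 2)
  if (n_atoms > 3 && stats::runif(1) < 0.5) {
    extra <- sample.int(n_atoms, 2L)
    edges <- rbind(edges, sort(extra))
  }
  node_features <- t(vapply(seq_len(n_atoms), function(i)
    featurize_atom(elements[i], hyb[i], arom[i], hcount[i]), numeric(11)))
  if (n_atoms == 1) node_features <- matrix(node_features, 1, 11)
  edge_features <- matrix(0, nrow(edges), 6)
  for (k in seq_len(nrow(edges))) {
    edge_features[k, sample.int(4, 1)] <- 1
    edge_features[k, 5] <- stats::runif(1, 1.2, 1.6)
    edge_features[k, 6] <- 1
  }
  structure(
    list(molecule_id = sprintf("rg_%d", seed), smiles = NA_character_,
         n_atoms = n_atoms, elements = elements, hydrogen_counts = hcount,
         aromatic = arom, hybridization = hyb, node_features = node_features,
         edges = edges, edge_features = edge_features, coords = NULL),
    class = "molecular_graph"
  )
}

# Apply a permutation to the atoms of a molecular graph.
permute_graph <- function(graph, perm) {
  inv <- order(perm)  # new index of old atom i is inv[i]
  g <- graph
  g$elements <- graph$elements[perm]
  g$hydrogen_counts <- graph$hydrogen_counts[perm]
  g$aromatic <- graph$aromatic[perm]
  g$hybridization <- graph$hybridization[perm]
  g$node_features <- graph$node_features[perm, , drop = FALSE]
  if (nrow(graph$edges)) {
    g$edges <- matrix(inv[graph$edges], ncol = 2)
  }
  if (!is.null(graph$coords)) g$coords <- graph$coords[perm, , drop = FALSE]
  g
}

# Collect labeled peaks (ground-truth pipeline output) from a synthetic
# dataset, optionally restricted to collision-free single-group peaks.
collect_labeled_peaks <- function(dataset, theta = 0.1, clean_only = FALSE) {
  out <- list()
  for (e in dataset) {
    peaks <- find_peaks(e$spectrum)
    for (pk in peaks) {
      mem <- assign_sticks_to_peak(e$sticks, pk)
      if (!length(mem)) next
      if (clean_only) {
        ids <- vapply(e$transitions[mem], `[[`, "", "state_id")
        grp <- which(vapply(e$planted, function(p) all(ids %in% p$state_ids),
                            TRUE))
        if (length(grp) != 1L || !e$planted[[grp]]$clean) next
        planted <- e$planted[[grp]]
      } else planted <- NULL
      lab <- labels_for_peak(e$sticks, e$transitions, pk, e$graph$n_atoms,
                             theta = theta)
      out[[length(out) + 1L]] <- list(entry = e, peak = pk, labels = lab,
                                      planted = planted)
    }
  }
  out
}
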