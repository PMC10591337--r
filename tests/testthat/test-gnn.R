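# The forward passes are checked against independent dense/scalar arithmetic
# on tiny graphs, the reverse passes against central finite differences, and
# training against memorization / schedule / reproducibility contracts.

toy_entry <- function(smiles, grid, seed) {
  tr <- generate_transitions(smiles, seed = seed, molecule_id = smiles)
  list(graph = tr$graph, spectrum = broaden(tr$sticks, grid))
}

test_that("forward output has one value per grid point for all architectures", {
  g <- random_graph(5, seed = 1)
  for (arch in c("gcn", "graphnet", "gatv2")) {
    model <- build_gnn(model_config(arch, hidden_sizes = c(8, 12), n_out = 100,
                                    n_heads = 2, seed = 2))
    out <- predict_spectrum(model, g)
    expect_length(out$intensities, 100)
    expect_equal(dim(out$activations), c(5, 12))
  }
})

test_that("a zero-weight model outputs its bias on a single-node graph", {
  model <- build_gnn(model_config("gcn", hidden_sizes = 4, n_out = 7, seed = 1))
  model$params <- zeros_like(model$params)
  model$params$bout <- seq(0.1, 0.7, by = 0.1)
  out <- predict_spectrum(model, random_graph(1, seed = 3))
  expect_equal(out$intensities, seq(0.1, 0.7, by = 0.1))
})

test_that("GCN layer equals dense normalized-adjacency propagation on a star", {
  # 4-node star: center 1 bonded to 2, 3, 4
  g <- random_graph(4, seed = 7)
  g$edges <- cbind(1L, 2:4)
  model <- build_gnn(model_config("gcn", hidden_sizes = 3, n_out = 2, seed = 5))
  fwd <- predict_spectrum(model, g)

  H <- g$node_features
  A <- matrix(0, 4, 4)
  for (k in 1:3) { A[g$edges[k, 1], g$edges[k, 2]] <- 1
                   A[g$edges[k, 2], g$edges[k, 1]] <- 1 }
  deg <- rowSums(A) + 1
  An <- diag(1 / sqrt(deg)) %*% (A + diag(4)) %*% diag(1 / sqrt(deg))
  p <- model$params$layers[[1]]
  Z <- An %*% H %*% p$W + matrix(p$b, 4, 3, byrow = TRUE)
  expected <- ifelse(Z > 0, Z, 0.01 * Z)
  expect_equal(fwd$activations, expected, tolerance = 1e-12,
               ignore_attr = TRUE)
  # after one layer a leaf state is unaffected by a change to another leaf
  g2 <- g
  g2$node_features[3, 11] <- g2$node_features[3, 11] + 1
  fwd2 <- predict_spectrum(model, g2)
  expect_equal(fwd2$activations[2, ], fwd$activations[2, ])
  expect_false(isTRUE(all.equal(fwd2$activations[1, ], fwd$activations[1, ])))
})

test_that("GATv2 attention matches scalar softmax arithmetic on a path", {
  # 3-node path 1-2-3, one head, one layer
  g <- random_graph(3, seed = 11)
  g$edges <- cbind(1:2, 2:3)
  model <- build_gnn(model_config("gatv2", hidden_sizes = 2, n_out = 2,
                                  n_heads = 1, seed = 6))
  ph <- model$params$layers[[1]]$heads$h1
  b <- model$params$layers[[1]]$b
  H <- g$node_features
  Zl <- H %*% ph$Wl; Zr <- H %*% ph$Wr
  nbr <- list(c(2L, 1L), c(1L, 3L, 2L), c(2L, 3L))  # neighbors + self
  lr02 <- function(x) ifelse(x > 0, x, 0.2 * x)
  expected <- matrix(0, 3, 2)
  for (t in 1:3) {
    logits <- vapply(nbr[[t]], function(s)
      sum(lr02(Zl[t, ] + Zr[s, ]) * ph$a), numeric(1))
    alpha <- exp(logits - max(logits))
    alpha <- alpha / sum(alpha)
    o <- colSums(alpha * Zr[nbr[[t]], , drop = FALSE]) + b
    expected[t, ] <- ifelse(o > 0, o, 0.01 * o)
    expect_equal(sum(alpha), 1)
  }
  fwd <- predict_spectrum(model, g)
  expect_equal(fwd$activations, expected, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("equal attention logits reduce GATv2 to uniform neighbor averaging", {
  g <- random_graph(4, seed = 13)
  model <- build_gnn(model_config("gatv2", hidden_sizes = 3, n_out = 2,
                                  n_heads = 1, seed = 8))
  model$params$layers[[1]]$heads$h1$a[] <- 0
  ph <- model$params$layers[[1]]$heads$h1
  H <- g$node_features
  Zr <- H %*% ph$Wr
  adj <- lapply(1:4, function(i) i)
  for (k in seq_len(nrow(g$edges))) {
    a <- g$edges[k, 1]; b2 <- g$edges[k, 2]
    adj[[a]] <- c(adj[[a]], b2); adj[[b2]] <- c(adj[[b2]], a)
  }
  b <- model$params$layers[[1]]$b
  expected <- t(vapply(1:4, function(t) {
    o <- colMeans(Zr[adj[[t]], , drop = FALSE]) + b
    ifelse(o > 0, o, 0.01 * o)
  }, numeric(3)))
  fwd <- predict_spectrum(model, g)
  expect_equal(fwd$activations, expected, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("GraphNet block matches a hand-unrolled update on a 2-node graph", {
  g <- random_graph(2, seed = 17)
  g$edges <- matrix(c(1L, 2L), 1, 2)
  cfg <- model_config("graphnet", hidden_sizes = 3, n_out = 2,
                      global_size = 2, seed = 9)
  model <- build_gnn(cfg)
  p <- model$params$layers[[1]]
  H <- g$node_features
  E <- g$edge_features
  U <- c(0, 0)
  lr <- function(x) ifelse(x > 0, x, 0.01 * x)
  # directed edges (1->2) and (2->1) share the undirected bond features
  e12 <- lr(c(E[1, ], H[1, ], H[2, ], U) %*% p$We + p$be)
  e21 <- lr(c(E[1, ], H[2, ], H[1, ], U) %*% p$We + p$be)
  h1 <- lr(c(H[1, ], e21, U) %*% p$Wv + p$bv)  # node 1 receives edge 2->1
  h2 <- lr(c(H[2, ], e12, U) %*% p$Wv + p$bv)
  fwd <- predict_spectrum(model, g)
  expect_equal(fwd$activations, rbind(h1, h2), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("analytic gradients match central finite differences", {
  graphs <- list(random_graph(4, seed = 31), random_graph(6, seed = 32),
                 random_graph(1, seed = 33))
  batch <- xascam:::batch_graphs(graphs)
  set.seed(40)
  Tm <- matrix(rnorm(3 * 5), 3, 5)
  for (arch in c("gcn", "graphnet", "gatv2")) {
    model <- build_gnn(model_config(arch, hidden_sizes = c(6, 8), n_out = 5,
                                    n_heads = 2, global_size = 4, seed = 41))
    loss_fn <- function(m)
      mean((xascam:::gnn_forward_batch(m, batch)$Y - Tm)^2)
    fwd <- xascam:::gnn_forward_batch(model, batch, keep_cache = TRUE)
    dY <- 2 * (fwd$Y - Tm) / length(Tm)
    grads <- xascam:::gnn_backward_batch(model, batch, fwd, dY)
    paths <- list()
    collect <- function(p, path) {
      if (is.list(p)) for (nm in names(p)) collect(p[[nm]], c(path, nm))
      else paths[[length(paths) + 1L]] <<- path
    }
    collect(model$params, character(0))
    for (pa in paths) {
      leaf <- model$params[[pa]]
      for (k in sample(seq_along(leaf), min(3, length(leaf)))) {
        eps <- 1e-6
        m2 <- model
        m2$params[[pa]][k] <- leaf[k] + eps
        lp <- loss_fn(m2)
        m2$params[[pa]][k] <- leaf[k] - eps
        lm <- loss_fn(m2)
        num <- (lp - lm) / (2 * eps)
        expect_equal(grads[[pa]][k], num, tolerance = 1e-4,
                     label = sprintf("%s %s[%d]", arch,
                                     paste(pa, collapse = "."), k))
      }
    }
  }
})

test_that("outputs are permutation-invariant, activations equivariant", {
  set.seed(51)
  for (arch in c("gcn", "graphnet", "gatv2")) {
    model <- build_gnn(model_config(arch, hidden_sizes = c(6, 8), n_out = 10,
                                    n_heads = 2, seed = 52))
    for (rep in 1:3) {
      g <- random_graph(sample(3:8, 1), seed = 100 + rep)
      perm <- sample(g$n_atoms)
      gp <- permute_graph(g, perm)
      f1 <- predict_spectrum(model, g)
      f2 <- predict_spectrum(model, gp)
      expect_equal(f2$intensities, f1$intensities, tolerance = 1e-10)
      expect_equal(f2$activations, f1$activations[perm, , drop = FALSE],
                   tolerance = 1e-10)
    }
  }
})

test_that("training memorizes a single molecule", {
  grid <- energy_grid(270, 300, 100)
  entry <- toy_entry("CCO", grid, seed = 61)
  model <- build_gnn(small_profile("gcn", n_out = 100, seed = 62), grid)
  fit <- train_gnn(model, list(entry),
                   train_config(epochs = 300, batch_size = 1, seed = 63))
  final_rmse <- tail(fit$history$train_rmse, 1)
  expect_lt(final_rmse, 1e-2 * max(entry$spectrum$intensities))
})

test_that("the learning-rate schedule follows the stated decay", {
  grid <- energy_grid(270, 300, 10)
  ds <- list(toy_entry("CC", grid, 71), toy_entry("CO", grid, 72))
  model <- build_gnn(model_config("gcn", hidden_sizes = 4, n_out = 10,
                                  seed = 73), grid)
  fit <- train_gnn(model, ds, train_config(epochs = 250, batch_size = 2,
                                           seed = 74))
  expect_equal(fit$history$lr[50], 1e-3)
  expect_equal(fit$history$lr[150], 1e-3 * 0.8)
  expect_equal(fit$history$lr[250], 1e-3 * 0.8^2)
})

test_that("identical seeds give identical training histories", {
  grid <- energy_grid(270, 300, 10)
  ds <- lapply(c("CCO", "CC", "CCN", "C=O", "CCC"), toy_entry, grid = grid,
               seed = 81)
  run <- function() {
    model <- build_gnn(model_config("gatv2", hidden_sizes = c(4, 4),
                                    n_out = 10, n_heads = 2, seed = 82), grid)
    train_gnn(model, ds, train_config(epochs = 20, batch_size = 3,
                                      seed = 83))$history
  }
  expect_identical(run(), run())
})

test_that("training rejects an empty dataset and mismatched grids", {
  grid <- energy_grid(270, 300, 10)
  model <- build_gnn(model_config("gcn", hidden_sizes = 4, n_out = 10), grid)
  expect_error(train_gnn(model, list(), train_config()), "empty")
  ds <- list(toy_entry("CC", energy_grid(270, 300, 20), 91))
  expect_error(train_gnn(model, ds, train_config()), "grid")
})

test_that("checkpoints round-trip through JSON", {
  grid <- energy_grid(270, 300, 100)
  g <- build_graph("CC(=O)N")
  for (arch in c("gcn", "gatv2", "graphnet")) {
    model <- build_gnn(model_config(arch, hidden_sizes = c(6, 8), n_out = 100,
                                    n_heads = 2, seed = 95), grid)
    path <- withr::local_tempfile(fileext = ".json")
    save_checkpoint(model, path)
    back <- load_checkpoint(path)
    expect_equal(predict_spectrum(back, g)$intensities,
                 predict_spectrum(model, g)$intensities, tolerance = 1e-12)
  }
})
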