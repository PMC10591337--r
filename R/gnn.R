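# Graph neural network regressors: GCN, GraphNet (with a global state), and
# multihead GATv2.  All three share the contract that makes CAM applicable:
# message-passing layers -> per-node activations F -> permutation-invariant
# readout -> single affine output layer.  Forward and reverse passes are
# written directly in matrix form over batched graphs (block-diagonal layout:
# node rows of all graphs stacked, edges indexed globally).

# ---- small numeric helpers -------------------------------------------------

lrelu <- function(x, slope) ifelse(x > 0, x, slope * x)
lrelu_grad <- function(x, slope) ifelse(x > 0, 1, slope)

# Sum rows of `vals` into `n` groups given by `idx` (all in 1..n).
agg_sum <- function(vals, idx, n) {
  out <- matrix(0, n, ncol(vals))
  if (nrow(vals)) {
    r <- rowsum(vals, idx)
    out[as.integer(rownames(r)), ] <- r
  }
  out
}

group_sum_vec <- function(x, idx, n) {
  out <- numeric(n)
  if (length(x)) {
    r <- rowsum(matrix(x, ncol = 1), idx)
    out[as.integer(rownames(r))] <- r[, 1]
  }
  out
}

group_max_vec <- function(x, idx, n) {
  out <- rep(-Inf, n)
  if (length(x)) {
    m <- tapply(x, idx, max)
    out[as.integer(names(m))] <- as.numeric(m)
  }
  out
}

glorot <- function(n_in, n_out) {
  l <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -l, l), n_in, n_out)
}

zeros_like <- function(p) {
  if (is.list(p)) lapply(p, zeros_like) else p * 0
}

# ---- configuration ---------------------------------------------------------

#' GNN model configuration
#'
#' @param architecture One of `"gcn"`, `"graphnet"`, `"gatv2"`.
#' @param hidden_sizes Output widths of the message-passing layers.  The
#'   full-scale profile is `c(128, 256, 512)`; [small_profile()] gives the
#'   CPU-friendly default used throughout the examples and tests.
#' @param n_out Output dimension; one unit per grid point (default 100).
#' @param n_heads Attention heads for GATv2 (default 4).  Intermediate layer
#'   widths must be divisible by `n_heads` (heads are concatenated); the
#'   final layer averages full-width heads.
#' @param readout `"sum"` (default; keeps CAM completeness exact) or
#'   `"mean"`.
#' @param output_bias Whether the output layer carries a bias (default TRUE).
#'   CAM completeness is exact only for a bias-free output layer.
#' @param leaky_slope Negative slope of the leaky-ReLU nonlinearity.
#' @param attn_slope Negative slope used inside the GATv2 attention logits.
#' @param global_size Width of the initial global state (GraphNet only).
#' @param d_node,d_edge Input feature dimensions (defaults match
#'   [build_graph()]).
#' @param seed Seed for weight initialization.
#' @return A `model_config` list.
#' @export
model_config <- function(architecture = c("gcn", "graphnet", "gatv2"),
                         hidden_sizes = c(128, 256, 512),
                         n_out = 100L, n_heads = 4L,
                         readout = c("sum", "mean"),
                         output_bias = TRUE,
                         leaky_slope = 0.01, attn_slope = 0.2,
                         global_size = 8L,
                         d_node = D_NODE, d_edge = D_EDGE,
                         seed = 1L) {
  architecture <- match.arg(architecture)
  readout <- match.arg(readout)
  hidden_sizes <- as.integer(hidden_sizes)
  if (!length(hidden_sizes) || any(hidden_sizes < 1L))
    stop("`hidden_sizes` must be a non-empty vector of positive widths",
         call. = FALSE)
  if (n_out < 1L) stop("`n_out` must be >= 1", call. = FALSE)
  if (n_heads < 1L) stop("`n_heads` must be >= 1", call. = FALSE)
  if (architecture == "gatv2" && length(hidden_sizes) > 1L) {
    inter <- hidden_sizes[-length(hidden_sizes)]
    if (any(inter %% n_heads != 0L))
      stop("intermediate GATv2 widths must be divisible by `n_heads`",
           call. = FALSE)
  }
  structure(
    list(architecture = architecture, hidden_sizes = hidden_sizes,
         n_out = as.integer(n_out), n_heads = as.integer(n_heads),
         readout = readout, output_bias = isTRUE(output_bias),
         leaky_slope = leaky_slope, attn_slope = attn_slope,
         global_size = as.integer(global_size),
         d_node = as.integer(d_node), d_edge = as.integer(d_edge),
         seed = as.integer(seed)),
    class = "model_config"
  )
}

#' Desk-scale model configuration
#'
#' Same contract as [model_config()] with hidden sizes `c(32, 64)`: small
#' enough for CPU training yet wide enough for the synthetic datasets.
#'
#' @param architecture Architecture name.
#' @param ... Passed to [model_config()].
#' @export
small_profile <- function(architecture = "gatv2", ...) {
  model_config(architecture = architecture, hidden_sizes = c(32L, 64L), ...)
}

#' Desk-scale training configuration
#'
#' [train_config()] defaults sized for datasets of a few hundred molecules:
#' 200 epochs with batches of 25 graphs (roughly ten optimizer steps per
#' epoch), everything else as in the full-scale protocol.  The full-scale
#' batch of 100 is appropriate for tens of thousands of samples; at desk
#' scale it would leave the optimizer only a couple of steps per epoch.
#'
#' @param ... Overrides passed to [train_config()].
#' @export
small_train_profile <- function(...) {
  args <- list(...)
  defaults <- list(epochs = 200L, batch_size = 25L)
  do.call(train_config, utils::modifyList(defaults, args))
}

#' Training configuration
#'
#' Defaults mirror the full-scale protocol: AdamW, learning rate 1e-3
#' multiplied by 0.8 every 100 epochs, batches of 100 graphs, an 80:20
#' train/validation split, and validation checks every 50 epochs.  Model
#' selection keeps the checkpoint with the best validation RMSE (ties broken
#' by validation RSE).
#'
#' @param epochs Number of epochs (default 1000).
#' @param lr Initial learning rate.
#' @param lr_decay Multiplicative decay factor.
#' @param decay_every Epochs between decays.
#' @param batch_size Graphs per batch.
#' @param val_fraction Fraction of the dataset held out for validation.
#' @param val_check_every Epochs between validation evaluations.
#' @param weight_decay AdamW decoupled weight decay.
#' @param seed Seed controlling the split and batch shuffling.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 1000L, lr = 1e-3, lr_decay = 0.8,
                         decay_every = 100L, batch_size = 100L,
                         val_fraction = 0.2, val_check_every = 50L,
                         weight_decay = 1e-2, seed = 1L) {
  if (lr <= 0) stop("`lr` must be positive", call. = FALSE)
  if (lr_decay <= 0 || lr_decay > 1)
    stop("`lr_decay` must be in (0, 1]", call. = FALSE)
  if (val_fraction <= 0 || val_fraction >= 1)
    stop("`val_fraction` must be in (0, 1)", call. = FALSE)
  structure(
    list(epochs = as.integer(epochs), lr = lr, lr_decay = lr_decay,
         decay_every = as.integer(decay_every),
         batch_size = as.integer(batch_size),
         val_fraction = val_fraction,
         val_check_every = as.integer(val_check_every),
         weight_decay = weight_decay, seed = as.integer(seed)),
    class = "train_config"
  )
}

# ---- parameter initialization ----------------------------------------------

.init_params <- function(cfg) {
  set.seed(cfg$seed)
  L <- length(cfg$hidden_sizes)
  layers <- vector("list", L)
  d_in <- cfg$d_node
  dg <- cfg$global_size
  de_in <- cfg$d_edge
  for (l in seq_len(L)) {
    K <- cfg$hidden_sizes[l]
    if (cfg$architecture == "gcn") {
      layers[[l]] <- list(W = glorot(d_in, K), b = numeric(K))
    } else if (cfg$architecture == "gatv2") {
      final <- l == L
      k_h <- if (final) K else K %/% cfg$n_heads
      heads <- lapply(seq_len(cfg$n_heads), function(h)
        list(Wl = glorot(d_in, k_h), Wr = glorot(d_in, k_h),
             a = stats::runif(k_h, -sqrt(3 / k_h), sqrt(3 / k_h))))
      names(heads) <- paste0("h", seq_len(cfg$n_heads))
      layers[[l]] <- list(heads = heads, b = numeric(K))
    } else {  # graphnet
      layers[[l]] <- list(
        We = glorot(de_in + 2L * d_in + dg, K), be = numeric(K),
        Wv = glorot(d_in + K + dg, K), bv = numeric(K),
        Wu = glorot(dg + K + K, K), bu = numeric(K)
      )
      de_in <- K
      dg <- K
    }
    d_in <- K
  }
  K <- cfg$hidden_sizes[L]
  list(layers = layers,
       Wout = glorot(K, cfg$n_out),
       bout = numeric(cfg$n_out))
}

#' Build a GNN spectrum regressor
#'
#' @param config A [model_config()].
#' @param grid Optional [energy_grid()] recording what the output units mean;
#'   attached automatically by [train_gnn()].
#' @return An object of class `xas_gnn` holding `config`, `params` and
#'   optionally `grid`.
#' @export
build_gnn <- function(config, grid = NULL) {
  stopifnot(inherits(config, "model_config"))
  structure(list(config = config, params = .init_params(config), grid = grid),
            class = "xas_gnn")
}

#' @export
print.xas_gnn <- function(x, ...) {
  cat(sprintf("<xas_gnn> %s, hidden [%s] -> %d outputs, readout %s\n",
              x$config$architecture,
              paste(x$config$hidden_sizes, collapse = ", "),
              x$config$n_out, x$config$readout))
  invisible(x)
}

# ---- batching --------------------------------------------------------------

# Stack graphs into one block-diagonal batch: node rows concatenated, edges
# duplicated in both directions and indexed globally.
batch_graphs <- function(graphs) {
  ns <- vapply(graphs, function(g) as.integer(g$n_atoms), integer(1))
  offsets <- cumsum(c(0L, ns[-length(ns)]))
  N <- sum(ns)
  X <- do.call(rbind, lapply(graphs, function(g) g$node_features))
  gid <- rep(seq_along(graphs), ns)
  src <- integer(0); dst <- integer(0)
  eattr_list <- list()
  for (i in seq_along(graphs)) {
    e <- graphs[[i]]$edges
    if (nrow(e)) {
      src <- c(src, e[, 1] + offsets[i], e[, 2] + offsets[i])
      dst <- c(dst, e[, 2] + offsets[i], e[, 1] + offsets[i])
      eattr_list[[length(eattr_list) + 1L]] <-
        rbind(graphs[[i]]$edge_features, graphs[[i]]$edge_features)
    }
  }
  eattr <- if (length(eattr_list)) do.call(rbind, eattr_list)
           else matrix(0, 0, D_EDGE)
  list(X = X, gid = gid, n_nodes = ns, n_graphs = length(graphs),
       src = src, dst = dst, eattr = eattr, N = N)
}

# ---- layer forward/backward ------------------------------------------------

.gcn_fwd <- function(p, H, batch, slope) {
  deg <- 1 + tabulate(batch$dst, batch$N)
  coef <- 1 / sqrt(deg[batch$src] * deg[batch$dst])
  M <- H / deg +
    agg_sum(coef * H[batch$src, , drop = FALSE], batch$dst, batch$N)
  Z <- sweep(M %*% p$W, 2, p$b, "+")
  list(H = lrelu(Z, slope), cache = list(Hin = H, M = M, Z = Z, deg = deg,
                                         coef = coef))
}

.gcn_bwd <- function(p, cache, dH, batch, slope) {
  dZ <- dH * lrelu_grad(cache$Z, slope)
  dW <- crossprod(cache$M, dZ)
  db <- colSums(dZ)
  dM <- dZ %*% t(p$W)
  dHin <- dM / cache$deg +
    agg_sum(cache$coef * dM[batch$dst, , drop = FALSE], batch$src, batch$N)
  list(grads = list(W = dW, b = db), dH = dHin)
}

.gat_fwd <- function(p, H, batch, slope, attn_slope, final) {
  N <- batch$N
  asrc <- c(batch$src, seq_len(N))
  adst <- c(batch$dst, seq_len(N))
  heads <- vector("list", length(p$heads))
  outs <- vector("list", length(p$heads))
  for (h in seq_along(p$heads)) {
    ph <- p$heads[[h]]
    Zl <- H %*% ph$Wl
    Zr <- H %*% ph$Wr
    q <- Zl[adst, , drop = FALSE] + Zr[asrc, , drop = FALSE]
    u <- lrelu(q, attn_slope)
    logit <- as.numeric(u %*% ph$a)
    mx <- group_max_vec(logit, adst, N)
    ex <- exp(logit - mx[adst])
    denom <- group_sum_vec(ex, adst, N)
    alpha <- ex / denom[adst]
    outs[[h]] <- agg_sum(alpha * Zr[asrc, , drop = FALSE], adst, N)
    heads[[h]] <- list(Zl = Zl, Zr = Zr, q = q, u = u, alpha = alpha)
  }
  O <- if (final) Reduce(`+`, outs) / length(outs) else do.call(cbind, outs)
  Z <- sweep(O, 2, p$b, "+")
  list(H = lrelu(Z, slope),
       cache = list(Hin = H, Z = Z, heads = heads, asrc = asrc, adst = adst,
                    final = final, k_h = ncol(heads[[1]]$Zl)))
}

.gat_bwd <- function(p, cache, dH, batch, slope, attn_slope) {
  N <- batch$N
  asrc <- cache$asrc
  adst <- cache$adst
  dZ <- dH * lrelu_grad(cache$Z, slope)
  db <- colSums(dZ)
  nH <- length(p$heads)
  k_h <- cache$k_h
  dHin <- matrix(0, nrow(cache$Hin), ncol(cache$Hin))
  gheads <- vector("list", nH)
  for (h in seq_len(nH)) {
    ph <- p$heads[[h]]
    ch <- cache$heads[[h]]
    dO <- if (cache$final) dZ / nH
          else dZ[, ((h - 1L) * k_h + 1L):(h * k_h), drop = FALSE]
    dO_e <- dO[adst, , drop = FALSE]
    Zr_e <- ch$Zr[asrc, , drop = FALSE]
    dalpha <- rowSums(dO_e * Zr_e)
    dZr <- agg_sum(ch$alpha * dO_e, asrc, N)
    s <- group_sum_vec(ch$alpha * dalpha, adst, N)
    dlogit <- ch$alpha * (dalpha - s[adst])
    du <- outer(dlogit, ph$a)
    da <- as.numeric(crossprod(ch$u, dlogit))
    dq <- du * lrelu_grad(ch$q, attn_slope)
    dZl <- agg_sum(dq, adst, N)
    dZr <- dZr + agg_sum(dq, asrc, N)
    dHin <- dHin + dZl %*% t(ph$Wl) + dZr %*% t(ph$Wr)
    gheads[[h]] <- list(Wl = crossprod(cache$Hin, dZl),
                        Wr = crossprod(cache$Hin, dZr), a = da)
  }
  names(gheads) <- names(p$heads)
  list(grads = list(heads = gheads, b = db), dH = dHin)
}

.graphnet_fwd <- function(p, H, Eat, U, batch, slope) {
  N <- batch$N; B <- batch$n_graphs
  egid <- batch$gid[batch$src]
  Xe <- cbind(Eat, H[batch$src, , drop = FALSE], H[batch$dst, , drop = FALSE],
              U[egid, , drop = FALSE])
  Ze <- sweep(Xe %*% p$We, 2, p$be, "+")
  Enew <- lrelu(Ze, slope)
  Me <- agg_sum(Enew, batch$dst, N)
  Xv <- cbind(H, Me, U[batch$gid, , drop = FALSE])
  Zv <- sweep(Xv %*% p$Wv, 2, p$bv, "+")
  Hnew <- lrelu(Zv, slope)
  Sh <- agg_sum(Hnew, batch$gid, B)
  Se <- agg_sum(Enew, egid, B)
  Xu <- cbind(U, Sh, Se)
  Zu <- sweep(Xu %*% p$Wu, 2, p$bu, "+")
  Unew <- lrelu(Zu, slope)
  list(H = Hnew, E = Enew, U = Unew,
       cache = list(Xe = Xe, Ze = Ze, Xv = Xv, Zv = Zv, Xu = Xu, Zu = Zu,
                    egid = egid, dn = ncol(H), de = ncol(Eat), dg = ncol(U)))
}

.graphnet_bwd <- function(p, cache, dH, dE, dU, batch, slope) {
  N <- batch$N; B <- batch$n_graphs
  dn <- cache$dn; de <- cache$de; dg <- cache$dg
  K <- ncol(cache$Zv)
  egid <- cache$egid
  # global update
  dZu <- dU * lrelu_grad(cache$Zu, slope)
  dWu <- crossprod(cache$Xu, dZu); dbu <- colSums(dZu)
  dXu <- dZu %*% t(p$Wu)
  dUin <- dXu[, seq_len(dg), drop = FALSE]
  dSh <- dXu[, dg + seq_len(K), drop = FALSE]
  dSe <- dXu[, dg + K + seq_len(K), drop = FALSE]
  # node update
  dHtot <- dH + dSh[batch$gid, , drop = FALSE]
  dZv <- dHtot * lrelu_grad(cache$Zv, slope)
  dWv <- crossprod(cache$Xv, dZv); dbv <- colSums(dZv)
  dXv <- dZv %*% t(p$Wv)
  dHin <- dXv[, seq_len(dn), drop = FALSE]
  dMe <- dXv[, dn + seq_len(K), drop = FALSE]
  dUin <- dUin + agg_sum(dXv[, dn + K + seq_len(dg), drop = FALSE],
                         batch$gid, B)
  # edge update
  dEtot <- dE + dSe[egid, , drop = FALSE] + dMe[batch$dst, , drop = FALSE]
  dZe <- dEtot * lrelu_grad(cache$Ze, slope)
  dWe <- crossprod(cache$Xe, dZe); dbe <- colSums(dZe)
  dXe <- dZe %*% t(p$We)
  dEin <- dXe[, seq_len(de), drop = FALSE]
  dHin <- dHin +
    agg_sum(dXe[, de + seq_len(dn), drop = FALSE], batch$src, N) +
    agg_sum(dXe[, de + dn + seq_len(dn), drop = FALSE], batch$dst, N)
  dUin <- dUin + agg_sum(dXe[, de + 2L * dn + seq_len(dg), drop = FALSE],
                         egid, B)
  list(grads = list(We = dWe, be = dbe, Wv = dWv, bv = dbv,
                    Wu = dWu, bu = dbu),
       dH = dHin, dE = dEin, dU = dUin)
}

# ---- full forward / backward -----------------------------------------------

# Forward over a batch.  Returns predictions Y (n_graphs x n_out), node
# activations F of the last message-passing layer (N x K), and (optionally)
# the cache needed for the reverse pass.
gnn_forward_batch <- function(model, batch, keep_cache = FALSE) {
  cfg <- model$config
  p <- model$params
  if (ncol(batch$X) != cfg$d_node)
    stop(sprintf("node features have %d columns, model expects %d",
                 ncol(batch$X), cfg$d_node), call. = FALSE)
  L <- length(cfg$hidden_sizes)
  H <- batch$X
  Eat <- batch$eattr
  U <- matrix(0, batch$n_graphs, cfg$global_size)
  caches <- vector("list", L)
  for (l in seq_len(L)) {
    pl <- p$layers[[l]]
    if (cfg$architecture == "gcn") {
      r <- .gcn_fwd(pl, H, batch, cfg$leaky_slope)
      H <- r$H
    } else if (cfg$architecture == "gatv2") {
      r <- .gat_fwd(pl, H, batch, cfg$leaky_slope, cfg$attn_slope, l == L)
      H <- r$H
    } else {
      r <- .graphnet_fwd(pl, H, Eat, U, batch, cfg$leaky_slope)
      H <- r$H; Eat <- r$E; U <- r$U
    }
    caches[[l]] <- r$cache
  }
  G <- agg_sum(H, batch$gid, batch$n_graphs)
  if (cfg$readout == "mean") G <- G / batch$n_nodes
  Y <- G %*% p$Wout
  if (cfg$output_bias) Y <- sweep(Y, 2, p$bout, "+")
  out <- list(Y = Y, F = H, G = G)
  if (keep_cache) out$caches <- caches
  out
}

# Reverse pass given dY; returns gradients with the same structure as params.
gnn_backward_batch <- function(model, batch, fwd, dY) {
  cfg <- model$config
  p <- model$params
  L <- length(cfg$hidden_sizes)
  gWout <- crossprod(fwd$G, dY)
  gbout <- if (cfg$output_bias) colSums(dY) else numeric(cfg$n_out)
  dG <- dY %*% t(p$Wout)
  dH <- dG[batch$gid, , drop = FALSE]
  if (cfg$readout == "mean") dH <- dH / batch$n_nodes[batch$gid]
  dE <- NULL; dU <- NULL
  if (cfg$architecture == "graphnet") {
    dE <- matrix(0, length(batch$src), cfg$hidden_sizes[L])
    dU <- matrix(0, batch$n_graphs, cfg$hidden_sizes[L])
  }
  glayers <- vector("list", L)
  for (l in rev(seq_len(L))) {
    pl <- p$layers[[l]]
    cl <- fwd$caches[[l]]
    if (cfg$architecture == "gcn") {
      r <- .gcn_bwd(pl, cl, dH, batch, cfg$leaky_slope)
      dH <- r$dH
    } else if (cfg$architecture == "gatv2") {
      r <- .gat_bwd(pl, cl, dH, batch, cfg$leaky_slope, cfg$attn_slope)
      dH <- r$dH
    } else {
      r <- .graphnet_bwd(pl, cl, dH, dE, dU, batch, cfg$leaky_slope)
      dH <- r$dH; dE <- r$dE; dU <- r$dU
    }
    glayers[[l]] <- r$grads
  }
  list(layers = glayers, Wout = gWout, bout = gbout)
}

#' Predict a spectrum for one molecule
#'
#' Runs the model forward on a single molecular graph and returns both the
#' predicted intensities and the per-node activations of the last
#' message-passing layer (the matrix CAM operates on).
#'
#' @param model An `xas_gnn`.
#' @param graph A `molecular_graph`.
#' @param clamp_nonneg If TRUE, negative predicted intensities are set to 0
#'   (reporting convenience; attribution always uses the raw output).
#' @return List with `intensities` (length `n_out`), `activations`
#'   (`n_atoms x K`), and `spectrum` (a [grid_spectrum()]) when the model
#'   carries a grid.
#' @export
predict_spectrum <- function(model, graph, clamp_nonneg = FALSE) {
  stopifnot(inherits(model, "xas_gnn"), inherits(graph, "molecular_graph"))
  fwd <- gnn_forward_batch(model, batch_graphs(list(graph)))
  y <- as.numeric(fwd$Y[1L, ])
  if (clamp_nonneg) y <- pmax(y, 0)
  out <- list(intensities = y, activations = fwd$F)
  if (!is.null(model$grid))
    out$spectrum <- grid_spectrum(model$grid, pmax(y, 0),
                                  molecule_id = graph$molecule_id)
  out
}

# ---- AdamW -----------------------------------------------------------------

.adamw_step <- function(params, grads, m, v, lr, wd, t,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  rec <- function(p, g, mm, vv) {
    if (is.list(p)) {
      for (nm in names(p)) {
        r <- rec(p[[nm]], g[[nm]], mm[[nm]], vv[[nm]])
        p[[nm]] <- r$p; mm[[nm]] <- r$m; vv[[nm]] <- r$v
      }
      list(p = p, m = mm, v = vv)
    } else {
      mm <- beta1 * mm + (1 - beta1) * g
      vv <- beta2 * vv + (1 - beta2) * g * g
      mhat <- mm / (1 - beta1^t)
      vhat <- vv / (1 - beta2^t)
      list(p = p - lr * (mhat / (sqrt(vhat) + eps) + wd * p), m = mm, v = vv)
    }
  }
  rec(params, grads, m, v)
}

.add_grads <- function(a, b) {
  if (is.list(a)) {
    for (nm in names(a)) a[[nm]] <- .add_grads(a[[nm]], b[[nm]])
    a
  } else a + b
}

# ---- training --------------------------------------------------------------

.eval_split <- function(model, entries, targets, batch_size) {
  n <- length(entries)
  sq <- 0; rses <- numeric(n)
  i <- 1L
  while (i <= n) {
    j <- min(i + batch_size - 1L, n)
    idx <- i:j
    b <- batch_graphs(lapply(entries[idx], `[[`, "graph"))
    Y <- gnn_forward_batch(model, b)$Y
    Tm <- targets[idx, , drop = FALSE]
    sq <- sq + sum((Y - Tm)^2)
    for (k in seq_along(idx)) {
      e <- entries[[idx[k]]]
      rses[idx[k]] <- rse(e$spectrum,
                          grid_spectrum(e$spectrum$grid, pmax(Y[k, ], 0)))
    }
    i <- j + 1L
  }
  list(rmse = sqrt(sq / (n * ncol(targets))), rse = mean(rses))
}

#' Train a GNN spectrum regressor
#'
#' Minimizes the mean squared error between predicted and target intensities
#' with AdamW (the reported loss is its square root, RMSE), decays the
#' learning rate by `lr_decay` every `decay_every` epochs, and evaluates the
#' held-out validation split every `val_check_every` epochs.  The returned
#' model is the checkpoint with the best validation RMSE, ties broken by
#' validation RSE; when the dataset is too small to hold out a validation
#' molecule, the final model is returned.
#'
#' @param model An `xas_gnn` from [build_gnn()].
#' @param dataset List of entries, each with fields `graph`
#'   (`molecular_graph`) and `spectrum` ([grid_spectrum()]).
#' @param cfg A [train_config()].
#' @param verbose Print progress every validation check.
#' @return List of class `xas_gnn_fit` with `model` (best checkpoint),
#'   `final_model`, `history` (data frame: epoch, lr, train_rmse, val_rmse,
#'   val_rse), and `val_indices`.
#' @export
train_gnn <- function(model, dataset, cfg = train_config(), verbose = FALSE) {
  stopifnot(inherits(model, "xas_gnn"), inherits(cfg, "train_config"))
  n <- length(dataset)
  if (!n) stop("dataset is empty", call. = FALSE)
  if (model$config$n_out != dataset[[1]]$spectrum$grid$n_grid)
    stop("model `n_out` must equal the dataset grid size", call. = FALSE)
  set.seed(cfg$seed)
  n_val <- floor(cfg$val_fraction * n)
  val_idx <- if (n_val > 0L) sort(sample.int(n, n_val)) else integer(0)
  tr_idx <- setdiff(seq_len(n), val_idx)
  if (!length(tr_idx)) stop("no training samples after the split", call. = FALSE)
  targets <- do.call(rbind, lapply(dataset, function(e) e$spectrum$intensities))
  model$grid <- dataset[[1]]$spectrum$grid

  m_state <- zeros_like(model$params)
  v_state <- zeros_like(model$params)
  t_step <- 0L
  best <- list(rmse = Inf, rse = Inf, params = model$params)
  hist <- data.frame(epoch = integer(0), lr = numeric(0),
                     train_rmse = numeric(0), val_rmse = numeric(0),
                     val_rse = numeric(0))
  for (epoch in seq_len(cfg$epochs)) {
    lr <- cfg$lr * cfg$lr_decay^((epoch - 1L) %/% cfg$decay_every)
    ord <- sample(tr_idx)
    sq <- 0; n_pred <- 0L
    i <- 1L
    while (i <= length(ord)) {
      j <- min(i + cfg$batch_size - 1L, length(ord))
      idx <- ord[i:j]
      b <- batch_graphs(lapply(dataset[idx], `[[`, "graph"))
      fwd <- gnn_forward_batch(model, b, keep_cache = TRUE)
      Tm <- targets[idx, , drop = FALSE]
      diff <- fwd$Y - Tm
      loss <- mean(diff^2)
      if (!is.finite(loss))
        stop(sprintf("training diverged (non-finite loss at epoch %d)", epoch),
             call. = FALSE)
      sq <- sq + sum(diff^2); n_pred <- n_pred + length(diff)
      dY <- 2 * diff / length(diff)
      grads <- gnn_backward_batch(model, b, fwd, dY)
      t_step <- t_step + 1L
      st <- .adamw_step(model$params, grads, m_state, v_state, lr,
                        cfg$weight_decay, t_step)
      model$params <- st$p; m_state <- st$m; v_state <- st$v
      i <- j + 1L
    }
    train_rmse <- sqrt(sq / n_pred)
    val_rmse <- NA_real_; val_rse <- NA_real_
    if ((epoch %% cfg$val_check_every == 0L || epoch == cfg$epochs)) {
      if (length(val_idx)) {
        ev <- .eval_split(model, dataset[val_idx],
                          targets[val_idx, , drop = FALSE], cfg$batch_size)
        val_rmse <- ev$rmse; val_rse <- ev$rse
        if (val_rmse < best$rmse ||
            (val_rmse == best$rmse && val_rse < best$rse)) {
          best <- list(rmse = val_rmse, rse = val_rse, params = model$params)
        }
      } else {
        best <- list(rmse = train_rmse, rse = NA_real_, params = model$params)
      }
      if (verbose)
        message(sprintf("epoch %4d lr %.2e train RMSE %.5f val RMSE %s",
                        epoch, lr, train_rmse,
                        ifelse(is.na(val_rmse), "-", sprintf("%.5f", val_rmse))))
    }
    hist <- rbind(hist, data.frame(epoch = epoch, lr = lr,
                                   train_rmse = train_rmse,
                                   val_rmse = val_rmse, val_rse = val_rse))
  }
  best_model <- model
  best_model$params <- best$params
  structure(list(model = best_model, final_model = model, history = hist,
                 val_indices = val_idx,
                 best_val_rmse = best$rmse, best_val_rse = best$rse),
            class = "xas_gnn_fit")
}

#' Constant mean-spectrum baseline
#'
#' The natural no-skill reference: predict, for every molecule, the mean of
#' the training spectra.  Returns the mean intensity vector.
#'
#' @param dataset List of entries with `spectrum` fields.
#' @return Numeric vector of mean intensities.
#' @export
mean_spectrum_baseline <- function(dataset) {
  colMeans(do.call(rbind, lapply(dataset, function(e) e$spectrum$intensities)))
}

#' Save / load a model checkpoint
#'
#' Checkpoints are JSON: configuration, weights and grid metadata, so they
#' are diffable and survive text-only archiving.
#'
#' @param model An `xas_gnn`.
#' @param path File path.
#' @return `load_checkpoint()` returns the restored `xas_gnn`.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "xas_gnn"))
  ser <- list(
    config = unclass(model$config),
    params = model$params,
    grid = if (!is.null(model$grid))
      list(e_min = model$grid$e_min, e_max = model$grid$e_max,
           n_grid = model$grid$n_grid)
  )
  jsonlite::write_json(ser, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(model_config, ser$config[names(ser$config) %in%
    names(formals(model_config))])
  model <- build_gnn(cfg)
  restore <- function(tpl, val) {
    if (is.list(tpl)) {
      for (nm in names(tpl)) tpl[[nm]] <- restore(tpl[[nm]], val[[nm]])
      tpl
    } else if (is.matrix(tpl)) {
      matrix(as.numeric(val), nrow(tpl), ncol(tpl))
    } else {
      as.numeric(val)
    }
  }
  model$params <- restore(model$params, ser$params)
  if (!is.null(ser$grid))
    model$grid <- energy_grid(ser$grid$e_min, ser$grid$e_max, ser$grid$n_grid)
  model
}
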