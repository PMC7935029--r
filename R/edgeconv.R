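#' Configuration of a connectivity-based GCN
#'
#' Describes the architecture: a stack of EdgeConv graph-convolution layers
#' sharing one k-NN graph across frames and subjects, skip connections
#' concatenating all prior conv outputs into the last conv layer, a node
#' pooling step collapsing the graph to one frame embedding, a temporal head
#' (mean over frames, or an LSTM consuming the frame sequence), and a softmax
#' classifier.
#'
#' @param n_conv_layers number of EdgeConv layers (default 5).
#' @param features_per_layer integer vector of output widths, one per conv
#'   layer.
#' @param temporal_head `"average_pool"` (deterministic default) or
#'   `"recurrent"` (single LSTM layer, final hidden state).
#' @param recurrent_hidden LSTM hidden size (ignored for average pooling).
#' @param n_classes number of output classes.
#' @param l2_lambda L2 penalty coefficient on weight matrices (not biases).
#' @param skip_connections concatenate conv outputs 1..L-1 as the input of
#'   conv layer L (default TRUE).
#' @param node_pool node-to-frame reduction: `"max"` (default; global max
#'   pooling over nodes), `"mean"`, or `"flatten"` (node-feature
#'   concatenation, preserving node-localized patterns -- used by the
#'   identification benchmark).
#' @param edge_mlp_depth linear+ReLU sublayers inside each EdgeConv block
#'   (default 1).
#' @param batch_norm batch-normalize each conv layer's aggregated node
#'   features (default TRUE); inference uses running statistics accumulated
#'   during training.
#' @return A `cgcn_config` list.
#' @export
cgcn_config <- function(n_conv_layers = 5,
                        features_per_layer = c(8, 8, 16, 16, 32),
                        temporal_head = c("average_pool", "recurrent"),
                        recurrent_hidden = 32,
                        n_classes = 2,
                        l2_lambda = 0,
                        skip_connections = TRUE,
                        node_pool = c("max", "mean", "flatten"),
                        edge_mlp_depth = 1,
                        batch_norm = TRUE) {
  temporal_head <- match.arg(temporal_head)
  node_pool <- match.arg(node_pool)
  features_per_layer <- as.integer(features_per_layer)
  if (length(features_per_layer) != n_conv_layers)
    stop("features_per_layer must have one width per conv layer (",
         n_conv_layers, ")")
  stopifnot(all(features_per_layer >= 1), n_classes >= 1, l2_lambda >= 0,
            recurrent_hidden >= 1, edge_mlp_depth >= 1)
  structure(list(
    n_conv_layers = as.integer(n_conv_layers),
    features_per_layer = features_per_layer,
    temporal_head = temporal_head,
    recurrent_hidden = as.integer(recurrent_hidden),
    n_classes = as.integer(n_classes),
    l2_lambda = l2_lambda,
    skip_connections = isTRUE(skip_connections),
    node_pool = node_pool,
    edge_mlp_depth = as.integer(edge_mlp_depth),
    batch_norm = isTRUE(batch_norm)
  ), class = "cgcn_config")
}

# input width of conv layer l given the chaining + skip rule (raw input F = 1)
.conv_input_width <- function(config, l) {
  f <- config$features_per_layer
  L <- config$n_conv_layers
  if (l == 1) 1L
  else if (l == L && config$skip_connections && L >= 2) sum(f[seq_len(L - 1)])
  else f[l - 1]
}

.embed_width <- function(config, n_nodes) {
  if (config$temporal_head == "recurrent") return(config$recurrent_hidden)
  f_top <- config$features_per_layer[config$n_conv_layers]
  if (config$node_pool == "flatten") n_nodes * f_top else f_top
}

.frame_width <- function(config, n_nodes) {
  f_top <- config$features_per_layer[config$n_conv_layers]
  if (config$node_pool == "flatten") n_nodes * f_top else f_top
}

#' Initialize a cGCN model bound to one graph
#'
#' Weights use fan-in-scaled Gaussian initialization; the LSTM forget-gate
#' bias starts at 1. The graph is fixed for the model's lifetime: the same
#' neighborhoods are shared by all subjects and all time frames.
#'
#' @param config a [cgcn_config()].
#' @param graph a `knn_graph` from [build_knn_graph()] or
#'   [build_random_graph()].
#' @param class_levels character vector of class labels in output order.
#' @param seed integer seed for weight initialization.
#' @return A `cgcn_model`.
#' @export
new_cgcn_model <- function(config, graph, class_levels, seed = 1L) {
  stopifnot(inherits(config, "cgcn_config"), inherits(graph, "knn_graph"))
  class_levels <- as.character(class_levels)
  if (length(class_levels) != config$n_classes)
    stop("class_levels length (", length(class_levels),
         ") must equal n_classes (", config$n_classes, ")")
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))

  he <- function(n_in, n_out)
    matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / n_in)), n_in, n_out)

  L <- config$n_conv_layers
  conv <- vector("list", L)
  for (l in seq_len(L)) {
    f_in <- .conv_input_width(config, l)
    f_out <- config$features_per_layer[l]
    widths <- c(2L * f_in, rep(f_out, config$edge_mlp_depth))
    subs <- vector("list", config$edge_mlp_depth)
    for (m in seq_len(config$edge_mlp_depth))
      subs[[m]] <- list(W = he(widths[m], widths[m + 1]),
                        b = numeric(widths[m + 1]))
    conv[[l]] <- subs
  }

  lstm <- NULL
  if (config$temporal_head == "recurrent") {
    f <- .frame_width(config, graph$n_nodes)
    h <- config$recurrent_hidden
    r <- 1 / sqrt(h)
    b <- numeric(4 * h)
    b[h + seq_len(h)] <- 1  # forget gate bias
    lstm <- list(
      Wx = matrix(stats::runif(f * 4 * h, -r, r), f, 4 * h),
      Wh = matrix(stats::runif(h * 4 * h, -r, r), h, 4 * h),
      b = b
    )
  }

  bn <- NULL
  if (config$batch_norm)
    bn <- lapply(seq_len(L), function(l) {
      f <- config$features_per_layer[l]
      list(gamma = rep(1, f), beta = numeric(f))
    })

  # linear softmax layer: gentler (Xavier) scale than the ReLU layers
  emb <- .embed_width(config, graph$n_nodes)
  cls <- list(W = matrix(stats::rnorm(emb * config$n_classes,
                                      sd = sqrt(1 / emb)),
                         emb, config$n_classes),
              b = numeric(config$n_classes))

  bn_stats <- NULL
  if (config$batch_norm)
    bn_stats <- lapply(seq_len(L), function(l) {
      f <- config$features_per_layer[l]
      list(mean = numeric(f), var = rep(1, f), n_updates = 0L)
    })

  structure(list(
    config = config, graph = graph, class_levels = class_levels,
    params = list(conv = conv, lstm = lstm, cls = cls, bn = bn),
    bn_stats = bn_stats,
    init_seed = as.integer(seed)
  ), class = "cgcn_model")
}

#' @export
print.cgcn_model <- function(x, ...) {
  cat(sprintf(
    "<cgcn_model> %d conv layers (%s), %s graph k=%d on %d nodes, head=%s, %d classes\n",
    x$config$n_conv_layers,
    paste(x$config$features_per_layer, collapse = ","),
    x$graph$kind, x$graph$k, x$graph$n_nodes,
    x$config$temporal_head, x$config$n_classes))
  invisible(x)
}

# ---- batched tensor plumbing ------------------------------------------------
# A batch of B clips of T frames over N nodes is one (B*T*N) x F matrix whose
# rows are ordered clip-major, then frame, then node.

# Shared layout info for a batch: rows are node-major within each of the
# n_blocks frames, so an M x F matrix (M = n_blocks * n) can be viewed as an
# n x (n_blocks * F) matrix by a free dim change; all neighbor gathers and
# scatters then index just the n graph rows via the base neighbor table.
.batch_indices <- function(graph, n_blocks) {
  list(n = graph$n_nodes, k = graph$k, n_blocks = n_blocks,
       nbrs = graph$neighbors)
}

# edge-row index vectors for the generic (deep-MLP) path
.edge_index_vectors <- function(idx) {
  n <- idx$n
  k <- idx$k
  base_nbr <- as.vector(t(idx$nbrs))
  base_ctr <- rep(seq_len(n), each = k)
  offs <- rep((seq_len(idx$n_blocks) - 1L) * n, each = n * k)
  list(ctr = offs + rep(base_ctr, idx$n_blocks),
       nbr = offs + rep(base_nbr, idx$n_blocks))
}

# gather neighbor slot j: rows m -> rows of the j-th neighbor of node(m)
.gather_neighbor <- function(X, idx, j) {
  m <- nrow(X)
  f <- ncol(X)
  dim(X) <- c(idx$n, m / idx$n * f)
  G <- X[idx$nbrs[, j], , drop = FALSE]
  dim(G) <- c(m, f)
  G
}

# feature-wise max over consecutive groups of `size` rows, with argmax
.max_over_groups <- function(A, size) {
  m <- nrow(A) %/% size
  f <- ncol(A)
  out <- A[seq(1L, by = size, length.out = m), , drop = FALSE]
  arg <- matrix(1L, m, f)
  if (size > 1) {
    for (j in 2:size) {
      Aj <- A[seq(j, by = size, length.out = m), , drop = FALSE]
      w <- Aj > out
      out[w] <- Aj[w]
      arg[w] <- j
    }
  }
  list(values = out, argmax = arg)
}

# scatter upstream gradient back to the argmax rows of the grouped matrix
.scatter_max_grad <- function(d_out, argmax, size) {
  m <- nrow(d_out)
  f <- ncol(d_out)
  dA <- matrix(0, m * size, f)
  ridx <- (seq_len(m) - 1L) * size + as.vector(argmax)
  dA[cbind(ridx, rep(seq_len(f), each = m))] <- as.vector(d_out)
  dA
}

.add_bias <- function(Z, b) Z + rep(b, each = nrow(Z))

# one EdgeConv layer, batched over frames; returns output + caches.
#
# Depth-1 fast path: with a single linear+ReLU unit and W = rbind(Wc, Wn)
# (central block, difference block), the edge activation is
#   relu(x_i (Wc - Wn) + x_j Wn + b),
# so P = H (Wc - Wn) + b and Q = H Wn are computed once per node and each of
# the k candidates is P + Q[neighbor]. Because relu is monotone the max can be
# taken on the pre-activation, and relu(max) routes gradient through exactly
# one edge per (node, feature) -- no edge-sized matrices are ever formed.
.edge_layer_forward <- function(H, idx, subs, k) {
  if (length(subs) == 1) {
    W <- subs[[1]]$W
    f_in <- ncol(H)
    f_out <- ncol(W)
    Wc <- W[seq_len(f_in), , drop = FALSE]
    Wn <- W[f_in + seq_len(f_in), , drop = FALSE]
    P <- .add_bias(H %*% (Wc - Wn), subs[[1]]$b)
    Q <- H %*% Wn
    m <- nrow(P)
    if (k == 1) {
      Z <- P + .gather_neighbor(Q, idx, 1L)
      return(list(out = pmax(Z, 0), argmax = matrix(1L, m, f_out),
                  fast = TRUE))
    }
    cand <- matrix(0, m * f_out, k)
    for (j in seq_len(k))
      cand[, j] <- P + .gather_neighbor(Q, idx, j)
    arg <- max.col(cand, ties.method = "first")
    Z <- matrix(cand[(arg - 1L) * (m * f_out) + seq_len(m * f_out)], m, f_out)
    return(list(out = pmax(Z, 0), argmax = matrix(arg, m, f_out),
                fast = TRUE))
  }
  ev <- .edge_index_vectors(idx)
  idx <- c(idx, ev)
  Hc <- H[idx$ctr, , drop = FALSE]
  A <- cbind(Hc, H[idx$nbr, , drop = FALSE] - Hc)
  acts <- vector("list", length(subs))
  for (m in seq_along(subs)) {
    A <- pmax(.add_bias(A %*% subs[[m]]$W, subs[[m]]$b), 0)
    acts[[m]] <- A
  }
  mx <- .max_over_groups(A, k)
  list(out = mx$values, acts = acts, argmax = mx$argmax, fast = FALSE)
}

.edge_layer_backward <- function(d_out, H, idx, subs, cache, k) {
  if (isTRUE(cache$fast)) {
    W <- subs[[1]]$W
    f_in <- ncol(H)
    f_out <- ncol(d_out)
    m_rows <- nrow(d_out)
    n <- idx$n
    wide <- m_rows / n * f_out
    Wc <- W[seq_len(f_in), , drop = FALSE]
    Wn <- W[f_in + seq_len(f_in), , drop = FALSE]
    S_c <- d_out * (cache$out > 0)         # grad on P at the selected edge
    S_n <- matrix(0, n, wide)              # grad on Q, scattered to neighbors
    for (j in seq_len(k)) {
      Mj <- S_c * (cache$argmax == j)
      dim(Mj) <- c(n, wide)
      acc <- rowsum(Mj, idx$nbrs[, j])
      rows <- as.integer(rownames(acc))
      S_n[rows, ] <- S_n[rows, , drop = FALSE] + acc
    }
    dim(S_n) <- c(m_rows, f_out)
    dA <- crossprod(H, S_c)                # gradient wrt (Wc - Wn)
    dB <- crossprod(H, S_n)                # gradient wrt Wn (Q route)
    dW <- rbind(dA, dB - dA)
    dH <- S_c %*% t(Wc - Wn) + S_n %*% t(Wn)
    return(list(dH = dH,
                dsubs = list(list(W = dW, b = colSums(S_c)))))
  }
  ev <- .edge_index_vectors(idx)
  idx <- c(idx, ev)
  dA <- .scatter_max_grad(d_out, cache$argmax, k)
  depth <- length(subs)
  dsubs <- vector("list", depth)
  Hc <- H[idx$ctr, , drop = FALSE]
  E <- cbind(Hc, H[idx$nbr, , drop = FALSE] - Hc)
  for (m in depth:1) {
    dZ <- dA * (cache$acts[[m]] > 0)
    A_in <- if (m == 1) E else cache$acts[[m - 1]]
    dsubs[[m]] <- list(W = crossprod(A_in, dZ), b = colSums(dZ))
    dA <- tcrossprod(dZ, subs[[m]]$W)
  }
  f_in <- ncol(H)
  dHc <- dA[, seq_len(f_in), drop = FALSE]
  dD <- dA[, f_in + seq_len(f_in), drop = FALSE]
  dH <- rowsum(dHc - dD, idx$ctr)          # every group 1..M present, sorted
  nb <- rowsum(dD, idx$nbr)
  rows <- as.integer(rownames(nb))
  dH[rows, ] <- dH[rows, , drop = FALSE] + nb
  list(dH = dH, dsubs = dsubs)
}

# batch normalization over node rows, one statistic per feature channel
.bn_forward <- function(H, par, stats, training, momentum = 0.9, eps = 1e-5) {
  if (training) {
    mu <- colMeans(H)
    va <- colMeans(H^2) - mu^2
    new_stats <- list(
      mean = if (stats$n_updates == 0L) mu else momentum * stats$mean + (1 - momentum) * mu,
      var = if (stats$n_updates == 0L) va else momentum * stats$var + (1 - momentum) * va,
      n_updates = stats$n_updates + 1L)
  } else {
    mu <- stats$mean
    va <- stats$var
    new_stats <- stats
  }
  m <- nrow(H)
  inv_std <- 1 / sqrt(va + eps)
  xhat <- (H - rep(mu, each = m)) * rep(inv_std, each = m)
  out <- xhat * rep(par$gamma, each = m) + rep(par$beta, each = m)
  list(out = out, xhat = xhat, inv_std = inv_std, new_stats = new_stats)
}

.bn_backward <- function(dY, par, cache) {
  m <- nrow(dY)
  dgamma <- colSums(dY * cache$xhat)
  dbeta <- colSums(dY)
  dxhat <- dY * rep(par$gamma, each = m)
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * cache$xhat)
  dH <- (dxhat - (rep(s1, each = m) + cache$xhat * rep(s2, each = m)) / m) *
    rep(cache$inv_std, each = m)
  list(dH = dH, dpar = list(gamma = dgamma, beta = dbeta))
}

.softmax_rows <- function(logits) {
  z <- exp(logits - apply(logits, 1, max))
  z / rowSums(z)
}

# Full forward pass over a stacked batch. H0: (B*T*N) x 1 matrix.
.cgcn_batch_forward <- function(model, H0, n_clips, n_frames, keep_cache = FALSE) {
  cfg <- model$config
  g <- model$graph
  n <- g$n_nodes
  L <- cfg$n_conv_layers
  n_blocks <- n_clips * n_frames
  idx <- .batch_indices(g, n_blocks)

  H_out <- vector("list", L)
  caches <- if (keep_cache) vector("list", L) else NULL
  inputs <- if (keep_cache) vector("list", L) else NULL
  bn_caches <- if (keep_cache) vector("list", L) else NULL
  new_bn_stats <- model$bn_stats
  H_prev <- H0
  for (l in seq_len(L)) {
    H_in <- if (l == L && cfg$skip_connections && L >= 2)
      do.call(cbind, H_out[seq_len(L - 1)]) else H_prev
    lay <- .edge_layer_forward(H_in, idx, model$params$conv[[l]], g$k)
    H_l <- lay$out
    if (cfg$batch_norm) {
      bn <- .bn_forward(H_l, model$params$bn[[l]], model$bn_stats[[l]],
                        training = keep_cache)
      H_l <- bn$out
      new_bn_stats[[l]] <- bn$new_stats
      if (keep_cache) bn_caches[[l]] <- bn[c("xhat", "inv_std")]
    }
    H_out[[l]] <- H_l
    H_prev <- H_l
    if (keep_cache) {
      caches[[l]] <- lay[c("acts", "argmax", "out", "fast")]
      inputs[[l]] <- H_in
    }
  }

  # node -> frame embedding
  HL <- H_out[[L]]
  node_arg <- NULL
  if (cfg$node_pool == "max") {
    np <- .max_over_groups(HL, n)
    frame_emb <- np$values
    node_arg <- np$argmax
  } else if (cfg$node_pool == "mean") {
    frame_emb <- rowsum(HL, rep(seq_len(n_blocks), each = n)) / n
  } else {
    # flatten: frame embedding = concatenation of all node features
    frame_emb <- HL
    dim(frame_emb) <- c(n, n_blocks, ncol(HL))
    frame_emb <- aperm(frame_emb, c(2, 1, 3))
    dim(frame_emb) <- c(n_blocks, n * ncol(HL))
  }

  # temporal head -> clip embedding
  lstm_cache <- NULL
  if (cfg$temporal_head == "average_pool") {
    clip_emb <- rowsum(frame_emb, rep(seq_len(n_clips), each = n_frames)) / n_frames
  } else {
    p <- model$params$lstm
    hdim <- cfg$recurrent_hidden
    B <- n_clips
    h <- matrix(0, B, hdim)
    cc <- matrix(0, B, hdim)
    steps <- if (keep_cache) vector("list", n_frames) else NULL
    hs <- if (keep_cache) vector("list", n_frames + 1) else NULL
    if (keep_cache) hs[[1]] <- h
    sig <- function(x) 1 / (1 + exp(-x))
    for (t in seq_len(n_frames)) {
      Xt <- frame_emb[(seq_len(B) - 1L) * n_frames + t, , drop = FALSE]
      G <- .add_bias(Xt %*% p$Wx + h %*% p$Wh, p$b)
      i_g <- sig(G[, seq_len(hdim), drop = FALSE])
      f_g <- sig(G[, hdim + seq_len(hdim), drop = FALSE])
      g_g <- tanh(G[, 2 * hdim + seq_len(hdim), drop = FALSE])
      o_g <- sig(G[, 3 * hdim + seq_len(hdim), drop = FALSE])
      c_prev <- cc
      cc <- f_g * c_prev + i_g * g_g
      h <- o_g * tanh(cc)
      if (keep_cache) {
        steps[[t]] <- list(i = i_g, f = f_g, g = g_g, o = o_g,
                           c = cc, c_prev = c_prev, X = Xt)
        hs[[t + 1]] <- h
      }
    }
    clip_emb <- h
    if (keep_cache) lstm_cache <- list(steps = steps, hs = hs)
  }

  logits <- .add_bias(clip_emb %*% model$params$cls$W, model$params$cls$b)
  probs <- .softmax_rows(logits)

  out <- list(probs = probs, logits = logits, new_bn_stats = new_bn_stats)
  if (keep_cache)
    out$cache <- list(H0 = H0, H_out = H_out, inputs = inputs, caches = caches,
                      bn_caches = bn_caches,
                      idx = idx, node_arg = node_arg, frame_emb = frame_emb,
                      clip_emb = clip_emb, lstm = lstm_cache,
                      n_clips = n_clips, n_frames = n_frames)
  out
}

# Cross-entropy loss + full backward pass; returns grads in the params layout.
.cgcn_loss_and_grads <- function(model, H0, y_idx, n_clips, n_frames) {
  cfg <- model$config
  fw <- .cgcn_batch_forward(model, H0, n_clips, n_frames, keep_cache = TRUE)
  cache <- fw$cache
  B <- n_clips
  probs <- fw$probs
  eps <- 1e-12
  data_loss <- -mean(log(pmax(probs[cbind(seq_len(B), y_idx)], eps)))

  l2 <- cfg$l2_lambda
  l2_loss <- 0
  if (l2 > 0) {
    wsum <- sum(vapply(unlist(model$params$conv, recursive = FALSE),
                       function(s) sum(s$W^2), numeric(1)))
    wsum <- wsum + sum(model$params$cls$W^2)
    if (!is.null(model$params$lstm))
      wsum <- wsum + sum(model$params$lstm$Wx^2) + sum(model$params$lstm$Wh^2)
    l2_loss <- l2 * wsum
  }

  # classifier
  Y <- matrix(0, B, cfg$n_classes)
  Y[cbind(seq_len(B), y_idx)] <- 1
  dlogits <- (probs - Y) / B
  dcls <- list(W = crossprod(cache$clip_emb, dlogits), b = colSums(dlogits))
  dclip <- tcrossprod(dlogits, model$params$cls$W)

  # temporal head backward -> gradient on frame embeddings
  n <- model$graph$n_nodes
  n_blocks <- B * n_frames
  dlstm <- NULL
  if (cfg$temporal_head == "average_pool") {
    dframe <- dclip[rep(seq_len(B), each = n_frames), , drop = FALSE] / n_frames
  } else {
    p <- model$params$lstm
    hdim <- cfg$recurrent_hidden
    lc <- cache$lstm
    dframe <- matrix(0, n_blocks, ncol(cache$frame_emb))
    dWx <- array(0, dim(p$Wx)); dWh <- array(0, dim(p$Wh)); db <- numeric(length(p$b))
    dh <- dclip
    dc <- matrix(0, B, hdim)
    for (t in rev(seq_len(n_frames))) {
      st <- lc$steps[[t]]
      tc <- tanh(st$c)
      do_g <- dh * tc * st$o * (1 - st$o)
      dc <- dc + dh * st$o * (1 - tc^2)
      di <- dc * st$g * st$i * (1 - st$i)
      dg <- dc * st$i * (1 - st$g^2)
      df <- dc * st$c_prev * st$f * (1 - st$f)
      dG <- cbind(di, df, dg, do_g)
      dWx <- dWx + crossprod(st$X, dG)
      dWh <- dWh + crossprod(lc$hs[[t]], dG)
      db <- db + colSums(dG)
      dframe[(seq_len(B) - 1L) * n_frames + t, ] <- tcrossprod(dG, p$Wx)
      dh <- tcrossprod(dG, p$Wh)
      dc <- dc * st$f
    }
    dlstm <- list(Wx = dWx, Wh = dWh, b = db)
  }

  # node pooling backward -> gradient on last conv output
  f_top <- cfg$features_per_layer[cfg$n_conv_layers]
  if (cfg$node_pool == "max") {
    dHL <- .scatter_max_grad(dframe, cache$node_arg, n)
  } else if (cfg$node_pool == "mean") {
    dHL <- dframe[rep(seq_len(n_blocks), each = n), , drop = FALSE] / n
  } else {
    dHL <- dframe
    dim(dHL) <- c(n_blocks, n, f_top)
    dHL <- aperm(dHL, c(2, 1, 3))
    dim(dHL) <- c(n_blocks * n, f_top)
  }

  # conv stack backward
  L <- cfg$n_conv_layers
  dconv <- vector("list", L)
  dbn <- if (cfg$batch_norm) vector("list", L) else NULL
  dH_out <- vector("list", L)
  dH_out[[L]] <- dHL
  f <- cfg$features_per_layer
  for (l in L:1) {
    d_l <- dH_out[[l]]
    if (cfg$batch_norm) {
      bnb <- .bn_backward(d_l, model$params$bn[[l]], cache$bn_caches[[l]])
      d_l <- bnb$dH
      dbn[[l]] <- bnb$dpar
    }
    bk <- .edge_layer_backward(d_l, cache$inputs[[l]], cache$idx,
                               model$params$conv[[l]], cache$caches[[l]],
                               model$graph$k)
    dconv[[l]] <- bk$dsubs
    if (l == L && cfg$skip_connections && L >= 2) {
      col0 <- 0L
      for (j in seq_len(L - 1)) {
        part <- bk$dH[, col0 + seq_len(f[j]), drop = FALSE]
        dH_out[[j]] <- if (is.null(dH_out[[j]])) part else dH_out[[j]] + part
        col0 <- col0 + f[j]
      }
    } else if (l >= 2) {
      dH_out[[l - 1]] <- if (is.null(dH_out[[l - 1]])) bk$dH
        else dH_out[[l - 1]] + bk$dH
    }
  }

  # L2 gradient on weight matrices
  if (l2 > 0) {
    for (l in seq_len(L))
      for (m in seq_along(dconv[[l]]))
        dconv[[l]][[m]]$W <- dconv[[l]][[m]]$W + 2 * l2 * model$params$conv[[l]][[m]]$W
    dcls$W <- dcls$W + 2 * l2 * model$params$cls$W
    if (!is.null(dlstm)) {
      dlstm$Wx <- dlstm$Wx + 2 * l2 * model$params$lstm$Wx
      dlstm$Wh <- dlstm$Wh + 2 * l2 * model$params$lstm$Wh
    }
  }

  list(loss = data_loss + l2_loss, data_loss = data_loss,
       grads = list(conv = dconv, lstm = dlstm, cls = dcls, bn = dbn),
       probs = probs, new_bn_stats = fw$new_bn_stats)
}

# stack a list of T x N clips into the batched (B*T*N) x 1 layout
.stack_clips <- function(clips) {
  matrix(unlist(lapply(clips, function(x) as.vector(t(x))), use.names = FALSE),
         ncol = 1)
}

#' One EdgeConv graph convolution
#'
#' Applies the asymmetric edge function to one frame of node features: for
#' every node i the MLP sees the concatenation of the central features x_i and
#' the neighbor difference x_j - x_i for each of its k out-neighbors j, and
#' the output is the feature-wise maximum over the k activations.
#'
#' @param x N x F numeric matrix of node features (one frame).
#' @param graph a `knn_graph` with N nodes.
#' @param mlp either a single `list(W, b)` (one linear + ReLU unit with W of
#'   size 2F x F_out) or a list of such sublayers for a deeper MLP.
#' @return An N x F_out matrix.
#' @export
edgeconv_forward <- function(x, graph, mlp) {
  x <- as.matrix(x)
  if (nrow(x) != graph$n_nodes)
    stop("x has ", nrow(x), " rows but the graph has ", graph$n_nodes, " nodes")
  if (!is.null(mlp$W)) mlp <- list(mlp)
  if (nrow(mlp[[1]]$W) != 2 * ncol(x))
    stop("edge MLP input width ", nrow(mlp[[1]]$W),
         " does not match 2*F = ", 2 * ncol(x))
  idx <- .batch_indices(graph, 1L)
  .edge_layer_forward(x, idx, mlp, graph$k)$out
}

#' Class probabilities for one clip
#'
#' Runs every frame of the clip through the conv stack on the model's shared
#' graph, pools nodes to per-frame embeddings, applies the temporal head over
#' the frames, and returns softmax class probabilities.
#'
#' @param model a `cgcn_model`.
#' @param clip T x N numeric matrix with N matching the model's graph.
#' @return Named numeric vector of class probabilities (sums to 1).
#' @export
cgcn_forward <- function(model, clip) {
  clip <- as.matrix(clip)
  if (nrow(clip) < 1) stop("clip must have at least one frame")
  if (ncol(clip) != model$graph$n_nodes)
    stop("clip has ", ncol(clip), " columns but the graph has ",
         model$graph$n_nodes, " nodes")
  fw <- .cgcn_batch_forward(model, .stack_clips(list(clip)), 1L, nrow(clip))
  stats::setNames(as.numeric(fw$probs[1, ]), model$class_levels)
}

#' Predict class probabilities for a batch of clips
#'
#' @param object a `cgcn_model`.
#' @param clips a single T x N matrix or a list of T x N matrices with equal
#'   T.
#' @param ... unused.
#' @return A B x n_classes matrix of probabilities, columns named by class.
#' @export
predict.cgcn_model <- function(object, clips, ...) {
  if (is.matrix(clips)) clips <- list(clips)
  Ts <- vapply(clips, nrow, integer(1))
  if (length(unique(Ts)) != 1)
    stop("all clips in a batch must have the same number of frames")
  ns <- vapply(clips, ncol, integer(1))
  if (any(ns != object$graph$n_nodes))
    stop("clip width does not match the model's graph")
  fw <- .cgcn_batch_forward(object, .stack_clips(clips), length(clips), Ts[1])
  colnames(fw$probs) <- object$class_levels
  fw$probs
}

#' Multi-hop receptive field of each node
#'
#' Set of nodes reachable from each node by following at most `n_layers`
#' directed edges (including the node itself). Stacking L conv layers lets a
#' node aggregate information from exactly this set.
#'
#' @param graph a `knn_graph`.
#' @param n_layers number of hops L >= 1.
#' @return List of length N; element i is the sorted integer vector of nodes
#'   reachable from node i.
#' @export
receptive_field <- function(graph, n_layers) {
  stopifnot(n_layers >= 1)
  n <- graph$n_nodes
  lapply(seq_len(n), function(i) {
    reached <- i
    frontier <- i
    for (h in seq_len(n_layers)) {
      if (length(frontier) == 0) break
      nxt <- unique(as.vector(graph$neighbors[frontier, , drop = FALSE]))
      frontier <- setdiff(nxt, reached)
      reached <- c(reached, frontier)
    }
    sort(reached)
  })
}
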