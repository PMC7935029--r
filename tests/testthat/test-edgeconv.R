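test_that("edgeconv_forward matches naive per-node enumeration", {
  set.seed(55)
  worst <- 0
  for (rep in 1:50) {
    n <- sample(5:20, 1)
    k <- sample(seq_len(min(5, n - 1)), 1)
    f_in <- sample(1:4, 1)
    f_out <- sample(1:5, 1)
    g <- build_random_graph(n, k, seed = rep)
    x <- matrix(rnorm(n * f_in), n, f_in)
    W <- matrix(rnorm(2 * f_in * f_out), 2 * f_in, f_out)
    b <- rnorm(f_out)
    worst <- max(worst, max(abs(edgeconv_forward(x, g, list(W = W, b = b)) -
                                  naive_edgeconv(x, g, W, b))))
  }
  expect_lt(worst, 1e-6)
})

test_that("a hand-set single unit reproduces the worked edge-function example", {
  # h(a, d) = ReLU(a + 2 d); center x = 1, neighbors {2, 0}
  g <- structure(list(n_nodes = 3L, k = 2L,
                      neighbors = rbind(c(2L, 3L), c(1L, 3L), c(1L, 2L)),
                      edge_values = matrix(NA_real_, 3, 2), kind = "random"),
                 class = "knn_graph")
  x <- matrix(c(1, 2, 0), 3, 1)
  out <- edgeconv_forward(x, g, list(W = matrix(c(1, 2), 2, 1), b = 0))
  # node 1: max(ReLU(1 + 2*1), ReLU(1 + 2*(-1))) = 3
  expect_equal(out[1, 1], 3)
  # node 2: max(ReLU(2 - 2), ReLU(2 - 4)) = 0
  expect_equal(out[2, 1], 0)
  # node 3: max(ReLU(0 + 2), ReLU(0 + 4)) = 4
  expect_equal(out[3, 1], 4)
})

test_that("identical neighborhoods collapse to the central-feature term", {
  g <- build_random_graph(6, 3, seed = 2)
  x <- matrix(2.5, 6, 2)  # every node identical, so all differences vanish
  W <- matrix(rnorm(4 * 3), 4, 3)
  b <- rnorm(3)
  out <- edgeconv_forward(x, g, list(W = W, b = b))
  expected <- pmax(as.numeric(c(2.5, 2.5, 0, 0) %*% W + b), 0)
  for (i in 1:6) expect_equal(as.numeric(out[i, ]), expected)
})

test_that("an identity-passthrough MLP returns ReLU of the input", {
  set.seed(3)
  g <- build_random_graph(8, 2, seed = 4)
  x <- matrix(rnorm(16), 8, 2)
  W <- rbind(diag(2), matrix(0, 2, 2))  # copies x_i, ignores the difference
  out <- edgeconv_forward(x, g, list(W = W, b = c(0, 0)))
  expect_equal(out, pmax(x, 0))
})

test_that("edgeconv output is invariant to neighbor-list order", {
  set.seed(6)
  g <- build_random_graph(12, 4, seed = 9)
  x <- matrix(rnorm(12 * 3), 12, 3)
  mlp <- list(W = matrix(rnorm(6 * 5), 6, 5), b = rnorm(5))
  base <- edgeconv_forward(x, g, mlp)
  for (rep in 1:5) {
    g2 <- g
    for (i in 1:12) g2$neighbors[i, ] <- sample(g$neighbors[i, ])
    expect_equal(edgeconv_forward(x, g2, mlp), base)
  }
})

test_that("deep edge MLPs run through the generic path consistently", {
  # a 2-layer MLP whose second layer is identity must equal the 1-layer MLP
  set.seed(13)
  g <- build_random_graph(10, 3, seed = 13)
  x <- matrix(abs(rnorm(10 * 2)), 10, 2)
  W1 <- matrix(rnorm(4 * 3), 4, 3)
  b1 <- rnorm(3)
  one <- edgeconv_forward(x, g, list(W = W1, b = b1))
  two <- edgeconv_forward(x, g, list(list(W = W1, b = b1),
                                     list(W = diag(3), b = rep(0, 3))))
  expect_equal(two, one, tolerance = 1e-12)
})

test_that("cgcn_forward returns a proper probability vector", {
  model <- tiny_model()
  clip <- random_clip(12)
  p <- cgcn_forward(model, clip)
  expect_length(p, 2)
  expect_named(p, c("class1", "class2"))
  expect_true(all(p >= 0))
  expect_equal(sum(p), 1, tolerance = 1e-6)
  expect_error(cgcn_forward(model, clip[, 1:5]), "nodes")
})

test_that("with the average-pool head, repeated frames equal a single frame", {
  model <- tiny_model()
  one <- random_clip(1, seed = 8)
  many <- one[rep(1, 7), , drop = FALSE]
  expect_equal(cgcn_forward(model, many), cgcn_forward(model, one),
               tolerance = 1e-9)
})

test_that("probabilities are invariant under consistent node relabeling", {
  g <- build_random_graph(15, 3, seed = 10)
  cfg <- cgcn_config(n_conv_layers = 3, features_per_layer = c(4, 4, 8),
                     n_classes = 3, node_pool = "max")
  model <- new_cgcn_model(cfg, g, c("a", "b", "c"), seed = 5)
  clip <- random_clip(6, 15, seed = 11)
  base <- cgcn_forward(model, clip)
  set.seed(77)
  for (rep in 1:10) {
    perm <- sample(15)
    g2 <- g
    g2$neighbors[perm, ] <- matrix(perm[g$neighbors], 15, 3)
    m2 <- model
    m2$graph <- g2
    expect_equal(cgcn_forward(m2, clip[, order(perm), drop = FALSE]), base,
                 tolerance = 1e-9)
  }
})

test_that("receptive fields match breadth-first search", {
  g <- build_random_graph(14, 3, seed = 21)
  for (L in 1:3) {
    rf <- receptive_field(g, L)
    for (i in c(1, 7, 14)) expect_equal(rf[[i]], naive_reachable(g, i, L))
  }
  # L = 1: self plus out-neighbors
  rf1 <- receptive_field(g, 1)
  for (i in 1:14) {
    expect_equal(rf1[[i]], sort(c(i, g$neighbors[i, ])))
    expect_lte(length(rf1[[i]]), 4)
  }
  # directed 5-cycle with k = 1: exactly 3 nodes within 2 hops
  cyc <- structure(list(n_nodes = 5L, k = 1L,
                        neighbors = matrix(c(2L, 3L, 4L, 5L, 1L), 5, 1),
                        edge_values = matrix(NA_real_, 5, 1), kind = "random"),
                   class = "knn_graph")
  expect_true(all(lengths(receptive_field(cyc, 2)) == 3))
  # complete graph, one hop reaches everyone
  full <- build_knn_graph(matrix(0.5, 6, 6) + diag(0.5, 6), 5)
  expect_true(all(lengths(receptive_field(full, 1)) == 6))
})

test_that("perturbing one node only reaches its multi-hop dependents", {
  # chain the conv op directly (no normalization), 2 layers
  set.seed(30)
  g <- build_random_graph(12, 2, seed = 31)
  mlp1 <- list(W = matrix(rnorm(2 * 3), 2, 3), b = rnorm(3))
  mlp2 <- list(W = matrix(rnorm(6 * 3), 6, 3), b = rnorm(3))
  fwd <- function(x) edgeconv_forward(edgeconv_forward(x, g, mlp1), g, mlp2)
  x <- matrix(rnorm(12), 12, 1)
  base <- fwd(x)
  # nodes whose 2-hop receptive field contains u may change; others must not
  rf <- receptive_field(g, 2)
  for (u in c(2, 9)) {
    x2 <- x
    x2[u, 1] <- x2[u, 1] + 3
    delta <- rowSums(abs(fwd(x2) - base)) > 1e-12
    dependents <- which(vapply(rf, function(s) u %in% s, logical(1)))
    expect_true(all(which(delta) %in% dependents))
  }
})

test_that("analytic gradients match numerical differentiation", {
  numeric_check <- function(head, node_pool, depth = 1) {
    g <- build_random_graph(6, 2, seed = 3)
    cfg <- cgcn_config(n_conv_layers = 3, features_per_layer = c(3, 2, 4),
                       temporal_head = head, recurrent_hidden = 3,
                       n_classes = 2, l2_lambda = 0.01, node_pool = node_pool,
                       edge_mlp_depth = depth)
    model <- new_cgcn_model(cfg, g, c("a", "b"), seed = 7)
    set.seed(19)
    # jitter off the ReLU kinks that zero-initialized biases sit on
    model$params <- rapply(model$params, function(x)
      x + rnorm(length(x), sd = 0.05), how = "replace")
    H0 <- matrix(rnorm(3 * 4 * 6), ncol = 1)
    y <- c(1L, 2L, 1L)
    loss_of <- function(m) cgcn:::.cgcn_loss_and_grads(m, H0, y, 3L, 4L)$loss
    an <- cgcn:::.cgcn_loss_and_grads(model, H0, y, 3L, 4L)$grads
    worst <- 0
    probe <- function(get, set, agrad) {
      p <- get(model)
      for (i in seq_along(p)) {
        m1 <- set(model, i, p[i] + 1e-5)
        m2 <- set(model, i, p[i] - 1e-5)
        worst <<- max(worst, abs(agrad[i] - (loss_of(m1) - loss_of(m2)) / 2e-5))
      }
    }
    for (l in 1:3) for (s in seq_len(depth)) for (w in c("W", "b"))
      probe(function(m) m$params$conv[[l]][[s]][[w]],
            function(m, i, v) { m$params$conv[[l]][[s]][[w]][i] <- v; m },
            an$conv[[l]][[s]][[w]])
    for (l in 1:3) for (w in c("gamma", "beta"))
      probe(function(m) m$params$bn[[l]][[w]],
            function(m, i, v) { m$params$bn[[l]][[w]][i] <- v; m },
            an$bn[[l]][[w]])
    for (w in c("W", "b"))
      probe(function(m) m$params$cls[[w]],
            function(m, i, v) { m$params$cls[[w]][i] <- v; m },
            an$cls[[w]])
    if (head == "recurrent")
      for (w in c("Wx", "Wh", "b"))
        probe(function(m) m$params$lstm[[w]],
              function(m, i, v) { m$params$lstm[[w]][i] <- v; m },
              an$lstm[[w]])
    worst
  }
  expect_lt(numeric_check("average_pool", "flatten"), 1e-5)
  expect_lt(numeric_check("average_pool", "max"), 1e-5)
  expect_lt(numeric_check("average_pool", "mean", depth = 2), 1e-5)
  expect_lt(numeric_check("recurrent", "max"), 1e-4)
})

test_that("checkpoints reload to bit-identical forward outputs", {
  model <- tiny_model(n_classes = 3)
  clip <- random_clip(9)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(model, path)
  reloaded <- load_checkpoint(path)
  expect_identical(cgcn_forward(reloaded, clip), cgcn_forward(model, clip))
  unlink(path)
})
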