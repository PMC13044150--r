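test_that("khopSubgraph follows breadth-first expansion", {
  # path graph 1-2-3-4-5
  A <- matrix(0, 5, 5)
  for (i in 1:4) A[i, i + 1] <- A[i + 1, i] <- 0.5
  expect_identical(khopSubgraph(A, 3, 1)$members, c(2L, 3L, 4L))
  k0 <- khopSubgraph(A, 3, 0)
  expect_identical(k0$members, 3L)
  expect_equal(nrow(k0$edges), 0)
  # k >= diameter reaches the whole connected component
  expect_identical(khopSubgraph(A, 1, 10)$members, 1:5)
  # induced edges are restricted to members
  e <- khopSubgraph(A, 3, 1)$edges
  expect_true(all(e %in% 2:4))
  expect_equal(nrow(e), 2)
})

test_that("subgraphEmbed equals a hand-unrolled message-passing oracle", {
  # 4-node fixture, fixed small-integer weights, 2 features
  A <- matrix(0, 4, 4)
  A[1, 2] <- A[2, 1] <- 2
  A[2, 3] <- A[3, 2] <- -1
  A[3, 4] <- A[4, 3] <- 3
  X <- matrix(c(1, 0, 2, -1,
                0, 1, 1, 2), 4, 2)
  pg <- list(Ws1 = matrix(c(1, 0, 0, 1), 2), Wn1 = matrix(c(0, 1, 1, 0), 2),
             b1 = c(1, -1),
             Ws2 = matrix(c(2, 0, 0, 2), 2), Wn2 = matrix(c(1, 1, 0, 1), 2),
             b2 = c(0, 1))
  # oracle: explicit two rounds of weighted-sum message passing per node,
  # full-graph propagation (valid for k >= 2)
  m1 <- matrix(0, 4, 2)
  for (i in 1:4) {
    agg <- c(0, 0)
    for (j in 1:4) agg <- agg + A[i, j] * X[j, ]
    m1[i, ] <- pmax(drop(X[i, ] %*% pg$Ws1) + drop(agg %*% pg$Wn1) + pg$b1, 0)
  }
  expS <- matrix(0, 4, 2)
  for (i in 1:4) {
    agg <- c(0, 0)
    for (j in 1:4) agg <- agg + A[i, j] * m1[j, ]
    expS[i, ] <- drop(m1[i, ] %*% pg$Ws2) + drop(agg %*% pg$Wn2) + pg$b2
  }
  expect_equal(subgraphEmbed(X, A, 2, pg), expS, tolerance = 1e-12)

  # k = 1 restricts second-round messages to each root's 1-hop subgraph:
  # node 1's 1-hop subgraph {1,2} excludes the 2-3 edge, so its embedding
  # differs from full propagation whenever node 3 feeds node 2
  S1 <- subgraphEmbed(X, A, 1, pg)
  expect_false(isTRUE(all.equal(S1[1, ], expS[1, ])))
  # ... but matches an explicit subgraph-restricted oracle
  m <- c(1, 2)                           # members of root 1's subgraph
  Am <- A[m, m]; Xm <- X[m, , drop = FALSE]
  m1m <- matrix(0, 2, 2)
  for (i in 1:2) {
    agg <- c(0, 0)
    for (j in 1:2) agg <- agg + Am[i, j] * Xm[j, ]
    m1m[i, ] <- pmax(drop(Xm[i, ] %*% pg$Ws1) + drop(agg %*% pg$Wn1) +
                       pg$b1, 0)
  }
  agg <- Am[1, 1] * m1m[1, ] + Am[1, 2] * m1m[2, ]
  expect_equal(S1[1, ],
               drop(m1m[1, ] %*% pg$Ws2) + drop(agg %*% pg$Wn2) + pg$b2,
               tolerance = 1e-12)

  # k = 0: no neighbour influence at all
  S0 <- subgraphEmbed(X, A, 0, pg)
  X2 <- X; X2[2:4, ] <- X2[2:4, ] + 5    # perturb everything but node 1
  expect_equal(subgraphEmbed(X2, A, 0, pg)[1, ], S0[1, ], tolerance = 1e-12)
})

test_that("isomorphic subgraphs with identical features embed identically", {
  # 4-cycle with equal weights: all nodes structurally equivalent
  A <- matrix(0, 4, 4)
  for (e in list(c(1, 2), c(2, 3), c(3, 4), c(4, 1)))
    A[e[1], e[2]] <- A[e[2], e[1]] <- 0.7
  X <- matrix(1, 4, 3)
  set.seed(5)
  pg <- list(Ws1 = matrix(rnorm(9), 3), Wn1 = matrix(rnorm(9), 3),
             b1 = rnorm(3), Ws2 = matrix(rnorm(9), 3),
             Wn2 = matrix(rnorm(9), 3), b2 = rnorm(3))
  S <- subgraphEmbed(X, A, 2, pg)
  for (i in 2:4) expect_equal(S[i, ], S[1, ], tolerance = 1e-12)
})

test_that("satLayer attention is a proper distribution and equivariant", {
  cfg <- satConfig(hidden_dim = 8, n_heads = 2, dropout_rate = 0)
  model <- tinyModel(c(a = 10L), hidden_dim = 8, n_heads = 2,
                     dropout_rate = 0)
  lp <- model@params$enc$a$layers[[1]]
  g <- randGraphTensors(10, seed = 3)
  set.seed(4)
  H <- matrix(rnorm(10 * 8), 10, 8)
  out <- satLayer(H, g$A, lp, cfg, return_attention = TRUE)
  for (Aj in out$attention) {
    expect_true(all(Aj >= 0))
    expect_equal(rowSums(Aj), rep(1, 10), tolerance = 1e-6)
  }
  expect_identical(dim(out$states), dim(H))

  # single-node graph: the node attends to itself with weight 1
  one <- satLayer(matrix(rnorm(8), 1, 8), matrix(0, 1, 1), lp, cfg,
                  return_attention = TRUE)
  for (Aj in one$attention) expect_equal(Aj[1, 1], 1)

  # permutation equivariance of the layer
  set.seed(6)
  perm <- sample(10)
  outP <- satLayer(H[perm, ], g$A[perm, perm], lp, cfg)
  expect_equal(outP, out$states[perm, ], tolerance = 1e-10)
})

test_that("k_hops = 0 encoder equals an independent plain transformer", {
  for (r in 1:20) {
    n <- sample(5:12, 1)
    cfg <- satConfig(k_hops = 0, n_layers = 2, hidden_dim = 8, n_heads = 2,
                     dropout_rate = 0)
    model <- initModel(setNames(as.integer(n), "a"), cfg, fusion_dim = 4,
                       clf_hidden = 4, seed = 100 + r)
    g <- randGraphTensors(n, seed = 200 + r)
    got <- encodeGraph(model, list(A = g$A, X = g$X), atlas = "a")
    ref <- refPlainEncoder(model@params$enc$a, cfg, g$X)
    expect_equal(as.numeric(got), as.numeric(ref), tolerance = 1e-5)
  }
})

test_that("graph embeddings are invariant to node permutation", {
  cfg <- satConfig(hidden_dim = 8, n_heads = 2, dropout_rate = 0)
  for (r in 1:20) {
    n <- sample(6:14, 1)
    model <- initModel(c(a = as.integer(n)), cfg, fusion_dim = 4,
                       clf_hidden = 4, seed = 300 + r)
    g <- randGraphTensors(n, seed = 400 + r)
    set.seed(500 + r)
    perm <- sample(n)
    e1 <- encodeGraph(model, list(A = g$A, X = g$X), atlas = "a")
    # consistent relabelling: each node keeps its feature vector and the
    # edge set is relabelled with it
    e2 <- encodeGraph(model,
                      list(A = g$A[perm, perm], X = g$X[perm, , drop = FALSE]),
                      atlas = "a")
    expect_equal(as.numeric(e2), as.numeric(e1), tolerance = 1e-5)
  }
})

test_that("identical node states collapse mean and max readouts together", {
  cfg_mean <- satConfig(hidden_dim = 8, n_heads = 2, dropout_rate = 0,
                        readout = "mean")
  cfg_max <- satConfig(hidden_dim = 8, n_heads = 2, dropout_rate = 0,
                       readout = "max")
  model <- initModel(c(a = 6L), cfg_mean, fusion_dim = 4, clf_hidden = 4,
                     seed = 11)
  # complete graph with equal weights + identical features: node states stay
  # identical through every layer, so mean and max pooling agree
  A <- matrix(0.4, 6, 6); diag(A) <- 0
  X <- matrix(rep(c(1, -2, 0.5, 3, 1, 0), each = 6), 6, 6)
  e1 <- encodeGraph(model, list(A = A, X = X), atlas = "a")
  m2 <- model; m2@satConfig <- unclass(cfg_max)
  e2 <- encodeGraph(m2, list(A = A, X = X), atlas = "a")
  expect_equal(as.numeric(e1), as.numeric(e2), tolerance = 1e-10)
})

test_that("one-layer encoder equals the composed satLayer + readout oracle", {
  cfg <- satConfig(k_hops = 2, n_layers = 1, hidden_dim = 4, n_heads = 1,
                   dropout_rate = 0)
  model <- initModel(c(a = 4L), cfg, fusion_dim = 3, clf_hidden = 3,
                     seed = 17)
  g <- randGraphTensors(4, seed = 18, K = 2)
  ep <- model@params$enc$a
  H0 <- g$X %*% ep$Win + matrix(ep$bin, 4, 4, byrow = TRUE)
  H1 <- satLayer(H0, g$A, ep$layers[[1]], cfg)
  expect_equal(as.numeric(encodeGraph(model, list(A = g$A, X = g$X),
                                      atlas = "a")),
               as.numeric(colMeans(H1)), tolerance = 1e-10)
})

test_that("evaluation passes are bit-identical (dropout off at eval)", {
  model <- tinyModel(c(a = 8L, b = 6L), hidden_dim = 8, n_heads = 2,
                     dropout_rate = 0.3)
  glist <- list(a = randGraphTensors(8, 1), b = randGraphTensors(6, 2))
  f1 <- atlasfuse:::.forwardSubject(model, glist)
  f2 <- atlasfuse:::.forwardSubject(model, glist)
  expect_identical(f1$probs, f2$probs)
  expect_identical(f1$weights, f2$weights)
  # training mode with dropout is stochastic
  set.seed(1); t1 <- atlasfuse:::.forwardSubject(model, glist, label = 1L,
                                                 training = TRUE, eps = 0.1)
  set.seed(2); t2 <- atlasfuse:::.forwardSubject(model, glist, label = 1L,
                                                 training = TRUE, eps = 0.1)
  expect_false(identical(t1$probs, t2$probs))
})

test_that("analytic gradients match central finite differences", {
  lossOf <- function(model, glist, params) {
    m <- model; m@params <- params
    atlasfuse:::.forwardSubject(m, glist, label = 1L, eps = 0.1)$loss
  }
  for (k in c(0L, 1L, 2L)) {
    cfg <- satConfig(k_hops = k, n_layers = 2, hidden_dim = 6, n_heads = 2,
                     dropout_rate = 0)
    model <- initModel(c(a = 5L), cfg, fusion_dim = 4, clf_hidden = 4,
                       seed = 70 + k)
    glist <- list(a = randGraphTensors(5, seed = 80 + k))
    fo <- atlasfuse:::.forwardSubject(model, glist, label = 1L,
                                      training = TRUE, eps = 0.1)
    gr <- atlasfuse:::.backwardSubject(model, fo$cache)
    # probe a handful of leaves spread over the architecture
    probes <- list(
      list(c("enc", "a", "Win"), 3L),
      list(c("enc", "a", "layers", "1", "Wn1"), 5L),
      list(c("enc", "a", "layers", "1", "Wq"), 2L),
      list(c("enc", "a", "layers", "2", "W2"), 4L),
      list(c("enc", "a", "layers", "2", "g2"), 1L),
      list(c("enc", "a", "Wp"), 2L),
      list(c("laff", "w"), 1L),
      list(c("clf", "Wc1"), 3L))
    h <- 1e-6
    for (pr in probes) {
      path <- pr[[1]]; i <- pr[[2]]
      getLeaf <- function(pl) {
        for (p in path)
          pl <- if (grepl("^[0-9]+$", p)) pl[[as.integer(p)]] else pl[[p]]
        pl
      }
      setLeaf <- function(pl, path, v) {
        p1 <- path[1]
        key <- if (grepl("^[0-9]+$", p1)) as.integer(p1) else p1
        if (length(path) == 1L) pl[[key]][i] <- v
        else pl[[key]] <- setLeaf(pl[[key]], path[-1], v)
        pl
      }
      base <- getLeaf(model@params)[i]
      num <- (lossOf(model, glist, setLeaf(model@params, path, base + h)) -
              lossOf(model, glist, setLeaf(model@params, path, base - h))) /
        (2 * h)
      ana <- getLeaf(gr)[i]
      expect_equal(ana, num, tolerance = 1e-3)
    }
  }
})

test_that("shape and degeneracy errors are explicit", {
  model <- tinyModel(c(a = 8L), hidden_dim = 8, n_heads = 2)
  expect_error(encodeGraph(model, list(A = matrix(0, 0, 0),
                                       X = matrix(0, 0, 8)), atlas = "a"),
               "empty graph")
  g <- randGraphTensors(6, 1)
  expect_error(encodeGraph(model, list(A = g$A, X = g$X), atlas = "a"),
               "shape error")
  expect_error(encodeGraph(model, g, atlas = "nope"), "unknown atlas")
})
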