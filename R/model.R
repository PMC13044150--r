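#' Initialise an untrained multi-atlas model
#'
#' Allocates all parameters: one SAT encoder per atlas (input projection,
#' per-layer subgraph-GNN + attention + feed-forward weights), per-atlas
#' projections to the shared fusion space, the shared fusion scorer and the
#' classifier head. Weight matrices use a symmetric uniform fan-in scheme
#' (`U(-1/sqrt(fan_in), 1/sqrt(fan_in))`); biases start at zero and layer-norm
#' gains at one. All randomness is drawn from one generator seeded by `seed`.
#'
#' @param atlases list of [AtlasSpec-class], or a named integer vector of
#'   per-atlas input feature dimensions (= ROI counts).
#' @param sat_config encoder configuration from [satConfig()].
#' @param fusion_dim dimension of the shared fusion space.
#' @param clf_hidden classifier hidden-layer width.
#' @param seed integer initialisation seed.
#' @return an untrained [MsatModel-class].
#' @export
initModel <- function(atlases, sat_config = satConfig(), fusion_dim = 16L,
                      clf_hidden = 16L, seed = 1L) {
  if (is.list(atlases)) {
    dims <- vapply(atlases, nRois, integer(1))
    names(dims) <- vapply(atlases, atlasName, character(1))
  } else {
    dims <- as.integer(atlases)
    names(dims) <- names(atlases)
  }
  if (is.null(names(dims)) || any(!nzchar(names(dims))))
    stop("atlases must be named")
  cfg <- sat_config
  h <- cfg$hidden_dim; f <- cfg$ffn_dim
  fusion_dim <- as.integer(fusion_dim); clf_hidden <- as.integer(clf_hidden)

  U <- function(nr, nc, fan) {
    a <- 1 / sqrt(fan)
    matrix(stats::runif(nr * nc, -a, a), nr, nc)
  }
  params <- withSeed(seed, {
    enc <- lapply(dims, function(d) {
      layers <- lapply(seq_len(cfg$n_layers), function(l) list(
        Ws1 = U(h, h, h), Wn1 = U(h, h, h), b1 = numeric(h),
        Ws2 = U(h, h, h), Wn2 = U(h, h, h), b2 = numeric(h),
        Wq = U(h, h, h), Wk = U(h, h, h), Wv = U(h, h, h),
        Wo = U(h, h, h), bo = numeric(h),
        g1 = rep(1, h), be1 = numeric(h),
        W1 = U(h, f, h), bf1 = numeric(f),
        W2 = U(f, h, f), bf2 = numeric(h),
        g2 = rep(1, h), be2 = numeric(h)))
      list(Win = U(d, h, d), bin = numeric(h), layers = layers,
           Wp = U(h, fusion_dim, h), bp = numeric(fusion_dim))
    })
    list(enc = enc,
         laff = list(w = U(fusion_dim, 1, fusion_dim)[, 1], b = 0),
         clf = list(Wc1 = U(fusion_dim, clf_hidden, fusion_dim),
                    bc1 = numeric(clf_hidden),
                    Wc2 = U(clf_hidden, 2L, clf_hidden),
                    bc2 = numeric(2L)))
  })
  new("MsatModel", atlasNames = names(dims), atlasDims = dims,
      satConfig = unclass(cfg), fusionDim = fusion_dim,
      clfHidden = clf_hidden, params = params, trained = FALSE,
      trainLog = list())
}

#' Extract the k-hop subgraph rooted at a node
#'
#' Breadth-first expansion to exactly `k` hops; the edge set is the subgraph
#' induced on the members. `k = 0` returns the root alone with no edges.
#'
#' @param x a [BrainGraph-class] or a symmetric adjacency matrix.
#' @param node root node index (1-based).
#' @param k nonnegative hop radius.
#' @return list with `root`, `members` (sorted, original indices) and `edges`
#'   (2-column matrix of member pairs, `i < j`, original indices).
#' @export
khopSubgraph <- function(x, node, k) {
  A <- if (is(x, "BrainGraph")) x@adjacency else as.matrix(x)
  n <- nrow(A)
  node <- as.integer(node); k <- as.integer(k)
  if (node < 1L || node > n) stop("node index out of range")
  if (k < 0L) stop("k must be nonnegative")
  reached <- logical(n); reached[node] <- TRUE
  frontier <- node
  hop <- 0L
  while (hop < k && length(frontier)) {
    nxt <- which(colSums(abs(A[frontier, , drop = FALSE])) > 0 & !reached)
    reached[nxt] <- TRUE
    frontier <- nxt
    hop <- hop + 1L
  }
  members <- which(reached)
  sub <- A[members, members, drop = FALSE]
  idx <- which(upper.tri(sub) & sub != 0, arr.ind = TRUE)
  edges <- cbind(i = members[idx[, 1]], j = members[idx[, 2]])
  list(root = node, members = members, edges = edges)
}

## ---- structural (k-hop subgraph GNN) embeddings -----------------------

# Two-round message passing with sum aggregation, ReLU after the first round,
# rooted readout. For k >= 2 the rooted readout on each node's k-hop induced
# subgraph equals plain full-graph propagation (every length-<=2 walk from the
# root stays inside the subgraph), so one shared fast path serves all roots.
# k = 1 restricts second-round messages to each root's 1-hop subgraph and is
# computed per root; k = 0 removes all neighbour terms.
.structEmbed <- function(H, Ag, k, lp) {
  n <- nrow(H)
  if (k >= 2L || n == 1L) {
    AH <- Ag %*% H
    P1 <- addBias(H %*% lp$Ws1 + AH %*% lp$Wn1, lp$b1)
    M1 <- relu(P1)
    AM1 <- Ag %*% M1
    S <- addBias(M1 %*% lp$Ws2 + AM1 %*% lp$Wn2, lp$b2)
    list(S = S, cache = list(mode = "full", AH = AH, P1 = P1, M1 = M1,
                             AM1 = AM1))
  } else if (k == 0L) {
    P1 <- addBias(H %*% lp$Ws1, lp$b1)
    M1 <- relu(P1)
    S <- addBias(M1 %*% lp$Ws2, lp$b2)
    list(S = S, cache = list(mode = "k0", P1 = P1, M1 = M1))
  } else {                                 # k == 1, per-root subgraphs
    h <- ncol(lp$Ws1)
    S <- matrix(0, n, h)
    roots <- vector("list", n)
    for (i in seq_len(n)) {
      m <- sort(unique(c(i, which(Ag[i, ] != 0))))
      r <- match(i, m)
      Am <- Ag[m, m, drop = FALSE]
      Hm <- H[m, , drop = FALSE]
      AHm <- Am %*% Hm
      P1m <- addBias(Hm %*% lp$Ws1 + AHm %*% lp$Wn1, lp$b1)
      M1m <- relu(P1m)
      agg <- drop(Am[r, , drop = FALSE] %*% M1m)
      S[i, ] <- drop(M1m[r, ] %*% lp$Ws2) + drop(agg %*% lp$Wn2) + lp$b2
      roots[[i]] <- list(m = m, r = r, Am = Am, Hm = Hm, AHm = AHm,
                         P1m = P1m, M1m = M1m, agg = agg)
    }
    list(S = S, cache = list(mode = "roots", roots = roots))
  }
}

.structEmbedBackward <- function(dS, cache, Ag, H, lp) {
  g <- list()
  if (cache$mode == "full") {
    M1 <- cache$M1
    g$Ws2 <- crossprod(M1, dS)
    g$Wn2 <- crossprod(cache$AM1, dS)
    g$b2 <- colSums(dS)
    dM1 <- dS %*% t(lp$Ws2) + t(Ag) %*% (dS %*% t(lp$Wn2))
    dP1 <- dM1 * (cache$P1 > 0)
    g$Ws1 <- crossprod(H, dP1)
    g$Wn1 <- crossprod(cache$AH, dP1)
    g$b1 <- colSums(dP1)
    dH <- dP1 %*% t(lp$Ws1) + t(Ag) %*% (dP1 %*% t(lp$Wn1))
  } else if (cache$mode == "k0") {
    M1 <- cache$M1
    g$Ws2 <- crossprod(M1, dS)
    g$Wn2 <- matrix(0, nrow(lp$Wn2), ncol(lp$Wn2))
    g$b2 <- colSums(dS)
    dM1 <- dS %*% t(lp$Ws2)
    dP1 <- dM1 * (cache$P1 > 0)
    g$Ws1 <- crossprod(H, dP1)
    g$Wn1 <- matrix(0, nrow(lp$Wn1), ncol(lp$Wn1))
    g$b1 <- colSums(dP1)
    dH <- dP1 %*% t(lp$Ws1)
  } else {                                 # per-root, k == 1
    h <- ncol(lp$Ws1)
    g$Ws1 <- matrix(0, h, h); g$Wn1 <- matrix(0, h, h); g$b1 <- numeric(h)
    g$Ws2 <- matrix(0, h, h); g$Wn2 <- matrix(0, h, h); g$b2 <- numeric(h)
    dH <- matrix(0, nrow(H), ncol(H))
    for (i in seq_along(cache$roots)) {
      rc <- cache$roots[[i]]
      ds <- dS[i, ]
      if (!any(ds != 0)) next
      g$Ws2 <- g$Ws2 + tcrossprod(rc$M1m[rc$r, ], ds)
      g$Wn2 <- g$Wn2 + tcrossprod(rc$agg, ds)
      g$b2 <- g$b2 + ds
      dM1m <- matrix(0, length(rc$m), h)
      dM1m[rc$r, ] <- drop(lp$Ws2 %*% ds)
      dM1m <- dM1m + tcrossprod(rc$Am[rc$r, ], drop(lp$Wn2 %*% ds))
      dP1m <- dM1m * (rc$P1m > 0)
      g$Ws1 <- g$Ws1 + crossprod(rc$Hm, dP1m)
      g$Wn1 <- g$Wn1 + crossprod(rc$AHm, dP1m)
      g$b1 <- g$b1 + colSums(dP1m)
      dH[rc$m, ] <- dH[rc$m, ] + dP1m %*% t(lp$Ws1) +
        t(rc$Am) %*% (dP1m %*% t(lp$Wn1))
    }
  }
  list(dH = dH, g = g)
}

#' Per-node structural embeddings from k-hop subgraphs
#'
#' Applies the two-round sum-aggregation message-passing network over each
#' node's k-hop induced subgraph and reads out the root, yielding one
#' structural embedding per node. Deterministic given parameters.
#'
#' @param node_states numeric matrix, one row per node.
#' @param adjacency symmetric weighted adjacency matrix (zero diagonal).
#' @param k nonnegative hop radius.
#' @param params list with `Ws1`, `Wn1`, `b1`, `Ws2`, `Wn2`, `b2`.
#' @return numeric matrix of structural embeddings, one row per node.
#' @export
subgraphEmbed <- function(node_states, adjacency, k, params) {
  H <- as.matrix(node_states)
  Ag <- as.matrix(adjacency)
  if (ncol(H) != nrow(params$Ws1))
    stop("shape error: node_states width ", ncol(H),
         " does not match GNN parameter fan-in ", nrow(params$Ws1))
  .structEmbed(H, Ag, as.integer(k), params)$S
}

## ---- layer-norm -------------------------------------------------------

.lnForward <- function(X, g, be) {
  n <- nrow(X)
  mu <- rowMeans(X)
  xc <- X - mu
  sig <- sqrt(rowMeans(xc^2) + 1e-5)
  xhat <- xc / sig
  list(Y = xhat * rep(g, each = n) + rep(be, each = n), xhat = xhat,
       sig = sig)
}

.lnBackward <- function(dY, cache, g) {
  n <- nrow(dY)
  xhat <- cache$xhat
  dg <- colSums(dY * xhat)
  dbe <- colSums(dY)
  dxh <- dY * rep(g, each = n)
  dX <- (dxh - rowMeans(dxh) - xhat * rowMeans(dxh * xhat)) / cache$sig
  list(dX = dX, dg = dg, dbe = dbe)
}

.dropoutMask <- function(nr, nc, rate) {
  matrix((stats::runif(nr * nc) >= rate) / (1 - rate), nr, nc)
}

## ---- SAT layer --------------------------------------------------------

.satLayerForward <- function(H, Ag, lp, cfg, training = FALSE) {
  n <- nrow(H); h <- cfg$hidden_dim
  nh <- cfg$n_heads; dh <- h %/% nh
  se <- .structEmbed(H, Ag, cfg$k_hops, lp)
  S <- se$S
  Q <- S %*% lp$Wq; K <- S %*% lp$Wk; V <- H %*% lp$Wv
  Oc <- matrix(0, n, h)
  attn <- vector("list", nh)
  for (j in seq_len(nh)) {
    idx <- ((j - 1L) * dh + 1L):(j * dh)
    Zj <- tcrossprod(Q[, idx, drop = FALSE], K[, idx, drop = FALSE]) /
      sqrt(dh)
    Aj <- rowSoftmax(Zj)
    attn[[j]] <- Aj
    Oc[, idx] <- Aj %*% V[, idx, drop = FALSE]
  }
  O <- addBias(Oc %*% lp$Wo, lp$bo)
  useDrop <- training && cfg$dropout_rate > 0
  maskO <- if (useDrop) .dropoutMask(n, h, cfg$dropout_rate) else NULL
  Od <- if (useDrop) O * maskO else O
  R1 <- H + Od
  ln1 <- .lnForward(R1, lp$g1, lp$be1)
  H1 <- ln1$Y
  F1pre <- addBias(H1 %*% lp$W1, lp$bf1)
  F1 <- relu(F1pre)
  F2 <- addBias(F1 %*% lp$W2, lp$bf2)
  maskF <- if (useDrop) .dropoutMask(n, h, cfg$dropout_rate) else NULL
  F2d <- if (useDrop) F2 * maskF else F2
  R2 <- H1 + F2d
  ln2 <- .lnForward(R2, lp$g2, lp$be2)
  list(Hout = ln2$Y,
       attn = attn,
       cache = list(H = H, se = se$cache, S = S, Q = Q, K = K, V = V,
                    attn = attn, Oc = Oc, maskO = maskO, ln1 = ln1, H1 = H1,
                    F1pre = F1pre, F1 = F1, maskF = maskF, ln2 = ln2))
}

.satLayerBackward <- function(dHout, cache, Ag, lp, cfg) {
  n <- nrow(dHout); h <- cfg$hidden_dim
  nh <- cfg$n_heads; dh <- h %/% nh
  g <- list()
  l2 <- .lnBackward(dHout, cache$ln2, lp$g2)
  g$g2 <- l2$dg; g$be2 <- l2$dbe
  dR2 <- l2$dX
  dH1 <- dR2
  dF2 <- if (!is.null(cache$maskF)) dR2 * cache$maskF else dR2
  g$W2 <- crossprod(cache$F1, dF2)
  g$bf2 <- colSums(dF2)
  dF1 <- dF2 %*% t(lp$W2)
  dF1p <- dF1 * (cache$F1pre > 0)
  g$W1 <- crossprod(cache$H1, dF1p)
  g$bf1 <- colSums(dF1p)
  dH1 <- dH1 + dF1p %*% t(lp$W1)
  l1 <- .lnBackward(dH1, cache$ln1, lp$g1)
  g$g1 <- l1$dg; g$be1 <- l1$dbe
  dR1 <- l1$dX
  dH <- dR1
  dO <- if (!is.null(cache$maskO)) dR1 * cache$maskO else dR1
  g$Wo <- crossprod(cache$Oc, dO)
  g$bo <- colSums(dO)
  dOc <- dO %*% t(lp$Wo)
  dQ <- matrix(0, n, h); dK <- matrix(0, n, h); dV <- matrix(0, n, h)
  for (j in seq_len(nh)) {
    idx <- ((j - 1L) * dh + 1L):(j * dh)
    Aj <- cache$attn[[j]]
    dOj <- dOc[, idx, drop = FALSE]
    dAj <- tcrossprod(dOj, cache$V[, idx, drop = FALSE])
    dV[, idx] <- crossprod(Aj, dOj)
    dZj <- (dAj - rowSums(dAj * Aj)) * Aj
    dQ[, idx] <- dZj %*% cache$K[, idx, drop = FALSE] / sqrt(dh)
    dK[, idx] <- crossprod(dZj, cache$Q[, idx, drop = FALSE]) / sqrt(dh)
  }
  g$Wv <- crossprod(cache$H, dV)
  dH <- dH + dV %*% t(lp$Wv)
  g$Wq <- crossprod(cache$S, dQ)
  g$Wk <- crossprod(cache$S, dK)
  dS <- dQ %*% t(lp$Wq) + dK %*% t(lp$Wk)
  sb <- .structEmbedBackward(dS, cache$se, Ag, cache$H, lp)
  dH <- dH + sb$dH
  g[names(sb$g)] <- sb$g
  # leaf order must mirror the layer parameter list exactly: the optimiser
  # pairs parameter and gradient trees positionally
  g <- g[c("Ws1", "Wn1", "b1", "Ws2", "Wn2", "b2", "Wq", "Wk", "Wv",
           "Wo", "bo", "g1", "be1", "W1", "bf1", "W2", "bf2", "g2", "be2")]
  list(dH = dH, g = g)
}

#' Apply one structure-aware transformer layer
#'
#' Multi-head attention whose query/key projections are computed from the
#' k-hop structural embeddings and value projections from the node states,
#' followed by residual + layer-norm and a feed-forward block. Output shape
#' equals input shape. Attention rows are nonnegative and sum to one per
#' query node and head.
#'
#' @param node_states numeric matrix, one row per node.
#' @param adjacency symmetric weighted adjacency matrix.
#' @param params one layer's parameter list (see [initModel()]).
#' @param config a [satConfig()].
#' @param training logical; enables dropout (stochastic, uses the current
#'   RNG stream).
#' @param return_attention logical; also return per-head attention matrices.
#' @return the updated node-state matrix; if `return_attention`, a list with
#'   elements `states` and `attention`.
#' @export
satLayer <- function(node_states, adjacency, params, config,
                     training = FALSE, return_attention = FALSE) {
  H <- as.matrix(node_states)
  if (ncol(H) != config$hidden_dim)
    stop("shape error: node_states width must equal hidden_dim")
  out <- .satLayerForward(H, as.matrix(adjacency), params, config, training)
  if (any(!is.finite(out$Hout)))
    stop("numerical error: non-finite activations in SAT layer")
  if (return_attention) list(states = out$Hout, attention = out$attn)
  else out$Hout
}

## ---- encoder ----------------------------------------------------------

.gnnAdjacency <- function(A, cfg)
  if (cfg$edge_mode == "binary") (A != 0) * 1 else A

.encForward <- function(ep, cfg, A, X, training = FALSE, collect = FALSE) {
  n <- nrow(X)
  if (n == 0L) stop("empty graph")
  if (ncol(X) != nrow(ep$Win))
    stop("shape error: feature dim ", ncol(X), " vs encoder fan-in ",
         nrow(ep$Win))
  Ag <- .gnnAdjacency(A, cfg)
  H <- addBias(X %*% ep$Win, ep$bin)
  layerCaches <- vector("list", cfg$n_layers)
  attn <- if (collect) vector("list", cfg$n_layers) else NULL
  for (l in seq_len(cfg$n_layers)) {
    out <- .satLayerForward(H, Ag, ep$layers[[l]], cfg, training)
    if (any(!is.finite(out$Hout)))
      stop("numerical error: non-finite activations in SAT layer ", l)
    layerCaches[[l]] <- out$cache
    if (collect) attn[[l]] <- Reduce(`+`, out$attn) / length(out$attn)
    H <- out$Hout
  }
  ro <- cfg$readout
  if (ro == "mean") {
    gvec <- colMeans(H); roCache <- NULL
  } else if (ro == "sum") {
    gvec <- colSums(H); roCache <- NULL
  } else {
    amax <- max.col(t(H), ties.method = "first")
    gvec <- H[cbind(amax, seq_len(ncol(H)))]
    roCache <- amax
  }
  z <- drop(gvec %*% ep$Wp) + ep$bp
  list(z = z, gvec = gvec, attn = attn,
       cache = list(A = A, Ag = Ag, X = X, n = n, layers = layerCaches,
                    Hfinal = H, roCache = roCache, gvec = gvec))
}

.encBackward <- function(dz, cache, ep, cfg) {
  n <- cache$n; h <- cfg$hidden_dim
  g <- list(Wp = tcrossprod(cache$gvec, dz) * 1,  # h x fusion
            bp = dz)
  dg <- drop(ep$Wp %*% dz)
  if (cfg$readout == "mean") {
    dH <- matrix(rep(dg / n, each = n), n, h)
  } else if (cfg$readout == "sum") {
    dH <- matrix(rep(dg, each = n), n, h)
  } else {
    dH <- matrix(0, n, h)
    dH[cbind(cache$roCache, seq_len(h))] <- dg
  }
  glayers <- vector("list", cfg$n_layers)
  for (l in rev(seq_len(cfg$n_layers))) {
    lb <- .satLayerBackward(dH, cache$layers[[l]], cache$Ag,
                            ep$layers[[l]], cfg)
    glayers[[l]] <- lb$g
    dH <- lb$dH
  }
  g$layers <- glayers
  dH0 <- dH
  g$Win <- crossprod(cache$X, dH0)
  g$bin <- colSums(dH0)
  g[c("Win", "bin", "layers", "Wp", "bp")]
}

#' Encode a brain graph into a graph-level embedding
#'
#' Runs the atlas-specific SAT encoder (stacked layers + readout) in
#' evaluation mode (dropout off; deterministic given parameters).
#'
#' @param model an [MsatModel-class].
#' @param graph a [BrainGraph-class], or a list with elements `A` (adjacency)
#'   and `X` (node features).
#' @param atlas atlas name selecting the encoder; defaults to the graph's
#'   atlas name.
#' @return numeric vector of length `hidden_dim` (the pre-projection graph
#'   embedding), with attribute `"z"` holding the fusion-space projection.
#' @export
encodeGraph <- function(model, graph, atlas = NULL) {
  if (is(graph, "BrainGraph")) {
    A <- graph@adjacency; X <- graph@nodeFeatures
    if (is.null(atlas)) atlas <- graph@atlasName
  } else {
    A <- graph$A; X <- graph$X
  }
  if (is.null(atlas) || !atlas %in% model@atlasNames)
    stop("unknown atlas '", atlas, "'")
  out <- .encForward(model@params$enc[[atlas]], model@satConfig, A, X,
                     training = FALSE)
  structure(out$gvec, z = out$z)
}
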