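# Independent oracles and small fixtures used across the suite. Everything
# here is deliberately written in the most literal way possible (loops,
# explicit formulas) and never calls the package code paths it checks.

# Pearson correlation of two vectors, straight from the definition
pearsonOracle <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  num <- sum((x - mx) * (y - my))
  den <- sqrt(sum((x - mx)^2)) * sqrt(sum((y - my)^2))
  num / den
}

# brute-force KNN edge set: per row, full sort (ties by lower index), take K,
# union-symmetrise; returns a sorted character key set "i-j"
knnOracleEdges <- function(v, K, metric = "signed") {
  n <- nrow(v)
  sim <- if (metric == "absolute") abs(v) else v
  sel <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    cand <- setdiff(seq_len(n), i)
    ord <- cand[order(-sim[i, cand], cand)]
    sel[i, ord[seq_len(K)]] <- TRUE
  }
  keys <- character(0)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && (sel[i, j] || sel[j, i]))
      keys <- c(keys, paste0(i, "-", j))
  }
  sort(keys)
}

edgeKeys <- function(graph) {
  el <- edgeList(graph)
  sort(paste0(el$i, "-", el$j))
}

# random correlation matrix with distinct off-diagonal entries
randCorr <- function(n, seed) {
  set.seed(seed)
  stats::cor(matrix(stats::rnorm((n + 5) * n), n + 5, n))
}

# small random brain graph tensors
randGraphTensors <- function(n, seed, K = 3) {
  set.seed(seed)
  g <- buildBrainGraph(matrix(stats::rnorm(40 * n), 40, n), K = K)
  list(A = adjacency(g), X = nodeFeatures(g))
}

# Benjamini-Hochberg step-up, literal: q_(i) = min_{j >= i} ( m p_(j) / j )
bhOracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  cummin_rev <- Inf
  for (i in m:1) {
    cummin_rev <- min(cummin_rev, m * p[ord[i]] / i)
    q[ord[i]] <- min(1, cummin_rev)
  }
  q
}

# AUC by exhaustive case-control pair counting, half credit for ties
aucOracle <- function(scores, labels) {
  cs <- scores[labels == 1]; ct <- scores[labels == 0]
  tot <- 0
  for (a in cs) for (b in ct)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(cs) * length(ct))
}

# ---- independent dense (structure-free) transformer encoder ----
# Plain self-attention encoder sharing the SAT parameter layout: the
# "structural" embedding is the per-node 2-layer MLP of the node state (the
# k = 0 limit), and attention is ordinary dense softmax attention. Written
# with explicit per-node loops.
refLayerNorm <- function(x, g, b) {
  mu <- mean(x)
  sg <- sqrt(mean((x - mu)^2) + 1e-5)
  (x - mu) / sg * g + b
}

refPlainEncoder <- function(params, cfg, X) {
  n <- nrow(X)
  h <- cfg$hidden_dim; nh <- cfg$n_heads; dh <- h / nh
  H <- matrix(0, n, h)
  for (i in seq_len(n)) H[i, ] <- drop(X[i, ] %*% params$Win) + params$bin
  for (lp in params$layers) {
    S <- matrix(0, n, h)
    for (i in seq_len(n)) {
      m1 <- pmax(drop(H[i, ] %*% lp$Ws1) + lp$b1, 0)
      S[i, ] <- drop(m1 %*% lp$Ws2) + lp$b2
    }
    Q <- S %*% lp$Wq; K <- S %*% lp$Wk; V <- H %*% lp$Wv
    O <- matrix(0, n, h)
    for (j in seq_len(nh)) {
      idx <- ((j - 1) * dh + 1):(j * dh)
      for (i in seq_len(n)) {
        logits <- numeric(n)
        for (t in seq_len(n))
          logits[t] <- sum(Q[i, idx] * K[t, idx]) / sqrt(dh)
        a <- exp(logits - max(logits)); a <- a / sum(a)
        for (t in seq_len(n)) O[i, idx] <- O[i, idx] + a[t] * V[t, idx]
      }
    }
    Hn <- matrix(0, n, h)
    for (i in seq_len(n)) {
      r1 <- H[i, ] + drop(O[i, ] %*% lp$Wo) + lp$bo
      h1 <- refLayerNorm(r1, lp$g1, lp$be1)
      ff <- drop(pmax(drop(h1 %*% lp$W1) + lp$bf1, 0) %*% lp$W2) + lp$bf2
      Hn[i, ] <- refLayerNorm(h1 + ff, lp$g2, lp$be2)
    }
    H <- Hn
  }
  if (cfg$readout == "mean") colMeans(H)
  else if (cfg$readout == "sum") colSums(H)
  else apply(H, 2, max)
}

# tiny trained-ish model helper
tinyModel <- function(dims, seed = 7, ...) {
  initModel(dims, satConfig(...), fusion_dim = 4L, clf_hidden = 4L,
            seed = seed)
}

# minimal in-memory cohort: two toy atlases, strong separable signal
tinyCohortData <- function(n_per_group = 6, seed = 1, n_timepoints = 60) {
  atl <- list(atlasSpec("tA", paste0("tA_R", 1:8)),
              atlasSpec("tB", paste0("tB_R", 1:10)))
  lm <- list(tA = rep(1:4, each = 2), tB = rep(1:5, each = 2))
  spec <- simSpec(atlases = atl, loading_map = lm,
                  n_cases = n_per_group, n_controls = n_per_group,
                  n_timepoints = n_timepoints, n_latent = 5L,
                  baseline_rho = 0.1, effect_base = 0.6,
                  effect_edges = list(c(1L, 2L)), effect_delta = -0.55,
                  noise_sd = 0.3, seed = seed)
  cohort <- generateCohort(spec)
  list(spec = spec, cohort = cohort, data = cohortGraphs(cohort, K = 5L))
}
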