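# Full-model forward and backward passes for one subject.
#
# glist: named list (per atlas, in model@atlasNames order) of lists with
# elements A (adjacency) and X (node features), or BrainGraph objects.

.subjectTensors <- function(g) {
  if (is(g, "BrainGraph")) list(A = g@adjacency, X = g@nodeFeatures)
  else g
}

.forwardSubject <- function(model, glist, label = NULL, training = FALSE,
                            eps = 0, collect = FALSE) {
  cfg <- model@satConfig
  M <- length(model@atlasNames)
  encOut <- vector("list", M)
  zs <- matrix(0, M, model@fusionDim,
               dimnames = list(model@atlasNames, NULL))
  for (m in seq_len(M)) {
    an <- model@atlasNames[m]
    ten <- .subjectTensors(glist[[an]])
    encOut[[m]] <- .encForward(model@params$enc[[an]], cfg, ten$A, ten$X,
                               training = training, collect = collect)
    zs[m, ] <- encOut[[m]]$z
  }
  lf <- model@params$laff
  s <- drop(zs %*% lf$w) + lf$b
  alpha <- softmaxVec(s)
  names(alpha) <- model@atlasNames
  fused <- drop(crossprod(zs, alpha))
  cl <- model@params$clf
  u0 <- drop(fused %*% cl$Wc1) + cl$bc1
  u <- relu(u0)
  useDrop <- training && cfg$dropout_rate > 0
  maskU <- if (useDrop) .dropoutMask(1, length(u), cfg$dropout_rate)[1, ] else NULL
  ud <- if (useDrop) u * maskU else u
  logits <- drop(ud %*% cl$Wc2) + cl$bc2
  p <- softmaxVec(logits)
  names(p) <- c("control", "case")

  out <- list(probs = p, weights = alpha, z = zs,
              attn = if (collect)
                setNames(lapply(encOut, `[[`, "attn"), model@atlasNames)
              else NULL)
  if (!is.null(label)) {
    tgt <- if (label == 0L) c(1 - eps, eps) else c(eps, 1 - eps)
    pc <- p
    if (any(pc < 1e-12 & tgt > 0)) {
      pc <- pmax(pc, 1e-12)             # documented probability floor
      message("probability clamped to 1e-12 in cross-entropy")
    }
    out$loss <- -sum(tgt * log(pc))
    out$target <- tgt
  }
  if (training)
    out$cache <- list(enc = encOut, zs = zs, alpha = alpha, fused = fused,
                      u0 = u0, u = u, maskU = maskU, ud = ud, probs = p,
                      target = if (!is.null(label)) out$target else NULL)
  out
}

.backwardSubject <- function(model, cache) {
  cfg <- model@satConfig
  cl <- model@params$clf
  lf <- model@params$laff
  M <- length(model@atlasNames)
  dlogits <- cache$probs - cache$target
  g <- list()
  g$clf <- list(Wc1 = NULL, bc1 = NULL,
                Wc2 = tcrossprod(cache$ud, dlogits), bc2 = dlogits)
  dud <- drop(cl$Wc2 %*% dlogits)
  du <- if (!is.null(cache$maskU)) dud * cache$maskU else dud
  du0 <- du * (cache$u0 > 0)
  g$clf$Wc1 <- tcrossprod(cache$fused, du0)
  g$clf$bc1 <- du0
  dfused <- drop(cl$Wc1 %*% du0)

  zs <- cache$zs; alpha <- cache$alpha
  dzs <- tcrossprod(alpha, dfused)              # fusion path: M x d_f
  dalpha <- drop(zs %*% dfused)
  ds <- alpha * (dalpha - sum(alpha * dalpha))  # softmax over atlas scores
  g$laff <- list(w = drop(crossprod(zs, ds)), b = sum(ds))
  dzs <- dzs + tcrossprod(ds, lf$w)

  g$enc <- vector("list", M)
  names(g$enc) <- model@atlasNames
  for (m in seq_len(M)) {
    an <- model@atlasNames[m]
    g$enc[[m]] <- .encBackward(dzs[m, ], cache$enc[[m]]$cache,
                               model@params$enc[[an]], cfg)
  }
  g[c("enc", "laff", "clf")]
}

#' Predict case probabilities for cohort subjects
#'
#' Evaluation-mode forward pass (dropout off, deterministic) through the full
#' multi-atlas model for each requested subject.
#'
#' @param model a trained (or initialised) [MsatModel-class].
#' @param data output of [cohortGraphs()].
#' @param idx subject indices to score; default all.
#' @return data.frame with `subject_id`, `label`, `prob_case`, `prediction`
#'   (argmax, ties toward control) and one `weight_<atlas>` column per atlas.
#' @export
predictCohort <- function(model, data, idx = NULL) {
  if (is.null(idx)) idx <- seq_along(data$labels)
  rows <- lapply(idx, function(i) {
    glist <- lapply(data$graphs, `[[`, i)
    fo <- .forwardSubject(model, glist)
    c(prob_case = unname(fo$probs[2]), fo$weights)
  })
  m <- do.call(rbind, rows)
  out <- data.frame(subject_id = data$subjectIDs[idx],
                    label = data$labels[idx],
                    prob_case = m[, "prob_case"],
                    prediction = as.integer(m[, "prob_case"] > 0.5))
  w <- m[, -1, drop = FALSE]
  colnames(w) <- paste0("weight_", colnames(w))
  cbind(out, as.data.frame(w))
}
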