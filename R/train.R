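#' Label-smoothed cross-entropy
#'
#' Cross-entropy of the predicted class distribution against the smoothed
#' target `(1 - eps, eps)` ordered by the true class. `eps = 0` recovers the
#' standard cross-entropy. Probabilities at zero where the target puts mass
#' are clamped to a floor of 1e-12 (with a message).
#'
#' @param probabilities length-2 vector on the simplex (control, case).
#' @param label true class, 0 control / 1 case.
#' @param eps smoothing mass in \[0, 0.5).
#' @return scalar loss.
#' @examples
#' smoothedCrossEntropy(c(0.8, 0.2), 0, 0.1)   # -(0.9 log 0.8 + 0.1 log 0.2)
#' @export
smoothedCrossEntropy <- function(probabilities, label, eps = 0.1) {
  p <- as.numeric(probabilities)
  if (length(p) != 2L || any(p < -1e-9) || abs(sum(p) - 1) > 1e-6)
    stop("probabilities must be a length-2 simplex vector")
  if (eps < 0 || eps >= 0.5) stop("eps must lie in [0, 0.5)")
  tgt <- if (label == 0) c(1 - eps, eps) else c(eps, 1 - eps)
  if (any(p < 1e-12 & tgt > 0)) {
    p <- pmax(p, 1e-12)
    message("probability clamped to 1e-12 in cross-entropy")
  }
  -sum(tgt * log(p))
}

#' Cosine-annealed learning rate
#'
#' Half-cosine interpolation from `base_lr` (step 0) down to `min_lr`
#' (step = `total_steps`).
#'
#' @param step current optimisation step, `0 <= step <= total_steps`.
#' @param total_steps total number of steps (> 0).
#' @param base_lr initial learning rate (default 0.001).
#' @param min_lr final learning rate (default 0).
#' @return learning rate at `step`.
#' @export
cosineLR <- function(step, total_steps, base_lr = 0.001, min_lr = 0) {
  if (total_steps <= 0) stop("parameter error: total_steps must be positive")
  if (any(step < 0) || any(step > total_steps))
    stop("step must lie in [0, total_steps]")
  min_lr + 0.5 * (base_lr - min_lr) * (1 + cos(pi * step / total_steps))
}

## ---- AdamW ------------------------------------------------------------

.adamwInit <- function(params)
  list(m = zeroLike(params), v = zeroLike(params), t = 0L)

# decoupled weight decay; lr supplied per step (cosine schedule)
.adamwStep <- function(params, grads, state, lr, weight_decay,
                       beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- mapParams(function(m, g) beta1 * m + (1 - beta1) * g,
                       state$m, grads)
  state$v <- mapParams(function(v, g) beta2 * v + (1 - beta2) * g^2,
                       state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  params <- mapParams(function(p, m, v)
    p - lr * (m / bc1 / (sqrt(v / bc2) + adam_eps) + weight_decay * p),
    params, state$m, state$v)
  list(params = params, state = state)
}

#' Train the multi-atlas model
#'
#' Minibatch AdamW on label-smoothed cross-entropy with a cosine learning-rate
#' schedule over `epochs * ceil(n / batch_size)` steps. Fully reproducible
#' given `seed`: parameter initialisation is untouched (the model comes in
#' initialised), and batch shuffling plus dropout are drawn from one generator
#' seeded here. A non-finite loss aborts with the offending epoch recorded.
#'
#' @param model an [MsatModel-class] (as returned by [initModel()]).
#' @param data output of [cohortGraphs()].
#' @param idx training subject indices (default all).
#' @param config a [trainConfig()].
#' @param seed RNG seed for shuffling and dropout; defaults to `config$seed`.
#' @param on_step optional callback `function(model, step, lr, loss)` invoked
#'   after every optimisation step (used e.g. to audit invariants).
#' @return the trained [MsatModel-class]; `trainLog` holds per-epoch mean
#'   losses, the step count, and the schedule endpoints.
#' @export
trainModel <- function(model, data, idx = NULL, config = trainConfig(),
                       seed = NULL, on_step = NULL) {
  if (is.null(idx)) idx <- seq_along(data$labels)
  if (length(idx) == 0L) stop("empty training split")
  if (is.null(seed)) seed <- config$seed
  labels <- data$labels[idx]
  nb <- ceiling(length(idx) / config$batch_size)
  totalSteps <- config$epochs * nb
  params <- model@params
  eps <- config$label_smoothing_eps

  glists <- lapply(idx, function(i) lapply(data$graphs, `[[`, i))

  withSeed(seed, {
    state <- .adamwInit(params)
    step <- 0L
    epochLoss <- numeric(config$epochs)
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(length(idx))
      lossSum <- 0
      for (b in seq_len(nb)) {
        rows <- ord[(((b - 1L) * config$batch_size) + 1L):
                      min(b * config$batch_size, length(idx))]
        gacc <- NULL
        bloss <- 0
        model@params <- params
        for (r in rows) {
          fo <- .forwardSubject(model, glists[[r]], label = labels[r],
                                training = TRUE, eps = eps)
          if (!is.finite(fo$loss))
            stop("divergence: non-finite loss at epoch ", ep)
          bloss <- bloss + fo$loss
          gr <- .backwardSubject(model, fo$cache)
          gacc <- if (is.null(gacc)) gr else addParams(gacc, gr)
        }
        gacc <- scaleParams(gacc, 1 / length(rows))
        lr <- cosineLR(step, totalSteps, config$learning_rate, config$min_lr)
        upd <- .adamwStep(params, gacc, state, lr, config$weight_decay)
        params <- upd$params
        state <- upd$state
        step <- step + 1L
        lossSum <- lossSum + bloss / length(rows)
        if (!is.null(on_step)) {
          model@params <- params
          on_step(model, step, lr, bloss / length(rows))
        }
      }
      epochLoss[ep] <- lossSum / nb
    }
    model@params <- params
    model@trained <- TRUE
    model@trainLog <- list(epoch_loss = epochLoss, steps = step,
                           total_steps = totalSteps, seed = seed,
                           n_train = length(idx),
                           base_lr = config$learning_rate,
                           min_lr = config$min_lr)
    model
  })
}
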