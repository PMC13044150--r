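# Numeric helpers shared by the encoder, fusion and training code.
# All matrices are base-R doubles; row-wise ops avoid apply() on hot paths.

relu <- function(x) pmax(x, 0)

# add a bias (length ncol) to every row of a column-major matrix
addBias <- function(M, b) M + rep(b, each = nrow(M))

# numerically stable row-wise softmax
rowSoftmax <- function(Z) {
  n <- nrow(Z)
  rm <- Z[cbind(seq_len(n), max.col(Z, ties.method = "first"))]
  E <- exp(Z - rm)
  E / rowSums(E)
}

softmaxVec <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

# run code with a temporary RNG seed, restoring the caller's RNG state
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# recursively apply a function leaf-wise over one or more parameter trees
mapParams <- function(f, p, ...) {
  rest <- list(...)
  if (is.list(p)) {
    out <- vector("list", length(p))
    names(out) <- names(p)
    for (i in seq_along(p))
      out[[i]] <- do.call(mapParams,
                          c(list(f, p[[i]]), lapply(rest, `[[`, i)))
    out
  } else {
    do.call(f, c(list(p), rest))
  }
}

zeroLike <- function(params) mapParams(function(x) x * 0, params)

addParams <- function(a, b) mapParams(`+`, a, b)

scaleParams <- function(a, s) mapParams(function(x) x * s, a)

# sum of squares across a parameter tree (diagnostics)
paramNormSq <- function(p) {
  tot <- 0
  walk <- function(x) {
    if (is.list(x)) lapply(x, walk) else tot <<- tot + sum(x^2)
    invisible(NULL)
  }
  walk(p)
  tot
}
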