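# Exact t-SNE for descriptor-space maps. The libraries profiled here are
# a few hundred to a few thousand molecules, well within reach of the
# O(n^2) exact gradient, so no tree approximation is used.

# Per-point conditional probabilities at the requested perplexity
# (binary search over the Gaussian bandwidth).
tsneAffinities <- function(D2, perplexity) {
  n <- nrow(D2)
  logU <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    beta <- 1
    lo <- -Inf; hi <- Inf
    di <- D2[i, -i]
    for (iter in 1:50) {
      p <- exp(-di * beta)
      sp <- sum(p)
      if (sp == 0) p <- rep(1 / length(p), length(p)) else p <- p / sp
      H <- -sum(p * log(pmax(p, 1e-300)))
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, 1e-12)
}

#' t-SNE embedding of a descriptor table
#'
#' Standardizes the columns (zero mean, unit variance; constant columns
#' are dropped) and computes a 2-D t-SNE map with the exact gradient,
#' early exaggeration, and momentum. Deterministic per seed.
#'
#' @param x numeric matrix or data.frame of descriptors (rows =
#'   molecules); non-numeric columns (e.g. \code{smiles}) are dropped.
#' @param seed integer seed.
#' @param perplexity Gaussian perplexity; requires
#'   \code{nrow(x) >= 3 * perplexity + 1}.
#' @param maxIter gradient-descent iterations.
#' @return numeric matrix, \code{nrow(x)} x 2.
#' @export
embedTsne <- function(x, seed = 1L, perplexity = 30, maxIter = 400L) {
  if (is.data.frame(x)) x <- x[vapply(x, is.numeric, logical(1))]
  X <- as.matrix(x)
  n <- nrow(X)
  if (n < 3 * perplexity + 1)
    stop("too few rows (", n, ") for perplexity ", perplexity)
  keep <- apply(X, 2, stats::sd) > 0
  X <- scale(X[, keep, drop = FALSE])
  D2 <- as.matrix(stats::dist(X))^2
  P <- tsneAffinities(D2, perplexity)

  withSeed(seed, {
    Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
    G <- matrix(0, n, 2)   # momentum accumulator
    gains <- matrix(1, n, 2)
    for (iter in seq_len(maxIter)) {
      ex <- if (iter <= 100) 4 else 1
      momentum <- if (iter <= 250) 0.5 else 0.8
      sumY <- rowSums(Y^2)
      num <- 1 / (1 + outer(sumY, sumY, "+") - 2 * tcrossprod(Y))
      diag(num) <- 0
      Q <- pmax(num / sum(num), 1e-12)
      W <- (ex * P - Q) * num
      grad <- 4 * (diag(rowSums(W)) - W) %*% Y
      gains <- pmax(0.01, ifelse(sign(grad) == sign(G),
                                 gains * 0.8, gains + 0.2))
      G <- momentum * G - 200 * gains * grad
      Y <- Y + G
      Y <- sweep(Y, 2, colMeans(Y))
    }
    Y
  })
}
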