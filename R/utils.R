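# Internal numeric and RNG helpers shared across modules.

CLASSES <- c("Normal", "MCI", "AD")

#' @importFrom stats rnorm runif qnorm sd var quantile pnorm pchisq
#' @importFrom utils head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

softmax <- function(x) {
  x <- x - max(x)
  e <- exp(x)
  e / sum(e)
}

# Row-wise softmax for a matrix of logits.
softmax_rows <- function(m) {
  m <- m - apply(m, 1L, max)
  e <- exp(m)
  e / rowSums(e)
}

gelu <- function(x) {
  # tanh approximation of the Gaussian error linear unit
  0.5 * x * (1 + tanh(sqrt(2 / pi) * (x + 0.044715 * x^3)))
}

relu <- function(x) pmax(x, 0)

sigmoid <- function(x) 1 / (1 + exp(-x))

l2_normalize <- function(x) {
  n <- sqrt(sum(x^2))
  if (n == 0) x else x / n
}

cosine_sim <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

# Xavier/Glorot uniform initialization, deterministic under the current RNG.
xavier_matrix <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(runif(n_in * n_out, -lim, lim), nrow = n_in, ncol = n_out)
}

# Deterministic 31-bit polynomial string hash, used to derive reproducible
# sub-seeds from identifiers.
hash31 <- function(s) {
  h <- 7
  for (b in utf8ToInt(s)) {
    h <- (h * 131 + b) %% 2147483647
  }
  as.integer(h)
}

# Derive a child seed from a base seed and a string key; stays below 2^31.
derive_seed <- function(seed, key) {
  as.integer((as.numeric(seed) * 48271 + hash31(key)) %% 2147483647)
}

# Stratified standard-normal draws: a shuffled qnorm grid whose sample mean
# is exactly zero. Used where the mean of a generated batch must track its
# configured target tightly.
stratified_normal <- function(n, sd = 1) {
  if (n == 0) return(numeric(0))
  g <- qnorm((seq_len(n) - 0.5) / n)
  g <- g - mean(g)
  sd * sample(g)
}

# Largest-remainder rounding of a non-negative vector so the rounded values
# sum to round(sum(x)).
apportion <- function(x) {
  base <- floor(x)
  resid <- x - base
  k <- round(sum(x)) - sum(base)
  if (k > 0) {
    idx <- order(resid, decreasing = TRUE)[seq_len(k)]
    base[idx] <- base[idx] + 1
  }
  as.integer(base)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
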