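# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

.assert <- function(cond, ...) {
  if (!isTRUE(cond)) stop(sprintf(...), call. = FALSE)
}

# ceiling of an integer-ish root; 27^(1/3) = 3.0000000000000004 in floating
# point, so snap to the nearest integer before taking the ceiling
.ceil_root <- function(d, power) {
  r <- d^(1 / power)
  if (abs(r - round(r)) < 1e-9) r <- round(r)
  as.integer(ceiling(r))
}

.leaky_relu <- function(x, slope = 0.2) {
  ifelse(x > 0, x, slope * x)
}

.leaky_relu_grad <- function(x, slope = 0.2) {
  ifelse(x > 0, 1, slope)
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

.row_softmax <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# pairwise Euclidean distances via one BLAS call; much faster than dist()
.pairwise_dist <- function(x) {
  r <- rowSums(x^2)
  d2 <- -2 * tcrossprod(x)
  d2 <- d2 + r            # adds r_i to row i (column-wise recycling)
  d2 <- t(d2) + r         # adds r_j to column j
  d2[d2 < 0] <- 0
  diag(d2) <- 0
  sqrt(d2)
}

# seeded stratified index split; fractions must sum to 1
.stratified_split <- function(labels, fractions, seed) {
  n <- length(labels)
  set.seed(seed)
  groups <- split(seq_len(n), labels)
  parts <- vector("list", length(fractions))
  for (g in groups) {
    g <- sample(g)
    sizes <- floor(fractions * length(g))
    # hand leftovers to the largest partition so small classes reach all parts
    sizes[which.max(fractions)] <- sizes[which.max(fractions)] +
      (length(g) - sum(sizes))
    at <- c(0L, cumsum(sizes))
    for (p in seq_along(fractions)) {
      if (sizes[p] > 0) parts[[p]] <- c(parts[[p]], g[(at[p] + 1L):at[p + 1L]])
    }
  }
  lapply(parts, sort)
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}
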