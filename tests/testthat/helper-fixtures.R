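# Shared fixture builders for the suite. All data are generated in code.

mkLayer <- function(m, name = "layer", compositional = FALSE) {
  if (is.null(rownames(m))) rownames(m) <- sprintf("S%03d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("f%03d", seq_len(ncol(m)))
  omicsLayer(m, name, compositional)
}

randomLayer <- function(n, p, seed = 1, name = "layer", sd = 1) {
  set.seed(seed)
  mkLayer(matrix(rnorm(n * p, sd = sd), n, p), name)
}

mkPartition <- function(labels, featureIDs = NULL, minModuleSize = 1) {
  labels <- as.integer(labels)
  if (is.null(featureIDs)) featureIDs <- sprintf("f%03d", seq_along(labels))
  colors <- ifelse(labels == 0L, "grey", paste0("c", labels))
  new("ModulePartition", featureIDs = featureIDs, labels = labels,
      colors = colors, minModuleSize = minModuleSize)
}

# exact-correlation construction: unit-sd vectors with prescribed sample
# correlation to a common reference, via Gram-Schmidt
unitSd <- function(x) (x - mean(x)) / stats::sd(x)

withExactCor <- function(y, r, noise) {
  # returns a unit-sd vector whose sample correlation with y is exactly r
  ys <- unitSd(y)
  z <- noise - mean(noise)
  z <- z - ys * sum(z * ys) / sum(ys * ys)   # orthogonal to centered y
  zs <- unitSd(z)
  r * ys + sqrt(1 - r^2) * zs
}

# brute-force topological overlap, straight from the definition
tomOracle <- function(a) {
  n <- nrow(a)
  tom <- diag(n)
  k <- numeric(n)
  for (i in seq_len(n)) k[i] <- sum(a[i, -i])
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    tom[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  tom
}

randomAdjacency <- function(n, seed) {
  set.seed(seed)
  a <- matrix(runif(n * n), n, n)
  a <- (a + t(a)) / 2
  diag(a) <- 1
  a
}

# Pearson correlation from the raw-sums textbook formula (independent of
# stats::cor)
handPearson <- function(x, y) {
  n <- length(x)
  (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
}
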