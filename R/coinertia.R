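# Integrative ordination: pairwise co-inertia, multiple co-inertia
# (MAXDIFF criterion) and Procrustes superposition with a permutation
# test.

.asCenteredMatrix <- function(x, scaleInertia = FALSE) {
  v <- if (is(x, "OmicsLayer")) layerValues(x) else as.matrix(x)
  v <- scale(v, center = TRUE, scale = FALSE)
  if (scaleInertia) {
    ss <- sum(v^2)
    if (ss == 0) stop("table has zero inertia")
    v <- v / sqrt(ss)
  }
  v
}

.jointSignFix <- function(loadings, scores, reference = NULL) {
  # one global flip per axis: the largest-|loading| element over the
  # concatenated table loadings is made positive
  all_load <- do.call(rbind, loadings)
  for (k in seq_len(ncol(all_load))) {
    i <- which.max(abs(all_load[, k]))
    if (all_load[i, k] < 0) {
      loadings <- lapply(loadings, function(m) { m[, k] <- -m[, k]; m })
      scores <- lapply(scores, function(m) { m[, k] <- -m[, k]; m })
      if (!is.null(reference)) reference[, k] <- -reference[, k]
      all_load[, k] <- -all_load[, k]
    }
  }
  list(loadings = loadings, scores = scores, reference = reference)
}

#' Pairwise co-inertia analysis
#'
#' Finds axes maximizing the covariance between the sample scores of two
#' tables measured on the same samples: the singular decomposition of the
#' cross-product of the centered tables. The covariance along axis k is
#' the k-th singular value divided by n.
#'
#' @param layerA,layerB [OmicsLayer-class] objects or matrices with
#'   identical sample order.
#' @param nAxes number of axes.
#' @param scaleInertia divide each centered table by the square root of
#'   its total sum of squares first (the normalization used by
#'   [multiCoInertia()]).
#' @return A [CoInertiaResult-class]; \code{loadings} hold the feature
#'   weights (drivers) per table.
#' @export
coInertia <- function(layerA, layerB, nAxes = 2, scaleInertia = FALSE) {
  nmA <- if (is(layerA, "OmicsLayer")) layerName(layerA) else "tableA"
  nmB <- if (is(layerB, "OmicsLayer")) layerName(layerB) else "tableB"
  Xa <- .asCenteredMatrix(layerA, scaleInertia)
  Xb <- .asCenteredMatrix(layerB, scaleInertia)
  if (!identical(rownames(Xa), rownames(Xb)))
    stop("the two tables must share the same samples in the same order")
  n <- nrow(Xa)
  sv <- svd(crossprod(Xa, Xb))
  nAxes <- min(nAxes, length(sv$d))
  U <- sv$u[, seq_len(nAxes), drop = FALSE]
  V <- sv$v[, seq_len(nAxes), drop = FALSE]
  rownames(U) <- colnames(Xa); rownames(V) <- colnames(Xb)
  sA <- Xa %*% U; sB <- Xb %*% V
  fix <- .jointSignFix(list(U, V), list(sA, sB))
  loadings <- stats::setNames(fix$loadings, c(nmA, nmB))
  tscores <- stats::setNames(fix$scores, c(nmA, nmB))
  ref <- (tscores[[1]] + tscores[[2]]) / 2
  new("CoInertiaResult", tableScores = tscores, reference = ref,
      covariances = sv$d[seq_len(nAxes)] / n, loadings = loadings,
      method = "coinertia")
}

#' Multiple co-inertia analysis of two or three layers
#'
#' Each centered, inertia-normalized table gets one unit weight vector per
#' axis; the axes maximize the summed pairwise covariances between the
#' table scores (the MAXDIFF criterion), solved by power iteration with a
#' deterministic start from the first principal component of the merged
#' table. After each axis every table is deflated in feature space by its
#' weight vector, so per-table weights are orthonormal across axes. With
#' exactly two tables the axes coincide with [coInertia()].
#'
#' The reference (synthetic) score of an axis is the sum of the per-table
#' scores; per-table scores are the triangle vertices of the usual
#' multi-table sample plot.
#'
#' @param layers list of 2-3 [OmicsLayer-class] objects or matrices,
#'   samples aligned.
#' @param nAxes number of axes.
#' @param tol convergence tolerance on the criterion.
#' @param maxIter maximum power iterations per axis.
#' @return A [CoInertiaResult-class]; \code{covariances} holds the
#'   per-axis mean pairwise covariance between table scores.
#' @export
multiCoInertia <- function(layers, nAxes = 2, tol = 1e-10, maxIter = 500) {
  if (length(layers) < 2) stop("multiple co-inertia needs at least 2 layers")
  if (length(layers) > 3) stop("at most 3 layers are supported")
  nms <- names(layers)
  if (is.null(nms))
    nms <- vapply(seq_along(layers), function(i)
      if (is(layers[[i]], "OmicsLayer")) layerName(layers[[i]])
      else paste0("table", i), character(1))
  Xs <- lapply(layers, .asCenteredMatrix, scaleInertia = TRUE)
  rn <- lapply(Xs, rownames)
  if (!all(vapply(rn[-1], identical, logical(1), rn[[1]])))
    stop("all tables must share the same samples in the same order")
  n <- nrow(Xs[[1]])
  K <- length(Xs)
  norm1 <- function(x) x / sqrt(sum(x^2))
  npairs <- K * (K - 1) / 2
  ws <- lapply(Xs, function(X)
    matrix(0, ncol(X), nAxes, dimnames = list(colnames(X), NULL)))
  tsc <- lapply(Xs, function(X)
    matrix(0, n, nAxes, dimnames = list(rownames(X), NULL)))
  refs <- matrix(0, n, nAxes, dimnames = list(rownames(Xs[[1]]), NULL))
  covs <- numeric(nAxes)
  Xd <- Xs
  for (ax in seq_len(nAxes)) {
    u <- svd(do.call(cbind, Xd), nu = 1, nv = 0)$u[, 1]
    w <- lapply(Xd, function(X) norm1(crossprod(X, u)))
    critOld <- -Inf
    for (it in seq_len(maxIter)) {
      ts <- mapply(function(X, wk) X %*% wk, Xd, w, SIMPLIFY = FALSE)
      tot <- Reduce(`+`, ts)
      w <- mapply(function(X, tk) norm1(crossprod(X, tot - tk)),
                  Xd, ts, SIMPLIFY = FALSE)
      ts <- mapply(function(X, wk) X %*% wk, Xd, w, SIMPLIFY = FALSE)
      crit <- 0
      for (a in seq_len(K - 1)) for (b in (a + 1):K)
        crit <- crit + sum(ts[[a]] * ts[[b]]) / n
      if (abs(crit - critOld) < tol) break
      critOld <- crit
    }
    pr <- 0
    for (a in seq_len(K - 1)) for (b in (a + 1):K)
      pr <- pr + sum(ts[[a]] * ts[[b]]) / n
    covs[ax] <- pr / npairs
    for (k in seq_len(K)) {
      ws[[k]][, ax] <- w[[k]]
      tsc[[k]][, ax] <- ts[[k]]
    }
    refs[, ax] <- Reduce(`+`, ts)
    # deflate each table by its own weight vector
    Xd <- mapply(function(X, wk) X - (X %*% wk) %*% t(wk), Xd, w,
                 SIMPLIFY = FALSE)
  }
  names(ws) <- nms; names(tsc) <- nms
  fix <- .jointSignFix(ws, tsc, refs)
  new("CoInertiaResult", tableScores = fix$scores, reference = fix$reference,
      covariances = covs, loadings = fix$loadings, method = "mcia")
}

#' Extract the features driving a co-inertia axis
#'
#' @param res a [CoInertiaResult-class].
#' @param layer table name.
#' @param axis axis index.
#' @param topN number of features to return (all when larger than the
#'   layer; 0 gives an empty list).
#' @return data.frame with columns feature and loading, in decreasing
#'   |loading| order; ties broken lexically by feature id.
#' @export
extractDrivers <- function(res, layer, axis = 1, topN = 10) {
  if (!layer %in% names(res@loadings))
    stop("unknown layer '", layer, "'; available: ",
         paste(names(res@loadings), collapse = ", "))
  L <- res@loadings[[layer]]
  if (axis < 1 || axis > ncol(L)) stop("axis out of range")
  ld <- L[, axis]
  ord <- order(-abs(ld), names(ld))
  ord <- ord[seq_len(min(topN, length(ord)))]
  data.frame(feature = names(ld)[ord], loading = unname(ld[ord]),
             row.names = NULL)
}

#' Triangle-plot vertex table
#'
#' Long-format per-table sample coordinates of a multi-table co-inertia:
#' each sample contributes one vertex per layer, the polygon drawn in the
#' usual multi-table sample plot.
#'
#' @param res a [CoInertiaResult-class].
#' @param axes two axis indices.
#' @return data.frame with columns sample, layer, axis1, axis2.
#' @export
triangleVertices <- function(res, axes = c(1, 2)) {
  do.call(rbind, lapply(names(res@tableScores), function(nm) {
    s <- res@tableScores[[nm]]
    data.frame(sample = rownames(s), layer = nm,
               axis1 = s[, axes[1]], axis2 = s[, axes[2]],
               row.names = NULL)
  }))
}

.procrustesM2 <- function(Ac, Bc) {
  d <- svd(crossprod(Ac, Bc))$d
  1 - sum(d)^2 / (sum(Ac^2) * sum(Bc^2))
}

#' Procrustes superposition of two ordinations
#'
#' Finds the translation, scaling and orthogonal rotation of the second
#' configuration that best superposes it on the first, and reports the
#' symmetric badness-of-fit m2 = 1 - (sum of singular values)^2 /
#' (trace(A'A) trace(B'B)) of the centered configurations. The PROTEST
#' permutation p-value is (1 + #\{permuted m2 <= observed\}) /
#' (nPermutations + 1), permuting the sample rows of the second
#' configuration.
#'
#' @param a,b [OrdinationResult-class] objects or coordinate matrices with
#'   the same samples in the same order.
#' @param nAxes number of axes to compare (default: all shared axes).
#' @param nPermutations permutations for the significance test (0 skips
#'   it).
#' @param seed RNG seed for the permutations.
#' @return A [ProcrustesResult-class].
#' @export
procrustesAnalysis <- function(a, b, nAxes = NULL, nPermutations = 999,
                               seed = 1) {
  A <- if (is(a, "OrdinationResult")) scores(a) else as.matrix(a)
  B <- if (is(b, "OrdinationResult")) scores(b) else as.matrix(b)
  if (nrow(A) != nrow(B))
    stop("configurations must have the same samples in the same order")
  if (!is.null(rownames(A)) && !is.null(rownames(B)) &&
      !identical(rownames(A), rownames(B)))
    stop("configurations must have the same samples in the same order")
  n <- nrow(A)
  if (n < 3) stop("procrustes needs at least 3 samples")
  if (is.null(nAxes)) nAxes <- min(ncol(A), ncol(B))
  A <- A[, seq_len(min(nAxes, ncol(A))), drop = FALSE]
  B <- B[, seq_len(min(nAxes, ncol(B))), drop = FALSE]
  # pad the narrower configuration with zero columns
  if (ncol(A) < nAxes) A <- cbind(A, matrix(0, n, nAxes - ncol(A)))
  if (ncol(B) < nAxes) B <- cbind(B, matrix(0, n, nAxes - ncol(B)))
  Ac <- scale(A, scale = FALSE)
  Bc <- scale(B, scale = FALSE)
  sv <- svd(crossprod(Bc, Ac))
  rot <- sv$u %*% t(sv$v)          # Bc %*% rot aligns with Ac
  scl <- sum(sv$d) / sum(Bc^2)
  trans <- as.numeric(colMeans(A) - scl * colMeans(B) %*% rot)
  m2 <- .procrustesM2(Ac, Bc)
  p <- NA_real_
  if (nPermutations > 0) {
    set.seed(seed)
    hits <- 0L
    for (i in seq_len(nPermutations)) {
      perm <- sample.int(n)
      if (.procrustesM2(Ac, Bc[perm, , drop = FALSE]) <= m2)
        hits <- hits + 1L
    }
    p <- (1 + hits) / (nPermutations + 1)
  }
  new("ProcrustesResult", m2 = max(m2, 0), rotation = rot, scale = scl,
      translation = trans, permutationP = p,
      nPermutations = as.numeric(nPermutations), seed = as.numeric(seed))
}
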