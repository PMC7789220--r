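# Orthogonal partial least squares (regression and discriminant) with
# VIP scores; used to cross-validate module-trait associations.

.norm1 <- function(x) x / sqrt(sum(x^2))

.encodeY <- function(y, yType = c("auto", "quantitative", "qualitative")) {
  yType <- match.arg(yType)
  if (yType == "auto")
    yType <- if (is.numeric(y)) "quantitative" else "qualitative"
  if (yType == "quantitative") {
    y <- as.numeric(y)
    if (stats::sd(y) == 0) stop("constant response")
    Y <- matrix(scale(y), ncol = 1, dimnames = list(NULL, "y"))
    list(Y = Y, encoding = "numeric")
  } else {
    f <- factor(y)
    if (nlevels(f) < 2) stop("qualitative response needs at least 2 levels")
    Y <- stats::model.matrix(~ 0 + f)
    colnames(Y) <- levels(f)
    Y <- scale(Y, center = TRUE, scale = FALSE)  # dummy columns centered only
    list(Y = Y, encoding = "dummy", levels = levels(f), classes = f)
  }
}

.predictiveWeight <- function(X, Y) {
  w <- .norm1(svd(crossprod(X, Y), nu = 1, nv = 0)$u[, 1])
  # deterministic orientation along X'Y[,1]
  ref <- crossprod(X, Y[, 1])
  if (sum(w * ref) < 0) w <- -w
  w
}

.oplsCore <- function(X, Y, nOrth) {
  Wo <- matrix(0, ncol(X), 0); Po <- matrix(0, ncol(X), 0)
  To <- matrix(0, nrow(X), 0)
  Xw <- X
  for (i in seq_len(nOrth)) {
    w <- .predictiveWeight(Xw, Y)
    t <- Xw %*% w
    p <- crossprod(Xw, t) / sum(t^2)
    wo <- p - as.numeric(crossprod(w, p)) * w
    nwo <- sqrt(sum(wo^2))
    if (nwo < 1e-12) {
      warning("no Y-orthogonal variation left after ", i - 1,
              " component(s)")
      break
    }
    wo <- wo / nwo
    to <- Xw %*% wo
    po <- crossprod(Xw, to) / sum(to^2)
    Xw <- Xw - to %*% t(po)
    Wo <- cbind(Wo, wo); Po <- cbind(Po, po); To <- cbind(To, to)
  }
  w <- .predictiveWeight(Xw, Y)
  t <- Xw %*% w
  p <- crossprod(Xw, t) / sum(t^2)
  cc <- crossprod(Y, t) / sum(t^2)
  R2Y <- 1 - sum((Y - t %*% t(cc))^2) / sum(Y^2)
  list(w = w, t = t, p = p, c = cc, Wo = Wo, Po = Po, To = To, R2Y = R2Y)
}

.removeOrtho <- function(X, Wo, Po) {
  for (i in seq_len(ncol(Wo))) {
    to <- X %*% Wo[, i]
    X <- X - to %*% t(Po[, i, drop = FALSE])
  }
  X
}

#' Fit an OPLS model
#'
#' Orthogonal-signal-corrected NIPALS: \code{nOrth} components of
#' X-variation orthogonal to the response are removed, then a single
#' predictive component is fitted. Predictors are standardized
#' internally; quantitative responses are standardized, qualitative
#' responses dummy-coded (centered columns), making the discriminant
#' variant (OPLS-DA).
#'
#' @param X samples-by-features matrix (at least 5 samples).
#' @param y response: numeric vector or factor/character.
#' @param nOrth number of orthogonal components (must be below rank(X)).
#' @param yType "auto" (default), "quantitative" or "qualitative".
#' @return An [OplsModel-class].
#' @export
oplsFit <- function(X, y, nOrth = 1,
                    yType = c("auto", "quantitative", "qualitative")) {
  X <- as.matrix(X)
  if (nrow(X) < 5) stop("OPLS needs at least 5 samples")
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance predictor(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  if (nOrth >= qr(X)$rank)
    stop("nOrth must be smaller than rank(X) = ", qr(X)$rank)
  enc <- .encodeY(y, yType)
  Xs <- scale(X)
  fit <- .oplsCore(Xs, enc$Y, nOrth)
  # per-feature correlation to the response; for dummy coding, the
  # max-|r| level column per feature
  rmat <- stats::cor(Xs, enc$Y)
  traitR <- if (ncol(rmat) == 1) rmat[, 1] else
    rmat[cbind(seq_len(nrow(rmat)), max.col(abs(rmat)))]
  fid <- colnames(X)
  if (is.null(fid)) fid <- paste0("x", seq_len(ncol(X)))
  new("OplsModel",
      scores = fit$t, loadings = fit$p, weights = matrix(fit$w, ncol = 1),
      yWeights = fit$c, orthoScores = fit$To, orthoLoadings = fit$Po,
      orthoWeights = fit$Wo, R2Y = min(max(fit$R2Y, 0), 1),
      yEncoding = enc$encoding, featureIDs = fid,
      traitR = stats::setNames(as.numeric(traitR), fid))
}

#' Variable importance in projection
#'
#' With a single predictive component, VIP_j = sqrt(p) |w_j| for the unit
#' weight vector w, so that sum(VIP^2) equals the number of features.
#'
#' @param model an [OplsModel-class].
#' @return data.frame with columns feature, vip and trait_r (the
#'   feature's correlation to the response).
#' @export
vipScores <- function(model) {
  p <- length(model@featureIDs)
  vip <- sqrt(p) * abs(model@weights[, 1])
  data.frame(feature = model@featureIDs, vip = as.numeric(vip),
             trait_r = as.numeric(model@traitR), row.names = NULL)
}

.makeFolds <- function(y, kFolds, seed, encoding) {
  n <- length(y)
  if (kFolds < 2 || kFolds > n) stop("kFolds must lie in [2, n]")
  set.seed(seed)
  fold <- integer(n)
  if (encoding == "dummy") {
    # stratified: deal each class round-robin so folds keep all classes
    f <- factor(y)
    for (lv in levels(f)) {
      idx <- sample(which(f == lv))
      fold[idx] <- rep_len(seq_len(kFolds), length(idx))
    }
  } else {
    fold[sample.int(n)] <- rep_len(seq_len(kFolds), n)
  }
  fold
}

#' Cross-validated predictive ability Q2
#'
#' Q2 = 1 - PRESS/SSY over seeded k-fold splits (stratified by class for
#' qualitative responses). Train-set standardization is applied to the
#' held-out samples; a Q2 at or below zero means the model predicts no
#' better than the response mean.
#'
#' @param X samples-by-features matrix.
#' @param y response vector or factor.
#' @param nOrth number of orthogonal components.
#' @param kFolds number of folds (default 7).
#' @param seed RNG seed making the split deterministic.
#' @param yType response type, as in [oplsFit()].
#' @return Q2 as a single number.
#' @export
oplsCrossValidate <- function(X, y, nOrth = 1, kFolds = 7, seed = 1,
                              yType = c("auto", "quantitative", "qualitative")) {
  X <- as.matrix(X)
  yType <- match.arg(yType)
  encoding <- if ((yType == "auto" && !is.numeric(y)) || yType == "qualitative")
    "dummy" else "numeric"
  fold <- .makeFolds(y, kFolds, seed, encoding)
  press <- 0; ssy <- 0
  for (k in sort(unique(fold))) {
    tr <- fold != k; te <- !tr
    ytr <- if (encoding == "dummy") factor(y[tr]) else y[tr]
    if (encoding == "dummy" && nlevels(ytr) < 2)
      stop("a training fold lost all but one class; reduce kFolds")
    mu <- colMeans(X[tr, , drop = FALSE])
    sdv <- apply(X[tr, , drop = FALSE], 2, stats::sd)
    if (any(sdv == 0)) stop("zero-variance predictor within a training fold")
    Xtr <- scale(X[tr, , drop = FALSE], mu, sdv)
    Xte <- scale(X[te, , drop = FALSE], mu, sdv)
    if (encoding == "numeric") {
      ym <- mean(y[tr]); ys <- stats::sd(y[tr])
      Ytr <- matrix((y[tr] - ym) / ys, ncol = 1)
      Yte <- matrix((y[te] - ym) / ys, ncol = 1)
    } else {
      f <- factor(y, levels = levels(factor(y)))
      D <- stats::model.matrix(~ 0 + f)
      dm <- colMeans(D[tr, , drop = FALSE])
      Ytr <- sweep(D[tr, , drop = FALSE], 2, dm)
      Yte <- sweep(D[te, , drop = FALSE], 2, dm)
    }
    fit <- .oplsCore(Xtr, Ytr, nOrth)
    Xte2 <- .removeOrtho(Xte, fit$Wo, fit$Po)
    Yhat <- (Xte2 %*% fit$w) %*% t(fit$c)
    press <- press + sum((Yte - Yhat)^2)
    ssy <- ssy + sum(Yte^2)
  }
  1 - press / ssy
}

#' OPLS validation of one module against a trait
#'
#' Fits an OPLS model using the module's features as predictors of the
#' chosen trait, and returns the per-feature VIP score paired with the
#' feature's correlation to the trait (the two hive-plot axes), together
#' with the module's internal network edges above \code{edgeCut}.
#'
#' @param layer an [OmicsLayer-class].
#' @param partition a [ModulePartition-class] for the layer.
#' @param module module id (at least 3 features).
#' @param adjacency the layer's full adjacency matrix.
#' @param annotation an [AnnotationTable-class], samples aligned.
#' @param trait trait name.
#' @param edgeCut adjacency weight above which an intra-module edge is
#'   reported.
#' @param nOrth orthogonal components for the fit.
#' @return list with \code{table} (feature, vip, trait_r), \code{edges}
#'   (feature_a, feature_b, weight) and \code{model}.
#' @export
moduleOplsValidation <- function(layer, partition, module, adjacency,
                                 annotation, trait, edgeCut = 0.1,
                                 nOrth = 1) {
  members <- partition@featureIDs[partition@labels == module]
  if (length(members) < 3)
    stop("module ", module, " has fewer than 3 features")
  d <- annotationData(annotation)
  if (!trait %in% names(d)) stop("unknown trait: ", trait)
  v <- layerValues(layer)
  stopifnot(identical(rownames(v), rownames(d)))
  model <- oplsFit(v[, members, drop = FALSE], d[[trait]], nOrth = nOrth)
  tab <- vipScores(model)
  a <- adjacency[members, members, drop = FALSE]
  ut <- which(upper.tri(a) & a > edgeCut, arr.ind = TRUE)
  edges <- data.frame(feature_a = members[ut[, 1]],
                      feature_b = members[ut[, 2]],
                      weight = a[ut], row.names = NULL)
  list(table = tab, edges = edges, model = model)
}
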