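# Exploratory ordination: PCA, sample distances, PCoA.

.signFix <- function(coords, loadings = NULL) {
  # orient each axis so its element of largest magnitude (loading if
  # available, else coordinate) is positive
  ref <- if (is.null(loadings)) coords else loadings
  for (k in seq_len(ncol(coords))) {
    i <- which.max(abs(ref[, k]))
    if (ref[i, k] < 0) {
      coords[, k] <- -coords[, k]
      if (!is.null(loadings)) loadings[, k] <- -loadings[, k]
    }
  }
  list(coordinates = coords, loadings = loadings)
}

#' Principal component analysis of one layer
#'
#' @param layer an [OmicsLayer-class] or numeric matrix (samples in rows).
#' @param center,scale passed to the underlying decomposition; scaling a
#'   zero-variance feature is an error.
#' @param nAxes number of axes to keep (at most min(n - 1, p)).
#' @return An [OrdinationResult-class]; eigenvalues are the variances
#'   along the principal axes.
#' @export
ordinatePCA <- function(layer, center = TRUE, scale = FALSE, nAxes = 2) {
  v <- if (is(layer, "OmicsLayer")) layerValues(layer) else as.matrix(layer)
  maxAxes <- min(nrow(v) - 1, ncol(v))
  if (nAxes > maxAxes)
    stop("nAxes must not exceed min(n_samples - 1, n_features) = ", maxAxes)
  if (scale) {
    sds <- apply(v, 2, stats::sd)
    if (any(sds == 0))
      stop("cannot scale zero-variance feature(s): ",
           paste(colnames(v)[sds == 0], collapse = ", "))
  }
  pc <- stats::prcomp(v, center = center, scale. = scale)
  ev <- pc$sdev^2
  coords <- pc$x[, seq_len(nAxes), drop = FALSE]
  load <- pc$rotation[, seq_len(nAxes), drop = FALSE]
  sf <- .signFix(coords, load)
  new("OrdinationResult", coordinates = sf$coordinates,
      eigenvalues = ev, explained = ev / sum(ev),
      loadings = sf$loadings, method = "pca")
}

#' Pairwise sample distances
#'
#' @param layer an [OmicsLayer-class] or matrix (samples in rows).
#' @param metric "euclidean", "bray" (Bray-Curtis; nonnegative input
#'   required) or "jaccard" (on presence/absence).
#' @return A [DistanceMatrix-class].
#' @export
distanceMatrix <- function(layer, metric = c("euclidean", "bray", "jaccard")) {
  metric <- match.arg(metric)
  v <- if (is(layer, "OmicsLayer")) layerValues(layer) else as.matrix(layer)
  if (metric %in% c("bray", "jaccard") && any(v < 0))
    stop(metric, " distance requires nonnegative values")
  d <- switch(metric,
    euclidean = stats::dist(v),
    bray = vegan::vegdist(v, method = "bray"),
    jaccard = vegan::vegdist(v, method = "jaccard", binary = TRUE))
  m <- as.matrix(d)
  diag(m) <- 0
  dimnames(m) <- list(rownames(v), rownames(v))
  new("DistanceMatrix", values = m, metric = metric)
}

#' Principal coordinates analysis (classical scaling)
#'
#' Double-centers -D^2/2 and eigendecomposes it. Negative eigenvalues
#' (from non-Euclidean distances) are reported in the spectrum; with
#' \code{correction = "constant-shift"} the Cailliez additive constant is
#' applied to the off-diagonal distances so the corrected spectrum is
#' nonnegative.
#'
#' @param dist a [DistanceMatrix-class].
#' @param correction "none" or "constant-shift".
#' @param nAxes number of axes requested; truncated with a warning when it
#'   exceeds the number of positive eigenvalues.
#' @return An [OrdinationResult-class]; explained fractions are computed
#'   over the positive eigenvalues.
#' @export
ordinatePCoA <- function(dist, correction = c("none", "constant-shift"),
                         nAxes = 2) {
  correction <- match.arg(correction)
  d <- dist@values
  n <- nrow(d)
  if (max(d) == 0) {
    coords <- matrix(0, n, nAxes,
                     dimnames = list(rownames(d), paste0("Axis", seq_len(nAxes))))
    return(new("OrdinationResult", coordinates = coords,
               eigenvalues = rep(0, n), explained = rep(0, nAxes),
               loadings = matrix(0, 0, 0), method = "pcoa"))
  }
  cs <- suppressWarnings(
    stats::cmdscale(d, k = min(nAxes, n - 1), eig = TRUE,
                    add = correction == "constant-shift"))
  ev <- sort(cs$eig, decreasing = TRUE)
  npos <- sum(ev > 1e-10 * max(abs(ev)))
  if (nAxes > npos) {
    warning("only ", npos, " positive eigenvalue(s); returning ", npos,
            " axes instead of ", nAxes)
    nAxes <- npos
  }
  coords <- cs$points[, seq_len(nAxes), drop = FALSE]
  colnames(coords) <- paste0("Axis", seq_len(nAxes))
  rownames(coords) <- rownames(d)
  coords <- .signFix(coords)$coordinates
  pos <- ev[ev > 0]
  new("OrdinationResult", coordinates = coords, eigenvalues = ev,
      explained = ev[seq_len(nAxes)] / sum(pos),
      loadings = matrix(0, 0, 0), method = "pcoa")
}
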