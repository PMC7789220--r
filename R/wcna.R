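# Per-layer weighted correlation network analysis: soft threshold,
# adjacency, topological overlap, modules, eigengenes, trait association.

# standard co-expression module palette; recycled with a numeric suffix
# when a layer yields more modules than names
.moduleColorNames <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
  "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
  "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
  "orange", "darkorange", "white", "skyblue", "saddlebrown", "steelblue")

.colorForModule <- function(id) {
  if (id == 0L) return("grey")
  base <- .moduleColorNames
  if (id <= length(base)) base[id]
  else paste0(base[(id - 1L) %% length(base) + 1L], ".",
              (id - 1L) %/% length(base) + 1L)
}

#' Feature-feature correlation matrix
#'
#' @param layer an [OmicsLayer-class] with at least 3 samples.
#' @param method "pearson" or "spearman".
#' @return symmetric features-by-features correlation matrix with unit
#'   diagonal.
#' @export
featureCorrelation <- function(layer, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  v <- layerValues(layer)
  if (nrow(v) < 3) stop("correlation needs at least 3 samples")
  sds <- apply(v, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance feature(s): ",
         paste(colnames(v)[sds == 0], collapse = ", "))
  r <- stats::cor(v, method = method)
  diag(r) <- 1
  r
}

#' Soft-thresholded adjacency
#'
#' Unsigned: a_ij = |r_ij|^power. Signed: a_ij = ((1 + r_ij)/2)^power.
#' The diagonal is set to 1.
#'
#' @param corr correlation matrix.
#' @param power soft-threshold exponent, at least 1.
#' @param networkType "unsigned" or "signed".
#' @return adjacency matrix with entries in [0,1].
#' @export
adjacencyMatrix <- function(corr, power = 6,
                            networkType = c("unsigned", "signed")) {
  networkType <- match.arg(networkType)
  if (power < 1) stop("power must be >= 1")
  a <- if (networkType == "unsigned") abs(corr)^power
       else ((1 + corr) / 2)^power
  diag(a) <- 1
  a
}

.scaleFreeFit <- function(k, nBins = 10) {
  # R^2 of the log10-log10 regression of binned degree frequency on bin
  # center, signed so positive slopes are penalized
  if (diff(range(k)) == 0) return(c(r2 = NA_real_, slope = NA_real_))
  br <- seq(min(k), max(k), length.out = nBins + 1)
  bin <- cut(k, br, include.lowest = TRUE)
  freq <- as.vector(table(bin)) / length(k)
  ctr <- (br[-1] + br[-length(br)]) / 2
  keep <- freq > 0 & ctr > 0
  if (sum(keep) < 2) return(c(r2 = NA_real_, slope = NA_real_))
  x <- log10(ctr[keep]); y <- log10(freq[keep])
  fit <- stats::lm(y ~ x)
  slope <- stats::coef(fit)[2]
  r2 <- summary(fit)$r.squared
  c(r2 = unname(sign(-slope) * r2), slope = unname(slope))
}

#' Choose the soft-threshold power for scale-free topology
#'
#' For each candidate power, builds the adjacency, computes connectivities
#' k_i = sum_{j != i} a_ij, bins them into \code{nBins} equal-width bins
#' and regresses log10(bin frequency) on log10(bin center). The signed fit
#' index sign(-slope) * R^2 penalizes degree distributions that increase
#' with k. The chosen power is the smallest candidate reaching
#' \code{r2Target}; if none does, the power with the best fit is returned
#' with a warning.
#'
#' @param corr correlation matrix.
#' @param candidates candidate powers.
#' @param networkType "unsigned" or "signed".
#' @param r2Target required signed scale-free fit (default 0.8).
#' @param nBins number of equal-width degree bins.
#' @return list with \code{report} (data.frame: power, r2, slope, meanK,
#'   medianK, maxK) and \code{power} (the chosen value, NA if no fit was
#'   defined for any candidate).
#' @export
pickSoftThreshold <- function(corr,
                              candidates = c(1:10, seq(12, 20, 2), 25, 30),
                              networkType = c("unsigned", "signed"),
                              r2Target = 0.8, nBins = 10) {
  networkType <- match.arg(networkType)
  if (length(candidates) < 2) stop("need at least 2 candidate powers")
  rows <- lapply(candidates, function(b) {
    a <- adjacencyMatrix(corr, b, networkType)
    k <- rowSums(a) - 1
    f <- .scaleFreeFit(k, nBins)
    data.frame(power = b, r2 = f["r2"], slope = f["slope"],
               meanK = mean(k), medianK = stats::median(k), maxK = max(k))
  })
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  ok <- which(!is.na(report$r2) & report$r2 >= r2Target)
  if (length(ok)) {
    power <- report$power[ok[1]]
  } else if (all(is.na(report$r2))) {
    warning("scale-free fit undefined for every candidate (degenerate ",
            "degree distribution); no power chosen")
    power <- NA_real_
  } else {
    power <- report$power[which.max(report$r2)]
    warning("no candidate reached the scale-free fit target ", r2Target,
            "; using power ", power, " (best R2 = ",
            signif(max(report$r2, na.rm = TRUE), 3), ")")
  }
  list(report = report, power = power, r2Target = r2Target)
}

#' Topological overlap similarity
#'
#' TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij) with
#' l_ij = sum_{u != i,j} a_iu a_uj and k_i = sum_{u != i} a_iu; the
#' diagonal is 1. Two features overlap strongly when they are connected
#' and share neighbors.
#'
#' @param adj symmetric adjacency matrix with entries in [0,1].
#' @return TOM matrix in [0,1].
#' @export
tomSimilarity <- function(adj) {
  if (max(abs(adj - t(adj))) > 1e-10) stop("adjacency must be symmetric")
  if (min(adj) < -1e-12 || max(adj) > 1 + 1e-12)
    stop("adjacency entries must lie in [0,1]")
  a <- adj
  diag(a) <- 0
  l <- a %*% a           # diag(a)=0 removes the u = i and u = j terms
  k <- rowSums(a)
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (l + a) / denom
  diag(tom) <- 1
  tom[tom > 1] <- 1      # guard against fp overshoot
  tom
}

#' Detect modules by static cut of the TOM dendrogram
#'
#' Average-linkage hierarchical clustering of the dissimilarity 1 - TOM,
#' cut at \code{cutHeight} times the maximum merge height. Clusters
#' smaller than \code{minModuleSize} are left unassigned (label 0, grey);
#' the rest are renumbered 1..K by decreasing size.
#'
#' @param tom TOM matrix from [tomSimilarity()].
#' @param params a [NetworkParams-class]; \code{minModuleSize} and
#'   \code{cutHeight} are used.
#' @return A [ModulePartition-class].
#' @export
detectModules <- function(tom, params = networkParams()) {
  stopifnot(is(params, "NetworkParams"))
  n <- ncol(tom)
  ids <- colnames(tom)
  if (is.null(ids)) ids <- paste0("f", seq_len(n))
  if (params@minModuleSize > n) {
    warning("minModuleSize exceeds the number of features; ",
            "all features left unassigned")
    return(new("ModulePartition", featureIDs = ids,
               labels = rep(0L, n), colors = rep("grey", n),
               minModuleSize = params@minModuleSize))
  }
  tree <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  h <- params@cutHeight * max(tree$height)
  raw <- stats::cutree(tree, h = h)
  sizes <- table(raw)
  keep <- as.integer(names(sizes)[sizes >= params@minModuleSize])
  labels <- integer(n)
  if (length(keep)) {
    # renumber by decreasing size; ties broken by original cluster id
    ord <- keep[order(-as.integer(sizes[as.character(keep)]), keep)]
    for (i in seq_along(ord)) labels[raw == ord[i]] <- i
  }
  new("ModulePartition", featureIDs = ids, labels = labels,
      colors = vapply(labels, .colorForModule, character(1)),
      minModuleSize = params@minModuleSize)
}

.eigengeneOf <- function(vsub) {
  # first left singular vector of the standardized submatrix, unit
  # variance, oriented along the mean standardized profile
  z <- scale(vsub)
  if (any(!is.finite(z)))
    stop("zero-variance feature inside a module: ",
         paste(colnames(vsub)[apply(vsub, 2, stats::sd) == 0], collapse = ", "))
  u <- svd(z, nu = 1, nv = 0)$u[, 1]
  e <- u / stats::sd(u)
  m <- rowMeans(z)
  s <- sum(e * m)
  if (s < 0) e <- -e
  e
}

#' Module eigengenes
#'
#' The eigengene of a module is the first left singular vector of its
#' standardized (zero-mean, unit-variance features) sample-by-feature
#' submatrix, scaled to unit variance and sign-oriented so it correlates
#' nonnegatively with the module's mean standardized profile. A singleton
#' module's eigengene is the standardized feature itself.
#'
#' @param layer an [OmicsLayer-class].
#' @param partition a [ModulePartition-class] for this layer's features;
#'   unassigned features (label 0) are ignored.
#' @return An [EigengeneMatrix-class] with one column per module.
#' @export
moduleEigengenes <- function(layer, partition) {
  v <- layerValues(layer)
  stopifnot(identical(colnames(v), partition@featureIDs))
  ids <- sort(unique(partition@labels[partition@labels > 0L]))
  if (!length(ids)) stop("partition contains no proper modules")
  em <- sapply(ids, function(m)
    .eigengeneOf(v[, partition@labels == m, drop = FALSE]))
  em <- matrix(em, nrow = nrow(v),
               dimnames = list(rownames(v), paste0("ME", ids)))
  new("EigengeneMatrix", values = em, moduleIDs = as.integer(ids))
}

#' Merge modules with similar eigengenes
#'
#' Iteratively merges the module pair with the smallest eigengene
#' dissimilarity 1 - cor while it is below \code{mergeCut}, recomputing
#' eigengenes after each merge. Modules are renumbered by decreasing size
#' at the end.
#'
#' @param layer an [OmicsLayer-class].
#' @param partition a [ModulePartition-class].
#' @param mergeCut dissimilarity threshold (default 0.25, i.e. merge
#'   modules whose eigengenes correlate above 0.75).
#' @return list with the merged \code{partition} and its
#'   \code{eigengenes}.
#' @export
mergeCloseModules <- function(layer, partition, mergeCut = 0.25) {
  labels <- partition@labels
  repeat {
    ids <- sort(unique(labels[labels > 0L]))
    if (length(ids) < 2) break
    tmp <- new("ModulePartition", featureIDs = partition@featureIDs,
               labels = labels,
               colors = vapply(labels, .colorForModule, character(1)),
               minModuleSize = 2)
    eg <- moduleEigengenes(layer, tmp)
    d <- 1 - stats::cor(eigengeneValues(eg))
    diag(d) <- Inf
    mn <- which(d == min(d), arr.ind = TRUE)[1, ]
    if (d[mn[1], mn[2]] >= mergeCut) break
    a <- ids[min(mn)]; b <- ids[max(mn)]
    labels[labels == b] <- a
  }
  # renumber by decreasing size
  ids <- unique(labels[labels > 0L])
  if (length(ids)) {
    sizes <- vapply(ids, function(m) sum(labels == m), integer(1))
    ord <- ids[order(-sizes, ids)]
    newLabels <- integer(length(labels))
    for (i in seq_along(ord)) newLabels[labels == ord[i]] <- i
    labels <- newLabels
  }
  part <- new("ModulePartition", featureIDs = partition@featureIDs,
              labels = labels,
              colors = vapply(labels, .colorForModule, character(1)),
              minModuleSize = partition@minModuleSize)
  list(partition = part, eigengenes = moduleEigengenes(layer, part))
}

.corTestGrid <- function(x, y, method = "pearson") {
  # correlate columns of x with columns of y; two-sided p from
  # t = r sqrt(n-2)/sqrt(1-r^2); constant columns give NA
  n <- nrow(x)
  if (method == "spearman") {
    x <- apply(x, 2, rank)
    y <- apply(y, 2, rank)
  }
  sx <- apply(x, 2, stats::sd); sy <- apply(y, 2, stats::sd)
  r <- suppressWarnings(stats::cor(x, y))
  r[sx == 0, ] <- NA; r[, sy == 0] <- NA
  rc <- pmin(pmax(r, -1), 1)
  t <- rc * sqrt(n - 2) / sqrt(pmax(1 - rc^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(t), df = n - 2)
  p[p == 0] <- .Machine$double.xmin  # keep p in (0,1]
  p[is.na(r)] <- NA
  list(r = r, p = p, n = n)
}

.expandTraits <- function(annotation) {
  # quantitative traits pass through; qualitative traits become one
  # indicator column per level, named trait.level
  d <- annotationData(annotation)
  cols <- list(); traitOf <- character()
  for (nm in names(d)) {
    x <- d[[nm]]
    if (is.numeric(x)) {
      cols[[nm]] <- as.numeric(x)
      traitOf[nm] <- nm
    } else {
      f <- factor(x)
      if (nlevels(f) < 2)
        stop("qualitative trait '", nm, "' has fewer than 2 observed levels")
      for (lv in levels(f)) {
        cn <- paste0(nm, ".", lv)
        cols[[cn]] <- as.numeric(f == lv)
        traitOf[cn] <- nm
      }
    }
  }
  m <- do.call(cbind, cols)
  rownames(m) <- rownames(d)
  list(values = m, traitOf = traitOf)
}

#' Module-trait correlation report
#'
#' Correlates every module eigengene with every trait column.
#' Quantitative traits are used directly; qualitative traits are expanded
#' to one indicator column per level (point-biserial correlation).
#' Two-sided p-values come from the t distribution with n - 2 degrees of
#' freedom; q-values are Benjamini-Hochberg adjusted across the whole
#' modules-by-trait-columns grid.
#'
#' @param eigengenes an [EigengeneMatrix-class].
#' @param annotation an [AnnotationTable-class] with the same samples in
#'   the same order.
#' @param method "pearson" (default) or "spearman".
#' @return data.frame with columns module, trait, column, r, p, q, n;
#'   constant trait columns yield NA correlations.
#' @export
moduleTraitCorrelation <- function(eigengenes, annotation,
                                   method = c("pearson", "spearman")) {
  method <- match.arg(method)
  em <- eigengeneValues(eigengenes)
  stopifnot(identical(rownames(em), sampleIDs(annotation)))
  ex <- .expandTraits(annotation)
  ct <- .corTestGrid(em, ex$values, method)
  grid <- expand.grid(module = moduleIDs(eigengenes),
                      column = colnames(ex$values),
                      stringsAsFactors = FALSE)
  grid$trait <- ex$traitOf[grid$column]
  grid$r <- as.vector(ct$r)
  grid$p <- as.vector(ct$p)
  grid$q <- NA_real_
  ok <- !is.na(grid$p)
  grid$q[ok] <- stats::p.adjust(grid$p[ok], method = "BH")
  grid$n <- ct$n
  grid[, c("module", "trait", "column", "r", "p", "q", "n")]
}

#' Per-sample module contributions
#'
#' Returns each sample's eigengene value for one module, paired with a
#' trait of interest, in sample order — the data behind the
#' sample-contribution bar plot that shows which samples drive a module.
#'
#' @param eigengenes an [EigengeneMatrix-class].
#' @param module module id.
#' @param annotation an [AnnotationTable-class], samples aligned.
#' @param trait trait name.
#' @return data.frame with columns sample, contribution, trait value.
#' @export
sampleContributions <- function(eigengenes, module, annotation, trait) {
  em <- eigengeneValues(eigengenes)
  col <- match(module, moduleIDs(eigengenes))
  if (is.na(col)) stop("unknown module: ", module)
  d <- annotationData(annotation)
  if (!trait %in% names(d)) stop("unknown trait: ", trait)
  stopifnot(identical(rownames(em), rownames(d)))
  out <- data.frame(sample = rownames(em), contribution = em[, col],
                    row.names = NULL)
  out[[trait]] <- d[[trait]]
  out
}

#' Module membership (kME)
#'
#' kME_jm = cor(feature j, eigengene m); the correlation of every feature
#' with every module eigengene, used to rank hub features.
#'
#' @param layer an [OmicsLayer-class].
#' @param eigengenes an [EigengeneMatrix-class] on the same samples.
#' @return features-by-modules correlation matrix.
#' @export
moduleMembership <- function(layer, eigengenes) {
  v <- layerValues(layer)
  em <- eigengeneValues(eigengenes)
  stopifnot(identical(rownames(v), rownames(em)))
  stats::cor(v, em)
}

#' Run the full single-layer network analysis
#'
#' Convenience wrapper: correlation, (optional) soft-threshold search,
#' adjacency, TOM, module detection and merging, eigengenes.
#'
#' @param layer an [OmicsLayer-class].
#' @param params a [NetworkParams-class].
#' @param autoPower when TRUE, [pickSoftThreshold()] overrides
#'   \code{params@power} (falling back to it if no fit is defined).
#' @return list with elements corr, adjacency, tom, partition, eigengenes,
#'   softThreshold (NULL unless autoPower) and params.
#' @export
runNetworkAnalysis <- function(layer, params = networkParams(),
                               autoPower = FALSE) {
  corr <- featureCorrelation(layer, params@correlation)
  st <- NULL
  power <- params@power
  if (autoPower) {
    st <- pickSoftThreshold(corr, networkType = params@networkType)
    if (!is.na(st$power)) power <- st$power
  }
  adj <- adjacencyMatrix(corr, power, params@networkType)
  tom <- tomSimilarity(adj)
  part <- detectModules(tom, params)
  if (sum(unique(part@labels) > 0L) >= 2 && params@mergeCut > 0) {
    merged <- mergeCloseModules(layer, part, params@mergeCut)
    part <- merged$partition
    eg <- merged$eigengenes
  } else if (any(part@labels > 0L)) {
    eg <- moduleEigengenes(layer, part)
  } else {
    eg <- NULL
  }
  list(corr = corr, adjacency = adj, tom = tom, partition = part,
       eigengenes = eg, softThreshold = st, params = params, power = power)
}
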