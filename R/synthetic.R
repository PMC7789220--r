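# Synthetic multi-omics generator with known ground truth: planted
# within-layer modules, shared cross-layer latent factors and trait
# effects. Used for validation in place of external example datasets.

#' Describe a synthetic multi-omics study
#'
#' Builds and validates the configuration consumed by
#' [generateMultiOmics()] and [makeNull()]. Data follow a latent factor
#' model: feature j of a module follows x_ij = lambda_j f_m(i) + eps_ij
#' with eps ~ N(0, noiseSd^2); the loadings lambda_j are drawn uniformly
#' in [0.8, 1.2] and rescaled so the expected within-module correlation
#' matches \code{withinCor}. Features outside any module are pure noise.
#'
#' @param nSamples number of samples.
#' @param layers named list; each entry is a list with \code{nFeatures},
#'   \code{moduleSizes} (vector; must sum to at most nFeatures) and
#'   \code{withinCor} (target within-module correlation, in (0,1)).
#' @param sharedFactors list of groups; each group is a list with
#'   \code{members} (list of c(layer, moduleIndex) pairs) and \code{cor}
#'   (correlation of later members' factors to the first member's factor;
#'   default 1 = identical factor).
#' @param traits named list; each entry is a list with \code{type}
#'   ("quantitative" or "qualitative") and \code{factor} = c(layer,
#'   moduleIndex) naming the driving latent factor. Quantitative traits
#'   take \code{beta} (linear effect, default 1) and \code{noiseSd}
#'   (default 0.5); qualitative traits take \code{quantiles} (thresholds
#'   on the factor, default 0.5 giving two balanced groups).
#' @param noiseSd feature noise standard deviation.
#' @param seed default RNG seed.
#' @return the validated config (class \code{list}).
#' @export
syntheticConfig <- function(nSamples, layers, sharedFactors = list(),
                            traits = list(), noiseSd = 1, seed = 1) {
  stopifnot(nSamples >= 3, length(layers) >= 1, !is.null(names(layers)))
  for (nm in names(layers)) {
    ly <- layers[[nm]]
    if (sum(ly$moduleSizes) > ly$nFeatures)
      stop("layer '", nm, "': module sizes exceed nFeatures")
    if (ly$withinCor <= 0 || ly$withinCor >= 1)
      stop("layer '", nm, "': withinCor must lie strictly inside (0,1)")
    if (any(ly$moduleSizes < 1)) stop("module sizes must be positive")
  }
  for (g in sharedFactors) {
    if (length(g$members) < 2) stop("a shared-factor group needs >= 2 members")
    for (m in g$members) {
      if (!m[1] %in% names(layers)) stop("unknown layer in sharedFactors: ", m[1])
      if (as.integer(m[2]) > length(layers[[m[1]]]$moduleSizes))
        stop("module index out of range in sharedFactors")
    }
    if (!is.null(g$cor) && (g$cor < -1 || g$cor > 1))
      stop("shared-factor cor must lie in [-1,1]")
  }
  for (nm in names(traits)) {
    tr <- traits[[nm]]
    if (!tr$type %in% c("quantitative", "qualitative"))
      stop("trait '", nm, "': type must be quantitative or qualitative")
    if (!tr$factor[1] %in% names(layers))
      stop("trait '", nm, "': unknown layer")
  }
  structure(list(nSamples = nSamples, layers = layers,
                 sharedFactors = sharedFactors, traits = traits,
                 noiseSd = noiseSd, seed = seed),
            class = c("syntheticConfig", "list"))
}

.meanPairCor <- function(lambda, sigma) {
  v <- lambda / sqrt(lambda^2 + sigma^2)
  cp <- tcrossprod(v)
  mean(cp[upper.tri(cp)])
}

.solveLoadings <- function(u, target, sigma) {
  # scale the raw loadings u so the expected within-module correlation
  # hits the target; the mean pair correlation is increasing in the scale
  if (length(u) == 1) return(u)  # singleton: correlation target is moot
  f <- function(cc) .meanPairCor(cc * u, sigma) - target
  cc <- stats::uniroot(f, c(1e-8, 1e6), tol = 1e-12)$root
  cc * u
}

.generate <- function(config, seed, null) {
  set.seed(seed)
  n <- config$nSamples
  samples <- sprintf("S%03d", seq_len(n))
  # factor per (layer, module); shared groups reuse/mix one group factor
  groupFactor <- lapply(config$sharedFactors, function(g) stats::rnorm(n))
  memberOf <- list()
  if (!null) {
    for (gi in seq_along(config$sharedFactors)) {
      g <- config$sharedFactors[[gi]]
      for (mi in seq_along(g$members)) {
        key <- paste(g$members[[mi]][1], g$members[[mi]][2], sep = ":")
        memberOf[[key]] <- list(group = gi, first = mi == 1,
                                cor = if (is.null(g$cor)) 1 else g$cor)
      }
    }
  }
  factors <- list()
  layers <- list()
  truthModules <- list()
  for (nm in names(config$layers)) {
    ly <- config$layers[[nm]]
    p <- ly$nFeatures
    X <- matrix(stats::rnorm(n * p, sd = config$noiseSd), n, p)
    labels <- integer(p)
    at <- 1L
    for (m in seq_along(ly$moduleSizes)) {
      s <- ly$moduleSizes[m]
      key <- paste(nm, m, sep = ":")
      mo <- memberOf[[key]]
      f <- if (is.null(mo)) {
        stats::rnorm(n)
      } else if (mo$first || mo$cor == 1) {
        groupFactor[[mo$group]]
      } else {
        mo$cor * groupFactor[[mo$group]] +
          sqrt(1 - mo$cor^2) * stats::rnorm(n)
      }
      factors[[key]] <- f
      u <- stats::runif(s, 0.8, 1.2)
      lambda <- .solveLoadings(u, ly$withinCor, config$noiseSd)
      idx <- at:(at + s - 1L)
      X[, idx] <- X[, idx] + tcrossprod(f, lambda)
      labels[idx] <- m
      at <- at + s
    }
    dimnames(X) <- list(samples, sprintf("%s_f%03d", nm, seq_len(p)))
    layers[[nm]] <- omicsLayer(X, nm)
    truthModules[[nm]] <- stats::setNames(labels, colnames(X))
  }
  # traits
  ann <- data.frame(row.names = samples)
  traitCoef <- list()
  for (tn in names(config$traits)) {
    tr <- config$traits[[tn]]
    key <- paste(tr$factor[1], tr$factor[2], sep = ":")
    f <- if (null) stats::rnorm(n) else factors[[key]]
    if (tr$type == "quantitative") {
      beta <- if (is.null(tr$beta)) 1 else tr$beta
      sdn <- if (is.null(tr$noiseSd)) 0.5 else tr$noiseSd
      ann[[tn]] <- beta * f + stats::rnorm(n, sd = sdn)
      traitCoef[[tn]] <- list(factor = key, beta = beta, noiseSd = sdn)
    } else {
      qs <- if (is.null(tr$quantiles)) 0.5 else tr$quantiles
      thr <- stats::quantile(f, probs = qs)
      ann[[tn]] <- factor(LETTERS[findInterval(f, thr) + 1L])
      traitCoef[[tn]] <- list(factor = key, quantiles = qs)
    }
  }
  truth <- list(modules = truthModules, factors = factors,
                sharedFactors = if (null) list() else config$sharedFactors,
                traitCoef = traitCoef, null = null, seed = seed)
  list(layers = layers, annotation = annotationTable(ann), truth = truth)
}

#' Generate a synthetic multi-omics dataset
#'
#' @param config a [syntheticConfig()].
#' @param seed RNG seed (default: the config's seed); the output is
#'   bit-identical for identical seeds.
#' @return list with \code{layers} (named list of [OmicsLayer-class]),
#'   \code{annotation} ([AnnotationTable-class]) and \code{truth} (planted
#'   module maps, latent factors, shared-factor groups and trait
#'   coefficients).
#' @export
generateMultiOmics <- function(config, seed = config$seed) {
  .generate(config, seed, null = FALSE)
}

#' Generate matched null data
#'
#' Same marginal structure as [generateMultiOmics()] (same layer sizes,
#' module sizes and within-module correlations) but all module factors are
#' independent across layers and every trait is driven by an independent
#' latent variable, so any detected cross-layer or trait association is a
#' false positive. Used for FDR and type-I error checks.
#'
#' @inheritParams generateMultiOmics
#' @return as [generateMultiOmics()].
#' @export
makeNull <- function(config, seed = config$seed) {
  .generate(config, seed, null = TRUE)
}

#' Draw sequencing-like compositional counts from a latent layer
#'
#' Per sample, the latent values are softmax-transformed into multinomial
#' proportions and \code{depth} reads are drawn, emulating an OTU/ASV
#' count table whose centered log-ratio transform recovers the latent
#' values up to sampling noise.
#'
#' @param layer an [OmicsLayer-class] of latent (real-valued) profiles.
#' @param depth total count per sample.
#' @param seed RNG seed.
#' @return An [OmicsLayer-class] of counts with the compositional flag
#'   set; every row sums to \code{depth}.
#' @export
generateCompositionalCounts <- function(layer, depth, seed = 1) {
  stopifnot(depth > 0)
  set.seed(seed)
  v <- layerValues(layer)
  counts <- t(apply(v, 1, function(x) {
    p <- exp(x - max(x))
    stats::rmultinom(1, depth, p / sum(p))[, 1]
  }))
  dimnames(counts) <- dimnames(v)
  omicsLayer(counts, paste0(layerName(layer), "_counts"),
             compositional = TRUE)
}

#' Reference synthetic configuration for network recovery
#'
#' Three layers of 150 features over 60 samples, each with three planted
#' modules of 40 features (30 unassigned noise features) at within-module
#' correlation 0.7, plus one binary trait driven by the first layer's
#' first module. The default study conditions used throughout the
#' package's validation.
#'
#' @param seed RNG seed stored in the config.
#' @return a [syntheticConfig()].
#' @export
referenceSyntheticConfig <- function(seed = 1) {
  oneLayer <- list(nFeatures = 150, moduleSizes = c(40, 40, 40),
                   withinCor = 0.7)
  syntheticConfig(
    nSamples = 60,
    layers = list(mrna = oneLayer, mirna = oneLayer, prot = oneLayer),
    traits = list(
      subtype = list(type = "qualitative", factor = c("mrna", 1),
                     quantiles = 0.5),
      severity = list(type = "quantitative", factor = c("mrna", 1),
                      beta = 1, noiseSd = 0.5)),
    noiseSd = 1, seed = seed)
}

#' Shared-factor synthetic configuration for cross-layer integration
#'
#' Three layers of 60 features over 50 samples, two planted modules of 30
#' per layer; the first modules of the first two layers share a latent
#' factor at correlation 0.8, and a binary trait is driven by that
#' factor. The conditions used to validate multilayer edge retention.
#'
#' @param seed RNG seed stored in the config.
#' @return a [syntheticConfig()].
#' @export
sharedFactorSyntheticConfig <- function(seed = 1) {
  oneLayer <- list(nFeatures = 60, moduleSizes = c(30, 30), withinCor = 0.7)
  syntheticConfig(
    nSamples = 50,
    layers = list(mrna = oneLayer, mirna = oneLayer, prot = oneLayer),
    sharedFactors = list(list(members = list(c("mrna", 1), c("mirna", 1)),
                              cor = 0.8)),
    traits = list(
      group = list(type = "qualitative", factor = c("mrna", 1),
                   quantiles = 0.5)),
    noiseSd = 1, seed = seed)
}
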