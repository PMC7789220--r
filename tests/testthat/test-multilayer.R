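mkEigengenes <- function(m, ids = seq_len(ncol(m))) {
  colnames(m) <- paste0("ME", ids)
  if (is.null(rownames(m))) rownames(m) <- sprintf("S%03d", seq_len(nrow(m)))
  new("EigengeneMatrix", values = m, moduleIDs = as.integer(ids))
}

test_that("eigengene cross-correlation finds planted links and is layer-order symmetric", {
  set.seed(90)
  n <- 30
  shared <- unitSd(rnorm(n))
  ea <- mkEigengenes(cbind(shared, unitSd(rnorm(n)), unitSd(rnorm(n))))
  eb <- mkEigengenes(cbind(unitSd(rnorm(n)), shared))
  edges <- eigengeneCrossCorrelation(list(a = ea, b = eb))
  expect_identical(nrow(edges), 6L)
  hit <- edges[edges$module_a == 1 & edges$module_b == 2, ]
  expect_equal(hit$r, 1, tolerance = 1e-12)
  expect_identical(which.min(edges$q), which(edges$module_a == 1 & edges$module_b == 2))

  swapped <- eigengeneCrossCorrelation(list(b = eb, a = ea))
  key1 <- paste(edges$module_a, edges$module_b)
  key2 <- paste(swapped$module_b, swapped$module_a)
  expect_equal(edges$r[order(key1)], swapped$r[order(key2)], tolerance = 1e-12)
  expect_equal(edges$q[order(key1)], swapped$q[order(key2)], tolerance = 1e-12)

  expect_error(eigengeneCrossCorrelation(list(a = ea)), "2 layers")
  tiny <- mkEigengenes(matrix(unitSd(c(0, 1)), 2, 1))
  expect_error(eigengeneCrossCorrelation(list(a = tiny, b = tiny)), "3 shared")
})

test_that("null cross-layer data produce BH-controlled false discoveries", {
  anyRej <- numeric(30)
  for (s in 1:30) {
    nl <- makeNull(sharedFactorSyntheticConfig(seed = 400 + s))
    egs <- mapply(function(ly, tm) {
      part <- mkPartition(tm, featureIDs = names(tm))
      moduleEigengenes(ly, part)
    }, nl$layers, nl$truth$modules, SIMPLIFY = FALSE)
    e <- eigengeneCrossCorrelation(egs)
    anyRej[s] <- any(e$q <= 0.05, na.rm = TRUE)
  }
  expect_lte(mean(anyRej), 0.15)
})

test_that("the multilayer graph keeps significant edges and trait-anchored nodes", {
  set.seed(91)
  n <- 40
  shared <- unitSd(rnorm(n))
  trait <- shared + rnorm(n, sd = 0.4)
  ea <- mkEigengenes(cbind(withExactCor(shared, 0.9, rnorm(n)), unitSd(rnorm(n))))
  eb <- mkEigengenes(cbind(unitSd(rnorm(n)), withExactCor(shared, 0.9, rnorm(n))))
  edges <- eigengeneCrossCorrelation(list(a = ea, b = eb))
  ann <- annotationTable(data.frame(t = trait, row.names = rownames(eigengeneValues(ea))))
  trs <- list(a = moduleTraitCorrelation(ea, ann),
              b = moduleTraitCorrelation(eb, ann))
  g <- buildMultiLayerGraph(edges, trs, "t", alpha = 0.05)
  ge <- graphEdges(g)
  expect_true(all(ge$q <= 0.05))
  expect_true(any(ge$module_a == 1 & ge$module_b == 2))
  expect_true(all(ge$layer_a != ge$layer_b))
  # monotone filter: graph content is a subset of the candidates
  expect_true(all(paste(ge$layer_a, ge$module_a, ge$module_b) %in%
                    paste(edges$layer_a, edges$module_a, edges$module_b)))
  # alpha = 0 retains nothing
  g0 <- buildMultiLayerGraph(edges, trs, "t", alpha = 0)
  expect_identical(nrow(graphEdges(g0)), 0L)
  expect_error(buildMultiLayerGraph(edges, trs, "nope"), "absent")
})

test_that("hive layout orders modules radially by trait correlation", {
  nodes <- data.frame(layer = c("a", "a", "b", "b", "c"),
                      module = c(1L, 2L, 1L, 2L, 1L),
                      size = NA_integer_,
                      trait_r = c(0.9, -0.2, 0.1, 0.5, -0.7),
                      trait_q = 0.01, anchor_column = "t")
  edges <- data.frame(layer_a = "a", module_a = 1L, layer_b = "b",
                      module_b = 1L, r = 0.8, p = 1e-4, q = 1e-3)
  g <- new("MultiLayerGraph", nodes = nodes, edges = edges,
           anchorTrait = "t", alpha = 0.05)
  h <- hiveLayout(g)
  a <- h[h$layer == "a", ]
  expect_gt(a$radius[a$module == 1], a$radius[a$module == 2])  # 0.9 outermost
  expect_identical(length(unique(h$angle)), 3L)
  expect_true(all(h$radius > 0 & h$radius <= 1))
  # input order does not matter
  g2 <- new("MultiLayerGraph", nodes = nodes[c(5, 3, 1, 4, 2), ], edges = edges,
            anchorTrait = "t", alpha = 0.05)
  h2 <- hiveLayout(g2)
  key <- function(d) d[order(d$layer, d$module), c("angle", "radius")]
  expect_equal(key(h), key(h2), ignore_attr = TRUE)
  empty <- new("MultiLayerGraph", nodes = nodes[0, ], edges = edges[0, ],
               anchorTrait = "t", alpha = 0.05)
  expect_error(hiveLayout(empty), "no nodes")
})

test_that("bipartite feature networks follow the strict magnitude threshold", {
  # 3x2 toy with hand-computed correlations
  a <- cbind(c(1, 2, 3, 4), c(1, 3, 2, 4), c(4, 1, 3, 2))
  b <- cbind(c(2, 4, 6, 8), c(4, 3, 2, 1))
  colnames(a) <- paste0("a", 1:3); colnames(b) <- paste0("b", 1:2)
  la <- mkLayer(a, "A"); lb <- mkLayer(b, "B")
  pa <- mkPartition(rep(1, 3), featureIDs = colnames(a))
  pb <- mkPartition(rep(1, 2), featureIDs = colnames(b))
  res <- bipartiteFeatureNetwork(la, pa, 1, lb, pb, 1, method = "pearson",
                                 threshold = 0)
  expect_identical(nrow(res$edges), 6L)
  for (i in 1:3) for (j in 1:2)
    expect_equal(res$matrix[i, j], handPearson(a[, i], b[, j]),
                 tolerance = 1e-12)
  # count at the displayed default threshold matches the hand computation
  handN <- sum(abs(outer(1:3, 1:2,
                         Vectorize(function(i, j) handPearson(a[, i], b[, j])))) > 0.35)
  res35 <- bipartiteFeatureNetwork(la, pa, 1, lb, pb, 1, method = "pearson",
                                   threshold = 0.35)
  expect_identical(nrow(res35$edges), as.integer(handN))

  # edge count is nonincreasing in the threshold; >= 1 excludes everything
  set.seed(92)
  n <- 25
  f <- rnorm(n)
  xa <- mkLayer(outer(f, runif(6, 0.8, 1.2)) + matrix(rnorm(n * 6, sd = .5), n), "xa")
  xb <- mkLayer(outer(f, runif(5, 0.8, 1.2)) + matrix(rnorm(n * 5, sd = .5), n), "xb")
  qa <- mkPartition(rep(1, 6)); qb <- mkPartition(rep(1, 5))
  counts <- vapply(c(0, 0.35, 0.7, 1), function(th)
    nrow(bipartiteFeatureNetwork(xa, qa, 1, xb, qb, 1, threshold = th)$edges),
    integer(1))
  expect_true(all(diff(counts) <= 0))
  expect_identical(counts[4], 0L)
  # a strongly rank-correlated planted pair survives the 0.35 default
  res2 <- bipartiteFeatureNetwork(xa, qa, 1, xb, qb, 1)  # spearman, 0.35
  expect_gt(nrow(res2$edges), 0)
  expect_true(all(abs(res2$edges$r) > 0.35))
  expect_error(bipartiteFeatureNetwork(xa, qa, 2, xb, qb, 1), "empty module")
})

test_that("graph and table exports write well-formed files", {
  sim <- generateMultiOmics(sharedFactorSyntheticConfig(seed = 94))
  nets <- lapply(sim$layers[1:2], runNetworkAnalysis,
                 params = networkParams(minModuleSize = 10))
  egs <- lapply(nets, `[[`, "eigengenes")
  edges <- eigengeneCrossCorrelation(egs)
  trs <- lapply(nets, function(nt)
    moduleTraitCorrelation(nt$eigengenes, sim$annotation))
  g <- buildMultiLayerGraph(edges, trs, "group",
                            partitions = lapply(nets, `[[`, "partition"))
  d <- tempfile()
  exportMultilayerTables(d, g)
  expect_true(file.exists(file.path(d, "multilayer_edges.tsv")))
  expect_true(file.exists(file.path(d, "multilayer_graph.graphml")))
  lay <- read.delim(file.path(d, "hive_layout.tsv"))
  expect_true(all(c("layer", "module", "angle", "radius") %in% names(lay)))
  nt <- nets[[1]]
  exportNetworkTables(d, "mrna", nt$partition, nt$eigengenes,
                      kme = moduleMembership(sim$layers$mrna, nt$eigengenes),
                      traitReport = trs[[1]])
  mods <- read.delim(file.path(d, "mrna_modules.tsv"))
  expect_identical(nrow(mods), 60L)
  expect_true(all(c("feature", "module", "color", "kME") %in% names(mods)))
})
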