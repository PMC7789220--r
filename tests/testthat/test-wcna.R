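test_that("featureCorrelation behaves like a correlation and rejects degeneracy", {
  set.seed(1)
  base <- matrix(rnorm(40), 10, 4)
  m <- cbind(base, base[, 1], -base[, 2], exp(base[, 3]))
  colnames(m) <- paste0("f", 1:7)
  ly <- mkLayer(m)
  r <- featureCorrelation(ly)
  expect_equal(r["f1", "f5"], 1)
  expect_equal(r["f2", "f6"], -1)
  expect_equal(r, t(r))
  expect_equal(unname(diag(r)), rep(1, 7))
  rs <- featureCorrelation(ly, "spearman")
  expect_equal(rs["f3", "f7"], 1)  # rank-invariant under monotone transform
  expect_error(featureCorrelation(mkLayer(cbind(rep(1, 10), base))),
               "zero-variance")
})

test_that("adjacencyMatrix applies the soft threshold", {
  r <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  expect_equal(adjacencyMatrix(r, 6, "unsigned")[1, 2], 0.015625)
  expect_equal(adjacencyMatrix(r, 1, "unsigned")[1, 2], 0.5)
  rn <- matrix(c(1, -1, -1, 1), 2, 2)
  for (b in c(1, 3, 6.5)) expect_equal(adjacencyMatrix(rn, b, "signed")[1, 2], 0)
  expect_error(adjacencyMatrix(r, 0.5), ">= 1")

  # power monotonicity: larger beta never increases off-diagonal adjacency
  set.seed(2)
  rr <- featureCorrelation(randomLayer(15, 8, seed = 2))
  a4 <- adjacencyMatrix(rr, 4); a7 <- adjacencyMatrix(rr, 7)
  off <- upper.tri(rr)
  expect_true(all(a7[off] <= a4[off] + 1e-15))
})

test_that("scale-free fit is exact on a two-bin power-law degree vector and degenerate cases are flagged", {
  # two distinct degree values -> two nonempty bins -> perfect log-log line
  k <- rep(c(1, 8), c(40, 4))
  f <- momicnet:::.scaleFreeFit(k)
  expect_equal(unname(f["r2"]), 1)
  expect_lt(unname(f["slope"]), 0)
  # increasing frequency with degree is penalized by the sign convention
  expect_lt(momicnet:::.scaleFreeFit(rep(c(1, 8), c(4, 40)))["r2"], 0)
  # all-equal degrees: undefined fit
  expect_true(is.na(momicnet:::.scaleFreeFit(rep(3, 50))["r2"]))
})

test_that("pickSoftThreshold reports per-candidate fits and degenerates gracefully", {
  allEq <- matrix(0.999, 12, 12); diag(allEq) <- 1
  expect_warning(st <- pickSoftThreshold(allEq, candidates = c(2, 4, 6)),
                 "undefined|target")
  expect_true(is.na(st$power) || st$power %in% c(2, 4, 6))
  expect_identical(nrow(st$report), 3L)
  expect_true(all(st$report$meanK >= 0))
  expect_error(pickSoftThreshold(allEq, candidates = 6), "2 candidate")

  sim <- generateMultiOmics(referenceSyntheticConfig(seed = 11))
  st2 <- pickSoftThreshold(featureCorrelation(sim$layers$mrna))
  expect_gte(st2$report$r2[st2$report$power == st2$power], 0.8)
})

test_that("tomSimilarity matches the brute-force definition and analytic graphs", {
  for (s in 1:10) {
    a <- randomAdjacency(15, seed = s)
    expect_lt(max(abs(tomSimilarity(a) - tomOracle(a))), 1e-10)
  }
  # complete K5: all off-diagonal overlap is (n-2+1)/(n-1) = 1
  k5 <- matrix(1, 5, 5)
  t5 <- tomSimilarity(k5)
  expect_equal(unname(t5[upper.tri(t5)]), rep(1, 10))
  # star K1,4: leaf-leaf overlap 1/2
  star <- matrix(0, 5, 5); star[1, 2:5] <- 1; star[2:5, 1] <- 1; diag(star) <- 1
  ts <- tomSimilarity(star)
  expect_equal(ts[2, 3], 0.5)
  expect_equal(ts[1, 2], (0 + 1) / (min(4, 1) + 1 - 1))
  # empty graph
  e <- diag(5)
  te <- tomSimilarity(e)
  expect_equal(unname(te[upper.tri(te)]), rep(0, 10))
  bad <- randomAdjacency(5, 1); bad[1, 2] <- bad[1, 2] + 1e-6
  expect_error(tomSimilarity(bad), "symmetric")
})

test_that("detectModules recovers perfect blocks and leaves noise unassigned", {
  blockCorr <- matrix(0, 12, 12)
  blockCorr[1:6, 1:6] <- 1; blockCorr[7:12, 7:12] <- 1
  tom <- tomSimilarity(adjacencyMatrix(blockCorr, 6))
  part <- detectModules(tom, networkParams(minModuleSize = 3))
  expect_identical(sort(unique(part@labels)), c(1L, 2L))
  expect_length(unique(part@labels[1:6]), 1L)
  expect_length(unique(part@labels[7:12]), 1L)

  noise0 <- 0
  for (s in 1:5) {
    ly <- randomLayer(30, 40, seed = 100 + s)
    tomN <- tomSimilarity(adjacencyMatrix(featureCorrelation(ly), 6))
    pn <- detectModules(tomN, networkParams(minModuleSize = 10))
    noise0 <- noise0 + (mean(pn@labels == 0L) > 0.5)
  }
  expect_gte(noise0, 4)

  expect_warning(all0 <- detectModules(tom, networkParams(minModuleSize = 13)),
                 "unassigned")
  expect_true(all(all0@labels == 0L))
})

test_that("module eigengenes equal the dense-SVD first component with the documented orientation", {
  for (s in 1:5) {
    set.seed(s)
    n <- 20; p <- 8
    f <- rnorm(n)
    m <- outer(f, runif(p, 0.5, 1.5)) + matrix(rnorm(n * p, sd = 0.6), n)
    ly <- mkLayer(m)
    eg <- moduleEigengenes(ly, mkPartition(rep(1, p)))
    e <- eigengeneValues(eg)[, 1]
    z <- scale(m)
    u <- svd(z)$u[, 1]; u <- u / sd(u)
    expect_lt(min(max(abs(e - u)), max(abs(e + u))), 1e-8)
    expect_gte(cor(e, rowMeans(z)), 0)
    expect_equal(sd(e), 1, tolerance = 1e-10)
  }
  # duplicated features leave the eigengene unchanged
  set.seed(9)
  m <- matrix(rnorm(60), 12, 5); colnames(m) <- paste0("f", 1:5)
  e1 <- eigengeneValues(moduleEigengenes(mkLayer(m),
          mkPartition(rep(1, 5), featureIDs = colnames(m))))
  m2 <- cbind(m, m); colnames(m2) <- paste0("f", 1:10)
  e2 <- eigengeneValues(moduleEigengenes(mkLayer(m2),
          mkPartition(rep(1, 10), featureIDs = colnames(m2))))
  expect_lt(max(abs(e1 - e2)), 1e-10)
  # singleton module: the standardized feature itself
  es <- moduleEigengenes(mkLayer(m),
          mkPartition(c(1, 1, 1, 0, 2), featureIDs = colnames(m)))
  expect_equal(unname(eigengeneValues(es)[, "ME2"]), unname(scale(m[, 5])[, 1]),
               tolerance = 1e-12)
})

test_that("mergeCloseModules joins redundant modules and is monotone in the cut", {
  set.seed(4)
  n <- 30
  f <- rnorm(n)
  m <- cbind(outer(f, runif(6, 0.8, 1.2)) + matrix(rnorm(n * 6, sd = 0.3), n),
             outer(f, runif(6, 0.8, 1.2)) + matrix(rnorm(n * 6, sd = 0.3), n),
             outer(rnorm(n), runif(6, 0.8, 1.2)) + matrix(rnorm(n * 6, sd = 0.3), n))
  ly <- mkLayer(m)
  part <- mkPartition(rep(1:3, each = 6))
  same <- mergeCloseModules(ly, part, mergeCut = 0)
  expect_identical(length(unique(same$partition@labels)), 3L)
  merged <- mergeCloseModules(ly, part, mergeCut = 0.25)
  expect_identical(length(unique(merged$partition@labels)), 2L)
  # modules 1 and 2 (same factor) collapsed together
  lab <- merged$partition@labels
  expect_length(unique(lab[1:12]), 1L)
  nMod <- vapply(c(0, 0.25, 0.6), function(mc)
    length(unique(mergeCloseModules(ly, part, mc)$partition@labels)),
    integer(1))
  expect_true(all(diff(nMod) <= 0))
})

test_that("module-trait correlations carry exact t-based p-values and joint BH control", {
  n <- 12
  set.seed(5)
  y <- rnorm(n)
  e1 <- unitSd(y)                               # r = 1 with the trait
  e2 <- withExactCor(y, 0, rnorm(n))            # r = 0
  em <- new("EigengeneMatrix",
            values = matrix(c(e1, e2), n, 2,
                            dimnames = list(sprintf("S%03d", 1:n), c("ME1", "ME2"))),
            moduleIDs = c(1L, 2L))
  ann <- annotationTable(data.frame(y = y, const = rep(1.5, n),
                                    row.names = sprintf("S%03d", 1:n)))
  rep <- moduleTraitCorrelation(em, ann)
  r1 <- rep[rep$module == 1 & rep$trait == "y", ]
  expect_equal(r1$r, 1, tolerance = 1e-12)
  expect_lt(r1$p, 1e-12)
  r2 <- rep[rep$module == 2 & rep$trait == "y", ]
  expect_equal(r2$r, 0, tolerance = 1e-12)
  expect_equal(r2$p, 1)
  expect_true(all(is.na(rep$r[rep$trait == "const"])))
  expect_true(all(rep$q >= rep$p - 1e-12, na.rm = TRUE))

  # qualitative traits expand to one indicator per level
  ann2 <- annotationTable(data.frame(g = rep(c("a", "b", "c"), each = 4),
                                     row.names = sprintf("S%03d", 1:n)))
  rep2 <- moduleTraitCorrelation(em, ann2)
  expect_setequal(unique(rep2$column), c("g.a", "g.b", "g.c"))
})

test_that("sample contributions pair the eigengene with the trait in sample order", {
  sim <- generateMultiOmics(referenceSyntheticConfig(seed = 21))
  net <- runNetworkAnalysis(sim$layers$mrna, networkParams(minModuleSize = 20))
  tr <- moduleTraitCorrelation(net$eigengenes, sim$annotation)
  # module most associated with the binary subtype trait
  sub <- tr[tr$trait == "subtype", ]
  m <- sub$module[which.max(abs(sub$r))]
  sc <- sampleContributions(net$eigengenes, m, sim$annotation, "subtype")
  expect_identical(nrow(sc), 60L)
  expect_identical(sc$sample, sampleIDs(sim$layers$mrna))
  gm <- tapply(sc$contribution, sc$subtype, mean)
  expect_lt(prod(gm), 0)                 # the two groups pull opposite ways
  expect_lt(abs(sum(sc$contribution)), 1e-8)
  expect_error(sampleContributions(net$eigengenes, 99, sim$annotation, "subtype"),
               "unknown module")
})

test_that("module membership (kME) separates own-module features in planted data", {
  sim <- generateMultiOmics(referenceSyntheticConfig(seed = 22))
  ly <- sim$layers$prot
  truth <- sim$truth$modules$prot
  part <- mkPartition(truth, featureIDs = names(truth))
  eg <- moduleEigengenes(ly, part)
  kme <- moduleMembership(ly, eg)
  expect_true(all(kme >= -1 - 1e-12 & kme <= 1 + 1e-12))
  for (m in 1:3) {
    own <- mean(kme[truth == m, paste0("ME", m)])
    other <- mean(kme[truth == m, paste0("ME", setdiff(1:3, m))])
    expect_gt(own, other + 0.3)
  }
  # a feature duplicating the eigengene has kME 1
  e <- eigengeneValues(eg)[, 1]
  ly2 <- mkLayer(cbind(layerValues(ly), dup = e))
  kme2 <- moduleMembership(ly2, eg)
  expect_equal(kme2["dup", "ME1"], 1, tolerance = 1e-12)
})
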