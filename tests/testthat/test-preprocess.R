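test_that("readLayer reads both orientations to the same object and rejects bad input", {
  m <- matrix(c(1.5, 2, 3, 4, 5, 6), 3, 2,
              dimnames = list(c("A", "B", "C"), c("f1", "f2")))
  fr <- tempfile(fileext = ".tsv")
  write.table(data.frame(sample = rownames(m), m), fr, sep = "\t",
              quote = FALSE, row.names = FALSE)
  lr <- readLayer(fr, "samples_in_rows", name = "x")
  expect_equal(unname(layerValues(lr)), unname(m))
  expect_identical(sampleIDs(lr), c("A", "B", "C"))

  fc <- tempfile(fileext = ".tsv")
  write.table(data.frame(feature = colnames(m), t(m)), fc, sep = "\t",
              quote = FALSE, row.names = FALSE)
  lc <- readLayer(fc, "samples_in_columns", name = "x")
  expect_equal(layerValues(lc), layerValues(lr))

  fdup <- tempfile(fileext = ".tsv")
  writeLines(c("id\tf1\tf2", "A\t1\t2", "A\t3\t4"), fdup)
  expect_error(readLayer(fdup, "samples_in_rows"), "duplicated sample")

  fbad <- tempfile(fileext = ".tsv")
  writeLines(c("id\tf1\tf2", "A\t1\tx", "B\t3\t4"), fbad)
  expect_error(readLayer(fbad, "samples_in_rows"), "non-numeric")
})

test_that("alignSamples intersects sample sets in a canonical order", {
  la <- mkLayer(matrix(1:6, 3, 2, dimnames = list(c("A", "B", "C"), NULL)), "a")
  lb <- mkLayer(matrix(1:6, 3, 2, dimnames = list(c("B", "C", "D"), NULL)), "b")
  ann <- annotationTable(data.frame(g = c("x", "y", "x", "y"),
                                    row.names = c("A", "B", "C", "D")))
  al <- alignSamples(list(la, lb), ann)
  expect_identical(sampleIDs(al$layers$a), c("B", "C"))
  expect_identical(sampleIDs(al$layers$b), c("B", "C"))
  expect_identical(sampleIDs(al$annotation), c("B", "C"))
  expect_identical(al$dropped$a, "A")
  expect_identical(al$dropped$b, "D")

  same <- alignSamples(list(la))
  expect_length(same$dropped$a, 0)

  ld <- mkLayer(matrix(1:4, 2, 2, dimnames = list(c("X", "Y"), NULL)), "d")
  expect_error(alignSamples(list(la, ld)), "no samples")
})

test_that("prevalenceFilter keeps features at or above the threshold and is monotone", {
  # prevalences 1.0, 0.8, 0.5, 0.2, 0.0 over 10 samples
  m <- cbind(rep(1, 10),
             c(rep(1, 8), 0, 0),
             c(rep(1, 5), rep(0, 5)),
             c(1, 1, rep(0, 8)),
             rep(0, 10))
  ly <- mkLayer(m)
  expect_identical(ncol(prevalenceFilter(ly, 0.5)), 3L)
  expect_identical(ncol(prevalenceFilter(ly, 0)), 5L)
  kept <- featureIDs(prevalenceFilter(ly, 0.3))
  expect_identical(kept, featureIDs(ly)[1:3])
  sparse <- mkLayer(cbind(c(1, 1, 0, 0), c(0, 1, 0, 0)))
  expect_error(prevalenceFilter(sparse, 0.9), "lower the threshold")

  # idempotence and monotonicity on random sparse data
  set.seed(42)
  rl <- mkLayer(matrix(rbinom(200, 1, 0.4) * runif(200), 20, 10))
  prev <- 0L
  for (thr in c(0, 0.2, 0.4, 0.6)) {
    f1 <- prevalenceFilter(rl, thr)
    expect_identical(featureIDs(prevalenceFilter(f1, thr)), featureIDs(f1))
    if (thr > 0) expect_lte(ncol(f1), prevOld)
    prevOld <- ncol(f1)
  }
})

test_that("clrTransform centers log parts so rows sum to zero", {
  ly <- mkLayer(rbind(c(1, 10, 100), c(1, 1, 1)))
  out <- clrTransform(ly, pseudocount = 0)
  expect_equal(unname(layerValues(out)[1, ]), c(-log(10), 0, log(10)),
               tolerance = 1e-12)
  expect_equal(unname(layerValues(out)[2, ]), c(0, 0, 0))
  expect_false(isCompositional(out))

  set.seed(7)
  counts <- mkLayer(matrix(rpois(300, 3), 15, 20), compositional = TRUE)
  cl <- clrTransform(counts)   # default pseudocount 1 for integer counts
  expect_lt(max(abs(rowSums(layerValues(cl)))), 1e-10)
  expect_true(all(is.finite(layerValues(cl))))

  neg <- mkLayer(matrix(c(-1, 2, 3, 4), 2, 2))
  expect_error(clrTransform(neg), "nonnegative")
  zero <- mkLayer(matrix(c(0, 2, 3, 4), 2, 2))
  expect_error(clrTransform(zero, pseudocount = 0), "pseudocount")
})

test_that("transformLayer dispatches the standard normalizations", {
  set.seed(1)
  ly <- mkLayer(matrix(rpois(60, 5), 6, 10))
  expect_equal(unname(rowSums(layerValues(transformLayer(ly, "tss")))),
               rep(1, 6))
  expect_equal(layerValues(transformLayer(ly, "log2")),
               log2(layerValues(ly) + 1))
  st <- transformLayer(ly, "standardize")
  expect_equal(unname(apply(layerValues(st), 2, sd)), rep(1, 10))
  con <- mkLayer(cbind(rep(2, 6), rnorm(6)))
  expect_error(transformLayer(con, "standardize"), "f001")
})

test_that("outlier detection flags a planted aberrant sample and rarely fires on homogeneous data", {
  hits <- 0
  for (s in 1:10) {
    set.seed(s)
    mu <- rnorm(60, sd = 2)
    X <- matrix(rep(mu, each = 30), 30) + matrix(rnorm(30 * 60), 30)
    X[7, ] <- rnorm(60, sd = sqrt(sum(mu^2) / 60 + 1))
    o <- detectOutliers(mkLayer(X))
    hits <- hits + (o$flagged[7] && sum(o$flagged) == 1)
  }
  expect_gte(hits, 9)

  flagFrac <- vapply(1:20, function(s) {
    set.seed(s)
    mean(detectOutliers(mkLayer(matrix(rnorm(50 * 80), 50, 80)))$flagged)
  }, numeric(1))
  expect_lt(mean(flagFrac), 0.02)

  # deterministic and guarded
  ly <- randomLayer(10, 5, seed = 3)
  expect_identical(detectOutliers(ly), detectOutliers(ly))
  expect_error(detectOutliers(randomLayer(2, 5)), "3 samples")
})

test_that("relativeAbundance aggregates lineages onto the simplex", {
  counts <- mkLayer(rbind(c(3, 1, 0, 2), c(0, 0, 0, 0)),
                    name = "otus")
  tax <- data.frame(Phylum = c("P", "Q", "P", NA),
                    Genus = c("g1", "g2", "g3", "g4"),
                    row.names = featureIDs(counts))
  ra <- relativeAbundance(counts, tax, "Phylum")
  expect_equal(ra["S001", "P"], 0.5)
  expect_equal(ra["S001", "Q"], 1 / 6)
  expect_equal(ra["S001", "Unclassified"], 2 / 6)
  expect_equal(unname(rowSums(ra)), c(1, 0))  # all-zero sample stays zero
  expect_error(relativeAbundance(counts, tax, "Species"), "unknown rank")

  # hand fraction: counts (3,1) on P,Q
  two <- mkLayer(matrix(c(3, 1), 1, 2))
  tax2 <- data.frame(Phylum = c("P", "Q"), row.names = featureIDs(two))
  ra2 <- relativeAbundance(two, tax2, "Phylum")
  expect_equal(unname(ra2[1, c("P", "Q")]), c(0.75, 0.25))
})
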